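## Principal component analysis for mixed quantitative/categorical data.
##
## Quantitative columns are centred and scaled to unit (population) variance;
## each categorical variable is expanded into level indicators, centred by
## the level frequency and scaled by 1/sqrt(frequency). With uniform row
## weights 1/n the total variance of the combined matrix is
## P = p_quant + (q - p_qual), where q is the total number of levels, and
## the spectrum reduces to correlation-matrix PCA when all columns are
## quantitative and to multiple correspondence analysis (times p_qual) when
## all are categorical.

#' Karlis-Saporta-Spinaki component-retention threshold
#'
#' Retain components whose eigenvalue exceeds `1 + 2*sqrt((P-1)/(n-1))`,
#' a parametric-bootstrap-motivated strengthening of the mean-eigenvalue
#' (Kaiser) rule.
#'
#' @param n sample size (rows)
#' @param P effective number of variables (quantitative columns plus levels
#'   minus categorical variables)
#' @return the eigenvalue threshold
#' @export
kss_threshold <- function(n, P) {
  if (!is_count(n) || n < 2) stop2("n must be an integer >= 2")
  if (!is.numeric(P) || P < 1) stop2("P must be >= 1")
  1 + 2 * sqrt((P - 1) / (n - 1))
}

## Build the weighted analysis matrix from a mixed data.frame.
## Returns the matrix plus every statistic needed to project new rows.
standardize_mixed <- function(data, quanti, quali) {
  n <- nrow(data)
  blocks <- list(); colinfo <- list()
  means <- sds <- numeric(0)
  for (v in quanti) {
    x <- as.numeric(data[[v]])
    if (anyNA(x)) stop2("missing values in quantitative column ", v)
    m <- mean(x); s <- sqrt(mean((x - m)^2))
    if (s < 1e-12) stop2("zero-variance quantitative column: ", v)
    means[v] <- m; sds[v] <- s
    blocks[[v]] <- matrix((x - m) / s, ncol = 1,
                          dimnames = list(NULL, v))
  }
  freqs <- list(); levels_ <- list()
  for (v in quali) {
    f <- factor(data[[v]])
    if (anyNA(f)) stop2("missing values in categorical column ", v)
    tab <- table(f)
    if (any(tab == 0))
      stop2("unobserved level in column ", v, ": ",
            paste(names(tab)[tab == 0], collapse = ", "))
    p <- as.numeric(tab) / n
    G <- outer(as.integer(f), seq_along(levels(f)), function(i, l) (i == l) + 0)
    Z <- sweep(sweep(G, 2, p, "-"), 2, sqrt(p), "/")
    colnames(Z) <- paste(v, levels(f), sep = ".")
    blocks[[v]] <- Z
    freqs[[v]] <- p
    levels_[[v]] <- levels(f)
  }
  W <- do.call(cbind, blocks)
  list(W = W, quanti = quanti, quali = quali, means = means, sds = sds,
       freqs = freqs, levels = levels_,
       P = length(quanti) + sum(lengths(levels_)) - length(quali))
}

#' Fit a mixed-data principal component analysis
#'
#' Columns of class numeric are treated as quantitative; factor, character
#' and logical columns (and any listed in `quali`) as categorical. Binary
#' 0/1 indicator columns should be passed as categorical, the convention
#' used throughout this package. The eigendecomposition uses uniform row
#' weights 1/n; loading signs are fixed by making the largest-magnitude
#' entry of each loading vector positive, so results are reproducible
#' across platforms. The number of retained dimensions `d` counts the
#' eigenvalues above the Karlis-Saporta-Spinaki threshold.
#'
#' @param data data.frame of the mixed variables (no id columns)
#' @param quali optional character vector of columns to force categorical
#' @return object of class `pcamix`: eigenvalues, loadings, scores of the
#'   training rows, scaling constants, `P`, the KSS threshold and `d`
#' @export
pcamix_fit <- function(data, quali = NULL) {
  data <- as.data.frame(data)
  is_cat <- vapply(data, function(x)
    is.factor(x) || is.character(x) || is.logical(x), logical(1))
  quali <- union(names(data)[is_cat], quali %||% character(0))
  quanti <- setdiff(names(data), quali)
  for (v in quali) data[[v]] <- factor(data[[v]])
  n <- nrow(data)
  std <- standardize_mixed(data, quanti, quali)
  if (n <= std$P)
    warning("fewer rows than effective variables; spectrum is rank-deficient",
            call. = FALSE)
  sv <- svd(std$W / sqrt(n))
  eig <- sv$d^2
  r <- sum(eig > max(eig[1], 1) * 1e-12)
  eig <- eig[seq_len(r)]
  V <- sv$v[, seq_len(r), drop = FALSE]
  ## deterministic sign: largest-|loading| entry positive
  for (j in seq_len(r)) {
    peak <- which.max(abs(V[, j]))
    if (V[peak, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(std$W)
  scores <- std$W %*% V
  thr <- kss_threshold(n, std$P)
  structure(list(
    eigenvalues = eig, loadings = V, scores = scores, n = n, P = std$P,
    quanti = quanti, quali = quali, means = std$means, sds = std$sds,
    freqs = std$freqs, levels = std$levels,
    kss = thr, d = sum(eig > thr)
  ), class = "pcamix")
}

#' @export
print.pcamix <- function(x, ...) {
  cat("Mixed-data PCA:", x$n, "rows,", length(x$quanti), "quantitative +",
      length(x$quali), "categorical variables (P =", x$P, ")\n")
  cat("Retained", x$d, "of", length(x$eigenvalues),
      "components (KSS threshold", signif(x$kss, 4), ")\n")
  cat("Leading eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Project rows onto fitted components
#'
#' Uses the stored centring/scaling constants and level frequencies, so
#' out-of-sample rows are placed in the training component space. Rows from
#' the training data reproduce the stored scores.
#'
#' @param object a fitted [pcamix_fit()] model
#' @param newdata data.frame sharing the training schema
#' @param ncomp number of components to return (default the KSS-retained
#'   `d`, minimum 1)
#' @param ... unused
#' @return score matrix (rows x ncomp)
#' @export
predict.pcamix <- function(object, newdata, ncomp = NULL, ...) {
  ncomp <- ncomp %||% max(object$d, 1L)
  ncomp <- min(ncomp, ncol(object$loadings))
  newdata <- as.data.frame(newdata)
  blocks <- list()
  for (v in object$quanti) {
    x <- as.numeric(newdata[[v]])
    blocks[[v]] <- matrix((x - object$means[v]) / object$sds[v], ncol = 1)
  }
  for (v in object$quali) {
    lev <- object$levels[[v]]
    f <- factor(newdata[[v]], levels = lev)
    if (anyNA(f))
      stop2("unseen level in column ", v, ": ",
            paste(setdiff(unique(as.character(newdata[[v]])), lev),
                  collapse = ", "))
    p <- object$freqs[[v]]
    G <- outer(as.integer(f), seq_along(lev), function(i, l) (i == l) + 0)
    blocks[[v]] <- sweep(sweep(G, 2, p, "-"), 2, sqrt(p), "/")
  }
  W <- do.call(cbind, blocks)
  W %*% object$loadings[, seq_len(ncomp), drop = FALSE]
}

#' Serialize / restore a fitted PCAmix model as JSON
#' @param object a `pcamix` model
#' @param path file path
#' @export
write_pcamix <- function(object, path) {
  obj <- unclass(object)
  obj$means <- as.list(obj$means)       # keep names through JSON
  obj$sds <- as.list(obj$sds)
  obj$loadings <- list(values = as.vector(obj$loadings),
                       dim = dim(obj$loadings),
                       rownames = rownames(obj$loadings))
  obj$scores <- NULL                    # recomputable; keep the file small
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pcamix
#' @export
read_pcamix <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- matrix(obj$loadings$values, obj$loadings$dim[1], obj$loadings$dim[2])
  rownames(L) <- obj$loadings$rownames
  obj$loadings <- L
  obj$means <- unlist(obj$means); obj$sds <- unlist(obj$sds)
  structure(obj, class = "pcamix")
}
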