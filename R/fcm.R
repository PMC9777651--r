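## Fuzzy c-means clustering (Bezdek) with k-means++ seeding and
## multi-restart best-objective selection.

#' Fit fuzzy c-means
#'
#' Minimizes `J = sum_i sum_k u_ik^m ||x_i - c_k||^2` with the standard
#' alternating updates: memberships `u_ik` proportional to
#' `d_ik^(-1/(m-1))` and centroids as `u^m`-weighted means. A point
#' coincident with a centroid receives membership 1 for that cluster (the
#' lowest such index when several coincide). Each restart seeds centroids
#' k-means++-style; the restart with the lowest final objective wins. Runs
#' are fully reproducible given `seed`.
#'
#' @param x numeric matrix of observations (rows) in score space
#' @param K number of clusters (1 <= K < n)
#' @param m fuzzifier, > 1 (default 2)
#' @param tol convergence threshold on `max |delta U|` (default 1e-6)
#' @param max_iter iteration cap per restart (default 300)
#' @param n_restarts independent restarts (default 5)
#' @param seed integer seed
#' @return object of class `fcm`: membership matrix `U` (rows sum to 1),
#'   `centers`, objective `J` and its per-iteration trace, `iter`, inputs
#' @export
fcm_fit <- function(x, K, m = 2, tol = 1e-6, max_iter = 300,
                    n_restarts = 5, seed = 1L) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop2("non-finite values in x")
  n <- nrow(x)
  if (!is_count(K)) stop2("K must be a positive integer")
  if (K > n) stop2("K (", K, ") exceeds the number of observations (", n, ")")
  if (K == n) stop2("K must be smaller than the number of observations")
  if (m <= 1) stop2("fuzzifier m must be > 1")
  if (K == 1L) {
    center <- matrix(colMeans(x), 1, ncol(x))
    d2 <- sq_dist(x, center)
    return(structure(list(U = matrix(1, n, 1), centers = center, m = m,
                          J = sum(d2), J_trace = sum(d2), iter = 0L,
                          K = 1L, seed = seed), class = "fcm"))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(substream_seed(seed, r))
    fit <- fcm_once(x, K, m, tol, max_iter)
    if (is.null(best) || fit$J < best$J) best <- fit
  }
  best$K <- as.integer(K)
  best$seed <- seed
  class(best) <- "fcm"
  best
}

fcm_once <- function(x, K, m, tol, max_iter) {
  centers <- x[kmeanspp_indices(x, K), , drop = FALSE]
  ## nudge seeds off the data points so the zero-distance singleton rule
  ## does not pin the seed observations at high fuzzifier values
  scale <- pmax(apply(x, 2, stats::sd), 1e-8)
  centers <- centers + matrix(stats::rnorm(length(centers), 0, 1e-4), K) *
    matrix(scale, K, ncol(x), byrow = TRUE)
  U <- memberships_from_centers(x, centers, m)
  trace <- numeric(0)
  J_prev <- Inf
  for (it in seq_len(max_iter)) {
    w <- U^m
    centers <- crossprod(w, x) / colSums(w)
    d2 <- sq_dist(x, centers)
    J <- sum(w * d2)
    if (J > J_prev + 1e-8 * max(1, abs(J_prev)))
      stop2("fuzzy c-means objective increased; numerical failure")
    trace <- c(trace, J)
    U_new <- memberships_from_d2(d2, m)
    delta <- max(abs(U_new - U))
    U <- U_new
    J_prev <- J
    if (delta < tol) break
  }
  list(U = U, centers = centers, m = m, J = J_prev, J_trace = trace,
       iter = it)
}

sq_dist <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * x %*% t(centers)
  pmax(d2, 0)
}

memberships_from_d2 <- function(d2, m) {
  n <- nrow(d2); K <- ncol(d2)
  U <- matrix(0, n, K)
  zero <- d2 < 1e-300
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    idx <- apply(zero[hit, , drop = FALSE], 1, which.max)  # lowest index
    U[cbind(which(hit), idx)] <- 1
  }
  ok <- !hit
  if (any(ok)) {
    g <- d2[ok, , drop = FALSE]^(-1 / (m - 1))
    U[ok, ] <- g / rowSums(g)
  }
  U
}

memberships_from_centers <- function(x, centers, m) {
  memberships_from_d2(sq_dist(x, centers), m)
}

kmeanspp_indices <- function(x, K) {
  n <- nrow(x)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1)
  d2 <- sq_dist(x, x[idx[1], , drop = FALSE])[, 1]
  for (k in 2:K) {
    if (all(d2 <= 0)) idx[k] <- sample.int(n, 1)
    else idx[k] <- sample.int(n, 1, prob = d2 / sum(d2))
    d2 <- pmin(d2, sq_dist(x, x[idx[k], , drop = FALSE])[, 1])
  }
  idx
}

#' Crisp cluster labels from a membership matrix
#'
#' Argmax per row; ties are broken toward the lowest cluster index.
#'
#' @param U row-stochastic membership matrix (or an `fcm` fit)
#' @return integer label vector
#' @export
crisp_assign <- function(U) {
  if (inherits(U, "fcm")) U <- U$U
  max.col(as.matrix(U), ties.method = "first")
}

#' @export
print.fcm <- function(x, ...) {
  cat("Fuzzy c-means: K =", x$K, ", m =", x$m, ", n =", nrow(x$U),
      "\nObjective J =", signif(x$J, 6), "after", x$iter, "iterations\n")
  invisible(x)
}
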