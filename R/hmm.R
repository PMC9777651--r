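## Hidden Markov model over yearly component-score sequences.
##
## K live states (one per cluster) emit diagonal-Gaussian score vectors;
## two extra absorbing states -- death (K+1) and dropout (K+2) -- are
## *observed* when a person exits, so their emission is degenerate (prob. 1
## in their own state) and only the incoming transition rates are
## estimated.  A censored sequence's likelihood is the live-part likelihood
## times the exit transition probability; survivors at the horizon
## contribute the live part only.

EXIT_LEVELS <- c("none", "death", "dropout")

#' Bundle score sequences for HMM estimation
#'
#' Persons are observed over contiguous waves `1..len`; a person who died or
#' dropped out carries an exit token one wave after their last score.
#'
#' @param scores numeric matrix of component scores, one row per active
#'   person-wave
#' @param person_id,wave vectors aligned with `scores` rows
#' @param exit named vector/factor per person: `"none"`, `"death"` or
#'   `"dropout"` (names = person ids); missing persons default to `"none"`
#' @return object of class `hmm_sequences`
#' @export
hmm_sequences <- function(scores, person_id, wave, exit = NULL) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(person_id), length(wave) == length(person_id))
  ids <- unique(person_id)
  n <- length(ids)
  d <- ncol(scores)
  len <- integer(n)
  ord <- order(match(person_id, ids), wave)
  person_id <- person_id[ord]; wave <- wave[ord]
  scores <- scores[ord, , drop = FALSE]
  len <- as.integer(table(factor(person_id, levels = ids)))
  Tmax <- max(len)
  Y <- array(NA_real_, c(n, Tmax, d))
  row <- 0L
  for (i in seq_len(n)) {
    w <- wave[row + seq_len(len[i])]
    if (!identical(as.integer(w), seq_len(len[i])))
      stop2("person ", ids[i], " has non-contiguous waves (",
            paste(w, collapse = ","), ")")
    Y[i, seq_len(len[i]), ] <- scores[row + seq_len(len[i]), ]
    row <- row + len[i]
  }
  ex <- integer(n)
  if (!is.null(exit)) {
    exit <- stats::setNames(as.character(exit), names(exit))
    pos <- match(as.character(ids), names(exit))
    lab <- ifelse(is.na(pos), "none", exit[pos])
    if (!all(lab %in% EXIT_LEVELS)) stop2("exit labels must be none/death/dropout")
    ex <- match(lab, EXIT_LEVELS) - 1L
  }
  structure(list(Y = Y, len = len, exit = ex, ids = ids, d = d, n = n,
                 Tmax = Tmax), class = "hmm_sequences")
}

#' Construct sequences from a panel and its score matrix
#'
#' @param panel the raw cohort panel (used for exit statuses)
#' @param features the feature table the scores were computed from
#' @param scores score matrix aligned with `features` rows
#' @return an [hmm_sequences()] object
#' @export
panel_sequences <- function(panel, features, scores) {
  exits <- panel[panel$status != "active", c("person_id", "status")]
  exit <- stats::setNames(ifelse(exits$status == "died", "death", "dropout"),
                          exits$person_id)
  hmm_sequences(scores, features$person_id, features$wave, exit)
}

#' HMM parameter container
#'
#' @param pi initial distribution over the K live states
#' @param A (K+2)x(K+2) row-stochastic transition matrix, last two rows
#'   absorbing (death, dropout)
#' @param mu K x d matrix of state emission means
#' @param sigma2 K x d matrix of emission variances
#' @param variance_floor lower bound applied to `sigma2`
#' @return object of class `hmm_params`
#' @export
hmm_params <- function(pi, A, mu, sigma2, variance_floor = 1e-4) {
  K <- length(pi)
  if (!is.matrix(A) || any(dim(A) != K + 2)) stop2("A must be (K+2)x(K+2)")
  if (any(abs(rowSums(A) - 1) > 1e-10)) stop2("A rows must sum to 1")
  for (s in (K + 1):(K + 2))
    if (A[s, s] != 1) stop2("row ", s, " must be absorbing")
  if (abs(sum(pi) - 1) > 1e-10 || any(pi < 0))
    stop2("pi must be a probability vector over live states")
  sigma2 <- pmax(sigma2, variance_floor)
  structure(list(K = K, d = ncol(mu), pi = pi, A = A, mu = mu,
                 sigma2 = sigma2, variance_floor = variance_floor),
            class = "hmm_params")
}

#' Initialize HMM parameters from a fuzzy clustering
#'
#' Emission means are the fuzzy centroids; variances are membership-weighted
#' within-cluster variances (floored); the initial distribution is the mean
#' wave-1 membership; the live transition block row-normalizes counts of
#' consecutive-wave crisp labels, and the death/dropout columns take the
#' empirical exit frequency from each crisp state.
#'
#' @param clustering an [fcm_fit()] result on the pooled person-wave scores
#' @param sequences an [hmm_sequences()] object (same row order as the
#'   clustering input)
#' @param variance_floor minimum emission variance (default 1e-4)
#' @return an [hmm_params()] object
#' @export
init_from_clusters <- function(clustering, sequences, variance_floor = 1e-4) {
  K <- clustering$K
  U <- clustering$U
  X <- flatten_scores(sequences)
  d <- sequences$d
  mu <- clustering$centers
  sigma2 <- matrix(0, K, d)
  for (k in seq_len(K)) {
    w <- U[, k] / sum(U[, k])
    sigma2[k, ] <- colSums(w * sweep(X, 2, mu[k, ])^2)
  }
  sigma2 <- pmax(sigma2, variance_floor)
  lab <- crisp_assign(U)
  ## empty crisp cluster: re-seed that state from the global distribution
  empty <- setdiff(seq_len(K), unique(lab))
  if (length(empty)) {
    message("re-seeding empty state(s) from the global distribution: ",
            paste(empty, collapse = ", "))
    for (k in empty) {
      mu[k, ] <- colMeans(X)
      sigma2[k, ] <- pmax(apply(X, 2, stats::var), variance_floor)
    }
  }
  ## map flat rows back to (person, wave)
  idx <- flat_index(sequences)
  lab_mat <- matrix(NA_integer_, sequences$n, sequences$Tmax)
  lab_mat[idx] <- lab
  ## wave-1 rows are the first row of each person block
  starts <- cumsum(c(1L, utils::head(sequences$len, -1L)))
  pi <- colMeans(U[starts, , drop = FALSE])
  pi <- pi / sum(pi)
  A <- matrix(0, K + 2, K + 2)
  for (i in seq_len(sequences$n)) {
    L <- sequences$len[i]
    if (L >= 2) for (t in seq_len(L - 1))
      A[lab_mat[i, t], lab_mat[i, t + 1]] <- A[lab_mat[i, t], lab_mat[i, t + 1]] + 1
    if (sequences$exit[i] > 0)
      A[lab_mat[i, L], K + sequences$exit[i]] <- A[lab_mat[i, L], K + sequences$exit[i]] + 1
  }
  for (k in seq_len(K)) {
    s <- sum(A[k, ])
    A[k, ] <- if (s > 0) A[k, ] / s else c(rep(1 / K, K), 0, 0)
  }
  A[K + 1, K + 1] <- 1
  A[K + 2, K + 2] <- 1
  hmm_params(pi, A, mu, sigma2, variance_floor)
}

flat_index <- function(seqs) {
  cbind(rep(seq_len(seqs$n), seqs$len),
        unlist(lapply(seqs$len, seq_len)))
}

flatten_scores <- function(seqs) {
  idx <- flat_index(seqs)
  X <- matrix(0, nrow(idx), seqs$d)
  for (j in seq_len(seqs$d))
    X[, j] <- matrix(seqs$Y[, , j], seqs$n, seqs$Tmax)[idx]
  X
}

## log emission densities: n x Tmax x K (NA beyond each person's length)
log_emissions <- function(seqs, params) {
  n <- seqs$n; Tm <- seqs$Tmax; K <- params$K; d <- seqs$d
  logB <- array(NA_real_, c(n, Tm, K))
  const <- -0.5 * (d * log(2 * pi) + rowSums(log(params$sigma2)))
  for (t in seq_len(Tm)) {
    act <- seqs$len >= t
    Yt <- matrix(seqs$Y[, t, ], n, d)[act, , drop = FALSE]
    for (k in seq_len(K)) {
      z <- sweep(Yt, 2, params$mu[k, ])
      q <- rowSums(sweep(z^2, 2, params$sigma2[k, ], "/"))
      logB[act, t, k] <- const[k] - 0.5 * q
    }
  }
  logB
}

## scaled forward-backward over all sequences at once
fb_all <- function(seqs, params, want_xi = TRUE) {
  n <- seqs$n; Tm <- seqs$Tmax; K <- params$K
  A <- params$A
  Alive <- A[seq_len(K), seq_len(K), drop = FALSE]
  logB <- log_emissions(seqs, params)
  ## per-(person,wave) emission rescaling so densities stay representable
  M <- matrix(logB[, , 1], n, Tm)
  if (K >= 2) for (k in 2:K) M <- pmax(M, matrix(logB[, , k], n, Tm))
  B <- exp(sweep(logB, c(1, 2), M))
  alpha <- array(NA_real_, c(n, Tm, K))
  s <- matrix(NA_real_, n, Tm)
  ll <- numeric(n)
  a <- sweep(matrix(B[, 1, ], n, K), 2, params$pi, "*")
  rs <- rowSums(a)
  if (any(!is.finite(rs)) || any(rs <= 0))
    stop2("non-finite likelihood in sequence(s): ",
          paste(utils::head(seqs$ids[!is.finite(rs) | rs <= 0], 5), collapse = ", "))
  alpha[, 1, ] <- a / rs
  s[, 1] <- rs
  ll <- log(rs) + M[, 1]
  for (t in 2:Tm) {
    if (Tm < 2) break
    act <- which(seqs$len >= t)
    if (!length(act)) break
    ap <- matrix(alpha[act, t - 1, ], length(act), K)
    a <- (ap %*% Alive) * matrix(B[act, t, ], length(act), K)
    rs <- rowSums(a)
    if (any(!is.finite(rs)) || any(rs <= 0))
      stop2("non-finite likelihood in sequence(s): ",
            paste(utils::head(seqs$ids[act][!is.finite(rs) | rs <= 0], 5),
                  collapse = ", "))
    alpha[act, t, ] <- a / rs
    s[act, t] <- rs
    ll[act] <- ll[act] + log(rs) + M[act, t]
  }
  ## exit factor: P(exit token | last live state)
  exited <- which(seqs$exit > 0)
  pe <- rep(1, n)
  if (length(exited)) {
    ex_col <- K + seqs$exit[exited]
    pe[exited] <- vapply(seq_along(exited), function(j)
      sum(alpha[exited[j], seqs$len[exited[j]], ] * A[seq_len(K), ex_col[j]]),
      numeric(1))
    if (any(pe[exited] <= 0))
      stop2("zero exit probability for sequence(s): ",
            paste(utils::head(seqs$ids[exited][pe[exited] <= 0], 5), collapse = ", "))
    ll[exited] <- ll[exited] + log(pe[exited])
  }
  ## backward pass (same scaling), posteriors, transition expectations
  beta <- array(NA_real_, c(n, Tm, K))
  for (i in seq_len(n)) {
    L <- seqs$len[i]
    beta[i, L, ] <- if (seqs$exit[i] > 0)
      A[seq_len(K), K + seqs$exit[i]] / pe[i] else rep(1, K)
  }
  if (Tm >= 2) for (t in (Tm - 1):1) {
    if (t < 1) break
    act <- which(seqs$len >= t + 1)
    if (!length(act)) next
    bn <- matrix(beta[act, t + 1, ], length(act), K) *
      matrix(B[act, t + 1, ], length(act), K)
    beta[act, t, ] <- (bn %*% t(Alive)) / s[act, t + 1]
  }
  gamma <- alpha * beta
  ## normalize (guards rounding; exact up to machine precision already)
  for (t in seq_len(Tm)) {
    act <- which(seqs$len >= t)
    g <- matrix(gamma[act, t, ], length(act), K)
    gamma[act, t, ] <- g / rowSums(g)
  }
  xi_sum <- NULL
  if (want_xi && Tm >= 2) {
    xi_sum <- matrix(0, K, K)
    for (t in seq_len(Tm - 1)) {
      act <- which(seqs$len >= t + 1)
      if (!length(act)) next
      ap <- matrix(alpha[act, t, ], length(act), K)
      bn <- matrix(beta[act, t + 1, ], length(act), K) *
        matrix(B[act, t + 1, ], length(act), K) / s[act, t + 1]
      xi_sum <- xi_sum + (t(ap) %*% bn) * Alive
    }
  }
  list(loglik = sum(ll), ll_per_seq = ll, gamma = gamma, xi_sum = xi_sum,
       B = B, logB = logB)
}

#' Forward-backward algorithm for one sequence
#'
#' Scaled forward-backward under the fitted model; returns the sequence
#' log-likelihood (including the exit transition factor when the sequence
#' ends in death or dropout) and the per-wave posterior state
#' probabilities over live states.
#'
#' @param y T x d matrix of score vectors (live waves)
#' @param params an [hmm_params()] object
#' @param exit `"none"`, `"death"` or `"dropout"`
#' @return list with `loglik` and `posteriors` (T x K, rows sum to 1)
#' @export
forward_backward <- function(y, params, exit = c("none", "death", "dropout")) {
  exit <- match.arg(exit)
  y <- as.matrix(y)
  if (ncol(y) != params$d) stop2("score dimension (", ncol(y),
                                 ") does not match emissions (", params$d, ")")
  seqs <- hmm_sequences(y, person_id = rep(1L, nrow(y)),
                        wave = seq_len(nrow(y)),
                        exit = stats::setNames(exit, "1"))
  fb <- fb_all(seqs, params, want_xi = FALSE)
  list(loglik = fb$loglik,
       posteriors = matrix(fb$gamma[1, seq_len(nrow(y)), ], nrow(y), params$K))
}

#' Baum-Welch estimation
#'
#' EM for the absorbing-state HMM. The total log-likelihood is asserted to
#' be non-decreasing across iterations; estimation stops when the relative
#' increase falls below `tol`. Absorbing rows are never updated; emission
#' variances are floored at `init$variance_floor`.
#'
#' @param sequences an [hmm_sequences()] object
#' @param init starting [hmm_params()]
#' @param max_iter iteration cap (default 500)
#' @param tol relative log-likelihood convergence threshold (default 1e-6)
#' @return list with `params` (fitted, `$loglik` filled in) and `trace`
#'   (log-likelihood per iteration)
#' @export
baum_welch <- function(sequences, init, max_iter = 500, tol = 1e-6) {
  params <- init
  K <- params$K
  n <- sequences$n
  trace <- numeric(0)
  X <- flatten_scores(sequences)
  idx <- flat_index(sequences)
  starts <- cumsum(c(1L, utils::head(sequences$len, -1L)))
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    fb <- fb_all(sequences, params)
    ll <- fb$loglik
    if (ll < ll_prev - 1e-6 * max(1, abs(ll_prev)))
      stop2("log-likelihood decreased at iteration ", it,
            " (", ll_prev, " -> ", ll, ")")
    trace <- c(trace, ll)
    converged <- is.finite(ll_prev) &&
      (ll - ll_prev) <= tol * max(1, abs(ll_prev))
    if (converged) break
    ll_prev <- ll
    ## flatten posteriors to the person-wave rows
    G <- matrix(0, nrow(X), K)
    for (k in seq_len(K)) G[, k] <- fb$gamma[, , k][idx]
    ## M step
    pi_new <- colMeans(G[starts, , drop = FALSE])
    pi_new <- pi_new / sum(pi_new)
    A <- params$A
    gamma_last_exit <- matrix(0, K, 2)   # expected exits from each state
    out_mass <- numeric(K)               # expected transitions out of state
    exited <- which(sequences$exit > 0)
    for (i in exited) {
      gL <- fb$gamma[i, sequences$len[i], ]
      gamma_last_exit[, sequences$exit[i]] <-
        gamma_last_exit[, sequences$exit[i]] + gL
    }
    live_num <- if (is.null(fb$xi_sum)) matrix(0, K, K) else fb$xi_sum
    denom <- rowSums(live_num) + rowSums(gamma_last_exit)
    for (k in seq_len(K)) {
      if (denom[k] > 0) {
        A[k, seq_len(K)] <- live_num[k, ] / denom[k]
        A[k, K + 1] <- gamma_last_exit[k, 1] / denom[k]
        A[k, K + 2] <- gamma_last_exit[k, 2] / denom[k]
      }
    }
    ## emissions
    wsum <- colSums(G)
    mu <- crossprod(G, X) / wsum
    sig <- matrix(0, K, ncol(X))
    for (k in seq_len(K)) {
      z <- sweep(X, 2, mu[k, ])
      sig[k, ] <- colSums(G[, k] * z^2) / wsum[k]
    }
    sig <- pmax(sig, params$variance_floor)
    params <- hmm_params(pi_new, A, mu, sig, params$variance_floor)
  }
  params$loglik <- ll
  params$n_iter <- it
  list(params = params, trace = trace)
}

#' Multi-restart Baum-Welch
#'
#' Runs EM from the cluster-based initialization plus `n_restarts - 1`
#' randomly perturbed versions of it and keeps the fit with the highest
#' log-likelihood. After selection, states are aligned to the fuzzy
#' centroids by nearest-centroid matching so pattern labels are stable
#' across restarts. Deterministic given `seed`.
#'
#' @param sequences an [hmm_sequences()] object
#' @param init cluster-based [hmm_params()] (see [init_from_clusters()])
#' @param n_restarts number of EM runs (default 100)
#' @param seed integer seed for the perturbations
#' @param max_iter,tol passed to [baum_welch()]
#' @return the best fit: list with `params`, `trace`, `logliks` of all
#'   restarts
#' @export
hmm_multi_restart <- function(sequences, init, n_restarts = 100, seed = 1L,
                              max_iter = 500, tol = 1e-6) {
  if (!is_count(n_restarts)) stop2("n_restarts must be >= 1")
  K <- init$K
  fits <- vector("list", n_restarts)
  errors <- character(0)
  for (r in seq_len(n_restarts)) {
    start <- if (r == 1) init else perturb_params(init, substream_seed(seed, r))
    fits[[r]] <- tryCatch(
      baum_welch(sequences, start, max_iter = max_iter, tol = tol),
      error = function(e) e)
    if (inherits(fits[[r]], "error"))
      errors <- c(errors, paste0("restart ", r, ": ", conditionMessage(fits[[r]])))
  }
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok))
    stop2("all restarts failed:\n", paste(errors, collapse = "\n"))
  lls <- vapply(fits[ok], function(f) f$params$loglik, numeric(1))
  best <- fits[ok][[which.max(lls)]]
  best$logliks <- lls
  ## stable labels: align fitted states to the initial centroids
  perm <- greedy_mu_match(best$params$mu, init$mu)
  best$params <- permute_states(best$params, perm)
  best
}

perturb_params <- function(init, seed) {
  set.seed(seed)
  K <- init$K; d <- init$d
  spread <- sqrt(pmax(apply(init$mu, 2, stats::var), init$variance_floor))
  mu <- init$mu + matrix(stats::rnorm(K * d, 0, 0.5), K, d) *
    matrix(spread, K, d, byrow = TRUE)
  sigma2 <- init$sigma2 * matrix(stats::runif(K * d, 0.5, 2), K, d)
  pi <- stats::rgamma(K, 2) ; pi <- pi / sum(pi)
  A <- init$A
  for (k in seq_len(K)) {
    w <- pmax(A[k, ], 1e-3) * exp(stats::rnorm(K + 2, 0, 0.5))
    A[k, ] <- w / sum(w)
  }
  A[K + 1, ] <- c(rep(0, K), 1, 0)
  A[K + 2, ] <- c(rep(0, K + 1), 1)
  hmm_params(pi, A, mu, sigma2, init$variance_floor)
}

greedy_mu_match <- function(mu_fit, mu_ref) {
  K <- nrow(mu_fit)
  perm <- integer(K)
  free_fit <- seq_len(K); free_ref <- seq_len(K)
  D <- as.matrix(stats::dist(rbind(mu_fit, mu_ref)))[seq_len(K), K + seq_len(K),
                                                     drop = FALSE]
  for (step in seq_len(K)) {
    sub <- D[free_fit, free_ref, drop = FALSE]
    w <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    perm[free_fit[w[1]]] <- free_ref[w[2]]
    free_fit <- free_fit[-w[1]]; free_ref <- free_ref[-w[2]]
  }
  perm
}

## relabel live states: state k becomes perm[k]
permute_states <- function(params, perm) {
  K <- params$K
  inv <- order(perm)
  idx <- c(inv, K + 1, K + 2)
  A <- params$A[idx, idx]
  p <- hmm_params(params$pi[inv], A, params$mu[inv, , drop = FALSE],
                  params$sigma2[inv, , drop = FALSE], params$variance_floor)
  p$loglik <- params$loglik
  p$n_iter <- params$n_iter
  p
}

#' Viterbi decoding of one sequence
#'
#' Most probable joint live-state path in log space; ties break toward the
#' lower state index. If the sequence ends in an exit, the exit transition
#' probability is included in the maximization.
#'
#' @inheritParams forward_backward
#' @return integer state path of length `nrow(y)`
#' @export
viterbi <- function(y, params, exit = c("none", "death", "dropout")) {
  exit <- match.arg(exit)
  y <- as.matrix(y)
  if (ncol(y) != params$d) stop2("score dimension mismatch")
  K <- params$K
  Tn <- nrow(y)
  logA <- log(params$A[seq_len(K), seq_len(K), drop = FALSE])
  logB <- matrix(0, Tn, K)
  const <- -0.5 * (params$d * log(2 * pi) + rowSums(log(params$sigma2)))
  for (k in seq_len(K)) {
    z <- sweep(y, 2, params$mu[k, ])
    logB[, k] <- const[k] - 0.5 * rowSums(sweep(z^2, 2, params$sigma2[k, ], "/"))
  }
  delta <- matrix(-Inf, Tn, K)
  psi <- matrix(0L, Tn, K)
  delta[1, ] <- log(params$pi) + logB[1, ]
  if (Tn >= 2) for (t in 2:Tn) {
    cand <- delta[t - 1, ] + logA          # K x K: from row to col
    psi[t, ] <- apply(cand, 2, which.max)  # first max = lowest index
    delta[t, ] <- cand[cbind(psi[t, ], seq_len(K))] + logB[t, ]
  }
  final <- delta[Tn, ]
  if (exit != "none")
    final <- final + log(params$A[seq_len(K), K + match(exit, EXIT_LEVELS) - 1L])
  path <- integer(Tn)
  path[Tn] <- which.max(final)
  if (Tn >= 2) for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Decode all trajectories of a sequence set
#'
#' Viterbi path per person plus the observed terminal exit state (death =
#' K+1, dropout = K+2) at the wave after the last live observation.
#'
#' @param sequences an [hmm_sequences()] object
#' @param params fitted [hmm_params()]
#' @return data.frame `person_id, wave, state` with attribute `posteriors`
#'   (per-wave live-state posteriors aligned with the live rows) and
#'   attribute `K`
#' @export
decode_trajectories <- function(sequences, params) {
  K <- params$K
  out <- vector("list", sequences$n)
  fb <- fb_all(sequences, params, want_xi = FALSE)
  idx <- flat_index(sequences)
  G <- matrix(0, nrow(idx), K)
  for (k in seq_len(K)) G[, k] <- fb$gamma[, , k][idx]
  for (i in seq_len(sequences$n)) {
    L <- sequences$len[i]
    y <- matrix(sequences$Y[i, seq_len(L), ], L, sequences$d)
    path <- viterbi(y, params, EXIT_LEVELS[sequences$exit[i] + 1L])
    if (sequences$exit[i] > 0) {
      path <- c(path, K + sequences$exit[i])
      wv <- seq_len(L + 1)
    } else wv <- seq_len(L)
    out[[i]] <- data.frame(person_id = sequences$ids[i], wave = wv,
                           state = path)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "posteriors") <- G
  attr(res, "K") <- K
  attr(res, "loglik") <- fb$loglik
  res
}

#' Log-likelihood profile over the number of states
#'
#' Fits the full cluster-init + multi-restart pipeline for each K in the
#' grid and reports the best log-likelihood; no automatic selection is
#' made -- the choice of K balances fit against interpretability and is
#' left to the analyst.
#'
#' @param sequences an [hmm_sequences()] object
#' @param K_grid integer vector of live-state counts to try
#' @param n_restarts EM restarts per K (default 10)
#' @param seed integer seed
#' @param m fuzzifier for the seeding clusterings
#' @param ... passed to [baum_welch()]
#' @return data.frame with columns `K`, `loglik`, `n_params`
#' @export
scan_K <- function(sequences, K_grid, n_restarts = 10, seed = 1L, m = 2, ...) {
  if (!length(K_grid)) stop2("K_grid must be non-empty")
  X <- flatten_scores(sequences)
  res <- lapply(K_grid, function(K) {
    cl <- fcm_fit(X, K, m = m, n_restarts = 3, seed = seed)
    init <- init_from_clusters(cl, sequences)
    fit <- hmm_multi_restart(sequences, init, n_restarts = n_restarts,
                             seed = seed, ...)
    d <- sequences$d
    data.frame(K = K, loglik = fit$params$loglik,
               n_params = (K - 1) + K * (K + 1) + 2 * K * d)
  })
  do.call(rbind, res)
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("Absorbing-state Gaussian HMM: K =", x$K, "live states +",
      "death/dropout, d =", x$d, "\n")
  if (!is.null(x$loglik)) cat("log-likelihood:", x$loglik, "\n")
  invisible(x)
}
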