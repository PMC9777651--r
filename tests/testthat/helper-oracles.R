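# Independent oracles and tiny fixtures shared across test files.

# exhaustive-path log-likelihood of a Gaussian HMM with optional observed
# terminal exit: direct sum over all K^T live paths
brute_force_loglik <- function(y, pi, A, mu, sigma2, exit = "none") {
  K <- length(pi)
  Tn <- nrow(y)
  paths <- as.matrix(expand.grid(rep(list(1:K), Tn)))
  exit_col <- switch(exit, none = 0L, death = K + 1L, dropout = K + 2L)
  total <- 0
  for (r in seq_len(nrow(paths))) {
    q <- paths[r, ]
    p <- pi[q[1]]
    for (t in seq_len(Tn)) {
      p <- p * prod(stats::dnorm(y[t, ], mu[q[t], ], sqrt(sigma2[q[t], ])))
      if (t > 1) p <- p * A[q[t - 1], q[t]]
    }
    if (exit_col > 0) p <- p * A[q[Tn], exit_col]
    total <- total + p
  }
  log(total)
}

# exhaustive Viterbi: argmax over all K^T paths, ties toward the
# lexicographically smallest path (expand.grid varies the first index
# fastest, so the first maximum is the lowest-index path)
brute_force_viterbi <- function(y, pi, A, mu, sigma2, exit = "none") {
  K <- length(pi)
  Tn <- nrow(y)
  paths <- as.matrix(expand.grid(rep(list(1:K), Tn)))
  exit_col <- switch(exit, none = 0L, death = K + 1L, dropout = K + 2L)
  best <- -Inf
  best_q <- NULL
  for (r in seq_len(nrow(paths))) {
    q <- paths[r, ]
    lp <- log(pi[q[1]])
    for (t in seq_len(Tn)) {
      lp <- lp + sum(stats::dnorm(y[t, ], mu[q[t], ], sqrt(sigma2[q[t], ]),
                                  log = TRUE))
      if (t > 1) lp <- lp + log(A[q[t - 1], q[t]])
    }
    if (exit_col > 0) lp <- lp + log(A[q[Tn], exit_col])
    if (lp > best + 1e-12) { best <- lp; best_q <- q }
  }
  unname(as.integer(best_q))
}

# principal inertias of a multiple correspondence analysis computed from
# scratch as the correspondence analysis of the indicator matrix
mca_inertias <- function(df) {
  df <- as.data.frame(lapply(df, factor))
  n <- nrow(df); p <- ncol(df)
  G <- do.call(cbind, lapply(df, function(f)
    outer(as.integer(f), seq_along(levels(f)), function(i, l) (i == l) + 0)))
  Pm <- G / (n * p)
  r <- rowSums(Pm); cs <- colSums(Pm)
  S <- diag(1 / sqrt(r)) %*% (Pm - outer(r, cs)) %*% diag(1 / sqrt(cs))
  sv <- svd(S)$d
  sv[sv > 1e-10]^2
}

# random row-stochastic live+absorbing transition matrix
random_absorbing_A <- function(K) {
  A <- matrix(0, K + 2, K + 2)
  for (k in 1:K) {
    w <- stats::rgamma(K + 2, 1)
    A[k, ] <- w / sum(w)
  }
  A[K + 1, ] <- c(rep(0, K), 1, 0)
  A[K + 2, ] <- c(rep(0, K + 1), 1)
  A
}

# small panel with known structure, used by prep and I/O tests
tiny_cohort <- function(n = 120, K = 2, seed = 42, n_waves = 3, ...) {
  generate_cohort(example_cohort_config(n, K = K, n_waves = n_waves,
                                        seed = seed, ...))
}

# simulate sequences directly from HMM parameters (independent of the
# cohort generator): latent chain + Gaussian emissions + absorbing exits
simulate_from_params <- function(params, n, Tn, seed = 1) {
  set.seed(seed)
  K <- params$K; d <- params$d
  rows <- list(); person <- wave <- integer(0)
  exit <- character(0)
  for (i in seq_len(n)) {
    s <- sample.int(K, 1, prob = params$pi)
    ex <- "none"
    for (t in seq_len(Tn)) {
      rows[[length(rows) + 1]] <- stats::rnorm(d, params$mu[s, ],
                                               sqrt(params$sigma2[s, ]))
      person <- c(person, i); wave <- c(wave, t)
      if (t < Tn) {
        s2 <- sample.int(K + 2, 1, prob = params$A[s, ])
        if (s2 > K) { ex <- c("death", "dropout")[s2 - K]; break }
        s <- s2
      }
    }
    exit[as.character(i)] <- ex
  }
  hmm_sequences(do.call(rbind, rows), person, wave, exit)
}

# mild random perturbation of true parameters for EM starts
perturbed_init <- function(truth, seed = 1) {
  set.seed(seed)
  K <- truth$K; d <- truth$d
  mu <- truth$mu + matrix(rnorm(K * d, 0, 0.5), K, d)
  A <- truth$A
  for (k in seq_len(K)) {
    w <- pmax(A[k, ], 0.02) * exp(rnorm(K + 2, 0, 0.2))
    A[k, ] <- w / sum(w)
  }
  A[K + 1, ] <- c(rep(0, K), 1, 0)
  A[K + 2, ] <- c(rep(0, K + 1), 1)
  hmm_params(rep(1 / K, K), A, mu, truth$sigma2)
}

# generating conditions used for the recovery benchmarks: immediate
# expression of the current latent pattern in disease onset
separated_config <- function(n, K, seed, n_waves = 5)
  example_cohort_config(n, K = K, n_waves = n_waves, seed = seed,
                        separation = 0.7, background = 0.04,
                        incidence_factor = 1.0)
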