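toy_params <- function(K = 2, d = 1, seed = 1) {
  set.seed(seed)
  pi <- rep(1 / K, K)
  A <- random_absorbing_A(K)
  mu <- matrix(seq_len(K * d), K, d)
  sigma2 <- matrix(runif(K * d, 0.5, 2), K, d)
  hmm_params(pi, A, mu, sigma2)
}

test_that("forward-backward matches exhaustive path enumeration", {
  set.seed(11)
  for (r in 1:5) {
    p <- toy_params(K = 2, d = 2, seed = r)
    y <- matrix(rnorm(6), 3, 2)
    for (exit in c("none", "death", "dropout")) {
      fb <- forward_backward(y, p, exit = exit)
      oracle <- brute_force_loglik(y, p$pi, p$A, p$mu, p$sigma2, exit)
      expect_equal(fb$loglik, oracle, tolerance = 1e-10)
      expect_equal(rowSums(fb$posteriors), rep(1, 3), tolerance = 1e-10)
    }
  }
})

test_that("single live state reduces to iid Gaussian log-density", {
  p <- hmm_params(1, rbind(c(0.9, 0.08, 0.02), c(0, 1, 0), c(0, 0, 1)),
                  matrix(0.5, 1, 1), matrix(2, 1, 1))
  y <- matrix(rnorm(5, 0.4, 1), 5, 1)
  fb <- forward_backward(y, p)
  iid <- sum(dnorm(y, 0.5, sqrt(2), log = TRUE)) + 4 * log(0.9)
  expect_equal(fb$loglik, iid, tolerance = 1e-10)
})

test_that("censored sequence likelihood factors into live part times exit rate", {
  ## T=2 toy by hand: one live state, death after wave 2
  A <- rbind(c(0.7, 0.2, 0.1), c(0, 1, 0), c(0, 0, 1))
  p <- hmm_params(1, A, matrix(0, 1, 1), matrix(1, 1, 1))
  y <- matrix(c(0.3, -0.2), 2, 1)
  hand <- sum(dnorm(y, 0, 1, log = TRUE)) + log(0.7) + log(0.2)
  expect_equal(forward_backward(y, p, exit = "death")$loglik, hand,
               tolerance = 1e-12)
})

test_that("viterbi equals brute-force argmax and honours tie/exit rules", {
  set.seed(12)
  for (r in 1:10) {
    p <- toy_params(K = 3, d = 1, seed = 100 + r)
    y <- matrix(rnorm(5, sd = 3), 5, 1)
    exit <- c("none", "death", "dropout")[1 + r %% 3]
    expect_equal(viterbi(y, p, exit),
                 brute_force_viterbi(y, p$pi, p$A, p$mu, p$sigma2, exit))
  }
  ## K=1: constant path
  p1 <- hmm_params(1, rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                   matrix(0, 1, 1), matrix(1, 1, 1))
  expect_equal(viterbi(matrix(rnorm(4), 4, 1), p1), rep(1L, 4))
  ## deterministic cyclic transitions force the path
  Ac <- rbind(c(0, 1, 0, 0), c(0, 0, 1, 0), c(1, 0, 0, 0), c(0, 0, 0, 1))
  Ac <- cbind(Ac, 0); Ac <- rbind(Ac, 0); Ac[5, 5] <- 1; Ac[4, 4] <- 1
  pc <- hmm_params(c(1, 0, 0), Ac, matrix(c(-10, 0, 10), 3, 1),
                   matrix(0.01, 3, 1))
  y <- matrix(c(-10, 0, 10, -10), 4, 1)
  expect_equal(viterbi(y, pc), c(1L, 2L, 3L, 1L))
})

test_that("viterbi path probability is at least the posterior-argmax path's", {
  set.seed(13)
  logp_path <- function(q, y, p, exit) {
    lp <- log(p$pi[q[1]]) + sum(vapply(seq_along(q), function(t)
      sum(dnorm(y[t, ], p$mu[q[t], ], sqrt(p$sigma2[q[t], ]), log = TRUE)),
      numeric(1)))
    if (length(q) > 1)
      lp <- lp + sum(log(p$A[cbind(q[-length(q)], q[-1])]))
    if (exit != "none")
      lp <- lp + log(p$A[q[length(q)], p$K + match(exit, c("death", "dropout"))])
    lp
  }
  for (r in 1:5) {
    p <- toy_params(K = 3, d = 1, seed = 200 + r)
    y <- matrix(rnorm(4, sd = 2), 4, 1)
    fb <- forward_backward(y, p)
    vit <- viterbi(y, p)
    pmax_path <- apply(fb$posteriors, 1, which.max)
    expect_gte(logp_path(vit, y, p, "none") - logp_path(pmax_path, y, p, "none"),
               -1e-10)
  }
})

test_that("cluster-based initialization reproduces counting on separated data", {
  ## hand-built scores: 6 persons, 2 waves, two point clusters, no exits
  sc <- rbind(matrix(c(0, 0), 6, 2, byrow = TRUE),
              matrix(c(10, 10), 6, 2, byrow = TRUE))
  ## interleave so persons 1-3 stay in cluster 1, person 4 moves 1 -> 2, etc.
  person <- c(1, 2, 3, 4, 5, 6, 1, 2, 3, 4, 5, 6)
  wave <- rep(1:2, each = 6)
  x <- matrix(0, 12, 2)
  lab1 <- c(1, 1, 1, 1, 2, 2)      # wave-1 clusters
  lab2 <- c(1, 1, 1, 2, 2, 2)      # wave-2 clusters (person 4 moved)
  x[wave == 1, ] <- rbind(c(0, 0), c(0, 0), c(0, 0), c(0, 0), c(10, 10), c(10, 10))[order(1:6), ]
  x[wave == 2, ] <- rbind(c(0, 0), c(0, 0), c(0, 0), c(10, 10), c(10, 10), c(10, 10))
  seqs <- hmm_sequences(x, person, wave)
  cl <- fcm_fit(x, 2, n_restarts = 3, seed = 5)
  init <- init_from_clusters(cl, seqs)
  ## identify which state sits at the origin
  k0 <- which.min(rowSums(init$mu^2))
  k1 <- 3 - k0
  ## transitions out of origin cluster: 3 of 4 stay, 1 of 4 moves
  expect_equal(init$A[k0, k0], 0.75, tolerance = 1e-10)
  expect_equal(init$A[k0, k1], 0.25, tolerance = 1e-10)
  expect_equal(init$A[k1, k1], 1, tolerance = 1e-10)
  expect_equal(sum(init$pi), 1, tolerance = 1e-12)
})

test_that("init sends exit mass to the death/dropout columns", {
  ## two persons in one cluster, both exit after wave 1: row = all exit
  x <- matrix(0, 2, 1)
  seqs <- hmm_sequences(x, c(1, 2), c(1, 1),
                        exit = c(`1` = "death", `2` = "dropout"))
  cl <- fcm_fit(rbind(x, matrix(5, 2, 1)), 2, n_restarts = 2, seed = 1)
  ## use a clustering on the real rows only
  cl2 <- structure(list(U = matrix(c(1, 1), 2, 1), centers = matrix(0, 1, 1),
                        m = 2, K = 1L), class = "fcm")
  init <- init_from_clusters(cl2, seqs)
  expect_equal(init$A[1, 2] + init$A[1, 3], 1, tolerance = 1e-12)
})

test_that("baum_welch: K=1 closed form, monotone trace, truth is a fixed point", {
  set.seed(14)
  ## K=1, no exits: ML is the sample mean/variance of all observations
  n <- 40; Tn <- 4
  y <- rnorm(n * Tn, 2, 1.5)
  seqs <- hmm_sequences(matrix(y, ncol = 1), rep(1:n, each = Tn),
                        rep(1:Tn, n))
  init <- hmm_params(1, rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                     matrix(0, 1, 1), matrix(1, 1, 1))
  fit <- baum_welch(seqs, init)
  expect_equal(as.vector(fit$params$mu), mean(y), tolerance = 1e-8)
  expect_equal(as.vector(fit$params$sigma2), mean((y - mean(y))^2),
               tolerance = 1e-6)
  expect_true(all(diff(fit$trace) >= -1e-6 * pmax(1, abs(fit$trace[-length(fit$trace)]))))
  ## initializing at the generating parameters: the likelihood barely moves
  ## (truth sits in the attraction basin of the MLE)
  p <- toy_params(K = 2, d = 1, seed = 3)
  sim <- simulate_from_params(p, n = 300, Tn = 5, seed = 4)
  fit2 <- baum_welch(sim, p, tol = 1e-6)
  tr <- fit2$trace
  expect_lt(tr[length(tr)] - tr[1], 0.005 * abs(tr[1]))
})

test_that("planted two-state model is recovered within 0.05 after matching", {
  set.seed(15)
  A <- rbind(c(0.75, 0.15, 0.07, 0.03),
             c(0.10, 0.80, 0.05, 0.05),
             c(0, 0, 1, 0), c(0, 0, 0, 1))
  truth <- hmm_params(c(0.5, 0.5), A, matrix(c(0, 6), 2, 1),
                      matrix(1, 2, 1))
  sim <- simulate_from_params(truth, n = 1000, Tn = 5, seed = 6)
  init <- perturbed_init(truth, seed = 7)
  fit <- baum_welch(sim, init)
  perm <- order(fit$params$mu[, 1])      # state matching on the means
  idx <- c(perm, 3, 4)
  Ahat <- fit$params$A[idx, idx]
  expect_lt(max(abs(Ahat - A)), 0.05)
})

test_that("multi-restart returns the best restart and is seed-stable", {
  set.seed(16)
  p <- toy_params(K = 2, d = 1, seed = 8)
  p$A[1, ] <- c(0.8, 0.1, 0.07, 0.03)
  p$A[2, ] <- c(0.1, 0.8, 0.05, 0.05)
  p <- hmm_params(p$pi, p$A, matrix(c(-3, 3), 2, 1), matrix(1, 2, 1))
  sim <- simulate_from_params(p, n = 200, Tn = 5, seed = 9)
  X <- mptraj:::flatten_scores(sim)
  cl <- fcm_fit(X, 2, n_restarts = 2, seed = 1)
  init <- init_from_clusters(cl, sim)
  single <- baum_welch(sim, init)
  multi1 <- hmm_multi_restart(sim, init, n_restarts = 1, seed = 5)
  expect_equal(multi1$params$loglik, single$params$loglik, tolerance = 1e-12)
  multi <- hmm_multi_restart(sim, init, n_restarts = 5, seed = 5)
  expect_gte(multi$params$loglik, max(multi$logliks) - 1e-9)
  multi_b <- hmm_multi_restart(sim, init, n_restarts = 5, seed = 17)
  expect_equal(multi$params$loglik, multi_b$params$loglik, tolerance = 1e-3)
})

test_that("scan_K shows an elbow at the planted K and is monotone in K", {
  set.seed(18)
  A <- rbind(c(0.8, 0.1, 0.1, 0, 0), c(0.1, 0.8, 0.1, 0, 0),
             c(0.1, 0.1, 0.8, 0, 0), c(0, 0, 0, 1, 0), c(0, 0, 0, 0, 1))
  truth <- hmm_params(rep(1 / 3, 3), A, matrix(c(-8, 0, 8), 3, 1),
                      matrix(1, 3, 1))
  sim <- simulate_from_params(truth, n = 250, Tn = 5, seed = 19)
  tab <- scan_K(sim, K_grid = 1:4, n_restarts = 2, seed = 20)
  expect_equal(tab$K, 1:4)
  ll <- tab$loglik
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-4])))
  gain_to_true <- (ll[3] - ll[2])
  gain_past <- max(ll[4] - ll[3], 1e-9)
  expect_gt(gain_to_true / gain_past, 5)
  expect_error(scan_K(sim, integer(0)), "non-empty")
})

test_that("decoded exits appear only at the exit wave", {
  gen <- tiny_cohort(200, K = 2, seed = 23, n_waves = 4)
  fit <- mpt_fit(gen$panel, K = 2, n_restarts = 2, seed = 3)
  dec <- fit$decoding
  for (p in unique(dec$person_id)) {
    s <- dec$state[dec$person_id == p]
    ex <- which(s > 2)
    if (length(ex)) expect_equal(ex, length(s))
  }
})

test_that("hmm params serialize to JSON and back", {
  p <- toy_params(K = 3, d = 2, seed = 30)
  p$loglik <- -123.45
  f <- tempfile(fileext = ".json")
  write_hmm(p, f)
  q <- read_hmm(f)
  expect_equal(q$A, p$A, tolerance = 1e-12)
  expect_equal(q$mu, p$mu, tolerance = 1e-12)
  expect_equal(q$loglik, p$loglik)
})
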