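## Top-level model: panel -> features -> PCAmix -> fuzzy c-means -> HMM.

#' Fit combined multimorbidity-polypharmacy pattern trajectories
#'
#' End-to-end estimator. The raw person-wave panel is turned into binary
#' disease/drug-group indicators (chronic-use threshold, baseline-use and
#' median-prevalence filters), reduced together with age and sex by
#' mixed-data PCA with the Karlis-Saporta-Spinaki retention rule, softly
#' clustered with fuzzy c-means, and modelled by a hidden Markov model with
#' one live state per cluster plus absorbing death and dropout states,
#' estimated by multi-restart Baum-Welch and decoded by Viterbi.
#'
#' @param panel long-format cohort panel (see [read_panel()] for the schema)
#' @param map drug-disease mapping (default [default_drug_disease_map()])
#' @param K number of patterns (default 8)
#' @param n_restarts Baum-Welch restarts (default 100)
#' @param m fuzzy c-means fuzzifier (default 2)
#' @param seed integer seed controlling clustering and restart perturbations
#' @param min_packages,baseline_use_fraction,median_prevalence_threshold,mapped_group_rule
#'   feature-construction settings, see [build_feature_table()]
#' @param fcm_restarts fuzzy c-means restarts (default 5)
#' @param max_iter,tol Baum-Welch iteration cap and convergence threshold
#' @param ncomp override the number of retained components (default: KSS)
#' @return object of class `mpt` with elements `features`, `pcamix`,
#'   `scores`, `clustering`, `hmm` (fitted params), `decoding`,
#'   `transitions`, `mortality`, `call`
#' @seealso [summary.mpt()], [predict.mpt()], [simulate.mpt()], [plot.mpt()]
#' @export
mpt_fit <- function(panel, map = default_drug_disease_map(), K = 8,
                    n_restarts = 100, m = 2, seed = 1L,
                    min_packages = 3, baseline_use_fraction = 0.01,
                    median_prevalence_threshold = 0.02,
                    mapped_group_rule = c("and", "diagnosis_only"),
                    fcm_restarts = 5, max_iter = 500, tol = 1e-6,
                    ncomp = NULL) {
  mapped_group_rule <- match.arg(mapped_group_rule)
  features <- build_feature_table(
    panel, map, min_packages = min_packages,
    baseline_use_fraction = baseline_use_fraction,
    median_prevalence_threshold = median_prevalence_threshold,
    mapped_group_rule = mapped_group_rule)
  groups <- attr(features, "groups")
  mix <- features[, c("age", "sex", groups), drop = FALSE]
  pca <- pcamix_fit(mix, quali = c("sex", groups))
  d <- max(ncomp %||% pca$d, 1L)
  scores <- pca$scores[, seq_len(min(d, ncol(pca$scores))), drop = FALSE]
  cl <- fcm_fit(scores, K, m = m, n_restarts = fcm_restarts, seed = seed)
  seqs <- panel_sequences(panel, features, scores)
  init <- init_from_clusters(cl, seqs)
  fit <- hmm_multi_restart(seqs, init, n_restarts = n_restarts, seed = seed,
                           max_iter = max_iter, tol = tol)
  decoding <- decode_trajectories(seqs, fit$params)
  structure(list(
    features = features, groups = groups, pcamix = pca, scores = scores,
    clustering = cl, sequences = seqs, hmm = fit$params,
    loglik_trace = fit$trace, restart_logliks = fit$logliks,
    decoding = decoding,
    transitions = empirical_transitions(decoding),
    mortality = mortality_by_pattern(decoding),
    K = as.integer(K), seed = seed, call = match.call()
  ), class = "mpt")
}

#' @export
print.mpt <- function(x, ...) {
  cat("Combined multimorbidity-polypharmacy pattern trajectories\n")
  cat("  person-waves:", nrow(x$features),
      " persons:", x$sequences$n,
      " groups:", length(x$groups), "\n")
  cat("  components retained:", ncol(x$scores),
      "(KSS threshold", signif(x$pcamix$kss, 4), ")\n")
  cat("  patterns (K):", x$K,
      "  HMM log-likelihood:", signif(x$hmm$loglik, 8), "\n")
  base <- table(factor(x$decoding$state[x$decoding$wave == 1], levels = 1:x$K))
  cat("  baseline pattern sizes:", paste(base, collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a fitted pattern-trajectory model
#'
#' @param object an `mpt` fit
#' @param waves waves for the group tables (default first and last)
#' @param ... unused
#' @return list of class `summary.mpt`: pattern sizes per wave, permanence,
#'   mortality, and the top overrepresented groups at the requested waves
#' @export
summary.mpt <- function(object, waves = NULL, ...) {
  dec <- object$decoding
  waves <- waves %||% c(1, max(object$features$wave))
  sizes <- table(factor(dec$state[dec$wave == 1], levels = 1:object$K))
  out <- list(
    K = object$K,
    n_persons = object$sequences$n,
    baseline_sizes = as.integer(sizes),
    permanence = object$transitions$permanence,
    mortality = object$mortality,
    loglik = object$hmm$loglik,
    top_groups = lapply(stats::setNames(waves, paste0("wave_", waves)),
                        function(t) top_groups(object$features, dec, t, top = 5))
  )
  class(out) <- "summary.mpt"
  out
}

#' @export
print.summary.mpt <- function(x, ...) {
  cat("Patterns:", x$K, " persons:", x$n_persons, "\n")
  cat("Baseline sizes:", paste(x$baseline_sizes, collapse = ", "), "\n")
  cat("Permanence (%):",
      paste(round_half_up(x$permanence, 1), collapse = ", "), "\n")
  cat("Mortality (%):  ",
      paste(round_half_up(x$mortality, 1), collapse = ", "), "\n")
  cat("Log-likelihood:", x$loglik, "\n")
  for (nm in names(x$top_groups)) {
    cat("\nTop overrepresented groups,", nm, "(O/E > 2 flagged):\n")
    print(utils::head(x$top_groups[[nm]][
      , c("pattern", "group", "prevalence", "oe", "exclusivity",
          "overrepresented")], 20), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.mpt <- function(object, ...) {
  list(pi = object$hmm$pi, A = object$hmm$A, mu = object$hmm$mu,
       sigma2 = object$hmm$sigma2)
}

#' @export
logLik.mpt <- function(object, ...) {
  K <- object$K; d <- ncol(object$scores)
  val <- object$hmm$loglik
  attr(val, "df") <- (K - 1) + K * (K + 1) + 2 * K * d
  attr(val, "nobs") <- object$sequences$n
  class(val) <- "logLik"
  val
}

#' Decode new panel data with a fitted model
#'
#' Builds the feature rows for the new panel using the training group set,
#' projects them with the stored PCAmix scaling, and Viterbi-decodes each
#' person's sequence under the fitted HMM.
#'
#' @param object an `mpt` fit
#' @param newdata a panel data.frame with the same schema as the training
#'   panel (default: refuse, decoding of the training panel is in
#'   `object$decoding`)
#' @param map drug-disease mapping used at training time
#' @param ... unused
#' @return decoded trajectories (as [decode_trajectories()])
#' @export
predict.mpt <- function(object, newdata, map = default_drug_disease_map(),
                        ...) {
  if (missing(newdata)) return(object$decoding)
  act <- newdata[newdata$status == "active", , drop = FALSE]
  rx <- chronic_drug_flags(act[, intersect(drug_cols(), names(act)),
                               drop = FALSE])
  dfl <- as.matrix(act[, intersect(disease_cols(), names(act)), drop = FALSE])
  groups <- map_disease_drug_groups(dfl, rx, map)
  feat <- data.frame(person_id = act$person_id, wave = act$wave,
                     age = act$age, sex = act$sex)
  feat <- cbind(feat, as.data.frame(groups[, object$groups, drop = FALSE]))
  attr(feat, "groups") <- object$groups
  sc <- predict(object$pcamix, feat[, c("age", "sex", object$groups)],
                ncomp = ncol(object$scores))
  seqs <- panel_sequences(newdata, feat, sc)
  decode_trajectories(seqs, object$hmm)
}

#' Simulate state trajectories and scores from a fitted model
#'
#' Draws latent pattern trajectories from the fitted initial distribution
#' and transition matrix (with absorbing death/dropout) and emits Gaussian
#' component scores, mirroring the generative assumptions of the HMM.
#'
#' @param object an `mpt` fit
#' @param nsim number of persons to simulate
#' @param seed integer seed
#' @param n_waves horizon (default the training horizon)
#' @param ... unused
#' @return data.frame `person_id, wave, state` plus score columns for live
#'   waves
#' @export
simulate.mpt <- function(object, nsim = 1, seed = NULL, n_waves = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  Tn <- n_waves %||% object$sequences$Tmax
  K <- object$K; d <- ncol(object$scores)
  h <- object$hmm
  rows <- list()
  for (i in seq_len(nsim)) {
    s <- sample.int(K, 1, prob = h$pi)
    for (t in seq_len(Tn)) {
      if (s <= K) {
        y <- stats::rnorm(d, h$mu[s, ], sqrt(h$sigma2[s, ]))
        rows[[length(rows) + 1]] <- c(i, t, s, y)
        s_next <- sample.int(K + 2, 1, prob = h$A[s, ])
      } else {
        rows[[length(rows) + 1]] <- c(i, t, s, rep(NA_real_, d))
        break
      }
      s <- s_next
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("person_id", "wave", "state", paste0("score_", seq_len(d)))
  out
}

#' Residual-style diagnostics: standardized score residuals
#'
#' For each live person-wave, the observed score vector minus the posterior
#' mean of the state emission means, scaled by the posterior-mixed standard
#' deviation. Approximately standard normal coordinates under a correct
#' model.
#'
#' @param object an `mpt` fit
#' @param ... unused
#' @return matrix of standardized residuals (live person-waves x d)
#' @export
residuals.mpt <- function(object, ...) {
  G <- attr(object$decoding, "posteriors")
  X <- flatten_scores(object$sequences)
  mu_hat <- G %*% object$hmm$mu
  var_hat <- G %*% (object$hmm$sigma2 + object$hmm$mu^2) - mu_hat^2
  (X - mu_hat) / sqrt(pmax(var_hat, object$hmm$variance_floor))
}

#' Sequence-index plot of decoded trajectories
#'
#' Base-graphics image of every person's decoded state sequence (rows
#' sorted by initial pattern, then sequence), live patterns in colour and
#' death/dropout in greys -- the standard way to show trajectory stability
#' and exits at a glance.
#'
#' @param x an `mpt` fit
#' @param max_persons cap on rows drawn (default 2000, evenly subsampled)
#' @param ... passed to [graphics::image()]
#' @export
plot.mpt <- function(x, max_persons = 2000, ...) {
  si <- sequence_index_export(x$decoding)
  K <- x$K
  mat <- as.matrix(si[, grep("^s[0-9]+$", names(si)), drop = FALSE])
  if (nrow(mat) > max_persons)
    mat <- mat[round(seq(1, nrow(mat), length.out = max_persons)), , drop = FALSE]
  cols <- c(grDevices::hcl.colors(K, "Dark 3"), "grey25", "grey80")
  graphics::image(t(mat), col = cols, axes = FALSE,
                  xlab = "wave", ylab = "persons (sorted by initial pattern)",
                  ...)
  graphics::axis(1, at = seq(0, 1, length.out = ncol(mat)),
                 labels = seq_len(ncol(mat)))
  invisible(x)
}

#' Serialize fitted HMM parameters to JSON
#' @param params an [hmm_params()] object (e.g. `fit$hmm`)
#' @param path file path
#' @export
write_hmm <- function(params, path) {
  obj <- list(K = params$K, d = params$d, pi = params$pi, A = params$A,
              mu = params$mu, sigma2 = params$sigma2,
              variance_floor = params$variance_floor,
              loglik = params$loglik %||% NA)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- hmm_params(o$pi, o$A, o$mu, o$sigma2, o$variance_floor)
  p$loglik <- o$loglik
  p
}
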