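## Pattern characterization: prevalence, observed/expected ratios,
## exclusivity, empirical transitions, permanence, mortality and the
## sequence-index export.

#' Observed/expected ratio of a group in a cluster
#'
#' Cluster prevalence divided by whole-population prevalence (both in %).
#' A group is overrepresented -- characterizing the cluster -- when the
#' ratio is strictly greater than 2.
#'
#' @param prev_cluster_pct group prevalence in the cluster (%)
#' @param prev_population_pct group prevalence in the active population (%)
#' @return the ratio, with attribute `overrepresented`; `NA` when the
#'   population prevalence is zero or missing
#' @export
oe_ratio <- function(prev_cluster_pct, prev_population_pct) {
  r <- ifelse(is.na(prev_population_pct) | prev_population_pct <= 0,
              NA_real_, prev_cluster_pct / prev_population_pct)
  attr(r, "overrepresented") <- !is.na(r) & r > 2
  r
}

#' Exclusivity of a group in a cluster
#'
#' Share (%) of all persons carrying the group who belong to the cluster;
#' values of 30% or more get the complementary salience flag.
#'
#' @param count_in_cluster persons with the group inside the cluster
#' @param count_in_population persons with the group in the whole active
#'   population
#' @return percentage with attribute `exclusive` (>= 30%); `NA` when the
#'   population count is zero
#' @export
exclusivity <- function(count_in_cluster, count_in_population) {
  if (any(count_in_cluster > count_in_population, na.rm = TRUE))
    stop2("cluster count cannot exceed population count")
  e <- ifelse(is.na(count_in_population) | count_in_population <= 0,
              NA_real_, 100 * count_in_cluster / count_in_population)
  attr(e, "exclusive") <- !is.na(e) & e >= 30
  e
}

#' Prevalence of a group within a pattern at a wave
#'
#' @param features feature table (person_id, wave, group indicator columns)
#' @param decoding decoded trajectories (see [decode_trajectories()])
#' @param k pattern index
#' @param g group column name
#' @param t wave
#' @return percentage of pattern-k members at wave t carrying group g;
#'   `NA` if the pattern is empty at that wave
#' @export
pattern_prevalence <- function(features, decoding, k, g, t) {
  dk <- decoding[decoding$wave == t & decoding$state == k, "person_id"]
  if (!length(dk)) return(NA_real_)
  rows <- features[features$wave == t & features$person_id %in% dk, g]
  100 * mean(rows)
}

#' Per-pattern group statistics at one wave
#'
#' Computes, for every (pattern, group) pair at wave `t`: prevalence in the
#' pattern, prevalence in the whole active population, O/E ratio,
#' exclusivity, and the overrepresentation (O/E > 2) and exclusivity
#' (>= 30%) flags.
#'
#' @inheritParams pattern_prevalence
#' @param t wave index
#' @return data.frame, one row per (pattern, group)
#' @export
group_stats <- function(features, decoding, t) {
  K <- attr(decoding, "K")
  groups <- attr(features, "groups") %||%
    setdiff(names(features), c("person_id", "wave", "age", "sex"))
  ft <- features[features$wave == t, , drop = FALSE]
  dt <- decoding[decoding$wave == t & decoding$state <= K, , drop = FALSE]
  state <- dt$state[match(ft$person_id, dt$person_id)]
  G <- as.matrix(ft[, groups, drop = FALSE])
  pop_count <- colSums(G)
  pop_prev <- 100 * colMeans(G)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    inK <- state == k
    nk <- sum(inK)
    if (nk == 0) {
      out[[k]] <- data.frame(pattern = k, group = groups, n_pattern = 0L,
                             prevalence = NA_real_, population_prevalence = pop_prev,
                             oe = NA_real_, exclusivity = NA_real_,
                             overrepresented = NA, exclusive = NA)
      next
    }
    cnt <- colSums(G[inK, , drop = FALSE])
    prev <- 100 * cnt / nk
    oe <- oe_ratio(prev, pop_prev)
    exc <- exclusivity(cnt, pop_count)
    out[[k]] <- data.frame(pattern = k, group = groups, n_pattern = nk,
                           prevalence = as.numeric(prev),
                           population_prevalence = as.numeric(pop_prev),
                           oe = as.numeric(oe),
                           exclusivity = as.numeric(exc),
                           overrepresented = as.logical(attr(oe, "overrepresented")),
                           exclusive = as.logical(attr(exc, "exclusive")))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$wave <- t
  res
}

#' Empirical transition matrix between decoded patterns
#'
#' Pools consecutive-wave state pairs over all waves (time-homogeneous
#' summary) and row-normalizes; exits are counted into the death/dropout
#' columns at the exit wave. Per-wave-pair matrices are available with
#' `by_wave = TRUE`.
#'
#' @param decoding decoded trajectories (with exit states K+1, K+2)
#' @param by_wave if TRUE, additionally return one matrix per wave pair
#' @return list of class `transition_summary`: `matrix` ((K+2)x(K+2),
#'   row-stochastic with absorbing exit rows), `counts`, `permanence`
#'   (diagonal of the live block, %), and optionally `by_wave`
#' @export
empirical_transitions <- function(decoding, by_wave = FALSE) {
  K <- attr(decoding, "K")
  if (is.null(K)) K <- max(decoding$state) - 2L
  d <- decoding[order(decoding$person_id, decoding$wave), ]
  same <- d$person_id[-1] == d$person_id[-nrow(d)] &
    d$wave[-1] == d$wave[-nrow(d)] + 1
  from <- d$state[-nrow(d)][same]
  to <- d$state[-1][same]
  counts <- matrix(0, K + 2, K + 2)
  tab <- table(factor(from, levels = 1:(K + 2)), factor(to, levels = 1:(K + 2)))
  counts[] <- as.numeric(tab)
  P <- counts
  for (k in seq_len(K)) {
    s <- sum(counts[k, ])
    ## a pattern never observed as origin carries no information: stay put
    P[k, ] <- if (s > 0) counts[k, ] / s else replace(rep(0, K + 2), k, 1)
  }
  P[K + 1, ] <- c(rep(0, K), 1, 0)
  P[K + 2, ] <- c(rep(0, K + 1), 1)
  res <- list(matrix = P, counts = counts,
              permanence = 100 * diag(P)[seq_len(K)], K = K)
  if (by_wave) {
    wv <- d$wave[-nrow(d)][same]
    res$by_wave <- lapply(sort(unique(wv)), function(t) {
      ct <- matrix(0, K + 2, K + 2)
      ct[] <- as.numeric(table(factor(from[wv == t], levels = 1:(K + 2)),
                               factor(to[wv == t], levels = 1:(K + 2))))
      sw <- rowSums(ct)
      ct / ifelse(sw > 0, sw, 1)
    })
  }
  class(res) <- "transition_summary"
  res
}

#' @export
print.transition_summary <- function(x, ...) {
  cat("Empirical transition matrix over", x$K, "patterns + death/dropout\n")
  cat("Permanence (%):", paste(round_half_up(x$permanence, 1), collapse = ", "),
      "\n")
  invisible(x)
}

#' Mortality by baseline pattern
#'
#' Percentage of each pattern's wave-1 members whose trajectory ends in
#' death within the study horizon.
#'
#' @param decoding decoded trajectories
#' @return named numeric vector (% per pattern)
#' @export
mortality_by_pattern <- function(decoding) {
  K <- attr(decoding, "K")
  if (is.null(K)) K <- max(decoding$state) - 2L
  base <- decoding[decoding$wave == 1, c("person_id", "state")]
  died <- decoding$person_id[decoding$state == K + 1]
  out <- numeric(K)
  for (k in seq_len(K)) {
    members <- base$person_id[base$state == k]
    out[k] <- if (length(members)) 100 * mean(members %in% died) else NA_real_
  }
  stats::setNames(out, paste0("pattern_", seq_len(K)))
}

#' Demographic and clinical summary per pattern and wave
#'
#' The cluster-characterization table: size, sex split, median (IQR)
#' chronic-disease and chronic-drug counts, mean (SD) age, polypharmacy and
#' multimorbidity percentages, median (IQR) visits and the deprivation
#' distribution, for each pattern at the requested waves.
#'
#' @param panel the raw cohort panel
#' @param decoding decoded trajectories
#' @param waves waves to summarize (default first and last observed)
#' @param min_packages chronic-use threshold used for the drug counts
#' @return data.frame, one row per (pattern, wave)
#' @export
summarize_patterns <- function(panel, decoding, waves = NULL,
                               min_packages = 3) {
  K <- attr(decoding, "K")
  waves <- waves %||% range(panel$wave[panel$status == "active"])
  med_iqr <- function(x) sprintf("%.1f [%.1f; %.1f]",
                                 stats::median(x),
                                 stats::quantile(x, 0.25),
                                 stats::quantile(x, 0.75))
  out <- list()
  for (t in waves) {
    pt <- panel[panel$wave == t & panel$status == "active", , drop = FALSE]
    dt <- decoding[decoding$wave == t & decoding$state <= K, , drop = FALSE]
    st <- dt$state[match(pt$person_id, dt$person_id)]
    dmat <- as.matrix(pt[, intersect(disease_cols(), names(pt)), drop = FALSE])
    rxf <- chronic_drug_flags(pt[, intersect(drug_cols(), names(pt)),
                                 drop = FALSE], min_packages)
    for (k in seq_len(K)) {
      inK <- which(st == k)
      if (!length(inK)) next
      sub <- pt[inK, ]
      out[[length(out) + 1]] <- data.frame(
        pattern = k, wave = t, n = length(inK),
        pct_female = 100 * mean(sub$sex == "F"),
        pct_male = 100 * mean(sub$sex == "M"),
        diseases_med_iqr = med_iqr(rowSums(dmat[inK, , drop = FALSE])),
        drugs_med_iqr = med_iqr(rowSums(rxf[inK, , drop = FALSE])),
        age_mean = mean(sub$age), age_sd = stats::sd(sub$age),
        pct_polypharmacy = 100 * mean(polypharmacy_flag(rxf[inK, , drop = FALSE])),
        pct_multimorbidity = 100 * mean(multimorbidity_flag(dmat[inK, , drop = FALSE])),
        visits_med_iqr = med_iqr(sub$visits),
        pct_medea_rural = 100 * mean(sub$medea == "R")
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Top groups per pattern ordered by O/E ratio
#'
#' Report-style table: for each pattern at wave `t`, the `top` groups by
#' descending O/E ratio (ties broken by ascending group id), with
#' prevalence, O/E and exclusivity rounded half-up to 2 decimals.
#'
#' @inheritParams group_stats
#' @param top number of groups per pattern (default 20)
#' @return data.frame ordered by (pattern, rank)
#' @export
top_groups <- function(features, decoding, t, top = 20) {
  gs <- group_stats(features, decoding, t)
  gs <- gs[!is.na(gs$oe), ]
  gs <- gs[order(gs$pattern, -gs$oe, gs$group), ]
  gs <- do.call(rbind, lapply(split(gs, gs$pattern), utils::head, top))
  gs$prevalence <- round_half_up(gs$prevalence, 2)
  gs$oe <- round_half_up(gs$oe, 2)
  gs$exclusivity <- round_half_up(gs$exclusivity, 2)
  rownames(gs) <- NULL
  gs
}

#' Sequence-index table of decoded trajectories
#'
#' One row per person: initial pattern and the full state sequence padded
#' to the horizon (death/dropout persist once entered), sorted by initial
#' pattern, then sequence, then person id -- the plot-ready form of a
#' sequence-index figure. Deterministic under row permutations of the
#' input.
#'
#' @param decoding decoded trajectories
#' @param horizon number of waves to pad to (default the maximum observed)
#' @return data.frame `person_id, initial, s1..s<horizon>`
#' @export
sequence_index_export <- function(decoding, horizon = NULL) {
  K <- attr(decoding, "K")
  if (is.null(K)) K <- max(decoding$state) - 2L
  horizon <- horizon %||% max(decoding$wave)
  d <- decoding[order(decoding$person_id, decoding$wave), ]
  sp <- split(d$state, d$person_id)
  ids <- names(sp)
  mat <- t(vapply(sp, function(s) {
    s <- s[seq_len(min(length(s), horizon))]
    c(s, rep(s[length(s)], horizon - length(s)))
  }, numeric(horizon)))
  seq_key <- apply(mat, 1, paste, collapse = "-")
  ord <- order(mat[, 1], seq_key, ids)
  out <- data.frame(person_id = ids[ord], initial = mat[ord, 1])
  colnames(mat) <- paste0("s", seq_len(horizon))
  out <- cbind(out, as.data.frame(mat[ord, , drop = FALSE]))
  rownames(out) <- NULL
  out
}
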