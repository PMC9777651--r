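## Published reference values shipped with the package.

#' Reference summary rows from a published cardiovascular-multimorbidity
#' cohort
#'
#' Small tables of values reported for a large primary-care cohort of
#' 65-99-year-olds with cardiovascular multimorbidity (114,516 persons at
#' baseline, 72,091 completing five yearly waves), used for
#' internal-consistency checks of the pattern statistics: selected
#' pattern/group rows (prevalence, O/E ratio, exclusivity, cluster and
#' population sizes) and whole-cohort counts (deaths, completers,
#' polypharmacy).
#'
#' @return `reference_group_rows()` and `reference_cohort_counts()` each
#'   return a data.frame read from the package's `extdata`
#' @export
reference_group_rows <- function() {
  utils::read.csv(system.file("extdata", "reference_group_rows.csv",
                              package = "mptraj"))
}

#' @rdname reference_group_rows
#' @export
reference_cohort_counts <- function() {
  utils::read.csv(system.file("extdata", "reference_cohort_counts.csv",
                              package = "mptraj"))
}

#' Reconstruct exclusivity from a reported prevalence/O-E table row
#'
#' Given a group's prevalence and O/E ratio inside a cluster, the cluster
#' size and the active population size, recovers the implied carrier counts
#' and recomputes exclusivity: the cluster's carrier count is
#' `prevalence x cluster N`, the population prevalence is
#' `prevalence / OE`, and exclusivity is the cluster share of all
#' carriers.
#'
#' @param prevalence_pct group prevalence in the cluster (%)
#' @param oe group observed/expected ratio in the cluster
#' @param cluster_n cluster size
#' @param population_n active population size
#' @return reconstructed exclusivity (%)
#' @export
reconstruct_exclusivity <- function(prevalence_pct, oe, cluster_n,
                                    population_n) {
  count_cluster <- prevalence_pct / 100 * cluster_n
  pop_prev <- prevalence_pct / oe
  count_population <- pop_prev / 100 * population_n
  as.numeric(exclusivity(count_cluster, count_population))
}
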