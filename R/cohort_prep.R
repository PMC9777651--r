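## Feature construction: chronic-use flags, polypharmacy / multimorbidity
## indicators, disease-drug group mapping and the median-prevalence filter.

#' Chronic drug-use flags from invoice counts
#'
#' A drug category is in chronic use during a wave when three or more
#' packages were invoiced (configurable threshold).
#'
#' @param invoice_counts non-negative integer matrix or data.frame
#'   (person-waves x drug categories)
#' @param min_packages packages needed for chronic use (default 3)
#' @return integer 0/1 matrix of the same shape
#' @export
chronic_drug_flags <- function(invoice_counts, min_packages = 3) {
  x <- as.matrix(invoice_counts)
  if (any(!is.finite(x)) || any(x < 0))
    stop2("invoice counts must be non-negative")
  f <- (x >= min_packages) + 0L
  dimnames(f) <- dimnames(x)
  f
}

#' Polypharmacy indicator
#'
#' Chronic use of five or more distinct drug categories (ATC 4th level).
#'
#' @param drug_flags binary matrix of chronic-use flags (rows = person-waves)
#' @param threshold number of categories defining polypharmacy (default 5)
#' @return integer 0/1 vector, one per row
#' @export
polypharmacy_flag <- function(drug_flags, threshold = 5) {
  m <- as.matrix(drug_flags)
  if (length(m) == 0) return(integer(nrow(m)))
  (rowSums(m) >= threshold) + 0L
}

#' Multimorbidity indicator
#'
#' Presence of two or more chronic diseases from the 60-category list.
#'
#' @param disease_flags binary matrix of disease indicators
#' @param threshold diseases defining multimorbidity (default 2)
#' @return integer 0/1 vector, one per row
#' @export
multimorbidity_flag <- function(disease_flags, threshold = 2) {
  m <- as.matrix(disease_flags)
  if (length(m) == 0) return(integer(nrow(m)))
  (rowSums(m) >= threshold) + 0L
}

#' Baseline-use filter for drug categories
#'
#' Keeps drug categories chronically used by at least `min_fraction` of the
#' population active at wave 1.
#'
#' @param panel a cohort panel (see [generate_cohort()])
#' @param min_fraction minimum baseline chronic-use prevalence (default 0.01)
#' @param min_packages chronic-use package threshold (default 3)
#' @return character vector of retained drug column names
#' @export
baseline_use_filter <- function(panel, min_fraction = 0.01, min_packages = 3) {
  if (nrow(panel) == 0) stop2("no active wave-1 records: empty baseline")
  base <- panel[panel$wave == min(panel$wave) & panel$status == "active", ,
                drop = FALSE]
  if (nrow(base) == 0) stop2("no active wave-1 records: empty baseline")
  rx <- base[, grep("^rx_", names(panel), value = TRUE), drop = FALSE]
  flags <- chronic_drug_flags(rx, min_packages)
  prev <- colMeans(flags)
  names(prev)[prev >= min_fraction]
}

#' Drug-category to disease-category mapping
#'
#' Validates and bundles the mapping used to build disease-drug groups: every
#' drug category maps to at least one disease category (possibly several),
#' and the mapped plus disease-only categories partition the disease list.
#'
#' @param map data.frame with columns `drug_id`, `disease_id`
#' @param disease_only character vector of disease categories with no mapped
#'   drug (treated as diagnosis-only groups)
#' @param diseases full disease-category universe (default the 60 panel
#'   columns)
#' @return object of class `drug_disease_map`
#' @export
drug_disease_map <- function(map, disease_only,
                             diseases = disease_cols()) {
  if (!all(c("drug_id", "disease_id") %in% names(map)))
    stop2("map needs columns drug_id, disease_id")
  map <- map[, c("drug_id", "disease_id")]
  mapped <- sort(unique(map$disease_id))
  if (length(intersect(mapped, disease_only)))
    stop2("categories cannot be both mapped and disease-only: ",
          paste(intersect(mapped, disease_only), collapse = ", "))
  if (!setequal(c(mapped, disease_only), diseases))
    stop2("mapped + disease-only categories must partition the disease list")
  structure(list(map = map, disease_only = sort(disease_only),
                 mapped = mapped, diseases = diseases),
            class = "drug_disease_map")
}

#' Default drug-disease mapping for synthetic cohorts
#'
#' Deterministic mapping in the shape of the real classification: 89 drug
#' categories cover the first 46 disease categories (some diseases have two
#' mapped drugs), and the remaining 14 categories are disease-only.
#'
#' @return a [drug_disease_map()]
#' @export
default_drug_disease_map <- function() {
  dis <- disease_cols()
  drg <- drug_cols()
  target <- dis[c(1:46, 1:43)]          # 89 drugs onto 46 diseases
  drug_disease_map(
    map = data.frame(drug_id = drg, disease_id = target,
                     stringsAsFactors = FALSE),
    disease_only = dis[47:60]
  )
}

#' Read / write a drug-disease mapping
#'
#' CSV with columns `drug_id`, `disease_id`; disease-only categories are a
#' one-id-per-line text file.
#'
#' @param map_path CSV path of drug-to-disease rows
#' @param disease_only_path text file, one disease id per line
#' @return a [drug_disease_map()]
#' @export
read_drug_disease_map <- function(map_path, disease_only_path) {
  map <- utils::read.csv(map_path, stringsAsFactors = FALSE)
  donly <- readLines(disease_only_path)
  donly <- donly[nzchar(trimws(donly))]
  drug_disease_map(map, trimws(donly))
}

#' @rdname read_drug_disease_map
#' @param map a `drug_disease_map`
#' @export
write_drug_disease_map <- function(map, map_path, disease_only_path) {
  utils::write.csv(map$map, map_path, row.names = FALSE)
  writeLines(map$disease_only, disease_only_path)
  invisible(NULL)
}

#' Build disease-drug group indicators
#'
#' For a mapped disease category the group indicator is 1 when the diagnosis
#' flag is 1 AND at least one mapped drug category is in chronic use (rule
#' `"and"`, the default); under rule `"diagnosis_only"` the diagnosis alone
#' suffices. Disease-only categories always use the diagnosis flag.
#'
#' @param disease_flags binary matrix (person-waves x disease categories)
#' @param drug_flags binary chronic-use matrix (person-waves x drug
#'   categories)
#' @param map a [drug_disease_map()]
#' @param rule `"and"` or `"diagnosis_only"`
#' @return integer 0/1 matrix, one column per disease category in `map`
#' @export
map_disease_drug_groups <- function(disease_flags, drug_flags, map,
                                    rule = c("and", "diagnosis_only")) {
  rule <- match.arg(rule)
  disease_flags <- as.matrix(disease_flags)
  drug_flags <- as.matrix(drug_flags)
  unknown <- setdiff(unique(map$map$drug_id), colnames(drug_flags))
  mp <- map$map
  if (length(unknown)) {
    warning("drug categories absent from the data ignored: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    mp <- mp[!(mp$drug_id %in% unknown), ]
  }
  groups <- matrix(0L, nrow(disease_flags), length(map$diseases),
                   dimnames = list(NULL, map$diseases))
  for (g in map$diseases) {
    diag <- disease_flags[, g]
    if (g %in% map$disease_only || rule == "diagnosis_only") {
      groups[, g] <- diag
    } else {
      drugs <- mp$drug_id[mp$disease_id == g]
      anyrx <- if (length(drugs))
        (rowSums(drug_flags[, drugs, drop = FALSE]) > 0) + 0L else 0L
      groups[, g] <- diag * anyrx
    }
  }
  groups
}

#' Median-prevalence filter over follow-up waves
#'
#' Keeps a group when the median across waves of its prevalence (among
#' persons active at each wave) is at least `threshold`.
#'
#' @param groups binary group-indicator matrix for active person-waves
#' @param wave wave index per row
#' @param threshold minimum median prevalence (default 0.02)
#' @return character vector of retained group ids
#' @export
median_prevalence_filter <- function(groups, wave, threshold = 0.02) {
  stopifnot(nrow(groups) == length(wave))
  waves <- sort(unique(wave))
  prev <- sapply(waves, function(t) colMeans(groups[wave == t, , drop = FALSE]))
  med <- apply(as.matrix(prev), 1, stats::median)
  colnames(groups)[med >= threshold]
}

#' Build the analysis feature table
#'
#' Runs the full preparation chain on a raw panel: per-wave chronic-use
#' flags, baseline-use filter on drug categories, disease-drug group
#' construction, median-prevalence filter, and assembly of one row per
#' active person-wave with the retained group indicators plus age and sex.
#'
#' @param panel a cohort panel
#' @param map a [drug_disease_map()]
#' @param min_packages chronic-use package threshold (default 3)
#' @param baseline_use_fraction baseline-use filter fraction (default 0.01)
#' @param median_prevalence_threshold group filter threshold (default 0.02)
#' @param mapped_group_rule `"and"` or `"diagnosis_only"`
#' @return a data.frame (`person_id`, `wave`, `age`, `sex`, retained group
#'   columns in ascending id order) with attributes `groups` (retained ids)
#'   and `drugs_kept` (drug categories passing the baseline filter)
#' @export
build_feature_table <- function(panel, map = default_drug_disease_map(),
                                min_packages = 3,
                                baseline_use_fraction = 0.01,
                                median_prevalence_threshold = 0.02,
                                mapped_group_rule = c("and", "diagnosis_only")) {
  mapped_group_rule <- match.arg(mapped_group_rule)
  if (anyDuplicated(panel[, c("person_id", "wave")]))
    stop2("duplicate (person_id, wave) rows in panel")
  act <- panel[panel$status == "active", , drop = FALSE]
  drugs_kept <- baseline_use_filter(panel, baseline_use_fraction, min_packages)
  rx <- as.matrix(act[, intersect(drug_cols(), names(act)), drop = FALSE])
  flags <- chronic_drug_flags(rx[, drugs_kept, drop = FALSE], min_packages)
  dflags <- as.matrix(act[, intersect(disease_cols(), names(act)), drop = FALSE])
  groups <- map_disease_drug_groups(dflags, flags, map, mapped_group_rule)
  kept <- median_prevalence_filter(groups, act$wave,
                                   median_prevalence_threshold)
  kept <- sort(kept)
  out <- data.frame(person_id = act$person_id, wave = act$wave,
                    age = act$age, sex = act$sex, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(groups[, kept, drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "groups") <- kept
  attr(out, "drugs_kept") <- drugs_kept
  out
}
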