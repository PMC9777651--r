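## Synthetic longitudinal cohort with known ground truth.
##
## Emulates a closed cohort of 65-99 year olds followed over yearly waves:
## each person carries a latent multimorbidity-polypharmacy pattern that
## evolves as a first-order Markov chain with absorbing death and dropout
## states; chronic-disease indicators are acquired monotonically and drug
## packages are invoiced with Poisson noise, both with pattern-specific
## profiles.

N_DISEASE <- 60L
N_DRUG <- 89L

disease_cols <- function() sprintf("d_%03d", 1:N_DISEASE)
drug_cols <- function() sprintf("rx_%03d", 1:N_DRUG)

panel_columns <- function() {
  c("person_id", "wave", "status", "age", "sex", "medea", "visits",
    disease_cols(), drug_cols())
}

#' Build a live+absorbing transition matrix
#'
#' Constructs a (K+2)x(K+2) row-stochastic matrix: K live pattern states
#' followed by absorbing death and dropout states. Each live row puts
#' `permanence` on its diagonal, splits `death`/`dropout` mass to the exits
#' and spreads the remainder uniformly over the other live states.
#'
#' @param K number of live pattern states
#' @param permanence probability of staying in the same live pattern
#' @param death,dropout per-wave exit probabilities from any live state
#' @return a (K+2)x(K+2) matrix with rows summing to 1
#' @export
default_transition_matrix <- function(K, permanence = 0.75,
                                      death = 0.08, dropout = 0.02) {
  stopifnot(is_count(K))
  move <- 1 - permanence - death - dropout
  if (move < 0) stop2("permanence + death + dropout must be <= 1")
  A <- matrix(0, K + 2, K + 2)
  for (k in 1:K) {
    A[k, 1:K] <- if (K > 1) move / (K - 1) else 0
    A[k, k] <- permanence + if (K == 1) move else 0
    A[k, K + 1] <- death
    A[k, K + 2] <- dropout
  }
  A[K + 1, K + 1] <- 1
  A[K + 2, K + 2] <- 1
  A
}

#' Configuration of a synthetic cohort
#'
#' Bundles and validates every parameter of the generator. All profile
#' matrices are indexed by latent pattern (rows). The last two states of
#' `transition_matrix` are absorbing death and dropout; wave-1 states are
#' drawn from `initial_distribution` over live patterns only.
#'
#' @param n_individuals cohort size at baseline
#' @param n_waves number of yearly waves (default 5)
#' @param K number of latent patterns
#' @param initial_distribution probability vector over the K patterns
#'   (default uniform)
#' @param transition_matrix (K+2)x(K+2) row-stochastic matrix; defaults to
#'   [default_transition_matrix()]
#' @param disease_profiles K x 60 matrix of baseline Bernoulli prevalences
#' @param drug_profiles K x 89 matrix of per-wave drug-use probabilities
#' @param incidence_factor per-wave onset probability of a not-yet-present
#'   disease, as a fraction of its baseline prevalence
#' @param invoice_rate mean yearly packages invoiced for a used drug category
#' @param sporadic_rate mean yearly packages for a non-used category
#' @param age_mean,age_sd length-K baseline age parameters (years); ages are
#'   truncated to [65, 99]
#' @param sex_prob length-K probability of male sex
#' @param visit_mean length-K mean yearly primary-care visits
#' @param seed integer seed; expanded into per-person substreams
#' @return an object of class `cohort_config`
#' @export
cohort_config <- function(n_individuals, n_waves = 5L, K = 8L,
                          initial_distribution = NULL,
                          transition_matrix = NULL,
                          disease_profiles, drug_profiles,
                          incidence_factor = 0.05,
                          invoice_rate = 6, sporadic_rate = 0.2,
                          age_mean = NULL, age_sd = NULL, sex_prob = NULL,
                          visit_mean = NULL, seed = 1L) {
  if (!is_count(n_individuals)) stop2("n_individuals must be a positive integer")
  if (!is_count(n_waves)) stop2("n_waves must be a positive integer")
  if (!is_count(K)) stop2("K must be a positive integer (K >= 1)")
  K <- as.integer(K)
  initial_distribution <- initial_distribution %||% rep(1 / K, K)
  if (length(initial_distribution) != K || any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-8)
    stop2("initial_distribution must be a length-K probability vector")
  transition_matrix <- transition_matrix %||% default_transition_matrix(K)
  if (!is.matrix(transition_matrix) ||
      any(dim(transition_matrix) != K + 2))
    stop2("transition_matrix must be (K+2)x(K+2)")
  rs <- rowSums(transition_matrix)
  bad <- which(abs(rs - 1) > 1e-12)
  if (length(bad))
    stop2("transition_matrix rows not summing to 1: ",
          paste(bad, collapse = ", "))
  for (s in (K + 1):(K + 2)) {
    if (transition_matrix[s, s] != 1 || any(transition_matrix[s, -s] != 0))
      stop2("row ", s, " (absorbing state) must have 1 on the diagonal")
  }
  check_profile <- function(p, ncol_exp, nm) {
    if (!is.matrix(p) || nrow(p) != K || ncol(p) != ncol_exp)
      stop2(nm, " must be a ", K, "x", ncol_exp, " matrix")
    if (any(p < 0 | p > 1)) stop2(nm, " entries must lie in [0,1]")
    p
  }
  disease_profiles <- check_profile(disease_profiles, N_DISEASE, "disease_profiles")
  drug_profiles <- check_profile(drug_profiles, N_DRUG, "drug_profiles")
  age_mean <- age_mean %||% rep(79, K)
  age_sd <- age_sd %||% rep(7, K)
  sex_prob <- sex_prob %||% rep(0.6, K)
  visit_mean <- visit_mean %||% rep(17, K)
  for (nm in c("age_mean", "age_sd", "sex_prob", "visit_mean")) {
    if (length(get(nm)) != K) stop2(nm, " must have length K")
  }
  structure(list(
    n_individuals = as.integer(n_individuals), n_waves = as.integer(n_waves),
    K = K, initial_distribution = initial_distribution,
    transition_matrix = transition_matrix,
    disease_profiles = disease_profiles, drug_profiles = drug_profiles,
    incidence_factor = incidence_factor, invoice_rate = invoice_rate,
    sporadic_rate = sporadic_rate, age_mean = age_mean, age_sd = age_sd,
    sex_prob = sex_prob, visit_mean = visit_mean, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Example configuration with well-separated planted patterns
#'
#' Convenience constructor emulating the structure of a primary-care cohort
#' of older adults with cardiovascular multimorbidity: each pattern has a
#' set of signature disease categories with high prevalence (planted so
#' their observed/expected ratio exceeds 2) over a common low-prevalence
#' background, drugs mapped to active diseases are used chronically, and 41
#' disease/drug groups are common enough to survive the 2% median-prevalence
#' filter while the remaining 19 are rare.
#'
#' @param n_individuals cohort size
#' @param K number of patterns (default 8)
#' @param n_waves number of waves (default 5)
#' @param seed integer seed
#' @param separation prevalence of a signature disease within its pattern
#' @param background prevalence of common non-signature diseases
#' @param ... passed on to [cohort_config()]
#' @return a `cohort_config`
#' @export
example_cohort_config <- function(n_individuals, K = 8L, n_waves = 5L,
                                  seed = 1L, separation = 0.65,
                                  background = 0.08, ...) {
  K <- as.integer(K)
  map <- default_drug_disease_map()
  common <- common_group_ids()              # 41 groups passing the filter
  rare <- setdiff(1:N_DISEASE, common)
  dp <- matrix(0, K, N_DISEASE)
  dp[, common] <- background
  dp[, rare] <- 0.002
  ## signature blocks: disjoint sets of common diseases per pattern
  sig <- split(common, rep_len(1:K, length(common)))
  for (k in 1:K) dp[k, sig[[k]]] <- separation
  ## drug use tracks the mapped disease's prevalence within each pattern
  rx <- matrix(0.05, K, N_DRUG)
  for (j in 1:N_DRUG) {
    dis <- map$map$disease_id[map$map$drug_id == drug_cols()[j]]
    for (k in 1:K) {
      p <- max(dp[k, match(dis, disease_cols())])
      rx[k, j] <- min(0.95, 0.15 + 1.1 * p)
    }
  }
  cohort_config(
    n_individuals = n_individuals, n_waves = n_waves, K = K,
    disease_profiles = dp, drug_profiles = rx,
    age_mean = seq(74, 84, length.out = K),
    age_sd = rep(6.5, K),
    sex_prob = seq(0.35, 0.85, length.out = K),
    seed = seed, ...
  )
}

## the 41 groups meant to pass the 2% median-prevalence filter in the
## example configuration: 35 mapped disease-drug groups + 6 disease-only
common_group_ids <- function() c(1:35, 47:52)

#' Generate a synthetic cohort panel with ground truth
#'
#' Simulates each person's latent pattern trajectory from the configured
#' Markov chain (absorbing death/dropout), then emits one panel record per
#' wave up to and including the exit wave. Chronic-disease indicators are
#' monotone non-decreasing within a person; drug invoice counts are Poisson
#' draws. Identical seed and configuration reproduce identical output, and
#' each person's records depend only on the seed and their own id.
#'
#' @param config a [cohort_config()]
#' @return a list with `panel` (data.frame, one row per person-wave) and
#'   `truth` (data.frame person_id, wave, true_state with states K+1 = death,
#'   K+2 = dropout, plus the generating config as attribute `config`)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop2("config must be a cohort_config")
  K <- config$K
  A <- config$transition_matrix
  Tn <- config$n_waves
  n <- config$n_individuals
  medea_levels <- c("R", paste0("U", 1:5))
  pid <- wv <- st_code <- age <- visits <- tru <- vector("list", n)
  sex <- medea <- character(n)
  dmat <- rxmat <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i))
    ## latent trajectory (wave 1 always a live pattern)
    states <- integer(Tn)
    states[1] <- sample.int(K, 1, prob = config$initial_distribution)
    if (Tn >= 2) for (t in 2:Tn) {
      prev <- states[t - 1]
      states[t] <- if (prev > K) prev else
        sample.int(K + 2, 1, prob = A[prev, ])
    }
    last <- if (any(states > K)) min(which(states > K)) else Tn
    k1 <- states[1]
    age0 <- round(rtrunc_norm(1, config$age_mean[k1], config$age_sd[k1], 65, 99))
    sex[i] <- if (stats::runif(1) < config$sex_prob[k1]) "M" else "F"
    medea[i] <- sample(medea_levels, 1)
    ## disease acquisition: baseline by pattern profile, then monotone onset
    d <- as.integer(stats::runif(N_DISEASE) < config$disease_profiles[k1, ])
    dm <- matrix(0L, last, N_DISEASE)
    rxm <- matrix(0L, last, N_DRUG)
    vis <- integer(last)
    for (t in seq_len(last)) {
      stt <- states[t]
      if (stt <= K) {
        if (t > 1) {
          onset <- stats::runif(N_DISEASE) <
            config$incidence_factor * config$disease_profiles[stt, ]
          d <- pmax(d, as.integer(onset))
        }
        use <- stats::runif(N_DRUG) < config$drug_profiles[stt, ]
        counts <- integer(N_DRUG)
        counts[use] <- stats::rpois(sum(use), config$invoice_rate)
        counts[!use] <- stats::rpois(sum(!use), config$sporadic_rate)
        vis[t] <- stats::rpois(1, config$visit_mean[stt])
      } else {
        counts <- integer(N_DRUG)  # exit wave: event marker only
        vis[t] <- 0L
      }
      dm[t, ] <- d
      rxm[t, ] <- counts
    }
    pid[[i]] <- rep.int(i, last)
    wv[[i]] <- seq_len(last)
    st_code[[i]] <- states[seq_len(last)]
    age[[i]] <- age0 + seq_len(last) - 1
    visits[[i]] <- vis
    dmat[[i]] <- dm
    rxmat[[i]] <- rxm
    tru[[i]] <- states[seq_len(last)]
  }
  len <- lengths(pid)
  codes <- unlist(st_code)
  status <- c("active", "died", "dropout")[pmin(pmax(codes - K, 0), 2) + 1]
  panel <- data.frame(
    person_id = unlist(pid), wave = unlist(wv), status = status,
    age = unlist(age), sex = rep.int(sex, len), medea = rep.int(medea, len),
    visits = unlist(visits), stringsAsFactors = FALSE
  )
  dall <- do.call(rbind, dmat)
  colnames(dall) <- disease_cols()
  rxall <- do.call(rbind, rxmat)
  colnames(rxall) <- drug_cols()
  panel <- cbind(panel, as.data.frame(dall), as.data.frame(rxall))
  truth <- data.frame(person_id = panel$person_id, wave = panel$wave,
                      true_state = codes)
  attr(truth, "config") <- config
  list(panel = panel, truth = truth)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  for (r in 1:20) {
    out <- x < lo | x > hi
    if (!any(out)) break
    x[out] <- stats::rnorm(sum(out), mean, sd)
  }
  pmin(pmax(x, lo), hi)
}

#' Write / read a cohort panel as CSV
#'
#' Long format, one row per person-wave, with the documented column set
#' (`person_id, wave, status, age, sex, medea, visits, d_001..d_060,
#' rx_001..rx_089`). `read_panel()` validates the header and errors listing
#' any missing mandatory column.
#'
#' @param panel a panel data.frame as produced by [generate_cohort()]
#' @param path file path
#' @return `read_panel()` returns the panel data.frame
#' @export
write_panel <- function(panel, path) {
  miss <- setdiff(panel_columns(), names(panel))
  if (length(miss)) stop2("panel is missing columns: ", paste(miss, collapse = ", "))
  utils::write.csv(panel[, panel_columns()], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  miss <- setdiff(panel_columns(), header)
  if (length(miss))
    stop2("panel file is missing mandatory columns: ",
          paste(miss, collapse = ", "))
  cls <- c(person_id = "integer", wave = "integer", status = "character",
           age = "numeric", sex = "character", medea = "character",
           visits = "integer")
  panel <- utils::read.csv(path, check.names = FALSE,
                           colClasses = cls[header[header %in% names(cls)]])
  panel[, panel_columns()]
}

#' Write / read the ground-truth state table
#' @param truth data.frame person_id, wave, true_state
#' @param path file path
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth[, c("person_id", "wave", "true_state")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path, colClasses = c("integer", "integer", "integer"))
}
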