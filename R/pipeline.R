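## End-to-end orchestration from a single configuration, with a manifest
## of seeds and output checksums for reproducibility.

#' Run the full pattern-trajectory pipeline
#'
#' Executes synthetic-cohort generation (or panel loading), feature
#' construction, PCAmix, fuzzy c-means, HMM fitting and all summary
#' exports, from one configuration. Every output lands in
#' `config$output_dir` together with a stage log and a manifest recording
#' the configuration, seeds and MD5 checksums; the same configuration and
#' seed reproduce identical checksums.
#'
#' @param config a named list or the path of a YAML/JSON file. Keys:
#'   `input` (either `mode = "synthetic"` with `n_individuals`, optional
#'   `K_true`, `n_waves`, `seed`, or `mode = "panel"` with `panel_path`,
#'   `map_path`, `disease_only_path`); `features` (optional
#'   `min_packages`, `baseline_use_fraction`, `median_prevalence_threshold`,
#'   `mapped_group_rule`); `model` (`K`, optional `m`, `n_restarts`,
#'   `seed`, `fcm_restarts`); `output_dir`.
#' @return the output directory, invisibly; the fitted `mpt` object is
#'   attached as attribute `fit`
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$output_dir %||% stop2("config$output_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  cat("", file = log_path)
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    log_line("start ", name)
    res <- tryCatch(expr, error = function(e)
      stop2("pipeline failed at stage '", name, "': ", conditionMessage(e)))
    log_line("done  ", name)
    res
  }
  input <- config$input %||% stop2("config$input is required")
  fcfg <- config$features %||% list()
  mcfg <- config$model %||% list()
  seed <- mcfg$seed %||% 1L

  loaded <- stage("input", {
    if (identical(input$mode, "synthetic")) {
      cc <- example_cohort_config(
        n_individuals = input$n_individuals %||% stop2("n_individuals required"),
        K = input$K_true %||% 8L, n_waves = input$n_waves %||% 5L,
        seed = input$seed %||% seed)
      gen <- generate_cohort(cc)
      write_ground_truth(gen$truth, file.path(out_dir, "ground_truth.csv"))
      list(panel = gen$panel, map = default_drug_disease_map())
    } else if (identical(input$mode, "panel")) {
      if (is.null(input$map_path) || !file.exists(input$map_path))
        stop2("mapping file missing: ", input$map_path %||% "<unset>")
      list(panel = read_panel(input$panel_path),
           map = read_drug_disease_map(input$map_path,
                                       input$disease_only_path))
    } else stop2("input$mode must be 'synthetic' or 'panel'")
  })

  fit <- stage("fit", mpt_fit(
    loaded$panel, loaded$map,
    K = mcfg$K %||% 8L, m = mcfg$m %||% 2,
    n_restarts = mcfg$n_restarts %||% 100L, seed = seed,
    fcm_restarts = mcfg$fcm_restarts %||% 5L,
    min_packages = fcfg$min_packages %||% 3,
    baseline_use_fraction = fcfg$baseline_use_fraction %||% 0.01,
    median_prevalence_threshold = fcfg$median_prevalence_threshold %||% 0.02,
    mapped_group_rule = fcfg$mapped_group_rule %||% "and"))

  stage("export", {
    utils::write.csv(fit$features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    write_pcamix(fit$pcamix, file.path(out_dir, "pcamix.json"))
    mem <- data.frame(person_id = fit$features$person_id,
                      wave = fit$features$wave)
    mem <- cbind(mem, as.data.frame(fit$clustering$U))
    names(mem)[-(1:2)] <- paste0("u_", seq_len(fit$K))
    utils::write.csv(mem, file.path(out_dir, "memberships.csv"),
                     row.names = FALSE)
    write_hmm(fit$hmm, file.path(out_dir, "hmm.json"))
    utils::write.csv(fit$decoding, file.path(out_dir, "trajectories.csv"),
                     row.names = FALSE)
    utils::write.csv(summarize_patterns(loaded$panel, fit$decoding),
                     file.path(out_dir, "patterns_summary.csv"),
                     row.names = FALSE)
    waves <- sort(unique(fit$features$wave))
    pg <- do.call(rbind, lapply(range(waves), function(t)
      group_stats(fit$features, fit$decoding, t)))
    utils::write.csv(pg, file.path(out_dir, "pattern_groups.csv"),
                     row.names = FALSE)
    tr <- fit$transitions
    tm <- as.data.frame(tr$matrix)
    names(tm) <- c(paste0("pattern_", seq_len(fit$K)), "death", "dropout")
    utils::write.csv(tm, file.path(out_dir, "transitions.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(pattern = seq_len(fit$K),
                                mortality_pct = unname(fit$mortality),
                                permanence_pct = unname(tr$permanence)),
                     file.path(out_dir, "mortality.csv"), row.names = FALSE)
    utils::write.csv(sequence_index_export(fit$decoding),
                     file.path(out_dir, "sequences.csv"), row.names = FALSE)
  })

  stage("manifest", {
    files <- setdiff(list.files(out_dir), c("manifest.json", "log.txt"))
    sums <- tools::md5sum(file.path(out_dir, files))
    names(sums) <- files
    manifest <- list(config = config, seed = seed,
                     package_version = as.character(utils::packageVersion("mptraj")),
                     checksums = as.list(sums))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })
  attr(out_dir, "fit") <- fit
  invisible(out_dir)
}

read_run_config <- function(path) {
  if (!file.exists(path)) stop2("no such config file: ", path)
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Validate a panel file against the expected schema and invariants
#'
#' Checks the column schema, duplicate (person, wave) keys, monotone
#' disease indicators, and that nobody reappears after death or dropout.
#' Returns a machine-readable issue table rather than erroring, so a
#' pipeline can report all problems at once.
#'
#' @param panel_path CSV panel path (or an in-memory panel data.frame)
#' @param map_path optional mapping CSV to validate alongside
#' @param disease_only_path optional disease-only list path
#' @return data.frame with columns `issue`, `person_id`, `wave`, `detail`
#'   (zero rows when clean)
#' @export
validate_panel <- function(panel_path, map_path = NULL,
                           disease_only_path = NULL) {
  issues <- list()
  add <- function(issue, person_id = NA, wave = NA, detail = "")
    issues[[length(issues) + 1]] <<- data.frame(
      issue = issue, person_id = person_id, wave = wave, detail = detail)
  panel <- if (is.data.frame(panel_path)) panel_path else
    tryCatch(read_panel(panel_path), error = function(e) e)
  if (inherits(panel, "error")) {
    add("schema", detail = conditionMessage(panel))
    return(do.call(rbind, issues))
  }
  dup <- duplicated(panel[, c("person_id", "wave")])
  for (i in which(dup))
    add("duplicate_key", panel$person_id[i], panel$wave[i])
  panel <- panel[order(panel$person_id, panel$wave), ]
  dcols <- intersect(disease_cols(), names(panel))
  sp <- split(seq_len(nrow(panel)), panel$person_id)
  for (rows in sp) {
    st <- panel$status[rows]
    ex <- which(st != "active")
    if (length(ex) && min(ex) < length(rows))
      add("absorbing_violation", panel$person_id[rows[1]],
          panel$wave[rows[min(ex)]],
          "records continue after death/dropout")
    if (length(rows) >= 2) {
      d <- as.matrix(panel[rows, dcols])
      drop1 <- which(diff(d) < 0, arr.ind = TRUE)
      if (nrow(drop1))
        add("nonmonotone_disease", panel$person_id[rows[1]],
            panel$wave[rows[drop1[1, 1] + 1]],
            paste("flag reverts in", dcols[drop1[1, 2]]))
    }
  }
  if (!is.null(map_path)) {
    m <- tryCatch(read_drug_disease_map(map_path, disease_only_path),
                  error = function(e) e)
    if (inherits(m, "error")) add("map_schema", detail = conditionMessage(m))
  }
  if (!length(issues))
    return(data.frame(issue = character(), person_id = integer(),
                      wave = integer(), detail = character()))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}
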