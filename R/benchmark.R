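#' Benchmark configuration
#'
#' Assembles and validates the configuration for [run_benchmark()]. Exactly
#' one of `cohort_path` (a cohort file on disk) or `scenario` (a
#' [sim_params()] scenario to simulate) must be given.
#'
#' @param cohort_path Path to a cohort file readable by [read_cohort()].
#' @param scenario Simulation scenario (`"paper_like"`, `"null"`,
#'   `"separable"`).
#' @param n_samples Simulated cohort size (ignored with `cohort_path`).
#' @param sim_seed Seed for the simulation.
#' @param markers Marker columns to benchmark; `NULL` = every panel gene
#'   plus `h_score` when present.
#' @param objectives Training objectives, subset of
#'   `c("youden", "screening")`.
#' @param min_specificity Screening specificity floor; default 0.3.
#' @param reference_labels Reference labels to benchmark against; any of
#'   `"mutation_status"`, `"k1n2_call"`, `"pathway_active_truth"`.
#' @param validation_fraction,split_seed Stratified-split settings (see
#'   [split_cohort()]); ignored when `split_assignment` is given or the
#'   cohort already carries a split.
#' @param split_assignment Optional path to an explicit split-assignment
#'   file (see [apply_split()]).
#' @param k1n2_cutoff `NULL` to consume the published `k1n2_call` column,
#'   or a fixed numeric cutoff on `k1n2_score` (see [k1n2_rule()]).
#' @param n_boot,ci_level,boot_seed Bootstrap settings for the validation
#'   AUC confidence intervals.
#' @return A validated `benchmark_config` list.
#' @export
benchmark_config <- function(cohort_path = NULL, scenario = NULL,
                             n_samples = 348L, sim_seed = 1L,
                             markers = NULL,
                             objectives = c("youden", "screening"),
                             min_specificity = 0.3,
                             reference_labels = c("mutation_status",
                                                  "k1n2_call"),
                             validation_fraction = 0.31, split_seed = 1L,
                             split_assignment = NULL,
                             k1n2_cutoff = NULL,
                             n_boot = 500L, ci_level = 0.95,
                             boot_seed = 1L) {
  if (is.null(cohort_path) == is.null(scenario)) {
    abort("Set exactly one of `cohort_path` or `scenario`.")
  }
  if (!is.numeric(min_specificity) || min_specificity < 0 ||
      min_specificity >= 1) {
    abort("`min_specificity` must be in [0, 1).")
  }
  objectives <- arg_match(objectives, values = c("youden", "screening"),
                          multiple = TRUE)
  reference_labels <- arg_match(
    reference_labels,
    values = c("mutation_status", "k1n2_call", "pathway_active_truth"),
    multiple = TRUE)
  structure(
    list(
      cohort_path = cohort_path, scenario = scenario,
      n_samples = as.integer(n_samples), sim_seed = as.integer(sim_seed),
      markers = markers, objectives = objectives,
      min_specificity = min_specificity,
      reference_labels = reference_labels,
      validation_fraction = validation_fraction,
      split_seed = as.integer(split_seed),
      split_assignment = split_assignment,
      k1n2_cutoff = k1n2_cutoff,
      n_boot = as.integer(n_boot), ci_level = ci_level,
      boot_seed = as.integer(boot_seed)
    ),
    class = "benchmark_config"
  )
}

#' Read a benchmark configuration from YAML
#'
#' @param path YAML file whose keys are [benchmark_config()] arguments.
#' @return A validated `benchmark_config`.
#' @export
read_benchmark_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(benchmark_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(benchmark_config, vals)
}

#' Run the full benchmark pipeline
#'
#' Orchestrates simulate/load, split, train, evaluate and report:
#'
#' 1. load the cohort (or simulate the configured scenario);
#' 2. populate the use/validation split (explicit assignment, pre-existing
#'    column, or seeded stratified split);
#' 3. per reference label, train the suite on the use subset only and
#'    evaluate on the validation subset;
#' 4. compute per-marker validation AUCs with stratified bootstrap CIs;
#' 5. write the results bundle.
#'
#' The bundle (under `output_dir`) contains `reports.tsv` (one row per
#' test x stratum x reference, the analogue of a combined benchmark
#' figure), `auc.tsv`, `rules.json`, `roc.tsv` (validation ROC points for
#' every marker x stratum x reference), `summary.md`, `log.txt`,
#' `manifest.json` (resolved config plus its hash), and, for simulated
#' input, `cohort.tsv` with a `sim_params.yaml` sidecar. All randomness is
#' seeded through the config, so identical configs give byte-identical
#' bundles. Stage failures are logged and isolated; unaffected strata are
#' still written.
#'
#' @param config A [benchmark_config()].
#' @param output_dir Directory to write the bundle to (created if absent).
#' @return Invisibly, a list with `cohort`, `suites`, `reports`, `auc` and
#'   `output_dir`.
#' @export
run_benchmark <- function(config, output_dir) {
  if (!inherits(config, "benchmark_config")) {
    abort("`config` must come from benchmark_config().")
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    invisible(NULL)
  }

  # --- input stage ---------------------------------------------------------
  if (!is.null(config$scenario)) {
    params <- sim_params(config$scenario, n_samples = config$n_samples,
                         seed = config$sim_seed)
    cohort <- simulate_cohort(params)
    write_cohort(cohort, file.path(output_dir, "cohort.tsv"))
    write_sim_params(params, file.path(output_dir, "sim_params.yaml"))
    note("input: simulated scenario '", config$scenario, "', n = ",
         nrow(cohort), ", seed ", config$sim_seed)
  } else {
    cohort <- read_cohort(config$cohort_path)
    note("input: read ", nrow(cohort), " samples from ", config$cohort_path)
  }

  # --- split stage ---------------------------------------------------------
  if (!is.null(config$split_assignment)) {
    cohort <- apply_split(cohort, config$split_assignment)
    note("split: explicit assignment file")
  } else if (!"split_group" %in% names(cohort) ||
             all(is.na(cohort$split_group))) {
    cohort <- split_cohort(cohort,
                           validation_fraction = config$validation_fraction,
                           seed = config$split_seed)
    note("split: stratified, validation fraction ",
         config$validation_fraction, ", seed ", config$split_seed)
  } else {
    note("split: taken from the cohort file")
  }
  note("split sizes: use = ",
       sum(cohort$split_group == "use", na.rm = TRUE), ", validation = ",
       sum(cohort$split_group == "validation", na.rm = TRUE))

  markers <- config$markers %||%
    c(cohort_panel(cohort),
      if ("h_score" %in% names(cohort)) "h_score")
  validator <- k1n2_rule(config$k1n2_cutoff)

  # --- train + evaluate per reference label --------------------------------
  suites <- list()
  reports <- list()
  aucs <- list()
  rocs <- list()
  for (ref in config$reference_labels) {
    stage <- tryCatch({
      # direction-mismatch diagnostics go to the run log, not the console
      suite <- withCallingHandlers(
        train_test_suite(
          cohort, markers, objectives = config$objectives, reference = ref,
          min_specificity = config$min_specificity, validator = validator),
        keapscreen_direction_mismatch = function(w) {
          note("train [", ref, "]: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      for (bad in which(suite$status == "error")) {
        note("train [", ref, "] ", suite$stratum[bad], "/",
             suite$marker[bad], "/", suite$objective[bad], ": ",
             suite$message[bad])
      }
      rep <- evaluate_suite(cohort, suite, reference = ref)
      rep$reference_label <- ref
      if ("message" %in% names(rep)) {
        for (bad in which(rep$status == "error")) {
          note("evaluate [", ref, "] ", rep$stratum[bad], "/",
               rep$marker[bad], ": ", rep$message[bad])
        }
      }
      list(suite = suite, report = rep)
    }, error = function(e) e)
    if (inherits(stage, "error")) {
      note("stage failed [reference ", ref, "]: ", conditionMessage(stage))
      next
    }
    suites[[ref]] <- stage$suite
    reports[[ref]] <- stage$report
    aucs[[ref]] <- benchmark_aucs(cohort, markers, ref, config, note)
    rocs[[ref]] <- benchmark_rocs(cohort, markers, ref, note)
  }
  reports <- list_rbind(reports)
  aucs <- list_rbind(aucs)
  rocs <- list_rbind(rocs)

  # --- write bundle --------------------------------------------------------
  readr::write_tsv(reports, file.path(output_dir, "reports.tsv"), na = "")
  readr::write_tsv(aucs, file.path(output_dir, "auc.tsv"), na = "")
  readr::write_tsv(rocs, file.path(output_dir, "roc.tsv"), na = "")
  write_rules_json(suites, file.path(output_dir, "rules.json"))
  cfg <- unclass(config)
  manifest <- list(
    package = "keapscreen",
    version = as.character(utils::packageVersion("keapscreen")),
    config = cfg,
    config_hash = rlang::hash(cfg),
    n_samples = nrow(cohort),
    stratum_counts = as.list(table(paste(cohort$histology,
                                         cohort$split_group, sep = "/")))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  summary_md <- report_summary(output_dir, write = FALSE)
  writeLines(summary_md, file.path(output_dir, "summary.md"))
  writeLines(log_lines, file.path(output_dir, "log.txt"))
  invisible(list(cohort = cohort, suites = suites, reports = reports,
                 auc = aucs, output_dir = output_dir))
}

# validation AUC + bootstrap CI per marker x stratum for one reference
benchmark_aucs <- function(cohort, markers, ref, config, note) {
  grid <- tidyr::expand_grid(stratum = c("LUAD", "LUSC", "pooled"),
                             marker = markers)
  rows <- pmap(grid, function(stratum, marker) {
    d <- subset_cohort(
      cohort, histology = if (stratum == "pooled") NULL else stratum,
      split_group = "validation")
    d$..score <- marker_scores(d, marker)
    d$..label <- reference_label(d, ref)
    d <- d[!is.na(d$..score) & !is.na(d$..label), , drop = FALSE]
    ci <- tryCatch(
      roc_auc_ci(d, .data$..score, .data$..label, n_boot = config$n_boot,
                 level = config$ci_level, seed = config$boot_seed),
      error = function(e) e)
    if (inherits(ci, "error")) {
      note("auc [", ref, "] ", stratum, "/", marker, ": ",
           conditionMessage(ci))
      return(NULL)
    }
    dplyr::bind_cols(
      tibble(reference_label = ref, stratum = stratum, marker = marker,
             n = nrow(d)),
      ci)
  })
  list_rbind(keep(rows, ~ !is.null(.x)))
}

# validation ROC points per marker x stratum for one reference
benchmark_rocs <- function(cohort, markers, ref, note) {
  grid <- tidyr::expand_grid(stratum = c("LUAD", "LUSC", "pooled"),
                             marker = markers)
  rows <- pmap(grid, function(stratum, marker) {
    d <- subset_cohort(
      cohort, histology = if (stratum == "pooled") NULL else stratum,
      split_group = "validation")
    d$..score <- marker_scores(d, marker)
    d$..label <- reference_label(d, ref)
    d <- d[!is.na(d$..score) & !is.na(d$..label), , drop = FALSE]
    rc <- tryCatch(roc_curve(d, .data$..score, .data$..label),
                   error = function(e) e)
    if (inherits(rc, "error")) {
      note("roc [", ref, "] ", stratum, "/", marker, ": ",
           conditionMessage(rc))
      return(NULL)
    }
    tibble(reference_label = ref, stratum = stratum, marker = marker,
           cutpoint = rc$cutpoint, fpr = rc$fpr, tpr = rc$tpr)
  })
  list_rbind(keep(rows, ~ !is.null(.x)))
}

write_rules_json <- function(suites, path) {
  serial <- imap(suites, function(suite, ref) {
    pmap(
      list(suite$marker, suite$stratum, suite$objective, suite$type,
           suite$status, suite$rule),
      function(marker, stratum, objective, type, status, rule) {
        out <- list(reference_label = ref, marker = marker,
                    stratum = stratum, objective = objective, type = type,
                    status = status)
        if (inherits(rule, "combined_rule")) {
          out$screen <- rule_fields(rule$screen)
          out$validator <- rule_fields(rule$validator)
        } else if (inherits(rule, "test_rule")) {
          out <- c(out, rule_fields(rule))
        }
        out
      })
  })
  jsonlite::write_json(serial, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

rule_fields <- function(rule) {
  list(marker = rule$marker,
       cutpoint = if (is.infinite(rule$cutpoint))
         as.character(rule$cutpoint) else rule$cutpoint,
       direction = rule$direction)
}

#' Summarize a results bundle
#'
#' Renders the benchmark reports as a human-readable markdown table (one
#' row per test x stratum x reference with sensitivity, specificity,
#' Youden's J and, for two-stage tests, the K1N2-testing reduction); every
#' number is read back from `reports.tsv`, never recomputed.
#'
#' @param output_dir Bundle directory written by [run_benchmark()].
#' @param write If `TRUE`, also (re)write `summary.md` in the bundle.
#' @return Character vector of markdown lines, invisibly.
#' @export
report_summary <- function(output_dir, write = FALSE) {
  path <- file.path(output_dir, "reports.tsv")
  if (!file.exists(path)) {
    abort(paste0("No reports.tsv in ", output_dir,
                 "; is this a results bundle?"))
  }
  rep <- readr::read_tsv(path, na = "", show_col_types = FALSE,
                         progress = FALSE)
  lines <- c("# Benchmark summary", "")
  ok <- rep[!is.na(rep$status) & rep$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0) {
    lines <- c(lines, "Zero tests were evaluated (all strata failed).")
  } else {
    show <- ok[is.na(ok$stage) | ok$stage != "screen", , drop = FALSE]
    fmt <- function(x) ifelse(is.na(x), "", sprintf("%.3f", x))
    lines <- c(
      lines,
      paste("| reference | stratum | test | objective | type | sens |",
            "spec | J | K1N2 reduction |"),
      "|---|---|---|---|---|---|---|---|---|",
      sprintf("| %s | %s | %s | %s | %s | %s | %s | %s | %s |",
              show$reference_label, show$stratum, show$marker,
              show$objective, show$type, fmt(show$sensitivity),
              fmt(show$specificity), fmt(show$youden_j),
              fmt(show$k1n2_reduction))
    )
  }
  if (write) writeLines(lines, file.path(output_dir, "summary.md"))
  invisible(lines)
}
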