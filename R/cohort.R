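#' Cohort tables
#'
#' A cohort is an ordinary tibble with one row per tumor sample. Required
#' columns are `sample_id` (unique identifier), `histology` (`"LUAD"` or
#' `"LUSC"`) and `mutation_status` (`"KEAP1mut"`, `"NFE2L2mut"` or `"WT"`).
#' Optional columns are `h_score` (integer 0--300, NQO1 immunohistochemistry),
#' `k1n2_score` (continuous 46-gene signature score, consumed as given),
#' `k1n2_call` (its published binary pathway call), `pathway_active_truth`
#' (latent truth, synthetic cohorts only) and `split_group` (`"use"` /
#' `"validation"`). Every remaining numeric column is treated as a normalized
#' log-scale expression value for one marker gene; the gene panel is recorded
#' in the `"panel"` attribute and re-inferred from the columns when absent.
#'
#' @name cohort
NULL

.cohort_reserved <- c(
  "sample_id", "histology", "mutation_status", "h_score",
  "k1n2_score", "k1n2_call", "pathway_active_truth", "split_group"
)

.histologies <- c("LUAD", "LUSC")
.mutation_levels <- c("KEAP1mut", "NFE2L2mut", "WT")
.split_levels <- c("use", "validation")

#' Marker gene panel of a cohort
#'
#' @param cohort A cohort tibble (see [cohort]).
#' @return Character vector of panel gene symbols. Uses the `"panel"`
#'   attribute when present, otherwise every numeric column that is not one
#'   of the reserved sample fields.
#' @export
cohort_panel <- function(cohort) {
  panel <- attr(cohort, "panel")
  if (!is.null(panel)) {
    return(panel)
  }
  cand <- setdiff(names(cohort), .cohort_reserved)
  cand[vapply(cohort[cand], is.numeric, logical(1))]
}

#' Validate a cohort table
#'
#' Checks the invariants of the cohort data model: required columns present,
#' unique sample ids, legal histology and mutation values, H-scores integers
#' in \[0, 300\], finite expression values, and legal split labels. Errors
#' name the first offending row.
#'
#' @param cohort A cohort tibble.
#' @param panel Optional character vector of expected panel genes; defaults
#'   to [cohort_panel()].
#' @return The cohort, invisibly, with its `"panel"` attribute set.
#' @export
validate_cohort <- function(cohort, panel = NULL) {
  if (!is.data.frame(cohort)) {
    abort("`cohort` must be a data frame.")
  }
  missing_cols <- setdiff(c("sample_id", "histology", "mutation_status"),
                          names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort is missing required column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  ids <- as.character(cohort$sample_id)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate sample_id: ", dup[1], "."))
  }
  bad <- which(!(cohort$histology %in% .histologies))
  if (length(bad) > 0) {
    abort(sprintf(
      "Row %d (sample_id %s): histology '%s' is not one of %s.",
      bad[1], ids[bad[1]], as.character(cohort$histology[bad[1]]),
      paste(.histologies, collapse = "/")))
  }
  bad <- which(!(cohort$mutation_status %in% .mutation_levels))
  if (length(bad) > 0) {
    abort(sprintf(
      "Row %d (sample_id %s): mutation_status '%s' is not one of %s.",
      bad[1], ids[bad[1]], as.character(cohort$mutation_status[bad[1]]),
      paste(.mutation_levels, collapse = "/")))
  }
  if ("h_score" %in% names(cohort)) {
    hs <- cohort$h_score
    ok <- is.na(hs) | (is.finite(hs) & hs >= 0 & hs <= 300 & hs == round(hs))
    if (!all(ok)) {
      bad <- which(!ok)[1]
      abort(sprintf(
        "Row %d (sample_id %s): h_score %s is not an integer in [0, 300].",
        bad, ids[bad], format(hs[bad])))
    }
  }
  if ("split_group" %in% names(cohort)) {
    sg <- cohort$split_group
    ok <- is.na(sg) | sg %in% .split_levels
    if (!all(ok)) {
      bad <- which(!ok)[1]
      abort(sprintf(
        "Row %d (sample_id %s): split_group '%s' is not 'use' or 'validation'.",
        bad, ids[bad], as.character(sg[bad])))
    }
  }
  panel <- panel %||% cohort_panel(cohort)
  missing_genes <- setdiff(panel, names(cohort))
  if (length(missing_genes) > 0) {
    abort(paste0("Panel gene column(s) absent from cohort: ",
                 paste(missing_genes, collapse = ", "), "."))
  }
  for (g in panel) {
    v <- cohort[[g]]
    if (!is.numeric(v)) {
      abort(sprintf("Expression column '%s' is not numeric.", g))
    }
    bad <- which(!is.na(v) & !is.finite(v))
    if (length(bad) > 0) {
      abort(sprintf(
        "Row %d (sample_id %s): non-finite expression value for gene %s.",
        bad[1], ids[bad[1]], g))
    }
  }
  attr(cohort, "panel") <- panel
  invisible(cohort)
}

#' Read a cohort file
#'
#' Reads a delimited UTF-8 cohort file (TSV by default, CSV for `.csv`
#' paths or `delim = ","`), one row per sample, empty cells as missing.
#' Column types are coerced to the cohort data model and the table is
#' validated before return.
#'
#' @param path Path to the file.
#' @param delim Field delimiter; default inferred from the file extension
#'   (`","` for `.csv`, otherwise tab).
#' @param panel Optional character vector naming the expression columns;
#'   defaults to every unreserved numeric column.
#' @param col_map Optional named character vector renaming file columns to
#'   the canonical names, e.g. `c(sample_id = "ID")`.
#' @return A validated cohort tibble with the `"panel"` attribute set.
#' @export
read_cohort <- function(path, delim = NULL, panel = NULL, col_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Cohort file not found: ", path))
  }
  delim <- delim %||%
    (if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
  raw <- readr::read_delim(
    path, delim = delim, na = "", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_guess())
  )
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      file_col <- col_map[[canon]]
      if (!file_col %in% names(raw)) {
        abort(paste0("col_map column '", file_col, "' not found in file."))
      }
      names(raw)[names(raw) == file_col] <- canon
    }
  }
  raw <- as_cohort_types(raw)
  validate_cohort(raw, panel = panel)
  attr(raw, "panel") <- panel %||% cohort_panel(raw)
  raw
}

# coerce columns read from text into the cohort model's types
as_cohort_types <- function(x) {
  if ("sample_id" %in% names(x)) x$sample_id <- as.character(x$sample_id)
  for (col in c("histology", "mutation_status", "split_group")) {
    if (col %in% names(x)) x[[col]] <- as.character(x[[col]])
  }
  if ("h_score" %in% names(x)) {
    hs <- x$h_score
    if (is.character(hs)) hs <- as.numeric(hs)
    x$h_score <- if (all(is.na(hs) | hs == round(hs))) as.integer(round(hs)) else hs
  }
  for (col in c("k1n2_call", "pathway_active_truth")) {
    if (col %in% names(x)) x[[col]] <- as_binary_call(x[[col]], col)
  }
  as_tibble(x)
}

as_binary_call <- function(v, what) {
  if (is.logical(v)) return(v)
  if (is.numeric(v)) {
    if (!all(is.na(v) | v %in% c(0, 1))) {
      abort(paste0("Column '", what, "' must be binary (0/1 or TRUE/FALSE)."))
    }
    return(v == 1)
  }
  if (is.character(v)) {
    up <- toupper(trimws(v))
    out <- rep(NA, length(v))
    out[up %in% c("TRUE", "T", "1", "YES")] <- TRUE
    out[up %in% c("FALSE", "F", "0", "NO")] <- FALSE
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad) > 0) {
      abort(sprintf("Row %d: column '%s' value '%s' is not a binary call.",
                    bad[1], what, v[bad[1]]))
    }
    return(as.logical(out))
  }
  abort(paste0("Column '", what, "' has unsupported type."))
}

#' Write a cohort file
#'
#' Writes the cohort as delimited text re-readable by [read_cohort()].
#' Missing values are written as empty cells (never 0).
#'
#' @param cohort A validated cohort tibble.
#' @param path Output path.
#' @param delim Field delimiter; default inferred from the extension as in
#'   [read_cohort()].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = NULL) {
  validate_cohort(cohort)
  delim <- delim %||%
    (if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
  out <- as_tibble(cohort)
  for (col in c("k1n2_call", "pathway_active_truth")) {
    if (col %in% names(out)) out[[col]] <- as.logical(out[[col]])
  }
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Collapse mutation status to the binary mutant label
#'
#' KEAP1 and NFE2L2 mutants are pooled as "positive" for classification;
#' the two genes stay separate in the `mutation_status` column for
#' reporting.
#'
#' @param mutation_status Character vector of mutation status values.
#' @return Logical vector, `TRUE` for `KEAP1mut` or `NFE2L2mut`.
#' @export
is_mutant <- function(mutation_status) {
  mutation_status %in% c("KEAP1mut", "NFE2L2mut")
}

#' Resolve the binary reference label of a cohort
#'
#' The benchmark's "positive" class is an explicit parameter, never
#' implicit: either the pooled mutant label, the published K1N2 pathway
#' call, or (synthetic cohorts) the latent pathway-activation truth.
#'
#' @param cohort A cohort tibble.
#' @param reference One of `"mutation_status"`, `"k1n2_call"`,
#'   `"pathway_active_truth"`.
#' @return Logical vector (may contain `NA` where the label is missing).
#' @export
reference_label <- function(cohort,
                            reference = c("mutation_status", "k1n2_call",
                                          "pathway_active_truth")) {
  reference <- arg_match(reference)
  if (reference == "mutation_status") {
    lab <- is_mutant(cohort$mutation_status)
    lab[is.na(cohort$mutation_status)] <- NA
    return(lab)
  }
  if (!reference %in% names(cohort)) {
    abort(paste0("Cohort has no '", reference, "' column."))
  }
  as.logical(cohort[[reference]])
}

#' Stratified use/validation split
#'
#' Assigns every sample to the `use` (training) or `validation` (held-out)
#' group by seeded stratified sampling. Per stratum of size `n`, exactly
#' `round(n * validation_fraction)` samples go to validation. The published
#' cohort split is not re-derivable, so the default is a reproducible
#' stratified split; an explicit assignment can be loaded with
#' [apply_split()] instead.
#'
#' @param cohort A cohort tibble.
#' @param validation_fraction Proportion in (0, 1) assigned to validation;
#'   default 0.31 (108 of 348 samples).
#' @param strata Character vector of stratification fields; `"mutant"`
#'   denotes the pooled mutant-vs-WT label. Default histology x mutant.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return The cohort with a populated `split_group` column.
#' @export
split_cohort <- function(cohort, validation_fraction = 0.31,
                         strata = c("histology", "mutant"), seed = 1L) {
  validate_cohort(cohort)
  if (!is.numeric(validation_fraction) || length(validation_fraction) != 1 ||
      validation_fraction <= 0 || validation_fraction >= 1) {
    abort("`validation_fraction` must be a single number in (0, 1).")
  }
  key <- stratum_key(cohort, strata)
  sizes <- table(key)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    abort(paste0("Stratum '", small[1], "' has fewer than 2 samples."))
  }
  split_group <- rep("use", nrow(cohort))
  withr::with_seed(seed, {
    for (s in names(sizes)) {
      idx <- which(key == s)
      k <- round(length(idx) * validation_fraction)
      if (k > 0) {
        split_group[sample(idx, k)] <- "validation"
      }
    }
  })
  cohort$split_group <- split_group
  attr(cohort, "panel") <- cohort_panel(cohort)
  cohort
}

stratum_key <- function(cohort, strata) {
  parts <- lapply(strata, function(s) {
    if (s == "mutant") {
      if_else(is_mutant(cohort$mutation_status), "mutant", "WT")
    } else if (s %in% names(cohort)) {
      as.character(cohort[[s]])
    } else {
      abort(paste0("Unknown stratum field: ", s))
    }
  })
  if (length(parts) == 0) {
    return(rep("all", nrow(cohort)))
  }
  do.call(paste, c(parts, sep = "/"))
}

#' Apply an explicit split assignment
#'
#' @param cohort A cohort tibble.
#' @param assignment Either a path to a two-column delimited file
#'   (`sample_id`, `group`) or a data frame with those columns; `group`
#'   values must be `use` or `validation`.
#' @return The cohort with `split_group` set from the assignment; samples
#'   absent from the assignment get `NA`.
#' @export
apply_split <- function(cohort, assignment) {
  validate_cohort(cohort)
  if (is.character(assignment) && length(assignment) == 1) {
    delim <- if (grepl("\\.csv$", assignment, ignore.case = TRUE)) "," else "\t"
    assignment <- readr::read_delim(assignment, delim = delim, na = "",
                                    show_col_types = FALSE, progress = FALSE)
  }
  if (!all(c("sample_id", "group") %in% names(assignment))) {
    abort("Split assignment needs columns 'sample_id' and 'group'.")
  }
  assignment$sample_id <- as.character(assignment$sample_id)
  bad <- setdiff(assignment$sample_id, cohort$sample_id)
  if (length(bad) > 0) {
    abort(paste0("Split assignment refers to unknown sample_id: ", bad[1], "."))
  }
  if (anyDuplicated(assignment$sample_id)) {
    abort("Split assignment has duplicated sample_id entries.")
  }
  if (!all(assignment$group %in% .split_levels)) {
    abort("Split assignment group values must be 'use' or 'validation'.")
  }
  idx <- match(cohort$sample_id, assignment$sample_id)
  cohort$split_group <- assignment$group[idx]
  attr(cohort, "panel") <- cohort_panel(cohort)
  cohort
}

#' Subset a cohort by histology and/or split group
#'
#' With no filters this is the identity. Histology-specific tests are
#' trained and assessed on the matching histology subset only.
#'
#' @param cohort A cohort tibble.
#' @param histology Optional, `"LUAD"` or `"LUSC"`.
#' @param split_group Optional, `"use"` or `"validation"`.
#' @return The filtered cohort tibble (panel attribute preserved).
#' @export
subset_cohort <- function(cohort, histology = NULL, split_group = NULL) {
  panel <- cohort_panel(cohort)
  out <- cohort
  if (!is.null(histology)) {
    histology <- arg_match(histology, .histologies)
    out <- out[out$histology == histology, , drop = FALSE]
  }
  if (!is.null(split_group)) {
    split_group <- arg_match(split_group, .split_levels)
    if (!"split_group" %in% names(out)) {
      abort("Cohort has no split; call split_cohort() or apply_split() first.")
    }
    out <- out[!is.na(out$split_group) & out$split_group == split_group, ,
               drop = FALSE]
  }
  out <- as_tibble(out)
  attr(out, "panel") <- panel
  out
}
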