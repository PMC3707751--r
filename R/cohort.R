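#' Per-patient cohort tables
#'
#' A `cohort_table` is a validated data frame with one row per patient,
#' carrying clinical covariates, two right-censored outcomes (overall
#' survival = time to breast-cancer death, disease-free survival = time to
#' recurrence) and one column of log2 relative expression per panel gene.
#'
#' Required clinical columns: `patient_id`, `os_months`, `os_event`,
#' `dfs_months`, `dfs_event`, `never_disease_free`, `age`, `tumor_size_mm`,
#' `nodes` ("pos"/"neg"), `grade` ("1","2","3-4"), `stage` ("1".."4"),
#' `er_status`, `pr_status` ("+"/"-"), `hormone_therapy`, `chemotherapy`,
#' `radiation` (0/1). Missing values are legal everywhere except
#' `patient_id`, `os_months` and `os_event`; patients flagged
#' `never_disease_free = 1` are excluded from recurrence models (but not from
#' mortality models) by [complete_cases()].
#'
#' @name cohort_table
NULL

.clinical_cols <- c("patient_id", "os_months", "os_event", "dfs_months",
                    "dfs_event", "never_disease_free", "age", "tumor_size_mm",
                    "nodes", "grade", "stage", "er_status", "pr_status",
                    "hormone_therapy", "chemotherapy", "radiation")

#' Construct / validate a cohort table
#'
#' @param data data frame holding the clinical columns and one numeric column
#'   per panel gene.
#' @param panel a [gene_panel()].
#' @return A `cohort_table` (data frame subclass) with a `panel` attribute.
#' @export
cohort_table <- function(data, panel = gene_panel()) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(.clinical_cols, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  missing_genes <- setdiff(unclass(panel), names(data))
  if (length(missing_genes)) {
    stop("missing expression column(s): ", paste(missing_genes, collapse = ", "))
  }
  if (anyDuplicated(data$patient_id)) {
    stop("duplicate patient_id: ",
         paste(unique(data$patient_id[duplicated(data$patient_id)]), collapse = ", "))
  }
  num_cols <- c("os_months", "os_event", "dfs_months", "dfs_event",
                "never_disease_free", "age", "tumor_size_mm",
                "hormone_therapy", "chemotherapy", "radiation", unclass(panel))
  for (cl in num_cols) {
    if (!is.numeric(data[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(data[[cl]])))) &
                     !is.na(data[[cl]]))
      if (length(bad)) {
        stop("non-numeric entry in column '", cl, "' at row ", bad[1])
      }
      data[[cl]] <- as.numeric(as.character(data[[cl]]))
    }
  }
  data$nodes <- factor(as.character(data$nodes), levels = c("pos", "neg"))
  data$grade <- factor(as.character(data$grade), levels = c("1", "2", "3-4"))
  data$stage <- factor(as.character(data$stage), levels = c("1", "2", "3", "4"))
  data$er_status <- factor(as.character(data$er_status), levels = c("+", "-"))
  data$pr_status <- factor(as.character(data$pr_status), levels = c("+", "-"))

  if (any(!is.finite(data$os_months) & data$os_event %in% 1)) {
    stop("os_event = 1 requires finite os_months")
  }
  for (cl in c("os_months", "dfs_months")) {
    if (any(data[[cl]] < 0, na.rm = TRUE)) stop(cl, " must be non-negative")
  }
  for (cl in c("os_event", "dfs_event", "never_disease_free",
               "hormone_therapy", "chemotherapy", "radiation")) {
    if (!all(data[[cl]] %in% c(0, 1, NA))) stop(cl, " must be binary 0/1")
  }
  expr <- as.matrix(data[unclass(panel)])
  if (any(is.infinite(expr))) stop("non-finite expression value")
  structure(data, panel = panel, class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  panel <- attr(x, "panel")
  cat(sprintf("Cohort: %d patients, %d panel genes\n", nrow(x), length(panel)))
  cat(sprintf("  OS events: %d/%d   DFS events: %d (%d missing, %d never disease-free)\n",
              sum(x$os_event == 1, na.rm = TRUE), nrow(x),
              sum(x$dfs_event == 1, na.rm = TRUE),
              sum(is.na(x$dfs_event)),
              sum(x$never_disease_free == 1, na.rm = TRUE)))
  invisible(x)
}

#' Expression matrix of a cohort
#'
#' @param cohort a `cohort_table`.
#' @param genes genes to extract (default: full panel).
#' @return numeric matrix, patients x genes.
#' @export
expression_matrix <- function(cohort, genes = attr(cohort, "panel")) {
  genes <- as.character(genes)
  bad <- setdiff(genes, names(cohort))
  if (length(bad)) stop("genes not in cohort: ", paste(bad, collapse = ", "))
  as.matrix(as.data.frame(cohort)[genes])
}

#' Read a cohort file
#'
#' Reads a tab- or comma-delimited text file (header row required; delimiter
#' auto-detected) into a validated [cohort_table]. Accepted missing-value
#' tokens on input are `NA`, the empty string and `NaN`. An optional JSON
#' sidecar can rename file-specific column names to the standard schema.
#'
#' @param path path to the delimited file.
#' @param panel a [gene_panel()]; gene columns are matched by symbol.
#' @param col_map optional named character vector or path to a JSON file
#'   mapping standard column names to the names used in the file.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path, panel = gene_panel(), col_map = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = c("NA", "", "NaN"),
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    if (is.character(col_map) && length(col_map) == 1L && file.exists(col_map)) {
      col_map <- unlist(jsonlite::read_json(col_map, simplifyVector = TRUE))
    }
    for (std in names(col_map)) {
      idx <- match(col_map[[std]], names(raw))
      if (!is.na(idx)) names(raw)[idx] <- std
    }
  }
  message(sprintf("read_cohort: %d rows from %s", nrow(raw), path))
  cohort_table(raw, panel = panel)
}

#' Write a cohort file
#'
#' Writes the cohort in the same delimited dialect [read_cohort()] accepts;
#' missing values are emitted as `NA` and numeric values at full (17
#' significant digit) precision so that a read/write cycle round-trips
#' exactly.
#'
#' @param cohort a `cohort_table`.
#' @param path output path.
#' @param sep field delimiter (tab by default).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = "\t") {
  df <- as.data.frame(cohort)
  for (cl in names(df)) {
    if (is.double(df[[cl]])) {
      v <- sprintf("%.17g", df[[cl]])
      v[is.na(df[[cl]])] <- NA
      df[[cl]] <- v
    }
  }
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Log2 relative expression from qPCR cycle thresholds
#'
#' The delta-delta-Ct relative quantification: with a reference transcript
#' (e.g. ACTB) for normalization and a calibrator sample, the log2 relative
#' expression of the target is
#' \deqn{-[(Ct_{target,s} - Ct_{ref,s}) - (Ct_{target,c} - Ct_{ref,c})]}
#' i.e. log2 of \eqn{2^{-\Delta\Delta Ct}}. Provided as an upstream
#' preparation utility; cohort expression columns are consumed already
#' log2-transformed.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_cal,ct_ref_cal cycle
#'   threshold values (vectorized, recycled to common length).
#' @return log2 relative expression.
#' @examples
#' ddct_log2_relative(25, 20, 27, 20)  # +2
#' @export
ddct_log2_relative <- function(ct_target_sample, ct_ref_sample,
                               ct_target_cal, ct_ref_cal) {
  args <- list(ct_target_sample, ct_ref_sample, ct_target_cal, ct_ref_cal)
  if (!all(vapply(args, function(a) all(is.finite(a)), logical(1)))) {
    stop("all Ct values must be finite")
  }
  -((ct_target_sample - ct_ref_sample) - (ct_target_cal - ct_ref_cal))
}

#' Complete-case filtering for one outcome
#'
#' Drops patients missing the outcome time/event or any requested covariate.
#' For the recurrence outcome (`dfs`), patients who were never disease-free
#' are additionally dropped; they remain available for mortality models.
#'
#' @param cohort a `cohort_table`.
#' @param outcome `"os"` or `"dfs"`.
#' @param covariates character vector of column names that must be non-missing
#'   (may be empty).
#' @param quiet suppress the per-reason drop-count message.
#' @return The filtered `cohort_table`.
#' @export
complete_cases <- function(cohort, outcome = c("os", "dfs"),
                           covariates = character(), quiet = FALSE) {
  outcome <- match.arg(outcome)
  covariates <- as.character(covariates)
  bad <- setdiff(covariates, names(cohort))
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  tcol <- paste0(outcome, "_months")
  ecol <- paste0(outcome, "_event")
  drop_outcome <- is.na(cohort[[tcol]]) | is.na(cohort[[ecol]])
  drop_ndf <- if (outcome == "dfs") cohort$never_disease_free %in% 1 else rep(FALSE, nrow(cohort))
  drop_cov <- rep(FALSE, nrow(cohort))
  for (cl in covariates) drop_cov <- drop_cov | is.na(cohort[[cl]])
  keep <- !(drop_outcome | drop_ndf | drop_cov)
  if (!quiet) {
    message(sprintf(
      "complete_cases(%s): kept %d/%d (dropped %d missing outcome, %d never disease-free, %d missing covariates)",
      outcome, sum(keep), nrow(cohort), sum(drop_outcome),
      sum(drop_ndf & !drop_outcome), sum(drop_cov & !drop_outcome & !drop_ndf)))
  }
  if (!any(keep)) stop("no complete cases")
  out <- cohort[keep, , drop = FALSE]
  attr(out, "panel") <- attr(cohort, "panel")
  class(out) <- class(cohort)
  out
}
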