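#' Pipeline configuration
#'
#' `run_pipeline()` accepts a plain named list or a path to a JSON file with
#' the same keys: `out_dir` (required), `seed`, `outcome`, `stages` (subset
#' of simulate, screen, select, evaluate, diagnose), `input` (path to an
#' existing cohort file; omitted = simulate one), `sim` (overrides passed to
#' [sim_config()]), `n_splits`, `n_perm`, `gene_set`, `clinical_vars`.
#'
#' @name pipeline_config
NULL

.config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.pipeline_defaults <- function(config) {
  defaults <- list(seed = 1L, outcome = "os",
                   stages = c("simulate", "screen", "select", "evaluate", "diagnose"),
                   input = NULL, sim = list(), n_splits = 100L, n_perm = NULL,
                   gene_set = NULL, clinical_vars = c("stage3", "er", "pr"))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.null(config$n_perm)) config$n_perm <- config$n_splits
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  config
}

#' Run the end-to-end discovery pipeline
#'
#' Executes the requested stages — cohort simulation (or ingestion),
#' univariate screening, stability selection, model comparison and
#' diagnostics — writing delimited tables and JSON summaries under
#' `config$out_dir`, plus a manifest recording every file, the seed, a
#' config hash and per-stage counts. Stage errors yield a nonzero status
#' with partial outputs preserved and the failure point recorded in the
#' manifest.
#'
#' @param config named list or path to a JSON configuration (see
#'   [pipeline_config]).
#' @return list with `status` (0 = success), `manifest` (parsed), and
#'   `manifest_path`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  config <- .pipeline_defaults(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, config_hash = .config_hash(config),
                   stages = list(), files = character(), status = 0,
                   failed_stage = NULL)
  outcome <- match.arg(config$outcome, c("os", "dfs"))
  seed <- as.integer(config$seed)
  emit <- function(name) {
    manifest$files <<- c(manifest$files, name)
    file.path(out_dir, name)
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  fail <- function(stage, e) {
    manifest$status <<- 1
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    write_manifest()
  }

  cohort <- NULL
  run_stage <- function(stage, fun) {
    if (manifest$status != 0) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      message("stage '", stage, "' failed: ", conditionMessage(e))
      fail(stage, e)
    })
  }

  run_stage("input", function() {
    if (!is.null(config$input)) {
      if (!file.exists(config$input)) stop("input file not found: ", config$input)
      cohort <<- read_cohort(config$input)
      manifest$stages$input <<- list(n_patients = nrow(cohort))
    } else if ("simulate" %in% config$stages) {
      cfg <- do.call(sim_config, c(config$sim, list(seed = seed)))
      cohort <<- generate_cohort(cfg)
      write_cohort(cohort, emit("cohort.tsv"))
      manifest$stages$simulate <<- list(
        n_patients = nrow(cohort),
        os_events = sum(cohort$os_event == 1, na.rm = TRUE),
        dfs_events = sum(cohort$dfs_event == 1, na.rm = TRUE))
    } else {
      stop("no input file and no simulate stage")
    }
  })

  if ("screen" %in% config$stages) run_stage("screen", function() {
    scr <- univariate_screen(cohort, outcome)
    utils::write.table(as.data.frame(scr), emit(paste0("screen_", outcome, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gene_hits <- scr$variable[scr$class == "gene" & scr$p_adj < 0.05]
    jsonlite::write_json(
      list(outcome = outcome, n_gene_rows = sum(scr$class == "gene"),
           n_clinical_rows = sum(scr$class == "clinical"),
           genes_fdr_significant = gene_hits),
      emit("screen_summary.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages$screen <<- list(rows = nrow(scr),
                                    genes_significant = length(gene_hits))
  })

  profile <- NULL
  if ("select" %in% config$stages) run_stage("select", function() {
    profile <<- stability_selection(cohort, outcome,
                                    n_splits = config$n_splits,
                                    n_perm = config$n_perm,
                                    master_seed = seed)
    utils::write.table(
      data.frame(gene = names(profile$counts), count = unname(profile$counts),
                 pct = unname(profile$pct)),
      emit("selection_counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      as.data.frame(profile$permutation$count_matrix),
      emit("permutation_counts.tsv"), sep = "\t", quote = FALSE, row.names = TRUE)
    coef_long <- do.call(rbind, lapply(seq_along(profile$coefficients), function(i) {
      cf <- profile$coefficients[[i]]
      if (is.null(cf) || !length(cf)) return(NULL)
      data.frame(split = i, gene = names(cf), coef = unname(cf))
    }))
    if (!is.null(coef_long)) {
      utils::write.table(coef_long, emit("selection_coefficients.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      list(outcome = outcome, n_splits = profile$n_splits,
           threshold = profile$threshold,
           threshold_pct = 100 * profile$threshold / profile$permutation$n_perm,
           significant = profile$significant,
           ambiguous_sign = profile$ambiguous_sign,
           signature = profile$signature, seed = seed),
      emit("select_summary.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages$select <<- list(n_splits = profile$n_splits,
                                    threshold = profile$threshold,
                                    signature = profile$signature)
  })

  if ("evaluate" %in% config$stages) run_stage("evaluate", function() {
    gene_set <- config$gene_set
    if (is.null(gene_set) && !is.null(profile) && length(profile$signature)) {
      gene_set <- profile$signature
    }
    ev <- compare_models(cohort, outcome, gene_set = gene_set,
                         clinical_vars = config$clinical_vars,
                         n_splits = config$n_splits, master_seed = seed)
    utils::write.table(ev$splits, emit("evaluate_splits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ev$km)) {
      utils::write.table(ev$km, emit("evaluate_km.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      list(outcome = outcome, gene_set = ev$gene_set,
           summary = ev$summary, differences = ev$differences, seed = seed),
      emit("evaluate_summary.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages$evaluate <<- list(
      n_splits = nrow(ev$splits), n_failed = ev$n_failed,
      median_c_genes = ev$summary$genes$median,
      median_c_clinical = ev$summary$clinical$median,
      median_c_combined = ev$summary$combined$median)
  })

  if ("diagnose" %in% config$stages) run_stage("diagnose", function() {
    panel <- unclass(attr(cohort, "panel"))
    block <- intersect(c("PGR", "NAT1", "SLC39A6", "ESR1", "TBC1D9"), panel)
    diag <- list(detectable_hr = detectable_hr(power_params()))
    if ("LRBA" %in% panel && length(block) >= 1) {
      rc <- residual_cox(cohort, "LRBA", block, outcome)
      hr <- hazard_ratios(rc)
      diag$lrba_residual <- list(hr = hr$hr[1], ci = c(hr$lower[1], hr$upper[1]),
                                 p = rc$p_value[[1]])
      marg <- fit_cox(expression_matrix(complete_cases(cohort, outcome, quiet = TRUE),
                                        "LRBA"),
                      complete_cases(cohort, outcome, quiet = TRUE)[[paste0(outcome, "_months")]],
                      complete_cases(cohort, outcome, quiet = TRUE)[[paste0(outcome, "_event")]])
      diag$lrba_marginal_hr <- unname(exp(stats::coef(marg)[1]))
    }
    jsonlite::write_json(diag, emit("diagnostics.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages$diagnose <<- list(done = TRUE)
  })

  write_manifest()
  manifest$files <- c(manifest$files, "manifest.json")
  invisible(list(status = manifest$status, manifest = manifest,
                 manifest_path = file.path(out_dir, "manifest.json")))
}

#' Render figures and a summary report from pipeline outputs
#'
#' Reads the per-split result files written by [run_pipeline()] and emits a
#' `report.md` plus deterministic figures: test C-index boxplots by model
#' variant (actual data; permuted-run overlays when a `permuted` results
#' directory is given), Kaplan-Meier overlays of the per-split low/high risk
#' classes, and coefficient boxplots for the selected genes. Panels whose
#' stage output is missing are skipped with a notice; numeric result files
#' are never modified.
#'
#' @param results_dir directory holding `run_pipeline()` outputs.
#' @param permuted_dir optional second results directory from a permuted-data
#'   run, overlaid on the Kaplan-Meier figure.
#' @return list with `status` (always 0) and the files written, invisibly.
#' @export
render_report <- function(results_dir, permuted_dir = NULL) {
  written <- character()
  notes <- character()
  rd <- function(name, dir = results_dir) {
    p <- file.path(dir, name)
    if (file.exists(p)) utils::read.table(p, header = TRUE, sep = "\t",
                                          stringsAsFactors = FALSE) else NULL
  }

  splits <- rd("evaluate_splits.tsv")
  if (!is.null(splits)) {
    f <- file.path(results_dir, "c_index_boxplots.pdf")
    grDevices::pdf(f, width = 6, height = 5)
    graphics::boxplot(splits[c("c_genes", "c_clinical", "c_combined")],
                      names = c("genes", "clinical", "combined"),
                      ylab = "test C-index", main = "C-index across splits")
    graphics::abline(h = 0.5, lty = 3)
    grDevices::dev.off()
    written <- c(written, f)
  } else {
    notes <- c(notes, "C-index panel skipped: evaluate_splits.tsv missing")
  }

  km <- rd("evaluate_km.tsv")
  if (!is.null(km)) {
    km_perm <- if (!is.null(permuted_dir)) rd("evaluate_km.tsv", permuted_dir) else NULL
    f <- file.path(results_dir, "km_overlay.pdf")
    grDevices::pdf(f, width = 6, height = 5)
    sub <- km[km$model == "genes", , drop = FALSE]
    graphics::plot(NA, xlim = c(0, max(km$time)), ylim = c(0, 1),
                   xlab = "Months", ylab = "Survival probability",
                   main = "Risk-class KM curves across splits")
    for (s in unique(sub$split)) {
      for (cl in c("low", "high")) {
        cv <- sub[sub$split == s & sub$class == cl, ]
        if (nrow(cv)) {
          graphics::lines(c(0, cv$time), c(1, cv$surv), type = "s",
                          col = grDevices::adjustcolor(if (cl == "low") "blue" else "red", 0.15))
        }
      }
    }
    if (!is.null(km_perm)) {
      subp <- km_perm[km_perm$model == "genes", , drop = FALSE]
      for (s in unique(subp$split)) {
        for (cl in c("low", "high")) {
          cv <- subp[subp$split == s & subp$class == cl, ]
          if (nrow(cv)) {
            graphics::lines(c(0, cv$time), c(1, cv$surv), type = "s",
                            col = grDevices::adjustcolor("grey40", 0.1))
          }
        }
      }
    }
    graphics::legend("bottomleft", legend = c("low risk", "high risk"),
                     col = c("blue", "red"), lty = 1, bty = "n")
    grDevices::dev.off()
    written <- c(written, f)
  } else {
    notes <- c(notes, "KM panel skipped: evaluate_km.tsv missing")
  }

  coefs <- rd("selection_coefficients.tsv")
  if (!is.null(coefs)) {
    f <- file.path(results_dir, "coefficient_boxplots.pdf")
    counts <- sort(table(coefs$gene), decreasing = TRUE)
    top <- names(counts)[seq_len(min(7, length(counts)))]
    grDevices::pdf(f, width = 6, height = 5)
    graphics::boxplot(split(coefs$coef[coefs$gene %in% top],
                            factor(coefs$gene[coefs$gene %in% top], levels = top)),
                      las = 2, ylab = "penalized coefficient",
                      main = "Selected-gene coefficients across splits")
    graphics::abline(h = 0, lty = 3)
    grDevices::dev.off()
    written <- c(written, f)
  } else {
    notes <- c(notes, "coefficient panel skipped: selection_coefficients.tsv missing")
  }

  report <- file.path(results_dir, "report.md")
  lines <- c("# Pipeline report", "")
  if (!length(written)) {
    lines <- c(lines, "No results found in this directory.")
  } else {
    lines <- c(lines, "Figures:", paste0("- ", basename(written)))
    if (!is.null(splits)) {
      med <- vapply(splits[c("c_genes", "c_clinical", "c_combined")],
                    stats::median, numeric(1))
      lines <- c(lines, "",
                 sprintf("Median test C-index: genes %.3f, clinical %.3f, combined %.3f (%d splits).",
                         med[1], med[2], med[3], nrow(splits)))
    }
  }
  if (length(notes)) lines <- c(lines, "", paste0("- ", notes))
  writeLines(lines, report)
  written <- c(written, report)
  invisible(list(status = 0, files = written, notes = notes))
}
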