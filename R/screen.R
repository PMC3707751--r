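#' False-discovery-rate adjustment
#'
#' Step-up FDR adjustment: BH (Benjamini-Hochberg) is `p_(i) * m / i` with a
#' cumulative minimum from the largest p-value, capped at 1; BY
#' (Benjamini-Yekutieli) multiplies BH by \eqn{c(m) = \sum_{i=1}^m 1/i} and
#' remains valid under arbitrary dependence — appropriate for the highly
#' intercorrelated gene-expression tests. Input order is preserved.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` or `"BY"`.
#' @return adjusted p-values, same order as input.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH")  # all 0.04
#' @export
adjust_pvalues <- function(pvals, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = method)
}

# reference-level contrast sets for the clinical screen
.screen_clinical_spec <- function() {
  list(
    age = list(type = "numeric"),
    tumor_size_mm = list(type = "numeric"),
    nodes = list(type = "factor", source = "nodes", levels = c("pos", "neg")),
    hormone_therapy = list(type = "binary"),
    chemotherapy = list(type = "binary"),
    radiation = list(type = "binary"),
    grade = list(type = "factor", source = "grade", levels = c("1", "2", "3-4")),
    stage = list(type = "factor", source = "stage", levels = c("1", "2", "3", "4")),
    er_pr = list(type = "erpr"))
}

.screen_one <- function(cohort, outcome, X, label) {
  tcol <- paste0(outcome, "_months")
  ecol <- paste0(outcome, "_event")
  keep <- stats::complete.cases(X) & !is.na(cohort[[tcol]]) & !is.na(cohort[[ecol]])
  if (outcome == "dfs") keep <- keep & !(cohort$never_disease_free %in% 1)
  Xk <- X[keep, , drop = FALSE]
  if (any(apply(Xk, 2, function(v) max(v) - min(v) == 0))) {
    warning("zero-variance variable skipped: ", label)
    return(NULL)
  }
  t_k <- cohort[[tcol]][keep]
  e_k <- cohort[[ecol]][keep]
  if (sum(e_k == 1) == 0) stop("zero events after filtering for ", label)
  fit <- fit_cox(Xk, t_k, e_k, ties = "efron")
  hr <- hazard_ratios(fit)
  data.frame(variable = label, level = colnames(Xk),
             n = fit$n, events = fit$nevent,
             hr = hr$hr, ci_lower = hr$lower, ci_upper = hr$upper,
             p = fit$p_value, row.names = NULL)
}

#' Univariate Cox screen of genes and clinical covariates
#'
#' Fits one Cox model per variable on that variable's complete cases (so
#' gene rows use every patient with the outcome while clinical rows use the
#' patients with that covariate recorded). Gene hazard ratios are per unit
#' increase in log2 expression, adjusted jointly by Benjamini-Yekutieli;
#' clinical contrasts use the conventional reference levels (stage 1, grade
#' 1, node-positive, ER+/PR+) and are adjusted by Benjamini-Hochberg.
#'
#' @param cohort a `cohort_table`.
#' @param outcome `"os"` or `"dfs"`.
#' @param genes genes to screen (default: full panel).
#' @param clinical_vars which clinical variables to screen (default: the
#'   standard set; `NULL` or empty to skip).
#' @param gene_fdr,clinical_fdr FDR methods per variable class.
#' @return Object of class `screen_table` (data frame): `variable`, `level`,
#'   `class`, `n`, `events`, `hr`, `ci_lower`, `ci_upper`, `p`, `p_adj`,
#'   `outcome`; gene rows sorted by raw p-value.
#' @export
univariate_screen <- function(cohort, outcome = c("os", "dfs"), genes = NULL,
                              clinical_vars = names(.screen_clinical_spec()),
                              gene_fdr = "BY", clinical_fdr = "BH") {
  outcome <- match.arg(outcome)
  if (is.null(genes)) genes <- unclass(attr(cohort, "panel"))

  gene_rows <- list()
  for (g in genes) {
    X <- matrix(as.numeric(cohort[[g]]), ncol = 1, dimnames = list(NULL, g))
    row <- .screen_one(cohort, outcome, X, g)
    if (!is.null(row)) {
      row$class <- "gene"
      gene_rows[[g]] <- row
    }
  }
  gene_tab <- do.call(rbind, gene_rows)
  if (!is.null(gene_tab)) {
    gene_tab$p_adj <- adjust_pvalues(gene_tab$p, gene_fdr)
    gene_tab <- gene_tab[order(gene_tab$p), , drop = FALSE]
  }

  spec <- .screen_clinical_spec()
  clin_rows <- list()
  for (v in clinical_vars) {
    sp <- spec[[v]]
    if (is.null(sp)) stop("unknown clinical variable: ", v)
    X <- switch(sp$type,
      numeric = matrix(as.numeric(cohort[[v]]), ncol = 1, dimnames = list(NULL, v)),
      binary = matrix(as.numeric(cohort[[v]]), ncol = 1,
                      dimnames = list(NULL, paste0(v, "_yes"))),
      factor = {
        src <- as.character(cohort[[sp$source]])
        m <- sapply(sp$levels[-1], function(lv) as.numeric(src == lv))
        m[is.na(src), ] <- NA
        colnames(m) <- paste0(sp$source, "_", sp$levels[-1])
        m
      },
      erpr = {
        joint <- paste0(as.character(cohort$er_status), "/",
                        as.character(cohort$pr_status))
        joint[is.na(cohort$er_status) | is.na(cohort$pr_status)] <- NA
        lv <- c("+/+", "+/-", "-/+", "-/-")
        m <- sapply(lv[-1], function(l) as.numeric(joint == l))
        m[is.na(joint), ] <- NA
        colnames(m) <- paste0("er_pr_", c("pos_neg", "neg_pos", "neg_neg"))
        m
      })
    row <- tryCatch(.screen_one(cohort, outcome, X, v), error = function(e) {
      warning("clinical variable '", v, "' skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(row)) {
      row$class <- "clinical"
      clin_rows[[v]] <- row
    }
  }
  clin_tab <- do.call(rbind, clin_rows)
  if (!is.null(clin_tab)) clin_tab$p_adj <- adjust_pvalues(clin_tab$p, clinical_fdr)

  out <- rbind(gene_tab, clin_tab)
  rownames(out) <- NULL
  out$outcome <- outcome
  structure(out, class = c("screen_table", "data.frame"))
}

#' @export
print.screen_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  cat(sprintf("Univariate Cox screen (%s): %d rows (%d genes, %d clinical contrasts)\n",
              toupper(df$outcome[1]), nrow(df), sum(df$class == "gene"),
              sum(df$class == "clinical")))
  print(utils::head(df[c("variable", "level", "n", "events", "hr",
                         "ci_lower", "ci_upper", "p", "p_adj")], 15))
  if (nrow(df) > 15) cat("  ...", nrow(df) - 15, "more rows\n")
  invisible(x)
}
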