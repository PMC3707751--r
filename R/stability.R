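#' Stage-stratified train/test split
#'
#' Allocates each stratum to training by largest-remainder rounding toward a
#' total training size of `round(fraction * n)`: each stratum starts at
#' `floor(fraction * n_s)` and the remaining slots go to the strata with the
#' largest fractional remainders, so training and test sets are balanced on
#' stratum composition. Missing stratum values form their own stratum; a
#' stratum of size 1 is assigned wholly to training (with a warning).
#'
#' @param cohort a `cohort_table` (or any data frame).
#' @param train_fraction training fraction in (0, 1).
#' @param strata column name to balance on (default `"stage"`).
#' @param seed integer seed; membership is reproducible.
#' @return list with elements `train` and `test` (disjoint, union = cohort).
#' @export
stratified_split <- function(cohort, train_fraction = 0.7, strata = "stage",
                             seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) stop("train_fraction must be in (0,1)")
  if (!strata %in% names(cohort)) stop("strata variable not found: ", strata)
  n <- nrow(cohort)
  g <- as.character(cohort[[strata]])
  g[is.na(g)] <- ".missing"
  levels_g <- sort(unique(g))
  sizes <- vapply(levels_g, function(l) sum(g == l), integer(1))
  target_total <- round(train_fraction * n)

  targets <- train_fraction * sizes
  alloc <- floor(targets)
  remainders <- targets - alloc
  singleton <- sizes == 1L
  if (any(singleton)) {
    warning("stratum of size 1 assigned wholly to training: ",
            paste(levels_g[singleton], collapse = ", "))
    alloc[singleton] <- 1L
    remainders[singleton] <- -Inf
  }
  deficit <- target_total - sum(alloc)
  ord <- order(remainders, decreasing = TRUE)
  k <- 1L
  while (deficit > 0 && k <= length(ord)) {
    s <- ord[k]
    if (!singleton[s] && alloc[s] < sizes[s]) {
      alloc[s] <- alloc[s] + 1L
      deficit <- deficit - 1L
    }
    k <- k + 1L
  }
  ord2 <- order(remainders)
  k <- 1L
  while (deficit < 0 && k <= length(ord2)) {
    s <- ord2[k]
    if (!singleton[s] && alloc[s] > 0L) {
      alloc[s] <- alloc[s] - 1L
      deficit <- deficit + 1L
    }
    k <- k + 1L
  }

  # strata are visited in sorted level order and members sorted by patient id
  # before sampling, so membership depends only on the seed and the patients,
  # not on the row order of the input table
  set.seed(as.integer(seed))
  train_idx <- integer(0)
  for (s in seq_along(levels_g)) {
    idx <- which(g == levels_g[s])
    if (!is.null(cohort$patient_id)) idx <- idx[order(cohort$patient_id[idx])]
    take <- min(alloc[s], length(idx))
    if (take > 0) train_idx <- c(train_idx, idx[sample.int(length(idx), take)])
  }
  train_idx <- sort(train_idx)
  subset_keep <- function(rows) {
    out <- cohort[rows, , drop = FALSE]
    attr(out, "panel") <- attr(cohort, "panel")
    class(out) <- class(cohort)
    out
  }
  list(train = subset_keep(train_idx),
       test = subset_keep(setdiff(seq_len(n), train_idx)))
}

# one split -> CV-tuned LASSO fit -> named vector of nonzero coefficients
.one_lasso_selection <- function(cohort, outcome, genes, split_seed, cv_seed,
                                 train_fraction = 0.7, k_folds = 10L,
                                 nlambda = 50L) {
  tcol <- paste0(outcome, "_months")
  ecol <- paste0(outcome, "_event")
  sp <- stratified_split(cohort, train_fraction = train_fraction,
                         strata = "stage", seed = split_seed)
  train <- sp$train
  if (sum(train[[ecol]] == 1) < 2) stop("fewer than 2 events in training set")
  X <- expression_matrix(train, genes)
  grid <- cox_lambda_grid(X, train[[tcol]], train[[ecol]], nlambda = nlambda)
  cv <- select_lambda_cv(X, train[[tcol]], train[[ecol]], k = k_folds,
                         lambda_seq = grid, seed = cv_seed)
  fit <- fit_cox_lasso(X, train[[tcol]], train[[ecol]], lambda = cv$lambda_opt)
  cf <- stats::coef(fit)
  cf[cf != 0]
}

#' Per-gene selection frequencies across resampling splits
#'
#' For each of `n_splits` stage-stratified 70/30 splits: tune the L1 penalty
#' by 10-fold cross-validation on the training set, fit the penalized Cox
#' model at the chosen penalty, and record which genes keep nonzero
#' coefficients (and their values). A split whose training set has fewer
#' than 2 events, or whose fit fails, is re-drawn once with a derived seed
#' and then skipped with a warning; counts are reported against the splits
#' that succeeded.
#'
#' @param cohort a `cohort_table`.
#' @param outcome `"os"` or `"dfs"`.
#' @param genes genes eligible for selection (default: full panel).
#' @param n_splits number of splits.
#' @param master_seed master seed; all split/CV seeds derive from it via
#'   [child_seed()].
#' @param train_fraction,k_folds,nlambda tuning of the per-split fit.
#' @return Object of class `selection_profile` (no permutation component
#'   yet): per-gene `counts` and `pct`, `coefficients` (per-split named
#'   vectors), `n_splits` (successful), `master_seed`.
#' @export
selection_frequencies <- function(cohort, outcome = c("os", "dfs"),
                                  genes = NULL, n_splits = 1000L,
                                  master_seed = 1L, train_fraction = 0.7,
                                  k_folds = 10L, nlambda = 50L) {
  outcome <- match.arg(outcome)
  if (is.null(genes)) genes <- unclass(attr(cohort, "panel"))
  genes <- as.character(genes)
  cc <- complete_cases(cohort, outcome, quiet = TRUE)
  counts <- stats::setNames(integer(length(genes)), genes)
  coefs <- vector("list", n_splits)
  n_ok <- 0L
  for (i in seq_len(n_splits)) {
    sel <- NULL
    for (attempt in 1:2) {
      sseed <- child_seed(master_seed, if (attempt == 1) 11L else 12L, i)
      cseed <- child_seed(master_seed, 13L, i + (attempt - 1L) * n_splits)
      sel <- tryCatch(
        .one_lasso_selection(cc, outcome, genes, sseed, cseed,
                             train_fraction, k_folds, nlambda),
        error = function(e) NULL)
      if (!is.null(sel)) break
    }
    if (is.null(sel)) {
      warning("split ", i, " failed after re-draw; skipped")
      next
    }
    n_ok <- n_ok + 1L
    coefs[[i]] <- sel
    counts[names(sel)] <- counts[names(sel)] + 1L
  }
  if (n_ok == 0L) stop("all splits failed")
  structure(list(counts = counts, pct = 100 * counts / n_ok,
                 coefficients = coefs, n_splits = n_ok,
                 n_requested = n_splits, outcome = outcome, genes = genes,
                 master_seed = as.integer(master_seed)),
            class = "selection_profile")
}

#' Permutation null for the selection counts
#'
#' Each replicate shuffles the outcome (time, event) pairs across patients
#' ([permute_outcomes()]), performs one stratified split, tunes the penalty
#' by cross-validation and fits the penalized model, recording which genes
#' are retained. The significance threshold is the highest per-gene total
#' count across the permuted replicates; observed genes are declared
#' significant only when their count is *strictly greater* than this
#' threshold.
#'
#' @inheritParams selection_frequencies
#' @param n_perm number of permutation replicates.
#' @return list with `count_matrix` (genes x replicates, 0/1), `counts`
#'   (per-gene totals), `threshold` (max of the totals), `n_perm`
#'   (successful replicates).
#' @export
permutation_null <- function(cohort, outcome = c("os", "dfs"), genes = NULL,
                             n_perm = 1000L, master_seed = 1L,
                             train_fraction = 0.7, k_folds = 10L,
                             nlambda = 50L) {
  outcome <- match.arg(outcome)
  if (is.null(genes)) genes <- unclass(attr(cohort, "panel"))
  genes <- as.character(genes)
  cc <- complete_cases(cohort, outcome, quiet = TRUE)
  mat <- matrix(0L, length(genes), n_perm, dimnames = list(genes, NULL))
  ok <- logical(n_perm)
  for (r in seq_len(n_perm)) {
    perm <- permute_outcomes(cc, outcome, seed = child_seed(master_seed, 14L, r))
    sel <- NULL
    for (attempt in 1:2) {
      sseed <- child_seed(master_seed, if (attempt == 1) 15L else 16L, r)
      cseed <- child_seed(master_seed, 17L, r + (attempt - 1L) * n_perm)
      sel <- tryCatch(
        .one_lasso_selection(perm, outcome, genes, sseed, cseed,
                             train_fraction, k_folds, nlambda),
        error = function(e) NULL)
      if (!is.null(sel)) break
    }
    if (is.null(sel)) {
      warning("permutation replicate ", r, " failed after re-draw; skipped")
      next
    }
    ok[r] <- TRUE
    mat[names(sel), r] <- 1L
  }
  if (!any(ok)) stop("all permutation replicates failed")
  mat <- mat[, ok, drop = FALSE]
  totals <- rowSums(mat)
  list(count_matrix = mat, counts = totals, threshold = max(totals),
       n_perm = ncol(mat))
}

#' Full stability-selection procedure
#'
#' Runs [selection_frequencies()] and [permutation_null()] at matched sizes,
#' derives the significant gene list (observed count strictly above the
#' permutation threshold, ordered by descending selection percentage), and
#' flags genes with ambiguous coefficient signs (neither sign accounts for at
#' least `sign_consistency` of that gene's nonzero coefficients across
#' splits). The final signature is the significant genes minus the
#' sign-ambiguous ones.
#'
#' @inheritParams selection_frequencies
#' @param n_perm permutation replicates (default: `n_splits`, so observed and
#'   null counts are on the same scale).
#' @param sign_consistency minimum fraction of same-sign nonzero coefficients
#'   for a gene to count as sign-consistent (default 0.9).
#' @return A complete `selection_profile` with `permutation` (count matrix,
#'   totals), `threshold`, `significant`, `ambiguous_sign` and `signature`.
#' @export
stability_selection <- function(cohort, outcome = c("os", "dfs"), genes = NULL,
                                n_splits = 1000L, n_perm = n_splits,
                                master_seed = 1L, train_fraction = 0.7,
                                k_folds = 10L, nlambda = 50L,
                                sign_consistency = 0.9) {
  outcome <- match.arg(outcome)
  prof <- selection_frequencies(cohort, outcome, genes, n_splits, master_seed,
                                train_fraction, k_folds, nlambda)
  null <- permutation_null(cohort, outcome, prof$genes, n_perm, master_seed,
                           train_fraction, k_folds, nlambda)
  prof$permutation <- null
  prof$threshold <- null$threshold
  # observed counts and threshold on a common scale when split counts differ
  thr_scaled <- null$threshold * prof$n_splits / null$n_perm
  sig <- names(prof$counts)[prof$counts > thr_scaled]
  sig <- sig[order(prof$counts[sig], decreasing = TRUE)]
  prof$significant <- sig

  sign_share <- vapply(prof$genes, function(g) {
    v <- unlist(lapply(prof$coefficients, function(cf) cf[g]))
    v <- v[!is.na(v) & v != 0]
    if (!length(v)) return(1)
    max(mean(v > 0), mean(v < 0))
  }, numeric(1))
  prof$sign_share <- sign_share
  prof$ambiguous_sign <- intersect(sig, names(sign_share)[sign_share < sign_consistency])
  prof$signature <- setdiff(sig, prof$ambiguous_sign)
  prof
}

#' Significant genes from a selection profile
#'
#' Genes whose observed selection count strictly exceeds the permutation
#' threshold, ordered by descending selection percentage.
#'
#' @param profile a `selection_profile` with a `threshold` component (or a
#'   `threshold` supplied explicitly).
#' @param threshold optional explicit threshold count.
#' @return data frame with columns `gene`, `count`, `pct`.
#' @export
significant_genes <- function(profile, threshold = profile$threshold) {
  if (is.null(threshold)) stop("no threshold available")
  keep <- profile$counts > threshold
  genes <- names(profile$counts)[keep]
  genes <- genes[order(profile$counts[genes], decreasing = TRUE)]
  data.frame(gene = genes, count = unname(profile$counts[genes]),
             pct = unname(profile$pct[genes]))
}

#' @export
print.selection_profile <- function(x, ...) {
  cat(sprintf("Stability selection (%s): %d/%d successful splits\n",
              toupper(x$outcome), x$n_splits, x$n_requested))
  top <- sort(x$pct, decreasing = TRUE)
  top <- top[top > 0]
  show <- utils::head(top, 10)
  cat("  top selections:",
      paste(sprintf("%s (%.1f%%)", names(show), show), collapse = ", "), "\n")
  if (!is.null(x$threshold)) {
    cat(sprintf("  permutation threshold: %d of %d (%.1f%%)\n",
                x$threshold, x$permutation$n_perm,
                100 * x$threshold / x$permutation$n_perm))
    cat("  significant:", if (length(x$significant)) paste(x$significant, collapse = ", ") else "(none)", "\n")
    if (length(x$ambiguous_sign)) {
      cat("  ambiguous sign (dropped from signature):",
          paste(x$ambiguous_sign, collapse = ", "), "\n")
    }
    cat("  signature:", if (length(x$signature)) paste(x$signature, collapse = ", ") else "(none)", "\n")
  }
  invisible(x)
}

#' @export
plot.selection_profile <- function(x, genes = NULL, ...) {
  if (is.null(genes)) {
    genes <- if (length(x$significant)) x$significant else
      names(sort(x$counts, decreasing = TRUE))[seq_len(min(7, length(x$counts)))]
  }
  vals <- lapply(genes, function(g) {
    v <- unlist(lapply(x$coefficients, function(cf) cf[g]))
    v[!is.na(v)]
  })
  names(vals) <- genes
  graphics::boxplot(vals, ylab = "penalized coefficient",
                    main = "Coefficients across training splits", las = 2, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
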