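# Random-forest regression backend and cross-validated prediction power.
#
# The forest itself (src/forest.cpp) follows the classic regression
# conventions: ntree bootstrap trees, mtry = floor(p/3) candidate features per
# node, nodes of <= `nodesize` samples become leaves, impurity importance is
# the per-feature total decrease in node sum of squares averaged over trees.

#' Random forest settings
#'
#' @param ntree number of trees (classic regression default 500).
#' @param mtry features tried per split; `NULL` means `max(1, floor(p/3))`.
#' @param nodesize maximal leaf size (regression default 5).
#' @return a list of settings accepted by the `control` arguments below.
#' @export
rf_control <- function(ntree = 500L, mtry = NULL, nodesize = 5L) {
  stopifnot(ntree >= 1, nodesize >= 1)
  list(ntree = as.integer(ntree), mtry = mtry, nodesize = as.integer(nodesize))
}

rf_fit_predict <- function(Xtr, ytr, Xte, control, seed) {
  mtry <- control$mtry %||% max(1L, floor(ncol(Xtr) / 3))
  .rf_fit_predict(as.matrix(Xtr), as.numeric(ytr), as.matrix(Xte),
                  control$ntree, as.integer(mtry), control$nodesize,
                  as.double(seed))
}

# Evaluate expr with a locally seeded RNG, restoring global state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

make_folds <- function(n, k, seed) {
  stopifnot(k >= 2, n >= k)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

spearman_rho <- function(x, y) cor(x, y, method = "spearman")

rfcv_predict <- function(features, target, folds, control, seed) {
  pred <- numeric(length(target))
  for (f in sort(unique(folds))) {
    te <- folds == f
    fit <- rf_fit_predict(features[!te, , drop = FALSE], target[!te],
                          features[te, , drop = FALSE], control,
                          next_seed(seed, f))
    pred[te] <- fit$predictions
  }
  pred
}

#' Cross-validated random-forest prediction power
#'
#' Fits a regression random forest on the out-of-fold principle over a seeded
#' k-fold partition and returns the Spearman correlation between the measured
#' target and its out-of-fold predictions — the "prediction power" of the
#' feature block for that variable.
#'
#' @param features numeric matrix, samples x features (typically
#'   arcsine-square-root transformed abundances).
#' @param target numeric vector; `NA`s are dropped pairwise (with a message).
#' @param k_folds number of folds (default 5; `k_folds = n` gives
#'   leave-one-out).
#' @param seed integer seed controlling the partition and tree growth.
#' @param control see [rf_control()].
#' @return Spearman rho between measurement and out-of-fold prediction.
#' @export
rfcv_performance <- function(features, target, k_folds = 5L, seed = 1L,
                             control = rf_control()) {
  features <- as.matrix(features)
  keep <- !is.na(target) & complete.cases(features)
  if (!all(keep)) {
    message(sum(!keep), " sample(s) with missing values dropped")
    features <- features[keep, , drop = FALSE]
    target <- target[keep]
  }
  n <- length(target)
  if (n < 4) stop("too few complete samples")
  if (var(target) == 0) stop("constant target: prediction power undefined")
  folds <- make_folds(n, k_folds, seed)
  pred <- rfcv_predict(features, target, folds, control, seed)
  spearman_rho(target, pred)
}

#' Permutation test for random-forest prediction power
#'
#' Recomputes the full cross-validated prediction power under `n_perm`
#' permutations of the target (the fold partition and tree seeds are reused,
#' so label permutation is the only source of variation) and reports the
#' add-one one-sided P value `(1 + #\{rho_perm >= rho_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams rfcv_performance
#' @param n_perm number of permutations (999 for confirmatory runs; smaller
#'   for screening).
#' @param factor_name label carried into the result row.
#' @return one-row data.frame: `factor`, `rho`, `p_perm`, `n_perm`,
#'   `k_folds`, `seed`.
#' @export
permutation_test <- function(features, target, n_perm = 999L, k_folds = 5L,
                             seed = 1L, control = rf_control(),
                             factor_name = "target") {
  if (n_perm < 1) stop("n_perm must be >= 1")
  features <- as.matrix(features)
  keep <- !is.na(target) & complete.cases(features)
  features <- features[keep, , drop = FALSE]
  target <- target[keep]
  n <- length(target)
  if (n < 4) stop("too few complete samples")
  if (var(target) == 0) stop("constant target: prediction power undefined")
  folds <- make_folds(n, k_folds, seed)
  rho_obs <- spearman_rho(target, rfcv_predict(features, target, folds, control, seed))
  perms <- with_seed(next_seed(seed, 1000L),
                     replicate(n_perm, sample.int(n), simplify = FALSE))
  rho_perm <- vapply(perms, function(pm) {
    tp <- target[pm]
    spearman_rho(tp, rfcv_predict(features, tp, folds, control, seed))
  }, numeric(1))
  p <- (1 + sum(rho_perm >= rho_obs)) / (n_perm + 1)
  data.frame(factor = factor_name, rho = rho_obs, p_perm = p,
             n_perm = as.integer(n_perm), k_folds = as.integer(k_folds),
             seed = as.integer(seed), stringsAsFactors = FALSE)
}

#' Rank a family of prediction-power results with BH correction
#'
#' Applies Benjamini-Hochberg step-up across the family of permutation P
#' values and orders factors by prediction power (rho, descending).
#'
#' @param results a list of rows from [permutation_test()] (or a single
#'   rbind-ed data.frame).
#' @return data.frame sorted by `rho` descending with a `q` column.
#' @export
rank_factor_importance <- function(results) {
  if (is.data.frame(results)) res <- results
  else res <- do.call(rbind, results)
  if (!nrow(res)) stop("empty result list")
  res$q <- p.adjust(res$p_perm, method = "BH")
  res[order(-res$rho), , drop = FALSE]
}

#' Screen every metadata variable for microbiome prediction power
#'
#' Convenience wrapper running [permutation_test()] for each coded metadata
#' column against the transformed abundance matrix, then
#' [rank_factor_importance()] across the family. Nominal variables are dummy
#' coded upstream, so each dummy is tested separately.
#'
#' @param features transformed abundance matrix (samples x taxa).
#' @param coded coded metadata matrix (samples x variables), from
#'   [preprocess_multiomics()].
#' @param n_perm,k_folds,seed,control passed to [permutation_test()].
#' @return ranked data.frame with `q` values.
#' @export
importance_screen <- function(features, coded, n_perm = 999L, k_folds = 5L,
                              seed = 1L, control = rf_control()) {
  rows <- lapply(seq_len(ncol(coded)), function(j) {
    permutation_test(features, coded[, j], n_perm = n_perm, k_folds = k_folds,
                     seed = next_seed(seed, j), control = control,
                     factor_name = colnames(coded)[j])
  })
  rank_factor_importance(rows)
}
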