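# "Wisdom of the crowds" consensus association network: Step 1 preprocessing,
# three association learners (Spearman, random forest importance, bootstrapped
# lasso), average-rank consensus with a Q-value gate, and Edgington combined-P
# replication across paired cohorts.

#' Consensus network settings
#'
#' @param top_k average ranks kept per target variable (default 5).
#' @param q_max Spearman Q-value gate for retained/replicated edges
#'   (default 0.1).
#' @param n_boot bootstrap replicates for the lasso learner (default 100).
#' @param missing_sample_max samples missing more than this fraction of
#'   metadata are removed (default 0.70).
#' @param prevalence_min taxon prevalence filter (default 0.10).
#' @param central_interval central quantile interval defining outliers for
#'   continuous variables (default 0.95, i.e. the 2.5th-97.5th percentiles).
#' @param k_folds folds for random forest and lambda cross-validation
#'   (default 5).
#' @param rf random-forest settings, see [rf_control()].
#' @param lambda_per_boot if `TRUE`, re-select lambda inside every bootstrap
#'   (default `FALSE`: lambda chosen once on the full data and frozen).
#' @param lambda_rule which cross-validated lambda counts as "best":
#'   `"1se"` (default; conservative, kills all coefficients under a null
#'   target) or `"min"`.
#' @param nzv_eps variance threshold below which a coded column counts as
#'   near-zero-variance.
#' @return list of settings.
#' @export
consensus_config <- function(top_k = 5L, q_max = 0.1, n_boot = 100L,
                             missing_sample_max = 0.70, prevalence_min = 0.10,
                             central_interval = 0.95, k_folds = 5L,
                             rf = rf_control(), lambda_per_boot = FALSE,
                             lambda_rule = c("1se", "min"), nzv_eps = 1e-10) {
  stopifnot(top_k >= 1, q_max > 0, q_max < 1, n_boot >= 1,
            central_interval > 0, central_interval <= 1)
  lambda_rule <- match.arg(lambda_rule)
  list(top_k = as.integer(top_k), q_max = q_max, n_boot = as.integer(n_boot),
       missing_sample_max = missing_sample_max, prevalence_min = prevalence_min,
       central_interval = central_interval, k_folds = as.integer(k_folds),
       rf = rf, lambda_per_boot = lambda_per_boot, lambda_rule = lambda_rule,
       nzv_eps = nzv_eps)
}

code_variable <- function(x, kind, name) {
  switch(kind,
    binary = {
      v <- if (is.numeric(x)) x else as.numeric(factor(x)) - 1
      out <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, name))
      out
    },
    ordinal = {
      v <- if (is.numeric(x)) x else as.numeric(ordered(x))
      matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, name))
    },
    continuous = matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, name)),
    nominal = {
      f <- factor(x)
      out <- sapply(levels(f), function(l) as.numeric(f == l))
      out[is.na(x), ] <- NA
      colnames(out) <- paste0(name, ".", levels(f))
      out
    },
    stop("unknown variable kind for '", name, "': ", kind)
  )
}

#' Preprocess a multi-omic sample set for association learning
#'
#' Implements the shared preprocessing stage: ordinal variables are converted
#' to integer codes, nominal variables to dummy columns; samples missing more
#' than `missing_sample_max` of their metadata are removed; per continuous
#' variable, values outside the central `central_interval` quantile range are
#' masked as outliers; remaining missing values are median-imputed;
#' near-zero-variance columns are dropped; taxa are prevalence-filtered and
#' arcsine-square-root transformed; and a z-scored copy of the coded matrix
#' is prepared for the linear learner.
#'
#' @param meta a [metadata_table()].
#' @param abund an [abundance_table()], row-aligned by sample id.
#' @param config see [consensus_config()].
#' @return list: `coded` (imputed numeric matrix), `coded_std` (z-scored
#'   copy), `taxa` (transformed abundance matrix), `log` (counts of dropped
#'   samples/columns/masked cells).
#' @export
preprocess_multiomics <- function(meta, abund, config = consensus_config()) {
  shared <- intersect(rownames(meta), rownames(abund))
  if (!length(shared)) stop("no shared samples between metadata and abundances")
  meta <- meta[shared, , drop = FALSE]
  kinds <- var_kinds(meta)
  abund <- abundance_table(unclass(abund)[shared, , drop = FALSE])

  miss_frac <- rowMeans(is.na(meta))
  drop_samples <- miss_frac > config$missing_sample_max
  if (all(drop_samples)) stop("all samples exceed the missingness cap")
  meta <- meta[!drop_samples, , drop = FALSE]
  abund <- abundance_table(unclass(abund)[!drop_samples, , drop = FALSE])

  coded <- do.call(cbind, lapply(names(meta), function(v)
    code_variable(meta[[v]], kinds[[v]], v)))
  rownames(coded) <- rownames(meta)
  cont_cols <- colnames(coded) %in% names(kinds)[kinds == "continuous"]

  masked <- 0L
  lo <- (1 - config$central_interval) / 2
  for (j in which(cont_cols)) {
    qs <- quantile(coded[, j], c(lo, 1 - lo), na.rm = TRUE, names = FALSE)
    out <- !is.na(coded[, j]) & (coded[, j] < qs[1] | coded[, j] > qs[2])
    masked <- masked + sum(out)
    coded[out, j] <- NA
  }
  for (j in seq_len(ncol(coded))) {
    nas <- is.na(coded[, j])
    if (any(nas)) coded[nas, j] <- median(coded[, j], na.rm = TRUE)
  }
  vars <- apply(coded, 2, var)
  nzv <- !is.finite(vars) | vars < config$nzv_eps
  coded <- coded[, !nzv, drop = FALSE]
  if (!ncol(coded)) stop("no metadata variables survive preprocessing")

  taxa <- arcsine_sqrt(unclass(prevalence_filter(abund, config$prevalence_min)))
  coded_std <- scale(coded)

  list(coded = coded, coded_std = coded_std, taxa = taxa,
       log = list(samples_dropped = sum(drop_samples),
                  outliers_masked = masked, nzv_dropped = sum(nzv)))
}

spearman_p_from_rho <- function(rho, n) {
  # asymptotic t approximation (tie-aware through the rho estimate)
  r <- pmin(pmax(rho, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(tt), df = n - 2)
}

#' Pairwise Spearman association grid
#'
#' Spearman correlation, tie-corrected asymptotic P and BH Q across the full
#' `A x B` family, one row per (target, predictor) pair. Cells with fewer
#' than 4 complete pairs are flagged `NA`.
#'
#' @param A numeric matrix of target variables (samples x targets).
#' @param B numeric matrix of predictor variables (samples x predictors).
#' @return data.frame: `target`, `predictor`, `rho`, `p`, `q`, `n`.
#' @export
spearman_edges <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("matrices must be row-aligned")
  if (is.null(colnames(A))) colnames(A) <- paste0("A", seq_len(ncol(A)))
  if (is.null(colnames(B))) colnames(B) <- paste0("B", seq_len(ncol(B)))
  grid <- expand.grid(predictor = colnames(B), target = colnames(A),
                      stringsAsFactors = FALSE)[, 2:1]
  if (!anyNA(A) && !anyNA(B)) {
    ra <- apply(A, 2, rank); rb <- apply(B, 2, rank)
    rho_m <- cor(ra, rb)
    rho <- as.vector(t(rho_m))
    n <- rep(nrow(A), nrow(grid))
  } else {
    rho <- n <- numeric(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      x <- A[, grid$target[i]]; y <- B[, grid$predictor[i]]
      ok <- !is.na(x) & !is.na(y)
      n[i] <- sum(ok)
      rho[i] <- if (n[i] >= 4) cor(rank(x[ok]), rank(y[ok])) else NA_real_
    }
  }
  p <- ifelse(is.na(rho), NA_real_, spearman_p_from_rho(rho, n))
  data.frame(grid, rho = rho, p = p, q = p.adjust(p, method = "BH"), n = n,
             stringsAsFactors = FALSE)
}

#' Random-forest importance scores for one target
#'
#' Impurity-based variable importance averaged over the `k_folds` fold-wise
#' training fits of the cross-validated random forest.
#'
#' @param features predictor matrix (samples x predictors).
#' @param target numeric target variable.
#' @param config see [consensus_config()].
#' @param seed integer seed.
#' @return named numeric vector of non-negative importances.
#' @export
rf_edge_scores <- function(features, target, config = consensus_config(),
                           seed = 1L) {
  features <- as.matrix(features)
  n <- length(target)
  folds <- make_folds(n, config$k_folds, seed)
  imp <- matrix(0, ncol(features), length(unique(folds)))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- rf_fit_predict(features[tr, , drop = FALSE], target[tr],
                          features[!tr, , drop = FALSE], config$rf,
                          next_seed(seed, f))
    imp[, f] <- fit$importance
  }
  setNames(rowMeans(imp), colnames(features))
}

#' Bootstrap-aggregated lasso scores for one target
#'
#' The L1 penalty lambda is chosen once by `k_folds`-fold cross-validation on
#' the full data (`glmnet::cv.glmnet`), then `n_boot` bootstrap fits at that
#' lambda are run, each on a 0.632 resample (`ceiling(0.632 n)` distinct
#' samples drawn without replacement). The score is the mean absolute
#' coefficient across bootstraps; the nonzero selection frequency is also
#' reported.
#'
#' @param features standardized predictor matrix.
#' @param target numeric target.
#' @param config see [consensus_config()].
#' @param seed integer seed.
#' @return list: `score` (named mean |coefficient|), `nonzero_freq`,
#'   `lambda`.
#' @export
lasso_edge_scores <- function(features, target, config = consensus_config(),
                              seed = 1L) {
  features <- as.matrix(features)
  n <- length(target)
  m <- ceiling(0.632 * n)
  foldid <- make_folds(n, config$k_folds, next_seed(seed, 1L))
  cvfit <- glmnet::cv.glmnet(features, target, foldid = foldid,
                             standardize = FALSE)
  lambda <- if (config$lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  boots <- with_seed(next_seed(seed, 2L),
                     replicate(config$n_boot, sample.int(n, m), simplify = FALSE))
  coefs <- vapply(boots, function(idx) {
    xb <- features[idx, , drop = FALSE]; yb <- target[idx]
    lam <- lambda
    if (config$lambda_per_boot) {
      cvb <- glmnet::cv.glmnet(xb, yb, nfolds = config$k_folds,
                               standardize = FALSE)
      lam <- if (config$lambda_rule == "min") cvb$lambda.min else cvb$lambda.1se
    }
    # short warm-start path ending exactly at lam: avoids interpolation
    # (which would smear exact zeros into tiny coefficients)
    path <- exp(seq(log(lam * 100), log(lam), length.out = 20))
    fit <- glmnet::glmnet(xb, yb, lambda = path, standardize = FALSE)
    as.numeric(coef(fit, s = lam, exact = FALSE))[-1]
  }, numeric(ncol(features)))
  coefs <- matrix(coefs, nrow = ncol(features))
  list(score = setNames(rowMeans(abs(coefs)), colnames(features)),
       nonzero_freq = setNames(rowMeans(coefs != 0), colnames(features)),
       lambda = lambda)
}

#' Average-rank consensus edges with a Q-value gate
#'
#' Per target variable, each learner ranks the predictors by decreasing
#' score (rank 1 = strongest association; |rho| for Spearman; ties receive
#' average ranks), the three ranks are averaged, the `top_k` predictors with
#' the smallest average rank are kept, and kept edges must additionally pass
#' the Spearman Q-value gate (`q < q_max`). The edge sign is the sign of the
#' Spearman rho.
#'
#' @param spearman data.frame from [spearman_edges()].
#' @param rf data.frame with columns `target`, `predictor`, `score` (from
#'   [rf_edge_scores()] stacked over targets).
#' @param lasso data.frame with columns `target`, `predictor`, `score`.
#' @param config see [consensus_config()].
#' @return list: `edges` (all scored pairs with ranks), `retained` (the
#'   consensus edge set).
#' @export
consensus_edges <- function(spearman, rf, lasso, config = consensus_config()) {
  key <- function(d) paste(d$target, d$predictor, sep = "\r")
  e <- spearman[, c("target", "predictor", "rho", "p", "q")]
  e$score_spearman <- abs(e$rho)
  e$score_rf <- rf$score[match(key(e), key(rf))]
  e$score_lasso <- lasso$score[match(key(e), key(lasso))]

  rank_desc <- function(s) if (all(is.na(s))) rep(NA_real_, length(s)) else
    rank(-s, ties.method = "average", na.last = "keep")
  by_target <- split(seq_len(nrow(e)), e$target)
  e$rank_spearman <- e$rank_rf <- e$rank_lasso <- NA_real_
  for (idx in by_target) {
    e$rank_spearman[idx] <- rank_desc(e$score_spearman[idx])
    e$rank_rf[idx] <- rank_desc(e$score_rf[idx])
    e$rank_lasso[idx] <- rank_desc(e$score_lasso[idx])
  }
  rk <- cbind(e$rank_spearman, e$rank_rf, e$rank_lasso)
  e$n_methods <- rowSums(!is.na(rk))
  e$avg_rank <- rowMeans(rk, na.rm = TRUE)
  e$sign <- ifelse(e$rho >= 0, "+", "-")

  keep <- logical(nrow(e))
  for (idx in by_target) {
    ord <- idx[order(e$avg_rank[idx], e$predictor[idx])]
    keep[head(ord, config$top_k)] <- TRUE
  }
  retained <- e[keep & !is.na(e$q) & e$q < config$q_max, , drop = FALSE]
  list(edges = e, retained = retained)
}

#' Edgington combined P value for two cohorts
#'
#' Combines two P values through the distribution of their sum (Irwin-Hall
#' for two uniforms): with `s = p1 + p2`, the combined P is `s^2 / 2` when
#' `s <= 1` and `1 - (2 - s)^2 / 2` otherwise. Vectorized.
#'
#' @param p1,p2 P values in `[0, 1]`.
#' @return combined P values.
#' @export
edgington_combine <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  s <- p1 + p2
  ifelse(s <= 1, s^2 / 2, 1 - (2 - s)^2 / 2)
}

#' Cross-cohort replication of consensus edges
#'
#' Intersects the edge grids of two cohorts by (target, predictor), combines
#' their Spearman P values with [edgington_combine()], applies BH across the
#' shared family, and calls an edge replicated when the combined Q passes
#' `q_max` and the association sign agrees between cohorts.
#'
#' @param edges1,edges2 edge data.frames (typically `$retained` from
#'   [consensus_edges()]) with `target`, `predictor`, `p`, `rho` columns.
#' @param config see [consensus_config()].
#' @return data.frame: edge id columns, per-cohort P, `p_combined`,
#'   `q_combined`, `sign_agreement`, `replicated`.
#' @export
replicate_edges <- function(edges1, edges2, config = consensus_config()) {
  m <- merge(edges1[, c("target", "predictor", "p", "rho")],
             edges2[, c("target", "predictor", "p", "rho")],
             by = c("target", "predictor"), suffixes = c("_cohort1", "_cohort2"))
  if (!nrow(m))
    return(data.frame(target = character(), predictor = character(),
                      p_cohort1 = double(), p_cohort2 = double(),
                      p_combined = double(), q_combined = double(),
                      sign_agreement = logical(), replicated = logical()))
  out <- data.frame(target = m$target, predictor = m$predictor,
                    p_cohort1 = m$p_cohort1, p_cohort2 = m$p_cohort2,
                    stringsAsFactors = FALSE)
  out$p_combined <- edgington_combine(m$p_cohort1, m$p_cohort2)
  out$q_combined <- p.adjust(out$p_combined, method = "BH")
  out$sign_agreement <- sign(m$rho_cohort1) == sign(m$rho_cohort2)
  out$replicated <- out$q_combined < config$q_max & out$sign_agreement
  out
}

#' Build the full consensus association network for one cohort
#'
#' Runs preprocessing, the three learners over every coded metadata variable
#' (targets) against the transformed taxa (predictors), and the average-rank
#' consensus.
#'
#' @param meta a [metadata_table()].
#' @param abund an [abundance_table()].
#' @param config see [consensus_config()].
#' @param seed integer seed.
#' @return list: `edges`, `retained`, `counts` (associations examined /
#'   retained), `prep` (preprocessing log).
#' @export
build_consensus_network <- function(meta, abund, config = consensus_config(),
                                    seed = 1L) {
  prep <- preprocess_multiomics(meta, abund, config)
  targets <- prep$coded
  sp <- spearman_edges(targets, prep$taxa)
  rf_rows <- list(); la_rows <- list()
  for (j in seq_len(ncol(targets))) {
    tn <- colnames(targets)[j]
    rf_s <- rf_edge_scores(prep$taxa, targets[, j], config, next_seed(seed, 2L * j))
    la_s <- lasso_edge_scores(scale(prep$taxa), prep$coded_std[, j], config,
                              next_seed(seed, 2L * j + 1L))
    rf_rows[[j]] <- data.frame(target = tn, predictor = names(rf_s),
                               score = unname(rf_s), stringsAsFactors = FALSE)
    la_rows[[j]] <- data.frame(target = tn, predictor = names(la_s$score),
                               score = unname(la_s$score), stringsAsFactors = FALSE)
  }
  cons <- consensus_edges(sp, do.call(rbind, rf_rows), do.call(rbind, la_rows),
                          config)
  list(edges = cons$edges, retained = cons$retained,
       counts = list(examined = nrow(cons$edges), retained = nrow(cons$retained)),
       prep = prep$log)
}

#' Export a consensus network
#'
#' Writes a GraphML file (positive edges cyan, negative edges red, matching
#' the conventional colouring of such association networks) and a tab-
#' delimited edge list.
#'
#' @param edges edge data.frame (e.g. `$retained`).
#' @param path_prefix output path prefix; writes `<prefix>.graphml` and
#'   `<prefix>_edges.tsv`.
#' @return invisibly, the two file paths.
#' @export
export_network <- function(edges, path_prefix) {
  if (!nrow(edges)) stop("no edges to export")
  cols <- intersect(c("target", "predictor", "sign", "avg_rank", "rho", "q"),
                    colnames(edges))
  el <- edges[, cols, drop = FALSE]
  tsv <- paste0(path_prefix, "_edges.tsv")
  write.table(el, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  if ("sign" %in% cols)
    igraph::E(g)$color <- ifelse(el$sign == "+", "cyan", "red")
  gml <- paste0(path_prefix, ".graphml")
  igraph::write_graph(g, gml, format = "graphml")
  invisible(c(graphml = gml, edges = tsv))
}
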