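small_cfg <- consensus_config(n_boot = 20, rf = rf_control(ntree = 50),
                              k_folds = 5)

test_that("preprocessing implements the shared cleanup stage", {
  df <- data.frame(
    cont = c(1000, rnorm(99)),                   # one extreme outlier
    bin = rep(c(0, 1), 50),
    nom = rep(c("x", "y", "z", "z"), 25),
    ord = rep(1:4, 25),
    flat = rep(7, 100),                          # near-zero variance
    holey = c(rep(NA, 30), rnorm(70)),
    row.names = sprintf("S%04d", 1:100))
  df$bin[2] <- NA
  kinds <- c(cont = "continuous", bin = "binary", nom = "nominal",
             ord = "ordinal", flat = "continuous", holey = "continuous")
  # sample 1 additionally misses most variables -> dropped at the 70% cap
  df[1, c("cont", "bin", "nom", "ord", "flat")] <- NA
  meta <- metadata_table(df, kinds)
  ab <- random_abund(100, 8, seed = 1)
  rownames(ab) <- rownames(df)

  prep <- preprocess_multiomics(meta, abundance_table(unclass(ab)),
                                consensus_config())
  expect_equal(prep$log$samples_dropped, 1)
  expect_false("flat" %in% colnames(prep$coded))
  expect_setequal(grep("^nom", colnames(prep$coded), value = TRUE),
                  c("nom.x", "nom.y", "nom.z"))
  expect_false(anyNA(prep$coded))
  expect_gte(prep$log$outliers_masked, 1)
  expect_true(all(prep$taxa >= 0 & prep$taxa <= pi / 2))
  expect_equal(nrow(prep$coded), nrow(prep$taxa))
})

test_that("a single extreme value is masked then imputed to the others' median", {
  base <- withr_seed(3, rnorm(99))
  df <- data.frame(v = c(base, 1e6), row.names = sprintf("S%03d", 1:100))
  meta <- metadata_table(df, c(v = "continuous"))
  ab <- random_abund(100, 5, seed = 2)
  rownames(ab) <- rownames(df)
  prep <- preprocess_multiomics(meta, abundance_table(unclass(ab)),
                                consensus_config())
  v <- prep$coded[, "v"]
  qs <- quantile(df$v, c(0.025, 0.975), names = FALSE)
  masked <- df$v < qs[1] | df$v > qs[2]
  expect_equal(unname(v[100]), median(df$v[!masked]))
})

test_that("coding, imputation, NZV and transform are idempotent", {
  # outlier re-masking is inherently non-idempotent (the central interval is
  # re-estimated), so the fixed-point property is checked with that stage off
  co <- generate_cohort(sim_config(n_samples = 60, seed = 9))
  cfg <- consensus_config(central_interval = 1)
  p1 <- preprocess_multiomics(co$metadata, co$abundance, cfg)
  meta2 <- metadata_table(as.data.frame(p1$coded),
                          setNames(rep("continuous", ncol(p1$coded)),
                                   colnames(p1$coded)))
  ab2 <- abundance_table(unclass(co$abundance)[rownames(p1$coded), ])
  p2 <- preprocess_multiomics(meta2, ab2, cfg)
  expect_equal(unname(p2$coded), unname(p1$coded))
  expect_equal(p2$taxa, p1$taxa)
})

test_that("spearman grid matches cor.test and flags short cells", {
  A <- withr_seed(4, matrix(rnorm(50 * 3), 50, dimnames = list(NULL, c("a1", "a2", "a3"))))
  B <- withr_seed(5, matrix(sample(1:5, 150, TRUE), 50,
                            dimnames = list(NULL, c("b1", "b2", "b3"))))
  edges <- spearman_edges(A, B)
  expect_equal(nrow(edges), 9)
  for (i in c(1, 5, 9)) {
    ref <- suppressWarnings(cor.test(A[, edges$target[i]], B[, edges$predictor[i]],
                                     method = "spearman", exact = FALSE))
    expect_equal(edges$rho[i], unname(ref$estimate), tolerance = 1e-12)
    expect_equal(edges$p[i], ref$p.value, tolerance = 1e-9)
  }

  self <- spearman_edges(cbind(x = A[, 1]), cbind(x = A[, 1]))
  expect_equal(self$rho, 1)
  expect_lt(self$p, 1e-20)
  rev4 <- spearman_edges(cbind(x = 1:4), cbind(y = 4:1))
  expect_equal(rev4$rho, -1)

  A[1:48, 2] <- NA
  miss <- spearman_edges(A, B)
  expect_true(all(is.na(miss$rho[miss$target == "a2"])))
})

test_that("spearman nulls stay flat and the Q gate stays shut", {
  A <- withr_seed(6, matrix(rnorm(100 * 20), 100))
  B <- withr_seed(7, matrix(rnorm(100 * 20), 100))
  edges <- spearman_edges(A, B)
  expect_equal(mean(edges$p), 0.5, tolerance = 0.05)
  expect_identical(sum(edges$q < 0.1), 0L)
})

test_that("rf scores surface the informative feature; constants get zero", {
  hits <- vapply(1:5, function(s) {
    X <- withr_seed(s, matrix(rnorm(300 * 30), 300))
    y <- X[, 17] + withr_seed(50 + s, rnorm(300, sd = 0.5))
    sc <- rf_edge_scores(X, y, small_cfg, seed = s)
    which.max(sc) == 17
  }, logical(1))
  expect_gte(sum(hits), 4)

  X <- withr_seed(8, matrix(rnorm(100 * 5), 100))
  X[, 3] <- 2
  sc <- rf_edge_scores(X, withr_seed(9, rnorm(100)), small_cfg, seed = 1)
  expect_equal(unname(sc[3]), 0)
  expect_true(all(sc >= 0))
})

test_that("bootstrapped lasso ranks the true predictor and kills pure noise", {
  X <- withr_seed(10, matrix(rnorm(200 * 10), 200,
                             dimnames = list(NULL, paste0("f", 1:10))))
  y <- 2 * X[, 4] + withr_seed(11, rnorm(200, sd = 0.1))
  sc <- lasso_edge_scores(X, y, small_cfg, seed = 1)
  expect_identical(names(which.max(sc$score)), "f4")
  expect_equal(unname(sc$nonzero_freq["f4"]), 1)

  # pure noise: with per-bootstrap lambda re-selection the penalty kills all
  # coefficients in the majority of replicate datasets (under the default
  # frozen-lambda scheme, resamples activate small spurious coefficients, so
  # null scores are merely small rather than exactly zero)
  boot_cfg <- consensus_config(n_boot = 20, lambda_per_boot = TRUE)
  dead <- vapply(1:5, function(s) {
    ynull <- withr_seed(500 + s, rnorm(200))
    scn <- lasso_edge_scores(X, ynull, boot_cfg, seed = s)
    median(scn$score) <= 1e-8
  }, logical(1))
  expect_gte(sum(dead), 3)
  frozen_null <- lasso_edge_scores(X, withr_seed(501, rnorm(200)), small_cfg,
                                   seed = 1)
  expect_lt(max(frozen_null$score), 0.1)

  one <- lasso_edge_scores(X, y, consensus_config(n_boot = 1), seed = 3)
  idx <- momnet:::with_seed(momnet:::next_seed(3L, 2L),
                            replicate(1, sample.int(200, ceiling(0.632 * 200)),
                                      simplify = FALSE))[[1]]
  fit <- glmnet::glmnet(X[idx, ], y[idx], standardize = FALSE)
  expect_equal(unname(sc1 <- one$score),
               abs(as.numeric(coef(fit, s = one$lambda)))[-1], tolerance = 1e-10)
})

test_that("consensus keeps the agreed top-k and enforces the Q gate", {
  preds <- paste0("t", 1:10)
  base <- data.frame(target = "y", predictor = preds,
                     rho = seq(0.95, 0.05, length.out = 10),
                     p = c(10^-(6:2), rep(0.4, 5)))
  base$q <- p.adjust(base$p, "BH")
  rf <- data.frame(target = "y", predictor = preds, score = 10:1)
  la <- data.frame(target = "y", predictor = preds, score = (10:1) / 10)
  cons <- consensus_edges(base, rf, la, consensus_config())
  expect_setequal(cons$retained$predictor, preds[1:5])
  expect_true(all(cons$edges$avg_rank[match(preds, cons$edges$predictor)] ==
                    1:10))

  # rank-1 predictor with an unconvincing Spearman Q is excluded
  gated <- base; gated$q[1] <- 0.5
  cons2 <- consensus_edges(gated, rf, la, consensus_config())
  expect_false(preds[1] %in% cons2$retained$predictor)

  # retained set invariant under monotone transformation of method scores
  rf2 <- rf; rf2$score <- exp(rf$score)
  la2 <- la; la2$score <- rank(la$score)
  cons3 <- consensus_edges(base, rf2, la2, consensus_config())
  expect_setequal(cons3$retained$predictor, cons$retained$predictor)

  # never more than top_k per target
  expect_lte(max(table(cons$retained$target)), 5)
})

test_that("edgington combination follows the Irwin-Hall closed form", {
  expect_equal(edgington_combine(0.5, 0.5), 0.5)
  expect_equal(edgington_combine(0.1, 0.1), 0.02)
  expect_equal(edgington_combine(0.9, 0.8), 1 - (2 - 1.7)^2 / 2)
  expect_equal(edgington_combine(0.2, 0.3), edgington_combine(0.3, 0.2))
  s <- withr_seed(13, runif(50)); t <- withr_seed(14, runif(50))
  expect_true(all(diff(edgington_combine(sort(s), 0.4)) >= 0))  # monotone
  expect_true(all(edgington_combine(s, t) >= 0 & edgington_combine(s, t) <= 1))
  expect_error(edgington_combine(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(edgington_combine(0.5, 1.2), "\\[0, 1\\]")
})

test_that("replication demands combined Q and sign agreement", {
  e1 <- data.frame(target = c("y", "y"), predictor = c("a", "b"),
                   p = c(0.01, 0.01), rho = c(0.5, 0.4))
  e2 <- data.frame(target = c("y", "y"), predictor = c("a", "b"),
                   p = c(0.01, 0.01), rho = c(0.6, -0.3))
  rep <- replicate_edges(e1, e2, consensus_config())
  expect_equal(rep$p_combined, c(2e-4, 2e-4))
  expect_identical(rep$replicated, c(TRUE, FALSE))   # b flips sign

  none <- replicate_edges(e1, data.frame(target = "z", predictor = "q",
                                         p = 0.5, rho = 0.1),
                          consensus_config())
  expect_identical(nrow(none), 0L)
})

test_that("network export round-trips and parses as GraphML", {
  edges <- data.frame(target = c("y1", "y2"), predictor = c("t1", "t2"),
                      sign = c("+", "-"), avg_rank = c(1, 2),
                      rho = c(0.5, -0.4), q = c(0.01, 0.02))
  prefix <- file.path(withr::local_tempdir(), "net")
  paths <- export_network(edges, prefix)
  g <- igraph::read_graph(paste0(prefix, ".graphml"), format = "graphml")
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::E(g)$color, c("cyan", "red"))
  back <- read.delim(paste0(prefix, "_edges.tsv"), stringsAsFactors = FALSE)
  expect_equal(back[order(back$target), c("target", "predictor", "rho")],
               edges[, c("target", "predictor", "rho")])
  expect_error(export_network(edges[0, ], prefix), "no edges")
})
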