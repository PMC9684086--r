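# Shared fixtures and independent oracles for the momnet suite.
# Everything here is generated in code; no binary fixtures.

# Fast settings used where tree quality does not matter (calibration and
# determinism checks); confirmatory tests use larger forests.
fast_rf <- rf_control(ntree = 50L)

random_abund <- function(n, k, seed = 1) {
  withr_seed(seed, {
    m <- matrix(rgamma(n * k, shape = 0.5), n, k)
    m <- m / rowSums(m)
    colnames(m) <- paste0("k__Bacteria|p__P", seq_len(k), "|g__G", seq_len(k),
                          "|s__Species_", sprintf("%02d", seq_len(k)))
    rownames(m) <- paste0("S", seq_len(n))
    abundance_table(m)
  })
}

withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Eight planted effects at the documented calibration giving |rho| ~= 0.4
# at n = 300 (binary 0.08, ordinal 0.04/level, continuous 0.03/unit).
planted_effects <- function(labs) {
  list(
    list(factor = "factor01_bin", taxon = labs[10], effect_size = 0.08, sign = 1),
    list(factor = "factor04_bin", taxon = labs[12], effect_size = 0.08, sign = -1),
    list(factor = "factor02_ord", taxon = labs[14], effect_size = 0.04, sign = 1),
    list(factor = "factor05_ord", taxon = labs[16], effect_size = 0.04, sign = -1),
    list(factor = "factor03_cont", taxon = labs[18], effect_size = 0.03, sign = 1),
    list(factor = "factor09_cont", taxon = labs[20], effect_size = 0.03, sign = -1),
    list(factor = "factor07_bin", taxon = labs[22], effect_size = 0.08, sign = 1),
    list(factor = "factor08_ord", taxon = labs[24], effect_size = 0.04, sign = 1))
}

# --- independent oracles -------------------------------------------------

# O(n^3) centroid-linkage agglomeration: clusters merge at the Euclidean
# distance between their centroids, recomputed from scratch each step.
centroid_linkage_oracle <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  members <- lapply(seq_len(n), identity)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(active)[-length(active)]) {
      for (j in (i + 1):length(active)) {
        ci <- colMeans(X[members[[active[i]]], , drop = FALSE])
        cj <- colMeans(X[members[[active[j]]], , drop = FALSE])
        d <- sqrt(sum((ci - cj)^2))
        if (d < bd) { bd <- d; best <- c(i, j) }
      }
    }
    heights[s] <- bd
    members[[n + s]] <- c(members[[active[best[1]]]], members[[active[best[2]]]])
    active <- c(active[-best], n + s)
  }
  sort(heights)
}

# Exhaustive two-sided Fisher P over the hypergeometric family with the
# observed margins (probabilities <= observed, with the standard relative
# tie tolerance).
fisher_p_oracle <- function(tab) {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - m2):min(k, m1)
  probs <- dhyper(support, m1, m2, k)
  obs <- dhyper(a, m1, m2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Conditional-MLE odds ratio oracle: direct maximization of the noncentral
# hypergeometric log-likelihood over log(psi) (independent of the package's
# score-equation root).
fisher_or_oracle <- function(tab) {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - m2):min(k, m1)
  if (a == min(support)) return(0)
  if (a == max(support)) return(Inf)
  w <- lchoose(m1, support) + lchoose(m2, k - support)
  loglik <- function(logpsi) {
    lp <- w + support * logpsi
    m <- max(lp)
    (w[support == a] + a * logpsi) - (m + log(sum(exp(lp - m))))
  }
  opt <- optimize(loglik, c(-60, 60), maximum = TRUE, tol = 1e-11)
  # parabolic polish around the smooth concave maximum
  x <- opt$maximum
  for (h in c(1e-3, 1e-5)) {
    f0 <- loglik(x); fp <- loglik(x + h); fm <- loglik(x - h)
    denom <- fp - 2 * f0 + fm
    if (is.finite(denom) && denom < 0) x <- x - 0.5 * h * (fp - fm) / denom
  }
  exp(x)
}
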