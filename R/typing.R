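# Dominance-based community typing and the accompanying group statistics.

taxon_label <- function(clade) {
  parts <- strsplit(clade, "|", fixed = TRUE)
  vapply(parts, function(p) sub("^[a-z]__", "", p[length(p)]), character(1))
}

#' Assign dominance-based community types
#'
#' A sample whose most abundant species reaches at least `threshold` of the
#' community is labelled by that species; all other samples form the
#' "diverse" type. The boundary is inclusive (a 50% species defines a type)
#' and exact-threshold ties are broken lexicographically by species label.
#'
#' @param table an [abundance_table()] (species-rank columns).
#' @param threshold dominance cutoff, default 0.5.
#' @return data.frame with `sample_id`, `type` (species label or
#'   `"diverse"`), `dominant_fraction`.
#' @export
assign_types <- function(table, threshold = 0.5) {
  stopifnot(nrow(table) >= 1)
  labs <- taxon_label(colnames(table))
  ord <- order(labs)       # lexicographic tie-break via first max over ordered cols
  m <- unclass(table)[, ord, drop = FALSE]
  labs <- labs[ord]
  top <- apply(m, 1, which.max)
  frac <- m[cbind(seq_len(nrow(m)), top)]
  type <- ifelse(frac >= threshold, labs[top], "diverse")
  if (any(frac == 0)) {
    warning("all-zero sample(s) labelled diverse")
    type[frac == 0] <- "diverse"
  }
  data.frame(sample_id = rownames(table), type = type,
             dominant_fraction = as.numeric(frac), stringsAsFactors = FALSE)
}

#' Order samples by centroid-linkage hierarchical clustering
#'
#' Agglomerative clustering of composition vectors with centroid linkage on
#' Euclidean distances (the classic heatmap dendrogram ordering for
#' community profiles). Centroid linkage is computed exactly by running
#' `hclust(method = "centroid")` on squared Euclidean distances; reported
#' merge heights are back-transformed to Euclidean units.
#'
#' @param table an [abundance_table()] (or any samples x features matrix).
#' @return list with `order` (sample index permutation), `merge` and
#'   `height` (Euclidean centroid distances at each merge), and `hclust`.
#' @export
cluster_order <- function(table) {
  n <- nrow(table)
  if (n < 2) return(list(order = seq_len(n), merge = NULL, height = NULL, hclust = NULL))
  d2 <- stats::dist(unclass(table))^2
  hc <- hclust(d2, method = "centroid")
  list(order = hc$order, merge = hc$merge,
       height = sqrt(pmax(hc$height, 0)), hclust = hc)
}

pooled_t_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  s2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  dm <- mean(x) - mean(y)
  if (s2 <= 0) return(if (dm == 0) 1 else 0)
  tt <- dm / sqrt(s2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tt), df = n1 + n2 - 2)
}

#' Test a covariate across community types
#'
#' Overall significance by a Gaussian-family likelihood-ratio test of
#' `covariate ~ type` against the intercept-only model (statistic
#' `n * log(RSS0 / RSS1)`, chi-squared with k - 1 df), followed by pairwise
#' pooled-variance Student's t-tests between all type pairs. Groups smaller
#' than `min_group` (after dropping missing covariate values) are excluded.
#'
#' @param assignment data.frame from [assign_types()] (or any vector of
#'   group labels aligned with `covariate`).
#' @param covariate numeric vector, may contain `NA`.
#' @param min_group minimum group size (default 3).
#' @return list with `covariate` (deparsed name), `overall_p`, `pairwise`
#'   (symmetric matrix of post hoc P values), `group_ns`, `n_groups`.
#' @export
type_covariate_test <- function(assignment, covariate, min_group = 3L) {
  groups <- if (is.data.frame(assignment)) assignment$type else as.character(assignment)
  ok <- !is.na(covariate) & !is.na(groups)
  groups <- groups[ok]; covariate <- as.numeric(covariate[ok])
  ns <- table(groups)
  small <- names(ns)[ns < min_group]
  if (length(small)) {
    message("excluding group(s) below min_group: ", paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    groups <- groups[keep]; covariate <- covariate[keep]
    ns <- table(groups)
  }
  k <- length(ns)
  if (k < 2) stop("need at least 2 groups of size >= min_group")
  n <- length(covariate)
  if (var(covariate) == 0) {
    overall_p <- 1
  } else {
    rss1 <- sum(unlist(tapply(covariate, groups, function(v) (v - mean(v))^2)))
    rss0 <- sum((covariate - mean(covariate))^2)
    stat <- if (rss1 <= 0) Inf else n * log(rss0 / rss1)
    overall_p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  }
  gnames <- names(ns)
  pw <- matrix(NA_real_, k, k, dimnames = list(gnames, gnames))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    p <- pooled_t_p(covariate[groups == gnames[i]], covariate[groups == gnames[j]])
    pw[i, j] <- pw[j, i] <- p
  }
  list(covariate = deparse(substitute(covariate)), overall_p = overall_p,
       pairwise = pw, group_ns = as.vector(ns), n_groups = k)
}

#' Fisher's exact test of species co-occurrence
#'
#' Builds the 2x2 presence/absence table of two species across samples and
#' tests association with Fisher's exact test: the two-sided P sums all
#' hypergeometric table probabilities not exceeding the observed one, and the
#' odds ratio is the conditional maximum-likelihood estimate under the
#' noncentral hypergeometric model (the sample cross-product ratio is also
#' reported). Degenerate margins (a species present or absent everywhere)
#' yield P = 1 and an undefined odds ratio, flagged.
#'
#' @param pres_a,pres_b logical/0-1 vectors of equal length, no missing.
#' @param table alternatively, a 2x2 count matrix
#'   (`rbind(c(both, a_only), c(b_only, neither))`) supplied directly.
#' @return list: `table`, `odds_ratio` (conditional MLE), `odds_ratio_sample`,
#'   `p_two_sided`, `degenerate`.
#' @export
fisher_cooccurrence <- function(pres_a, pres_b, table = NULL) {
  if (is.null(table)) {
    if (length(pres_a) != length(pres_b)) stop("vectors must have equal length")
    if (anyNA(pres_a) || anyNA(pres_b)) stop("missing values not allowed")
    a <- as.logical(pres_a); b <- as.logical(pres_b)
    table <- rbind(c(sum(a & b), sum(a & !b)), c(sum(!a & b), sum(!a & !b)))
  }
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  or_sample <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(table = table, odds_ratio = NaN, odds_ratio_sample = or_sample,
                p_two_sided = 1, degenerate = TRUE))
  }
  ft <- fisher.test(table)
  list(table = table, odds_ratio = cond_mle_or(table),
       odds_ratio_sample = or_sample, p_two_sided = ft$p.value,
       degenerate = FALSE)
}

# Conditional maximum-likelihood odds ratio of a 2x2 table: root of the
# noncentral-hypergeometric score equation E[a | margins, psi] = a_obs.
# (The stock fisher.test estimate solves the same equation but only to about
# 1e-4 relative precision, too coarse here.)
cond_mle_or <- function(tab) {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - m2):min(k, m1)
  if (a <= min(support)) return(0)
  if (a >= max(support)) return(Inf)
  w <- lchoose(m1, support) + lchoose(m2, k - support)
  score <- function(logpsi) {
    lp <- w + support * logpsi
    lp <- lp - max(lp)
    sum(support * exp(lp)) / sum(exp(lp)) - a
  }
  exp(stats::uniroot(score, c(-80, 80), tol = 1e-13)$root)
}

#' Two-group Wilcoxon rank-sum comparison
#'
#' Exact enumeration of the rank-sum distribution over all
#' `choose(n1 + n2, n1)` group assignments when both groups have at most 10
#' observations (valid under ties); otherwise the normal approximation with
#' tie correction. Two-sided.
#'
#' @param x,y numeric vectors (the two groups), each nonempty.
#' @return two-sided P value.
#' @export
ranksum_compare <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (n1 <= 10 && n2 <= 10) {
    combos <- utils::combn(n, n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    return(mean(abs(sums - mu) >= abs(W - mu) - 1e-9))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  min(1, 2 * stats::pnorm(-abs(W - mu) / sqrt(sigma2)))
}
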