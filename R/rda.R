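# Redundancy analysis: multivariate least squares of a (transformed)
# response matrix on coded predictors, with forward selection under the
# double stopping rule (per-step Freedman-Lane permutation alpha + global
# adjusted R-squared ceiling).

center_cols <- function(m) sweep(as.matrix(m), 2, colMeans(m))

# R^2 of column-centered Y on the column space of column-centered X.
# Rank-deficient X is handled by pivoted QR (collinear columns dropped).
rda_r2 <- function(Yc, Xc, warn = TRUE) {
  qrx <- qr(Xc)
  if (warn && qrx$rank < ncol(Xc))
    warning(ncol(Xc) - qrx$rank, " collinear predictor column(s) dropped")
  Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  fitted <- Q %*% crossprod(Q, Yc)
  list(r2 = sum(fitted^2) / sum(Yc^2), rank = qrx$rank)
}

ezekiel_adj <- function(r2, n, m) 1 - (1 - r2) * (n - 1) / (n - m - 1)

#' Redundancy analysis fit
#'
#' Column-centers response matrix `Y` and predictor matrix `X`, regresses
#' every response column on `X` by least squares, and reports the fraction of
#' total response variance captured by the fitted values (the RDA
#' R-squared) together with the Ezekiel adjusted R-squared
#' `1 - (1 - R2)(n - 1)/(n - m - 1)`.
#'
#' @param Y numeric response matrix (e.g. arcsine-square-root transformed
#'   abundances), samples x variables.
#' @param X numeric coded predictor matrix, row-aligned with `Y`.
#' @return list: `r2`, `adj_r2`, `n`, `m` (predictor columns after dropping
#'   collinear ones).
#' @export
rda_fit <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X must be row-aligned")
  if (anyNA(Y) || anyNA(X)) stop("complete data required (impute upstream)")
  n <- nrow(Y)
  Yc <- center_cols(Y); Xc <- center_cols(X)
  fit <- rda_r2(Yc, Xc)
  m <- fit$rank
  if (n <= m + 1) stop("need n >= m + 2 samples")
  list(r2 = fit$r2, adj_r2 = ezekiel_adj(fit$r2, n, m), n = n, m = m)
}

#' Forward selection of predictors for redundancy analysis
#'
#' Greedy forward-stepwise RDA: at each step the candidate maximizing the
#' added R-squared enters, its addition is tested by a Freedman-Lane
#' permutation test (residuals of `Y` under the already-selected model are
#' permuted `n_perm` times; add-one one-sided P on the added-R-squared
#' statistic), and selection stops when the P value reaches `alpha`, when the
#' cumulative adjusted R-squared would exceed the adjusted R-squared of the
#' full candidate model (double stopping), or when candidates are exhausted.
#'
#' @param Y response matrix as in [rda_fit()].
#' @param candidates coded candidate predictor matrix (one column per
#'   candidate).
#' @param alpha per-step significance cutoff (default 0.05).
#' @param n_perm permutations per step (default 999; `0` disables the
#'   permutation test and the alpha rule).
#' @param seed integer seed for the permutations.
#' @param force_all if `TRUE`, both stopping rules are disabled and all
#'   candidates are ranked (diagnostic mode).
#' @return list: `selected` (names in entry order), `trace` (data.frame of
#'   step, predictor, added_r2, cum_r2, cum_adj_r2, p), `stop_reason`
#'   (`"alpha"`, `"global_adjR2"` or `"exhausted"`), `global_adj_r2`.
#' @export
forward_select <- function(Y, candidates, alpha = 0.05, n_perm = 999L,
                           seed = 1L, force_all = FALSE) {
  Y <- as.matrix(Y); candidates <- as.matrix(candidates)
  if (is.null(colnames(candidates)) && ncol(candidates) > 0)
    colnames(candidates) <- paste0("X", seq_len(ncol(candidates)))
  n <- nrow(Y)
  Yc <- center_cols(Y)
  trace <- data.frame(step = integer(), predictor = character(),
                      added_r2 = double(), cum_r2 = double(),
                      cum_adj_r2 = double(), p = double(),
                      stringsAsFactors = FALSE)
  if (ncol(candidates) == 0)
    return(list(selected = character(), trace = trace,
                stop_reason = "exhausted", global_adj_r2 = NA_real_))

  Xall <- center_cols(candidates)
  global <- if (n > ncol(candidates) + 1) {
    f <- rda_r2(Yc, Xall, warn = FALSE)
    ezekiel_adj(f$r2, n, f$rank)
  } else NA_real_

  selected <- integer()
  r2_cur <- 0
  stop_reason <- "exhausted"
  perm_seed <- seed
  repeat {
    remaining <- setdiff(seq_len(ncol(candidates)), selected)
    if (!length(remaining)) break
    r2_with <- vapply(remaining, function(j) {
      rda_r2(Yc, Xall[, c(selected, j), drop = FALSE], warn = FALSE)$r2
    }, numeric(1))
    best <- remaining[which.max(r2_with)]
    added <- max(r2_with) - r2_cur
    step <- length(selected) + 1L

    p <- NA_real_
    if (n_perm >= 1) {
      # Freedman-Lane: permute reduced-model residuals, keep fitted part
      if (length(selected)) {
        qs <- qr(Xall[, selected, drop = FALSE])
        Qs <- qr.Q(qs)[, seq_len(qs$rank), drop = FALSE]
        fit_s <- Qs %*% crossprod(Qs, Yc)
      } else fit_s <- matrix(0, n, ncol(Yc))
      resid_s <- Yc - fit_s
      perms <- with_seed(next_seed(perm_seed, step),
                         replicate(n_perm, sample.int(n), simplify = FALSE))
      Xstep <- Xall[, c(selected, best), drop = FALSE]
      r2_red <- function(Ystar) {
        if (!length(selected)) return(0)
        rda_r2(Ystar, Xall[, selected, drop = FALSE], warn = FALSE)$r2
      }
      added_perm <- vapply(perms, function(pm) {
        Ystar <- fit_s + resid_s[pm, , drop = FALSE]
        Ystar <- sweep(Ystar, 2, colMeans(Ystar))
        rda_r2(Ystar, Xstep, warn = FALSE)$r2 - r2_red(Ystar)
      }, numeric(1))
      p <- (1 + sum(added_perm >= added - 1e-12)) / (n_perm + 1)
      if (!force_all && p >= alpha) { stop_reason <- "alpha"; break }
    }

    cum_r2 <- r2_cur + added
    cum_adj <- ezekiel_adj(cum_r2, n, length(selected) + 1L)
    if (!force_all && !is.na(global) && cum_adj > global + 1e-9) {
      stop_reason <- "global_adjR2"; break
    }
    selected <- c(selected, best)
    r2_cur <- cum_r2
    trace <- rbind(trace, data.frame(
      step = step, predictor = colnames(candidates)[best], added_r2 = added,
      cum_r2 = cum_r2, cum_adj_r2 = cum_adj, p = p, stringsAsFactors = FALSE))
    if (n - length(selected) <= 2) break   # no residual df for further steps
  }
  list(selected = trace$predictor, trace = trace, stop_reason = stop_reason,
       global_adj_r2 = global)
}

#' Bidirectional between-ome effect size
#'
#' Runs [forward_select()] in both directions between two omic blocks and
#' reports the adjusted R-squared of each selected model — the "arrow
#' weights" of a global between-ome association diagram.
#'
#' @param block_a,block_b numeric matrices, row-aligned samples.
#' @param ... passed to [forward_select()].
#' @return list with `a_to_b` and `b_to_a`, each holding the selection and
#'   the adjusted R-squared of the final model.
#' @export
ome_effect_size <- function(block_a, block_b, ...) {
  dir_fit <- function(Y, X) {
    sel <- forward_select(Y, X, ...)
    adj <- if (length(sel$selected)) {
      utils::tail(sel$trace$cum_adj_r2, 1)
    } else 0
    list(selection = sel, adj_r2 = adj)
  }
  list(a_to_b = dir_fit(block_b, block_a), b_to_a = dir_fit(block_a, block_b))
}
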