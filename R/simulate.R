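# Synthetic multi-omic cohort generator with planted ground truth.
#
# The generator emulates the statistical structure the downstream analyses
# assume: lactobacilli-dominated compositional profiles partitioned into
# dominance-defined community types, a mixed-kind host factor table, and
# factor -> taxon effects planted on the arcsine-square-root scale so that
# the standard transformation makes them approximately linear.

sim_clade <- function(phylum, class, order, family, genus, species) {
  paste0("k__Bacteria|p__", phylum, "|c__", class, "|o__", order,
         "|f__", family, "|g__", genus, "|s__", genus, "_", species)
}

lacto <- function(sp) sim_clade("Firmicutes", "Bacilli", "Lactobacillales",
                                "Lactobacillaceae", "Lactobacillus", sp)

#' Default taxon panel for the simulator
#'
#' Thirty species-rank clade strings spanning the common vaginal community
#' dominants (lactobacilli, G. vaginalis, A. vaginae) plus accompanying
#' anaerobes and commensals.
#'
#' @return character vector of clade strings.
#' @export
default_taxa <- function() {
  c(lacto("crispatus"), lacto("iners"), lacto("gasseri"), lacto("jensenii"),
    lacto("johnsonii"), lacto("vaginalis"),
    sim_clade("Actinobacteria", "Actinobacteria", "Bifidobacteriales",
              "Bifidobacteriaceae", "Gardnerella", "vaginalis"),
    sim_clade("Actinobacteria", "Coriobacteriia", "Coriobacteriales",
              "Coriobacteriaceae", "Atopobium", "vaginae"),
    sim_clade("Actinobacteria", "Actinobacteria", "Bifidobacteriales",
              "Bifidobacteriaceae", "Bifidobacterium", "breve"),
    sim_clade("Bacteroidetes", "Bacteroidia", "Bacteroidales",
              "Prevotellaceae", "Prevotella", "bivia"),
    sim_clade("Bacteroidetes", "Bacteroidia", "Bacteroidales",
              "Prevotellaceae", "Prevotella", "timonensis"),
    sim_clade("Firmicutes", "Bacilli", "Lactobacillales", "Streptococcaceae",
              "Streptococcus", "anginosus"),
    sim_clade("Firmicutes", "Bacilli", "Lactobacillales", "Streptococcaceae",
              "Streptococcus", "agalactiae"),
    sim_clade("Firmicutes", "Negativicutes", "Veillonellales",
              "Veillonellaceae", "Megasphaera", "genomosp"),
    sim_clade("Firmicutes", "Clostridia", "Clostridiales",
              "Peptoniphilaceae", "Peptoniphilus", "harei"),
    sim_clade("Firmicutes", "Clostridia", "Clostridiales",
              "Peptoniphilaceae", "Anaerococcus", "tetradius"),
    sim_clade("Firmicutes", "Clostridia", "Clostridiales",
              "Peptoniphilaceae", "Finegoldia", "magna"),
    sim_clade("Actinobacteria", "Actinobacteria", "Actinomycetales",
              "Actinomycetaceae", "Mobiluncus", "curtisii"),
    sim_clade("Fusobacteria", "Fusobacteriia", "Fusobacteriales",
              "Leptotrichiaceae", "Sneathia", "amnii"),
    sim_clade("Fusobacteria", "Fusobacteriia", "Fusobacteriales",
              "Leptotrichiaceae", "Sneathia", "sanguinegens"),
    sim_clade("Proteobacteria", "Gammaproteobacteria", "Enterobacterales",
              "Enterobacteriaceae", "Escherichia", "coli"),
    sim_clade("Tenericutes", "Mollicutes", "Mycoplasmatales",
              "Mycoplasmataceae", "Ureaplasma", "parvum"),
    sim_clade("Tenericutes", "Mollicutes", "Mycoplasmatales",
              "Mycoplasmataceae", "Mycoplasma", "hominis"),
    sim_clade("Chlamydiae", "Chlamydiia", "Chlamydiales", "Chlamydiaceae",
              "Chlamydia", "trachomatis"),
    sim_clade("Actinobacteria", "Actinobacteria", "Corynebacteriales",
              "Corynebacteriaceae", "Corynebacterium", "amycolatum"),
    sim_clade("Firmicutes", "Bacilli", "Bacillales", "Staphylococcaceae",
              "Staphylococcus", "epidermidis"),
    sim_clade("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae",
              "Shuttleworthia", "satelles"),
    sim_clade("Bacteroidetes", "Bacteroidia", "Bacteroidales",
              "Porphyromonadaceae", "Porphyromonas", "uenonis"),
    sim_clade("Actinobacteria", "Actinobacteria", "Actinomycetales",
              "Actinomycetaceae", "Varibaculum", "cambriense"),
    sim_clade("Firmicutes", "Clostridia", "Clostridiales",
              "Clostridiales_Family_XI", "Parvimonas", "micra"),
    sim_clade("Proteobacteria", "Gammaproteobacteria", "Pasteurellales",
              "Pasteurellaceae", "Haemophilus", "influenzae"))
}

#' Default host factor panel
#'
#' A mixed-kind questionnaire-style factor set: binary history items, ordinal
#' counts, a nominal category and continuous measurements.
#'
#' @param n_factors total number of factors (default 20); kinds are cycled
#'   binary / ordinal / continuous with one nominal factor.
#' @return list of factor specifications (`name`, `kind`, parameters).
#' @export
default_factors <- function(n_factors = 20L) {
  specs <- list()
  kinds <- rep(c("binary", "ordinal", "continuous"), length.out = n_factors)
  kinds[min(6L, n_factors)] <- "nominal"
  for (i in seq_len(n_factors)) {
    specs[[i]] <- switch(kinds[i],
      binary = list(name = sprintf("factor%02d_bin", i), kind = "binary", p = 0.4),
      ordinal = list(name = sprintf("factor%02d_ord", i), kind = "ordinal",
                     probs = c(0.4, 0.3, 0.2, 0.1)),
      nominal = list(name = sprintf("factor%02d_nom", i), kind = "nominal",
                     levels = c("A", "B", "C"), probs = c(0.5, 0.3, 0.2)),
      continuous = list(name = sprintf("factor%02d_cont", i), kind = "continuous",
                        mean = 0, sd = 1))
  }
  specs
}

#' Simulator configuration
#'
#' @param n_samples cohort size (>= 2).
#' @param taxa clade-string taxon panel (default [default_taxa()]).
#' @param type_weights named probabilities over community-type labels;
#'   names are species labels (matched against the `s__` suffix) or
#'   `"diverse"`; must sum to 1.
#' @param dominance_conc Dirichlet concentration of the dominant taxon
#'   (default 10, against a total companion mass of 4): the dominant share is
#'   approximately Beta(10, 4), and draws below the 0.5 dominance threshold
#'   are rejected and redrawn so planted type labels are exact.
#' @param diverse_conc symmetric concentration for "diverse" samples
#'   (default 0.7); draws where any taxon reaches 0.5 are rejected.
#' @param factors factor specification list (default [default_factors()]).
#' @param effects list of planted effects, each
#'   `list(factor=, taxon=, effect_size=, sign=)`: the named taxon's
#'   arcsine-square-root-transformed abundance is shifted by
#'   `sign * effect_size * value` of the factor before renormalization.
#' @param missing_rate completely-at-random missingness applied to metadata
#'   only (default 0.05).
#' @param seed integer master seed; all draws derive from it.
#' @return validated configuration list (class `sim_config`).
#' @export
sim_config <- function(n_samples = 300L, taxa = default_taxa(),
                       type_weights = c("Lactobacillus_crispatus" = 0.25,
                                        "Lactobacillus_iners" = 0.23,
                                        "Gardnerella_vaginalis" = 0.12,
                                        "Lactobacillus_gasseri" = 0.05,
                                        "Lactobacillus_jensenii" = 0.05,
                                        diverse = 0.30),
                       dominance_conc = 10, diverse_conc = 0.7,
                       factors = default_factors(), effects = list(),
                       missing_rate = 0.05, seed = 1L) {
  stopifnot(n_samples >= 2, missing_rate >= 0, missing_rate < 1,
            dominance_conc > 0, diverse_conc > 0)
  if (abs(sum(type_weights) - 1) > 1e-9) stop("type_weights must sum to 1")
  labels <- taxon_label(taxa)
  fnames <- vapply(factors, `[[`, character(1), "name")
  for (tw in setdiff(names(type_weights), "diverse"))
    if (!tw %in% labels) stop("type label not in taxa: ", tw)
  for (ef in effects) {
    if (!ef$factor %in% fnames) stop("effect names unknown factor: ", ef$factor)
    if (!ef$taxon %in% labels && !ef$taxon %in% taxa)
      stop("effect names unknown taxon: ", ef$taxon)
    if (ef$effect_size < 0) stop("effect_size must be >= 0")
    if (!ef$sign %in% c(-1, 1)) stop("effect sign must be +1 or -1")
  }
  kinds <- vapply(factors, `[[`, character(1), "kind")
  bad <- setdiff(kinds, c("binary", "ordinal", "nominal", "continuous"))
  if (length(bad)) stop("unknown factor kind: ", paste(bad, collapse = ", "))
  if (any(kinds[vapply(effects, function(e) match(e$factor, fnames), 1L)] == "nominal"))
    stop("planted effects on nominal factors are not supported")
  structure(list(n_samples = as.integer(n_samples), taxa = taxa,
                 type_weights = type_weights, dominance_conc = dominance_conc,
                 diverse_conc = diverse_conc, factors = factors,
                 effects = effects, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

draw_composition <- function(type, config, labels) {
  K <- length(config$taxa)
  if (type == "diverse") {
    for (i in 1:100) {
      x <- rdirichlet1(rep(config$diverse_conc, K))
      if (max(x) < 0.5) return(x)
    }
    # bounded retries exhausted: shrink towards uniform until under the cap
    while (max(x) >= 0.5) x <- 0.5 * (x + 1 / K)
    return(x)
  }
  j <- match(type, labels)
  alpha <- rep(4 / (K - 1), K)
  alpha[j] <- config$dominance_conc
  best <- NULL
  for (i in 1:100) {
    x <- rdirichlet1(alpha)
    if (x[j] >= 0.5) return(x)
    if (is.null(best) || x[j] > best[j]) best <- x
  }
  # bounded retries exhausted: pin the dominant share just above threshold
  best[j] <- 0
  best <- best / sum(best) * 0.45
  best[j] <- 0.55
  best
}

draw_factor <- function(spec, n) {
  switch(spec$kind,
    binary = rbinom(n, 1, spec$p),
    ordinal = sample(seq_along(spec$probs) - 1L, n, TRUE, spec$probs),
    nominal = sample(spec$levels, n, TRUE, spec$probs),
    continuous = rnorm(n, spec$mean, spec$sd))
}

factor_numeric <- function(x, kind) {
  if (kind == "nominal") stop("nominal factors carry no planted effects")
  as.numeric(x)
}

#' Generate a synthetic multi-omic cohort
#'
#' Draws a community type per sample, a Dirichlet composition conditional on
#' the type (rejection-sampled so the planted dominance labels are exact), a
#' mixed-kind factor table, and realizes each planted effect by shifting the
#' target taxon's arcsine-square-root-transformed abundance by
#' `sign * effect_size * factor_value` before back-transforming and
#' renormalizing the sample. Metadata missingness is applied completely at
#' random after the effects are realized. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list: `abundance` ([abundance_table()]), `metadata`
#'   ([metadata_table()]), `truth` (per-sample `types`, planted `edges`
#'   data.frame).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    labels <- taxon_label(config$taxa)
    types <- sample(names(config$type_weights), n, TRUE, config$type_weights)
    comp <- t(vapply(types, draw_composition, numeric(length(config$taxa)),
                     config = config, labels = labels))
    dimnames(comp) <- list(sprintf("S%04d", seq_len(n)), config$taxa)

    kinds <- vapply(config$factors, `[[`, character(1), "kind")
    names(kinds) <- vapply(config$factors, `[[`, character(1), "name")
    meta <- as.data.frame(lapply(config$factors, draw_factor, n = n),
                          col.names = names(kinds))
    rownames(meta) <- rownames(comp)

    for (ef in config$effects) {
      j <- if (ef$taxon %in% labels) match(ef$taxon, labels)
           else match(ef$taxon, config$taxa)
      v <- factor_numeric(meta[[ef$factor]], kinds[[ef$factor]])
      y <- asin(sqrt(comp[, j]))
      y <- pmin(pmax(y + ef$sign * ef$effect_size * v, 0), pi / 2)
      comp[, j] <- sin(y)^2
    }
    comp <- comp / rowSums(comp)

    if (config$missing_rate > 0) {
      mask <- matrix(runif(n * ncol(meta)) < config$missing_rate, n)
      for (j in seq_len(ncol(meta))) meta[mask[, j], j] <- NA
    }

    edges <- if (length(config$effects)) {
      data.frame(factor = vapply(config$effects, `[[`, character(1), "factor"),
                 taxon = vapply(config$effects, function(e)
                   if (e$taxon %in% labels) e$taxon else taxon_label(e$taxon),
                   character(1)),
                 sign = vapply(config$effects, `[[`, numeric(1), "sign"),
                 effect_size = vapply(config$effects, `[[`, numeric(1),
                                      "effect_size"),
                 stringsAsFactors = FALSE)
    } else data.frame(factor = character(), taxon = character(),
                      sign = numeric(), effect_size = numeric())

    list(abundance = abundance_table(comp),
         metadata = metadata_table(meta, kinds),
         truth = list(types = setNames(types, rownames(comp)), edges = edges))
  })
}

#' Generate a replicate cohort sharing the same planted truth
#'
#' Re-runs [generate_cohort()] with the same configuration (hence identical
#' planted edges) under an independent seed, after checking the supplied
#' truth is consistent with the configuration.
#'
#' @param config the [sim_config()] used for the first cohort.
#' @param truth the `truth` element returned by [generate_cohort()].
#' @param seed2 seed for the replicate (must differ from `config$seed` for
#'   independent noise).
#' @return as [generate_cohort()].
#' @export
generate_replicate_cohort <- function(config, truth, seed2) {
  stopifnot(inherits(config, "sim_config"))
  planted <- vapply(config$effects, function(e)
    paste(e$factor, taxon_label(e$taxon)), character(1))
  have <- paste(truth$edges$factor, truth$edges$taxon)
  if (!setequal(planted, have))
    stop("truth does not match the configuration's planted effects")
  config$seed <- as.integer(seed2)
  generate_cohort(config)
}

#' Write a generated cohort to disk
#'
#' Profiles as MetaPhlAn-style TSV (percentages), metadata as CSV with a
#' JSON kind sidecar, truth as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return invisibly, the written paths.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, paste0(prefix, "_profiles.tsv"))
  mp <- file.path(dir, paste0(prefix, "_metadata.csv"))
  tp <- file.path(dir, paste0(prefix, "_truth.json"))
  write_profile_table(cohort$abundance, pp)
  write_metadata_table(cohort$metadata, mp)
  jsonlite::write_json(list(types = as.list(cohort$truth$types),
                            edges = cohort$truth$edges),
                       tp, auto_unbox = TRUE, digits = NA)
  invisible(c(profiles = pp, metadata = mp, truth = tp))
}
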