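# Stage orchestration: simulate -> io/filter -> typing -> importance -> rda
# -> network -> replicate, with a JSON run manifest per stage.

#' Pipeline run configuration
#'
#' @param out_dir output directory.
#' @param seed global seed; every stage derives its own sub-seed.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "type", "importance", "rda", "network", "replicate")`.
#' @param profiles,metadata optional paths to existing input tables (used
#'   when `"simulate"` is not among the stages).
#' @param sim a [sim_config()] for the simulate stage.
#' @param consensus a [consensus_config()].
#' @param n_perm permutations for the importance and rda stages.
#' @param alpha forward-selection cutoff.
#' @param replicate_seed seed for the replicate cohort.
#' @return configuration list.
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c("simulate", "type", "importance", "rda",
                                  "network", "replicate"),
                       profiles = NULL, metadata = NULL,
                       sim = sim_config(seed = seed),
                       consensus = consensus_config(),
                       n_perm = 99L, alpha = 0.05,
                       replicate_seed = next_seed(seed, 7L)) {
  known <- c("simulate", "type", "importance", "rda", "network", "replicate")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
       profiles = profiles, metadata = metadata, sim = sim,
       consensus = consensus, n_perm = as.integer(n_perm), alpha = alpha,
       replicate_seed = as.integer(replicate_seed))
}

write_manifest <- function(dir, stage, inputs, outputs, config_digest, seed) {
  md5_by_name <- function(paths) {
    if (!length(paths)) return(list())
    as.list(setNames(unname(tools::md5sum(paths)), basename(paths)))
  }
  manifest <- list(stage = stage, seed = seed, config_md5 = config_digest,
                   inputs = md5_by_name(inputs), outputs = md5_by_name(outputs))
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  # analysis parameters only: paths differ across reruns of the same analysis
  slim <- config[setdiff(names(config),
                         c("sim", "consensus", "out_dir", "profiles", "metadata"))]
  slim$sim_seed <- config$sim$seed
  slim$sim_n <- config$sim$n_samples
  jsonlite::write_json(slim, tmp, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline
#'
#' Executes the toggled stages on a synthetic or supplied cohort and writes
#' every artifact together with a JSON manifest (input/output checksums,
#' seed, config digest). Reruns with an identical configuration reproduce
#' identical outputs.
#'
#' @param config see [run_config()].
#' @return invisibly, a list of per-stage manifest paths and key results.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dg <- config_digest(config)
  manifests <- list()
  results <- list()

  cohort <- NULL
  if ("simulate" %in% config$stages) {
    cohort <- generate_cohort(config$sim)
    paths <- write_cohort(cohort, config$out_dir, "cohort1")
    manifests$simulate <- write_manifest(config$out_dir, "simulate",
                                         character(), paths, dg, config$seed)
  } else {
    if (is.null(config$profiles) || is.null(config$metadata))
      stop("profiles/metadata paths required when not simulating")
    cohort <- list(abundance = read_profile_table(config$profiles),
                   metadata = read_metadata_table(config$metadata))
  }
  abund <- cohort$abundance
  meta <- cohort$metadata

  if ("type" %in% config$stages) {
    ty <- assign_types(abund)
    ord <- cluster_order(prevalence_filter(abund, config$consensus$prevalence_min))
    tp <- file.path(config$out_dir, "community_types.tsv")
    write.table(ty[ord$order, ], tp, sep = "\t", quote = FALSE, row.names = FALSE)
    manifests$type <- write_manifest(config$out_dir, "type", character(), tp,
                                     dg, config$seed)
    results$types <- ty
  }

  prep <- preprocess_multiomics(meta, abund, config$consensus)

  if ("importance" %in% config$stages) {
    imp <- importance_screen(prep$taxa, prep$coded, n_perm = config$n_perm,
                             k_folds = config$consensus$k_folds,
                             seed = next_seed(config$seed, 2L),
                             control = config$consensus$rf)
    ip <- file.path(config$out_dir, "importance.tsv")
    write.table(imp, ip, sep = "\t", quote = FALSE, row.names = FALSE)
    manifests$importance <- write_manifest(config$out_dir, "importance",
                                           character(), ip, dg, config$seed)
    results$importance <- imp
  }

  if ("rda" %in% config$stages) {
    sel <- forward_select(prep$taxa, prep$coded_std, alpha = config$alpha,
                          n_perm = config$n_perm,
                          seed = next_seed(config$seed, 3L))
    rp <- file.path(config$out_dir, "rda_forward_selection.tsv")
    write.table(sel$trace, rp, sep = "\t", quote = FALSE, row.names = FALSE)
    sp <- file.path(config$out_dir, "rda_summary.json")
    jsonlite::write_json(list(selected = sel$selected,
                              stop_reason = sel$stop_reason,
                              global_adj_r2 = sel$global_adj_r2),
                         sp, auto_unbox = TRUE, digits = NA)
    manifests$rda <- write_manifest(config$out_dir, "rda", character(),
                                    c(rp, sp), dg, config$seed)
    results$rda <- sel
  }

  net <- NULL
  if ("network" %in% config$stages) {
    net <- build_consensus_network(meta, abund, config$consensus,
                                   seed = next_seed(config$seed, 4L))
    np <- if (nrow(net$retained)) {
      export_network(net$retained, file.path(config$out_dir, "network"))
    } else character()
    cp <- file.path(config$out_dir, "network_counts.json")
    jsonlite::write_json(net$counts, cp, auto_unbox = TRUE, digits = NA)
    manifests$network <- write_manifest(config$out_dir, "network", character(),
                                        c(unname(np), cp), dg, config$seed)
    results$network <- net
  }

  if ("replicate" %in% config$stages) {
    if (is.null(net)) stop("replicate stage requires the network stage")
    cohort2 <- generate_replicate_cohort(config$sim, cohort$truth,
                                         config$replicate_seed)
    write_cohort(cohort2, config$out_dir, "cohort2")
    net2 <- build_consensus_network(cohort2$metadata, cohort2$abundance,
                                    config$consensus,
                                    seed = next_seed(config$seed, 5L))
    rep <- replicate_edges(net$retained, net2$retained, config$consensus)
    pp <- file.path(config$out_dir, "replication.tsv")
    write.table(rep, pp, sep = "\t", quote = FALSE, row.names = FALSE)
    manifests$replicate <- write_manifest(config$out_dir, "replicate",
                                          character(), pp, dg, config$seed)
    results$replication <- rep
  }

  invisible(list(manifests = manifests, results = results))
}

#' Command-line entry point
#'
#' Minimal subcommand CLI (`simulate`, `type`, `importance`, `rda`,
#' `network`, `replicate`, `all`) with flags `--out`, `--seed`, `--n-perm`,
#' `--top-k`, `--q-max`, `--n-samples`. Exits non-zero on failure. Install
#' target: `inst/scripts/momnet`.
#'
#' @param args character vector of arguments (default: the command line).
#' @return exit status, invisibly (0 ok, 1 stage failure, 2 config error).
#' @export
momnet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: momnet <simulate|type|importance|rda|network|replicate|all>",
                 "[--out DIR] [--seed N] [--n-perm N] [--top-k N] [--q-max X]",
                 "[--n-samples N]")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  opts <- list(out = "momnet_out", seed = 1L, `n-perm` = 99L, `top-k` = 5L,
               `q-max` = 0.1, `n-samples` = 150L)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts) || i == length(args)) {
      message("bad flag: ", args[i], "\n", usage)
      return(invisible(2L))
    }
    opts[[key]] <- utils::type.convert(args[i + 1], as.is = TRUE)
    i <- i + 2
  }
  stages <- if (cmd == "all") {
    c("simulate", "type", "importance", "rda", "network", "replicate")
  } else if (cmd %in% c("simulate", "type", "importance", "rda", "network",
                        "replicate")) {
    unique(c("simulate", if (cmd == "replicate") "network", cmd))
  } else {
    message("unknown command: ", cmd, "\n", usage)
    return(invisible(2L))
  }
  cfg <- run_config(out_dir = opts$out, seed = as.integer(opts$seed),
                    stages = stages,
                    sim = sim_config(n_samples = opts$`n-samples`,
                                     seed = as.integer(opts$seed)),
                    consensus = consensus_config(top_k = opts$`top-k`,
                                                 q_max = opts$`q-max`),
                    n_perm = as.integer(opts$`n-perm`))
  status <- tryCatch({ run_pipeline(cfg); 0L },
                     error = function(e) { message("stage failure: ",
                                                   conditionMessage(e)); 1L })
  invisible(status)
}
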