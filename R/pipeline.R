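## Run configuration, end-to-end orchestration and a thin CLI.

#' Default run configuration
#'
#' Every stochastic stage receives an explicit seed derived from
#' `config$seed`; the whole configuration is echoed verbatim into the
#' run log.  The default scenario is a small, quick demonstration
#' cross; the simulation defaults inside [sim_scenario()] carry the
#' full-protocol values.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    n_lines = 100,
    chromosomes = c("1" = 100, "2" = 100, "3" = 100),
    marker_spacing = 10,
    times = seq(0, 180, by = 12),
    qtl_effects = data.frame(
      chr = c("1", "2"), pos = c(50, 30), param = c("mu", "A"),
      effect = c(0.15, 8), stringsAsFactors = FALSE),
    obs_sd = 1.5,
    step_cM = 2,
    error_prob = 0.002,
    n_perm = 150,
    alpha = 0.05,
    max_qtl = 6,
    link_dist_cM = 10,
    match_dist_cM = 10,
    proteome = list(n_genes = 40, n_intervals = 2, divergence = 0.1,
                    paralog = list(n = 6, divergence = 0.35, n_fail = 0)),
    min_score = 50)
  ovr <- list(...)
  cfg[names(ovr)] <- ovr
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file; keys override [default_config()].
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  ovr <- yaml::read_yaml(path)
  if (!is.null(ovr$qtl_effects)) ovr$qtl_effects <-
    as.data.frame(do.call(rbind, lapply(ovr$qtl_effects, as.data.frame)))
  do.call(default_config, ovr)
}

#' Run the full pipeline on a simulated scenario
#'
#' simulate -> phenotype table -> curve fits -> tQTL and pQTL maps ->
#' track linking and matching -> heatmap -> proteome simulation ->
#' interval orthology -> candidate table, with every artifact written
#' under `out_dir` and a run log recording version, seeds, config and
#' input digests.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created).
#' @return Named list of output paths and key results, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  map <- simulate_genetic_map(config$chromosomes, config$marker_spacing)
  cross <- simulate_ril_genotypes(map, config$n_lines,
                                  seed = config$seed)
  paths$cross <- write_cross(cross, file.path(out_dir, "genotypes.csv"))
  scen <- sim_scenario(qtl_effects = config$qtl_effects,
                       obs_sd = config$obs_sd, times = config$times,
                       seed = config$seed + 1)
  sim <- simulate_phenotypes(cross, scen)
  paths$angles <- write_angles(sim$angles, sim$times,
                               file.path(out_dir, "angles.csv"))
  paths$truth <- write_truth(sim$truth,
                             file.path(out_dir, "phenotype_truth.json"))
  params <- fit_parameter_table(sim$angles, sim$times)
  paths$parameters <- write_parameters(params,
                                       file.path(out_dir, "parameters.csv"))
  gp <- calc_genoprob(cross, step_cM = config$step_cM,
                      error_prob = config$error_prob)
  tq <- map_tqtl(gp, sim$angles, sim$times, n_perm = config$n_perm,
                 alpha = config$alpha, seed = config$seed + 100,
                 max_qtl = config$max_qtl)
  hm_path <- file.path(out_dir, "tqtl_heatmap.png")
  render_heatmap(tq$heatmap, tq$info, tq$times, hm_path)
  paths$heatmap <- hm_path
  utils::write.csv(data.frame(tq$info, tq$heatmap,
                              check.names = FALSE),
                   file.path(out_dir, "tqtl_heatmap.csv"),
                   row.names = FALSE)
  pq <- map_pqtl(gp, params, n_perm = config$n_perm, alpha = config$alpha,
                 seed = config$seed + 200, max_qtl = config$max_qtl)
  paths$pqtl <- write_qtl_model(pq, file.path(out_dir, "pqtl_models.json"))
  tracks <- link_tqtl_over_time(tq, link_dist_cM = config$link_dist_cM)
  mt <- match_tqtl_pqtl(tracks, pq, match_dist_cM = config$match_dist_cM)
  paths$match <- write_tsv_table(mt$summary,
                                 file.path(out_dir, "track_match.tsv"))
  pr <- config$proteome
  sp <- simulate_proteomes(n_genes = pr$n_genes,
                           n_intervals = pr$n_intervals,
                           divergence = pr$divergence,
                           paralog_spec = pr$paralog,
                           seed = config$seed + 300,
                           out_dir = file.path(out_dir, "proteomes"))
  orth <- qtl_orthologs(
    sp$annotations$a, sp$proteomes$a, sp$intervals$a, sp$anchors$a,
    sp$annotations$b, sp$proteomes$b, sp$intervals$b, sp$anchors$b,
    min_score = config$min_score)
  paths$bbh <- write_tsv_table(orth$table, file.path(out_dir, "bbh_table.tsv"))

  log_path <- file.path(out_dir, "run.log")
  digests <- tools::md5sum(unlist(paths[c("cross", "angles")]))
  writeLines(c(
    sprintf("graviqtl %s", as.character(utils::packageVersion("graviqtl"))),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "config:", yaml::as.yaml(unclass(config)),
    "input digests:",
    sprintf("  %s  %s", digests, names(digests))), log_path)
  paths$log <- log_path
  invisible(list(paths = paths, tqtl = tq, pqtl = pq, tracks = tracks,
                 match = mt, orthology = orth))
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions.  Subcommands:
#' `simulate`, `phenotype`, `fit`, `scan`, `tqtl`, `pqtl`, `orthology`,
#' `report`, `all`.  Returns an exit status instead of quitting so it
#' can be tested in-process; the installed script
#' `inst/cli/graviqtl.R` forwards `commandArgs()` and quits with the
#' returned status.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status (0 = success).
#' @export
cli_main <- function(argv) {
  usage <- paste(
    "usage: graviqtl <simulate|phenotype|fit|scan|tqtl|pqtl|orthology|report|all>",
    "[--config FILE] [--out DIR] [--seed N] [--pheno FILE] [--cross FILE]",
    sep = "\n  ")
  if (length(argv) < 1) { message(usage); return(1L) }
  cmd <- argv[1]
  known <- c("simulate", "phenotype", "fit", "scan", "tqtl", "pqtl",
             "orthology", "report", "all")
  if (!cmd %in% known) {
    message("unknown subcommand: ", cmd, "\n", usage)
    return(1L)
  }
  opts <- list(out = "graviqtl_out")
  i <- 2
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (i + 1 > length(argv)) { message("missing value for --", key); return(1L) }
    opts[[key]] <- argv[i + 1]
    i <- i + 2
  }
  cfg <- if (!is.null(opts$config)) read_config(opts$config) else
    default_config()
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  out <- opts$out
  res <- try(switch(
    cmd,
    all = run_pipeline(cfg, out),
    simulate = {
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      map <- simulate_genetic_map(cfg$chromosomes, cfg$marker_spacing)
      cross <- simulate_ril_genotypes(map, cfg$n_lines, seed = cfg$seed)
      write_cross(cross, file.path(out, "genotypes.csv"))
      sim <- simulate_phenotypes(cross, sim_scenario(
        qtl_effects = cfg$qtl_effects, obs_sd = cfg$obs_sd,
        times = cfg$times, seed = cfg$seed + 1))
      write_angles(sim$angles, sim$times, file.path(out, "angles.csv"))
      write_truth(sim$truth, file.path(out, "phenotype_truth.json"))
    },
    phenotype = {
      if (is.null(opts$images)) stop("phenotype needs --images DIR")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      files <- sort(list.files(opts$images, pattern = "\\.(png|tif|tiff)$",
                               full.names = TRUE))
      if (length(files) == 0) stop("no images found in ", opts$images)
      frames <- read_image_stack(files)
      times <- seq(0, by = 3, length.out = length(frames))
      s <- measure_series(frames, times)
      write_angles(matrix(s$angles, 1, dimnames = list(s$id, NULL)),
                   s$times, file.path(out, "angles.csv"))
    },
    fit = {
      if (is.null(opts$pheno)) stop("fit needs --pheno angles.csv")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      a <- read_angles(opts$pheno)
      write_parameters(fit_parameter_table(a$angles, a$times),
                       file.path(out, "parameters.csv"))
    },
    scan = ,
    tqtl = ,
    pqtl = {
      if (is.null(opts$cross) || is.null(opts$pheno))
        stop(cmd, " needs --cross genotypes.csv and --pheno FILE")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      cross <- read_cross(opts$cross)
      gp <- calc_genoprob(cross, step_cM = cfg$step_cM,
                          error_prob = cfg$error_prob)
      if (cmd == "pqtl") {
        params <- read_parameters(opts$pheno)
        pq <- map_pqtl(gp, params, n_perm = cfg$n_perm, alpha = cfg$alpha,
                       seed = cfg$seed)
        write_qtl_model(pq, file.path(out, "pqtl_models.json"))
      } else {
        a <- read_angles(opts$pheno)
        if (cmd == "scan") {
          sc <- scanone_hk(gp, a$angles[, ncol(a$angles)])
          utils::write.csv(sc, file.path(out, "scan.csv"),
                           row.names = FALSE)
        } else {
          tq <- map_tqtl(gp, a$angles, a$times, n_perm = cfg$n_perm,
                         alpha = cfg$alpha, seed = cfg$seed)
          render_heatmap(tq$heatmap, tq$info, tq$times,
                         file.path(out, "tqtl_heatmap.png"))
        }
      }
    },
    orthology = {
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      pr <- cfg$proteome
      sp <- simulate_proteomes(n_genes = pr$n_genes,
                               n_intervals = pr$n_intervals,
                               divergence = pr$divergence,
                               paralog_spec = pr$paralog, seed = cfg$seed,
                               out_dir = file.path(out, "proteomes"))
      orth <- qtl_orthologs(
        sp$annotations$a, sp$proteomes$a, sp$intervals$a, sp$anchors$a,
        sp$annotations$b, sp$proteomes$b, sp$intervals$b, sp$anchors$b,
        min_score = cfg$min_score)
      write_tsv_table(orth$table, file.path(out, "bbh_table.tsv"))
    },
    report = {
      message("report: see run directory artifacts written by 'all'")
      NULL
    }), silent = TRUE)
  if (inherits(res, "try-error")) {
    message("error: ", attr(res, "condition")$message)
    return(1L)
  }
  if (is.integer(res) && length(res) == 1) return(res)
  0L
}
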