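#' Assemble a run configuration
#'
#' Exactly one input source: either paths to genotype/phenotype files or a
#' \code{\link{simulation_config}}. A JSON file with the same keys can be
#' loaded with \code{\link{load_run_config}}; explicit arguments override
#' file values.
#'
#' @param input either a \code{simulation_config} or a named list of paths
#'   (\code{raw1}, \code{map1}, \code{raw2}, \code{map2}, \code{pheno}).
#' @param model one of \code{"bayes-hom"}, \code{"bayes-het"},
#'   \code{"gblup"}.
#' @param partition_mode \code{"all"}, \code{"chromosome"} or
#'   \code{"window:N"} (e.g. \code{"window:100"}).
#' @param mcmc an \code{\link{mcmc_config}} (ignored for gblup).
#' @param out output directory.
#' @param seed integer seed.
#' @param force overwrite a partial output directory.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(input, model = c("bayes-het", "bayes-hom", "gblup"),
                       partition_mode = "window:100",
                       mcmc = mcmc_config(), out = "mtregvar_run",
                       seed = 1L, force = FALSE) {
  model <- match.arg(model)
  if (!inherits(input, "simulation_config")) {
    stopifnot(is.list(input),
              all(c("raw1", "map1", "raw2", "map2", "pheno") %in%
                    names(input)))
  }
  parse_partition_mode(partition_mode)  # validate early
  structure(list(input = input, model = model,
                 partition_mode = partition_mode, mcmc = mcmc, out = out,
                 seed = as.integer(seed), force = force),
            class = "run_config")
}

parse_partition_mode <- function(mode) {
  if (mode == "all") return(list(mode = "all_snp"))
  if (mode == "chromosome") return(list(mode = "per_chromosome"))
  if (grepl("^window:[0-9]+$", mode))
    return(list(mode = "fixed_size",
                window = as.integer(sub("^window:", "", mode))))
  stop(sprintf("invalid partition mode '%s' (use all | chromosome | window:N)",
               mode))
}

#' Load a run configuration from a JSON file
#'
#' Keys mirror \code{\link{run_config}} arguments; \code{mcmc} is a nested
#' object with \code{n_cycles}, \code{burn_in}, \code{thin}. Overrides given
#' as \code{...} win over file values.
#'
#' @param path JSON file.
#' @param ... overrides.
#' @return a \code{run_config}.
#' @export
load_run_config <- function(path, ...) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  over <- list(...)
  cfg[names(over)] <- over
  mc <- do.call(mcmc_config, as.list(cfg$mcmc %||% list()))
  run_config(input = as.list(cfg$input), model = cfg$model %||% "bayes-het",
             partition_mode = cfg$partition_mode %||% "window:100",
             mcmc = mc, out = cfg$out %||% "mtregvar_run",
             seed = cfg$seed %||% 1L, force = isTRUE(cfg$force))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end workflow
#'
#' Loads or simulates the two-population data, partitions the genome, fits
#' the requested model and writes a deterministic directory layout: an input
#' manifest with checksums, the region table, thinned chain samples (Bayes
#' models), per-region summaries, the model fit report and a log carrying
#' versions and the seed. The three partition scenarios are logged under
#' their conventional names (all SNP / per chromosome / per window).
#'
#' @param config a \code{\link{run_config}}.
#' @return invisibly, a list with the fitted object, the
#'   \code{model_fit_report} and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out
  if (dir.exists(out) && length(list.files(out)) > 0 && !config$force)
    stop(sprintf("output directory '%s' is non-empty; use force = TRUE", out))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  if (inherits(config$input, "simulation_config")) {
    sim_cfg <- config$input
    sim_cfg$seed <- config$seed
    sim <- simulate_dataset(sim_cfg)
    panels <- sim$panels
    drp <- list(sim$drp1, sim$drp2)
    input_files <- character(0)
  } else {
    paths <- unlist(config$input)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop(sprintf("input file(s) not found: %s",
                   paste(missing, collapse = ", ")))
    panels <- harmonize_panels(
      read_plink_raw(config$input$raw1, config$input$map1, "pop1"),
      read_plink_raw(config$input$raw2, config$input$map2, "pop2"))
    pops <- unique(read.table(config$input$pheno, header = TRUE,
                              sep = "\t")$population)
    if (length(pops) != 2) stop("phenotype file must carry two populations")
    drp <- list(read_drp_tsv(config$input$pheno, population = pops[1]),
                read_drp_tsv(config$input$pheno, population = pops[2]))
    input_files <- paths
  }

  pm <- parse_partition_mode(config$partition_mode)
  partition <- if (pm$mode == "fixed_size")
    partition_regions(panels[[1]]$map, "fixed_size", window = pm$window)
  else partition_regions(panels[[1]]$map, pm$mode)
  scenario <- c(all_snp = "all SNP", per_chromosome = "per chromosome",
                fixed_size = "per window")[[pm$mode]]

  write_region_bed(partition, panels[[1]]$map,
                   file.path(out, "regions.tsv"))

  mcmc <- config$mcmc
  mcmc$seed <- config$seed
  if (config$model == "gblup") {
    grm <- build_grm(panels)
    fit <- reml_bivariate(grm, drp)
    report <- totals_and_h2(fit)
    gebv <- gebv_from_components(grm, fit, drp)
    write.table(gebv, file.path(out, "gebv.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    fit <- if (config$model == "bayes-het")
      gibbs_heterogeneous(panels, drp, partition, mcmc)
    else gibbs_homogeneous(panels, drp, mcmc, partition = partition)
    report <- totals_and_h2(fit)
    regions <- summarize_regions(fit)
    write_region_results(regions, panels[[1]]$map, partition,
                         file.path(out, "region_summaries.tsv"))
    write.table(round(fit$samples, 10), file.path(out, "chain.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report_path <- file.path(out, "model_fit_report.json")
  jsonlite::write_json(unclass(report), report_path, auto_unbox = TRUE,
                       digits = NA)

  manifest <- list(
    created = "run",  # no timestamps: outputs must be bit-reproducible
    seed = config$seed, model = config$model,
    partition_mode = config$partition_mode, scenario = scenario,
    n_regions = nrow(partition),
    inputs = if (length(input_files))
      as.list(tools::md5sum(input_files)) else "simulated")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_lines <- c(
    sprintf("mtregvar %s | R %s", as.character(utils::packageVersion("mtregvar")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed=%d model=%s scenario=%s regions=%d", config$seed,
            config$model, scenario, nrow(partition)))
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(list(fit = fit, report = report, out = out,
                 partition = partition))
}

#' Truth-vs-estimate recovery experiment on synthetic data
#'
#' Repeatedly simulates a dataset, fits the requested models and tabulates
#' estimate against truth: bias, RMSE and 2-SE coverage for the total
#' genomic variance of each population, the total covariance and the overall
#' correlation, plus (heterogeneous model) the per-region correlation of the
#' estimated with the true region-variance proportions (Spearman).
#'
#' @param sim_config a \code{\link{simulation_config}} (its seed field is
#'   replaced per replicate, derived from \code{seed}).
#' @param models character subset of c("bayes-hom", "bayes-het", "gblup").
#' @param n_replicates number of replicates (>= 1).
#' @param mcmc an \code{\link{mcmc_config}} for the Bayes fits.
#' @param seed master seed; replicate r uses seed + r.
#' @return list of class \code{recovery_experiment}: \code{replicates}
#'   (long data.frame: replicate, model, quantity, truth, estimate, se) and
#'   \code{summary} (bias / RMSE / coverage per model x quantity).
#' @export
recovery_experiment <- function(sim_config, models = "bayes-het",
                                n_replicates = 10L,
                                mcmc = mcmc_config(6000, 2000, 5),
                                seed = 1L) {
  stopifnot(n_replicates >= 1)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    cfg <- sim_config
    cfg$seed <- as.integer(seed + r)
    sim <- simulate_dataset(cfg)
    truth <- sim$truth$totals
    for (model in models) {
      mc <- mcmc; mc$seed <- as.integer(seed + r)
      if (model == "gblup") {
        fit <- reml_bivariate(build_grm(sim$panels),
                              list(sim$drp1, sim$drp2))
        rep_ <- totals_and_h2(fit)
        extra <- NULL
      } else {
        fit <- if (model == "bayes-het")
          gibbs_heterogeneous(sim$panels, list(sim$drp1, sim$drp2),
                              sim$partition, mc)
        else gibbs_homogeneous(sim$panels, list(sim$drp1, sim$drp2), mc,
                               partition = sim$partition)
        rep_ <- totals_and_h2(fit)
        regions <- summarize_regions(fit)
        extra <- data.frame(
          replicate = r, model = model, quantity = "prop_rank_cor",
          truth = 1,
          estimate = cor(regions$prop_vg1,
                         sim$truth$regions$vg1 / sum(sim$truth$regions$vg1),
                         method = "spearman"),
          se = NA_real_)
      }
      rows[[length(rows) + 1L]] <- rbind(
        data.frame(replicate = r, model = model,
                   quantity = c("vg1_total", "vg2_total", "cov_total",
                                "corr_overall"),
                   truth = c(truth$vg1, truth$vg2, truth$cov, truth$corr),
                   estimate = c(rep_$va1, rep_$va2, rep_$cov, rep_$corr),
                   se = c(rep_$va1_se, rep_$va2_se, rep_$cov_se,
                          rep_$corr_se)),
        extra)
    }
  }
  reps <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(reps, reps[c("model", "quantity")]),
    function(g) data.frame(
      model = g$model[1], quantity = g$quantity[1],
      bias = mean(g$estimate - g$truth),
      rmse = sqrt(mean((g$estimate - g$truth)^2)),
      coverage_2se = mean(abs(g$estimate - g$truth) <= 2 * g$se))))
  rownames(agg) <- NULL
  structure(list(replicates = reps, summary = agg),
            class = "recovery_experiment")
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate}, \code{regions}, \code{bayes}, \code{gblup},
#' \code{summarize} (alias of running bayes/gblup through the pipeline) and
#' \code{recover}. Installed as \code{exec/mtregvar}; also callable as
#' \code{mtregvar_main(c("bayes", "--config", "run.json", ...))}.
#'
#' @param args character vector of command-line arguments (default: the
#'   process's).
#' @return exit status, invisibly.
#' @export
mtregvar_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mtregvar <simulate|regions|bayes|gblup|recover> [options]",
    "  common options: --config FILE.json --seed N --out DIR --force",
    "  bayes options:  --model hom|het --partition all|chromosome|window:N",
    "                  --cycles N --burnin N --thin N", sep = "\n")
  if (length(args) == 0) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1]; args <- args[-1]
  opt <- list(seed = 1L, out = "mtregvar_out", force = FALSE,
              model = "het", partition = "window:100",
              cycles = 50000L, burnin = 20000L, thin = 20L,
              config = NULL, replicates = 10L)
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (key == "force") { opt$force <- TRUE; i <- i + 1; next }
    if (i == length(args)) stop(sprintf("missing value for --%s", key))
    val <- args[i + 1]
    opt[[key]] <- if (key %in% c("seed", "cycles", "burnin", "thin",
                                 "replicates")) as.integer(val) else val
    i <- i + 2
  }
  mc <- mcmc_config(opt$cycles, opt$burnin, opt$thin, seed = opt$seed)
  switch(cmd,
    simulate = {
      sim <- simulate_dataset(simulation_config(seed = opt$seed))
      write_simulated_dataset(sim, opt$out)
      cat(sprintf("simulated dataset written to %s\n", opt$out))
    },
    regions = {
      if (is.null(opt$config)) stop("regions needs --config with input paths")
      cfg <- load_run_config(opt$config, out = opt$out, seed = opt$seed)
      panels <- harmonize_panels(
        read_plink_raw(cfg$input$raw1, cfg$input$map1, "pop1"),
        read_plink_raw(cfg$input$raw2, cfg$input$map2, "pop2"))
      pm <- parse_partition_mode(opt$partition)
      part <- if (pm$mode == "fixed_size")
        partition_regions(panels[[1]]$map, "fixed_size", pm$window)
      else partition_regions(panels[[1]]$map, pm$mode)
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      write_region_bed(part, panels[[1]]$map,
                       file.path(opt$out, "regions.tsv"))
      cat(sprintf("%d regions written\n", nrow(part)))
    },
    bayes = ,
    gblup = {
      model <- if (cmd == "gblup") "gblup"
               else if (opt$model == "hom") "bayes-hom" else "bayes-het"
      cfg <- if (!is.null(opt$config))
        load_run_config(opt$config, model = model,
                        partition_mode = opt$partition, out = opt$out,
                        seed = opt$seed, force = opt$force)
      else run_config(input = simulation_config(seed = opt$seed),
                      model = model, partition_mode = opt$partition,
                      mcmc = mc, out = opt$out, seed = opt$seed,
                      force = opt$force)
      cfg$mcmc <- mc
      res <- run_pipeline(cfg)
      print(res$report)
    },
    recover = {
      exp <- recovery_experiment(simulation_config(seed = opt$seed),
                                 models = if (opt$model == "gblup") "gblup"
                                 else paste0("bayes-",
                                             ifelse(opt$model == "hom",
                                                    "hom", "het")),
                                 n_replicates = opt$replicates,
                                 mcmc = mc, seed = opt$seed)
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      write.table(exp$replicates, file.path(opt$out, "replicates.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(exp$summary, file.path(opt$out, "summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      print(exp$summary)
    },
    { cat(usage, "\n"); return(invisible(1L)) })
  invisible(0L)
}
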