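#' Read and validate a pipeline run configuration
#'
#' Configurations are YAML (or an equivalent R list) with a versioned
#' schema. Recognised top-level keys: `version` (1), `seed`, `output_dir`,
#' `stages` (character vector from `simulate`, `fit_spectra`, `stark_fit`,
#' `broadening`, `fields`, `reaction_field`, `potential`), `stark`
#' (`dmu0`, `dalpha`, `nu_vac`, `dmu_hb`, `dalpha_hb`), `two_level`
#' (`gamma_angle`, `n`), `fit` (`constrain_extremum`), `simulate`
#' (arguments of [ensemble_spec()]), `inputs` (`protein_table`,
#' `spectra_manifest`, `structures`, `charge_table`), `electrostatics`
#' (`axis_from`, `axis_to`, `exclude`), `reaction_field` (`dmu_ind`,
#' `dalpha`, `cavity`).
#'
#' @param config path to a YAML file or a named list.
#' @return validated config list (class `run_config`).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    stopifnot(file.exists(config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    version = 1L, seed = 1L, output_dir = NULL, stages = character(0),
    stark = list(dmu0 = 4.47, dalpha = -35, nu_vac = 20725,
                 dmu_hb = NULL, dalpha_hb = -49),
    two_level = list(gamma_angle = 20, n = 1.33),
    fit = list(constrain_extremum = TRUE),
    simulate = list(), inputs = list(),
    electrostatics = list(axis_from = "CA2", axis_to = "CE2",
                          exclude = "none"),
    reaction_field = list()
  )
  cfg <- utils::modifyList(defaults, config)
  if (!identical(as.integer(cfg$version), 1L))
    stop("unsupported config version: ", cfg$version, call. = FALSE)
  known <- c("simulate", "fit_spectra", "stark_fit", "broadening",
             "fields", "reaction_field", "potential")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (p in c(cfg$inputs$protein_table, cfg$inputs$spectra_manifest,
              unlist(cfg$inputs$structures)))
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

.stage_log <- function(quiet, stage, msg) {
  if (!quiet)
    message(sprintf("[%s] %-14s %s", format(Sys.time(), "%H:%M:%S"),
                    stage, msg))
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in order -- `simulate` (synthetic ensemble
#' with ground truth), `fit_spectra` (paired 1PA/2PA decomposition to a
#' dipole-change table), `stark_fit` (ensemble parabola and derived
#' electro-optic constants), `broadening` (width-vs-dipole regression),
#' `fields` (per-protein total and, when a cluster reference is configured,
#' long-range field estimates), `reaction_field` (induced-dipole and
#' cavity-model solvent fields), `potential` (projected fields from
#' charge-annotated structures) -- and assembles a machine-readable report
#' with units in every key name and full provenance (config hash, seed,
#' package version). When `output_dir` is set the report is written to
#' `report.json` there.
#'
#' @param config path to a YAML config, or a list (see
#'   [read_run_config()]).
#' @param quiet suppress stage logging.
#' @return report list (class `pipeline_report`), invisibly when written to
#'   disk.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- read_run_config(config)
  report <- list(provenance = list(
    package = "starkfp",
    version = as.character(utils::packageVersion("starkfp")),
    seed = cfg$seed,
    config_hash = .config_hash(cfg),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ))
  st <- cfg$stark
  params_total <- stark_params(st$dmu0, st$dalpha, st$nu_vac, "vacuum")
  cfg2l <- two_level_config(cfg$two_level$gamma_angle, cfg$two_level$n)
  table <- NULL

  if ("simulate" %in% cfg$stages) {
    .stage_log(quiet, "simulate", "generating synthetic ensemble")
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    sim_args$stark <- params_total
    sim_args$cfg <- cfg2l
    spec <- do.call(ensemble_spec, sim_args)
    table <- gen_protein_ensemble(spec)
    if (!is.null(cfg$output_dir)) {
      dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
      write_protein_table(table, file.path(cfg$output_dir,
                                           "proteins.tsv"))
    }
    report$simulate <- list(n_proteins = nrow(table),
                            seed = sim_args$seed)
  }

  if ("fit_spectra" %in% cfg$stages) {
    man_path <- cfg$inputs$spectra_manifest
    if (is.null(man_path))
      stop("stage fit_spectra requires inputs$spectra_manifest",
           call. = FALSE)
    man <- utils::read.csv(man_path, strip.white = TRUE)
    stopifnot(all(c("name", "one_photon", "two_photon") %in% names(man)))
    base <- dirname(man_path)
    .stage_log(quiet, "fit_spectra",
               sprintf("decomposing %d spectrum pairs", nrow(man)))
    rows <- lapply(seq_len(nrow(man)), function(i) {
      nb <- if ("n_bands" %in% names(man)) man$n_bands[i] else 4L
      resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
      res <- analyze_spectra(read_spectrum(resolve(man$one_photon[i])),
                             read_spectrum(resolve(man$two_photon[i])),
                             n_bands = nb, cfg = cfg2l)
      data.frame(name = man$name[i], hb_class = "", dmu = res$dmu,
                 nu00 = res$nu00, w = res$width, eps00 = res$eps00,
                 sigma2_00 = res$sigma2_00, mu = res$mu)
    })
    table <- do.call(rbind, rows)
    report$fit_spectra <- lapply(seq_len(nrow(table)), function(i)
      list(name = table$name[i], dmu_D = table$dmu[i],
           nu00_cm1 = table$nu00[i], width_cm1 = table$w[i],
           mu_D = table$mu[i], sigma2_00_GM = table$sigma2_00[i]))
  }

  if (is.null(table) && !is.null(cfg$inputs$protein_table))
    table <- read_protein_table(cfg$inputs$protein_table)

  needs_table <- intersect(c("stark_fit", "broadening", "fields"),
                           cfg$stages)
  if (length(needs_table) && is.null(table))
    stop("stage(s) ", paste(needs_table, collapse = ", "),
         " need a protein table (simulate, fit_spectra or ",
         "inputs$protein_table)", call. = FALSE)

  if ("stark_fit" %in% cfg$stages) {
    .stage_log(quiet, "stark_fit",
               sprintf("fitting Stark parabola to %d proteins", nrow(table)))
    sf <- fit_stark_parabola(table$dmu, table$nu00, nu_vac = st$nu_vac,
                             constrain_extremum = cfg$fit$constrain_extremum)
    report$stark_fit <- list(
      A_cm1_D2 = sf$fit$A, B_cm1_D1 = sf$fit$B, C_cm1 = sf$fit$C,
      A_sd = sf$fit$param_sd[["A"]], C_sd = sf$fit$param_sd[["C"]],
      chi2 = sf$fit$chi2,
      dalpha_A3 = sf$derived[["dalpha"]],
      dalpha_sd_A3 = sf$derived[["dalpha_sd"]],
      dmu0_D = sf$derived[["dmu0"]], dmu0_sd_D = sf$derived[["dmu0_sd"]])
    if (!is.null(sf$params)) params_total <- sf$params
  }

  if ("broadening" %in% cfg$stages) {
    if (!"w" %in% names(table))
      stop("broadening stage needs a w column", call. = FALSE)
    .stage_log(quiet, "broadening", "regressing w^2 on dmu^2")
    bf <- fit_broadening(table$dmu, table$w)
    report$broadening <- list(
      deltaE_MVcm = bf$deltaE, deltaE_sd_MVcm = bf$deltaE_se,
      gamma_cm1 = bf$gamma, gamma_sd_cm1 = bf$gamma_se,
      degenerate = bf$degenerate)
  }

  if ("fields" %in% cfg$stages) {
    .stage_log(quiet, "fields", "per-protein field estimates")
    totals <- vapply(table$dmu, function(d)
      field_of_delta_mu(d, params_total)$value, numeric(1))
    fields <- data.frame(name = table$name, dmu_D = table$dmu,
                         E_total_MVcm = totals)
    if (!is.null(st$dmu_hb)) {
      params_lr <- stark_params(st$dmu_hb, st$dalpha_hb, st$nu_vac,
                                "cluster")
      fields$E_long_range_MVcm <- vapply(table$dmu, function(d)
        field_of_delta_mu(d, params_lr)$value, numeric(1))
    }
    report$fields <- fields
  }

  if ("reaction_field" %in% cfg$stages) {
    .stage_log(quiet, "reaction_field", "solvent reaction fields")
    rf <- cfg$reaction_field
    out <- list()
    if (!is.null(rf$dmu_ind)) {
      da <- rf$dalpha %||% st$dalpha
      out$induced <- lapply(rf$dmu_ind, function(d)
        list(dmu_ind_D = d,
             E_R_MVcm = reaction_field_induced(d, da)$value))
    }
    if (!is.null(rf$cavity)) {
      cm <- do.call(cavity_model, rf$cavity)
      out$cavity <- list(E_R_MVcm = reaction_field_cavity(cm)$value)
    }
    report$reaction_field <- out
  }

  if ("potential" %in% cfg$stages) {
    paths <- cfg$inputs$structures
    if (is.null(paths))
      stop("stage potential requires inputs$structures", call. = FALSE)
    el <- cfg$electrostatics
    report$potential <- lapply(paths, function(p) {
      .stage_log(quiet, "potential", paste("projecting", basename(p)))
      sys <- if (grepl("\\.pqr$", p, ignore.case = TRUE)) read_pqr(p)
        else read_pdb_charges(p, cfg$inputs$charge_table)
      excl <- el$exclude
      if (!is.null(excl) && !identical(excl, "none") &&
          !excl %in% names(sys$selections)) excl <- NULL
      af <- axis_field(sys, exclude = excl, axis_from = el$axis_from,
                       axis_to = el$axis_to)
      stats <- snapshot_statistics(af)
      list(structure = basename(p), E_MVcm = stats$mean,
           E_sd_MVcm = stats$sd, n_frames = af$n_frames,
           r2 = mean(af$r2, na.rm = TRUE))
    })
  }

  class(report) <- "pipeline_report"
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable hash of the canonicalised config (md5 of its JSON serialisation)
.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Command-line entry point
#'
#' Thin subcommand dispatcher intended for
#' `Rscript -e 'starkfp::starkfp_main()' <subcommand> ...`. Subcommands
#' `run`, `simulate`, `stark-fit`, `broadening`, `fields`,
#' `reaction-field`, `potential` map onto pipeline stages (`run` executes
#' the stage list from the config file). Flags: `--config`, `--seed`,
#' `--out`, `--table`, `--axis-from`, `--axis-to`, `--exclude`,
#' `--free-quadratic`, `--quiet`.
#'
#' @param args character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly (0 on success).
#' @export
starkfp_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: starkfp <run|simulate|stark-fit|broadening|fields|",
        "reaction-field|potential> [--config F] [--seed N] [--out DIR]\n",
        sep = "")
    return(invisible(1L))
  }
  sub <- args[[1]]
  rest <- args[-1]
  opt <- list(config = NULL, seed = NULL, out = NULL, table = NULL,
              axis_from = NULL, axis_to = NULL, exclude = NULL,
              free_quadratic = FALSE, quiet = FALSE)
  i <- 1L
  while (i <= length(rest)) {
    a <- rest[[i]]
    grab <- function() { i <<- i + 1L; rest[[i]] }
    switch(a,
      "--config" = { opt$config <- grab() },
      "--seed" = { opt$seed <- as.integer(grab()) },
      "--out" = { opt$out <- grab() },
      "--table" = { opt$table <- grab() },
      "--axis-from" = { opt$axis_from <- grab() },
      "--axis-to" = { opt$axis_to <- grab() },
      "--exclude" = { opt$exclude <- grab() },
      "--free-quadratic" = { opt$free_quadratic <- TRUE },
      "--constrain-extremum" = { opt$free_quadratic <- FALSE },
      "--quiet" = { opt$quiet <- TRUE },
      { message("unknown flag: ", a); return(invisible(1L)) }
    )
    i <- i + 1L
  }
  cfg <- if (!is.null(opt$config)) yaml::read_yaml(opt$config) else list()
  stage_map <- c("simulate" = "simulate", "fit-spectra" = "fit_spectra",
                 "stark-fit" = "stark_fit", "broadening" = "broadening",
                 "fields" = "fields", "reaction-field" = "reaction_field",
                 "potential" = "potential")
  if (sub %in% names(stage_map)) cfg$stages <- unname(stage_map[[sub]])
  else if (!identical(sub, "run")) {
    message("unknown subcommand: ", sub)
    return(invisible(1L))
  }
  if (!is.null(opt$seed)) cfg$seed <- opt$seed
  if (!is.null(opt$out)) cfg$output_dir <- opt$out
  if (!is.null(opt$table)) {
    cfg$inputs <- cfg$inputs %||% list()
    cfg$inputs$protein_table <- opt$table
  }
  el <- cfg$electrostatics %||% list()
  if (!is.null(opt$axis_from)) el$axis_from <- opt$axis_from
  if (!is.null(opt$axis_to)) el$axis_to <- opt$axis_to
  if (!is.null(opt$exclude)) el$exclude <- opt$exclude
  cfg$electrostatics <- el
  if (opt$free_quadratic) cfg$fit <- list(constrain_extremum = FALSE)
  status <- tryCatch({
    run_pipeline(cfg, quiet = opt$quiet)
    0L
  }, error = function(e) {
    message("pipeline failed: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
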