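# Orchestration: configuration, seeded end-to-end runs, tabular I/O with
# parameter provenance headers.

# small stable string digest (31-bit polynomial hash; exact in doubles)
.digest32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write / read a delimited table with a provenance comment header
#'
#' Tables are comma-delimited UTF-8 with a header row; lines starting with
#' `#` carry the seed and a digest of the generating parameters and are
#' skipped on read.
#'
#' @param df data.frame to write.
#' @param path File path.
#' @param seed Integer seed recorded in the header.
#' @param params Optional object whose deparsed form is digested into the
#'   header.
#' @return `write_table_seeded()` returns `path` invisibly;
#'   `read_table_seeded()` returns the data.frame with a `seed` attribute.
#' @export
write_table_seeded <- function(df, path, seed, params = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# germscreen seed=%d params_digest=%s", as.integer(seed),
                     .digest32(deparse(params))), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_seeded
#' @export
read_table_seeded <- function(path) {
  first <- readLines(path, n = 1)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  seed <- suppressWarnings(as.integer(sub(".*seed=([0-9]+).*", "\\1", first)))
  attr(df, "seed") <- seed
  df
}

#' Build a pipeline run configuration
#'
#' @param seed Integer RNG seed; recorded in every output.
#' @param out_dir Output directory (created if absent).
#' @param scenario Preset name; `"default"` runs the three follow-up
#'   chemicals plus vehicle, `"smoke"` a minimal two-chemical run.
#' @param alpha Significance level in `(0, 1)`.
#' @param n_events Sorter events per screened well.
#' @param n_gonads Gonads per cytology arm.
#' @param n_mothers Mothers per plate-phenotype arm.
#' @param n_calibration Events per calibration run.
#' @param benchmark Benchmark chemical for hit calling (`NULL`: rank only).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("germscreen-run-"),
                       scenario = c("default", "smoke"), alpha = 0.05,
                       n_events = 5000, n_gonads = 100, n_mothers = 100,
                       n_calibration = 4000, benchmark = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(alpha > 0, alpha < 1)
  if (scenario == "smoke") {
    n_events <- min(n_events, 500); n_gonads <- min(n_gonads, 30)
    n_mothers <- min(n_mothers, 30); n_calibration <- min(n_calibration, 1500)
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 scenario = scenario, alpha = alpha, n_events = n_events,
                 n_gonads = n_gonads, n_mothers = n_mothers,
                 n_calibration = n_calibration, benchmark = benchmark),
            class = "run_config")
}

#' Read a run configuration from a YAML key-value file
#'
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

.scenario_exposures <- function(scenario) {
  if (scenario == "smoke") {
    list(DMSO = exposure_preset("DMSO"), DBP = exposure_preset("DBP"),
         TCMTB = exposure_preset("TCMTB"))
  } else {
    list(DMSO = exposure_preset("DMSO"), DBP = exposure_preset("DBP"),
         permethrin = exposure_preset("permethrin"),
         TCMTB = exposure_preset("TCMTB"))
  }
}

#' Run the simulate-calibrate-screen-phenostats-qpcr pipeline
#'
#' Executes the stages in dependency order under a single seeded RNG
#' stream, writing per-stage CSV outputs (with seed/parameter provenance
#' headers), a calibration YAML, a JSON report and a log file into
#' `config$out_dir`. Running twice with the same configuration produces
#' byte-identical outputs.
#'
#' @param config A [run_config()] (or path to a YAML config file).
#' @param stages Character vector of stages to run; dependencies are added
#'   automatically. Default: all of `simulate`, `calibrate`, `screen`,
#'   `phenostats`, `qpcr`, `report`.
#' @return Invisible list with the screen summary, plate phenotypes,
#'   cytology results, qPCR results and output paths.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "calibrate", "screen",
                                    "phenostats", "qpcr", "report")) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "calibrate", "screen", "phenostats", "qpcr",
                  "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  # screening requires calibration; everything requires simulated inputs
  if (any(c("screen", "phenostats", "qpcr", "report") %in% stages)) {
    stages <- union(stages, "simulate")
  }
  if ("screen" %in% stages && !"calibrate" %in% stages) {
    stop("gating stage required: screening needs a calibration (add 'calibrate')")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- c(sprintf("germscreen %s", as.character(utils::packageVersion("germscreen"))),
                 sprintf("seed=%d scenario=%s", config$seed, config$scenario),
                 sprintf("config_digest=%s",  # output location excluded
                         .digest32(deparse(unclass(config)[names(config) != "out_dir"]))))
  set.seed(config$seed)
  strain <- strain_preset("col-121")
  exposures <- .scenario_exposures(config$scenario)
  out <- list(paths = list())
  k <- sim_constants()

  # -- simulate ------------------------------------------------------------
  events <- simulate_screen_events(exposures, strain,
                                   n_events = config$n_events, n_reps = 3)
  calib_stages <- c(debris = 0.1, L1 = 0.05, L2 = 0.05, L3 = 0.1, L4 = 0.3,
                    adult = 0.4)
  calib_neg <- simulate_biosort_run(strain, exposures$DMSO,
                                    config$n_calibration, calib_stages)
  calib_pos <- simulate_biosort_run(strain_preset("him-8"), exposures$DMSO,
                                    config$n_calibration, calib_stages)
  brood <- do.call(rbind, lapply(names(exposures), function(cc) {
    b <- simulate_brood(strain, exposures[[cc]], config$n_mothers)
    cbind(condition = cc, b)
  }))
  germ <- lapply(exposures, simulate_germline, strain = strain,
                 n_gonads = config$n_gonads)
  germ_cep1 <- lapply(exposures, simulate_germline,
                      strain = strain_preset("cep-1"),
                      n_gonads = config$n_gonads)
  ct_tab <- do.call(rbind, unlist(lapply(c(15, 25), function(temp) {
    lapply(exposures, function(ex) {
      simulate_qpcr(strain_preset("glp-1"), ex, temp,
                    n_bio = if (temp == 15) 3 else 4)
    })
  }), recursive = FALSE))
  if ("simulate" %in% stages) {
    p <- file.path(config$out_dir, "events.csv")
    write_table_seeded(events, p, config$seed, exposures)
    out$paths$events <- p
    p <- file.path(config$out_dir, "brood.csv")
    write_table_seeded(brood, p, config$seed, exposures)
    out$paths$brood <- p
    p <- file.path(config$out_dir, "ct_table.csv")
    write_table_seeded(ct_tab, p, config$seed, exposures)
    out$paths$ct_table <- p
    log_lines <- c(log_lines,
                   sprintf("events_digest=%s", .digest32(utils::capture.output(utils::write.csv(events, row.names = FALSE)))),
                   sprintf("brood_digest=%s", .digest32(utils::capture.output(utils::write.csv(brood, row.names = FALSE)))))
  }

  # -- calibrate -----------------------------------------------------------
  if ("calibrate" %in% stages) {
    gate <- fit_adult_gate(calib_neg)
    gated_neg <- calib_neg[calib_neg$tof >= gate$tof_min &
                           calib_neg$tof <= gate$tof_max, ]
    gated_pos <- calib_pos[calib_pos$tof >= gate$tof_min &
                           calib_pos$tof <= gate$tof_max, ]
    thr <- fit_gfp_threshold(gated_neg$gfp_peak, gated_pos$gfp_peak)
    p <- file.path(config$out_dir, "calibration.yml")
    write_calibration(gate, thr, p)
    out$paths$calibration <- p
    out$gate <- gate; out$threshold <- thr
    log_lines <- c(log_lines, sprintf("gate=[%.2f,%.2f] tau=%.3f",
                                      gate$tof_min, gate$tof_max, thr$tau))
  }

  # -- screen --------------------------------------------------------------
  if ("screen" %in% stages) {
    summary <- run_screen(events, out$gate, out$threshold, vehicle = "DMSO",
                          benchmark = config$benchmark)
    p <- file.path(config$out_dir, "screen_summary.csv")
    write_table_seeded(summary, p, config$seed, exposures)
    out$paths$screen_summary <- p
    out$screen <- summary
  }

  # -- phenostats ----------------------------------------------------------
  if ("phenostats" %in% stages) {
    out$plate <- plate_phenotypes(brood, vehicle = "DMSO")
    p <- file.path(config$out_dir, "plate_phenotypes.csv")
    write_table_seeded(out$plate, p, config$seed, exposures)
    out$paths$plate <- p
    chems <- setdiff(names(exposures), "DMSO")
    out$zones <- do.call(rbind, lapply(chems, function(cc) {
      cbind(condition = cc,
            zone_profile_compare(germ[[cc]]$foci, germ$DMSO$foci))
    }))
    p <- file.path(config$out_dir, "zone_profiles.csv")
    write_table_seeded(out$zones, p, config$seed, exposures)
    out$paths$zones <- p
    corpses <- do.call(rbind, c(
      lapply(names(exposures), function(cc) {
        data.frame(condition = cc, genotype = "col-121",
                   count = germ[[cc]]$corpses$corpse_count)
      }),
      lapply(names(exposures), function(cc) {
        data.frame(condition = cc, genotype = "cep-1",
                   count = germ_cep1[[cc]]$corpses$corpse_count)
      })))
    ca <- corpse_analysis(corpses, vehicle = "DMSO", alpha = config$alpha)
    out$corpses <- ca
    p <- file.path(config$out_dir, "corpse_summary.csv")
    write_table_seeded(ca$summary, p, config$seed, exposures)
    out$paths$corpses <- p
    out$diakinesis <- lapply(germ, function(g) diakinesis_tally(g$diakinesis))
    out$gonad_defects <- do.call(rbind, lapply(chems, function(cc) {
      cbind(condition = cc,
            gonad_defect_compare(germ[[cc]]$defects, germ$DMSO$defects))
    }))
    p <- file.path(config$out_dir, "gonad_defects.csv")
    write_table_seeded(out$gonad_defects, p, config$seed, exposures)
    out$paths$gonad_defects <- p
  }

  # -- qpcr ----------------------------------------------------------------
  if ("qpcr" %in% stages) {
    chems <- setdiff(names(exposures), "DMSO")
    out$qpcr <- lapply(chems, function(cc) {
      res <- qpcr_analysis(ct_tab, treated = cc, vehicle = "DMSO",
                           alpha = config$alpha)
      list(table = res, attribution = attr(res, "attribution"))
    })
    names(out$qpcr) <- chems
    flat <- do.call(rbind, lapply(chems, function(cc) {
      cbind(condition = cc, out$qpcr[[cc]]$table)
    }))
    p <- file.path(config$out_dir, "qpcr_results.csv")
    write_table_seeded(flat, p, config$seed, exposures)
    out$paths$qpcr <- p
  }

  # -- report --------------------------------------------------------------
  if ("report" %in% stages) {
    report <- list(seed = config$seed, scenario = config$scenario,
                   alpha = config$alpha,
                   n_chemicals = length(exposures) - 1)
    if (!is.null(out$screen)) {
      report$n_hits <- if ("hit" %in% names(out$screen))
        sum(out$screen$hit) else NA
      report$mean_folds <- stats::setNames(as.list(out$screen$mean_fold),
                                           out$screen$chemical)
    }
    if (!is.null(out$corpses)) {
      dep <- out$corpses$dependence
      if (!is.null(dep)) {
        report$cep1_dependence <- stats::setNames(as.list(dep$label),
                                                  dep$condition)
      }
    }
    p <- file.path(config$out_dir, "report.json")
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out$paths$report <- p
  }

  writeLines(log_lines, log_path)
  out$paths$log <- log_path
  invisible(out)
}
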