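# Well scoring, fold-increase aggregation, paired testing and hit calling.

#' Score one screened well from event classifications
#'
#' @param classes Factor from [classify_events()] for the well's events.
#' @return List of class `well_result`: `n_adults` (gated adults),
#'   `n_gfp_pos`, `fraction`.
#' @export
score_well <- function(classes) {
  n_adults <- sum(classes != "out_of_gate")
  if (n_adults == 0) stop("well failed: no gated adults")
  n_pos <- sum(classes == "adult_gfp_pos")
  structure(list(n_adults = n_adults, n_gfp_pos = n_pos,
                 fraction = n_pos / n_adults),
            class = "well_result")
}

#' Fold increase of a chemical well over its matched vehicle well
#'
#' `fold = (f_chem + eps) / (f_vehicle + eps)` with continuity constant
#' `eps = 1 / (2 * n_adults_vehicle)`, which bounds folds when the vehicle
#' fraction is zero and introduces vanishing bias at screening sample sizes
#' (300+ gated adults per well).
#'
#' @param chem_fraction,vehicle_fraction GFP-positive fractions from the
#'   same biological replicate batch.
#' @param n_adults_vehicle Gated adult count of the vehicle well.
#' @return Fold value.
#' @export
fold_change <- function(chem_fraction, vehicle_fraction, n_adults_vehicle) {
  stopifnot(n_adults_vehicle > 0,
            chem_fraction >= 0, chem_fraction <= 1,
            vehicle_fraction >= 0, vehicle_fraction <= 1)
  eps <- 1 / (2 * n_adults_vehicle)
  (chem_fraction + eps) / (vehicle_fraction + eps)
}

#' Summarise one chemical across replicates against matched vehicle wells
#'
#' Computes the per-replicate fold increases, their mean and SEM, and a
#' paired two-tailed t-test of the chemical versus vehicle fractions paired
#' by biological replicate. When every paired difference is zero the t
#' statistic is undefined and the p-value is 1 by convention.
#'
#' @param chem_wells data.frame of the chemical's wells with columns
#'   `replicate`, `fraction`, `n_adults` (one row per replicate).
#' @param vehicle_wells Same for the matched vehicle wells.
#' @param chemical Optional chemical name carried into the result.
#' @return One-row data.frame: `chemical`, `n_reps`, `folds`
#'   (comma-separated per-replicate folds), `mean_fold`, `sem_fold`,
#'   `p_value`.
#' @export
summarize_chemical <- function(chem_wells, vehicle_wells, chemical = NA) {
  need <- c("replicate", "fraction", "n_adults")
  stopifnot(all(need %in% names(chem_wells)), all(need %in% names(vehicle_wells)))
  m <- match(chem_wells$replicate, vehicle_wells$replicate)
  if (anyNA(m)) stop("every chemical replicate needs a matched vehicle replicate")
  if (nrow(chem_wells) < 2) stop("need at least 2 replicates for the paired test")
  veh <- vehicle_wells[m, ]
  folds <- mapply(fold_change, chem_wells$fraction, veh$fraction, veh$n_adults)
  diffs <- chem_wells$fraction - veh$fraction
  p <- if (all(abs(diffs) < .Machine$double.eps)) 1 else
    stats::t.test(chem_wells$fraction, veh$fraction, paired = TRUE)$p.value
  data.frame(chemical = chemical, n_reps = nrow(chem_wells),
             folds = paste(signif(folds, 6), collapse = ","),
             mean_fold = mean(folds),
             sem_fold = stats::sd(folds) / sqrt(length(folds)),
             p_value = p)
}

#' Rank chemicals and call hits against a benchmark chemical
#'
#' A chemical is a hit iff its mean fold strictly exceeds the benchmark's.
#' Rank 1 is the largest mean fold; ties break alphabetically by name.
#'
#' @param summaries data.frame with at least `chemical` and `mean_fold`
#'   columns (one row per chemical).
#' @param benchmark Benchmark chemical name (must be present).
#' @return `summaries` with added `rank` and `hit` columns, sorted by rank.
#' @export
call_hits <- function(summaries, benchmark = "BPA") {
  stopifnot(all(c("chemical", "mean_fold") %in% names(summaries)))
  if (!benchmark %in% summaries$chemical) {
    stop("benchmark chemical '", benchmark, "' not among summaries")
  }
  ord <- order(-summaries$mean_fold, summaries$chemical)
  out <- summaries[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  bench_fold <- out$mean_fold[out$chemical == benchmark]
  out$hit <- out$mean_fold > bench_fold
  rownames(out) <- NULL
  out
}

#' Run the screen analysis over a classified event table
#'
#' Splits events by chemical and replicate, scores each well, summarises
#' each chemical against the matched vehicle wells and calls hits.
#'
#' @param events data.frame of sorter events with `chemical`, `replicate`,
#'   `tof`, `gfp_peak` columns (e.g. from [simulate_screen_events()]).
#' @param gate,threshold Calibration objects (see [fit_adult_gate()] and
#'   [fit_gfp_threshold()]).
#' @param vehicle Vehicle condition name among `chemical` values.
#' @param benchmark Benchmark chemical for hit calling; `NULL` to skip
#'   ranking (returns unranked summaries).
#' @return data.frame from [call_hits()] (or unranked summaries), plus a
#'   `wells` attribute with the per-well scores.
#' @export
run_screen <- function(events, gate, threshold, vehicle = "DMSO",
                       benchmark = "BPA") {
  stopifnot(all(c("chemical", "replicate") %in% names(events)))
  if (!vehicle %in% events$chemical) stop("vehicle wells missing from events")
  cls <- classify_events(events, gate, threshold)
  key <- interaction(events$chemical, events$replicate, drop = TRUE)
  wells <- do.call(rbind, lapply(split(seq_len(nrow(events)), key), function(i) {
    sc <- score_well(cls[i])
    data.frame(chemical = events$chemical[i[1]],
               replicate = events$replicate[i[1]],
               n_adults = sc$n_adults, n_gfp_pos = sc$n_gfp_pos,
               fraction = sc$fraction)
  }))
  rownames(wells) <- NULL
  veh_wells <- wells[wells$chemical == vehicle, ]
  chems <- setdiff(unique(wells$chemical), vehicle)
  summaries <- do.call(rbind, lapply(chems, function(cc) {
    summarize_chemical(wells[wells$chemical == cc, ], veh_wells, chemical = cc)
  }))
  if (!is.null(benchmark)) summaries <- call_hits(summaries, benchmark)
  attr(summaries, "wells") <- wells
  summaries
}
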