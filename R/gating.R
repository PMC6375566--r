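# Adult-gate and GFP-threshold calibration; event classification.

#' Fit the adult time-of-flight gate from a stage-labelled run
#'
#' The gate spans the 0.5th to 99.5th time-of-flight percentile of labelled
#' adults; the lower bound is then raised, if necessary, until at most 1% of
#' labelled L4 events fall inside. When no lower bound achieves the 1%
#' criterion while keeping at least half of the adults (e.g. the two
#' distributions are identical), the gate is still returned at the widest
#' adult-preserving setting with `separable = FALSE`.
#'
#' @param labeled_events data.frame with columns `tof` and `true_stage`,
#'   containing at least 50 `"adult"` and 50 `"L4"` events.
#' @return Object of class `adult_gate`: `tof_min`, `tof_max`, achieved
#'   `adult_capture` and `l4_contamination` rates, and `separable` flag.
#' @export
fit_adult_gate <- function(labeled_events) {
  if (is.null(labeled_events$true_stage) || is.null(labeled_events$tof)) {
    stop("labeled_events must have 'tof' and 'true_stage' columns")
  }
  adult_tof <- labeled_events$tof[labeled_events$true_stage == "adult"]
  l4_tof <- labeled_events$tof[labeled_events$true_stage == "L4"]
  if (length(adult_tof) < 50) stop("need at least 50 labelled adult events")
  if (length(l4_tof) < 50) stop("need at least 50 labelled L4 events")
  q <- stats::quantile(adult_tof, c(0.005, 0.995), names = FALSE)
  tof_min <- q[1]; tof_max <- q[2]
  inside <- function(x, lo) x >= lo & x <= tof_max
  separable <- TRUE
  if (mean(inside(l4_tof, tof_min)) > 0.01) {
    # smallest lower bound leaving <= 1% of L4 inside: just above the
    # (n - floor(0.01 n))-th largest L4 time-of-flight
    allowed <- floor(0.01 * length(l4_tof))
    cut <- sort(l4_tof[l4_tof <= tof_max], decreasing = TRUE)
    if (length(cut) > allowed) {
      new_min <- cut[allowed + 1] * (1 + 1e-9)
      if (mean(adult_tof >= new_min & adult_tof <= tof_max) >= 0.5) {
        tof_min <- max(tof_min, new_min)
      } else {
        separable <- FALSE
      }
    }
  }
  structure(list(tof_min = tof_min, tof_max = tof_max,
                 adult_capture = mean(inside(adult_tof, tof_min)),
                 l4_contamination = mean(inside(l4_tof, tof_min)),
                 separable = separable),
            class = "adult_gate")
}

#' @export
print.adult_gate <- function(x, ...) {
  cat(sprintf("Adult ToF gate [%.1f, %.1f]: %.1f%% adult capture, %.2f%% L4 contamination%s\n",
              x$tof_min, x$tof_max, 100 * x$adult_capture,
              100 * x$l4_contamination,
              if (x$separable) "" else " (INSEPARABLE at 1% criterion)"))
  invisible(x)
}

#' Fit the GFP-positivity threshold from the two reference strains
#'
#' Candidate thresholds are the midpoints between adjacent sorted unique GFP
#' peak heights pooled across both runs, plus one candidate below the
#' minimum and one above the maximum. Treating every gated adult of the
#' GFP-reporter strain as truly negative and every gated adult of the
#' reporter;him-8 strain as truly positive, the threshold minimising the sum
#' of false-positive and false-negative rates is chosen; ties break toward
#' the larger threshold. If even the best candidate misclassifies nearly
#' everything (FPR + FNR >= 0.95, i.e. the two runs are indistinguishable)
#' the calibration is unusable and an error is thrown.
#'
#' @param neg_gfp Numeric GFP peak heights of gated adults from the negative
#'   reference strain (or a data.frame with a `gfp_peak` column).
#' @param pos_gfp Same for the positive (him-8) reference strain.
#' @return Object of class `gfp_threshold`: `tau`, `fpr_neg`, `fnr_pos`.
#' @export
fit_gfp_threshold <- function(neg_gfp, pos_gfp) {
  if (is.data.frame(neg_gfp)) neg_gfp <- neg_gfp$gfp_peak
  if (is.data.frame(pos_gfp)) pos_gfp <- pos_gfp$gfp_peak
  if (length(neg_gfp) == 0 || length(pos_gfp) == 0) {
    stop("both calibration runs must be non-empty")
  }
  vals <- sort(unique(c(neg_gfp, pos_gfp)))
  cands <- c(vals[1] - 1,
             if (length(vals) > 1) (vals[-1] + vals[-length(vals)]) / 2,
             vals[length(vals)] + 1)
  obj <- vapply(cands, function(tau) {
    mean(neg_gfp > tau) + mean(pos_gfp <= tau)
  }, numeric(1))
  best <- min(obj)
  if (best >= 0.95) {
    stop("unusable calibration: reference runs are indistinguishable ",
         "(best FPR + FNR = ", format(best, digits = 3), ")")
  }
  tau <- max(cands[abs(obj - best) < 1e-12])
  structure(list(tau = tau, fpr_neg = mean(neg_gfp > tau),
                 fnr_pos = mean(pos_gfp <= tau)),
            class = "gfp_threshold")
}

#' @export
print.gfp_threshold <- function(x, ...) {
  cat(sprintf("GFP+ threshold tau = %.3f (FPR %.3f, FNR %.3f)\n",
              x$tau, x$fpr_neg, x$fnr_pos))
  invisible(x)
}

#' Classify sorter events with a calibrated gate and threshold
#'
#' An event is in-gate iff its time-of-flight lies in
#' `[tof_min, tof_max]`; a gated adult is GFP-positive iff its GFP peak
#' height strictly exceeds the threshold (an event exactly at the threshold
#' is negative).
#'
#' @param events data.frame with `tof` and `gfp_peak` columns.
#' @param gate An [fit_adult_gate()] result.
#' @param threshold A [fit_gfp_threshold()] result.
#' @return Factor with levels `out_of_gate`, `adult_gfp_neg`,
#'   `adult_gfp_pos`, one per event.
#' @export
classify_events <- function(events, gate, threshold) {
  stopifnot(inherits(gate, "adult_gate"), inherits(threshold, "gfp_threshold"))
  in_gate <- events$tof >= gate$tof_min & events$tof <= gate$tof_max
  cls <- ifelse(!in_gate, "out_of_gate",
                ifelse(events$gfp_peak > threshold$tau,
                       "adult_gfp_pos", "adult_gfp_neg"))
  factor(cls, levels = c("out_of_gate", "adult_gfp_neg", "adult_gfp_pos"))
}

#' Serialize / restore a calibration
#'
#' Calibrations are stored as a small YAML key-value file (threshold,
#' gate bounds, achieved rates) so a single instrument-session calibration
#' can be reused across screen runs.
#'
#' @param gate An [fit_adult_gate()] result.
#' @param threshold A [fit_gfp_threshold()] result.
#' @param path Output file path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns `list(gate, threshold)`.
#' @export
write_calibration <- function(gate, threshold, path) {
  stopifnot(inherits(gate, "adult_gate"), inherits(threshold, "gfp_threshold"))
  yaml::write_yaml(list(gate = unclass(gate), threshold = unclass(threshold)),
                   path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$gate) || is.null(raw$threshold)) {
    stop("not a calibration file: ", path)
  }
  list(gate = structure(raw$gate, class = "adult_gate"),
       threshold = structure(raw$threshold, class = "gfp_threshold"))
}
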