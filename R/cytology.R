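# Plate-phenotype and germline-cytology statistics.

#' Embryonic and larval lethality fractions
#'
#' `emb = (eggs - hatched) / eggs`, `larval = (hatched - adults) / hatched`.
#' Undefined fractions (zero denominator) are returned as `NA`.
#'
#' @param eggs,hatched,adults Non-negative integer counts (vectorised),
#'   nested as `adults <= hatched <= eggs`.
#' @return data.frame with columns `emb_lethality`, `larval_lethality`.
#' @export
lethality_fractions <- function(eggs, hatched, adults) {
  if (any(eggs < 0) || any(hatched < 0) || any(adults < 0)) {
    stop("counts must be non-negative")
  }
  if (any(hatched > eggs) || any(adults > hatched)) {
    stop("counts must be nested: adults <= hatched <= eggs")
  }
  emb <- ifelse(eggs > 0, (eggs - hatched) / eggs, NA_real_)
  larv <- ifelse(hatched > 0, (hatched - adults) / hatched, NA_real_)
  data.frame(emb_lethality = emb, larval_lethality = larv)
}

#' Summarise plate phenotypes per condition
#'
#' Per-mother lethality fractions plus condition-level means with standard
#' errors and Mann-Whitney comparisons against a vehicle condition.
#'
#' @param brood data.frame with columns `condition`, `eggs`, `hatched`,
#'   `adults` (one row per mother).
#' @param vehicle Name of the vehicle condition present in `brood`.
#' @return data.frame, one row per condition: mean/SEM of brood size and of
#'   both lethality fractions, and two-tailed Mann-Whitney p-values versus
#'   vehicle (NA for the vehicle row).
#' @export
plate_phenotypes <- function(brood, vehicle = "DMSO") {
  stopifnot(all(c("condition", "eggs", "hatched", "adults") %in% names(brood)))
  if (!vehicle %in% brood$condition) stop("vehicle condition not present")
  lf <- lethality_fractions(brood$eggs, brood$hatched, brood$adults)
  brood <- cbind(brood, lf)
  sem <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  veh <- brood[brood$condition == vehicle, ]
  conds <- unique(brood$condition)
  rows <- lapply(conds, function(cc) {
    g <- brood[brood$condition == cc, ]
    p_brood <- p_emb <- p_larv <- NA_real_
    if (cc != vehicle) {
      p_brood <- mann_whitney_two_tailed(g$eggs, veh$eggs)$p_value
      p_emb <- mann_whitney_two_tailed(g$emb_lethality[!is.na(g$emb_lethality)],
                                       veh$emb_lethality[!is.na(veh$emb_lethality)])$p_value
      gl <- g$larval_lethality[!is.na(g$larval_lethality)]
      vl <- veh$larval_lethality[!is.na(veh$larval_lethality)]
      if (length(gl) > 0 && length(vl) > 0) {
        p_larv <- mann_whitney_two_tailed(gl, vl)$p_value
      }
    }
    data.frame(condition = cc, n_mothers = nrow(g),
               brood_mean = mean(g$eggs), brood_sem = sem(g$eggs),
               emb_lethality = mean(g$emb_lethality, na.rm = TRUE),
               emb_sem = sem(g$emb_lethality),
               larval_lethality = mean(g$larval_lethality, na.rm = TRUE),
               larval_sem = sem(g$larval_lethality),
               p_brood = p_brood, p_emb = p_emb, p_larval = p_larv)
  })
  do.call(rbind, rows)
}

#' Assign a normalised gonad-axis position to one of seven equal zones
#'
#' The distal tip is position 0; zones are half-open equal-width bins, so
#' `zone = floor(7 * position) + 1`.
#'
#' @param position Numeric in `[0, 1)`; vectorised.
#' @return Integer zone in `1..7`.
#' @export
zone_assign <- function(position) {
  if (any(position < 0 | position >= 1)) stop("position must lie in [0, 1)")
  as.integer(floor(7 * position) + 1L)
}

#' Compare zone-wise RAD-51 focus profiles between two arms
#'
#' Nucleus-level per-zone means with standard errors for each arm, plus a
#' per-zone two-tailed Mann-Whitney test (no multiplicity correction across
#' zones, matching conventional reporting of zone profiles).
#'
#' @param exposed,vehicle Focus tables: data.frames with columns `zone` and
#'   `foci` (one row per nucleus), e.g. the `foci` element of a
#'   [simulate_germline()] result.
#' @return data.frame with one row per zone: means, SEMs, nucleus counts,
#'   `p_value` and test `method`.
#' @export
zone_profile_compare <- function(exposed, vehicle) {
  for (df in list(exposed, vehicle)) {
    stopifnot(all(c("zone", "foci") %in% names(df)))
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- lapply(1:7, function(z) {
    e <- exposed$foci[exposed$zone == z]
    v <- vehicle$foci[vehicle$zone == z]
    if (length(e) == 0 || length(v) == 0) stop("zone ", z, " is empty")
    tst <- mann_whitney_two_tailed(e, v)
    data.frame(zone = z, n_exposed = length(e), mean_exposed = mean(e),
               sem_exposed = sem(e), n_vehicle = length(v),
               mean_vehicle = mean(v), sem_vehicle = sem(v),
               p_value = tst$p_value, method = tst$method)
  })
  do.call(rbind, rows)
}

#' Germ-cell corpse analysis with CEP-1 dependence calls
#'
#' Mean corpse counts per condition and genotype, fold over the matched
#' vehicle group, Mann-Whitney tests versus vehicle, and — when both a
#' CEP-1-functional and a CEP-1-deficient arm are present — a dependence
#' label per condition: an elevation is `cep-1-dependent` iff it is
#' significant in the functional background and not in the deficient one.
#'
#' @param corpses data.frame with columns `condition`, `genotype`, `count`
#'   (one row per gonad).
#' @param vehicle Vehicle condition name.
#' @param cep1_positive,cep1_negative Genotype labels of the
#'   CEP-1-functional and CEP-1-deficient arms.
#' @param alpha Significance level for the dependence call.
#' @return List with `summary` (per condition x genotype: n, mean, SEM,
#'   fold over vehicle, p, stars) and `dependence` (per non-vehicle
#'   condition: p in each background and label).
#' @export
corpse_analysis <- function(corpses, vehicle = "DMSO",
                            cep1_positive = "col-121",
                            cep1_negative = "cep-1", alpha = 0.05) {
  stopifnot(all(c("condition", "genotype", "count") %in% names(corpses)))
  combos <- unique(corpses[, c("condition", "genotype")])
  if (!all(unique(corpses$genotype) %in%
           corpses$genotype[corpses$condition == vehicle])) {
    stop("every genotype needs a vehicle group")
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cc <- combos$condition[i]; gg <- combos$genotype[i]
    x <- corpses$count[corpses$condition == cc & corpses$genotype == gg]
    v <- corpses$count[corpses$condition == vehicle & corpses$genotype == gg]
    p <- if (cc == vehicle) NA_real_ else mann_whitney_two_tailed(x, v)$p_value
    data.frame(condition = cc, genotype = gg, n = length(x),
               mean_corpses = mean(x), sem = sem(x),
               fold_vs_vehicle = mean(x) / mean(v), p_value = p,
               stars = if (is.na(p)) "" else .stars(p))
  })
  summary <- do.call(rbind, rows)

  dependence <- NULL
  genos <- unique(corpses$genotype)
  if (all(c(cep1_positive, cep1_negative) %in% genos)) {
    conds <- setdiff(unique(corpses$condition), vehicle)
    dependence <- do.call(rbind, lapply(conds, function(cc) {
      get_p <- function(gg) {
        r <- summary[summary$condition == cc & summary$genotype == gg, ]
        if (nrow(r) == 0) stop("missing genotype arm for condition ", cc)
        r$p_value
      }
      p_pos <- get_p(cep1_positive); p_neg <- get_p(cep1_negative)
      label <- if (p_pos < alpha && p_neg >= alpha) "cep-1-dependent"
               else if (p_pos < alpha) "cep-1-independent"
               else "no-elevation"
      data.frame(condition = cc, p_cep1_functional = p_pos,
                 p_cep1_deficient = p_neg, label = label)
    }))
  }
  list(summary = summary, dependence = dependence)
}

#' Tally diakinesis oocyte records
#'
#' @param records data.frame with columns `n_dapi_bodies` and
#'   `defect_class` (one row per scored oocyte).
#' @return List with `classes` (class, n, percent), `dapi_histogram`
#'   (n_dapi_bodies, n, percent), `modal_dapi` and `n_total`.
#' @export
diakinesis_tally <- function(records) {
  stopifnot(all(c("n_dapi_bodies", "defect_class") %in% names(records)))
  if (nrow(records) == 0) stop("no diakinesis records")
  n <- nrow(records)
  cls <- as.data.frame(table(defect_class = records$defect_class),
                       stringsAsFactors = FALSE)
  names(cls)[2] <- "n"
  cls$percent <- 100 * cls$n / n
  hist <- as.data.frame(table(n_dapi_bodies = records$n_dapi_bodies),
                        stringsAsFactors = FALSE)
  names(hist)[2] <- "n"
  hist$n_dapi_bodies <- as.integer(hist$n_dapi_bodies)
  hist$percent <- 100 * hist$n / n
  list(classes = cls,
       dapi_histogram = hist,
       modal_dapi = hist$n_dapi_bodies[which.max(hist$n)],
       n_total = n)
}

#' Tally pachytene gonad-defect flags against a vehicle arm
#'
#' Percentages of gonads with gaps, nuclear aggregates and
#' leptotene/zygotene-like chromatin, with two-sided Fisher exact tests
#' versus the vehicle arm.
#'
#' @param exposed,vehicle data.frames with logical columns `gap`,
#'   `aggregate`, `lz_like` (one row per gonad), e.g. the `defects` element
#'   of a [simulate_germline()] result.
#' @return data.frame with one row per defect category.
#' @export
gonad_defect_compare <- function(exposed, vehicle) {
  cats <- c("gap", "aggregate", "lz_like")
  stopifnot(all(cats %in% names(exposed)), all(cats %in% names(vehicle)))
  rows <- lapply(cats, function(cat) {
    a <- sum(exposed[[cat]]); b <- nrow(exposed) - a
    c_ <- sum(vehicle[[cat]]); d <- nrow(vehicle) - c_
    tst <- fisher_exact_two_sided(a, b, c_, d)
    data.frame(defect = cat, n_exposed = nrow(exposed),
               pct_exposed = 100 * a / nrow(exposed),
               n_vehicle = nrow(vehicle),
               pct_vehicle = 100 * c_ / nrow(vehicle),
               p_value = tst$p_value, stars = .stars(tst$p_value))
  })
  do.call(rbind, rows)
}
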