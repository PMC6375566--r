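# Generative simulator: broods, sorter event streams, germline cytology and
# qPCR Ct tables. All functions draw from R's global RNG stream so that a
# single set.seed() call up front makes an entire run reproducible.

.clip01 <- function(p) pmin(1, pmax(0, p))

.effective_dose <- function(strain, exposure) exposure$dose * strain$permeability

#' Simulate per-mother brood records
#'
#' Each mother lays `eggs ~ Poisson(mu_brood * (1 - brood effect))`; each egg
#' independently fails as an embryo with the baseline plus exposure-driven
#' probability; each hatchling fails as a larva likewise; each surviving
#' adult is male with probability `p_male + delta_p(dose)` (nondisjunction
#' increment on the effective, permeability-scaled dose).
#'
#' @param strain A [strain_params()] object.
#' @param exposure An [exposure_params()] object.
#' @param n_mothers Number of mothers (>= 1).
#' @return data.frame with columns `mother`, `eggs`, `hatched`, `adults`,
#'   `males`; `males <= adults <= hatched <= eggs` row-wise.
#' @export
simulate_brood <- function(strain, exposure, n_mothers) {
  stopifnot(inherits(strain, "strain_params"),
            inherits(exposure, "exposure_params"), n_mothers >= 1)
  k <- .sim_constants
  d <- .effective_dose(strain, exposure)
  mu_eggs <- k$mu_brood * (1 - .clip01(hill_effect(d, exposure$brood)))
  p_emb <- k$base_emb_lethality + hill_effect(d, exposure$emb)
  p_larv <- k$base_larval_lethality + hill_effect(d, exposure$larv)
  p_male <- strain$p_male + hill_effect(d, exposure$nd)
  probs <- c(p_emb, p_larv, p_male)
  if (any(probs < -1e-12) || any(probs > 1 + 1e-12)) {
    stop("composed probabilities outside [0, 1]; check presets")
  }
  p_emb <- .clip01(p_emb); p_larv <- .clip01(p_larv); p_male <- .clip01(p_male)
  eggs <- stats::rpois(n_mothers, mu_eggs)
  hatched <- stats::rbinom(n_mothers, eggs, 1 - p_emb)
  adults <- stats::rbinom(n_mothers, hatched, 1 - p_larv)
  males <- stats::rbinom(n_mothers, adults, p_male)
  data.frame(mother = seq_len(n_mothers), eggs = eggs, hatched = hatched,
             adults = adults, males = males)
}

#' Simulate a worm-sorter event stream
#'
#' Each event is one sorted object. Its developmental stage is drawn from a
#' mixture over `{debris, L1..L4, adult}`; time-of-flight follows a
#' stage-specific lognormal (adults largest); adults carry an in-utero
#' embryo load `n_embryos ~ Poisson(mu_embryos)`, each embryo independently
#' GFP-positive (male-destined) with the strain/exposure male probability;
#' the recorded GFP peak height is lognormal autofluorescence plus a fixed
#' per-embryo brightness times the number of GFP-positive embryos.
#'
#' @inheritParams simulate_brood
#' @param composition Named stage mixture weights summing to 1; defaults to
#'   the screening-well composition in [sim_constants()].
#' @param n_events Number of events (>= 0).
#' @return data.frame with columns `tof`, `gfp_peak`, `true_stage`,
#'   `n_embryos`, `n_gfp_embryos`.
#' @export
simulate_biosort_run <- function(strain, exposure, n_events,
                                 composition = NULL) {
  stopifnot(inherits(strain, "strain_params"),
            inherits(exposure, "exposure_params"))
  if (n_events < 0) stop("n_events must be non-negative")
  k <- .sim_constants
  if (is.null(composition)) composition <- k$composition_screen
  if (!all(names(composition) %in% k$stages)) stop("unknown stage in composition")
  if (abs(sum(composition) - 1) > 1e-8) stop("mixture weights must sum to 1")
  empty <- data.frame(tof = numeric(0), gfp_peak = numeric(0),
                      true_stage = character(0), n_embryos = integer(0),
                      n_gfp_embryos = integer(0))
  if (n_events == 0) return(empty)
  d <- .effective_dose(strain, exposure)
  p_male <- .clip01(strain$p_male + hill_effect(d, exposure$nd))
  stage <- sample(names(composition), n_events, replace = TRUE,
                  prob = composition)
  tof <- stats::rlnorm(n_events, k$tof_meanlog[stage], k$tof_sdlog[stage])
  is_adult <- stage == "adult"
  n_embryos <- integer(n_events)
  n_embryos[is_adult] <- stats::rpois(sum(is_adult), k$mu_embryos)
  n_gfp <- integer(n_events)
  n_gfp[is_adult] <- stats::rbinom(sum(is_adult), n_embryos[is_adult], p_male)
  auto <- stats::rlnorm(n_events, k$auto_meanlog, k$auto_sdlog)
  gfp_peak <- auto + k$gfp_per_embryo * n_gfp
  data.frame(tof = tof, gfp_peak = gfp_peak, true_stage = stage,
             n_embryos = n_embryos, n_gfp_embryos = n_gfp)
}

# zone-wise per-nucleus focus rates for a strain x exposure combination
.zone_rates <- function(strain, exposure) {
  k <- .sim_constants
  lam <- k$zone_lambda
  mitotic_bg <- mean(lam[1:2])
  d <- .effective_dose(strain, exposure)
  mult <- 1 + hill_effect(d, exposure$dsb)
  if (!strain$spo11_active) {
    # no meiotic breaks: meiotic zones drop to mitotic background and the
    # chemical elevation (being SPO-11-dependent) does not appear
    lam[3:7] <- mitotic_bg
  } else if (!strain$rad54_functional) {
    # turnover lost: foci report cumulative break formation, non-decreasing
    lam[3:7] <- lam[2] + cumsum(k$rad54_inc * mult)
  } else {
    lam[3:7] <- lam[3:7] * mult
  }
  lam
}

#' Simulate germline cytology profiles
#'
#' For each gonad: per-nucleus RAD-51 focus counts in seven equal zones
#' (Poisson with zone baseline rates scaled by the exposure break-load
#' multiplier; meiotic zones collapse to mitotic background without SPO-11;
#' rates become cumulative and non-decreasing across pachytene without
#' RAD-54); an apoptotic corpse count (Poisson, physiological rate plus
#' CEP-1-gated solvent and damage terms); diakinesis records for the last
#' two oocytes (6 DAPI bodies when bivalents form, 12 univalents without
#' SPO-11, defect classes drawn from exposure-specific probabilities); and
#' Bernoulli pachytene gonad-defect flags (gaps, aggregates,
#' leptotene/zygotene-like organisation).
#'
#' @inheritParams simulate_brood
#' @param n_gonads Number of gonads (>= 1).
#' @return Object of class `germline_sim`: a list of data.frames `foci`
#'   (gonad, zone, nucleus, foci), `corpses` (gonad, corpse_count),
#'   `diakinesis` (gonad, oocyte, n_dapi_bodies, defect_class) and
#'   `defects` (gonad, gap, aggregate, lz_like).
#' @export
simulate_germline <- function(strain, exposure, n_gonads) {
  stopifnot(inherits(strain, "strain_params"),
            inherits(exposure, "exposure_params"), n_gonads >= 1)
  k <- .sim_constants
  d <- .effective_dose(strain, exposure)
  lam <- .zone_rates(strain, exposure)
  npz <- k$nuclei_per_zone
  zones <- rep(rep(1:7, each = npz), times = n_gonads)
  gonad <- rep(seq_len(n_gonads), each = 7 * npz)
  foci <- stats::rpois(length(zones), lam[zones])
  foci_df <- data.frame(gonad = gonad, zone = zones,
                        nucleus = rep(seq_len(npz), times = 7 * n_gonads),
                        foci = foci)

  apo <- hill_effect(d, exposure$apoptosis)
  lam_corpse <- k$lambda_phys +
    (if (strain$cep1_functional)
       (exposure$solvent == "DMSO") * k$lambda_dmso + k$lambda_dmg * apo
     else 0)
  corpses <- data.frame(gonad = seq_len(n_gonads),
                        corpse_count = stats::rpois(n_gonads, lam_corpse))

  n_ooc <- k$oocytes_per_gonad
  probs <- k$diakinesis_base
  inc <- exposure$diakinesis_inc * apo
  probs[names(inc)] <- probs[names(inc)] + inc
  probs["normal"] <- 1 - sum(probs[names(probs) != "normal"])
  if (probs["normal"] < 0) stop("diakinesis class probabilities exceed 1")
  cls <- sample(names(probs), n_gonads * n_ooc, replace = TRUE, prob = probs)
  extra <- sample(1:6, n_gonads * n_ooc, replace = TRUE)
  n_bodies <- if (!strain$spo11_active) {
    rep(12L, n_gonads * n_ooc)  # 12 univalents, no crossovers
  } else {
    ifelse(cls == "fragments", 6L + extra, 6L)
  }
  if (!strain$spo11_active) cls <- rep("normal", n_gonads * n_ooc)
  dia <- data.frame(gonad = rep(seq_len(n_gonads), each = n_ooc),
                    oocyte = rep(c(-1L, -2L), times = n_gonads),
                    n_dapi_bodies = n_bodies, defect_class = cls)

  base_def <- k$gonad_defect_base
  pdef <- base_def
  if (!is.null(exposure$gonad_defects)) {
    ref <- hill_effect(exposure$defect_ref_dose, exposure$apoptosis)
    scale <- if (ref > 0) apo / ref else 0
    tgt <- exposure$gonad_defects[names(base_def)]
    pdef <- stats::setNames(.clip01(base_def + (tgt - base_def) * scale),
                            names(base_def))
  }
  defects <- data.frame(
    gonad = seq_len(n_gonads),
    gap = stats::rbinom(n_gonads, 1, pdef[["gap"]]) == 1,
    aggregate = stats::rbinom(n_gonads, 1, pdef[["aggregate"]]) == 1,
    lz_like = stats::rbinom(n_gonads, 1, pdef[["lz_like"]]) == 1)

  structure(list(foci = foci_df, corpses = corpses, diakinesis = dia,
                 defects = defects),
            class = "germline_sim")
}

#' Simulate a qPCR Ct table for one condition
#'
#' True relative expression of each panel gene is its somatic log2 change
#' plus its germline log2 change when a germline is present at the rearing
#' temperature (temperature-sensitive germline-less adults at 25 C report
#' soma only). `Ct = base_Ct - log2(relative expression) + plate offset +
#' Gaussian noise`; the per-sample plate offset is shared by every well of a
#' biological replicate and cancels in delta-Ct. The reference gene is
#' unaffected by exposure.
#'
#' @inheritParams simulate_brood
#' @param temp Rearing temperature in degrees C (15 or 25).
#' @param genes Target genes; defaults to [qpcr_panel()]. The reference gene
#'   is always appended.
#' @param n_bio Biological replicates (>= 1).
#' @param n_tech Technical replicates per well (>= 1).
#' @param sigma_ct Technical Ct noise standard deviation (cycles).
#' @return data.frame with columns `gene`, `condition`, `temp_c`, `bio_rep`,
#'   `tech_rep`, `ct`.
#' @export
simulate_qpcr <- function(strain, exposure, temp, genes = qpcr_panel(),
                          n_bio = 3, n_tech = 3,
                          sigma_ct = sim_constants()$sigma_ct) {
  stopifnot(inherits(strain, "strain_params"),
            inherits(exposure, "exposure_params"),
            n_bio >= 1, n_tech >= 1)
  k <- .sim_constants
  ref <- k$ct_reference_gene
  unknown <- setdiff(names(exposure$expr), c(genes, ref))
  if (length(unknown) > 0) {
    stop("expression effect for unknown gene(s): ",
         paste(unknown, collapse = ", "))
  }
  genes <- unique(c(genes, ref))
  has_germline <- germline_present_at(strain, temp)
  base_ct <- 16 + (seq_along(genes) %% 7)  # gene-specific baseline cycles
  names(base_ct) <- genes
  base_ct[ref] <- 16
  log2fc <- vapply(genes, function(g) {
    eff <- exposure$expr[[g]]
    if (is.null(eff) || g == ref) 0 else eff[2] + if (has_germline) eff[1] else 0
  }, numeric(1))
  rows <- expand.grid(tech_rep = seq_len(n_tech), gene = genes,
                      bio_rep = seq_len(n_bio), stringsAsFactors = FALSE)
  plate <- stats::rnorm(n_bio, 0, k$sigma_plate)
  ct <- base_ct[rows$gene] - log2fc[rows$gene] + plate[rows$bio_rep] +
    stats::rnorm(nrow(rows), 0, sigma_ct)
  data.frame(gene = rows$gene, condition = exposure$chemical, temp_c = temp,
             bio_rep = rows$bio_rep, tech_rep = rows$tech_rep,
             ct = as.numeric(ct))
}

#' Simulate sorter event streams for a multi-chemical screen
#'
#' Generates one sorter run per chemical per biological replicate, including
#' the matched vehicle well for every replicate batch.
#'
#' @param exposures Named list of [exposure_params()] (vehicle included,
#'   conventionally named `"DMSO"`).
#' @param strain A [strain_params()] object (default the screening strain).
#' @param n_events Events per well.
#' @param n_reps Biological replicates.
#' @param composition Optional stage mixture (see [simulate_biosort_run()]).
#' @return data.frame of events with added `chemical` and `replicate` columns.
#' @export
simulate_screen_events <- function(exposures, strain = strain_preset("col-121"),
                                   n_events = 500, n_reps = 3,
                                   composition = NULL) {
  stopifnot(length(exposures) > 0)
  out <- vector("list", length(exposures) * n_reps)
  i <- 0
  for (rep_id in seq_len(n_reps)) {
    for (chem in names(exposures)) {
      ev <- simulate_biosort_run(strain, exposures[[chem]], n_events,
                                 composition)
      if (nrow(ev) > 0) {
        ev$chemical <- chem
        ev$replicate <- rep_id
      }
      i <- i + 1
      out[[i]] <- ev
    }
  }
  do.call(rbind, out[vapply(out, nrow, integer(1)) > 0])
}
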