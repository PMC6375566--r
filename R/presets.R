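# Strain genetics, dose-response parameterisation and simulator constants.

#' Hill dose-response parameters
#'
#' @param ec50 Half-maximal external dose in umol/L (>= 0).
#' @param n Hill coefficient (> 0).
#' @param emax Endpoint-specific maximum effect.
#' @return Object of class `hill_params`.
#' @export
hill_params <- function(ec50, n = 1, emax = 0) {
  stopifnot(ec50 >= 0, n > 0)
  structure(list(ec50 = ec50, n = n, emax = emax), class = "hill_params")
}

#' Hill dose-response effect
#'
#' `emax * dose^n / (ec50^n + dose^n)`: zero at dose 0, `emax / 2` at the
#' EC50, approaching `emax` at saturating dose. A degenerate `ec50 = 0` is
#' treated as a step: full effect at any positive dose.
#'
#' @param dose External dose in umol/L (>= 0); vectorised.
#' @param params A [hill_params()] object.
#' @return Effect value(s) on the endpoint's scale.
#' @export
hill_effect <- function(dose, params) {
  stopifnot(inherits(params, "hill_params"))
  if (any(dose < 0)) stop("dose must be non-negative")
  if (params$ec50 == 0) return(ifelse(dose > 0, params$emax, 0))
  dn <- dose^params$n
  params$emax * dn / (params$ec50^params$n + dn)
}

# null (no-effect) dose response
.hill_none <- function() hill_params(ec50 = 1, n = 1, emax = 0)

#' Strain parameters
#'
#' Describes a genetic background for the simulator. `p_male` is the
#' per-embryo probability of being male-destined (X0) absent any exposure;
#' self-fertilising wild-type hermaphrodites produce < 0.2% males, while the
#' him-8 mutant produces 36.7% through elevated X nondisjunction.
#'
#' @param name Strain label.
#' @param p_male Baseline male-destined embryo probability in `[0, 1]`.
#' @param permeability Multiplier (>= 1 typically) on the effective external
#'   dose; the cuticle-permeable screening background uses 1 by convention.
#' @param cep1_functional Is p53/CEP-1-dependent apoptosis intact?
#' @param spo11_active Is meiotic double-strand-break formation active?
#' @param rad54_functional Is RAD-51 turnover at break sites intact? When
#'   `FALSE`, breaks accumulate and zone focus rates become cumulative.
#' @param glp1_ts Temperature-sensitive germline-less background: raised at
#'   the restrictive temperature (25 C) adults lack a germline.
#' @return Object of class `strain_params`.
#' @export
strain_params <- function(name, p_male = 0.001, permeability = 1,
                          cep1_functional = TRUE, spo11_active = TRUE,
                          rad54_functional = TRUE, glp1_ts = FALSE) {
  stopifnot(p_male >= 0, p_male <= 1, permeability >= 0)
  structure(list(name = name, p_male = p_male, permeability = permeability,
                 cep1_functional = cep1_functional,
                 spo11_active = spo11_active,
                 rad54_functional = rad54_functional,
                 glp1_ts = glp1_ts),
            class = "strain_params")
}

#' Built-in strain presets
#'
#' * `"col-121"` — the cuticle-permeable screening background carrying the
#'   male-specific GFP reporter; baseline male frequency 0.1%.
#' * `"him-8"` — positive calibration strain, 36.7% male progeny.
#' * `"cep-1"` — p53 mutant; damage-induced apoptosis abolished.
#' * `"rad-54"` — repair mutant trapping RAD-51 at breaks.
#' * `"spo-11-depleted"` — no meiotic double-strand breaks; diakinesis
#'   oocytes carry 12 univalents.
#' * `"glp-1"` — temperature-sensitive germline-less at 25 C.
#'
#' @param name One of the preset names above.
#' @return A [strain_params()] object.
#' @export
strain_preset <- function(name = c("col-121", "him-8", "cep-1", "rad-54",
                                   "spo-11-depleted", "glp-1")) {
  name <- match.arg(name)
  switch(name,
    "col-121" = strain_params("col-121"),
    "him-8" = strain_params("him-8", p_male = 0.367),
    "cep-1" = strain_params("cep-1", cep1_functional = FALSE),
    "rad-54" = strain_params("rad-54", rad54_functional = FALSE),
    "spo-11-depleted" = strain_params("spo-11-depleted", spo11_active = FALSE),
    "glp-1" = strain_params("glp-1", glp1_ts = TRUE)
  )
}

#' Is a germline present at a given rearing temperature?
#'
#' @param strain A [strain_params()] object.
#' @param temp Rearing temperature in degrees C.
#' @return Logical. Temperature-sensitive germline-less strains lack a
#'   germline at and above 25 C; all other strains always have one.
#' @export
germline_present_at <- function(strain, temp) {
  stopifnot(inherits(strain, "strain_params"))
  if (!strain$glp1_ts) TRUE else temp < 25
}

#' Exposure parameters
#'
#' Bundles a chemical identity, an external dose and per-endpoint Hill
#' dose-response parameterisations. All probability-type effects are clipped
#' to `[0, 1]` when applied.
#'
#' @param chemical Chemical name (`"DMSO"` for the vehicle).
#' @param dose External dose in umol/L.
#' @param solvent `"DMSO"` or `"water"`; the DMSO vehicle carries a small
#'   basal CEP-1-dependent apoptosis elevation.
#' @param nd Nondisjunction increment (delta p on the male-destined embryo
#'   probability), a [hill_params()].
#' @param brood Fractional brood reduction, [hill_params()] with emax <= 1.
#' @param emb Embryonic-lethality increment, [hill_params()].
#' @param larv Larval-lethality increment, [hill_params()].
#' @param apoptosis Unit-scaled damage-apoptosis activation ([hill_params()]
#'   with emax in `[0, 1]`), multiplied by the damage corpse rate.
#' @param dsb Double-strand-break multiplier increment: meiotic-zone RAD-51
#'   focus rates are scaled by `1 + hill_effect(dose, dsb)`.
#' @param expr Named list of per-gene log2 expression changes, each a numeric
#'   `c(germline, soma)` pair.
#' @param diakinesis_inc Maximum added probabilities for diakinesis defect
#'   classes, named numeric over `fragments`, `bridges`, `frayed`, scaled by
#'   the unit apoptosis Hill curve.
#' @param gonad_defects Target probabilities of pachytene gonad defects
#'   (`gap`, `aggregate`, `lz_like`) at the reference dose `defect_ref_dose`;
#'   increments over the vehicle baseline scale with the unit Hill curve.
#' @param defect_ref_dose Dose at which `gonad_defects` are attained.
#' @return Object of class `exposure_params`.
#' @export
exposure_params <- function(chemical, dose, solvent = "DMSO",
                            nd = .hill_none(), brood = .hill_none(),
                            emb = .hill_none(), larv = .hill_none(),
                            apoptosis = .hill_none(), dsb = .hill_none(),
                            expr = list(),
                            diakinesis_inc = c(fragments = 0, bridges = 0,
                                               frayed = 0),
                            gonad_defects = NULL,
                            defect_ref_dose = dose) {
  stopifnot(dose >= 0, solvent %in% c("DMSO", "water"))
  structure(list(chemical = chemical, dose = dose, solvent = solvent,
                 nd = nd, brood = brood, emb = emb, larv = larv,
                 apoptosis = apoptosis, dsb = dsb, expr = expr,
                 diakinesis_inc = diakinesis_inc,
                 gonad_defects = gonad_defects,
                 defect_ref_dose = defect_ref_dose),
            class = "exposure_params")
}

#' Built-in exposure presets
#'
#' Vehicle (0.1% DMSO) plus the three follow-up chemicals at any dose.
#' Dose-response anchors (all on external dose in the cuticle-permeable
#' background): embryonic lethality becomes appreciable from 100 uM for DBP
#' and permethrin and from 10 uM for TCMTB; brood size falls ~50% at 500 uM
#' DBP/permethrin and at 100-500 uM TCMTB; damage apoptosis gives a 2-3x
#' corpse increase at the working doses (100, 100 and 10 uM respectively);
#' all three elevate meiotic break load and chk-1 germline expression, and
#' DBP additionally perturbs spo-11, mre-11 and prmt-5 in the germline.
#'
#' @param chemical One of `"DMSO"`, `"DBP"`, `"permethrin"`, `"TCMTB"`.
#' @param dose External dose in umol/L; defaults to the working dose used in
#'   the follow-up assays (0 for DMSO, 100 for DBP/permethrin, 10 for TCMTB).
#' @return An [exposure_params()] object.
#' @export
exposure_preset <- function(chemical = c("DMSO", "DBP", "permethrin", "TCMTB"),
                            dose = NULL) {
  chemical <- match.arg(chemical)
  defaults <- c(DMSO = 0, DBP = 100, permethrin = 100, TCMTB = 10)
  if (is.null(dose)) dose <- unname(defaults[chemical])
  base_defects <- .sim_constants$gonad_defect_base
  switch(chemical,
    DMSO = exposure_params("DMSO", dose = 0),
    DBP = exposure_params("DBP", dose = dose,
      nd = hill_params(50, 1.5, 0.004),
      brood = hill_params(500, 2, 1),
      emb = hill_params(150, 2, 0.4),
      apoptosis = hill_params(40, 2, 1),
      dsb = hill_params(40, 2, 1.2),
      expr = list("chk-1" = c(0.8, 0), "spo-11" = c(1.0, 0),
                  "mre-11" = c(-0.8, 0), "prmt-5" = c(0.9, 0)),
      diakinesis_inc = c(fragments = 0.18, bridges = 0.08, frayed = 0.12),
      gonad_defects = c(gap = 0.302, aggregate = 0.208, lz_like = 0.245),
      defect_ref_dose = 100),
    permethrin = exposure_params("permethrin", dose = dose,
      nd = hill_params(50, 1.5, 0.0035),
      brood = hill_params(500, 2, 1),
      emb = hill_params(150, 2, 0.4),
      apoptosis = hill_params(40, 2, 1),
      dsb = hill_params(40, 2, 1.1),
      expr = list("chk-1" = c(0.8, 0)),
      diakinesis_inc = c(fragments = 0.12, bridges = 0.06, frayed = 0.16),
      gonad_defects = c(gap = base_defects[["gap"]], aggregate = 0.217,
                        lz_like = 0.478),
      defect_ref_dose = 100),
    TCMTB = exposure_params("TCMTB", dose = dose,
      nd = hill_params(5, 1.5, 0.004),
      brood = hill_params(60, 2, 0.55),
      emb = hill_params(30, 1.5, 0.35),
      larv = hill_params(400, 3, 0.15),
      apoptosis = hill_params(4, 2, 1),
      dsb = hill_params(4, 2, 1.2),
      expr = list("chk-1" = c(0.8, 0)),
      diakinesis_inc = c(fragments = 0.15, bridges = 0.07, frayed = 0.13),
      gonad_defects = c(gap = 0.18, aggregate = 0.333, lz_like = 0.317),
      defect_ref_dose = 10)
  )
}

# Documented simulator preset constants. Time-of-flight distributions are
# stage-specific lognormals (adults largest); zone_lambda is the baseline
# per-nucleus RAD-51 focus rate for germline zones z1..z7 (low in the mitotic
# tip, peaking at mid-pachytene z5, falling by late pachytene z7);
# rad54_inc are per-zone new-break increments accumulated z3..z7 when repair
# turnover is lost; corpse rates are lambda_phys (physiological),
# lambda_dmso (basal CEP-1-dependent solvent term) and lambda_dmg (maximum
# damage-induced term).
.sim_constants <- list(
  stages = c("debris", "L1", "L2", "L3", "L4", "adult"),
  tof_meanlog = c(debris = log(30), L1 = log(55), L2 = log(100),
                  L3 = log(180), L4 = log(300), adult = log(650)),
  tof_sdlog = c(debris = 0.5, L1 = 0.2, L2 = 0.2, L3 = 0.18, L4 = 0.12,
                adult = 0.15),
  composition_screen = c(debris = 0.15, L1 = 0.02, L2 = 0.03, L3 = 0.05,
                         L4 = 0.15, adult = 0.60),
  mu_embryos = 12,
  gfp_per_embryo = 30,
  auto_meanlog = log(5),
  auto_sdlog = 0.4,
  mu_brood = 250,
  base_emb_lethality = 0.005,
  base_larval_lethality = 0.005,
  zone_lambda = c(0.15, 0.2, 0.8, 1.8, 2.6, 1.9, 0.9),
  rad54_inc = c(0.8, 1.2, 1.4, 0.8, 0.3),
  nuclei_per_zone = 20,
  lambda_phys = 1.2,
  lambda_dmso = 0.6,
  lambda_dmg = 3.5,
  diakinesis_base = c(normal = 0.95, fragments = 0.02, bridges = 0.01,
                      frayed = 0.02),
  gonad_defect_base = c(gap = 0.109, aggregate = 0.073, lz_like = 0.055),
  oocytes_per_gonad = 2,
  ct_reference_gene = "gpd-1",
  sigma_ct = 0.2,
  sigma_plate = 0.3,
  qpcr_panel = c("spo-11", "mre-11", "rad-50", "rad-51", "msh-4", "msh-5",
                 "brc-1", "chk-1", "chk-2", "atm-1", "atl-1", "cep-1",
                 "egl-1", "ced-3", "prmt-5")
)

#' Simulator preset constants
#'
#' Returns the documented constants the generative simulator runs on:
#' stage-specific time-of-flight lognormal parameters, in-utero embryo load
#' mean, per-embryo GFP brightness and autofluorescence parameters, mean
#' brood size and baseline lethalities, zone-wise RAD-51 focus baseline
#' rates, corpse-count rates, diakinesis and gonad-defect baselines, and the
#' qPCR panel with its noise levels.
#'
#' @return Named list of constants.
#' @export
sim_constants <- function() .sim_constants

#' Default qPCR gene panel
#'
#' Fifteen conserved double-strand-break formation, repair and DNA-damage
#' response genes, plus the reference gene `gpd-1` (GAPDH) used for
#' normalisation.
#'
#' @return Character vector of panel gene names (reference gene excluded).
#' @export
qpcr_panel <- function() .sim_constants$qpcr_panel
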