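# Chemical-library handling and dose arithmetic.

# IUPAC conventional atomic weights (abridged to 5 significant figures).
.atomic_weights <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Ti = 47.867, V = 50.942, Cr = 51.996, Mn = 54.938,
  Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38,
  As = 74.922, Se = 78.971, Br = 79.904, Mo = 95.95, Ag = 107.87,
  Cd = 112.41, Sn = 118.71, Sb = 121.76, I = 126.90, Ba = 137.33,
  W = 183.84, Pt = 195.08, Au = 196.97, Hg = 200.59, Pb = 207.2
)

#' Parse a molecular formula in Hill notation
#'
#' Accepts plain element-count formulas such as `"C16H22O4"` or `"H2O"`:
#' element symbols each optionally followed by a positive integer count.
#' Isotopes, charges, hydrates and parenthesised groups are not supported.
#'
#' @param formula Single non-empty character string.
#' @return Named integer vector of element counts (all counts >= 1).
#' @examples
#' parse_formula("C16H22O4")
#' @seealso [hill_string()], [molecular_weight()]
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("'formula' must be a single non-empty character string")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("malformed formula: ", formula)
  }
  elements <- sub("[0-9]*$", "", tokens)
  counts <- sub("^[A-Za-z]+", "", tokens)
  counts <- ifelse(counts == "", "1", counts)
  counts <- as.integer(counts)
  unknown <- setdiff(elements, names(.atomic_weights))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(counts < 1L)) stop("element counts must be positive integers")
  out <- tapply(counts, factor(elements, levels = unique(elements)), sum)
  res <- as.integer(out)
  names(res) <- names(out)
  res
}

#' Canonical Hill-notation string for an element-count mapping
#'
#' Carbon first, hydrogen second, remaining elements alphabetical; when no
#' carbon is present all elements are alphabetical.
#'
#' @param counts Named integer vector as returned by [parse_formula()].
#' @return Single character string.
#' @export
hill_string <- function(counts) {
  if (length(counts) == 0) return("")
  els <- names(counts)
  if ("C" %in% els) {
    ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else {
    ord <- sort(els)
  }
  counts <- counts[ord]
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Molecular weight from an element-count mapping or formula
#'
#' @param counts Named integer vector of element counts, or a Hill-notation
#'   formula string (parsed with [parse_formula()]).
#' @return Molar mass in g/mol. The empty mapping gives 0.
#' @examples
#' molecular_weight("C16H22O4")
#' @export
molecular_weight <- function(counts) {
  if (is.character(counts)) counts <- parse_formula(counts)
  if (length(counts) == 0) return(0)
  unknown <- setdiff(names(counts), names(.atomic_weights))
  if (length(unknown) > 0) {
    stop("no standard atomic weight for: ", paste(unknown, collapse = ", "))
  }
  sum(.atomic_weights[names(counts)] * as.numeric(counts))
}

#' Convert a molar concentration to a mass concentration
#'
#' A dose of `conc` micromolar of a compound with molar mass `molar_mass`
#' corresponds to `conc * molar_mass / 1000` micrograms per millilitre
#' (e.g. 100 uM dibutyl phthalate, 278.35 g/mol, is 27.8 ug/ml).
#'
#' @param conc Concentration in umol/L; must be non-negative.
#' @param molar_mass Molar mass in g/mol; must be positive.
#' @return Concentration in ug/ml.
#' @seealso [ug_per_ml_to_micromolar()] for the inverse.
#' @export
micromolar_to_ug_per_ml <- function(conc, molar_mass) {
  stopifnot(is.numeric(conc), is.numeric(molar_mass))
  if (any(conc < 0)) stop("concentration must be non-negative")
  if (any(molar_mass <= 0)) stop("molar mass must be positive")
  conc * molar_mass / 1000
}

#' @rdname micromolar_to_ug_per_ml
#' @param conc_ug_ml Concentration in ug/ml; must be non-negative.
#' @export
ug_per_ml_to_micromolar <- function(conc_ug_ml, molar_mass) {
  stopifnot(is.numeric(conc_ug_ml), is.numeric(molar_mass))
  if (any(conc_ug_ml < 0)) stop("concentration must be non-negative")
  if (any(molar_mass <= 0)) stop("molar mass must be positive")
  conc_ug_ml * 1000 / molar_mass
}

.chem_categories <- c("pesticide", "phthalate", "crude-oil",
                      "hydraulic-fracturing", "dioxin", "plasticizer",
                      "vehicle")

#' Load and validate a chemical-library table
#'
#' The table is comma-delimited UTF-8 with header row exactly
#' `name,category,formula,dose_uM,solvent`. Each formula is parsed and the
#' molar mass and mass-concentration screen dose are added. Chemicals
#' dissolved in DMSO are assumed stocked at 0.1 mol/L unless a `stock_M`
#' column says otherwise.
#'
#' @param path Path to the CSV file. Lines starting with `#` are ignored.
#' @param default_dose_uM Screen dose assumed when `dose_uM` is missing
#'   (default 100 umol/L).
#' @return A data.frame with columns `name`, `category`, `formula`,
#'   `molar_mass`, `dose_uM`, `dose_ug_ml`, `stock_M`, `solvent`.
#' @export
load_chemical_library <- function(path, default_dose_uM = 100) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("name", "category", "formula", "dose_uM", "solvent")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0) stop("chemical library table is empty")
  if (anyDuplicated(tab$name)) {
    stop("duplicate chemical names: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  }
  bad_cat <- setdiff(unique(tab$category), .chem_categories)
  if (length(bad_cat) > 0) {
    stop("unknown category: ", paste(bad_cat, collapse = ", "))
  }
  tab$dose_uM[is.na(tab$dose_uM)] <- default_dose_uM
  if (any(tab$dose_uM < 0)) stop("screen dose must be non-negative")
  if (!all(tab$solvent %in% c("DMSO", "water"))) {
    stop("solvent must be 'DMSO' or 'water'")
  }
  counts <- lapply(tab$formula, parse_formula)
  tab$molar_mass <- vapply(counts, molecular_weight, numeric(1))
  tab$dose_ug_ml <- micromolar_to_ug_per_ml(tab$dose_uM, tab$molar_mass)
  if (is.null(tab$stock_M)) tab$stock_M <- ifelse(tab$solvent == "DMSO", 0.1, NA)
  tab[, c("name", "category", "formula", "molar_mass", "dose_uM",
          "dose_ug_ml", "stock_M", "solvent")]
}

#' Path to the bundled 46-chemical screen library
#'
#' @return Path to `chemical_library.csv` inside the installed package.
#' @export
germscreen_library_path <- function() {
  system.file("extdata", "chemical_library.csv", package = "germscreen",
              mustWork = TRUE)
}
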