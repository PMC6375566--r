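# Delta-delta-Ct relative quantification and germline-versus-soma
# attribution via the temperature-sensitive germline-less design.

#' Per-gene delta-Ct for one sample
#'
#' Technical replicates are averaged first; then
#' `delta_Ct = mean Ct(target) - mean Ct(reference)`. Unbalanced technical
#' replication is tolerated (mean of the available wells) and flagged.
#'
#' @param records data.frame of one sample's wells with columns `gene`,
#'   `tech_rep`, `ct`.
#' @param reference_gene Reference gene name (default `"gpd-1"`); must be
#'   present in the sample.
#' @return data.frame with columns `gene`, `delta_ct`, `n_tech`,
#'   `unbalanced` (reference gene excluded).
#' @export
delta_ct <- function(records, reference_gene = "gpd-1") {
  stopifnot(all(c("gene", "ct") %in% names(records)))
  if (!reference_gene %in% records$gene) {
    stop("reference gene '", reference_gene, "' missing from sample")
  }
  means <- tapply(records$ct, records$gene, mean)
  ns <- tapply(records$ct, records$gene, length)
  genes <- setdiff(names(means), reference_gene)
  data.frame(gene = genes,
             delta_ct = as.numeric(means[genes] - means[reference_gene]),
             n_tech = as.integer(ns[genes]),
             unbalanced = as.integer(ns[genes]) != max(ns))
}

#' Relative expression (fold change) of treated versus vehicle samples
#'
#' `fold = 2^-(mean dCt_treated - mean dCt_vehicle)` with amplification
#' efficiency fixed at 2, and an unpaired two-tailed t-test (Welch) on the
#' per-biological-replicate delta-Ct values.
#'
#' @param treated,vehicle Numeric vectors of per-biological-replicate
#'   delta-Ct values for one gene (>= 2 each for the test).
#' @return List of class `germscreen_test` with `fold`, `statistic` (t),
#'   `p_value`, `method`, `n1`, `n2`.
#' @export
relative_expression <- function(treated, vehicle) {
  if (length(treated) < 2 || length(vehicle) < 2) {
    stop("need at least 2 biological replicates per arm")
  }
  ddct <- mean(treated) - mean(vehicle)
  fold <- 2^(-ddct)
  # noise-free replicates make the t statistic undefined: p is 1 when the
  # arms agree and 0 when they are separated with zero variance
  tt <- tryCatch(stats::t.test(treated, vehicle), error = function(e) NULL)
  if (is.null(tt)) {
    t_stat <- NA_real_
    p <- if (abs(ddct) < 1e-12) 1 else 0
  } else {
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(fold = fold, statistic = t_stat, p_value = p,
                 method = "welch_t", n1 = length(treated),
                 n2 = length(vehicle)),
            class = "germscreen_test")
}

#' Attribute an expression change to the germline or the soma
#'
#' Adults of the temperature-sensitive germline-less mutant report combined
#' soma + germline expression when raised at 15 C but soma-only expression
#' at 25 C. A change significant at 15 C and not at 25 C is
#' `germline_specific`; a change significant at 25 C is `somatic`;
#' otherwise `none`.
#'
#' @param result_15c,result_25c [relative_expression()] results (or any
#'   list with a `p_value`) for the same gene at each temperature.
#' @param alpha Significance level (default 0.05).
#' @return `"germline_specific"`, `"somatic"` or `"none"`.
#' @export
germline_attribution <- function(result_15c, result_25c, alpha = 0.05) {
  p15 <- result_15c$p_value; p25 <- result_25c$p_value
  if (is.null(p15) || is.null(p25) || is.na(p15) || is.na(p25)) {
    stop("both temperature arms are required")
  }
  if (p25 < alpha) "somatic"
  else if (p15 < alpha) "germline_specific"
  else "none"
}

#' Full qPCR analysis of a Ct table
#'
#' For each gene and temperature: average technical replicates, compute
#' per-biological-replicate delta-Ct against the reference gene, fold
#' change of the treated condition over vehicle, Welch t-test, and (when
#' both temperatures are present) the germline/soma attribution label.
#'
#' @param ct_table data.frame with columns `gene`, `condition`, `temp_c`,
#'   `bio_rep`, `tech_rep`, `ct`.
#' @param treated,vehicle Condition names to compare.
#' @param reference_gene Reference gene (default `"gpd-1"`).
#' @param alpha Significance level for attribution.
#' @return data.frame with one row per gene x temperature (`fold`,
#'   `p_value`, `stars`) and an `attribution` attribute data.frame (gene,
#'   label) when both temperatures are available.
#' @export
qpcr_analysis <- function(ct_table, treated, vehicle = "DMSO",
                          reference_gene = "gpd-1", alpha = 0.05) {
  need <- c("gene", "condition", "temp_c", "bio_rep", "tech_rep", "ct")
  stopifnot(all(need %in% names(ct_table)))
  for (cond in c(treated, vehicle)) {
    if (!cond %in% ct_table$condition) stop("condition not present: ", cond)
  }
  dct_by <- function(cond, temp) {
    sub <- ct_table[ct_table$condition == cond & ct_table$temp_c == temp, ]
    reps <- lapply(split(sub, sub$bio_rep), delta_ct,
                   reference_gene = reference_gene)
    for (i in seq_along(reps)) reps[[i]]$bio_rep <- names(reps)[i]
    do.call(rbind, reps)
  }
  temps <- sort(unique(ct_table$temp_c))
  rows <- list(); per_gene <- list()
  for (temp in temps) {
    tr <- dct_by(treated, temp); veh <- dct_by(vehicle, temp)
    for (g in unique(tr$gene)) {
      res <- relative_expression(tr$delta_ct[tr$gene == g],
                                 veh$delta_ct[veh$gene == g])
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, temp_c = temp, fold = res$fold, p_value = res$p_value,
        stars = .stars(res$p_value))
      per_gene[[g]][[as.character(temp)]] <- res
    }
  }
  out <- do.call(rbind, rows)
  if (all(c(15, 25) %in% temps)) {
    attr(out, "attribution") <- do.call(rbind, lapply(names(per_gene), function(g) {
      data.frame(gene = g,
                 label = germline_attribution(per_gene[[g]][["15"]],
                                              per_gene[[g]][["25"]], alpha))
    }))
  }
  out
}
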