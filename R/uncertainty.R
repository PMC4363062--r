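#' Systematic uncertainty components of a point-dose measurement
#'
#' Relative (percent, 1SD) systematic components combined in quadrature with
#' the type-A statistical uncertainty: phantom positioning (10%), dosimeter
#' positioning (10%), x-ray source output variation (5%) and cable
#' irradiation (1%). The separate fraction-irradiated uncertainty (25%)
#' enters at the tissue level, not at the point level.
#'
#' @param phantom_positioning,dosimeter_positioning,source_variation,cable_irradiation
#'   Percent 1SD values, all >= 0.
#' @param fraction_uncertainty Percent 1SD on each fraction irradiated f_i.
#' @return A list of class `systematic_components`.
#' @export
systematic_components <- function(phantom_positioning = 10,
                                  dosimeter_positioning = 10,
                                  source_variation = 5,
                                  cable_irradiation = 1,
                                  fraction_uncertainty = 25) {
  vals <- c(phantom_positioning, dosimeter_positioning, source_variation,
            cable_irradiation, fraction_uncertainty)
  if (any(vals < 0)) stop("uncertainty components must be >= 0")
  structure(list(phantom_positioning = phantom_positioning,
                 dosimeter_positioning = dosimeter_positioning,
                 source_variation = source_variation,
                 cable_irradiation = cable_irradiation,
                 fraction_uncertainty = fraction_uncertainty),
            class = "systematic_components")
}

#' Combined point-dose uncertainty
#'
#' Quadrature (weighted sum of variances) of the type-A statistical
#' uncertainty with the point-level systematic components:
#' u_c = sqrt(type_a^2 + pos_phantom^2 + pos_dosimeter^2 + source^2 +
#' cable^2). Returned unrounded; round half-up to integer percent for
#' display.
#'
#' @param type_a Type-A uncertainty in percent (>= 0). Vectorised.
#' @param sys A [systematic_components()] object.
#' @return Combined point uncertainty u_c in percent (unrounded).
#' @export
combine_point_uncertainty <- function(type_a, sys = systematic_components()) {
  if (any(type_a < 0)) stop("type_a must be >= 0")
  sqrt(type_a^2 + sys$phantom_positioning^2 + sys$dosimeter_positioning^2 +
         sys$source_variation^2 + sys$cable_irradiation^2)
}

#' Tissue-dose uncertainty
#'
#' Propagates independent sub-unit contributions into one tissue-level
#' relative uncertainty. Each sub-unit's relative variance is its point-dose
#' variance plus the fraction-irradiated variance, u_i^2 + fraction_u^2; the
#' tissue value is the contribution-weighted quadrature
#' u_T = sqrt(sum_i (c_i * sqrt(u_i^2 + fraction_u^2))^2) / sum_i c_i.
#' Sub-units are treated as independent of one another; dosimeters sharing a
#' sub-unit (and hence its f_i) should be combined into a single (c_i, u_i)
#' term first, so their common fraction error is not spuriously averaged
#' away.
#'
#' @param contributions Data.frame or list with columns/fields `c_uSv`
#'   (sub-unit dose contributions, uSv) and `u_pct` (their point-dose
#'   relative uncertainties, %).
#' @param fraction_u Fraction-irradiated uncertainty in percent (default 25).
#' @return Tissue relative uncertainty in percent (unrounded).
#' @export
tissue_uncertainty <- function(contributions, fraction_u = 25) {
  c_i <- contributions$c_uSv
  u_i <- contributions$u_pct
  if (sum(c_i) <= 0) stop("all-zero contributions; tissue uncertainty undefined")
  u_sub <- sqrt(u_i^2 + fraction_u^2)
  sqrt(sum((c_i * u_sub)^2)) / sum(c_i)
}

#' Expanded effective-dose uncertainty
#'
#' Combines per-tissue contributions and uncertainties by weighted sum of
#' variances, u = sqrt(sum_T (c_T * u_T)^2) / sum_T c_T, then expands by the
#' coverage factor: U_c = k * u (k = 2 for ~95% coverage).
#'
#' @param tissue_terms Data.frame or list with `contribution_uSv` and
#'   `u_pct`.
#' @param k Coverage factor (> 0, default 2).
#' @return Expanded relative uncertainty U_c in percent (unrounded).
#' @export
expanded_effective_uncertainty <- function(tissue_terms, k = 2) {
  c_T <- tissue_terms$contribution_uSv
  u_T <- tissue_terms$u_pct
  if (!length(c_T)) stop("no tissue terms supplied")
  if (sum(c_T) <= 0) stop("total contribution must be > 0")
  if (k <= 0) stop("coverage factor k must be > 0")
  k * sqrt(sum((c_T * u_T)^2)) / sum(c_T)
}

# internal: relative uncertainty (%) of one fraction entry's dose term.
# For mean and per-site-sum aggregation alike, independent member point
# errors combine as sqrt(sum (D_d u_d)^2) / sum D_d.
.entry_point_u <- function(entry, estimates, u_by_id) {
  d <- .lookup_doses(estimates, entry$dosimeters)
  u <- u_by_id[as.character(entry$dosimeters)]
  if (anyNA(u)) stop("missing point uncertainty for dosimeter ",
                     paste(entry$dosimeters[is.na(u)], collapse = ", "))
  if (sum(d) == 0) return(0)
  sqrt(sum((d * u)^2)) / sum(d)
}

#' Full uncertainty budget for a study
#'
#' Builds the complete budget from dose estimates: per-dosimeter type-A and
#' combined point uncertainties, per-tissue uncertainties (point terms
#' propagated per fraction entry plus the fraction-irradiated term), and the
#' expanded effective-dose uncertainty.
#'
#' @param estimates Data.frame with `dosimeter_no`, `mean_dose` (mGy) and
#'   `rel_sd` (type-A, %).
#' @param model A `phantom_model`.
#' @param fractions A `fraction_table`.
#' @param weights A `tissue_weights` object.
#' @param sys A [systematic_components()] object.
#' @param k Coverage factor for the expanded uncertainty.
#' @return An object of class `uncertainty_budget`: `per_dosimeter`
#'   (data.frame: dosimeter_no, mean_dose, type_a_pct, u_c_pct),
#'   `per_tissue` (tissue, contribution_uSv, u_pct), `combined_pct`,
#'   `expanded_pct`, `k`, and the `effective_dose` result the weights imply.
#' @export
uncertainty_budget <- function(estimates, model, fractions, weights,
                               sys = systematic_components(), k = 2) {
  if (anyNA(estimates$rel_sd)) {
    stop("type-A uncertainty undefined (single exposure?) for dosimeter ",
         paste(estimates$dosimeter_no[is.na(estimates$rel_sd)], collapse = ", "))
  }
  per_dosimeter <- data.frame(
    dosimeter_no = estimates$dosimeter_no,
    mean_dose = estimates$mean_dose,
    type_a_pct = estimates$rel_sd,
    u_c_pct = combine_point_uncertainty(estimates$rel_sd, sys)
  )
  u_by_id <- stats::setNames(per_dosimeter$u_c_pct,
                             as.character(per_dosimeter$dosimeter_no))

  groups <- resolve_groups(model, fractions)
  ed <- compute_effective_dose(estimates, model, fractions, weights)

  per_tissue <- do.call(rbind, lapply(names(groups$groups), function(tis) {
    entries <- groups$groups[[tis]]
    sub <- data.frame(
      c_uSv = vapply(entries, function(e)
        weights$w_R * 1000 * .entry_dose_mGy(e, estimates), numeric(1)),
      u_pct = vapply(entries, .entry_point_u, numeric(1),
                     estimates = estimates, u_by_id = u_by_id)
    )
    data.frame(tissue = tis,
               contribution_uSv = ed$tissues$contribution_uSv[
                 match(tis, ed$tissues$tissue)],
               u_pct = tissue_uncertainty(sub, sys$fraction_uncertainty),
               stringsAsFactors = FALSE)
  }))

  combined <- expanded_effective_uncertainty(per_tissue, k = 1)
  structure(list(per_dosimeter = per_dosimeter, per_tissue = per_tissue,
                 combined_pct = combined, expanded_pct = k * combined, k = k,
                 effective_dose = ed),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat("uncertainty budget (", nrow(x$per_dosimeter), " dosimeters)\n", sep = "")
  pd <- x$per_dosimeter
  pd$u_c_pct <- round_half_up(pd$u_c_pct)
  print(pd, row.names = FALSE)
  pt <- x$per_tissue
  pt$u_pct <- round_half_up(pt$u_pct)
  print(pt, row.names = FALSE)
  cat(sprintf("combined effective-dose uncertainty: %.1f%%; expanded (k=%g): %.1f%%\n",
              x$combined_pct, x$k, x$expanded_pct))
  invisible(x)
}
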