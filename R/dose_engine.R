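#' Per-dosimeter mean dose and type-A spread
#'
#' Averages the repeated absorbed-dose readings of one dosimeter and computes
#' the relative 1SD spread (sample SD, n-1 denominator, as a percent of the
#' mean). That spread is the type-A statistical uncertainty of the point
#' dose; no sqrt(n) reduction is applied, matching the convention of quoting
#' the 1SD variation of single exposures.
#'
#' @param record A [dosimeter_record()] with at least one reading, or a bare
#'   numeric vector of readings.
#' @return A data.frame row of class `dose_estimate`: `dosimeter_no`,
#'   `mean_dose` (mGy), `rel_sd` (%; `NA` when undefined), `n_exposures`.
#' @export
mean_dose <- function(record) {
  if (is.numeric(record)) {
    readings <- record
    no <- NA_integer_
  } else {
    stopifnot(inherits(record, "dosimeter_record"))
    readings <- record$readings
    no <- record$dosimeter_no
  }
  if (!length(readings)) stop("cannot average zero readings")
  m <- mean(readings)
  rel_sd <- if (length(readings) < 2L) {
    NA_real_  # spread undefined from one exposure
  } else if (m == 0) {
    if (stats::sd(readings) > 0) NA_real_ else 0
  } else {
    100 * stats::sd(readings) / m
  }
  out <- data.frame(dosimeter_no = no, mean_dose = m, rel_sd = rel_sd,
                    n_exposures = length(readings))
  class(out) <- c("dose_estimate", class(out))
  out
}

#' Mean doses for every dosimeter in a phantom model
#'
#' @param model A `phantom_model` whose records carry readings.
#' @return Data.frame of dose estimates, one row per dosimeter.
#' @export
dose_estimates <- function(model) {
  stopifnot(inherits(model, "phantom_model"))
  do.call(rbind, lapply(model$records, function(r) {
    df <- mean_dose(r)
    class(df) <- "data.frame"
    df
  }))
}

# internal: mean dose (mGy) looked up from an estimates data.frame
.lookup_doses <- function(estimates, ids) {
  pos <- match(ids, estimates$dosimeter_no)
  if (anyNA(pos)) {
    stop("no dose estimate for dosimeter ",
         paste(ids[is.na(pos)], collapse = ", "))
  }
  estimates$mean_dose[pos]
}

# internal: one fraction entry's dose contribution in mGy
.entry_dose_mGy <- function(entry, estimates) {
  d <- .lookup_doses(estimates, entry$dosimeters)
  switch(entry$aggregation,
    mean_then_fraction = entry$f_i * mean(d),
    group_mean         = entry$f_i * mean(d),
    per_site_fraction  = entry$f_i * sum(d),
    stop("unknown aggregation mode: ", entry$aggregation)
  )
}

#' Equivalent dose of one tissue group
#'
#' Applies the radiation-weighted point-dose sum
#' H_T = w_R * sum_i f_i * D_Ti over the tissue's fraction entries, where
#' each entry's dose D is its members' mean or per-site sum depending on its
#' aggregation mode. Readings are in mGy; H_T is returned in uSv (w_R in
#' Sv/Gy, so 1 mGy of absorbed dose is 1000 uSv of equivalent dose for
#' x-rays). The mGy-to-uSv conversion happens here and nowhere else.
#'
#' @param group One tissue's resolved entry list, as found in
#'   `resolve_groups(...)$groups[[tissue]]`.
#' @param estimates Data.frame of dose estimates (see [dose_estimates()]).
#' @param tissue Tissue label for the result.
#' @param w_R Radiation weighting factor (1 for x-rays).
#' @return An object of class `equivalent_dose`: `tissue`, `H_uSv`, and
#'   `contributions` (data.frame with per-entry subunit, f_i, dose in uSv and
#'   member dosimeters).
#' @export
equivalent_dose <- function(group, estimates, tissue, w_R = 1) {
  per_entry <- do.call(rbind, lapply(group, function(e) {
    data.frame(subunit = e$subunit, f_i = e$f_i,
               aggregation = e$aggregation,
               c_uSv = w_R * 1000 * .entry_dose_mGy(e, estimates),
               dosimeters = paste(e$dosimeters, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  structure(list(tissue = tissue, H_uSv = sum(per_entry$c_uSv),
                 contributions = per_entry),
            class = "equivalent_dose")
}

#' Effective dose from per-tissue equivalent doses
#'
#' E = sum_T w_T * H_T, with remainder organs (muscle, lymphatic nodes) each
#' weighted by w_remainder / remainder_count instead of an individual w_T.
#' Percent shares are computed on the unrounded contributions.
#'
#' @param H_results List of `equivalent_dose` objects, one per tissue
#'   (tissues must be distinct).
#' @param weights A `tissue_weights` object covering every tissue present.
#' @param protocol Optional protocol metadata attached to the result.
#' @return An object of class `effective_dose`: `E_uSv`, `tissues`
#'   (data.frame: tissue, H_uSv, weight, contribution_uSv, pct), `protocol`.
#' @export
effective_dose <- function(H_results, weights, protocol = NULL) {
  stopifnot(inherits(weights, "tissue_weights"))
  tis <- vapply(H_results, function(h) h$tissue, character(1))
  if (anyDuplicated(tis)) stop("duplicate tissue in H_results: ",
                               tis[duplicated(tis)][1])
  w <- vapply(tis, effective_weight, numeric(1), weights = weights)
  H <- vapply(H_results, function(h) h$H_uSv, numeric(1))
  contrib <- w * H
  E <- sum(contrib)
  tissues <- data.frame(tissue = tis, H_uSv = H, weight = w,
                        contribution_uSv = contrib,
                        pct = if (E > 0) 100 * contrib / E else NA_real_,
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(E_uSv = E, tissues = tissues, protocol = protocol,
                 H_results = H_results),
            class = "effective_dose")
}

#' @export
print.effective_dose <- function(x, digits = 1, ...) {
  if (!is.null(x$protocol)) cat("protocol:", format(x$protocol), "\n")
  df <- x$tissues
  df$contribution_uSv <- round(df$contribution_uSv, digits)
  df$pct <- round_half_up(df$pct)
  print(df[c("tissue", "contribution_uSv", "pct")], row.names = FALSE)
  cat("effective dose:", round(x$E_uSv, digits), "uSv\n")
  invisible(x)
}

#' Round half away from zero
#'
#' Display rounding used throughout the reports (R's `round()` rounds half to
#' even, which does not match conventional dose-table rounding).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-tissue contribution breakdown
#'
#' Percent shares of the effective dose, computed on unrounded contributions
#' and rounded half-up to integers for display.
#'
#' @param result An `effective_dose` object, or a named numeric vector of
#'   per-tissue contributions in uSv.
#' @param total Denominator in uSv; defaults to the sum of contributions
#'   (pass a separately quoted total to reproduce a published table's
#'   percentages).
#' @return Data.frame: `tissue`, `contribution_uSv`, `pct` (exact), `pct_display`
#'   (integer).
#' @export
contribution_breakdown <- function(result, total = NULL) {
  if (inherits(result, "effective_dose")) {
    contrib <- stats::setNames(result$tissues$contribution_uSv,
                               result$tissues$tissue)
  } else {
    contrib <- result
    if (is.null(names(contrib))) stop("contributions must be named by tissue")
  }
  if (is.null(total)) total <- sum(contrib)
  if (total <= 0) stop("effective dose is zero; percentages undefined")
  pct <- 100 * contrib / total
  data.frame(tissue = names(contrib), contribution_uSv = unname(contrib),
             pct = unname(pct), pct_display = unname(round_half_up(pct)),
             stringsAsFactors = FALSE)
}

#' Fold ratio between two effective doses
#'
#' @param E_a Numerator effective dose (uSv).
#' @param E_b Denominator effective dose (uSv, > 0).
#' @return List with `ratio` (raw) and `display` (character: nearest integer
#'   fold at >= 10, one decimal below).
#' @export
dose_ratio <- function(E_a, E_b) {
  if (E_b <= 0) stop("denominator effective dose must be > 0")
  r <- E_a / E_b
  display <- if (r >= 10) {
    sprintf("%d-fold", as.integer(round_half_up(r)))
  } else {
    sprintf("%.1f-fold", round_half_up(r, 1))
  }
  list(ratio = r, display = display)
}

#' End-to-end effective dose for one study
#'
#' Convenience wrapper: resolve tissue groups, form equivalent doses, and
#' weight into the effective dose.
#'
#' @param estimates Data.frame of dose estimates (`dosimeter_no`,
#'   `mean_dose` in mGy; see [dose_estimates()] / [read_readings_csv()]).
#' @param model A `phantom_model`.
#' @param fractions A `fraction_table`.
#' @param weights A `tissue_weights` object.
#' @param protocol Optional protocol metadata.
#' @return An `effective_dose` object.
#' @export
compute_effective_dose <- function(estimates, model, fractions, weights,
                                   protocol = NULL) {
  groups <- resolve_groups(model, fractions)
  H <- lapply(names(groups$groups), function(tis) {
    equivalent_dose(groups$groups[[tis]], estimates, tis, w_R = weights$w_R)
  })
  effective_dose(H, weights, protocol = protocol)
}
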