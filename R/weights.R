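#' ICRP-103 tissue weighting configuration
#'
#' Holds the tissue weighting factors w_T, the membership and size of the
#' remainder-tissue group, and the radiation weighting factor w_R (1 Sv/Gy
#' for x-rays). In an extremity study only a handful of weighted tissues are
#' present; remainder members each receive w_remainder / remainder_count,
#' with remainder_count = 13 (the size of the ICRP-103 remainder set).
#'
#' @param w_T Named numeric vector mapping tissue label to weighting factor.
#'   Remainder members are not listed here; they share `w_remainder`.
#' @param w_remainder Collective remainder weight (ICRP 103: 0.12).
#' @param remainder_members Character vector of tissues treated as remainder
#'   organs (here muscle and lymphatic nodes).
#' @param remainder_count Number of tissues the remainder weight is split
#'   over (ICRP 103: 13).
#' @param w_R Radiation weighting factor, 1 for x-rays.
#' @return An object of class `tissue_weights`.
#' @export
tissue_weight_table <- function(w_T = c(bone_marrow = 0.12, bone_surface = 0.01,
                                        skin = 0.01),
                                w_remainder = 0.12,
                                remainder_members = c("muscle", "lymphatic_nodes"),
                                remainder_count = 13L,
                                w_R = 1) {
  if (any(w_T <= 0)) stop("all w_T must be > 0")
  if (w_remainder <= 0) stop("w_remainder must be > 0")
  if (remainder_count < 1) stop("remainder_count must be >= 1")
  if (length(intersect(names(w_T), remainder_members))) {
    stop("a tissue cannot be both named and a remainder member")
  }
  structure(list(w_T = w_T, w_remainder = w_remainder,
                 remainder_members = remainder_members,
                 remainder_count = as.integer(remainder_count), w_R = w_R),
            class = "tissue_weights")
}

#' Effective weight applied to one tissue's equivalent dose
#'
#' Named tissues get their own w_T; remainder members get
#' w_remainder / remainder_count.
#'
#' @param weights A `tissue_weights` object.
#' @param tissue Tissue label.
#' @return Numeric weight.
#' @export
effective_weight <- function(weights, tissue) {
  if (tissue %in% names(weights$w_T)) return(unname(weights$w_T[[tissue]]))
  if (tissue %in% weights$remainder_members) {
    return(weights$w_remainder / weights$remainder_count)
  }
  stop("no weighting factor for tissue '", tissue, "'")
}

#' Validate a weighting table against the ICRP-103 reference constants
#'
#' Report-only check of the weighting factors actually used against the
#' ICRP-103 values relevant to an extremity study (bone marrow 0.12, bone
#' surface 0.01, skin 0.01, remainder 0.12) and w_R = 1 for x-rays.
#'
#' @param weights A `tissue_weights` object.
#' @return A data.frame of deviations (zero rows when fully conformant) with
#'   columns `quantity`, `expected`, `actual`.
#' @export
validate_weights <- function(weights) {
  ref <- c(bone_marrow = 0.12, bone_surface = 0.01, skin = 0.01)
  dev <- data.frame(quantity = character(0), expected = numeric(0),
                    actual = numeric(0), stringsAsFactors = FALSE)
  for (tis in names(ref)) {
    actual <- if (tis %in% names(weights$w_T)) weights$w_T[[tis]] else NA_real_
    if (is.na(actual) || abs(actual - ref[[tis]]) > 1e-12) {
      dev <- rbind(dev, data.frame(quantity = paste0("w_T[", tis, "]"),
                                   expected = ref[[tis]], actual = actual))
    }
  }
  if (abs(weights$w_remainder - 0.12) > 1e-12) {
    dev <- rbind(dev, data.frame(quantity = "w_remainder", expected = 0.12,
                                 actual = weights$w_remainder))
  }
  if (abs(weights$w_R - 1) > 1e-12) {
    dev <- rbind(dev, data.frame(quantity = "w_R", expected = 1,
                                 actual = weights$w_R))
  }
  dev
}
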