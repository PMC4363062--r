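#' One fraction-irradiated entry
#'
#' Ties a sub-unit of a tissue (a bone, a skin site, or a whole-tissue group)
#' to its fraction irradiated f_i -- the share of the whole-body organ mass
#' (or area) contained in the exposed region -- and the dosimeters measuring
#' it. The aggregation mode fixes how member doses combine into the entry's
#' dose contribution (see [equivalent_dose()]):
#' \describe{
#'   \item{mean_then_fraction}{f_i times the mean of member doses (bone
#'     marrow: several dosimeters sample one bone).}
#'   \item{per_site_fraction}{f_i applied to each member site's dose, summed
#'     (skin and bone surface: each site carries the fraction).}
#'   \item{group_mean}{f_i times the mean of all member doses (muscle,
#'     lymphatic nodes: the group is one organ).}
#' }
#'
#' @param tissue One of [tissue_classes()].
#' @param subunit Sub-organ label.
#' @param f_i Fraction irradiated, in (0, 1].
#' @param dosimeters Integer vector of member dosimeter numbers (non-empty).
#' @param aggregation One of the modes above.
#' @return A list of class `fraction_entry`.
#' @export
fraction_entry <- function(tissue, subunit, f_i, dosimeters,
                           aggregation = c("mean_then_fraction",
                                           "per_site_fraction", "group_mean")) {
  tissue <- match.arg(tissue, tissue_classes())
  aggregation <- match.arg(aggregation)
  if (!is.numeric(f_i) || length(f_i) != 1L || f_i <= 0 || f_i > 1) {
    stop("f_i must be a single value in (0, 1]")
  }
  dosimeters <- as.integer(dosimeters)
  if (!length(dosimeters)) stop("a fraction entry needs at least one dosimeter")
  structure(list(tissue = tissue, subunit = subunit, f_i = f_i,
                 dosimeters = dosimeters, aggregation = aggregation),
            class = "fraction_entry")
}

#' Assemble a fraction table
#'
#' @param entries List of [fraction_entry()] objects. A dosimeter may appear
#'   in at most one entry.
#' @return An object of class `fraction_table`.
#' @export
fraction_table <- function(entries) {
  stopifnot(is.list(entries))
  ids <- unlist(lapply(entries, function(e) e$dosimeters))
  if (anyDuplicated(ids)) {
    stop("dosimeter appears in more than one fraction entry: ",
         ids[duplicated(ids)][1])
  }
  structure(list(entries = entries), class = "fraction_table")
}

#' @export
print.fraction_table <- function(x, ...) {
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.fraction_table <- function(x, ...) {
  do.call(rbind, lapply(x$entries, function(e) {
    data.frame(tissue = e$tissue, subunit = e$subunit, f_i = e$f_i,
               dosimeters = paste(e$dosimeters, collapse = ";"),
               aggregation = e$aggregation, stringsAsFactors = FALSE)
  }))
}

#' Du Bois body surface area
#'
#' The classical Du Bois-Du Bois allometric formula,
#' BSA = 0.007184 * W^0.425 * H^0.725, with W in kg and H in cm, giving body
#' surface area in m^2. Used to turn a locally measured skin area into a
#' whole-body skin fraction. The constants live in one place so an alternate
#' coefficient set can be swapped in.
#'
#' @param height_cm Standing height in cm (> 0).
#' @param weight_kg Body mass in kg (> 0).
#' @param coef Coefficients `c(k, w_exp, h_exp)`.
#' @return Body surface area in m^2.
#' @export
du_bois_area <- function(height_cm, weight_kg,
                         coef = c(k = 0.007184, w_exp = 0.425, h_exp = 0.725)) {
  if (any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("height and weight must be > 0")
  }
  coef[["k"]] * weight_kg^coef[["w_exp"]] * height_cm^coef[["h_exp"]]
}

#' Reference anthropometric data for fraction derivations
#'
#' @param height_cm Height in cm.
#' @param weight_kg Weight in kg.
#' @param total_muscle_mass_g Whole-body muscle mass in g (reference adult:
#'   28000 g).
#' @param total_skin_area_m2 Whole-body skin area in m^2; computed from the
#'   Du Bois formula when not supplied.
#' @return A list of class `body_reference`.
#' @export
body_reference <- function(height_cm = 180, weight_kg = 70,
                           total_muscle_mass_g = 28000,
                           total_skin_area_m2 = NULL) {
  if (height_cm <= 0 || weight_kg <= 0) stop("height and weight must be > 0")
  if (is.null(total_skin_area_m2)) {
    total_skin_area_m2 <- du_bois_area(height_cm, weight_kg)
  }
  structure(list(height_cm = height_cm, weight_kg = weight_kg,
                 total_muscle_mass_g = total_muscle_mass_g,
                 total_skin_area_m2 = total_skin_area_m2),
            class = "body_reference")
}

#' Regional skin-area specification
#'
#' Skin area over calf layers is perimeter x slab thickness; over foot layers
#' it is measured planimetrically.
#'
#' @param layer_perimeters Data.frame with columns `layer`, `perimeter_mm`.
#' @param layer_thickness_mm Slab thickness in mm.
#' @param planimetric_areas Data.frame with columns `layer`, `area_mm2`.
#' @return A list of class `region_area_spec`.
#' @export
region_area_spec <- function(layer_perimeters = NULL, layer_thickness_mm = 25,
                             planimetric_areas = NULL) {
  if (!is.null(layer_perimeters) && any(layer_perimeters$perimeter_mm <= 0)) {
    stop("perimeters must be positive")
  }
  if (!is.null(planimetric_areas) && any(planimetric_areas$area_mm2 <= 0)) {
    stop("planimetric areas must be positive")
  }
  if (layer_thickness_mm <= 0) stop("layer thickness must be positive")
  structure(list(layer_perimeters = layer_perimeters,
                 layer_thickness_mm = layer_thickness_mm,
                 planimetric_areas = planimetric_areas),
            class = "region_area_spec")
}

#' Regional skin area in m^2
#'
#' @param region A `region_area_spec`.
#' @return Area in m^2 (sum of perimeter x thickness bands plus planimetric
#'   foot areas).
#' @export
region_skin_area <- function(region) {
  stopifnot(inherits(region, "region_area_spec"))
  a <- 0
  if (!is.null(region$layer_perimeters)) {
    a <- a + sum(region$layer_perimeters$perimeter_mm * region$layer_thickness_mm)
  }
  if (!is.null(region$planimetric_areas)) {
    a <- a + sum(region$planimetric_areas$area_mm2)
  }
  a / 1e6  # mm^2 -> m^2
}

#' Skin fraction irradiated
#'
#' Ratio of the regional skin area to whole-body skin area. A region larger
#' than the body is almost surely a unit error: it raises an error unless
#' `cap = TRUE`, which caps at 1 with a warning.
#'
#' @param region A `region_area_spec`.
#' @param total_area_m2 Whole-body skin area in m^2 (> 0).
#' @param cap Cap at 1 instead of erroring when region > total.
#' @return Dimensionless fraction.
#' @export
skin_fraction <- function(region, total_area_m2, cap = FALSE) {
  if (total_area_m2 <= 0) stop("total skin area must be > 0")
  f <- region_skin_area(region) / total_area_m2
  if (f > 1) {
    if (cap) {
      warning("regional skin area exceeds total body area; capping fraction at 1")
      f <- 1
    } else {
      stop("regional skin area exceeds total body area (", signif(f, 3),
           "x); check units or pass cap = TRUE")
    }
  }
  f
}

#' Total regional marrow percentage from calf and foot contributions
#'
#' The exposed ankle volume spans two literature-derived marrow pools: the
#' calf sections of tibia and fibula (MRI volumetry) and the foot/ankle
#' skeleton (cadaver data). Their whole-body marrow-mass percentages simply
#' add.
#'
#' @param calf_pct Calf (tibia + fibula) marrow as % of whole-body marrow
#'   mass (reference value 0.7).
#' @param foot_pct Foot/ankle marrow as % of whole-body marrow mass
#'   (reference value 0.4).
#' @return Total regional marrow percentage.
#' @export
marrow_region_fraction <- function(calf_pct = 0.7, foot_pct = 0.4) {
  if (calf_pct < 0 || foot_pct < 0) stop("marrow percentages must be >= 0")
  calf_pct + foot_pct
}

#' Default ankle fraction table
#'
#' The shipped fraction-irradiated configuration for the six-layer ankle
#' phantom: per-bone red-marrow fractions (total 1.2% of whole-body marrow),
#' the calcaneal-tuberosity bone-surface sites (4.9% of whole-body bone
#' surface, one entry carrying both sites), two skin sites (0.9% and 2.6% of
#' whole-body skin area), the muscle group (0.9% of whole-body muscle mass)
#' and the lymphatic-node group (1% of whole-body nodes). Talus marrow
#' (dosimeter 15) has no fraction assigned by default and is reported unused;
#' pass `include_talus = TRUE` to fold it into a marrow entry of its own.
#'
#' @param include_talus Add a talus marrow entry (dosimeter 15) with
#'   `talus_f`.
#' @param talus_f Fraction for the optional talus entry.
#' @param bone_surface_aggregation Aggregation mode for the bone-surface
#'   entry: `"per_site_fraction"` (default; each tuberosity site carries the
#'   4.9% fraction) or `"group_mean"` (the two sites are averaged first).
#'   Both are defensible readings of "averaging the equivalent doses"; the
#'   per-site mode is the one consistent with the bundled study's published
#'   dose table.
#' @return A `fraction_table`.
#' @export
default_ankle_fractions <- function(include_talus = FALSE, talus_f = 0.001,
                                    bone_surface_aggregation = c("per_site_fraction",
                                                                 "group_mean")) {
  bone_surface_aggregation <- match.arg(bone_surface_aggregation)
  entries <- list(
    fraction_entry("bone_marrow", "tibia",       0.007, c(1L, 4L, 7L, 9L),
                   "mean_then_fraction"),
    fraction_entry("bone_marrow", "fibula",      0.001, c(6L, 11L),
                   "mean_then_fraction"),
    fraction_entry("bone_marrow", "navicular",   0.001, 14L, "mean_then_fraction"),
    fraction_entry("bone_marrow", "metatarsals", 0.001, 16L, "mean_then_fraction"),
    fraction_entry("bone_marrow", "calcaneus",   0.002, 18L, "mean_then_fraction"),
    fraction_entry("bone_surface", "calcaneal_tuberosity", 0.049, c(13L, 19L),
                   bone_surface_aggregation),
    fraction_entry("skin", "superior_extensor_retinaculum", 0.009, 8L,
                   "per_site_fraction"),
    fraction_entry("skin", "calcaneal_tendon", 0.026, 10L, "per_site_fraction"),
    fraction_entry("muscle", "ankle_muscles", 0.009, c(2L, 3L, 5L, 20L),
                   "group_mean"),
    fraction_entry("lymphatic_nodes", "ankle_nodes", 0.010, c(12L, 17L),
                   "group_mean")
  )
  if (include_talus) {
    entries <- append(entries, list(
      fraction_entry("bone_marrow", "talus", talus_f, 15L, "mean_then_fraction")
    ), after = 5L)
  }
  fraction_table(entries)
}
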