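#' Construct a phantom layer
#'
#' A layered anthropomorphic extremity phantom is described slab by slab.
#' Layer indices follow the phantom manufacturer's numbering (23--28 for the
#' ankle section used in the bundled study) and are kept verbatim.
#'
#' @param index Integer layer number.
#' @param thickness_mm Slab thickness in mm (default 25).
#' @param perimeter_mm Optional outer perimeter in mm, used for skin-area
#'   estimation on calf layers.
#' @param description Free-text note.
#' @return A list of class `phantom_layer`.
#' @export
phantom_layer <- function(index, thickness_mm = 25, perimeter_mm = NULL,
                          description = "") {
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index)) stop("layer index must be a single integer")
  if (!is.numeric(thickness_mm) || thickness_mm <= 0) stop("layer thickness must be > 0")
  if (!is.null(perimeter_mm) && perimeter_mm <= 0) stop("layer perimeter must be > 0")
  structure(list(index = index, thickness_mm = thickness_mm,
                 perimeter_mm = perimeter_mm, description = description),
            class = "phantom_layer")
}

#' Tissue classes recognised in the phantom
#'
#' The five tissue classes that carry dosimeters in an ankle study: red bone
#' marrow, bone (endosteal) surface, skin, muscle and lymphatic nodes. Muscle
#' and lymphatic nodes belong to the ICRP-103 remainder set.
#'
#' @return Character vector of valid tissue labels.
#' @export
tissue_classes <- function() {
  c("bone_marrow", "bone_surface", "skin", "muscle", "lymphatic_nodes")
}

#' Construct a dosimeter record
#'
#' One physical point dosimeter: its identity, placement (layer, anatomical
#' site, tissue class, sub-unit such as the bone it sits in) and, optionally,
#' its repeated absorbed-dose readings in mGy.
#'
#' @param dosimeter_no Integer id, unique within a study.
#' @param layer Phantom layer index the dosimeter sits in.
#' @param site Anatomical site name (free text).
#' @param tissue One of [tissue_classes()].
#' @param subunit Sub-organ label (bone name for marrow, site name for skin);
#'   defaults to `site`.
#' @param readings Numeric vector of absorbed doses in mGy, one per exposure
#'   repetition; may be empty at construction.
#' @param depth_mm Nominal depth of the dosimeter below the phantom surface in
#'   mm; used only by the synthetic dose-field generator.
#' @return A list of class `dosimeter_record`.
#' @export
dosimeter_record <- function(dosimeter_no, layer, site, tissue,
                             subunit = site, readings = numeric(0),
                             depth_mm = 0) {
  tissue <- match.arg(tissue, tissue_classes())
  dosimeter_no <- as.integer(dosimeter_no)
  if (length(dosimeter_no) != 1L || is.na(dosimeter_no)) {
    stop("dosimeter_no must be a single integer")
  }
  readings <- as.numeric(readings)
  if (any(readings < 0)) stop("readings must all be >= 0 (absorbed dose in mGy)")
  if (depth_mm < 0) stop("depth_mm must be >= 0")
  structure(list(dosimeter_no = dosimeter_no, layer = as.integer(layer),
                 site = site, tissue = tissue, subunit = subunit,
                 readings = readings, depth_mm = depth_mm),
            class = "dosimeter_record")
}

#' Assemble and validate a phantom model
#'
#' Binds layers and dosimeter placements into a single validated object with
#' lookup by dosimeter number and by (tissue, subunit).
#'
#' @param layers List of [phantom_layer()] objects.
#' @param records List of [dosimeter_record()] objects.
#' @return An object of class `phantom_model` with elements `layers` (list
#'   keyed by index), `records` (list keyed by dosimeter number) and
#'   `placements` (a data.frame summary).
#' @export
build_phantom <- function(layers, records) {
  stopifnot(is.list(layers), is.list(records))
  idx <- vapply(layers, function(l) l$index, integer(1))
  if (anyDuplicated(idx)) stop("duplicate layer index: ", idx[duplicated(idx)][1])
  ids <- vapply(records, function(r) r$dosimeter_no, integer(1))
  if (anyDuplicated(ids)) {
    stop("duplicate dosimeter_no: ", ids[duplicated(ids)][1])
  }
  rec_layers <- vapply(records, function(r) r$layer, integer(1))
  unknown <- setdiff(rec_layers, idx)
  if (length(unknown)) {
    stop("dosimeter record references unknown layer: ",
         paste(unknown, collapse = ", "))
  }
  placements <- if (length(records)) {
    data.frame(
      dosimeter_no = ids,
      layer = rec_layers,
      site = vapply(records, function(r) r$site, character(1)),
      tissue = vapply(records, function(r) r$tissue, character(1)),
      subunit = vapply(records, function(r) r$subunit, character(1)),
      depth_mm = vapply(records, function(r) r$depth_mm, numeric(1)),
      n_readings = vapply(records, function(r) length(r$readings), integer(1)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(dosimeter_no = integer(0), layer = integer(0),
               site = character(0), tissue = character(0),
               subunit = character(0), depth_mm = numeric(0),
               n_readings = integer(0))
  }
  names(layers) <- as.character(idx)
  names(records) <- as.character(ids)
  structure(list(layers = layers, records = records, placements = placements),
            class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat("phantom_model:", length(x$layers), "layers,",
      nrow(x$placements), "dosimeters\n")
  if (nrow(x$placements)) {
    tab <- table(x$placements$tissue)
    cat("  per tissue:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Look up a dosimeter record
#'
#' @param model A `phantom_model`.
#' @param dosimeter_no Integer id.
#' @return The matching `dosimeter_record`.
#' @export
get_dosimeter <- function(model, dosimeter_no) {
  r <- model$records[[as.character(dosimeter_no)]]
  if (is.null(r)) stop("no dosimeter numbered ", dosimeter_no, " in phantom model")
  r
}

#' Resolve tissue groups from a fraction table
#'
#' Joins the phantom placements with a fraction-irradiated table, returning
#' per-tissue groups of (subunit, f_i, member dosimeters). Dosimeters not
#' claimed by any fraction entry are reported as unused, which is legal (a
#' placement can be observational only).
#'
#' @param model A `phantom_model`.
#' @param fractions A `fraction_table` (see [fraction_table()]).
#' @return An object of class `tissue_group_set`: list with `groups` (per
#'   tissue, a list of resolved entries) and `unused` (integer vector of
#'   unclaimed dosimeter numbers).
#' @export
resolve_groups <- function(model, fractions) {
  stopifnot(inherits(model, "phantom_model"), inherits(fractions, "fraction_table"))
  all_ids <- model$placements$dosimeter_no
  claimed <- integer(0)
  groups <- list()
  for (e in fractions$entries) {
    missing <- setdiff(e$dosimeters, all_ids)
    if (length(missing)) {
      stop("fraction entry '", e$tissue, "/", e$subunit,
           "' cites missing dosimeter: ", paste(missing, collapse = ", "))
    }
    claimed <- c(claimed, e$dosimeters)
    resolved <- list(subunit = e$subunit, f_i = e$f_i,
                     aggregation = e$aggregation,
                     dosimeters = e$dosimeters,
                     records = lapply(e$dosimeters, get_dosimeter, model = model))
    groups[[e$tissue]] <- c(groups[[e$tissue]], list(resolved))
  }
  structure(list(groups = groups,
                 unused = sort(setdiff(all_ids, claimed))),
            class = "tissue_group_set")
}

#' @export
print.tissue_group_set <- function(x, ...) {
  for (tis in names(x$groups)) {
    subs <- vapply(x$groups[[tis]], function(g) g$subunit, character(1))
    cat(tis, ": ", length(subs), " entr", if (length(subs) == 1) "y" else "ies",
        " (", paste(subs, collapse = ", "), ")\n", sep = "")
  }
  if (length(x$unused)) {
    cat("unused dosimeters:", paste(x$unused, collapse = ", "), "\n")
  }
  invisible(x)
}
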