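#' Path to a bundled data file
#'
#' @param file File name under the package's `extdata` directory; empty to
#'   list the directory.
#' @return Absolute path.
#' @export
ankledose_example <- function(file = "") {
  if (file == "") {
    system.file("extdata", package = "ankledose")
  } else {
    p <- system.file("extdata", file, package = "ankledose", mustWork = TRUE)
    p
  }
}

#' Read a phantom configuration (YAML)
#'
#' Schema: top-level `layers` (list of index/thickness_mm/perimeter_mm) and
#' `dosimeters` (list of dosimeter_no/layer/site/tissue/subunit/depth_mm).
#'
#' @param path YAML file.
#' @return A `phantom_model`.
#' @export
read_phantom_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$layers) || is.null(cfg$dosimeters)) {
    stop("phantom config must have 'layers' and 'dosimeters' sections: ", path)
  }
  layers <- lapply(cfg$layers, function(l) {
    phantom_layer(l$index, thickness_mm = l$thickness_mm %||% 25,
                  perimeter_mm = l$perimeter_mm,
                  description = l$description %||% "")
  })
  records <- lapply(cfg$dosimeters, function(d) {
    dosimeter_record(d$dosimeter_no, d$layer, d$site, d$tissue,
                     subunit = d$subunit %||% d$site,
                     depth_mm = d$depth_mm %||% 0)
  })
  build_phantom(layers, records)
}

#' Write a phantom configuration (YAML)
#'
#' @param model A `phantom_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_phantom_config <- function(model, path) {
  stopifnot(inherits(model, "phantom_model"))
  cfg <- list(
    layers = lapply(unname(model$layers), function(l) {
      out <- list(index = l$index, thickness_mm = l$thickness_mm)
      if (!is.null(l$perimeter_mm)) out$perimeter_mm <- l$perimeter_mm
      if (nzchar(l$description)) out$description <- l$description
      out
    }),
    dosimeters = lapply(unname(model$records), function(r) {
      list(dosimeter_no = r$dosimeter_no, layer = r$layer, site = r$site,
           tissue = r$tissue, subunit = r$subunit, depth_mm = r$depth_mm)
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a fraction-table configuration (YAML)
#'
#' Schema: top-level `entries`, each with tissue/subunit/f_i/dosimeters/
#' aggregation.
#'
#' @param path YAML file.
#' @return A `fraction_table`.
#' @export
read_fraction_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$entries)) stop("fraction config must have 'entries': ", path)
  fraction_table(lapply(cfg$entries, function(e) {
    fraction_entry(e$tissue, e$subunit, e$f_i, unlist(e$dosimeters),
                   e$aggregation)
  }))
}

#' Write a fraction-table configuration (YAML)
#'
#' @param fractions A `fraction_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fraction_config <- function(fractions, path) {
  stopifnot(inherits(fractions, "fraction_table"))
  cfg <- list(entries = lapply(fractions$entries, function(e) {
    list(tissue = e$tissue, subunit = e$subunit, f_i = e$f_i,
         dosimeters = as.list(e$dosimeters), aggregation = e$aggregation)
  }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a tissue-weight configuration (YAML)
#'
#' @param path YAML file.
#' @return A `tissue_weights` object.
#' @export
read_weight_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  tissue_weight_table(w_T = unlist(cfg$w_T),
                      w_remainder = cfg$w_remainder,
                      remainder_members = unlist(cfg$remainder_members),
                      remainder_count = cfg$remainder_count,
                      w_R = cfg$w_R)
}

#' Write a tissue-weight configuration (YAML)
#'
#' @param weights A `tissue_weights` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_weight_config <- function(weights, path) {
  stopifnot(inherits(weights, "tissue_weights"))
  yaml::write_yaml(list(w_T = as.list(weights$w_T),
                        w_remainder = weights$w_remainder,
                        remainder_members = as.list(weights$remainder_members),
                        remainder_count = weights$remainder_count,
                        w_R = weights$w_R), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a dosimeter-readings CSV
#'
#' Two schemas are accepted, distinguished by the header:
#' \describe{
#'   \item{long}{columns `dosimeter_no`, `exposure_index`, `dose_mGy`: one
#'     row per exposure; rows are averaged per dosimeter.}
#'   \item{pre-averaged}{columns `dosimeter_no`, `mean_dose_mGy`,
#'     `rel_sd_pct`, `n`: one row per dosimeter.}
#' }
#' Units are part of the header contract (mGy); any other column set is a
#' format error.
#'
#' @param path CSV file (comma-separated, dot decimal).
#' @return Data.frame of dose estimates: `dosimeter_no`, `mean_dose` (mGy),
#'   `rel_sd` (%), `n_exposures`.
#' @export
read_readings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  long_cols <- c("dosimeter_no", "exposure_index", "dose_mGy")
  avg_cols <- c("dosimeter_no", "mean_dose_mGy", "rel_sd_pct", "n")
  if (all(long_cols %in% names(df))) {
    bad <- which(df$dose_mGy < 0)
    if (length(bad)) stop("negative dose at row ", bad[1], " of ", path)
    est <- do.call(rbind, lapply(split(df, df$dosimeter_no), function(g) {
      e <- mean_dose(g$dose_mGy)
      e$dosimeter_no <- g$dosimeter_no[1]
      class(e) <- "data.frame"
      e
    }))
    est <- est[order(est$dosimeter_no), ]
    rownames(est) <- NULL
    est
  } else if (all(avg_cols %in% names(df))) {
    bad <- which(df$mean_dose_mGy < 0)
    if (length(bad)) stop("negative dose at row ", bad[1], " of ", path)
    out <- data.frame(dosimeter_no = as.integer(df$dosimeter_no),
                      mean_dose = df$mean_dose_mGy,
                      rel_sd = df$rel_sd_pct,
                      n_exposures = as.integer(df$n))
    extra <- setdiff(names(df), avg_cols)
    for (col in extra) out[[col]] <- df[[col]]
    out
  } else {
    stop("unrecognised readings CSV header in ", path,
         " (expected dosimeter_no/exposure_index/dose_mGy or ",
         "dosimeter_no/mean_dose_mGy/rel_sd_pct/n; dose unit is part of the header)")
  }
}

#' Bundled reference study: measured ankle doses
#'
#' Per-dosimeter mean absorbed doses, type-A spreads and reported combined
#' point uncertainties for the bundled high-resolution CBCT ankle study
#' (small-FOV scan, six exposures per dosimeter), as a pre-averaged estimates
#' table.
#'
#' @return Data.frame with `dosimeter_no`, `mean_dose` (mGy), `rel_sd` (%),
#'   `n_exposures`, `reported_u_c_pct`.
#' @export
ankle_study_doses <- function() {
  read_readings_csv(ankledose_example("cbct_hires_doses.csv"))
}

#' Bundled reference study: published per-tissue effective-dose table
#'
#' Per-tissue contributions (uSv) and effective doses for the six imaging
#' protocols of the bundled ankle comparison study (MSCT, three CBCT fields
#' of view, a second CBCT device and AP+LAT plain radiography), as reported
#' to 0.1 uSv.
#'
#' @return Data.frame with a `tissue` column (five tissues plus
#'   `effective_dose`) and one numeric column per protocol.
#' @export
published_effective_doses <- function() {
  utils::read.csv(ankledose_example("published_effective_doses.csv"),
                  stringsAsFactors = FALSE)
}

#' Default six-layer ankle phantom model
#'
#' @return A `phantom_model` built from the shipped configuration.
#' @export
default_ankle_phantom <- function() {
  read_phantom_config(ankledose_example("ankle_phantom.yaml"))
}

#' Default ICRP-103 weighting configuration
#'
#' @return A `tissue_weights` object from the shipped configuration.
#' @export
default_icrp_weights <- function() {
  read_weight_config(ankledose_example("icrp103_weights.yaml"))
}

#' Study configuration for an end-to-end run
#'
#' @param readings Path to a readings CSV (see [read_readings_csv()]).
#' @param phantom Path to a phantom YAML, or a `phantom_model`; default the
#'   shipped ankle phantom.
#' @param fractions Path to a fraction YAML, or a `fraction_table`; default
#'   the shipped ankle table.
#' @param weights Path to a weight YAML, or a `tissue_weights`; default
#'   ICRP 103.
#' @param protocol Protocol label carried into reports.
#' @param sys [systematic_components()] for the budget.
#' @param k Coverage factor.
#' @return A list of class `study_config`.
#' @export
study_config <- function(readings,
                         phantom = NULL, fractions = NULL, weights = NULL,
                         protocol = NULL, sys = systematic_components(),
                         k = 2) {
  if (is.character(readings) && !file.exists(readings)) {
    stop("readings file not found: ", readings)
  }
  structure(list(readings = readings,
                 phantom = phantom %||% default_ankle_phantom(),
                 fractions = fractions %||% default_ankle_fractions(),
                 weights = weights %||% default_icrp_weights(),
                 protocol = protocol, sys = sys, k = k),
            class = "study_config")
}

.resolve_cfg <- function(x, reader) if (is.character(x)) reader(x) else x

#' Run one study end to end and write its report
#'
#' Reads the readings, computes per-tissue equivalent doses, the effective
#' dose and the full uncertainty budget, and (optionally) writes a report:
#' a CSV of per-tissue contributions and an aligned-text summary that also
#' logs every analysis option in effect, so the report is self-describing.
#' Outputs are deterministic for fixed inputs.
#'
#' @param config A [study_config()].
#' @param out_dir Directory for report files; `NULL` skips writing.
#' @param timestamp Include a timestamp header line in the text report.
#' @return A list of class `study_result`: `effective_dose`, `budget`,
#'   `breakdown`, and paths of any files written.
#' @export
run_study <- function(config, out_dir = NULL, timestamp = FALSE) {
  stopifnot(inherits(config, "study_config"))
  phantom <- .resolve_cfg(config$phantom, read_phantom_config)
  fractions <- .resolve_cfg(config$fractions, read_fraction_config)
  weights <- .resolve_cfg(config$weights, read_weight_config)
  estimates <- if (is.character(config$readings)) {
    read_readings_csv(config$readings)
  } else {
    config$readings
  }
  budget <- uncertainty_budget(estimates, phantom, fractions, weights,
                               sys = config$sys, k = config$k)
  ed <- budget$effective_dose
  ed$protocol <- config$protocol
  breakdown <- contribution_breakdown(ed)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tab <- merge(breakdown, budget$per_tissue[c("tissue", "u_pct")],
                 by = "tissue", sort = FALSE)
    csv <- file.path(out_dir, "effective_dose_report.csv")
    utils::write.csv(tab, csv, row.names = FALSE)
    txt <- file.path(out_dir, "effective_dose_report.txt")
    con <- file(txt, "w")
    on.exit(close(con), add = TRUE)
    if (timestamp) writeLines(paste("# generated", format(Sys.time())), con)
    writeLines(c(
      sprintf("protocol: %s", config$protocol %||% "(unspecified)"),
      sprintf("aggregation modes: %s",
              paste(unique(vapply(fractions$entries, function(e)
                paste0(e$tissue, "=", e$aggregation), character(1))),
                collapse = ", ")),
      sprintf("remainder split: w=%g over %d tissues",
              weights$w_remainder, weights$remainder_count),
      sprintf("coverage factor k = %g", config$k),
      "",
      utils::capture.output(print(ed)),
      sprintf("expanded effective-dose uncertainty U_c = %d%%",
              as.integer(round_half_up(budget$expanded_pct)))
    ), con)
    files <- c(csv = csv, txt = txt)
  }
  structure(list(effective_dose = ed, budget = budget, breakdown = breakdown,
                 files = files),
            class = "study_result")
}
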