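# Independent brute-force reference: explicit loops over
# (tissue, entry, dosimeter) applying the weighted point-dose sums directly,
# sharing no code path with the engine.
brute_force_E <- function(estimates, fractions, weights) {
  dose_of <- function(id) {
    estimates$mean_dose[estimates$dosimeter_no == id]
  }
  H <- list()  # uSv per tissue
  for (e in fractions$entries) {
    term <- 0
    if (e$aggregation == "per_site_fraction") {
      for (id in e$dosimeters) term <- term + e$f_i * dose_of(id)
    } else {
      s <- 0
      for (id in e$dosimeters) s <- s + dose_of(id)
      term <- e$f_i * s / length(e$dosimeters)
    }
    tis <- e$tissue
    H[[tis]] <- (if (is.null(H[[tis]])) 0 else H[[tis]]) +
      weights$w_R * 1000 * term
  }
  E <- 0
  for (tis in names(H)) {
    w <- if (tis %in% names(weights$w_T)) {
      weights$w_T[[tis]]
    } else {
      weights$w_remainder / weights$remainder_count
    }
    E <- E + w * H[[tis]]
  }
  list(E = E, H = H)
}

# Small random study configuration for property tests.
random_study <- function(seed) {
  set.seed(seed)
  n <- sample(4:12, 1)
  ids <- seq_len(n)
  tissues <- sample(tissue_classes(), n, replace = TRUE)
  layers <- list(phantom_layer(1))
  records <- lapply(ids, function(i) {
    dosimeter_record(i, 1, paste0("site", i), tissues[i],
                     subunit = paste0("sub", i))
  })
  phantom <- build_phantom(layers, records)
  # partition dosimeters of each tissue into entries with random modes
  entries <- list()
  for (tis in unique(tissues)) {
    members <- ids[tissues == tis]
    while (length(members)) {
      take <- sample(seq_along(members), 1)
      grp <- members[seq_len(take)]
      members <- members[-seq_len(take)]
      entries[[length(entries) + 1]] <- fraction_entry(
        tis, paste0(tis, "_", grp[1]), stats::runif(1, 0.001, 0.05), grp,
        sample(c("mean_then_fraction", "per_site_fraction", "group_mean"), 1))
    }
  }
  fractions <- fraction_table(entries)
  estimates <- data.frame(dosimeter_no = ids,
                          mean_dose = stats::runif(n, 0.1, 12),
                          rel_sd = stats::runif(n, 2, 35),
                          n_exposures = 6L)
  list(phantom = phantom, fractions = fractions,
       weights = tissue_weight_table(), estimates = estimates)
}

# Aggregate a long readings table into a dose-estimates data.frame.
estimates_from_readings <- function(readings) {
  out <- do.call(rbind, lapply(split(readings, readings$dosimeter_no),
                               function(g) {
    e <- mean_dose(g$dose_mGy)
    e$dosimeter_no <- g$dosimeter_no[1]
    class(e) <- "data.frame"
    e
  }))
  out[order(out$dosimeter_no), ]
}
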