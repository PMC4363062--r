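test_that("default phantom validates and indexes the twenty placements", {
  ph <- default_ankle_phantom()
  expect_s3_class(ph, "phantom_model")
  expect_length(ph$layers, 6)
  expect_equal(sort(vapply(ph$layers, function(l) l$index, integer(1))),
               23:28, ignore_attr = TRUE)
  expect_equal(nrow(ph$placements), 20)
  # the placement table lists ten marrow positions (four tissue classes fill
  # the other ten); the narrative count of nine in the source material
  # undercounts its own table
  tab <- table(ph$placements$tissue)
  expect_equal(unname(tab[["bone_marrow"]]), 10)
  expect_equal(unname(tab[["muscle"]]), 4)
  expect_equal(unname(tab[["skin"]]), 2)
  expect_equal(unname(tab[["bone_surface"]]), 2)
  expect_equal(unname(tab[["lymphatic_nodes"]]), 2)
  expect_equal(get_dosimeter(ph, 15)$site, "Talus")
})

test_that("phantom construction rejects inconsistent inputs and allows empty", {
  expect_s3_class(build_phantom(list(phantom_layer(23)), list()),
                  "phantom_model")
  rec <- function(no, layer = 23) dosimeter_record(no, layer, "Tibia",
                                                   "bone_marrow")
  expect_error(build_phantom(list(phantom_layer(23)), list(rec(7), rec(7))),
               "duplicate dosimeter_no: 7")
  expect_error(build_phantom(list(phantom_layer(23)), list(rec(1, 99))),
               "unknown layer: 99")
  expect_error(build_phantom(list(phantom_layer(23), phantom_layer(23)),
                             list()), "duplicate layer")
  expect_error(dosimeter_record(1, 23, "x", "bone_marrow", readings = -1),
               ">= 0")
  expect_error(phantom_layer(23, thickness_mm = 0), "> 0")
})

test_that("group resolution follows the fraction table and reports unused dosimeters", {
  ph <- default_ankle_phantom()
  gs <- resolve_groups(ph, default_ankle_fractions())
  marrow <- gs$groups$bone_marrow
  expect_equal(vapply(marrow, function(g) g$subunit, character(1)),
               c("tibia", "fibula", "navicular", "metatarsals", "calcaneus"))
  tibia <- marrow[[1]]
  expect_equal(tibia$f_i, 0.007)
  expect_equal(tibia$dosimeters, c(1L, 4L, 7L, 9L))
  # talus (15) carries no default fraction: reported unused, not an error
  expect_equal(gs$unused, 15L)
  # partition: 19 assigned once each, none twice
  assigned <- unlist(lapply(unlist(gs$groups, recursive = FALSE),
                            function(g) g$dosimeters))
  expect_length(assigned, 19)
  expect_false(anyDuplicated(assigned) > 0)

  bad <- fraction_table(list(fraction_entry("skin", "x", 0.01, 99L)))
  expect_error(resolve_groups(ph, bad), "99")
})

test_that("talus marrow can be folded in as a configurable extra entry", {
  ph <- default_ankle_phantom()
  gs <- resolve_groups(ph, default_ankle_fractions(include_talus = TRUE))
  expect_length(gs$unused, 0)
  subs <- vapply(gs$groups$bone_marrow, function(g) g$subunit, character(1))
  expect_true("talus" %in% subs)
})

test_that("weight validation flags deviations from the ICRP-103 constants", {
  expect_equal(nrow(validate_weights(default_icrp_weights())), 0)
  w2 <- tissue_weight_table(w_R = 2)
  expect_equal(validate_weights(w2)$quantity, "w_R")
  w3 <- tissue_weight_table(w_T = c(bone_marrow = 0.12, bone_surface = 0.05,
                                    skin = 0.01))
  expect_true("w_T[bone_surface]" %in% validate_weights(w3)$quantity)
})

test_that("phantom and fraction configs round-trip through YAML unchanged", {
  ph <- default_ankle_phantom()
  fr <- default_ankle_fractions()
  d <- withr::local_tempdir()
  p1 <- write_phantom_config(ph, file.path(d, "ph.yaml"))
  p2 <- write_fraction_config(fr, file.path(d, "fr.yaml"))
  expect_equal(read_phantom_config(p1), ph)
  expect_equal(read_fraction_config(p2), fr)
  w <- default_icrp_weights()
  p3 <- write_weight_config(w, file.path(d, "w.yaml"))
  expect_equal(read_weight_config(p3), w)
})
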