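test_that("blank images yield empty detections, not errors", {
  z <- matrix(0, 128, 128)
  img <- image_set(z, z, z, pixel_scale = 0.25)
  expect_equal(nrow(detect_beads(img)), 0)
  expect_equal(nrow(detect_cells(img)), 0)
})

test_that("noiseless wells are detected completely and precisely", {
  r <- noiseless_well()              # 20 beads per class, 25 cells
  b <- detect_beads(r$images)
  tb <- r$truth$beads
  # every analyte bead found from RED, every reference bead from GREEN
  expect_equal(sum(b$channel == "analyte"), 40)
  expect_equal(sum(b$channel == "reference"), 20)
  j <- match_truth(b, tb)
  expect_true(all(!duplicated(j)))
  d <- sqrt((b$x - tb$x[j])^2 + (b$y - tb$y[j])^2)
  expect_lt(max(d), 1)
  expect_lt(max(abs(b$diameter_um - tb$diameter_um[j])), 0.5)
  # size demultiplexing agrees with ground truth for every bead
  cb <- classify_beads(b)
  j2 <- match_truth(cb, tb)
  expect_identical(cb$bead_class, tb$class[j2])
})

test_that("bead size classification follows the dead-zone rule", {
  mk <- function(d, channel = "analyte")
    data.frame(x = 50, y = 50, diameter_um = d, circularity = 1,
               channel = channel, bead_class = NA_character_)
  beads <- rbind(mk(9.1), mk(14.8), mk(12.0),
                 mk(12, "reference"), mk(12.02, "reference"),
                 mk(11.98, "reference"))
  out <- classify_beads(beads)
  expect_equal(out$bead_class[out$channel == "analyte"], c("PR3", "MPO"))
  expect_equal(attr(out, "n_unclassified"), 1)   # 12.0 um candidate excluded
  expect_error(classify_beads(mk(9.1)),
               class = "cytobead_missing_reference")
})

test_that("size classification tolerates 5% diameter noise at >= 98% accuracy", {
  set.seed(55)
  n <- 500
  true_class <- sample(c("PR3", "MPO"), n, replace = TRUE)
  d_true <- ifelse(true_class == "PR3", 9, 15)
  beads <- data.frame(
    id = seq_len(n), x = 1, y = 1,
    diameter_um = d_true * rnorm(n, 1, 0.05),
    circularity = 1, channel = "analyte", bead_class = NA_character_)
  ref <- data.frame(id = NA, x = 1, y = 1,
                    diameter_um = 12 * rnorm(20, 1, 0.05),
                    circularity = 1, channel = "reference",
                    bead_class = NA_character_)
  out <- classify_beads(rbind(beads, ref))
  ana <- out[out$channel == "analyte", ]
  # the dead zone exists to avoid misassignment: accuracy is judged over
  # the assignments made, and the exclusion rate must stay small
  expect_gte(mean(ana$bead_class == true_class[ana$id]), 0.98)
  expect_lte(attr(out, "n_unclassified") / n, 0.05)
})

test_that("halo measurement recovers the rendered amplitude", {
  # uniform green plane: signal equals background, MFI 0
  img <- image_set(matrix(0, 128, 128), matrix(37.5, 128, 128),
                   matrix(0, 128, 128), pixel_scale = 0.25)
  expect_equal(measure_halo(img, 64, 64, 9), 0)
  # noiseless render: measured MFI within 2% of the known amplitude
  r <- noiseless_well()
  cb <- measure_halos(r$images, classify_beads(detect_beads(r$images)))
  tb <- r$truth$beads
  j <- match_truth(cb, tb)
  pr3 <- cb$bead_class == "PR3"
  expect_lt(max(abs(cb$halo_mfi[pr3] - tb$halo_amplitude[j][pr3]) /
                  tb$halo_amplitude[j][pr3]), 0.02)
  # border bead: skipped with a warning
  expect_warning(out <- measure_halo(r$images, 5, 5, 9), "border")
  expect_true(is.na(out))
})

test_that("negative samples read out at the assay floor", {
  cfg <- simulation_config(field_size = c(640L, 640L), n_cells = 0L,
                           n_beads_per_class = 6L, rng_seed = 21L)
  r <- render_sample(sample_spec(pattern = "NEGATIVE"), cfg)
  cb <- measure_halos(r$images, classify_beads(detect_beads(r$images)))
  mfi <- cb$halo_mfi[cb$bead_class %in% c("PR3", "MPO")]
  # mean at or below the (attenuated) floor plus 3 SD of the bead scatter
  expect_lt(mean(mfi), true_bead_curve()$A + 3 * sd(mfi))
})

test_that("cells are detected with accurate centers and pattern bands", {
  r <- noiseless_well()              # 25 cells, pattern C at titer 320
  cells <- detect_cells(r$images)
  expect_gte(nrow(cells), 24)
  j <- match_truth(cells, r$truth$cells)
  expect_true(all(!duplicated(j)))
  d <- sqrt((cells$x - r$truth$cells$x[j])^2 +
              (cells$y - r$truth$cells$y[j])^2)
  expect_lt(max(d), 2)
  # C pattern: cytoplasm dominates the rim in >= 90% of cells
  expect_gte(mean(cells$cytoplasm_mfi > cells$rim_mfi), 0.9)
})

test_that("P-pattern staining puts the signal on the perinuclear rim", {
  r <- cached_render("p_pattern",
                     sample_spec(pattern = "P", titer = 320),
                     cell_cfg(31L))
  cells <- detect_cells(r$images)
  expect_gte(nrow(cells), 23)
  expect_gte(mean(cells$rim_mfi > cells$cytoplasm_mfi), 0.9)
  expect_identical(as.character(classify_pattern(cells)), "P")
})

test_that("pattern voting follows the threshold, ratio and majority rules", {
  mk_cells <- function(n, rim, cyto, gran = 0.6)
    data.frame(x = 1, y = 1, nucleus_area_um2 = 20,
               rim_mfi = rep(rim, n), cytoplasm_mfi = rep(cyto, n),
               granularity = gran)
  # everything below threshold: NEGATIVE
  dim_cells <- mk_cells(30, 2, 3)
  expect_identical(as.character(
    classify_pattern(dim_cells, threshold = 10)), "NEGATIVE")
  # mixed calls: 15 P vs 40 C resolves to C by majority
  mixed <- rbind(mk_cells(15, 100, 10), mk_cells(40, 10, 100))
  expect_identical(as.character(classify_pattern(mixed, threshold = 10)), "C")
  # fewer than 20 positive cells: NEGATIVE even if each call is clear
  few <- mk_cells(19, 100, 10)
  expect_identical(as.character(classify_pattern(few, threshold = 10)),
                   "NEGATIVE")
  # C calls additionally require granularity
  smooth <- mk_cells(30, 10, 100, gran = 0.1)
  expect_identical(as.character(classify_pattern(smooth, threshold = 10)),
                   "NEGATIVE")
})

test_that("sample summaries enforce the object-count minima", {
  r <- noiseless_well()
  beads <- measure_halos(r$images, classify_beads(detect_beads(r$images)))
  cells <- detect_cells(r$images)
  # 40 analyte beads < 50: insufficient
  err <- tryCatch(summarize_sample(beads, cells),
                  cytobead_insufficient_objects = identity)
  expect_s3_class(err, "cytobead_insufficient_objects")
  expect_equal(err$n_beads, 40)
  # relaxing the minima gives a valid readout near the true response
  ro <- summarize_sample(beads, cells, min_beads = 40, min_cells = 20,
                         min_positive = 20)
  expect_s3_class(ro, "sample_readout")
  expect_identical(ro$pattern, "C")
  truth_mfi <- eval_5pl(true_bead_curve(), r$truth$spec$pr3_conc)
  expect_lt(abs(ro$pr3_mfi - truth_mfi) / truth_mfi, 0.05)
  # dropping every PR3 bead leaves the class unmeasurable
  no_pr3 <- beads[beads$bead_class != "PR3", ]
  expect_error(summarize_sample(no_pr3, cells, min_beads = 20),
               class = "cytobead_missing_class")
})

test_that("measured PR3 MFI rises monotonically with concentration", {
  conc <- c(0, 0.5, 2, 8, 32, 128)
  mfi <- sapply(seq_along(conc), function(i) {
    mean(sapply(1:2, function(rep) {
      cfg <- simulation_config(field_size = c(640L, 640L), n_cells = 0L,
                               n_beads_per_class = 6L,
                               rng_seed = 40000L + 10L * i + rep)
      sp <- sample_spec(pr3_conc = conc[i],
                        pattern = if (conc[i] > 0) "C" else "NEGATIVE",
                        titer = if (conc[i] > 0) 80 else NA)
      r <- render_sample(sp, cfg)
      cb <- measure_halos(r$images, classify_beads(detect_beads(r$images)))
      mean(cb$halo_mfi[cb$bead_class == "PR3"])
    }))
  })
  expect_gt(cor(mfi, conc, method = "spearman"), 0.95)
  expect_true(all(diff(mfi) > 0))
})

test_that("MFIs are scale-equivariant and pattern calls scale-invariant", {
  r <- cached_render("scale_eq",
                     sample_spec(pr3_conc = 10, mpo_conc = 10, pattern = "C",
                                 titer = 160),
                     simulation_config(field_size = c(640L, 640L),
                                       n_cells = 21L, n_beads_per_class = 4L,
                                       rng_seed = 13L))
  k <- 2.7
  img2 <- r$images
  img2$green <- img2$green * k
  b1 <- measure_halos(r$images, classify_beads(detect_beads(r$images)))
  b2 <- measure_halos(img2, classify_beads(detect_beads(img2)))
  a1 <- b1[b1$bead_class == "PR3", ]
  a2 <- b2[b2$bead_class == "PR3", ]
  j <- match_truth(a2, a1)
  expect_equal(a2$halo_mfi, k * a1$halo_mfi[j], tolerance = 1e-6)
  c1 <- detect_cells(r$images)
  c2 <- detect_cells(img2)
  expect_equal(c2$rim_mfi, k * c1$rim_mfi, tolerance = 1e-6)
  expect_equal(c2$cytoplasm_mfi, k * c1$cytoplasm_mfi, tolerance = 1e-6)
  expect_equal(attr(c2, "positivity_threshold"),
               k * attr(c1, "positivity_threshold"))
  expect_identical(as.character(classify_pattern(c1, min_positive = 15)),
                   as.character(classify_pattern(c2, min_positive = 15)))
})
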