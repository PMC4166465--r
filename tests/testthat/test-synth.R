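test_that("configuration and sample invariants are enforced", {
  expect_error(simulation_config(pixel_scale = 0), "pixel_scale")
  expect_error(simulation_config(bead_diameters = c(PR3 = 12, REF = 9,
                                                    MPO = 15)), "ordered")
  expect_error(simulation_config(read_noise_sd = -1), ">= 0")
  expect_error(sample_spec(pr3_conc = -1), ">= 0")
  expect_error(sample_spec(pattern = "NEGATIVE", titer = 80), "NEGATIVE")
  expect_error(sample_spec(pattern = "C", titer = 30), "ladder")
})

test_that("rendering is deterministic and conserves every object", {
  cfg <- simulation_config(field_size = c(512L, 512L), n_cells = 6L,
                           n_beads_per_class = 5L, rng_seed = 123L)
  sp <- sample_spec(pr3_conc = 5, mpo_conc = 50, pattern = "P", titer = 160)
  r1 <- render_sample(sp, cfg)
  r2 <- render_sample(sp, cfg)
  expect_identical(r1$images$green, r2$images$green)   # bit-identical
  expect_identical(r1$images$dapi, r2$images$dapi)
  expect_identical(r1$truth$beads, r2$truth$beads)
  expect_equal(unname(table(r1$truth$beads$class)[c("MPO", "PR3", "REF")]),
               rep(5L, 3), ignore_attr = TRUE)
  expect_equal(nrow(r1$truth$cells), 6)
})

test_that("zero-analyte wells sit at the 5PL floor, single-analyte wells halo once", {
  cfg <- noiseless_cfg(seed = 5L, n_cells = 0L, n_beads = 4L,
                       field = c(512L, 512L))
  r0 <- render_sample(sample_spec(pattern = "NEGATIVE"), cfg)
  floor_amp <- true_bead_curve()$A
  expect_equal(unique(r0$truth$beads$halo_amplitude[
    r0$truth$beads$class != "REF"]), floor_amp)
  # PR3-only sample: halo above floor on 9 um beads only
  r1 <- render_sample(sample_spec(pr3_conc = 25, pattern = "C", titer = 320),
                      noiseless_cfg(seed = 6L, n_cells = 1L, n_beads = 4L,
                                    field = c(512L, 512L)))
  tb <- r1$truth$beads
  expect_true(all(tb$halo_amplitude[tb$class == "PR3"] > floor_amp))
  expect_equal(unique(tb$halo_amplitude[tb$class == "MPO"]), floor_amp)
  expect_equal(unique(tb$diameter_um[tb$class == "PR3"]), 9)
})

test_that("noiseless bead geometry matches the spec within one pixel", {
  r <- noiseless_well()
  oracle <- pixel_count_oracle(r$images$red, r$images$pixel_scale)
  tb <- r$truth$beads[r$truth$beads$class != "REF", ]
  expect_equal(nrow(oracle), nrow(tb))
  j <- match_truth(oracle, tb)
  expect_true(all(!duplicated(j)))
  # equivalent-area diameter within 1 px of the specified diameter
  tol_um <- r$images$pixel_scale
  expect_lt(max(abs(oracle$diameter_um - tb$diameter_um[j])), tol_um)
})

test_that("true halo amplitude is non-decreasing in concentration", {
  curve <- true_bead_curve()
  conc <- c(0, 0.5, 2, 8, 32, 128)
  amps <- eval_5pl(curve, conc)
  expect_true(all(diff(amps) > 0))
  # and the rendered truth reflects it
  cfg <- noiseless_cfg(seed = 2L, n_cells = 0L, n_beads = 3L,
                       field = c(384L, 384L))
  amp_rendered <- sapply(conc, function(x) {
    r <- render_sample(sample_spec(pr3_conc = x,
                                   pattern = if (x > 0) "C" else "NEGATIVE",
                                   titer = if (x > 0) 80 else NA), cfg)
    unique(r$truth$beads$halo_amplitude[r$truth$beads$class == "PR3"])
  })
  expect_equal(amp_rendered, amps)
})

test_that("dilution series scales concentrations and stays monotone", {
  base <- sample_spec(pr3_conc = 32, mpo_conc = 32, pattern = "C",
                      titer = 640)
  cfg <- noiseless_cfg(seed = 9L, n_cells = 0L, n_beads = 3L,
                       field = c(384L, 384L))
  dil <- 20 * 2^(0:7)
  ser <- render_dilution_series(base, dil, cfg)
  expect_length(ser, 8)
  concs <- sapply(ser, function(s) s$truth$spec$pr3_conc)
  expect_equal(concs, 32 * 20 / dil)
  amps <- sapply(ser, function(s)
    unique(s$truth$beads$halo_amplitude[s$truth$beads$class == "PR3"]))
  expect_true(all(diff(amps) < 0))   # strictly diluting out
  # two-point case: second well carries half the concentration
  two <- render_dilution_series(base, c(20, 40), cfg)
  expect_equal(two[[2]]$truth$spec$pr3_conc, base$pr3_conc / 2)
  expect_error(render_dilution_series(base, numeric(0), cfg), "empty")
  expect_error(render_dilution_series(base, c(40, 20), cfg), "increasing")
})

test_that("cohort generation is reproducible and honors prevalence", {
  cfg <- simulation_config(rng_seed = 77L)
  expect_equal(length(generate_cohort(list(list(label = "empty", n = 0,
                                                prev_pr3 = 0, prev_mpo = 0)),
                                      cfg, render = FALSE)), 0)
  g1 <- list(list(label = "all-pos", n = 25, prev_pr3 = 1, prev_mpo = 0))
  coh <- generate_cohort(g1, cfg, render = FALSE)
  expect_true(all(sapply(coh, function(s) s$spec$pr3_conc > 0)))
  expect_true(all(sapply(coh, function(s) s$spec$pattern == "C")))
  # determinism: an independent re-draw with the same seed matches
  g2 <- list(list(label = "mixed", n = 200, prev_pr3 = 0.3, prev_mpo = 0.1))
  draw1 <- generate_cohort(g2, cfg, render = FALSE)
  draw2 <- generate_cohort(g2, cfg, render = FALSE)
  pos1 <- sum(sapply(draw1, function(s) s$spec$pr3_conc > 0))
  pos2 <- sum(sapply(draw2, function(s) s$spec$pr3_conc > 0))
  expect_identical(pos1, pos2)
  # requested prevalence within binomial sampling error (4 sigma)
  expect_lt(abs(pos1 - 60), 4 * sqrt(200 * 0.3 * 0.7))
  expect_error(generate_cohort(list(list(label = "bad", n = 5,
                                         prev_pr3 = 1.2, prev_mpo = 0)),
                               cfg, render = FALSE), "\\[0, 1\\]")
})

test_that("impossible placements fail with an explicit error", {
  tiny <- simulation_config(field_size = c(64L, 64L), n_cells = 10L,
                            n_beads_per_class = 0L, rng_seed = 1L)
  expect_error(render_sample(sample_spec(pattern = "NEGATIVE"), tiny),
               "placement|too small")
})
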