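test_that("eval_5pl matches the closed-form special values", {
  cv <- fivepl_curve(A = 100, B = 1.2, C = 10, D = 5000, G = 1)
  expect_identical(eval_5pl(cv, 0), 100)                 # zero-dose asymptote
  expect_equal(eval_5pl(cv, 10), (100 + 5000) / 2)       # midpoint at x = C, G = 1
  cv2 <- fivepl_curve(A = 100, B = 1.2, C = 10, D = 5000, G = 2)
  expect_equal(eval_5pl(cv2, 10), 5000 + (100 - 5000) / 4)
  # decreasing orientation works the same way
  cvd <- fivepl_curve(A = 4000, B = 2, C = 5, D = 50, G = 1)
  expect_identical(eval_5pl(cvd, 0), 4000)
  expect_equal(eval_5pl(cvd, 5), (4000 + 50) / 2)
})

test_that("eval/invert round trip is exact to 1e-9 over random curves", {
  set.seed(421)
  worst <- 0
  for (i in 1:100) {
    cv <- fivepl_curve(A = runif(1, 10, 200), B = runif(1, 0.5, 3),
                       C = runif(1, 1, 50), D = runif(1, 1000, 8000),
                       G = runif(1, 0.3, 3))
    # draw doses over the informative span of the curve; inversion at the
    # asymptotes is ill-conditioned in any parameterization
    x <- cv$C * exp(runif(1, log(0.05), log(20)))
    worst <- max(worst, abs(invert_5pl(cv, eval_5pl(cv, x)) - x) / x)
  }
  expect_lt(worst, 1e-9)
})

test_that("invert_5pl distinguishes below-floor from above-ceiling", {
  cv <- fivepl_curve(A = 100, B = 1.2, C = 10, D = 5000, G = 1)
  expect_error(invert_5pl(cv, 100), class = "cytobead_below_floor")
  expect_error(invert_5pl(cv, 50), class = "cytobead_below_floor")
  expect_error(invert_5pl(cv, 5000), class = "cytobead_above_ceiling")
  expect_error(invert_5pl(cv, 6000), class = "cytobead_above_ceiling")
  # decreasing curve: low responses mean saturation, not floor
  cvd <- fivepl_curve(A = 5000, B = 1.2, C = 10, D = 100, G = 1)
  expect_error(invert_5pl(cvd, 50), class = "cytobead_above_ceiling")
  expect_error(invert_5pl(cvd, 6000), class = "cytobead_below_floor")
})

test_that("fit_5pl recovers generating parameters from exact data", {
  truth <- fivepl_curve(A = 100, B = 1.2, C = 10, D = 5000, G = 1)
  conc <- 32 / 2^(0:7)
  std <- data.frame(concentration = conc, mfi = eval_5pl(truth, conc))
  fit <- fit_5pl(std)
  rel <- abs(c(fit$A, fit$B, fit$C, fit$D, fit$G) -
               c(100, 1.2, 10, 5000, 1)) / c(100, 1.2, 10, 5000, 1)
  expect_lt(max(rel), 0.01)
  expect_equal(fit$valid_range, range(conc))
})

test_that("5PL fit of G = 1 data agrees with an independent 4PL fit", {
  truth <- fivepl_curve(A = 80, B = 1.5, C = 8, D = 4200, G = 1)
  conc <- c(0.25, 0.5, 1, 2, 4, 8, 16, 32)
  mfi <- eval_5pl(truth, conc)
  fit5 <- fit_5pl(data.frame(concentration = conc, mfi = mfi))
  # oracle: direct 4PL fit, a separate model family and code path
  fit4 <- minpack.lm::nlsLM(
    y ~ D + (A - D) / (1 + (x / C)^B),
    data = data.frame(x = conc, y = mfi),
    start = list(A = 80, D = 4000, C = 8, B = 1.5))
  p4 <- coef(fit4)
  grid <- exp(seq(log(0.25), log(32), length.out = 40))
  y5 <- eval_5pl(fit5, grid)
  y4 <- p4[["D"]] + (p4[["A"]] - p4[["D"]]) / (1 + (grid / p4[["C"]])^p4[["B"]])
  expect_lt(max(abs(y5 - y4) / y4), 1e-3)
  expect_equal(fit5$G, 1, tolerance = 0.01)
})

test_that("fit_5pl rejects underdetermined input", {
  truth <- fivepl_curve(A = 100, B = 1.2, C = 10, D = 5000, G = 1)
  conc <- c(1, 2, 4, 8, 16)
  expect_error(
    fit_5pl(data.frame(concentration = conc, mfi = eval_5pl(truth, conc))),
    "at least 6")
})

test_that("two-point recalibration with on-curve adjusters is a no-op", {
  master <- fivepl_curve(A = 100, B = 1.2, C = 10, D = 5000, G = 1)
  adj <- data.frame(concentration = c(2, 50),
                    mfi = eval_5pl(master, c(2, 50)))
  rc <- recalibrate_two_point(master, adj)
  expect_equal(attr(rc, "gain"), 1)
  expect_equal(attr(rc, "offset"), 0)
  expect_equal(rc$A, master$A)
  expect_equal(rc$D, master$D)
})

test_that("recalibration absorbs a pure gain drift", {
  master <- fivepl_curve(A = 100, B = 1.2, C = 10, D = 5000, G = 1)
  adj <- data.frame(concentration = c(2, 50),
                    mfi = 1.3 * eval_5pl(master, c(2, 50)))
  rc <- recalibrate_two_point(master, adj)
  expect_equal(attr(rc, "gain"), 1.3)
  expect_equal(attr(rc, "offset"), 0)
  # back-calculated concentrations of drifted standards equal the originals
  x <- c(0.5, 2, 7, 20, 80)
  expect_equal(invert_5pl(rc, 1.3 * eval_5pl(master, x)), x)
})

test_that("recalibration refuses an inverted run", {
  master <- fivepl_curve(A = 100, B = 1.2, C = 10, D = 5000, G = 1)
  y <- eval_5pl(master, c(2, 50))
  expect_error(
    recalibrate_two_point(master,
                          data.frame(concentration = c(2, 50), mfi = rev(y))),
    "gain")
})

test_that("curve certificates round-trip through JSON", {
  truth <- fivepl_curve(A = 100, B = 1.2, C = 10, D = 5000, G = 1)
  conc <- 32 / 2^(0:7)
  fit <- fit_5pl(data.frame(concentration = conc, mfi = eval_5pl(truth, conc)),
                 lot_id = "LOT-01")
  path <- withr::local_tempfile(fileext = ".json")
  write_curve_certificate(fit, path)
  back <- read_curve_certificate(path)
  expect_equal(back[c("A", "B", "C", "D", "G")],
               fit[c("A", "B", "C", "D", "G")])
  expect_identical(back$lot_id, "LOT-01")
})
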