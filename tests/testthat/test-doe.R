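test_that("face-centred CCD has the canonical block structure", {
  for (cc in c(1, 3, 5)) {
    d <- ccd_face_centered(lysis_factors(), n_center = cc)
    expect_equal(nrow(d$coded), 8 + 6 + cc)
    expect_equal(sum(d$row_labels == "factorial"), 8)
    axial <- d$coded[d$row_labels == "axial", , drop = FALSE]
    expect_true(all(rowSums(axial != 0) == 1))
    expect_true(all(abs(axial[axial != 0]) == 1))  # face-centred: on the faces
    centers <- d$coded[d$row_labels == "center", , drop = FALSE]
    expect_true(all(centers == 0))
  }
  expect_error(ccd_face_centered(list(factor_def("a", 0, 1)), 3), "2..6")
  expect_error(factor_def("flat", 5, 5), "low")
})

test_that("decoding reproduces the lysis factor ranges and midpoints", {
  d <- ccd_face_centered(lysis_factors(), n_center = 3)
  j <- match("contact_time_min", d$factors$name)
  expect_equal(min(d$natural[, j]), 30)
  expect_equal(max(d$natural[, j]), 240)
  expect_equal(unique(d$natural[d$coded[, j] == 0, j]), 135)
  center_row <- d$natural[d$row_labels == "center", , drop = FALSE][1, ]
  expect_equal(unname(center_row),
               c(135, 5.5e6, 0.6))
  expect_equal(range(d$natural[, "triton_pct"]), c(0.2, 1.0))
  expect_equal(range(d$natural[, "cell_density_per_mL"]), c(1e6, 1e7))
})

test_that("coded columns are balanced and the factorial block orthogonal", {
  d <- ccd_face_centered(lysis_factors(), n_center = 4)
  expect_true(all(abs(colMeans(d$coded)) < 1e-12))
  fact <- d$coded[d$row_labels == "factorial", ]
  mm <- cbind(fact, fact[, 1] * fact[, 2], fact[, 1] * fact[, 3],
              fact[, 2] * fact[, 3])
  g <- crossprod(mm)
  expect_true(all(abs(g[upper.tri(g)]) < 1e-12))
})

test_that("noiseless responses from a quadratic are recovered exactly", {
  truth <- c(50, 4, -2, 1, -6, -3, -5, 2, -1, 0.5)
  dat <- gen_doe_dataset(truth, noise_sd = 0)
  fit <- fit_quadratic(dat$design, dat$responses)
  expect_lt(max(abs(coef(fit) - truth)) / max(abs(truth)), 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("constant responses give a null surface", {
  d <- ccd_face_centered(lysis_factors(), n_center = 3)
  fit <- fit_quadratic(d, rep(7, nrow(d$coded)))
  expect_true(all(abs(coef(fit)[-1]) < 1e-12))
  expect_equal(unname(coef(fit)[1]), 7)
  expect_equal(fit$r_squared, 0)
  expect_equal(fit$model_p, 1)
})

test_that("dilution factors rescale responses before fitting", {
  truth <- c(10, 2, 1, -1, -2, -1, -1, 0.5, 0.2, -0.3)
  dat <- gen_doe_dataset(truth, noise_sd = 0)
  # diluted responses with matching correction factors recover the same surface
  dil <- rep(c(2, 4), length.out = length(dat$responses))
  fit <- fit_quadratic(dat$design, dat$responses / dil, dilution_factors = dil)
  expect_lt(max(abs(coef(fit) - truth)), 1e-8)
  expect_error(fit_quadratic(dat$design, dat$responses, dilution_factors = 0),
               "dilution")
})

test_that("under-determined designs are rejected naming the deficiency", {
  d <- ccd_face_centered(lysis_factors(), n_center = 3)
  short <- list(coded = d$coded[1:5, ], factors = d$factors)
  expect_error(fit_quadratic(short, rep(1, 5)), "rank-deficient")
  expect_error(fit_quadratic(d, 1:5), "length")
})

test_that("refitting on a fit's own predictions is idempotent", {
  truth <- c(20, 1, -2, 3, -4, -2, -3, 1, 0.5, -0.5)
  dat <- gen_doe_dataset(truth, noise_sd = 1.5, seed = 99)
  fit1 <- fit_quadratic(dat$design, dat$responses)
  preds <- predict(fit1, dat$design$coded, scale = "coded")
  fit2 <- fit_quadratic(dat$design, preds)
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-9)
})

test_that("coefficient recovery error shrinks monotonically with noise", {
  truth <- c(100, 5, -3, 2, -8, -4, -6, 1.5, -1, 0.5)
  sds <- c(8, 4, 2, 1, 0.25, 0)
  rmse <- vapply(sds, function(s) {
    errs <- vapply(1:50, function(seed) {
      dat <- gen_doe_dataset(truth, noise_sd = s, seed = seed)
      sqrt(mean((coef(fit_quadratic(dat$design, dat$responses)) - truth)^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
  expect_lt(rmse[length(rmse)], 1e-10)
})

test_that("interior stationary maxima of concave surfaces are found analytically", {
  # f = 10 + 2x - y - x^2 - y^2 + 0*xy over [-1,1]^2: optimum (1, -0.5) -> no,
  # stationary at x = 1, boundary-touching; use interior one instead
  f2 <- list(factor_def("x", -1, 1), factor_def("y", -1, 1))
  truth <- c(10, 1, -0.8, -2, -2, 0.4)
  dat <- gen_doe_dataset(truth, factors = f2, n_center = 2, noise_sd = 0)
  fit <- fit_quadratic(dat$design, dat$responses)
  opt <- optimum_within_bounds(fit)
  # analytic stationary point: solve 2 A x = -b
  A <- matrix(c(-2, 0.2, 0.2, -2), 2)
  expect_equal(unname(opt$coded), drop(solve(2 * A, -c(1, -0.8))),
               tolerance = 1e-9)
})

test_that("monotone surfaces maximize on the appropriate face", {
  f2 <- list(factor_def("x", 0, 10), factor_def("y", 0, 10))
  truth <- c(5, -3, 1, 0, 0, 0)  # linear: decreasing in x, increasing in y
  dat <- gen_doe_dataset(truth, factors = f2, n_center = 2, noise_sd = 0)
  opt <- optimum_within_bounds(fit_quadratic(dat$design, dat$responses))
  expect_equal(unname(opt$coded), c(-1, 1), tolerance = 1e-9)
  expect_equal(unname(opt$natural), c(0, 10), tolerance = 1e-8)
})

test_that("pinned factors are respected by the constrained optimizer", {
  truth <- c(10, 0, 0, 5, -1, -1, -1, 0, 0, 0)  # rises with triton
  dat <- gen_doe_dataset(truth, noise_sd = 0)
  fit <- fit_quadratic(dat$design, dat$responses)
  opt <- optimum_within_bounds(fit, fixed = c(triton_pct = 0.2))
  expect_equal(unname(opt$natural["triton_pct"]), 0.2)
  expect_equal(unname(opt$coded["triton_pct"]), -1)
})

test_that("the exact box optimizer agrees with a dense grid oracle", {
  f2 <- list(factor_def("a", -1, 1), factor_def("b", -1, 1))
  grid1 <- seq(-1, 1, by = 0.001)
  for (seed in 1:20) {
    set.seed(seed)
    truth <- c(runif(1, -5, 5), runif(2, -4, 4), runif(2, -4, 1), runif(1, -2, 2))
    dat <- gen_doe_dataset(truth, factors = f2, n_center = 2, noise_sd = 0)
    fit <- fit_quadratic(dat$design, dat$responses)
    opt <- optimum_within_bounds(fit)
    b <- coef(fit)
    # independent vectorized evaluation over the full 0.001 grid
    gx <- rep(grid1, times = length(grid1))
    gy <- rep(grid1, each = length(grid1))
    z <- b[1] + b[2] * gx + b[3] * gy + b[4] * gx^2 + b[5] * gy^2 +
      b[6] * gx * gy
    imax <- which.max(z)
    expect_gte(opt$predicted, z[imax] - 1e-9)
    expect_lte(max(abs(opt$coded - c(gx[imax], gy[imax]))), 0.001 + 1e-9)
  }
})

test_that("contour grids equal direct surface evaluation", {
  truth <- c(30, 3, -2, 4, -5, -2, -6, 1, -0.5, 0.8)
  dat <- gen_doe_dataset(truth, noise_sd = 0)
  fit <- fit_quadratic(dat$design, dat$responses)
  g <- contour_grid(fit, c("contact_time_min", "triton_pct"),
                    fixed_levels = c(cell_density_per_mL = 1e6),
                    resolution = 7)
  expect_equal(nrow(g), 49)
  direct <- predict(fit, data.frame(
    contact_time_min = g$contact_time_min,
    cell_density_per_mL = 1e6,
    triton_pct = g$triton_pct))
  expect_equal(g$response, direct, tolerance = 1e-12)
  # resolution 1 collapses to the low-corner prediction
  g1 <- contour_grid(fit, c("contact_time_min", "triton_pct"),
                     fixed_levels = c(cell_density_per_mL = 1e6),
                     resolution = 1)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$contact_time_min, 30)
  # grids at the two pinned densities differ when density terms are nonzero
  g_hi <- contour_grid(fit, c("contact_time_min", "triton_pct"),
                       fixed_levels = c(cell_density_per_mL = 1e7),
                       resolution = 7)
  expect_gt(max(abs(g_hi$response - g$response)), 1e-6)
  expect_error(contour_grid(fit, c("contact_time_min", "nope"),
                            fixed_levels = c(cell_density_per_mL = 1e6)),
               "unknown factor")
})

test_that("a synthetic boundary-optimum study is detected as significant", {
  # truth surface maximized at the low-detergent face, moderate noise
  truth <- c(100, 0, 0, -12, -2, -2, -3, 0, 0, 0)
  dat <- gen_doe_dataset(truth, n_center = 3, noise_sd = 0.05 * 30, seed = 2024)
  fit <- fit_quadratic(dat$design, dat$responses)
  expect_lt(fit$model_p, 0.05)
  opt <- optimum_within_bounds(fit)
  expect_equal(unname(opt$natural["triton_pct"]), 0.2, tolerance = 1e-6)
})
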