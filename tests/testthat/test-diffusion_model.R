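test_that("concentration matches the closed form and its peak structure", {
  p <- diffusion_params(D = 12, t0 = 320, B = 1)
  # direct evaluation at the source at observation start
  expect_equal(dye_concentration(p, x = 0, t = 0),
               1 / sqrt(pi * 12 * 320), tolerance = 1e-12)
  # at x = 0 the exponential term is 1 for any parameters
  for (tt in c(0, 50, 1234)) {
    v <- dye_concentration(p, 0, tt)
    expect_equal(v * sqrt(pi * p$D * (tt + p$t0)) / p$B, 1, tolerance = 1e-12)
  }
  expect_true(all(dye_concentration(p, seq(0, 200, 25), 100) > 0))

  # peak over t sits at x^2/(2D) on the injection clock
  p0 <- diffusion_params(D = 12, t0 = 0, B = 1)
  tg <- seq(1, 600, by = 0.05)
  curve <- dye_concentration(p0, 60, tg)
  expect_equal(tg[which.max(curve)], 60^2 / (2 * 12), tolerance = 1e-3)
  expect_equal(peak_time(p0, 60), 150)
  expect_equal(peak_time(p0, 0), 0)
  # delayed observation: peak predates recording, observed clamp at 0
  expect_equal(peak_time(p, 60, observed = TRUE), 0)
  expect_equal(peak_time(diffusion_params(12, 100), 60, observed = TRUE), 50)
})

test_that("concentration rejects singular and out-of-domain input", {
  p0 <- diffusion_params(D = 12, t0 = 0)
  expect_error(dye_concentration(p0, 10, 0), "singular")
  expect_error(dye_concentration(p0, -1, 10), ">= 0")
  expect_error(dye_concentration(p0, 10, -1), ">= 0")
  expect_error(diffusion_params(D = -1), "'D'")
  expect_error(diffusion_params(D = 1, t0 = -5), "'t0'")
  expect_error(diffusion_params(D = 1, B = 0), "'B'")
})

test_that("half_time matches the analytic limit and the brute-force oracle", {
  p <- diffusion_params(D = 12, t0 = 320)
  expect_identical(half_time(p, 0), 3 * 320)
  # frozen dense-grid oracle values (dt = 0.01 s)
  expect_equal(half_time(p, 30), 1081.14, tolerance = 0.05 / 1081)
  expect_equal(half_time(p, 60), 1569.32, tolerance = 0.05 / 1569)
  expect_gt(half_time(p, 60), half_time(p, 30))
  expect_error(half_time(diffusion_params(12, 0), 30), "t0 > 0")
})

test_that("half_time agrees with the dense-grid oracle across a parameter grid", {
  for (D in c(1, 4, 12)) for (t0 in c(100, 320, 600)) for (x in c(0, 10, 30)) {
    p <- diffusion_params(D, t0)
    expect_equal(half_time(p, x), oracle_half_time(D, t0, x),
                 tolerance = 0.06 / oracle_half_time(D, t0, x),
                 label = sprintf("half_time(D=%g,t0=%g,x=%g)", D, t0, x))
  }
})

test_that("half_time is strictly increasing in distance and in delay", {
  xs <- c(0, 10, 25, 40, 60)
  for (D in c(2, 12)) {
    taus <- half_time(diffusion_params(D, 320), xs)
    expect_true(all(diff(taus) > 0))
  }
  t0s <- c(100, 320, 600, 1200)
  for (x in c(10, 40)) {
    taus <- vapply(t0s, function(t0) half_time(diffusion_params(12, t0), x),
                   numeric(1))
    expect_true(all(diff(taus) > 0))
  }
})

test_that("f(D) evaluates the printed polynomial", {
  expect_equal(f_of_D(12), 3.892)
  expect_equal(f_of_D(1), 7.643)
  expect_equal(f_of_D(10), 4.34)
  expect_warning(f_of_D(25), "range")
  fc <- f_correction(c2 = 0, c1 = 0, c0 = 4)
  expect_equal(f_of_D(5, fc), 4)
  # positivity over the supported range
  expect_true(all(f_of_D(seq(1, 20, 0.5)) > 0))
})

test_that("wave_speed is the distance/half-time ratio", {
  expect_equal(wave_speed(70, 700), 0.10)
  expect_equal(wave_speed(0, 500), 0)
  expect_equal(wave_speed(50, 500), 0.10)
  expect_error(wave_speed(50, 0), "tau_half")
})

test_that("solve_Dv inverts the quotient relation and is monotone in R0", {
  expect_equal(solve_Dv(70, 700), 8.369, tolerance = 1e-3)
  # the returned root satisfies the defining relation
  Dv <- solve_Dv(50, 900)
  expect_equal(4 * Dv * 900 / f_of_D(Dv), 50^2, tolerance = 1e-6)
  expect_equal(solve_Dv(0, 700), 0)
  expect_gt(solve_Dv(40, 700), solve_Dv(20, 700))
  # product reading yields a much smaller coefficient
  expect_lt(solve_Dv(70, 700, reading = "product"), 1)
  expect_error(solve_Dv(500, 700), "bracket")
})

test_that("concentration satisfies the 1-D diffusion PDE on a grid", {
  p <- diffusion_params(D = 12, t0 = 320, B = 3)
  hx <- 1e-2; ht <- 1e-2
  worst <- 0
  for (x in seq(0 + hx, 200, length.out = 9))
    for (tt in seq(1, 3000, length.out = 9)) {
      Ct <- (dye_concentration(p, x, tt + ht) -
             dye_concentration(p, x, tt - ht)) / (2 * ht)
      Cxx <- (dye_concentration(p, x + hx, tt) -
              2 * dye_concentration(p, x, tt) +
              dye_concentration(p, x - hx, tt)) / hx^2
      resid <- abs(Ct - p$D * Cxx) / (abs(Ct) + abs(p$D * Cxx))
      worst <- max(worst, resid)
    }
  expect_lt(worst, 1e-6)
})

test_that("half-line mass is conserved at B for all times", {
  p <- diffusion_params(D = 8.9, t0 = 50, B = 7)
  for (tt in c(0, 10, 500, 2999)) {
    m <- stats::integrate(function(x) dye_concentration(p, x, tt),
                          0, Inf, rel.tol = 1e-10)$value
    expect_equal(m, p$B, tolerance = 1e-8)
  }
})

test_that("concentration depends on D and time only through their product", {
  p1 <- diffusion_params(D = 6, t0 = 100, B = 2)
  p2 <- diffusion_params(D = 12, t0 = 50, B = 2)
  x <- c(0, 15, 40, 90)
  # u1 = 300 with D=6 equals D*u of u2 = 150 with D=12
  expect_equal(dye_concentration(p1, x, 200), dye_concentration(p2, x, 100),
               tolerance = 1e-12)
})
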