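parent_cell <- function(cfg, diameter = 1.4e-6) {
  rho <- cfg$biomass_density
  tibble::tibble(x = 5e-6, y = 5e-6, z = diameter / 2,
                 diameter = diameter, mass = rho * pi * diameter^3 / 6,
                 lineage = 7L, mu_max = 1, K_s = 3.5e-5)
}

test_that("division conserves mass exactly and splits 40-60%", {
  cfg <- sim_config(n_initial = 9, spacing = 10)
  cell <- parent_cell(cfg)
  st <- 12345
  for (i in 1:50) {
    dv <- divide_cell(cell, st, cfg)
    st <- dv$state
    # conserved at machine precision (the split is m1, m - m1)
    expect_equal(sum(dv$daughters$mass), cell$mass, tolerance = 1e-15)
    f <- dv$daughters$mass[1] / cell$mass
    expect_gt(f, 0.4)
    expect_lt(f, 0.6)
    expect_identical(dv$daughters$lineage, c(7L, 7L))
    expect_equal(dv$daughters$K_s, rep(3.5e-5, 2))
  }
})

test_that("daughters are tangent and centred on the parent", {
  cfg <- sim_config(n_initial = 9, spacing = 10)
  cell <- parent_cell(cfg)
  dv <- divide_cell(cell, 99, cfg)
  d <- dv$daughters
  gap <- sqrt(diff(d$x)^2 + diff(d$y)^2 + diff(d$z)^2) -
    sum(d$diameter) / 2
  # tangent unless the substratum clamp lifted a daughter
  if (all(d$z > d$diameter / 2)) expect_equal(gap, 0, tolerance = 1e-12)
  # diameters follow the sphere-density convention
  rho <- cfg$biomass_density
  expect_equal(d$diameter, (6 * d$mass / (rho * pi))^(1 / 3))
})

test_that("below-threshold cells refuse to divide", {
  cfg <- sim_config(n_initial = 9, spacing = 10)
  small <- parent_cell(cfg, diameter = 1.2e-6)
  expect_error(divide_cell(small, 1, cfg),
               class = "driftbalance_division_error")
})

test_that("biomass fractions are uniform on (0.4, 0.6)", {
  f <- division_fractions(2024, 10000)$fractions
  expect_true(all(f > 0.4 & f < 0.6))
  ks <- suppressWarnings(ks.test(f, "punif", 0.4, 0.6))
  expect_gt(ks$p.value, 0.01)
  # the stream helper consumes draws in the same order as divide_cell
  cfg <- sim_config(n_initial = 9, spacing = 10)
  cell <- parent_cell(cfg)
  st <- 2024
  f10 <- numeric(10)
  for (i in 1:10) {
    dv <- divide_cell(cell, st, cfg)
    f10[i] <- dv$daughters$mass[1] / cell$mass
    st <- dv$state
  }
  expect_equal(f10, division_fractions(2024, 10)$fractions,
               tolerance = 1e-12)
})

test_that("division directions are uniform on the sphere", {
  st <- 555
  n <- 4000
  u <- matrix(0, n, 3)
  cfg <- sim_config(n_initial = 9, spacing = 10)
  cell <- parent_cell(cfg)
  cell$z <- 5e-6 # keep clear of the substratum clamp
  for (i in 1:n) {
    dv <- divide_cell(cell, st, cfg)
    st <- dv$state
    v <- c(diff(dv$daughters$x), diff(dv$daughters$y),
           diff(dv$daughters$z))
    u[i, ] <- v / sqrt(sum(v^2))
  }
  # components of a uniform direction have mean 0 and variance 1/3
  expect_lt(max(abs(colMeans(u))), 4 / sqrt(3 * n))
  expect_equal(unname(apply(u, 2, var)), rep(1 / 3, 3), tolerance = 0.1)
  # z-component itself is U(-1, 1)
  ks <- suppressWarnings(ks.test(u[, 3], "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})
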