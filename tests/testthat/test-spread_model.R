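test_that("labeling_probability follows 1 - (1 - U)^M and validates input", {
  expect_equal(labeling_probability(0.28, 1), 0.28)
  expect_equal(labeling_probability(0, 5), 0)
  expect_equal(labeling_probability(0.28, 2), 0.4816)  # 1 - 0.72^2
  expect_equal(labeling_probability(1, 3), 1)
  # bounds U <= p <= min(1, M U)
  for (U in c(0.05, 0.3, 0.9)) {
    p <- labeling_probability(U, 1:6)
    expect_true(all(p >= U - 1e-15))
    expect_true(all(p <= pmin(1, (1:6) * U) + 1e-15))
  }
  expect_error(labeling_probability(1.2, 1), "U")
  expect_error(labeling_probability(-0.1, 2), "U")
  expect_error(labeling_probability(0.5, 0), "M")
  expect_error(labeling_probability(0.5, 1.5), "M")
})

test_that("evaluate_model reproduces the hand-derived two-population values", {
  e <- evaluate_model(2, 1, 2, 0.28)
  # pa = 0.28, pb = 0.4816; IF = (2*0.28 + 0.4816)/3; SF = (0.56 + 0.9632)/4
  expect_equal(e$pa, 0.28)
  expect_equal(e$pb, 0.4816)
  expect_equal(e$IF, 1.0416 / 3, tolerance = 1e-12)
  expect_equal(e$SF, 1.5232 / 4, tolerance = 1e-12)
  expect_equal(e$ratio, 0.91, tolerance = 0.005)
  expect_equal(evaluate_model(10, 1, 2, 0.35)$ratio, 0.95, tolerance = 0.01)
  # equal multiplicity: IF = SF for any R and U
  for (R in c(0.2, 1, 7)) {
    e <- evaluate_model(R, 3, 3, 0.41)
    expect_equal(e$IF, e$SF, tolerance = 1e-14)
    expect_equal(e$ratio, 1)
  }
  expect_error(evaluate_model(-1, 1, 2, 0.3), "R")
})

test_that("IF/SF is defined as 1 when U = 0 and model endpoints are exact", {
  e0 <- evaluate_model(2, 1, 3, 0)
  expect_equal(e0$IF, 0)
  expect_equal(e0$SF, 0)
  expect_equal(e0$ratio, 1)
  e1 <- evaluate_model(2, 1, 3, 1)
  expect_equal(e1$IF, 1)
  expect_equal(e1$SF, 1)
})

test_that("evaluate_mixture generalizes and reduces to the two-population model", {
  m <- multiplicity_mix(c(1, 2), c(2 / 3, 1 / 3))  # f1/f2 = R = 2
  em <- evaluate_mixture(m, 0.28)
  e2 <- evaluate_model(2, 1, 2, 0.28)
  expect_equal(em$IF, e2$IF, tolerance = 1e-12)
  expect_equal(em$SF, e2$SF, tolerance = 1e-12)
  expect_equal(evaluate_mixture(multiplicity_mix(1, 1), 0.4)$SF, 0.4)
  ez <- evaluate_mixture(default_multiplicity_mix(), 0)
  expect_equal(ez$IF, 0)
  expect_equal(ez$SF, 0)
  # random two-entry mixes agree with evaluate_model to 1e-12
  set.seed(11)
  for (i in 1:20) {
    f1 <- runif(1, 0.05, 0.95)
    Ms <- sample(1:6, 2)
    U <- runif(1)
    em <- evaluate_mixture(multiplicity_mix(Ms, c(f1, 1 - f1)), U)
    e2 <- evaluate_model(f1 / (1 - f1), Ms[1], Ms[2], U)
    expect_equal(em$IF, e2$IF, tolerance = 1e-12)
    expect_equal(em$SF, e2$SF, tolerance = 1e-12)
  }
  expect_error(multiplicity_mix(integer(0), numeric(0)))
  expect_error(multiplicity_mix(c(1, 1), c(0.5, 0.5)), "distinct")
  expect_error(multiplicity_mix(c(1, 2), c(0.6, 0.6)), "sum to 1")
  expect_gte(mean_multiplicity(default_multiplicity_mix()), 1)
})

test_that("solve_unitary_efficiency inverts SF and round-trips to 1e-8", {
  expect_equal(solve_unitary_efficiency(0.4, 10, 1, 2), 0.3615,
               tolerance = 1e-3)
  # round trip at a stated parameter point
  sf <- evaluate_model(3, 1, 3, 0.22)$SF
  expect_lt(abs(solve_unitary_efficiency(sf, 3, 1, 3) - 0.22), 1e-8)
  # randomized round trips (absolute 1e-8, matching the solver's 1e-9 tol)
  set.seed(7)
  for (i in 1:25) {
    R <- exp(runif(1, log(0.05), log(50)))
    Ma <- sample(1:4, 1); Mb <- sample(1:4, 1)
    U <- runif(1, 0.01, 0.99)
    sf <- evaluate_model(R, Ma, Mb, U)$SF
    expect_lt(abs(solve_unitary_efficiency(sf, R, Ma, Mb) - U), 1e-8)
  }
  expect_error(solve_unitary_efficiency(0, 2, 1, 2), "SF_target")
  expect_error(solve_unitary_efficiency(1, 2, 1, 2), "SF_target")
})

test_that("minimize_if_sf_over_R finds the shallow interior minimum", {
  m <- minimize_if_sf_over_R(0.22, 1, 3, 0.01, 100)
  expect_equal(m$ratio_star, 0.8, tolerance = 0.01)
  m2 <- minimize_if_sf_over_R(0.28, 1, 2, 0.01, 100)
  expect_gt(m2$R_star, 1.5)
  expect_lt(m2$R_star, 2.5)
  # refinement result can never be worse than any grid point
  grid <- exp(seq(log(0.01), log(100), length.out = 400))
  vals <- vapply(grid, function(R) evaluate_model(R, 1, 3, 0.22)$ratio,
                 numeric(1))
  expect_lte(m$ratio_star, min(vals) + 1e-9)
  # equal multiplicity: ratio constant at 1
  m3 <- minimize_if_sf_over_R(0.5, 2, 2, 0.1, 10)
  expect_equal(m3$ratio_star, 1)
  expect_error(minimize_if_sf_over_R(0.2, 1, 2, 5, 1), "R_min")
})

test_that("sweep_curves evaluates pointwise and stays monotone in U", {
  one <- sweep_curves(0.28, 2, 1, 2)
  expect_equal(nrow(one), 1L)
  e <- evaluate_model(2, 1, 2, 0.28)
  expect_equal(one$SF, e$SF)
  expect_equal(one$IF, e$IF)

  sw <- sweep_curves(0.28, c(1, 2, 3), 1, 2)
  expect_equal(sw$ratio, c(0.919, 0.912, 0.916), tolerance = 5e-4)

  grid <- sweep_curves(seq(0.05, 0.95, by = 0.05), c(0.5, 2, 8), 1, 3)
  for (R in unique(grid$R)) {
    sf_col <- grid$SF[grid$R == R][order(grid$U[grid$R == R])]
    expect_true(all(diff(sf_col) >= 0))
  }
  expect_error(sweep_curves(numeric(0), 1, 1, 2), "nonempty")
})

test_that("sweep CSV output has the contract header and 6 significant digits", {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  sw <- sweep_curves(c(0.123456789, 0.5), c(1, 2), 1, 2)
  write_sweep_csv(sw, path)
  lines <- readLines(path)
  expect_equal(lines[1], "U,R,Ma,Mb,SF,IF,ratio")
  back <- read.csv(path)
  expect_equal(back$U[1], 0.123457)  # 6 significant digits
  expect_equal(back$SF, signif(sw$SF, 6))
})

test_that("model invariants hold over randomized parameter grids", {
  set.seed(42)
  for (i in 1:50) {
    R <- exp(runif(1, log(0.02), log(80)))
    Ma <- sample(1:5, 1); Mb <- sample(1:5, 1)
    U <- runif(1, 0.01, 0.99)
    e <- evaluate_model(R, Ma, Mb, U)
    expect_lte(e$IF, e$SF + 1e-14)
    if (Ma == Mb) {
      expect_equal(e$IF, e$SF, tolerance = 1e-14)
    } else {
      expect_lt(e$IF, e$SF)  # strict inequality when Ma != Mb, 0 < U < 1
    }
    # monotone in U
    e_hi <- evaluate_model(R, Ma, Mb, min(1, U + 0.01))
    expect_gte(e_hi$SF, e$SF)
    expect_gte(e_hi$IF, e$IF)
  }
})

test_that("small-U limit matches the analytic derivatives at U = 0", {
  # dp/dU at 0 is M, so dIF/dU = (R Ma + Mb)/(R + 1) and
  # dSF/dU = (R Ma^2 + Mb^2)/(Ma R + Mb)
  cases <- list(c(2, 1, 2), c(10, 1, 2), c(0.5, 1, 3), c(3, 2, 5))
  for (cs in cases) {
    R <- cs[1]; Ma <- cs[2]; Mb <- cs[3]
    U <- 1e-6
    e <- evaluate_model(R, Ma, Mb, U)
    dIF <- (R * Ma + Mb) / (R + 1)
    dSF <- (R * Ma^2 + Mb^2) / (Ma * R + Mb)
    expect_equal(e$IF / U, dIF, tolerance = 1e-4)
    expect_equal(e$SF / U, dSF, tolerance = 1e-4)
  }
})
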