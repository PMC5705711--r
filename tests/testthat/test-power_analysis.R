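test_that("variance factor matches direct arithmetic and the perfect-detection limit", {
  # direct arithmetic: psi (1-psi) plus the imperfect-detection penalty
  p <- 0.61; K <- 3
  p_star <- 1 - (1 - p)^K
  v_direct <- 0.49 * (0.51 + (1 - p_star) / (p_star - K * p * (1 - p)^(K - 1)))
  expect_equal(asymptotic_var_factor(0.49, 0.61, 3), v_direct)
  expect_equal(v_direct, 0.2938, tolerance = 1e-4)

  # p -> 1 collapses to the binomial-proportion variance
  expect_equal(asymptotic_var_factor(0.3, 1 - 1e-12, 4), 0.3 * 0.7,
               tolerance = 1e-9)

  expect_gte(asymptotic_var_factor(0.5, 0.3, 5), 0.25)
  expect_error(asymptotic_var_factor(0.5, 0.3, 1), "K must be >= 2")
})

test_that("power spec applies the effect-size convention it is given", {
  prop <- power_spec(0.49, 0.30, "proportional", p = 0.61, K = 20, S = 143)
  expect_equal(prop$psi2, 0.49 * 0.70)
  abs_ <- power_spec(0.70, 0.30, "absolute", p = 0.61, K = 20, S = 143)
  expect_equal(abs_$psi2, 0.40)
  expect_error(power_spec(0.2, 0.3, "absolute", p = 0.6, K = 4, S = 50),
               "absolute")
  expect_error(power_spec(0.49, 1, "proportional", p = 0.61, K = 20, S = 143),
               "proportional")
})

test_that("Wald power at zero effect equals alpha exactly", {
  for (alpha in c(0.05, 0.1, 0.2)) {
    sp <- power_spec(0.49, 0, "proportional", p = 0.61, K = 20, S = 143,
                     alpha = alpha)
    expect_equal(wald_power(sp), alpha, tolerance = 1e-12)
  }
})

test_that("Wald power is monotone in sites, effect size and initial occupancy", {
  pw_S <- vapply(c(50, 100, 200, 400), function(S)
    wald_power(power_spec(0.49, 0.2, "proportional", p = 0.61, K = 20, S = S)),
    0)
  expect_true(all(diff(pw_S) > 0))

  pw_R <- vapply(c(0.1, 0.2, 0.3, 0.4), function(R)
    wald_power(power_spec(0.49, R, "proportional", p = 0.61, K = 20, S = 143)),
    0)
  expect_true(all(diff(pw_R) > 0))

  # higher initial occupancy -> larger power at fixed proportional effect
  pw_psi <- vapply(c(0.2, 0.35, 0.49, 0.6), function(psi1)
    wald_power(power_spec(psi1, 0.3, "proportional", p = 0.61, K = 20, S = 143)),
    0)
  expect_true(all(diff(pw_psi) > 0))
})

test_that("required sites is the minimal integer achieving the target power", {
  specs <- list(
    power_spec(0.49, 0.15, "proportional", p = 0.61, K = 20, alpha = 0.1,
               target_power = 0.8),
    power_spec(0.49, 0.30, "proportional", p = 0.61, K = 20, alpha = 0.1,
               target_power = 0.8),
    power_spec(0.6, 0.2, "absolute", p = 0.5, K = 4, alpha = 0.05,
               target_power = 0.9))
  for (sp in specs) {
    S <- required_sites(sp)
    at <- function(S_) occudesign:::.wald_power_at(sp, S_)
    expect_gte(at(S), sp$target_power)
    expect_lt(at(S - 1), sp$target_power)
  }
})

test_that("near-perfect detection sample size matches a brute-force scan", {
  sp <- power_spec(0.6, 0.5, "absolute", p = 1 - 1e-9, K = 2, alpha = 0.05,
                   target_power = 0.8)
  S <- required_sites(sp)
  expect_lte(S, 15)
  scan <- which(vapply(2:30, function(S_) occudesign:::.wald_power_at(sp, S_),
                       0) >= 0.8)[1] + 1
  expect_identical(S, as.integer(scan))
})

test_that("halving the detectable change roughly quadruples the sites needed", {
  S_small <- required_sites(power_spec(0.6, 0.1, "absolute", p = 0.7, K = 5,
                                       alpha = 0.1, target_power = 0.8))
  S_large <- required_sites(power_spec(0.6, 0.2, "absolute", p = 0.7, K = 5,
                                       alpha = 0.1, target_power = 0.8))
  expect_gt(S_small / S_large, 3)
  expect_lt(S_small / S_large, 5)
})

test_that("empirical power agrees with the analytic value and calibrates type-I error", {
  sp <- power_spec(0.49, 0.3, "proportional", p = 0.61, K = 20, S = 143,
                   alpha = 0.1)
  res <- empirical_power(sp, n_iter = 600, seed = 17)
  tol <- 3 * sqrt(res$analytic_power * (1 - res$analytic_power) / res$n_iter)
  expect_lt(abs(res$empirical_power - res$analytic_power), tol)

  null_sp <- power_spec(0.49, 0, "proportional", p = 0.61, K = 20, S = 143,
                        alpha = 0.1)
  null_res <- empirical_power(null_sp, n_iter = 600, seed = 18)
  expect_lt(abs(null_res$empirical_power - 0.1),
            3 * sqrt(0.1 * 0.9 / null_res$n_iter))
})

test_that("empirical power is reproducible for a fixed seed", {
  sp <- power_spec(0.49, 0.3, "proportional", p = 0.61, K = 20, S = 60,
                   alpha = 0.1)
  a <- empirical_power(sp, n_iter = 500, seed = 4)
  b <- empirical_power(sp, n_iter = 500, seed = 4)
  expect_identical(a$empirical_power, b$empirical_power)
  expect_identical(a$n_degenerate, b$n_degenerate)
})

test_that("power curve grids emit one row per cell", {
  out <- power_curves(0.49, effects = c(0.15, 0.2, 0.3), p_grid = 0.61,
                      K_grid = 20, S_grid = c(50, 143, 200, 300), alpha = 0.1)
  expect_identical(nrow(out), 12L)
  expect_true(all(out$power >= 0 & out$power <= 1))
  expect_error(power_curves(0.49, numeric(0), p_grid = 0.61, K_grid = 20,
                            S_grid = 100), "empty grid")
})

test_that("required-sites planning table covers the alpha x power grid", {
  tab <- required_sites_table(0.49, 0.2, "proportional", p = 0.61, K = 20,
                              alphas = c(0.05, 0.1, 0.2),
                              powers = c(0.8, 0.9, 0.95))
  expect_identical(nrow(tab), 9L)
  # stricter alpha or higher target power always needs more sites
  for (pw in unique(tab$target_power)) {
    sub <- tab[tab$target_power == pw, ]
    expect_true(all(diff(sub$required_sites[order(sub$alpha)]) < 0))
  }
  for (al in unique(tab$alpha)) {
    sub <- tab[tab$alpha == al, ]
    expect_true(all(diff(sub$required_sites[order(sub$target_power)]) > 0))
  }
})
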