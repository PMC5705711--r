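test_that("log-likelihood matches closed forms on single-site cases", {
  h1 <- detection_history(rbind(c(1L)))
  expect_equal(occupancy_loglik(qlogis(0.5), qlogis(0.5), h1), log(0.25))

  h2 <- detection_history(rbind(c(0L, 0L)))
  expect_equal(occupancy_loglik(qlogis(0.3), qlogis(0.56), h2),
               log(0.3 * 0.44^2 + 0.7))

  # a missing visit contributes no factor
  h3 <- detection_history(rbind(c(1L, NA)))
  expect_equal(occupancy_loglik(qlogis(0.5), qlogis(0.5), h3), log(0.25))
})

test_that("log-likelihood equals the latent-state enumeration oracle", {
  set.seed(101)
  for (rep in 1:30) {
    S <- sample(2:8, 1); K <- sample(2:4, 1)
    y <- random_instance(S, K)
    h <- detection_history(y)
    b_psi <- rnorm(1); b_p <- rnorm(1)
    ours <- occupancy_loglik(b_psi, b_p, h)
    oracle <- oracle_loglik_enum(rep(plogis(b_psi), S),
                                 matrix(plogis(b_p), S, K), y)
    expect_equal(ours, oracle, tolerance = 1e-10)
  }
})

test_that("log-likelihood with covariates equals the enumeration oracle", {
  set.seed(202)
  for (rep in 1:20) {
    S <- sample(4:8, 1); K <- 3
    y <- random_instance(S, K, miss_prob = 0.1)
    h <- detection_history(y)
    elev <- runif(S, 1700, 2100)
    site_covs <- data.frame(site = h$site_ids, elevation = elev)
    obs <- sample(rep(c("high", "low"), length.out = K))
    sv <- expand.grid(occ = h$occasion_labels, site = h$site_ids,
                      stringsAsFactors = FALSE)[, c("site", "occ")]
    sv$observer <- rep(obs, times = S)
    spec <- occu_spec(psi = "elevation", p = "observer")
    beta_psi <- rnorm(2, sd = 0.8); beta_p <- rnorm(2, sd = 0.8)
    ours <- occupancy_loglik(beta_psi, beta_p, h, site_covs, sv, spec)
    # replicate the internal standardisation: centred/scaled numeric,
    # treatment contrast for the factor (levels sorted: high < low)
    e_std <- (elev - mean(elev)) / sd(elev)
    psi_vec <- plogis(beta_psi[1] + beta_psi[2] * e_std)
    p_mat <- t(vapply(seq_len(S), function(i)
      plogis(beta_p[1] + beta_p[2] * (obs == "low")), numeric(K)))
    expect_equal(ours, oracle_loglik_enum(psi_vec, p_mat, y), tolerance = 1e-10)
  }
})

test_that("constant-model MLE agrees with dense grid search on a toy set", {
  set.seed(7)
  y <- rbind(c(1L, 0L, 1L), c(0L, 0L, 0L), c(1L, 1L, 0L), c(0L, 0L, 0L),
             c(0L, 1L, 0L), c(0L, 0L, 0L), c(1L, 0L, 0L), c(0L, 0L, 0L),
             c(0L, 0L, 1L), c(0L, 0L, 0L))
  h <- detection_history(y)
  fit <- fit_occupancy(h, spec = occu_spec(), n_starts = 3, seed = 1)
  oracle <- oracle_grid_mle(y, step = 0.002)
  expect_true(fit$converged)
  expect_equal(unname(plogis(fit$beta_psi)), oracle$psi, tolerance = 3e-3)
  expect_equal(unname(plogis(fit$beta_p)), oracle$p, tolerance = 3e-3)
  expect_gte(fit$loglik, oracle$loglik - 1e-8)
  expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)
})

test_that("fitted likelihood at the MLE is at least that at the truth", {
  set.seed(33)
  z <- rbinom(120, 1, 0.5)
  y <- matrix(rbinom(120 * 4, 1, 0.6), 120, 4) * z
  h <- detection_history(y)
  fit <- fit_occupancy(h, spec = occu_spec(), n_starts = 3, seed = 2)
  expect_gte(fit$loglik, occupancy_loglik(qlogis(0.5), qlogis(0.6), h))
})

test_that("constant model recovers generating parameters on a large survey", {
  set.seed(42)
  S <- 500; K <- 5
  z <- rbinom(S, 1, 0.6)
  y <- matrix(rbinom(S * K, 1, 0.7), S, K) * z
  fit <- fit_occupancy(detection_history(y), spec = occu_spec(),
                       n_starts = 3, seed = 1)
  expect_true(fit$converged)
  se_psi <- sqrt(asymptotic_var_factor(0.6, 0.7, K) / S)
  expect_lt(abs(plogis(fit$beta_psi) - 0.6), 3 * se_psi)
  expect_lt(abs(plogis(fit$beta_p) - 0.7), 0.05)
})

test_that("saturated all-ones data gives a flagged boundary fit", {
  y <- matrix(1L, 15, 4)
  fit <- fit_occupancy(detection_history(y), spec = occu_spec(),
                       n_starts = 2, seed = 1)
  expect_true(fit$boundary)
  expect_false(fit$converged)
  expect_gt(plogis(fit$beta_psi), 0.99)
  expect_gt(plogis(fit$beta_p), 0.99)
})

test_that("zero detections overall gives a flagged degenerate fit", {
  y <- matrix(0L, 15, 4)
  fit <- fit_occupancy(detection_history(y), spec = occu_spec(),
                       n_starts = 2, seed = 1)
  expect_true(fit$boundary)
  expect_false(fit$converged)
})

fake_fit <- function(aic, k, n_sites = 100) {
  structure(list(aic = aic, n_params = as.integer(k),
                 loglik = (2 * k - aic) / 2, n_sites = as.integer(n_sites),
                 spec = occu_spec()), class = "occupancy_fit")
}

test_that("selection table implements delta-AIC and Akaike weights", {
  # equal AIC -> equal weights
  tab <- build_selection_table(list(fake_fit(100, 2), fake_fit(100, 3)),
                               names = c("m1", "m2"))
  expect_equal(tab$weight, c(0.5, 0.5))
  expect_identical(tab$model[1], "m1")   # tie broken by fewer parameters

  # delta AIC of 2 -> weight ratio exp(-1)
  tab2 <- build_selection_table(list(fake_fit(100, 2), fake_fit(102, 2)),
                                names = c("a", "b"))
  expect_equal(tab2$weight[2] / tab2$weight[1], exp(-1))

  # three models, direct arithmetic
  tab3 <- build_selection_table(
    list(fake_fit(100, 2), fake_fit(101, 2), fake_fit(110, 2)),
    names = c("a", "b", "c"))
  w <- c(1, exp(-0.5), exp(-5)); w <- w / sum(w)
  expect_equal(tab3$weight, w)
  expect_equal(tab3$delta_aic, c(0, 1, 10))
  expect_equal(sum(tab3$weight), 1, tolerance = 1e-12)

  # ordering and weights invariant under a constant shift of all logliks
  shifted <- lapply(list(100, 101, 110), function(a) {
    f <- fake_fit(a, 2); f$loglik <- f$loglik + 7; f$aic <- f$aic - 14; f
  })
  tab4 <- build_selection_table(shifted, names = c("a", "b", "c"))
  expect_identical(tab4$model, tab3$model)
  expect_equal(tab4$weight, tab3$weight)

  expect_error(build_selection_table(list()), "empty")
  expect_error(build_selection_table(list(fake_fit(1, 2, 10), fake_fit(1, 2, 20))),
               "identical data")
})

test_that("predictions are constant without covariates and CIs stay in (0,1)", {
  set.seed(5)
  z <- rbinom(100, 1, 0.5)
  y <- matrix(rbinom(400, 1, 0.6), 100, 4) * z
  h <- detection_history(y)
  fit <- fit_occupancy(h, spec = occu_spec(), n_starts = 3, seed = 1)
  pr <- predict_parameters(fit, h)
  expect_equal(length(unique(pr$psi$estimate)), 1L)
  expect_true(all(pr$psi$lower > 0 & pr$psi$upper < 1))
  expect_true(all(pr$psi$lower < pr$psi$estimate &
                  pr$psi$estimate < pr$psi$upper))
  expect_true(all(pr$p$lower < pr$p$estimate & pr$p$estimate < pr$p$upper))
})

test_that("prediction rejects unseen factor levels by name", {
  set.seed(8)
  cfg <- one_month_config()
  st <- generate_study(cfg, seed = 3)
  fit <- fit_occupancy(st$history, st$site_covs, st$survey_covs,
                       occu_spec(psi = "zone"), n_starts = 2, seed = 1)
  bad_covs <- st$site_covs
  bad_covs$zone[1] <- "alpine"
  expect_error(predict_parameters(fit, st$history, bad_covs, st$survey_covs),
               "alpine")
})

test_that("correlation screen drops the later-listed of a collinear pair", {
  set.seed(9)
  x <- rnorm(100)
  df <- data.frame(a = x, b = x + rnorm(100, sd = 0.1), c = rnorm(100),
                   f = sample(c("u", "v"), 100, TRUE))
  out <- screen_covariates(df, c("a", "b", "c", "f"))
  expect_identical(out$kept, c("a", "c", "f"))
  expect_identical(out$dropped$dropped, "b")
  expect_identical(out$dropped$against, "a")
})

test_that("stepwise selection with one candidate each yields the four stage-2 models", {
  set.seed(12)
  st <- generate_study(one_month_config(), seed = 21)
  # force retention of both stage-1 p-structures so the full 2 x 2 cross runs
  sel <- stepwise_select(st$history, st$site_covs, st$survey_covs,
                         p_candidates = "observer_experience",
                         psi_candidates = "zone",
                         delta_retain = Inf, n_starts = 2, seed = 1)
  expect_identical(nrow(sel$table), 4L)
  expect_setequal(sel$table$model,
                  c("psi(.)p(.)", "psi(.)p(observer_experience)",
                    "psi(zone)p(.)", "psi(zone)p(observer_experience)"))
  expect_equal(sum(sel$table$weight), 1, tolerance = 1e-12)
  expect_identical(format(sel$best_fit$spec), sel$table$model[1])
})
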