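#' Asymptotic per-site variance factor of the occupancy MLE
#'
#' Under the constant single-season model with S sites and K visits, the
#' asymptotic variance of the occupancy MLE is `v / S` with
#' `v = psi * [ (1 - psi) + (1 - p*) / (p* - K p (1 - p)^(K-1)) ]`,
#' where `p* = 1 - (1 - p)^K` is the cumulative detection probability. The
#' second term is the price of imperfect detection; as p approaches 1 the
#' factor collapses to the binomial-proportion variance `psi (1 - psi)`.
#'
#' @param psi,p Probabilities in (0, 1).
#' @param K Number of visits; must be >= 2 (with a single visit psi and p are
#'   not separately identifiable).
#' @return The variance factor v (scalar).
#' @examples
#' asymptotic_var_factor(0.49, 0.61, 3)   # ~0.2938
#' @export
asymptotic_var_factor <- function(psi, p, K) {
  stopifnot(psi > 0, psi < 1, p > 0, p < 1)
  if (K < 2) stop("K must be >= 2: psi and p are non-separable from one visit")
  p_star <- 1 - (1 - p)^K
  denom <- p_star - K * p * (1 - p)^(K - 1)
  if (denom <= 0) stop("degenerate information: p* - K p (1-p)^(K-1) <= 0")
  v <- psi * ((1 - psi) + (1 - p_star) / denom)
  if (!is.finite(v)) stop("non-finite variance factor")
  v
}

#' Specify a two-period occupancy power problem
#'
#' Collects everything the Wald power machinery needs: initial occupancy,
#' the effect size (decline) and its convention, per-visit detection, visits
#' and sites per period, the two-tailed significance level, and optionally a
#' target power when solving for the number of sites.
#'
#' The effect conventions differ and the choice matters: `proportional`
#' means `psi2 = psi1 * (1 - effect)` (a 30% decline of psi1 = 0.49 gives
#' psi2 = 0.343); `absolute` means `psi2 = psi1 - effect`.
#'
#' @param psi1 Initial occupancy, in (0, 1).
#' @param effect Effect size (decline), interpreted per `convention`.
#' @param convention `"proportional"` or `"absolute"`.
#' @param p Per-visit detection probability.
#' @param K Visits per site per period (>= 2).
#' @param S Sites per period (both periods use the same sites), or `NULL`
#'   when solving for S.
#' @param alpha Two-tailed significance level (default 0.1: for monitoring,
#'   a missed decline — a type II error — is usually costlier than a false
#'   alarm, so alpha is set above the conventional 0.05).
#' @param target_power Desired power G = 1 - beta, needed by
#'   [required_sites()].
#' @return A `power_spec` list, with `psi2` computed.
#' @export
power_spec <- function(psi1, effect, convention = c("proportional", "absolute"),
                       p, K, S = NULL, alpha = 0.1, target_power = NULL) {
  convention <- match.arg(convention)
  stopifnot(psi1 > 0, psi1 < 1, p > 0, p < 1, K >= 2,
            alpha > 0, alpha < 1)
  psi2 <- switch(convention,
                 proportional = psi1 * (1 - effect),
                 absolute = psi1 - effect)
  if (psi2 <= 0 || psi2 >= 1)
    stop(sprintf("psi2 = %.4f outside (0, 1) under the %s convention",
                 psi2, convention))
  if (!is.null(target_power)) stopifnot(target_power > 0, target_power < 1)
  if (!is.null(S)) stopifnot(S >= 2)
  structure(list(psi1 = psi1, psi2 = psi2, effect = effect,
                 convention = convention, p = p, K = as.integer(K),
                 S = if (is.null(S)) NULL else as.integer(S),
                 alpha = alpha, target_power = target_power),
            class = "power_spec")
}

#' Analytic power of the two-period Wald test on the probability scale
#'
#' Power of the two-tailed z-test comparing occupancy estimates from two
#' independent survey periods:
#' `G = Phi(D/SE - z_{a/2}) + Phi(-D/SE - z_{a/2})` with `D = psi1 - psi2`
#' and `SE = sqrt((v1 + v2) / S)`, where `v_i` is
#' [asymptotic_var_factor()] at `psi_i`. At zero effect this reduces to
#' exactly alpha.
#'
#' @param spec A [power_spec()] with `S` set.
#' @return Analytic power G in \[0, 1\].
#' @examples
#' wald_power(power_spec(0.49, 0.30, "proportional", p = 0.61, K = 20,
#'                       S = 143, alpha = 0.1))   # ~0.82
#' @export
wald_power <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  if (is.null(spec$S)) stop("spec has no S; set S or use required_sites()")
  .wald_power_at(spec, spec$S)
}

.wald_power_at <- function(spec, S) {
  v1 <- asymptotic_var_factor(spec$psi1, spec$p, spec$K)
  v2 <- asymptotic_var_factor(spec$psi2, spec$p, spec$K)
  se <- sqrt((v1 + v2) / S)
  delta <- spec$psi1 - spec$psi2
  z <- stats::qnorm(1 - spec$alpha / 2)
  stats::pnorm(delta / se - z) + stats::pnorm(-delta / se - z)
}

#' Number of sites required for a target power
#'
#' Closed-form sample size for the two-period Wald test,
#' `S = ceil[(z_{a/2} + z_beta)^2 (v1 + v2) / D^2]`, then verified against
#' [wald_power()] and adjusted so the returned S is the smallest integer
#' whose analytic power reaches the target.
#'
#' @param spec A [power_spec()] with `target_power` set (any `S` is ignored).
#' @return Integer number of sites per period.
#' @examples
#' required_sites(power_spec(0.49, 0.15, "proportional", p = 0.61, K = 20,
#'                           alpha = 0.1, target_power = 0.8))   # 565
#' @export
required_sites <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  if (is.null(spec$target_power)) stop("spec has no target_power")
  delta <- spec$psi1 - spec$psi2
  if (delta == 0) stop("zero effect size: required sites undefined")
  v1 <- asymptotic_var_factor(spec$psi1, spec$p, spec$K)
  v2 <- asymptotic_var_factor(spec$psi2, spec$p, spec$K)
  za <- stats::qnorm(1 - spec$alpha / 2)
  zb <- stats::qnorm(spec$target_power)
  S <- ceiling((za + zb)^2 * (v1 + v2) / delta^2 - 1e-12)
  S <- max(2, S)
  # the closed form ignores the far-tail term of the two-tailed power;
  # nudge to the exact minimal integer
  while (S > 2 && .wald_power_at(spec, S - 1) >= spec$target_power) S <- S - 1
  while (.wald_power_at(spec, S) < spec$target_power) S <- S + 1
  as.integer(S)
}

#' Empirical power of the two-period Wald test by simulation
#'
#' Simulates the full pipeline the analytic formula approximates: for each
#' iteration, two independent constant-model surveys are generated (period 1
#' at psi1, period 2 at psi2; same S, K, p), each is fitted by maximum
#' likelihood, and the Wald statistic
#' `z = (psi1_hat - psi2_hat) / sqrt(se1^2 + se2^2)` is compared with
#' `z_{alpha/2}`. For degenerate (boundary) fits the standard error is
#' rebuilt from the asymptotic variance factor at estimates clamped to
#' `[1e-6, 1 - 1e-6]`; iterations with a non-finite statistic count as
#' non-rejections and are reported in `n_degenerate`.
#'
#' @param spec A [power_spec()] with `S` set.
#' @param n_iter Number of simulated two-period studies (>= 500).
#' @param seed Integer seed.
#' @return A `power_result`: `analytic_power`, `empirical_power`, its
#'   binomial Monte-Carlo standard error `mc_se`, `n_iter`, `n_degenerate`,
#'   and the spec.
#' @export
empirical_power <- function(spec, n_iter = 2000, seed = 1) {
  stopifnot(inherits(spec, "power_spec"), n_iter >= 500)
  if (is.null(spec$S)) stop("spec has no S")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))

  S <- spec$S; K <- spec$K
  zcrit <- stats::qnorm(1 - spec$alpha / 2)
  clamp <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  se_of <- function(f) {
    if (!f$boundary && f$converged && is.finite(f$se_psi)) f$se_psi
    else sqrt(asymptotic_var_factor(clamp(f$psi_hat), clamp(f$p_hat), K) / S)
  }
  reject <- logical(n_iter); degen <- logical(n_iter)
  for (i in seq_len(n_iter)) {
    f1 <- fit_constant_counts(sim_counts(spec$psi1, spec$p, S, K), rep(K, S))
    f2 <- fit_constant_counts(sim_counts(spec$psi2, spec$p, S, K), rep(K, S))
    z <- (f1$psi_hat - f2$psi_hat) / sqrt(se_of(f1)^2 + se_of(f2)^2)
    degen[i] <- f1$boundary || f2$boundary || !is.finite(z)
    reject[i] <- is.finite(z) && abs(z) > zcrit
  }
  emp <- mean(reject)
  structure(list(
    analytic_power = wald_power(spec),
    empirical_power = emp,
    mc_se = sqrt(emp * (1 - emp) / n_iter),
    n_iter = n_iter, n_degenerate = sum(degen),
    seed = seed, spec = spec
  ), class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Two-period Wald power (psi1 = %.3g -> psi2 = %.3g, %s effect %.3g)\n",
              s$psi1, s$psi2, s$convention, s$effect))
  cat(sprintf("  p = %.3g, K = %d, S = %d, alpha = %.3g\n", s$p, s$K, s$S, s$alpha))
  cat(sprintf("  analytic power:  %.4f\n", x$analytic_power))
  cat(sprintf("  empirical power: %.4f (MC se %.4f, %d iterations, %d degenerate)\n",
              x$empirical_power, x$mc_se, x$n_iter, x$n_degenerate))
  invisible(x)
}

#' Analytic power over a design grid
#'
#' One [wald_power()] evaluation per combination of effect size, detection,
#' visits and sites; the tidy result maps directly onto power-against-effort
#' curves.
#'
#' @param psi1 Initial occupancy.
#' @param effects Vector of effect sizes.
#' @param convention Effect convention, as in [power_spec()].
#' @param p_grid,K_grid,S_grid Vectors of detection probabilities, visit
#'   counts and site counts.
#' @param alpha Two-tailed significance level.
#' @return Data.frame with one row per grid cell: `effect`, `psi2`, `p`, `K`,
#'   `S`, `alpha`, `power`.
#' @export
power_curves <- function(psi1, effects, convention = "proportional",
                         p_grid, K_grid, S_grid, alpha = 0.1) {
  grid <- expand.grid(effect = effects, p = p_grid, K = K_grid, S = S_grid)
  if (nrow(grid) == 0) stop("empty grid")
  grid$alpha <- alpha
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sp <- power_spec(psi1, grid$effect[i], convention, p = grid$p[i],
                     K = grid$K[i], S = grid$S[i], alpha = alpha)
    c(psi2 = sp$psi2, power = wald_power(sp))
  })
  cbind(grid, do.call(rbind, res))
}

#' Required-sites table over significance levels and target powers
#'
#' Tabulates [required_sites()] over a grid of alpha and target power, the
#' standard planning table for choosing a monitoring design.
#'
#' @param psi1,effect,convention,p,K As in [power_spec()].
#' @param alphas Vector of significance levels.
#' @param powers Vector of target powers.
#' @return Data.frame with columns `alpha`, `target_power`, `required_sites`.
#' @export
required_sites_table <- function(psi1, effect, convention = "proportional",
                                 p, K, alphas = c(0.05, 0.1, 0.2),
                                 powers = c(0.8, 0.9, 0.95)) {
  grid <- expand.grid(alpha = alphas, target_power = powers)
  grid$required_sites <- vapply(seq_len(nrow(grid)), function(i) {
    required_sites(power_spec(psi1, effect, convention, p = p, K = K,
                              alpha = grid$alpha[i],
                              target_power = grid$target_power[i]))
  }, 0L)
  grid
}
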