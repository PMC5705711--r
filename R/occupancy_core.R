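#' Specify a single-season occupancy model
#'
#' The model has two logit-linear predictors: occupancy probability psi
#' (site-level) and per-visit detection probability p (site- or visit-level).
#' An empty covariate list means the parameter is constant across sites/visits.
#'
#' @param psi Character vector of site-covariate names for occupancy
#'   (empty = constant psi).
#' @param p Character vector of covariate names for detection; each name must
#'   exist in the survey-covariate table or, failing that, the site table
#'   (empty = constant p).
#' @return An `occu_spec` object.
#' @examples
#' occu_spec()                                  # psi(.) p(.)
#' occu_spec(psi = "elevation", p = "observer_experience")
#' @export
occu_spec <- function(psi = character(0), p = character(0)) {
  psi <- as.character(psi); p <- as.character(p)
  if (anyDuplicated(psi)) stop("duplicate psi covariate")
  if (anyDuplicated(p)) stop("duplicate p covariate")
  structure(list(psi = psi, p = p), class = "occu_spec")
}

#' @export
format.occu_spec <- function(x, ...) {
  lab <- function(v) if (length(v) == 0) "." else paste(v, collapse = "+")
  sprintf("psi(%s)p(%s)", lab(x$psi), lab(x$p))
}

#' @export
print.occu_spec <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# Centre/scale numeric columns, coerce character to factor; remembers the
# transformation so predictions use the training standardisation and levels.
standardize_frame <- function(df, info = NULL) {
  if (is.null(info)) {
    info <- list()
    for (v in names(df)) {
      x <- df[[v]]
      if (is.character(x) || is.logical(x)) x <- factor(x)
      if (is.factor(x)) {
        info[[v]] <- list(type = "factor", levels = levels(x))
        df[[v]] <- x
      } else {
        s <- stats::sd(x)
        if (!is.finite(s) || s == 0) s <- 1
        info[[v]] <- list(type = "numeric", center = mean(x), scale = s)
        df[[v]] <- (x - mean(x)) / s
      }
    }
    attr(df, "std_info") <- info
    df
  } else {
    for (v in names(df)) {
      inf <- info[[v]]
      if (is.null(inf)) next
      if (inf$type == "factor") {
        x <- as.character(df[[v]])
        bad <- setdiff(unique(x), inf$levels)
        if (length(bad) > 0)
          stop("unseen covariate level in '", v, "': ", paste(bad, collapse = ", "))
        df[[v]] <- factor(x, levels = inf$levels)
      } else {
        df[[v]] <- (df[[v]] - inf$center) / inf$scale
      }
    }
    attr(df, "std_info") <- info
    df
  }
}

design_matrix <- function(covnames, data, n) {
  if (length(covnames) == 0)
    return(matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(Intercept)")))
  missing <- setdiff(covnames, names(data))
  if (length(missing) > 0)
    stop("covariate(s) not found: ", paste(missing, collapse = ", "))
  stats::model.matrix(stats::reformulate(covnames), data = data)
}

# Assemble the numerical pieces of the likelihood: psi design matrix (one row
# per site), p design matrix (one row per observed visit), the detection
# vector and a site index for each visit. Covariates are standardised here.
build_model_frames <- function(history, site_covs, survey_covs, spec,
                               std_info = NULL) {
  validate_history(history)
  m <- history$matrix
  S <- nrow(m); K <- ncol(m)
  obs <- !is.na(t(m))                      # site-major, occasion-minor
  y <- as.integer(t(m))[as.vector(obs)]
  site_of_visit <- rep(seq_len(S), each = K)[as.vector(obs)]

  site_df <- NULL
  if (!is.null(site_covs)) {
    site_df <- validate_site_covs(site_covs, history)
    site_df <- site_df[, setdiff(names(site_df), "site"), drop = FALSE]
  }
  needed_p <- spec$p
  p_long <- NULL
  if (length(needed_p) > 0) {
    cols <- list()
    survey_df <- NULL
    if (!is.null(survey_covs)) {
      survey_df <- validate_survey_covs(survey_covs, history)
    }
    for (v in needed_p) {
      if (!is.null(survey_df) && v %in% names(survey_df)) {
        cols[[v]] <- survey_df[[v]][as.vector(obs)]
      } else if (!is.null(site_df) && v %in% names(site_df)) {
        cols[[v]] <- rep(site_df[[v]], each = K)[as.vector(obs)]
      } else {
        stop("detection covariate '", v, "' not found in survey or site covariates")
      }
    }
    p_long <- as.data.frame(cols, stringsAsFactors = FALSE)
  }

  psi_df <- if (length(spec$psi) > 0) {
    if (is.null(site_df)) stop("psi covariates requested but no site covariates supplied")
    site_df[, spec$psi, drop = FALSE]
  } else NULL

  if (is.null(std_info)) {
    std <- list(psi = NULL, p = NULL)
    if (!is.null(psi_df)) { psi_df <- standardize_frame(psi_df); std$psi <- attr(psi_df, "std_info") }
    if (!is.null(p_long)) { p_long <- standardize_frame(p_long); std$p <- attr(p_long, "std_info") }
  } else {
    std <- std_info
    if (!is.null(psi_df)) psi_df <- standardize_frame(psi_df, std$psi)
    if (!is.null(p_long)) p_long <- standardize_frame(p_long, std$p)
  }

  X_psi <- design_matrix(spec$psi, psi_df, S)
  X_p <- design_matrix(spec$p, p_long, length(y))
  list(X_psi = X_psi, X_p = X_p, y = y, site_of_visit = site_of_visit,
       n_sites = S, n_visits = length(y), std_info = std,
       detected = as.vector(rowsum(y, site_of_visit) > 0))
}

#' Single-season occupancy log-likelihood
#'
#' Zero-inflated binomial likelihood of MacKenzie-type single-season occupancy
#' models. A site with at least one detection contributes
#' `psi_i * prod_t p_it^y (1-p_it)^(1-y)`; a site never detected contributes
#' `psi_i * prod_t (1-p_it) + (1-psi_i)` (either occupied-but-missed or truly
#' unoccupied). Products run over observed visits only; missing visits drop
#' out (occasion-wise deletion). Assumes closure within the season and no
#' false positives.
#'
#' @param beta_psi,beta_p Coefficient vectors on the logit scale
#'   (intercept first), conformable with the design matrices implied by
#'   `spec` after centring/scaling of continuous covariates.
#' @param history A `detection_history`.
#' @param site_covs,survey_covs Covariate tables (may be `NULL` for constant
#'   models).
#' @param spec An [occu_spec()].
#' @return The log-likelihood (scalar).
#' @examples
#' h <- detection_history(rbind(c(1L)))
#' occupancy_loglik(qlogis(0.5), qlogis(0.5), h, spec = occu_spec()) # log(0.25)
#' @export
occupancy_loglik <- function(beta_psi, beta_p, history, site_covs = NULL,
                             survey_covs = NULL, spec = occu_spec()) {
  fr <- build_model_frames(history, site_covs, survey_covs, spec)
  if (length(beta_psi) != ncol(fr$X_psi) || length(beta_p) != ncol(fr$X_p))
    stop("coefficient length does not match design matrix")
  if (!all(is.finite(fr$X_psi)) || !all(is.finite(fr$X_p)))
    stop("non-finite covariate value")
  .loglik_frames(c(beta_psi, beta_p), fr)
}

.loglik_frames <- function(theta, fr) {
  k1 <- ncol(fr$X_psi)
  eta_psi <- drop(fr$X_psi %*% theta[seq_len(k1)])
  eta_p <- drop(fr$X_p %*% theta[-seq_len(k1)])
  psi <- stats::plogis(eta_psi)
  lp <- stats::plogis(eta_p, log.p = TRUE)           # log p
  lq <- stats::plogis(-eta_p, log.p = TRUE)          # log (1-p)
  ll_visit <- fr$y * lp + (1 - fr$y) * lq
  ll_det <- drop(rowsum(ll_visit, fr$site_of_visit))
  det <- fr$detected
  out <- numeric(fr$n_sites)
  out[det] <- log(psi[det]) + ll_det[det]
  out[!det] <- log(psi[!det] * exp(ll_det[!det]) + (1 - psi[!det]))
  sum(out)
}

.grad_frames <- function(theta, fr) {
  k1 <- ncol(fr$X_psi)
  eta_psi <- drop(fr$X_psi %*% theta[seq_len(k1)])
  eta_p <- drop(fr$X_p %*% theta[-seq_len(k1)])
  psi <- stats::plogis(eta_psi)
  p <- stats::plogis(eta_p)
  lq <- stats::plogis(-eta_p, log.p = TRUE)
  ll_visit <- fr$y * stats::plogis(eta_p, log.p = TRUE) + (1 - fr$y) * lq
  ll_det <- drop(rowsum(ll_visit, fr$site_of_visit))
  det <- fr$detected
  q_site <- exp(ll_det)                               # prod (1-p) for non-detected
  D <- psi * q_site + (1 - psi)
  # d loglik / d eta_psi per site
  g_psi <- ifelse(det, 1 - psi, psi * (1 - psi) * (q_site - 1) / D)
  # d loglik / d eta_p per visit
  site_factor <- ifelse(det, NA_real_, (psi * q_site / D))
  g_p <- ifelse(det[fr$site_of_visit],
                fr$y - p,
                -p * site_factor[fr$site_of_visit])
  c(drop(crossprod(fr$X_psi, g_psi)), drop(crossprod(fr$X_p, g_p)))
}

#' Fit a single-season occupancy model by maximum likelihood
#'
#' Maximises [occupancy_loglik()] over the logit-scale coefficients with a
#' multi-start quasi-Newton optimiser (BFGS with analytic gradients; the
#' first start comes from naive occupancy and detection rates, the rest are
#' seeded perturbations, guarding against local optima near the boundary).
#' Standard errors come from the inverse observed information at the optimum.
#'
#' @param history A `detection_history`.
#' @param site_covs,survey_covs Covariate tables, or `NULL`.
#' @param spec An [occu_spec()].
#' @param n_starts Number of optimiser starts (default 5).
#' @param seed Integer seed for the start perturbations.
#' @return An `occupancy_fit`: coefficients (`beta_psi`, `beta_p`), `loglik`,
#'   `aic` (2k - 2 loglik), `se`, `vcov`, `converged`, `boundary`, `n_sites`,
#'   `n_params`, the spec and standardisation info needed by
#'   [predict_parameters()].
#' @details With zero detections overall the likelihood is maximised on the
#'   boundary (psi or p driven to 0); such fits are returned with
#'   `converged = FALSE`, `boundary = TRUE`, probability estimates clamped to
#'   `1e-6`, and no trustworthy standard errors.
#' @export
fit_occupancy <- function(history, site_covs = NULL, survey_covs = NULL,
                          spec = occu_spec(), n_starts = 5, seed = 1) {
  fr <- build_model_frames(history, site_covs, survey_covs, spec)
  if (fr$n_sites < 2) stop("need at least 2 sites")
  k1 <- ncol(fr$X_psi); k2 <- ncol(fr$X_p)
  k <- k1 + k2
  clamp <- function(x, lo = 1e-6) pmin(pmax(x, lo), 1 - lo)

  nav <- mean(fr$detected)
  det_rate <- if (sum(fr$y) > 0) {
    keep <- fr$detected[fr$site_of_visit]
    mean(fr$y[keep])
  } else 0
  start0 <- c(stats::qlogis(clamp(nav, 0.02)), rep(0, k1 - 1),
              stats::qlogis(clamp(det_rate, 0.02)), rep(0, k2 - 1))

  nll <- function(th) -.loglik_frames(th, fr)
  gnll <- function(th) -.grad_frames(th, fr)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))

  best <- NULL
  for (s in seq_len(max(1, n_starts))) {
    th0 <- if (s == 1) start0 else start0 + stats::rnorm(k, sd = 0.75)
    opt <- tryCatch(
      stats::optim(th0, nll, gnll, method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimiser starts failed")

  theta <- best$par
  # Newton polish toward a small gradient norm
  for (it in 1:10) {
    g <- gnll(theta)
    if (sqrt(sum(g^2)) < 1e-8) break
    H <- tryCatch(stats::optimHess(theta, nll, gnll), error = function(e) NULL)
    if (is.null(H)) break
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cand <- theta - step
    if (nll(cand) <= nll(theta) + 1e-10) theta <- cand else break
  }

  eta_psi <- drop(fr$X_psi %*% theta[seq_len(k1)])
  eta_p <- drop(fr$X_p %*% theta[-seq_len(k1)])
  psi_hat <- stats::plogis(eta_psi); p_hat <- stats::plogis(eta_p)
  boundary <- any(psi_hat < 1e-6 | psi_hat > 1 - 1e-6) ||
              any(p_hat < 1e-6 | p_hat > 1 - 1e-6) || sum(fr$y) == 0

  H <- tryCatch(stats::optimHess(theta, nll, gnll), error = function(e) NULL)
  V <- NULL; se <- rep(NA_real_, k)
  hess_pd <- FALSE
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(V)) && all(diag(V) > 0)) {
      se <- sqrt(diag(V)); hess_pd <- TRUE
    }
  }
  gnorm <- sqrt(sum(gnll(theta)^2))
  converged <- best$convergence == 0 && hess_pd && !boundary &&
               gnorm < 1e-4 * max(1, abs(best$value))

  ll <- -nll(theta)
  fit <- structure(list(
    beta_psi = stats::setNames(theta[seq_len(k1)], colnames(fr$X_psi)),
    beta_p = stats::setNames(theta[-seq_len(k1)], colnames(fr$X_p)),
    loglik = ll, aic = 2 * k - 2 * ll,
    se = se, vcov = V,
    converged = converged, boundary = boundary, grad_norm = gnorm,
    n_sites = fr$n_sites, n_params = k,
    spec = spec, std_info = fr$std_info
  ), class = "occupancy_fit")
  fit
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat(sprintf("Occupancy fit %s: loglik = %.4f, AIC = %.4f, k = %d, sites = %d\n",
              format(x$spec), x$loglik, x$aic, x$n_params, x$n_sites))
  if (!x$converged) cat("  WARNING: not converged",
                        if (x$boundary) "(boundary fit)" else "", "\n")
  co <- c(x$beta_psi, x$beta_p)
  nm <- c(paste0("psi:", names(x$beta_psi)), paste0("p:", names(x$beta_p)))
  print(data.frame(term = nm, estimate = unname(co), se = x$se,
                   row.names = NULL))
  invisible(x)
}

#' Predicted occupancy and detection probabilities with confidence intervals
#'
#' Per-site psi-hat and per-visit p-hat on the probability scale. 95%
#' confidence intervals are delta-method intervals computed on the logit
#' scale and back-transformed, so they always lie inside (0, 1).
#'
#' @param fit A converged `occupancy_fit`.
#' @param history The `detection_history` to predict for.
#' @param site_covs,survey_covs Covariate tables (standardised internally with
#'   the training centring/scaling; unseen factor levels are an error).
#' @param level Confidence level (default 0.95).
#' @return A list with data.frames `psi` (site, estimate, se, lower, upper)
#'   and `p` (site, occ, estimate, se, lower, upper; observed visits only).
#' @export
predict_parameters <- function(fit, history, site_covs = NULL,
                               survey_covs = NULL, level = 0.95) {
  stopifnot(inherits(fit, "occupancy_fit"))
  if (!fit$converged)
    warning("predicting from a non-converged fit; intervals are unreliable")
  fr <- build_model_frames(history, site_covs, survey_covs, fit$spec,
                           std_info = fit$std_info)
  k1 <- length(fit$beta_psi)
  z <- stats::qnorm(1 - (1 - level) / 2)
  V <- fit$vcov
  if (is.null(V)) stop("fit has no covariance matrix; cannot form intervals")
  pred_block <- function(X, beta, Vsub) {
    eta <- drop(X %*% beta)
    se_eta <- sqrt(pmax(rowSums((X %*% Vsub) * X), 0))
    data.frame(estimate = stats::plogis(eta),
               se = se_eta * stats::dlogis(eta),   # delta method, prob scale
               lower = stats::plogis(eta - z * se_eta),
               upper = stats::plogis(eta + z * se_eta))
  }
  psi <- cbind(site = history$site_ids,
               pred_block(fr$X_psi, fit$beta_psi, V[seq_len(k1), seq_len(k1), drop = FALSE]))
  obs <- !is.na(t(history$matrix))
  occ_of_visit <- rep(history$occasion_labels, times = nrow(history$matrix))[as.vector(obs)]
  p <- cbind(site = history$site_ids[fr$site_of_visit], occ = occ_of_visit,
             pred_block(fr$X_p, fit$beta_p, V[-seq_len(k1), -seq_len(k1), drop = FALSE]))
  list(psi = psi, p = p)
}

#' AIC model-selection table with Akaike weights
#'
#' Ranks candidate fits by AIC; reports delta AIC relative to the best model
#' and Akaike weights `exp(-delta/2) / sum exp(-delta/2)` (the probability of
#' being the best model in the set). Models within delta AIC < 2 of the best
#' are conventionally considered to have strong support. Ties are broken by
#' fewer parameters, then model name.
#'
#' @param fits List of `occupancy_fit` objects fitted to the same data.
#' @param names Optional model names; defaults to `format()` of each spec.
#' @return A data.frame (class `model_selection_table`) with columns
#'   `model`, `k`, `loglik`, `aic`, `delta_aic`, `weight`, sorted by AIC.
#' @export
build_selection_table <- function(fits, names = NULL) {
  if (length(fits) == 0) stop("empty model list")
  stopifnot(all(vapply(fits, inherits, TRUE, "occupancy_fit")))
  ns <- vapply(fits, `[[`, 0L, "n_sites")
  if (length(unique(ns)) != 1) stop("fits are not on identical data (site counts differ)")
  if (is.null(names)) names <- vapply(fits, function(f) format(f$spec), "")
  aic <- vapply(fits, `[[`, 0, "aic")
  k <- vapply(fits, `[[`, 0L, "n_params")
  ord <- order(aic, k, names)
  tab <- data.frame(model = names[ord], k = k[ord],
                    loglik = vapply(fits, `[[`, 0, "loglik")[ord],
                    aic = aic[ord], row.names = NULL)
  tab$delta_aic <- tab$aic - tab$aic[1]
  w <- exp(-tab$delta_aic / 2)
  tab$weight <- w / sum(w)
  attr(tab, "fits") <- fits[ord]
  class(tab) <- c("model_selection_table", "data.frame")
  tab
}

#' Correlation screen for candidate covariates
#'
#' Drops the later-listed member of any pair of numeric covariates with
#' absolute Pearson correlation above the threshold (conventionally 0.7), so
#' that near-collinear candidates never enter the same model set. Categorical
#' covariates are not screened.
#'
#' @param data Data.frame holding the candidate columns.
#' @param candidates Character vector of candidate covariate names, in
#'   priority order.
#' @param threshold Absolute-correlation cutoff (default 0.7).
#' @return List with `kept` (names surviving), `dropped` (data.frame of
#'   dropped name, partner, r).
#' @export
screen_covariates <- function(data, candidates, threshold = 0.7) {
  kept <- character(0)
  dropped <- data.frame(dropped = character(0), against = character(0),
                        r = numeric(0))
  for (v in candidates) {
    if (!v %in% names(data)) stop("candidate covariate '", v, "' not in data")
    x <- data[[v]]
    if (!is.numeric(x)) { kept <- c(kept, v); next }
    clash <- FALSE
    for (u in kept) {
      y <- data[[u]]
      if (!is.numeric(y)) next
      r <- suppressWarnings(stats::cor(x, y, use = "complete.obs"))
      if (is.finite(r) && abs(r) > threshold) {
        dropped <- rbind(dropped, data.frame(dropped = v, against = u, r = r))
        clash <- TRUE
        break
      }
    }
    if (!clash) kept <- c(kept, v)
  }
  list(kept = kept, dropped = dropped)
}

#' Two-stage stepwise occupancy model selection
#'
#' Mirrors the standard design for sparse monitoring data: detection first,
#' occupancy second. Stage 1 fits a constant-psi model for each single
#' detection covariate plus the fully constant model and ranks them by AIC;
#' the p-structures within `delta_retain` (default 2) of the best are kept.
#' Stage 2 crosses every retained p-structure with each single occupancy
#' covariate and the constant psi, and returns the stage-2 selection table
#' plus the AIC-best fit. Candidates failing the correlation screen are
#' dropped up front; non-convergent fits are excluded from ranking and
#' reported, never silently ranked.
#'
#' @param history A `detection_history`.
#' @param site_covs,survey_covs Covariate tables.
#' @param p_candidates,psi_candidates Character vectors of candidate covariate
#'   names for detection and occupancy.
#' @param delta_retain Stage-1 retention threshold on delta AIC (default 2).
#' @param n_starts,seed Passed to [fit_occupancy()].
#' @return List with `table` (stage-2 `model_selection_table`), `best_fit`,
#'   `stage1` (stage-1 table), `screened_out`, `failed` (model names that did
#'   not converge).
#' @export
stepwise_select <- function(history, site_covs = NULL, survey_covs = NULL,
                            p_candidates = character(0),
                            psi_candidates = character(0),
                            delta_retain = 2, n_starts = 5, seed = 1) {
  # correlation screens, per covariate table
  screened <- data.frame()
  if (length(psi_candidates) > 0) {
    sc <- screen_covariates(site_covs, psi_candidates)
    psi_candidates <- sc$kept
    if (nrow(sc$dropped) > 0) screened <- rbind(screened, cbind(stage = "psi", sc$dropped))
  }
  if (length(p_candidates) > 0) {
    K <- ncol(history$matrix)
    src <- lapply(p_candidates, function(v) {
      if (!is.null(survey_covs) && v %in% names(survey_covs)) {
        validate_survey_covs(survey_covs, history)[[v]]
      } else if (!is.null(site_covs) && v %in% names(site_covs)) {
        rep(validate_site_covs(site_covs, history)[[v]], each = K)
      } else stop("candidate covariate '", v, "' not in data")
    })
    names(src) <- p_candidates
    sc <- screen_covariates(as.data.frame(src, stringsAsFactors = FALSE),
                            p_candidates)
    p_candidates <- sc$kept
    if (nrow(sc$dropped) > 0) screened <- rbind(screened, cbind(stage = "p", sc$dropped))
  }

  failed <- character(0)
  try_fit <- function(spec) {
    f <- tryCatch(fit_occupancy(history, site_covs, survey_covs, spec,
                                n_starts = n_starts, seed = seed),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) {
      failed <<- c(failed, format(spec)); return(NULL)
    }
    f
  }

  # Stage 1: detection structures, constant occupancy
  p_structs <- c(list(character(0)), lapply(p_candidates, identity))
  s1_fits <- Filter(Negate(is.null),
                    lapply(p_structs, function(pc) try_fit(occu_spec(p = pc))))
  if (length(s1_fits) == 0) stop("no stage-1 model converged")
  s1 <- build_selection_table(s1_fits)
  retained <- lapply(attr(s1, "fits")[s1$delta_aic < delta_retain],
                     function(f) f$spec$p)

  # Stage 2: retained p-structures x occupancy structures
  psi_structs <- c(list(character(0)), lapply(psi_candidates, identity))
  combos <- expand.grid(p = seq_along(retained), psi = seq_along(psi_structs))
  s2_fits <- list(); seen <- character(0)
  for (i in seq_len(nrow(combos))) {
    spec <- occu_spec(psi = psi_structs[[combos$psi[i]]], p = retained[[combos$p[i]]])
    id <- format(spec)
    if (id %in% seen) next
    seen <- c(seen, id)
    f <- if (id %in% vapply(s1_fits, function(x) format(x$spec), "")) {
      s1_fits[[which(vapply(s1_fits, function(x) format(x$spec), "") == id)]]
    } else try_fit(spec)
    if (!is.null(f)) s2_fits <- c(s2_fits, list(f))
  }
  if (length(s2_fits) == 0) stop("no stage-2 model converged")
  tab <- build_selection_table(s2_fits)
  list(table = tab, best_fit = attr(tab, "fits")[[1]], stage1 = s1,
       screened_out = screened, failed = unique(failed))
}
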