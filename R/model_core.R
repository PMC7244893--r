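#' Canonical parameter order
#'
#' All parameter vectors in the package use this fixed order:
#' `alpha2` (first-year occurrence intercept), `alpha0` (colonization logit),
#' `alpha1` (persistence increment), `alphaS`, `alphaE`, `alphaE2`, `alphaB`
#' (snare, elevation, elevation-squared and ban effects on occurrence),
#' `beta0` (detection intercept), `betaB` (border effect on detection).
#' @export
param_names <- function() {
  c("alpha2", "alpha0", "alpha1", "alphaS", "alphaE", "alphaE2", "alphaB",
    "beta0", "betaB")
}

#' Construct a parameter vector
#'
#' A named numeric vector in the canonical order (see [param_names()]), all
#' entries on the logit scale. Parameters excluded by the model specification
#' (snare and/or ban effects) are structurally fixed at 0.
#'
#' @param alpha2 first-year occurrence intercept.
#' @param alpha0 colonization logit: `plogis(alpha0)` is the probability an
#'   unoccupied site becomes occupied the next year.
#' @param alpha1 persistence increment: `plogis(alpha0 + alpha1)` is the
#'   probability an occupied site stays occupied.
#' @param alphaS,alphaE,alphaE2,alphaB covariate effects on occurrence
#'   (snares, elevation, elevation squared, ban).
#' @param beta0 detection intercept; `betaB` border effect on detection.
#' @param betaB see above.
#' @param spec optional [model_spec()]; excluded terms are forced to 0.
#' @return Named numeric vector of length 9.
#' @export
param_vector <- function(alpha2 = 0, alpha0 = 0, alpha1 = 0, alphaS = 0,
                         alphaE = 0, alphaE2 = 0, alphaB = 0, beta0 = 0,
                         betaB = 0, spec = NULL) {
  p <- c(alpha2 = alpha2, alpha0 = alpha0, alpha1 = alpha1, alphaS = alphaS,
         alphaE = alphaE, alphaE2 = alphaE2, alphaB = alphaB, beta0 = beta0,
         betaB = betaB)
  if (!all(is.finite(p))) stop("parameters must be finite", call. = FALSE)
  if (!is.null(spec)) {
    if (!spec$include_snares) p["alphaS"] <- 0
    if (!spec$include_ban) p["alphaB"] <- 0
  }
  p
}

#' Names of the free (estimated) parameters under a model spec
#' @param spec a [model_spec()].
#' @return Character vector, subset of [param_names()].
#' @export
free_params <- function(spec) {
  nm <- param_names()
  if (!spec$include_snares) nm <- setdiff(nm, "alphaS")
  if (!spec$include_ban) nm <- setdiff(nm, "alphaB")
  nm
}

#' Numerically stable inverse logit
#'
#' `1 / (1 + exp(-x))`, computed so that extreme arguments neither overflow
#' nor underflow to an exact 0 or 1 before |x| of several hundred.
#'
#' @param x real number(s) on the logit scale.
#' @return Probability in (0, 1); the lower tail switches to `exp(x)` below
#'   x = -30 so it reaches the subnormal range instead of rounding to 0.
#' @export
inv_logit <- function(x) {
  out <- stats::plogis(x)
  low <- x < -30
  if (any(low)) out[low] <- exp(x[low])
  out
}

#' Logit transform
#' @param p probability in (0, 1).
#' @return `log(p / (1 - p))`.
#' @export
logit <- function(p) stats::qlogis(p)

#' First-year occurrence probability
#'
#' `logit(psi[i,1]) = alpha2 + alphaS*SNARES[i,1] + alphaE*ELEV[i] +
#' alphaE2*ELEV2[i]` (plus `alphaB*BAN[1]` only when the model spec opts in;
#' by default the ban term is absent from the first year).
#'
#' @param p parameter vector (canonical order).
#' @param snares_std,elev_std,elev2_std standardized covariate values for the
#'   site (first-year snare count; elevation; squared standardized elevation).
#' @param ban first-year ban indicator (used only with
#'   `first_year_includes_ban`).
#' @param spec a [model_spec()].
#' @return Occupancy probability, strictly in (0, 1).
#' @export
occ_prob_first_year <- function(p, snares_std = 0, elev_std = 0,
                                elev2_std = 0, ban = 0, spec = model_spec()) {
  eta <- p["alpha2"] + p["alphaS"] * snares_std + p["alphaE"] * elev_std +
    p["alphaE2"] * elev2_std
  if (spec$first_year_includes_ban) eta <- eta + p["alphaB"] * ban
  unname(inv_logit(eta))
}

#' Autologistic occurrence probability (years 2..K)
#'
#' `logit(psi[i,k]) = alpha0 + alpha1*z[i,k-1] + alphaS*SNARES[i,k] +
#' alphaE*ELEV[i] + alphaE2*ELEV2[i] + alphaB*BAN[k]`. With all covariates at
#' zero this is the colonization probability when `z_prev = 0` and the
#' persistence probability when `z_prev = 1`.
#'
#' @param p parameter vector.
#' @param z_prev previous-year occupancy state (0 or 1).
#' @param snares_std,elev_std,elev2_std,ban standardized covariates for the
#'   site-year (ban is the raw 0/1 indicator).
#' @return Transition probability into occupancy, strictly in (0, 1).
#' @export
occ_prob <- function(p, z_prev, snares_std = 0, elev_std = 0, elev2_std = 0,
                     ban = 0) {
  eta <- p["alpha0"] + p["alpha1"] * z_prev + p["alphaS"] * snares_std +
    p["alphaE"] * elev_std + p["alphaE2"] * elev2_std + p["alphaB"] * ban
  unname(inv_logit(eta))
}

#' Per-occasion detection probability
#'
#' `logit(p[i]) = beta0 + betaB*BORDER[i]`: constant across occasions and
#' years for a given site.
#'
#' @param p parameter vector.
#' @param border_std standardized distance to the park border.
#' @return Detection probability, strictly in (0, 1).
#' @export
det_prob <- function(p, border_std = 0) {
  unname(inv_logit(p["beta0"] + p["betaB"] * border_std))
}

# ---------------------------------------------------------------------------
# Likelihood internals.
#
# Because detection probability is constant within a site, the per-year
# emission depends on the detection history only through (d, J): the number of
# detection-positive sampled occasions and the number of sampled occasions.
# build_design() precomputes those counts and the covariate matrices once so
# repeated likelihood evaluations (MCMC, optimization) are cheap.

build_design <- function(sd, cv, spec) {
  det <- apply(sd$y == 1, c(1, 3), sum, na.rm = TRUE)     # d, sites x years
  eff <- apply(!is.na(sd$y), c(1, 3), sum)                # J, sites x years
  list(d = det, J = eff,
       snares = cv$snares_std, elev = cv$elev_std, elev2 = cv$elev2_std,
       border = cv$border_std, ban = cv$ban,
       n_sites = sd$n_sites, n_years = sd$n_years, spec = spec)
}

# Forward recursion over the two-state latent chain, vectorized over sites.
# Returns the per-site log-likelihood vector. Years with zero effort
# contribute emission 1 for both states but still advance the chain, so the
# "previous year" semantics of the autologistic term are preserved.
forward_loglik <- function(p, ds) {
  spec <- ds$spec
  n <- ds$n_sites; K <- ds$n_years
  pdet <- inv_logit(p["beta0"] + p["betaB"] * ds$border)   # length n
  # emission per site-year: P(history | z = 1) and P(history | z = 0)
  em1 <- pdet^ds$d * (1 - pdet)^(ds$J - ds$d)
  em0 <- (ds$d == 0) * 1
  eta1 <- p["alpha2"] + p["alphaS"] * ds$snares[, 1] +
    p["alphaE"] * ds$elev + p["alphaE2"] * ds$elev2
  if (spec$first_year_includes_ban) eta1 <- eta1 + p["alphaB"] * ds$ban[1]
  psi1 <- inv_logit(eta1)

  a1 <- psi1 * em1[, 1]
  a0 <- (1 - psi1) * em0[, 1]
  ll <- numeric(n)
  if (K >= 2) for (k in 2:K) {
    s <- a0 + a1
    ll <- ll + log(s)
    a0 <- a0 / s; a1 <- a1 / s
    eta <- p["alpha0"] + p["alphaS"] * ds$snares[, k] +
      p["alphaE"] * ds$elev + p["alphaE2"] * ds$elev2 +
      p["alphaB"] * ds$ban[k]
    g <- inv_logit(eta)               # colonization given z_prev = 0
    phi <- inv_logit(eta + p["alpha1"])  # persistence given z_prev = 1
    a1n <- (a0 * g + a1 * phi) * em1[, k]
    a0n <- (a0 * (1 - g) + a1 * (1 - phi)) * em0[, k]
    a0 <- a0n; a1 <- a1n
  }
  ll + log(a0 + a1)
}

#' Marginal log-likelihood of one site's detection history
#'
#' Computes `log P(y_site | p)` by exact two-state forward recursion over the
#' latent occupancy chain: the initial mass is `(psi[i,1], 1 - psi[i,1])`, the
#' per-year emission is the product of Bernoulli detection terms over sampled
#' occasions (missing occasions contribute factor 1), and transitions follow
#' the autologistic occurrence model. Years with zero effort use emission 1
#' for both states but still advance the chain.
#'
#' @param p parameter vector (canonical order, see [param_vector()]).
#' @param y_site occasions x years matrix of 0/1/`NA` outcomes.
#' @param snares_std numeric vector of length `n_years` (standardized snare
#'   counts at this site).
#' @param elev_std,elev2_std,border_std scalars: the site's standardized
#'   covariates.
#' @param ban 0/1 vector of length `n_years`.
#' @param spec a [model_spec()].
#' @return The log-likelihood (a scalar). An all-missing site returns 0 with
#'   a warning.
#' @export
site_loglik <- function(p, y_site, snares_std = NULL, elev_std = 0,
                        elev2_std = elev_std^2, border_std = 0, ban = NULL,
                        spec = model_spec()) {
  y_site <- as.matrix(y_site)
  K <- ncol(y_site)
  if (is.null(snares_std)) snares_std <- rep(0, K)
  if (is.null(ban)) ban <- rep(0L, K)
  if (all(is.na(y_site)))
    warning("site has no sampled occasion in any year; log-likelihood is 0",
            call. = FALSE)
  ds <- list(
    d = matrix(colSums(y_site == 1, na.rm = TRUE), 1),
    J = matrix(colSums(!is.na(y_site)), 1),
    snares = matrix(snares_std, 1), elev = elev_std, elev2 = elev2_std,
    border = border_std, ban = ban, n_sites = 1L, n_years = K, spec = spec)
  as.numeric(forward_loglik(p, ds))
}

#' Total marginal log-likelihood of a survey
#'
#' Sum of [site_loglik()] over sites, computed with a vectorized forward
#' recursion.
#'
#' @param p parameter vector.
#' @param sd a [survey_data()] object.
#' @param cv a [covariate_set()] object.
#' @param spec a [model_spec()].
#' @return Scalar log-likelihood; finite for finite parameters.
#' @export
total_loglik <- function(p, sd, cv, spec = model_spec()) {
  issues <- validate_inputs(sd, cv, spec)
  if (any(issues$severity == "fatal"))
    stop("invalid inputs:\n  ",
         paste(issues$message[issues$severity == "fatal"], collapse = "\n  "),
         call. = FALSE)
  p <- do.call(param_vector, c(as.list(unname(p[param_names()])),
                               list(spec = spec)))
  sum(forward_loglik(p, build_design(sd, cv, spec)))
}
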