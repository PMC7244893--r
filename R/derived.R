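bci <- function(x) unname(stats::quantile(x, c(0.025, 0.975)))

#' Colonization and persistence summaries
#'
#' Under the autologistic parameterization, `plogis(alpha0)` is the
#' colonization probability (an unoccupied site becomes occupied the next
#' year) and `plogis(alpha0 + alpha1)` the persistence probability (an
#' occupied site stays occupied). Each retained draw is transformed, then
#' summarized by the posterior mean and equal-tailed 95% credible interval.
#' `distinct` flags the convention used to mark a clear colonization /
#' persistence difference: the two 95% intervals do not overlap.
#'
#' @param chains a `posterior_chains` object.
#' @return List with `colonization` and `persistence` (each `mean`, `lower`,
#'   `upper`) and logical `distinct`.
#' @export
colonization_persistence <- function(chains) {
  dr <- pooled_draws(chains)
  if (!all(c("alpha0", "alpha1") %in% colnames(dr)))
    stop("chains do not contain alpha0 and alpha1", call. = FALSE)
  gam <- inv_logit(dr[, "alpha0"])
  phi <- inv_logit(dr[, "alpha0"] + dr[, "alpha1"])
  ci_g <- bci(gam); ci_p <- bci(phi)
  list(
    colonization = list(mean = mean(gam), lower = ci_g[1], upper = ci_g[2]),
    persistence = list(mean = mean(phi), lower = ci_p[1], upper = ci_p[2]),
    distinct = ci_g[2] < ci_p[1] || ci_p[2] < ci_g[1])
}

#' Posterior summary and significance flag for one effect
#'
#' An effect is called "significant" when its 95% equal-tailed credible
#' interval excludes zero.
#'
#' @param chains a `posterior_chains` object.
#' @param param parameter name (e.g. `"alphaS"`).
#' @return List with `mean`, `lower`, `upper` (logit scale) and logical
#'   `significant`.
#' @export
effect_significance <- function(chains, param) {
  dr <- pooled_draws(chains)
  if (!param %in% colnames(dr))
    stop("unknown parameter: ", param, call. = FALSE)
  x <- dr[, param]
  ci <- bci(x)
  list(mean = mean(x), lower = ci[1], upper = ci[2],
       significant = ci[1] > 0 || ci[2] < 0)
}

# Forward-filtering backward-sampling of the latent occupancy states for all
# sites at one parameter draw. Returns either a sampled z matrix
# (sites x years) or the smoothed marginal P(z = 1 | y) matrix.
ffbs_draw <- function(p, ds, sample = TRUE) {
  spec <- ds$spec
  n <- ds$n_sites; K <- ds$n_years
  pdet <- inv_logit(p["beta0"] + p["betaB"] * ds$border)
  em1 <- pdet^ds$d * (1 - pdet)^(ds$J - ds$d)
  em0 <- (ds$d == 0) * 1
  eta1 <- p["alpha2"] + p["alphaS"] * ds$snares[, 1] +
    p["alphaE"] * ds$elev + p["alphaE2"] * ds$elev2
  if (spec$first_year_includes_ban) eta1 <- eta1 + p["alphaB"] * ds$ban[1]
  psi1 <- inv_logit(eta1)

  A1 <- matrix(0, n, K); A0 <- matrix(0, n, K)   # filtered (normalized)
  G <- matrix(0, n, K); PHI <- matrix(0, n, K)   # transition probs into k
  a1 <- psi1 * em1[, 1]; a0 <- (1 - psi1) * em0[, 1]
  s <- a0 + a1
  A1[, 1] <- a1 / s; A0[, 1] <- a0 / s
  if (K >= 2) for (k in 2:K) {
    eta <- p["alpha0"] + p["alphaS"] * ds$snares[, k] +
      p["alphaE"] * ds$elev + p["alphaE2"] * ds$elev2 +
      p["alphaB"] * ds$ban[k]
    g <- inv_logit(eta); phi <- inv_logit(eta + p["alpha1"])
    G[, k] <- g; PHI[, k] <- phi
    a1 <- (A0[, k - 1] * g + A1[, k - 1] * phi) * em1[, k]
    a0 <- (A0[, k - 1] * (1 - g) + A1[, k - 1] * (1 - phi)) * em0[, k]
    s <- a0 + a1
    A1[, k] <- a1 / s; A0[, k] <- a0 / s
  }

  if (sample) {
    z <- matrix(0L, n, K)
    z[, K] <- stats::rbinom(n, 1, A1[, K])
    if (K >= 2) for (k in (K - 1):1) {
      tr1 <- ifelse(z[, k + 1] == 1, PHI[, k + 1], 1 - PHI[, k + 1])
      tr0 <- ifelse(z[, k + 1] == 1, G[, k + 1], 1 - G[, k + 1])
      w1 <- A1[, k] * tr1
      w0 <- A0[, k] * tr0
      z[, k] <- stats::rbinom(n, 1, w1 / (w1 + w0))
    }
    z
  } else {
    # backward smoothing: P(z_k = 1 | all data)
    Z <- matrix(0, n, K)
    Z[, K] <- A1[, K]
    if (K >= 2) for (k in (K - 1):1) {
      # split the smoothed mass at k+1 back over states at k
      p11 <- A1[, k] * PHI[, k + 1]
      p01 <- A0[, k] * G[, k + 1]
      p10 <- A1[, k] * (1 - PHI[, k + 1])
      p00 <- A0[, k] * (1 - G[, k + 1])
      Z[, k] <- Z[, k + 1] * p11 / (p11 + p01) +
        (1 - Z[, k + 1]) * p10 / (p10 + p00)
    }
    Z
  }
}

#' Yearly mean occupancy
#'
#' For each retained posterior draw, samples the latent occupancy states of
#' every site conditionally on the observed detection histories
#' (forward-filtering backward-sampling along each site's chain) and averages
#' them over the monitored sites, giving the finite-sample mean occupancy
#' `(1/N) * sum_i z[i,k]` per year. The per-year posterior mean and 95%
#' credible interval of that quantity are returned. Sites where a detection
#' occurred in year k have `z[i,k] = 1` with probability one.
#'
#' With `type = "expected"` the smoothed occupancy probabilities
#' `P(z[i,k] = 1 | y)` are averaged instead of sampled states, removing the
#' finite-sample sampling noise.
#'
#' @param chains a `posterior_chains` object from [run_mcmc()].
#' @param type `"finite_sample"` (default) or `"expected"`.
#' @param seed seed for the conditional state sampling.
#' @return Data frame with columns `year`, `mean`, `lower`, `upper`.
#' @export
mean_occupancy_by_year <- function(chains, type = c("finite_sample",
                                                    "expected"), seed = 1) {
  type <- match.arg(type)
  dr <- pooled_draws(chains)
  ds <- chains$design
  full0 <- param_vector(spec = chains$spec)
  set.seed(seed)
  occ <- t(apply(dr, 1, function(theta) {
    full0[chains$param_names] <- theta
    z <- ffbs_draw(full0, ds, sample = type == "finite_sample")
    colMeans(z)
  }))                                      # draws x years
  data.frame(
    year = chains$year_labels,
    mean = colMeans(occ),
    lower = apply(occ, 2, stats::quantile, 0.025),
    upper = apply(occ, 2, stats::quantile, 0.975),
    row.names = NULL)
}

#' Full derived summary
#'
#' Convenience wrapper building the standard report: colonization/persistence,
#' per-covariate effect summaries, and yearly mean occupancy.
#'
#' @param chains a `posterior_chains` object.
#' @param seed seed for the latent-state sampling.
#' @return List with `colonization_persistence`, `effects` (data frame) and
#'   `occupancy_by_year` (data frame).
#' @export
derived_summaries <- function(chains, seed = 1) {
  eff_names <- intersect(c("alphaS", "alphaE", "alphaE2", "alphaB", "betaB"),
                         chains$param_names)
  effs <- do.call(rbind, lapply(eff_names, function(nm) {
    e <- effect_significance(chains, nm)
    data.frame(parameter = nm, mean = e$mean, lower = e$lower,
               upper = e$upper, significant = e$significant)
  }))
  list(colonization_persistence = colonization_persistence(chains),
       effects = effs,
       occupancy_by_year = mean_occupancy_by_year(chains, seed = seed))
}
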