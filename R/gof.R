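# Marginal (chain-implied) occupancy probability per site-year: the forward
# run of the occurrence model without conditioning on data.
marginal_occupancy <- function(p, ds) {
  spec <- ds$spec
  n <- ds$n_sites; K <- ds$n_years
  m <- matrix(0, n, K)
  eta1 <- p["alpha2"] + p["alphaS"] * ds$snares[, 1] +
    p["alphaE"] * ds$elev + p["alphaE2"] * ds$elev2
  if (spec$first_year_includes_ban) eta1 <- eta1 + p["alphaB"] * ds$ban[1]
  m[, 1] <- inv_logit(eta1)
  if (K >= 2) for (k in 2:K) {
    eta <- p["alpha0"] + p["alphaS"] * ds$snares[, k] +
      p["alphaE"] * ds$elev + p["alphaE2"] * ds$elev2 +
      p["alphaB"] * ds$ban[k]
    g <- inv_logit(eta); phi <- inv_logit(eta + p["alpha1"])
    m[, k] <- m[, k - 1] * phi + (1 - m[, k - 1]) * g
  }
  m
}

#' Pearson-type discrepancy statistic
#'
#' The discrepancy aggregates at the site-year level: with `d` the number of
#' detection-positive occasions in a site-year, `J` the number of sampled
#' occasions, `psi` the marginal occupancy probability of the site-year and
#' `p` the site's detection probability, the count `d` is (marginalizing over
#' the latent state) a mixture of `Binomial(J, p)` with weight `psi` and a
#' point mass at zero, so
#' `E[d] = psi * J * p` and
#' `Var[d] = psi * J * p * (1 - p) + psi * (1 - psi) * (J * p)^2`.
#' The statistic is the sum over sampled site-years of
#' `(d - E[d])^2 / (Var[d] + 1e-6)`; the small epsilon guards the division.
#'
#' @param d site x year matrix of detection-positive occasion counts.
#' @param J site x year matrix of sampled occasion counts.
#' @param psi site x year matrix of marginal occupancy probabilities.
#' @param p detection probability per site (vector, recycled over years).
#' @return Scalar discrepancy.
#' @export
discrepancy <- function(d, J, psi, p) {
  mu <- psi * J * p
  v <- psi * J * p * (1 - p) + psi * (1 - psi) * (J * p)^2
  contrib <- (d - mu)^2 / (v + 1e-6)
  sum(contrib[J > 0])
}

#' Posterior-predictive Bayesian p-value
#'
#' For each retained posterior draw, a replicate survey is simulated under
#' the drawn parameters on exactly the observed design (the effort mask —
#' which occasions were sampled — is preserved), and the discrepancy
#' statistic is computed for the observed and the replicated data. The
#' Bayesian p-value is the fraction of draws whose replicated discrepancy
#' exceeds the observed one, with ties counted as one half. Values near 0.5
#' indicate an adequate fit; extreme values (below 0.05 or above 0.95)
#' indicate the model is inadequate.
#'
#' @param chains a `posterior_chains` object from [run_mcmc()].
#' @param seed seed for replicate simulation.
#' @param max_draws cap on the number of draws used (default all).
#' @return Object of class `gof_result`: list with `bayes_p`, `adequate`
#'   (inside the (0.05, 0.95) band), `discrepancy_observed`,
#'   `discrepancy_replicated`, `n_draws_used`.
#' @export
bayes_p <- function(chains, seed = 1, max_draws = Inf) {
  dr <- pooled_draws(chains)
  if (nrow(dr) < 100)
    stop("goodness of fit needs >= 100 retained draws", call. = FALSE)
  if (nrow(dr) > max_draws)
    dr <- dr[seq(1, nrow(dr), length.out = max_draws), , drop = FALSE]
  ds <- chains$design
  full0 <- param_vector(spec = chains$spec)
  n <- ds$n_sites; K <- ds$n_years
  set.seed(seed)
  D_obs <- numeric(nrow(dr)); D_rep <- numeric(nrow(dr))
  for (i in seq_len(nrow(dr))) {
    full0[chains$param_names] <- dr[i, ]
    p <- full0
    pdet <- inv_logit(p["beta0"] + p["betaB"] * ds$border)
    psi <- marginal_occupancy(p, ds)
    D_obs[i] <- discrepancy(ds$d, ds$J, psi, pdet)
    # replicate under the drawn parameters, same effort mask
    z <- matrix(0L, n, K)
    eta1 <- p["alpha2"] + p["alphaS"] * ds$snares[, 1] +
      p["alphaE"] * ds$elev + p["alphaE2"] * ds$elev2
    if (ds$spec$first_year_includes_ban)
      eta1 <- eta1 + p["alphaB"] * ds$ban[1]
    z[, 1] <- stats::rbinom(n, 1, inv_logit(eta1))
    if (K >= 2) for (k in 2:K) {
      eta <- p["alpha0"] + p["alpha1"] * z[, k - 1] +
        p["alphaS"] * ds$snares[, k] + p["alphaE"] * ds$elev +
        p["alphaE2"] * ds$elev2 + p["alphaB"] * ds$ban[k]
      z[, k] <- stats::rbinom(n, 1, inv_logit(eta))
    }
    d_rep <- matrix(stats::rbinom(n * K, as.vector(ds$J),
                                  as.vector(z * pdet)), n, K)
    D_rep[i] <- discrepancy(d_rep, ds$J, psi, pdet)
  }
  pval <- mean(D_rep > D_obs) + 0.5 * mean(D_rep == D_obs)
  structure(
    list(bayes_p = pval, adequate = pval > 0.05 && pval < 0.95,
         discrepancy_observed = D_obs, discrepancy_replicated = D_rep,
         n_draws_used = nrow(dr)),
    class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("Bayesian p-value: %.3f (%s fit, %d draws)\n", x$bayes_p,
              if (x$adequate) "adequate" else "inadequate", x$n_draws_used))
  invisible(x)
}
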