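# Independent oracles and small fixture builders used across the suite.

# Brute-force marginal likelihood of one site's history: enumerate all 2^K
# latent occupancy sequences, accumulate P(z) * P(y | z). Deliberately
# scalar and naive -- it shares nothing with the forward recursion it checks.
brute_force_site_loglik <- function(p, y_site, snares_std = NULL,
                                    elev_std = 0, elev2_std = elev_std^2,
                                    border_std = 0, ban = NULL,
                                    spec = model_spec()) {
  y_site <- as.matrix(y_site)
  K <- ncol(y_site)
  if (is.null(snares_std)) snares_std <- rep(0, K)
  if (is.null(ban)) ban <- rep(0L, K)
  pdet <- plogis(p["beta0"] + p["betaB"] * border_std)

  emission <- function(z, k) {
    ys <- y_site[, k]
    ys <- ys[!is.na(ys)]
    if (!length(ys)) return(1)
    if (z == 0) return(as.numeric(all(ys == 0)))
    prod(ifelse(ys == 1, pdet, 1 - pdet))
  }
  psi1 <- plogis(p["alpha2"] + p["alphaS"] * snares_std[1] +
                   p["alphaE"] * elev_std + p["alphaE2"] * elev2_std +
                   if (spec$first_year_includes_ban)
                     p["alphaB"] * ban[1] else 0)
  trans <- function(z_prev, z_new, k) {
    eta <- p["alpha0"] + p["alpha1"] * z_prev +
      p["alphaS"] * snares_std[k] + p["alphaE"] * elev_std +
      p["alphaE2"] * elev2_std + p["alphaB"] * ban[k]
    pr <- plogis(eta)
    if (z_new == 1) pr else 1 - pr
  }
  total <- 0
  for (idx in 0:(2^K - 1)) {
    z <- as.integer(intToBits(idx)[1:K])
    pr <- (if (z[1] == 1) psi1 else 1 - psi1) * emission(z[1], 1)
    if (K >= 2) for (k in 2:K)
      pr <- pr * trans(z[k - 1], z[k], k) * emission(z[k], k)
    total <- total + pr
  }
  log(unname(total))
}

# Random parameter vector with moderate logit-scale values.
random_params <- function() {
  param_vector(alpha2 = rnorm(1, 0, 1), alpha0 = rnorm(1, 0, 1),
               alpha1 = rnorm(1, 0, 1), alphaS = rnorm(1, 0, 0.5),
               alphaE = rnorm(1, 0, 0.5), alphaE2 = rnorm(1, 0, 0.5),
               alphaB = rnorm(1, 0, 0.5), beta0 = rnorm(1, 0, 1),
               betaB = rnorm(1, 0, 0.5))
}

# Random single-site history: occasions x years with optional missingness.
random_history <- function(J, K, miss_rate = 0.15) {
  y <- matrix(rbinom(J * K, 1, 0.4), J, K)
  y[runif(J * K) < miss_rate] <- NA
  if (all(is.na(y))) y[1, 1] <- 1
  y
}

# A small complete survey + covariates for fitting tests.
make_small_dataset <- function(n_sites = 20, n_years = 4, seed = 42,
                               true_params = param_vector(
                                 alpha2 = 0.5, alpha0 = 0, alpha1 = 1,
                                 beta0 = 0.2, betaB = 0.3)) {
  sc <- scenario(n_sites = n_sites, n_years = n_years,
                 true_params = true_params, seed = seed,
                 ban_start_year = min(4, n_years),
                 missing_occasion_rate = 0)
  simulate_dataset(sc)
}
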