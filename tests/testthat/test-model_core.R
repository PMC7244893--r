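test_that("inverse logit is correct and stable at extreme arguments", {
  expect_equal(inv_logit(0), 0.5)
  expect_equal(inv_logit(logit(0.71)), 0.71)
  expect_gt(inv_logit(-745), 0)
  expect_true(is.finite(log(inv_logit(-745))))
})

test_that("occurrence predictors follow the autologistic equations", {
  p0 <- param_vector()
  expect_equal(occ_prob_first_year(p0), 0.5)
  expect_equal(occ_prob(p0, z_prev = 0), 0.5)

  p <- param_vector(alpha2 = 1)
  expect_equal(occ_prob_first_year(p), plogis(1), tolerance = 1e-6)

  # colonization / persistence readout on the logit scale
  p <- param_vector(alpha0 = logit(0.71), alpha1 = logit(0.88) - logit(0.71))
  expect_equal(occ_prob(p, z_prev = 0), 0.71)
  expect_equal(occ_prob(p, z_prev = 1), 0.88)

  # snares depress occupancy when their effect is negative
  p <- param_vector(alphaS = -0.49)
  expect_lt(occ_prob_first_year(p, snares_std = 1),
            occ_prob_first_year(p, snares_std = 0))

  # a positive ban effect raises occupancy when the ban is on
  p1 <- param_vector(alphaB = 0.5); p2 <- param_vector(alphaB = 1.5)
  expect_gt(occ_prob(p2, z_prev = 0, ban = 1),
            occ_prob(p1, z_prev = 0, ban = 1))

  # first-year predictor omits the ban by default
  p <- param_vector(alphaB = 3)
  expect_equal(occ_prob_first_year(p, ban = 1), 0.5)
  expect_gt(occ_prob_first_year(p, ban = 1,
                                spec = model_spec(first_year_includes_ban = TRUE)),
            0.5)
})

test_that("detection probability depends on border distance as specified", {
  expect_equal(det_prob(param_vector()), 0.5)
  expect_equal(det_prob(param_vector(beta0 = logit(0.3)), border_std = 0),
               0.3)
  p <- param_vector(betaB = 0.6)
  expect_gt(det_prob(p, border_std = 1), det_prob(p, border_std = -1))
})

test_that("parameter vector enforces structural zeros and finiteness", {
  spec <- model_spec(include_snares = FALSE, include_ban = FALSE)
  p <- param_vector(alphaS = 2, alphaB = 3, spec = spec)
  expect_equal(unname(p[c("alphaS", "alphaB")]), c(0, 0))
  expect_setequal(free_params(spec),
                  setdiff(param_names(), c("alphaS", "alphaB")))
  expect_error(param_vector(alpha0 = Inf), "finite")
})

test_that("single-year likelihood matches its closed forms", {
  # all-zero history: psi (1-p)^J + (1 - psi)
  p <- param_vector()                      # psi = 0.5, p = 0.5
  y <- matrix(0, 2, 1)
  expect_equal(site_loglik(p, y), log(0.5 * 0.25 + 0.5), tolerance = 1e-12)

  # with a detection the unoccupied branch vanishes
  y <- matrix(c(1, 0), 2, 1)
  expect_equal(site_loglik(p, y), log(0.5 * 0.5 * 0.5), tolerance = 1e-12)
})

test_that("forward recursion equals brute-force enumeration", {
  set.seed(101)
  for (rep in 1:30) {
    K <- sample(1:6, 1); J <- sample(1:5, 1)
    p <- random_params()
    y <- random_history(J, K)
    sn <- rnorm(K); el <- rnorm(1); bo <- rnorm(1)
    ban <- as.integer(seq_len(K) >= sample(1:(K + 1), 1))
    expect_equal(
      site_loglik(p, y, snares_std = sn, elev_std = el, border_std = bo,
                  ban = ban),
      brute_force_site_loglik(p, y, snares_std = sn, elev_std = el,
                              border_std = bo, ban = ban),
      tolerance = 1e-10)
  }
})

test_that("zero-effort years advance the chain with unit emission", {
  p <- random_params()
  set.seed(7)
  y <- random_history(3, 4, miss_rate = 0)
  y[, 2] <- NA                              # year 2 never sampled
  expect_equal(site_loglik(p, y), brute_force_site_loglik(p, y),
               tolerance = 1e-10)
})

test_that("an all-missing site returns zero log-likelihood with a warning", {
  y <- matrix(NA_real_, 3, 2)
  expect_warning(ll <- site_loglik(param_vector(), y), "no sampled occasion")
  expect_equal(ll, 0)
})

test_that("total likelihood sums sites and is permutation invariant", {
  sim <- make_small_dataset()
  p <- sim$scenario$true_params
  ll <- total_loglik(p, sim$survey, sim$covariates, sim$spec)
  expect_true(is.finite(ll))

  # single-site survey equals site_loglik for that site
  i <- 3
  sd1 <- survey_data(sim$survey$y[i, , , drop = FALSE],
                     sim$survey$site_ids[i], sim$survey$year_labels)
  ll1 <- site_loglik(p, sim$survey$y[i, , ],
                     snares_std = sim$covariates$snares_std[i, ],
                     elev_std = sim$covariates$elev_std[i],
                     elev2_std = sim$covariates$elev2_std[i],
                     border_std = sim$covariates$border_std[i],
                     ban = sim$covariates$ban)
  cv1 <- sim$covariates
  cv1$elev_raw <- cv1$elev_raw[i]; cv1$border_raw <- cv1$border_raw[i]
  cv1$elev_std <- cv1$elev_std[i]; cv1$elev2_std <- cv1$elev2_std[i]
  cv1$border_std <- cv1$border_std[i]
  cv1$snares_raw <- cv1$snares_raw[i, , drop = FALSE]
  cv1$snares_std <- cv1$snares_std[i, , drop = FALSE]
  cv1$n_sites <- 1L
  expect_equal(total_loglik(p, sd1, cv1, sim$spec), ll1, tolerance = 1e-12)

  # permuting sites leaves the total unchanged
  set.seed(9)
  perm <- sample(sim$survey$n_sites)
  sd_p <- survey_data(sim$survey$y[perm, , ], sim$survey$site_ids[perm],
                      sim$survey$year_labels)
  cv_p <- sim$covariates
  for (f in c("elev_raw", "border_raw", "elev_std", "elev2_std",
              "border_std"))
    cv_p[[f]] <- cv_p[[f]][perm]
  cv_p$snares_raw <- cv_p$snares_raw[perm, ]
  cv_p$snares_std <- cv_p$snares_std[perm, ]
  expect_equal(total_loglik(p, sd_p, cv_p, sim$spec), ll, tolerance = 1e-10)

  # permuting occasions within a site-year leaves the total unchanged
  y2 <- sim$survey$y
  y2[1, , 2] <- y2[1, rev(seq_len(dim(y2)[2])), 2]
  sd_o <- survey_data(y2, sim$survey$site_ids, sim$survey$year_labels)
  expect_equal(total_loglik(p, sd_o, sim$covariates, sim$spec), ll,
               tolerance = 1e-12)

  # duplicating every site doubles the log-likelihood
  sd_d <- survey_data(sim$survey$y[rep(1:sim$survey$n_sites, 2), , ])
  cv_d <- covariate_set(rep(sim$covariates$elev_raw, 2),
                        rep(sim$covariates$border_raw, 2),
                        sim$covariates$snares_raw[rep(1:sim$survey$n_sites,
                                                      2), ],
                        ban = sim$covariates$ban)
  # reuse the original standardization so the duplicated design is identical
  for (f in c("elev_std", "border_std"))
    cv_d[[f]] <- rep(sim$covariates[[f]], 2)
  cv_d$elev2_std <- rep(sim$covariates$elev2_std, 2)
  cv_d$snares_std <- sim$covariates$snares_std[rep(1:sim$survey$n_sites,
                                                   2), ]
  expect_equal(total_loglik(p, sd_d, cv_d, sim$spec), 2 * ll,
               tolerance = 1e-8)
})

test_that("near-certain detection reduces to the observed-chain likelihood", {
  # with p -> 1 and full effort the history reveals z, and the marginal
  # likelihood collapses to the Markov-chain probability of that z sequence
  set.seed(13)
  p <- param_vector(alpha2 = 0.3, alpha0 = -0.4, alpha1 = 1.2, beta0 = 35)
  K <- 5; J <- 4
  z <- rbinom(K, 1, 0.6)
  y <- matrix(rep(z, each = J), J, K)
  chain_ll <- log(ifelse(z[1] == 1, plogis(0.3), 1 - plogis(0.3))) +
    sum(log(ifelse(z[-1] == 1,
                   plogis(-0.4 + 1.2 * z[-K]),
                   1 - plogis(-0.4 + 1.2 * z[-K]))))
  expect_equal(site_loglik(p, y), chain_ll, tolerance = 1e-8)
})
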