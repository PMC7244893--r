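# Builds a minimal posterior_chains object from a draws matrix so the
# summary transforms can be exercised on controlled draws.
fake_chains <- function(draws_mat, design = NULL, spec = model_spec(),
                        year_labels = NULL) {
  n <- nrow(draws_mat)
  d <- array(NA_real_, c(2, ceiling(n / 2), ncol(draws_mat)),
             dimnames = list(NULL, NULL, colnames(draws_mat)))
  idx <- rep(1:2, length.out = n)
  d[1, , ] <- draws_mat[idx == 1, ][seq_len(dim(d)[2]), ]
  d[2, , ] <- draws_mat[idx == 2, ][seq_len(dim(d)[2]), ]
  structure(list(draws = d, param_names = colnames(draws_mat),
                 config = NULL, spec = spec, design = design,
                 year_labels = year_labels),
            class = "posterior_chains")
}

const_draws <- function(p, n = 200) {
  m <- matrix(rep(p, each = n), n, length(p))
  colnames(m) <- names(p)
  m
}

test_that("colonization and persistence transform draw by draw", {
  p <- param_vector(alpha0 = logit(0.71), alpha1 = logit(0.88) - logit(0.71))
  ch <- fake_chains(const_draws(p))
  cp <- colonization_persistence(ch)
  expect_equal(cp$colonization$mean, 0.71, tolerance = 1e-10)
  expect_equal(cp$persistence$mean, 0.88, tolerance = 1e-10)
  expect_equal(cp$colonization$lower, cp$colonization$upper)
  expect_true(cp$distinct)       # zero-width intervals cannot overlap

  # alpha1 = 0 makes the two probabilities identical
  p0 <- param_vector(alpha0 = 0.3)
  cp0 <- colonization_persistence(fake_chains(const_draws(p0)))
  expect_equal(cp0$colonization$mean, cp0$persistence$mean)
  expect_false(cp0$distinct)
})

test_that("interval transforms commute with the monotone inverse logit", {
  set.seed(31)
  m <- const_draws(param_vector())
  m[, "alpha0"] <- rnorm(nrow(m), 0.5, 1)
  ch <- fake_chains(m)
  cp <- colonization_persistence(ch)
  # percentile-then-transform equals transform-then-percentile
  pooled <- pooled_draws(ch)[, "alpha0"]
  # equality is exact up to the quantile interpolation between adjacent
  # order statistics, which the smooth transform perturbs only slightly
  expect_equal(unname(cp$colonization$lower),
               unname(plogis(quantile(pooled, 0.025))), tolerance = 1e-4)
  expect_equal(unname(cp$colonization$upper),
               unname(plogis(quantile(pooled, 0.975))), tolerance = 1e-4)
})

test_that("effect significance follows the 95% interval convention", {
  p <- param_vector(alphaS = -0.49)
  es <- effect_significance(fake_chains(const_draws(p)), "alphaS")
  expect_equal(es$mean, -0.49)
  expect_true(es$significant)

  m <- const_draws(param_vector())
  set.seed(32)
  m[, "alphaB"] <- rnorm(nrow(m), 0, 1)
  es <- effect_significance(fake_chains(m), "alphaB")
  expect_false(es$significant)
  expect_error(effect_significance(fake_chains(m), "gamma9"), "unknown")
})

test_that("with certain detection mean occupancy equals the observed rate", {
  # p ~ 1 and full effort: the latent states are pinned to the data, so
  # every draw returns exactly the observed fraction of detection-positive
  # sites per year
  set.seed(33)
  n <- 15; K <- 4; J <- 3
  z <- matrix(rbinom(n * K, 1, 0.6), n, K)
  y <- array(0, c(n, J, K))
  for (k in 1:K) y[, , k] <- matrix(rep(z[, k], J), n, J)
  sdv <- survey_data(y)
  cv <- covariate_set(runif(n, 290, 2300), runif(n, 0, 6),
                      matrix(rpois(n * K, 2), n, K),
                      ban = c(0, 0, 1, 1))
  spec <- model_spec()
  ds <- aloccu:::build_design(sdv, cv, spec)
  p <- param_vector(beta0 = 35)
  ch <- fake_chains(const_draws(p, 120), design = ds, spec = spec,
                    year_labels = 1:K)
  occ <- mean_occupancy_by_year(ch, seed = 2)
  expect_equal(occ$mean, colMeans(z), tolerance = 1e-12)
  expect_equal(occ$lower, colMeans(z), tolerance = 1e-12)
  expect_equal(occ$upper, colMeans(z), tolerance = 1e-12)

  # all-zero histories with high detection pin occupancy near zero
  y0 <- array(0, c(n, J, K))
  ds0 <- aloccu:::build_design(survey_data(y0), cv, spec)
  ch0 <- fake_chains(const_draws(p, 120), design = ds0, spec = spec,
                     year_labels = 1:K)
  occ0 <- mean_occupancy_by_year(ch0, seed = 2)
  expect_lt(max(occ0$upper), 0.05)
})

test_that("sampled states honor detections and smoothing matches sampling", {
  sim <- make_small_dataset(n_sites = 25, n_years = 5)
  ds <- aloccu:::build_design(sim$survey, sim$covariates, sim$spec)
  p <- sim$scenario$true_params
  set.seed(34)
  for (r in 1:20) {
    z <- aloccu:::ffbs_draw(p, ds, sample = TRUE)
    expect_true(all(z[ds$d > 0] == 1))
  }
  # smoothed marginals agree with the Monte-Carlo average of sampled states
  set.seed(35)
  zbar <- Reduce(`+`, lapply(1:400, function(i)
    aloccu:::ffbs_draw(p, ds, sample = TRUE))) / 400
  zsm <- aloccu:::ffbs_draw(p, ds, sample = FALSE)
  expect_lt(max(abs(zbar - zsm)), 0.12)
  expect_true(all(zsm[ds$d > 0] > 1 - 1e-12))
})
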