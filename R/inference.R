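#' MCMC configuration
#'
#' Defaults follow the study protocol of the analysis this package supports:
#' three chains of 100,000 iterations, a burn-in of 5,000, and thinning by 20.
#' A much shorter protocol (e.g. `n_iter = 5000, n_burnin = 1000, thin = 5`)
#' is adequate for simulation experiments and is what the package's own test
#' harnesses use.
#'
#' @param n_chains number of independent chains (default 3).
#' @param n_iter iterations per chain (default 100000).
#' @param n_burnin iterations discarded as burn-in (default 5000).
#' @param thin keep every `thin`-th post-burn-in draw (default 20).
#' @param seed integer seed; chains get independent sub-seeds derived from it.
#' @param proposal_scale `"adaptive"` (default) for Robbins-Monro scaling of
#'   a joint random-walk proposal with empirically adapted covariance, or a
#'   fixed positive step size.
#' @return Object of class `mcmc_config`. Retained draws per chain are
#'   `floor((n_iter - n_burnin) / thin)`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 100000, n_burnin = 5000,
                        thin = 20, seed = 1, proposal_scale = "adaptive") {
  if (n_burnin >= n_iter) stop("`n_burnin` must be < `n_iter`", call. = FALSE)
  if (thin < 1) stop("`thin` must be >= 1", call. = FALSE)
  structure(
    list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
         n_burnin = as.integer(n_burnin), thin = as.integer(thin),
         seed = as.integer(seed), proposal_scale = proposal_scale),
    class = "mcmc_config")
}

#' Log prior density
#'
#' Independent zero-mean Gaussian priors with standard deviation
#' `spec$prior_sd` on every free parameter; structurally excluded parameters
#' contribute nothing. With the default sd of 10 these are diffuse on the
#' logit scale.
#'
#' @param p parameter vector (canonical order).
#' @param spec a [model_spec()].
#' @return Scalar log prior density.
#' @export
log_prior <- function(p, spec = model_spec()) {
  fp <- free_params(spec)
  sum(stats::dnorm(p[fp], 0, spec$prior_sd, log = TRUE))
}

# Starting values: occurrence intercepts at the logit of the naive occupancy
# proportion (fraction of site-years with >= 1 detection), detection
# intercept at the logit of the per-occasion detection frequency among
# detection-positive site-years, covariate effects at 0.
start_values <- function(ds, spec) {
  sampled <- ds$J > 0
  naive_occ <- mean(ds$d[sampled] > 0)
  naive_occ <- min(max(naive_occ, 0.02), 0.98)
  pos <- ds$d > 0
  naive_det <- if (any(pos)) sum(ds$d[pos]) / sum(ds$J[pos]) else 0.1
  naive_det <- min(max(naive_det, 0.02), 0.98)
  param_vector(alpha2 = logit(naive_occ), alpha0 = logit(naive_occ),
               alpha1 = 0, beta0 = logit(naive_det), spec = spec)
}

# One adaptive random-walk Metropolis chain on the free parameters of the
# marginalized posterior. Adaptation (Haario-style empirical covariance plus
# Robbins-Monro scaling toward 23% acceptance) runs only during burn-in and
# is frozen afterwards, preserving detailed balance for the retained draws.
run_one_chain <- function(log_post, init, cfg, chain_seed, jitter_sd = 0.3) {
  set.seed(chain_seed)
  d <- length(init)
  cur <- init + stats::rnorm(d, 0, jitter_sd)
  lp_cur <- log_post(cur)
  tries <- 0
  while (!is.finite(lp_cur) && tries < 100) {
    cur <- init + stats::rnorm(d, 0, jitter_sd)
    lp_cur <- log_post(cur)
    tries <- tries + 1
  }
  if (!is.finite(lp_cur))
    stop("initialization failure: non-finite posterior after 100 re-draws",
         call. = FALSE)

  adaptive <- identical(cfg$proposal_scale, "adaptive")
  log_lambda <- if (adaptive) log(0.1) else log(cfg$proposal_scale)
  chol_prop <- diag(d)
  # running moments for covariance adaptation
  mu <- cur; M2 <- diag(1e-4, d); n_seen <- 1
  target_acc <- 0.234

  n_keep <- (cfg$n_iter - cfg$n_burnin) %/% cfg$thin
  draws <- matrix(NA_real_, n_keep, d)
  lp_trace <- numeric(n_keep)
  kept <- 0L; n_acc <- 0L

  for (it in seq_len(cfg$n_iter)) {
    prop <- cur + exp(log_lambda) * as.numeric(chol_prop %*% stats::rnorm(d))
    lp_prop <- log_post(prop)
    acc_p <- if (is.finite(lp_prop)) min(1, exp(lp_prop - lp_cur)) else 0
    if (stats::runif(1) < acc_p) {
      cur <- prop; lp_cur <- lp_prop; n_acc <- n_acc + 1L
    }
    in_burnin <- it <= cfg$n_burnin
    if (adaptive && in_burnin) {
      # running covariance (Welford), proposal refreshed periodically
      n_seen <- n_seen + 1
      delta <- cur - mu
      mu <- mu + delta / n_seen
      M2 <- M2 + tcrossprod(delta, cur - mu)
      log_lambda <- log_lambda + (acc_p - target_acc) / sqrt(it)
      if (it >= 200 && it %% 50 == 0) {
        cov_emp <- M2 / (n_seen - 1) + diag(1e-8, d)
        ch <- tryCatch(chol(cov_emp), error = function(e) NULL)
        if (!is.null(ch)) chol_prop <- t(ch) * (2.38 / sqrt(d))
      }
    }
    if (!in_burnin && (it - cfg$n_burnin) %% cfg$thin == 0 && kept < n_keep) {
      kept <- kept + 1L
      draws[kept, ] <- cur
      lp_trace[kept] <- lp_cur
    }
  }
  list(draws = draws, lp = lp_trace, accept_rate = n_acc / cfg$n_iter)
}

#' Fit the model by MCMC
#'
#' Samples the posterior proportional to `exp(total_loglik + log_prior)`
#' using the exactly marginalized likelihood (no data augmentation), with an
#' adaptive random-walk Metropolis sampler whose adaptation is frozen at the
#' end of burn-in. Chains are independently seeded from `cfg$seed`, so a run
#' is reproducible bit-for-bit for a fixed seed, package version and
#' platform.
#'
#' @param sd a [survey_data()] object.
#' @param cv a [covariate_set()] object.
#' @param spec a [model_spec()].
#' @param cfg an [mcmc_config()].
#' @return Object of class `posterior_chains`: list with `draws` (a
#'   chains x retained-iterations x parameters array over the free
#'   parameters), `param_names`, `accept_rates`, `lp`, `config`, `spec`, and
#'   the design internals needed by downstream summaries.
#' @export
run_mcmc <- function(sd, cv, spec = model_spec(), cfg = mcmc_config()) {
  issues <- validate_inputs(sd, cv, spec)
  if (any(issues$severity == "fatal"))
    stop("invalid inputs:\n  ",
         paste(issues$message[issues$severity == "fatal"], collapse = "\n  "),
         call. = FALSE)
  ds <- build_design(sd, cv, spec)
  fp <- free_params(spec)
  full0 <- param_vector(spec = spec)

  expand <- function(theta) { full0[fp] <- theta; full0 }
  log_post <- function(theta) {
    p <- expand(theta)
    sum(forward_loglik(p, ds)) + log_prior(p, spec)
  }
  init <- start_values(ds, spec)[fp]

  set.seed(cfg$seed)
  chain_seeds <- sample.int(.Machine$integer.max, cfg$n_chains)
  chains <- lapply(seq_len(cfg$n_chains), function(ch)
    run_one_chain(log_post, init, cfg, chain_seeds[ch]))

  n_keep <- nrow(chains[[1]]$draws)
  draws <- array(NA_real_, c(cfg$n_chains, n_keep, length(fp)),
                 dimnames = list(NULL, NULL, fp))
  for (ch in seq_len(cfg$n_chains)) draws[ch, , ] <- chains[[ch]]$draws
  structure(
    list(draws = draws, param_names = fp,
         accept_rates = vapply(chains, `[[`, 0, "accept_rate"),
         lp = t(vapply(chains, `[[`, numeric(n_keep), "lp")),
         config = cfg, spec = spec, design = ds,
         site_ids = sd$site_ids, year_labels = sd$year_labels),
    class = "posterior_chains")
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat("Posterior chains:", dim(x$draws)[1], "chains x", dim(x$draws)[2],
      "retained draws x", length(x$param_names), "parameters\n")
  cat("  acceptance rates:",
      paste(sprintf("%.2f", x$accept_rates), collapse = ", "), "\n")
  print(summary(x))
  invisible(x)
}

#' Posterior summary table
#'
#' @param object a `posterior_chains` object.
#' @param ... unused.
#' @return Data frame with mean, sd, 2.5/50/97.5 percentiles and the
#'   Gelman-Rubin statistic per free parameter.
#' @export
summary.posterior_chains <- function(object, ...) {
  pooled <- pooled_draws(object)
  rhat <- tryCatch(gelman_rubin(object), error = function(e)
    rep(NA_real_, ncol(pooled)))
  data.frame(
    parameter = colnames(pooled),
    mean = colMeans(pooled),
    sd = apply(pooled, 2, stats::sd),
    q2.5 = apply(pooled, 2, stats::quantile, 0.025),
    q50 = apply(pooled, 2, stats::quantile, 0.5),
    q97.5 = apply(pooled, 2, stats::quantile, 0.975),
    rhat = rhat, row.names = NULL)
}

#' Pool retained draws across chains
#' @param chains a `posterior_chains` object.
#' @return Matrix, (chains * retained iterations) x parameters.
#' @export
pooled_draws <- function(chains) {
  d <- chains$draws
  out <- do.call(rbind, lapply(seq_len(dim(d)[1]), function(ch)
    matrix(d[ch, , ], dim(d)[2], dim(d)[3])))
  colnames(out) <- chains$param_names
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The plain (non-rank) PSRF per parameter. With `m` chains of length `n`,
#' chain means `xbar_j` and within-chain variances `s2_j`:
#' `W = mean(s2_j)`, `B/n = var(xbar_j)`,
#' `Rhat = sqrt(((n - 1)/n * W + B/n) / W)`,
#' floored at 1: the finite-sample factor `(n-1)/n` can push the ratio a
#' hair below 1 when the chains agree perfectly, and values below 1 carry no
#' diagnostic meaning. Values near 1 indicate the chains have mixed; a
#' common rule flags parameters with Rhat > 1.1.
#'
#' @param chains a `posterior_chains` object (or a chains x iterations x
#'   parameters array).
#' @return Named numeric vector of Rhat values, each >= a finite-sample
#'   floor slightly below 1.
#' @export
gelman_rubin <- function(chains) {
  d <- if (inherits(chains, "posterior_chains")) chains$draws else chains
  m <- dim(d)[1]; n <- dim(d)[2]
  if (m < 2) stop("Gelman-Rubin diagnostic needs >= 2 chains", call. = FALSE)
  if (n < 10) stop("Gelman-Rubin diagnostic needs >= 10 draws per chain",
                   call. = FALSE)
  vapply(seq_len(dim(d)[3]), function(j) {
    x <- d[, , j, drop = TRUE]          # m x n
    W <- mean(apply(x, 1, stats::var))
    Bn <- stats::var(rowMeans(x))       # B / n
    if (W == 0) return(1)
    sqrt(max(1, ((n - 1) / n * W + Bn) / W))
  }, numeric(1)) -> rhat
  names(rhat) <- dimnames(d)[[3]]
  rhat
}

#' Maximum-likelihood fit
#'
#' Numerical maximization of the marginal log-likelihood over the free
#' parameters with multiple seeded starts (BFGS). Useful as a fast check on
#' the Bayesian fit and for simulation work.
#'
#' @param sd,cv,spec data, covariates and model specification.
#' @param starts number of optimization starts (default 5).
#' @param seed seed for start jitter.
#' @return List with `par` (full parameter vector, structurally excluded
#'   terms at 0), `loglik`, `convergence` (TRUE when the best start
#'   converged), and `degenerate` (TRUE when the fit is flagged as a boundary
#'   estimate, e.g. the species was never detected).
#' @export
fit_mle <- function(sd, cv, spec = model_spec(), starts = 5, seed = 1) {
  issues <- validate_inputs(sd, cv, spec)
  if (any(issues$severity == "fatal"))
    stop("invalid inputs:\n  ",
         paste(issues$message[issues$severity == "fatal"], collapse = "\n  "),
         call. = FALSE)
  ds <- build_design(sd, cv, spec)
  fp <- free_params(spec)
  full0 <- param_vector(spec = spec)
  negll <- function(theta) {
    full0[fp] <- theta
    v <- -sum(forward_loglik(full0, ds))
    if (!is.finite(v)) 1e10 else v
  }
  never_detected <- all(ds$d == 0)
  if (never_detected)
    warning("species never detected: maximum-likelihood fit is degenerate",
            call. = FALSE)
  init <- start_values(ds, spec)[fp]
  set.seed(seed)
  fits <- lapply(seq_len(starts), function(s) {
    st <- if (s == 1) init else init + stats::rnorm(length(fp), 0, 0.5)
    tryCatch(stats::optim(st, negll, method = "BFGS",
                          control = list(maxit = 500)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("optimization failure: all starts failed",
                          call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  par <- full0; par[fp] <- best$par
  boundary <- any(abs(best$par) > 15)
  list(par = par, loglik = -best$value,
       convergence = best$convergence == 0,
       degenerate = never_detected || boundary)
}
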