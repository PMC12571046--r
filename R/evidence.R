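# Marginal likelihoods by bridge sampling, Bayes-factor model comparison
# with prior-sensitivity sweeps, and counterfactual power analysis.

#' Reduced model specifications for the interaction comparison
#'
#' Two non-nested competitors sharing main effects and random-effect
#' structure: model A carries the grammaticality-by-agreement-type
#' interaction only, model B the grammaticality-by-lexical-category
#' interaction only.  `interaction_prior_sd` sets the prior scale of the
#' interaction coefficient (the quantity swept in the sensitivity
#' analysis); all other priors stay at their defaults.
#'
#' @param measure response column.
#' @param interaction_prior_sd prior sd of the interaction coefficient
#'   (default: the family's default slope prior sd).
#' @param ... passed to [model_spec()] (chains, iterations, ...).
#' @return list with elements `A` and `B` (two `model_spec`s).
#' @export
reduced_model_specs <- function(measure = "total_duration",
                                interaction_prior_sd = NULL, ...) {
  response <- if (measure %in% c("fp_reg", "reg_in")) "bernoulli" else "lognormal"
  mains <- c("Gram", "Gen", "AgrType", "LexCat")
  mk <- function(interaction) {
    pr <- default_priors(response)
    if (!is.null(interaction_prior_sd)) {
      pr$beta_sd <- stats::setNames(
        c(pr$beta_sd, interaction_prior_sd), c("", interaction))
    }
    model_spec(measure = measure, response = response,
               predictors = c(mains, interaction), priors = pr, ...)
  }
  list(A = mk("GramxAgrType"), B = mk("GramxLexCat"))
}

# ---- prior-warped parameterizations for bridge sampling ----
#
# Every coordinate is mapped through its prior CDF to the standard-normal
# scale: fixed effects are standardized by their Normal prior, scales go
# through the Exponential CDF, canonical partial correlations through
# their scaled-Beta CDF, and the non-centred random effects are already
# standard normal.  Weakly identified coordinates then have near-N(0,1)
# posteriors, so the bridge's multivariate-normal proposal overlaps the
# posterior well in every direction, and the warped prior contributes
# exactly sum(dnorm(x, log = TRUE)) with no extra Jacobian bookkeeping.

cpc_alphas <- function(q, lkj_eta) {
  if (q <= 1) return(numeric(0))
  unlist(lapply(2:q, function(i) lkj_eta + (q - 1 - seq_len(i - 1)) / 2))
}

warp_tau <- function(tau, rate) {
  stats::qnorm(stats::pexp(tau, rate, log.p = TRUE), log.p = TRUE)
}
unwarp_tau <- function(x, rate) {
  stats::qexp(stats::pnorm(x, log.p = TRUE), rate, log.p = TRUE)
}
warp_cpc <- function(yv, alphas) {
  r <- tanh(yv)
  stats::qnorm(stats::pbeta((r + 1) / 2, alphas, alphas, log.p = TRUE),
               log.p = TRUE)
}
unwarp_cpc_r <- function(x, alphas) {
  2 * stats::qbeta(stats::pnorm(x, log.p = TRUE), alphas, alphas,
                   log.p = TRUE) - 1
}

# lower-triangular Cholesky factor from canonical partial correlations
chol_from_cpc_r <- function(r, q) {
  L <- diag(q)
  idx <- 1
  for (i in seq_len(q)[-1]) {
    ss <- 0
    for (j in seq_len(i - 1)) {
      L[i, j] <- r[idx] * sqrt(max(1 - ss, 0))
      ss <- ss + L[i, j]^2
      idx <- idx + 1
    }
    L[i, i] <- sqrt(max(1 - ss, 1e-12))
  }
  L
}

warp_meta <- function(fit) {
  qb <- ncol(fit$U); qc <- ncol(fit$V)
  list(qb = qb, qc = qc,
       mb = qb * (qb - 1) / 2, mc = qc * (qc - 1) / 2,
       ab = cpc_alphas(qb, fit$priors$lkj_eta),
       ac = cpc_alphas(qc, fit$priors$lkj_eta),
       rate = fit$priors$sd_rate, sigma_rate = fit$priors$sigma_rate,
       bm = fit$priors$beta_mean, bs = fit$priors$beta_sd)
}

grab_block <- function(fit, block) {
  do.call(rbind, lapply(fit$chains, function(ch) as.matrix(ch[[block]])))
}

warped_draws <- function(fit, include_z) {
  w <- warp_meta(fit)
  beta <- grab_block(fit, "beta")
  th <- cbind(sweep(sweep(beta, 2, w$bm), 2, w$bs, "/"),
              warp_tau(grab_block(fit, "tau_b"), w$rate),
              warp_tau(grab_block(fit, "tau_c"), w$rate))
  if (w$mb > 0) {
    th <- cbind(th, t(apply(grab_block(fit, "cpc_b"), 1, warp_cpc, w$ab)))
  }
  if (w$mc > 0) {
    cb <- grab_block(fit, "cpc_c")
    wc <- t(apply(cb, 1, warp_cpc, w$ac))
    if (w$mc == 1) wc <- t(wc)
    th <- cbind(th, wc)
  }
  if (fit$family == 0) {
    th <- cbind(th, warp_tau(as.numeric(grab_block(fit, "sigma")),
                             w$sigma_rate))
  }
  if (include_z) {
    if (!fit$store_z) {
      stop("fit was run without store_z = TRUE; random-effect draws needed")
    }
    th <- cbind(th, grab_block(fit, "zb"), grab_block(fit, "zc"))
  }
  th
}

# log unnormalized posterior on the warped scale, with the random effects
# integrated out analytically (gaussian family only): y | beta, tau, L,
# sigma is multivariate normal with low-rank-plus-diagonal covariance,
# evaluated via the Woodbury identity.
log_marg_posterior_warped <- function(fit) {
  stopifnot(fit$family == 0)
  w <- warp_meta(fit)
  n_part <- length(fit$participants); n_item <- length(fit$items)
  y <- fit$y; U <- fit$U; V <- fit$V
  pid <- fit$pid + 1L; iid <- fit$iid + 1L
  n <- length(y)
  qb <- w$qb; qc <- w$qc
  r_dim <- qb * n_part + qc * n_item
  function(theta) {
    pos <- 0
    take <- function(k) {
      v <- theta[pos + seq_len(k)]
      pos <<- pos + k
      v
    }
    beta <- w$bm + w$bs * take(qb)
    tau_b <- unwarp_tau(take(qb), w$rate)
    tau_c <- unwarp_tau(take(qc), w$rate)
    rb <- if (w$mb > 0) unwarp_cpc_r(take(w$mb), w$ab) else numeric(0)
    rc <- if (w$mc > 0) unwarp_cpc_r(take(w$mc), w$ac) else numeric(0)
    sigma <- unwarp_tau(take(1), w$sigma_rate)
    sig2 <- sigma^2
    Ab <- tau_b * chol_from_cpc_r(rb, qb)
    Ac <- tau_c * chol_from_cpc_r(rc, qc)
    Z <- matrix(0, n, r_dim)
    Ub <- U %*% Ab
    Vc <- V %*% Ac
    for (k in seq_len(qb)) {
      Z[cbind(seq_len(n), (pid - 1) * qb + k)] <- Ub[, k]
    }
    off <- qb * n_part
    for (k in seq_len(qc)) {
      Z[cbind(seq_len(n), off + (iid - 1) * qc + k)] <- Vc[, k]
    }
    resid <- y - as.numeric(U %*% beta)
    C <- crossprod(Z) / sig2
    diag(C) <- diag(C) + 1
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Ztr <- crossprod(Z, resid) / sig2
    u <- backsolve(ch, backsolve(ch, Ztr, transpose = TRUE))
    quad <- sum(resid^2) / sig2 - sum(Ztr * u)
    logdet <- n * log(sig2) + 2 * sum(log(diag(ch)))
    ll <- -0.5 * (n * log(2 * pi) + logdet + quad) - sum(y)
    ll + sum(stats::dnorm(theta, log = TRUE))
  }
}

# full-space warped log posterior (used for the bernoulli family)
log_full_posterior_warped <- function(fit) {
  w <- warp_meta(fit)
  n_part <- length(fit$participants); n_item <- length(fit$items)
  y <- fit$y; U <- fit$U; V <- fit$V
  pid <- fit$pid + 1L; iid <- fit$iid + 1L
  fam <- fit$family
  qb <- w$qb; qc <- w$qc
  function(theta) {
    pos <- 0
    take <- function(k) {
      v <- theta[pos + seq_len(k)]
      pos <<- pos + k
      v
    }
    beta <- w$bm + w$bs * take(qb)
    tau_b <- unwarp_tau(take(qb), w$rate)
    tau_c <- unwarp_tau(take(qc), w$rate)
    rb <- if (w$mb > 0) unwarp_cpc_r(take(w$mb), w$ab) else numeric(0)
    rc <- if (w$mc > 0) unwarp_cpc_r(take(w$mc), w$ac) else numeric(0)
    sigma <- if (fam == 0) unwarp_tau(take(1), w$sigma_rate) else NULL
    zb <- matrix(take(qb * n_part), qb, n_part)
    zc <- matrix(take(qc * n_item), qc, n_item)
    Bb <- (tau_b * chol_from_cpc_r(rb, qb)) %*% zb
    Cc <- (tau_c * chol_from_cpc_r(rc, qc)) %*% zc
    eta <- as.numeric(U %*% beta) +
      rowSums(U * t(Bb)[pid, , drop = FALSE]) +
      rowSums(V * t(Cc)[iid, , drop = FALSE])
    ll <- if (fam == 0) {
      sum(stats::dnorm(y, eta, sigma, log = TRUE)) - sum(y)
    } else {
      sum(y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0))
    }
    ll + sum(stats::dnorm(theta, log = TRUE))
  }
}

#' Bridge-sampling estimate of a log normalizing constant
#'
#' Iterative (optimal) bridge estimator with a multivariate-normal
#' proposal matched to the first half of the posterior sample; the second
#' half enters the bridge.  Returns the log marginal likelihood and an
#' approximate Monte-Carlo standard error (proposal terms treated as
#' independent, posterior terms discounted by their effective sample
#' size).
#'
#' @param draws matrix of posterior draws (rows) in the unconstrained
#'   space on which `log_post` is defined.
#' @param log_post function: unconstrained parameter vector -> log
#'   unnormalized posterior density (log-likelihood + normalized
#'   log-prior).
#' @param n_proposal number of proposal draws (default: rows of the
#'   bridge half).
#' @param maxiter,tol iteration controls.
#' @return list with `logml`, `mcse`, `niter`.
#' @export
bridge_sampler <- function(draws, log_post, n_proposal = NULL,
                           maxiter = 500, tol = 1e-10) {
  draws <- as.matrix(draws)
  n <- nrow(draws); d <- ncol(draws)
  half <- seq_len(floor(n / 2))
  fitd <- draws[half, , drop = FALSE]
  post <- draws[-half, , drop = FALSE]
  n1 <- nrow(post)
  if (is.null(n_proposal)) n_proposal <- n1
  m <- colMeans(fitd)
  S <- stats::cov(fitd)
  S <- S + diag(1e-8 + 1e-6 * pmax(diag(S), 1e-8), d)
  R <- chol(S)
  prop <- matrix(stats::rnorm(n_proposal * d), n_proposal, d) %*% R +
    matrix(m, n_proposal, d, byrow = TRUE)
  ldet <- sum(log(diag(R)))
  log_g <- function(X) {
    Z <- (X - matrix(m, nrow(X), d, byrow = TRUE)) %*%
      backsolve(R, diag(d), transpose = TRUE)
    -0.5 * rowSums(Z^2) - ldet - 0.5 * d * log(2 * pi)
  }
  lq_post <- apply(post, 1, log_post)
  lq_prop <- apply(prop, 1, log_post)
  l1 <- lq_post - log_g(post)   # at posterior draws
  l2 <- lq_prop - log_g(prop)   # at proposal draws
  if (any(!is.finite(l1))) stop("non-finite log-density at posterior draws")
  l2[!is.finite(l2)] <- -Inf    # proposal can land outside support tails
  lstar <- stats::median(l1)
  s1 <- n1 / (n1 + n_proposal); s2 <- n_proposal / (n1 + n_proposal)
  r <- 1  # shifted ratio r~ = ml * exp(-lstar)
  e2 <- exp(l2 - lstar); e1 <- exp(l1 - lstar)
  niter <- 0
  repeat {
    niter <- niter + 1
    num <- mean(e2 / (s1 * e2 + s2 * r))
    den <- mean(1 / (s1 * e1 + s2 * r))
    r_new <- num / den
    if (!is.finite(r_new) || r_new <= 0) stop("bridge iteration diverged")
    if (abs(r_new - r) / r < tol || niter >= maxiter) { r <- r_new; break }
    r <- r_new
  }
  f1 <- e2 / (s1 * e2 + s2 * r)
  f2 <- 1 / (s1 * e1 + s2 * r)
  ess2 <- tryCatch(ess_bulk(matrix(f2, ncol = 1)), error = function(e) n1)
  if (!is.finite(ess2) || ess2 < 2) ess2 <- n1
  re2 <- stats::var(f1) / (n_proposal * mean(f1)^2) +
    stats::var(f2) / (ess2 * mean(f2)^2)
  list(logml = log(r) + lstar, mcse = sqrt(max(re2, 0)), niter = niter)
}

#' Marginal likelihood of a fitted hierarchical model
#'
#' Bridge sampling.  For the lognormal family the random effects are
#' integrated out in closed form (multivariate-normal marginal via the
#' Woodbury identity) and the bridge runs over the fixed effects,
#' log scales and correlation parameters only; for the Bernoulli family
#' the bridge runs over the full unconstrained parameter space including
#' the non-centred random effects, which requires `store_z = TRUE` and is
#' noisier.
#'
#' @param fit a `motr_fit`.
#' @param method currently `"bridge_sampling"`.
#' @param seed seed for the proposal draws.
#' @param ... passed to [bridge_sampler()].
#' @return list with `logml`, `mcse`, `niter`, `method`.
#' @export
marginal_likelihood <- function(fit, method = "bridge_sampling", seed = 1,
                                ...) {
  method <- match.arg(method, "bridge_sampling")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(substream_seed(seed, 77))
  if (fit$family == 0) {
    th <- warped_draws(fit, include_z = FALSE)
    lp <- log_marg_posterior_warped(fit)
  } else {
    th <- warped_draws(fit, include_z = TRUE)
    lp <- log_full_posterior_warped(fit)
  }
  out <- bridge_sampler(th, lp, ...)
  out$method <- method
  out
}

bf_label <- function(bf) {
  x <- max(bf, 1 / bf)
  side <- if (bf >= 1) "GramxAgrType" else "GramxLexCat"
  band <- if (x <= 1 + 1e-12) "equivocal"
  else if (x <= 3) "anecdotal"
  else if (x <= 10) "moderate"
  else if (x <= 30) "strong"
  else if (x <= 100) "very strong"
  else "extreme"
  if (band == "equivocal") band else paste0(band, " (", side, ")")
}

#' Bayes-factor comparison with a prior-sensitivity sweep
#'
#' For each measure and each interaction prior scale, fits the
#' `GramxAgrType`-only and `GramxLexCat`-only reduced models and reports
#' the Bayes factor `BF = exp(logml_A - logml_B)` (values above 1 favor
#' the agreement-type model).  Non-converged fits are flagged and left
#' unlabeled.
#'
#' @param measures_df measures data.frame.
#' @param measure_names character vector of response columns to sweep.
#' @param prior_sds positive prior standard deviations for the
#'   interaction coefficient.
#' @param seed integer seed.
#' @param chains,iterations,warmup sampler settings per reduced fit.
#' @param X contrast matrix (default study contrasts).
#' @return data.frame: `measure`, `prior_sd`, `bf`, `log_mlik_A`,
#'   `log_mlik_B`, `mcse`, `label`, `converged`.
#' @export
bayes_factor_sweep <- function(measures_df, measure_names = "total_duration",
                               prior_sds = c(0.05, 0.1, 0.25), seed = 1,
                               chains = 2, iterations = 1500, warmup = 500,
                               X = NULL) {
  stopifnot(all(prior_sds > 0))
  if (is.null(X)) X <- hypothesis_to_contrast(default_hypothesis_matrix())
  rows <- list()
  k <- 0
  for (ms in measure_names) {
    for (psd in prior_sds) {
      k <- k + 1
      specs <- reduced_model_specs(ms, interaction_prior_sd = psd,
                                   chains = chains,
                                   iterations = iterations, warmup = warmup)
      store_z <- specs$A$response == "bernoulli"
      fitA <- fit_reading_model(measures_df, specs$A, X = X,
                                seed = substream_seed(seed, 40000 + 2 * k),
                                store_z = store_z)
      fitB <- fit_reading_model(measures_df, specs$B, X = X,
                                seed = substream_seed(seed, 40001 + 2 * k),
                                store_z = store_z)
      mlA <- marginal_likelihood(fitA, seed = substream_seed(seed, 50000 + k))
      mlB <- marginal_likelihood(fitB, seed = substream_seed(seed, 60000 + k))
      conv <- attr(fitA$summary, "converged") && attr(fitB$summary, "converged")
      bf <- exp(mlA$logml - mlB$logml)
      rows[[k]] <- data.frame(
        measure = ms, prior_sd = psd, bf = bf,
        log_mlik_A = mlA$logml, log_mlik_B = mlB$logml,
        mcse = sqrt(mlA$mcse^2 + mlB$mcse^2),
        label = if (conv) bf_label(bf) else NA_character_,
        converged = conv)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Counterfactual simulation-based power analysis
#'
#' For each (items, participants) grid point, simulates `n_sims`
#' datasets from the generative model, refits the full hierarchical model
#' with reduced sampler settings, and records the fraction of replicates
#' in which the target interaction is detected: with the `"cri"`
#' criterion, its 95% credible interval excludes zero; with `"pvalue"`, a
#' normal-approximation two-sided p-value falls below .05.  Raw
#' proportions are reported (no monotone smoothing); per-replicate seeds
#' are recorded for exact re-runs.
#'
#' @param params a [generative_params()] holding the assumed truth.
#' @param grid data.frame with columns `n_items`, `n_participants`.
#' @param n_sims replicates per grid point (default 100).
#' @param criterion `"cri"` or `"pvalue"`.
#' @param effect target coefficient (default `"GramxAgrType"`).
#' @param seed integer seed.
#' @param chains,iterations,warmup reduced sampler settings for the
#'   counterfactual refits.
#' @param measure measure column the simulated response populates.
#' @return data.frame: `n_items`, `n_participants`, `n_sims`,
#'   `criterion`, `power`; attribute `replicates` holds per-replicate
#'   detection flags and seeds.
#' @export
power_grid <- function(params = generative_params(),
                       grid = data.frame(n_items = 24, n_participants = 32),
                       n_sims = 100, criterion = c("cri", "pvalue"),
                       effect = "GramxAgrType", seed = 1,
                       chains = 2, iterations = 800, warmup = 400,
                       measure = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(n_sims >= 1)
  X <- hypothesis_to_contrast(default_hypothesis_matrix())
  if (is.null(measure)) {
    measure <- if (params$response == "lognormal") "total_duration" else "fp_reg"
  }
  spec <- model_spec(measure = measure, response = params$response,
                     chains = chains, iterations = iterations,
                     warmup = warmup)
  rows <- list(); reps <- list()
  for (g in seq_len(nrow(grid))) {
    n_items <- grid$n_items[g]; n_part <- grid$n_participants[g]
    if (n_items %% 6 != 0) {
      stop("n_items must be divisible by 6 (three elements, ",
           "grammaticality counterbalanced)")
    }
    hits <- logical(n_sims); seeds <- integer(n_sims)
    for (s in seq_len(n_sims)) {
      seeds[s] <- substream_seed(seed, 70000 + g * 1009 + s)
      plan <- study_plan(n_participants = n_part,
                         n_items_per_element = n_items / 3)
      des <- make_design(plan, seed = seeds[s])
      sim <- simulate_measures(des, params, X, measure = measure,
                               seed = seeds[s])
      fit <- fit_reading_model(sim$measures, spec, X = X, seed = seeds[s])
      fe <- fit$summary[fit$summary$parameter == effect, ]
      hits[s] <- if (criterion == "cri") {
        fe$q2.5 > 0 || fe$q97.5 < 0
      } else {
        b <- fixef_draws(fit)[, effect]
        2 * stats::pnorm(-abs(mean(b) / stats::sd(b))) < 0.05
      }
    }
    rows[[g]] <- data.frame(n_items = n_items, n_participants = n_part,
                            n_sims = n_sims, criterion = criterion,
                            power = sum(hits) / n_sims)
    reps[[g]] <- data.frame(n_items = n_items, n_participants = n_part,
                            sim = seq_len(n_sims), seed = seeds,
                            detected = hits)
  }
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- do.call(rbind, reps)
  out
}
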