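test_that("reduced specs carry exactly one interaction each", {
  specs <- reduced_model_specs("go_past")
  expect_true("GramxAgrType" %in% specs$A$predictors)
  expect_false("GramxLexCat" %in% specs$A$predictors)
  expect_true("GramxLexCat" %in% specs$B$predictors)
  expect_false("GramxAgrType" %in% specs$B$predictors)
  expect_setequal(setdiff(specs$A$predictors, "GramxAgrType"),
                  setdiff(specs$B$predictors, "GramxLexCat"))
  expect_equal(specs$A$response, specs$B$response)
  # the swept prior scale lands on the interaction coefficient only
  specs2 <- reduced_model_specs("total_duration", interaction_prior_sd = 0.3)
  expect_equal(unname(specs2$A$priors$beta_sd["GramxAgrType"]), 0.3)
  binspec <- reduced_model_specs("fp_reg")
  expect_equal(binspec$A$response, "bernoulli")
})

test_that("bridge sampling matches closed-form conjugate evidence", {
  set.seed(201)
  # normal-normal: y_i ~ N(theta, s^2), theta ~ N(m0, t0^2)
  n <- 40; s <- 1.3; m0 <- 0.4; t0 <- 1.8
  y <- rnorm(n, 0.9, s)
  post_prec <- 1 / t0^2 + n / s^2
  post_mean <- (m0 / t0^2 + sum(y) / s^2) / post_prec
  draws <- matrix(rnorm(4000, post_mean, sqrt(1 / post_prec)), ncol = 1)
  lp <- function(th) sum(dnorm(y, th, s, log = TRUE)) +
    dnorm(th, m0, t0, log = TRUE)
  Sig <- diag(s^2, n) + t0^2
  analytic <- -0.5 * (n * log(2 * pi) +
                        as.numeric(determinant(Sig)$modulus) +
                        drop(t(y - m0) %*% solve(Sig, y - m0)))
  br <- bridge_sampler(draws, lp)
  expect_lt(abs(br$logml - analytic), 3 * br$mcse)
  # Bernoulli with a logit-normal prior, evidence by dense quadrature
  yb <- rbinom(60, 1, 0.35)
  lpb <- function(a) sum(dbinom(yb, 1, plogis(a), log = TRUE)) +
    dnorm(a, 0, 1.5, log = TRUE)
  gr <- seq(-10, 10, length.out = 10001)
  lg <- vapply(gr, lpb, numeric(1))
  quad <- log(sum(exp(lg - max(lg)))) + max(lg) + log(diff(gr)[1])
  dens <- exp(lg - quad); cdf <- cumsum(dens) * diff(gr)[1]
  keep <- !duplicated(cdf)
  dr <- matrix(approx(cdf[keep], gr[keep], runif(4000), rule = 2)$y, ncol = 1)
  br2 <- bridge_sampler(dr, lpb)
  expect_lt(abs(br2$logml - quad), max(3 * br2$mcse, 0.01))
})

test_that("the collapsed likelihood equals a dense multivariate-normal oracle", {
  sim <- small_measures_sim(n_participants = 4, n_ipe = 2, seed = 202)
  spec <- model_spec("total_duration", chains = 1, iterations = 300,
                     warmup = 100)
  fit <- fit_reading_model(sim$measures, spec, seed = 202, store_z = TRUE)
  lp <- motr:::log_marg_posterior_warped(fit)
  th <- motr:::warped_draws(fit, include_z = FALSE)[17, ]
  got <- lp(th)
  # reconstruct the parameters and evaluate the marginal density densely
  w <- motr:::warp_meta(fit)
  pos <- 0
  take <- function(k) { v <- th[pos + seq_len(k)]; pos <<- pos + k; v }
  beta <- w$bm + w$bs * take(w$qb)
  tau_b <- motr:::unwarp_tau(take(w$qb), w$rate)
  tau_c <- motr:::unwarp_tau(take(w$qc), w$rate)
  rb <- motr:::unwarp_cpc_r(take(w$mb), w$ab)
  rc <- motr:::unwarp_cpc_r(take(w$mc), w$ac)
  sigma <- motr:::unwarp_tau(take(1), w$sigma_rate)
  Lb <- motr:::chol_from_cpc_r(rb, w$qb)
  Lc <- motr:::chol_from_cpc_r(rc, w$qc)
  Sb <- diag(tau_b) %*% Lb %*% t(Lb) %*% diag(tau_b)
  Sc <- diag(tau_c) %*% Lc %*% t(Lc) %*% diag(tau_c)
  n <- length(fit$y)
  Sig <- diag(sigma^2, n)
  for (a in 1:n) for (b in 1:n) {
    if (fit$pid[a] == fit$pid[b])
      Sig[a, b] <- Sig[a, b] + fit$U[a, ] %*% Sb %*% fit$U[b, ]
    if (fit$iid[a] == fit$iid[b])
      Sig[a, b] <- Sig[a, b] + fit$V[a, ] %*% Sc %*% fit$V[b, ]
  }
  resid <- fit$y - as.numeric(fit$U %*% beta)
  want <- -0.5 * (n * log(2 * pi) +
                    as.numeric(determinant(Sig)$modulus) +
                    drop(t(resid) %*% solve(Sig, resid))) -
    sum(fit$y) + sum(dnorm(th, log = TRUE))
  expect_equal(got, want, tolerance = 1e-8)
  # the full-space density is finite at stored draws for both families
  lpf <- motr:::log_full_posterior_warped(fit)
  expect_true(is.finite(lpf(motr:::warped_draws(fit, include_z = TRUE)[5, ])))
})

test_that("marginal likelihood estimates are stable across estimator runs", {
  sim <- small_measures_sim(n_participants = 10, n_ipe = 4, seed = 203)
  specs <- reduced_model_specs("total_duration", interaction_prior_sd = 0.1,
                               chains = 2, iterations = 1500, warmup = 500)
  fit <- fit_reading_model(sim$measures, specs$A, seed = 203)
  m1 <- marginal_likelihood(fit, seed = 1)
  m2 <- marginal_likelihood(fit, seed = 2)
  expect_lt(abs(m1$logml - m2$logml),
            max(4 * sqrt(m1$mcse^2 + m2$mcse^2), 0.5))
  expect_gt(m1$mcse, 0)
})

test_that("a model compared to itself has a Bayes factor of one", {
  sim <- small_measures_sim(n_participants = 10, n_ipe = 4, seed = 204)
  specs <- reduced_model_specs("total_duration", interaction_prior_sd = 0.1,
                               chains = 2, iterations = 2000, warmup = 500)
  fitA1 <- fit_reading_model(sim$measures, specs$A, seed = 204)
  fitA2 <- fit_reading_model(sim$measures, specs$A, seed = 205)
  mlA1 <- marginal_likelihood(fitA1, seed = 11)
  mlA2 <- marginal_likelihood(fitA2, seed = 12)
  expect_lt(abs(mlA1$logml - mlA2$logml), 1)  # log BF(A, A) ~ 0
})

test_that("evidence favors the model whose interaction truly generated the data", {
  # true GramxAgrType interaction, zero GramxLexCat: median BF over
  # replicates should exceed 1
  beta <- stats::setNames(rep(0, 8), names(generative_params()$beta))
  beta["Gram"] <- 0.08; beta["GramxAgrType"] <- 0.18
  params <- generative_params(beta = beta, sd_b = c(0.2, rep(0.03, 8)),
                              sd_c = rep(0.03, 7), sigma = 0.4)
  logbf <- numeric(3)
  for (r in 1:3) {
    des <- make_design(study_plan(n_participants = 24,
                                  n_items_per_element = 4), seed = 210 + r)
    sim <- simulate_measures(des, params, seed = 210 + r)
    res <- bayes_factor_sweep(sim$measures, "total_duration",
                              prior_sds = 0.1, seed = 210 + r,
                              chains = 2, iterations = 2000, warmup = 500)
    logbf[r] <- log(res$bf)
  }
  expect_gt(median(logbf), 0)
})

test_that("widening the interaction prior penalizes evidence under a null effect", {
  # Bartlett/Lindley behavior: with a true zero interaction, a 10x wider
  # interaction prior lowers the model's marginal likelihood
  beta <- stats::setNames(rep(0, 8), names(generative_params()$beta))
  beta["Gram"] <- 0.08
  params <- generative_params(beta = beta, sd_b = c(0.2, rep(0.03, 8)),
                              sd_c = rep(0.03, 7), sigma = 0.4)
  des <- make_design(study_plan(n_participants = 24), seed = 220)
  sim <- simulate_measures(des, params, seed = 220)
  ml <- numeric(2)
  for (i in seq_along(c(0.05, 0.5))) {
    psd <- c(0.05, 0.5)[i]
    specs <- reduced_model_specs("total_duration", interaction_prior_sd = psd,
                                 chains = 2, iterations = 2000, warmup = 500)
    fit <- fit_reading_model(sim$measures, specs$A, seed = 220)
    ml[i] <- marginal_likelihood(fit, seed = 220)$logml
  }
  expect_gt(ml[1], ml[2])
})

test_that("bf labels follow the interpretation ladder", {
  expect_match(motr:::bf_label(5), "moderate \\(GramxAgrType\\)")
  expect_match(motr:::bf_label(2), "anecdotal \\(GramxAgrType\\)")
  expect_match(motr:::bf_label(1 / 5), "moderate \\(GramxLexCat\\)")
  expect_match(motr:::bf_label(50), "very strong")
  expect_equal(motr:::bf_label(1), "equivocal")
})

test_that("power is a raw detection proportion with recorded seeds", {
  beta <- stats::setNames(rep(0, 8), names(generative_params()$beta))
  beta["Gram"] <- 0.1; beta["GramxAgrType"] <- 0.5  # huge effect
  params <- generative_params(beta = beta, sd_b = c(0.2, rep(0.02, 8)),
                              sd_c = rep(0.02, 7), sigma = 0.3)
  res <- power_grid(params, data.frame(n_items = 12, n_participants = 12),
                    n_sims = 1, seed = 301, chains = 1, iterations = 400,
                    warmup = 200)
  expect_true(res$power %in% c(0, 1))  # n_sims = 1 is a single Bernoulli
  reps <- attr(res, "replicates")
  expect_equal(nrow(reps), 1)
  expect_true(all(c("seed", "detected") %in% names(reps)))
  expect_error(power_grid(params, data.frame(n_items = 10,
                                             n_participants = 4)),
               "divisible by 6")
})

test_that("a large interaction is detected more often than at tiny samples", {
  beta <- stats::setNames(rep(0, 8), names(generative_params()$beta))
  beta["Gram"] <- 0.1; beta["GramxAgrType"] <- 0.4
  params <- generative_params(beta = beta, sd_b = c(0.2, rep(0.02, 8)),
                              sd_c = rep(0.02, 7), sigma = 0.3)
  res <- power_grid(params,
                    data.frame(n_items = c(12, 24),
                               n_participants = c(6, 36)),
                    n_sims = 8, seed = 302, chains = 1, iterations = 500,
                    warmup = 250)
  # stochastic two-point monotonicity with slack for 8 replicates
  expect_gte(res$power[2], res$power[1] - 0.25)
  expect_gt(res$power[2], 0.5)
})
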