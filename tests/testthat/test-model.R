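test_that("Table-style default priors differ by family", {
  rt <- default_priors("lognormal")
  expect_equal(rt$beta0_mean, 6)
  expect_equal(rt$beta0_sd, 1)
  expect_equal(rt$beta_sd, 0.1)
  expect_equal(rt$sd_rate, 2)
  expect_equal(rt$lkj_eta, 2)
  expect_equal(rt$sigma_rate, 2)
  bin <- default_priors("bernoulli")
  expect_equal(bin$beta0_mean, 0)
  expect_equal(bin$beta_sd, 1)
  expect_true(is.na(bin$sigma_rate))  # no residual scale for the binary model
})

test_that("prior predictive reading times sit in the hundreds of milliseconds", {
  # beta0 ~ Normal(6, 1) on log-ms puts the central tendency near e^6
  set.seed(101)
  b0 <- rnorm(20000, 6, 1)
  med <- median(exp(b0))
  expect_gt(med, 150)
  expect_lt(med, 1000)
})

test_that("the Polya-Gamma sampler matches the analytic mean", {
  set.seed(102)
  for (z in c(0.1, 1, 3)) {
    x <- motr:::rpg_vec(rep(z, 40000))
    expect_equal(mean(x), tanh(z / 2) / (2 * z), tolerance = 0.01)
  }
  x0 <- motr:::rpg_vec(rep(0, 40000))
  expect_equal(mean(x0), 0.25, tolerance = 0.01)
  expect_equal(var(x0), 1 / 24, tolerance = 0.05)
})

test_that("fits are reproducible from the seed and flag dropped rows", {
  sim <- small_measures_sim(n_participants = 8, n_ipe = 2, seed = 103)
  m <- sim$measures
  m$total_duration[1:3] <- NA
  spec <- model_spec("total_duration", chains = 2, iterations = 400,
                     warmup = 200)
  f1 <- fit_reading_model(m, spec, seed = 7)
  f2 <- fit_reading_model(m, spec, seed = 7)
  expect_identical(f1$summary, f2$summary)
  expect_equal(f1$n_dropped, 3)
  f3 <- fit_reading_model(m, spec, seed = 8)
  expect_false(identical(f1$summary$mean, f3$summary$mean))
  mneg <- sim$measures; mneg$total_duration[1] <- -2
  expect_error(fit_reading_model(mneg, spec, seed = 7), "positive durations")
})

test_that("a near-noiseless simulation pins the intercept", {
  des <- make_design(study_plan(n_participants = 16), seed = 104)
  beta <- stats::setNames(rep(0, 8), names(generative_params()$beta))
  params <- generative_params(beta0 = 6, beta = beta, sd_b = rep(0, 9),
                              sd_c = rep(0, 7), sigma = 0.01)
  sim <- simulate_measures(des, params, seed = 104)
  spec <- model_spec("total_duration", chains = 2, iterations = 600,
                     warmup = 300)
  fit <- fit_reading_model(sim$measures, spec, seed = 104)
  b0 <- fit$summary[fit$summary$parameter == "(Intercept)", ]
  expect_equal(b0$mean, 6, tolerance = 0.01)
})

test_that("posterior means track an independent frequentist fit on log RTs", {
  sim <- small_measures_sim(n_participants = 24, n_ipe = 8, seed = 105)
  spec <- model_spec("total_duration", chains = 2, iterations = 1000,
                     warmup = 400)
  fit <- fit_reading_model(sim$measures, spec, seed = 105)
  X <- hypothesis_to_contrast(default_hypothesis_matrix())
  mf <- attach_contrasts(sim$measures, X)
  mf$ly <- log(mf$total_duration)
  form <- stats::as.formula(paste(
    "ly ~", paste(attr(mf, "predictors"), collapse = "+"),
    "+ (1 | participant) + (1 | item)"))
  lf <- lme4::lmer(form, data = mf)
  co <- summary(lf)$coefficients
  fe <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  post <- fit$summary$mean[match(rownames(co), fit$summary$parameter)]
  # intercept and main effects are well identified: near-exact agreement
  mains <- c("(Intercept)", "Gram", "Gen", "AgrType", "LexCat")
  expect_lt(max(abs(post[match(mains, rownames(co))] -
                      fe[mains])), 0.02)
  # interaction terms are noisy in the frequentist fit and shrunk by the
  # Normal(0, 0.1) prior; they must still agree within sampling error
  expect_true(all(abs(post - fe) < 2 * se + 0.02))
})

test_that("summaries carry diagnostics and the convergence flag", {
  sim <- small_measures_sim(n_participants = 8, n_ipe = 2, seed = 106)
  spec <- model_spec("total_duration", chains = 2, iterations = 400,
                     warmup = 200)
  fit <- fit_reading_model(sim$measures, spec, seed = 106)
  s <- fit$summary
  expect_true(all(c("rhat", "ess") %in% names(s)))
  expect_true(all(is.finite(s$rhat)))
  expect_true(all(s$q2.5 <= s$mean & s$mean <= s$q97.5))
  expect_type(attr(s, "converged"), "logical")
  expect_length(attr(s, "accept_corr"), 2)
})

test_that("rhat and ess behave on iid and degenerate chains", {
  set.seed(107)
  x <- matrix(rnorm(4000), ncol = 4)
  expect_lt(abs(rhat(x) - 1), 0.02)
  expect_gt(ess_bulk(x), 2000)
  # split disagreement inflates rhat
  y <- x; y[, 1] <- y[, 1] + 3
  expect_gt(rhat(y), 1.2)
  expect_true(is.na(rhat(matrix(1, 100, 4))))
})

test_that("back-transformation matches the closed form at a point mass", {
  # beta0 = 6, Gram = 0.1, everything else 0:
  # Gram effect in ms = e^{6.05} - e^{5.95}
  sim <- small_measures_sim(n_participants = 4, n_ipe = 2, seed = 108)
  spec <- model_spec("total_duration", chains = 1, iterations = 60,
                     warmup = 30)
  fit <- fit_reading_model(sim$measures, spec, seed = 108)
  point <- c(6, 0.1, rep(0, 7))
  for (ch in seq_along(fit$chains)) {
    fit$chains[[ch]]$beta <- matrix(rep(point, each = 30), nrow = 30)
  }
  bt <- back_transform(fit, "Gram")
  expect_equal(bt$mean, exp(6.05) - exp(5.95), tolerance = 1e-9)
  expect_equal(bt$q2.5, bt$q97.5)  # point mass
  # zero-weight rows back-transform to exactly zero
  attr(fit$X, "hypothesis") <- rbind(attr(fit$X, "hypothesis"),
                                     Null = rep(0, 12))
  bt0 <- back_transform(fit, "Null")
  expect_equal(bt0$mean, 0)
  expect_error(back_transform(fit, "NoSuchEffect"), "absent")
  # draw-level and posterior-mean methods agree at a point mass
  btm <- back_transform(fit, "Gram", method = "posterior_mean")
  expect_equal(btm$mean, exp(6.05) - exp(5.95), tolerance = 1e-9)
})

test_that("a symmetric binary point mass back-transforms to zero effects", {
  des <- make_design(study_plan(n_participants = 4), seed = 109)
  sim <- simulate_measures(des, generative_params("bernoulli"), seed = 109)
  spec <- model_spec("fp_reg", chains = 1, iterations = 60, warmup = 30)
  fit <- fit_reading_model(sim$measures, spec, seed = 109)
  fit$chains[[1]]$beta <- matrix(0, nrow = 30, ncol = 9)
  bt <- back_transform(fit)
  expect_equal(bt$mean, rep(0, 8))
})

test_that("marginal mismatch costs separate elements with a designed penalty", {
  # per-element mismatch penalties (modAdj 0.18, predAdj 0, verb 0) mapped
  # onto the contrast coefficients: Gram is their mean, the interactions
  # their respective element-vs-rest differences
  p <- c(modAdj = 0.18, predAdj = 0, verb = 0)
  beta <- stats::setNames(rep(0, 8), names(generative_params()$beta))
  beta["Gram"] <- mean(p)
  beta["GramxAgrType"] <- p["modAdj"] - (p["predAdj"] + p["verb"]) / 2
  beta["GramxLexCat"] <- p["verb"] - (p["modAdj"] + p["predAdj"]) / 2
  params <- generative_params(beta = beta, sd_b = c(0.2, rep(0.02, 8)),
                              sd_c = rep(0.02, 7), sigma = 0.35)
  des <- make_design(study_plan(n_participants = 48), seed = 110)
  sim <- simulate_measures(des, params, seed = 110)
  spec <- model_spec("total_duration", chains = 2, iterations = 1200,
                     warmup = 400)
  fit <- fit_reading_model(sim$measures, spec, seed = 110)
  mc <- marginal_mismatch_cost(fit, c("modAdj", "predAdj", "verb"))
  expect_equal(mc$element, c("modAdj", "predAdj", "verb"))
  expect_gt(mc$q2.5[mc$element == "modAdj"], 0)
  expect_lt(mc$q2.5[mc$element == "predAdj"], 0)
  expect_gt(mc$q97.5[mc$element == "predAdj"], 0)
  expect_true(all(mc$tail_prob >= 0 & mc$tail_prob <= 1))
  expect_true(all(mc$p_normal >= 0 & mc$p_normal <= 1))
  expect_error(marginal_mismatch_cost(fit, "noun"), "unknown element")
})

test_that("marginal contrast weights sum to zero by construction", {
  cl <- design_cells()
  for (e in c("modAdj", "predAdj", "verb")) {
    w <- numeric(12)
    w[cl$element == e & cl$grammaticality == "mismatch"] <- 1 / 2
    w[cl$element == e & cl$grammaticality == "match"] <- -1 / 2
    expect_equal(sum(w), 0)
  }
})
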