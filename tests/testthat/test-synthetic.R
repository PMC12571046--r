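test_that("the default plan yields the study's trial counts and balance", {
  des <- make_design(study_plan(n_participants = 64), seed = 1)
  expect_equal(nrow(des), 64 * 76)  # 72 experimental + 4 practice
  one <- des[des$participant == 1, ]
  expect_equal(sum(one$item_type == "target"), 24)
  expect_equal(sum(one$item_type == "filler"), 48)
  expect_equal(sum(one$item_type == "practice"), 4)
  expect_equal(sum(one$has_question), 42)
  # 8 targets per element, half mismatch, gender balanced within
  tab <- table(one$element, one$grammaticality)
  expect_true(all(tab == 4))
  tab3 <- table(one$element, one$grammaticality, one$gender)
  expect_true(all(tab3[, , ] == 2))
  # half the fillers ungrammatical
  expect_equal(sum(one$grammaticality[one$item_type == "filler"] == "mismatch"),
               24)
  # condition x list balance is exactly uniform within every list
  targ <- des[des$item_type == "target", ]
  for (l in unique(targ$list)) {
    tab <- table(targ$grammaticality[targ$list == l],
                 targ$element[targ$list == l])
    expect_true(all(tab == tab[1]))
  }
})

test_that("the Latin square rotates item versions across lists", {
  des <- make_design(study_plan(n_participants = 3), seed = 2)
  targ <- des[des$item_type == "target", ]
  # one participant per list; every item appears in both grammaticalities
  # somewhere across the three lists
  for (it in unique(targ$item)) {
    gs <- targ$grammaticality[targ$item == it]
    expect_setequal(unique(gs), c("match", "mismatch"))
  }
  # participants on the same list see identical condition assignments
  des2 <- make_design(study_plan(n_participants = 6), seed = 2)
  t2 <- des2[des2$item_type == "target", ]
  a <- t2[t2$participant == 1, c("item", "grammaticality", "gender")]
  b <- t2[t2$participant == 4, c("item", "grammaticality", "gender")]
  expect_equal(a[order(a$item), ], b[order(b$item), ], ignore_attr = TRUE)
})

test_that("designs and simulations are seed-deterministic and extensible", {
  p <- study_plan(n_participants = 4)
  expect_identical(make_design(p, seed = 9), make_design(p, seed = 9))
  expect_false(identical(make_design(p, seed = 9), make_design(p, seed = 10)))
  # adding participants never perturbs earlier ones
  d4 <- make_design(study_plan(n_participants = 4), seed = 9)
  d6 <- make_design(study_plan(n_participants = 6), seed = 9)
  expect_identical(d4, d6[d6$participant <= 4, ])
  s1 <- simulate_measures(d4, generative_params(), seed = 3)
  s2 <- simulate_measures(d4, generative_params(), seed = 3)
  expect_identical(s1$measures, s2$measures)
})

test_that("odd per-element item counts are rejected", {
  expect_error(study_plan(n_items_per_element = 7), "counterbalance")
})

test_that("degenerate noise collapses simulated RTs to exp(beta0)", {
  des <- make_design(study_plan(n_participants = 2), seed = 4)
  params <- generative_params(
    beta0 = 6, beta = stats::setNames(rep(0, 8), names(generative_params()$beta)),
    sd_b = rep(0, 9), sd_c = rep(0, 7), sigma = 1e-9)
  sim <- simulate_measures(des, params, seed = 4)
  expect_equal(sim$measures$total_duration, rep(exp(6), 48), tolerance = 1e-6)
})

test_that("cell-mean ratios follow the lognormal linear predictor", {
  # Gram coefficient 0.1 and no noise across many simulated participants:
  # mismatch/match cell-mean ratio = e^{0.1} within Monte-Carlo error
  des <- make_design(study_plan(n_participants = 300), seed = 5)
  beta <- stats::setNames(rep(0, 8), names(generative_params()$beta))
  beta["Gram"] <- 0.1
  params <- generative_params(beta0 = 6, beta = beta, sd_b = rep(0, 9),
                              sd_c = rep(0, 7), sigma = 0.3)
  sim <- simulate_measures(des, params, seed = 5)
  m <- sim$measures
  ratio <- mean(m$total_duration[m$grammaticality == "mismatch"]) /
    mean(m$total_duration[m$grammaticality == "match"])
  expect_equal(ratio, exp(0.1), tolerance = 0.02)
})

test_that("a flat Bernoulli model regresses half the time", {
  des <- make_design(study_plan(n_participants = 200), seed = 6)
  beta <- stats::setNames(rep(0, 8), names(generative_params()$beta))
  params <- generative_params("bernoulli", beta0 = 0, beta = beta,
                              sd_b = rep(0, 9), sd_c = rep(0, 7))
  sim <- simulate_measures(des, params, seed = 6)
  expect_equal(mean(sim$measures$fp_reg), 0.5, tolerance = 0.02)
})

test_that("non-positive-definite correlation inputs are rejected", {
  bad <- diag(9); bad[1, 2] <- bad[2, 1] <- 1.2
  des <- make_design(study_plan(n_participants = 2), seed = 7)
  expect_error(
    simulate_measures(des, generative_params(corr_b = bad), seed = 7),
    "positive-definite")
})

test_that("LKJ draws have the known marginal moments", {
  set.seed(77)
  rs <- replicate(4000, rcorr_lkj(3, 2)[1, 2])
  # marginal of an off-diagonal under LKJ(eta) in d=3: 2*Beta(a,a)-1, a=2.5
  expect_lt(abs(mean(rs)), 0.02)
  expect_lt(abs(var(rs) - 1 / (2 * 2.5 + 1)), 0.01)
  expect_true(all(eigen(rcorr_lkj(6, 1))$values > 0))
})

test_that("saccadic trajectories realize their region targets on round trip", {
  plan <- study_plan(n_participants = 2, n_items_per_element = 2,
                     n_fillers = 2, n_practice = 0, n_questions = 8)
  des <- make_design(plan, seed = 15)
  rt <- simulate_region_times(des, generative_params(), seed = 15)
  traj <- simulate_trajectories(des, rt$region_times, p_regress = 0,
                                p_regress_mismatch = 0, seed = 15)
  m <- process_trajectories(traj$samples, traj$layouts, policy = NULL)
  rt2 <- rt$region_times
  tgt <- rt2$target_ms[match(paste(m$participant, m$trial, m$unit),
                             paste(rt2$participant, rt2$trial, rt2$region))]
  expect_lt(max(abs(m$total_duration - tgt)), 50)
  expect_true(all(m$fp_reg == 0) && all(m$reg_in == 0))
  expect_equal(m$gaze_duration, m$total_duration)
})

test_that("forced regressions mark FPReg at the launch and RegIn at the landing", {
  plan <- study_plan(n_participants = 1, n_items_per_element = 2,
                     n_fillers = 0, n_practice = 0, n_questions = 6)
  des <- make_design(plan, seed = 16)
  rt <- simulate_region_times(des, generative_params(), seed = 16)
  traj <- simulate_trajectories(des, rt$region_times, p_regress = 1,
                                p_regress_mismatch = 1, regress_from = 3,
                                regress_to = 2, seed = 16)
  m <- process_trajectories(traj$samples, traj$layouts, policy = NULL)
  expect_true(all(m$fp_reg[m$unit == 3] == 1))
  expect_true(all(m$reg_in[m$unit == 2] == 1))
  # go-past of the launch region includes the regressive revisit
  expect_true(all(m$go_past[m$unit == 3] > m$gaze_duration[m$unit == 3]))
})

test_that("sub-period region targets skip the word with a warning", {
  plan <- study_plan(n_participants = 1, n_items_per_element = 2,
                     n_fillers = 0, n_practice = 0, n_questions = 6)
  des <- make_design(plan, seed = 17)
  rt <- simulate_region_times(des, generative_params(), seed = 17)
  rt$region_times$target_ms[rt$region_times$region == 4] <- 10
  expect_warning(
    traj <- simulate_trajectories(des, rt$region_times, p_regress = 0,
                                  p_regress_mismatch = 0, seed = 17),
    "skipped")
  m <- process_trajectories(traj$samples, traj$layouts, policy = NULL)
  expect_true(all(is.na(m$total_duration[m$unit == 4])))
})

test_that("comprehension simulation respects per-participant accuracy", {
  des <- make_design(study_plan(n_participants = 2), seed = 18)
  comp <- simulate_comprehension(des, accuracy = c(1, 0), seed = 18)
  acc <- tapply(comp$correct, comp$participant, mean)
  expect_equal(as.numeric(acc), c(1, 0))
  expect_equal(as.numeric(table(comp$participant)), c(42, 42))
})
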