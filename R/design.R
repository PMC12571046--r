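# Synthetic study designs, generative reading-measure model, and
# trajectory simulation with known ground truth.

#' Study plan for the factorial agreement experiment
#'
#' Defaults reproduce the study's counting scheme: 24 target items (8 per
#' agreeing element), 48 fillers (half grammatical), 4 practice items,
#' 3 experimental lists, and 42 comprehension questions over the 72
#' non-practice items.
#'
#' @param n_participants number of participants.
#' @param n_items_per_element targets per agreeing element (default 8).
#' @param n_fillers,n_practice,n_lists,n_questions see Description.
#' @return a `study_plan` list.
#' @export
study_plan <- function(n_participants = 64, n_items_per_element = 8,
                       n_fillers = 48, n_practice = 4, n_lists = 3,
                       n_questions = 42) {
  if (n_items_per_element %% 2 != 0) {
    stop("n_items_per_element must be even to counterbalance grammaticality")
  }
  if (n_questions > 3 * n_items_per_element + n_fillers) {
    stop("more questions than non-practice items")
  }
  structure(list(n_participants = n_participants,
                 n_items_per_element = n_items_per_element,
                 n_fillers = n_fillers, n_practice = n_practice,
                 n_lists = n_lists, n_questions = n_questions),
            class = "study_plan")
}

substream_seed <- function(master, counter) {
  # derived per-participant seeds: adding participants never perturbs
  # earlier ones; kept below 2^31
  as.integer((as.numeric(master) %% 1048576 * 2027 + counter * 7919 + 1) %%
               2147483647)
}

#' Generate a trial table under the Latin-square list design
#'
#' Targets rotate through the four item versions (grammaticality x gender)
#' across lists so that, per participant, each agreeing element contributes
#' `n_items_per_element` trials, half mismatch and gender-balanced within
#' grammaticality.  Participants are assigned to lists round-robin.  Half
#' of the fillers are ungrammatical; practice items are generated but
#' flagged for exclusion.  Trial order is shuffled per participant from a
#' derived substream of `seed`.
#'
#' @param plan a [study_plan()].
#' @param seed master RNG seed.
#' @return data.frame with one row per participant x trial: `participant`,
#'   `list`, `trial`, `item`, `item_type` (target/filler/practice),
#'   `element`, `grammaticality`, `gender`, `has_question`.
#' @export
make_design <- function(plan = study_plan(), seed = 1) {
  elements <- c("modAdj", "predAdj", "verb")
  n_t <- 3 * plan$n_items_per_element
  targets <- data.frame(
    item = seq_len(n_t),
    item_type = "target",
    element = rep(elements, each = plan$n_items_per_element),
    k = rep(seq_len(plan$n_items_per_element) - 1L, 3)
  )
  fillers <- data.frame(item = 100 + seq_len(plan$n_fillers),
                        k = seq_len(plan$n_fillers) - 1L)
  practice <- data.frame(item = 900 + seq_len(plan$n_practice),
                         k = seq_len(plan$n_practice) - 1L)
  # deterministic question assignment: all targets, then every filler whose
  # within-block index falls below the remaining quota
  q_fillers <- plan$n_questions - n_t
  if (q_fillers < 0) stop("n_questions smaller than the number of targets")
  rows <- vector("list", plan$n_participants)
  for (p in seq_len(plan$n_participants)) {
    l <- (p - 1L) %% plan$n_lists
    version <- (targets$k + l) %% 4L
    tt <- data.frame(
      participant = p, list = l + 1L, item = targets$item,
      item_type = "target", element = targets$element,
      grammaticality = ifelse(version %% 2L == 0L, "match", "mismatch"),
      gender = ifelse(version %/% 2L == 0L, "feminine", "masculine"),
      has_question = TRUE
    )
    ff <- if (nrow(fillers) > 0) data.frame(
      participant = p, list = l + 1L, item = fillers$item,
      item_type = "filler", element = NA_character_,
      grammaticality = ifelse(fillers$k %% 2L == 0L, "match", "mismatch"),
      gender = NA_character_,
      has_question = fillers$k < q_fillers
    ) else NULL
    pp <- if (nrow(practice) > 0) data.frame(
      participant = p, list = l + 1L, item = practice$item,
      item_type = "practice", element = NA_character_,
      grammaticality = "match", gender = NA_character_,
      has_question = FALSE
    ) else NULL
    main <- rbind(tt, ff)
    ord <- local({
      old <- .Random.seed_get()
      on.exit(.Random.seed_set(old))
      set.seed(substream_seed(seed, p))
      sample.int(nrow(main))
    })
    main <- main[ord, , drop = FALSE]
    out <- rbind(pp, main)
    # globally unique trial ids so layouts/samples key cleanly by trial
    out$trial <- (p - 1L) * nrow(out) + seq_len(nrow(out))
    rows[[p]] <- out
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[, c("participant", "list", "trial", "item", "item_type", "element",
          "grammaticality", "gender", "has_question")]
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Ground-truth parameters for the generative hierarchical model
#'
#' Houses the intercept, the contrast-predictor coefficients, the
#' random-effect standard deviations and correlation matrices for
#' participants and items, and the residual scale.  Defaults are chosen to
#' resemble total-duration reading times on a critical region: a ~490 ms
#' baseline (log-ms intercept 6.2), a mismatch penalty of 0.10 on the log
#' scale, small negative agreement-type and lexical-category effects, a
#' modest positive grammaticality-by-agreement-type interaction, and
#' residual/random-effect scales typical of reading-time data.  For the
#' binary family the intercept is on the log-odds scale (default -1.5,
#' a ~18% baseline regression rate, mismatch log-odds effect 0.5).
#'
#' @param response `"lognormal"` or `"bernoulli"`.
#' @param beta0 intercept (log-ms or log-odds).
#' @param beta named coefficient vector over the 8 default predictors.
#' @param sd_b,sd_c random-effect standard deviations (participant: length
#'   1 + 8; item: length 1 + number of within-item predictors, default 7).
#' @param corr_b,corr_c correlation matrices (default identity).
#' @param sigma residual scale on the log scale (lognormal only).
#' @return a `generative_params` list.
#' @export
generative_params <- function(response = c("lognormal", "bernoulli"),
                              beta0 = NULL, beta = NULL,
                              sd_b = NULL, sd_c = NULL,
                              corr_b = NULL, corr_c = NULL, sigma = 0.45) {
  response <- match.arg(response)
  eff <- c("Gram", "Gen", "AgrType", "LexCat", "GramxAgrType",
           "GramxLexCat", "GramxGenxAgrType", "GramxGenxLexCat")
  if (is.null(beta)) {
    beta <- if (response == "lognormal") {
      stats::setNames(c(0.10, 0.00, -0.10, -0.08, 0.05, 0, 0, 0), eff)
    } else {
      stats::setNames(c(0.50, 0.00, -0.20, -0.10, 0.20, 0, 0, 0), eff)
    }
  }
  if (is.null(beta0)) beta0 <- if (response == "lognormal") 6.2 else -1.5
  q_b <- length(beta) + 1
  if (is.null(sd_b)) sd_b <- c(0.25, rep(0.05, length(beta)))
  if (is.null(corr_b)) corr_b <- diag(q_b)
  p <- list(response = response, beta0 = beta0, beta = beta,
            sd_b = sd_b, corr_b = corr_b, sd_c = sd_c, corr_c = corr_c,
            sigma = sigma)
  class(p) <- "generative_params"
  p
}

check_pd_corr <- function(R, what) {
  if (!isSymmetric(unname(R), tol = 1e-8) ||
      any(abs(diag(R) - 1) > 1e-8) ||
      min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
    stop(what, " is not a symmetric positive-definite correlation matrix")
  }
  invisible(R)
}

#' Draw a random correlation matrix from the LKJ distribution
#'
#' Onion-method sampler; shape `eta = 1` is uniform over correlation
#' matrices and larger `eta` concentrates mass near the identity.
#'
#' @param d dimension.
#' @param eta shape parameter (> 0).
#' @return a d x d correlation matrix.
#' @export
rcorr_lkj <- function(d, eta = 2) {
  stopifnot(d >= 1, eta > 0)
  if (d == 1) return(matrix(1, 1, 1))
  b <- eta + (d - 2) / 2
  r <- 2 * stats::rbeta(1, b, b) - 1
  R <- matrix(c(1, r, r, 1), 2, 2)
  if (d == 2) return(R)
  for (k in 2:(d - 1)) {
    b <- b - 1 / 2
    y <- stats::rbeta(1, k / 2, b)
    u <- stats::rnorm(k)
    u <- u / sqrt(sum(u^2))
    w <- sqrt(y) * u
    q <- t(chol(R)) %*% w
    R <- rbind(cbind(R, q), c(q, 1))
  }
  unname(R)
}

#' Simulate reading measures from the generative hierarchical model
#'
#' Draws per-participant and per-item random effects from multivariate
#' normals with the stated scales and correlations, forms the linear
#' predictor from the contrast-coded cells, and draws lognormal reading
#' times or Bernoulli regression indicators.  Between-item predictors
#' (those constant within an agreeing element) are excluded from the
#' by-item random-effect structure.  Filler/practice rows, if present in
#' the design, are simulated from the same model with all condition
#' effects zeroed.
#'
#' @param design trial table from [make_design()] (or any data.frame with
#'   `participant`, `item`, `grammaticality`, `gender`, `element`).
#' @param params a [generative_params()].
#' @param X a `contrast_matrix` ([hypothesis_to_contrast()]).
#' @param measure which measure column the draws populate (default
#'   `"total_duration"` for lognormal, `"fp_reg"` for bernoulli).
#' @param seed RNG seed.
#' @return list with `measures` (a measures data.frame with column
#'   `region = 3` and the simulated measure filled) and `truth` (all
#'   latent parameters and random-effect draws).
#' @export
simulate_measures <- function(design, params, X = NULL, measure = NULL,
                              seed = 1) {
  stopifnot(inherits(params, "generative_params"))
  if (is.null(X)) X <- hypothesis_to_contrast(default_hypothesis_matrix())
  if (is.null(measure)) {
    measure <- if (params$response == "lognormal") "total_duration" else "fp_reg"
  }
  targets <- design[design_is_target(design), , drop = FALSE]
  eff <- setdiff(colnames(X), "(Intercept)")
  if (!setequal(names(params$beta), eff)) {
    stop("params$beta names do not match contrast matrix predictors")
  }
  beta_full <- c(params$beta0, params$beta[eff])
  Xa <- X[, c("(Intercept)", eff), drop = FALSE]
  lab <- cell_label(targets)
  U <- Xa[lab, , drop = FALSE]          # n x (1+P) participant design
  within <- !between_item_flags(X)[eff]
  item_cols <- c("(Intercept)", eff[within])
  V <- Xa[lab, item_cols, drop = FALSE]  # n x (1+q) item design
  q_b <- ncol(U); q_c <- ncol(V)
  sd_b <- params$sd_b
  sd_c <- if (is.null(params$sd_c)) c(0.10, rep(0.03, q_c - 1)) else params$sd_c
  corr_b <- params$corr_b
  corr_c <- if (is.null(params$corr_c)) diag(q_c) else params$corr_c
  stopifnot(length(sd_b) == q_b, length(sd_c) == q_c)
  check_pd_corr(corr_b, "corr_b"); check_pd_corr(corr_c, "corr_c")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(substream_seed(seed, 0))
  participants <- sort(unique(targets$participant))
  items <- sort(unique(targets$item))
  Lb <- t(chol(corr_b)); Lc <- t(chol(corr_c))
  b <- t(vapply(participants, function(i)
    as.numeric(diag(sd_b, q_b) %*% Lb %*% stats::rnorm(q_b)), numeric(q_b)))
  cc <- t(vapply(items, function(j)
    as.numeric(diag(sd_c, q_c) %*% Lc %*% stats::rnorm(q_c)), numeric(q_c)))
  pi_ <- match(targets$participant, participants)
  ij <- match(targets$item, items)
  eta <- as.numeric(U %*% beta_full) +
    rowSums(U * b[pi_, , drop = FALSE]) +
    rowSums(V * cc[ij, , drop = FALSE])
  y <- if (params$response == "lognormal") {
    stats::rlnorm(length(eta), meanlog = eta, sdlog = params$sigma)
  } else {
    stats::rbinom(length(eta), 1, stats::plogis(eta))
  }
  meas <- data.frame(
    participant = targets$participant, item = targets$item, region = 3L,
    gaze_duration = NA_real_, go_past = NA_real_,
    total_duration = NA_real_, fp_reg = NA_real_, reg_in = NA_real_,
    grammaticality = targets$grammaticality, gender = targets$gender,
    element = targets$element, source = "motr"
  )
  meas[[measure]] <- y
  truth <- list(beta0 = params$beta0, beta = params$beta, b = b, c = cc,
                sd_b = sd_b, sd_c = sd_c, corr_b = corr_b, corr_c = corr_c,
                sigma = params$sigma, response = params$response,
                eta = eta, seed = seed, item_predictors = item_cols)
  list(measures = meas, truth = truth)
}

design_is_target <- function(design) {
  if ("item_type" %in% names(design)) design$item_type == "target"
  else !is.na(design$element)
}

between_item_flags <- function(X) {
  cl <- design_cells()
  eff <- setdiff(colnames(X), "(Intercept)")
  vapply(eff, function(e) {
    all(tapply(X[cl$cell, e], cl$element, function(v) diff(range(v)) < 1e-12))
  }, logical(1))
}

#' Simulate per-region target dwell times for whole trials
#'
#' Region 3 (the critical region, containing the head noun) follows the
#' generative hierarchical model; the other regions draw lognormal
#' baseline times without condition effects.  Filler and practice trials
#' use baseline times in every region.
#'
#' @param design trial table from [make_design()].
#' @param params a [generative_params()] (lognormal).
#' @param X contrast matrix.
#' @param baseline_meanlog log-ms mean dwell for non-critical regions.
#' @param baseline_sdlog log-ms sd for non-critical regions.
#' @param seed RNG seed.
#' @return list: `region_times` (data.frame participant, trial, item,
#'   region, target_ms) and `truth` from [simulate_measures()].
#' @export
simulate_region_times <- function(design, params = generative_params(),
                                  X = NULL, baseline_meanlog = 6.0,
                                  baseline_sdlog = 0.25, seed = 1) {
  if (is.null(X)) X <- hypothesis_to_contrast(default_hypothesis_matrix())
  sim <- simulate_measures(design, params, X, measure = "total_duration",
                           seed = seed)
  crit <- sim$measures
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  rows <- vector("list", length(unique(design$participant)))
  for (p in sort(unique(design$participant))) {
    set.seed(substream_seed(seed, 10000 + p))
    dd <- design[design$participant == p, , drop = FALSE]
    base <- matrix(stats::rlnorm(nrow(dd) * 5, baseline_meanlog,
                                 baseline_sdlog), ncol = 5)
    long <- data.frame(
      participant = p,
      trial = rep(dd$trial, each = 5),
      item = rep(dd$item, each = 5),
      region = rep(1:5, nrow(dd)),
      target_ms = as.numeric(t(base))
    )
    # target trials: the critical region realizes the hierarchical model draw
    crit_key <- paste(crit$participant, crit$item)
    sel <- long$region == 3
    hit <- match(paste(long$participant[sel], long$item[sel]), crit_key)
    long$target_ms[sel][!is.na(hit)] <- crit$total_duration[hit[!is.na(hit)]]
    rows[[p]] <- long
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(region_times = out, truth = sim$truth)
}

#' Synthesize single-line word layouts from a fixed-width character metric
#'
#' One word per region, five regions per trial.  Word lengths are drawn
#' deterministically from the trial's item id, so layouts are reproducible
#' and length-sensitive.
#'
#' @param design trial table (one layout per distinct `trial` per
#'   participant is not needed: layouts are keyed by `trial`).
#' @param char_px pixels per character (monospace), default 14.
#' @param gap_px inter-word gap, default 14.
#' @param y_top,height vertical extent of the text line.
#' @return layout data.frame in the [read_layout()] schema.
#' @export
template_layout <- function(design, char_px = 14, gap_px = 14,
                            y_top = 300, height = 36) {
  trials <- unique(design[, c("trial", "item")])
  rows <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    item <- trials$item[i]
    lens <- 4 + (item * c(7, 3, 11, 5, 13)) %% 6  # 4..9 chars, item-keyed
    x0 <- 40
    wr <- vector("list", 5)
    for (w in 1:5) {
      x1 <- x0 + lens[w] * char_px
      wr[[w]] <- data.frame(
        trial = trials$trial[i], word_index = w - 1L,
        text = strrep(letters[(item + w) %% 26 + 1], lens[w]),
        x_min = x0, x_max = x1, y_min = y_top, y_max = y_top + height,
        region = w
      )
      x0 <- x1 + gap_px
    }
    rows[[i]] <- do.call(rbind, wr)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate mouse trajectories realizing target region times
#'
#' The saccadic profile dwells near each word's center for its target time
#' (samples every 50 ms, small positional jitter inside the box), jumping
#' between words in one inter-sample step; the smooth profile sweeps each
#' word at piecewise-constant velocity so traversal time matches the
#' target.  With probability `p_regress` (`p_regress_mismatch` on mismatch
#' trials) a regression is inserted after the first pass on region
#' `regress_from`: the cursor returns to region `regress_to` for a drawn
#' revisit time and then resumes at the next unread region.  Target times
#' shorter than one sample period cause the word to be skipped, with a
#' warning.
#'
#' @param design trial table from [make_design()].
#' @param region_times data.frame from [simulate_region_times()].
#' @param layouts layout table; defaults to [template_layout()] on `design`.
#' @param profile `"saccadic"` or `"smooth"`.
#' @param p_regress,p_regress_mismatch regression probabilities by
#'   grammaticality (defaults 0.12 / 0.17).
#' @param regress_from region whose first pass launches the regression
#'   (default 4, the region after the critical one).
#' @param regress_to landing region (default 3).
#' @param revisit_meanlog,revisit_sdlog lognormal revisit-time parameters.
#' @param jitter_px positional jitter inside word boxes (saccadic).
#' @param seed RNG seed.
#' @return list: `samples` (read_samples schema), `layouts`.
#' @export
simulate_trajectories <- function(design, region_times, layouts = NULL,
                                  profile = c("saccadic", "smooth"),
                                  p_regress = 0.12, p_regress_mismatch = 0.17,
                                  regress_from = 4, regress_to = 3,
                                  revisit_meanlog = 5.6, revisit_sdlog = 0.3,
                                  jitter_px = 3, seed = 1) {
  profile <- match.arg(profile)
  if (is.null(layouts)) layouts <- template_layout(design)
  period <- MOTR_PERIOD_MS
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  out <- vector("list", 0)
  skipped <- 0L
  for (p in sort(unique(design$participant))) {
    set.seed(substream_seed(seed, 20000 + p))
    dd <- design[design$participant == p, , drop = FALSE]
    for (r in seq_len(nrow(dd))) {
      tr <- dd$trial[r]
      lay <- layouts[layouts$trial == tr, , drop = FALSE]
      lay <- lay[order(lay$word_index), ]
      rt <- region_times[region_times$participant == p &
                           region_times$trial == tr, , drop = FALSE]
      tgt <- rt$target_ms[match(lay$region, rt$region)]
      is_mm <- !is.na(dd$grammaticality[r]) &&
        dd$grammaticality[r] == "mismatch"
      p_reg <- if (is_mm) p_regress_mismatch else p_regress
      do_reg <- stats::runif(1) < p_reg
      # visit plan: (region, dwell) pairs in reading order, with an
      # optional regressive revisit after the first pass on regress_from
      plan <- data.frame(word = seq_len(nrow(lay)), ms = tgt)
      if (do_reg && regress_from <= nrow(lay) && regress_to < regress_from) {
        revisit <- stats::rlnorm(1, revisit_meanlog, revisit_sdlog)
        plan <- rbind(plan[seq_len(regress_from), ],
                      data.frame(word = regress_to, ms = revisit),
                      if (regress_from < nrow(lay))
                        plan[seq(regress_from + 1, nrow(lay)), ])
      }
      n_samp <- round(plan$ms / period)
      if (any(n_samp < 1)) {
        skipped <- skipped + sum(n_samp < 1)
        plan <- plan[n_samp >= 1, , drop = FALSE]
        n_samp <- n_samp[n_samp >= 1]
      }
      xs <- ys <- numeric(sum(n_samp))
      k <- 0
      for (v in seq_len(nrow(plan))) {
        w <- plan$word[v]
        cx <- (lay$x_min[w] + lay$x_max[w]) / 2
        cy <- (lay$y_min[w] + lay$y_max[w]) / 2
        m <- n_samp[v]
        if (profile == "saccadic") {
          jx <- pmin(pmax(stats::rnorm(m, 0, jitter_px),
                          lay$x_min[w] - cx + 1), lay$x_max[w] - cx - 1)
          jy <- pmin(pmax(stats::rnorm(m, 0, jitter_px),
                          lay$y_min[w] - cy + 1), lay$y_max[w] - cy - 1)
          xs[k + seq_len(m)] <- cx + jx
          ys[k + seq_len(m)] <- cy + jy
        } else {
          # constant-velocity sweep across the word's box
          xs[k + seq_len(m)] <- seq(lay$x_min[w] + 1, lay$x_max[w] - 1,
                                    length.out = m)
          ys[k + seq_len(m)] <- cy
        }
        k <- k + m
      }
      out[[length(out) + 1]] <- data.frame(
        participant = p, trial = tr,
        t = seq(0, by = period, length.out = length(xs)), x = xs, y = ys)
    }
  }
  if (skipped > 0) {
    warning(skipped, " word visit(s) below one sample period were skipped")
  }
  samples <- do.call(rbind, out)
  rownames(samples) <- NULL
  list(samples = samples, layouts = layouts)
}

#' Simulate comprehension-question responses
#'
#' @param design trial table from [make_design()].
#' @param accuracy scalar or per-participant named/indexed vector of
#'   probabilities of a correct answer.
#' @param seed RNG seed.
#' @return comprehension data.frame (`participant`, `item`, `correct`).
#' @export
simulate_comprehension <- function(design, accuracy = 0.92, seed = 1) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  qs <- design[design$has_question, , drop = FALSE]
  rows <- vector("list", 0)
  participants <- sort(unique(qs$participant))
  acc <- rep(accuracy, length.out = length(participants))
  for (idx in seq_along(participants)) {
    p <- participants[idx]
    set.seed(substream_seed(seed, 30000 + p))
    qq <- qs[qs$participant == p, , drop = FALSE]
    rows[[idx]] <- data.frame(
      participant = p, item = qq$item,
      correct = stats::rbinom(nrow(qq), 1, acc[idx]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
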