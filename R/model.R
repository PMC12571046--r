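# Bayesian hierarchical models for reading measures: lognormal durations,
# Bernoulli regression indicators, crossed random effects with
# LKJ-correlated slopes.

#' Default mildly informative priors
#'
#' Reading times (lognormal): intercept Normal(6, 1) on log-ms (a ~403 ms
#' central tendency), slopes Normal(0, 0.1), random-effect standard
#' deviations Exponential(2), correlation matrices LKJ(2) (favoring
#' correlations around zero), residual scale Exponential(2).  Binary
#' measures (Bernoulli-logit): intercept and slopes Normal(0, 1), same
#' random-effect priors, no residual scale.
#'
#' @param response `"lognormal"` or `"bernoulli"`.
#' @return list with `beta0_mean`, `beta0_sd`, `beta_sd`, `sd_rate`,
#'   `lkj_eta`, `sigma_rate`.
#' @export
default_priors <- function(response = c("lognormal", "bernoulli")) {
  response <- match.arg(response)
  if (response == "lognormal") {
    list(beta0_mean = 6, beta0_sd = 1, beta_sd = 0.1,
         sd_rate = 2, lkj_eta = 2, sigma_rate = 2)
  } else {
    list(beta0_mean = 0, beta0_sd = 1, beta_sd = 1,
         sd_rate = 2, lkj_eta = 2, sigma_rate = NA_real_)
  }
}

#' Specify a hierarchical reading-measure model
#'
#' @param measure response column: one of `"gaze_duration"`, `"go_past"`,
#'   `"total_duration"`, `"fp_reg"`, `"reg_in"` (or any numeric column).
#' @param response likelihood family; defaults to lognormal for duration
#'   measures and bernoulli for `fp_reg`/`reg_in`.
#' @param predictors character vector of contrast predictors; default all
#'   non-intercept columns of the contrast matrix at fit time.
#' @param priors prior list as from [default_priors()]; `beta_sd` may be a
#'   single value or a named vector giving per-predictor prior scales
#'   (used by the Bayes-factor prior-sensitivity sweep).
#' @param chains,iterations,warmup,thin sampler settings (defaults 4
#'   chains of 4000 iterations, 2000 warmup).
#' @return a `model_spec` list.
#' @export
model_spec <- function(measure = "total_duration", response = NULL,
                       predictors = NULL, priors = NULL,
                       chains = 4, iterations = 4000, warmup = 2000,
                       thin = 1) {
  if (is.null(response)) {
    response <- if (measure %in% c("fp_reg", "reg_in")) "bernoulli" else "lognormal"
  }
  response <- match.arg(response, c("lognormal", "bernoulli"))
  if (is.null(priors)) priors <- default_priors(response)
  stopifnot(warmup < iterations, chains >= 1)
  structure(list(measure = measure, response = response,
                 predictors = predictors, priors = priors,
                 chains = chains, iterations = iterations,
                 warmup = warmup, thin = thin),
            class = "model_spec")
}

#' Fit the hierarchical model by Gibbs sampling
#'
#' By-participant random effects cover the intercept and every predictor;
#' by-item random effects cover the intercept and the within-item
#' predictors only.  Rows with a missing response are dropped (and
#' counted); lognormal responses must be positive.  Chains are run
#' serially from seeds derived from `seed`; two runs with the same seed
#' and data produce identical draws.
#'
#' @param measures a measures data.frame (design factor columns required;
#'   predictor columns are attached from `X` if absent).
#' @param spec a [model_spec()].
#' @param X a `contrast_matrix`; default [default_hypothesis_matrix()]
#'   converted via [hypothesis_to_contrast()].
#' @param seed integer seed.
#' @param store_z keep random-effect draws (needed for marginal
#'   likelihood estimation).
#' @return an object of class `motr_fit`.
#' @export
fit_reading_model <- function(measures, spec = model_spec(), X = NULL,
                              seed = 1, store_z = FALSE) {
  if (is.null(X)) X <- hypothesis_to_contrast(default_hypothesis_matrix())
  predictors <- spec$predictors
  if (is.null(predictors)) predictors <- setdiff(colnames(X), "(Intercept)")
  if (!all(predictors %in% names(measures))) {
    measures <- attach_contrasts(measures, X)
  }
  y_raw <- measures[[spec$measure]]
  keep <- !is.na(y_raw)
  n_dropped <- sum(!keep)
  dat <- measures[keep, , drop = FALSE]
  y <- y_raw[keep]
  if (spec$response == "lognormal") {
    if (any(y <= 0)) stop("lognormal response requires positive durations")
    y_work <- log(y)
    family <- 0L
  } else {
    if (!all(y %in% c(0, 1))) stop("bernoulli response must be 0/1")
    y_work <- y
    family <- 1L
  }
  U <- cbind(1, as.matrix(dat[, predictors, drop = FALSE]))
  colnames(U) <- c("(Intercept)", predictors)
  between <- between_item_flags(X)[predictors]
  item_cols <- c("(Intercept)", predictors[!between])
  V <- U[, item_cols, drop = FALSE]
  participants <- sort(unique(dat$participant))
  items <- sort(unique(dat$item))
  pid <- match(dat$participant, participants) - 1L
  iid <- match(dat$item, items) - 1L
  pr <- spec$priors
  beta_sd <- rep(pr$beta_sd, length.out = length(predictors))
  if (!is.null(names(pr$beta_sd))) {
    beta_sd <- rep(pr$beta_sd[[1]], length(predictors))
    hit <- intersect(names(pr$beta_sd), predictors)
    beta_sd[match(hit, predictors)] <- pr$beta_sd[hit]
  }
  beta_mean <- c(pr$beta0_mean, rep(0, length(predictors)))
  beta_sd_full <- c(pr$beta0_sd, beta_sd)
  chains <- vector("list", spec$chains)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  for (ch in seq_len(spec$chains)) {
    set.seed(substream_seed(seed, 500 + ch))
    chains[[ch]] <- gibbs_hier(
      y_work, family, U, V, pid, iid, length(participants), length(items),
      beta_mean, beta_sd_full,
      pr$sd_rate, pr$lkj_eta,
      if (is.na(pr$sigma_rate)) 2 else pr$sigma_rate,
      match(item_cols, colnames(U)) - 1L,
      spec$iterations, spec$warmup, spec$thin, store_z)
  }
  fit <- structure(list(
    spec = spec, X = X, predictors = predictors, item_cols = item_cols,
    chains = chains, family = family, y = y_work, U = U, V = V,
    pid = pid, iid = iid,
    participants = participants, items = items,
    priors = list(beta_mean = beta_mean, beta_sd = beta_sd_full,
                  sd_rate = pr$sd_rate, lkj_eta = pr$lkj_eta,
                  sigma_rate = if (is.na(pr$sigma_rate)) 2 else pr$sigma_rate),
    n_dropped = n_dropped, seed = seed, store_z = store_z
  ), class = "motr_fit")
  fit$summary <- posterior_summary(fit)
  fit
}

param_block <- function(fit, block) {
  # iterations x chains x dim array for a stored block
  mats <- lapply(fit$chains, function(ch) as.matrix(ch[[block]]))
  arr <- array(unlist(mats), dim = c(nrow(mats[[1]]), ncol(mats[[1]]),
                                     length(mats)))
  aperm(arr, c(1, 3, 2))
}

#' Combined posterior draws of the fixed effects
#'
#' @param fit a `motr_fit`.
#' @return matrix (draws x coefficients), columns named by predictor.
#' @export
fixef_draws <- function(fit) {
  out <- do.call(rbind, lapply(fit$chains, function(ch) ch$beta))
  colnames(out) <- c("(Intercept)", fit$predictors)
  out
}

#' Posterior summary with convergence diagnostics
#'
#' One row per monitored parameter (fixed effects, random-effect scales,
#' residual scale): posterior mean, 2.5/50/97.5 percent quantiles, split
#' R-hat and bulk effective sample size.  The `converged` attribute flags
#' whether all R-hat are at most 1.01 and all ESS at least 400.
#'
#' @param fit a `motr_fit`.
#' @return data.frame of summaries; attributes `converged`,
#'   `max_rhat`, `min_ess`, `accept_corr` (MH acceptance rates of the
#'   correlation updates), `n_dropped`.
#' @export
posterior_summary <- function(fit) {
  blocks <- list(
    beta = c("(Intercept)", fit$predictors),
    tau_b = paste0("sd_participant[", c("(Intercept)", fit$predictors), "]"),
    tau_c = paste0("sd_item[", fit$item_cols, "]")
  )
  rows <- list()
  for (b in names(blocks)) {
    arr <- param_block(fit, b)
    for (k in seq_len(dim(arr)[3])) {
      m <- arr[, , k]
      rows[[blocks[[b]][k]]] <- summarize_param(m)
    }
  }
  if (fit$family == 0) {
    sig <- sapply(fit$chains, function(ch) as.numeric(ch$sigma))
    rows[["sigma"]] <- summarize_param(sig)
  }
  out <- do.call(rbind, rows)
  out <- data.frame(parameter = names(rows), out, row.names = NULL)
  attr(out, "max_rhat") <- max(out$rhat, na.rm = TRUE)
  attr(out, "min_ess") <- min(out$ess, na.rm = TRUE)
  attr(out, "converged") <- attr(out, "max_rhat") <= 1.01 &&
    attr(out, "min_ess") >= 400
  attr(out, "accept_corr") <- c(
    participant = mean(sapply(fit$chains, `[[`, "accept_b")),
    item = mean(sapply(fit$chains, `[[`, "accept_c")))
  attr(out, "n_dropped") <- fit$n_dropped
  out
}

summarize_param <- function(m) {
  v <- as.vector(m)
  data.frame(mean = mean(v),
             q2.5 = unname(stats::quantile(v, 0.025)),
             median = unname(stats::quantile(v, 0.5)),
             q97.5 = unname(stats::quantile(v, 0.975)),
             rhat = rhat(m), ess = ess_bulk(m))
}

#' @export
print.motr_fit <- function(x, ...) {
  cat("Hierarchical", x$spec$response, "model of", x$spec$measure, "\n")
  cat(sprintf("  %d observations (%d dropped), %d participants, %d items\n",
              length(x$y), x$n_dropped, length(x$participants),
              length(x$items)))
  cat(sprintf("  %d chains x %d iterations (%d warmup)\n", x$spec$chains,
              x$spec$iterations, x$spec$warmup))
  s <- x$summary
  fe <- s[s$parameter %in% c("(Intercept)", x$predictors), ]
  print(data.frame(fe[, c("parameter", "mean", "q2.5", "q97.5", "rhat")],
                   row.names = NULL), digits = 3)
  if (!attr(s, "converged")) {
    cat("! convergence flag: max R-hat", round(attr(s, "max_rhat"), 3),
        ", min ESS", round(attr(s, "min_ess")), "\n")
  }
  invisible(x)
}

#' @export
summary.motr_fit <- function(object, ...) object$summary

#' Back-transform an effect to the millisecond or probability scale
#'
#' Per posterior draw, computes the 12 cell-level linear predictors from
#' the fixed effects via the contrast matrix, applies the inverse link
#' (exp for lognormal, logistic for Bernoulli) cellwise, and applies the
#' effect's hypothesis-row weights to the transformed cell values, so the
#' result reads as a difference between (averaged) condition means.  With
#' `method = "posterior_mean"` the same computation is done once at the
#' posterior mean of the fixed effects (delta-style shortcut) instead of
#' per draw.
#'
#' @param fit a `motr_fit`.
#' @param effect effect label (row of the hypothesis matrix); default all
#'   fitted predictors.
#' @param method `"draws"` (default) or `"posterior_mean"`.
#' @return data.frame with `effect`, `mean`, `q2.5`, `q97.5` on the
#'   response scale; attribute `draws` holds the per-draw effect values
#'   (draws method only).
#' @export
back_transform <- function(fit, effect = NULL,
                           method = c("draws", "posterior_mean")) {
  method <- match.arg(method)
  H <- attr(fit$X, "hypothesis")
  if (is.null(effect)) effect <- fit$predictors
  missing_eff <- setdiff(effect, rownames(H))
  if (length(missing_eff) > 0) {
    stop("effect(s) absent from hypothesis matrix: ",
         paste(missing_eff, collapse = ", "))
  }
  Xc <- fit$X[, c("(Intercept)", fit$predictors), drop = FALSE]
  inv_link <- if (fit$family == 0) exp else stats::plogis
  if (method == "draws") {
    B <- fixef_draws(fit)                    # draws x (1+P)
    cells <- inv_link(B %*% t(Xc))           # draws x 12
    eff_draws <- cells %*% t(H[effect, rownames(Xc), drop = FALSE])
    out <- data.frame(
      effect = effect,
      mean = colMeans(eff_draws),
      q2.5 = apply(eff_draws, 2, stats::quantile, 0.025),
      q97.5 = apply(eff_draws, 2, stats::quantile, 0.975),
      row.names = NULL)
    attr(out, "draws") <- eff_draws
    out
  } else {
    b <- colMeans(fixef_draws(fit))
    cells <- inv_link(as.numeric(Xc %*% b))
    data.frame(effect = effect,
               mean = as.numeric(H[effect, rownames(Xc), drop = FALSE] %*% cells),
               q2.5 = NA_real_, q97.5 = NA_real_, row.names = NULL)
  }
}

#' Per-element mismatch cost via marginal means
#'
#' For each requested agreeing element, the mismatch minus match marginal
#' effect on the response scale (averaging over gender), with a 95%
#' credible interval, the two-sided posterior tail probability of a sign
#' reversal, and a normal-approximation p-value for comparability with
#' frequentist marginal-means output.
#'
#' @param fit a `motr_fit`.
#' @param elements subset of `c("modAdj", "predAdj", "verb")`.
#' @return data.frame, one row per element.
#' @export
marginal_mismatch_cost <- function(fit, elements = c("modAdj", "predAdj")) {
  cl <- design_cells()
  bad <- setdiff(elements, unique(cl$element))
  if (length(bad) > 0) stop("unknown element level(s): ",
                            paste(bad, collapse = ", "))
  Xc <- fit$X[, c("(Intercept)", fit$predictors), drop = FALSE]
  inv_link <- if (fit$family == 0) exp else stats::plogis
  B <- fixef_draws(fit)
  cells <- inv_link(B %*% t(Xc))
  rows <- lapply(elements, function(e) {
    wts <- stats::setNames(numeric(nrow(cl)), cl$cell)
    mm <- cl$cell[cl$element == e & cl$grammaticality == "mismatch"]
    ma <- cl$cell[cl$element == e & cl$grammaticality == "match"]
    wts[mm] <- 1 / length(mm)
    wts[ma] <- -1 / length(ma)
    d <- as.numeric(cells %*% wts[rownames(Xc)])
    p_pos <- mean(d > 0)
    zstat <- mean(d) / stats::sd(d)
    data.frame(element = e, mean = mean(d),
               q2.5 = unname(stats::quantile(d, 0.025)),
               q97.5 = unname(stats::quantile(d, 0.975)),
               tail_prob = 2 * min(p_pos, 1 - p_pos),
               p_normal = 2 * stats::pnorm(-abs(zstat)),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Table-style summary of back-transformed effects
#'
#' One row per effect with the posterior mean and 95% CrI on both the
#' log/logit scale and the back-transformed (ms or probability) scale;
#' the layout of the reported results tables.
#'
#' @param fit a `motr_fit`.
#' @return data.frame.
#' @export
effects_table <- function(fit) {
  s <- fit$summary
  fe <- s[s$parameter %in% fit$predictors, ]
  bt <- back_transform(fit)
  data.frame(effect = fe$parameter,
             est_link = fe$mean, link_q2.5 = fe$q2.5, link_q97.5 = fe$q97.5,
             est_response = bt$mean[match(fe$parameter, bt$effect)],
             resp_q2.5 = bt$q2.5[match(fe$parameter, bt$effect)],
             resp_q97.5 = bt$q97.5[match(fe$parameter, bt$effect)],
             row.names = NULL)
}
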