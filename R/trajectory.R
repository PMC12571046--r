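# From raw mouse samples to attentional associations and reading measures.

MOTR_PERIOD_MS <- 50  # nominal inter-sample gap at 20 Hz

#' Assign every mouse sample to its nearest word
#'
#' Distance is Euclidean from the sample point to the nearest point of each
#' word's bounding box (zero if the point lies inside the box; boxes are
#' half-open on the right/bottom but containment ties are resolved by the
#' same nearest-distance rule).  Exact ties go to the leftmost (lowest
#' `word_index`) word, deterministically.
#'
#' @param samples data.frame with columns `t`, `x`, `y` for one trial,
#'   ordered by `t`.
#' @param layout a single-trial layout data.frame with columns
#'   `word_index`, `x_min`, `x_max`, `y_min`, `y_max` (see [read_layout()]).
#' @return integer vector of word indices (0-based), one per sample.
#' @export
assign_nearest_word <- function(samples, layout) {
  if (nrow(layout) == 0) stop("layout has no words")
  ord <- order(layout$word_index)
  layout <- layout[ord, ]
  n <- nrow(samples)
  d <- matrix(Inf, nrow = n, ncol = nrow(layout))
  for (w in seq_len(nrow(layout))) {
    dx <- pmax(layout$x_min[w] - samples$x, samples$x - layout$x_max[w], 0)
    dy <- pmax(layout$y_min[w] - samples$y, samples$y - layout$y_max[w], 0)
    d[, w] <- sqrt(dx^2 + dy^2)
  }
  # max.col on negated distances with ties.method="first" => leftmost wins
  layout$word_index[max.col(-d, ties.method = "first")]
}

#' Merge consecutive same-word samples into attentional associations
#'
#' A maximal run of consecutive samples assigned to the same word becomes
#' one association.  Its duration is the onset of the next run minus its
#' own onset; the final run's duration is the time from its onset to the
#' last sample plus one nominal sample period (50 ms), so a single-sample
#' trial yields one 50 ms association.
#'
#' @param samples per-trial data.frame ordered by `t` with a `word` column
#'   of word indices (from [assign_nearest_word()]) or separate arguments.
#' @param word optional integer vector of per-sample word indices
#'   overriding `samples$word`.
#' @param layout optional layout used to attach a `region` column.
#' @param period_ms nominal sampling period (default 50).
#' @return data.frame with columns `word_index`, `region` (if layout
#'   given), `onset`, `duration`, one row per association, ordered by
#'   onset; consecutive rows never share `word_index`.
#' @export
merge_associations <- function(samples, word = NULL, layout = NULL,
                               period_ms = MOTR_PERIOD_MS) {
  if (is.null(word)) word <- samples$word
  stopifnot(length(word) == nrow(samples))
  if (nrow(samples) == 0) {
    return(data.frame(word_index = integer(0), onset = numeric(0),
                      duration = numeric(0)))
  }
  if (is.unsorted(samples$t, strictly = TRUE)) {
    stop("sample times must be strictly increasing within a trial")
  }
  run_id <- cumsum(c(1L, as.integer(word[-1] != word[-length(word)])))
  onset <- samples$t[!duplicated(run_id)]
  widx <- word[!duplicated(run_id)]
  last_t <- samples$t[length(word)]
  duration <- c(onset[-1], last_t + period_ms) - onset
  out <- data.frame(word_index = widx, onset = onset, duration = duration)
  if (!is.null(layout)) {
    out$region <- layout$region[match(out$word_index, layout$word_index)]
  }
  out
}

#' Association filtering policy
#'
#' Mirrors fixation-exclusion practice: associations shorter than
#' `min_duration` or longer than `max_duration` are removed (the
#' comparisons are strict, so durations of exactly 160 or 4000 ms are
#' kept).  If `remerge_after_filter`, associations on the same word that
#' become adjacent after removal are re-merged (durations summed) and the
#' merged result re-checked against the maximum only.
#'
#' @param min_duration,max_duration ms bounds (defaults 160 and 4000).
#' @param remerge_after_filter logical, default TRUE.
#' @export
filter_policy <- function(min_duration = 160, max_duration = 4000,
                          remerge_after_filter = TRUE) {
  stopifnot(min_duration > 0, min_duration < max_duration)
  structure(list(min_duration = min_duration, max_duration = max_duration,
                 remerge_after_filter = remerge_after_filter),
            class = "filter_policy")
}

#' Filter associations by duration
#'
#' @param assocs association data.frame from [merge_associations()].
#' @param policy a [filter_policy()].
#' @return filtered associations; attribute `n_removed` records counts.
#' @export
filter_associations <- function(assocs, policy = filter_policy()) {
  keep <- assocs$duration >= policy$min_duration &
    assocs$duration <= policy$max_duration
  n_short <- sum(assocs$duration < policy$min_duration)
  n_long <- sum(assocs$duration > policy$max_duration)
  out <- assocs[keep, , drop = FALSE]
  if (policy$remerge_after_filter && nrow(out) > 1) {
    run_id <- cumsum(c(1L, as.integer(
      out$word_index[-1] != out$word_index[-nrow(out)])))
    merged <- data.frame(
      word_index = out$word_index[!duplicated(run_id)],
      onset = out$onset[!duplicated(run_id)],
      duration = as.numeric(tapply(out$duration, run_id, sum))
    )
    if ("region" %in% names(out)) {
      merged$region <- out$region[!duplicated(run_id)]
    }
    merged <- merged[merged$duration <= policy$max_duration, , drop = FALSE]
    out <- merged
  }
  rownames(out) <- NULL
  attr(out, "n_removed") <- c(short = n_short, long = n_long)
  out
}

#' Compute the five reading measures from a trial's associations
#'
#' For each unit (word or region) the measures follow the standard
#' eye-movement definitions: gaze duration is the dwell during the first
#' pass, ending at the first association off the unit in either direction;
#' go-past time sums all associations from the first encounter until the
#' first association strictly to the right (missing if the unit is never
#' exited rightward before trial end); total duration sums every
#' association on the unit; `fp_reg` is 1 iff the first association after
#' the first pass lies to the left; `reg_in` is 1 iff the unit receives an
#' association after having been exited rightward, 0 if fixated but never
#' so revisited.  Units never associated get all measures missing.
#'
#' @param assocs filtered associations for one trial (must carry `region`
#'   when `granularity = "region"`).
#' @param layout the trial layout (defines the full set of units).
#' @param granularity `"region"` (default) or `"word"`.
#' @return data.frame with one row per unit: `unit`, `gaze_duration`,
#'   `go_past`, `total_duration`, `fp_reg`, `reg_in`.
#' @export
compute_measures <- function(assocs, layout, granularity = c("region", "word")) {
  granularity <- match.arg(granularity)
  if (nrow(assocs) > 0 &&
      any(!assocs$word_index %in% layout$word_index)) {
    stop("association references a word absent from the layout")
  }
  if (granularity == "region") {
    units <- sort(unique(layout$region))
    seq_units <- layout$region[match(assocs$word_index, layout$word_index)]
    dur <- assocs$duration
    if (length(seq_units) > 0) {
      # collapse consecutive same-region associations into region dwells
      run <- cumsum(c(1L, as.integer(seq_units[-1] != seq_units[-length(seq_units)])))
      dur <- as.numeric(tapply(dur, run, sum))
      seq_units <- seq_units[!duplicated(run)]
    }
  } else {
    units <- sort(unique(layout$word_index))
    seq_units <- assocs$word_index
    dur <- assocs$duration
  }
  out <- lapply(units, function(u) measures_for_unit(u, seq_units, dur))
  out <- do.call(rbind, out)
  out <- as.data.frame(out)
  names(out) <- c("gaze_duration", "go_past", "total_duration",
                  "fp_reg", "reg_in")
  cbind(data.frame(unit = units), out)
}

# Single-unit measure walk over an association sequence (units + durations).
measures_for_unit <- function(u, seq_units, dur) {
  k_on <- which(seq_units == u)
  if (length(k_on) == 0) {
    return(c(gaze_duration = NA_real_, go_past = NA_real_,
             total_duration = NA_real_, fp_reg = NA_real_, reg_in = NA_real_))
  }
  f <- k_on[1]
  n <- length(seq_units)
  # first pass: consecutive run on u starting at its first encounter
  e <- f
  while (e < n && seq_units[e + 1] == u) e <- e + 1
  gaze <- sum(dur[f:e])
  fp_reg <- if (e < n) as.numeric(seq_units[e + 1] < u) else 0
  right <- which(seq_units > u & seq_len(n) >= f)
  go_past <- if (length(right) == 0) NA_real_ else sum(dur[f:(right[1] - 1)])
  total <- sum(dur[k_on])
  exited_right <- FALSE
  reg_in <- 0
  for (k in seq_len(n)) {
    if (seq_units[k] == u) {
      if (exited_right) { reg_in <- 1; break }
    } else if (seq_units[k] > u && k > f) {
      exited_right <- TRUE
    }
  }
  c(gaze_duration = gaze, go_past = go_past, total_duration = total,
    fp_reg = fp_reg, reg_in = reg_in)
}

#' Run the full trajectory pipeline over many trials
#'
#' Convenience wrapper: per trial, assign nearest words, merge, filter and
#' compute region-level (or word-level) measures.
#'
#' @param samples samples data.frame (`participant`, `trial`, `t`, `x`, `y`).
#' @param layouts layout data.frame for all trials (see [read_layout()]).
#' @param policy a [filter_policy()] or NULL to skip duration filtering.
#' @param granularity `"region"` or `"word"`.
#' @return measures data.frame with one row per participant x trial x unit
#'   and a `counts` attribute (samples, associations in/out per trial).
#' @export
process_trajectories <- function(samples, layouts, policy = filter_policy(),
                                 granularity = "region") {
  keys <- unique(samples[, c("participant", "trial")])
  res <- vector("list", nrow(keys))
  counts <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    tr <- samples[samples$participant == keys$participant[i] &
                    samples$trial == keys$trial[i], , drop = FALSE]
    tr <- tr[order(tr$t), , drop = FALSE]
    lay <- layouts[layouts$trial == keys$trial[i], , drop = FALSE]
    if (nrow(lay) == 0) stop("no layout for trial ", keys$trial[i])
    w <- assign_nearest_word(tr, lay)
    assoc <- merge_associations(tr, word = w, layout = lay)
    n_assoc_raw <- nrow(assoc)
    if (!is.null(policy)) assoc <- filter_associations(assoc, policy)
    m <- compute_measures(assoc, lay, granularity)
    m$participant <- keys$participant[i]
    m$trial <- keys$trial[i]
    res[[i]] <- m
    counts[[i]] <- data.frame(participant = keys$participant[i],
                              trial = keys$trial[i], n_samples = nrow(tr),
                              n_assoc_raw = n_assoc_raw,
                              n_assoc_kept = nrow(assoc))
  }
  out <- do.call(rbind, res)
  out <- out[, c("participant", "trial", "unit", "gaze_duration", "go_past",
                 "total_duration", "fp_reg", "reg_in")]
  rownames(out) <- NULL
  attr(out, "counts") <- do.call(rbind, counts)
  out
}

#' Exclude participants with low comprehension accuracy
#'
#' @param measures measures data.frame with a `participant` column.
#' @param comprehension data.frame with `participant` and binary `correct`.
#' @param threshold minimum accuracy retained (default 0.8; the comparison
#'   is strict, so a participant at exactly the threshold is kept).
#' @return the retained measures; attribute `exclusions` is a data.frame of
#'   per-participant accuracy with an `excluded` flag.
#' @export
filter_participants <- function(measures, comprehension, threshold = 0.8) {
  stopifnot(all(comprehension$correct %in% c(0, 1)))
  participants <- unique(measures$participant)
  no_records <- setdiff(participants, unique(comprehension$participant))
  if (length(no_records) > 0) {
    stop("participants without comprehension records: ",
         paste(no_records, collapse = ", "))
  }
  acc <- tapply(comprehension$correct, comprehension$participant, mean)
  report <- data.frame(participant = names(acc),
                       accuracy = as.numeric(acc),
                       excluded = as.numeric(acc) < threshold,
                       row.names = NULL)
  drop <- report$participant[report$excluded]
  out <- measures[!measures$participant %in% drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- report
  out
}
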