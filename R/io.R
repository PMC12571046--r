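# On-disk schemas: samples, layouts, measures, comprehension records.
# All files are plain CSV with documented headers.

SAMPLE_COLS <- c("participant", "trial", "t", "x", "y")
LAYOUT_COLS <- c("trial", "word_index", "text", "x_min", "x_max",
                 "y_min", "y_max", "region")
MEASURE_COLS <- c("participant", "item", "region", "gaze_duration",
                  "go_past", "total_duration", "fp_reg", "reg_in",
                  "grammaticality", "gender", "element", "source")
COMPREHENSION_COLS <- c("participant", "item", "correct")

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s: missing column(s) %s", what,
                 paste(miss, collapse = ", ")))
  }
}

#' Read raw mouse samples
#'
#' Expects a CSV with header columns `participant`, `trial`, `t` (ms from
#' trial onset), `x`, `y` (px, origin top-left).  Rows are returned sorted
#' by time within each participant/trial (with a warning if the file was
#' out of order); duplicated time stamps within a trial are a validation
#' error naming the trial.
#'
#' @param path CSV file path.
#' @return data.frame of samples.
#' @export
read_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, SAMPLE_COLS, "samples")
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)) || any(!is.finite(df$t))) {
    stop("samples: non-finite t/x/y values")
  }
  ord <- order(df$participant, df$trial, df$t)
  if (is.unsorted(ord)) {
    warning("samples were not time-ordered; sorting")
  }
  df <- df[ord, , drop = FALSE]
  key <- paste(df$participant, df$trial)
  dup <- duplicated(cbind(key, df$t))
  if (any(dup)) {
    stop("samples: duplicated time stamps within trial(s) ",
         paste(unique(df$trial[dup]), collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_samples
#' @param samples samples data.frame.
#' @export
write_samples <- function(samples, path) {
  check_columns(samples, SAMPLE_COLS, "samples")
  utils::write.csv(samples[, SAMPLE_COLS], path, row.names = FALSE)
  invisible(path)
}

#' Read per-trial word layouts
#'
#' Expects a CSV with columns `trial`, `word_index` (0-based, contiguous),
#' `text`, `x_min`, `x_max`, `y_min`, `y_max` (px; boxes half-open on the
#' right/bottom) and `region` (1-5).  Validates that word indices are
#' contiguous from 0, region labels are non-decreasing in word order, and
#' boxes of distinct words do not overlap.
#'
#' @param path CSV file path.
#' @return data.frame of word boxes.
#' @export
read_layout <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, LAYOUT_COLS, "layout")
  validate_layout(df)
  df
}

validate_layout <- function(df) {
  for (tr in unique(df$trial)) {
    lay <- df[df$trial == tr, , drop = FALSE]
    lay <- lay[order(lay$word_index), , drop = FALSE]
    if (!identical(as.integer(lay$word_index), seq_len(nrow(lay)) - 1L)) {
      stop("layout: word_index not contiguous from 0 in trial ", tr)
    }
    if (is.unsorted(lay$region)) {
      stop("layout: region labels decrease with word order in trial ", tr)
    }
    if (any(lay$x_max <= lay$x_min) || any(lay$y_max <= lay$y_min)) {
      stop("layout: degenerate bounding box in trial ", tr)
    }
    n <- nrow(lay)
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
          overlap_x <- lay$x_min[i] < lay$x_max[j] & lay$x_min[j] < lay$x_max[i]
          overlap_y <- lay$y_min[i] < lay$y_max[j] & lay$y_min[j] < lay$y_max[i]
          if (overlap_x && overlap_y) {
            stop("layout: overlapping boxes for words ", lay$word_index[i],
                 " and ", lay$word_index[j], " in trial ", tr)
          }
        }
      }
    }
  }
  invisible(df)
}

#' @rdname read_layout
#' @param layout layout data.frame.
#' @export
write_layout <- function(layout, path) {
  check_columns(layout, LAYOUT_COLS, "layout")
  validate_layout(layout)
  utils::write.csv(layout[, LAYOUT_COLS], path, row.names = FALSE)
  invisible(path)
}

#' Read a reading-measures table
#'
#' The table carries the five reading measures (durations in ms, binary
#' regression indicators; empty cells denote missing, e.g. skipped-then-
#' revisited regions can lack a gaze duration while having a total
#' duration) plus the three design factors.  Rows are tagged with their
#' `source` so identical models can be fit to mouse-tracking and
#' eye-tracking tables alike.
#'
#' @param path CSV file path.
#' @param source `"motr"` or `"eyetracking"`; overrides/sets the `source`
#'   column.
#' @return validated data.frame of measure rows.
#' @export
read_measures <- function(path, source = c("motr", "eyetracking")) {
  source <- match.arg(source)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$source <- source
  check_columns(df, MEASURE_COLS, "measures")
  validate_measures(df)
  df
}

validate_measures <- function(df) {
  levels_ok <- list(
    grammaticality = c("match", "mismatch"),
    gender = c("feminine", "masculine"),
    element = c("modAdj", "predAdj", "verb"),
    source = c("motr", "eyetracking")
  )
  for (f in names(levels_ok)) {
    bad <- setdiff(unique(df[[f]]), levels_ok[[f]])
    if (length(bad) > 0) {
      stop(sprintf("measures: unknown %s level(s) %s; allowed: %s", f,
                   paste(bad, collapse = ", "),
                   paste(levels_ok[[f]], collapse = ", ")))
    }
  }
  for (m in c("gaze_duration", "go_past", "total_duration")) {
    if (any(df[[m]] < 0, na.rm = TRUE)) stop("measures: negative ", m)
  }
  both <- !is.na(df$gaze_duration) & !is.na(df$go_past)
  if (any(df$gaze_duration[both] > df$go_past[both] + 1e-9)) {
    stop("measures: gaze_duration exceeds go_past")
  }
  both <- !is.na(df$gaze_duration) & !is.na(df$total_duration)
  if (any(df$gaze_duration[both] > df$total_duration[both] + 1e-9)) {
    stop("measures: gaze_duration exceeds total_duration")
  }
  for (m in c("fp_reg", "reg_in")) {
    if (!all(df[[m]] %in% c(0, 1, NA))) stop("measures: non-binary ", m)
  }
  invisible(df)
}

#' @rdname read_measures
#' @param measures measures data.frame.
#' @export
write_measures <- function(measures, path) {
  check_columns(measures, MEASURE_COLS, "measures")
  validate_measures(measures)
  utils::write.csv(measures[, MEASURE_COLS], path, row.names = FALSE)
  invisible(path)
}

#' Read comprehension-question records
#'
#' @param path CSV with columns `participant`, `item`, `correct` (0/1).
#' @return validated data.frame.
#' @export
read_comprehension <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, COMPREHENSION_COLS, "comprehension")
  if (!all(df$correct %in% c(0, 1))) stop("comprehension: correct must be 0/1")
  df
}

#' @rdname read_comprehension
#' @param comprehension comprehension data.frame.
#' @export
write_comprehension <- function(comprehension, path) {
  check_columns(comprehension, COMPREHENSION_COLS, "comprehension")
  utils::write.csv(comprehension[, COMPREHENSION_COLS], path,
                   row.names = FALSE)
  invisible(path)
}
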