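# Brute-force oracle for the five reading measures: a literal walk over an
# association sequence, written independently of the pipeline code.

oracle_measures <- function(units_seq, durs, all_units) {
  out <- lapply(all_units, function(u) {
    on_u <- which(units_seq == u)
    if (length(on_u) == 0) {
      return(data.frame(unit = u, gaze_duration = NA_real_,
                        go_past = NA_real_, total_duration = NA_real_,
                        fp_reg = NA_real_, reg_in = NA_real_))
    }
    f <- on_u[1]
    # first pass: scan forward from the first encounter while still on u
    e <- f
    while (e + 1 <= length(units_seq) && units_seq[e + 1] == u) e <- e + 1
    gaze <- sum(durs[f:e])
    # fp_reg: where does the reader go right after the first pass?
    fp_reg <- 0
    if (e + 1 <= length(units_seq) && units_seq[e + 1] < u) fp_reg <- 1
    # go-past: everything from first encounter to just before the first
    # association strictly right of u; censored if never exited rightward
    gp <- NA_real_
    for (k in f:length(units_seq)) {
      if (units_seq[k] > u) {
        gp <- sum(durs[f:(k - 1)])
        break
      }
    }
    total <- sum(durs[on_u])
    # reg_in: an association on u after u has been exited to the right
    reg_in <- 0
    seen_u <- FALSE
    exited_right <- FALSE
    for (k in seq_along(units_seq)) {
      if (units_seq[k] == u) {
        if (exited_right) reg_in <- 1
        seen_u <- TRUE
      } else if (seen_u && units_seq[k] > u) {
        exited_right <- TRUE
      }
    }
    data.frame(unit = u, gaze_duration = gaze, go_past = gp,
               total_duration = total, fp_reg = fp_reg, reg_in = reg_in)
  })
  do.call(rbind, out)
}

# random association sequence over units 1..n_units
rand_assoc_seq <- function(n_units, n_assoc) {
  units_seq <- sample.int(n_units, n_assoc, replace = TRUE)
  durs <- round(stats::runif(n_assoc, 50, 900), 1)
  list(units = units_seq, durs = durs)
}

# single-line layout with one word per region, regions 1..n
unit_layout <- function(n) {
  data.frame(trial = 1, word_index = seq_len(n) - 1L,
             text = strrep("x", 4),
             x_min = (seq_len(n) - 1) * 100, x_max = (seq_len(n) - 1) * 100 + 80,
             y_min = 0, y_max = 30, region = seq_len(n))
}

# run the pipeline's measure computation on a raw unit sequence
pipeline_measures <- function(units_seq, durs, n_units) {
  lay <- unit_layout(n_units)
  assocs <- data.frame(word_index = units_seq - 1L,
                       onset = cumsum(c(0, durs[-length(durs)])),
                       duration = durs,
                       region = units_seq)
  compute_measures(assocs, lay, granularity = "region")
}

small_measures_sim <- function(n_participants = 12, n_ipe = 4, seed = 1,
                               params = generative_params()) {
  des <- make_design(study_plan(n_participants = n_participants,
                                n_items_per_element = n_ipe), seed = seed)
  simulate_measures(des, params, seed = seed)
}
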