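#' Timing configuration for the finger-tapping task
#'
#' Defaults reproduce the published paradigm: a 4.0 s cue indicating the
#' starting finger, then at least three dot trials at 1.3 s intervals
#' (dot 0.8 s, fixation cross 0.5 s), and an end-of-block button probe
#' testing whether the subject kept track of the tapping sequence.
#'
#' @param cue_duration Cue presentation, seconds.
#' @param iti Inter-trial interval (dot onset to dot onset), seconds.
#' @param dot_duration Dot stimulus duration, seconds.
#' @param fixation_duration Fixation-cross duration after each dot, seconds.
#' @param probe_duration Time allotted to the button probe, seconds.
#' @param inter_block_interval Rest between the probe and the next cue,
#'   seconds.
#' @param lead_in Recording time before the first cue, seconds (must leave
#'   room for pre-stimulus epoch baselines).
#' @return A list of validated timing parameters.
#' @export
paradigm_timing <- function(cue_duration = 4.0, iti = 1.3, dot_duration = 0.8,
                            fixation_duration = 0.5, probe_duration = 1.0,
                            inter_block_interval = 2.0, lead_in = 2.0) {
  cfg <- list(cue_duration = cue_duration, iti = iti,
              dot_duration = dot_duration,
              fixation_duration = fixation_duration,
              probe_duration = probe_duration,
              inter_block_interval = inter_block_interval, lead_in = lead_in)
  bad <- vapply(cfg, function(x)
    !is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0, logical(1))
  if (any(bad))
    stop_config("non-positive or non-numeric timing parameter(s): ",
                paste(names(cfg)[bad], collapse = ", "))
  if (cfg$dot_duration + cfg$fixation_duration > cfg$iti)
    stop_config("dot_duration + fixation_duration must fit inside iti")
  cfg
}

#' Simulate the block/trial structure of a tapping session
#'
#' Generates the event schedule of one session: `n_blocks` blocks, each with
#' a cue (random starting finger 1-4), a random number of dot trials drawn
#' from `trial_counts`, and a button probe after the final trial.
#'
#' @param session `"ME"` (motor execution) or `"MI"` (motor imagery).
#' @param n_blocks Number of blocks (default 20).
#' @param trial_counts Allowed trials per block; subset of `3:5`, minimum 3.
#' @param timing Output of [paradigm_timing()].
#' @param seed Integer seed; identical seeds give identical paradigms.
#' @return An object of class `"tap_paradigm"`: list with `session`,
#'   `timing`, and `blocks` (each block a list with `cue_onset`,
#'   `cue_duration`, `starting_finger`, `trial_onsets`, `dot_duration`,
#'   `fixation_duration`, `probe_onset`).
#' @export
simulate_paradigm <- function(session = c("ME", "MI"), n_blocks = 20,
                              trial_counts = 3:5,
                              timing = paradigm_timing(), seed = 1L) {
  session <- match.arg(session)
  if (!is_count(n_blocks)) stop_config("n_blocks must be a non-negative integer")
  trial_counts <- as.integer(trial_counts)
  if (length(trial_counts) == 0L || !all(trial_counts %in% 3:5))
    stop_config("trial_counts must be a non-empty subset of {3, 4, 5}")
  if (min(trial_counts) < 3L)
    stop_config("every block needs at least 3 trials")

  blocks <- with_seed(seed, {
    t0 <- timing$lead_in
    lapply(seq_len(n_blocks), function(b) {
      n_tr <- if (length(trial_counts) == 1L) trial_counts else
        sample(trial_counts, 1L)
      cue_onset <- t0
      first_dot <- cue_onset + timing$cue_duration
      trial_onsets <- first_dot + (seq_len(n_tr) - 1L) * timing$iti
      probe_onset <- trial_onsets[n_tr] + timing$iti
      t0 <<- probe_onset + timing$probe_duration + timing$inter_block_interval
      list(block_index = b, cue_onset = cue_onset,
           cue_duration = timing$cue_duration,
           starting_finger = sample.int(4L, 1L),
           trial_onsets = trial_onsets, dot_duration = timing$dot_duration,
           fixation_duration = timing$fixation_duration,
           probe_onset = probe_onset)
    })
  })
  structure(list(session = session, timing = timing, blocks = blocks),
            class = "tap_paradigm")
}

#' Flatten a paradigm into an events table
#'
#' @param paradigm A [simulate_paradigm()] object.
#' @return Data frame with columns `onset` (s), `duration` (s),
#'   `trial_type` (`cue`, `dot`, `probe`), `block_index`, `trial_index`
#'   (NA for non-dot events).
#' @export
paradigm_events <- function(paradigm) {
  stopifnot(inherits(paradigm, "tap_paradigm"))
  if (length(paradigm$blocks) == 0L)
    return(data.frame(onset = numeric(), duration = numeric(),
                      trial_type = character(), block_index = integer(),
                      trial_index = integer()))
  rows <- lapply(paradigm$blocks, function(b) {
    n <- length(b$trial_onsets)
    data.frame(
      onset = c(b$cue_onset, b$trial_onsets, b$probe_onset),
      duration = c(b$cue_duration, rep(b$dot_duration, n),
                   paradigm$timing$probe_duration),
      trial_type = c("cue", rep("dot", n), "probe"),
      block_index = b$block_index,
      trial_index = c(NA_integer_, seq_len(n), NA_integer_),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Total session duration in seconds
#' @param paradigm A [simulate_paradigm()] object.
#' @param tail_pad Seconds appended after the last probe.
#' @export
paradigm_duration <- function(paradigm, tail_pad = 5.0) {
  if (length(paradigm$blocks) == 0L) return(paradigm$timing$lead_in + tail_pad)
  b <- paradigm$blocks[[length(paradigm$blocks)]]
  b$probe_onset + paradigm$timing$probe_duration + tail_pad
}

#' Simulate end-of-block button-probe outcomes
#'
#' Per-block compliance outcomes are i.i.d. Bernoulli draws. The default
#' rates are the observed group accuracies: 0.904 for motor execution and
#' 0.845 for motor imagery.
#'
#' @param paradigm A [simulate_paradigm()] object.
#' @param p_correct Probability of a correct probe response; default depends
#'   on `paradigm$session`.
#' @param seed Integer seed.
#' @return Data frame of class `"tap_responses"` with `block_index` and
#'   `response` (`"correct"`/`"incorrect"`).
#' @export
simulate_responses <- function(paradigm,
                               p_correct = if (paradigm$session == "ME")
                                 0.904 else 0.845,
                               seed = 1L) {
  stopifnot(inherits(paradigm, "tap_paradigm"))
  assert_prob(p_correct, "p_correct")
  n <- length(paradigm$blocks)
  ok <- with_seed(seed, rbinom(n, 1L, p_correct) == 1L)
  out <- data.frame(block_index = seq_len(n),
                    response = ifelse(ok, "correct", "incorrect"),
                    stringsAsFactors = FALSE)
  class(out) <- c("tap_responses", class(out))
  out
}

#' @export
print.tap_paradigm <- function(x, ...) {
  n_tr <- vapply(x$blocks, function(b) length(b$trial_onsets), integer(1))
  cat(sprintf("<tap_paradigm> %s session: %d blocks, %s trials/block, %.1f s\n",
              x$session, length(x$blocks),
              if (length(n_tr)) paste(range(n_tr), collapse = "-") else "0",
              paradigm_duration(x)))
  invisible(x)
}
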