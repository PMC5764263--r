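#' Band-limited oscillatory source activity with task-related suppression
#'
#' Generates narrowband (e.g. mu 8-12 Hz) noise at selected ROI sources
#' whose amplitude is scaled by a suppression factor `s < 1` while trials
#' are performed — the generative counterpart of event-related
#' desynchronization. A per-trial suppression vector makes the
#' desynchronization deepen over successive trials.
#'
#' @param paradigm A [simulate_paradigm()] object.
#' @param fs Sampling rate, Hz.
#' @param duration Total duration, seconds.
#' @param components List of component specs, each a list with `roi`
#'   (node label), `freq` (center, Hz), `bandwidth` (Hz), `amplitude`
#'   (source units, RMS), `suppression` (scalar, or vector applied to
#'   successive trials within each block).
#' @param seed Integer seed.
#' @return 4 x n matrix of oscillatory source activity (rows in node
#'   order; zero where no component is defined).
#' @export
simulate_oscillations <- function(paradigm, fs,
                                  duration = paradigm_duration(paradigm),
                                  components = list(
                                    list(roi = "M1", freq = 10,
                                         bandwidth = 4, amplitude = 0.3,
                                         suppression = 0.5)),
                                  seed = 1L) {
  n <- round(duration * fs)
  out <- matrix(0, 4, n, dimnames = list(roi_nodes(), NULL))
  with_seed(seed, {
    for (cmp in components) {
      band <- cmp$freq + c(-0.5, 0.5) * (cmp$bandwidth %||% 4)
      x <- bandpass_filter(rnorm(n), fs, band, order = 4)
      x <- x / sd(x) * cmp$amplitude
      env <- rep(1, n)
      supp <- cmp$suppression %||% 1
      for (b in paradigm$blocks) {
        for (k in seq_along(b$trial_onsets)) {
          s_k <- supp[min(k, length(supp))]
          i0 <- max(1L, round(b$trial_onsets[k] * fs) + 1L)
          i1 <- min(n, i0 + round(paradigm$timing$iti * fs) - 1L)
          env[i0:i1] <- s_k
        }
      }
      ri <- match(cmp$roi, roi_nodes())
      out[ri, ] <- out[ri, ] + x * env
    }
  })
  out
}

#' Simulate a complete task session at the scalp
#'
#' The full stated world of the generator: paradigm and responses, ground
#' truth bilinear network dynamics driven by dot stimuli, oscillatory
#' mu-band activity with task suppression at M1, pink-noise distractor
#' sources, Gaussian-spread lead field projection with channel noise, and
#' injected blink artifacts.
#'
#' @param session `"ME"` or `"MI"`.
#' @param n_blocks Blocks per session (default 20).
#' @param fs Raw sampling rate, Hz (default 1024, so the 512 Hz target is
#'   a true downsample).
#' @param network Ground-truth [motor_network()]; default input PMC for
#'   ME, SMA for MI, structure 2.
#' @param leadfield A [simulate_leadfield()] (built if `NULL`).
#' @param osc_components Passed to [simulate_oscillations()]; `NULL`
#'   disables oscillatory sources.
#' @param dyn_scale Source-unit scale of the network dynamics.
#' @param distractor_sd Pink-noise SD per distractor source.
#' @param noise Channel noise list (`pink_sd`, `sensor_sd`, uV).
#' @param blink_rate,blink_amplitude_uv Artifact settings ([inject_artifacts()]).
#' @param p_correct Probe accuracy; default 0.904 (ME) / 0.845 (MI).
#' @param seed Master seed; sub-stages use fixed offsets from it.
#' @return List: `recording` (events attached, blinks injected),
#'   `paradigm`, `responses`, `sources` (n_sources x n), `network`,
#'   `leadfield`.
#' @export
simulate_session <- function(session = c("ME", "MI"), n_blocks = 20,
                             fs = 1024,
                             network = NULL, leadfield = NULL,
                             osc_components = list(
                               list(roi = "M1", freq = 10, bandwidth = 4,
                                    amplitude = 0.3, suppression = 0.5)),
                             dyn_scale = 1, distractor_sd = 0.15,
                             noise = list(pink_sd = 4, sensor_sd = 2),
                             blink_rate = 0.15, blink_amplitude_uv = 85,
                             p_correct = NULL, seed = 1L) {
  session <- match.arg(session)
  seed <- as.integer(seed)
  network <- network %||%
    motor_network(if (session == "ME") "PMC" else "SMA", structure = 2)
  leadfield <- leadfield %||% simulate_leadfield(seed = seed)
  paradigm <- simulate_paradigm(session, n_blocks, seed = seed)
  responses <- simulate_responses(
    paradigm, p_correct %||% if (session == "ME") 0.904 else 0.845,
    seed = seed + 1L)
  dur <- paradigm_duration(paradigm)
  inp <- paradigm_inputs(paradigm, fs, dur)
  dyn <- simulate_network_dynamics(network, inp$u_drive, inp$u_mod,
                                   dt = 1 / fs) * dyn_scale
  if (!is.null(osc_components) && length(osc_components))
    dyn <- dyn + simulate_oscillations(paradigm, fs, dur, osc_components,
                                       seed = seed + 2L)
  n_src <- ncol(leadfield$gain)
  sources <- matrix(0, n_src, inp$n,
                    dimnames = list(leadfield$source_labels, NULL))
  sources[1:4, ] <- dyn
  if (n_src > 4 && distractor_sd > 0) {
    sources[5:n_src, ] <- with_seed(seed + 3L, {
      t(vapply(5:n_src, function(i) pink_noise(inp$n, distractor_sd),
               numeric(inp$n)))
    })
  }
  events <- paradigm_events(paradigm)
  events$response <- responses$response[events$block_index]
  rec <- project_to_scalp(sources, leadfield, fs, noise, events,
                          seed = seed + 4L)
  rec <- inject_artifacts(rec, blink_rate, blink_amplitude_uv,
                          montage = leadfield$montage %||% montage_1020_32(),
                          seed = seed + 5L)
  list(recording = rec, paradigm = paradigm, responses = responses,
       sources = sources, network = network, leadfield = leadfield)
}
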