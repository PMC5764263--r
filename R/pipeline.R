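#' Default run configuration
#'
#' All stages' parameters in one nested list, serializable to TOML/JSON.
#' The defaults are the full replication scale (20 subjects, 20 blocks,
#' 16 models); tests and examples scale these down explicitly.
#'
#' @param ... Name-value overrides applied on top of the defaults
#'   (`modifyList` semantics, so sections can be partially overridden).
#' @return Nested list of class `"run_config"`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 1,
    n_subjects = 20,
    sessions = c("ME", "MI"),
    simulate = list(n_blocks = 20, fs = 1024, ground_truth_structure = 2,
                    blink_rate = 0.15, blink_amplitude_uv = 85,
                    mu_suppression = 0.5, n_distractors = 20),
    preprocess = list(band_low = 0.1, band_high = 50, fs_target = 512,
                      tmin = -1.0, tmax = 4.0, reject_uv = 100,
                      blink_removal = "template_regression", flat_uv = 0.2),
    ersp = list(channels = c("C3", "C4"), freq_lo = 4, freq_hi = 30),
    source = list(lambda = "auto", roi_radius_mm = 20),
    dcm = list(fs = 64, duration = 4, max_iter = 32, tol = 0.1,
               n_models = 16, data_scale_sd = 0.15),
    stats = list(q = 0.05))
  ov <- list(...)
  if (length(ov)) cfg <- modifyList(cfg, ov)
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

#' Load a run configuration from TOML
#' @param path TOML file (see [write_toml()]).
#' @return A `"run_config"` (defaults filled for unspecified keys).
#' @export
read_run_config <- function(path) {
  do.call(default_run_config, read_toml(path))
}

#' Split epochs into correct/incorrect response streams
#'
#' Partitions retained epochs by the probe outcome of their block; every
#' retained block must have a logged response.
#'
#' @param epochs An `"eeg_epochs"` object.
#' @param responses A [simulate_responses()] table (or data frame with
#'   `block_index`, `response`).
#' @return List with `correct` and `incorrect` epoch objects and `counts`.
#' @export
split_streams <- function(epochs, responses) {
  missing <- setdiff(epochs$info$block_index, responses$block_index)
  if (length(missing))
    stop_input("no response logged for block(s): ",
               paste(missing, collapse = ", "))
  resp <- responses$response[match(epochs$info$block_index,
                                   responses$block_index)]
  pick <- function(keep) {
    out <- epochs
    out$data <- epochs$data[keep, , , drop = FALSE]
    out$info <- epochs$info[keep, , drop = FALSE]
    out
  }
  res <- list(correct = pick(resp == "correct"),
              incorrect = pick(resp == "incorrect"))
  res$counts <- c(correct = sum(resp == "correct"),
                  incorrect = sum(resp == "incorrect"))
  if (res$counts["incorrect"] == 0L)
    warning("incorrect-response stream is empty", call. = FALSE)
  res
}

## Average epochs and prepare the ROI series a DCM is fitted to: crop to
## [0, duration) s relative to the first dot, downsample to the model
## rate, rescale to a reference SD so the shrinkage priors act on a
## common scale (minimum-norm units are arbitrary).
prepare_dcm_data <- function(roi_array, epochs, dcm_cfg) {
  avg <- apply(roi_array, c(2, 3), mean)
  times <- epoch_times(epochs)
  keep <- times >= 0 & times < dcm_cfg$duration
  avg <- avg[, keep, drop = FALSE]
  avg <- resample_signal(avg, epochs$fs, dcm_cfg$fs)
  target_n <- round(dcm_cfg$duration * dcm_cfg$fs)
  avg <- avg[, seq_len(min(ncol(avg), target_n)), drop = FALSE]
  if (ncol(avg) < target_n)
    avg <- cbind(avg, matrix(0, 4, target_n - ncol(avg)))
  sc <- dcm_cfg$data_scale_sd / max(mean(apply(avg, 1, sd)), 1e-12)
  avg * sc
}

#' Run the complete replication pipeline
#'
#' Orchestrates simulate, preprocess, ERSP, source extraction, DCM
#' inversion (models x subjects x streams), family-level BMS and group
#' statistics, writing every stage artifact plus a provenance manifest
#' into `out_dir`. Deterministic given `config$seed`.
#'
#' @param config A [default_run_config()].
#' @param out_dir Output directory (created).
#' @return `out_dir`, invisibly; artifacts on disk, including
#'   `manifest.json` listing the seven stages.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed0 <- as.integer(config$seed)
  stage_log <- character(0)
  note <- function(s) stage_log <<- c(stage_log, s)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  p_cfg <- preproc_config(
    band = c(config$preprocess$band_low, config$preprocess$band_high),
    fs_target = config$preprocess$fs_target,
    epoch_window = c(config$preprocess$tmin, config$preprocess$tmax),
    reject_uv = config$preprocess$reject_uv,
    blink_removal = config$preprocess$blink_removal,
    flat_uv = config$preprocess$flat_uv)
  roiset <- default_roiset(radius_mm = config$source$roi_radius_mm)
  leadfield <- simulate_leadfield(
    roiset = roiset, n_distractors = config$simulate$n_distractors,
    seed = seed0)
  space <- build_model_space()
  n_models <- config$dcm$n_models
  inputs <- dcm_inputs(fs = config$dcm$fs, duration = config$dcm$duration)

  streams <- list()     # per stream: list of per-subject ROI matrices
  ersp_rows <- list()
  rejections <- list()
  current_stage <- "simulate"
  tryCatch({
    for (subj in seq_len(config$n_subjects)) {
      for (session in config$sessions) {
        current_stage <- "simulate"
        sseed <- seed0 + 1000L * subj + 100L * match(session, c("ME", "MI"))
        sim <- simulate_session(
          session, n_blocks = config$simulate$n_blocks,
          fs = config$simulate$fs, leadfield = leadfield,
          osc_components = list(list(
            roi = "M1", freq = 10, bandwidth = 4, amplitude = 0.3,
            suppression = config$simulate$mu_suppression)),
          blink_rate = config$simulate$blink_rate,
          blink_amplitude_uv = config$simulate$blink_amplitude_uv,
          seed = sseed)
        raw_dir <- file.path(out_dir, "raw")
        dir.create(raw_dir, showWarnings = FALSE)
        stem <- sprintf("sub-%02d_ses-%s", subj, session)
        write_edf(sim$recording, file.path(raw_dir, paste0(stem, ".edf")))
        write_events_tsv(sim$recording$events,
                         file.path(raw_dir, paste0(stem, "_events.tsv")))

        current_stage <- "preprocess"
        ep <- preprocess_recording(sim$recording, config = p_cfg)
        rejections[[stem]] <- ep$rejection_log

        current_stage <- "ersp"
        if (dim(ep$data)[1] >= 2) {
          em <- compute_ersp(ep, freqs = config$ersp$freq_lo:config$ersp$freq_hi,
                             channels = config$ersp$channels)
          tb <- ersp_band_table(em)
          tb$subject <- subj
          tb$session <- session
          ersp_rows[[stem]] <- tb
        }

        current_stage <- "source_recon"
        roi <- epochs_to_roi(ep, leadfield, roiset,
                             lambda = config$source$lambda)

        current_stage <- "dcm"
        sp <- split_streams(ep, sim$responses)
        for (resp in c("correct", "incorrect")) {
          eps <- sp[[resp]]
          if (dim(eps$data)[1] == 0L) next
          keep <- match(eps$info$block_index, ep$info$block_index)
          dat <- prepare_dcm_data(roi[keep, , , drop = FALSE], eps,
                                  config$dcm)
          key <- paste0(session, "_", resp)
          streams[[key]] <- c(streams[[key]] %||% list(), list(dat))
        }
      }
    }

    current_stage <- "dcm"
    fits <- list()     # fits[[stream]][[model]][[subject]]
    evidence <- list() # per stream: subjects x models
    for (key in names(streams)) {
      dats <- streams[[key]]
      Fm <- matrix(NA_real_, length(dats), n_models)
      fits[[key]] <- vector("list", n_models)
      for (m in seq_len(n_models)) {
        fits[[key]][[m]] <- lapply(dats, function(d)
          dcm_invert(space$models[[m]], d, inputs,
                     max_iter = config$dcm$max_iter, tol = config$dcm$tol))
        Fm[, m] <- vapply(fits[[key]][[m]], `[[`, numeric(1), "free_energy")
      }
      evidence[[key]] <- Fm
      write.table(data.frame(model = seq_len(n_models),
                             summed_log_evidence = colSums(Fm)),
                  file.path(out_dir, paste0("evidence_", key, ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }

    current_stage <- "bms"
    sub_space <- space
    sub_space$models <- space$models[seq_len(n_models)]
    sub_space$family_of <- space$family_of[seq_len(n_models)]
    sub_space$model_index <- seq_len(n_models)
    bms_out <- list()
    tables <- list()
    for (key in names(streams)) {
      res <- run_bms(sub_space, evidence[[key]])
      bms_out[[key]] <- list(
        summed_F = res$summed_F, p_model = res$p_model,
        p_family = as.list(res$p_family),
        dominant_family = res$dominant_family,
        best_model = res$best_model)
      tables[[key]] <- coupling_table(fits[[key]][[res$best_model]])
    }
    jsonlite::write_json(bms_out, file.path(out_dir, "bms.json"),
                         auto_unbox = TRUE, digits = NA)

    current_stage <- "stats"
    stats_out <- list()
    for (key in names(tables)) {
      if (nrow(tables[[key]]) < 2L) {
        warning("stream ", key, " has < 2 subjects; group statistics skipped",
                call. = FALSE)
        next
      }
      stats_out[[key]] <- list(anova = one_way_anova(tables[[key]]))
      write.table(
        data.frame(edge = colnames(tables[[key]]),
                   mean = colMeans(tables[[key]]),
                   sd = apply(tables[[key]], 2, sd)),
        file.path(out_dir, paste0("couplings_", key, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(tables$ME_correct) && !is.null(tables$MI_correct) &&
        nrow(tables$ME_correct) >= 2 && nrow(tables$MI_correct) >= 2 &&
        nrow(tables$ME_correct) == nrow(tables$MI_correct)) {
      cmp <- compare_streams(tables$ME_correct, tables$MI_correct,
                             q = config$stats$q)
      write.table(cmp, file.path(out_dir, "ttest_ME_vs_MI_correct.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      stats_out$ME_vs_MI_correct <- cmp
    }
    saveRDS_free <- function(obj, path) # plain-text stats dump
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
    saveRDS_free(stats_out, file.path(out_dir, "stats.json"))
  }, error = function(e) {
    stop("pipeline stage '", current_stage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  })

  manifest <- list(
    package = "eegdcm",
    version = as.character(utils::packageVersion("eegdcm")),
    seed = seed0,
    n_subjects = config$n_subjects,
    stages = c("simulate", "preprocess", "ersp", "source_recon", "dcm",
               "bms", "stats"),
    n_models = n_models,
    streams = names(streams),
    rejected_epochs = sum(vapply(rejections, nrow, integer(1))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(ersp_rows))
    write.table(do.call(rbind, ersp_rows),
                file.path(out_dir, "ersp_bands.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}
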