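# Shared fixture builders; everything is generated in code at test time.

# Minimal recording: given channel x sample matrix, wrap as eeg_recording.
make_recording <- function(data, fs, labels = paste0("ch", seq_len(nrow(data))),
                           events = NULL) {
  structure(list(data = data, fs = fs, channel_labels = labels,
                 events = events, artifact_log = NULL),
            class = "eeg_recording")
}

# Minimal epochs object from an n_epochs x n_channels x n_samples array.
make_epochs <- function(arr, fs, tmin = -1,
                        labels = paste0("ch", seq_len(dim(arr)[2]))) {
  dimnames(arr) <- list(NULL, labels, NULL)
  structure(list(data = arr, fs = fs, tmin = tmin, channel_labels = labels,
                 info = data.frame(block_index = seq_len(dim(arr)[1])),
                 rejection_log = data.frame(epoch = integer(),
                                            block_index = integer(),
                                            channel = character(),
                                            reason = character())),
            class = "eeg_epochs")
}

# Identity lead field over k sources (channels == sources).
identity_leadfield <- function(k) {
  list(gain = diag(k), channel_labels = paste0("ch", seq_len(k)),
       source_positions = matrix(0, k, 3),
       source_labels = paste0("s", seq_len(k)))
}
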