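#' Continuous multichannel record
#'
#' Pre-epoching representation: channels x samples voltages with event
#' onsets (sample indices) and their trial metadata.
#'
#' @param data numeric matrix `[channels, samples]` in microvolts.
#' @param srate sampling rate, Hz.
#' @param onsets integer vector of onset sample indices (strictly
#'   increasing).
#' @param trials data frame of per-onset metadata (one row per onset), or
#'   `NULL`.
#' @param channels channel labels.
#' @return An object of class `eeg_continuous`.
#' @export
eeg_continuous <- function(data, srate, onsets, trials = NULL,
                           channels = NULL) {
  stopifnot(is.matrix(data))
  onsets <- as.integer(onsets)
  if (length(onsets) && any(diff(onsets) <= 0))
    stop("onsets must be strictly increasing")
  if (is.null(trials))
    trials <- data.frame(onset = onsets)
  if (nrow(trials) != length(onsets))
    stop("trials must have one row per onset")
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  structure(list(data = data, srate = as.numeric(srate), onsets = onsets,
                 trials = trials, channels = as.character(channels)),
            class = "eeg_continuous")
}

#' Segment a continuous record into epochs
#'
#' Cuts one epoch per event onset, spanning `window[1]..window[2]` seconds
#' around the onset sample. Sample count per epoch is
#' `round((window[2] - window[1]) * srate) + 1`.
#'
#' @param record an [eeg_continuous()].
#' @param window epoch limits in seconds relative to onset.
#' @return An [eeg_epochs()]; metadata rows are carried over.
#' @export
epoch_continuous <- function(record, window = c(-2, 3)) {
  stopifnot(inherits(record, "eeg_continuous"))
  srate <- record$srate
  rel <- round(window[1] * srate):round(window[2] * srate)
  n_samp <- ncol(record$data)
  bad <- record$onsets + rel[1] < 1 | record$onsets + rel[length(rel)] > n_samp
  if (any(bad))
    stop("epoch window exceeds record bounds at onset(s): ",
         paste(record$onsets[bad], collapse = ", "))
  n_tr <- length(record$onsets)
  out <- array(0, dim = c(n_tr, nrow(record$data), length(rel)))
  for (i in seq_len(n_tr))
    out[i, , ] <- record$data[, record$onsets[i] + rel, drop = FALSE]
  eeg_epochs(out, srate, rel / srate, record$trials, record$channels)
}

#' Re-reference epochs to the common average
#'
#' Subtracts, at every sample, the mean over all channels, so the output
#' channel mean is zero at each sample.
#'
#' @param epochs an [eeg_epochs()] with at least 2 channels.
#' @return Re-referenced [eeg_epochs()].
#' @export
rereference_average <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  if (d[2] < 2L) stop("average reference requires at least 2 channels")
  # channel-major view: channels x (trials*samples), subtract column means
  perm <- matrix(aperm(epochs$data, c(2, 1, 3)), nrow = d[2])
  perm <- sweep(perm, 2, colMeans(perm), "-")
  data <- aperm(array(perm, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  eeg_epochs(data, epochs$srate, epochs$times, epochs$trials,
             epochs$channels)
}

#' Demean, detrend and DFT-notch epochs
#'
#' Per trial and channel: removes the whole-trial mean, the best-fit line,
#' and then the power-line component by least-squares fit-and-subtract of a
#' sine/cosine pair at `notch_hz` (a discrete-Fourier-transform filter).
#'
#' @param epochs an [eeg_epochs()].
#' @param notch_hz notch frequency, Hz; must be below Nyquist.
#' @return Cleaned [eeg_epochs()].
#' @export
clean_epochs <- function(epochs, notch_hz = 50) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (notch_hz >= epochs$srate / 2)
    stop("notch frequency must be below the Nyquist frequency")
  d <- dim(epochs$data)
  t <- epochs$times
  # regression basis: intercept, linear trend, sine/cosine at the notch
  basis <- cbind(1, t - mean(t),
                 cos(2 * pi * notch_hz * t), sin(2 * pi * notch_hz * t))
  qrb <- qr(basis)
  # flatten to samples x (trials*channels) and project out the basis
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])
  resid <- flat - basis %*% qr.coef(qrb, flat)
  data <- aperm(array(resid, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  eeg_epochs(data, epochs$srate, epochs$times, epochs$trials,
             epochs$channels)
}

#' Downsample epochs by an integer factor
#'
#' Anti-alias FIR low-pass (zero-phase, applied forwards and backwards)
#' followed by decimation. The factor `srate / target` must be an integer;
#' the new sample count is `floor((n - 1) * target / srate) + 1`.
#'
#' @param epochs an [eeg_epochs()].
#' @param target target sampling rate, Hz.
#' @return Downsampled [eeg_epochs()].
#' @export
downsample <- function(epochs, target = 256) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  q <- epochs$srate / target
  if (abs(q - round(q)) > 1e-9)
    stop("srate must be an integer multiple of the target rate")
  q <- as.integer(round(q))
  if (q == 1L) return(epochs)
  d <- dim(epochs$data)
  # FIR low-pass at 80% of the new Nyquist, zero-phase via filtfilt
  h <- as.numeric(signal::fir1(64, 0.8 / q))
  keep <- seq(1, d[3], by = q)
  out <- array(0, dim = c(d[1], d[2], length(keep)))
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2])) {
      y <- signal::filtfilt(h, 1, epochs$data[i, j, ])
      out[i, j, ] <- y[keep]
    }
  eeg_epochs(out, target, epochs$times[keep], epochs$trials,
             epochs$channels)
}

#' Reject trials by peak-to-peak amplitude
#'
#' Automated stand-in for visual trial rejection: drops every trial whose
#' maximum peak-to-peak amplitude across channels exceeds the threshold.
#'
#' @param epochs an [eeg_epochs()].
#' @param ptp_threshold peak-to-peak threshold in microvolts (> 0).
#' @return The surviving [eeg_epochs()], with attribute `"rejection_log"`:
#'   a data frame of dropped trial indices and their peak-to-peak values.
#' @export
reject_amplitude <- function(epochs, ptp_threshold = 150) {
  stopifnot(inherits(epochs, "eeg_epochs"), ptp_threshold > 0)
  ptp <- apply(epochs$data, 1, function(tr)
    max(apply(tr, 1, function(ch) diff(range(ch)))))
  drop <- which(ptp > ptp_threshold)
  log <- data.frame(trial = drop,
                    reason = rep("ptp_exceeded", length(drop)),
                    ptp = ptp[drop])
  out <- if (length(drop)) subset_trials(epochs, -drop) else epochs
  attr(out, "rejection_log") <- log
  out
}

#' Standard preprocessing chain
#'
#' Applies the fixed-order pipeline: average re-reference, demean/detrend/
#' notch, amplitude rejection, and (if needed) downsampling to the target
#' rate. Input may already be epoched; [epoch_continuous()] handles the
#' segmentation step for continuous records.
#'
#' @param epochs an [eeg_epochs()].
#' @param notch_hz notch frequency (Hz).
#' @param ptp_threshold rejection threshold (microvolts); `NULL` skips
#'   rejection.
#' @param target_srate final sampling rate (Hz).
#' @return Preprocessed [eeg_epochs()].
#' @export
preprocess_epochs <- function(epochs, notch_hz = 50, ptp_threshold = 150,
                              target_srate = 256) {
  out <- rereference_average(epochs)
  out <- clean_epochs(out, notch_hz)
  if (!is.null(ptp_threshold)) out <- reject_amplitude(out, ptp_threshold)
  if (out$srate > target_srate) out <- downsample(out, target_srate)
  out
}
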