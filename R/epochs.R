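#' Epoched EEG container
#'
#' Constructs the package's central data structure: a trials x channels x
#' samples voltage array (microvolts) with a time axis relative to stimulus
#' onset and a per-trial metadata table.
#'
#' @param data numeric array `[trials, channels, samples]`.
#' @param srate sampling rate, Hz.
#' @param times numeric vector of sample times in seconds (length =
#'   `dim(data)[3]`).
#' @param trials data frame with one row per trial (columns such as
#'   `subject`, `group`, `phase`, `story`, `event`, `mode`, `is_target`).
#' @param channels character vector of channel labels (length =
#'   `dim(data)[2]`).
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, srate, times, trials, channels) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (length(times) != dim(data)[3])
    stop("times length must equal the sample dimension")
  if (nrow(trials) != dim(data)[1])
    stop("trial table must have one row per trial")
  if (length(channels) != dim(data)[2])
    stop("channel labels must match the channel dimension")
  if (anyNA(data) || any(!is.finite(data)))
    stop("epoch data contains non-finite values")
  structure(list(data = data, srate = as.numeric(srate),
                 times = as.numeric(times), trials = trials,
                 channels = as.character(channels)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("eeg_epochs: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$srate))
  cat(sprintf("  time %g..%g s\n", x$times[1], x$times[length(x$times)]))
  if (nrow(x$trials))
    cat("  trial columns:", paste(names(x$trials), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

n_trials <- function(epochs) dim(epochs$data)[1]

#' Write / read an epoch container as a plain-text directory
#'
#' The container is a directory holding `meta.json` (sampling rate, time
#' axis, channel labels), `trials.tsv` (trial table) and `data.tsv`
#' (long-format trial, channel, sample index, value). Intended for small
#' exchange and round-trip testing, not bulk storage.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param path directory to create/read.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` the
#'   reconstructed `eeg_epochs`.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(srate = epochs$srate, times = epochs$times,
               channels = epochs$channels, dim = dim(epochs$data))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(epochs$trials, file.path(path, "trials.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  d <- dim(epochs$data)
  long <- data.frame(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    sample = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(epochs$data))
  utils::write.table(long, file.path(path, "data.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  trials <- utils::read.delim(file.path(path, "trials.tsv"),
                              stringsAsFactors = FALSE)
  long <- utils::read.delim(file.path(path, "data.tsv"))
  d <- as.integer(meta$dim)
  data <- array(0, dim = d)
  data[cbind(long$trial, long$channel, long$sample)] <- long$value
  eeg_epochs(data, meta$srate, meta$times, trials, meta$channels)
}

subset_trials <- function(epochs, keep) {
  if (is.logical(keep)) keep <- which(keep)
  eeg_epochs(epochs$data[keep, , , drop = FALSE], epochs$srate,
             epochs$times, epochs$trials[keep, , drop = FALSE],
             epochs$channels)
}
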