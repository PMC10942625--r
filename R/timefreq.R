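#' Sliding Hanning-window time-frequency decomposition
#'
#' For each output time `t` and frequency `f`, a Hanning taper of length
#' `n_cycles / f` seconds (rounded to an odd number of samples) is centred
#' on `t` and the power at `f` is the squared magnitude of the tapered
#' discrete Fourier coefficient. Power is amplitude-calibrated: a
#' stationary sinusoid of amplitude `a` at a bin frequency yields power
#' `a^2 / 2` at every valid time and every frequency. Times where the full
#' window is not supported by the epoch are invalid and stored as `NA`.
#'
#' @param epochs an [eeg_epochs()].
#' @param fmin,fmax,fstep frequency grid in Hz (default 2-45 Hz in 1 Hz
#'   steps).
#' @param n_cycles cycles per window (default 5).
#' @param tstep output time step in seconds (default 0.05, which puts 41
#'   points on 0-2 s).
#' @param out_times optional explicit vector of output time centres;
#'   default is the full `tstep` grid across the epoch.
#' @return An object of class `tfr`: `power` `[trials, channels, freqs,
#'   times]`, `freqs`, `times`, `valid` (freqs x times logical matrix),
#'   `trials`, `channels`.
#' @export
hanning_tfr <- function(epochs, fmin = 2, fmax = 45, fstep = 1,
                        n_cycles = 5, tstep = 0.05, out_times = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"), tstep > 0)
  srate <- epochs$srate
  t_axis <- epochs$times
  epoch_len <- t_axis[length(t_axis)] - t_axis[1]
  if (fmin < 1 / epoch_len)
    stop("fmin must be at least 1 / epoch length")
  freqs <- seq(fmin, fmax, by = fstep)
  if (is.null(out_times)) {
    imin <- ceiling(t_axis[1] / tstep - 1e-9)
    imax <- floor(t_axis[length(t_axis)] / tstep + 1e-9)
    out_times <- (imin:imax) * tstep
  }
  d <- dim(epochs$data)
  ns <- d[3]
  flat <- matrix(epochs$data, nrow = d[1] * d[2])  # (trial,ch) x samples

  power <- array(NA_real_, dim = c(d[1], d[2], length(freqs),
                                   length(out_times)))
  valid <- matrix(FALSE, length(freqs), length(out_times))
  centers <- round((out_times - t_axis[1]) * srate) + 1L

  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    n <- round(n_cycles / f * srate)
    if (n %% 2 == 0) n <- n + 1L
    half <- (n - 1L) / 2L
    ok <- centers - half >= 1L & centers + half <= ns
    if (!any(ok)) {
      warning(sprintf("frequency %g Hz: window longer than epoch; all times masked", f))
      next
    }
    valid[fi, ] <- ok
    h <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
    rel <- (-half):half
    carrier <- exp(-2i * pi * f * rel / srate) * h * (2 / sum(h))
    idx_ok <- which(ok)
    wr <- matrix(0, ns, length(idx_ok))
    wi <- matrix(0, ns, length(idx_ok))
    for (k in seq_along(idx_ok)) {
      rows <- centers[idx_ok[k]] + rel
      wr[rows, k] <- Re(carrier)
      wi[rows, k] <- Im(carrier)
    }
    cr <- flat %*% wr
    ci <- flat %*% wi
    power[, , fi, idx_ok] <- array((cr^2 + ci^2) / 2,
                                   dim = c(d[1], d[2], length(idx_ok)))
  }

  structure(list(power = power, freqs = freqs, times = out_times,
                 valid = valid, trials = epochs$trials,
                 channels = epochs$channels, srate = srate),
            class = "tfr")
}

#' @export
print.tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("tfr: %d trials/conditions x %d channels x %d freqs x %d times\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  freqs %g..%g Hz; times %g..%g s; %d invalid (freq,time) bins\n",
              min(x$freqs), max(x$freqs), min(x$times), max(x$times),
              sum(!x$valid)))
  invisible(x)
}

#' Absolute baseline correction
#'
#' Subtracts, per trial/condition, channel and frequency, the mean power
#' over the baseline window. At low frequencies the sliding window may not
#' cover the full baseline; the mean is then taken over the valid part,
#' and an error is raised only if a frequency has no valid baseline bin.
#'
#' @param tfr a [hanning_tfr()] result.
#' @param window baseline limits in seconds (default -1.8 to -1).
#' @return A `tfr` with baselined power (values may be negative).
#' @export
baseline_absolute <- function(tfr, window = c(-1.8, -1)) {
  stopifnot(inherits(tfr, "tfr"))
  in_win <- tfr$times >= window[1] - 1e-9 & tfr$times <= window[2] + 1e-9
  if (!any(in_win)) stop("baseline window contains no output time bins")
  d <- dim(tfr$power)
  for (fi in seq_along(tfr$freqs)) {
    use <- in_win & tfr$valid[fi, ]
    if (!any(use)) {
      bad <- tfr$freqs[fi]
      stop("no valid baseline bins for frequency ", bad, " Hz")
    }
    base <- apply(tfr$power[, , fi, use, drop = FALSE], c(1, 2), mean)
    tfr$power[, , fi, ] <- tfr$power[, , fi, ] - as.vector(base)
  }
  tfr
}

#' Average repetitions within condition cells
#'
#' Averages trial-level power within each (subject, story, event, phase)
#' cell, excluding target trials. The result is a condition-level `tfr`
#' whose `trials` table has one row per cell (with `n_trials` counts).
#'
#' @param tfr a trial-level `tfr` whose `trials` table has columns
#'   `subject`, `story`, `event`, `phase`, `mode`, `is_target`.
#' @return A condition-level `tfr`.
#' @export
average_reps <- function(tfr) {
  stopifnot(inherits(tfr, "tfr"))
  tab <- tfr$trials
  keep <- !tab$is_target
  cells <- unique(tab[keep, c("subject", "group", "phase", "story",
                              "event", "mode")])
  cells <- cells[order(cells$subject, cells$phase, cells$story,
                       cells$event), ]
  rownames(cells) <- NULL
  d <- dim(tfr$power)
  out <- array(NA_real_, dim = c(nrow(cells), d[2], d[3], d[4]))
  n_tr <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- which(keep & tab$subject == cells$subject[i] &
                   tab$phase == cells$phase[i] &
                   tab$story == cells$story[i] &
                   tab$event == cells$event[i])
    if (!length(sel))
      stop(sprintf("empty cell: subject %s phase %s story %s event %s",
                   cells$subject[i], cells$phase[i], cells$story[i],
                   cells$event[i]))
    n_tr[i] <- length(sel)
    out[i, , , ] <- colMeans(tfr$power[sel, , , , drop = FALSE], dims = 1)
  }
  cells$n_trials <- n_tr
  structure(list(power = out, freqs = tfr$freqs, times = tfr$times,
                 valid = tfr$valid, trials = cells,
                 channels = tfr$channels, srate = tfr$srate),
            class = "tfr")
}

#' Extract theta-band feature vectors
#'
#' Slices the 4-7 Hz x 0-2 s block of a `tfr`: four frequency bins and,
#' at the default 50 ms step, 41 time bins.
#'
#' @param tfr a `tfr` covering 4-7 Hz and 0-2 s.
#' @param freq_range theta limits in Hz.
#' @param time_range feature window in seconds.
#' @return An object of class `theta_features`: `values`
#'   `[condition, channels, freqs, times]` plus the condition table.
#' @export
theta_features <- function(tfr, freq_range = c(4, 7),
                           time_range = c(0, 2)) {
  stopifnot(inherits(tfr, "tfr"))
  fi <- which(tfr$freqs >= freq_range[1] - 1e-9 &
                tfr$freqs <= freq_range[2] + 1e-9)
  ti <- which(tfr$times >= time_range[1] - 1e-9 &
                tfr$times <= time_range[2] + 1e-9)
  if (!length(fi) || !length(ti))
    stop("tfr does not cover the requested theta frequency/time block")
  if (!all(tfr$valid[fi, ti]))
    stop("theta feature block contains invalid (masked) bins")
  structure(list(values = tfr$power[, , fi, ti, drop = FALSE],
                 freqs = tfr$freqs[fi], times = tfr$times[ti],
                 trials = tfr$trials, channels = tfr$channels),
            class = "theta_features")
}

#' @export
print.theta_features <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("theta_features: %d conditions x %d channels x %d freqs x %d times\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}
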