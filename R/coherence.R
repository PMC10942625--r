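#' Number of sliding windows inside a span
#'
#' @param span_start,span_end span limits in seconds.
#' @param length window length in seconds.
#' @param step slide step in seconds.
#' @return `floor((span_end - span_start - length) / step) + 1`; 31 for
#'   the default 0-2 s span with 0.5 s windows sliding by 0.05 s.
#' @export
n_windows <- function(span_start = 0, span_end = 2, length = 0.5,
                      step = 0.05) {
  if (step <= 0) stop("step must be positive")
  if (length > span_end - span_start)
    stop("window length exceeds the span")
  as.integer(floor((span_end - span_start - length) / step + 1e-9) + 1L)
}

#' First discrete prolate spheroidal (Slepian) sequence
#'
#' Computed exactly as the leading eigenvector of the standard symmetric
#' tridiagonal matrix for time-half-bandwidth product `n * w`.
#'
#' @param n sequence length in samples.
#' @param w normalized half-bandwidth (cycles per sample).
#' @return Unit-norm numeric vector of length `n` (positive mean).
#' @export
dpss_taper <- function(n, w) {
  stopifnot(n >= 2, w > 0, w < 0.5)
  t <- seq_len(n) - 1
  md <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  od <- t[-1] * (n - t[-1]) / 2
  m <- diag(md)
  m[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- od
  m[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- od
  e <- eigen(m, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Sliding-window trial-averaged cross-spectra at one frequency
#'
#' Windows of `window` seconds slide over `span` in steps of `step`. In
#' each window, dpss-tapered Fourier coefficients at `f0` are computed per
#' trial and channel, and the cross-spectral matrix is the average of
#' their outer products over trials (and tapers). The taper count follows
#' the stated spectral smoothing: `K = max(1, round(2 * window * smoothing)
#' - 1)` (1 for the default 0.5 s window with 1.5 Hz smoothing).
#'
#' @param epochs an [eeg_epochs()].
#' @param f0 analysis frequency in Hz (default 5.5, the mean theta
#'   frequency).
#' @param smoothing spectral half-bandwidth in Hz (default 1.5).
#' @param window,step,span sliding-window geometry in seconds.
#' @return An object of class `cross_spectra`: complex array
#'   `S [windows, channels, channels]` (Hermitian per window), window
#'   centre times, parameters, `n_trials`.
#' @export
sliding_cross_spectra <- function(epochs, f0 = 5.5, smoothing = 1.5,
                                  window = 0.5, step = 0.05,
                                  span = c(0, 2)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  if (d[1] < 2L)
    stop("cross-spectra need at least 2 trials")
  srate <- epochs$srate
  t_axis <- epochs$times
  if (span[1] < t_axis[1] - 1e-9 || span[2] > t_axis[length(t_axis)] + 1e-9)
    stop("epochs do not cover the requested span")
  nw <- n_windows(span[1], span[2], window, step)
  wlen <- round(window * srate)
  n_tapers <- max(1L, as.integer(round(2 * window * smoothing)) - 1L)
  tapers <- vapply(seq_len(n_tapers), function(k)
    dpss_seq_k(wlen, smoothing / srate, k), numeric(wlen))

  starts <- span[1] + (seq_len(nw) - 1L) * step
  S <- array(0i, dim = c(nw, d[2], d[2]))
  rel <- seq_len(wlen) - 1L
  for (wi in seq_len(nw)) {
    i0 <- round((starts[wi] - t_axis[1]) * srate) + 1L
    idx <- i0 + rel
    seg <- matrix(epochs$data[, , idx], nrow = d[1] * d[2])
    acc <- matrix(0i, d[2], d[2])
    for (k in seq_len(n_tapers)) {
      carrier <- tapers[, k] * exp(-2i * pi * f0 * rel / srate)
      xf <- seg %*% carrier                  # (trial,ch) coefficients
      xf <- matrix(xf, d[1], d[2])           # trials x channels
      acc <- acc + crossprod(Conj(xf), xf)   # sum_t conj(x_i) x_j ??
    }
    # crossprod(Conj(xf), xf)[i, j] = sum_t x_i* x_j; we want X_i conj(X_j)
    S[wi, , ] <- Conj(acc) / (d[1] * n_tapers)
  }
  structure(list(S = S, times = starts + window / 2, f0 = f0,
                 smoothing = smoothing, window = window, step = step,
                 span = span, n_tapers = n_tapers, n_trials = d[1],
                 channels = epochs$channels),
            class = "cross_spectra")
}

# k-th Slepian sequence (k = 1 is the leading one)
dpss_seq_k <- function(n, w, k) {
  if (k == 1L) return(dpss_taper(n, w))
  t <- seq_len(n) - 1
  md <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  od <- t[-1] * (n - t[-1]) / 2
  m <- diag(md)
  m[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- od
  m[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- od
  e <- eigen(m, symmetric = TRUE)
  v <- e$vectors[, k]
  v / sqrt(sum(v^2))
}

#' @export
print.cross_spectra <- function(x, ...) {
  d <- dim(x$S)
  cat(sprintf("cross_spectra: %d windows x %d x %d channels @ %g Hz (%d taper(s), %d trials)\n",
              d[1], d[2], d[3], x$f0, x$n_tapers, x$n_trials))
  invisible(x)
}

#' Imaginary coherence from cross-spectra
#'
#' For each unordered channel pair `(i < j)` and window, the coherency is
#' `C = S_ij / sqrt(S_ii S_jj)` and the value returned is its (signed)
#' imaginary part. Zero-lag (volume-conducted or instantaneously mixed)
#' signals give exactly zero.
#'
#' @param cs a [sliding_cross_spectra()] result.
#' @return Numeric matrix `[pairs, windows]` with `rownames` from
#'   [pair_labels()]; `NA` where a channel has zero power.
#' @export
imaginary_coherence <- function(cs) {
  stopifnot(inherits(cs, "cross_spectra"))
  d <- dim(cs$S)
  n <- d[2]
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  out <- matrix(NA_real_, nrow(pairs), d[1])
  for (wi in seq_len(d[1])) {
    s <- cs$S[wi, , ]
    pw <- Re(diag(s))
    denom <- sqrt(pw[pairs[, 1]] * pw[pairs[, 2]])
    num <- Im(s[pairs])
    val <- num / denom
    val[denom <= 0] <- NA_real_
    out[, wi] <- val
  }
  rownames(out) <- pair_labels(cs$channels)
  out
}

#' Condition-wise imaginary coherence stacks
#'
#' Computes imaginary coherence per subject, phase, mode and event (trials
#' pooled across that mode's stories), then forms the linked stack as the
#' average of the event-A and event-B values and keeps the non-linked
#' event X as its own separate stack.
#'
#' @param epochs preprocessed [eeg_epochs()] for the whole cohort, with a
#'   trial table carrying `subject`, `group`, `phase`, `mode`, `event`,
#'   `is_target`.
#' @param linked_events events averaged into the linked stack.
#' @param nonlinked_event the event kept separate.
#' @param ... passed to [sliding_cross_spectra()].
#' @return A list of class `coherence_stack`: `imcoh`
#'   `[subject, condition, pairs, windows]`, `condition_keys`
#'   (`linked_<phase>_<mode>`, `nonlinked_<phase>_<mode>`), `subjects`,
#'   `groups`, `pair_labels`, `times`.
#' @export
coherence_conditions <- function(epochs, linked_events = c("A", "B"),
                                 nonlinked_event = "X", ...) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  tab <- epochs$trials
  subjects <- sort(unique(tab$subject))
  phases <- unique(tab$phase)
  modes <- unique(tab$mode[!is.na(tab$mode)])
  conds <- expand.grid(pair = c("linked", "nonlinked"), phase = phases,
                       mode = modes, stringsAsFactors = FALSE)
  conds <- conds[order(conds$pair, conds$phase, conds$mode), ]
  keys <- paste(conds$pair, conds$phase, conds$mode, sep = "_")

  imcoh <- NULL
  groups <- character(length(subjects))
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    groups[si] <- tab$group[tab$subject == s][1]
    for (ci in seq_len(nrow(conds))) {
      cond <- conds[ci, ]
      evs <- if (cond$pair == "linked") linked_events else nonlinked_event
      mats <- lapply(evs, function(e) {
        sel <- which(tab$subject == s & tab$phase == cond$phase &
                       tab$mode %in% cond$mode & tab$event == e &
                       !tab$is_target)
        if (length(sel) < 2L)
          stop(sprintf("fewer than 2 trials for subject %s %s/%s event %s",
                       s, cond$phase, cond$mode, e))
        imaginary_coherence(
          sliding_cross_spectra(subset_trials(epochs, sel), ...))
      })
      val <- Reduce(`+`, mats) / length(mats)
      if (is.null(imcoh))
        imcoh <- array(NA_real_, dim = c(length(subjects), nrow(conds),
                                         nrow(val), ncol(val)))
      imcoh[si, ci, , ] <- val
    }
  }
  cs_probe <- sliding_cross_spectra(
    subset_trials(epochs, which(tab$subject == subjects[1])[1:2]), ...)
  structure(list(imcoh = imcoh, condition_keys = keys,
                 conditions = conds, subjects = subjects, groups = groups,
                 pair_labels = pair_labels(epochs$channels),
                 times = cs_probe$times),
            class = "coherence_stack")
}

#' @export
print.coherence_stack <- function(x, ...) {
  d <- dim(x$imcoh)
  cat(sprintf("coherence_stack: %d subjects x %d conditions x %d pairs x %d windows\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Per-subject coherence difference wave
#'
#' Forms the (post - pre) x (imagination - observation) difference of the
#' linked (or non-linked) stacks, the group-level unit for the pair-space
#' cluster test.
#'
#' @param stack a [coherence_conditions()] result.
#' @param pair `"linked"` or `"nonlinked"`.
#' @return Array `[subject, pairs, windows]` with subject/group attributes.
#' @export
coherence_contrast <- function(stack, pair = c("linked", "nonlinked")) {
  pair <- match.arg(pair)
  k <- stack$condition_keys
  pick <- function(phase, mode)
    which(k == paste(pair, phase, mode, sep = "_"))
  v <- stack$imcoh[, pick("post", "imagination"), , , drop = FALSE] -
    stack$imcoh[, pick("pre", "imagination"), , , drop = FALSE] -
    stack$imcoh[, pick("post", "observation"), , , drop = FALSE] +
    stack$imcoh[, pick("pre", "observation"), , , drop = FALSE]
  out <- array(v, dim = dim(stack$imcoh)[c(1, 3, 4)])
  attr(out, "subjects") <- stack$subjects
  attr(out, "groups") <- stack$groups
  out
}
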