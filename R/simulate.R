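#' Simulate a synthetic narrative-insight EEG session
#'
#' Generates epoched EEG with planted, controllable effects plus a behavior
#' table for a two-group cohort. The signal model per trial is:
#' instantaneously mixed 1/f^beta background noise (zero-lag mixing, hence
#' no imaginary coherence by construction), plus a 0-2 s theta oscillation
#' whose per-channel amplitude follows a latent pattern over channels x
#' theta frequencies (4-7 Hz), plus - on designated channel pairs - a
#' common 5.5 Hz source with one channel delayed by `lag_phase`, scaled by
#' the group x phase x mode coupling strength `gamma`. For linked events A
#' and B, post-phase patterns are `(1 - alpha) * own + alpha * shared`
#' with `alpha` from the subject's group x mode cell, so cross-event
#' pattern similarity grows with `alpha`.
#'
#' @param design a [session_design()].
#' @param effects a [latent_effects()].
#' @param n_subjects_per_group subjects per group (>= 1).
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param montage a [make_montage()] result or a subset of it with
#'   `design$n_channels` rows; default builds the packaged montage (or its
#'   first `n_channels` rows).
#' @param return_data if `FALSE`, only trial tables, behavior and latent
#'   patterns are generated (no voltage arrays); useful for structural
#'   checks on the full-size design.
#' @return A list of class `session_sim` with elements `epochs`
#'   (an [eeg_epochs()] over all subjects, or `NULL`), `trials` (the full
#'   trial table), `behavior` (one row per subject), `patterns` (latent
#'   per-subject pattern list), `design`, `effects`, `montage`.
#' @export
simulate_session <- function(design, effects, n_subjects_per_group, seed,
                             montage = NULL, return_data = TRUE) {
  validate_session_design(design)
  validate_latent_effects(effects)
  stopifnot(n_subjects_per_group >= 1)
  montage <- resolve_montage(design, montage)

  subjects <- data.frame(
    subject = seq_len(2L * n_subjects_per_group),
    group = rep(design$groups[1:2], each = n_subjects_per_group),
    stringsAsFactors = FALSE)

  per_subj <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    per_subj[[i]] <- simulate_subject(
      design, effects, subject = subjects$subject[i],
      group = subjects$group[i],
      seed = subject_seed(seed, i), montage = montage,
      return_data = return_data,
      pattern_seed = subject_seed(seed, 0L))
  }

  trials <- do.call(rbind, lapply(per_subj, `[[`, "trials"))
  rownames(trials) <- NULL
  behavior <- do.call(rbind, lapply(per_subj, `[[`, "behavior"))
  rownames(behavior) <- NULL
  patterns <- lapply(per_subj, `[[`, "patterns")
  names(patterns) <- subjects$subject

  epochs <- NULL
  if (return_data) {
    data <- do.call(abind3, lapply(per_subj, `[[`, "data"))
    epochs <- eeg_epochs(data, design$analysis_srate,
                         per_subj[[1]]$times, trials, montage$label)
  }
  structure(list(epochs = epochs, trials = trials, behavior = behavior,
                 patterns = patterns, design = design, effects = effects,
                 montage = montage),
            class = "session_sim")
}

#' @export
print.session_sim <- function(x, ...) {
  cat(sprintf("session_sim: %d subjects, %d trials%s\n",
              nrow(x$behavior), nrow(x$trials),
              if (is.null(x$epochs)) " (metadata only)" else ""))
  if (!is.null(x$epochs)) print(x$epochs)
  invisible(x)
}

resolve_montage <- function(design, montage) {
  if (is.null(montage)) {
    montage <- make_montage()
    if (design$n_channels < nrow(montage))
      montage <- subset_montage(montage,
                                montage$label[seq_len(design$n_channels)])
  }
  if (nrow(montage) != design$n_channels)
    stop("montage rows must equal design$n_channels")
  montage
}

subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483587)
}

# bind arrays along the first dimension (remaining dims must agree)
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  total <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(0, dim = c(total, d[-1]))
  block <- prod(d[-1])
  flat <- matrix(0, total, block)
  at <- 1L
  for (p in parts) {
    n <- dim(p)[1]
    flat[at:(at + n - 1L), ] <- matrix(p, n, block)
    at <- at + n
  }
  array(flat, dim = c(total, d[-1]))
}

story_modes <- function(design) {
  # stories split evenly and deterministically across modes
  rep(design$modes, each = design$n_stories / length(design$modes))
}

# -- per-subject generation ---------------------------------------------

simulate_subject <- function(design, effects, subject, group, seed,
                             montage, return_data = TRUE,
                             pattern_seed = NULL) {
  n_ch <- design$n_channels
  srate <- design$analysis_srate
  times <- epoch_times(design$epoch_window, srate)
  modes_by_story <- story_modes(design)

  # canonical (stimulus-driven) event patterns are drawn from their own
  # stream so that all subjects share them; subject-level randomness
  # (noise, trial order, phases) uses the subject seed
  set.seed(if (is.null(pattern_seed)) seed else pattern_seed)
  patterns <- draw_patterns(design, effects, group, montage)
  set.seed(seed)
  trial_list <- lapply(design$phases, function(ph)
    phase_trial_table(design, subject, group, ph, modes_by_story))
  trials <- do.call(rbind, trial_list)
  rownames(trials) <- NULL

  data <- NULL
  if (return_data) {
    data <- array(0, dim = c(nrow(trials), n_ch, length(times)))
    mix <- random_rotation(n_ch)
    sig_idx <- which(times >= 0 & times <= 2)
    ramp <- signal_ramp(length(sig_idx), srate)
    pair_idx <- coupling_pair_indices(effects, montage)
    for (ph in design$phases) {
      rows <- which(trials$phase == ph)
      noise <- background_noise(length(rows) * n_ch, length(times),
                                effects$noise_exponent)
      # [trials*channels, samples] -> [trials, channels, samples]
      dim(noise) <- c(length(rows), n_ch, length(times))
      amp0 <- effects$pattern_snr * noise_sd_uv()
      for (k in seq_along(rows)) {
        tr <- trials[rows[k], ]
        # background sources are mixed instantaneously (zero lag); the
        # planted oscillations below are channel-local and never mixed
        x <- noise_sd_uv() * (mix %*% noise[k, , ])
        if (!tr$is_target) {
          w <- patterns[[ph]][[tr$story]][[tr$event]]
          # theta oscillation, random phase per trial and frequency,
          # common over channels (instantaneous -> no imaginary coherence)
          nf <- length(theta_freqs())
          phases_f <- stats::runif(nf, 0, 2 * pi)
          carr <- sin(outer(2 * pi * theta_freqs(), times[sig_idx]) +
                        phases_f) * rep(ramp, each = nf)
          # amplitude is the square root of the latent power pattern,
          # piecewise over the pattern's time segments
          nseg <- dim(w)[3]
          seg_of <- pmin(nseg,
                         1L + floor(nseg * (times[sig_idx] - 0) / 2))
          for (sg in seq_len(nseg)) {
            cols <- which(seg_of == sg)
            if (!length(cols)) next
            amp_m <- matrix(sqrt(w[, , sg]), nrow = dim(w)[1])
            x[patterns$chan_idx, sig_idx[cols]] <-
              x[patterns$chan_idx, sig_idx[cols]] +
              amp0 * (amp_m %*% carr[, cols, drop = FALSE])
          }
          g <- effects$gamma[group, ph, tr$mode]
          if (g > 0 && nrow(pair_idx)) {
            for (p in seq_len(nrow(pair_idx))) {
              phi <- stats::runif(1, 0, 2 * pi)
              src <- sin(2 * pi * 5.5 * times[sig_idx] + phi) * ramp
              lag <- sin(2 * pi * 5.5 * times[sig_idx] + phi -
                           effects$lag_phase) * ramp
              x[pair_idx[p, 1], sig_idx] <-
                x[pair_idx[p, 1], sig_idx] + g * amp0 * src
              x[pair_idx[p, 2], sig_idx] <-
                x[pair_idx[p, 2], sig_idx] + g * amp0 * lag
            }
          }
        }
        data[rows[k], , ] <- x
      }
    }
  }

  behavior <- draw_behavior(design, effects, subject, group)
  list(trials = trials, data = data, times = times, behavior = behavior,
       patterns = patterns)
}

theta_freqs <- function() c(4, 5, 6, 7)

noise_sd_uv <- function() 10

epoch_times <- function(window, srate) {
  n <- round((window[2] - window[1]) * srate) + 1L
  window[1] + (seq_len(n) - 1L) / srate
}

signal_ramp <- function(n, srate) {
  ramp_n <- min(round(0.05 * srate), floor(n / 4))
  r <- rep(1, n)
  if (ramp_n > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    r[seq_len(ramp_n)] <- up
    r[n + 1 - seq_len(ramp_n)] <- up
  }
  r
}

random_rotation <- function(n) {
  qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
}

pattern_to_channels <- function(w_col, chan_idx, n_ch) {
  v <- numeric(n_ch)
  v[chan_idx] <- w_col
  v
}

coupling_pair_indices <- function(effects, montage) {
  cp <- effects$coupling_pairs
  if (is.null(cp) || !nrow(cp)) return(matrix(integer(0), 0, 2))
  keep <- cp[, 1] %in% montage$label & cp[, 2] %in% montage$label
  cp <- cp[keep, , drop = FALSE]
  cbind(match(cp[, 1], montage$label), match(cp[, 2], montage$label))
}

# latent theta power patterns: per story, per event, pattern_channels x 4
# freqs, nonnegative, unit mean. The pattern lives in the power domain
# (oscillation amplitude is its square root), so the post-phase mixing
# (1 - alpha) * own + alpha * shared(story) for linked events A and B acts
# linearly on the quantity the downstream RSA correlates.
draw_patterns <- function(design, effects, group, montage) {
  chans <- effects$pattern_channels
  if (is.null(chans)) chans <- montage$label
  chan_idx <- match(chans, montage$label)
  if (anyNA(chan_idx)) stop("pattern_channels not all present in montage")
  nf <- length(theta_freqs())
  nseg <- pattern_segments(effects)
  modes_by_story <- story_modes(design)
  norm_mean <- function(m) m / mean(m)
  draw <- function(spread = 1)
    norm_mean(array(stats::rexp(length(chan_idx) * nf * nseg)^spread,
                    dim = c(length(chan_idx), nf, nseg)))
  pre <- post <- vector("list", design$n_stories)
  for (s in seq_len(design$n_stories)) {
    u <- stats::setNames(lapply(design$events, function(e) draw()),
                         design$events)
    # the shared narrative pattern is drawn with a wider spread than the
    # event-specific ones so that a given mixing fraction alpha produces a
    # comparable, reliably positive A-B power correlation per channel
    shared <- draw(spread = 2)
    a <- effects$alpha[group, modes_by_story[s]]
    p <- u
    for (e in intersect(c("A", "B"), design$events))
      p[[e]] <- (1 - a) * u[[e]] + a * shared
    pre[[s]] <- u
    post[[s]] <- p
  }
  list(pre = pre, post = post, chan_idx = chan_idx)
}

pattern_segments <- function(effects) {
  ns <- effects$n_segments
  if (is.null(ns)) 4L else as.integer(ns)
}

# pseudorandom trial order: block structure (each event of each story once
# per block), no identical consecutive videos across block boundaries,
# targets interleaved at the design rate
phase_trial_table <- function(design, subject, group, phase,
                              modes_by_story) {
  combos <- expand.grid(story = seq_len(design$n_stories),
                        event = design$events,
                        stringsAsFactors = FALSE)
  blocks <- vector("list", design$reps_per_phase)
  prev_last <- NULL
  for (b in seq_len(design$reps_per_phase)) {
    repeat {
      ord <- sample.int(nrow(combos))
      ok <- TRUE
      if (!is.null(prev_last))
        ok <- !(combos$story[ord[1]] == prev_last[1] &&
                  combos$event[ord[1]] == prev_last[2])
      no_rep <- all(diff(ord) != 0)  # permutation, trivially true
      if (ok && no_rep) break
    }
    blocks[[b]] <- combos[ord, ]
    prev_last <- c(combos$story[ord[nrow(combos)]],
                   combos$event[ord[nrow(combos)]])
  }
  tab <- do.call(rbind, blocks)
  tab$rep <- rep(seq_len(design$reps_per_phase), each = nrow(combos))
  n_main <- nrow(tab)
  n_targets <- round(design$target_rate * n_main)
  if (n_targets > 0) {
    # interleave targets at random positions, keeping the constrained
    # pseudorandom order of the main trials intact
    targ <- data.frame(story = NA_integer_, event = "target",
                       rep = NA_integer_)
    slots <- sort(sample.int(n_main + n_targets, n_targets))
    out <- vector("list", n_main + n_targets)
    is_target_slot <- seq_len(n_main + n_targets) %in% slots
    tab <- rbind(tab, targ[rep(1, n_targets), ])
    ord <- integer(n_main + n_targets)
    ord[is_target_slot] <- n_main + seq_len(n_targets)
    ord[!is_target_slot] <- seq_len(n_main)
    tab <- tab[ord, ]
  }
  data.frame(subject = subject, group = group, phase = phase,
             story = tab$story, event = tab$event, rep = tab$rep,
             mode = ifelse(is.na(tab$story), NA_character_,
                           modes_by_story[ifelse(is.na(tab$story), 1,
                                                 tab$story)]),
             is_target = tab$event == "target",
             iti_ms = round(stats::runif(nrow(tab), design$iti_range[1],
                                         design$iti_range[2])),
             stringsAsFactors = FALSE, row.names = NULL)
}

# 1/f^beta noise, one unit-variance source per row; spectra are drawn
# Hermitian so the inverse FFT is real up to rounding
background_noise <- function(n_src, n_samples, beta) {
  nh <- (n_samples - 1L) %/% 2L
  scale <- seq_len(nh)^(-beta / 2)
  half <- matrix(complex(real = stats::rnorm(nh * n_src),
                         imaginary = stats::rnorm(nh * n_src)),
                 nh, n_src) * scale
  spec <- matrix(0i, n_samples, n_src)
  spec[1 + seq_len(nh), ] <- half
  spec[n_samples + 1L - seq_len(nh), ] <- Conj(half)
  if (n_samples %% 2L == 0L)
    spec[nh + 2L, ] <- stats::rnorm(n_src) * (nh + 1)^(-beta / 2)
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n_samples
  sds <- sqrt(pmax(colMeans(x^2) - colMeans(x)^2, 1e-30))
  t(x) / sds
}

draw_behavior <- function(design, effects, subject, group) {
  shift <- effects$behavior_effect[[group]]
  if (is.null(shift) || is.na(shift)) shift <- 0
  lam <- function(base, linked) base * exp(shift * linked)
  out <- data.frame(
    subject = subject, group = group,
    details_linked_central = stats::rpois(1, lam(5, 1)),
    details_linked_peripheral = stats::rpois(1, lam(8, 1)),
    details_nonlinked_central = stats::rpois(1, lam(4, 0)),
    details_nonlinked_peripheral = stats::rpois(1, lam(7, 0)),
    stringsAsFactors = FALSE)
  for (m in design$modes)
    out[[paste0("naming_", m)]] <- stats::rpois(1, lam(3, 1))
  out
}
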