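#' Narrative-insight session design
#'
#' Describes the structure of one narrative-insight EEG session: stories,
#' events per story, repetitions per phase, insight modes, stimulation
#' groups, timing, and sampling rates. Defaults follow the standard design:
#' 10 stories, events A/B/X repeated 18 times in each of the pre and post
#' phases, 5 stories linked via imagination and 5 via observation, target
#' trials at 11% of each phase, epochs of -2..3 s around stimulus onset,
#' 64 channels at 256 Hz (after downsampling from a 1024 Hz recording).
#'
#' @param n_stories number of storylines.
#' @param events labels of the per-story events; "A" and "B" become linked
#'   during the insight phase while "X" stays non-linked.
#' @param reps_per_phase repetitions of every event within a phase.
#' @param phases analysed phases (the insight phase itself is not analysed).
#' @param modes insight modes; stories are split evenly across modes.
#' @param groups stimulation groups.
#' @param iti_range inter-trial interval range in milliseconds.
#' @param target_rate fraction of each phase's trials that are attention
#'   targets (flagged and excluded from analysis).
#' @param epoch_window epoch limits in seconds relative to stimulus onset.
#' @param raw_srate acquisition sampling rate in Hz.
#' @param analysis_srate analysis sampling rate in Hz.
#' @param n_channels number of scalp electrodes.
#' @return An object of class `session_design`.
#' @examples
#' d <- session_design()
#' count_phase_trials(d, "pre")
#' @export
session_design <- function(n_stories = 10L,
                           events = c("A", "B", "X"),
                           reps_per_phase = 18L,
                           phases = c("pre", "post"),
                           modes = c("imagination", "observation"),
                           groups = c("sham", "cTBS"),
                           iti_range = c(700, 1300),
                           target_rate = 0.11,
                           epoch_window = c(-2, 3),
                           raw_srate = 1024,
                           analysis_srate = 256,
                           n_channels = 64L) {
  design <- structure(list(
    n_stories = as.integer(n_stories),
    events = as.character(events),
    reps_per_phase = as.integer(reps_per_phase),
    phases = as.character(phases),
    modes = as.character(modes),
    groups = as.character(groups),
    iti_range = as.numeric(iti_range),
    target_rate = as.numeric(target_rate),
    epoch_window = as.numeric(epoch_window),
    raw_srate = as.numeric(raw_srate),
    analysis_srate = as.numeric(analysis_srate),
    n_channels = as.integer(n_channels)
  ), class = "session_design")
  validate_session_design(design)
  design
}

validate_session_design <- function(design) {
  stopifnot(inherits(design, "session_design"))
  if (design$reps_per_phase < 1L)
    stop("reps_per_phase must be >= 1")
  if (design$n_stories %% length(design$modes) != 0L)
    stop("n_stories must be divisible by the number of insight modes")
  if (!(design$epoch_window[1] < 0 && 0 < design$epoch_window[2]))
    stop("epoch_window must straddle stimulus onset (start < 0 < end)")
  if (design$target_rate < 0 || design$target_rate >= 1)
    stop("target_rate must lie in [0, 1)")
  if (anyDuplicated(design$events))
    stop("event labels must be unique")
  invisible(design)
}

#' @export
print.session_design <- function(x, ...) {
  cat("Narrative-insight session design\n")
  cat(sprintf("  %d stories x events {%s} x %d reps per phase\n",
              x$n_stories, paste(x$events, collapse = ", "),
              x$reps_per_phase))
  cat(sprintf("  phases: %s | modes: %s | groups: %s\n",
              paste(x$phases, collapse = "/"),
              paste(x$modes, collapse = "/"),
              paste(x$groups, collapse = "/")))
  cat(sprintf("  %d channels, %g Hz analysis rate, epochs %g..%g s, target rate %.2f\n",
              x$n_channels, x$analysis_srate,
              x$epoch_window[1], x$epoch_window[2], x$target_rate))
  invisible(x)
}

#' Number of non-target trials in one phase
#'
#' @param design a [session_design()].
#' @param phase phase label, one of `design$phases`.
#' @return Integer count: stories x events x repetitions. With the default
#'   design this is 540 for either phase.
#' @export
count_phase_trials <- function(design, phase) {
  validate_session_design(design)
  if (!is.character(phase) || length(phase) != 1L ||
      !(phase %in% design$phases))
    stop(sprintf("unknown phase '%s'; expected one of: %s",
                 as.character(phase)[1],
                 paste(design$phases, collapse = ", ")))
  as.integer(design$n_stories * length(design$events) * design$reps_per_phase)
}

#' Continuous theta burst stimulation protocol
#'
#' Metadata descriptor for the cTBS protocol: bursts of `pulses_per_triplet`
#' pulses at `intra_burst_freq`, triplets repeated at `triplet_rate`, for
#' `duration` seconds at `intensity_fraction_of_mt` of the motor threshold.
#' The default protocol (3-pulse 50 Hz triplets at 5 Hz for 40 s at 80% MT)
#' delivers 600 pulses.
#'
#' @param pulses_per_triplet pulses per burst.
#' @param intra_burst_freq within-burst pulse frequency, Hz.
#' @param triplet_rate burst repetition rate, Hz.
#' @param duration stimulation duration, seconds.
#' @param intensity_fraction_of_mt stimulator intensity as a fraction of the
#'   individual motor threshold.
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(pulses_per_triplet = 3,
                          intra_burst_freq = 50,
                          triplet_rate = 5,
                          duration = 40,
                          intensity_fraction_of_mt = 0.8) {
  p <- structure(list(
    pulses_per_triplet = as.numeric(pulses_per_triplet),
    intra_burst_freq = as.numeric(intra_burst_freq),
    triplet_rate = as.numeric(triplet_rate),
    duration = as.numeric(duration),
    intensity_fraction_of_mt = as.numeric(intensity_fraction_of_mt)
  ), class = "stim_protocol")
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals[names(vals) != "duration"] <= 0) ||
      p$duration < 0)
    stop("stim_protocol fields must be positive (duration may be zero)")
  if (p$triplet_rate * p$pulses_per_triplet > p$intra_burst_freq)
    stop("triplet_rate x pulses_per_triplet must not exceed intra_burst_freq")
  p
}

#' Total number of magnetic pulses delivered by a cTBS protocol
#'
#' @param protocol a [stim_protocol()].
#' @return `round(triplet_rate * pulses_per_triplet * duration)`; 600 for
#'   the default protocol.
#' @export
total_pulses <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  as.integer(round(protocol$triplet_rate * protocol$pulses_per_triplet *
                     protocol$duration))
}

#' Latent effects planted by the session simulator
#'
#' Parameters of the generative model behind [simulate_session()]. `alpha`
#' is the integration strength: the fraction of a shared story pattern mixed
#' into the post-phase theta patterns of the linked events A and B, per
#' group x mode cell. `gamma` scales planted phase-lagged theta sources on
#' designated channel pairs, per group x phase x mode cell. The background
#' is instantaneously mixed 1/f^beta noise, so it contributes no imaginary
#' coherence by construction.
#'
#' @param alpha numeric matrix `groups x modes` in `[0, 1]`; rows named by
#'   group, columns by mode. Default: 0.6 in the sham/imagination cell
#'   (integration present), 0 elsewhere.
#' @param pattern_snr amplitude of the event-specific theta pattern relative
#'   to the background noise standard deviation.
#' @param gamma numeric array `groups x phases x modes`, nonnegative
#'   coupling strength of the planted lagged theta source. Default: coupling
#'   1 everywhere except the cTBS post-phase imagination cell (0.3),
#'   emulating a post-insight connectivity drop under stimulation.
#' @param lag_phase phase lag (radians at the coupling frequency) between
#'   the two channels of a planted pair.
#' @param noise_exponent spectral slope beta of the 1/f^beta background.
#' @param behavior_effect per-group log-scale shift of recall counts,
#'   named numeric vector.
#' @param coupling_pairs 2-column character matrix of channel label pairs
#'   receiving the planted lagged source.
#' @param pattern_channels channel labels carrying event-specific theta
#'   patterns; `NULL` means all channels.
#' @param n_segments number of equal time segments of the 0-2 s stimulus
#'   window over which the latent power pattern varies (dynamic event
#'   representations; default 4).
#' @return An object of class `latent_effects`.
#' @export
latent_effects <- function(alpha = NULL,
                           pattern_snr = 1.5,
                           gamma = NULL,
                           lag_phase = pi / 2,
                           noise_exponent = 1,
                           behavior_effect = c(sham = 0.25, cTBS = 0),
                           coupling_pairs = default_coupling_pairs(),
                           pattern_channels = NULL,
                           n_segments = 4L) {
  groups <- c("sham", "cTBS")
  modes <- c("imagination", "observation")
  phases <- c("pre", "post")
  if (is.null(alpha)) {
    alpha <- matrix(0, 2, 2, dimnames = list(groups, modes))
    alpha["sham", "imagination"] <- 0.6
  }
  if (is.null(gamma)) {
    gamma <- array(1, dim = c(2, 2, 2),
                   dimnames = list(groups, phases, modes))
    gamma["cTBS", "post", "imagination"] <- 0.3
  }
  eff <- structure(list(
    alpha = alpha,
    pattern_snr = as.numeric(pattern_snr),
    gamma = gamma,
    lag_phase = as.numeric(lag_phase),
    noise_exponent = as.numeric(noise_exponent),
    behavior_effect = behavior_effect,
    coupling_pairs = coupling_pairs,
    pattern_channels = pattern_channels,
    n_segments = as.integer(n_segments)
  ), class = "latent_effects")
  validate_latent_effects(eff)
  eff
}

validate_latent_effects <- function(eff) {
  stopifnot(inherits(eff, "latent_effects"))
  if (any(eff$alpha < 0 | eff$alpha > 1))
    stop("alpha must lie in [0, 1]")
  if (eff$pattern_snr < 0) stop("pattern_snr must be >= 0")
  if (any(eff$gamma < 0)) stop("gamma must be >= 0")
  if (eff$noise_exponent < 0) stop("noise_exponent must be >= 0")
  invisible(eff)
}

#' Default planted coupling pairs (centro-temporal to frontal)
#' @return 2-column character matrix of channel labels.
#' @export
default_coupling_pairs <- function() {
  cbind(c("C4", "C6", "T8", "T8"),
        c("Fp1", "Fp1", "Fp1", "AF7"))
}
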