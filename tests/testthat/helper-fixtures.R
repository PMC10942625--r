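# shared fixtures for scaled-down sessions

scaled_montage <- function() {
  subset_montage(make_montage(),
                 c("Fp1", "AF7", "FT7", "T7", "TP7", "P7", "C4", "T8"))
}

zero_gamma <- function() {
  array(0, dim = c(2, 2, 2),
        dimnames = list(c("sham", "cTBS"), c("pre", "post"),
                        c("imagination", "observation")))
}

alpha_cell <- function(sham_imagination = 0) {
  a <- matrix(0, 2, 2, dimnames = list(c("sham", "cTBS"),
                                       c("imagination", "observation")))
  a["sham", "imagination"] <- sham_imagination
  a
}

scaled_design <- function(n_stories = 2, reps = 3, srate = 64,
                          n_channels = 8) {
  session_design(n_stories = n_stories, reps_per_phase = reps,
                 n_channels = n_channels, raw_srate = srate,
                 analysis_srate = srate, epoch_window = c(-2, 2.7))
}

# sinusoidal test epochs: one trial per row of `amps` (channels x 1),
# fixed frequency, plus optional noise
sine_epochs <- function(n_trials, n_channels, freq, srate = 256,
                        t_lim = c(0, 2), amp = 1, noise_sd = 0,
                        seed = 1) {
  set.seed(seed)
  times <- seq(t_lim[1], t_lim[2], by = 1 / srate)
  dat <- array(0, dim = c(n_trials, n_channels, length(times)))
  for (i in seq_len(n_trials)) {
    ph <- stats::runif(1, 0, 2 * pi)
    for (ch in seq_len(n_channels))
      dat[i, ch, ] <- amp * sin(2 * pi * freq * times + ph) +
        stats::rnorm(length(times), sd = noise_sd)
  }
  eeg_epochs(dat, srate, times, data.frame(trial = seq_len(n_trials)),
             paste0("ch", seq_len(n_channels)))
}

# run simulate -> preprocess -> tfr -> features for one cohort; returns a
# theta_features object spanning all subjects
simulate_features <- function(design, effects, n_per_group, seed,
                              montage) {
  ot <- sort(unique(c(seq(-1.8, -1, 0.05), seq(0, 2, 0.05))))
  featv <- NULL
  feattab <- NULL
  ps <- thetalink:::subject_seed(seed, 0L)
  groups <- design$groups
  for (i in seq_len(2 * n_per_group)) {
    grp <- groups[1 + (i > n_per_group)]
    sub <- thetalink:::simulate_subject(
      design, effects, i, grp, thetalink:::subject_seed(seed, i),
      montage, pattern_seed = ps)
    ep <- eeg_epochs(sub$data, design$analysis_srate, sub$times,
                     sub$trials, montage$label)
    ep <- preprocess_epochs(ep, notch_hz = min(50, design$analysis_srate /
                                                 2 - 1),
                            ptp_threshold = NULL,
                            target_srate = design$analysis_srate)
    tf <- baseline_absolute(hanning_tfr(ep, fmin = 4, fmax = 7,
                                        out_times = ot))
    ft <- theta_features(average_reps(tf))
    featv <- if (is.null(featv)) ft$values else
      thetalink:::abind3(featv, ft$values)
    feattab <- rbind(feattab, ft$trials)
  }
  structure(list(values = featv, freqs = 4:7,
                 times = seq(0, 2, 0.05), trials = feattab,
                 channels = montage$label),
            class = "theta_features")
}

# study conditions for the scaled planted-effect recovery runs:
# 16 subjects per group, 8-channel montage, 8 stories (4 per insight
# mode) x 4 repetitions at 64 Hz, dynamic theta patterns on FT7/T7/TP7
# with pattern SNR 2, no planted coupling
planted_channels <- function() c("FT7", "T7", "TP7")

planted_rsa_replicate <- function(alpha_val, seed, n_per_group = 16) {
  ds <- session_design(n_stories = 8, reps_per_phase = 4,
                       n_channels = 8, raw_srate = 64,
                       analysis_srate = 64, epoch_window = c(-2, 2.7))
  eff <- latent_effects(alpha = alpha_cell(alpha_val),
                        gamma = zero_gamma(), pattern_snr = 2,
                        n_segments = 2,
                        pattern_channels = planted_channels())
  mont <- scaled_montage()
  ft <- simulate_features(ds, eff, n_per_group, seed, mont)
  maps <- build_rdm_set(ft)
  cm <- compose_contrast(maps, rsa_contrast_weights("linked_interaction"))
  adj <- build_adjacency(mont, 0.3)
  is_a <- cm$groups == "sham"
  ct <- cluster_test(cm$value[is_a, , , , drop = FALSE],
                     cm$value[!is_a, , , , drop = FALSE],
                     adj, 0.001, 500, seed = seed)
  sig <- Filter(function(cl) cl$p < 0.05, ct$clusters)
  if (!length(sig))
    return(list(detected = FALSE, coverage = 0, p = NA_real_))
  chans <- unique(mont$label[do.call(rbind,
                                     lapply(sig, `[[`, "voxels"))[, 1]])
  cov <- mean(planted_channels() %in% chans)
  list(detected = cov >= 0.8, coverage = cov, p = sig[[1]]$p)
}
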