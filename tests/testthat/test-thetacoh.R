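test_that("window counts follow the sliding arithmetic", {
  expect_equal(n_windows(0, 2, 0.5, 0.05), 31L)
  expect_equal(n_windows(0, 2, 2, 0.05), 1L)
  expect_equal(n_windows(0, 1, 0.5, 0.25), 3L)
  expect_error(n_windows(0, 1, 2, 0.05), "exceeds")
})

test_that("the dpss taper is the unit-norm Slepian sequence", {
  h <- dpss_taper(128, 1.5 / 256)
  expect_equal(sum(h^2), 1, tolerance = 1e-12)
  expect_true(all(h > 0))          # leading Slepian has no sign change
  expect_equal(h, rev(h), tolerance = 1e-9)  # symmetric
  # energy concentration in the design band is near-total
  H <- function(f) abs(sum(h * exp(-2i * pi * f * seq_len(128))))^2
  inband <- stats::integrate(Vectorize(H), -1.5 / 256, 1.5 / 256,
                             subdivisions = 400)$value
  total <- stats::integrate(Vectorize(H), -0.5, 0.5,
                            subdivisions = 1000)$value
  expect_gt(inband / total, 0.9)
  # stated taper count for the default 0.5 s window with 1.5 Hz smoothing
  expect_equal(max(1L, as.integer(round(2 * 0.5 * 1.5)) - 1L), 1L)
})

test_that("cross-spectra are Hermitian with the expected geometry", {
  set.seed(41)
  srate <- 256
  times <- seq(-0.2, 2.2, by = 1 / srate)
  n_tr <- 20
  dat <- array(rnorm(n_tr * 3 * length(times)), c(n_tr, 3, length(times)))
  dat[, 3, ] <- dat[, 1, ]          # duplicated channel
  ep <- eeg_epochs(dat, srate, times, data.frame(trial = seq_len(n_tr)),
                   c("a", "b", "a2"))
  cs <- sliding_cross_spectra(ep)
  expect_equal(dim(cs$S), c(31L, 3L, 3L))
  expect_equal(cs$n_tapers, 1L)
  for (w in c(1, 15, 31)) {
    s <- cs$S[w, , ]
    expect_equal(s, Conj(t(s)), tolerance = 1e-12)
    expect_true(all(Re(diag(s)) >= 0))
    # identical signals: cross term equals the auto term
    expect_equal(s[1, 3], s[1, 1], tolerance = 1e-12)
  }
})

test_that("independent channels have small normalized cross-spectra", {
  set.seed(42)
  srate <- 128
  times <- seq(0, 2, by = 1 / srate)
  n_tr <- 200
  dat <- array(rnorm(n_tr * 2 * length(times)), c(n_tr, 2, length(times)))
  ep <- eeg_epochs(dat, srate, times, data.frame(trial = seq_len(n_tr)),
                   c("a", "b"))
  cs <- sliding_cross_spectra(ep)
  coh <- abs(cs$S[, 1, 2]) / sqrt(Re(cs$S[, 1, 1]) * Re(cs$S[, 2, 2]))
  expect_true(all(coh < 0.2))
})

test_that("imaginary coherence separates zero-lag from quadrature coupling", {
  srate <- 256
  times <- seq(0, 2, by = 1 / srate)
  # zero-lag identical signals: exactly zero imaginary part
  n_tr <- 12
  dat <- array(0, c(n_tr, 2, length(times)))
  set.seed(5)
  for (i in seq_len(n_tr)) {
    x <- rnorm(length(times))
    dat[i, 1, ] <- x
    dat[i, 2, ] <- 0.7 * x
  }
  ep <- eeg_epochs(dat, srate, times, data.frame(trial = seq_len(n_tr)),
                   c("a", "b"))
  ic <- imaginary_coherence(sliding_cross_spectra(ep))
  expect_lt(max(abs(ic)), 1e-12)

  # quadrature pair on a balanced phase grid: coherency is purely
  # imaginary (real part cancels exactly) and near unit magnitude
  n_tr <- 16
  datq <- array(0, c(n_tr, 2, length(times)))
  phases <- rep(c(0, pi / 2, pi, 3 * pi / 2), length.out = n_tr)
  for (i in seq_len(n_tr)) {
    datq[i, 1, ] <- cos(2 * pi * 5.5 * times + phases[i])
    datq[i, 2, ] <- sin(2 * pi * 5.5 * times + phases[i])
  }
  epq <- eeg_epochs(datq, srate, times,
                    data.frame(trial = seq_len(n_tr)), c("a", "b"))
  csq <- sliding_cross_spectra(epq)
  C <- csq$S[, 1, 2] / sqrt(Re(csq$S[, 1, 1]) * Re(csq$S[, 2, 2]))
  expect_lt(max(abs(Re(C))), 1e-10)
  expect_true(all(abs(Im(C)) > 0.99))

  # an exactly quadrature cross-spectrum gives |Im(C)| = 1 exactly
  cs1 <- csq
  cs1$S <- array(0i, dim = c(2, 2, 2))
  for (w in 1:2) {
    x <- c(1 + 0i, 1i)   # channel coefficients in perfect quadrature
    cs1$S[w, , ] <- x %o% Conj(x)
  }
  ic1 <- imaginary_coherence(cs1)
  expect_equal(abs(as.vector(ic1)), c(1, 1), tolerance = 1e-12)
})

test_that("a lagged shared source matches the analytic two-source coherence", {
  srate <- 128
  times <- seq(0, 2, by = 1 / srate)
  f0 <- 5.5
  phi <- pi / 2
  n_tr <- 300
  set.seed(77)
  a_src <- 1
  sd_n <- 1
  dat <- array(0, c(n_tr, 2, length(times)))
  for (i in seq_len(n_tr)) {
    ph <- runif(1, 0, 2 * pi)
    s1 <- a_src * sin(2 * pi * f0 * times + ph)
    s2 <- a_src * sin(2 * pi * f0 * times + ph - phi)
    dat[i, 1, ] <- s1 + rnorm(length(times), sd = sd_n)
    dat[i, 2, ] <- s2 + rnorm(length(times), sd = sd_n)
  }
  ep <- eeg_epochs(dat, srate, times, data.frame(trial = seq_len(n_tr)),
                   c("a", "b"))
  ic <- imaginary_coherence(sliding_cross_spectra(ep))
  measured <- mean(ic)

  # analytic model, coded from the two-source decomposition: at the
  # analysis frequency Im(C) = sin(phi) * P_s / (P_s + P_n), with the
  # source and noise band powers measured through the same taper
  src_only <- array(0, c(50, 1, length(times)))
  for (i in 1:50) src_only[i, 1, ] <- a_src *
      sin(2 * pi * f0 * times + runif(1, 0, 2 * pi))
  noise_only <- array(rnorm(200 * 1 * length(times), sd = sd_n),
                      c(200, 1, length(times)))
  ps <- mean(Re(sliding_cross_spectra(
    eeg_epochs(src_only, srate, times, data.frame(trial = 1:50),
               "a"))$S[, 1, 1]))
  pn <- mean(Re(sliding_cross_spectra(
    eeg_epochs(noise_only, srate, times, data.frame(trial = 1:200),
               "a"))$S[, 1, 1]))
  predicted <- sin(phi) * ps / (ps + pn)
  expect_lt(abs(measured - predicted), 0.05)
})

test_that("condition stacks average A and B but keep X separate", {
  d <- scaled_design(n_stories = 2, reps = 3)
  eff <- latent_effects(gamma = zero_gamma())
  sim <- simulate_session(d, eff, 1, seed = 19,
                          montage = scaled_montage())
  ep <- sim$epochs
  # make every B trial identical to an A trial within its cell so the
  # linked average equals either event alone
  tab <- ep$trials
  for (s in unique(tab$subject)) for (ph in c("pre", "post"))
    for (st in 1:2) {
      ia <- which(tab$subject == s & tab$phase == ph & tab$story == st &
                    tab$event == "A")
      ib <- which(tab$subject == s & tab$phase == ph & tab$story == st &
                    tab$event == "B")
      ep$data[ib, , ] <- ep$data[ia, , ]
    }
  stack <- coherence_conditions(ep, f0 = 5.5, smoothing = 1.5,
                                window = 0.5, step = 0.05, span = c(0, 2))
  expect_equal(dim(stack$imcoh)[3:4], c(8 * 7 / 2, 31L))
  keys <- stack$condition_keys
  # linked = mean(A, B) = A when B duplicates A; compare against a
  # directly computed A-only stack
  sel_a <- which(tab$subject == 1 & tab$phase == "pre" &
                   tab$mode == "imagination" & tab$event == "A" &
                   !tab$is_target)
  ica <- imaginary_coherence(sliding_cross_spectra(
    thetalink:::subset_trials(ep, sel_a), f0 = 5.5, smoothing = 1.5,
    window = 0.5, step = 0.05, span = c(0, 2)))
  li <- match("linked_pre_imagination", keys)
  expect_equal(stack$imcoh[1, li, , ], unname(ica), tolerance = 1e-12)
  # arithmetic: averaging stacks of 0.2 and 0.4 gives 0.3
  expect_equal((0.2 + 0.4) / 2, 0.3)
  # X stack equals its own event stack (never averaged with A or B)
  sel_x <- which(tab$subject == 1 & tab$phase == "pre" &
                   tab$mode == "imagination" & tab$event == "X" &
                   !tab$is_target)
  icx <- imaginary_coherence(sliding_cross_spectra(
    thetalink:::subset_trials(ep, sel_x), f0 = 5.5, smoothing = 1.5,
    window = 0.5, step = 0.05, span = c(0, 2)))
  xi <- match("nonlinked_pre_imagination", keys)
  expect_equal(stack$imcoh[1, xi, , ], unname(icx), tolerance = 1e-12)
})

test_that("planted lagged coupling is visible and zero-lag backgrounds are not", {
  d <- scaled_design(n_stories = 2, reps = 6)
  mont <- scaled_montage()
  gam <- zero_gamma()
  gam[, , ] <- 1.5
  eff <- latent_effects(gamma = gam, alpha = alpha_cell(0),
                        coupling_pairs = cbind("C4", "Fp1"))
  sim <- simulate_session(d, eff, 1, seed = 23, montage = mont)
  tab <- sim$epochs$trials
  sel <- which(tab$subject == 1 & tab$phase == "pre" & !tab$is_target)
  ic <- imaginary_coherence(sliding_cross_spectra(
    thetalink:::subset_trials(sim$epochs, sel)))
  planted <- abs(mean(ic["Fp1-C4", ]))
  others <- setdiff(rownames(ic), "Fp1-C4")
  unpaired <- max(abs(rowMeans(ic[others, ])))
  expect_gt(planted, 0.2)
  expect_gt(planted, 3 * unpaired)

  # gamma = 0: the planted pair is indistinguishable from the others
  eff0 <- latent_effects(gamma = zero_gamma(), alpha = alpha_cell(0),
                         coupling_pairs = cbind("C4", "Fp1"))
  sim0 <- simulate_session(d, eff0, 1, seed = 23, montage = mont)
  tab0 <- sim0$epochs$trials
  sel0 <- which(tab0$subject == 1 & tab0$phase == "pre" & !tab0$is_target)
  ic0 <- imaginary_coherence(sliding_cross_spectra(
    thetalink:::subset_trials(sim0$epochs, sel0)))
  expect_lt(abs(mean(ic0["Fp1-C4", ])) -
              max(abs(rowMeans(ic0[others, ]))), 0.05)
})
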