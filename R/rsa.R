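#' Time-by-time similarity map between two theta feature slices
#'
#' Entry `(t1, t2)` is the Fisher-z transformed Pearson correlation between
#' the frequency-wise power vectors of the two inputs at `t1` and `t2`.
#' Correlations are clipped to `1 - 1e-6` in magnitude before `atanh`;
#' zero-variance vectors give `NA` entries.
#'
#' @param feat1,feat2 numeric matrices `[freqs, times]` for one channel.
#' @return Numeric `[times1, times2]` matrix of Fisher-z values.
#' @export
similarity_map <- function(feat1, feat2) {
  if (!is.matrix(feat1) || !is.matrix(feat2) ||
      nrow(feat1) != nrow(feat2))
    stop("feature slices must be freqs x times matrices with equal rows")
  r <- suppressWarnings(stats::cor(feat1, feat2))
  r[!is.finite(r)] <- NA_real_
  fisher_z(r)
}

fisher_z <- function(r, clip = 1 - 1e-6) {
  atanh(pmin(pmax(r, -clip), clip))
}

#' Build the 8-condition similarity map set
#'
#' For each subject, channel, phase and mode, correlates the story-level
#' theta features of event A with event B (linked) and A with X
#' (non-linked) within each story, Fisher-z transforms the maps, and
#' averages them across that mode's stories (missing entries excluded
#' pairwise). Each within-story pair is used exactly once; no cross-story
#' pairs are formed. With two phases and two modes this yields the
#' 8-condition set linked/non-linked x pre/post x imagination/observation.
#'
#' @param features a [theta_features()] object at story level (one row per
#'   subject x phase x story x event).
#' @param linked_events the event pair forming the linked condition.
#' @param nonlinked_events the event pair forming the non-linked condition.
#' @return An object of class `similarity_maps`: `z` array
#'   `[subject, condition, channel, t1, t2]`, `conditions` (data frame with
#'   `pair`, `phase`, `mode`), `subjects`, `groups`, `channels`, `times`.
#' @export
build_rdm_set <- function(features, linked_events = c("A", "B"),
                          nonlinked_events = c("A", "X")) {
  stopifnot(inherits(features, "theta_features"))
  tab <- features$trials
  subjects <- sort(unique(tab$subject))
  phases <- unique(tab$phase)
  modes <- unique(tab$mode[!is.na(tab$mode)])
  nt <- length(features$times)
  nch <- length(features$channels)

  conditions <- expand.grid(pair = c("linked", "nonlinked"),
                            phase = phases, mode = modes,
                            stringsAsFactors = FALSE)
  conditions <- conditions[order(conditions$pair, conditions$phase,
                                 conditions$mode), ]
  rownames(conditions) <- NULL

  z <- array(NA_real_,
             dim = c(length(subjects), nrow(conditions), nch, nt, nt))
  groups <- character(length(subjects))

  for (si in seq_along(subjects)) {
    s <- subjects[si]
    groups[si] <- tab$group[tab$subject == s][1]
    for (ci in seq_len(nrow(conditions))) {
      cond <- conditions[ci, ]
      ev <- if (cond$pair == "linked") linked_events else nonlinked_events
      stories <- sort(unique(tab$story[tab$subject == s &
                                         tab$mode == cond$mode &
                                         !is.na(tab$story)]))
      if (!length(stories))
        stop("no stories for mode ", cond$mode)
      acc <- array(0, dim = c(nch, nt, nt))
      cnt <- array(0L, dim = c(nch, nt, nt))
      for (st in stories) {
        i1 <- which(tab$subject == s & tab$phase == cond$phase &
                      tab$story == st & tab$event == ev[1])
        i2 <- which(tab$subject == s & tab$phase == cond$phase &
                      tab$story == st & tab$event == ev[2])
        if (length(i1) != 1L || length(i2) != 1L)
          stop(sprintf("story %s is missing event %s or %s in phase %s",
                       st, ev[1], ev[2], cond$phase))
        for (ch in seq_len(nch)) {
          m <- similarity_map(features$values[i1, ch, , ],
                              features$values[i2, ch, , ])
          good <- is.finite(m)
          acc[ch, , ][good] <- acc[ch, , ][good] + m[good]
          cnt[ch, , ][good] <- cnt[ch, , ][good] + 1L
        }
      }
      zc <- acc / cnt
      zc[cnt == 0L] <- NA_real_
      if (all(!is.finite(zc)))
        stop("condition ", paste(cond, collapse = "/"),
             " has only missing similarity bins")
      z[si, ci, , , ] <- zc
    }
  }
  structure(list(z = z, conditions = conditions, subjects = subjects,
                 groups = groups, channels = features$channels,
                 times = features$times),
            class = "similarity_maps")
}

#' @export
print.similarity_maps <- function(x, ...) {
  d <- dim(x$z)
  cat(sprintf("similarity_maps: %d subjects x %d conditions x %d channels x %d x %d bins\n",
              d[1], d[2], d[3], d[4], d[5]))
  print(x$conditions)
  invisible(x)
}

condition_key <- function(conditions) {
  paste(conditions$pair, conditions$phase, conditions$mode, sep = "_")
}

#' Compose a signed contrast over similarity-map conditions
#'
#' Builds a per-subject difference wave: a weighted sum of condition maps.
#' Weights are named by `pair_phase_mode` (e.g.
#' `linked_post_imagination`). For difference contrasts the weights must
#' sum to zero.
#'
#' @param maps a [build_rdm_set()] result.
#' @param weights named numeric vector of condition weights.
#' @param require_zero_sum enforce a zero weight sum (default `TRUE`).
#' @return An object of class `contrast_map`: `value`
#'   `[subject, channel, t1, t2]` plus subject/group metadata.
#' @export
compose_contrast <- function(maps, weights, require_zero_sum = TRUE) {
  stopifnot(inherits(maps, "similarity_maps"))
  keys <- condition_key(maps$conditions)
  unknown <- setdiff(names(weights), keys)
  if (length(unknown))
    stop("unknown conditions in weights: ", paste(unknown, collapse = ", "))
  if (require_zero_sum && abs(sum(weights)) > 1e-12)
    stop("difference contrast weights must sum to 0")
  d <- dim(maps$z)
  out <- array(0, dim = d[-2])
  for (nm in names(weights)) {
    ci <- match(nm, keys)
    out <- out + weights[[nm]] * maps$z[, ci, , , , drop = TRUE]
  }
  if (length(dim(out)) != 4L)  # single-subject case drops the first dim
    out <- array(out, dim = d[-2])
  structure(list(value = out, weights = weights, subjects = maps$subjects,
                 groups = maps$groups, channels = maps$channels,
                 times = maps$times),
            class = "contrast_map")
}

#' Built-in difference-wave contrasts
#'
#' `rsa_contrast_weights("linked_interaction")` is the
#' (post - pre) x (imagination - observation) contrast on linked maps,
#' `"nonlinked_interaction"` the same on non-linked maps, and
#' `"four_way"` additionally differences linked - non-linked.
#'
#' @param name contrast name.
#' @return Named weight vector usable with [compose_contrast()].
#' @export
rsa_contrast_weights <- function(name = c("linked_interaction",
                                          "nonlinked_interaction",
                                          "four_way",
                                          "linked_post_pre",
                                          "nonlinked_post_pre")) {
  name <- match.arg(name)
  w <- function(...) c(...)
  switch(name,
    linked_interaction = w(linked_post_imagination = 1,
                           linked_pre_imagination = -1,
                           linked_post_observation = -1,
                           linked_pre_observation = 1),
    nonlinked_interaction = w(nonlinked_post_imagination = 1,
                              nonlinked_pre_imagination = -1,
                              nonlinked_post_observation = -1,
                              nonlinked_pre_observation = 1),
    four_way = w(linked_post_imagination = 1,
                 linked_pre_imagination = -1,
                 linked_post_observation = -1,
                 linked_pre_observation = 1,
                 nonlinked_post_imagination = -1,
                 nonlinked_pre_imagination = 1,
                 nonlinked_post_observation = 1,
                 nonlinked_pre_observation = -1),
    linked_post_pre = w(linked_post_imagination = 0.5,
                        linked_post_observation = 0.5,
                        linked_pre_imagination = -0.5,
                        linked_pre_observation = -0.5),
    nonlinked_post_pre = w(nonlinked_post_imagination = 0.5,
                           nonlinked_post_observation = 0.5,
                           nonlinked_pre_imagination = -0.5,
                           nonlinked_pre_observation = -0.5))
}
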