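#' Pipeline configuration with study defaults
#'
#' Returns the full nested configuration of the analysis pipeline. Every
#' default matches the study parameters: 10 stories x 18 repetitions,
#' TFR 2-45 Hz with 5-cycle Hanning windows, absolute baseline -1.8 to
#' -1 s, theta features 4-7 Hz over 0-2 s, cluster threshold
#' `alpha_cluster = 0.001` with 10,000 permutations, coherence at 5.5 Hz
#' with 1.5 Hz smoothing in 0.5 s windows sliding by 0.05 s.
#'
#' @param ... named overrides, e.g. `cohort = list(n_per_group = 8)`;
#'   nested lists are merged field by field.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  base <- list(
    design = session_design(),
    effects = latent_effects(),
    cohort = list(n_per_group = 8L),
    seed = 1L,
    preprocess = list(notch_hz = 50, ptp_threshold = 150,
                      target_srate = 256),
    tfr = list(fmin = 2, fmax = 45, fstep = 1, n_cycles = 5,
               tstep = 0.05, baseline = c(-1.8, -1)),
    rsa = list(freq_range = c(4, 7), time_range = c(0, 2)),
    cluster = list(alpha_cluster = 0.001, n_perm = 10000L, seed = 1L,
                   distance_quantile = 0.10),
    coherence = list(f0 = 5.5, smoothing = 1.5, window = 0.5,
                     step = 0.05, span = c(0, 2), enabled = TRUE),
    stats = list(behavior_outcome = "naming_imagination")
  )
  overrides <- list(...)
  cfg <- merge_config(base, overrides)
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

merge_config <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]]) &&
        !inherits(base[[nm]], c("session_design", "latent_effects")))
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]])
    else
      base[[nm]] <- overrides[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  validate_session_design(cfg$design)
  validate_latent_effects(cfg$effects)
  stopifnot(cfg$cohort$n_per_group >= 1,
            cfg$cluster$alpha_cluster > 0, cfg$cluster$alpha_cluster < 1,
            cfg$cluster$n_perm >= 1,
            cfg$coherence$window > 0, cfg$coherence$step > 0,
            cfg$tfr$tstep > 0)
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path`; `read_config` a
#'   `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  plain <- rapply(unclass(cfg), identity, how = "list")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$design <- do.call(session_design, raw$design[names(formals(session_design))[
    names(formals(session_design)) %in% names(raw$design)]])
  if (!is.null(raw$effects)) {
    eff <- raw$effects
    eff$alpha <- matrix(unlist(eff$alpha), 2, 2,
                        dimnames = list(c("sham", "cTBS"),
                                        c("imagination", "observation")))
    gam <- array(unlist(eff$gamma), dim = c(2, 2, 2),
                 dimnames = list(c("sham", "cTBS"), c("pre", "post"),
                                 c("imagination", "observation")))
    raw$effects <- latent_effects(
      alpha = eff$alpha, pattern_snr = eff$pattern_snr, gamma = gam,
      lag_phase = eff$lag_phase, noise_exponent = eff$noise_exponent,
      behavior_effect = unlist(eff$behavior_effect),
      coupling_pairs = if (!is.null(eff$coupling_pairs))
        matrix(unlist(eff$coupling_pairs), ncol = 2) else
          default_coupling_pairs(),
      pattern_channels = unlist(eff$pattern_channels))
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Chains simulate -> preprocess -> time-frequency -> RSA -> cluster
#' statistics -> coherence -> follow-up statistics, streaming subject by
#' subject so only condition-level summaries are held in memory. Identical
#' configurations (including seeds) give identical reports.
#'
#' @param config a [pipeline_config()].
#' @param montage optional montage override (defaults to the packaged
#'   montage truncated to `design$n_channels`).
#' @return A list of class `run_report`: cluster tables for the linked and
#'   non-linked RSA contrasts and the linked coherence contrast, follow-up
#'   test results, correlation comparisons, behavior table, provenance
#'   (seeds, sizes, warnings).
#' @export
run_pipeline <- function(config = pipeline_config(), montage = NULL) {
  validate_config(config)
  design <- config$design
  effects <- config$effects
  montage <- resolve_montage(design, montage)
  warnings_log <- character(0)

  n_pg <- config$cohort$n_per_group
  subjects <- data.frame(
    subject = seq_len(2L * n_pg),
    group = rep(design$groups[1:2], each = n_pg))

  base_times <- sort(unique(c(
    seq(config$tfr$baseline[1], config$tfr$baseline[2],
        by = config$tfr$tstep),
    seq(config$rsa$time_range[1], config$rsa$time_range[2],
        by = config$tfr$tstep))))

  feat_vals <- NULL
  feat_tab <- NULL
  coh <- NULL
  behavior <- NULL
  for (i in seq_len(nrow(subjects))) {
    sim <- simulate_subject(design, effects,
                            subject = subjects$subject[i],
                            group = subjects$group[i],
                            seed = subject_seed(config$seed, i),
                            montage = montage,
                            pattern_seed = subject_seed(config$seed, 0L))
    ep <- eeg_epochs(sim$data, design$analysis_srate, sim$times,
                     sim$trials, montage$label)
    ep <- preprocess_epochs(ep, min(config$preprocess$notch_hz,
                                    design$analysis_srate / 2 - 1),
                            config$preprocess$ptp_threshold,
                            design$analysis_srate)
    tf <- hanning_tfr(ep, fmin = config$rsa$freq_range[1],
                      fmax = config$rsa$freq_range[2],
                      fstep = config$tfr$fstep,
                      n_cycles = config$tfr$n_cycles,
                      tstep = config$tfr$tstep, out_times = base_times)
    tf <- baseline_absolute(tf, config$tfr$baseline)
    tf <- average_reps(tf)
    ft <- theta_features(tf, config$rsa$freq_range,
                         config$rsa$time_range)
    feat_vals <- if (is.null(feat_vals)) ft$values else
      abind3(feat_vals, ft$values)
    feat_tab <- rbind(feat_tab, ft$trials)

    if (isTRUE(config$coherence$enabled)) {
      st <- coherence_conditions(ep, f0 = config$coherence$f0,
                                 smoothing = config$coherence$smoothing,
                                 window = config$coherence$window,
                                 step = config$coherence$step,
                                 span = config$coherence$span)
      if (is.null(coh)) {
        coh <- st
      } else {
        coh$imcoh <- abind_subjects(coh$imcoh, st$imcoh)
        coh$subjects <- c(coh$subjects, st$subjects)
        coh$groups <- c(coh$groups, st$groups)
      }
    }
    behavior <- rbind(behavior, sim$behavior)
  }
  rownames(feat_tab) <- NULL

  features <- structure(list(values = feat_vals,
                             freqs = seq(config$rsa$freq_range[1],
                                         config$rsa$freq_range[2],
                                         by = config$tfr$fstep),
                             times = seq(config$rsa$time_range[1],
                                         config$rsa$time_range[2],
                                         by = config$tfr$tstep),
                             trials = feat_tab,
                             channels = montage$label),
                        class = "theta_features")
  maps <- build_rdm_set(features)
  adjacency <- build_adjacency(montage,
                               config$cluster$distance_quantile)

  group_of <- function(obj_groups) obj_groups == design$groups[1]
  rsa_tests <- list()
  for (contrast in c("linked_interaction", "nonlinked_interaction",
                     "four_way")) {
    cm <- compose_contrast(maps, rsa_contrast_weights(contrast))
    is_a <- group_of(cm$groups)
    rsa_tests[[contrast]] <- cluster_test(
      cm$value[is_a, , , , drop = FALSE],
      cm$value[!is_a, , , , drop = FALSE],
      adjacency, config$cluster$alpha_cluster,
      config$cluster$n_perm, config$cluster$seed)
  }

  coh_test <- NULL
  if (!is.null(coh)) {
    pair_adj <- build_pair_adjacency(adjacency)
    cc <- coherence_contrast(coh, "linked")
    is_a <- group_of(attr(cc, "groups"))
    coh_test <- cluster_test(cc[is_a, , , drop = FALSE],
                             cc[!is_a, , , drop = FALSE],
                             pair_adj, config$cluster$alpha_cluster,
                             config$cluster$n_perm, config$cluster$seed)
  }

  followups <- NULL
  corr_comparison <- NULL
  main <- rsa_tests$linked_interaction
  if (length(main$clusters) && main$clusters[[1]]$p < 0.05) {
    cl <- main$clusters[[1]]
    means <- extract_cluster_means(maps, cl)
    followups <- rsa_followups(means, design)
    cm <- compose_contrast(maps, rsa_contrast_weights("linked_interaction"))
    contrast_mean <- vapply(seq_len(dim(cm$value)[1]), function(si)
      mean(cm$value[cbind(si, cl$voxels[, 1], cl$voxels[, 2],
                          cl$voxels[, 3])]), numeric(1))
    outcome <- behavior[[config$stats$behavior_outcome]]
    corr_comparison <- brain_behavior_comparison(
      contrast_mean, outcome, maps$groups, design$groups)
  }

  structure(list(config = config, behavior = behavior,
                 rsa_tests = rsa_tests, coherence_test = coh_test,
                 followups = followups,
                 corr_comparison = corr_comparison,
                 n_subjects = nrow(subjects),
                 n_conditions = nrow(maps$conditions),
                 n_coherence_windows = if (!is.null(coh))
                   dim(coh$imcoh)[4] else NA_integer_,
                 seeds = list(simulation = config$seed,
                              permutation = config$cluster$seed),
                 warnings = warnings_log),
            class = "run_report")
}

abind_subjects <- function(a, b) {
  d <- dim(a)
  out <- array(NA_real_, dim = c(d[1] + dim(b)[1], d[-1]))
  idx_a <- seq_len(d[1])
  out[idx_a, , , ] <- a
  out[-idx_a, , , ] <- b
  out
}

rsa_followups <- function(means, design) {
  out <- list()
  for (g in design$groups) {
    sel <- means$group == g
    out[[paste0(g, "_imagination_post_vs_pre")]] <- paired_t(
      means$linked_pre_imagination[sel],
      means$linked_post_imagination[sel])
  }
  out$interaction <- mixed_2x2_interaction(
    means$group,
    means$linked_pre_imagination - means$linked_pre_observation,
    means$linked_post_imagination - means$linked_post_observation)
  out
}

brain_behavior_comparison <- function(brain, outcome, groups,
                                      group_levels) {
  sel1 <- groups == group_levels[1]
  sel2 <- groups == group_levels[2]
  if (sum(sel1) < 4 || sum(sel2) < 4) return(NULL)
  c1 <- correlate(brain[sel1], outcome[sel1])
  c2 <- correlate(brain[sel2], outcome[sel2])
  if (is.na(c1$r) || is.na(c2$r)) return(NULL)
  list(group1 = c1, group2 = c2,
       comparison = compare_correlations(c1$r, c1$n, c2$r, c2$n))
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  cat(sprintf("  %d subjects, %d RDM conditions, %s coherence windows\n",
              x$n_subjects, x$n_conditions,
              as.character(x$n_coherence_windows)))
  for (nm in names(x$rsa_tests)) {
    cl <- x$rsa_tests[[nm]]$clusters
    cat(sprintf("  RSA %s: %d cluster(s)%s\n", nm, length(cl),
                if (length(cl)) sprintf(", min p = %.4g",
                                        min(vapply(cl, `[[`, 1, "p")))
                else ""))
  }
  if (!is.null(x$coherence_test)) {
    cl <- x$coherence_test$clusters
    cat(sprintf("  coherence linked: %d cluster(s)%s\n", length(cl),
                if (length(cl)) sprintf(", min p = %.4g",
                                        min(vapply(cl, `[[`, 1, "p")))
                else ""))
  }
  invisible(x)
}

#' Serialize / restore a run report
#'
#' Writes the report as a schema-versioned JSON master file plus TSV
#' tables (behavior, cluster voxel lists) in a directory.
#'
#' @param report a [run_pipeline()] result.
#' @param path output directory.
#' @return `write_report` returns `path` invisibly; `read_report` the
#'   restored report (as plain lists).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cluster_table <- function(ct) {
    if (is.null(ct) || !length(ct$clusters)) return(NULL)
    do.call(rbind, lapply(seq_along(ct$clusters), function(k) {
      cl <- ct$clusters[[k]]
      data.frame(cluster = k, sign = cl$sign, mass = cl$mass, p = cl$p,
                 ci_range = cl$ci_range, n_voxels = nrow(cl$voxels))
    }))
  }
  master <- list(
    schema_version = "1.0",
    seeds = report$seeds,
    n_subjects = report$n_subjects,
    n_conditions = report$n_conditions,
    n_coherence_windows = report$n_coherence_windows,
    rsa_clusters = lapply(report$rsa_tests, cluster_table),
    coherence_clusters = cluster_table(report$coherence_test),
    followups = lapply(report$followups, unclass),
    corr_comparison = if (!is.null(report$corr_comparison))
      list(r1 = report$corr_comparison$group1$r,
           r2 = report$corr_comparison$group2$r,
           z = report$corr_comparison$comparison$z,
           p = report$corr_comparison$comparison$p) else NULL,
    warnings = report$warnings)
  jsonlite::write_json(master, file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(report$behavior, file.path(path, "behavior.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (nm in names(report$rsa_tests)) {
    ct <- report$rsa_tests[[nm]]
    if (length(ct$clusters)) {
      vox <- do.call(rbind, lapply(seq_along(ct$clusters), function(k)
        cbind(cluster = k, as.data.frame(ct$clusters[[k]]$voxels))))
      utils::write.table(vox,
                         file.path(path, paste0("voxels_", nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(file.path(path, "report.json"),
                      simplifyVector = TRUE)
}
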