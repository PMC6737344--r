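#' Condition-by-time coupling specification
#'
#' Target inter-ROI (ATL-SCC) correlations for each condition-by-time
#' cell of a simulated subject. Defaults loosely mimic the magnitudes of
#' published group means for this trial design but are synthetic values,
#' not measurements.
#'
#' @param r_guilt_pre,r_indig_pre,r_guilt_post,r_indig_post Target
#'   correlations in (-1, 1).
#' @return An object of class \code{coupling_spec}.
#' @export
coupling_spec <- function(r_guilt_pre = 0.15, r_indig_pre = 0.40,
                          r_guilt_post = 0.15, r_indig_post = 0.40) {
  vals <- c(guilt_pre = unname(r_guilt_pre), indig_pre = unname(r_indig_pre),
            guilt_post = unname(r_guilt_post),
            indig_post = unname(r_indig_post))
  if (any(abs(vals) >= 1)) stop("coupling targets must lie in (-1, 1)")
  structure(as.list(vals), class = "coupling_spec")
}

rcorr_pair <- function(n, r) {
  z <- matrix(stats::rnorm(2L * n), ncol = 2L)
  x <- z[, 1]
  y <- r * z[, 1] + sqrt(1 - r^2) * z[, 2]
  cbind(x, y)
}

#' Generate a correlated two-ROI series
#'
#' Bivariate Gaussian samples with the requested population correlation,
#' scaled by \code{noise_sd}, with an optional slow sinusoidal drift
#' added independently to each ROI (drift attenuates the realised
#' correlation; the default is drift-free so the target is also the
#' population correlation of the emitted series).
#'
#' @param n_volumes Number of samples (>= 2).
#' @param target_r Population correlation, |target_r| < 1.
#' @param noise_sd Signal scale (default 1).
#' @param drift_amplitude Amplitude of the low-frequency drift
#'   (default 0).
#' @param drift_period_volumes Drift period (default 100 volumes).
#' @param seed Optional integer seed; the output is bit-identical under
#'   the same seed.
#' @return List with numeric vectors \code{atl} and \code{scc}.
#' @export
generate_pair_series <- function(n_volumes, target_r, noise_sd = 1,
                                 drift_amplitude = 0,
                                 drift_period_volumes = 100, seed = NULL) {
  if (abs(target_r) >= 1) stop("|target_r| must be < 1")
  stopifnot(n_volumes >= 2L)
  if (!is.null(seed)) set.seed(seed)
  xy <- rcorr_pair(n_volumes, target_r) * noise_sd
  if (drift_amplitude > 0) {
    t <- seq_len(n_volumes)
    ph <- stats::runif(2, 0, 2 * pi)
    xy[, 1] <- xy[, 1] +
      drift_amplitude * sin(2 * pi * t / drift_period_volumes + ph[1])
    xy[, 2] <- xy[, 2] +
      drift_amplitude * sin(2 * pi * t / drift_period_volumes + ph[2])
  }
  list(atl = xy[, 1], scc = xy[, 2])
}

generate_motion_trace <- function(n_volumes, spike_prob = 0.02,
                                  base_sd = 0.05) {
  m <- matrix(stats::rnorm(n_volumes * 6L, sd = base_sd), ncol = 6L)
  spikes <- stats::runif(n_volumes) < spike_prob
  if (any(spikes)) {
    # translation spike large enough to cross a 1 mm RMS threshold
    m[spikes, 1] <- m[spikes, 1] +
      sample(c(-1, 1), sum(spikes), TRUE) * stats::runif(sum(spikes), 2, 4)
  }
  colnames(m) <- c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")
  m
}

generate_run_series <- function(timeline, r_by_condition, noise_sd = 1,
                                drift_amplitude = 0,
                                drift_period_volumes = 100,
                                activation_amplitude = 0) {
  n <- timeline$total_volumes
  atl <- numeric(n); scc <- numeric(n)
  b <- timeline$blocks
  for (bi in seq_len(nrow(b))) {
    vols <- seq.int(b$start_volume[bi], length.out = b$n_volumes[bi]) + 1L
    cond <- b$condition[bi]
    r <- if (is_emotional(cond)) r_by_condition[[cond]] else 0
    xy <- rcorr_pair(length(vols), r) * noise_sd
    if (is_emotional(cond)) xy <- xy + activation_amplitude
    atl[vols] <- xy[, 1]; scc[vols] <- xy[, 2]
  }
  if (drift_amplitude > 0) {
    t <- seq_len(n)
    ph <- stats::runif(2, 0, 2 * pi)
    atl <- atl + drift_amplitude * sin(2 * pi * t / drift_period_volumes + ph[1])
    scc <- scc + drift_amplitude * sin(2 * pi * t / drift_period_volumes + ph[2])
  }
  list(atl = atl, scc = scc)
}

#' Generate a full synthetic subject dataset
#'
#' Assembles the four-run session: a pre-training localizer, two
#' neurofeedback runs and a post-training localizer, each with its
#' paradigm timeline, two-ROI series realising the requested coupling
#' per condition-by-time cell, and a 6-parameter motion trace with
#' occasional spikes. Neurofeedback runs use the midpoint of the pre and
#' post couplings per condition. Seed-deterministic.
#'
#' @param coupling A \code{coupling_spec} (the recorded ground truth).
#' @param group \code{"ACTIVE"} or \code{"CONTROL"}.
#' @param subject_id Identifier string.
#' @param age,gender Demographics used by the allocation routines.
#' @param noise_sd,drift_amplitude,motion_spike_prob Generator noise,
#'   drift and motion-spike settings.
#' @param tr_seconds Repetition time.
#' @param include_nf Also generate the two neurofeedback runs (default
#'   TRUE; the offline connectivity statistics only need the
#'   localizers).
#' @param seed Optional integer seed.
#' @return An object of class \code{subject_dataset}.
#' @export
generate_subject <- function(coupling = coupling_spec(), group = "ACTIVE",
                             subject_id = "SUBJ0001", age = 40,
                             gender = "F", noise_sd = 1,
                             drift_amplitude = 0, motion_spike_prob = 0.02,
                             tr_seconds = 2, include_nf = TRUE,
                             seed = NULL) {
  stopifnot(inherits(coupling, "coupling_spec"))
  group <- match.arg(group, c("ACTIVE", "CONTROL"))
  if (!is.null(seed)) set.seed(seed)

  loc <- build_localizer_run(tr_seconds)
  nf <- build_neurofeedback_run(tr_seconds)
  make_run <- function(tl, r_guilt, r_indig) {
    s <- generate_run_series(tl,
                             list(GUILT = r_guilt, INDIGNATION = r_indig),
                             noise_sd = noise_sd,
                             drift_amplitude = drift_amplitude)
    s$timeline <- tl
    s$motion <- generate_motion_trace(tl$total_volumes,
                                      spike_prob = motion_spike_prob)
    s
  }
  runs <- list(localizer_pre = make_run(loc, coupling$guilt_pre,
                                        coupling$indig_pre))
  if (include_nf) {
    g_mid <- (coupling$guilt_pre + coupling$guilt_post) / 2
    i_mid <- (coupling$indig_pre + coupling$indig_post) / 2
    runs$nf_run_1 <- make_run(nf, g_mid, i_mid)
    runs$nf_run_2 <- make_run(nf, g_mid, i_mid)
  }
  runs$localizer_post <- make_run(loc, coupling$guilt_post,
                                  coupling$indig_post)
  structure(list(subject_id = subject_id, group = group, age = age,
                 gender = gender, runs = runs, coupling_truth = coupling),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("<subject_dataset> %s (%s arm, age %s, %s): runs %s\n",
              x$subject_id, x$group, x$age, x$gender,
              paste(names(x$runs), collapse = ", ")))
  invisible(x)
}

#' Effect profile for cohort generation
#'
#' Describes how couplings differ by group, time and condition across a
#' simulated cohort. Under the \code{"active_effect"} profile the active
#' arm's guilt coupling increases from pre to post training by
#' \code{delta_guilt_active} on the Fisher-z scale (control unchanged);
#' under \code{"null"} no cell differs systematically. Per-subject
#' heterogeneity is added on the Fisher-z scale.
#'
#' @param kind \code{"active_effect"} or \code{"null"}.
#' @param base Baseline \code{coupling_spec} shared by both arms.
#' @param delta_guilt_active Fisher-z increment of the active arm's
#'   post-training guilt coupling (default 0.5, i.e. about +0.4 in r
#'   around small baselines).
#' @param subject_sd Per-subject random intercept SD (Fisher-z scale).
#' @param cell_sd Per-cell jitter SD (Fisher-z scale).
#' @return An object of class \code{effect_profile}.
#' @export
effect_profile <- function(kind = c("active_effect", "null"),
                           base = coupling_spec(),
                           delta_guilt_active = 0.5,
                           subject_sd = 0.1, cell_sd = 0.1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, base = base,
                 delta_guilt_active = delta_guilt_active,
                 subject_sd = subject_sd, cell_sd = cell_sd),
            class = "effect_profile")
}

draw_subject_coupling <- function(profile, group) {
  z <- atanh(unlist(profile$base[c("guilt_pre", "indig_pre",
                                   "guilt_post", "indig_post")]))
  z <- z + stats::rnorm(1, sd = profile$subject_sd) +
    stats::rnorm(4, sd = profile$cell_sd)
  if (profile$kind == "active_effect" && group == "ACTIVE")
    z["guilt_post"] <- z["guilt_post"] + profile$delta_guilt_active
  r <- tanh(z)
  coupling_spec(r["guilt_pre"], r["indig_pre"],
                r["guilt_post"], r["indig_post"])
}

#' Generate a two-arm cohort
#'
#' Draws \code{n_per_group} subjects per arm with couplings sampled from
#' the effect profile; ages and genders are drawn to resemble the trial
#' population (mean age about 45, mostly female). Per-subject seeds are
#' derived deterministically from the master seed.
#'
#' @param n_per_group Subjects per arm (default 14, the trial's arm
#'   size).
#' @param profile An \code{effect_profile}.
#' @param seed Master seed.
#' @param include_nf Generate neurofeedback runs too (see
#'   \code{\link{generate_subject}}).
#' @param motion_spike_prob Motion-spike probability per volume.
#' @return List of \code{subject_dataset}, length \code{2 *
#'   n_per_group}, alternating arms.
#' @export
generate_cohort <- function(n_per_group = 14, profile = effect_profile(),
                            seed = NULL, include_nf = FALSE,
                            motion_spike_prob = 0.02) {
  stopifnot(n_per_group >= 2L, inherits(profile, "effect_profile"))
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * n_per_group
  groups <- rep(c("ACTIVE", "CONTROL"), n_per_group)
  ages <- round(stats::rnorm(n, 45, 14))
  genders <- sample(c("F", "M"), n, TRUE, prob = c(0.75, 0.25))
  couplings <- lapply(seq_len(n),
                      function(i) draw_subject_coupling(profile, groups[i]))
  subj_seeds <- sample.int(2^31 - 1L, n)
  lapply(seq_len(n), function(i) {
    generate_subject(couplings[[i]], groups[i],
                     subject_id = sprintf("SUBJ%04d", i),
                     age = ages[i], gender = genders[i],
                     motion_spike_prob = motion_spike_prob,
                     include_nf = include_nf, seed = subj_seeds[i])
  })
}

#' Responsive-participant specification
#'
#' A closed-loop test double standing in for a participant who learns
#' from reinforcement. Under INCREASE-rule feedback the attainable
#' coupling drifts upward in proportion to the received level's excess
#' over neutral; when feedback is below neutral the coupling relaxes
#' toward the participant's baseline at \code{relax_rate}. Under
#' STABILISE-rule feedback the participant maintains their current
#' strategy and the coupling does not drift.
#'
#' @param learning_rate Coupling change per feedback volume per unit of
#'   normalised positive feedback (default 0.02); 0 disables learning.
#' @param relax_rate Fractional relaxation toward baseline per unit of
#'   normalised negative feedback (default 0.02).
#' @param r_min,r_max Attainable coupling bounds, within (-1, 1).
#' @return An object of class \code{agent_spec}.
#' @export
agent_spec <- function(learning_rate = 0.02, relax_rate = 0.02,
                       r_min = -0.9, r_max = 0.9) {
  stopifnot(learning_rate >= 0, relax_rate >= 0,
            r_min > -1, r_max < 1, r_min < r_max)
  structure(list(learning_rate = learning_rate, relax_rate = relax_rate,
                 r_min = r_min, r_max = r_max),
            class = "agent_spec")
}

#' One learning step of the responsive participant
#'
#' @param current_r Current true coupling.
#' @param level_feedback Thermometer level just displayed (percent).
#' @param agent An \code{agent_spec}.
#' @param rule Reinforcement rule the feedback was generated under.
#' @param baseline_r The participant's pre-training coupling (relaxation
#'   target; defaults to \code{current_r}, i.e. no relaxation).
#' @return Next coupling value, clamped to the agent's bounds.
#'   \code{learning_rate = 0} returns \code{current_r} unchanged under
#'   any feedback.
#' @export
responsive_agent_step <- function(current_r, level_feedback, agent,
                                  rule = "INCREASE",
                                  baseline_r = current_r) {
  stopifnot(inherits(agent, "agent_spec"))
  if (rule != "INCREASE" || agent$learning_rate == 0) return(current_r)
  drive <- (level_feedback - 50) / 50     # in [-1, 1]
  nxt <- if (drive >= 0) {
    current_r + agent$learning_rate * drive
  } else {
    current_r + agent$relax_rate * drive * (current_r - baseline_r)
  }
  min(agent$r_max, max(agent$r_min, nxt))
}

#' Closed-loop neurofeedback session with a responsive participant
#'
#' Streams the neurofeedback runs volume by volume: at each volume a
#' two-ROI sample is drawn at the participant's current true coupling
#' (independent samples during subtraction), fed through the feedback
#' engine, and the displayed level drives the participant's learning
#' during guilt blocks via \code{\link{responsive_agent_step}} (under
#' the arm's guilt rule; indignation feedback reinforces stability and
#' leaves the coupling unchanged).
#'
#' @param agent An \code{agent_spec}.
#' @param group \code{"ACTIVE"} or \code{"CONTROL"}.
#' @param r_guilt_start,r_indig_start Initial couplings.
#' @param n_runs Number of neurofeedback runs (default 2).
#' @param config An \code{engine_config}.
#' @param tr_seconds Repetition time.
#' @param seed Optional seed.
#' @return List with the concatenated \code{trace} (a
#'   \code{feedback_trace} with an \code{r_true} column), the guilt
#'   coupling trajectory, and \code{final_r_guilt} /
#'   \code{initial_r_guilt}.
#' @export
run_closed_loop <- function(agent = agent_spec(), group = "ACTIVE",
                            r_guilt_start = 0.2, r_indig_start = 0.4,
                            n_runs = 2L, config = engine_config(),
                            tr_seconds = 2, seed = NULL) {
  group <- match.arg(group, c("ACTIVE", "CONTROL"))
  guilt_rule <- if (group == "ACTIVE") "INCREASE" else "STABILISE"
  if (!is.null(seed)) set.seed(seed)
  r_guilt <- r_guilt_start
  r_indig <- r_indig_start
  traces <- list()
  for (run in seq_len(n_runs)) {
    tl <- build_neurofeedback_run(tr_seconds)
    state <- new_feedback_state(config)
    sub_baseline <- NULL
    rec <- list()
    for (bi in seq_len(nrow(tl$blocks))) {
      cond <- tl$blocks$condition[bi]
      nvol <- tl$blocks$n_volumes[bi]
      start <- tl$blocks$start_volume[bi]
      if (cond == "SUBTRACTION") {
        xy <- rcorr_pair(nvol, 0)
        sub_baseline <- colMeans(xy)
        next
      }
      rule <- if (cond == "GUILT") guilt_rule else "STABILISE"
      state <- reset_block(state)
      for (pos in seq_len(nvol)) {
        r_true <- if (cond == "GUILT") r_guilt else r_indig
        xy <- rcorr_pair(1L, r_true)
        if (pos <= config$discard_volumes) next
        atl_n <- xy[1] - sub_baseline[1]
        scc_n <- xy[2] - sub_baseline[2]
        res <- feedback_step(state, atl_n, scc_n, cond, rule)
        state <- res$state
        if (cond == "GUILT")
          r_guilt <- responsive_agent_step(r_guilt, res$level, agent,
                                           rule = rule,
                                           baseline_r = r_guilt_start)
        rec[[length(rec) + 1L]] <-
          data.frame(volume = start + pos - 1L, condition = cond,
                     r = res$r, score = res$score, level = res$level,
                     gated = FALSE, rule = rule, run = run,
                     r_true = r_true, stringsAsFactors = FALSE)
      }
    }
    traces[[run]] <- do.call(rbind, rec)
  }
  trace <- do.call(rbind, traces)
  rownames(trace) <- NULL
  trace <- structure(trace, class = c("feedback_trace", "data.frame"),
                     gated_count = 0L, config = config,
                     condition_means = tapply(trace$level, trace$condition,
                                              mean),
                     group = group)
  list(trace = trace,
       r_guilt_trajectory = trace$r_true[trace$condition == "GUILT"],
       initial_r_guilt = r_guilt_start,
       final_r_guilt = r_guilt)
}

#' Voxel-level 4D synthetic fixture
#'
#' Builds a small 4D volume in which each ROI's voxels share a latent
#' block-design signal plus independent voxel noise, so that the mean
#' over the ROI recovers the latent series. Voxels outside the two ROIs
#' are pure noise. Used to exercise the full image path (GLM map,
#' top-fraction selection, mean-signal extraction).
#'
#' @param timeline An \code{nf_timeline}.
#' @param grid An \code{nf_grid}.
#' @param atl_voxels,scc_voxels 1-based linear voxel indices of the two
#'   ROIs.
#' @param r_by_condition Named list of couplings per emotional
#'   condition.
#' @param activation_amplitude Mean BOLD offset of emotional blocks in
#'   ATL voxels and of guilt blocks in SCC voxels (drives the selection
#'   contrasts).
#' @param voxel_noise_sd Independent per-voxel noise SD.
#' @param seed Optional seed.
#' @return List with the 4D \code{series} array and the latent
#'   \code{atl}/\code{scc} series.
#' @export
generate_voxel_dataset <- function(timeline, grid, atl_voxels, scc_voxels,
                                   r_by_condition = list(GUILT = 0.3,
                                                         INDIGNATION = 0.4),
                                   activation_amplitude = 1,
                                   voxel_noise_sd = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- timeline$total_volumes
  lat <- generate_run_series(timeline, r_by_condition)
  act_atl <- as.numeric(is_emotional(timeline$conditions)) *
    activation_amplitude
  act_scc <- as.numeric(timeline$conditions == "GUILT") *
    activation_amplitude
  nvox <- grid_n_voxels(grid)
  Y <- matrix(stats::rnorm(n * nvox, sd = voxel_noise_sd), nrow = n)
  Y[, atl_voxels] <- Y[, atl_voxels] + lat$atl + act_atl
  Y[, scc_voxels] <- Y[, scc_voxels] + lat$scc + act_scc
  list(series = array(t(Y), dim = c(grid$dim, n)),
       atl = lat$atl + act_atl, scc = lat$scc + act_scc)
}

#' Write a subject's fixtures to disk
#'
#' Emits, per run, the ROI series TSV, the events TSV (+ JSON sidecar)
#' and the motion TSV, plus a ground-truth JSON for the subject.
#'
#' @param dataset A \code{subject_dataset}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_subject_fixtures <- function(dataset, dir) {
  stopifnot(inherits(dataset, "subject_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rn in names(dataset$runs)) {
    run <- dataset$runs[[rn]]
    utils::write.table(data.frame(atl = run$atl, scc = run$scc),
                       file.path(dir, paste0(rn, "_roi.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_events_tsv(run$timeline, file.path(dir, paste0(rn, "_events.tsv")))
    utils::write.table(run$motion, file.path(dir, paste0(rn, "_motion.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(subject_id = dataset$subject_id,
                            group = dataset$group, age = dataset$age,
                            gender = dataset$gender,
                            coupling_truth = unclass(dataset$coupling_truth)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
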