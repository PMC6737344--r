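#' Feedback engine configuration
#'
#' All tunable parameters of the streaming correlation-feedback engine.
#'
#' @param window_volumes Sliding-window length in volumes (default 10):
#'   the Pearson correlation driving feedback is computed over the last
#'   \code{window_volumes} retained samples, updated every volume.
#' @param discard_volumes Volumes discarded at the start of every
#'   emotional block (default 5), which carry high carry-over
#'   correlations after the subtraction baseline.
#' @param sigmoid_midpoint,sigmoid_slope Parameters of the logistic map
#'   from correlation to display score (midpoint 0, slope 5 by default).
#' @param stabilise_band_sd Half-width of the "stable" band in units of
#'   the running SD of the correlation history (default 1).
#' @param motion_rms_threshold_translation_mm,motion_rms_threshold_rotation_deg
#'   Motion-gating thresholds on the RMS of the three translation /
#'   rotation parameters; a volume is included only if both RMS values
#'   are strictly below threshold (defaults 1 mm, 1 degree).
#' @param level_step Thermometer step, in percentage points, by which the
#'   level moves up or down per reinforcement decision (default 10).
#' @param neutral_level Level displayed before the first full window of a
#'   block (default 50).
#' @param weighting Weighting of the "weighted mean of the last 10
#'   correlations": \code{"linear"} (linearly decaying with recency, the
#'   default) or \code{"uniform"}.
#' @param reference_n How many recent correlations enter the weighted
#'   mean (default 10).
#' @return An object of class \code{engine_config}.
#' @export
engine_config <- function(window_volumes = 10L,
                          discard_volumes = 5L,
                          sigmoid_midpoint = 0,
                          sigmoid_slope = 5,
                          stabilise_band_sd = 1,
                          motion_rms_threshold_translation_mm = 1,
                          motion_rms_threshold_rotation_deg = 1,
                          level_step = 10,
                          neutral_level = 50,
                          weighting = c("linear", "uniform"),
                          reference_n = 10L) {
  weighting <- match.arg(weighting)
  stopifnot(window_volumes >= 2L, discard_volumes >= 0L,
            stabilise_band_sd > 0,
            motion_rms_threshold_translation_mm > 0,
            motion_rms_threshold_rotation_deg > 0,
            level_step > 0, neutral_level >= 0, neutral_level <= 100,
            reference_n >= 1L)
  structure(list(window_volumes = as.integer(window_volumes),
                 discard_volumes = as.integer(discard_volumes),
                 sigmoid_midpoint = sigmoid_midpoint,
                 sigmoid_slope = sigmoid_slope,
                 stabilise_band_sd = stabilise_band_sd,
                 motion_rms_threshold_translation_mm =
                   motion_rms_threshold_translation_mm,
                 motion_rms_threshold_rotation_deg =
                   motion_rms_threshold_rotation_deg,
                 level_step = level_step,
                 neutral_level = neutral_level,
                 weighting = weighting,
                 reference_n = as.integer(reference_n)),
            class = "engine_config")
}

#' Normalise an ROI sample against the preceding baseline block
#'
#' Real-time signal-level normalisation: the mean ROI signal over the
#' entire preceding subtraction block is subtracted from the current
#' sample, which removes local signal trends. Applied independently to
#' each ROI.
#'
#' @param raw_value Current raw ROI mean signal (scalar or vector).
#' @param preceding_subtraction_block_values Raw ROI samples of the whole
#'   preceding subtraction block.
#' @return Normalised value(s).
#' @export
normalize_volume <- function(raw_value, preceding_subtraction_block_values) {
  if (length(preceding_subtraction_block_values) == 0L)
    stop("no preceding subtraction block: paradigm must open with SUBTRACTION")
  raw_value - mean(preceding_subtraction_block_values)
}

#' Sliding-window Pearson correlation
#'
#' Plain Pearson correlation of the two ROI windows. A zero-variance
#' window yields 0 (with a \code{degenerate} attribute) rather than NaN,
#' so the real-time loop never halts.
#'
#' @param atl_window,scc_window Equal-length numeric windows (length >= 2).
#' @return Correlation in [-1, 1]; attribute \code{degenerate} is TRUE
#'   when either window had zero variance.
#' @export
window_correlation <- function(atl_window, scc_window) {
  n <- length(atl_window)
  stopifnot(n == length(scc_window), n >= 2L)
  xa <- atl_window - mean(atl_window)
  xs <- scc_window - mean(scc_window)
  va <- sum(xa^2); vs <- sum(xs^2)
  if (va <= 0 || vs <= 0)
    return(structure(0, degenerate = TRUE))
  r <- sum(xa * xs) / sqrt(va * vs)
  structure(min(1, max(-1, r)), degenerate = FALSE)
}

#' Sigmoid display weighting of a correlation
#'
#' Strictly increasing logistic map from the window correlation to a
#' score in (0, 1); the score equals 0.5 at the configured midpoint.
#'
#' @param r Correlation value(s).
#' @param config An \code{engine_config}.
#' @return Score(s) in (0, 1).
#' @export
sigmoid_weight <- function(r, config = engine_config()) {
  1 / (1 + exp(-config$sigmoid_slope * (r - config$sigmoid_midpoint)))
}

#' Score-to-level mapping against the sigmoid's analytic range
#'
#' Maps a sigmoid score to a percent level relative to the minimum and
#' maximum attainable score over r in [-1, 1].
#'
#' @inheritParams sigmoid_weight
#' @param score Score(s) from \code{sigmoid_weight}.
#' @return Percent in [0, 100].
#' @export
level_from_score <- function(score, config = engine_config()) {
  lo <- sigmoid_weight(-1, config)
  hi <- sigmoid_weight(1, config)
  100 * (score - lo) / (hi - lo)
}

#' Motion gating of a volume
#'
#' Computes the root mean square of the three translation parameters
#' (mm) and of the three rotation parameters (degrees) separately. The
#' volume is included only if both RMS values are strictly below their
#' thresholds; crossing either threshold raises the on-screen warning
#' and excludes the volume from all feedback computation.
#'
#' @param motion_params_6dof Numeric vector of length 6: three
#'   translations (mm) then three rotations (degrees).
#' @param config An \code{engine_config}.
#' @return List with logical \code{include} and \code{warning}.
#' @export
motion_gate <- function(motion_params_6dof, config = engine_config()) {
  if (length(motion_params_6dof) != 6L || anyNA(motion_params_6dof))
    stop("motion_params_6dof must be 6 finite values (3 translations mm, 3 rotations deg)")
  rms_t <- sqrt(mean(motion_params_6dof[1:3]^2))
  rms_r <- sqrt(mean(motion_params_6dof[4:6]^2))
  include <- rms_t < config$motion_rms_threshold_translation_mm &&
    rms_r < config$motion_rms_threshold_rotation_deg
  list(include = include, warning = !include,
       rms_translation = rms_t, rms_rotation = rms_r)
}

weighted_reference_mean <- function(history, config) {
  h <- utils::tail(history, config$reference_n)
  w <- if (config$weighting == "linear") seq_along(h) else rep(1, length(h))
  sum(w * h) / sum(w)
}

#' Fresh streaming feedback state
#'
#' @param config An \code{engine_config}.
#' @return An object of class \code{feedback_state}. Correlation
#'   histories are kept per emotional condition and reset at run
#'   boundaries; sample buffers and the thermometer level reset at each
#'   emotional block.
#' @export
new_feedback_state <- function(config = engine_config()) {
  structure(list(config = config,
                 atl_buffer = numeric(0),
                 scc_buffer = numeric(0),
                 history = list(GUILT = numeric(0), INDIGNATION = numeric(0)),
                 current_level = config$neutral_level,
                 gated_count = 0L),
            class = "feedback_state")
}

reset_block <- function(state) {
  state$atl_buffer <- numeric(0)
  state$scc_buffer <- numeric(0)
  state$current_level <- state$config$neutral_level
  state
}

#' One engine step on a feedback-eligible volume
#'
#' Pushes the normalised ATL/SCC samples into the window buffers,
#' computes the sliding-window correlation once the window is full,
#' compares it against the moving target (weighted mean of the last 10
#' correlations, band of one running SD of the history so far) and moves
#' the thermometer level by one step up or down according to the rule:
#' \describe{
#'   \item{INCREASE}{up iff r exceeds the weighted mean plus one running
#'     SD, down otherwise;}
#'   \item{STABILISE}{up iff r stays within the weighted mean plus/minus
#'     \code{stabilise_band_sd} running SDs, down otherwise.}
#' }
#' Before the window is full the neutral level is displayed, and the
#' first correlation of a run/condition (empty reference history) leaves
#' the level unchanged.
#'
#' @param state A \code{feedback_state}.
#' @param atl_value,scc_value Normalised ROI samples for this volume.
#' @param condition \code{"GUILT"} or \code{"INDIGNATION"}.
#' @param rule \code{"INCREASE"} or \code{"STABILISE"}.
#' @return List with the updated \code{state}, \code{level}, \code{r}
#'   (NA during warm-up) and \code{score}.
#' @export
feedback_step <- function(state, atl_value, scc_value, condition, rule) {
  stopifnot(inherits(state, "feedback_state"))
  if (!is_emotional(condition))
    stop("feedback_step must not be called during SUBTRACTION")
  rule <- match.arg(rule, c("INCREASE", "STABILISE"))
  cfg <- state$config

  state$atl_buffer <- utils::tail(c(state$atl_buffer, atl_value),
                                  cfg$window_volumes)
  state$scc_buffer <- utils::tail(c(state$scc_buffer, scc_value),
                                  cfg$window_volumes)

  if (length(state$atl_buffer) < cfg$window_volumes) {
    state$current_level <- cfg$neutral_level
    return(list(state = state, level = cfg$neutral_level,
                r = NA_real_, score = NA_real_))
  }

  r <- as.numeric(window_correlation(state$atl_buffer, state$scc_buffer))
  score <- sigmoid_weight(r, cfg)
  hist <- state$history[[condition]]
  if (length(hist) >= 1L) {
    wm <- weighted_reference_mean(hist, cfg)
    s <- if (length(hist) >= 2L) stats::sd(hist) else 0
    up <- if (rule == "INCREASE") r > wm + s
          else abs(r - wm) <= cfg$stabilise_band_sd * s
    step <- if (up) cfg$level_step else -cfg$level_step
    state$current_level <- min(100, max(0, state$current_level + step))
  }
  state$history[[condition]] <- c(hist, r)
  list(state = state, level = state$current_level, r = r, score = score)
}

#' Replay a run through the feedback engine
#'
#' Streams one run's two ROI signal series through the engine exactly as
#' during acquisition: subtraction blocks accumulate the baseline used to
#' normalise the following emotional block; the first
#' \code{discard_volumes} of each emotional block are skipped; motion
#' RMS gating excludes volumes from all computation (the level holds and
#' the gated count increments); buffers and level reset at each emotional
#' block, correlation histories accumulate per condition over the run.
#'
#' @param atl_raw,scc_raw Raw ROI mean-signal series (one value per
#'   volume).
#' @param timeline The run's \code{nf_timeline}.
#' @param guilt_rule Rule applied during guilt blocks (\code{"INCREASE"}
#'   for the active arm, \code{"STABILISE"} for the control arm);
#'   indignation blocks always use \code{"STABILISE"}.
#' @param motion Optional volumes-by-6 motion-parameter matrix.
#' @param config An \code{engine_config}.
#' @param state Optional prior \code{feedback_state} (histories persist
#'   if supplied; by default a fresh state, i.e. per-run histories).
#' @return An object of class \code{feedback_trace}: a data frame with
#'   one row per retained (non-discarded) emotional volume and columns
#'   \code{volume}, \code{condition}, \code{r}, \code{score},
#'   \code{level}, \code{gated}, \code{rule}; attributes carry the gated
#'   count and config.
#' @export
engine_replay <- function(atl_raw, scc_raw, timeline,
                          guilt_rule = c("INCREASE", "STABILISE"),
                          motion = NULL, config = engine_config(),
                          state = NULL) {
  stopifnot(inherits(timeline, "nf_timeline"))
  guilt_rule <- match.arg(guilt_rule)
  n <- timeline$total_volumes
  if (length(atl_raw) != n || length(scc_raw) != n)
    stop("series length (", length(atl_raw), ") does not match the timeline (",
         n, " volumes)")
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n || ncol(motion) != 6L)
      stop("motion must be a ", n, " x 6 matrix")
  }
  if (is.null(state)) state <- new_feedback_state(config)

  blocks <- timeline$blocks
  sub_baseline <- c(atl = NA_real_, scc = NA_real_)
  rec <- vector("list", n)
  ri <- 0L
  for (bi in seq_len(nrow(blocks))) {
    cond <- blocks$condition[bi]
    vols <- seq.int(blocks$start_volume[bi],
                    length.out = blocks$n_volumes[bi])
    if (cond == "SUBTRACTION") {
      sub_baseline <- c(atl = mean(atl_raw[vols + 1L]),
                        scc = mean(scc_raw[vols + 1L]))
      next
    }
    if (anyNA(sub_baseline))
      stop("emotional block without a preceding subtraction block")
    rule <- if (cond == "GUILT") guilt_rule else "STABILISE"
    state <- reset_block(state)
    for (pos in seq_along(vols)) {
      if (pos <= config$discard_volumes) next
      v <- vols[pos]
      gated <- FALSE
      if (!is.null(motion)) {
        g <- motion_gate(motion[v + 1L, ], config)
        gated <- !g$include
      }
      if (gated) {
        state$gated_count <- state$gated_count + 1L
        res <- list(level = state$current_level, r = NA_real_,
                    score = NA_real_)
      } else {
        atl_n <- normalize_volume(atl_raw[v + 1L], sub_baseline["atl"])
        scc_n <- normalize_volume(scc_raw[v + 1L], sub_baseline["scc"])
        res <- feedback_step(state, atl_n, scc_n, cond, rule)
        state <- res$state
      }
      ri <- ri + 1L
      rec[[ri]] <- data.frame(volume = v, condition = cond, r = res$r,
                              score = res$score, level = res$level,
                              gated = gated, rule = rule,
                              stringsAsFactors = FALSE)
    }
  }
  trace <- do.call(rbind, rec[seq_len(ri)])
  rownames(trace) <- NULL
  structure(trace, class = c("feedback_trace", "data.frame"),
            gated_count = state$gated_count, config = config,
            state = state)
}

#' Run the full neurofeedback session of a subject
#'
#' Replays both neurofeedback runs of a subject dataset under the arm's
#' reinforcement rules: guilt blocks use the INCREASE rule in the ACTIVE
#' arm and the STABILISE rule in the CONTROL arm; indignation blocks use
#' STABILISE in both arms.
#'
#' @param dataset A \code{subject_dataset} (see
#'   \code{\link{generate_subject}}) containing neurofeedback runs.
#' @param group \code{"ACTIVE"} or \code{"CONTROL"}; defaults to the
#'   dataset's arm.
#' @param config An \code{engine_config}.
#' @return A \code{feedback_trace} over both runs (extra column
#'   \code{run}), with per-condition average thermometer positions in
#'   attribute \code{condition_means} and the total gated count in
#'   attribute \code{gated_count}.
#' @export
run_feedback_session <- function(dataset, group = dataset$group,
                                 config = engine_config()) {
  stopifnot(inherits(dataset, "subject_dataset"))
  group <- match.arg(group, c("ACTIVE", "CONTROL"))
  guilt_rule <- if (group == "ACTIVE") "INCREASE" else "STABILISE"
  nf_runs <- dataset$runs[grep("^nf", names(dataset$runs))]
  if (length(nf_runs) == 0L) stop("dataset contains no neurofeedback runs")
  traces <- lapply(seq_along(nf_runs), function(i) {
    run <- nf_runs[[i]]
    tr <- engine_replay(run$atl, run$scc, run$timeline,
                        guilt_rule = guilt_rule, motion = run$motion,
                        config = config)
    tr$run <- names(nf_runs)[i]
    tr
  })
  gated <- sum(vapply(traces, attr, 0L, "gated_count"))
  out <- do.call(rbind, lapply(traces, as.data.frame))
  rownames(out) <- NULL
  cm <- tapply(out$level[!out$gated], out$condition[!out$gated], mean)
  structure(out, class = c("feedback_trace", "data.frame"),
            gated_count = gated, config = config,
            condition_means = cm, group = group)
}

#' @export
print.feedback_trace <- function(x, ...) {
  cat(sprintf("<feedback_trace> %d feedback volumes, %d gated\n",
              nrow(x), attr(x, "gated_count") %||% sum(x$gated)))
  cm <- attr(x, "condition_means")
  if (!is.null(cm))
    cat("  mean thermometer level:",
        paste(sprintf("%s=%.1f%%", names(cm), cm), collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a feedback trace TSV
#'
#' Columns exactly: volume, condition, r, score, level, gated, rule
#' (plus run when present).
#'
#' @param trace A \code{feedback_trace}.
#' @param path File path.
#' @export
write_trace_tsv <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  tr <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  structure(tr, class = c("feedback_trace", "data.frame"))
}
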