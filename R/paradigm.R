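#' Condition labels of the blame-rebalance paradigm
#'
#' The paradigm alternates mental-subtraction baseline blocks with two
#' emotional autobiographical-memory conditions: guilt and indignation.
#' Subtraction is the non-emotional baseline used for signal normalisation.
#'
#' @return Character vector of condition labels.
#' @export
nf_conditions <- function() c("SUBTRACTION", "GUILT", "INDIGNATION")

#' @rdname nf_conditions
#' @export
nf_emotional_conditions <- function() c("GUILT", "INDIGNATION")

is_emotional <- function(condition) condition %in% nf_emotional_conditions()

#' Build a block-design paradigm timeline
#'
#' Constructs the per-volume timeline of a run. A run opens with a
#' subtraction block and strictly alternates subtraction and emotional
#' blocks, so that every emotional block has a preceding subtraction
#' baseline (required by the feedback engine's normalisation). Two run
#' kinds exist:
#' \describe{
#'   \item{LOCALIZER (runs 1 and 4)}{4 guilt blocks and 4 indignation
#'     blocks of 15 volumes each, interleaved with 8 subtraction blocks of
#'     10 volumes: 200 volumes, 400 s at TR = 2 s. Used for ROI selection
#'     (run 1) and pre/post outcome measurement.}
#'   \item{NEUROFEEDBACK (runs 2 and 3)}{4 guilt and 4 indignation blocks
#'     of 30 volumes each, interleaved with 8 subtraction blocks of 15
#'     volumes: 360 volumes.}
#' }
#'
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param emotional_order Order of the 8 emotional blocks; a character
#'   vector recycled to length 8 containing exactly 4 \code{"GUILT"} and 4
#'   \code{"INDIGNATION"} entries. Default alternates G, I, G, I, ...
#' @return An object of class \code{nf_timeline}: a list with
#'   \code{run_kind}, \code{tr_seconds}, \code{blocks} (data frame with
#'   \code{condition}, \code{start_volume} (0-based), \code{n_volumes},
#'   \code{block_ordinal}), \code{total_volumes} and \code{conditions}
#'   (per-volume label vector).
#' @examples
#' tl <- build_localizer_run()
#' tl$total_volumes  # 200
#' @export
build_localizer_run <- function(tr_seconds = 2,
                                emotional_order = c("GUILT", "INDIGNATION")) {
  build_timeline("LOCALIZER", tr_seconds,
                 emotional_len = 15L, subtraction_len = 10L,
                 emotional_order = emotional_order)
}

#' @rdname build_localizer_run
#' @export
build_neurofeedback_run <- function(tr_seconds = 2,
                                    emotional_order = c("GUILT", "INDIGNATION")) {
  build_timeline("NEUROFEEDBACK", tr_seconds,
                 emotional_len = 30L, subtraction_len = 15L,
                 emotional_order = emotional_order)
}

build_timeline <- function(run_kind, tr_seconds, emotional_len,
                           subtraction_len, emotional_order) {
  stopifnot(is.numeric(tr_seconds), length(tr_seconds) == 1L, tr_seconds > 0)
  emotional_order <- rep_len(as.character(emotional_order), 8L)
  if (!all(emotional_order %in% nf_emotional_conditions()))
    stop("emotional_order must contain only GUILT / INDIGNATION labels")
  if (sum(emotional_order == "GUILT") != 4L)
    stop("emotional_order must contain exactly 4 GUILT and 4 INDIGNATION blocks")

  cond <- character(16L)
  len <- integer(16L)
  cond[seq(1L, 16L, 2L)] <- "SUBTRACTION"
  len[seq(1L, 16L, 2L)] <- subtraction_len
  cond[seq(2L, 16L, 2L)] <- emotional_order
  len[seq(2L, 16L, 2L)] <- emotional_len

  start <- cumsum(c(0L, len))[seq_len(16L)]
  ordinal <- stats::ave(seq_along(cond), cond, FUN = seq_along)
  blocks <- data.frame(condition = cond, start_volume = start,
                       n_volumes = len, block_ordinal = as.integer(ordinal),
                       stringsAsFactors = FALSE)
  out <- list(run_kind = run_kind,
              tr_seconds = tr_seconds,
              blocks = blocks,
              total_volumes = sum(len),
              conditions = rep(cond, len))
  class(out) <- "nf_timeline"
  out
}

#' @export
print.nf_timeline <- function(x, ...) {
  cat(sprintf("<nf_timeline> %s run: %d volumes, TR %.1f s (%.0f s)\n",
              x$run_kind, x$total_volumes, x$tr_seconds,
              x$total_volumes * x$tr_seconds))
  tab <- table(x$conditions)
  cat("  volumes per condition:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  %d blocks, opening with %s\n",
              nrow(x$blocks), x$blocks$condition[1L]))
  invisible(x)
}

#' Condition at a given volume
#'
#' @param timeline An \code{nf_timeline}.
#' @param volume_index 0-based volume index (scalar or vector).
#' @return Condition label(s) of the block containing each volume.
#' @export
condition_at <- function(timeline, volume_index) {
  stopifnot(inherits(timeline, "nf_timeline"))
  if (any(volume_index < 0L | volume_index >= timeline$total_volumes))
    stop("volume_index out of range [0, ", timeline$total_volumes - 1L, "]")
  timeline$conditions[volume_index + 1L]
}

block_index_at <- function(timeline, volume_index) {
  # 1-based row in timeline$blocks for each 0-based volume index
  findInterval(volume_index, timeline$blocks$start_volume)
}

#' Retained analysis volumes of an emotional condition
#'
#' For each block of the requested emotional condition, drops the first
#' \code{discard_n} volumes (they carry carry-over correlations from the
#' preceding subtraction block) and returns the retained 0-based volume
#' indices in temporal order.
#'
#' @inheritParams condition_at
#' @param condition \code{"GUILT"} or \code{"INDIGNATION"}.
#' @param discard_n Number of initial volumes discarded per block
#'   (default 5).
#' @return Integer vector of 0-based retained volume indices.
#' @export
analysis_volumes <- function(timeline, condition, discard_n = 5L) {
  stopifnot(inherits(timeline, "nf_timeline"))
  if (!is_emotional(condition))
    stop("analysis_volumes is defined for emotional conditions only")
  if (discard_n < 0L) stop("discard_n must be >= 0")
  b <- timeline$blocks[timeline$blocks$condition == condition, , drop = FALSE]
  if (any(discard_n >= b$n_volumes))
    stop("discard_n (", discard_n, ") must be smaller than the block length")
  unlist(lapply(seq_len(nrow(b)), function(i) {
    seq.int(b$start_volume[i] + discard_n,
            b$start_volume[i] + b$n_volumes[i] - 1L)
  }), use.names = FALSE)
}

#' Export / import a timeline as a BIDS-style events table
#'
#' Writes \code{onset}, \code{duration} (seconds) and \code{trial_type}
#' to a tab-separated file, with the repetition time and run kind in a
#' JSON sidecar next to it.
#'
#' @param timeline An \code{nf_timeline}.
#' @param path Path of the events TSV to write; the sidecar replaces the
#'   extension with \code{.json}.
#' @return \code{path}, invisibly.
#' @export
write_events_tsv <- function(timeline, path) {
  stopifnot(inherits(timeline, "nf_timeline"))
  b <- timeline$blocks
  ev <- data.frame(onset = b$start_volume * timeline$tr_seconds,
                   duration = b$n_volumes * timeline$tr_seconds,
                   trial_type = b$condition)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(list(RepetitionTime = timeline$tr_seconds,
                            RunKind = timeline$run_kind,
                            TotalVolumes = timeline$total_volumes),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  tr <- meta$RepetitionTime
  n <- as.integer(round(ev$duration / tr))
  start <- as.integer(round(ev$onset / tr))
  ordinal <- stats::ave(seq_len(nrow(ev)), ev$trial_type, FUN = seq_along)
  blocks <- data.frame(condition = ev$trial_type, start_volume = start,
                       n_volumes = n, block_ordinal = as.integer(ordinal),
                       stringsAsFactors = FALSE)
  out <- list(run_kind = meta$RunKind, tr_seconds = tr, blocks = blocks,
              total_volumes = sum(n), conditions = rep(ev$trial_type, n))
  class(out) <- "nf_timeline"
  out
}

#' Per-volume condition column
#'
#' @inheritParams write_events_tsv
#' @return \code{path}, invisibly.
#' @export
write_condition_column_tsv <- function(timeline, path) {
  stopifnot(inherits(timeline, "nf_timeline"))
  utils::write.table(
    data.frame(volume = seq_len(timeline$total_volumes) - 1L,
               condition = timeline$conditions),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
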