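#' Z-score a series
#'
#' Standardises to mean 0 and (sample) SD 1; used so regression slopes
#' between the two ROI time courses are standardised coefficients.
#'
#' @param series Numeric vector, length >= 2.
#' @return Standardised vector.
#' @export
zscore <- function(series) {
  if (length(series) < 2L) stop("zscore needs at least 2 values")
  s <- stats::sd(series)
  if (!is.finite(s) || s == 0) stop("zscore is undefined for a constant series")
  (series - mean(series)) / s
}

cell_names <- c("guilt_pre", "indig_pre", "guilt_post", "indig_post")

#' Per-subject connectivity effects from condition-by-time cells
#'
#' Fits one ordinary least-squares model per subject over all four
#' condition-by-time cells, with a separate intercept and a separate
#' z(ATL) slope per cell (equivalently, the full interaction of z(ATL)
#' with condition and time). Series are z-scored within each cell before
#' fitting so the slopes are standardised coefficients. Per cell the
#' model yields the slope, its t value, the model's residual degrees of
#' freedom, and the within-subject effect size d = 2 t / sqrt(df).
#'
#' @param cells Named list (\code{guilt_pre}, \code{indig_pre},
#'   \code{guilt_post}, \code{indig_post}); each element a list with
#'   numeric \code{atl} and \code{scc} of equal length.
#' @param subject_id Identifier carried into the result.
#' @param group Optional arm label.
#' @return An object of class \code{connectivity_effect}: a list with
#'   per-cell \code{beta}, \code{t}, \code{d}, common \code{df} and the
#'   fitted model.
#' @export
effects_from_cells <- function(cells, subject_id = NA_character_,
                               group = NA_character_) {
  stopifnot(all(cell_names %in% names(cells)))
  dat <- do.call(rbind, lapply(cell_names, function(cn) {
    cl <- cells[[cn]]
    if (length(cl$atl) < 3L)
      stop("cell ", cn, " has too few volumes (", length(cl$atl), ")")
    data.frame(cell = cn, atl = zscore(cl$atl), scc = zscore(cl$scc))
  }))
  dat$cell <- factor(dat$cell, levels = cell_names)
  fit <- stats::lm(scc ~ 0 + cell + cell:atl, data = dat)
  sm <- summary(fit)$coefficients
  slope_rows <- paste0("cell", cell_names, ":atl")
  beta <- sm[slope_rows, "Estimate"]
  tval <- sm[slope_rows, "t value"]
  df <- fit$df.residual
  d <- 2 * tval / sqrt(df)
  names(beta) <- names(tval) <- names(d) <- cell_names
  structure(list(subject_id = subject_id, group = group,
                 beta = beta, t = tval, df = df, d = d, model = fit),
            class = "connectivity_effect")
}

#' Per-subject connectivity effects from a subject dataset
#'
#' Extracts the retained emotional analysis volumes (first
#' \code{discard_n} of each block dropped) of the pre- and post-training
#' localizer runs, optionally excludes motion-gated volumes, and fits
#' the condition-by-time interaction model of
#' \code{\link{effects_from_cells}}.
#'
#' @param dataset A \code{subject_dataset}.
#' @param discard_n Initial volumes discarded per emotional block
#'   (default 5).
#' @param config \code{engine_config} used for motion gating.
#' @param gate_motion Exclude motion-gated volumes (default TRUE).
#' @return A \code{connectivity_effect}.
#' @export
subject_effects <- function(dataset, discard_n = 5L,
                            config = engine_config(), gate_motion = TRUE) {
  stopifnot(inherits(dataset, "subject_dataset"))
  runs <- list(pre = dataset$runs$localizer_pre,
               post = dataset$runs$localizer_post)
  if (any(vapply(runs, is.null, TRUE)))
    stop("dataset must contain localizer_pre and localizer_post runs")
  cells <- list()
  for (tm in names(runs)) {
    run <- runs[[tm]]
    for (cond in nf_emotional_conditions()) {
      idx <- analysis_volumes(run$timeline, cond, discard_n)
      if (gate_motion && !is.null(run$motion)) {
        keep <- vapply(idx, function(v)
          motion_gate(run$motion[v + 1L, ], config)$include, TRUE)
        idx <- idx[keep]
      }
      cn <- paste0(if (cond == "GUILT") "guilt" else "indig", "_", tm)
      cells[[cn]] <- list(atl = run$atl[idx + 1L], scc = run$scc[idx + 1L])
    }
  }
  effects_from_cells(cells, subject_id = dataset$subject_id,
                     group = dataset$group)
}

#' @export
print.connectivity_effect <- function(x, ...) {
  cat(sprintf("<connectivity_effect> %s (%s), df = %d\n",
              x$subject_id, x$group, x$df))
  print(round(rbind(beta = x$beta, t = x$t, d = x$d), 3))
  invisible(x)
}

#' @export
coef.connectivity_effect <- function(object, ...) object$beta

#' Guilt-selective training effect of one subject
#'
#' The difference-of-differences (guilt minus indignation, post minus
#' pre) of the per-cell effects; the quantity whose between-group t-test
#' is equivalent to the three-way ANOVA interaction.
#'
#' @param effect A \code{connectivity_effect}.
#' @param scale \code{"beta"} (standardised slopes, default) or
#'   \code{"d"} (within-subject Cohen's d).
#' @return Scalar: (guilt_post - indig_post) - (guilt_pre - indig_pre).
#' @export
interaction_difference <- function(effect, scale = c("beta", "d")) {
  scale <- match.arg(scale)
  v <- if (inherits(effect, "connectivity_effect")) effect[[scale]] else effect
  if (!all(cell_names %in% names(v))) stop("all four cells must be present")
  unname((v["guilt_post"] - v["indig_post"]) -
           (v["guilt_pre"] - v["indig_pre"]))
}

effects_table <- function(effects, scale = "beta") {
  do.call(rbind, lapply(effects, function(e) {
    v <- e[[scale]]
    data.frame(subject_id = e$subject_id, group = e$group,
               guilt_pre = v[["guilt_pre"]], indig_pre = v[["indig_pre"]],
               guilt_post = v[["guilt_post"]], indig_post = v[["indig_post"]],
               stringsAsFactors = FALSE)
  }))
}

pooled_sd <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2))
}

#' Group-level comparison of connectivity effects
#'
#' The trial's primary analysis: a repeated-measures ANOVA of the
#' per-subject effects with within-subject factors condition (guilt,
#' indignation) and time (pre, post) and the between-subject factor
#' group (ACTIVE, CONTROL), together with the equivalent independent
#' t-test on the per-subject difference-of-differences scores, whose p
#' value coincides with the three-way interaction term. Group
#' descriptives are reported per cell; the mean difference follows the
#' CONTROL minus ACTIVE sign convention, and the between-group effect
#' size is Cohen's d from the pooled (Bessel-corrected) SD of the
#' difference scores.
#'
#' @param effects List of \code{connectivity_effect} (one per subject)
#'   or a data frame as produced internally with columns
#'   \code{subject_id}, \code{group} and the four cells.
#' @param scale \code{"beta"} or \code{"d"} (per-cell effect scale).
#' @return An object of class \code{nf_group_result}.
#' @export
group_compare <- function(effects, scale = c("beta", "d")) {
  scale <- match.arg(scale)
  tab <- if (is.data.frame(effects)) effects else effects_table(effects, scale)
  if (min(table(tab$group)) < 2L)
    stop("each group needs at least 2 subjects")

  long <- stats::reshape(tab, direction = "long",
                         varying = cell_names, v.names = "value",
                         times = cell_names, timevar = "cell",
                         idvar = "subject_id")
  long$condition <- factor(ifelse(grepl("^guilt", long$cell),
                                  "guilt", "indignation"))
  long$time <- factor(ifelse(grepl("_pre$", long$cell), "pre", "post"),
                      levels = c("pre", "post"))
  long$group <- factor(long$group, levels = c("ACTIVE", "CONTROL"))
  long$subject_id <- factor(long$subject_id)

  aov_fit <- stats::aov(value ~ group * condition * time +
                          Error(subject_id / (condition * time)),
                        data = long)
  anova_tab <- anova_effect_table(aov_fit)

  diffs <- apply(tab[, cell_names], 1, function(v)
    (v["guilt_post"] - v["indig_post"]) - (v["guilt_pre"] - v["indig_pre"]))
  ga <- diffs[tab$group == "ACTIVE"]
  gc <- diffs[tab$group == "CONTROL"]
  tt <- stats::t.test(gc, ga, var.equal = TRUE)
  d_between <- (mean(gc) - mean(ga)) / pooled_sd(gc, ga)

  desc <- do.call(rbind, lapply(cell_names, function(cn) {
    do.call(rbind, lapply(c("ACTIVE", "CONTROL"), function(g) {
      v <- tab[tab$group == g, cn]
      data.frame(cell = cn, group = g, m = mean(v), sd = stats::sd(v))
    }))
  }))

  structure(list(anova = anova_tab,
                 t_test = list(t = unname(tt$statistic),
                               df = unname(tt$parameter),
                               p = tt$p.value,
                               mean_difference = mean(gc) - mean(ga),
                               se = unname(tt$stderr),
                               conf_int = unname(tt$conf.int),
                               d = d_between,
                               sign_convention = "CONTROL - ACTIVE"),
                 descriptives = desc,
                 scale = scale,
                 n = table(tab$group)),
            class = "nf_group_result")
}

anova_effect_table <- function(aov_fit) {
  sm <- summary(aov_fit)
  rows <- list()
  for (stratum in sm) {
    t <- stratum[[1]]
    keep <- !grepl("Residual", rownames(t))
    for (i in which(keep)) {
      rows[[length(rows) + 1L]] <-
        data.frame(effect = trimws(rownames(t)[i]),
                   df = t$Df[i], F = t$`F value`[i], p = t$`Pr(>F)`[i])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.nf_group_result <- function(x, ...) {
  cat("<nf_group_result> repeated-measures ANOVA on per-subject",
      x$scale, "effects\n")
  print(transform(x$anova, F = round(F, 3), p = signif(p, 3)))
  with(x$t_test, cat(sprintf(
    "difference-score t-test (%s): diff = %.3f, se = %.3f, t(%d) = %.2f, p = %.3g, d = %.2f\n",
    x$t_test$sign_convention, mean_difference, se, df, t, p, d)))
  invisible(x)
}

#' ANCOVA confirmation of the group effect
#'
#' Models the post-training outcome on group with the pre-training value
#' as covariate, on complete cases only; the number of listwise-deleted
#' subjects is reported.
#'
#' @param post,pre Numeric outcome vectors (may contain NA).
#' @param groups Group labels (ACTIVE/CONTROL).
#' @return List with the fitted \code{lm}, the group coefficient
#'   (CONTROL relative to ACTIVE), its t and p, and \code{n_excluded}.
#' @export
ancova_check <- function(post, pre, groups) {
  stopifnot(length(post) == length(pre), length(post) == length(groups))
  groups <- factor(groups, levels = c("ACTIVE", "CONTROL"))
  complete <- stats::complete.cases(post, pre, groups)
  n_excluded <- sum(!complete)
  if (!any(complete)) stop("no complete cases")
  d <- data.frame(post = post, pre = pre, group = groups)[complete, ]
  fit <- stats::lm(post ~ group + pre, data = d)
  sm <- summary(fit)$coefficients
  list(model = fit,
       group_coefficient = sm["groupCONTROL", "Estimate"],
       t = sm["groupCONTROL", "t value"],
       p = sm["groupCONTROL", "Pr(>|t|)"],
       n_used = sum(complete), n_excluded = n_excluded)
}

#' Minimised randomisation of a subject stream
#'
#' Sequential covariate-adaptive allocation: the first
#' \code{n_random_first} subjects are randomised (in balanced random
#' order across the two arms), and each later subject joins the arm that
#' minimises a running imbalance score combining the absolute difference
#' in mean age (scaled by the ages' SD so far), the absolute difference
#' in male counts, and (with a small weight) the group-size difference;
#' exact ties are broken by a random draw. The allocation can be written
#' to a concealed text file.
#'
#' @param age Numeric vector, one entry per subject in arrival order.
#' @param gender Character vector (\code{"M"}/\code{"F"}).
#' @param n_random_first Size of the initial random phase (default 2).
#' @param w_age,w_gender,w_size Score weights (defaults 1, 1, 0.25).
#' @param seed Optional seed making the allocation reproducible.
#' @param file Optional path of the allocation text file.
#' @return An object of class \code{allocation_state}: data frame
#'   \code{log} (subject, age, gender, group) plus per-group totals.
#' @export
minimised_allocate <- function(age, gender, n_random_first = 2L,
                               w_age = 1, w_gender = 1, w_size = 0.25,
                               seed = NULL, file = NULL) {
  n <- length(age)
  stopifnot(n >= 1L, length(gender) == n)
  if (!is.null(seed)) set.seed(seed)
  groups <- character(n)
  imbalance <- function(gvec, upto) {
    a <- which(gvec[seq_len(upto)] == "ACTIVE")
    c_ <- which(gvec[seq_len(upto)] == "CONTROL")
    if (length(a) == 0L || length(c_) == 0L) return(Inf)
    sd_age <- stats::sd(age[seq_len(upto)])
    if (!is.finite(sd_age) || sd_age == 0) sd_age <- 1
    w_age * abs(mean(age[a]) - mean(age[c_])) / sd_age +
      w_gender * abs(sum(gender[a] == "M") - sum(gender[c_] == "M")) +
      w_size * abs(length(a) - length(c_))
  }
  for (i in seq_len(n)) {
    if (i <= n_random_first) {
      # balanced random phase: arms assigned in random order
      if (i == 1L) phase <- sample(rep_len(c("ACTIVE", "CONTROL"),
                                           min(n_random_first, n)))
      groups[i] <- phase[i]
      next
    }
    score <- vapply(c("ACTIVE", "CONTROL"), function(g) {
      trial <- groups; trial[i] <- g
      imbalance(trial, i)
    }, 0)
    groups[i] <- if (abs(score[1] - score[2]) < 1e-12) {
      sample(c("ACTIVE", "CONTROL"), 1L)
    } else {
      names(score)[which.min(score)]
    }
  }
  log <- data.frame(subject = seq_len(n), age = age, gender = gender,
                    group = groups, stringsAsFactors = FALSE)
  if (!is.null(file))
    utils::write.table(log, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  totals <- do.call(rbind, lapply(c("ACTIVE", "CONTROL"), function(g) {
    sel <- groups == g
    data.frame(group = g, n = sum(sel),
               mean_age = if (any(sel)) mean(age[sel]) else NA_real_,
               n_male = sum(sel & gender == "M"))
  }))
  structure(list(log = log, totals = totals), class = "allocation_state")
}

#' @export
print.allocation_state <- function(x, ...) {
  cat("<allocation_state>\n")
  print(x$totals)
  invisible(x)
}

#' Thermometer feedback summary
#'
#' Per-condition average thermometer position (percent over non-gated
#' feedback volumes) per trace, aggregated by arm with an independent
#' t-test per condition.
#'
#' @param traces List of \code{feedback_trace}.
#' @param groups Arm label per trace.
#' @return List with the per-subject \code{levels} data frame and a
#'   per-condition \code{comparison} data frame (group means, SDs,
#'   difference CONTROL - ACTIVE, t, p).
#' @export
thermometer_summary <- function(traces, groups) {
  stopifnot(length(traces) == length(groups), length(traces) >= 1L)
  levels_df <- do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- as.data.frame(traces[[i]])
    if (nrow(tr) == 0L) stop("empty feedback trace")
    ok <- !tr$gated
    means <- tapply(tr$level[ok], tr$condition[ok], mean)
    data.frame(trace = i, group = groups[i],
               condition = names(means), mean_level = as.numeric(means),
               stringsAsFactors = FALSE)
  }))
  comparison <- do.call(rbind, lapply(unique(levels_df$condition),
                                      function(cond) {
    d <- levels_df[levels_df$condition == cond, ]
    a <- d$mean_level[d$group == "ACTIVE"]
    c_ <- d$mean_level[d$group == "CONTROL"]
    tt <- if (length(a) >= 2L && length(c_) >= 2L)
      tryCatch(stats::t.test(c_, a, var.equal = TRUE),
               error = function(e) NULL) else NULL
    data.frame(condition = cond,
               m_active = mean(a), sd_active = stats::sd(a),
               m_control = mean(c_), sd_control = stats::sd(c_),
               diff = mean(c_) - mean(a),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               stringsAsFactors = FALSE)
  }))
  list(levels = levels_df, comparison = comparison)
}

#' Published group-level cell means of the primary outcome
#'
#' Group means and SDs of the standardised ATL-to-SCC regression effects
#' per measure (guilt, indignation, guilt vs. indignation) and
#' condition-by-time cell, as printed in the trial's primary-outcome
#' table. Shipped as a plain-text table for arithmetic cross-checks.
#'
#' @return Data frame with columns \code{measure}, \code{group},
#'   \code{time}, \code{m}, \code{sd}.
#' @export
trial_cell_means <- function() {
  path <- system.file("extdata", "trial_cell_means.csv",
                      package = "nfcoupling", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute pre-training group differences from the cell means
#'
#' For each primary-outcome measure, recomputes the CONTROL minus ACTIVE
#' difference of the pre-training cell means, the arithmetic reported in
#' the primary-outcome table's footnote.
#'
#' @param cells Cell-mean table (default \code{\link{trial_cell_means}}).
#' @return Named numeric vector of CONTROL - ACTIVE pre-training
#'   differences per measure.
#' @export
pretraining_group_differences <- function(cells = trial_cell_means()) {
  pre <- cells[cells$time == "pre", ]
  out <- sapply(unique(pre$measure), function(ms) {
    d <- pre[pre$measure == ms, ]
    d$m[d$group == "CONTROL"] - d$m[d$group == "ACTIVE"]
  })
  round(out, 2)
}
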