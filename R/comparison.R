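#' Individual child trajectory
#'
#' An ordered series of (age, score) assessments for one child, optionally
#' annotated with clinical events (e.g. device activations) for charting.
#'
#' @param child_id Child identifier.
#' @param age_months Strictly increasing assessment ages (months).
#' @param score Scores in \[0, 64\], same length as `age_months`.
#' @param annotations Optional data frame with columns `age_months`, `label`.
#' @return An object of class `flip_trajectory`: list with `child_id`,
#'   `points` (data frame `age_months, score`) and `annotations`.
#' @export
child_trajectory <- function(child_id, age_months, score, annotations = NULL) {
  if (length(age_months) != length(score) || !length(age_months)) {
    stop_arg("`age_months` and `score` must be equal-length, non-empty")
  }
  if (is.unsorted(age_months, strictly = TRUE)) {
    stop_arg("trajectory ages must be strictly increasing")
  }
  if (any(score < 0 | score > 64)) stop_arg("trajectory scores must lie in [0, 64]")
  if (!is.null(annotations) &&
      !all(c("age_months", "label") %in% names(annotations))) {
    stop_arg("`annotations` must have columns age_months, label")
  }
  structure(
    list(child_id = as.character(child_id),
         points = data.frame(age_months = age_months, score = score),
         annotations = annotations),
    class = "flip_trajectory"
  )
}

#' Sample percentiles in 6-month age bins
#'
#' Partitions (0, 72] months into equal lower-open, upper-closed bins
#' ("0 < age <= 6" and so on), and computes sample percentiles of score per
#' bin using the linear-interpolation order-statistic estimator with plotting
#' position p(k) = (k-1)/(n-1) (quantile type 7). Bins with fewer than
#' `min_count` records carry no percentile values. Binned percentiles plotted
#' at bin midpoints are the standard rough check of fitted centile curves
#' against the data.
#'
#' @param records Data frame of cohort records.
#' @param taus Quantile levels to compute (default 0.16, 0.50, 0.84).
#' @param bin_width Bin width in months; must divide 72 (default 6).
#' @param min_count Minimum records per bin for percentiles to be reported
#'   (default 5).
#' @return Data frame with one row per bin: `lo`, `hi`, `midpoint`, `count`
#'   and one `p<tau>` column per level (NA below `min_count`).
#' @export
binned_sample_percentiles <- function(records, taus = c(0.16, 0.50, 0.84),
                                      bin_width = 6, min_count = 5L) {
  assert_tau(taus)
  if (bin_width <= 0 || 72 %% bin_width != 0) {
    stop_arg("`bin_width` must divide 72 months")
  }
  validate_records(records, min_n = NULL, min_span = NULL)
  edges <- seq(0, 72, by = bin_width)
  bin <- findInterval(records$age_months, edges, left.open = TRUE,
                      rightmost.closed = TRUE)
  out <- data.frame(lo = edges[-length(edges)], hi = edges[-1])
  out$midpoint <- (out$lo + out$hi) / 2
  out$count <- vapply(seq_len(nrow(out)), function(i) sum(bin == i), integer(1))
  for (tau in taus) {
    col <- paste0("p", tau)
    out[[col]] <- vapply(seq_len(nrow(out)), function(i) {
      if (out$count[i] < min_count) return(NA_real_)
      unname(quantile(records$score[bin == i], probs = tau, type = 7))
    }, numeric(1))
  }
  out
}

#' Compare binned sample percentiles with fitted centile curves
#'
#' For each quantile level shared by the bin summary and the table, reports
#' the difference (sample minus fitted) at each bin midpoint and the maximum
#' absolute difference, as a numeric counterpart of overlaying sample
#' percentiles on the fitted curves.
#'
#' @param bins Output of [binned_sample_percentiles()].
#' @param table A [percentile_table()] object whose levels include those of
#'   `bins`.
#' @return List with `by_tau` (per-level data frame of `midpoint`, `sample`,
#'   `fitted`, `diff`), `max_abs_by_tau` and `max_abs` overall (NA when no
#'   comparable values exist).
#' @export
compare_bins_to_curves <- function(bins, table) {
  stopifnot(inherits(table, "flip_norms"))
  tau_cols <- grep("^p0\\.", names(bins), value = TRUE)
  taus <- as.numeric(sub("^p", "", tau_cols))
  missing_tau <- setdiff(taus, table$tau)
  if (length(missing_tau)) {
    stop_arg("table lacks centile level(s): ", paste(missing_tau, collapse = ", "))
  }
  by_tau <- list()
  max_abs <- setNames(rep(NA_real_, length(taus)), as.character(taus))
  for (i in seq_along(taus)) {
    row <- which(table$tau == taus[i])
    p <- unlist(table[row, c("a1", "a2", "a3", "a4")])
    fitted <- logistic_eval(p, bins$midpoint)
    d <- data.frame(midpoint = bins$midpoint, sample = bins[[tau_cols[i]]],
                    fitted = fitted)
    d$diff <- d$sample - d$fitted
    by_tau[[as.character(taus[i])]] <- d
    if (any(!is.na(d$diff))) max_abs[i] <- max(abs(d$diff), na.rm = TRUE)
  }
  list(by_tau = by_tau, max_abs_by_tau = max_abs,
       max_abs = if (all(is.na(max_abs))) NA_real_ else max(max_abs, na.rm = TRUE))
}

#' Descriptive three-segment linear fit
#'
#' Fits an independent least-squares line to each of three age segments
#' (by default (0, 30], (30, 54], (54, 72] months), the descriptive summary
#' of fast early listening-skill acquisition followed by flattening. Slopes
#' are in score points per month.
#'
#' @param records Data frame of cohort records.
#' @param breakpoints Two interior breakpoints in months (default 30, 54).
#' @return Data frame with one row per segment: `lo`, `hi`, `n`, `slope`,
#'   `intercept`, `r_squared`.
#' @export
segmented_linear_fit <- function(records, breakpoints = c(30, 54)) {
  validate_records(records, min_n = NULL, min_span = NULL)
  if (length(breakpoints) != 2L || is.unsorted(breakpoints, strictly = TRUE) ||
      breakpoints[1] <= 0 || breakpoints[2] >= 72) {
    stop_arg("`breakpoints` must be two increasing ages inside (0, 72)")
  }
  edges <- c(0, breakpoints, 72)
  out <- list()
  for (s in 1:3) {
    inseg <- records$age_months > edges[s] & records$age_months <= edges[s + 1]
    n <- sum(inseg)
    if (n < 3L) {
      stop_arg("segment (", edges[s], ", ", edges[s + 1], "] contains ", n,
               " records; at least 3 required")
    }
    d <- records[inseg, ]
    fit <- lm(score ~ age_months, data = d)
    r2 <- summary(fit)$r.squared
    out[[s]] <- data.frame(lo = edges[s], hi = edges[s + 1], n = n,
                           slope = unname(coef(fit)[2]),
                           intercept = unname(coef(fit)[1]),
                           r_squared = r2)
  }
  do.call(rbind, out)
}

#' Compare a child's trajectory against the normative envelope
#'
#' Locates every assessment relative to the centile curves
#' (via [score_to_percentile()]) and raises descriptive flags:
#'
#' * `divergence` -- at least `k` consecutive assessments fall below the
#'   16th-centile curve (below the normative envelope);
#' * `plateau` -- over some span of at least `m` months the child's score
#'   rises by less than `d` points while the median curve rises by at least
#'   `2 d` over the same span;
#' * `converging` -- the centile band improves between the last two
#'   assessments.
#'
#' Flags are descriptive analytics, not clinical decisions.
#'
#' @param trajectory A [child_trajectory()] object.
#' @param table A [percentile_table()] object.
#' @param k Consecutive below-envelope assessments required for `divergence`
#'   (default 2).
#' @param d Score-gain threshold for `plateau` (default 2 points).
#' @param m Minimum span for `plateau` (default 6 months).
#' @return An object of class `flip_trajectory_report`: list with
#'   `points` (data frame `age_months, score, tau, band, below_envelope`),
#'   `flags` (named logical: divergence, plateau, converging) and
#'   `plateau_spans` (data frame of flagged spans).
#' @export
trajectory_report <- function(trajectory, table, k = 2L, d = 2, m = 6) {
  stopifnot(inherits(trajectory, "flip_trajectory"),
            inherits(table, "flip_norms"))
  pts <- trajectory$points
  n <- nrow(pts)
  per <- lapply(seq_len(n), function(i)
    score_to_percentile(table, pts$age_months[i], pts$score[i]))
  pts$tau <- vapply(per, `[[`, numeric(1), "tau")
  pts$band <- vapply(per, `[[`, character(1), "band")

  idx16 <- which(table$tau == 0.16)
  below_env <- if (length(idx16)) {
    p16 <- unlist(table[idx16, c("a1", "a2", "a3", "a4")])
    pts$score < pmin(pmax(logistic_eval(p16, pts$age_months), 0), 64)
  } else {
    pts$tau < 0.16
  }
  pts$below_envelope <- below_env

  divergence <- has_run(below_env, k)

  med_row <- which(table$tau == 0.5)
  plateau_spans <- data.frame(from = numeric(), to = numeric())
  plateau <- FALSE
  if (length(med_row) && n >= 2L) {
    med <- unlist(table[med_row, c("a1", "a2", "a3", "a4")])
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        span <- pts$age_months[j] - pts$age_months[i]
        if (span < m) next
        child_gain <- pts$score[j] - pts$score[i]
        norm_gain <- logistic_eval(med, pts$age_months[j]) -
          logistic_eval(med, pts$age_months[i])
        if (child_gain < d && norm_gain >= 2 * d) {
          plateau <- TRUE
          plateau_spans <- rbind(plateau_spans,
                                 data.frame(from = pts$age_months[i],
                                            to = pts$age_months[j]))
        }
      }
    }
  }

  converging <- FALSE
  if (n >= 2L) {
    band_idx <- match(pts$band, band_labels)
    converging <- band_idx[n] > band_idx[n - 1L]
  }

  structure(
    list(child_id = trajectory$child_id,
         points = pts,
         flags = c(divergence = divergence, plateau = plateau,
                   converging = converging),
         plateau_spans = plateau_spans),
    class = "flip_trajectory_report"
  )
}

has_run <- function(x, k) {
  run <- 0L
  for (v in x) {
    run <- if (isTRUE(v)) run + 1L else 0L
    if (run >= k) return(TRUE)
  }
  FALSE
}

#' @export
print.flip_trajectory_report <- function(x, ...) {
  cat(sprintf("Trajectory report for child %s (%d assessments)\n",
              x$child_id, nrow(x$points)))
  df <- x$points
  df$tau <- round(df$tau, 3)
  print(df, row.names = FALSE)
  on_flags <- names(x$flags)[x$flags]
  cat("flags: ", if (length(on_flags)) paste(on_flags, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}
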