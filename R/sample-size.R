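#' Maximum median-curve error of one simulated cohort
#'
#' One Monte Carlo replicate of the sample-size procedure: simulate a cohort
#' from the percentile table, refit the median (tau = 0.5) logistic curve by
#' pinball-loss minimisation, and return the maximum absolute difference
#' between the fitted and the true median curve over integer ages 1..72
#' months. Evaluation deliberately starts at 1 month (the precision criterion
#' is stated over ages 1..72) even though norms are reported from 3 months.
#'
#' @param table A [percentile_table()] object containing a `tau = 0.5` entry.
#' @param n Number of children with ages uniform on (0, 72]; ignored when
#'   `design` is given.
#' @param design Optional [load_design()] object; when supplied the cohort
#'   follows its age-block structure.
#' @param seed Integer seed for this replicate.
#' @param eval_ages Integer ages at which the error is evaluated (default
#'   1..72).
#' @param generator `"cross-sectional"` (default; what the centile fits
#'   consume) or `"longitudinal"` (children drawn from the two-component
#'   rate/unreliability model, one assessment per scheduled age).
#' @param sigma_b,sigma_w Variability parameters for the longitudinal
#'   generator.
#' @param n_starts,maxit Fit options forwarded to [fit_quantile_curve()]
#'   (defaults 8 starts, 1000 iterations: the median fit on a single cohort
#'   is well-conditioned).
#' @return Non-negative scalar: the max absolute error in score points.
#' @export
replicate_max_error <- function(table, n = NULL, design = NULL, seed = 1L,
                                eval_ages = 1:72,
                                generator = c("cross-sectional", "longitudinal"),
                                sigma_b = 0.15, sigma_w = 2,
                                n_starts = 8L, maxit = 1000L) {
  stopifnot(inherits(table, "flip_norms"))
  generator <- match.arg(generator)
  if (is.null(design)) {
    if (is.null(n) || n < 40) stop_arg("need `n` >= 40 or a `design`")
  }
  med_row <- which(table$tau == 0.5)
  if (!length(med_row)) stop_arg("table must contain a tau = 0.5 (median) entry")
  med <- unlist(table[med_row, c("a1", "a2", "a3", "a4")])

  records <- simulate_replicate_cohort(table, n, design, seed, generator,
                                       sigma_b, sigma_w)
  fit <- fit_quantile_curve(records, 0.5, seed = derive_seed(seed, 1L),
                            n_starts = n_starts, maxit = maxit)
  max(abs(logistic_eval(fit$params, eval_ages) - logistic_eval(med, eval_ages)))
}

simulate_replicate_cohort <- function(table, n, design, seed, generator,
                                      sigma_b, sigma_w) {
  if (generator == "cross-sectional") {
    if (!is.null(design)) {
      generate_cohort(design, table, seed = seed)
    } else {
      with_seed(seed, {
        ages <- runif(n, 0.01, 72)
        data.frame(child_id = sprintf("sim%05d", seq_len(n)),
                   age_months = ages,
                   score = quantile_function(table, ages, runif(n)),
                   stringsAsFactors = FALSE)
      })
    }
  } else {
    # one longitudinal child per enrolee, one random assessment age each,
    # preserving the cross-sectional shape the fitter consumes
    counts <- if (!is.null(design)) design$blocks$count else
      table(cut(rep(1, n), 1))  # unused branch guard
    if (is.null(design)) {
      ages <- with_seed(seed, runif(n, 0.01, 72))
      n_children <- n
    } else {
      min_age <- design$min_child_age
      b <- design$blocks
      ages <- with_seed(seed, unlist(lapply(seq_len(nrow(b)), function(i) {
        if (b$count[i] == 0L) return(numeric(0))
        runif(b$count[i], max(b$lo[i], min_age), b$hi[i])
      })))
      n_children <- length(ages)
    }
    scores <- vapply(seq_len(n_children), function(i) {
      traj <- generate_longitudinal_child(table, ages[i], sigma_b = sigma_b,
                                          sigma_w = sigma_w,
                                          seed = derive_seed(seed, 1000L + i))
      traj$points$score[1]
    }, numeric(1))
    data.frame(child_id = sprintf("sim%05d", seq_len(n_children)),
               age_months = ages, score = scores, stringsAsFactors = FALSE)
  }
}

#' Estimate the probability of meeting the median-precision criterion
#'
#' Runs `replicates` Monte Carlo replicates of [replicate_max_error()] and
#' estimates the probability that the fitted median curve's maximum error
#' over ages 1..72 months is at most `error_bound` score points, as the
#' proportion of replicates in which that occurs. Replicates whose fit fails
#' are counted as exceeding the bound (conservative) and reported.
#'
#' @inheritParams replicate_max_error
#' @param replicates Number of Monte Carlo replicates (use >= 50 for
#'   reported runs).
#' @param error_bound Maximum tolerated absolute error in the estimated
#'   median (default 2 score points on the 0..64 scale).
#' @param seed Integer seed; per-replicate seeds are derived from it.
#' @param ... Passed on to [replicate_max_error()].
#' @return List with `probability`, `se` (binomial Monte Carlo standard
#'   error), `replicates`, `failed_fits`, `error_bound` and `max_errors`
#'   (the per-replicate max-error sample, `NA` for failed fits).
#' @examples
#' \donttest{
#' estimate_probability(load_reference_table(), design = design_actual(),
#'                      replicates = 50, seed = 1)
#' }
#' @export
estimate_probability <- function(table, n = NULL, design = NULL,
                                 replicates = 200L, error_bound = 2,
                                 seed = 1L, ...) {
  if (replicates < 1L) stop_arg("`replicates` must be at least 1")
  if (error_bound <= 0) stop_arg("`error_bound` must be positive")
  errs <- vapply(seq_len(replicates), function(r) {
    tryCatch(
      replicate_max_error(table, n = n, design = design,
                          seed = derive_seed(seed, r), ...),
      error = function(e) NA_real_
    )
  }, numeric(1))
  failed <- sum(is.na(errs))
  hit <- !is.na(errs) & errs <= error_bound
  p <- mean(hit)
  list(probability = p,
       se = sqrt(p * (1 - p) / replicates),
       replicates = replicates,
       failed_fits = failed,
       error_bound = error_bound,
       max_errors = errs)
}

#' Find the minimum sample size meeting a precision target
#'
#' Scans candidate sample sizes in ascending order and returns the smallest
#' whose estimated probability of keeping the median-curve error within the
#' bound reaches the target. The full probability profile is returned; the
#' probability is non-decreasing in `n` up to Monte Carlo noise.
#'
#' @inheritParams estimate_probability
#' @param candidates Ascending integer sample sizes to try.
#' @param target_prob Required probability (default 0.90).
#' @param early_stop Stop scanning after the first qualifying `n`
#'   (default TRUE).
#' @return An object of class `flip_samplesize`: list with `profile` (data
#'   frame `n, probability, se, failed_fits`), `selected_n` (or `NA`),
#'   `target_prob`, `error_bound`.
#' @export
find_min_sample_size <- function(table, candidates, target_prob = 0.90,
                                 replicates = 200L, error_bound = 2,
                                 seed = 1L, early_stop = TRUE, ...) {
  if (!length(candidates)) stop_arg("`candidates` must be non-empty")
  if (is.unsorted(candidates, strictly = TRUE)) {
    stop_arg("`candidates` must be strictly increasing")
  }
  if (target_prob <= 0 || target_prob >= 1) {
    stop_arg("`target_prob` must lie in (0, 1)")
  }
  rows <- list()
  selected <- NA_integer_
  for (i in seq_along(candidates)) {
    est <- estimate_probability(table, n = candidates[i], replicates = replicates,
                                error_bound = error_bound,
                                seed = derive_seed(seed, 100000L + i), ...)
    rows[[i]] <- data.frame(n = candidates[i], probability = est$probability,
                            se = est$se, failed_fits = est$failed_fits)
    if (is.na(selected) && est$probability >= target_prob) {
      selected <- candidates[i]
      if (early_stop) break
    }
  }
  structure(
    list(profile = do.call(rbind, rows), selected_n = selected,
         target_prob = target_prob, error_bound = error_bound),
    class = "flip_samplesize"
  )
}

#' @export
print.flip_samplesize <- function(x, ...) {
  cat(sprintf("Monte Carlo sample-size scan (error bound %g, target probability %g)\n",
              x$error_bound, x$target_prob))
  print(x$profile, row.names = FALSE)
  cat("selected n: ", if (is.na(x$selected_n)) "none qualified" else x$selected_n,
      "\n", sep = "")
  invisible(x)
}
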