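#' Check (pinball) loss of quantile regression
#'
#' The defining objective of quantile regression at level tau:
#' \deqn{\sum_i r_i (\tau - 1[r_i < 0])}
#' over residuals \eqn{r_i = \mathrm{observed}_i - \mathrm{fitted}_i}. It is
#' minimised by the conditional tau-quantile.
#'
#' @param residuals Numeric vector of residuals.
#' @param tau Quantile level in (0, 1).
#' @return Non-negative scalar loss.
#' @examples
#' pinball_loss(c(2, -1), 0.9)  # 2*0.9 + 1*0.1
#' @export
pinball_loss <- function(residuals, tau) {
  assert_tau(tau)
  if (length(tau) != 1L) stop_arg("`tau` must be a single level")
  if (!is.numeric(residuals) || any(!is.finite(residuals))) {
    stop_arg("`residuals` must be finite numbers")
  }
  sum(residuals * (tau - (residuals < 0)))
}

#' Default parameter box for the logistic centile fit
#'
#' Bounds for the four-parameter logistic search: `a1` in \[-40, 30\] score
#' points, `a2` in `(a1 + 1, 64]` (the instrument maximum), `a3` in (0, 1\]
#' per month, `a4` in \[1, 60\] months.
#'
#' @return List with elements `a1`, `a2_max`, `a3`, `a4`.
#' @export
default_fit_bounds <- function() {
  list(a1 = c(-40, 30), a2_max = 64, a3 = c(0, 1), a4 = c(1, 60))
}

# Bijection between the bounded parameter box and an unconstrained space, so
# a simplex search never leaves the box. a2 is parameterised relative to a1
# (a2 in (a1 + 1, 64)), keeping a2 > a1 structural.
params_to_unconstrained <- function(p, bounds) {
  clip01 <- function(x) pmin(pmax(x, 1e-12), 1 - 1e-12)
  c(qlogis(clip01((p[1] - bounds$a1[1]) / diff(bounds$a1))),
    qlogis(clip01((p[2] - p[1] - 1) / (bounds$a2_max - p[1] - 1))),
    qlogis(clip01((p[3] - bounds$a3[1]) / diff(bounds$a3))),
    qlogis(clip01((p[4] - bounds$a4[1]) / diff(bounds$a4))))
}

unconstrained_to_params <- function(t, bounds) {
  a1 <- bounds$a1[1] + diff(bounds$a1) * plogis(t[1])
  a2 <- a1 + 1 + (bounds$a2_max - a1 - 1) * plogis(t[2])
  a3 <- bounds$a3[1] + diff(bounds$a3) * plogis(t[3])
  a4 <- bounds$a4[1] + diff(bounds$a4) * plogis(t[4])
  c(a1 = unname(a1), a2 = unname(a2), a3 = unname(a3), a4 = unname(a4))
}

validate_records <- function(records, min_n = 20L, min_span = 12) {
  required <- c("child_id", "age_months", "score")
  if (!is.data.frame(records) || !all(required %in% names(records))) {
    stop_arg("`records` must be a data frame with columns ",
             paste(required, collapse = ", "))
  }
  if (any(!is.finite(records$age_months)) || any(records$age_months <= 0)) {
    stop_arg("record ages must be positive finite months")
  }
  if (any(!is.finite(records$score)) || any(records$score < 0) ||
      any(records$score > 64)) {
    stop_arg("record scores must lie in [0, 64]")
  }
  if (!is.null(min_n) && nrow(records) < min_n) {
    stop_arg("need at least ", min_n, " records to fit, got ", nrow(records))
  }
  if (!is.null(min_span) &&
      diff(range(records$age_months)) < min_span) {
    stop_arg("record ages must span at least ", min_span, " months")
  }
  invisible(records)
}

# moment-based initial guess used as the centre of the multi-start cloud
initial_guess <- function(records, bounds) {
  sc <- records$score
  age <- records$age_months
  a2 <- min(max(sc), bounds$a2_max - 0.5)
  a1 <- max(min(sc) - 1, bounds$a1[1] + 1)
  if (a2 <= a1 + 1.5) a2 <- a1 + 2
  half <- (a1 + a2) / 2
  a4 <- age[which.min(abs(sc - half))]
  a4 <- min(max(a4, bounds$a4[1] + 0.5), bounds$a4[2] - 0.5)
  # crude global slope -> logistic rate: max slope of the 4PL is a3*(a2-a1)/4
  slope <- (max(sc) - min(sc)) / max(diff(range(age)), 1)
  a3 <- min(max(4 * slope / (a2 - a1), 0.02), bounds$a3[2] - 0.01)
  c(a1, a2, a3, a4)
}

#' Fit one logistic centile curve by pinball-loss minimisation
#'
#' Estimates the four-parameter logistic curve for quantile level `tau` by
#' direct minimisation of [pinball_loss()] over the parameter box, using a
#' derivative-free simplex (Nelder-Mead) search in a transformed unconstrained
#' space with `n_starts` deterministic jittered starts around a moment-based
#' initial guess. The check loss is non-smooth, so multi-start local search is
#' used rather than a gradient method. The upper asymptote is bounded by the
#' instrument maximum (64), which is typically active for high centiles.
#'
#' @param records Data frame of cohort records (`child_id, age_months, score`),
#'   at least 20 rows spanning at least 12 months of age.
#' @param tau Quantile level in (0, 1).
#' @param bounds Parameter box, as [default_fit_bounds()] (list with `a1`,
#'   `a2_max`, `a3`, `a4`).
#' @param n_starts Number of local searches (default 16).
#' @param seed Integer seed making the jittered starts reproducible.
#' @param maxit Simplex iteration cap per start (default 2000).
#' @param reltol Relative convergence tolerance per start (default 1e-10).
#' @return An object of class `flip_fit`: list with `tau`, `params`
#'   ([logistic_params()]), `loss`, `n`, `converged`, `starts_used`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(design_target(), load_reference_table(), seed = 1)
#' fit_quantile_curve(cohort, 0.5, seed = 1, n_starts = 4)
#' }
#' @export
fit_quantile_curve <- function(records, tau, bounds = default_fit_bounds(),
                               n_starts = 16L, seed = 1L, maxit = 2000L,
                               reltol = 1e-10) {
  assert_tau(tau)
  if (length(tau) != 1L) stop_arg("`tau` must be a single level")
  validate_records(records)
  if (n_starts < 1L) stop_arg("`n_starts` must be at least 1")

  age <- records$age_months
  sc <- records$score
  objective <- function(t) {
    p <- unconstrained_to_params(t, bounds)
    r <- sc - (p[1] + (p[2] - p[1]) / (1 + exp(-p[3] * (age - p[4]))))
    sum(r * (tau - (r < 0)))
  }

  t0 <- params_to_unconstrained(initial_guess(records, bounds), bounds)
  best <- NULL
  converged <- FALSE
  with_seed(seed, {
    for (k in seq_len(n_starts)) {
      tk <- if (k == 1L) t0 else t0 + rnorm(4L, 0, 0.5)
      opt <- tryCatch(
        optim(tk, objective, method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = reltol)),
        error = function(e) NULL
      )
      if (is.null(opt)) next
      if (is.null(best) || opt$value < best$value) {
        best <- opt
        converged <- opt$convergence == 0L
      }
    }
  })
  if (is.null(best)) {
    stop_arg("all ", n_starts, " optimisation starts failed for tau = ", tau)
  }
  p <- unconstrained_to_params(best$par, bounds)
  structure(
    list(tau = tau,
         params = logistic_params(p[1], p[2], p[3], p[4]),
         loss = best$value,
         n = nrow(records),
         converged = converged,
         starts_used = n_starts),
    class = "flip_fit"
  )
}

#' @export
print.flip_fit <- function(x, ...) {
  cat(sprintf("Logistic quantile fit, tau = %g (n = %d, %s)\n", x$tau, x$n,
              if (x$converged) "converged" else "not converged"))
  print(round(unclass(x$params), 4))
  cat(sprintf("  pinball loss: %.4f over %d starts\n", x$loss, x$starts_used))
  invisible(x)
}

#' Fit a full centile family
#'
#' Fits one logistic curve per quantile level, independently (no joint
#' non-crossing constraint, matching per-centile quantile regression);
#' crossing is checked afterwards and reported, never repaired.
#'
#' @inheritParams fit_quantile_curve
#' @param taus Strictly increasing quantile levels; default the seven
#'   reference levels 5th, 10th, 16th, 50th, 84th, 90th, 95th.
#' @param min_age Minimum reporting age recorded on the resulting table.
#' @param ... Passed on to [fit_quantile_curve()].
#' @return A [percentile_table()] object with attributes `fits` (the list of
#'   per-tau `flip_fit` objects, or condition objects for levels that failed)
#'   and `non_crossing` (the [check_non_crossing()] report).
#' @export
fit_all_percentiles <- function(records, taus = c(0.05, 0.10, 0.16, 0.50,
                                                  0.84, 0.90, 0.95),
                                min_age = 3, seed = 1L, ...) {
  if (!length(taus)) stop_arg("`taus` must be non-empty")
  assert_tau(taus)
  if (is.unsorted(taus, strictly = TRUE)) {
    stop_arg("`taus` must be strictly increasing")
  }
  fits <- lapply(seq_along(taus), function(i) {
    tryCatch(fit_quantile_curve(records, taus[i],
                                seed = derive_seed(seed, i), ...),
             error = function(e) e)
  })
  names(fits) <- as.character(taus)
  ok <- !vapply(fits, inherits, logical(1), "condition")
  if (!any(ok)) stop_arg("every centile fit failed; first error: ",
                         conditionMessage(fits[[1]]))
  entries <- do.call(rbind, lapply(fits[ok], function(f) {
    data.frame(tau = f$tau, a1 = f$params[["a1"]], a2 = f$params[["a2"]],
               a3 = f$params[["a3"]], a4 = f$params[["a4"]])
  }))
  tab <- percentile_table(entries, min_age = min_age)
  attr(tab, "fits") <- fits
  attr(tab, "non_crossing") <- check_non_crossing(tab)
  tab
}

#' Brute-force grid search oracle for the pinball objective
#'
#' Exhaustively evaluates the pinball loss of the four-parameter logistic
#' over a Cartesian parameter grid. Intended as an independent check on the
#' simplex optimiser (its loss can never beat the optimiser by more than grid
#' resolution allows). Ties are broken by enumeration order (a1, then a2, a3,
#' a4 ascending).
#'
#' @param records Data frame of cohort records.
#' @param tau Quantile level in (0, 1).
#' @param grid List with numeric vectors `a1`, `a2`, `a3`, `a4` of candidate
#'   values; at most 1e6 combinations.
#' @return List with `params` (named numeric) and `loss`.
#' @export
brute_force_fit <- function(records, tau, grid) {
  assert_tau(tau)
  if (!all(c("a1", "a2", "a3", "a4") %in% names(grid))) {
    stop_arg("`grid` must supply vectors a1, a2, a3, a4")
  }
  sizes <- vapply(grid[c("a1", "a2", "a3", "a4")], length, integer(1))
  if (prod(as.double(sizes)) > 1e6) {
    stop_arg("grid too large: ", format(prod(as.double(sizes))),
             " combinations exceeds 1e6")
  }
  validate_records(records, min_n = 1L, min_span = NULL)
  age <- records$age_months
  sc <- records$score
  best_loss <- Inf
  best <- NULL
  # enumeration order: a4 fastest would break documented tie-break; iterate
  # a1 outermost, a4 innermost varying last
  for (a1 in grid$a1) for (a2 in grid$a2) {
    if (a2 <= a1) next
    for (a3 in grid$a3) {
      if (a3 <= 0) next
      for (a4 in grid$a4) {
        r <- sc - (a1 + (a2 - a1) / (1 + exp(-a3 * (age - a4))))
        loss <- sum(r * (tau - (r < 0)))
        if (loss < best_loss) {
          best_loss <- loss
          best <- c(a1 = a1, a2 = a2, a3 = a3, a4 = a4)
        }
      }
    }
  }
  if (is.null(best)) stop_arg("grid contains no valid parameter combination")
  list(params = best, loss = best_loss)
}
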