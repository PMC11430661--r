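#' Age-block recruitment designs
#'
#' A design is a set of twelve contiguous 6-month age blocks covering
#' (0, 72] months with a recruitment count per block, plus the minimum child
#' age actually observable (1.5 months in the normative study, since newborn
#' hearing screening precedes enrolment). Two designs are packaged:
#' `design_target()` is the minimum-recruitment design (36 children per
#' block, 432 in total) and `design_actual()` carries the achieved per-block
#' counts of the normative study.
#'
#' @param path Path to a design JSON document
#'   (`{blocks:[{lo, hi, count}], min_child_age}`).
#' @return An object of class `flip_design`: list with `name`, `blocks`
#'   (data frame `lo, hi, count`) and `min_child_age`.
#' @examples
#' sum(design_target()$blocks$count)  # 432
#' @export
load_design <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    error = function(e) stop_arg("cannot parse design: ", conditionMessage(e))
  )
  blocks <- as.data.frame(doc$blocks)
  validate_design(list(
    name = if (is.null(doc$name)) "custom" else doc$name,
    blocks = blocks,
    min_child_age = if (is.null(doc$min_child_age)) 1.5 else doc$min_child_age
  ))
}

validate_design <- function(x) {
  b <- x$blocks
  if (!is.data.frame(b) || !all(c("lo", "hi", "count") %in% names(b))) {
    stop_arg("design blocks must have columns lo, hi, count")
  }
  if (nrow(b) != 12L || any(b$lo != seq(0, 66, 6)) || any(b$hi != seq(6, 72, 6))) {
    stop_arg("design must have 12 contiguous 6-month blocks covering (0, 72]")
  }
  if (any(b$count < 0) || any(b$count != round(b$count))) {
    stop_arg("block counts must be non-negative integers")
  }
  if (x$min_child_age <= 0 || x$min_child_age >= 6) {
    stop_arg("min_child_age must lie in (0, 6)")
  }
  structure(x, class = "flip_design")
}

#' @rdname load_design
#' @export
design_target <- function() load_design(extdata_path("design_target.json"))

#' @rdname load_design
#' @export
design_actual <- function() load_design(extdata_path("design_actual.json"))

#' Conditional quantile function induced by a percentile table
#'
#' Turns the seven fitted centile curves into a full conditional distribution
#' of score given age: table levels tau are mapped to normal scores
#' \eqn{\Phi^{-1}(\tau)}, the curve values at the age are linearly
#' interpolated against those normal scores, and ranks `u` outside the
#' table's outermost levels are linearly extrapolated in normal-score space
#' from the outermost segment. Results are clamped to the instrument range
#' \[0, 64\]. This is the inverse-CDF construction used by the cohort
#' generator.
#'
#' @param table A [percentile_table()] object.
#' @param age Age(s) in months, in (0, 72]; recycled against `u`.
#' @param u Latent rank(s) in (0, 1).
#' @return Continuous score(s) in \[0, 64\], non-decreasing in `u` at fixed
#'   age.
#' @examples
#' quantile_function(load_reference_table(), 24, 0.5)  # the median curve at 24
#' @export
quantile_function <- function(table, age, u) {
  stopifnot(inherits(table, "flip_norms"))
  if (!is.numeric(u) || any(!is.finite(u)) || any(u <= 0) || any(u >= 1)) {
    stop_arg("`u` must lie strictly between 0 and 1")
  }
  if (any(age <= 0 | age > 72)) stop_arg("`age` must lie in (0, 72]")
  n <- max(length(age), length(u))
  age <- rep_len(age, n)
  u <- rep_len(u, n)

  z <- qnorm(table$tau)
  m <- length(z)
  vals <- eval_table_raw(table, age)           # n x m (or vector when n = 1)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  zu <- qnorm(u)
  out <- numeric(n)

  below <- zu <= z[1]
  above <- zu >= z[m]
  mid <- !(below | above)
  if (any(below)) {
    slope <- (vals[below, 2L] - vals[below, 1L]) / (z[2] - z[1])
    out[below] <- vals[below, 1L] + slope * (zu[below] - z[1])
  }
  if (any(above)) {
    slope <- (vals[above, m] - vals[above, m - 1L]) / (z[m] - z[m - 1L])
    out[above] <- vals[above, m] + slope * (zu[above] - z[m])
  }
  if (any(mid)) {
    iv <- findInterval(zu[mid], z)
    rows <- which(mid)
    lo <- vals[cbind(rows, iv)]
    hi <- vals[cbind(rows, iv + 1L)]
    w <- (zu[mid] - z[iv]) / (z[iv + 1L] - z[iv])
    out[mid] <- lo + w * (hi - lo)
  }
  pmin(pmax(out, 0), 64)
}

#' Generate a cross-sectional synthetic cohort
#'
#' Emulates the normative study's cross-sectional sample: for each age block,
#' the block's count of children is drawn with ages uniform over the block
#' (respecting the design's minimum child age in the first block), each child
#' receives an independent latent rank `u` uniform on (0, 1), and the score
#' is the conditional quantile [quantile_function()] of the supplied
#' percentile table at (age, u). Continuous scores are the default, suited to
#' estimation experiments; `rounding = "integer"` rounds to whole scores for
#' realism.
#'
#' @param design A [load_design()] object.
#' @param table A [percentile_table()] object.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param rounding `"continuous"` (default) or `"integer"`.
#' @param id_prefix Prefix for generated child ids.
#' @return Data frame of cohort records (`child_id, age_months, score`).
#' @examples
#' cohort <- generate_cohort(design_target(), load_reference_table(), seed = 1)
#' nrow(cohort)  # 432
#' @export
generate_cohort <- function(design, table, seed,
                            rounding = c("continuous", "integer"),
                            id_prefix = "sim") {
  stopifnot(inherits(design, "flip_design"), inherits(table, "flip_norms"))
  rounding <- match.arg(rounding)
  b <- design$blocks
  total <- sum(b$count)
  with_seed(seed, {
    ages <- numeric(0)
    for (i in seq_len(nrow(b))) {
      if (b$count[i] == 0L) next
      lo <- max(b$lo[i], design$min_child_age)
      ages <- c(ages, runif(b$count[i], lo, b$hi[i]))
    }
    u <- runif(total)
    score <- if (total) quantile_function(table, ages, u) else numeric(0)
    if (rounding == "integer") score <- round(score)
    data.frame(
      child_id = if (total) sprintf("%s%05d", id_prefix, seq_len(total)) else character(0),
      age_months = ages,
      score = score,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a longitudinal synthetic child
#'
#' Emulates repeated assessments of one child with the two variability
#' components of the sample-size simulation: a child-specific rate of score
#' growth (between-child variation) and per-assessment unreliability
#' (within-child variation). The child's rate multiplier
#' \eqn{r \sim \mathrm{LogNormal}(0, \sigma_b)} acts on effective age -- the
#' latent score at age `x` is the median curve evaluated at `r * x` (clamped
#' to (0, 72]) -- and each scheduled observation adds independent
#' \eqn{N(0, \sigma_w)} noise, clamped to \[0, 64\].
#'
#' @param table A [percentile_table()] object containing a `tau = 0.5` entry.
#' @param schedule Assessment ages in months, strictly increasing, in
#'   (0, 72].
#' @param sigma_b Between-child rate variability (SD of log rate multiplier,
#'   dimensionless; default 0.15).
#' @param sigma_w Within-child assessment noise SD (score points; default 2).
#' @param seed Integer seed.
#' @param child_id Identifier for the generated child.
#' @return A [child_trajectory()] object with attribute `rate_multiplier`.
#' @examples
#' generate_longitudinal_child(load_reference_table(), seq(6, 66, 6), seed = 1)
#' @export
generate_longitudinal_child <- function(table, schedule, sigma_b = 0.15,
                                        sigma_w = 2, seed, child_id = "sim-long") {
  stopifnot(inherits(table, "flip_norms"))
  if (!length(schedule)) stop_arg("`schedule` must contain at least one age")
  if (any(schedule <= 0 | schedule > 72)) stop_arg("schedule ages must lie in (0, 72]")
  if (is.unsorted(schedule, strictly = TRUE)) {
    stop_arg("schedule ages must be strictly increasing")
  }
  if (sigma_b < 0 || sigma_w < 0) stop_arg("sigma_b and sigma_w must be non-negative")
  med_row <- which(table$tau == 0.5)
  if (!length(med_row)) stop_arg("table must contain a tau = 0.5 (median) entry")
  med <- unlist(table[med_row, c("a1", "a2", "a3", "a4")])
  with_seed(seed, {
    r <- exp(rnorm(1L, 0, sigma_b))
    eff_age <- pmin(pmax(r * schedule, 1e-6), 72)
    latent <- logistic_eval(med, eff_age)
    score <- pmin(pmax(latent + rnorm(length(schedule), 0, sigma_w), 0), 64)
    traj <- child_trajectory(child_id, schedule, score)
    attr(traj, "rate_multiplier") <- r
    traj
  })
}
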