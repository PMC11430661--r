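#' Plot centile curves with optional cohort and trajectory overlays
#'
#' Draws the percentile family as dotted curves over age (from the table's
#' minimum reporting age to 72 months), optionally with cohort records as
#' points and an individual child's trajectory as a connected line with event
#' markers -- the standard normative chart a clinician reads.
#'
#' @param table A [percentile_table()] object.
#' @param cohort Optional data frame of cohort records, drawn as grey points.
#' @param trajectory Optional [child_trajectory()] object.
#' @param taus Levels to draw (default: all in the table).
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_norms <- function(table, cohort = NULL, trajectory = NULL, taus = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_arg("plot_norms() requires the ggplot2 package")
  }
  stopifnot(inherits(table, "flip_norms"))
  if (is.null(taus)) taus <- table$tau
  ages <- seq(attr(table, "min_age"), 72, by = 0.25)
  curves <- do.call(rbind, lapply(taus, function(tau) {
    row <- which(table$tau == tau)
    if (!length(row)) return(NULL)
    p <- unlist(table[row, c("a1", "a2", "a3", "a4")])
    data.frame(age_months = ages,
               score = pmin(pmax(logistic_eval(p, ages), 0), 64),
               centile = sprintf("%gth", 100 * tau))
  }))
  gg <- ggplot2::ggplot()
  if (!is.null(cohort)) {
    gg <- gg + ggplot2::geom_point(
      data = cohort, ggplot2::aes(x = .data$age_months, y = .data$score),
      colour = "grey70", alpha = 0.5, size = 0.8)
  }
  gg <- gg + ggplot2::geom_line(
    data = curves,
    ggplot2::aes(x = .data$age_months, y = .data$score, group = .data$centile,
                 colour = .data$centile),
    linetype = "dotted", linewidth = 0.8)
  if (!is.null(trajectory)) {
    gg <- gg + ggplot2::geom_line(
      data = trajectory$points,
      ggplot2::aes(x = .data$age_months, y = .data$score), colour = "black") +
      ggplot2::geom_point(
        data = trajectory$points,
        ggplot2::aes(x = .data$age_months, y = .data$score), colour = "black")
    if (!is.null(trajectory$annotations)) {
      ann <- trajectory$annotations
      ann$score <- vapply(ann$age_months, function(a) {
        i <- which.min(abs(trajectory$points$age_months - a))
        trajectory$points$score[i]
      }, numeric(1))
      gg <- gg + ggplot2::geom_point(
        data = ann, ggplot2::aes(x = .data$age_months, y = .data$score),
        shape = 8, size = 3, colour = "red")
    }
  }
  gg + ggplot2::labs(x = "Age (months)", y = "FLI-P score", colour = "Centile") +
    ggplot2::coord_cartesian(ylim = c(0, 64)) +
    ggplot2::theme_minimal()
}
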