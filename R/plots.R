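#' Plot a lineage tree's growth curve
#'
#' @param object A [lineage_tree][grow_lineage].
#' @param ... Unused.
#' @return A ggplot: population size versus synchronous iteration, with the
#'   one-division-per-step (linear topology) reference line.
#' @export
autoplot.lineage_tree <- function(object, ...) {
  df <- tibble(t = seq_along(object$growth_curve) - 1L, n = object$growth_curve)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$n)) +
    ggplot2::geom_abline(slope = 1, intercept = 1, linetype = 3, colour = "grey50") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "synchronous iteration t", y = "population size N(t)",
      title = sprintf("%s growth, p = %g, phi = %g: N_f = %d",
                      object$engine, object$p, object$phi, object$final_size)
    )
}

#' Heatmap of a deterministic parameter sweep
#'
#' @param object A `det_map` from [sweep_deterministic()].
#' @param ... Unused.
#' @return A ggplot raster of `log2(N_f)` over the `(p, phi)` plane.
#' @export
autoplot.det_map <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$p, y = .data$phi, fill = log2(.data$nf))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log2 N_f") +
    ggplot2::labs(x = "asymmetry fraction p", y = "threshold phi",
                  title = "Deterministic final population size")
}

#' Heatmap of a stochastic sweep's confidence
#'
#' @param object A `conf_map` from [sweep_stochastic()].
#' @param fill `"confidence"` (default) or `"mode"`.
#' @param ... Unused.
#' @return A ggplot raster over the `(p, phi)` plane.
#' @export
autoplot.conf_map <- function(object, fill = c("confidence", "mode"), ...) {
  fill <- match.arg(fill)
  df <- as_tibble(object)
  if (fill == "mode") df$fill_val <- log2(df$mode) else df$fill_val <- df$confidence
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p, y = .data$phi, fill = .data$fill_val)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (fill == "mode") "log2 mode N_f" else "confidence") +
    ggplot2::labs(x = "asymmetry fraction p", y = "threshold phi",
                  title = sprintf("Stochastic sweep, n0 = %d, %d replicates",
                                  attr(object, "n0"), attr(object, "reps")))
}

#' Bar plot of a replicate size distribution
#'
#' @param object A [size_distribution][simulate_size_distribution].
#' @param ... Unused.
#' @return A ggplot of replicate counts per final size, the mode highlighted.
#' @export
autoplot.size_distribution <- function(object, ...) {
  df <- object$counts
  df$is_mode <- df$nf == object$mode
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nf, y = .data$prop, fill = .data$is_mode)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "final population size N_f", y = "fraction of replicates",
      title = sprintf("p = %g, phi = %g, n0 = %d: mode %d (confidence %.2f)",
                      object$p, object$phi, object$n0, object$mode, object$confidence)
    )
}

#' Line plot of a robustness curve
#'
#' @param object A [robustness_curve()].
#' @param ... Unused.
#' @return A ggplot of the probability of the target final size versus the
#'   perturbation width.
#' @export
autoplot.robustness_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$sigma, y = .data$prob_target)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = sprintf("perturbation width sigma (%% of mean, applied to %s)",
                  object$which[1L]),
      y = sprintf("P(N_f = %d)", attr(object, "target_nf")),
      title = sprintf("Robustness of N_f = %d at p = %g, phi = %g, n0 = %d",
                      attr(object, "target_nf"), attr(object, "p"),
                      attr(object, "phi"), attr(object, "n0"))
    )
}
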