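# broom-style accessors and ggplot2 autoplot methods for run reports and
# benchmark tables.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a generation run: per-iteration tallies
#' @param x an `fg_run`.
#' @param ... unused.
#' @return tibble with one row per iteration (attempted, rejected,
#'   duplicates, scored, selected).
#' @method tidy fg_run
#' @export
tidy.fg_run <- function(x, ...) {
  x$iterations
}

#' One-row summary of a generation run
#' @param x an `fg_run`.
#' @param ... unused.
#' @method glance fg_run
#' @export
glance.fg_run <- function(x, ...) {
  tibble::tibble(
    n_probes = nrow(x$probes),
    n_scored = nrow(x$all),
    n_final = nrow(x$final),
    iterations = nrow(x$iterations),
    best_energy = if (nrow(x$final)) min(x$final$binding_energy) else NA_real_,
    best_pli = if (nrow(x$final)) max(x$final$pli_score) else NA_real_
  )
}

#' Tidy a benchmark table
#' @param x an `fg_benchmark`.
#' @param ... unused.
#' @method tidy fg_benchmark
#' @export
tidy.fg_benchmark <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a benchmark: counts per reproduction class
#' @param x an `fg_benchmark`.
#' @param ... unused.
#' @method glance fg_benchmark
#' @export
glance.fg_benchmark <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    skipped = sum(x$skipped),
    reproduced = sum(x$class == "reproduced", na.rm = TRUE),
    almost = sum(x$class == "almost", na.rm = TRUE),
    failed = sum(x$class == "failed", na.rm = TRUE),
    exact_regrowth = sum(x$found_exact)
  )
}

#' Plot a generation run: scores of the final structures by iteration
#' @param object an `fg_run`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fg_run
#' @export
autoplot.fg_run <- function(object, ...) {
  d <- object$final
  if (!nrow(d)) stop("empty run: nothing to plot")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$binding_energy, y = .data$pli_score,
                                  color = factor(.data$iteration))) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "binding energy (empirical, kcal/mol-like)",
                  y = "PLI score", color = "iteration",
                  title = "Generated structures") +
    ggplot2::theme_minimal()
}

#' Plot a benchmark table: RMSD vs ligand size, rotatable bonds as point size
#' @param object an `fg_benchmark`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fg_benchmark
#' @export
autoplot.fg_benchmark <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[!d$skipped & !is.na(d$rmsd), , drop = FALSE]
  if (!nrow(d)) stop("no benchmark rows to plot")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$heavy_atoms, y = .data$rmsd,
                                  size = .data$rotatable_bonds,
                                  color = .data$class)) +
    ggplot2::geom_hline(yintercept = c(2, 4.5), linetype = "dashed",
                        color = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_color_manual(values = c(reproduced = "#2e7d32",
                                           almost = "#f9a825",
                                           failed = "#c62828")) +
    ggplot2::labs(x = "ligand heavy atoms", y = "pose RMSD (angstroms)",
                  size = "rotatable bonds", color = "outcome",
                  title = "Pose-reproduction benchmark") +
    ggplot2::theme_minimal()
}
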