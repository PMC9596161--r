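#' @importFrom rlang %||%
NULL

new_drive_run <- function(record, config, end, release_time, outcome = NULL) {
  structure(
    list(record = record, config = config, end = end,
         release_time = release_time, outcome = outcome),
    class = "drive_run"
  )
}

#' @export
print.drive_run <- function(x, ...) {
  tcol <- if ("week" %in% names(x$record)) "week" else "generation"
  cat(sprintf("<drive_run %s, drive %s>\n", x$config$model, x$config$drive))
  cat(sprintf("  ended by %s at %s %d; final N = %d\n", x$end, tcol,
              max(x$record[[tcol]]), x$record$n[nrow(x$record)]))
  if (!is.null(x$outcome)) {
    cat("  outcome:", as.character(x$outcome$outcome), "\n")
  }
  invisible(x)
}

#' Tidy a simulation run
#'
#' Returns the per-step record (one row per generation or week) as a
#' tibble: population size, allele counts, fertile females, and for
#' spatial runs the wild-type homozygote count and Green's coefficient.
#'
#' @param x A `drive_run`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy drive_run
#' @export
tidy.drive_run <- function(x, ...) {
  x$record
}

#' One-row summary of a simulation run
#'
#' @param x A `drive_run`.
#' @param ... Unused.
#' @return A tibble with the model, drive, how the run ended, final
#'   census, and — for spatial runs — the classified outcome and chase
#'   statistics.
#' @method glance drive_run
#' @export
glance.drive_run <- function(x, ...) {
  tcol <- if ("week" %in% names(x$record)) "week" else "generation"
  base <- tibble::tibble(
    model = x$config$model, drive = x$config$drive, end = x$end,
    final_time = max(x$record[[tcol]]),
    final_n = x$record$n[nrow(x$record)],
    final_dr = x$record$dr[nrow(x$record)],
    elapsed_secs = x$config$elapsed_secs %||% NA_real_
  )
  if (!is.null(x$outcome)) base <- dplyr::bind_cols(base, x$outcome)
  base
}

#' Plot a simulation run
#'
#' Drive/resistance allele frequencies and the population size over time.
#'
#' @param object A `drive_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot drive_run
#' @export
autoplot.drive_run <- function(object, ...) {
  rec <- object$record
  tcol <- if ("week" %in% names(rec)) "week" else "generation"
  df <- rec |>
    dplyr::mutate(
      `drive allele` = .data$dr / pmax(2 * .data$n, 1),
      `r2 allele` = .data$r2 / pmax(2 * .data$n, 1),
      `population / capacity` = .data$n / max(.data$n)
    ) |>
    tidyr::pivot_longer(c("drive allele", "r2 allele",
                          "population / capacity"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data[[tcol]], .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      y = "frequency / relative size", colour = NULL,
      title = sprintf("%s release in the %s model", object$config$drive,
                      object$config$model)
    ) +
    ggplot2::theme_minimal()
}

#' Tidy a genetic-load measurement
#'
#' @param x A `genetic_load` object from [measure_genetic_load()].
#' @param ... Unused.
#' @return The per-step load series as a tibble.
#' @method tidy genetic_load
#' @export
tidy.genetic_load <- function(x, ...) {
  x$series
}

#' One-row summary of a genetic-load measurement
#'
#' @param x A `genetic_load` object.
#' @param ... Unused.
#' @return A tibble with drive, model and equilibrium load.
#' @method glance genetic_load
#' @export
glance.genetic_load <- function(x, ...) {
  tibble::tibble(drive = x$config$drive, model = x$config$model,
                 load = x$load)
}

#' Plot a genetic-load trajectory
#'
#' @param object A `genetic_load` object.
#' @param ... Unused.
#' @return A ggplot of the per-step load with the equilibrium estimate.
#' @method autoplot genetic_load
#' @export
autoplot.genetic_load <- function(object, ...) {
  s <- object$series
  tcol <- names(s)[1]
  ggplot2::ggplot(s, ggplot2::aes(.data[[tcol]], .data$load)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$load, linetype = 2) +
    ggplot2::labs(y = "genetic load",
                  title = sprintf("%s: equilibrium load %.3f",
                                  object$config$drive, object$load)) +
    ggplot2::theme_minimal()
}

#' Plot a parameter sweep as an outcome heat map
#'
#' One tile per (migration, growth rate) cell, coloured by the
#' representative outcome (see [representative_outcome()]).
#'
#' @param object A `drive_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot drive_sweep
#' @export
autoplot.drive_sweep <- function(object, ...) {
  pal <- c(
    suppression_no_chase = "#1b7837", suppression_after_chase = "#7fbf7b",
    long_term_chase = "#d73027", drive_loss_after_chase = "#fdae61",
    drive_loss_no_chase = "#fee08b"
  )
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(factor(.data$migration),
                               factor(.data$growth_rate),
                               fill = .data$representative)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::labs(x = "migration value", y = "low-density growth rate",
                  fill = "outcome",
                  title = sprintf("%s, %s", object$config$drive,
                                  object$config$model)) +
    ggplot2::theme_minimal()
}

#' @method tidy drive_sweep
#' @export
tidy.drive_sweep <- function(x, ...) {
  x$replicates
}

#' @method glance drive_sweep
#' @export
glance.drive_sweep <- function(x, ...) {
  x$cells
}

#' @export
print.drive_sweep <- function(x, ...) {
  cat(sprintf("<drive_sweep %s, drive %s: %d cells x %d reps>\n",
              x$config$model, x$config$drive, nrow(x$cells),
              x$config$reps))
  invisible(x)
}
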