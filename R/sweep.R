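#' Default migration grid for a sweep
#'
#' The discrete-generation models sweep the migration value from 0.01 to
#' 0.06; the weekly models sweep the mean weekly displacement from 0.008
#' to 0.046 in steps of 0.0038, covering the same per-generation net
#' migration. Growth rates run 2 to 12 in both.
#'
#' @param model One of the four model names (see [run_sweep()]).
#' @return Numeric vector of migration values.
#' @export
default_migration_grid <- function(model) {
  if (grepl("^anopheles", model)) seq(0.008, 0.046, by = 0.0038)
  else seq(0.01, 0.06, by = 0.01)
}

.run_model <- function(model, drive, capacity, growth_rate, migration,
                       max_time, seed, ...) {
  switch(model,
    "discrete-panmictic" = run_discrete_panmictic(
      drive, capacity = capacity, growth_rate = growth_rate,
      max_time = max_time, seed = seed, ...),
    "discrete-spatial" = run_discrete_spatial(
      drive, capacity = capacity, growth_rate = growth_rate,
      migration = migration, max_time = max_time, seed = seed, ...),
    "anopheles-panmictic" = run_anopheles(
      drive, adult_female_capacity = capacity, growth_rate = growth_rate,
      migration = migration, weeks = max_time, spatial = FALSE,
      seed = seed, ...),
    "anopheles-spatial" = run_anopheles(
      drive, adult_female_capacity = capacity, growth_rate = growth_rate,
      migration = migration, weeks = max_time, spatial = TRUE,
      seed = seed, ...),
    stop("unknown model '", model, "'", call. = FALSE)
  )
}

#' Sweep migration and low-density growth rate
#'
#' Runs `reps` replicates of a spatial model for every cell of a
#' migration-by-growth-rate grid, tallies the five outcomes per cell, and
#' derives the representative outcome and duration-weighted chase
#' statistics. Every cell and replicate gets an independent seed from
#' [cell_seed()], so a sweep with `reps = 1` reproduces the matching
#' single run bitwise. A replicate that fails is kept as a row with an
#' `error` message, never dropped.
#'
#' @param model `"discrete-spatial"` or `"anopheles-spatial"` (the
#'   panmictic models are accepted for completeness).
#' @param drive Preset name or [drive_params()].
#' @param migration_values,growth_rates Grid axes; defaults are the
#'   standard grids ([default_migration_grid()] and 2:12).
#' @param reps Replicates per cell (20).
#' @param capacity Carrying capacity (discrete) or adult female capacity
#'   (anopheles).
#' @param max_time Generation or week cap per replicate.
#' @param seed Base seed.
#' @param ... Passed to the underlying `run_*` function.
#' @return A `drive_sweep`: `$cells` (one row per cell with tallies,
#'   representative outcome and chase statistics), `$replicates` (one row
#'   per run). See [autoplot.drive_sweep()].
#' @export
run_sweep <- function(model, drive,
                      migration_values = default_migration_grid(model),
                      growth_rates = 2:12, reps = 20, capacity = 10000,
                      max_time = 300, seed = 1, ...) {
  reps_rows <- list()
  for (i in seq_along(migration_values)) {
    for (j in seq_along(growth_rates)) {
      for (r in seq_len(reps)) {
        sd <- cell_seed(seed, i, j, r)
        row <- tryCatch({
          run <- .run_model(model, drive, capacity, growth_rates[j],
                            migration_values[i], max_time, sd, ...)
          g <- glance(run)
          g$error <- NA_character_
          g
        }, error = function(e) {
          tibble::tibble(model = model, drive = as.character(drive)[1],
                         end = NA_character_, error = conditionMessage(e))
        })
        row$migration <- migration_values[i]
        row$growth_rate <- growth_rates[j]
        row$replicate <- r
        row$seed <- sd
        reps_rows[[length(reps_rows) + 1]] <- row
      }
    }
  }
  replicates <- dplyr::bind_rows(reps_rows)
  valid <- dplyr::filter(replicates, !is.na(.data$end))
  nrep <- dplyr::count(valid, .data$migration, .data$growth_rate,
                       name = "n_reps")
  tally <- valid |>
    dplyr::filter(!is.na(.data$outcome)) |>
    dplyr::count(.data$migration, .data$growth_rate, .data$outcome) |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "n",
                       values_fill = 0L, names_expand = TRUE)
  chase <- valid |>
    dplyr::group_by(.data$migration, .data$growth_rate) |>
    dplyr::summarise(
      mean_chase_duration = mean(.data$chase_duration, na.rm = TRUE),
      chase_fertile_ratio = .weighted_or_na(
        .data$fertile_female_ratio, .data$chase_duration),
      .groups = "drop"
    )
  cells <- nrep |>
    dplyr::left_join(tally, by = c("migration", "growth_rate")) |>
    dplyr::left_join(chase, by = c("migration", "growth_rate")) |>
    dplyr::mutate(dplyr::across(dplyr::any_of(.outcome_levels),
                                ~ tidyr::replace_na(.x, 0L)))
  for (lv in setdiff(.outcome_levels, names(cells))) cells[[lv]] <- 0L
  cells$representative <- factor(
    apply(as.matrix(cells[, .outcome_levels]), 1, function(v) {
      as.character(representative_outcome(stats::setNames(v, .outcome_levels)))
    }),
    levels = .outcome_levels
  )
  structure(
    list(cells = cells, replicates = replicates,
         config = list(model = model,
                       drive = if (inherits(drive, "drive_params"))
                         attr(drive, "drive") else drive,
                       migration_values = migration_values,
                       growth_rates = growth_rates, reps = reps,
                       capacity = capacity, max_time = max_time,
                       seed = seed)),
    class = "drive_sweep"
  )
}

# chase-duration-weighted mean that tolerates all-NA cells
.weighted_or_na <- function(x, w) {
  ok <- !is.na(x) & !is.na(w) & w > 0
  if (!any(ok)) return(NA_real_)
  sum(x[ok] * w[ok]) / sum(w[ok])
}
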