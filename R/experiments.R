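.eight_drives <- c("zpg", "zpg2", "zpgX", "zpg2X", "nos", "nosF", "nosF2",
                   "nosF3")

#' Equilibrium genetic load of every drive
#'
#' Replicated rescue-mode load measurements ([measure_genetic_load()])
#' for a set of drive presets, with the replicate mean and its standard
#' error.
#'
#' @param drives Character vector of preset names.
#' @param model `"discrete"` or `"anopheles"`.
#' @param reps Replicates per drive (20).
#' @param rescue_size Rescue population size (discrete) or adult female
#'   capacity (anopheles).
#' @param seed Base seed; replicate seeds derive from it via
#'   [cell_seed()].
#' @param ... Passed to [measure_genetic_load()].
#' @return A tibble: `drive`, `model`, `load` (mean), `se`, `reps`.
#' @export
genetic_load_table <- function(drives = .eight_drives,
                               model = c("discrete", "anopheles"),
                               reps = 20, rescue_size = 10000, seed = 1,
                               ...) {
  model <- match.arg(model)
  purrr::map_dfr(seq_along(drives), function(i) {
    loads <- vapply(seq_len(reps), function(r) {
      measure_genetic_load(drives[i], model = model,
                           rescue_size = rescue_size,
                           seed = cell_seed(seed, i, if (model == "discrete") 1 else 2, r),
                           ...)$load
    }, numeric(1))
    tibble::tibble(drive = drives[i], model = model, load = mean(loads),
                   se = stats::sd(loads) / sqrt(reps), reps = reps)
  })
}

#' Mean drive-allele-frequency trajectories
#'
#' Replicated panmictic releases at 0.5% starting allele frequency (1%
#' heterozygote release), averaged per generation — the standard view of
#' how fast each drive spreads.
#'
#' @param drives Preset names.
#' @param reps Replicates per drive.
#' @param capacity Carrying capacity.
#' @param generations Generations after release.
#' @param seed Base seed.
#' @param ... Passed to [run_discrete_panmictic()].
#' @return A tibble: `drive`, `generation`, `dr_frequency` (mean over
#'   replicates; a replicate that ended early carries its last frequency
#'   forward).
#' @export
allele_frequency_trajectories <- function(drives = .eight_drives, reps = 10,
                                          capacity = 10000,
                                          generations = 100, seed = 1,
                                          ...) {
  purrr::map_dfr(seq_along(drives), function(i) {
    mat <- sapply(seq_len(reps), function(r) {
      run <- run_discrete_panmictic(drives[i], capacity = capacity,
                                    max_time = generations,
                                    seed = cell_seed(seed, i, 3, r), ...)
      rec <- run$record[run$record$generation >= 0, ]
      f <- rec$dr / pmax(2 * rec$n, 1)
      c(f, rep(f[length(f)], generations + 1 - length(f)))
    })
    tibble::tibble(drive = drives[i], generation = 0:generations,
                   dr_frequency = rowMeans(mat))
  })
}

#' Spatial outcome table for a set of drives
#'
#' Replicated spatial releases at one (migration, growth-rate) setting,
#' reported as outcome percentages plus chase statistics — the tabular
#' counterpart of an outcome bar chart.
#'
#' @param drives Preset names.
#' @param model `"discrete"` or `"anopheles"` (spatial variants).
#' @param growth_rate Low-density growth rate.
#' @param migration Migration value (model default when `NULL`).
#' @param reps Replicates per drive.
#' @param capacity Carrying capacity / adult female capacity.
#' @param max_time Generation or week cap.
#' @param seed Base seed.
#' @param ... Passed to the run function.
#' @return A tibble with one row per drive: outcome counts, suppression
#'   rate, mean chase duration, and the duration-weighted fertile-female
#'   ratio during chases.
#' @export
spatial_outcome_table <- function(drives = .eight_drives,
                                  model = c("discrete", "anopheles"),
                                  growth_rate = 10, migration = NULL,
                                  reps = 20, capacity = 10000,
                                  max_time = 300, seed = 1, ...) {
  model <- match.arg(model)
  full <- paste0(model, "-spatial")
  if (is.null(migration)) migration <- if (model == "discrete") 0.04 else 0.0307
  purrr::map_dfr(seq_along(drives), function(i) {
    sw <- run_sweep(full, drives[i], migration_values = migration,
                    growth_rates = growth_rate, reps = reps,
                    capacity = capacity, max_time = max_time,
                    seed = cell_seed(seed, i, 4, 1), ...)
    cells <- sw$cells
    supp <- cells$suppression_no_chase + cells$suppression_after_chase
    tibble::tibble(
      drive = drives[i], model = full, reps = cells$n_reps,
      suppression_rate = supp / cells$n_reps,
      cells[.outcome_levels],
      representative = cells$representative,
      mean_chase_duration = cells$mean_chase_duration,
      chase_fertile_ratio = cells$chase_fertile_ratio
    )
  })
}

#' Genetic-load parity between the two panmictic models
#'
#' Measures the equilibrium genetic load of each drive in both the
#' discrete-generation and the weekly Anopheles rescue models and reports
#' the per-drive difference; the two should agree closely because the
#' allele-level mechanics are identical per birth.
#'
#' @inheritParams genetic_load_table
#' @param discrete_size,anopheles_size Rescue population size and adult
#'   female capacity.
#' @return A tibble (`drive`, `load_discrete`, `load_anopheles`, `diff`)
#'   with the maximum absolute difference in attribute `max_diff`.
#' @export
validate_parity <- function(drives = .eight_drives, reps = 20,
                            discrete_size = 10000, anopheles_size = 5000,
                            seed = 1, ...) {
  d <- genetic_load_table(drives, "discrete", reps = reps,
                          rescue_size = discrete_size, seed = seed, ...)
  a <- genetic_load_table(drives, "anopheles", reps = reps,
                          rescue_size = anopheles_size, seed = seed, ...)
  out <- tibble::tibble(
    drive = d$drive, load_discrete = d$load, load_anopheles = a$load,
    diff = a$load - d$load
  )
  attr(out, "max_diff") <- max(abs(out$diff))
  out
}

#' Write an experiment table with its configuration echo
#'
#' Saves a result tibble as CSV next to a JSON echo of the call's
#' resolved parameters, so any table can be regenerated from its sidecar.
#'
#' @param result A tibble (or object with a `config` element).
#' @param path Output CSV path; the JSON echo gets the same stem.
#' @param config Named list of resolved parameters to echo.
#' @return `path`, invisibly.
#' @export
write_experiment <- function(result, path, config = list()) {
  tbl <- if (is.data.frame(result)) result else result$cells
  utils::write.csv(tbl, path, row.names = FALSE)
  if (!is.data.frame(result) && !is.null(result$config)) {
    config <- utils::modifyList(result$config, config)
  }
  jsonlite::write_json(config, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
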