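#' Beverton-Holt fecundity scaling
#'
#' Scales a female's fecundity by how far the population is below carrying
#' capacity: `w * beta / ((beta - 1) * (n / capacity) + 1)`, where `beta`
#' is the low-density growth rate. At capacity the factor is one; in an
#' empty landscape it is `beta`.
#'
#' @param w Baseline fecundity multiplier(s).
#' @param n Current population size (or local equivalent).
#' @param capacity Carrying capacity `K`.
#' @param growth_rate Low-density growth rate `beta` (> 1).
#' @return Scaled fecundity, same length as `w`.
#' @export
#' @examples
#' beverton_holt_scale(1, 50000, 50000, 10)   # 1 at capacity
#' beverton_holt_scale(1, 0, 50000, 10)       # beta when empty
beverton_holt_scale <- function(w, n, capacity, growth_rate) {
  stopifnot(capacity > 0, growth_rate > 1, n >= 0)
  w * growth_rate / ((growth_rate - 1) * (n / capacity) + 1)
}

# one discrete, non-overlapping generation of the panmictic model.
# Each fertile female takes a uniform-random mate; offspring counts are
# Binomial(50, w'/25), so a wild-type female at capacity averages two.
.step_panmictic <- function(pop, params, capacity, growth_rate) {
  males <- which(!pop$female)
  moms <- which(.fertile_female(pop))
  if (!length(moms) || !length(males)) {
    return(.pop(0))
  }
  dads <- .resample(males, length(moms))
  w <- .w_female(pop$a[moms], pop$b[moms], params) *
    .w_male(pop$a[dads], pop$b[dads], params)
  wprime <- beverton_holt_scale(w, .pop_n(pop), capacity, growth_rate)
  counts <- rbinom(length(moms), 50, pmin(wprime / 25, 1))
  mi <- rep(moms, counts)
  di <- rep(dads, counts)
  ch <- .make_children(pop$a[mi], pop$b[mi], pop$a[di], pop$b[di], params)
  ch
}

# heterozygote release cohort: n individuals, equal sexes
.release_cohort <- function(n, spatial = FALSE, center = c(0.5, 0.5),
                            radius = 0.01) {
  rel <- .pop(n, female = rep(c(TRUE, FALSE), length.out = n), a = 0L, b = 1L,
              spatial = FALSE)
  if (spatial) {
    pts <- .circle_points(n, center[1], center[2], radius)
    rel$x <- pts$x
    rel$y <- pts$y
  }
  rel
}

.record_row <- function(t, pop, extra = NULL) {
  ac <- .allele_counts(pop)
  row <- tibble::tibble(
    generation = t, n = .pop_n(pop),
    wt = ac[["wt"]], dr = ac[["dr"]], r2 = ac[["r2"]],
    fertile_females = sum(.fertile_female(pop))
  )
  if (!is.null(extra)) row <- dplyr::bind_cols(row, tibble::as_tibble(extra))
  row
}

#' Run the discrete-generation panmictic model
#'
#' Simulates a sexually reproducing diploid population with
#' non-overlapping generations and Beverton-Holt density dependence. The
#' wild-type population equilibrates for `burn_in` generations, then
#' drive/wild-type heterozygotes amounting to `release_fraction` of the
#' population are added (half of them female). The run ends when the
#' population is eliminated, the drive allele is lost, or `max_time`
#' generations have elapsed.
#'
#' @param drive Preset name or [drive_params()] object. The `wildtype`
#'   preset carries no construct, so nothing is released.
#' @param capacity Carrying capacity (default 50,000).
#' @param growth_rate Low-density growth rate `beta` (default 10).
#' @param release_fraction Heterozygote release size as a fraction of the
#'   population (default 0.01, i.e. 0.5% allele frequency).
#' @param burn_in Wild-type equilibration generations before release.
#' @param max_time Generation cap.
#' @param seed Integer RNG seed; set for a reproducible run.
#' @return A `drive_run` object; see [tidy.drive_run()] and
#'   [glance.drive_run()].
#' @export
#' @examples
#' run <- run_discrete_panmictic("nosF3", capacity = 2000, max_time = 40,
#'                               seed = 1)
#' glance(run)
run_discrete_panmictic <- function(drive, capacity = 50000, growth_rate = 10,
                                   release_fraction = 0.01, burn_in = 10,
                                   max_time = 1000, seed = NULL) {
  t_start <- Sys.time()
  params <- .as_params(drive)
  if (!is.null(seed)) set.seed(seed)
  pop <- .pop(capacity)
  rows <- vector("list", burn_in + max_time + 1)
  released <- FALSE
  release_gen <- NA_integer_
  end <- "max_time"
  t <- 0
  for (g in seq_len(burn_in)) {
    pop <- .step_panmictic(pop, params, capacity, growth_rate)
    t <- t + 1
    rows[[t]] <- .record_row(t - burn_in - 1, pop)
  }
  if (!.is_inert(params)) {
    n_rel <- max(1, round(release_fraction * .pop_n(pop)))
    pop <- .pop_bind(pop, .release_cohort(n_rel))
    released <- TRUE
    release_gen <- 0L
  }
  rows[[t + 1]] <- .record_row(0L, pop)
  t <- t + 1
  for (g in seq_len(max_time)) {
    pop <- .step_panmictic(pop, params, capacity, growth_rate)
    t <- t + 1
    rows[[t]] <- .record_row(g, pop)
    if (.pop_n(pop) == 0) {
      end <- "elimination"
      break
    }
    if (released && .allele_counts(pop)[["dr"]] == 0) {
      end <- "drive_loss"
      break
    }
  }
  record <- dplyr::bind_rows(rows[seq_len(t)])
  config <- list(
    model = "discrete-panmictic", drive = attr(params, "drive"),
    params = unclass(params), capacity = capacity, growth_rate = growth_rate,
    release_fraction = release_fraction, burn_in = burn_in,
    max_time = max_time, seed = seed
  )
  config$elapsed_secs <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  new_drive_run(record, config, end, release_gen)
}
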