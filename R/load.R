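#' Analytic genetic load of a pure X-shredder
#'
#' With perfect homing and shredding fixed in all males, a shredding rate
#' `s` leaves a fraction `(1 - s) / (2 - s)` of offspring female, so the
#' reproductive capacity relative to an unbiased population of the same
#' size is `2 (1 - s) / (2 - s)` and the load `1 - 2 (1 - s) / (2 - s)`.
#'
#' @param s X-shredding rate.
#' @return Genetic load in \[0, 1\].
#' @export
#' @examples
#' xshredder_load(0.93)  # ~ 0.87
xshredder_load <- function(s) {
  1 - 2 * (1 - s) / (2 - s)
}

# per-generation load of the discrete rescue population:
# P_actual = sum of pair fecundity multipliers over fertile females,
# P_ideal  = N / 2 (same-size all-wild-type population)
.discrete_rescue <- function(params, rescue_size, generations,
                             release_fraction, burn_in, start) {
  if (start == "equilibrium" && !.is_inert(params)) {
    state <- .equilibrium_state(params)
    pop <- .sample_state(rescue_size, state, params)
  } else {
    pop <- .pop(rescue_size)
    for (g in seq_len(burn_in)) {
      pop <- .rescue_next(pop, params, rescue_size)$pop
    }
    if (!.is_inert(params)) {
      n_rel <- max(1, round(release_fraction * .pop_n(pop)))
      pop <- .pop_bind(pop, .release_cohort(n_rel))
    }
  }
  loads <- numeric(generations)
  for (g in seq_len(generations)) {
    st <- .rescue_next(pop, params, rescue_size)
    loads[g] <- st$load
    pop <- st$pop
    if (!.pop_n(pop)) {
      if (g < generations) loads[(g + 1):generations] <- 1
      break
    }
  }
  loads
}

.rescue_next <- function(pop, params, rescue_size) {
  males <- which(!pop$female)
  moms <- which(.fertile_female(pop))
  if (!length(moms) || !length(males)) {
    return(list(load = 1, pop = .pop(0)))
  }
  dads <- .resample(males, length(moms))
  w <- .w_female(pop$a[moms], pop$b[moms], params) *
    .w_male(pop$a[dads], pop$b[dads], params)
  load <- 1 - sum(w) / (.pop_n(pop) / 2)
  if (sum(w) <= 0) {
    return(list(load = 1, pop = .pop(0)))
  }
  pick <- .resample(seq_along(moms), rescue_size, prob = w)
  ch <- .make_children(pop$a[moms[pick]], pop$b[moms[pick]],
                       pop$a[dads[pick]], pop$b[dads[pick]], params)
  list(load = load, pop = ch)
}

# Weekly rescue variant: the cohort is the fixed weekly recruit count and
# P_ideal is the standing fertile-female count of an all-wild-type
# population with that recruitment, i.e. the female capacity itself.
.anopheles_rescue <- function(params, female_capacity, weeks,
                              release_fraction, remating, start) {
  pop <- .anopheles_init(female_capacity, spatial = FALSE)
  recruits <- round(2 * female_capacity * .equil_factor)
  if (start == "equilibrium" && !.is_inert(params)) {
    # overwrite the wild-type genotypes with the equilibrium composition,
    # keeping the equilibrium age/stage/mating structure
    state <- .equilibrium_state(params)
    fem <- which(pop$female)
    mal <- which(!pop$female)
    fs <- .sample_females(length(fem), state)
    pop$a[fem] <- fs$a
    pop$b[fem] <- fs$b
    pop$dep[fem] <- fs$dep
    ms <- .sample_males(length(mal), state)
    pop$a[mal] <- ms$a
    pop$b[mal] <- ms$b
    st_idx <- which(pop$mated)
    fg <- .sample_fathers(length(st_idx), state, params)
    pop$fa[st_idx] <- fg$fa
    pop$fb[st_idx] <- fg$fb
  } else if (!.is_inert(params)) {
    n_rel <- max(1, round(release_fraction * sum(pop$age >= 2L)))
    rel <- .release_cohort(n_rel)
    rel$age <- rep(2L, n_rel)
    rel$mated <- rep(FALSE, n_rel)
    rel$fa <- rep(NA_integer_, n_rel)
    rel$fb <- rep(NA_integer_, n_rel)
    pop <- .pop_bind(pop, rel[names(pop)])
  }
  loads <- numeric(weeks)
  for (wk in seq_len(weeks)) {
    pop <- .weekly_cull(pop)
    pop <- update_mating(pop, radius = NULL, remating = remating)
    ad <- pop$age >= 2L
    moms_all <- which(ad & pop$mated & .fertile_female(pop))
    w_all <- .w_female(pop$a[moms_all], pop$b[moms_all], params) *
      .w_male(pop$fa[moms_all], pop$fb[moms_all], params)
    loads[wk] <- 1 - sum(w_all) / female_capacity
    lay <- runif(length(moms_all)) < 0.5
    moms <- moms_all[lay]
    w <- w_all[lay]
    if (length(moms) && sum(w) > 0) {
      pick <- .resample(seq_along(moms), recruits, prob = w)
      mi <- moms[pick]
      kids <- .make_children(pop$a[mi], pop$b[mi], pop$fa[mi], pop$fb[mi],
                             params)
      kids$age <- rep(0L, recruits)
      kids$mated <- rep(FALSE, recruits)
      kids$fa <- rep(NA_integer_, recruits)
      kids$fb <- rep(NA_integer_, recruits)
      pop <- .pop_bind(pop, kids[names(pop)])
    }
  }
  loads
}

#' Measure the equilibrium genetic load of a drive
#'
#' Genetic load is the fractional reduction in the reproductive capacity
#' of a population at the drive's equilibrium frequency, relative to an
#' all-wild-type population of the same size. To read it without the
#' population collapsing, the model runs in "rescue" mode: every step the
#' next cohort is regenerated at a fixed size from the fertile females,
#' sampled in proportion to their pair fecundity, so genotype frequencies
#' evolve exactly as at capacity while the census never shrinks. The
#' per-step load is `1 - P_actual / P_ideal`, with `P_actual` the
#' fecundity-weighted fertile-female mass and `P_ideal` that of the
#' same-size all-wild-type population; X-shredder sex-ratio bias enters
#' through the female count.
#'
#' By default (`start = "equilibrium"`) the rescue population is
#' initialised at the drive's expected equilibrium composition from
#' [genotype_recursion()], so the averaging window reads the equilibrium
#' load directly for every drive — including slow-establishing ones like
#' nos, which needs hundreds of generations to equilibrate from a small
#' release, and the X-shredder drives, whose transient frequency
#' overshoot passes through a fertile-female bottleneck that small rescue
#' populations cannot cross reliably. With `start = "release"` the
#' classic protocol is used instead: a heterozygote release of
#' `release_fraction` into a wild-type population.
#'
#' @param drive Preset name or [drive_params()].
#' @param model `"discrete"` (discrete-generation panmictic rescue of
#'   `rescue_size` individuals) or `"anopheles"` (weekly rescue with
#'   `rescue_size` adult females and the matching fixed weekly
#'   recruitment).
#' @param rescue_size Fixed cohort size (discrete) or adult female
#'   capacity (anopheles).
#' @param generations Post-release generations to run (100); the weekly
#'   model converts via [mean_generation_time()].
#' @param window Generations averaged for the equilibrium value (61:100).
#' @param release_fraction Heterozygote release as a fraction of the
#'   population (0.5; only with `start = "release"`).
#' @param burn_in Pre-release generations (discrete model,
#'   `start = "release"` only).
#' @param start `"equilibrium"` (default) or `"release"`; see Details.
#' @param remating Weekly re-mating probability (anopheles model).
#' @param seed Integer RNG seed.
#' @return A `genetic_load` object with the equilibrium `load`, the
#'   per-step `series`, and the configuration; see [glance.genetic_load()].
#' @export
#' @examples
#' gl <- measure_genetic_load("nosF3", rescue_size = 1000,
#'                            generations = 40, window = 21:40, seed = 1)
#' glance(gl)
measure_genetic_load <- function(drive, model = c("discrete", "anopheles"),
                                 rescue_size = 10000, generations = 100,
                                 window = 61:100, release_fraction = 0.5,
                                 burn_in = 10, remating = 0.05,
                                 start = c("equilibrium", "release"),
                                 seed = NULL) {
  model <- match.arg(model)
  start <- match.arg(start)
  params <- .as_params(drive)
  if (!is.null(seed)) set.seed(seed)
  if (model == "discrete") {
    loads <- .agg_discrete_rescue(params, rescue_size, generations,
                                  release_fraction, burn_in, start)
    series <- tibble::tibble(generation = seq_along(loads), load = loads)
    sel <- loads[window]
  } else {
    gt <- mean_generation_time()
    weeks <- round(max(generations) * gt)
    loads <- .agg_anopheles_rescue(params, rescue_size, weeks,
                                   release_fraction, remating, start)
    series <- tibble::tibble(week = seq_along(loads), load = loads)
    wk_lo <- round((min(window) - 1) * gt) + 1
    sel <- loads[wk_lo:weeks]
  }
  est <- min(max(mean(sel), 0), 1)
  structure(
    list(
      load = est, series = series, window = window,
      config = list(model = model, drive = attr(params, "drive"),
                    params = unclass(params), rescue_size = rescue_size,
                    generations = generations, start = start,
                    release_fraction = release_fraction, seed = seed)
    ),
    class = "genetic_load"
  )
}

#' @export
print.genetic_load <- function(x, ...) {
  cat(sprintf("<genetic_load %s [%s]: %.4f>\n", x$config$drive,
              x$config$model, x$load))
  invisible(x)
}
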