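#' Pick a mate within a radius
#'
#' A female samples potential mates uniformly from the circle of the given
#' radius (the migration value) around her; if the circle holds no male
#' she does not reproduce this step.
#'
#' @param female_x,female_y Female coordinates.
#' @param male_x,male_y Male coordinates.
#' @param radius Mate-search radius.
#' @return Integer vector of chosen male indices (1-based), 0 when the
#'   circle is empty.
#' @export
find_mate <- function(female_x, female_y, male_x, male_y, radius) {
  stopifnot(radius > 0)
  cpp_pick_within(male_x, male_y, female_x, female_y, radius)
}

#' Local-density Beverton-Holt fecundity
#'
#' The spatial analogue of [beverton_holt_scale()]: the density a female
#' experiences is the number of individuals (any sex or fertility, herself
#' included) within `density_radius`, divided by the circle's area, compared
#' to the density `capacity` individuals would have if spread evenly over
#' the unit square.
#'
#' @param w Baseline fecundity multiplier(s).
#' @param local_count Individuals within `density_radius` of the female,
#'   herself included.
#' @param capacity Carrying capacity of the arena.
#' @param growth_rate Low-density growth rate `beta`.
#' @param density_radius Radius of the density neighbourhood (0.01).
#' @return Scaled fecundity.
#' @export
local_fecundity <- function(w, local_count, capacity, growth_rate,
                            density_radius = 0.01) {
  rho_i <- local_count / (pi * density_radius^2)
  w * growth_rate / ((growth_rate - 1) * (rho_i / capacity) + 1)
}

#' Disperse an offspring from its mother
#'
#' Axis-wise Gaussian displacement with standard deviation `sigma` (the
#' migration value), giving a mean displacement of `sigma * sqrt(pi / 2)`.
#' Displacements leaving the unit square are redrawn wholesale, so the
#' distribution near a border is truncated, never clipped onto it.
#'
#' @param mother_x,mother_y Mother coordinates.
#' @param sigma Axis-wise displacement standard deviation.
#' @return A list with `x` and `y` offspring coordinates.
#' @export
disperse_offspring <- function(mother_x, mother_y, sigma) {
  if (sigma <= 0) return(list(x = mother_x, y = mother_y))
  .disperse(mother_x, mother_y, sigma)
}

# positions of wild-type homozygotes (the Green's coefficient convention)
.wtwt_xy <- function(pop) {
  i <- pop$a == 0L & pop$b == 0L
  list(x = pop$x[i], y = pop$y[i], n = sum(i))
}

.step_spatial <- function(pop, params, capacity, growth_rate, migration,
                          density_radius) {
  males <- which(!pop$female)
  moms <- which(.fertile_female(pop))
  if (!length(moms) || !length(males)) return(.pop(0, spatial = TRUE))
  mate <- find_mate(pop$x[moms], pop$y[moms], pop$x[males], pop$y[males],
                    migration)
  keep <- mate > 0
  moms <- moms[keep]
  if (!length(moms)) return(.pop(0, spatial = TRUE))
  dads <- males[mate[keep]]
  local <- 1 + cpp_radius_sum(pop$x, pop$y, 1.0, pop$x[moms], pop$y[moms],
                              density_radius, 0L, moms - 1L)
  w <- .w_female(pop$a[moms], pop$b[moms], params) *
    .w_male(pop$a[dads], pop$b[dads], params)
  wprime <- local_fecundity(w, local, capacity, growth_rate, density_radius)
  counts <- rbinom(length(moms), 50, pmin(wprime / 25, 1))
  mi <- rep(moms, counts)
  di <- rep(dads, counts)
  ch <- .make_children(pop$a[mi], pop$b[mi], pop$a[di], pop$b[di], params)
  pos <- disperse_offspring(pop$x[mi], pop$y[mi], migration)
  ch$x <- pos$x
  ch$y <- pos$y
  ch[c("a", "b", "female", "dep", "x", "y")]
}

#' Run the discrete-generation spatial model
#'
#' The panmictic model extended to the unit square: mates are found within
#' the migration radius, fecundity responds to local density, and
#' offspring disperse from their mothers by a Gaussian step. Wild-type
#' homozygote clustering (Green's coefficient) and allele counts are
#' recorded each generation; after the run, chasing is detected and the
#' outcome classified.
#'
#' @inheritParams run_discrete_panmictic
#' @param migration Migration value: mate-search radius and dispersal
#'   standard deviation (default 0.04).
#' @param density_radius Radius of the local-density neighbourhood (0.01).
#' @param release_radius Radius of the central release circle (0.01).
#' @return A `drive_run` with a per-generation record (including `greens`)
#'   and a classified outcome; see [glance.drive_run()].
#' @export
run_discrete_spatial <- function(drive, capacity = 50000, growth_rate = 10,
                                 migration = 0.04, release_fraction = 0.01,
                                 burn_in = 10, max_time = 1000,
                                 density_radius = 0.01,
                                 release_radius = 0.01, seed = NULL) {
  t_start <- Sys.time()
  params <- .as_params(drive)
  if (!is.null(seed)) set.seed(seed)
  pop <- .pop(capacity, spatial = TRUE)
  rows <- vector("list", burn_in + max_time + 1)
  released <- FALSE
  end <- "max_time"
  t <- 0
  grec <- function(pop) {
    pts <- .wtwt_xy(pop)
    list(wt_homozygotes = pts$n, greens = greens_coefficient(pts$x, pts$y))
  }
  for (g in seq_len(burn_in)) {
    pop <- .step_spatial(pop, params, capacity, growth_rate, migration,
                         density_radius)
    t <- t + 1
    rows[[t]] <- .record_row(g - burn_in - 1, pop, grec(pop))
  }
  if (!.is_inert(params)) {
    n_rel <- max(1, round(release_fraction * .pop_n(pop)))
    pop <- .pop_bind(pop, .release_cohort(n_rel, spatial = TRUE,
                                          radius = release_radius))
    released <- TRUE
  }
  t <- t + 1
  rows[[t]] <- .record_row(0L, pop, grec(pop))
  for (g in seq_len(max_time)) {
    pop <- .step_spatial(pop, params, capacity, growth_rate, migration,
                         density_radius)
    t <- t + 1
    rows[[t]] <- .record_row(g, pop, grec(pop))
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
    model = "discrete-spatial", drive = attr(params, "drive"),
    params = unclass(params), capacity = capacity, growth_rate = growth_rate,
    migration = migration, release_fraction = release_fraction,
    burn_in = burn_in, max_time = max_time, density_radius = density_radius,
    release_radius = release_radius, seed = seed
  )
  post <- record[record$generation >= 0, ]
  chase <- detect_chase_start(post$greens, post$wt, time = post$generation)
  outcome <- classify_outcome(record, chase, release_time = 0,
                              max_time = max_time)
  config$elapsed_secs <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  new_drive_run(record, config, end, 0L, outcome)
}
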