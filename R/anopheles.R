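# Weekly adult survival schedules: an adult in its k-th adult week
# survives to week k+1 with schedule[k]. Males never pass their third
# adult week, females never their sixth; a female cohort thus accrues
# 1 + 5/6 + 2/3 + 1/2 + 1/3 + 1/6 = 3.5 expected adult-female-weeks.
.male_sched <- c(2 / 3, 1 / 2, 0)
.female_sched <- c(5 / 6, 4 / 5, 3 / 4, 2 / 3, 1 / 2, 0)

# stationary age weights (cumulative survivorship per adult week)
.female_agew <- cumprod(c(1, .female_sched[-6]))
.male_agew <- cumprod(c(1, .male_sched[-3]))

# expected older-juvenile adjustment: weekly recruits per adult female at
# equilibrium are 2/3.5 = 0.5714..., written 2 x 0.285714 in the
# competition closure
.equil_factor <- 1 / 3.5

.expected_competition <- function(female_capacity) {
  female_capacity * (25 + 2 * .equil_factor * 5)
}

#' Weekly adult survival probability
#'
#' @param sex `"female"` or `"male"`.
#' @param adult_week Week of adult life (1 = first adult week).
#' @return Survival probability to the next week (0 past the schedule).
#' @export
#' @examples
#' weekly_survival("male", 3)    # males never pass their third adult week
#' weekly_survival("female", 1)
weekly_survival <- function(sex = c("female", "male"), adult_week) {
  sex <- match.arg(sex)
  sched <- if (sex == "female") .female_sched else .male_sched
  ifelse(adult_week >= 1 & adult_week <= length(sched), sched[pmin(adult_week, length(sched))], 0)
}

#' Mean generation time of the weekly life-cycle model
#'
#' The survivorship-weighted mean parental age at reproduction, averaged
#' over the sexes (weekly reproduction probability is constant with age,
#' so it cancels). Adulthood starts at age two weeks; females average
#' 3.667 weeks, males 2.667, giving 3.167 weeks per generation — hence
#' 3,167 weeks stand in for 1,000 discrete generations.
#'
#' @return Mean generation time in weeks.
#' @export
mean_generation_time <- function() {
  fem <- sum((2:7) * .female_agew) / sum(.female_agew)
  mal <- sum((2:4) * .male_agew) / sum(.male_agew)
  (fem + mal) / 2
}

#' Density-dependent juvenile survival (panmictic)
#'
#' All juvenile mortality is applied in one cull immediately after egg
#' generation. With `n` new juveniles, `o` surviving week-old larvae
#' (each exerting five-fold competition), and the expected competition of
#' a population at capacity, the competition ratio is
#' `r = (n + 5 o) / expected` and the survival rate
#' `beta / (25 ((beta - 1) r + 1)) * (2 / 3.5)^r`. At `r = 1` this yields
#' exact replacement; as `r -> 0` it tends to `beta / 25`.
#'
#' @param n_new New juveniles this week (raw egg count).
#' @param o_old Surviving week-old larvae.
#' @param growth_rate Low-density growth rate `beta`.
#' @param female_capacity Adult females at capacity (default 25,000).
#' @return Survival probability, clamped to \[0, 1\].
#' @export
#' @examples
#' juvenile_survival_panmictic(625000, 14286, 10)  # ~ replacement
juvenile_survival_panmictic <- function(n_new, o_old, growth_rate,
                                        female_capacity = 25000) {
  r <- (n_new + 5 * o_old) / .expected_competition(female_capacity)
  s <- growth_rate / (25 * ((growth_rate - 1) * r + 1)) *
    (2 * .equil_factor)^r
  pmin(pmax(s, 0), 1)
}

#' Density-dependent juvenile survival (spatial)
#'
#' The spatial version replaces global counts with a local competition
#' kernel: another new offspring contributes `1 - d / radius` competition
#' at distance `d` (0 beyond the radius; mean 1/3 within it), and week-old
#' larvae contribute five-fold. The competition faced is divided by the
#' expected local competition at capacity,
#' `female_capacity * (25 + 2 * (1/3.5) * 5) * pi * radius^2 / 3`, and the
#' survival formula of [juvenile_survival_panmictic()] is applied to that
#' ratio.
#'
#' @param x,y New-offspring coordinates.
#' @param old_x,old_y Week-old larva coordinates.
#' @param growth_rate Low-density growth rate `beta`.
#' @param female_capacity Adult females at capacity.
#' @param radius Competition radius (0.01).
#' @return Survival probability per new offspring.
#' @export
juvenile_survival_spatial <- function(x, y, old_x, old_y, growth_rate,
                                      female_capacity = 25000,
                                      radius = 0.01) {
  comp <- cpp_radius_sum(x, y, 1.0, x, y, radius, 1L, seq_along(x) - 1L)
  if (length(old_x)) {
    comp <- comp + 5 * cpp_radius_sum(old_x, old_y, 1.0, x, y, radius, 1L,
                                      integer())
  }
  expected <- .expected_competition(female_capacity) * pi * radius^2 / 3
  r <- comp / expected
  s <- growth_rate / (25 * ((growth_rate - 1) * r + 1)) *
    (2 * .equil_factor)^r
  pmin(pmax(s, 0), 1)
}

#' Weekly adult migration
#'
#' Adults move every week by the same Gaussian rule used for natal
#' dispersal, except that the migration value specifies the mean weekly
#' displacement, so the axis-wise standard deviation is
#' `migration_value / sqrt(pi / 2)`. Out-of-arena draws are redrawn.
#'
#' @param x,y Current coordinates.
#' @param migration_value Mean weekly displacement (default 0.0307).
#' @return A list with updated `x` and `y`.
#' @export
adult_migration <- function(x, y, migration_value = 0.0307) {
  if (migration_value <= 0) return(list(x = x, y = y))
  .disperse(x, y, migration_value / sqrt(pi / 2))
}

#' Weekly mating update
#'
#' Unmated adult females attempt to mate with a uniform-random adult male
#' (within `radius` of themselves in the spatial variant; they retry next
#' week if none is found). Females that have already mated store the
#' male's genotype and keep using it to fertilise eggs, but re-mate with
#' probability `remating` per week, replacing the stored genotype; a
#' spatial re-mating attempt that finds no male keeps the stored mate.
#' Mating precedes reproduction within the week.
#'
#' @param pop Population list/tibble with columns `a`, `b`, `female`,
#'   `age`, `mated`, `fa`, `fb` (and `x`, `y` when spatial).
#' @param radius Mate-search radius, or `NULL` for panmictic mating.
#' @param remating Weekly re-mating probability (0.05).
#' @return The population with updated `mated`, `fa`, `fb`.
#' @export
update_mating <- function(pop, radius = NULL, remating = 0.05) {
  adult <- pop$age >= 2L
  males <- which(adult & !pop$female)
  if (!length(males)) return(pop)
  need <- which(adult & pop$female & !pop$mated)
  rem <- which(adult & pop$female & pop$mated)
  if (length(rem)) rem <- rem[runif(length(rem)) < remating]
  seekers <- c(need, rem)
  if (!length(seekers)) return(pop)
  if (is.null(radius)) {
    got <- males[.resample(seq_along(males), length(seekers))]
    found <- rep(TRUE, length(seekers))
  } else {
    pick <- find_mate(pop$x[seekers], pop$y[seekers], pop$x[males],
                      pop$y[males], radius)
    found <- pick > 0
    got <- males[pick[found]]
  }
  hit <- seekers[found]
  pop$mated[hit] <- TRUE
  pop$fa[hit] <- pop$a[got]
  pop$fb[hit] <- pop$b[got]
  pop
}

#' Weekly egg production of one female
#'
#' An adult, mated, fertile female successfully reproduces in a given
#' week with probability `weekly_prob`; if she does, her egg count is
#' Poisson with mean `eggs_per_week` times the fecundity product of the
#' pair ([fecundity_multiplier()]). Egg numbers are never density
#' dependent — density acts on juvenile survival instead.
#'
#' @param mother,father [genotype()] objects (father = stored mate).
#' @inheritParams gamete_distribution
#' @param eggs_per_week Mean weekly egg number at full fitness (50).
#' @param weekly_prob Weekly reproduction probability (0.5).
#' @return An integer egg count (0 for sterile mothers).
#' @export
produce_eggs <- function(mother, father, params, eggs_per_week = 50,
                         weekly_prob = 0.5) {
  params <- .as_params(params)
  if (!is_fertile_female(mother)) return(0L)
  if (runif(1) >= weekly_prob) return(0L)
  rpois(1, eggs_per_week * fecundity_multiplier(mother, father, params))
}

# ---- weekly engine -------------------------------------------------------

# equilibrium wild-type starting population
.anopheles_init <- function(female_capacity, spatial) {
  recruits <- round(2 * female_capacity * .equil_factor)
  n_fem <- round(female_capacity * .female_agew / sum(.female_agew))
  n_mal <- round(recruits / 2 * .male_agew)
  ages <- c(rep(2:7, n_fem), rep(2:4, n_mal), rep(0L, recruits), rep(1L, recruits))
  female <- c(rep(TRUE, sum(n_fem)), rep(FALSE, sum(n_mal)),
              runif(2 * recruits) < 0.5)
  n <- length(ages)
  pop <- .pop(n, female = female, spatial = spatial)
  pop$age <- as.integer(ages)
  pop$mated <- female & ages >= 2L
  pop$fa <- ifelse(pop$mated, 0L, NA_integer_)
  pop$fb <- ifelse(pop$mated, 0L, NA_integer_)
  pop
}

# age/survival cull at the week rollover (reproduction has already had its
# chance the previous week)
.weekly_cull <- function(pop) {
  p <- rep(1, .pop_n(pop))
  ad <- pop$age >= 2L
  wk <- pop$age - 1L
  fem <- which(ad & pop$female)
  mal <- which(ad & !pop$female)
  p[fem] <- ifelse(wk[fem] <= 6, .female_sched[pmin(wk[fem], 6)], 0)
  p[mal] <- ifelse(wk[mal] <= 3, .male_sched[pmin(wk[mal], 3)], 0)
  keep <- runif(length(p)) < p
  pop <- .pop_subset(pop, keep)
  pop$age <- pop$age + 1L
  pop
}

.anopheles_record <- function(t, pop, recruits, spatial) {
  ad <- pop$age >= 2L
  adp <- .pop_subset(pop, ad)
  ac <- .allele_counts(adp)
  row <- tibble::tibble(
    week = t, n = sum(ad),
    adult_females = sum(adp$female),
    wt = ac[["wt"]], dr = ac[["dr"]], r2 = ac[["r2"]],
    fertile_females = sum(.fertile_female(adp)),
    juveniles = .pop_n(pop) - sum(ad),
    recruits = recruits
  )
  if (spatial) {
    pts <- .wtwt_xy(adp)
    row$wt_homozygotes <- pts$n
    row$greens <- greens_coefficient(pts$x, pts$y)
  }
  row
}

# one natural-mode week; returns list(pop, recruits)
.anopheles_week <- function(pop, params, female_capacity, growth_rate,
                            migration, spatial, remating,
                            competition_radius) {
  pop <- .weekly_cull(pop)
  if (!.pop_n(pop)) return(list(pop = pop, recruits = 0L))
  if (spatial) {
    ad <- which(pop$age >= 2L)
    mv <- adult_migration(pop$x[ad], pop$y[ad], migration)
    pop$x[ad] <- mv$x
    pop$y[ad] <- mv$y
  }
  pop <- update_mating(pop, radius = if (spatial) migration else NULL,
                       remating = remating)
  ad <- pop$age >= 2L
  moms <- which(ad & pop$mated & .fertile_female(pop))
  moms <- moms[runif(length(moms)) < 0.5]
  o_idx <- which(pop$age == 1L)
  recruits <- 0L
  kids <- NULL
  if (length(moms)) {
    w <- .w_female(pop$a[moms], pop$b[moms], params) *
      .w_male(pop$fa[moms], pop$fb[moms], params)
    eggs <- rpois(length(moms), 50 * w)
    n_new <- sum(eggs)
    if (n_new > 0) {
      if (!spatial) {
        s <- juvenile_survival_panmictic(n_new, length(o_idx), growth_rate,
                                         female_capacity)
        surv <- rbinom(length(moms), eggs, s)
        mi <- rep(moms, surv)
      } else {
        mi_all <- rep(moms, eggs)
        pos <- disperse_offspring(pop$x[mi_all], pop$y[mi_all],
                                  migration / sqrt(pi / 2))
        s_i <- juvenile_survival_spatial(pos$x, pos$y, pop$x[o_idx],
                                         pop$y[o_idx], growth_rate,
                                         female_capacity,
                                         competition_radius)
        keep <- runif(n_new) < s_i
        mi <- mi_all[keep]
        kx <- pos$x[keep]
        ky <- pos$y[keep]
      }
      recruits <- length(mi)
      if (recruits > 0) {
        kids <- .make_children(pop$a[mi], pop$b[mi], pop$fa[mi], pop$fb[mi],
                               params)
        kids$age <- rep(0L, recruits)
        kids$mated <- rep(FALSE, recruits)
        kids$fa <- rep(NA_integer_, recruits)
        kids$fb <- rep(NA_integer_, recruits)
        if (spatial) {
          kids$x <- kx
          kids$y <- ky
        }
        kids <- kids[names(pop)]
      }
    }
  }
  if (!is.null(kids)) pop <- .pop_bind(pop, kids)
  list(pop = pop, recruits = as.integer(recruits))
}

# drive is lost only when no drive allele survives in individuals or in
# stored sperm
.drive_gone <- function(pop) {
  if (any(pop$a == 1L) || any(pop$b == 1L)) return(FALSE)
  st <- which(pop$mated)
  !(any(pop$fa[st] == 1L, na.rm = TRUE) || any(pop$fb[st] == 1L, na.rm = TRUE))
}

#' Run the weekly Anopheles life-cycle model
#'
#' Overlapping generations in weekly steps: age-structured adult survival,
#' once-per-lifetime mating with sperm storage and a 5% weekly re-mating
#' chance, Poisson egg production (density independent), and a single
#' larval-competition cull that determines which offspring reach
#' adulthood. The spatial variant adds weekly adult migration, natal
#' dispersal, radius-limited mating, and a local larval competition
#' kernel. One generation corresponds to ~3.167 weeks
#' ([mean_generation_time()]).
#'
#' @inheritParams run_discrete_panmictic
#' @param adult_female_capacity Adult females at capacity (default
#'   25,000; total adults then ~40,000).
#' @param migration Mean weekly displacement and (spatial) mate-search
#'   radius (default 0.0307, matching the discrete default of 0.04 per
#'   generation).
#' @param weeks Week cap (default 3,167 ~ 1,000 generations).
#' @param burn_in Pre-release equilibration weeks (32 ~ 10 generations).
#' @param spatial Run the continuous-space variant?
#' @param remating Weekly re-mating probability (0.05).
#' @param competition_radius Larval competition radius (0.01).
#' @param release_radius Radius of the central release circle (0.01).
#' @return A `drive_run`; spatial runs carry a classified outcome.
#' @export
run_anopheles <- function(drive, adult_female_capacity = 25000,
                          growth_rate = 10, migration = 0.0307,
                          weeks = 3167, burn_in = 32,
                          release_fraction = 0.01, spatial = FALSE,
                          remating = 0.05, competition_radius = 0.01,
                          release_radius = 0.01, seed = NULL) {
  t_start <- Sys.time()
  params <- .as_params(drive)
  if (!is.null(seed)) set.seed(seed)
  pop <- .anopheles_init(adult_female_capacity, spatial)
  rows <- vector("list", burn_in + weeks + 1)
  released <- FALSE
  end <- "max_time"
  t <- 0
  for (wkk in seq_len(burn_in)) {
    st <- .anopheles_week(pop, params, adult_female_capacity, growth_rate,
                          migration, spatial, remating, competition_radius)
    pop <- st$pop
    t <- t + 1
    rows[[t]] <- .anopheles_record(wkk - burn_in - 1, pop, st$recruits, spatial)
  }
  if (!.is_inert(params)) {
    n_rel <- max(1, round(release_fraction * sum(pop$age >= 2L)))
    rel <- .release_cohort(n_rel, spatial = spatial, radius = release_radius)
    rel$age <- rep(2L, n_rel)
    rel$mated <- rep(FALSE, n_rel)
    rel$fa <- rep(NA_integer_, n_rel)
    rel$fb <- rep(NA_integer_, n_rel)
    pop <- .pop_bind(pop, rel[names(pop)])
    released <- TRUE
  }
  t <- t + 1
  rows[[t]] <- .anopheles_record(0L, pop, 0L, spatial)
  for (wkk in seq_len(weeks)) {
    st <- .anopheles_week(pop, params, adult_female_capacity, growth_rate,
                          migration, spatial, remating, competition_radius)
    pop <- st$pop
    t <- t + 1
    rows[[t]] <- .anopheles_record(wkk, pop, st$recruits, spatial)
    if (.pop_n(pop) == 0) {
      end <- "elimination"
      break
    }
    if (released && .drive_gone(pop)) {
      end <- "drive_loss"
      break
    }
  }
  record <- dplyr::bind_rows(rows[seq_len(t)])
  config <- list(
    model = if (spatial) "anopheles-spatial" else "anopheles-panmictic",
    drive = attr(params, "drive"), params = unclass(params),
    adult_female_capacity = adult_female_capacity,
    growth_rate = growth_rate, migration = migration, weeks = weeks,
    burn_in = burn_in, release_fraction = release_fraction,
    spatial = spatial, remating = remating,
    competition_radius = competition_radius, seed = seed
  )
  outcome <- NULL
  if (spatial) {
    post <- record[record$week >= 0, ]
    # +/- 16-week extremum window ~ the 5-generation rule of the
    # discrete-generation chase detector
    chase <- detect_chase_start(post$greens, post$wt, time = post$week,
                                window = 16)
    outcome <- classify_outcome(record, chase, release_time = 0,
                                max_time = weeks)
  }
  config$elapsed_secs <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  new_drive_run(record, config, end, 0L, outcome)
}
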