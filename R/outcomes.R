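.outcome_levels <- c(
  "suppression_no_chase", "suppression_after_chase", "long_term_chase",
  "drive_loss_after_chase", "drive_loss_no_chase"
)

#' Green's coefficient of spatial clustering
#'
#' The unit square is divided into an 8 x 8 grid and the points counted
#' per section; with `N` points total, section mean `n` and sample
#' variance `s2`, `G = (s2 / n - 1) / (N - 1)`. `G` is ~0 for
#' Poisson-random points and 1 when all points share one section. By
#' convention only wild-type homozygotes are counted when monitoring a
#' drive release.
#'
#' @param x,y Point coordinates in \[0, 1\].
#' @param grid Sections per axis (8).
#' @return `G`, or `NA` for fewer than two points.
#' @export
greens_coefficient <- function(x, y, grid = 8) {
  n_pts <- length(x)
  if (n_pts <= 1) return(NA_real_)
  ix <- pmin(grid - 1, floor(x * grid))
  iy <- pmin(grid - 1, floor(y * grid))
  counts <- tabulate(ix * grid + iy + 1, nbins = grid * grid)
  nbar <- mean(counts)
  (var(counts) / nbar - 1) / (n_pts - 1)
}

# centred moving average used to suppress single-step noise
.smooth3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  out <- (c(v[1], v[-n]) + v + c(v[-1], v[n])) / 3
  out[1] <- mean(v[1:2])
  out[n] <- mean(v[(n - 1):n])
  out
}

# first index that is the strict extremum of a centred +/- half window
.first_extremum <- function(v, half = 5, maximum = TRUE) {
  n <- length(v)
  if (n < 2 * half + 1) return(NA_integer_)
  for (i in (half + 1):(n - half)) {
    win <- v[(i - half):(i + half)]
    ok <- if (maximum) v[i] > max(win[-(half + 1)]) else v[i] < min(win[-(half + 1)])
    if (ok) return(i)
  }
  NA_integer_
}

#' Detect the onset of chasing
#'
#' Chasing begins when drive-cleared areas start to be recolonised: the
#' wild-type cluster at the landscape edge stops growing tighter, so
#' Green's coefficient passes its first local maximum, and the wild-type
#' allele count passes its first local minimum. The chase start is the
#' earlier of the two. Both series are smoothed with a 3-step moving
#' average and an extremum must be the strict extremum of a centred
#' 11-step window, mirroring the observation that the two events fall
#' within about five steps of one another.
#'
#' @param g_series Green's coefficient per step, from release onward.
#' @param wt_series Wild-type allele count per step, from release onward.
#' @param time Time value for each step (defaults to 1-based index).
#' @param window Half-width of the extremum window (5).
#' @return The chase start time, or `NA` if no chase is detected.
#' @export
detect_chase_start <- function(g_series, wt_series,
                               time = seq_along(g_series), window = 5) {
  stopifnot(length(g_series) == length(wt_series),
            length(time) == length(g_series))
  g <- .smooth3(ifelse(is.na(g_series), 0, g_series))
  w <- .smooth3(wt_series)
  i_g <- .first_extremum(g, window, maximum = TRUE)
  i_w <- .first_extremum(w, window, maximum = FALSE)
  cand <- c(i_g, i_w)
  cand <- cand[!is.na(cand)]
  if (!length(cand)) return(time[NA_integer_])
  time[min(cand)]
}

#' Classify the outcome of a spatial release
#'
#' Five terminal outcomes are distinguished: complete suppression with or
#' without a prior period of chasing, long-term chasing (drive still
#' present when the simulation ends), and drive loss with or without
#' chasing. For chases, the mean genotype-fertile female count from chase
#' start to chase end and its ratio to the pre-release fertile female
#' count are also reported.
#'
#' @param record A run record tibble with columns `generation` (or
#'   `week`), `n`, `dr`, `fertile_females`.
#' @param chase_start Chase start time from [detect_chase_start()], or
#'   `NA`.
#' @param release_time Time of the drive release (default 0).
#' @param max_time The simulation's time cap, used to recognise runs that
#'   ended by the clock.
#' @return A one-row tibble: `outcome`, `chase_start`, `chase_end`,
#'   `chase_duration`, `time_to_elimination_from_chase`,
#'   `avg_fertile_females_during_chase`, `fertile_female_ratio`,
#'   `chase_detected`.
#' @export
classify_outcome <- function(record, chase_start, release_time = 0,
                             max_time = NULL) {
  tcol <- if ("week" %in% names(record)) "week" else "generation"
  tt <- record[[tcol]]
  last <- nrow(record)
  eliminated <- record$n[last] == 0
  drive_lost <- !eliminated && record$dr[last] == 0
  chased <- !is.na(chase_start)
  outcome <- if (eliminated) {
    if (chased) "suppression_after_chase" else "suppression_no_chase"
  } else if (drive_lost) {
    if (chased) "drive_loss_after_chase" else "drive_loss_no_chase"
  } else {
    "long_term_chase"
  }
  chase_end <- if (!chased) NA_real_ else tt[last]
  stat <- chase_female_statistic(record, chase_start,
                                 release_time = release_time)
  tibble::tibble(
    outcome = factor(outcome, levels = .outcome_levels),
    chase_start = if (chased) chase_start else NA_real_,
    chase_end = chase_end,
    chase_duration = if (chased) chase_end - chase_start else NA_real_,
    time_to_elimination_from_chase =
      if (chased && eliminated) tt[last] - chase_start else NA_real_,
    avg_fertile_females_during_chase = stat$mean_fertile_females,
    fertile_female_ratio = stat$ratio,
    chase_detected = chased
  )
}

#' Fertile-female statistic of a chase
#'
#' The mean genotype-fertile female count from the start of chasing to the
#' end of the run, and its ratio to the pre-release fertile female count.
#' Sterile females play no role; fertility is judged from the genotype.
#'
#' @inheritParams classify_outcome
#' @return A one-row tibble with `mean_fertile_females`, `ratio`,
#'   `duration` (`NA` when no chase was detected).
#' @export
chase_female_statistic <- function(record, chase_start, release_time = 0) {
  tcol <- if ("week" %in% names(record)) "week" else "generation"
  tt <- record[[tcol]]
  if (is.na(chase_start)) {
    return(tibble::tibble(mean_fertile_females = NA_real_, ratio = NA_real_,
                          duration = NA_real_))
  }
  pre_idx <- which(tt < release_time)
  pre <- record$fertile_females[if (length(pre_idx)) max(pre_idx) else 1L]
  inchase <- tt >= chase_start
  m <- mean(record$fertile_females[inchase])
  tibble::tibble(mean_fertile_females = m, ratio = m / pre,
                 duration = tt[length(tt)] - chase_start)
}

#' Representative outcome of a replicate set
#'
#' Summarises outcome tallies the way sweep heat maps are coloured: each
#' pair of one `suppression_no_chase` and one `long_term_chase` outcome is
#' first converted into two `suppression_after_chase` outcomes (the two
#' are opposite tails of the same borderline dynamics); the modal outcome
#' after that adjustment is returned. Ties break in the order
#' suppression_no_chase > suppression_after_chase > long_term_chase >
#' drive_loss_after_chase > drive_loss_no_chase.
#'
#' @param tallies Named vector or table of outcome counts (names from the
#'   five outcome levels).
#' @return The representative outcome as a length-one factor.
#' @export
#' @examples
#' representative_outcome(c(suppression_no_chase = 10, long_term_chase = 10))
representative_outcome <- function(tallies) {
  counts <- stats::setNames(rep(0, length(.outcome_levels)), .outcome_levels)
  tallies <- unlist(as.list(tallies))
  bad <- setdiff(names(tallies), .outcome_levels)
  if (length(bad)) stop("unknown outcome(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  counts[names(tallies)] <- counts[names(tallies)] + as.numeric(tallies)
  pairs <- min(counts["suppression_no_chase"], counts["long_term_chase"])
  counts["suppression_no_chase"] <- counts["suppression_no_chase"] - pairs
  counts["long_term_chase"] <- counts["long_term_chase"] - pairs
  counts["suppression_after_chase"] <- counts["suppression_after_chase"] + 2 * pairs
  best <- .outcome_levels[which.max(counts)]  # which.max takes the first tie
  factor(best, levels = .outcome_levels)
}
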