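# sample() that treats a length-one x as a single candidate, never 1:x
.resample <- function(x, size, replace = TRUE, prob = NULL) {
  if (length(x) == 1L) {
    if (is.null(prob) || prob[1] > 0) return(rep(x, size))
    stop("zero-probability single candidate")
  }
  sample(x, size, replace = replace, prob = prob)
}

#' Derive a per-cell, per-replicate seed for a parameter sweep
#'
#' A small deterministic hash of the base seed and the grid/replicate
#' indices, so every sweep cell gets an independent, reproducible stream
#' and a sweep with one replicate reproduces a single run bitwise.
#'
#' @param base_seed Integer base seed.
#' @param i,j Grid indices (migration, growth rate).
#' @param rep Replicate index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
cell_seed <- function(base_seed, i, j, rep = 1) {
  m <- 2147483629
  h <- as.double(base_seed) %% m
  for (v in c(i, j, rep)) {
    h <- (h * 48271 + as.double(v) + 11) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# population container: named list of parallel vectors.
# a, b      integer allele codes (0 WT, 1 DR, 2 R2)
# female    logical
# dep       logical (paternal-deposition sterility)
# optional: x, y (positions), age, mated, fa, fb (stored mate alleles)
.pop <- function(n, female = NULL, a = 0L, b = 0L, spatial = FALSE) {
  if (is.null(female)) female <- runif(n) < 0.5
  out <- list(
    a = rep_len(as.integer(a), n), b = rep_len(as.integer(b), n),
    female = female, dep = rep(FALSE, n)
  )
  if (spatial) {
    out$x <- runif(n)
    out$y <- runif(n)
  }
  out
}

.pop_n <- function(pop) length(pop$a)

.pop_subset <- function(pop, idx) lapply(pop, `[`, idx)

.pop_bind <- function(p1, p2) {
  stopifnot(identical(names(p1), names(p2)))
  mapply(c, p1, p2, SIMPLIFY = FALSE)
}

# allele tallies over a population (2N alleles)
.allele_counts <- function(pop) {
  al <- c(pop$a, pop$b)
  c(wt = sum(al == 0L), dr = sum(al == 1L), r2 = sum(al == 2L))
}

# uniform positions within a circle
.circle_points <- function(n, cx, cy, radius) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  list(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Gaussian axis-wise displacement; out-of-arena draws redrawn wholesale
.disperse <- function(x, y, sigma) {
  n <- length(x)
  nx <- x + stats::rnorm(n, 0, sigma)
  ny <- y + stats::rnorm(n, 0, sigma)
  bad <- which(nx < 0 | nx > 1 | ny < 0 | ny > 1)
  while (length(bad)) {
    nx[bad] <- x[bad] + stats::rnorm(length(bad), 0, sigma)
    ny[bad] <- y[bad] + stats::rnorm(length(bad), 0, sigma)
    ok <- nx[bad] >= 0 & nx[bad] <= 1 & ny[bad] >= 0 & ny[bad] <= 1
    bad <- bad[!ok]
  }
  list(x = nx, y = ny)
}
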