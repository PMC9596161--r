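# Deterministic expected-value recursion over genotype x sex x
# deposition-flag frequencies. One step maps the current adult
# composition to the expected composition of the next cohort under the
# same mating and fecundity rules as the stochastic models (fertile
# mothers weighted by pair fecundity, fathers uniform then
# fecundity-weighted). Density dependence cancels from frequencies, so
# the recursion describes both the natural model at capacity and the
# rescue mode exactly, in expectation.

.rec_genos <- list(c(0L, 0L), c(0L, 1L), c(0L, 2L), c(1L, 1L), c(1L, 2L),
                   c(2L, 2L))
.rec_names <- c("WT/WT", "DR/WT", "WT/R2", "DR/DR", "DR/R2", "R2/R2")
.rec_hasW <- vapply(.rec_genos, function(g) any(g == 0L), logical(1))
.rec_hasD <- vapply(.rec_genos, function(g) any(g == 1L), logical(1))
.rec_isWD <- .rec_names == "DR/WT"

# genotype index lookup for an unordered allele pair (codes 0:2)
.rec_gidx_tab <- local({
  m <- matrix(0L, 3, 3)
  m[1, 1] <- 1L                 # WT/WT
  m[1, 2] <- m[2, 1] <- 2L      # DR/WT
  m[1, 3] <- m[3, 1] <- 3L      # WT/R2
  m[2, 2] <- 4L                 # DR/DR
  m[2, 3] <- m[3, 2] <- 5L      # DR/R2
  m[3, 3] <- 6L                 # R2/R2
  m
})

.rec_gidx <- function(a, b) {
  .rec_gidx_tab[cbind(a + 1L, b + 1L)]
}

# gamete distribution over allele codes 0:2 for genotype index gi
.rec_gam <- function(gi, res, conv) {
  g <- .rec_genos[[gi]]
  p <- c(0, 0, 0)
  het <- .rec_isWD[gi]
  for (al in g) {
    if (al == 0L && het) {
      p[3] <- p[3] + 0.5 * res
      p[2] <- p[2] + 0.5 * (1 - res) * conv
      p[1] <- p[1] + 0.5 * (1 - res) * (1 - conv)
    } else {
      p[al + 1L] <- p[al + 1L] + 0.5
    }
  }
  p
}

# one recursion step; state = list(F = 6 x 2 matrix (fertile-flag,
# deposition-sterile), M = length-6 vector), all summing to 1
.rec_step <- function(state, p) {
  wF <- ifelse(.rec_isWD, 1 - p$somatic_cost_female, 1)
  wM <- ifelse(.rec_isWD, 1 - p$somatic_cost_male, 1)
  if (sum(state$M) <= 0) return(NULL)
  fdist <- state$M * wM / sum(state$M)
  newF <- matrix(0, 6, 2)
  newM <- rep(0, 6)
  e <- p$embryo_resistance_maternal
  pd <- p$paternal_deposition
  s <- p$x_shredding
  for (m in 1:6) {
    fw <- state$F[m, 1] * .rec_hasW[m] * wF[m]
    if (fw == 0) next
    gm <- .rec_gam(m, p$germline_resistance_female, p$drive_conversion_female)
    for (f in 1:6) {
      if (fdist[f] == 0) next
      gf <- .rec_gam(f, p$germline_resistance_male, p$drive_conversion_male)
      pmale <- if (.rec_hasD[f] && s > 0) 1 / (2 - s) else 0.5
      for (a in 0:2) {
        if (gm[a + 1] == 0) next
        for (b in 0:2) {
          pr <- gm[a + 1] * gf[b + 1] * fw * fdist[f]
          if (pr == 0) next
          # embryo conversion of each WT allele when the mother carries DR
          opts_a <- if (a == 0L && .rec_hasD[m] && e > 0) {
            list(c(0L, 1 - e), c(2L, e))
          } else list(c(a, 1))
          opts_b <- if (b == 0L && .rec_hasD[m] && e > 0) {
            list(c(0L, 1 - e), c(2L, e))
          } else list(c(b, 1))
          for (oa in opts_a) {
            for (ob in opts_b) {
              gi <- .rec_gidx(oa[1], ob[1])
              w <- pr * oa[2] * ob[2]
              newM[gi] <- newM[gi] + w * pmale
              pf <- w * (1 - pmale)
              if (pf == 0) next
              # paternal deposition sterilises drive-carrying daughters
              if (pd > 0 && .rec_hasD[f] && (oa[1] == 1L || ob[1] == 1L)) {
                newF[gi, 2] <- newF[gi, 2] + pf * pd
                newF[gi, 1] <- newF[gi, 1] + pf * (1 - pd)
              } else {
                newF[gi, 1] <- newF[gi, 1] + pf
              }
            }
          }
        }
      }
    }
  }
  tot <- sum(newF) + sum(newM)
  if (tot <= 0) return(NULL)
  list(F = newF / tot, M = newM / tot)
}

.rec_load <- function(state, p) {
  wF <- ifelse(.rec_isWD, 1 - p$somatic_cost_female, 1)
  wM <- ifelse(.rec_isWD, 1 - p$somatic_cost_male, 1)
  if (sum(state$M) <= 0) return(1)
  ewf <- sum(state$M * wM) / sum(state$M)
  1 - 2 * sum(state$F[, 1] * .rec_hasW * wF) * ewf
}

.rec_freqs <- function(state) {
  gmass <- rowSums(state$F) + state$M
  al <- vapply(seq_len(6), function(i) {
    g <- .rec_genos[[i]]
    c(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(3))
  tot <- as.numeric(al %*% gmass) / 2
  c(wt = tot[1], dr = tot[2], r2 = tot[3])
}

.rec_init <- function(release_frequency) {
  F <- matrix(0, 6, 2)
  M <- rep(0, 6)
  F[2, 1] <- release_frequency / 2
  M[2] <- release_frequency / 2
  F[1, 1] <- 0.5 - release_frequency / 2
  M[1] <- 0.5 - release_frequency / 2
  list(F = F, M = M)
}

#' Deterministic genotype-frequency recursion
#'
#' Iterates the expected genotype x sex x deposition-flag composition of
#' successive cohorts under the drive's inheritance rules. Because
#' density dependence scales every female alike, the expected genotype
#' frequencies of the stochastic models follow this recursion at
#' capacity, making it both a fast expectation engine (equilibrium allele
#' frequencies, expected genetic load) and a reference for the
#' individual-based runs.
#'
#' @param drive Preset name or [drive_params()].
#' @param generations Steps to iterate (500 reaches equilibrium for all
#'   shipped presets).
#' @param release_frequency Initial drive heterozygote frequency (0.5,
#'   i.e. drive allele frequency 0.25), split equally between the sexes.
#' @return A tibble with one row per generation: expected `wt`, `dr`,
#'   `r2` allele frequencies, the fraction of females that are fertile,
#'   and the expected genetic `load`.
#' @export
#' @examples
#' rec <- genotype_recursion("nos", generations = 400)
#' tail(rec, 1)  # equilibrium load ~ 0.96
genotype_recursion <- function(drive, generations = 500,
                               release_frequency = 0.5) {
  p <- .as_params(drive)
  state <- .rec_init(release_frequency)
  rows <- vector("list", generations + 1)
  for (t in 0:generations) {
    fr <- .rec_freqs(state)
    rows[[t + 1]] <- tibble::tibble(
      generation = t, wt = fr[["wt"]], dr = fr[["dr"]], r2 = fr[["r2"]],
      fertile_female_mass = sum(state$F[, 1] * .rec_hasW),
      load = min(max(.rec_load(state, p), 0), 1)
    )
    if (t < generations) {
      nxt <- .rec_step(state, p)
      if (is.null(nxt)) {
        # reproduction failed entirely; composition frozen, load 1
        rows[[t + 2]] <- rows[[t + 1]]
        rows[[t + 2]]$generation <- t + 1
        rows[[t + 2]]$load <- 1
        out <- dplyr::bind_rows(rows[seq_len(t + 2)])
        return(out)
      }
      state <- nxt
    }
  }
  dplyr::bind_rows(rows)
}

# equilibrium composition used to seed rescue-mode load measurement;
# deterministic, so cached per parameter set
.equilibrium_state <- function(params, generations = 500,
                               release_frequency = 0.1) {
  key <- paste(format(unlist(params), digits = 15), collapse = "|")
  if (is.null(.preset_env$eq_cache)) .preset_env$eq_cache <- list()
  hit <- .preset_env$eq_cache[[key]]
  if (!is.null(hit)) return(hit)
  state <- .rec_init(release_frequency)
  for (t in seq_len(generations)) {
    nxt <- .rec_step(state, params)
    if (is.null(nxt)) break
    state <- nxt
  }
  .preset_env$eq_cache[[key]] <- state
  state
}

.rec_a <- vapply(.rec_genos, `[`, integer(1), 1)
.rec_b <- vapply(.rec_genos, `[`, integer(1), 2)

# draw n female genotypes (with deposition flag) from a recursion state
.sample_females <- function(n, state) {
  pick <- .resample(seq_len(12), n, prob = pmax(c(state$F[, 1], state$F[, 2]), 0))
  gidx <- (pick - 1L) %% 6L + 1L
  list(a = .rec_a[gidx], b = .rec_b[gidx], dep = pick > 6L)
}

.sample_males <- function(n, state) {
  pick <- .resample(seq_len(6), n, prob = pmax(state$M, 0))
  list(a = .rec_a[pick], b = .rec_b[pick])
}

# sample n individuals from a recursion state; returns a .pop-style list
.sample_state <- function(n, state, params) {
  p_female <- sum(state$F) / (sum(state$F) + sum(state$M))
  female <- runif(n) < p_female
  nf <- sum(female)
  a <- integer(n)
  b <- integer(n)
  dep <- rep(FALSE, n)
  if (nf) {
    fs <- .sample_females(nf, state)
    a[female] <- fs$a
    b[female] <- fs$b
    dep[female] <- fs$dep
  }
  if (n - nf) {
    ms <- .sample_males(n - nf, state)
    a[!female] <- ms$a
    b[!female] <- ms$b
  }
  list(a = a, b = b, female = female, dep = dep)
}

# stored-mate genotype draw: mates are chosen uniformly among males, so
# the stored distribution is the male genotype distribution (the male
# fecundity weight acts later, through the pair fecundity)
.sample_fathers <- function(n, state, params) {
  pick <- .resample(seq_len(6), n, prob = pmax(state$M, 0))
  list(
    fa = vapply(pick, function(i) .rec_genos[[i]][1], integer(1)),
    fb = vapply(pick, function(i) .rec_genos[[i]][2], integer(1))
  )
}
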