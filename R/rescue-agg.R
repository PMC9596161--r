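# Aggregated-count rescue engine.
#
# In rescue mode every transition probability depends only on an
# individual's cell — genotype x deposition flag (x age x stored-mate
# genotype in the weekly model) — so the individual-based process can be
# simulated exactly on cell counts with binomial/multinomial draws. This
# makes the cost of a load measurement independent of the population
# size, which matters because the fertile-female pool at equilibrium is
# small for high-load drives and small rescue populations are biased
# toward the wild-type-loss boundary.
#
# Child cells: 1..12 = female genotype 1..6 with deposition flag FALSE
# (1..6) / TRUE (7..12); 13..18 = male genotype 1..6.

# exact offspring-cell distribution for a (mother, father) genotype pair
.child_dist <- function(m, f, p) {
  gm <- .rec_gam(m, p$germline_resistance_female, p$drive_conversion_female)
  gf <- .rec_gam(f, p$germline_resistance_male, p$drive_conversion_male)
  s <- p$x_shredding
  e <- p$embryo_resistance_maternal
  pd <- p$paternal_deposition
  pmale <- if (.rec_hasD[f] && s > 0) 1 / (2 - s) else 0.5
  out <- numeric(18)
  for (a in 0:2) {
    if (gm[a + 1] == 0) next
    for (b in 0:2) {
      pr <- gm[a + 1] * gf[b + 1]
      if (pr == 0) next
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
          out[12 + gi] <- out[12 + gi] + w * pmale
          pf <- w * (1 - pmale)
          if (pf == 0) next
          if (pd > 0 && .rec_hasD[f] && (oa[1] == 1L || ob[1] == 1L)) {
            out[gi + 6] <- out[gi + 6] + pf * pd
            out[gi] <- out[gi] + pf * (1 - pd)
          } else {
            out[gi] <- out[gi] + pf
          }
        }
      }
    }
  }
  out
}

# 36 x 18 matrix, row (m - 1) * 6 + f
.child_dist_matrix <- function(p) {
  cd <- matrix(0, 36, 18)
  for (m in 1:6) {
    if (!.rec_hasW[m]) next  # only fertile mother genotypes are needed
    for (f in 1:6) cd[(m - 1) * 6 + f, ] <- .child_dist(m, f, p)
  }
  cd
}

# counts sampled from a recursion state: list(Fc = 12, Mc = 6)
.agg_sample_state <- function(n, state) {
  mass <- pmax(c(state$F[, 1], state$F[, 2], state$M), 0)
  cnt <- as.vector(stats::rmultinom(1, n, mass))
  list(Fc = cnt[1:12], Mc = cnt[13:18])
}

# one aggregated discrete-rescue generation; returns load + next counts
.agg_discrete_next <- function(Fc, Mc, p, rescue_size, cd, wF, wM) {
  ntot <- sum(Fc) + sum(Mc)
  fertile <- which(.rec_hasW)  # genotypes 1..3; deposition cells excluded
  if (sum(Fc[fertile]) == 0 || sum(Mc) == 0) {
    return(list(load = 1, Fc = rep(0L, 12), Mc = rep(0L, 6)))
  }
  pairw <- matrix(0, 6, 6)
  for (m in fertile) {
    nm <- Fc[m]
    if (nm == 0) next
    alloc <- as.vector(stats::rmultinom(1, nm, Mc))
    pairw[m, ] <- alloc * wF[m] * wM
  }
  load <- 1 - sum(pairw) / (ntot / 2)
  if (sum(pairw) <= 0) {
    return(list(load = 1, Fc = rep(0L, 12), Mc = rep(0L, 6)))
  }
  kid_alloc <- as.vector(stats::rmultinom(1, rescue_size, as.vector(pairw)))
  newF <- rep(0L, 12)
  newM <- rep(0L, 6)
  for (k in which(kid_alloc > 0)) {
    m <- (k - 1) %% 6 + 1
    f <- (k - 1) %/% 6 + 1
    cc <- as.vector(stats::rmultinom(1, kid_alloc[k], cd[(m - 1) * 6 + f, ]))
    newF <- newF + cc[1:12]
    newM <- newM + cc[13:18]
  }
  list(load = load, Fc = newF, Mc = newM)
}

.agg_discrete_rescue <- function(params, rescue_size, generations,
                                 release_fraction, burn_in, start) {
  cd <- .child_dist_matrix(params)
  wF <- ifelse(.rec_isWD, 1 - params$somatic_cost_female, 1)
  wM <- ifelse(.rec_isWD, 1 - params$somatic_cost_male, 1)
  if (start == "equilibrium" && !.is_inert(params)) {
    st <- .agg_sample_state(rescue_size, .equilibrium_state(params))
    Fc <- st$Fc
    Mc <- st$Mc
  } else {
    nf <- rbinom(1, rescue_size, 0.5)
    Fc <- rep(0L, 12)
    Mc <- rep(0L, 6)
    Fc[1] <- nf
    Mc[1] <- rescue_size - nf
    if (!.is_inert(params)) {
      n_rel <- max(1, round(release_fraction * rescue_size))
      Fc[2] <- Fc[2] + ceiling(n_rel / 2)
      Mc[2] <- Mc[2] + floor(n_rel / 2)
    }
  }
  loads <- numeric(generations)
  for (g in seq_len(generations)) {
    st <- .agg_discrete_next(Fc, Mc, params, rescue_size, cd, wF, wM)
    loads[g] <- st$load
    Fc <- st$Fc
    Mc <- st$Mc
    if (sum(Fc) + sum(Mc) == 0) {
      if (g < generations) loads[(g + 1):generations] <- 1
      break
    }
  }
  loads
}

# ---- weekly aggregated rescue -------------------------------------------
# Fem: 12 x 6 x 7 (genotype-dep x adult week x mate status; status 1 =
# unmated, 1 + g = stored father genotype g). Mal: 6 x 3. Juv: 18 x 2
# (child cell x age 0/1).

.agg_anopheles_rescue <- function(params, female_capacity, weeks,
                                  release_fraction, remating, start) {
  cd <- .child_dist_matrix(params)
  wF <- ifelse(.rec_isWD, 1 - params$somatic_cost_female, 1)
  wM <- ifelse(.rec_isWD, 1 - params$somatic_cost_male, 1)
  recruits <- round(2 * female_capacity * .equil_factor)
  n_fem_age <- round(female_capacity * .female_agew / sum(.female_agew))
  n_mal_age <- round(recruits / 2 * .male_agew)

  Fem <- array(0L, c(12, 6, 7))
  Mal <- matrix(0L, 6, 3)
  Juv <- matrix(0L, 18, 2)
  equilibrium <- start == "equilibrium" && !.is_inert(params)
  state <- if (equilibrium) .equilibrium_state(params) else NULL
  fem_mass <- if (equilibrium) pmax(c(state$F[, 1], state$F[, 2]), 0) else c(1, rep(0, 11))
  mal_mass <- if (equilibrium) pmax(state$M, 0) else c(1, rep(0, 5))
  birth_mass <- if (equilibrium) {
    pmax(c(state$F[, 1], state$F[, 2], state$M), 0)
  } else c(0.5, rep(0, 11), 0.5, rep(0, 5))
  for (wk in 1:6) {
    gd <- as.vector(stats::rmultinom(1, n_fem_age[wk], fem_mass))
    for (cell in which(gd > 0)) {
      fat <- as.vector(stats::rmultinom(1, gd[cell], mal_mass))
      Fem[cell, wk, 2:7] <- Fem[cell, wk, 2:7] + fat
    }
  }
  for (wk in 1:3) {
    Mal[, wk] <- as.vector(stats::rmultinom(1, n_mal_age[wk], mal_mass))
  }
  for (ag in 1:2) {
    Juv[, ag] <- as.vector(stats::rmultinom(1, recruits, birth_mass))
  }
  if (!equilibrium && !.is_inert(params)) {
    n_rel <- max(1, round(release_fraction * (sum(Fem) + sum(Mal))))
    Fem[2, 1, 1] <- Fem[2, 1, 1] + ceiling(n_rel / 2)
    Mal[2, 1] <- Mal[2, 1] + floor(n_rel / 2)
  }

  fertile_cells <- which(.rec_hasW)  # 1..3, deposition-clean only
  loads <- numeric(weeks)
  for (wk in seq_len(weeks)) {
    # survival + aging
    newFem <- array(0L, c(12, 6, 7))
    for (aw in 1:5) {
      n <- Fem[, aw, ]
      newFem[, aw + 1, ] <- matrix(rbinom(length(n), n, .female_sched[aw]),
                                   12, 7)
    }
    newMal <- matrix(0L, 6, 3)
    for (aw in 1:2) {
      newMal[, aw + 1] <- rbinom(6, Mal[, aw], .male_sched[aw])
    }
    newFem[1:12, 1, 1] <- Juv[1:12, 2]
    newMal[, 1] <- Juv[13:18, 2]
    Juv[, 2] <- Juv[, 1]
    Juv[, 1] <- 0L
    Fem <- newFem
    Mal <- newMal
    # mating: unmated females mate; mated re-mate at 5%
    Mg <- rowSums(Mal)
    if (sum(Mg) > 0) {
      for (aw in 1:6) {
        seekers <- Fem[, aw, 1]
        rem <- rbinom(12 * 6, Fem[, aw, 2:7], remating)
        rem <- matrix(rem, 12, 6)
        Fem[, aw, 2:7] <- Fem[, aw, 2:7] - rem
        tot <- seekers + rowSums(rem)
        for (cell in which(tot > 0)) {
          alloc <- as.vector(stats::rmultinom(1, tot[cell], Mg))
          Fem[cell, aw, 2:7] <- Fem[cell, aw, 2:7] + alloc
        }
        Fem[, aw, 1] <- 0L
      }
    }
    # load over all mated fertile females
    mated <- apply(Fem[fertile_cells, , 2:7, drop = FALSE], c(1, 3), sum)
    pairn <- mated  # 3 x 6: mother genotype x stored father genotype
    pw <- pairn * outer(wF[fertile_cells], wM)
    loads[wk] <- 1 - sum(pw) / female_capacity
    # egg laying: each mated fertile female lays with probability 0.5
    lay <- matrix(rbinom(length(pairn), as.integer(pairn), 0.5),
                  nrow(pairn), ncol(pairn))
    lw <- lay * outer(wF[fertile_cells], wM)
    if (sum(lw) > 0) {
      kid_alloc <- as.vector(stats::rmultinom(1, recruits, as.vector(lw)))
      ka <- matrix(kid_alloc, nrow(lw), ncol(lw))
      for (m_i in seq_along(fertile_cells)) {
        for (f in 1:6) {
          if (ka[m_i, f] == 0) next
          m <- fertile_cells[m_i]
          cc <- as.vector(stats::rmultinom(1, ka[m_i, f],
                                           cd[(m - 1) * 6 + f, ]))
          Juv[, 1] <- Juv[, 1] + cc
        }
      }
    }
  }
  loads
}
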