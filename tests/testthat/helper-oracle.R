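# Independent oracles, written from the model definition and kept separate
# from the package's own code paths.

# ---- exact gamete enumeration -------------------------------------------
# Enumerates the sequential germline modification tree for one parent:
# pick either allele with probability 1/2; a wild-type allele in a DR/WT
# heterozygote first becomes R2 (rate res), else DR (rate conv).
oracle_gametes <- function(a1, a2, res, conv) {
  out <- c(WT = 0, DR = 0, R2 = 0)
  het <- setequal(c(a1, a2), c("WT", "DR"))
  for (al in c(a1, a2)) {
    if (al == "WT" && het) {
      out["R2"] <- out["R2"] + 0.5 * res
      out["DR"] <- out["DR"] + 0.5 * (1 - res) * conv
      out["WT"] <- out["WT"] + 0.5 * (1 - res) * (1 - conv)
    } else {
      out[al] <- out[al] + 0.5
    }
  }
  out
}

# ---- brute-force Green's coefficient ------------------------------------
oracle_greens <- function(x, y, grid = 8) {
  n <- length(x)
  if (n <= 1) return(NA_real_)
  counts <- numeric(grid * grid)
  k <- 1
  for (i in seq_len(grid)) {
    for (j in seq_len(grid)) {
      lo_x <- (i - 1) / grid
      hi_x <- i / grid
      lo_y <- (j - 1) / grid
      hi_y <- j / grid
      counts[k] <- sum(x >= lo_x & (x < hi_x | (i == grid & x <= 1)) &
                         y >= lo_y & (y < hi_y | (j == grid & y <= 1)))
      k <- k + 1
    }
  }
  (stats::var(counts) / mean(counts) - 1) / (n - 1)
}

# ---- independent genotype-frequency recursion ---------------------------
# Expected-value recursion over genotype x sex x deposition-sterility
# frequencies, built by explicit enumeration with expand.grid (a different
# construction from the package's engine).

oracle_genotypes <- c("WT/WT", "DR/WT", "WT/R2", "DR/DR", "DR/R2", "R2/R2")

oracle_split <- function(g) strsplit(g, "/", fixed = TRUE)[[1]]

oracle_recursion_step <- function(fem, fem_dep, mal, p) {
  # fem, fem_dep, mal: named numeric over oracle_genotypes (fem_dep =
  # deposition-sterile females); total mass 1
  has_wt <- vapply(oracle_genotypes, function(g) "WT" %in% oracle_split(g), logical(1))
  has_dr <- vapply(oracle_genotypes, function(g) "DR" %in% oracle_split(g), logical(1))
  is_het <- oracle_genotypes == "DR/WT"
  w_mom <- ifelse(is_het, 1 - p$somatic_cost_female, 1)
  w_dad <- ifelse(is_het, 1 - p$somatic_cost_male, 1)
  dad_prob <- mal * w_dad
  dad_prob <- dad_prob / sum(mal)
  new_fem <- new_dep <- new_mal <- stats::setNames(numeric(6), oracle_genotypes)
  for (mg in oracle_genotypes) {
    mom_mass <- fem[mg] * has_wt[oracle_genotypes == mg] *
      w_mom[oracle_genotypes == mg]
    if (mom_mass == 0) next
    als <- oracle_split(mg)
    gm <- oracle_gametes(als[1], als[2], p$germline_resistance_female,
                         p$drive_conversion_female)
    for (fg in oracle_genotypes) {
      if (dad_prob[fg] == 0) next
      alf <- oracle_split(fg)
      gf <- oracle_gametes(alf[1], alf[2], p$germline_resistance_male,
                           p$drive_conversion_male)
      p_male <- if (has_dr[oracle_genotypes == fg] && p$x_shredding > 0) {
        1 / (2 - p$x_shredding)
      } else 0.5
      combos <- expand.grid(a = names(gm), b = names(gf),
                            stringsAsFactors = FALSE)
      for (k in seq_len(nrow(combos))) {
        pr0 <- gm[combos$a[k]] * gf[combos$b[k]] * mom_mass * dad_prob[fg]
        if (pr0 == 0) next
        # embryo conversion: each WT allele -> R2 at rate e if mother has DR
        e <- if (has_dr[oracle_genotypes == mg]) p$embryo_resistance_maternal else 0
        conv <- function(al) {
          if (al == "WT" && e > 0) list(c("WT", 1 - e), c("R2", e)) else list(c(al, 1))
        }
        for (ca in conv(combos$a[k])) {
          for (cb in conv(combos$b[k])) {
            pr <- pr0 * as.numeric(ca[2]) * as.numeric(cb[2])
            pair <- sort(c(ca[1], cb[1]))
            child <- if (pair[1] == pair[2]) paste(pair[1], pair[2], sep = "/") else {
              # canonical order: DR first, then WT, then R2
              ord <- c(DR = 1, WT = 2, R2 = 3)
              paste(pair[order(ord[pair])], collapse = "/")
            }
            child <- sub("^WT/DR$", "DR/WT", child)
            child <- sub("^R2/WT$", "WT/R2", child)
            child <- sub("^R2/DR$", "DR/R2", child)
            new_mal[child] <- new_mal[child] + pr * p_male
            pf <- pr * (1 - p_male)
            child_has_dr <- "DR" %in% c(ca[1], cb[1])
            if (p$paternal_deposition > 0 && has_dr[oracle_genotypes == fg] &&
                child_has_dr) {
              new_dep[child] <- new_dep[child] + pf * p$paternal_deposition
              new_fem[child] <- new_fem[child] + pf * (1 - p$paternal_deposition)
            } else {
              new_fem[child] <- new_fem[child] + pf
            }
          }
        }
      }
    }
  }
  tot <- sum(new_fem) + sum(new_dep) + sum(new_mal)
  list(fem = new_fem / tot, dep = new_dep / tot, mal = new_mal / tot)
}

# run the oracle recursion from a heterozygote release; returns per-
# generation drive allele frequency and genetic load
oracle_recursion <- function(params, generations, release = 0.25) {
  fem <- dep <- mal <- stats::setNames(numeric(6), oracle_genotypes)
  fem["DR/WT"] <- release / 2
  mal["DR/WT"] <- release / 2
  fem["WT/WT"] <- 0.5 - release / 2
  mal["WT/WT"] <- 0.5 - release / 2
  has_wt <- vapply(oracle_genotypes, function(g) "WT" %in% oracle_split(g), logical(1))
  is_het <- oracle_genotypes == "DR/WT"
  w_mom <- ifelse(is_het, 1 - params$somatic_cost_female, 1)
  w_dad <- ifelse(is_het, 1 - params$somatic_cost_male, 1)
  dr_count <- function(g) sum(oracle_split(g) == "DR")
  drn <- vapply(oracle_genotypes, dr_count, numeric(1))
  out <- data.frame(generation = 0:generations, dr = NA_real_, load = NA_real_)
  for (t in 0:generations) {
    mass <- fem + dep + mal
    out$dr[t + 1] <- sum(drn * mass) / 2
    ewf <- sum(mal * w_dad) / sum(mal)
    out$load[t + 1] <- 1 - 2 * sum(fem * has_wt * w_mom) * ewf
    if (t < generations) {
      st <- oracle_recursion_step(fem, dep, mal, params)
      fem <- st$fem
      dep <- st$dep
      mal <- st$mal
    }
  }
  out
}

# ---- misc helpers --------------------------------------------------------
drive_names8 <- c("zpg", "zpg2", "zpgX", "zpg2X", "nos", "nosF", "nosF2",
                  "nosF3")

expect_within_se <- function(est, expected, se, k = 3) {
  expect_lt(abs(est - expected), k * se + 1e-12)
}
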