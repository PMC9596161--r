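preset_names <- c(drive_names8, "wildtype")

all_genotypes <- list(
  c("WT", "WT"), c("DR", "WT"), c("WT", "R2"),
  c("DR", "DR"), c("DR", "R2"), c("R2", "R2")
)

test_that("shipped presets carry the published drive characteristics", {
  tab <- drive_presets()
  expect_setequal(tab$drive, preset_names)
  zpg <- drive_params("zpg")
  expect_equal(zpg$drive_conversion_female, 0.99)
  expect_equal(zpg$drive_conversion_male, 0.96)
  expect_equal(zpg$germline_resistance_female, 0.01)
  expect_equal(zpg$germline_resistance_male, 0.02)
  expect_equal(zpg$embryo_resistance_maternal, 0.08)
  expect_equal(zpg$paternal_deposition, 0.69)
  expect_equal(zpg$somatic_cost_female, 0.3)
  nos <- drive_params("nos")
  expect_equal(nos$drive_conversion_male, 0.98)
  expect_equal(nos$embryo_resistance_maternal, 0.14)
  expect_equal(nos$somatic_cost_female, 0.45)
  expect_equal(nos$somatic_cost_male, 0.45)
  expect_equal(drive_params("zpgX")$x_shredding, 0.93)
  expect_equal(drive_params("nosF3")$somatic_cost_female, 0)
  # no functional-resistance state exists anywhere in the allele alphabet
  expect_error(genotype("r1", "WT"), "alleles must be")
  expect_error(drive_params("zpg", drive_conversion_female = 1.2), "0, 1")
})

test_that("gamete distributions match the exact enumeration oracle", {
  for (d in preset_names) {
    p <- drive_params(d)
    for (g in all_genotypes) {
      for (sex in c("female", "male")) {
        got <- gamete_distribution(genotype(g[1], g[2], sex), p)
        res <- if (sex == "female") p$germline_resistance_female else
          p$germline_resistance_male
        conv <- if (sex == "female") p$drive_conversion_female else
          p$drive_conversion_male
        want <- oracle_gametes(g[1], g[2], res, conv)
        expect_equal(got, want, tolerance = 1e-14)
        expect_equal(sum(got), 1, tolerance = 1e-12)
      }
    }
  }
  # frozen worked examples from the enumeration oracle
  expect_equal(
    gamete_distribution(genotype("DR", "WT", "female"), "zpg"),
    c(WT = 0.00495, DR = 0.99005, R2 = 0.005)
  )
  expect_equal(
    gamete_distribution(genotype("DR", "WT", "male"), "zpg"),
    c(WT = 0.0196, DR = 0.9704, R2 = 0.01)
  )
  expect_equal(gamete_distribution(genotype("DR", "R2", "female"), "zpg"),
               c(WT = 0, DR = 0.5, R2 = 0.5))
  expect_equal(gamete_distribution(genotype("WT", "WT", "male"), "nos"),
               c(WT = 1, DR = 0, R2 = 0))
})

test_that("drive heterozygote transmission is 0.5 (1 + total conversion)", {
  set.seed(11)
  n <- 1e5
  for (d in c("zpg", "nosF3")) {
    p <- drive_params(d)
    kids <- drivesim:::.gam_draw(rep(0L, n), rep(1L, n), TRUE, p)
    c_total <- (1 - p$germline_resistance_female) * p$drive_conversion_female
    expected <- 0.5 * (1 + c_total)
    se <- sqrt(expected * (1 - expected) / n)
    expect_within_se(mean(kids == 1L), expected, se)
  }
  # all-zero parameters: Mendelian segregation
  p0 <- drive_params("wildtype")
  kids <- drivesim:::.gam_draw(rep(0L, 1e5), rep(1L, 1e5), FALSE, p0)
  expect_within_se(mean(kids == 1L), 0.5, sqrt(0.25 / 1e5))
  expect_true(all(kids %in% c(0L, 1L)))  # never an allele outside the pair
})

test_that("X-shredding biases offspring sex without touching counts", {
  drive_dad <- genotype("DR", "WT", "male")
  wt_dad <- genotype("WT", "WT", "male")
  expect_equal(p_male_offspring(drive_dad, "zpg"), 0.5)      # s = 0
  expect_equal(p_male_offspring(wt_dad, "zpgX"), 0.5)        # no drive
  expect_equal(p_male_offspring(drive_dad, "zpgX"), 1 / 1.07)
  expect_equal(p_male_offspring(drive_dad, drive_params("zpgX", x_shredding = 1)), 1)
  set.seed(12)
  sexes <- offspring_sex(drive_dad, "zpgX", n = 1e5)
  expect_length(sexes, 1e5)
  expect_within_se(mean(sexes == "male"), 1 / 1.07,
                   sqrt((1 / 1.07) * (1 - 1 / 1.07) / 1e5))
})

test_that("embryo effects convert maternal-background WT alleles and
           deposition sterilises drive-carrying daughters", {
  set.seed(13)
  wt_child <- genotype("WT", "WT", "female")
  mom_wt <- genotype("WT", "WT", "female")
  mom_dr <- genotype("DR", "WT", "female")
  dad_wt <- genotype("WT", "WT", "male")
  dad_dr <- genotype("DR", "WT", "male")
  # wild-type mother: child untouched
  expect_identical(apply_embryo_effects(wt_child, mom_wt, dad_wt, "zpg"),
                   wt_child)
  # drive mother, zpg rate 0.08: P(WT/WT survives unconverted) = 0.92^2
  n <- 4e4
  surv <- replicate(n, {
    ch <- apply_embryo_effects(wt_child, mom_dr, dad_wt, "zpg")
    ch$allele_a == "WT" && ch$allele_b == "WT"
  })
  expect_within_se(mean(surv), 0.8464, sqrt(0.8464 * 0.1536 / n))
  # paternal deposition: drive-carrying daughter of a zpg drive father
  dr_daughter <- genotype("DR", "WT", "female")
  dep <- replicate(n / 4, {
    apply_embryo_effects(dr_daughter, mom_wt, dad_dr, "zpg")$deposition_sterile
  })
  expect_within_se(mean(dep), 0.69, sqrt(0.69 * 0.31 / (n / 4)))
  # a daughter without a drive allele escapes deposition, as does any
  # daughter under the no-deposition interpretation (zpg2)
  r2_daughter <- genotype("WT", "R2", "female")
  expect_false(any(replicate(200, {
    apply_embryo_effects(r2_daughter, mom_wt, dad_dr, "zpg")$deposition_sterile
  })))
  expect_false(any(replicate(200, {
    apply_embryo_effects(dr_daughter, mom_wt, dad_dr, "zpg2")$deposition_sterile
  })))
})

test_that("female fertility requires a wild-type allele and no deposition", {
  expect_true(is_fertile_female(genotype("WT", "WT", "female")))
  expect_true(is_fertile_female(genotype("DR", "WT", "female")))
  expect_true(is_fertile_female(genotype("WT", "R2", "female")))
  expect_false(is_fertile_female(genotype("DR", "DR", "female")))
  expect_false(is_fertile_female(genotype("DR", "R2", "female")))
  expect_false(is_fertile_female(genotype("R2", "R2", "female")))
  expect_false(is_fertile_female(genotype("DR", "WT", "female",
                                          deposition_sterile = TRUE)))
  expect_error(is_fertile_female(genotype("WT", "WT", "male")), "male")
})

test_that("somatic fitness costs act on DR/WT heterozygotes only", {
  het_f <- genotype("DR", "WT", "female")
  het_m <- genotype("DR", "WT", "male")
  wt_f <- genotype("WT", "WT", "female")
  wt_m <- genotype("WT", "WT", "male")
  expect_equal(fecundity_multiplier(wt_f, wt_m, "nos"), 1)
  expect_equal(fecundity_multiplier(het_f, wt_m, "nos"), 0.55)
  expect_equal(fecundity_multiplier(het_f, het_m, "nos"), 0.3025)
  expect_equal(fecundity_multiplier(het_f, het_m, "nosF3"), 1)
  expect_equal(fecundity_multiplier(het_f, het_m, "nosF"), 0.55)
  # homozygous males carry no somatic cost
  expect_equal(fecundity_multiplier(wt_f, genotype("DR", "DR", "male"), "nos"), 1)
})
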