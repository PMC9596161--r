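# Allele coding used throughout the package:
#   0 = WT (wild-type), 1 = DR (drive), 2 = R2 (nonfunctional resistance).
# Only r2-type resistance exists in this model; function-preserving r1
# alleles are deliberately absent.
.allele_levels <- c("WT", "DR", "R2")

.allele_code <- function(x) {
  i <- match(x, .allele_levels)
  if (anyNA(i)) stop("alleles must be one of ", paste(.allele_levels, collapse = ", "),
                     call. = FALSE)
  i - 1L
}

.allele_name <- function(code) .allele_levels[code + 1L]

#' Construct a drive-locus genotype
#'
#' A genotype is an unordered pair of alleles at the drive locus (WT, DR or
#' R2), a sex, and a flag marking sterility caused by paternally deposited
#' Cas9. The flag is mosaic somatic damage, so it never alters the
#' carrier's own germline drive activity, and it can only be set on
#' females.
#'
#' @param allele_a,allele_b `"WT"`, `"DR"` or `"R2"`.
#' @param sex `"female"` or `"male"`.
#' @param deposition_sterile Logical; only allowed for females.
#' @return A `genotype` object.
#' @export
#' @examples
#' genotype("DR", "WT", "female")
genotype <- function(allele_a, allele_b, sex = c("female", "male"),
                     deposition_sterile = FALSE) {
  sex <- match.arg(sex)
  a <- .allele_code(allele_a)
  b <- .allele_code(allele_b)
  if (deposition_sterile && sex != "female") {
    stop("deposition_sterile can only be TRUE for females", call. = FALSE)
  }
  structure(
    list(allele_a = .allele_name(min(a, b)), allele_b = .allele_name(max(a, b)),
         sex = sex, deposition_sterile = isTRUE(deposition_sterile)),
    class = "genotype"
  )
}

#' @export
print.genotype <- function(x, ...) {
  cat(sprintf("<genotype %s/%s %s%s>\n", x$allele_a, x$allele_b, x$sex,
              if (x$deposition_sterile) " (deposition-sterile)" else ""))
  invisible(x)
}

.has_drive <- function(g) g$allele_a == "DR" || g$allele_b == "DR"
.has_wt <- function(g) g$allele_a == "WT" || g$allele_b == "WT"
.is_het_dr_wt <- function(g) {
  s <- sort(c(g$allele_a, g$allele_b))
  s[1] == "DR" && s[2] == "WT"
}

#' Germline gamete distribution of a parent
#'
#' Drive activity in the germline modifies wild-type alleles only in
#' DR/WT heterozygotes, sequentially and per gametocyte: a wild-type
#' allele first becomes an R2 resistance allele with the sex-specific
#' germline resistance rate; if it stays wild-type it is converted to a
#' drive allele with the sex-specific conversion rate. A gamete then
#' carries one of the two post-modification alleles with equal
#' probability.
#'
#' @param parent A [genotype()].
#' @param params A [drive_params()] object or preset name.
#' @return Named numeric vector of probabilities over `WT`, `DR`, `R2`,
#'   summing to one.
#' @export
#' @examples
#' gamete_distribution(genotype("DR", "WT", "female"), "zpg")
gamete_distribution <- function(parent, params) {
  params <- .as_params(params)
  res <- if (parent$sex == "female") params$germline_resistance_female else
    params$germline_resistance_male
  conv <- if (parent$sex == "female") params$drive_conversion_female else
    params$drive_conversion_male
  p <- c(WT = 0, DR = 0, R2 = 0)
  het <- .is_het_dr_wt(parent)
  for (al in c(parent$allele_a, parent$allele_b)) {
    if (al == "WT" && het) {
      p["R2"] <- p["R2"] + 0.5 * res
      p["DR"] <- p["DR"] + 0.5 * (1 - res) * conv
      p["WT"] <- p["WT"] + 0.5 * (1 - res) * (1 - conv)
    } else {
      p[al] <- p[al] + 0.5
    }
  }
  p
}

#' Probability that an offspring is male
#'
#' An X-shredder in a drive-carrying father destroys a fraction `s` of
#' X-bearing gametes, so the offspring is male with probability
#' `1 / (2 - s)`. Shredding biases the sex ratio only; it never reduces
#' the offspring count.
#'
#' @inheritParams gamete_distribution
#' @param father The father's [genotype()].
#' @return A single probability.
#' @export
p_male_offspring <- function(father, params) {
  params <- .as_params(params)
  s <- params$x_shredding
  if (s > 0 && .has_drive(father)) 1 / (2 - s) else 0.5
}

#' Draw offspring sexes given a father
#'
#' @inheritParams p_male_offspring
#' @param n Number of offspring to draw.
#' @return Character vector of `"female"` / `"male"`.
#' @export
offspring_sex <- function(father, params, n = 1) {
  ifelse(runif(n) < p_male_offspring(father, params), "male", "female")
}

#' Apply embryo-stage drive effects to an offspring
#'
#' Two maternal/paternal carry-over effects act on the early embryo:
#' (i) if the mother carries a drive allele, each wild-type allele in the
#' child is independently converted to R2 with the maternal embryo
#' resistance rate, whether or not the child inherited the drive; (ii) if
#' the father carries a drive allele and the drive deposits Cas9
#' paternally, a drive-carrying daughter is rendered sterile with the
#' paternal deposition rate. Deposition is mosaic: the daughter's own
#' germline drive activity is untouched.
#'
#' @param child,mother,father [genotype()] objects; the child's alleles
#'   must already be drawn from the parental gametes.
#' @inheritParams gamete_distribution
#' @return The child's genotype after embryo effects.
#' @export
apply_embryo_effects <- function(child, mother, father, params) {
  params <- .as_params(params)
  a <- .allele_code(child$allele_a)
  b <- .allele_code(child$allele_b)
  e <- params$embryo_resistance_maternal
  if (e > 0 && .has_drive(mother)) {
    if (a == 0L && runif(1) < e) a <- 2L
    if (b == 0L && runif(1) < e) b <- 2L
  }
  dep <- child$deposition_sterile
  pd <- params$paternal_deposition
  if (pd > 0 && .has_drive(father) && child$sex == "female" &&
      (a == 1L || b == 1L) && runif(1) < pd) {
    dep <- TRUE
  }
  genotype(.allele_name(a), .allele_name(b), child$sex, dep)
}

#' Is a female fertile?
#'
#' The drive target is a haplosufficient female-fertility gene, so any
#' female lacking a wild-type allele is sterile, as is any female
#' sterilised by paternal Cas9 deposition.
#'
#' @param g A female [genotype()].
#' @return Logical.
#' @export
is_fertile_female <- function(g) {
  if (g$sex != "female") stop("is_fertile_female() called on a male", call. = FALSE)
  .has_wt(g) && !g$deposition_sterile
}

#' Fecundity multiplier of a mating pair
#'
#' Somatic (leaky) Cas9 expression reduces fecundity in DR/WT
#' heterozygotes only: the mother's factor is `1 - somatic_cost_female`,
#' and for drives with a male somatic cost the pair's fecundity is also
#' reduced by `1 - somatic_cost_male` when the father is a DR/WT
#' heterozygote.
#'
#' @param mother,father [genotype()] objects.
#' @inheritParams gamete_distribution
#' @return A fraction in \[0, 1\].
#' @export
fecundity_multiplier <- function(mother, father, params) {
  params <- .as_params(params)
  wm <- if (.is_het_dr_wt(mother)) 1 - params$somatic_cost_female else 1
  wf <- if (.is_het_dr_wt(father)) 1 - params$somatic_cost_male else 1
  wm * wf
}

# ---- vectorised internals ------------------------------------------------
# Population columns are raw vectors; alleles use the 0/1/2 integer codes.

# draw one gamete per row; A, B = parent allele codes replicated per
# offspring, all from parents of one sex
.gam_draw <- function(A, B, female_parent, params) {
  m <- length(A)
  if (!m) return(integer())
  res <- if (female_parent) params$germline_resistance_female else
    params$germline_resistance_male
  conv <- if (female_parent) params$drive_conversion_female else
    params$drive_conversion_male
  pick <- ifelse(runif(m) < 0.5, A, B)
  het <- pmin(A, B) == 0L & pmax(A, B) == 1L
  idx <- which(het & pick == 0L)
  if (length(idx)) {
    toR <- runif(length(idx)) < res
    pick[idx[toR]] <- 2L
    rem <- idx[!toR]
    if (length(rem)) {
      hit <- runif(length(rem)) < conv
      pick[rem[hit]] <- 1L
    }
  }
  pick
}

# embryo conversion + sex + paternal deposition for a cohort.
# ma, mb: mother's alleles per child; fa, fb: father's alleles per child.
.make_children <- function(ma, mb, fa, fb, params) {
  m <- length(ma)
  if (!m) {
    return(list(a = integer(), b = integer(), female = logical(), dep = logical()))
  }
  a <- .gam_draw(ma, mb, TRUE, params)
  b <- .gam_draw(fa, fb, FALSE, params)
  e <- params$embryo_resistance_maternal
  if (e > 0) {
    mom_d <- ma == 1L | mb == 1L
    i <- which(mom_d & a == 0L)
    if (length(i)) a[i[runif(length(i)) < e]] <- 2L
    j <- which(mom_d & b == 0L)
    if (length(j)) b[j[runif(length(j)) < e]] <- 2L
  }
  dad_d <- fa == 1L | fb == 1L
  s <- params$x_shredding
  p_male <- ifelse(dad_d & s > 0, 1 / (2 - s), 0.5)
  female <- runif(m) >= p_male
  dep <- rep(FALSE, m)
  pd <- params$paternal_deposition
  if (pd > 0) {
    k <- which(female & dad_d & (a == 1L | b == 1L))
    if (length(k)) dep[k[runif(length(k)) < pd]] <- TRUE
  }
  list(a = a, b = b, female = female, dep = dep)
}

# vectorised fertility / fitness helpers
.fertile_female <- function(pop) {
  pop$female & (pop$a == 0L | pop$b == 0L) & !pop$dep
}

.w_female <- function(a, b, params) {
  ifelse(pmin(a, b) == 0L & pmax(a, b) == 1L, 1 - params$somatic_cost_female, 1)
}

.w_male <- function(a, b, params) {
  ifelse(pmin(a, b) == 0L & pmax(a, b) == 1L, 1 - params$somatic_cost_male, 1)
}
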