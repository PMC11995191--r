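# Permutation tests via pseudo-family reassembly.
#
# At each component locus of a SNP-set the (mother, father, child) genotype
# triple is kept intact; pseudo-families are then formed by reassembling
# those per-locus fragments across families. Permuting loci in independent
# blocks preserves every per-locus marginal (the triad genotype multiset at
# each locus is untouched) while destroying cross-block joint structure:
#   - epistasis test: one block per chromosome (maternal and child
#     components of the same chromosome are non-separable, as if linked);
#   - maternal-fetal test: two blocks, all maternal vs all child components.
# Because the nominating search and the test share the data, the resulting
# tail probability is reported as an "h-value": evidence, not a strictly
# valid p-value.

#' Permutation-unit partition for a SNP-set
#'
#' @param cohort A [triad_cohort()].
#' @param set A [snp_set()].
#' @param test `"epistasis"` (units = chromosomes) or `"maternal-fetal"`
#'   (units = origins; requires both origins present and no chromosome shared
#'   across origins).
#' @return List of integer vectors of component indices (positions in the
#'   canonical ordering of `set`), partitioning the set.
#' @export
permutation_units <- function(cohort, set, test = c("epistasis", "maternal-fetal")) {
  test <- match.arg(test)
  set <- as_snp_set(set)
  chrom <- cohort$loci$chromosome[set$locus_index]
  if (test == "epistasis") {
    return(unname(split(seq_len(nrow(set)), chrom)))
  }
  if (length(unique(set$origin)) < 2)
    abort_validation("maternal-fetal test undefined: SNP-set has a single origin")
  shared <- intersect(chrom[set$origin == "maternal"],
                      chrom[set$origin == "child"])
  if (length(shared))
    abort_validation(
      "maternal-fetal test unavailable: maternal and child components share ",
      "chromosome ", shared[1], "; permuting the two origin blocks ",
      "independently would break the within-family linkage there")
  unname(split(seq_len(nrow(set)), set$origin == "maternal"))
}

#' Reassemble pseudo-families for a SNP-set
#'
#' Draws one uniform permutation of family indices per unit and applies it
#' jointly to the mother, father and child genotype columns of that unit's
#' loci. Within a unit the triad structure is intact, and every locus keeps
#' its observed multiset of genotype triples; only cross-unit joint structure
#' is randomized. Uses the current RNG state.
#'
#' @param cohort A [triad_cohort()].
#' @param set A [snp_set()].
#' @param units Partition from [permutation_units()].
#' @return A [triad_cohort()] with permuted rows at the set's loci.
#' @export
reassemble_pseudo_families <- function(cohort, set, units) {
  set <- as_snp_set(set)
  out <- cohort
  n <- n_families(cohort)
  for (u in units) {
    loci <- unique(set$locus_index[u])
    perm <- sample.int(n)
    out$mothers[, loci] <- cohort$mothers[perm, loci]
    out$fathers[, loci] <- cohort$fathers[perm, loci]
    out$children[, loci] <- cohort$children[perm, loci]
  }
  out
}

# shared permutation-test engine on precomputed base matrices; the full
# recoding pipeline is re-run inside every replicate so the null reflects
# the data-adaptive scoring
permutation_test <- function(cohort, set, units, B, seed, test_label) {
  set <- as_snp_set(set)
  base <- component_base(cohort, set$locus_index, set$origin)
  observed <- fitness_from_base(base$add, base$rec2, base$rec0, base$block)
  n <- nrow(base$add)

  old <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  null_scores <- numeric(B)
  add <- base$add; rec2 <- base$rec2; rec0 <- base$rec0
  for (b in seq_len(B)) {
    pa <- add; p2 <- rec2; p0 <- rec0
    for (u in units) {
      perm <- sample.int(n)
      pa[, u] <- add[perm, u]
      p2[, u] <- rec2[perm, u]
      p0[, u] <- rec0[perm, u]
    }
    null_scores[b] <- tryCatch(
      fitness_from_base(pa, p2, p0, base$block),
      error = function(e) 0)
  }
  h <- (1 + sum(null_scores >= observed)) / (B + 1)
  structure(
    list(observed_score = observed, null_scores = null_scores, h_value = h,
         B = B, units = units, seed = seed, test = test_label, set = set),
    class = "permutation_result"
  )
}

#' Epistasis h-value for a SNP-set
#'
#' Compares the observed fitness score to scores from `B` pseudo-family
#' reassemblies whose permutation units are the chromosomes represented in
#' the set. The reassembly preserves each unlinked component's marginal
#' transmission distortion but destroys super-multiplicative joint effects,
#' so a small h-value is evidence of epistasis. When all components lie on
#' one chromosome the reassembly is a pure family relabeling, the score is
#' unchanged by construction, and `h = 1` is returned with a warning.
#'
#' h is computed with the add-one convention `(1 + #\{null >= obs\})/(B + 1)`,
#' so `1/(B+1) <= h <= 1`; ties count toward the numerator.
#'
#' @param cohort A [triad_cohort()].
#' @param set A [snp_set()].
#' @param B Number of permutation replicates (default 10000).
#' @param seed RNG seed.
#' @return Object of class `permutation_result`: `observed_score`,
#'   `null_scores`, `h_value`, `B`, `units`, `seed`, `test`, `set`.
#' @export
epistasis_h_value <- function(cohort, set, B = 10000L, seed = 1L) {
  set <- as_snp_set(set)
  if (B < 1) abort_validation("B must be >= 1")
  units <- permutation_units(cohort, set, "epistasis")
  if (length(units) == 1) {
    warning("all components are on one chromosome: the reassembly only ",
            "relabels families, so the epistasis test is degenerate (h = 1)",
            call. = FALSE)
    base <- component_base(cohort, set$locus_index, set$origin)
    observed <- fitness_from_base(base$add, base$rec2, base$rec0, base$block)
    return(structure(
      list(observed_score = observed, null_scores = rep(observed, B),
           h_value = 1, B = B, units = units, seed = seed,
           test = "epistasis", set = set),
      class = "permutation_result"))
  }
  permutation_test(cohort, set, units, B, seed, "epistasis")
}

#' Maternal-fetal interaction h-value for a SNP-set
#'
#' Permutes all maternal components as one unit and all child components as
#' another. Marginal effects and epistasis *within* each origin block are
#' preserved; any joint maternal-fetal structure is destroyed, so a small
#' h-value specifically supports joint involvement of maternal and child
#' SNPs. Requires at least one component of each origin and no chromosome
#' shared between the origins (otherwise reassembly would generate
#' Mendelian-impossible pseudo-families).
#'
#' @inheritParams epistasis_h_value
#' @return Object of class `permutation_result`.
#' @export
maternal_fetal_h_value <- function(cohort, set, B = 10000L, seed = 1L) {
  set <- as_snp_set(set)
  if (B < 1) abort_validation("B must be >= 1")
  units <- permutation_units(cohort, set, "maternal-fetal")
  permutation_test(cohort, set, units, B, seed, "maternal-fetal")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation_result (", x$test, "): observed S = ",
      format(x$observed_score, digits = 6), ", B = ", x$B,
      ", h = ", format(x$h_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Joint risk-genotype carrier counts
#'
#' Counts families in which the "case side" (child at every child-origin
#' component, mother at every maternal-origin component) carries the
#' provisional risk genotype at all components, versus the "control side"
#' (complement sibling and father). Carriage means at least one risk allele,
#' or exactly two under a recessive flag; risk-allele orientation and
#' recessive flags are taken from `fitness_result`. A large case-side excess
#' accompanies genuine joint effects.
#'
#' @param cohort A [triad_cohort()].
#' @param set A [snp_set()].
#' @param fitness_result Result of [score_fitness()] for the same set.
#' @return Named integer vector `c(case_side, control_side)`.
#' @export
count_joint_carriers <- function(cohort, set, fitness_result) {
  set <- as_snp_set(set)
  stopifnot(inherits(fitness_result, "fitness_result"))
  flips <- fitness_result$risk_allele_flips
  rec <- fitness_result$recessive_flags
  ok <- fitness_result$informative_mask

  carries <- function(g, j) {
    # risk-allele count is g when unflipped, 2-g when flipped
    r <- if (flips[j]) 2 - g else g
    if (rec[j]) r == 2 else r >= 1
  }
  n <- n_families(cohort)
  case_all <- rep(TRUE, n)
  ctrl_all <- rep(TRUE, n)
  for (j in seq_len(nrow(set))) {
    li <- set$locus_index[j]
    m <- cohort$mothers[, li]
    f <- cohort$fathers[, li]
    if (set$origin[j] == "child") {
      k <- cohort$children[, li]
      case_g <- k
      ctrl_g <- m + f - k
    } else {
      case_g <- m
      ctrl_g <- f
    }
    case_all <- case_all & carries(case_g, j)
    ctrl_all <- ctrl_all & carries(ctrl_g, j)
  }
  c(case_side = sum(case_all[ok], na.rm = TRUE),
    control_side = sum(ctrl_all[ok], na.rm = TRUE))
}
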