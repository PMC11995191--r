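# Simulator for case-parent triad cohorts.
#
# Parents are drawn i.i.d. from one haplotype population, so mating symmetry
# holds by construction; children receive one Mendelian-transmitted allele
# (or recombined haplotype) per parent; a child is affected with probability
#   expit( logit(baseline) + sum_sets log(RR) * I_set
#                          + sum_singletons log(RR) * I(carrier) ),
# where I_set = 1 iff the child carries >= 1 copy of the designated risk
# allele at every child-origin member AND the mother does at every
# maternal-origin member (dominant coding). Families are rejection-sampled
# until n_families affected children accumulate.

#' Specify a simulation scenario
#'
#' @param n_chromosomes Number of chromosomes (default 4).
#' @param loci_per_chromosome Loci per chromosome (default 1250, i.e. 5000
#'   loci on the default 4 chromosomes).
#' @param maf_range Uniform sampling bounds for per-locus designated-allele
#'   frequency (default `c(0.05, 0.5)`, must stay above 0.01).
#' @param ld_rho Adjacent-locus AR(1) copula correlation of haplotype
#'   alleles; 0 (default) makes loci independent. Capped at 0.89 so pairwise
#'   R^2 stays below 0.8.
#' @param baseline_risk Disease probability with no risk genotype
#'   (default 0.01).
#' @param epistatic_sets List of `list(members = data.frame(locus, origin),
#'   relative_risk)`: each set multiplies the odds by `relative_risk` when
#'   the joint dominant carrier indicator is 1. Default relative risk for a
#'   strong epistatic set is 10.
#' @param singleton_effects List of `list(locus, origin, relative_risk)`:
#'   independent (non-epistatic) dominant effects, typical relative risk
#'   near 2.
#' @param effect_maf Allele frequency assigned (not sampled) to every effect
#'   locus, ensuring non-trivial carriage (default 0.25).
#' @param n_families Number of affected triads to accumulate (default 1000).
#' @param seed RNG seed.
#' @return A validated list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_chromosomes = 4L, loci_per_chromosome = 1250L,
                         maf_range = c(0.05, 0.5), ld_rho = 0,
                         baseline_risk = 0.01, epistatic_sets = list(),
                         singleton_effects = list(), effect_maf = 0.25,
                         n_families = 1000L, seed = 1L) {
  scn <- list(n_chromosomes = as.integer(n_chromosomes),
              loci_per_chromosome = as.integer(loci_per_chromosome),
              maf_range = maf_range, ld_rho = ld_rho,
              baseline_risk = baseline_risk, epistatic_sets = epistatic_sets,
              singleton_effects = singleton_effects, effect_maf = effect_maf,
              n_families = as.integer(n_families), seed = as.integer(seed))
  if (scn$n_chromosomes < 1 || scn$loci_per_chromosome < 1)
    abort_validation("need at least one chromosome and one locus")
  if (length(maf_range) != 2 || maf_range[1] <= 0.01 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    abort_validation("maf_range must satisfy 0.01 < low <= high <= 0.5")
  if (ld_rho < 0 || ld_rho > 0.89)
    abort_validation("ld_rho must be in [0, 0.89] (keeps pairwise R^2 < 0.8)")
  if (baseline_risk <= 0 || baseline_risk >= 1)
    abort_validation("baseline_risk must be in (0, 1)")
  if (baseline_risk < 1e-6)
    abort_validation("baseline_risk below 1e-6: expected acceptance too low")
  if (effect_maf <= 0.01 || effect_maf > 0.5)
    abort_validation("effect_maf must be in (0.01, 0.5]")
  L <- scn$n_chromosomes * scn$loci_per_chromosome
  eff <- scenario_effect_table(scn)
  if (nrow(eff)) {
    if (any(eff$locus < 1 | eff$locus > L))
      abort_validation("effect locus index out of range")
    if (any(eff$relative_risk <= 1))
      abort_validation("relative risks must exceed 1")
    if (anyDuplicated(eff$locus))
      abort_validation("effect loci must be distinct across all effects")
    if (!all(eff$origin %in% c("child", "maternal")))
      abort_validation("effect origin must be 'child' or 'maternal'")
  }
  class(scn) <- "sim_scenario"
  scn
}

# flat table of all effect loci: locus, origin, relative_risk, effect id
scenario_effect_table <- function(scn) {
  rows <- list()
  for (i in seq_along(scn$epistatic_sets)) {
    s <- scn$epistatic_sets[[i]]
    m <- as.data.frame(s$members, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      locus = as.integer(m$locus), origin = as.character(m$origin),
      relative_risk = s$relative_risk, effect = paste0("set", i),
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(scn$singleton_effects)) {
    s <- scn$singleton_effects[[i]]
    rows[[length(rows) + 1]] <- data.frame(
      locus = as.integer(s$locus), origin = as.character(s$origin),
      relative_risk = s$relative_risk, effect = paste0("single", i),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(locus = integer(0), origin = character(0),
                      relative_risk = numeric(0), effect = character(0)))
  do.call(rbind, rows)
}

# disease probability for a batch given effect-locus genotype columns
# (mother and child matrices restricted to the effect loci, in effect-table
# order)
disease_prob <- function(scn, eff, mother_eff, child_eff) {
  eta <- rep(stats::qlogis(scn$baseline_risk), nrow(mother_eff))
  carrier <- function(r) {
    g <- if (eff$origin[r] == "child") child_eff[, r] else mother_eff[, r]
    g >= 1
  }
  for (i in seq_along(scn$epistatic_sets)) {
    rows <- which(eff$effect == paste0("set", i))
    ind <- rep(TRUE, nrow(mother_eff))
    for (r in rows) ind <- ind & carrier(r)
    eta <- eta + log(scn$epistatic_sets[[i]]$relative_risk) * ind
  }
  for (i in seq_along(scn$singleton_effects)) {
    r <- which(eff$effect == paste0("single", i))
    eta <- eta + log(scn$singleton_effects[[i]]$relative_risk) * carrier(r)
  }
  stats::plogis(eta)
}

# draw a batch of triad genotypes at an arbitrary set of loci, independent
# loci (ld_rho = 0): parents Binomial(2, maf), child = one Mendelian allele
# from each parent
draw_triads_indep <- function(nb, maf) {
  L <- length(maf)
  pm <- matrix(stats::rbinom(nb * L, 2, rep(maf, each = nb)), nb, L)
  pf <- matrix(stats::rbinom(nb * L, 2, rep(maf, each = nb)), nb, L)
  kk <- matrix(stats::rbinom(nb * L, 1, pm / 2), nb, L) +
        matrix(stats::rbinom(nb * L, 1, pf / 2), nb, L)
  list(m = pm, f = pf, k = kk)
}

# AR(1)-copula haplotypes for one chromosome: nh haplotypes x L loci of 0/1
# alleles with latent adjacent correlation rho
draw_haplotypes <- function(nh, maf, rho) {
  L <- length(maf)
  z <- matrix(stats::rnorm(nh * L), nh, L)
  if (rho > 0 && L > 1) {
    for (j in 2:L) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
  }
  thr <- stats::qnorm(maf)
  (z < rep(thr, each = nh)) + 0L
}

# recombine a parent's two haplotypes into one transmitted haplotype:
# Poisson(1) crossovers at uniform positions, random starting phase
transmit_haplotype <- function(h1, h2) {
  L <- ncol(h1)
  n <- nrow(h1)
  out <- h1
  for (i in seq_len(n)) {
    nco <- stats::rpois(1, 1)
    cuts <- sort(ceiling(stats::runif(nco) * (L - 1)))
    phase <- sample(c(TRUE, FALSE), 1)
    seg <- rep(phase, L)
    if (length(cuts)) for (cut in cuts) seg[(cut + 1):L] <- !seg[cut + 1]
    out[i, ] <- ifelse(seg, h1[i, ], h2[i, ])
  }
  out
}

# full-genome triad batch under the haplotype model (used when ld_rho > 0)
draw_triads_haplo <- function(nb, maf, chrom, rho) {
  L <- length(maf)
  m <- f <- k <- matrix(0L, nb, L)
  for (ch in unique(chrom)) {
    cols <- which(chrom == ch)
    mh1 <- draw_haplotypes(nb, maf[cols], rho)
    mh2 <- draw_haplotypes(nb, maf[cols], rho)
    fh1 <- draw_haplotypes(nb, maf[cols], rho)
    fh2 <- draw_haplotypes(nb, maf[cols], rho)
    m[, cols] <- mh1 + mh2
    f[, cols] <- fh1 + fh2
    k[, cols] <- transmit_haplotype(mh1, mh2) + transmit_haplotype(fh1, fh2)
  }
  list(m = m, f = f, k = k)
}

#' Simulate a case-parent triad cohort
#'
#' Generates affected triads under the scenario's risk model (see
#' [sim_scenario()]). Parents are i.i.d. draws from one haplotype
#' population, so mating symmetry holds by construction, and every child
#' genotype is built from transmitted parental alleles, so all cohorts pass
#' Mendelian validation with zero warnings. With `ld_rho = 0` loci are
#' independent and an exact per-locus sampling path is used: the
#' rejection-sampling step draws genotypes only at the effect loci, and the
#' remaining loci are filled in for accepted families (valid because the
#' triad genotype distribution factorizes over independent loci). With
#' `ld_rho > 0` whole-genome haplotype batches are drawn with Poisson(1)
#' recombination per chromosome.
#'
#' @param scenario A [sim_scenario()].
#' @return List with `cohort` (a [triad_cohort()]), `truth` (effect table
#'   with per-family disease probabilities, acceptance statistics), and
#'   `candidates` (the full mirrored candidate list: every locus as both a
#'   maternal and a child candidate).
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  scn <- scenario
  old <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(scn$seed)

  L <- scn$n_chromosomes * scn$loci_per_chromosome
  chrom <- rep(paste0("chr", seq_len(scn$n_chromosomes)),
               each = scn$loci_per_chromosome)
  maf <- stats::runif(L, scn$maf_range[1], scn$maf_range[2])
  eff <- scenario_effect_table(scn)
  if (nrow(eff)) maf[eff$locus] <- scn$effect_maf

  n <- scn$n_families
  acc_m <- acc_f <- acc_k <- NULL
  acc_p <- numeric(0)
  drawn <- 0L
  accepted <- 0L
  max_draws <- max(5e6, 50 * n / scn$baseline_risk)

  if (scn$ld_rho == 0) {
    # rejection-sample at effect loci only
    eff_maf <- if (nrow(eff)) maf[eff$locus] else numeric(0)
    batch <- max(5000L, ceiling(2 * n / scn$baseline_risk / 10))
    while (length(acc_p) < n) {
      if (drawn > max_draws)
        stop("acceptance rate too low (", length(acc_p), "/", drawn,
             " after ", drawn, " draws); check baseline_risk", call. = FALSE)
      if (nrow(eff)) {
        tri <- draw_triads_indep(batch, eff_maf)
        p <- disease_prob(scn, eff, tri$m, tri$k)
      } else {
        tri <- list(m = matrix(0L, batch, 0), f = matrix(0L, batch, 0),
                    k = matrix(0L, batch, 0))
        p <- rep(scn$baseline_risk, batch)
      }
      aff <- stats::rbinom(batch, 1, p) == 1
      drawn <- drawn + batch
      accepted <- accepted + sum(aff)
      if (any(aff)) {
        acc_m <- rbind(acc_m, tri$m[aff, , drop = FALSE])
        acc_f <- rbind(acc_f, tri$f[aff, , drop = FALSE])
        acc_k <- rbind(acc_k, tri$k[aff, , drop = FALSE])
        acc_p <- c(acc_p, p[aff])
      }
    }
    keep <- seq_len(n)
    acc_m <- acc_m[keep, , drop = FALSE]
    acc_f <- acc_f[keep, , drop = FALSE]
    acc_k <- acc_k[keep, , drop = FALSE]
    acc_p <- acc_p[keep]
    # fill the non-effect loci for the accepted families
    mothers <- fathers <- children <- matrix(0L, n, L)
    rest <- setdiff(seq_len(L), eff$locus)
    if (length(rest)) {
      tri <- draw_triads_indep(n, maf[rest])
      mothers[, rest] <- tri$m
      fathers[, rest] <- tri$f
      children[, rest] <- tri$k
    }
    if (nrow(eff)) {
      mothers[, eff$locus] <- acc_m
      fathers[, eff$locus] <- acc_f
      children[, eff$locus] <- acc_k
    }
  } else {
    mothers <- fathers <- children <- matrix(0L, 0, L)
    batch <- max(500L, ceiling(2 * n * min(10, 1 / scn$baseline_risk) / 10))
    while (length(acc_p) < n) {
      if (drawn > max_draws)
        stop("acceptance rate too low; check baseline_risk", call. = FALSE)
      tri <- draw_triads_haplo(batch, maf, chrom, scn$ld_rho)
      p <- if (nrow(eff))
        disease_prob(scn, eff, tri$m[, eff$locus, drop = FALSE],
                     tri$k[, eff$locus, drop = FALSE])
      else rep(scn$baseline_risk, batch)
      aff <- stats::rbinom(batch, 1, p) == 1
      drawn <- drawn + batch
      accepted <- accepted + sum(aff)
      if (any(aff)) {
        mothers <- rbind(mothers, tri$m[aff, , drop = FALSE])
        fathers <- rbind(fathers, tri$f[aff, , drop = FALSE])
        children <- rbind(children, tri$k[aff, , drop = FALSE])
        acc_p <- c(acc_p, p[aff])
      }
    }
    mothers <- mothers[seq_len(n), , drop = FALSE]
    fathers <- fathers[seq_len(n), , drop = FALSE]
    children <- children[seq_len(n), , drop = FALSE]
    acc_p <- acc_p[seq_len(n)]
  }

  loci <- data.frame(
    locus_id = sprintf("snp%05d", seq_len(L)),
    chromosome = chrom,
    position = rep(seq_len(scn$loci_per_chromosome), scn$n_chromosomes) * 10000L,
    stringsAsFactors = FALSE
  )
  cohort <- triad_cohort(mothers, fathers, children, loci,
                         on_violation = "error")
  candidates <- make_candidates(
    cohort, rep(seq_len(L), each = 2), rep(c("child", "maternal"), L))
  truth <- list(
    effects = eff,
    maf = maf,
    risk_allele = "designated (1-coded) allele at every effect locus",
    disease_prob = acc_p,
    acceptance_rate = accepted / drawn,  # all acceptances, incl. overshoot
    n_drawn = drawn,
    scenario = scn
  )
  list(cohort = cohort, truth = truth, candidates = candidates)
}

#' Down-sample a mirrored candidate list around the true effect loci
#'
#' Builds a candidate list of `n_candidates` SNPs (`n_candidates / 2` loci,
#' each mirrored as a maternal and a child candidate): the effect loci are
#' always included, the remaining loci are sampled uniformly without
#' replacement from the rest of the cohort.
#'
#' @param cohort A [triad_cohort()].
#' @param n_candidates Even total number of candidate SNPs, at least twice
#'   the number of effect loci.
#' @param truth Truth object from [simulate_cohort()].
#' @param seed RNG seed.
#' @return Candidate data frame (columns `locus_index`, `origin`,
#'   `locus_id`).
#' @export
make_candidate_list <- function(cohort, n_candidates, truth, seed = 1L) {
  if (n_candidates %% 2 != 0) abort_validation("n_candidates must be even")
  eff_loci <- unique(truth$effects$locus)
  n_loci_needed <- n_candidates / 2
  if (n_loci_needed < length(eff_loci))
    abort_validation("n_candidates must be at least 2 x (number of effect loci)")
  if (n_loci_needed > n_loci(cohort))
    abort_validation("n_candidates exceeds twice the available loci")
  old <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  rest <- setdiff(seq_len(n_loci(cohort)), eff_loci)
  extra <- sample(rest, n_loci_needed - length(eff_loci))
  loci <- sort(c(eff_loci, extra))
  make_candidates(cohort, rep(loci, each = 2),
                  rep(c("child", "maternal"), length(loci)))
}
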