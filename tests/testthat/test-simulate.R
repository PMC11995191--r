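test_that("scenario validation catches inconsistent specifications", {
  expect_error(sim_scenario(maf_range = c(0.005, 0.5)), "maf_range")
  expect_error(sim_scenario(ld_rho = 0.95), "ld_rho")
  expect_error(sim_scenario(baseline_risk = 0), "baseline_risk")
  expect_error(sim_scenario(
    epistatic_sets = list(list(members = data.frame(locus = c(1, 2),
                                                    origin = "child"),
                               relative_risk = 0.9))), "relative risks")
  expect_error(sim_scenario(
    loci_per_chromosome = 5,
    epistatic_sets = list(list(members = data.frame(locus = c(1, 1),
                                                    origin = c("child",
                                                               "maternal")),
                               relative_risk = 5))), "distinct")
})

test_that("simulated cohorts are Mendelian-consistent by construction", {
  sim <- planted_mf_sim(1, n_families = 200, loci_per_chromosome = 10)
  expect_equal(attr(sim$cohort, "n_masked"), 0L)
  # the full mirrored candidate list covers every locus twice
  expect_equal(nrow(sim$candidates), 2 * n_loci(sim$cohort))
  # haplotype path (ld_rho > 0) also yields valid triads
  scn <- sim_scenario(n_chromosomes = 2, loci_per_chromosome = 20,
                      ld_rho = 0.5, baseline_risk = 0.3, n_families = 100,
                      seed = 3)
  sim2 <- simulate_cohort(scn)
  expect_equal(attr(sim2$cohort, "n_masked"), 0L)
  # adjacent loci are correlated but R^2 stays below the pruning cap
  g <- sim2$cohort$mothers
  r2 <- sapply(1:19, function(j) cor(g[, j], g[, j + 1])^2)
  expect_gt(mean(r2), 0.05)
  expect_lt(max(r2), 0.8)
})

test_that("the simulator is deterministic given the seed", {
  scn <- sim_scenario(loci_per_chromosome = 10, n_families = 50,
                      baseline_risk = 0.2, seed = 11)
  s1 <- simulate_cohort(scn)
  s2 <- simulate_cohort(scn)
  expect_identical(s1$cohort$children, s2$cohort$children)
  expect_identical(s1$truth$disease_prob, s2$truth$disease_prob)
  c1 <- make_candidate_list(s1$cohort, 10, s1$truth, seed = 5)
  c2 <- make_candidate_list(s1$cohort, 10, s1$truth, seed = 5)
  expect_identical(c1, c2)
})

test_that("with no effects the acceptance rate matches the baseline risk", {
  scn <- sim_scenario(loci_per_chromosome = 5, n_families = 800,
                      baseline_risk = 0.1, seed = 21)
  sim <- simulate_cohort(scn)
  # acceptance is binomial(drawn, 0.1); allow 4 SE around the baseline
  se <- sqrt(0.1 * 0.9 / sim$truth$n_drawn)
  expect_lt(abs(sim$truth$acceptance_rate - 0.1), 4 * se + 1e-3)
  # transmission to affected children is undistorted: among heterozygous
  # parents, the designated allele is transmitted about half the time
  m <- sim$cohort$mothers; f <- sim$cohort$fathers; k <- sim$cohort$children
  het_m <- m == 1
  # transmitted maternal allele = child minus paternal transmitted; recover
  # it from the complement: child allele from mother = k - (allele from f)
  # simpler: pool over loci where father is homozygous (transmission known)
  known <- het_m & (f != 1)
  trans <- (k - f / 2)[known]  # f/2 is the forced paternal allele
  expect_lt(abs(mean(trans) - 0.5), 4 * sd(trans) / sqrt(length(trans)))
})

test_that("parental genotypes show mating symmetry and Hardy-Weinberg", {
  co <- null_cohort(700, loci_per_chromosome = 3, seed = 31)
  # mating symmetry: ordered pair (g1, g2) as frequent as (g2, g1)
  stat <- 0; df <- 0
  for (li in seq_len(n_loci(co))) {
    m <- co$mothers[, li]; f <- co$fathers[, li]
    for (a in 0:1) for (b in (a + 1):2) {
      n_ab <- sum(m == a & f == b); n_ba <- sum(m == b & f == a)
      if (n_ab + n_ba > 0) {
        stat <- stat + (n_ab - n_ba)^2 / (n_ab + n_ba)
        df <- df + 1
      }
    }
  }
  expect_gt(stats::pchisq(stat, df, lower.tail = FALSE), 0.01)

  # Hardy-Weinberg goodness of fit at each locus (parents pooled)
  for (li in seq_len(n_loci(co))) {
    g <- c(co$mothers[, li], co$fathers[, li])
    p <- mean(g) / 2
    expected <- length(g) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    observed <- tabulate(g + 1, 3)
    chi <- sum((observed - expected)^2 / pmax(expected, 1e-9))
    expect_gt(stats::pchisq(chi, 1, lower.tail = FALSE), 0.001)
  }
})

test_that("maternal-only epistasis distorts mothers, not transmissions", {
  case_excess <- numeric(10)
  for (s in 1:10) {
    sim <- planted_mf_sim(700 + s, n_families = 300, loci_per_chromosome = 5,
                          origins = c("maternal", "maternal", "maternal"))
    co <- sim$cohort
    loci <- sim$planted$locus_index
    joint <- function(g) rowSums(g[, loci] >= 1) == 3
    case_excess[s] <- sum(joint(co$mothers)) - sum(joint(co$fathers))
    # child transmission undistorted: heterozygous-mother transmission ~ 1/2
    het <- co$mothers[, loci] == 1 & co$fathers[, loci] != 1
    trans <- (co$children[, loci] - co$fathers[, loci] / 2)[het]
    expect_lt(abs(mean(trans) - 0.5), 4 * sd(trans) / sqrt(length(trans)))
  }
  expect_true(all(case_excess > 0))
})

test_that("a vanishing effect leaves the case genotype distribution at HWE", {
  scn <- sim_scenario(loci_per_chromosome = 5, n_families = 600,
                      baseline_risk = 0.2,
                      epistatic_sets = list(list(
                        members = data.frame(locus = c(2, 7),
                                             origin = "child"),
                        relative_risk = 1.0001)),
                      seed = 41)
  sim <- simulate_cohort(scn)
  for (li in c(2, 7)) {
    g <- sim$cohort$children[, li]
    p <- 0.25  # effect_maf
    expected <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    observed <- tabulate(g + 1, 3) / length(g)
    expect_lt(max(abs(observed - expected)), 0.06)
  }
})

test_that("candidate down-sampling keeps effect loci and mirrors every locus", {
  sim <- planted_mf_sim(51, n_families = 100, loci_per_chromosome = 10)
  cand <- make_candidate_list(sim$cohort, 24, sim$truth, seed = 7)
  expect_equal(nrow(cand), 24)
  expect_equal(length(unique(cand$locus_index)), 12)
  expect_true(all(sim$planted$locus_index %in% cand$locus_index))
  # every locus appears exactly once per origin
  tab <- table(cand$locus_index, cand$origin)
  expect_true(all(tab == 1))
  expect_error(make_candidate_list(sim$cohort, 23, sim$truth), "even")
  expect_error(make_candidate_list(sim$cohort, 4, sim$truth), "at least")
  expect_error(make_candidate_list(sim$cohort, 2 * n_loci(sim$cohort) + 2,
                                   sim$truth), "exceeds")
  # full mirror of the cohort
  full <- make_candidate_list(sim$cohort, 2 * n_loci(sim$cohort), sim$truth,
                              seed = 1)
  expect_equal(nrow(full), 2 * n_loci(sim$cohort))
})
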