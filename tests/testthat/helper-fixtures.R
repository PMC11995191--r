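# Shared fixtures, built in code.

# A tiny fully deterministic cohort: 4 families x 4 loci on 3 chromosomes.
toy_cohort <- function() {
  loci <- data.frame(
    locus_id = c("rsA", "rsB", "rsC", "rsD"),
    chromosome = c("1", "1", "2", "3"),
    position = c(100L, 5000L, 200L, 300L)
  )
  m <- rbind(c(1, 2, 1, 0),
             c(2, 1, 1, 1),
             c(0, 0, 2, 2),
             c(1, 1, 0, 1))
  f <- rbind(c(1, 0, 1, 0),
             c(0, 1, 2, 1),
             c(1, 2, 0, 0),
             c(1, 1, 1, 2))
  k <- rbind(c(2, 1, 1, 0),
             c(1, 1, 2, 1),
             c(1, 1, 1, 1),
             c(0, 1, 1, 2))
  triad_cohort(m, f, k, loci)
}

# Null cohort (no genetic effects): affected status independent of genotype,
# so a high baseline keeps the rejection sampler fast.
null_cohort <- function(n_families, n_chromosomes = 4, loci_per_chromosome = 2,
                        seed = 1) {
  scn <- sim_scenario(n_chromosomes = n_chromosomes,
                      loci_per_chromosome = loci_per_chromosome,
                      baseline_risk = 0.5, n_families = n_families, seed = seed)
  simulate_cohort(scn)$cohort
}

# The standard planted maternal-fetal scenario (1 maternal + 2 child SNPs on
# distinct chromosomes, joint relative risk 10, baseline risk 0.01) at a
# configurable locus density. The default loci_per_chromosome = 100 keeps
# unit tests quick; acceptance-scale checks pass 1250.
planted_mf_sim <- function(seed, n_families = 1000, loci_per_chromosome = 100,
                           origins = c("maternal", "child", "child")) {
  lpc <- loci_per_chromosome
  loci <- c(lpc %/% 2, lpc + lpc %/% 2, 2 * lpc + lpc %/% 2)
  scn <- sim_scenario(
    n_families = n_families, baseline_risk = 0.01,
    loci_per_chromosome = lpc,
    epistatic_sets = list(list(members = data.frame(locus = loci,
                                                    origin = origins),
                               relative_risk = 10)),
    seed = seed)
  sim <- simulate_cohort(scn)
  sim$planted <- snp_set(loci, origins)
  sim
}

# exhaustive fitness maximum over all d-subsets of a candidate pool
# (enumeration oracle, independent of the evolutionary search)
exhaustive_best <- function(cohort, candidates, d) {
  combos <- utils::combn(nrow(candidates), d)
  scores <- apply(combos, 2, function(idx) {
    tryCatch(score_fitness(cohort, snp_set(candidates$locus_index[idx],
                                           candidates$origin[idx]))$score,
             error = function(e) 0)
  })
  best <- which.max(scores)
  list(score = scores[best],
       set = snp_set(candidates$locus_index[combos[, best]],
                     candidates$origin[combos[, best]]),
       scores = scores)
}

set_key_of <- function(set) epitriad:::snp_set_key(set)

# full-scale (5,000-locus) planted simulations are shared between acceptance
# blocks; memoised by seed
.sim_cache <- new.env(parent = emptyenv())
planted_mf_sim_fullscale <- function(seed) {
  key <- as.character(seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- planted_mf_sim(seed, loci_per_chromosome = 1250)
  .sim_cache[[key]]
}

# number of planted SNPs (locus, origin pairs) contained in the top-ranked set
planted_in_top <- function(res, planted) {
  top <- res$sets[[1]]
  sum(paste(top$locus_index, top$origin) %in%
        paste(planted$locus_index, planted$origin))
}
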