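---
title: "Mining maternal and fetal epistasis in case-parent triads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining maternal and fetal epistasis in case-parent triads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pregnancy involves two genomes. Variants carried by the mother can shape the
intrauterine environment and affect the child's risk of disease whether or
not the child inherits them, and maternal and fetal genotypes can act
synergistically (including same-locus "incompatibility" effects of the
Rh-factor kind). `epitriad` searches a list of candidate SNPs — each
designated as a *child* or a *maternal* candidate — for small sets (2–5
SNPs) whose joint carriage pattern in case-parent triads suggests
epistatic involvement in risk, and then applies permutation tests that
separate genuinely joint (super-multiplicative) effects from bundles of
independent marginal effects.

The design is the case-parents triad: an affected child and both biological
parents, all genotyped, autosomes only. Two comparisons drive everything:

* **Child SNPs — case vs complement sibling.** Under Mendelian
  transmission the two parental alleles *not* transmitted to the case form
  a "complement sibling" with genotype `mother + father − child`. Under a
  no-effect null the difference `child − complement` has expectation zero
  at every locus.
* **Maternal SNPs — mother vs father.** Under *mating symmetry* (parental
  genotype pairs (g1, g2) and (g2, g1) equally probable in the source
  population — weaker than random mating, and robust to stratification),
  the father is a matched control for the mother: `mother − father` has
  expectation zero unless maternal carriage is risk-related.

## The fitness score

For a SNP-set of size $d$, family $i$ contributes the coded difference
vector $x_i$ (child-minus-complement or mother-minus-father per component).
The score is a weighted, shrunken paired-Hotelling-type quadratic form

$$ S = w \, \bar{x}_s^{\top} \hat\Sigma^{-1} \bar{x}_s, $$

computed by `score_fitness()` as a fixed pipeline:

1. **Recoding.** Per component, the orientation is flipped so the mean
   difference is non-negative (this designates the provisional risk
   allele), and a recessive coding
   $I(\text{case side} = 2) - I(\text{control side} = 2)$ replaces the
   additive difference when its absolute standardized mean (mean / standard
   error) strictly exceeds the additive one's; ties keep additive, and a
   zero-variance coding counts as standardized mean 0.
2. **Weights.** $w_i = 2^{\sum_j |x_{ij}|}$: families with long difference
   vectors carry geometrically more weight because they are the informative
   ones for joint effects. The weight is bounded by $4^d \le 1024$ for
   $d \le 5$, so no overflow is possible.
3. **Covariance.** The weighted covariance of the difference vectors, with
   every entry linking components on *different* chromosomes set to zero
   (a maternal and a child component of the same chromosome stay in one
   block), projected block-diagonally so the matrix stays positive
   semi-definite, plus a ridge $10^{-6}\,\mathrm{tr}(\hat\Sigma)/d$ on the
   diagonal to guarantee invertibility. If the trace itself is zero (all
   components degenerate) the ridge falls back to the absolute constant
   $10^{-6}$ so the solve never fails.
4. **Shrinkage.** With $\mu_{\min} = \min_j \max(\bar{x}_{w,j}, 0)$, the
   weighted mean is rescaled to length $\sqrt{d}\,\mu_{\min}$ whenever it
   is longer. A truly epistatic set should show over-carriage at *all* $d$
   loci, so any component with no over-transmission ($\mu_{\min} = 0$)
   forces $S = 0$.

The score is invariant to which allele is designated at each locus
(recoding $g \to 2-g$ everywhere), to family order, and to member order
within the set; duplicating the cohort doubles $w$ and $S$ exactly. These
are tested as properties.

The exact weighting, shrinkage and recessive-detection rules are deliberate
design choices of this package, each isolated behind a single function
(`recode_matrix()`, the weight line, and the shrinkage block inside
`fitness_from_base()`) so alternatives can be swapped without touching
anything else.

## The island-model search

`ga_search()` evolves populations of SNP-sets of fixed size $d$ per island:
fitness-proportional (roulette) selection with elitism (2 sets copied
unchanged), union crossover (rate 0.8), per-component replacement mutation
(rate 0.01), and an origin-swap mutation (rate 0.005) that exchanges a
component for the same locus's other-origin candidate — a cheap hop between
the maternal and fetal copy of a locus. Islands stop after 50 generations
without improvement (or 500 generations); every 50 generations the best
sets migrate along a ring within 4-island clusters. Fitness ties are broken
lexicographically by set key, and per-island RNG streams are derived from
the master seed, so results are exactly reproducible and independent of
island execution order (islands run sequentially here; the per-island
streams are what would make a parallel run equivalent).

Because the shrinkage rule zeroes the score of any set with a
non-overcarried component, partial overlaps with a true set gain little
fitness and the landscape is close to flat away from the planted optimum.
Search effort must therefore grow with the candidate pool — the published
analyses ran 1,000 islands for 10,000 candidates. `islands_for_pool()`
encodes the scaling used here, one island per five candidates with a floor
of eight: 8 islands for 24 candidates, 20 for 100, 100 for 500. With it,
the planted-set experiments below recover reliably in minutes on one core.

## Permutation tests and h-values

`epistasis_h_value()` keeps each locus's (mother, father, child) triple
intact, then reassembles pseudo-families by independently permuting the
per-chromosome blocks of the set across families. Per-locus marginals
(hence marginal transmission distortion) are exactly preserved; joint
cross-chromosome structure is destroyed. The full data-adaptive pipeline —
including recoding — is re-run inside every replicate; freezing the
observed recoding would bias the test anti-conservatively. The tail
probability uses the add-one convention $h = (1 + \#\{S_b \ge S\})/(B+1)$,
with ties counted conservatively, so $1/(B+1) \le h \le 1$. When all
components share one chromosome the reassembly is a pure relabeling and
$h = 1$ by construction (a warning says so).

`maternal_fetal_h_value()` permutes all maternal components as one unit
and all child components as another, preserving marginal effects and
*within-origin* epistasis while destroying joint maternal-fetal structure.
It refuses sets where the two origins share a chromosome, since
independent permutation would manufacture Mendelian-impossible
pseudo-families.

Because the same families nominate the sets and feed the test, these are
*h-values* — evidence indices, not valid p-values. Only on independent
data would the same procedure yield p-values.

A practical caveat found while validating: with the weight function above
(which depends on $|x|$, not its sign) and the cross-chromosome covariance
zeroed in the quadratic form, joint effects move the statistic only through
the coupling of weights and means. The epistasis h-value for a strongly
planted set is therefore variable across simulation replicates — usually
below 0.05 but occasionally much larger — and the tests assert medians over
replicates rather than single draws.

`count_joint_carriers()` reports the companion descriptive statistic: how
many families carry the provisional joint risk genotype on the case side
(child at child components, mother at maternal ones) versus the control
side (complement sibling and father).

## Graphical scores

`select_top_sets()` keeps the 10 highest-fitness sets per set size;
`compute_graphical_scores()` gives each selected set weight
$u = -\log_{10}(h)$ and sums $u$ over sets containing a SNP (SNP score) or
a pair (pair score). Degenerate tests ($h = 1$) contribute zero and drop
out. The choice of $-\log_{10}$ is isolated in one function; any
decreasing transform would preserve the tested invariants
(pair ≤ min of members, additivity over disjoint collections).
`export_network()` writes GraphML/DOT/TSV with maternal SNPs as squares
and child SNPs as circles, sized by score.

## The simulator

`simulate_cohort()` is the package's stand-in for template-based triad
simulators that resample real genotype data. Parents are i.i.d. draws from
one haplotype population — mating symmetry holds *by construction* — and
children receive one Mendelian-transmitted allele per parent, so every
simulated cohort passes validation with zero masked triples. A child is
affected with probability

$$ \operatorname{expit}\!\big(\operatorname{logit}(b) +
   \textstyle\sum_{\text{sets}} \log(RR)\, I_{\text{set}} +
   \sum_{\text{singletons}} \log(RR)\, I_{\text{carrier}}\big), $$

where $I_{\text{set}} = 1$ iff the child carries at least one risk allele
at every child-origin member *and* the mother at every maternal-origin
member (dominant coding). Families are rejection-sampled until the target
number of affected triads accumulates.

Defaults are the study conditions: 1,000 families, 4 chromosomes × 1,250
loci, allele frequencies uniform on [0.05, 0.5], baseline risk 0.01, joint
relative risk 10 for epistatic sets ("fairly strong" epistasis), near 2
for non-epistatic singletons. Effect-locus frequencies are fixed at 0.25
rather than sampled so joint carriage is never vanishingly rare. With
`ld_rho = 0` (default) loci are independent and an exact shortcut is used:
the rejection step draws genotypes only at the effect loci and the
remaining loci are filled afterwards for accepted families — valid because
the triad genotype distribution factorizes over independent loci. With
`ld_rho > 0` whole-genome haplotypes are drawn from an AR(1) copula
(`ld_rho` capped at 0.89, keeping pairwise $R^2 < 0.8$) with Poisson(1)
recombination per chromosome, uniform crossover positions.

What the simulator does *not* emulate: realistic LD blocks from real
templates, population stratification, imprinting, sex chromosomes, and
genotyping error. Passing tests therefore demonstrate correctness of the
machinery and calibration under idealized sampling, not performance on
real GWAS data.

## Problem sizes used in the tests

The shipped suite exercises the full study conditions where they matter —
recovery checks simulate 1,000 affected triads over 5,000 loci and search
24, 100 (ten replicates) and 500 candidates at $d = 3$ — and scales down
where only the property is at stake: calibration uses 200 null cohorts of
100 families with 99 permutations each (h-values uniform by
Kolmogorov–Smirnov), search-vs-enumeration uses a 24-candidate pool
(2,024 possible triples, 20 seeded runs), and the oracle comparisons for
the fitness pipeline run on cohorts of 50–600 families. Seeds follow a
plain 1, 2, …, k convention throughout.

## A worked run

```{r}
library(epitriad)

scn <- sim_scenario(
  n_families = 1000, baseline_risk = 0.01,
  epistatic_sets = list(list(
    members = data.frame(locus = c(625, 1875, 3125),
                         origin = c("maternal", "child", "child")),
    relative_risk = 10)),
  seed = 1)
sim <- simulate_cohort(scn)

cand <- make_candidate_list(sim$cohort, 24, sim$truth, seed = 2)
res <- ga_search(sim$cohort, cand,
                 ga_config(d = 3, n_islands = islands_for_pool(24), seed = 3))
head(res$ranked, 3)

top <- res$sets[[1]]
epistasis_h_value(sim$cohort, top, B = 999, seed = 4)
maternal_fetal_h_value(sim$cohort, top, B = 999, seed = 4)
count_joint_carriers(sim$cohort, top, score_fitness(sim$cohort, top))
```

## Known limitations

* h-values on search-selected sets are not p-values; no multiple-testing
  correction is attempted (the scores are exploratory evidence).
* Families missing one parent entirely cannot be represented; sporadic
  missing genotypes simply make a family uninformative for sets that need
  them.
* Linkage is decided purely by chromosome label; a distance threshold
  would be a natural extension.
* Imprinting can masquerade as maternal-fetal interaction under this
  design; distinguishing them needs parent-of-origin follow-up, which is
  out of scope.
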