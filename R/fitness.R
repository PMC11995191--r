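# Genotype-difference vectors and the fitness score S for a SNP-set.
#
# For a set of d candidate SNPs the i-th family contributes a d-vector of
# coded genotype differences: case minus complement sibling for child-origin
# components, mother minus father for maternal-origin components. Under the
# no-effect null each element has expectation zero; joint over-transmission
# of risk alleles pushes the vectors into a common orthant. The score
# S = w * xbar_s' Sigma^-1 xbar_s (a weighted, shrunken paired-Hotelling-type
# quadratic form) quantifies that alignment.

RIDGE_EPS <- 1e-6

# Per-component base codings for a set of (locus, origin) components:
#   add  - additive difference (case side minus control side allele counts)
#   rec2 - I(case side == 2) - I(control side == 2)   [recessive, designated allele]
#   rec0 - I(case side == 0) - I(control side == 0)   [recessive, opposite allele]
# plus the chromosome block label per component. NA rows mark families missing
# any genotype the component needs (all three members for child components,
# both parents for maternal ones).
component_base <- function(cohort, locus_index, origin) {
  n <- n_families(cohort)
  d <- length(locus_index)
  add <- rec2 <- rec0 <- matrix(NA_real_, n, d)
  is_child <- origin == "child"
  if (any(is_child)) {
    li <- locus_index[is_child]
    m <- cohort$mothers[, li, drop = FALSE]
    f <- cohort$fathers[, li, drop = FALSE]
    k <- cohort$children[, li, drop = FALSE]
    comp <- m + f - k
    add[, is_child] <- 2 * k - m - f            # child - complement
    rec2[, is_child] <- (k == 2) - (comp == 2)
    rec0[, is_child] <- (k == 0) - (comp == 0)
  }
  if (any(!is_child)) {
    li <- locus_index[!is_child]
    m <- cohort$mothers[, li, drop = FALSE]
    f <- cohort$fathers[, li, drop = FALSE]
    add[, !is_child] <- m - f                   # mother - father
    rec2[, !is_child] <- (m == 2) - (f == 2)
    rec0[, !is_child] <- (m == 0) - (f == 0)
  }
  list(add = add, rec2 = rec2, rec0 = rec0,
       block = cohort$loci$chromosome[locus_index])
}

#' Genotype-difference matrix for a SNP-set
#'
#' Computes, for each informative family, the d-vector of coded genotype
#' differences: `child - complement_sibling` for child-origin components and
#' `mother - father` for maternal-origin components. A family is informative
#' iff every component's required genotypes are non-missing (all three
#' members for child components, both parents for maternal ones); other
#' families are dropped and flagged.
#'
#' @param cohort A [triad_cohort()].
#' @param set A [snp_set()] (or data frame with `locus_index`, `origin`).
#' @return An object of class `diff_matrix`: list with `values`
#'   (n_informative x d additive differences), `family_index` (cohort row of
#'   each value row), `informative_mask` (per-family logical), `set`, and the
#'   per-component chromosome `block` labels.
#' @export
difference_vectors <- function(cohort, set) {
  set <- as_snp_set(set)
  if (any(set$locus_index < 1 | set$locus_index > n_loci(cohort)))
    abort_validation("locus_index out of range for this cohort")
  base <- component_base(cohort, set$locus_index, set$origin)
  ok <- stats::complete.cases(base$add)
  if (!any(ok)) stop("no informative families for this SNP-set", call. = FALSE)
  structure(
    list(values = base$add[ok, , drop = FALSE],
         rec2 = base$rec2[ok, , drop = FALSE],
         rec0 = base$rec0[ok, , drop = FALSE],
         family_index = which(ok),
         informative_mask = ok,
         block = base$block,
         set = set),
    class = "diff_matrix"
  )
}

# Data-driven per-component recoding, applied to an informative-family
# difference matrix:
#   (a) orientation: flip the sign of a component iff its unweighted mean is
#       negative, so post-flip means are >= 0 (this designates the
#       provisional risk allele);
#   (b) mode of inheritance: swap the additive difference for the recessive
#       coding iff the recessive coding's absolute standardized mean
#       (mean / standard error) strictly exceeds the additive one's.
# Zero variance under a coding makes its standardized mean 0; zero variance
# under both codings flags the component degenerate.
recode_matrix <- function(x, rec2, rec0) {
  n <- nrow(x)
  d <- ncol(x)
  if (n < 2) stop("recoding needs at least 2 informative families", call. = FALSE)
  flips <- colMeans(x) < 0
  if (any(flips)) x[, flips] <- -x[, flips]
  # under a flipped orientation the risk allele is the opposite allele, so
  # "carries two risk alleles" becomes "genotype == 0"
  rec <- rec2
  if (any(flips)) rec[, flips] <- rec0[, flips]

  std_mean <- function(m) {
    mu <- colMeans(m)
    v <- (colSums(m * m) - n * mu^2) / (n - 1)
    v[v < 0] <- 0
    se <- sqrt(v / n)
    z <- ifelse(se > 0, mu / se, 0)
    list(z = z, var = v)
  }
  sa <- std_mean(x)
  sr <- std_mean(rec)
  recessive <- abs(sr$z) > abs(sa$z)
  if (any(recessive)) x[, recessive] <- rec[, recessive]
  degenerate <- sa$var == 0 & sr$var == 0
  list(values = x, flips = flips, recessive = recessive, degenerate = degenerate)
}

#' Recode components of a difference matrix
#'
#' Applies the data-driven per-component recoding used inside the fitness
#' score: orientation flips so each component's mean difference is
#' non-negative (choosing the provisional risk allele), then adoption of a
#' recessive coding — `I(case side carries 2 risk alleles) - I(control side
#' carries 2)` — whenever its absolute standardized mean strictly exceeds the
#' additive coding's (ties keep additive).
#'
#' @param diffs A `diff_matrix` from [difference_vectors()].
#' @return List with the recoded `diff_matrix` (`diffs`), logical vectors
#'   `flips`, `recessive_flags`, and `degenerate` (zero variance under both
#'   codings).
#' @export
recode_components <- function(diffs) {
  stopifnot(inherits(diffs, "diff_matrix"))
  r <- recode_matrix(diffs$values, diffs$rec2, diffs$rec0)
  out <- diffs
  out$values <- r$values
  list(diffs = out, flips = r$flips, recessive_flags = r$recessive,
       degenerate = r$degenerate)
}

# Full fitness pipeline on base coding matrices (NA rows = uninformative
# families). Kept as one function so search and permutation testing share a
# single fast path. Returns the score only unless full = TRUE.
fitness_from_base <- function(add, rec2, rec0, block, full = FALSE) {
  ok <- stats::complete.cases(add)
  if (sum(ok) < 2) stop("no informative families", call. = FALSE)
  x <- add[ok, , drop = FALSE]
  r <- recode_matrix(x, rec2[ok, , drop = FALSE], rec0[ok, , drop = FALSE])
  x <- r$values
  n <- nrow(x)
  d <- ncol(x)

  # family weights: geometric in the L1 length of the coded difference vector
  w <- 2^rowSums(abs(x))
  W <- sum(w)
  xbar <- colSums(w * x) / W
  xc <- x - rep(xbar, each = n)
  Sigma <- crossprod(xc, w * xc) / W
  # super-multiplicative focus: only within-chromosome covariance is retained
  same_block <- outer(block, block, "==")
  Sigma[!same_block] <- 0
  ridge <- RIDGE_EPS * sum(diag(Sigma)) / d
  if (ridge <= 0) ridge <- RIDGE_EPS  # numerical floor for all-degenerate input
  diag(Sigma) <- diag(Sigma) + ridge

  # shrinkage: a truly epistatic set over-carries at all d loci, so cap the
  # mean vector's length at sqrt(d) times the smallest non-negative component
  mu_min <- min(pmax(xbar, 0))
  nrm <- sqrt(sum(xbar^2))
  if (mu_min <= 0) {
    xs <- numeric(d)
  } else if (nrm > sqrt(d) * mu_min) {
    xs <- xbar * (sqrt(d) * mu_min / nrm)
  } else {
    xs <- xbar
  }
  score <- if (all(xs == 0)) 0 else W * drop(crossprod(xs, solve(Sigma, xs)))
  if (!full) return(score)
  list(score = score, risk_allele_flips = r$flips,
       recessive_flags = r$recessive, degenerate = r$degenerate,
       weights = w, weight_sum = W, weighted_mean = xbar, shrunken_mean = xs,
       covariance = Sigma, n_informative = n)
}

#' Fitness score for a SNP-set
#'
#' Runs the full scoring pipeline: difference vectors, data-driven recoding,
#' family weights `w_i = 2^(sum_j |x_ij|)`, weighted mean and weighted
#' covariance, zeroing of cross-chromosome covariance blocks (a maternal and
#' a child component on the same chromosome stay in one block) plus a ridge
#' `1e-6 * tr(Sigma)/d` on the diagonal, shrinkage of the weighted mean, and
#' finally `S = w * xbar_s' Sigma^-1 xbar_s`. The shrinkage rescales the
#' weighted mean to length `sqrt(d) * mu_min`, where `mu_min` is the smallest
#' non-negative component mean — so any component with no over-transmission
#' (mean <= 0 after orientation) forces `S = 0`.
#'
#' @param cohort A [triad_cohort()].
#' @param set A [snp_set()].
#' @return Object of class `fitness_result`: list with `score`,
#'   `risk_allele_flips`, `recessive_flags`, `degenerate`, `weights`,
#'   `weight_sum`, `weighted_mean`, `shrunken_mean`, `covariance`,
#'   `informative_mask`, `set`.
#' @export
score_fitness <- function(cohort, set) {
  set <- as_snp_set(set)
  base <- component_base(cohort, set$locus_index, set$origin)
  ok <- stats::complete.cases(base$add)
  res <- fitness_from_base(base$add, base$rec2, base$rec0, base$block,
                           full = TRUE)
  res$informative_mask <- ok
  res$set <- set
  class(res) <- "fitness_result"
  res
}

#' @export
print.fitness_result <- function(x, ...) {
  cat("fitness_result: S =", format(x$score, digits = 6), "over",
      x$n_informative, "informative families\n")
  tags <- paste0(x$set$locus_index, ":", substr(x$set$origin, 1, 1),
                 ifelse(x$recessive_flags, " (rec)", ""))
  cat("  components:", paste(tags, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a fitness result to JSON
#'
#' @param x A `fitness_result`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to a file).
#' @export
fitness_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "fitness_result"))
  obj <- list(
    score = x$score,
    set = data.frame(locus_index = x$set$locus_index, origin = x$set$origin),
    risk_allele_flips = x$risk_allele_flips,
    recessive_flags = x$recessive_flags,
    weight_sum = x$weight_sum,
    weighted_mean = x$weighted_mean,
    shrunken_mean = x$shrunken_mean,
    covariance = x$covariance,
    n_informative = x$n_informative
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
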