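# Island-model evolutionary search over SNP-sets of fixed size d.
#
# Each island evolves its own population of SNP-sets (fitness-proportional
# selection with elitism, union crossover, replacement mutation, and an
# origin-swap mutation that hops between the maternal and child copy of a
# locus). Islands are grouped into clusters; every migration_interval
# generations each island's best sets are copied to the next island in a
# ring within its cluster. Results are pooled, deduplicated and ranked.

#' Configuration for the evolutionary search
#'
#' @param d SNP-set size (>= 2; typical analyses scan d = 2..5).
#' @param n_islands Number of island populations (desk default 8; scale up
#'   for large candidate pools).
#' @param cluster_size Islands per migration cluster (default 4).
#' @param island_pop SNP-sets per island (default 50).
#' @param max_generations Hard generation cap per island (default 500).
#' @param patience Generations without best-fitness improvement before an
#'   island stops (default 50).
#' @param crossover_rate Probability a child is produced by crossover rather
#'   than cloning (default 0.8).
#' @param mutation_rate Per-component probability of replacement by a random
#'   candidate not already in the set (default 0.01).
#' @param origin_swap_rate Per-component probability of swapping
#'   maternal <-> child at the same locus, when the mirrored candidate exists
#'   in the pool (default 0.005).
#' @param migration_interval Generations between migrations (default 50).
#' @param elitism Number of top sets copied unchanged each generation, and
#'   the number of migrants sent (default 2).
#' @param seed Master RNG seed; per-island seeds are derived as
#'   `seed + island` so results do not depend on execution order.
#' @return A validated list of class `ga_config`.
#' @export
ga_config <- function(d, n_islands = 8L, cluster_size = 4L, island_pop = 50L,
                      max_generations = 500L, patience = 50L,
                      crossover_rate = 0.8, mutation_rate = 0.01,
                      origin_swap_rate = 0.005, migration_interval = 50L,
                      elitism = 2L, seed = 1L) {
  cfg <- list(d = as.integer(d), n_islands = as.integer(n_islands),
              cluster_size = as.integer(cluster_size),
              island_pop = as.integer(island_pop),
              max_generations = as.integer(max_generations),
              patience = as.integer(patience),
              crossover_rate = crossover_rate, mutation_rate = mutation_rate,
              origin_swap_rate = origin_swap_rate,
              migration_interval = as.integer(migration_interval),
              elitism = as.integer(elitism), seed = as.integer(seed))
  if (cfg$d < 2) abort_validation("d must be >= 2")
  if (cfg$island_pop <= cfg$elitism)
    abort_validation("island_pop must exceed elitism")
  rates <- c(cfg$crossover_rate, cfg$mutation_rate, cfg$origin_swap_rate)
  if (any(rates < 0 | rates > 1)) abort_validation("rates must be in [0, 1]")
  if (cfg$n_islands < 1 || cfg$cluster_size < 1)
    abort_validation("n_islands and cluster_size must be >= 1")
  if (cfg$seed + cfg$n_islands >= 2^31)
    abort_validation("seed too large")
  class(cfg) <- "ga_config"
  cfg
}

#' Recommended island count for a candidate pool
#'
#' Search effort must grow with the candidate pool for the initial
#' populations to seed the pool adequately (the published analyses ran 1,000
#' islands for 10,000 candidate SNPs). This helper scales one island per five
#' candidates with a floor of eight, which recovers planted sets reliably at
#' desk scale (24-500 candidates).
#'
#' @param n_candidates Number of candidate SNPs.
#' @return Integer island count, `max(8, ceiling(n_candidates / 5))`.
#' @export
islands_for_pool <- function(n_candidates) {
  max(8L, as.integer(ceiling(n_candidates / 5)))
}

# --- internal island machinery ----------------------------------------------

# Candidate pool context: base coding matrices for all K candidates, the
# mirror index (candidate with same locus, other origin; NA if absent), and a
# memoising score function (cache shared across islands; same data).
make_pool <- function(cohort, candidates) {
  base <- component_base(cohort, candidates$locus_index, candidates$origin)
  cache <- new.env(parent = emptyenv())
  score_set <- function(idx) {
    key <- paste(idx, collapse = ",")
    s <- cache[[key]]
    if (!is.null(s)) return(s)
    s <- tryCatch(
      fitness_from_base(base$add[, idx, drop = FALSE],
                        base$rec2[, idx, drop = FALSE],
                        base$rec0[, idx, drop = FALSE],
                        base$block[idx]),
      error = function(e) 0)
    cache[[key]] <- s
    s
  }
  mirror <- integer(nrow(candidates))
  key <- paste(candidates$locus_index, candidates$origin)
  other <- paste(candidates$locus_index,
                 ifelse(candidates$origin == "child", "maternal", "child"))
  mirror <- match(other, key)
  list(K = nrow(candidates), score_set = score_set, mirror = mirror,
       candidates = candidates, cache = cache)
}

# sorted candidate-index row -> population key
row_key <- function(idx) paste(idx, collapse = ",")

island_init <- function(pool, cfg) {
  pop <- t(vapply(seq_len(cfg$island_pop),
                  function(i) sort(sample.int(pool$K, cfg$d)),
                  integer(cfg$d)))
  fit <- apply(pop, 1, pool$score_set)
  st <- list(pop = pop, fit = fit, generation = 0L,
             best_fit = -Inf, best_key = "", stale = 0L, done = FALSE,
             trace = numeric(0))
  island_note_best(st)
}

# update best-ever bookkeeping (lexicographic key breaks fitness ties)
island_note_best <- function(st) {
  o <- order(-st$fit, apply(st$pop, 1, row_key))
  top <- o[1]
  if (st$fit[top] > st$best_fit) {
    st$best_fit <- st$fit[top]
    st$best_key <- row_key(st$pop[top, ])
    st$stale <- 0L
  }
  st
}

island_generation <- function(st, pool, cfg) {
  pop <- st$pop
  fit <- st$fit
  np <- nrow(pop)
  ord <- order(-fit, apply(pop, 1, row_key))
  n_child <- np - cfg$elitism
  probs <- if (sum(fit) > 0) fit / sum(fit) else rep(1 / np, np)

  new_pop <- pop
  new_fit <- fit
  if (cfg$elitism > 0) {
    new_pop[seq_len(cfg$elitism), ] <- pop[ord[seq_len(cfg$elitism)], , drop = FALSE]
    new_fit[seq_len(cfg$elitism)] <- fit[ord[seq_len(cfg$elitism)]]
  }
  for (i in seq_len(n_child)) {
    par <- sample.int(np, 2, replace = TRUE, prob = probs)
    if (stats::runif(1) < cfg$crossover_rate) {
      u <- union(pop[par[1], ], pop[par[2], ])
      child <- if (length(u) == cfg$d) u else sample(u, cfg$d)
    } else {
      child <- pop[par[1], ]
    }
    # replacement mutation
    mut <- which(stats::runif(cfg$d) < cfg$mutation_rate)
    for (j in mut) {
      avail <- setdiff(seq_len(pool$K), child)
      if (length(avail)) child[j] <- avail[sample.int(length(avail), 1)]
    }
    # origin-swap mutation: hop to the mirrored candidate at the same locus
    sw <- which(stats::runif(cfg$d) < cfg$origin_swap_rate)
    for (j in sw) {
      m <- pool$mirror[child[j]]
      if (!is.na(m) && !(m %in% child)) child[j] <- m
    }
    child <- sort(child)
    k <- cfg$elitism + i
    new_pop[k, ] <- child
    new_fit[k] <- pool$score_set(child)
  }
  st$pop <- new_pop
  st$fit <- new_fit
  st$generation <- st$generation + 1L
  st$stale <- st$stale + 1L
  st <- island_note_best(st)
  st$trace <- c(st$trace, st$best_fit)
  st$done <- st$stale >= cfg$patience || st$generation >= cfg$max_generations
  st
}

# advance an island up to n_gen generations (stops early at convergence),
# swapping its private RNG stream in and out
island_advance <- function(st, pool, cfg, n_gen) {
  old <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  assign(".Random.seed", st$rng, envir = .GlobalEnv)
  for (g in seq_len(n_gen)) {
    if (st$done) break
    st <- island_generation(st, pool, cfg)
  }
  st$rng <- get(".Random.seed", envir = .GlobalEnv)
  st
}

#' Run a single island population
#'
#' Evolves one island to convergence (patience generations without
#' improvement, or the generation cap) with no migration. Mostly useful for
#' diagnostics and testing; [ga_search()] runs the full island model.
#'
#' @param cohort A [triad_cohort()].
#' @param candidates Candidate data frame (see [make_candidates()]).
#' @param config A [ga_config()].
#' @param island_seed RNG seed for this island.
#' @return List with the final `pop` (matrix of candidate indices), `fit`,
#'   best-ever `best_fit`/`best_key`, `generation` count, and the per-
#'   generation best-fitness `trace`.
#' @export
run_island <- function(cohort, candidates, config, island_seed) {
  stopifnot(inherits(config, "ga_config"))
  if (nrow(candidates) < config$d)
    abort_validation("fewer candidates (", nrow(candidates),
                     ") than the set size d = ", config$d)
  pool <- make_pool(cohort, candidates)
  old <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(island_seed)
  st <- island_init(pool, config)
  st$rng <- get(".Random.seed", envir = .GlobalEnv)
  while (!st$done) st <- island_advance(st, pool, config, config$max_generations)
  st[c("pop", "fit", "best_fit", "best_key", "generation", "trace")]
}

#' Migrate best sets around a ring of islands
#'
#' Each island sends copies of its `n_migrants` best sets to the next island
#' in the ring; the receiver's worst sets are replaced. A single-island
#' cluster is a no-op.
#'
#' @param islands List of islands, each a list with `pop` (matrix of
#'   candidate indices, one set per row) and `fit` (fitness per row).
#' @param n_migrants Number of sets each island forwards (default 2).
#' @return The updated list of islands.
#' @export
migrate <- function(islands, n_migrants = 2L) {
  k <- length(islands)
  if (k < 2) return(islands)
  pick_top <- function(isl) {
    o <- order(-isl$fit, apply(isl$pop, 1, row_key))
    head(o, n_migrants)
  }
  outgoing <- lapply(islands, function(isl) {
    sel <- pick_top(isl)
    list(pop = isl$pop[sel, , drop = FALSE], fit = isl$fit[sel])
  })
  for (i in seq_len(k)) {
    from <- if (i == 1) k else i - 1
    mig <- outgoing[[from]]
    isl <- islands[[i]]
    worst <- head(order(isl$fit, apply(isl$pop, 1, row_key)), nrow(mig$pop))
    isl$pop[worst, ] <- mig$pop
    isl$fit[worst] <- mig$fit
    islands[[i]] <- isl
  }
  islands
}

#' Island-model evolutionary search
#'
#' Runs `n_islands` island populations in lockstep with migration every
#' `migration_interval` generations inside `cluster_size`-island clusters
#' (ring topology), then pools all final populations, deduplicates the
#' SNP-sets and ranks them by fitness (ties broken lexicographically).
#' Per-island RNG streams are derived from `config$seed`, so re-running with
#' the same seed reproduces the result exactly.
#'
#' @param cohort A [triad_cohort()].
#' @param candidates Candidate data frame (columns `locus_index`, `origin`,
#'   `locus_id`).
#' @param config A [ga_config()].
#' @return Object of class `search_result`: list with `ranked` (data frame:
#'   rank, score, set_key, locus_ids, origins), `sets` (list of [snp_set()]s
#'   in rank order), `scores`, `per_island_best`, `config`, `seed`.
#' @export
ga_search <- function(cohort, candidates, config) {
  stopifnot(inherits(config, "ga_config"))
  if (nrow(candidates) < config$d)
    abort_validation("fewer candidates (", nrow(candidates),
                     ") than the set size d = ", config$d)
  pool <- make_pool(cohort, candidates)
  old <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))

  islands <- vector("list", config$n_islands)
  for (i in seq_len(config$n_islands)) {
    set.seed(config$seed + i)
    st <- island_init(pool, config)
    st$rng <- get(".Random.seed", envir = .GlobalEnv)
    islands[[i]] <- st
  }
  clusters <- split(seq_len(config$n_islands),
                    ceiling(seq_len(config$n_islands) / config$cluster_size))

  while (!all(vapply(islands, `[[`, TRUE, "done"))) {
    for (i in seq_len(config$n_islands))
      islands[[i]] <- island_advance(islands[[i]], pool, config,
                                     config$migration_interval)
    if (all(vapply(islands, `[[`, TRUE, "done"))) break
    for (cl in clusters) {
      if (length(cl) < 2) next
      migrated <- migrate(islands[cl], n_migrants = config$elitism)
      for (j in seq_along(cl)) {
        st <- islands[[cl[j]]]
        st$pop <- migrated[[j]]$pop
        st$fit <- migrated[[j]]$fit
        prev_best <- st$best_fit
        st <- island_note_best(st)
        if (st$best_fit > prev_best) st$done <- FALSE  # migrant improved: revive
        islands[[cl[j]]] <- st
      }
    }
  }

  all_pop <- do.call(rbind, lapply(islands, `[[`, "pop"))
  all_fit <- unlist(lapply(islands, `[[`, "fit"))
  keys <- apply(all_pop, 1, row_key)
  keep <- !duplicated(keys)
  all_pop <- all_pop[keep, , drop = FALSE]
  all_fit <- all_fit[keep]
  keys <- keys[keep]
  o <- order(-all_fit, keys)
  all_pop <- all_pop[o, , drop = FALSE]
  all_fit <- all_fit[o]
  keys <- keys[o]

  sets <- lapply(seq_len(nrow(all_pop)), function(r) {
    idx <- all_pop[r, ]
    snp_set(candidates$locus_index[idx], candidates$origin[idx])
  })
  ranked <- data.frame(
    rank = seq_along(keys),
    score = all_fit,
    set_key = vapply(sets, snp_set_key, ""),
    locus_ids = vapply(seq_len(nrow(all_pop)), function(r)
      paste(candidates$locus_id[all_pop[r, ]], collapse = ","), ""),
    origins = vapply(seq_len(nrow(all_pop)), function(r)
      paste(candidates$origin[all_pop[r, ]], collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  per_island_best <- data.frame(
    island = seq_len(config$n_islands),
    best_score = vapply(islands, `[[`, 0, "best_fit"),
    generations = vapply(islands, `[[`, 0L, "generation")
  )
  structure(
    list(ranked = ranked, sets = sets, scores = all_fit,
         per_island_best = per_island_best, config = config,
         seed = config$seed),
    class = "search_result"
  )
}

#' @export
print.search_result <- function(x, ...) {
  cat("search_result: d =", x$config$d, "-", nrow(x$ranked),
      "distinct SNP-sets; top score", format(x$scores[1], digits = 6), "\n")
  print(head(x$ranked, 5), row.names = FALSE)
  invisible(x)
}

#' Serialize a search result
#'
#' Writes the ranked SNP-sets as JSON (full detail) and/or a TSV summary.
#'
#' @param x A `search_result`.
#' @param json_path,tsv_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
search_to_files <- function(x, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(x, "search_result"))
  written <- character(0)
  if (!is.null(json_path)) {
    obj <- list(d = x$config$d, seed = x$seed,
                config = unclass(x$config),
                ranked = x$ranked,
                per_island_best = x$per_island_best)
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, json_path)
  }
  if (!is.null(tsv_path)) {
    data.table::fwrite(x$ranked, tsv_path, sep = "\t", quote = FALSE)
    written <- c(written, tsv_path)
  }
  invisible(written)
}
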