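# SNP-level and SNP-pair-level graphical scores and network export.
#
# Evidence is aggregated over the top SNP-sets from searches at several set
# sizes: each selected set contributes u = -log10(h) (its epistasis h-value)
# to every member SNP and every within-set SNP pair. Sets whose test is
# degenerate (h = 1) contribute 0 and drop out naturally.

#' Select the top SNP-sets per set size
#'
#' Takes, for each search result (one per set size d), the `k`
#' highest-fitness deduplicated SNP-sets (fitness ties broken
#' lexicographically by set key, as in the search ranking) and returns their
#' union across d.
#'
#' @param search_results_by_d List of `search_result` objects (one per d).
#' @param k Sets kept per d (default 10).
#' @return List of class `selected_sets`; each element has `d`, `set`
#'   (a [snp_set()]), `score`, and `set_key`.
#' @export
select_top_sets <- function(search_results_by_d, k = 10L) {
  if (k < 1) abort_validation("k must be >= 1")
  if (inherits(search_results_by_d, "search_result"))
    search_results_by_d <- list(search_results_by_d)
  out <- list()
  for (res in search_results_by_d) {
    stopifnot(inherits(res, "search_result"))
    take <- seq_len(min(k, length(res$sets)))
    for (i in take) {
      out[[length(out) + 1]] <- list(
        d = res$config$d, set = res$sets[[i]], score = res$scores[i],
        set_key = res$ranked$set_key[i])
    }
  }
  class(out) <- "selected_sets"
  out
}

snp_tag <- function(locus_index, origin) paste0(locus_index, ":", origin)

#' Graphical scores from selected sets and their h-values
#'
#' Each selected set contributes weight `u = -log10(h)` to every member SNP
#' and to every unordered pair of members, where `h` is the set's epistasis
#' h-value (floored at `h_floor` so a reported 0 cannot produce an infinite
#' weight). By construction `pair_score(s, t) <= min(snp_score(s),
#' snp_score(t))` and scores add over disjoint set collections.
#'
#' @param selected A `selected_sets` object from [select_top_sets()].
#' @param h_values Numeric vector of epistasis h-values, aligned with
#'   `selected`.
#' @param h_floor Lower floor applied to h (default `1e-6`; with B
#'   permutations h is already at least `1/(B+1)`).
#' @return Object of class `graphical_scores`: list with `snp_scores`
#'   (data frame: locus_index, origin, score), `pair_scores` (data frame:
#'   locus_index1, origin1, locus_index2, origin2, score), and
#'   `contributing_sets` (the selected sets with their h-values).
#' @export
compute_graphical_scores <- function(selected, h_values, h_floor = 1e-6) {
  stopifnot(inherits(selected, "selected_sets"))
  if (length(h_values) != length(selected))
    abort_validation("h_values must align with the selected sets")
  h <- pmax(pmin(h_values, 1), h_floor)
  u <- -log10(h)

  snp_env <- new.env(parent = emptyenv())
  pair_env <- new.env(parent = emptyenv())
  bump <- function(env, key, val) {
    cur <- env[[key]]
    env[[key]] <- if (is.null(cur)) val else cur + val
  }
  for (i in seq_along(selected)) {
    if (u[i] <= 0) next
    set <- selected[[i]]$set
    tags <- snp_tag(set$locus_index, set$origin)
    for (t in tags) bump(snp_env, t, u[i])
    if (length(tags) >= 2) {
      pr <- utils::combn(sort(tags), 2)
      for (p in seq_len(ncol(pr)))
        bump(pair_env, paste(pr[1, p], pr[2, p], sep = "|"), u[i])
    }
  }
  parse_tag <- function(tag) {
    parts <- strsplit(tag, ":", fixed = TRUE)[[1]]
    list(locus_index = as.integer(parts[1]), origin = parts[2])
  }
  snp_keys <- sort(ls(snp_env))
  snp_scores <- data.frame(
    locus_index = vapply(snp_keys, function(k) parse_tag(k)$locus_index, 1L),
    origin = vapply(snp_keys, function(k) parse_tag(k)$origin, ""),
    score = vapply(snp_keys, function(k) snp_env[[k]], 1),
    stringsAsFactors = FALSE, row.names = NULL
  )
  pair_keys <- sort(ls(pair_env))
  pair_scores <- data.frame(
    locus_index1 = integer(0), origin1 = character(0),
    locus_index2 = integer(0), origin2 = character(0), score = numeric(0),
    stringsAsFactors = FALSE
  )
  if (length(pair_keys)) {
    halves <- strsplit(pair_keys, "|", fixed = TRUE)
    pair_scores <- data.frame(
      locus_index1 = vapply(halves, function(h2) parse_tag(h2[1])$locus_index, 1L),
      origin1 = vapply(halves, function(h2) parse_tag(h2[1])$origin, ""),
      locus_index2 = vapply(halves, function(h2) parse_tag(h2[2])$locus_index, 1L),
      origin2 = vapply(halves, function(h2) parse_tag(h2[2])$origin, ""),
      score = vapply(pair_keys, function(k) pair_env[[k]], 1),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  contributing <- lapply(seq_along(selected), function(i)
    c(selected[[i]], list(h_value = h_values[i])))
  structure(list(snp_scores = snp_scores, pair_scores = pair_scores,
                 contributing_sets = contributing),
            class = "graphical_scores")
}

#' Export a SNP interaction network
#'
#' Builds an igraph network whose vertices are the scored SNPs (attributes:
#' `locus_id`, `origin`, `score`, and `shape` — `"square"` for maternal,
#' `"circle"` for child SNPs) and whose edges carry the pair scores, then
#' writes it as GraphML, DOT, or a TSV edge list. Optionally renders a
#' static plot in which vertex size and edge width scale with the scores.
#'
#' @param scores A `graphical_scores` object.
#' @param cohort The [triad_cohort()] (resolves locus indices to ids).
#' @param out_path Output file path.
#' @param format `"graphml"`, `"dot"`, or `"tsv"`.
#' @param plot_file Optional PNG path for a static network plot.
#' @return `out_path`, invisibly.
#' @export
export_network <- function(scores, cohort, out_path,
                           format = c("graphml", "dot", "tsv"),
                           plot_file = NULL) {
  stopifnot(inherits(scores, "graphical_scores"))
  format <- match.arg(format)
  g <- network_graph(scores, cohort)
  if (format == "tsv") {
    es <- scores$pair_scores
    df <- data.frame(
      snp1 = paste0(cohort$loci$locus_id[es$locus_index1], ":", es$origin1),
      snp2 = paste0(cohort$loci$locus_id[es$locus_index2], ":", es$origin2),
      score = es$score
    )
    data.table::fwrite(df, out_path, sep = "\t", quote = FALSE)
  } else {
    igraph::write_graph(g, out_path, format = format)
  }
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 900, height = 900)
    on.exit(grDevices::dev.off(), add = TRUE)
    vs <- igraph::V(g)$score
    ew <- if (igraph::ecount(g)) igraph::E(g)$weight else numeric(0)
    plot(g,
         vertex.size = 8 + 12 * vs / max(vs, 1e-9),
         vertex.shape = igraph::V(g)$shape,
         vertex.label = igraph::V(g)$name,
         edge.width = if (length(ew)) 0.5 + 4 * ew / max(ew) else 1)
  }
  invisible(out_path)
}

# igraph object from graphical scores (vertices: snp_score > 0)
network_graph <- function(scores, cohort) {
  sn <- scores$snp_scores
  sn <- sn[sn$score > 0, , drop = FALSE]
  vname <- paste0(cohort$loci$locus_id[sn$locus_index], ":", sn$origin)
  g <- igraph::make_empty_graph(n = nrow(sn), directed = FALSE)
  if (nrow(sn)) {
    g <- igraph::set_vertex_attr(g, "name", value = vname)
    g <- igraph::set_vertex_attr(g, "locus_id",
                                 value = cohort$loci$locus_id[sn$locus_index])
    g <- igraph::set_vertex_attr(g, "origin", value = sn$origin)
    g <- igraph::set_vertex_attr(g, "score", value = sn$score)
    g <- igraph::set_vertex_attr(
      g, "shape", value = ifelse(sn$origin == "maternal", "square", "circle"))
  }
  pr <- scores$pair_scores
  if (nrow(pr)) {
    from <- paste0(cohort$loci$locus_id[pr$locus_index1], ":", pr$origin1)
    to <- paste0(cohort$loci$locus_id[pr$locus_index2], ":", pr$origin2)
    g <- igraph::add_edges(g, rbind(match(from, vname), match(to, vname)))
    g <- igraph::set_edge_attr(g, "weight", value = pr$score)
  }
  g
}
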