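#' Build an igraph object from an edge data frame
#'
#' @param edges Data frame with `source` and `target` columns.
#' @param taxa Optional vertex universe; defaults to the incident taxa.
#' @return A directed igraph graph.
#' @export
as_network_graph <- function(edges, taxa = NULL) {
  if (is.null(taxa)) taxa <- sort(unique(c(edges$source, edges$target)))
  igraph::graph_from_data_frame(edges[, c("source", "target"), drop = FALSE],
                                directed = TRUE, vertices = taxa)
}

#' Node centralities of a directed interaction sub-network
#'
#' Indegree centrality (how many taxa influence a target) is normalized
#' by n - 1; betweenness (directed shortest paths through a node) by
#' (n - 1)(n - 2), where n is the node count of the sub-network spanned
#' by its edges.  Eigenvector centrality (reported only, no downstream
#' rule uses it) is scaled to maximum 1.  Taxa from the universe that are
#' absent from the sub-network mediate nothing there and score 0.
#'
#' @param edges Edge data frame (`source`, `target`).
#' @param taxa Full taxon universe to report over.
#' @return Data frame: `taxon`, `indegree_norm`, `betweenness_norm`,
#'   `eigenvector`.
#' @export
centralities <- function(edges, taxa) {
  if (nrow(edges) == 0) stop("empty graph")
  present <- sort(unique(c(edges$source, edges$target)))
  g <- as_network_graph(edges, present)
  n <- length(present)
  indeg <- igraph::degree(g, mode = "in") / (n - 1)
  btw <- if (n > 2) {
    igraph::betweenness(g, directed = TRUE, weights = NA) / ((n - 1) * (n - 2))
  } else {
    stats::setNames(rep(0, n), present)
  }
  eig <- suppressWarnings(
    igraph::eigen_centrality(g, directed = TRUE, weights = NA)$vector)
  out <- data.frame(taxon = taxa,
                    indegree_norm = 0, betweenness_norm = 0, eigenvector = 0,
                    stringsAsFactors = FALSE)
  m <- match(present, taxa)
  ok <- !is.na(m)
  out$indegree_norm[m[ok]] <- unname(indeg)[ok]
  out$betweenness_norm[m[ok]] <- unname(btw)[ok]
  out$eigenvector[m[ok]] <- unname(eig)[ok]
  out
}

#' Centrality profiles across interaction-strength levels
#'
#' Computes [centralities()] of the top-`S` strongest sub-network for
#' every `S` in the strength grid (use `Inf` for "all interactions").
#'
#' @param edges Reliable-edge data frame with a `strength` column.
#' @param taxa Taxon universe.
#' @param grid Numeric strength levels (default
#'   `c(500, 1000, 1500, 2000, Inf)`).
#' @return Long data frame with a `level` column (`"top500"`, ...,
#'   `"all"`) ahead of the centrality columns.
#' @export
centrality_profiles <- function(edges, taxa, grid = c(500, 1000, 1500, 2000, Inf)) {
  do.call(rbind, lapply(grid, function(S) {
    cent <- centralities(top_k_edges(edges, S), taxa)
    cbind(level = if (is.finite(S)) paste0("top", S) else "all", cent,
          stringsAsFactors = FALSE)
  }))
}

#' Topological-niche scores between perturbed and control networks
#'
#' For each taxon and centrality measure, sums the perturbed-minus-control
#' centrality difference over all strength levels and normalizes by the
#' maximum absolute sum across taxa, so scores span \[-1, 1\] with at
#' least one taxon at +/-1 whenever any difference is nonzero
#' (`normalization = "max_abs_sum"`, the default).  The literal per-taxon
#' variant (`"per_taxon_max"`) divides each taxon's sum by the maximum of
#' its own per-level differences instead; it is provided for comparison
#' but does not guarantee the \[-1, 1\] range.
#'
#' @param profiles_b,profiles_c Outputs of [centrality_profiles()] for the
#'   perturbed (B) and control (C) networks over the same taxa and grid.
#' @param band Half-width of the non-influential band (default 0.1).
#' @param normalization `"max_abs_sum"` or `"per_taxon_max"`.
#' @return Data frame: `taxon`, `niche_indegree`, `niche_betweenness`,
#'   `niche_class`.
#' @export
niche_scores <- function(profiles_b, profiles_c, band = 0.1,
                         normalization = c("max_abs_sum", "per_taxon_max")) {
  normalization <- match.arg(normalization)
  key_b <- paste(profiles_b$level, profiles_b$taxon)
  key_c <- paste(profiles_c$level, profiles_c$taxon)
  if (!setequal(key_b, key_c) || length(key_b) != length(key_c)) {
    stop("grid/taxon mismatch between the two profile sets")
  }
  profiles_c <- profiles_c[match(key_b, key_c), , drop = FALSE]
  taxa <- unique(profiles_b$taxon)
  score_for <- function(col) {
    diff <- profiles_b[[col]] - profiles_c[[col]]
    raw <- tapply(diff, factor(profiles_b$taxon, levels = taxa), sum)
    if (normalization == "max_abs_sum") {
      denom <- max(abs(raw))
      if (denom == 0) rep(0, length(raw)) else as.numeric(raw / denom)
    } else {
      denom <- tapply(diff, factor(profiles_b$taxon, levels = taxa),
                      function(v) max(abs(v)))
      ifelse(denom == 0, 0, as.numeric(raw / denom))
    }
  }
  ni <- score_for("indegree_norm")
  nb <- score_for("betweenness_norm")
  data.frame(taxon = taxa, niche_indegree = ni, niche_betweenness = nb,
             niche_class = niche_classify(ni, nb, band),
             stringsAsFactors = FALSE)
}

#' Classify a taxon's topological niche
#'
#' Both scores above the band: niche after the perturbation
#' (`bioaug_niche`); both below: niche in the control (`control_niche`);
#' both inside the +/- band: `none`; opposite signs with both outside the
#' band: `ambiguous`.  Mixed cases (one inside, one outside) fall back to
#' `none`.
#'
#' @param niche_indegree,niche_betweenness Scores in \[-1, 1\]
#'   (vectorized).
#' @param band Half-width of the non-influential band (default 0.1).
#' @return Character vector of classes.
#' @export
niche_classify <- function(niche_indegree, niche_betweenness, band = 0.1) {
  stopifnot(length(niche_indegree) == length(niche_betweenness))
  ifelse(niche_indegree > band & niche_betweenness > band, "bioaug_niche",
  ifelse(niche_indegree < -band & niche_betweenness < -band, "control_niche",
  ifelse(abs(niche_indegree) > band & abs(niche_betweenness) > band,
         "ambiguous", "none")))
}
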