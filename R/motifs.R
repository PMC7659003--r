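## Canonical motif identifiers use the row-major adjacency bitmask of an
## n-node digraph: edge i -> j contributes 2^(n^2 - (n(i-1) + j)), and the
## canonical id of an isomorphism class is the minimum mask over all n!
## node relabelings.  Under this convention the 3-node convergence motif
## is 36, the chain 12, the feed-forward loop 38, the reciprocal-dyad-
## plus-in-edge 74, the reciprocal hub 78 and the feedback cycle 98.

.motif_cache <- new.env(parent = emptyenv())

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Encode a labeled digraph as its adjacency bitmask
#'
#' @param adj Square 0/1 adjacency matrix (`adj[i, j] = 1` for edge
#'   i -> j), no self-loops.
#' @return Integer mask: edge i -> j contributes
#'   `2^(n^2 - (n*(i-1) + j))`.
#' @export
motif_id_encode <- function(adj) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  stopifnot(n == ncol(adj))
  if (any(diag(adj) != 0)) stop("self-loop present")
  w <- outer(seq_len(n), seq_len(n),
             function(i, j) 2^(n^2 - (n * (i - 1) + j)))
  as.integer(sum(w[adj != 0]))
}

#' Decode a motif id into its adjacency matrix
#'
#' @param n Number of nodes (3 or 4).
#' @param id Integer mask in `[0, 2^(n^2))`.
#' @return The n x n adjacency matrix of the labeled digraph the mask
#'   encodes.
#' @export
motif_id_decode <- function(n, id) {
  stopifnot(n >= 2, id >= 0, id < 2^(n^2))
  bits <- as.integer(intToBits(id))[seq_len(n^2)]  # bit 1 = 2^0 = cell (n,n)
  adj <- matrix(rev(bits), n, n, byrow = TRUE)
  if (any(diag(adj) != 0)) stop("id sets a diagonal (self-loop) bit")
  adj
}

# canonical id for every mask of an n-node digraph (NA for self-loop masks)
.canonical_map <- function(n) {
  key <- paste0("canon", n)
  if (!is.null(.motif_cache[[key]])) return(.motif_cache[[key]])
  nn <- n^2
  ids <- 0:(2^nn - 1)
  bits <- vapply(seq_len(nn), function(m) (ids %/% 2^(nn - m)) %% 2,
                 numeric(length(ids)))  # column m = cell with weight 2^(nn-m)
  perms <- .permutations(n)
  W <- matrix(0, nn, nrow(perms))
  for (p in seq_len(nrow(perms))) {
    invp <- order(perms[p, ])
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        m <- n * (i - 1) + j
        W[m, p] <- 2^(nn - (n * (invp[i] - 1) + invp[j]))
      }
    }
  }
  cand <- bits %*% W
  canon <- as.integer(do.call(pmin, as.data.frame(cand)))
  diag_cells <- n * (seq_len(n) - 1) + seq_len(n)
  has_loop <- rowSums(bits[, diag_cells, drop = FALSE]) > 0
  canon[has_loop] <- NA_integer_
  .motif_cache[[key]] <- canon
  canon
}

#' Canonical motif id of a labeled digraph
#'
#' The minimum of [motif_id_encode()] over all node relabelings, so that
#' every isomorphic labeling maps to the same id.
#'
#' @param adj Square 0/1 adjacency matrix without self-loops.
#' @return Integer canonical id.
#' @export
motif_id_canonical <- function(adj) {
  n <- nrow(as.matrix(adj))
  .canonical_map(n)[motif_id_encode(adj) + 1L]
}

.is_weakly_connected <- function(adj) {
  n <- nrow(adj)
  u <- (adj + t(adj)) > 0
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- which(colSums(u[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Enumerate the connected canonical motif classes on n nodes
#'
#' Exhaustively canonicalizes every possible mask and keeps the classes
#' whose representative digraph is weakly connected: 13 classes for
#' n = 3, 199 for n = 4.
#'
#' @param n Number of nodes (3 or 4).
#' @return Sorted integer vector of canonical ids.
#' @export
motif_classes <- function(n) {
  key <- paste0("classes", n)
  if (!is.null(.motif_cache[[key]])) return(.motif_cache[[key]])
  canon <- .canonical_map(n)
  uniq <- sort(unique(canon[!is.na(canon)]))
  conn <- vapply(uniq, function(id) .is_weakly_connected(motif_id_decode(n, id)),
                 logical(1))
  out <- uniq[conn]
  .motif_cache[[key]] <- out
  out
}

.edges_to_indices <- function(edges, taxa = NULL) {
  if (is.null(taxa)) taxa <- sort(unique(c(edges$source, edges$target)))
  list(taxa = taxa,
       from = match(edges$source, taxa) - 1L,
       to = match(edges$target, taxa) - 1L)
}

#' Census of connected induced n-node subgraphs
#'
#' Enumerates every weakly connected induced subgraph on `n` nodes
#' exactly once (ESU enumeration) and tallies them by canonical motif id.
#'
#' @param edges Edge data frame (`source`, `target`); parallel edges are
#'   collapsed, self-loops dropped.
#' @param n Motif size, 3 or 4.
#' @param collect_id Optional canonical id whose instances (node sets)
#'   should be returned.
#' @return Named numeric vector of counts (names are canonical ids).
#'   When `collect_id` is given, the instances are attached as attribute
#'   `"instances"` (character matrix, one row per instance).
#' @export
motif_census <- function(edges, n, collect_id = NULL) {
  stopifnot(n %in% c(3L, 4L))
  if (nrow(edges) == 0) return(stats::setNames(numeric(0), character(0)))
  ix <- .edges_to_indices(edges)
  res <- esu_census_cpp(length(ix$taxa), ix$from, ix$to, as.integer(n),
                        .canonical_map(n),
                        if (is.null(collect_id)) -1L else as.integer(collect_id))
  out <- stats::setNames(res$counts, as.character(res$ids))
  if (!is.null(collect_id)) {
    inst <- res$instances
    im <- matrix(ix$taxa[inst + 1L], nrow = nrow(inst), ncol = ncol(inst))
    attr(out, "instances") <- im
  }
  out
}

#' Degree- and reciprocity-preserving network randomization
#'
#' Edge-switch null model: non-reciprocal arcs are rewired pairwise
#' (a->b, c->d becomes a->d, c->b) rejecting any switch that would
#' duplicate an edge, create a self-loop or create a reciprocal pair;
#' reciprocal dyads are rewired as units among themselves.  Every node's
#' in-degree and out-degree and the global count of reciprocal dyads are
#' therefore preserved exactly.  Graphs admitting no legal switch are
#' returned unchanged.
#'
#' @param edges Edge data frame (`source`, `target`).
#' @param seed Optional RNG seed.
#' @param switch_factor Attempted switches per edge (default 100).
#' @return Randomized edge data frame (`source`, `target`).
#' @export
randomize_network <- function(edges, seed = NULL, switch_factor = 100) {
  if (nrow(edges) < 2) return(edges[, c("source", "target"), drop = FALSE])
  if (!is.null(seed)) set.seed(seed)
  ix <- .edges_to_indices(edges)
  res <- switch_randomize_cpp(length(ix$taxa), ix$from, ix$to,
                              as.integer(switch_factor * nrow(edges)))
  data.frame(source = ix$taxa[res$from + 1L], target = ix$taxa[res$to + 1L],
             stringsAsFactors = FALSE)
}

#' Motif significance against the switching null model
#'
#' Compares each motif type's real count with its distribution over
#' `n_random` randomized networks.  A type is significant when its
#' z-score reaches `z_threshold` and its real count reaches `min_count`
#' (the published defaults of the classical motif-detection tools).
#' When the null ensemble has zero spread, z is 0 if the real count
#' equals the null mean and infinite (flagged, never significant)
#' otherwise.
#'
#' @param edges Edge data frame (`source`, `target`).
#' @param n Motif size, 3 or 4.
#' @param n_random Number of null networks (default 100, >= 2).
#' @param seed Optional RNG seed.
#' @param z_threshold Minimum z for significance (default 2).
#' @param min_count Minimum real count for significance (default 4).
#' @param switch_factor Passed to [randomize_network()].
#' @return Data frame: `n`, `canonical_id`, `count_real`, `null_mean`,
#'   `null_sd`, `z`, `significant`.
#' @export
motif_significance <- function(edges, n, n_random = 100, seed = NULL,
                               z_threshold = 2, min_count = 4,
                               switch_factor = 100) {
  stopifnot(n_random >= 2)
  if (!is.null(seed)) set.seed(seed)
  real <- motif_census(edges, n)
  nulls <- vector("list", n_random)
  for (r in seq_len(n_random)) {
    nulls[[r]] <- motif_census(randomize_network(edges,
                                                 switch_factor = switch_factor), n)
  }
  ids <- sort(unique(c(names(real), unlist(lapply(nulls, names)))))
  if (length(ids) == 0) {
    return(data.frame(n = integer(), canonical_id = integer(),
                      count_real = numeric(), null_mean = numeric(),
                      null_sd = numeric(), z = numeric(),
                      significant = logical()))
  }
  null_mat <- vapply(nulls, function(cnt) {
    v <- cnt[ids]
    v[is.na(v)] <- 0
    unname(v)
  }, numeric(length(ids)))
  null_mat <- matrix(null_mat, nrow = length(ids))
  count_real <- unname(ifelse(is.na(real[ids]), 0, real[ids]))
  null_mean <- rowMeans(null_mat)
  null_sd <- apply(null_mat, 1, stats::sd)
  z <- ifelse(null_sd > 0, (count_real - null_mean) / null_sd,
              ifelse(count_real == null_mean, 0,
                     ifelse(count_real > null_mean, Inf, -Inf)))
  data.frame(n = as.integer(n), canonical_id = as.integer(ids),
             count_real = count_real, null_mean = null_mean,
             null_sd = null_sd, z = z,
             significant = is.finite(z) & z >= z_threshold &
               count_real >= min_count,
             stringsAsFactors = FALSE)
}

#' Motif significance scan across strength levels
#'
#' Runs [motif_significance()] on the top-`S` strongest sub-network for
#' every strength level of the grid and every motif size.
#'
#' @param edges Reliable-edge data frame with a `strength` column.
#' @param sizes Motif sizes (default `c(3, 4)`).
#' @param grid Strength levels (default `c(500, 1000, 1500, 2000)`).
#' @param ... Passed to [motif_significance()].
#' @return Data frame of motif records with a leading `strength` column.
#' @export
motif_scan <- function(edges, sizes = c(3L, 4L),
                       grid = c(500, 1000, 1500, 2000), ...) {
  do.call(rbind, lapply(grid, function(S) {
    sub <- top_k_edges(edges, S)
    do.call(rbind, lapply(sizes, function(n) {
      cbind(strength = S, motif_significance(sub, n, ...))
    }))
  }))
}

#' Representative motifs across strength levels
#'
#' A motif type is representative in a network when it is significant at
#' three or more of the four interaction-strength levels.
#'
#' @param records Output of [motif_scan()] (needs >= 3 grid levels).
#' @param min_levels Required number of significant levels (default 3).
#' @return Data frame: `n`, `canonical_id`, `n_levels_significant`.
#' @export
representative_motifs <- function(records, min_levels = 3) {
  if (length(unique(records$strength)) < 3) {
    stop("need records for >= 3 strength levels")
  }
  sig <- records[records$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(data.frame(n = integer(), canonical_id = integer(),
                      n_levels_significant = integer()))
  }
  agg <- stats::aggregate(strength ~ n + canonical_id, data = sig,
                          FUN = function(s) length(unique(s)))
  names(agg)[3] <- "n_levels_significant"
  out <- agg[agg$n_levels_significant >= min_levels, , drop = FALSE]
  out <- out[order(out$n, out$canonical_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Connected 3-node sub-motifs embedded in a 4-node motif type
#'
#' Decodes the canonical 4-node representative and returns the canonical
#' types of its weakly connected induced 3-node subgraphs.
#'
#' @param id4 Canonical id of a 4-node motif type.
#' @return Named numeric vector: counts per embedded 3-node canonical id.
#' @export
submotif_census <- function(id4) {
  adj <- motif_id_decode(4L, id4)
  triples <- utils::combn(4, 3)
  ids <- c()
  for (q in seq_len(ncol(triples))) {
    sub <- adj[triples[, q], triples[, q]]
    if (.is_weakly_connected(sub)) ids <- c(ids, motif_id_canonical(sub))
  }
  if (length(ids) == 0) return(stats::setNames(numeric(0), character(0)))
  tab <- table(ids)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Fraction of a 4-node motif's instances carrying a correlated feedback loop
#'
#' Among the instances of a given 4-node motif type in a network, the
#' percentage containing at least one induced 3-node feedback cycle
#' (canonical id 98) whose taxa belong to the correlated set.  With
#' `mode = "all"` (default) all three cycle members must be correlated;
#' `mode = "any"` requires at least one.
#'
#' @param edges Edge data frame (`source`, `target`).
#' @param motif_id Canonical id of the 4-node motif type.
#' @param correlated_taxa Character vector of correlated taxon IDs.
#' @param mode `"all"` or `"any"`.
#' @param feedback_id Canonical id of the embedded cycle (default 98).
#' @return Percentage in \[0, 100\], or `NA` when the motif type has no
#'   instance in the network.
#' @export
correlated_feedback_fraction <- function(edges, motif_id, correlated_taxa,
                                         mode = c("all", "any"),
                                         feedback_id = 98L) {
  mode <- match.arg(mode)
  cnt <- motif_census(edges, 4L, collect_id = motif_id)
  inst <- attr(cnt, "instances")
  if (is.null(inst) || nrow(inst) == 0) return(NA_real_)
  ekeys <- new.env(parent = emptyenv())
  for (q in seq_len(nrow(edges))) {
    assign(paste(edges$source[q], edges$target[q]), TRUE, envir = ekeys)
  }
  has_edge <- function(a, b) !is.null(ekeys[[paste(a, b)]])
  triples <- utils::combn(4, 3)
  hit <- vapply(seq_len(nrow(inst)), function(r) {
    nodes <- inst[r, ]
    for (q in seq_len(ncol(triples))) {
      tri <- nodes[triples[, q]]
      adj <- matrix(0L, 3, 3)
      for (a in 1:3) for (b in 1:3) {
        if (a != b && has_edge(tri[a], tri[b])) adj[a, b] <- 1L
      }
      if (sum(adj) == 0 || !.is_weakly_connected(adj)) next
      if (motif_id_canonical(adj) != feedback_id) next
      ok <- if (mode == "all") all(tri %in% correlated_taxa)
            else any(tri %in% correlated_taxa)
      if (ok) return(TRUE)
    }
    FALSE
  }, logical(1))
  100 * mean(hit)
}
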