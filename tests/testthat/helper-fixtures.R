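# Shared fixtures and independent oracles, built in code at test time.

# relative-percent table from arbitrary positive values
rel_table <- function(values, condition, dates, taxa = NULL) {
  if (is.null(taxa)) taxa <- sprintf("t%02d", seq_len(nrow(values)))
  rownames(values) <- taxa
  rel <- sweep(values, 2, colSums(values), "/") * 100
  abundance_table(rel, condition, dates, units = "relative_percent", taxa = taxa)
}

# random simple digraph as an edge data frame
rand_digraph <- function(nv, p, seed) {
  set.seed(seed)
  adj <- matrix(stats::runif(nv * nv) < p, nv, nv)
  diag(adj) <- FALSE
  w <- which(adj, arr.ind = TRUE)
  data.frame(source = sprintf("n%02d", w[, 1]), target = sprintf("n%02d", w[, 2]),
             stringsAsFactors = FALSE)
}

# adjacency matrix from an edge list on 1..n labels
adj_from_edges <- function(edges, n) {
  a <- matrix(0L, n, n)
  for (e in edges) a[e[1], e[2]] <- 1L
  a
}

# brute-force all-subsets census oracle (independent of the ESU path)
census_oracle <- function(edges, n) {
  taxa <- sort(unique(c(edges$source, edges$target)))
  key <- paste(edges$source, edges$target)
  counts <- numeric(0)
  if (length(taxa) < n) return(counts)
  connected <- function(adj) {
    u <- (adj + t(adj)) > 0
    seen <- c(TRUE, rep(FALSE, nrow(adj) - 1))
    repeat {
      nxt <- which(colSums(u[seen, , drop = FALSE]) > 0 & !seen)
      if (length(nxt) == 0) break
      seen[nxt] <- TRUE
    }
    all(seen)
  }
  for (cmb in utils::combn(taxa, n, simplify = FALSE)) {
    adj <- matrix(0L, n, n)
    for (a in 1:n) for (b in 1:n) {
      if (a != b && paste(cmb[a], cmb[b]) %in% key) adj[a, b] <- 1L
    }
    if (sum(adj) == 0 || !connected(adj)) next
    id <- as.character(motif_id_canonical(adj))
    counts[id] <- if (is.na(counts[id])) 1 else counts[id] + 1
  }
  counts[order(as.integer(names(counts)))]
}

expect_census_equal <- function(got, want) {
  got <- got[order(as.integer(names(got)))]
  expect_equal(length(got), length(want))
  if (length(want) > 0) {
    expect_identical(names(got), names(want))
    expect_equal(unname(as.numeric(got)), unname(as.numeric(want)))
  }
}

# exhaustive shortest-path betweenness oracle for small digraphs
betweenness_oracle <- function(adj) {
  nv <- nrow(adj)
  dist <- matrix(Inf, nv, nv)
  for (s in 1:nv) {
    dist[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(u) which(adj[u, ] == 1))))
      nxt <- nxt[dist[s, nxt] == Inf]
      dist[s, nxt] <- d
      frontier <- nxt
    }
  }
  b <- numeric(nv)
  for (s in 1:nv) for (t in 1:nv) {
    if (s == t || !is.finite(dist[s, t])) next
    paths <- list()
    rec <- function(node, path) {
      if (node == t) {
        paths[[length(paths) + 1]] <<- path
        return(invisible())
      }
      for (u in which(adj[node, ] == 1)) {
        if (is.finite(dist[u, t]) && dist[u, t] == dist[node, t] - 1) {
          rec(u, c(path, u))
        }
      }
    }
    rec(s, s)
    for (p in paths) {
      for (v in setdiff(p, c(s, t))) b[v] <- b[v] + 1 / length(paths)
    }
  }
  b
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# depth-normalized, relative tables on a shared taxon universe (the
# pipeline's preprocessing, exposed for module-level tests)
prep_pair <- function(ds) {
  tc <- normalize_counts(ds$tableC)
  tb <- normalize_counts(ds$tableB)
  keep <- union(tc$taxa, tb$taxa)
  restrict <- function(tab) {
    miss <- setdiff(keep, tab$taxa)
    vals <- rbind(tab$values,
                  matrix(0, length(miss), ncol(tab$values),
                         dimnames = list(miss, colnames(tab$values))))
    abundance_table(vals[keep, , drop = FALSE], tab$samples$condition,
                    tab$samples$date_index, "counts", taxa = keep)
  }
  list(C = to_relative(restrict(tc)), B = to_relative(restrict(tb)))
}
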