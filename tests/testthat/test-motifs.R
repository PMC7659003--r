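test_that("the encoding reproduces the published 3-node motif dictionary", {
  conv <- adj_from_edges(list(c(2, 1), c(3, 1)), 3)
  expect_equal(motif_id_encode(conv), 36L)
  cyc <- adj_from_edges(list(c(1, 3), c(3, 2), c(2, 1)), 3)
  expect_equal(motif_id_encode(cyc), 98L)
  ff <- adj_from_edges(list(c(2, 1), c(3, 1), c(3, 2)), 3)
  expect_equal(motif_id_encode(ff), 38L)
  loop <- diag(3)
  expect_error(motif_id_encode(loop), "self-loop")

  # canonical ids: convergence 36, divergence 6, chain 12, feed-forward 38,
  # cycle 98, reciprocal hub 78, dyad-plus-in-edge 74
  div <- adj_from_edges(list(c(1, 2), c(1, 3)), 3)
  chain <- adj_from_edges(list(c(1, 2), c(2, 3)), 3)
  hub <- adj_from_edges(list(c(1, 3), c(3, 1), c(2, 3), c(3, 2)), 3)
  dyad <- adj_from_edges(list(c(2, 3), c(3, 2), c(1, 3)), 3)
  expect_equal(motif_id_canonical(conv), 36L)
  expect_equal(motif_id_canonical(div), 6L)
  expect_equal(motif_id_canonical(chain), 12L)
  expect_equal(motif_id_canonical(ff), 38L)
  expect_equal(motif_id_canonical(cyc), 98L)
  expect_equal(motif_id_canonical(hub), 78L)
  expect_equal(motif_id_canonical(dyad), 74L)
  # every relabeling of the cycle maps to the same canonical id
  perms <- perturbnet:::.permutations(3)
  for (p in seq_len(nrow(perms))) {
    expect_equal(motif_id_canonical(cyc[perms[p, ], perms[p, ]]), 98L)
  }
})

test_that("decode inverts encode and rejects self-loop bits", {
  for (id in c(6L, 12L, 36L, 38L, 74L, 78L, 98L)) {
    adj <- motif_id_decode(3, id)
    expect_equal(motif_id_encode(adj), id)
    expect_equal(motif_id_canonical(adj), id)  # canonical ids are fixed points
  }
  # bit for cell (1,1) has weight 2^(9-1) = 256
  expect_error(motif_id_decode(3, 256), "self-loop")
})

test_that("exhaustive enumeration finds 13 and 199 connected classes", {
  expect_equal(length(motif_classes(3)), 13)
  expect_equal(length(motif_classes(4)), 199)
  expect_true(all(c(6, 12, 36, 38, 74, 78, 98) %in% motif_classes(3)))
  expect_true(all(c(404, 4418) %in% motif_classes(4)))
})

test_that("the census equals the brute-force all-subsets oracle", {
  cyc <- data.frame(source = c("a", "b", "c"), target = c("b", "c", "a"))
  expect_census_equal(motif_census(cyc, 3), c("98" = 1))
  expect_equal(length(motif_census(cyc[0, ], 3)), 0)
  for (seed in 1:10) {
    ed <- rand_digraph(sample(6:12, 1), 0.15, 400 + seed)
    if (nrow(ed) < 2) next
    for (n in 3:4) {
      expect_census_equal(motif_census(ed, n), census_oracle(ed, n))
    }
  }
})

test_that("randomization preserves degrees, edge count and reciprocity", {
  for (seed in 1:5) {
    ed <- rand_digraph(12, 0.25, 500 + seed)
    r <- randomize_network(ed, seed = seed)
    expect_equal(nrow(r), nrow(ed))
    expect_equal(table(factor(r$source, levels = unique(c(ed$source, ed$target)))),
                 table(factor(ed$source, levels = unique(c(ed$source, ed$target)))))
    expect_equal(table(factor(r$target, levels = unique(c(ed$source, ed$target)))),
                 table(factor(ed$target, levels = unique(c(ed$source, ed$target)))))
    mut <- function(e) sum(paste(e$target, e$source) %in% paste(e$source, e$target))
    expect_equal(mut(r), mut(ed))
    expect_equal(anyDuplicated(paste(r$source, r$target)), 0)
  }
  # a single-edge graph admits no switch
  one <- data.frame(source = "a", target = "b")
  expect_equal(randomize_network(one, seed = 1), one)
})

test_that("motif z-scores behave at the degenerate and significant ends", {
  # the 3-cycle admits no legal switch: null == real, z = 0 everywhere
  cyc <- data.frame(source = c("a", "b", "c"), target = c("b", "c", "a"))
  rec <- motif_significance(cyc, 3, n_random = 10, seed = 41)
  expect_equal(rec$z, 0)
  expect_false(any(rec$significant))
  # a graph overloaded with feed-forward triangles is flagged, but a type
  # below min_count never is
  set.seed(42)
  ed <- do.call(rbind, lapply(0:9, function(q) {
    a <- paste0("a", q); b <- paste0("b", q); c <- paste0("c", q)
    data.frame(source = c(a, a, b, c), target = c(b, c, c, paste0("a", (q + 1) %% 10)))
  }))
  rec2 <- motif_significance(ed, 3, n_random = 30, seed = 43)
  ffl <- rec2[rec2$canonical_id == 38, ]
  expect_equal(ffl$count_real, 10)
  expect_true(ffl$significant)
  low <- rec2[rec2$count_real < 4, ]
  if (nrow(low) > 0) expect_false(any(low$significant))
})

test_that("representative motifs need three of four strength levels", {
  mk <- function(id, sig) data.frame(strength = c(500, 1000, 1500, 2000),
                                     n = 4L, canonical_id = id,
                                     count_real = 10, null_mean = 1,
                                     null_sd = 1, z = 9, significant = sig)
  records <- rbind(mk(404L, c(TRUE, TRUE, TRUE, TRUE)),
                   mk(406L, c(TRUE, TRUE, TRUE, FALSE)),
                   mk(908L, c(TRUE, TRUE, FALSE, FALSE)))
  rep4 <- representative_motifs(records)
  expect_setequal(rep4$canonical_id, c(404, 406))
  expect_error(representative_motifs(mk(404L, rep(TRUE, 4))[1:2, ]),
               ">= 3 strength levels")
})

test_that("4-node types embed the expected 3-node types", {
  expect_true("74" %in% names(submotif_census(404)))
  # the directed 4-cycle embeds only the 2-edge chain (type 12)
  cyc4 <- motif_id_canonical(adj_from_edges(list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)), 4))
  expect_equal(names(submotif_census(cyc4)), "12")
  # any connected 4-node type with a reciprocal edge embeds a 3-node type
  # with a reciprocal edge
  has_mutual <- function(adj) any(adj == 1 & t(adj) == 1)
  for (id in motif_classes(4)) {
    adj <- motif_id_decode(4, id)
    if (!has_mutual(adj)) next
    subs <- as.integer(names(submotif_census(id)))
    expect_true(any(vapply(subs, function(s) has_mutual(motif_id_decode(3, s)),
                           logical(1))),
                info = paste("4-node type", id))
  }
})

test_that("correlated feedback fractions match a direct instance scan", {
  # one 4-node instance: 3-cycle a-b-c plus pendant edge d -> a
  g1 <- data.frame(source = c("a", "b", "c", "d"), target = c("b", "c", "a", "a"))
  type1 <- motif_id_canonical(adj_from_edges(list(c(1, 2), c(2, 3), c(3, 1), c(4, 1)), 4))
  # the cycle-plus-in-edge graph is the looped type 4418 (embeds the 98 cycle)
  expect_equal(type1, 4418L)
  expect_equal(correlated_feedback_fraction(g1, type1, c("a", "b", "c", "d")), 100)
  expect_equal(correlated_feedback_fraction(g1, type1, character(0)), 0)
  # "any" mode is weaker than "all"
  expect_equal(correlated_feedback_fraction(g1, type1, "a", mode = "any"), 100)
  expect_equal(correlated_feedback_fraction(g1, type1, "a", mode = "all"), 0)
  # absent motif type
  expect_true(is.na(correlated_feedback_fraction(g1, 404, "a")))
  # seeded random graph against a brute-force scan over collected instances
  ed <- rand_digraph(10, 0.3, 600)
  corr <- sprintf("n%02d", 1:5)
  for (ty in utils::head(as.integer(names(motif_census(ed, 4))), 5)) {
    got <- correlated_feedback_fraction(ed, ty, corr)
    cnt <- motif_census(ed, 4, collect_id = ty)
    inst <- attr(cnt, "instances")
    key <- paste(ed$source, ed$target)
    brute <- mean(apply(inst, 1, function(nodes) {
      for (tri in utils::combn(nodes, 3, simplify = FALSE)) {
        adj <- matrix(0L, 3, 3)
        for (a in 1:3) for (b in 1:3) {
          if (a != b && paste(tri[a], tri[b]) %in% key) adj[a, b] <- 1L
        }
        if (sum(adj) == 6 - 3 && all(rowSums(adj) == 1) && all(colSums(adj) == 1) &&
            motif_id_canonical(adj) == 98 && all(tri %in% corr)) return(TRUE)
      }
      FALSE
    })) * 100
    expect_equal(got, brute)
  }
})
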