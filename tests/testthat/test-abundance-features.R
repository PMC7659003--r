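test_that("abundance tables round-trip through TSV and report parse errors with context", {
  vals <- matrix(c(5, 0, 3, 2, 1, 4), 3, 2,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  md <- data.frame(sample = c("s1", "s2"), condition = c("C", "B"),
                   date_index = c(1, 1))
  tab <- abundance_table(vals, md$condition, md$date_index, taxa = rownames(vals))
  tsv <- tempfile(fileext = ".tsv")
  write_abundance_table(tab, tsv)
  back <- read_abundance_table(tsv, paste0(tsv, ".meta.tsv"))
  expect_equal(dim(back), c(3, 2))
  expect_equal(back$values, tab$values)
  expect_identical(back$taxa, tab$taxa)

  expect_error(abundance_table(matrix(c(1, -2), 1, 2,
                                      dimnames = list("a", c("s1", "s2"))),
                               c("C", "B"), c(1, 1)),
               "taxon 'a', sample 's2'")
  expect_error(abundance_table(vals, c("C", "C"), c(1, 1)), "duplicate")
  expect_error(abundance_table(vals, "C", 1), "one entry per sample")
  md_bad <- md[1, ]
  df <- data.frame(taxon = rownames(vals), vals, check.names = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_abundance_table(tsv, md_bad), "without metadata")
})

test_that("a study-shaped table (113 taxa x 14 samples) is accepted", {
  set.seed(8)
  vals <- matrix(rpois(113 * 14, 50), 113, 14)
  tab <- abundance_table(vals, rep(c("C", "B"), each = 7), rep(1:7, 2))
  expect_equal(dim(tab), c(113, 14))
})

test_that("depth normalization equalizes depths and applies the every-sample discard rule", {
  vals <- rbind(kept = c(600, 1300, 2500), weak = c(0.5, 1.5, 2),
                gone = c(0.6, 1.2, 2.1), absent = c(0, 0, 0))
  # make depths exactly 1000, 2000, 4000
  vals <- rbind(vals, filler = c(1000, 2000, 4000) - colSums(vals))
  tab <- abundance_table(vals, c("C", "C", "C"), 1:3)
  out <- normalize_counts(tab)
  # samples scaled by 1, 1/2, 1/4: the kept taxon becomes (600, 650, 625)
  expect_equal(unname(out$values["kept", ]), c(600, 650, 625))
  # weak: adjusted (0.5, 0.75, 0.5) -> < 1 everywhere -> discarded
  # gone: adjusted (0.6, 0.6, 0.525) -> discarded; kept reaches >= 1
  expect_setequal(attr(out, "discarded_taxa"), c("weak", "gone", "absent"))
  expect_true("kept" %in% out$taxa)
  # taxon reaching 1 in at least one sample is retained
  tab2 <- abundance_table(rbind(a = c(0.5, 1.2), b = c(100, 100)),
                          c("C", "C"), 1:2)
  expect_true("a" %in% normalize_counts(tab2)$taxa)
  expect_error(normalize_counts(abundance_table(rbind(a = c(1, 0)),
                                                c("C", "C"), 1:2)),
               "zero-depth")
})

test_that("relative conversion sums to 100, is idempotent and scaling-invariant", {
  tab <- abundance_table(rbind(a = c(1, 2), b = c(1, 3), c = c(2, 5)),
                         c("C", "C"), 1:2)
  rel <- to_relative(tab)
  expect_equal(unname(rel$values[, 1]), c(25, 25, 50))
  expect_equal(to_relative(rel)$values, rel$values, tolerance = 1e-9)
  set.seed(3)
  rnd <- abundance_table(matrix(runif(60, 0.1, 10), 10, 6),
                         rep("C", 6), 1:6)
  expect_equal(unname(colSums(to_relative(rnd)$values)), rep(100, 6),
               tolerance = 1e-6)
  # normalize then relative equals relative alone (no taxon discarded here)
  expect_equal(to_relative(normalize_counts(rnd))$values,
               to_relative(rnd)$values, tolerance = 1e-9)
  expect_error(to_relative(abundance_table(rbind(a = c(1, 0)), c("C", "C"), 1:2)),
               "all-zero")
})

test_that("mean over detected samples follows the nonzero denominator", {
  expect_equal(mean_nonzero(c(2, 0, 4)), 3)
  expect_equal(mean_nonzero(c(5, 5, 5)), 5)
  expect_equal(mean_nonzero(c(0, 0, 0)), 0)
})

test_that("abundance levels partition taxa with inclusive low-level boundaries", {
  expect_equal(classify_level(1.5, c(1, 2))[c("level", "core", "nR")],
               list(level = "H", core = TRUE, nR = FALSE))
  r <- classify_level(0.05, c(0.1, 0, 0.05))
  expect_equal(r$level, "R")
  expect_false(r$core)
  expect_true(r$nR)
  expect_equal(classify_level(0.1, c(0.1, 0.1))$level, "L")
  expect_equal(classify_level(1, c(1, 1))$level, "L")
  set.seed(4)
  lv <- vapply(10^runif(200, -3, 1.2),
               function(m) classify_level(m, 1)$level, character(1))
  expect_true(all(lv %in% c("H", "L", "R")))
})

test_that("diversity indices match closed forms", {
  di <- diversity_indices(rep(25, 4))
  expect_equal(unname(di["shannon"]), log(4), tolerance = 1e-9)
  expect_equal(unname(di["inv_simpson"]), 4, tolerance = 1e-9)
  di1 <- diversity_indices(c(100, 0, 0))
  expect_equal(unname(di1["shannon"]), 0)
  expect_equal(unname(di1["inv_simpson"]), 1)
  # S_obs = 10, F1 = 4, F2 = 2 -> 10 + 16/4 = 14
  cnt <- c(rep(1, 4), rep(2, 2), rep(5, 4))
  expect_equal(unname(diversity_indices(cnt, counts = cnt)["chao1"]), 14)
  cnt0 <- c(rep(1, 3), rep(5, 2))  # F2 = 0 fallback: 5 + 3*2/2 = 8
  expect_equal(unname(diversity_indices(cnt0, counts = cnt0)["chao1"]), 8)
  expect_error(diversity_indices(numeric(0)), "empty")
})

test_that("paired test matches the closed-form t statistic and maps directions", {
  cp <- 1:7
  bp <- cp + c(1, 1, 1, 1, 1, 1, 1.5)
  d <- bp - cp
  t_manual <- mean(d) / (sd(d) / sqrt(7))
  p_manual <- 2 * pt(-abs(t_manual), df = 6)
  res <- paired_diff_test(cp, bp)
  expect_equal(t_manual, 15, tolerance = 1e-12)  # engineered case
  expect_equal(res$p, p_manual, tolerance = 1e-12)
  expect_equal(res$diff_status, "Diff_UP")

  expect_equal(paired_diff_test(cp, cp), list(diff_status = "NDiff_DN", p = 1,
                                              mean_diff = 0))
  # constant nonzero shift: perfectly consistent, p = 0
  expect_equal(paired_diff_test(cp, cp + 2)$p, 0)
  # antisymmetry: swapping conditions flips direction, preserves p
  set.seed(5)
  for (rep in 1:20) {
    a <- runif(7)
    b <- runif(7)
    r1 <- paired_diff_test(a, b)
    r2 <- paired_diff_test(b, a)
    expect_equal(r1$p, r2$p)
    expect_equal(gsub("UP|DN", "", r1$diff_status),
                 gsub("UP|DN", "", r2$diff_status))
    expect_equal(grepl("UP", r1$diff_status), grepl("DN", r2$diff_status))
  }
})

test_that("presence partition is disjoint and covers all present taxa", {
  tc <- abundance_table(rbind(a = c(1, 2), b = c(0, 0)), c("C", "C"), 1:2)
  tb <- abundance_table(rbind(a = c(0, 0), b = c(3, 1)), c("B", "B"), 1:2)
  pp <- presence_partition(tc, tb)
  expect_equal(pp$shared, character(0))
  expect_equal(pp$C_only, "a")
  expect_equal(pp$B_only, "b")
  set.seed(6)
  for (rep in 1:10) {
    vc <- matrix(rbinom(40, 1, 0.5) * runif(40), 10, 4)
    vb <- matrix(rbinom(40, 1, 0.5) * runif(40), 10, 4)
    rownames(vc) <- rownames(vb) <- sprintf("t%02d", 1:10)
    tc <- abundance_table(vc, rep("C", 4), 1:4)
    tb <- abundance_table(vb, rep("B", 4), 1:4)
    pp <- presence_partition(tc, tb)
    present <- sum(rowSums(vc) > 0 | rowSums(vb) > 0)
    expect_equal(length(pp$shared) + length(pp$C_only) + length(pp$B_only),
                 present)
    expect_equal(anyDuplicated(unlist(pp)), 0)
  }
})

test_that("taxon annotation combines level, core and differential calls", {
  set.seed(7)
  base <- matrix(rlnorm(20 * 7, 0, 0.2), 20, 7)
  vb <- base
  vb[1, ] <- vb[1, ] * 3       # strong planted increase
  tc <- rel_table(base, rep("C", 7), 1:7)
  tb <- rel_table(vb, rep("B", 7), 1:7)
  ann <- annotate_taxa(tc, tb)
  expect_equal(nrow(ann), 20)
  expect_true(all(ann$level %in% c("H", "L", "R")))
  expect_equal(ann$diff_status[1], "Diff_UP")
  expect_true(all(ann$diff_p >= 0 & ann$diff_p <= 1))
  # nR implies rare and not core
  expect_true(all(!ann$nR | (ann$level == "R" & !ann$core)))
})
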