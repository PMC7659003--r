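test_that("the worked 2-taxon case is recovered from its own simulation", {
  model <- list(b = c(0.1, -0.1),
                A = matrix(c(-0.01, 0.02, 0, -0.03), 2, 2))
  x <- simulate_glv(model, c(5, 5), n_steps = 6)
  tab <- abundance_table(x, rep("C", 7), 1:7)
  fit <- fit_glv(tab, ridge = 0)
  expect_equal(unname(fit$b), model$b, tolerance = 1e-6)
  expect_equal(unname(fit$A), unname(model$A), tolerance = 1e-6)
})

test_that("noiseless community data is recovered as a linear-algebra identity", {
  set.seed(21)
  model <- gen_interactions(20, density = 0.2, self_limitation = 0.3)
  x0 <- model$xstar * exp(rnorm(20, 0, 0.4))
  x <- simulate_glv(model, x0, n_steps = 40)
  fit <- fit_glv(abundance_table(x, rep("C", 41), 1:41), ridge = 0)
  expect_lt(max(abs(fit$A - model$A)), 1e-6)
  expect_lt(max(abs(fit$b - model$b)), 1e-6)
})

test_that("degenerate inputs give zero coefficients or flags", {
  # constant series: log growth identically zero -> coefficients zero
  x <- matrix(rep(c(2, 3, 1), 5), 3, 5)
  fit <- fit_glv(abundance_table(x, rep("C", 5), 1:5), ridge = 1e-3)
  expect_equal(max(abs(fit$A)), 0)
  expect_equal(max(abs(fit$b)), 0)
  # a taxon that is always zero has no usable transition and is flagged
  x2 <- rbind(matrix(rlnorm(4 * 6), 4, 6), 0)
  fit2 <- fit_glv(abundance_table(x2, rep("C", 6), 1:6,
                                  taxa = sprintf("t%d", 1:5)), ridge = 1e-3)
  expect_equal(fit2$flagged, "t5")
  expect_equal(unname(fit2$A["t5", ]), rep(0, 5))
})

test_that("ensemble inclusion matches the member fraction and is deterministic", {
  set.seed(22)
  model <- gen_interactions(12, density = 0.25, self_limitation = 0.3)
  x <- simulate_glv(model, model$xstar * exp(rnorm(12, 0, 0.4)),
                    n_steps = 20, process_noise_sd = 0.05)
  tab <- abundance_table(x, rep("C", 21), 1:21)
  st1 <- ensemble_infer(tab, n_networks = 150, member_frac = 0.75, seed = 9)
  st2 <- ensemble_infer(tab, n_networks = 150, member_frac = 0.75, seed = 9)
  expect_identical(st1, st2)
  # inclusion frequency of a taxon ~ Binomial(n_networks, member_frac)
  # (diagonal pairs are excluded; use n_observed of a fixed ordered pair
  # relative to pairwise inclusion m(m-1)/(n(n-1)))
  m <- floor(0.75 * 12)
  p_pair <- m * (m - 1) / (12 * 11)
  expect_lt(abs(mean(st1$n_observed) / 150 - p_pair), 0.02)
  sd3 <- 3 * sqrt(150 * p_pair * (1 - p_pair))
  expect_true(all(abs(st1$n_observed - 150 * p_pair) <= sd3 + 3))
})

test_that("full-membership ensembles on identifiable data are fully coherent", {
  set.seed(23)
  model <- gen_interactions(8, density = 0.4, self_limitation = 0.3)
  x <- simulate_glv(model, model$xstar * exp(rnorm(8, 0, 0.5)), n_steps = 16)
  tab <- abundance_table(x, rep("C", 17), 1:17)
  st <- ensemble_infer(tab, n_networks = 25, member_frac = 1, ridge = 0, seed = 2)
  true_edges <- which(model$A != 0 & row(model$A) != col(model$A), arr.ind = TRUE)
  for (q in seq_len(nrow(true_edges))) {
    i <- true_edges[q, 1]; j <- true_edges[q, 2]
    row <- st[st$target == model$taxa[i] & st$source == model$taxa[j], ]
    expect_equal(row$coherence, 1)
    expect_equal(row$sign, if (model$A[i, j] > 0) "+" else "-")
  }
})

test_that("reliability combines the coherence rule with the exact binomial test", {
  mk <- function(n_pos, n_neg) {
    data.frame(source = "a", target = "b", sign = "+", strength = 1,
               coherence = max(n_pos, n_neg) / (n_pos + n_neg),
               n_observed = n_pos + n_neg, n_signed = n_pos + n_neg,
               n_pos = n_pos, n_neg = n_neg)
  }
  expect_equal(nrow(reliability_filter(mk(190, 10))), 1)   # coherence 0.95
  expect_equal(nrow(reliability_filter(mk(160, 40))), 0)   # coherence 0.80
  # coherence 1 over 3 runs: binomial p = 0.125 -> not reliable
  expect_equal(nrow(reliability_filter(mk(3, 0))), 0)
  expect_equal(pbinom(2, 3, 0.5, lower.tail = FALSE), 0.125)
  # monotone in the threshold
  set.seed(24)
  many <- do.call(rbind, lapply(1:50, function(q) {
    np <- rbinom(1, 100, 0.9)
    df <- mk(np, 100 - np)
    df$source <- paste0("s", q)
    df
  }))
  e90 <- reliability_filter(many, 0.9)
  e95 <- reliability_filter(many, 0.95)
  expect_lte(nrow(e95), nrow(e90))
  expect_true(all(paste(e95$source, e95$target) %in%
                    paste(e90$source, e90$target)))
})

test_that("top-k selection is ordered, tie-stable and caps at the edge count", {
  set.seed(25)
  ed <- data.frame(source = sprintf("s%02d", 1:40),
                   target = sprintf("t%02d", sample(40)),
                   strength = sample(rep(runif(20), 2)))
  expect_equal(nrow(top_k_edges(ed, 100)), 40)
  expect_identical(top_k_edges(ed, 100)$strength, sort(ed$strength, decreasing = TRUE))
  kept <- top_k_edges(ed, 15)
  excl <- setdiff(paste(ed$source, ed$target), paste(kept$source, kept$target))
  expect_gte(min(kept$strength),
             max(ed$strength[paste(ed$source, ed$target) %in% excl]))
  # deterministic tie-break
  expect_identical(top_k_edges(ed, 15), top_k_edges(ed[sample(40), ], 15))
})

test_that("simulation fit score rewards self-consistency and degrades with noise", {
  # zero model on constant data scores 1
  zero <- list(b = rep(0, 3), A = matrix(0, 3, 3))
  tab <- abundance_table(matrix(rep(c(1, 2, 3), 5), 3, 5), rep("C", 5), 1:5)
  expect_equal(simulation_fit_score(zero, tab), 1)
  # model refit on its own noiseless output scores ~1
  set.seed(26)
  model <- gen_interactions(6, density = 0.4, self_limitation = 0.3)
  x <- simulate_glv(model, model$xstar * exp(rnorm(6, 0, 0.4)), n_steps = 12)
  tabx <- abundance_table(x, rep("C", 13), 1:13)
  fit <- fit_glv(tabx, ridge = 0)
  expect_gte(simulation_fit_score(fit, tabx), 0.99)
  # increasing process noise degrades the score of the noiseless model
  scores <- vapply(c(0, 0.3, 1), function(s) {
    xs <- simulate_glv(model, model$xstar, n_steps = 12,
                       process_noise_sd = s, seed = 31)
    simulation_fit_score(model, abundance_table(xs, rep("C", 13), 1:13))
  }, numeric(1))
  expect_gt(scores[1], scores[2])
  expect_gt(scores[2], scores[3])
})
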