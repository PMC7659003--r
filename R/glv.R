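#' Fit a generalized Lotka-Volterra model by gradient matching
#'
#' For each taxon i the discrete per-capita log growth
#' \eqn{y_i(k) = \ln(x_i(k+1)/x_i(k)) / \Delta t_k} is regressed on an
#' intercept plus the abundances of all taxa at time k, by
#' ridge-regularized least squares (the intercept is not penalized).
#' The intercept estimates the intrinsic growth rate \eqn{b_i} and the
#' slope on taxon j estimates the interaction coefficient \eqn{a_{ij}}
#' (effect of j on i, i.e. a directed edge j -> i).  Transitions where a
#' taxon is zero at either endpoint are skipped for that taxon (its log
#' growth is undefined there); a taxon with no usable transition gets an
#' all-zero row and is flagged.
#'
#' @param table An [abundance_table()] restricted to one condition with
#'   >= 3 time points (use [subset_condition()]).
#' @param ridge Ridge penalty (default `1e-3`; use 0 for plain least
#'   squares, which falls back to a pivoting minimum-norm fit when the
#'   design is rank deficient).
#' @return Object of class `glv_model`: list with `b` (growth-rate
#'   vector), `A` (interaction matrix, rows = target taxon i, columns =
#'   source taxon j), `taxa` and `flagged` (taxa with no usable
#'   transition).
#' @export
fit_glv <- function(table, ridge = 1e-3) {
  stopifnot(inherits(table, "abundance_table"))
  ord <- order(table$samples$date_index)
  x <- table$values[, ord, drop = FALSE]
  dts <- diff(table$samples$date_index[ord])
  tt <- ncol(x)
  if (tt < 3) stop("need >= 3 time points")
  n <- nrow(x)
  ntr <- tt - 1
  # usable transition mask per taxon: strictly positive at both endpoints
  usable <- (x[, 1:ntr, drop = FALSE] > 0) & (x[, 2:tt, drop = FALSE] > 0)
  y <- matrix(NA_real_, n, ntr)
  y[usable] <- (log(x[, 2:tt, drop = FALSE] / x[, 1:ntr, drop = FALSE]) /
                  rep(dts, each = n))[usable]
  design <- cbind(1, t(x[, 1:ntr, drop = FALSE]))  # ntr x (n+1)

  b <- numeric(n)
  A <- matrix(0, n, n, dimnames = list(table$taxa, table$taxa))
  flagged <- logical(n)
  # taxa sharing a usable-transition mask share a design matrix: solve in groups
  keys <- apply(usable, 1, function(u) paste(as.integer(u), collapse = ""))
  for (key in unique(keys)) {
    rows <- which(keys == key)
    tr <- which(usable[rows[1], ])
    if (length(tr) == 0) {
      flagged[rows] <- TRUE
      next
    }
    Z <- design[tr, , drop = FALSE]
    Y <- t(y[rows, tr, drop = FALSE])
    if (ridge > 0) {
      P <- diag(c(0, rep(ridge, n)))
      coefs <- solve(crossprod(Z) + P, crossprod(Z, Y))
    } else {
      coefs <- stats::lm.fit(Z, Y)$coefficients
      coefs[is.na(coefs)] <- 0
    }
    coefs <- matrix(coefs, ncol = length(rows))
    b[rows] <- coefs[1, ]
    A[rows, ] <- t(coefs[-1, , drop = FALSE])
  }
  structure(list(b = stats::setNames(b, table$taxa), A = A, taxa = table$taxa,
                 flagged = table$taxa[flagged]),
            class = "glv_model")
}

#' @export
print.glv_model <- function(x, ...) {
  cat(sprintf("glv_model: %d taxa, %d nonzero interactions\n",
              length(x$taxa), sum(x$A != 0) - sum(diag(x$A) != 0)))
  invisible(x)
}

#' Simulate a discrete-time generalized Lotka-Volterra community
#'
#' Multiplicative update
#' \eqn{x_i(k+1) = x_i(k) \exp(\Delta t (b_i + \sum_j a_{ij} x_j(k)) + \epsilon)}
#' with optional Gaussian process noise; values falling below
#' `extinction_floor` are set to 0 (and stay there, since the update is
#' multiplicative).  This forward model is exactly the one [fit_glv()]
#' inverts, so noiseless recovery is a linear-algebra identity.
#'
#' @param model A `glv_model` (or list with `b` and `A`).
#' @param x0 Strictly positive initial abundance vector.
#' @param n_steps Number of update steps (output has `n_steps + 1` columns).
#' @param dt Time step.
#' @param process_noise_sd SD of the per-taxon, per-step log-scale noise.
#' @param extinction_floor Abundances below this are set to 0 (default 0:
#'   no extinction).
#' @param seed Optional RNG seed.
#' @param cap Abundances above `cap` are truncated with a warning.
#' @return Matrix taxa x (n_steps + 1).
#' @export
simulate_glv <- function(model, x0, n_steps, dt = 1, process_noise_sd = 0,
                         extinction_floor = 0, seed = NULL, cap = 1e8) {
  if (!is.null(seed)) set.seed(seed)
  b <- model$b
  A <- model$A
  n <- length(b)
  stopifnot(length(x0) == n, all(x0 > 0))
  out <- matrix(0, n, n_steps + 1)
  rownames(out) <- rownames(A)
  out[, 1] <- x0
  warned <- FALSE
  for (k in seq_len(n_steps)) {
    x <- out[, k]
    growth <- dt * (b + as.vector(A %*% x))
    if (process_noise_sd > 0) {
      growth <- growth + stats::rnorm(n, 0, process_noise_sd)
    }
    xn <- x * exp(growth)
    if (any(!is.finite(xn)) || any(xn > cap)) {
      xn[!is.finite(xn) | xn > cap] <- cap
      if (!warned) {
        warning("trajectory overflow truncated at cap = ", cap)
        warned <- TRUE
      }
    }
    xn[xn < extinction_floor] <- 0
    out[, k + 1] <- xn
  }
  out
}

#' Ensemble network inference by taxon subsampling
#'
#' Fits [fit_glv()] on many random subsets of the community (default the
#' protocol parameters: 1000 networks, each on 90% of the taxa) and
#' aggregates, per ordered taxon pair, the sign outcomes of the
#' interaction coefficient across runs.  A run contributes a signed
#' outcome for pair j -> i whenever both taxa are included and
#' \eqn{|a_{ij}|} exceeds `magnitude_floor`.  Coherence is the modal-sign
#' fraction among signed outcomes; strength is the median \eqn{|a_{ij}|}
#' over the modal-sign runs.
#'
#' @param table One-condition [abundance_table()].
#' @param n_networks Number of ensemble fits (default 1000).
#' @param member_frac Fraction of taxa per fit (default 0.9).
#' @param ridge Ridge penalty passed to [fit_glv()].
#' @param seed Optional RNG seed.
#' @param magnitude_floor Coefficients at or below this magnitude count
#'   as numerically zero, not as signed outcomes.
#' @return Data frame (class also `interaction_stats`) with one row per
#'   ordered pair observed at least once: `source`, `target`, `sign`,
#'   `strength`, `coherence`, `n_observed`, `n_signed`, `n_pos`, `n_neg`.
#' @export
ensemble_infer <- function(table, n_networks = 1000, member_frac = 0.9,
                           ridge = 1e-3, seed = NULL,
                           magnitude_floor = 1e-10) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_networks >= 1, member_frac > 0, member_frac <= 1)
  n <- nrow(table$values)
  m <- floor(member_frac * n)
  if (m < 2) stop("member_frac leaves fewer than 2 taxa")
  vals <- array(NA_real_, c(n, n, n_networks))
  for (r in seq_len(n_networks)) {
    idx <- sort(sample.int(n, m))
    # sub-community columns no longer sum to 100; units flag is irrelevant
    # to the regression, so the subset is carried as a plain-value table
    sub <- abundance_table(table$values[idx, , drop = FALSE],
                           table$samples$condition, table$samples$date_index,
                           units = "counts", taxa = table$taxa[idx])
    fit <- fit_glv(sub, ridge = ridge)
    vals[idx, idx, r] <- fit$A
  }
  n_obs <- rowSums(!is.na(vals), dims = 2)
  n_pos <- rowSums(vals > magnitude_floor, na.rm = TRUE, dims = 2)
  n_neg <- rowSums(vals < -magnitude_floor, na.rm = TRUE, dims = 2)

  pairs <- which(n_obs > 0 & row(n_obs) != col(n_obs), arr.ind = TRUE)
  res <- data.frame(
    source = table$taxa[pairs[, 2]], target = table$taxa[pairs[, 1]],
    sign = NA_character_, strength = NA_real_, coherence = NA_real_,
    n_observed = n_obs[pairs], n_signed = n_pos[pairs] + n_neg[pairs],
    n_pos = n_pos[pairs], n_neg = n_neg[pairs], stringsAsFactors = FALSE)
  for (q in seq_len(nrow(pairs))) {
    i <- pairs[q, 1]; j <- pairs[q, 2]
    np <- n_pos[i, j]; nn <- n_neg[i, j]
    if (np + nn == 0) next
    v <- vals[i, j, ]
    if (np >= nn) {
      res$sign[q] <- "+"
      res$strength[q] <- stats::median(v[!is.na(v) & v > magnitude_floor])
      res$coherence[q] <- np / (np + nn)
    } else {
      res$sign[q] <- "-"
      res$strength[q] <- stats::median(abs(v[!is.na(v) & v < -magnitude_floor]))
      res$coherence[q] <- nn / (np + nn)
    }
  }
  res <- res[order(res$source, res$target), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("interaction_stats", "data.frame")
  res
}

#' Filter ensemble edge statistics to reliable interactions
#'
#' An interaction is reliable when its sign coherence reaches
#' `coherence_threshold` (default the 90% rule) and a one-sided exact
#' binomial test of the modal-sign count against a null proportion of
#' 0.5 is significant at `alpha`.
#'
#' @param stats_df Output of [ensemble_infer()].
#' @param coherence_threshold Minimum modal-sign fraction (default 0.9).
#' @param alpha Significance level of the binomial proportion test.
#' @return Data frame of retained edges: `source`, `target`, `sign`,
#'   `strength`, `coherence`, `n_observed`, `p_prop`, `reliable`
#'   (all `TRUE`), sorted by decreasing strength.
#' @export
reliability_filter <- function(stats_df, coherence_threshold = 0.9,
                               alpha = 0.05) {
  stopifnot(coherence_threshold > 0.5, coherence_threshold <= 1)
  modal <- pmax(stats_df$n_pos, stats_df$n_neg)
  n_signed <- stats_df$n_pos + stats_df$n_neg
  p_prop <- ifelse(n_signed > 0,
                   stats::pbinom(modal - 1, n_signed, 0.5, lower.tail = FALSE),
                   NA_real_)
  keep <- !is.na(stats_df$coherence) &
    stats_df$coherence >= coherence_threshold & !is.na(p_prop) & p_prop < alpha
  out <- stats_df[keep, c("source", "target", "sign", "strength",
                          "coherence", "n_observed"), drop = FALSE]
  out$p_prop <- p_prop[keep]
  out$reliable <- rep(TRUE, nrow(out))
  out <- out[order(-out$strength, out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strongest-k interactions of a network
#'
#' Returns the `k` reliable edges of largest strength, breaking boundary
#' ties by (source, target) lexicographic order; `k` larger than the edge
#' count returns all edges.
#'
#' @param edges Edge data frame with `source`, `target`, `strength`.
#' @param k Number of edges to keep (`Inf` for all).
#' @return The sub-network's edge data frame.
#' @export
top_k_edges <- function(edges, k) {
  stopifnot(k >= 1)
  ord <- order(-edges$strength, edges$source, edges$target)
  out <- edges[ord[seq_len(min(k, nrow(edges)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Forward-simulation fit score of a gLV model
#'
#' Simulates the model forward from the first observed sample and scores
#' the agreement with the observed trajectory as one minus the mean
#' Bray-Curtis dissimilarity over time points (in \[0, 1\]).  A diverging
#' simulation scores 0 with a warning.
#'
#' @param model A `glv_model`.
#' @param table The one-condition [abundance_table()] it was fit to.
#' @return Scalar score in \[0, 1\].
#' @export
simulation_fit_score <- function(model, table) {
  ord <- order(table$samples$date_index)
  x <- table$values[, ord, drop = FALSE]
  tt <- ncol(x)
  x0 <- x[, 1]
  x0[x0 <= 0] <- min(x0[x0 > 0]) / 2  # simulation needs positive start
  sim <- tryCatch(
    withCallingHandlers(
      simulate_glv(model, x0, n_steps = tt - 1),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (is.null(sim) || any(!is.finite(sim)) || any(colSums(sim) <= 0) ||
      max(sim) >= 1e8) {
    warning("simulation diverged; score 0")
    return(0)
  }
  bc <- vapply(seq_len(tt), function(k) {
    vegan::vegdist(rbind(sim[, k], x[, k]), method = "bray")[1]
  }, numeric(1))
  max(0, min(1, 1 - mean(bc)))
}
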