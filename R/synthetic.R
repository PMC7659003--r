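#' Draw a random sparse gLV interaction model
#'
#' Off-diagonal interactions are present independently with probability
#' `density`; a `negative_fraction` share of the present ones are
#' negative (competition/inhibition), the rest positive.  Magnitudes are
#' half-normal with scale `magnitude_scale` (default
#' `0.3 / sqrt(density * n_taxa)`, which keeps the community spectral
#' radius well inside the stable region).  Diagonal entries are negative
#' (self-limitation).  Growth rates are set so that a drawn lognormal
#' abundance profile `xstar` is a fixed point (`b = -A xstar`), and each
#' row of the interaction matrix is scaled by `1 / xstar_i` so the
#' community Jacobian at the fixed point is independent of the abundance
#' unevenness — giving stationary, stable, identifiable dynamics around a
#' realistic uneven community.
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param density Off-diagonal interaction probability in (0, 1].
#' @param negative_fraction Fraction of negative interactions.
#' @param magnitude_scale Half-normal scale of interaction magnitudes.
#' @param self_limitation Magnitude of the (negative) diagonal.
#' @param seed Optional RNG seed.
#' @return A `glv_model` with extra elements `xstar` (the equilibrium
#'   profile) and the generator parameters.
#' @export
gen_interactions <- function(n_taxa, density = 0.1, negative_fraction = 0.7,
                             magnitude_scale = NULL, self_limitation = 0.5,
                             seed = NULL) {
  stopifnot(n_taxa >= 2, density > 0, density <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(magnitude_scale)) {
    magnitude_scale <- 0.3 / sqrt(density * n_taxa)
  }
  taxa <- sprintf("taxon_%03d", seq_len(n_taxa))
  A <- matrix(0, n_taxa, n_taxa, dimnames = list(taxa, taxa))
  off <- which(row(A) != col(A))
  present <- off[stats::runif(length(off)) < density]
  signs <- ifelse(stats::runif(length(present)) < negative_fraction, -1, 1)
  A[present] <- signs * abs(stats::rnorm(length(present), 0, magnitude_scale))
  diag(A) <- -self_limitation
  xstar <- stats::rlnorm(n_taxa, meanlog = 0, sdlog = 1.2)
  names(xstar) <- taxa
  A <- A / xstar  # row scaling: Jacobian at xstar is I + dt * (A * xstar)
  b <- -as.vector(A %*% xstar)
  structure(list(b = stats::setNames(b, taxa), A = A, taxa = taxa,
                 flagged = character(0), xstar = xstar,
                 params = list(density = density,
                               negative_fraction = negative_fraction,
                               magnitude_scale = magnitude_scale,
                               self_limitation = self_limitation)),
            class = "glv_model")
}

#' Plant correlated trajectory templates into paired condition data
#'
#' Replaces designated taxa's trajectories, in both conditions
#' congruently, by one of three date-indexed templates — `ascent`
#' (monotone rise from 0.5 to 1.5 times the taxon's scale), `descent`
#' (the mirror image) or `convex` (symmetric rise-then-fall peaking
#' mid-series) — plus independent Gaussian noise per condition, so that
#' each planted taxon's control and perturbed trajectories are highly
#' self-correlated by construction.
#'
#' @param trajC,trajB Taxa x time matrices (same taxa and time points).
#' @param groups Named list of taxon-index (or rowname) vectors with
#'   names among `ascent`, `descent`, `convex`; groups must be disjoint.
#' @param noise_sd Gaussian noise SD relative to the taxon scale.
#' @param seed Optional RNG seed.
#' @param scale Per-taxon template scale; default each taxon's own mean
#'   across both input matrices (floored at a small positive value).
#' @return List with modified `C` and `B` matrices.
#' @export
plant_patterns <- function(trajC, trajB, groups, noise_sd = 0, seed = NULL,
                           scale = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(dim(trajC) == dim(trajB)))
  all_idx <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_idx)) stop("pattern groups must be disjoint")
  tt <- ncol(trajC)
  if (tt < 4) stop("template longer than series: need >= 4 time points")
  u <- seq(0, 1, length.out = tt)
  templates <- list(
    ascent = 0.5 + u,
    descent = 1.5 - u,
    convex = 1.5 - 4 * (u - 0.5)^2  # 0.5 at the ends, peak 1.5 mid-series
  )
  for (gname in names(groups)) {
    if (!gname %in% names(templates)) stop("unknown pattern group: ", gname)
    for (i in groups[[gname]]) {
      ri <- if (is.character(i)) match(i, rownames(trajC)) else i
      sc <- if (is.null(scale)) {
        max(mean(c(trajC[ri, ], trajB[ri, ])), 1e-3)
      } else scale
      base <- templates[[gname]] * sc
      trajC[ri, ] <- pmax(base + stats::rnorm(tt, 0, noise_sd * sc), 0)
      trajB[ri, ] <- pmax(base + stats::rnorm(tt, 0, noise_sd * sc), 0)
    }
  }
  list(C = trajC, B = trajB)
}

#' Multinomial read-count sampling of relative trajectories
#'
#' Draws each sample's sequencing depth from a truncated (at 1) rounded
#' normal and distributes it over taxa by a multinomial on the sample's
#' relative abundances, so column sums equal the drawn depths exactly.
#' The default depth parameters emulate a MiSeq 16S family-level run
#' (19,392 +/- 982 reads per sample).
#'
#' @param rel Taxa x samples matrix of relative abundances (any positive
#'   scale; columns are normalized internally).
#' @param depth_mean,depth_sd Normal depth parameters.
#' @param seed Optional RNG seed.
#' @return Integer matrix of counts with the dimensions of `rel`.
#' @export
sample_counts <- function(rel, depth_mean = 19392, depth_sd = 982,
                          seed = NULL) {
  stopifnot(depth_mean > 0)
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(0L, nrow(rel), ncol(rel), dimnames = dimnames(rel))
  for (k in seq_len(ncol(rel))) {
    depth <- max(1, round(stats::rnorm(1, depth_mean, depth_sd)))
    p <- rel[, k] / sum(rel[, k])
    out[, k] <- stats::rmultinom(1, depth, p)[, 1]
  }
  out
}

#' Default configuration of the synthetic community generator
#'
#' The defaults emulate the shape of a family-level anaerobic-digester
#' time series: 113 taxa over 7 paired dates per condition, sequencing
#' depth 19,392 +/- 982 reads, 25 planted correlated-trajectory taxa
#' split over ascent/descent/convex groups, 33 planted differential taxa,
#' and one invader taxon absent from the control and held at a constant
#' low relative abundance (0.4%) after the perturbation.
#'
#' @param ... Overrides of the listed defaults.
#' @return Named list of generator settings.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    n_taxa = 113, n_dates = 7,
    depth_mean = 19392, depth_sd = 982,
    density = 0.1, negative_fraction = 0.7,
    magnitude_scale = NULL, self_limitation = 0.5,
    process_noise_sd = 0.05,
    n_pattern = c(ascent = 8, descent = 8, convex = 9),
    pattern_noise_sd = 0.05,
    n_diff_up = 16, n_diff_dn = 17,
    diff_effect = 3,          # shift in units of the within-date noise SD
    diff_noise_sd = 0.1,      # within-date multiplicative noise of diff taxa
    n_rewired = 10,           # interaction rows resampled in the B model
    invader_abundance = 0.4   # constant relative % of the invader in B
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) stop("unknown config fields: ",
                                paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Generate a paired synthetic community dataset with known truth
#'
#' Simulates the control condition from a random stationary gLV model and
#' the perturbed condition from a modified model (a subset of interaction
#' rows rewired, plus an invader taxon absent before the perturbation and
#' held at a constant low relative abundance after it).  Planted
#' structure is then layered on the relative-abundance trajectories:
#' correlated ascent/descent/convex templates applied congruently in both
#' conditions, and differential taxa whose perturbed trajectories are the
#' control ones shifted multiplicatively by `1 + diff_effect *
#' diff_noise_sd` (up) or its reciprocal (down) under within-date noise.
#' Finally read counts are drawn by multinomial sampling at realistic
#' depths.  Everything is a deterministic function of `seed`.
#'
#' @param config A [synthetic_config()] list.
#' @param seed Master seed (integer).
#' @return List with `tableC` and `tableB` (count [abundance_table()]s)
#'   and `truth` — growth rates, true interaction matrices of both
#'   conditions, planted group memberships, differential taxa and
#'   directions, the invader, and all seeds.
#' @export
generate_dataset <- function(config = synthetic_config(), seed = 1L) {
  cfg <- config
  set.seed(seed)
  n <- cfg$n_taxa
  tt <- cfg$n_dates
  model <- gen_interactions(n, cfg$density, cfg$negative_fraction,
                            cfg$magnitude_scale, cfg$self_limitation)
  taxa <- model$taxa

  # --- planted role assignment (disjoint), invader is the last taxon
  invader <- taxa[n]
  # differential taxa drawn from the more abundant half so the planted
  # shift is not drowned by count noise
  rank_ab <- order(-model$xstar)
  eligible_diff <- setdiff(taxa[rank_ab[seq_len(floor(n / 2))]], invader)
  n_diff <- cfg$n_diff_up + cfg$n_diff_dn
  diff_taxa <- sample(eligible_diff, n_diff)
  diff_up <- diff_taxa[seq_len(cfg$n_diff_up)]
  diff_dn <- setdiff(diff_taxa, diff_up)
  eligible_pat <- setdiff(taxa, c(invader, diff_taxa))
  pat_taxa <- sample(eligible_pat, sum(cfg$n_pattern))
  groups <- split(pat_taxa, rep(names(cfg$n_pattern), cfg$n_pattern))

  # --- condition C: stationary gLV around xstar
  x0 <- model$xstar * exp(stats::rnorm(n, 0, 0.05))
  trajC <- simulate_glv(model, x0, n_steps = tt - 1,
                        process_noise_sd = cfg$process_noise_sd,
                        extinction_floor = 1e-8)
  # --- condition B: rewired interaction rows for a configured subset
  modelB <- model
  rewired <- sample(setdiff(taxa, invader), cfg$n_rewired)
  for (tx in rewired) {
    i <- match(tx, taxa)
    row <- modelB$A[i, ]
    off <- setdiff(seq_len(n), i)
    modelB$A[i, off] <- row[sample(off)]
  }
  # keep xstar a fixed point of the perturbed model so B stays stationary
  modelB$b <- stats::setNames(-as.vector(modelB$A %*% model$xstar), taxa)
  x0b <- model$xstar * exp(stats::rnorm(n, 0, 0.05))
  trajB <- simulate_glv(modelB, x0b, n_steps = tt - 1,
                        process_noise_sd = cfg$process_noise_sd,
                        extinction_floor = 1e-8)

  # --- relative abundances (percent)
  relC <- sweep(trajC, 2, colSums(trajC), "/") * 100
  relB <- sweep(trajB, 2, colSums(trajB), "/") * 100

  # invader: absent before the perturbation, constant and rare after
  inv_i <- match(invader, taxa)
  relC[inv_i, ] <- 0
  relB[inv_i, ] <- cfg$invader_abundance

  # planted correlated-trajectory groups (congruent in C and B)
  planted <- plant_patterns(relC, relB, groups,
                            noise_sd = cfg$pattern_noise_sd)
  relC <- planted$C
  relB <- planted$B

  # planted differential shifts: B is C shifted multiplicatively under
  # within-date noise; effect expressed in units of that noise SD
  shift_up <- 1 + cfg$diff_effect * cfg$diff_noise_sd
  for (tx in diff_taxa) {
    i <- match(tx, taxa)
    shift <- if (tx %in% diff_up) shift_up else 1 / shift_up
    eps <- stats::rnorm(tt, 0, cfg$diff_noise_sd)
    relB[i, ] <- pmax(relC[i, ] * shift * (1 + eps), 0)
  }

  relC <- sweep(relC, 2, colSums(relC), "/") * 100
  relB <- sweep(relB, 2, colSums(relB), "/") * 100

  seed_counts <- sample.int(.Machine$integer.max %/% 2, 2)
  countsC <- sample_counts(relC, cfg$depth_mean, cfg$depth_sd,
                           seed = seed_counts[1])
  countsB <- sample_counts(relB, cfg$depth_mean, cfg$depth_sd,
                           seed = seed_counts[2])
  dates <- seq_len(tt)
  tableC <- abundance_table(countsC, rep("C", tt), dates, units = "counts",
                            taxa = taxa)
  tableB <- abundance_table(countsB, rep("B", tt), dates, units = "counts",
                            taxa = taxa)
  truth <- list(
    b = model$b, A = model$A, A_B = modelB$A, xstar = model$xstar,
    pattern_groups = groups, diff_up = diff_up, diff_dn = diff_dn,
    diff_effect = cfg$diff_effect, diff_noise_sd = cfg$diff_noise_sd,
    rewired = rewired, invader = invader,
    depth_mean = cfg$depth_mean, depth_sd = cfg$depth_sd,
    master_seed = seed, count_seeds = seed_counts,
    config = cfg[setdiff(names(cfg), "magnitude_scale")]
  )
  list(tableC = tableC, tableB = tableB, truth = truth)
}

#' Serialize / restore a synthetic ground-truth record
#'
#' Lossless JSON serialization (type- and precision-preserving) so a
#' truth record can be stored next to the generated tables and
#' round-trips bit-exactly.
#'
#' @param truth Truth list from [generate_dataset()].
#' @param path File path.
#' @return `write_truth` invisibly returns `path`; `read_truth` returns
#'   the truth list.
#' @export
write_truth <- function(truth, path) {
  # 17 significant digits guarantee an exact double round trip
  writeLines(jsonlite::serializeJSON(truth, digits = I(17)), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}
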