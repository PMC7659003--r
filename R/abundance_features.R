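#' Mean abundance over nonzero samples
#'
#' The averaged abundance level of a taxon: the sum of its abundances
#' divided by the number of samples in which it is detected (strictly
#' positive).  A taxon absent everywhere gets 0 so that condition-specific
#' rare taxa pass through the pipeline instead of erroring.
#'
#' @param profile Numeric abundance vector (one taxon across samples).
#' @return Scalar mean over nonzero entries, or 0 for an all-zero profile.
#' @export
mean_nonzero <- function(profile) {
  npos <- sum(profile > 0)
  if (npos == 0) return(0)
  sum(profile) / npos
}

#' Classify a taxon's abundance level and core status
#'
#' Levels follow the relative-abundance thresholds: high (`H`) when the
#' mean over detected samples exceeds 1%, rare (`R`) when it is below
#' 0.1%, low (`L`) for the inclusive band \[0.1%, 1%\].  A core taxon is
#' detected (nonzero) in every sample; `nR` marks rare taxa with at least
#' one zero sample.
#'
#' @param mean_nonzero Mean relative abundance (%) over detected samples.
#' @param profile The taxon's relative-abundance vector.
#' @return List with `level` (`"H"`, `"L"` or `"R"`), `core`, `nR`.
#' @export
classify_level <- function(mean_nonzero, profile) {
  level <- if (mean_nonzero > 1) "H" else if (mean_nonzero < 0.1) "R" else "L"
  core <- all(profile > 0)
  list(level = level, core = core, nR = (level == "R" && !core))
}

#' Paired differential-abundance test between conditions
#'
#' Two-sided paired Student's t-test on date-aligned control (C) and
#' perturbed (B) abundances of one taxon.  Status is `Diff_UP`/`Diff_DN`
#' when p < alpha with the perturbed mean higher/lower, otherwise
#' `NDiff_UP`/`NDiff_DN` by the sign of the mean difference.  Identically
#' zero differences give p = 1 (tie broken to `NDiff_DN`); a constant
#' nonzero difference is a perfectly consistent shift and gets p = 0.
#'
#' @param c_profile,b_profile Date-aligned abundance vectors (length >= 2).
#' @param alpha Significance level (default 0.05).
#' @return List with `diff_status`, `p` and `mean_diff` (B minus C).
#' @export
paired_diff_test <- function(c_profile, b_profile, alpha = 0.05) {
  if (length(c_profile) != length(b_profile)) stop("length mismatch")
  if (length(c_profile) < 2) stop("need >= 2 paired samples")
  d <- b_profile - c_profile
  if (all(d == 0)) {
    return(list(diff_status = "NDiff_DN", p = 1, mean_diff = 0))
  }
  p <- if (stats::sd(d) == 0) 0 else stats::t.test(b_profile, c_profile, paired = TRUE)$p.value
  up <- mean(d) > 0
  status <- if (p < alpha) {
    if (up) "Diff_UP" else "Diff_DN"
  } else {
    if (up) "NDiff_UP" else "NDiff_DN"
  }
  list(diff_status = status, p = p, mean_diff = mean(d))
}

#' Annotate every taxon with its abundance features
#'
#' Combines both conditions' relative-abundance profiles to compute, per
#' taxon: the mean over detected samples, the H/L/R level, core and nR
#' flags (across all samples of both conditions), and the paired
#' differential status between conditions.
#'
#' @param tableC,tableB Relative-percent [abundance_table()]s over the
#'   same taxa, with matching date indices.
#' @param alpha Significance level for the paired t-test.
#' @return Data frame with columns `taxon`, `mean_nonzero`, `level`,
#'   `core`, `nR`, `diff_status`, `diff_p`.
#' @export
annotate_taxa <- function(tableC, tableB, alpha = 0.05) {
  if (!identical(tableC$taxa, tableB$taxa)) stop("taxon universes differ")
  stopifnot(tableC$units == "relative_percent", tableB$units == "relative_percent")
  oc <- order(tableC$samples$date_index)
  ob <- order(tableB$samples$date_index)
  if (!identical(sort(tableC$samples$date_index), sort(tableB$samples$date_index))) {
    stop("conditions do not share the same date indices")
  }
  vc <- tableC$values[, oc, drop = FALSE]
  vb <- tableB$values[, ob, drop = FALSE]
  res <- lapply(seq_along(tableC$taxa), function(i) {
    comb <- c(vc[i, ], vb[i, ])
    mnz <- mean_nonzero(comb)
    lvl <- classify_level(mnz, comb)
    dt <- paired_diff_test(vc[i, ], vb[i, ], alpha)
    data.frame(taxon = tableC$taxa[i], mean_nonzero = mnz, level = lvl$level,
               core = lvl$core, nR = lvl$nR, diff_status = dt$diff_status,
               diff_p = dt$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
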