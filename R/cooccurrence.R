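#' Pearson correlation with t-transform significance
#'
#' Shared backbone of the self- and pairwise-correlation records: Pearson
#' r with a two-sided p-value from the t transform with n - 2 degrees of
#' freedom.  Zero-variance inputs return `r = NA` flagged non-significant.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @param alpha Significance level.
#' @return List with `r`, `p`, `significant`, `n`.
#' @keywords internal
cor_record <- function(x, y, alpha = 0.05) {
  n <- length(x)
  if (n != length(y)) stop("length mismatch")
  if (n < 3) stop("need >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, significant = FALSE, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       significant = is.finite(ct$p.value) && ct$p.value < alpha, n = n)
}

#' Self-correlation of one taxon across conditions
#'
#' Pearson correlation between a taxon's control (C) and perturbed (B)
#' trajectories, used to flag taxa whose abundance pattern is conserved
#' across the perturbation.
#'
#' @param c_profile,b_profile Date-aligned abundance vectors.
#' @param taxon Taxon ID (for the output record).
#' @param alpha Significance level.
#' @return One-row data frame: `kind = "self"`, `taxon_i`, `taxon_j`, `r`,
#'   `p`, `significant`.
#' @export
corr_self <- function(c_profile, b_profile, taxon = NA_character_, alpha = 0.05) {
  rec <- cor_record(c_profile, b_profile, alpha)
  data.frame(kind = "self", taxon_i = taxon, taxon_j = taxon,
             r = rec$r, p = rec$p, significant = rec$significant,
             stringsAsFactors = FALSE)
}

#' Pairwise correlation of two taxa within one condition
#'
#' @param profile_i,profile_j Same-condition abundance vectors of two taxa.
#' @param taxon_i,taxon_j Taxon IDs.
#' @param condition `"C"` or `"B"`; sets the record kind (`within-C` /
#'   `within-B`).
#' @param alpha Significance level.
#' @return One-row data frame as in [corr_self()].
#' @export
corr_pair <- function(profile_i, profile_j, taxon_i = NA_character_,
                      taxon_j = NA_character_, condition = c("C", "B"),
                      alpha = 0.05) {
  condition <- match.arg(condition)
  rec <- cor_record(profile_i, profile_j, alpha)
  data.frame(kind = paste0("within-", condition), taxon_i = taxon_i,
             taxon_j = taxon_j, r = rec$r, p = rec$p,
             significant = rec$significant, stringsAsFactors = FALSE)
}

#' Critical Pearson correlation at a given sample size
#'
#' The |r| above which the t-transform test with n - 2 df is two-sided
#' significant at level alpha.
#'
#' @param n Number of paired observations.
#' @param alpha Significance level.
#' @return Scalar critical |r|.
#' @export
critical_r <- function(n, alpha = 0.05) {
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(tc^2 + n - 2)
}

#' Classify a trajectory as ascent, descent or convex
#'
#' Fits abundance against the date index by least squares with a linear
#' and a quadratic model.  The trajectory is "convex" (rise-then-fall
#' peak) when the quadratic coefficient is negative, the parabola's vertex
#' lies strictly inside the observed date range, and the quadratic term
#' significantly improves the fit (F-test p < 0.05); otherwise the sign
#' of the linear slope decides ascent vs descent.  The rule is invariant
#' under positive affine rescaling of the profile.
#'
#' @param profile Numeric trajectory (length >= 4).
#' @param dates Optional numeric date indices (default `seq_along`).
#' @return `"ascent"`, `"descent"` or `"convex"`; a constant profile
#'   returns `"descent"` with attribute `degenerate = TRUE`.
#' @export
trend_pattern <- function(profile, dates = seq_along(profile)) {
  if (length(profile) < 4) stop("need >= 4 time points")
  if (stats::sd(profile) == 0) {
    return(structure("descent", degenerate = TRUE))
  }
  k <- as.numeric(dates)
  lin <- stats::lm(profile ~ k)
  quad <- stats::lm(profile ~ k + I(k^2))
  c2 <- stats::coef(quad)[["I(k^2)"]]
  if (!is.na(c2) && c2 < 0) {
    vertex <- -stats::coef(quad)[["k"]] / (2 * c2)
    pF <- stats::anova(lin, quad)[["Pr(>F)"]][2]
    if (!is.na(pF) && pF < 0.05 && vertex > min(k) && vertex < max(k)) {
      return("convex")
    }
  }
  if (stats::coef(lin)[["k"]] > 0) "ascent" else "descent"
}

#' Build co-occurrence clusters from paired condition tables
#'
#' Three-step procedure: (1) per-taxon C and B relative-abundance
#' profiles are concatenated and clustered by average-linkage
#' hierarchical clustering on the 1 - Pearson-r distance, cutting the
#' tree at `cut_height`; (2) within each cluster, a pairwise link is
#' retained when the within-condition correlation is significant and at
#' least one endpoint is an "anchor" — a taxon with significant
#' self-correlation between its C and B trajectories; members with no
#' retained link are dropped; (3) each link is tagged `before` or `after`
#' the perturbation by which condition's correlation is significant.
#'
#' @param tableC,tableB Relative-percent [abundance_table()]s over the
#'   same taxa with matching date indices.
#' @param alpha Significance level for all correlation tests.
#' @param cut_height Tree-cut distance; default `1 - critical_r(n_total,
#'   alpha)` where `n_total` is the concatenated profile length.
#' @return Object of class `cooccurrence_clusters`: list with `members`
#'   (data frame: `cluster`, `taxon`, `anchor`, `pattern`, `epoch`),
#'   `links` (per-link records), `self` (self-correlation table),
#'   `tree` (the hclust object) and `cut_height`.
#' @export
build_cooccurrence_clusters <- function(tableC, tableB, alpha = 0.05,
                                        cut_height = NULL) {
  if (!identical(tableC$taxa, tableB$taxa)) stop("taxon universes differ")
  if (length(tableC$taxa) < 2) stop("need >= 2 taxa")
  oc <- order(tableC$samples$date_index)
  ob <- order(tableB$samples$date_index)
  vc <- tableC$values[, oc, drop = FALSE]
  vb <- tableB$values[, ob, drop = FALSE]
  comb <- cbind(vc, vb)
  taxa <- tableC$taxa
  if (is.null(cut_height)) cut_height <- 1 - critical_r(ncol(comb), alpha)

  usable <- apply(comb, 1, stats::sd) > 0
  self <- do.call(rbind, lapply(which(usable), function(i) {
    corr_self(vc[i, ], vb[i, ], taxon = taxa[i], alpha = alpha)
  }))
  empty <- structure(list(
    members = data.frame(cluster = character(), taxon = character(),
                         anchor = logical(), pattern = character(),
                         epoch = character(), stringsAsFactors = FALSE),
    links = data.frame(cluster = character(), taxon_i = character(),
                       taxon_j = character(), epoch = character(),
                       r = numeric(), p = numeric(), stringsAsFactors = FALSE),
    self = self, tree = NULL, cut_height = cut_height),
    class = "cooccurrence_clusters")
  idx <- which(usable)
  if (length(idx) < 2 || is.null(self) || !any(self$significant)) return(empty)

  d <- 1 - stats::cor(t(comb[idx, , drop = FALSE]))
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  grp <- stats::cutree(tree, h = cut_height)
  anchors <- self$taxon_i[self$significant]

  links <- list()
  for (g in unique(grp)) {
    members_g <- idx[grp == g]
    if (length(members_g) < 2) next
    prs <- utils::combn(members_g, 2)
    for (q in seq_len(ncol(prs))) {
      i <- prs[1, q]; j <- prs[2, q]
      if (!(taxa[i] %in% anchors) && !(taxa[j] %in% anchors)) next
      for (cond in c("C", "B")) {
        v <- if (cond == "C") vc else vb
        rec <- cor_record(v[i, ], v[j, ], alpha)
        if (isTRUE(rec$significant)) {
          links[[length(links) + 1]] <- data.frame(
            cluster_raw = g, taxon_i = taxa[i], taxon_j = taxa[j],
            epoch = if (cond == "C") "before" else "after",
            r = rec$r, p = rec$p, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(links) == 0) return(empty)
  links <- do.call(rbind, links)

  # relabel clusters G1, G2, ... in taxon order of first appearance
  member_taxa <- unique(c(rbind(links$taxon_i, links$taxon_j)))
  first_tax <- vapply(split(c(links$taxon_i, links$taxon_j),
                            rep(links$cluster_raw, 2)),
                      function(tt) min(match(tt, taxa)), numeric(1))
  lab_map <- stats::setNames(paste0("G", rank(first_tax, ties.method = "first")),
                             names(first_tax))
  links$cluster <- unname(lab_map[as.character(links$cluster_raw)])
  links$cluster_raw <- NULL
  links <- links[order(links$cluster, links$taxon_i, links$taxon_j, links$epoch), ,
                 drop = FALSE]
  rownames(links) <- NULL

  members <- do.call(rbind, lapply(member_taxa, function(tx) {
    lk <- links[links$taxon_i == tx | links$taxon_j == tx, ]
    ep <- sort(unique(lk$epoch))
    i <- match(tx, taxa)
    data.frame(cluster = lk$cluster[1], taxon = tx,
               anchor = tx %in% anchors,
               pattern = as.character(trend_pattern((vc[i, ] + vb[i, ]) / 2,
                                                    sort(tableC$samples$date_index))),
               epoch = paste(ep, collapse = "+"),
               stringsAsFactors = FALSE)
  }))
  members <- members[order(members$cluster, match(members$taxon, taxa)), ,
                     drop = FALSE]
  rownames(members) <- NULL
  structure(list(members = members, links = links, self = self, tree = tree,
                 cut_height = cut_height),
            class = "cooccurrence_clusters")
}

#' @export
print.cooccurrence_clusters <- function(x, ...) {
  cat(sprintf("cooccurrence_clusters: %d clusters, %d member taxa, %d links (cut %.3f)\n",
              length(unique(x$members$cluster)), nrow(x$members),
              nrow(x$links), x$cut_height))
  invisible(x)
}

#' Association between two categorical taxon features
#'
#' Cross-tabulates two per-taxon label vectors and tests independence
#' with Fisher's exact test: exact hypergeometric for 2x2 tables, Monte
#' Carlo (seeded) for larger tables.
#'
#' @param labels_a,labels_b Per-taxon categorical labels (same length).
#' @param seed Seed for the Monte Carlo p-value.
#' @param B Number of Monte Carlo replicates (default 1e5).
#' @return List with `table` (the contingency table) and `p`.
#' @export
feature_association <- function(labels_a, labels_b, seed = 1L, B = 1e5) {
  labels_a <- factor(labels_a)
  labels_b <- factor(labels_b)
  if (nlevels(labels_a) < 2 || nlevels(labels_b) < 2) {
    stop("each label dimension needs >= 2 categories")
  }
  tab <- table(labels_a, labels_b)
  p <- if (all(dim(tab) == c(2, 2))) {
    stats::fisher.test(tab)$p.value
  } else {
    set.seed(seed)
    stats::fisher.test(tab, simulate.p.value = TRUE, B = B)$p.value
  }
  list(table = tab, p = p)
}
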