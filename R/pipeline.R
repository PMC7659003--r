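#' Default analysis configuration
#'
#' Collects every tunable threshold of the analysis with the protocol's
#' stated constants as defaults: abundance levels at 1% and 0.1%, global
#' significance 0.05, ensemble of 1000 networks each on 90% of taxa,
#' 90% sign-coherence for reliable edges, the +/-0.1 niche band, motif
#' z-threshold 2 with minimum count 4, and the strength grid
#' 500/1000/1500/2000 (plus "all interactions" for the niche statistic).
#'
#' @param ... Overrides of the listed defaults (nested lists are replaced
#'   wholesale).
#' @return Named list of settings (class `perturbnet_config`).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    alpha = 0.05,
    level_high = 1, level_rare = 0.1,
    coherence = 0.9,
    niche_band = 0.1,
    z_threshold = 2, min_count = 4,
    ensemble = list(n_networks = 1000, member_frac = 0.9, ridge = 1e-3),
    strength_grid = c(500, 1000, 1500, 2000),
    motif_sizes = c(3L, 4L),
    n_random = 100,
    switch_factor = 100,
    fisher_B = 1e5,
    cut_height = NULL,
    seed = 1L,
    synthetic = synthetic_config()
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) stop("unknown config fields: ",
                                paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$alpha > 0, cfg$alpha < 1,
            cfg$coherence > 0.5, cfg$coherence <= 1,
            cfg$niche_band >= 0, cfg$niche_band < 1,
            cfg$ensemble$member_frac > 0, cfg$ensemble$member_frac <= 1,
            cfg$ensemble$n_networks >= 1, cfg$n_random >= 2)
  class(cfg) <- c("perturbnet_config", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the YAML override the [pipeline_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `perturbnet_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(pipeline_config, over)
}

#' Run the full perturbation-network analysis
#'
#' End-to-end orchestration: depth normalization and relative-abundance
#' conversion, per-taxon feature annotation and presence partition,
#' per-sample diversity, co-occurrence clustering, per-condition ensemble
#' gLV network inference with reliability filtering, centrality and
#' topological-niche computation across the strength grid, 3-/4-node
#' motif significance and representativeness, and the PCA report.  All
#' randomness derives from `seed`, so reruns with the same inputs and
#' seed are identical.
#'
#' @param config A [pipeline_config()].
#' @param tables Optional list with count [abundance_table()]s `tableC`
#'   and `tableB`; when `NULL` a synthetic dataset is generated from
#'   `config$synthetic`.
#' @param seed Master seed (default `config$seed`).
#' @param out_dir Optional directory; when given, every result table is
#'   written as TSV (with the seed recorded in a header comment).
#' @param verbose Log stage progress and timings to stderr.
#' @return List bundle: `annotations`, `venn`, `diversity`, `clusters`,
#'   `networks` (per condition: ensemble stats and reliable edges),
#'   `centrality` (per condition), `niche`, `motifs`, `representative`,
#'   `pca`, `truth` (synthetic runs only), `config`, `seed`.
#' @export
run_pipeline <- function(config = pipeline_config(), tables = NULL,
                         seed = config$seed, out_dir = NULL, verbose = TRUE) {
  t0 <- proc.time()[3]
  say <- function(fmt, ...) {
    if (verbose) message(sprintf("[%6.1fs] ", proc.time()[3] - t0),
                         sprintf(fmt, ...))
  }
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max %/% 2, 8)

  truth <- NULL
  if (is.null(tables)) {
    say("generating synthetic dataset (%d taxa, %d dates/condition)",
        config$synthetic$n_taxa, config$synthetic$n_dates)
    ds <- generate_dataset(config$synthetic, seed = stage_seeds[1])
    tables <- ds[c("tableC", "tableB")]
    truth <- ds$truth
  }
  tabC <- tables$tableC
  tabB <- tables$tableB

  if (tabC$units == "counts") tabC <- normalize_counts(tabC)
  if (tabB$units == "counts") tabB <- normalize_counts(tabB)
  # keep a common taxon universe across conditions after the discard step
  keep <- union(tabC$taxa, tabB$taxa)
  restrict <- function(tab, full) {
    miss <- setdiff(keep, tab$taxa)
    vals <- rbind(tab$values,
                  matrix(0, length(miss), ncol(tab$values),
                         dimnames = list(miss, colnames(tab$values))))
    vals <- vals[keep, , drop = FALSE]
    abundance_table(vals, tab$samples$condition, tab$samples$date_index,
                    units = tab$units, taxa = keep)
  }
  countsC <- restrict(tabC, keep)
  countsB <- restrict(tabB, keep)
  relC <- to_relative(countsC)
  relB <- to_relative(countsB)
  say("normalized: %d taxa retained", length(keep))

  annotations <- annotate_taxa(relC, relB, alpha = config$alpha)
  venn <- presence_partition(relC, relB)
  say("annotated taxa: %d differential of %d",
      sum(annotations$diff_p < config$alpha), nrow(annotations))

  # Chao1 needs raw integer counts; Shannon/inverse Simpson use relative
  orig <- list(C = tables$tableC, B = tables$tableB)
  diversity <- do.call(rbind, lapply(list(C = relC, B = relB), function(tab) {
    cond0 <- tab$samples$condition[1]
    cnt0 <- orig[[cond0]]
    cnt <- if (cnt0$units == "counts") restrict(cnt0, keep)
           else (if (cond0 == "C") countsC else countsB)
    do.call(rbind, lapply(seq_len(ncol(tab$values)), function(k) {
      di <- diversity_indices(tab$values[, k], counts = cnt$values[, k])
      data.frame(sample = tab$samples$sample[k],
                 condition = tab$samples$condition[k],
                 date_index = tab$samples$date_index[k],
                 shannon = di["shannon"], inv_simpson = di["inv_simpson"],
                 chao1 = di["chao1"], row.names = NULL)
    }))
  }))
  rownames(diversity) <- NULL

  clusters <- build_cooccurrence_clusters(relC, relB, alpha = config$alpha,
                                          cut_height = config$cut_height)
  say("co-occurrence: %d clusters over %d taxa",
      length(unique(clusters$members$cluster)), nrow(clusters$members))

  networks <- list()
  for (cond in c("C", "B")) {
    rel <- if (cond == "C") relC else relB
    st <- ensemble_infer(rel,
                         n_networks = config$ensemble$n_networks,
                         member_frac = config$ensemble$member_frac,
                         ridge = config$ensemble$ridge,
                         seed = stage_seeds[if (cond == "C") 2 else 3])
    edges <- reliability_filter(st, coherence_threshold = config$coherence,
                                alpha = config$alpha)
    networks[[cond]] <- list(stats = st, edges = edges)
    say("network %s: %d reliable of %d observed interactions",
        cond, nrow(edges), nrow(st))
  }

  grid_all <- c(config$strength_grid, Inf)
  centrality <- lapply(networks, function(nw) {
    centrality_profiles(nw$edges, keep, grid = grid_all)
  })
  niche <- niche_scores(centrality$B, centrality$C, band = config$niche_band)
  say("niche: %d taxa outside the non-influential band",
      sum(niche$niche_class != "none"))

  motifs <- list()
  representative <- list()
  for (cond in c("C", "B")) {
    set.seed(stage_seeds[if (cond == "C") 4 else 5])
    motifs[[cond]] <- motif_scan(networks[[cond]]$edges,
                                 sizes = config$motif_sizes,
                                 grid = config$strength_grid,
                                 n_random = config$n_random,
                                 z_threshold = config$z_threshold,
                                 min_count = config$min_count,
                                 switch_factor = config$switch_factor)
    representative[[cond]] <- representative_motifs(motifs[[cond]])
    say("motifs %s: %d significant records, %d representative types",
        cond, sum(motifs[[cond]]$significant), nrow(representative[[cond]]))
  }

  pca <- pca_report(relC, relB, annotations = annotations,
                    clusters = clusters)
  say("PCA: PC1+PC2 explain %.2f%% of variance",
      sum(pca$variance_explained[1:2]))

  bundle <- list(annotations = annotations, venn = venn,
                 diversity = diversity, clusters = clusters,
                 networks = networks, centrality = centrality, niche = niche,
                 motifs = motifs, representative = representative, pca = pca,
                 truth = truth, config = config, seed = seed)
  if (!is.null(out_dir)) write_result_bundle(bundle, out_dir)
  bundle
}

#' PCA report over combined condition samples
#'
#' Centered (unscaled) principal-component analysis of the samples x taxa
#' relative-abundance matrix of both conditions.  Loadings are annotated
#' with each taxon's abundance features and, when co-occurrence clusters
#' are supplied, a cluster-epoch code (cluster label plus `b`/`a`/`ba`
#' for links before/after/both relative to the perturbation).
#'
#' @param tableC,tableB Relative-percent [abundance_table()]s.
#' @param annotations Optional [annotate_taxa()] output to join.
#' @param clusters Optional [build_cooccurrence_clusters()] output.
#' @return List with `variance_explained` (percent per component,
#'   non-increasing), `scores` (samples x PCs with condition metadata)
#'   and `loadings` (taxa x PCs with annotations).
#' @export
pca_report <- function(tableC, tableB, annotations = NULL, clusters = NULL) {
  if (!identical(tableC$taxa, tableB$taxa)) stop("taxon universes differ")
  x <- t(cbind(tableC$values, tableB$values))
  if (nrow(x) < 3) stop("need >= 3 samples")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scores <- data.frame(
    sample = c(tableC$samples$sample, tableB$samples$sample),
    condition = c(tableC$samples$condition, tableB$samples$condition),
    date_index = c(tableC$samples$date_index, tableB$samples$date_index),
    pc$x, stringsAsFactors = FALSE, row.names = NULL)
  loadings <- data.frame(taxon = tableC$taxa, pc$rotation,
                         stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(annotations)) {
    loadings <- merge(loadings, annotations, by = "taxon", sort = FALSE)
  }
  if (!is.null(clusters) && nrow(clusters$members) > 0) {
    code <- vapply(clusters$members$epoch, function(e) {
      switch(e, before = "b", after = "a", "ba")
    }, character(1))
    loadings$cluster_code <- NA_character_
    m <- match(clusters$members$taxon, loadings$taxon)
    loadings$cluster_code[m] <- paste0(clusters$members$cluster, code)
  }
  list(variance_explained = ve, scores = scores, loadings = loadings)
}

#' Write a pipeline result bundle as TSV/JSON artifacts
#'
#' Every table is written with a header comment recording the seed, so
#' artifacts are self-describing and reruns are comparable.
#'
#' @param bundle Output of [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_result_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- sprintf("# perturbnet seed=%d", bundle$seed)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    con <- file(p, "w")
    writeLines(header, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    paths <<- c(paths, p)
  }
  wt(bundle$annotations, "annotations")
  wt(bundle$diversity, "diversity")
  wt(bundle$clusters$members, "cluster_members")
  wt(bundle$clusters$links, "cluster_links")
  for (cond in names(bundle$networks)) {
    wt(bundle$networks[[cond]]$edges, paste0("edges_", cond))
    wt(bundle$centrality[[cond]], paste0("centrality_", cond))
    wt(bundle$motifs[[cond]], paste0("motifs_", cond))
    wt(bundle$representative[[cond]], paste0("representative_", cond))
  }
  wt(bundle$niche, "niche")
  wt(bundle$pca$scores, "pca_scores")
  wt(bundle$pca$loadings, "pca_loadings")
  venn_df <- data.frame(
    taxon = unlist(bundle$venn, use.names = FALSE),
    set = rep(names(bundle$venn), lengths(bundle$venn)))
  wt(venn_df, "venn")
  if (!is.null(bundle$truth)) {
    tp <- file.path(dir, "truth.json")
    write_truth(bundle$truth, tp)
    paths <- c(paths, tp)
  }
  invisible(paths)
}
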