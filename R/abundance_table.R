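#' Construct a time-series abundance table
#'
#' An `abundance_table` holds a taxa-by-samples matrix together with the
#' sample metadata (condition and sampling-date index) needed by every
#' downstream step.  Values are either raw sequence counts (`units =
#' "counts"`) or relative abundances in percent (`units =
#' "relative_percent"`, each sample column summing to 100).
#'
#' @param values Numeric matrix, taxa in rows, samples in columns.  Row
#'   names (or `taxa`) identify taxa; column names identify samples.
#' @param condition Character vector, one of `"C"` (control) or `"B"`
#'   (bioaugmentation/perturbed) per sample column.
#' @param date_index Integer vector of sampling-date indices, one per
#'   sample column.  `(condition, date_index)` pairs must be unique.
#' @param units `"counts"` or `"relative_percent"`.
#' @param taxa Optional character vector of taxon IDs overriding row names.
#' @return An object of class `abundance_table`: a list with elements
#'   `values`, `taxa`, `samples` (data frame with `sample`, `condition`,
#'   `date_index`) and `units`.
#' @export
abundance_table <- function(values, condition, date_index,
                            units = c("counts", "relative_percent"),
                            taxa = rownames(values)) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (is.null(taxa)) taxa <- paste0("taxon_", seq_len(nrow(values)))
  if (length(taxa) != nrow(values)) stop("taxa must have one entry per row")
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon ID: ", paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  if (length(condition) != ncol(values) || length(date_index) != ncol(values)) {
    stop("condition/date_index must have one entry per sample column")
  }
  condition <- as.character(condition)
  if (!all(condition %in% c("C", "B"))) stop("condition must be 'C' or 'B'")
  date_index <- as.integer(date_index)
  if (any(!is.finite(values))) stop("non-finite abundance value")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative value at taxon '%s', sample '%s'",
                 taxa[neg[1, 1]], colnames(values)[neg[1, 2]]))
  }
  key <- paste(condition, date_index)
  if (anyDuplicated(key)) {
    stop("duplicate (condition, date_index) pair: ", key[duplicated(key)][1])
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0(condition, date_index)
  }
  if (units == "relative_percent") {
    cs <- colSums(values)
    if (any(abs(cs - 100) > 1e-6)) {
      stop("relative_percent columns must sum to 100 (worst column: ",
           colnames(values)[which.max(abs(cs - 100))], ")")
    }
  }
  rownames(values) <- taxa
  structure(list(
    values = values,
    taxa = taxa,
    samples = data.frame(sample = colnames(values), condition = condition,
                         date_index = date_index, stringsAsFactors = FALSE),
    units = units
  ), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$units))
  cat("conditions:", paste(sprintf("%s=%d", names(table(x$samples$condition)),
                                   table(x$samples$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Read an abundance table and its sample metadata from TSV files
#'
#' The abundance TSV has taxon IDs in the first column and one column per
#' sample.  Metadata is either a data frame or a path to a 3-column TSV
#' (`sample`, `condition`, `date_index`) mapping each sample column.
#'
#' @param path Path to the abundance TSV.
#' @param metadata Data frame or TSV path with columns `sample`,
#'   `condition`, `date_index`.
#' @param units `"counts"` (default) or `"relative_percent"`.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, metadata, units = "counts") {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("abundance TSV needs a taxon column plus >=1 sample column")
  taxa <- as.character(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric value at taxon '%s' (row %d), sample '%s'",
                 taxa[bad[1, 1]], bad[1, 1], colnames(vals)[bad[1, 2]]))
  }
  if (is.character(metadata) && length(metadata) == 1) {
    metadata <- utils::read.delim(metadata, header = TRUE,
                                  stringsAsFactors = FALSE)
  }
  need <- c("sample", "condition", "date_index")
  if (!all(need %in% names(metadata))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  missing <- setdiff(colnames(vals), metadata$sample)
  if (length(missing) > 0) {
    stop("sample column without metadata: ", paste(missing, collapse = ", "))
  }
  md <- metadata[match(colnames(vals), metadata$sample), ]
  abundance_table(vals, md$condition, md$date_index, units = units, taxa = taxa)
}

#' Write an abundance table to TSV
#'
#' @param table An [abundance_table()].
#' @param path Output TSV path; metadata is written alongside as
#'   `<path>.meta.tsv` unless `meta_path` is given.
#' @param meta_path Optional explicit metadata path.
#' @return Invisibly, the table.
#' @export
write_abundance_table <- function(table, path, meta_path = paste0(path, ".meta.tsv")) {
  df <- data.frame(taxon = table$taxa, table$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table)
}

#' Restrict an abundance table to one condition (and order by date)
#'
#' @param table An [abundance_table()].
#' @param condition `"C"` or `"B"`.
#' @return An [abundance_table()] with samples of that condition, ordered
#'   by `date_index`.
#' @export
subset_condition <- function(table, condition) {
  keep <- which(table$samples$condition == condition)
  keep <- keep[order(table$samples$date_index[keep])]
  if (length(keep) == 0) stop("no samples with condition ", condition)
  abundance_table(table$values[, keep, drop = FALSE],
                  table$samples$condition[keep],
                  table$samples$date_index[keep],
                  units = table$units, taxa = table$taxa)
}

#' Depth-normalize a count table
#'
#' Rescales every sample to the minimum total sequencing depth across
#' samples (each sample's counts are multiplied by `min(depth) / depth`,
#' the expected-value analogue of rarefying to even depth), then removes
#' taxa whose adjusted read count is below 1 in every sample (taxa
#' reaching 1 adjusted read in at least one sample are kept).
#'
#' @param table An [abundance_table()] in counts mode.
#' @return The adjusted [abundance_table()] (still `units = "counts"`);
#'   the IDs of removed taxa are in `attr(, "discarded_taxa")`.
#' @export
normalize_counts <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$units != "counts") stop("normalize_counts expects a counts table")
  depths <- colSums(table$values)
  if (any(depths <= 0)) {
    stop("zero-depth sample: ", table$samples$sample[which(depths <= 0)[1]])
  }
  adj <- sweep(table$values, 2, min(depths) / depths, "*")
  discard <- apply(adj, 1, function(v) all(v < 1))
  out <- abundance_table(adj[!discard, , drop = FALSE],
                         table$samples$condition, table$samples$date_index,
                         units = "counts", taxa = table$taxa[!discard])
  attr(out, "discarded_taxa") <- table$taxa[discard]
  out
}

#' Convert a table to relative abundances (percent)
#'
#' Rescales every sample column to sum to 100.  Idempotent on tables that
#' are already relative.
#'
#' @param table An [abundance_table()].
#' @return An [abundance_table()] with `units = "relative_percent"`.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  cs <- colSums(table$values)
  if (any(cs <= 0)) {
    stop("all-zero sample column: ", table$samples$sample[which(cs <= 0)[1]])
  }
  rel <- sweep(table$values, 2, cs, "/") * 100
  abundance_table(rel, table$samples$condition, table$samples$date_index,
                  units = "relative_percent", taxa = table$taxa)
}

#' Presence/absence partition of taxa between two conditions
#'
#' A taxon is "present" in a condition when it is nonzero in at least one
#' of that condition's samples.  Returns the Venn partition of present
#' taxa into shared, control-only and perturbed-only sets.
#'
#' @param tableC,tableB [abundance_table()]s over the same taxa.
#' @return List with character vectors `shared`, `C_only`, `B_only`.
#' @export
presence_partition <- function(tableC, tableB) {
  if (!identical(tableC$taxa, tableB$taxa)) stop("taxon universes differ")
  inC <- rowSums(tableC$values > 0) > 0
  inB <- rowSums(tableB$values > 0) > 0
  list(shared = tableC$taxa[inC & inB],
       C_only = tableC$taxa[inC & !inB],
       B_only = tableC$taxa[!inC & inB])
}

#' Alpha-diversity indices for one sample
#'
#' Shannon (natural log) and inverse Simpson indices are computed on the
#' abundance profile; the Chao1 richness estimate additionally needs the
#' integer count profile (singletons/doubletons), using
#' \eqn{S_{obs} + F_1^2/(2 F_2)} with the usual
#' \eqn{S_{obs} + F_1 (F_1 - 1)/2} fallback when no doubletons exist.
#'
#' @param profile Numeric vector of one sample's abundances (any scale).
#' @param counts Optional integer count vector for Chao1; when omitted
#'   Chao1 is `NA`.
#' @return Named numeric vector `shannon`, `inv_simpson`, `chao1`.
#' @export
diversity_indices <- function(profile, counts = NULL) {
  if (length(profile) == 0 || sum(profile) <= 0) stop("empty sample")
  shannon <- unname(vegan::diversity(profile, index = "shannon"))
  inv_simpson <- unname(vegan::diversity(profile, index = "invsimpson"))
  chao1 <- NA_real_
  if (!is.null(counts)) {
    counts <- round(counts)
    s_obs <- sum(counts > 0)
    f1 <- sum(counts == 1)
    f2 <- sum(counts == 2)
    chao1 <- if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
  }
  c(shannon = shannon, inv_simpson = inv_simpson, chao1 = chao1)
}
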