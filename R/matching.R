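#' Read a sample map linking assays
#'
#' A sample map is a TSV with a `cohort_sample` column plus one column per
#' assay (`mirna_sample`, `gene_sample`, `protein_sample`); empty or NA
#' cells mean the assay lacks that sample.
#'
#' @param path path to the mapping TSV.
#' @return data.frame of class `sample_map`.
#' @export
read_sample_map <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!"cohort_sample" %in% names(df))
    stop("sample map needs a 'cohort_sample' column", call. = FALSE)
  if (anyDuplicated(df$cohort_sample))
    stop("duplicate cohort_sample entries in sample map", call. = FALSE)
  class(df) <- c("sample_map", "data.frame")
  df
}

#' Cohort view: sample-aligned multi-assay slices
#'
#' Bundles 2-3 assays restricted to a matched sample set with identical
#' sample ordering, tagged with tissue and condition. Protein data is
#' typically available only for tumor cohorts (TCGA provides no
#' normal-tissue protein assay), so `has_protein` is FALSE unless a protein
#' matrix survived matching.
#'
#' @param matrices named list of [expression_matrix] objects (names =
#'   assays), all with identical sample ordering.
#' @param tissue tissue label (e.g. "BRCA").
#' @param condition `"tumor"` or `"normal"`.
#' @return Object of class `cohort_view` with fields `tissue`, `condition`,
#'   `matrices`, `n`, `has_protein`.
#' @export
cohort_view <- function(matrices, tissue = "tissue",
                        condition = c("tumor", "normal")) {
  condition <- match.arg(condition)
  stopifnot(is.list(matrices), length(matrices) >= 1)
  sids <- lapply(matrices, function(m) m$sample_ids)
  if (length(unique(sids)) != 1)
    stop("all assay matrices must share one sample ordering", call. = FALSE)
  structure(list(tissue = tissue, condition = condition, matrices = matrices,
                 n = length(sids[[1]]),
                 has_protein = "protein" %in% names(matrices)),
            class = "cohort_view")
}

#' @export
print.cohort_view <- function(x, ...) {
  cat(sprintf("<cohort_view> %s/%s: n=%d, assays: %s\n", x$tissue, x$condition,
              x$n, paste(names(x$matrices), collapse = ", ")))
  invisible(x)
}

# collapse aliquot columns sharing a barcode prefix by their mean
.aggregate_by_prefix <- function(m, prefix_length) {
  grp <- substr(m$sample_ids, 1L, prefix_length)
  ug <- sort(unique(grp))  # canonical order: invariant to input column order
  vals <- matrix(NA_real_, nrow = nrow(m$values), ncol = length(ug),
                 dimnames = list(m$feature_ids, ug))
  for (g in ug) {
    cols <- which(grp == g)
    v <- if (length(cols) == 1L) m$values[, cols] else
      rowMeans(m$values[, cols, drop = FALSE], na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    vals[, g] <- v
  }
  expression_matrix(vals, m$assay)
}

#' Match samples across assays into a cohort view
#'
#' Aligns 2-3 assay matrices on a common sample set. Strategies:
#' * `exact` — intersect identical sample ids;
#' * `prefix` — group sample ids by their first `prefix_length` characters
#'   (TCGA barcodes: patient + sample-type field, 15 characters), average
#'   multiple aliquots of one group within an assay (arithmetic mean on the
#'   abundance scale), then intersect prefixes;
#' * `mapfile` — follow an explicit [read_sample_map()] table; only rows
#'   with all supplied assays present are kept.
#'
#' @param matrices named list of [expression_matrix] (>= 2 assays; names in
#'   mirna/gene/protein).
#' @param strategy matching strategy.
#' @param map `sample_map` (required for `strategy = "mapfile"`).
#' @param prefix_length barcode prefix length for `strategy = "prefix"`.
#' @param min_samples minimum matched-sample count (default 8); below it the
#'   cohort is rejected because permutation p-values and signs are
#'   unreliable.
#' @param tissue,condition labels stored on the resulting cohort.
#' @return A [cohort_view].
#' @export
match_samples <- function(matrices, strategy = c("exact", "prefix", "mapfile"),
                          map = NULL, prefix_length = 15L, min_samples = 8L,
                          tissue = "tissue", condition = "tumor") {
  strategy <- match.arg(strategy)
  stopifnot(is.list(matrices), length(matrices) >= 2,
            all(names(matrices) %in% c("mirna", "gene", "protein")))
  if (strategy == "prefix")
    matrices <- lapply(matrices, .aggregate_by_prefix, prefix_length = prefix_length)
  if (strategy == "mapfile") {
    if (is.null(map)) stop("strategy 'mapfile' requires a sample map", call. = FALSE)
    cols <- paste0(names(matrices), "_sample")
    missing_cols <- setdiff(cols, names(map))
    if (length(missing_cols) > 0)
      stop("sample map lacks column(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    keep <- rep(TRUE, nrow(map))
    for (i in seq_along(matrices)) {
      ids <- map[[cols[i]]]
      present <- !is.na(ids) & nzchar(ids) & ids %in% matrices[[i]]$sample_ids
      keep <- keep & present
    }
    if (sum(keep) < min_samples) {
      per_assay <- vapply(seq_along(matrices), function(i) {
        ids <- map[[cols[i]]]
        sum(!is.na(ids) & nzchar(ids) & ids %in% matrices[[i]]$sample_ids)
      }, integer(1))
      stop(sprintf("cohort too small: %d matched sample(s) < min_samples=%d (limiting assay: %s)",
                   sum(keep), min_samples,
                   names(matrices)[which.min(per_assay)]), call. = FALSE)
    }
    sub <- map[keep, , drop = FALSE]
    sliced <- lapply(seq_along(matrices), function(i) {
      m <- matrices[[i]]
      v <- m$values[, sub[[cols[i]]], drop = FALSE]
      colnames(v) <- sub$cohort_sample
      expression_matrix(v, m$assay)
    })
    names(sliced) <- names(matrices)
    return(cohort_view(sliced, tissue = tissue, condition = condition))
  }
  # exact (and post-aggregation prefix): intersect sample ids
  common <- sort(Reduce(intersect, lapply(matrices, function(m) m$sample_ids)))
  if (length(common) < min_samples) {
    sizes <- vapply(matrices, function(m) length(m$sample_ids), integer(1))
    stop(sprintf("cohort too small: %d matched sample(s) < min_samples=%d (limiting assay: %s)",
                 length(common), min_samples,
                 names(matrices)[which.min(sizes)]), call. = FALSE)
  }
  sliced <- lapply(matrices, function(m)
    expression_matrix(m$values[, common, drop = FALSE], m$assay))
  cohort_view(sliced, tissue = tissue, condition = condition)
}
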