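#' Expression matrix container
#'
#' An `expression_matrix` holds one assay's features x samples abundance
#' grid. miRNA and gene assays carry FPKM-like non-negative values; protein
#' assays carry already-normalized array intensities, which may be negative.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   feature ids as rownames and sample ids as colnames.
#' @param assay one of `"mirna"`, `"gene"`, `"protein"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `assay`, `values` (the validated matrix), `feature_ids`, `sample_ids`.
#' @export
expression_matrix <- function(values, assay = c("mirna", "gene", "protein")) {
  assay <- match.arg(assay)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("`values` must have feature rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(fid))
    stop("duplicate feature ids: ", paste(unique(fid[duplicated(fid)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "),
         call. = FALSE)
  if (assay %in% c("mirna", "gene")) {
    neg <- which(values < 0, arr.ind = TRUE)
    if (nrow(neg) > 0)
      stop(sprintf("negative value in %s assay at feature '%s', sample '%s'",
                   assay, fid[neg[1, 1]], sid[neg[1, 2]]), call. = FALSE)
  }
  structure(list(assay = assay, values = values,
                 feature_ids = fid, sample_ids = sid),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> assay=%s, %d features x %d samples\n",
              x$assay, length(x$feature_ids), length(x$sample_ids)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV
#'
#' Expects a UTF-8 tab-delimited file whose first column holds feature ids
#' and whose remaining column headers are sample ids. Cells must parse as
#' numbers or equal `na_token`. Rows that are entirely missing are dropped
#' (with a message); other missing cells are kept and handled downstream by
#' per-pair complete-case filtering.
#'
#' @param path path to the TSV file.
#' @param assay assay tag, one of `"mirna"`, `"gene"`, `"protein"`.
#' @param na_token string representing a missing value (default `"NA"`).
#' @return An [expression_matrix].
#' @export
read_expression_matrix <- function(path, assay = c("mirna", "gene", "protein"),
                                   na_token = "NA") {
  assay <- match.arg(assay)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = na_token, colClasses = "character")
  if (ncol(df) < 2)
    stop("expression TSV needs a feature-id column plus >=1 sample column: ",
         path, call. = FALSE)
  fid <- df[[1]]
  sid <- colnames(df)[-1]
  if (anyDuplicated(sid))
    stop("duplicate sample ids in header of ", path, ": ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(fid))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "), call. = FALSE)
  vals <- matrix(NA_real_, nrow = length(fid), ncol = length(sid),
                 dimnames = list(fid, sid))
  for (j in seq_along(sid)) {
    raw <- df[[j + 1]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw))
    if (length(bad) > 0)
      stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s' in %s",
                   raw[bad[1]], fid[bad[1]], sid[j], path), call. = FALSE)
    vals[, j] <- num
  }
  all_na <- rowSums(!is.na(vals)) == 0
  if (any(all_na)) {
    message(sum(all_na), " all-missing feature row(s) dropped: ",
            paste(utils::head(fid[all_na], 5), collapse = ", "))
    vals <- vals[!all_na, , drop = FALSE]
  }
  expression_matrix(vals, assay)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: first column `id`, one column per
#' sample, missing cells serialized as `na_token`. Values are written at
#' full precision (round-trip safe).
#'
#' @param x an [expression_matrix].
#' @param path output path.
#' @param na_token missing-value token (default `"NA"`).
#' @export
write_expression_matrix <- function(x, path, na_token = "NA") {
  stopifnot(inherits(x, "expression_matrix"))
  chr <- matrix(sprintf("%.17g", x$values), nrow = nrow(x$values))
  chr[is.na(x$values)] <- NA_character_
  df <- data.frame(id = x$feature_ids, chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", x$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = na_token)
  invisible(path)
}
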