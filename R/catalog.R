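#' Validated miRNA-target interaction catalog
#'
#' A catalog of wet-lab validated miRNA-target pairs (miRTarBase-style):
#' each record carries the miRNA id, the target gene symbol, the kind of
#' experimental support, and a source accession. Pairs are unique on
#' (mirna_id, gene_symbol).
#'
#' @param records data.frame with columns `mirna_id`, `gene_symbol`,
#'   `support_type`, `source_id`.
#' @return An object of class `interaction_catalog`.
#' @export
interaction_catalog <- function(records) {
  req <- c("mirna_id", "gene_symbol", "support_type", "source_id")
  stopifnot(is.data.frame(records))
  for (col in setdiff(req, names(records)))
    records[[col]] <- rep(NA_character_, nrow(records))
  records <- records[, req, drop = FALSE]
  for (col in req) records[[col]] <- as.character(records[[col]])
  if (nrow(records) > 0 &&
      (any(!nzchar(records$mirna_id) | is.na(records$mirna_id)) ||
       any(!nzchar(records$gene_symbol) | is.na(records$gene_symbol))))
    stop("mirna_id and gene_symbol must be non-empty", call. = FALSE)
  key <- paste(records$mirna_id, records$gene_symbol, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate (miRNA, gene) pair(s) dropped; first record kept")
    records <- records[!dup, , drop = FALSE]
  }
  rownames(records) <- NULL
  structure(list(records = records), class = "interaction_catalog")
}

#' @export
print.interaction_catalog <- function(x, ...) {
  cat(sprintf("<interaction_catalog> %d validated miRNA-target pair(s)\n",
              nrow(x$records)))
  invisible(x)
}

# header aliases recognized case-insensitively, in lookup priority order
.catalog_aliases <- list(
  mirna_id    = c("mirna_id", "mirna", "mir_id"),
  gene_symbol = c("gene_symbol", "target gene", "target_gene", "gene", "target"),
  support_type = c("support_type", "support type", "experiments"),
  source_id   = c("source_id", "mirtarbase id", "id")
)

#' Read an interaction catalog from CSV
#'
#' Accepts miRTarBase-export-style headers (e.g. `miRTarBase ID`, `miRNA`,
#' `Target Gene`, `Support Type`), matched case-insensitively. Duplicated
#' (miRNA, gene) pairs are dropped keeping the first record; missing
#' optional columns default to NA.
#'
#' @param path path to a comma-delimited file with a header row.
#' @return An [interaction_catalog].
#' @export
read_interaction_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0 ||
      length(readLines(path, n = 1L, warn = FALSE)) == 0) {
    warning("empty catalog file: ", path, call. = FALSE)
    return(interaction_catalog(data.frame(mirna_id = character(),
                                          gene_symbol = character())))
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  lower <- tolower(trimws(names(df)))
  pick <- function(field) {
    hit <- match(.catalog_aliases[[field]], lower)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0) NULL else df[[hit[1]]]
  }
  mirna <- pick("mirna_id")
  gene <- pick("gene_symbol")
  if (is.null(mirna))
    stop("catalog is missing a miRNA id column in ", path, call. = FALSE)
  if (is.null(gene))
    stop("catalog is missing a target gene column in ", path, call. = FALSE)
  out <- data.frame(mirna_id = mirna, gene_symbol = gene,
                    stringsAsFactors = FALSE)
  sup <- pick("support_type"); src <- pick("source_id")
  if (!is.null(sup)) out$support_type <- sup
  if (!is.null(src)) out$source_id <- src
  if (nrow(out) == 0) warning("catalog has no records: ", path, call. = FALSE)
  interaction_catalog(out)
}

#' Write an interaction catalog to CSV
#'
#' @param x an [interaction_catalog].
#' @param path output path.
#' @export
write_interaction_catalog <- function(x, path) {
  stopifnot(inherits(x, "interaction_catalog"))
  utils::write.csv(x$records, path, row.names = FALSE, na = "")
  invisible(path)
}
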