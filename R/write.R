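#' Write a characterization table
#'
#' Serializes characterization rows with columns, in order: mirna_id,
#' gene_symbol, tissue, condition, n_used, p_mirna_gene, sign_mirna_gene,
#' p_gene_protein, sign_gene_protein, interaction_type. P-values are printed
#' in scientific notation with 3 significant digits (e.g. `1.60e-03`);
#' absent protein fields are serialized as the NA token.
#'
#' @param rows a characterization data.frame (possibly empty).
#' @param path output path.
#' @param format `"tsv"`, `"csv"` or `"json"`.
#' @param na_token missing-value token for tsv/csv (default `"NA"`).
#' @export
write_characterization_table <- function(rows, path,
                                         format = c("tsv", "csv", "json"),
                                         na_token = "NA") {
  format <- match.arg(format)
  cols <- c("mirna_id", "gene_symbol", "tissue", "condition", "n_used",
            "p_mirna_gene", "sign_mirna_gene", "p_gene_protein",
            "sign_gene_protein", "interaction_type")
  df <- as.data.frame(rows)[, cols, drop = FALSE]
  fmt_p <- function(p) ifelse(is.na(p), NA_character_,
                              formatC(p, format = "e", digits = 2))
  df$p_mirna_gene <- fmt_p(df$p_mirna_gene)
  df$p_gene_protein <- fmt_p(df$p_gene_protein)
  if (format == "json") {
    jsonlite::write_json(df, path, na = "null", auto_unbox = FALSE,
                         dataframe = "rows", pretty = TRUE)
  } else {
    utils::write.table(df, path, sep = if (format == "tsv") "\t" else ",",
                       quote = FALSE, row.names = FALSE, na = na_token)
  }
  invisible(path)
}

#' Read a characterization table written by [write_characterization_table()]
#'
#' @param path input path.
#' @param format `"tsv"`, `"csv"` or `"json"`.
#' @param na_token missing-value token for tsv/csv.
#' @return data.frame with the characterization schema (p-value columns
#'   numeric at the written 3-significant-digit precision).
#' @export
read_characterization_table <- function(path, format = c("tsv", "csv", "json"),
                                        na_token = "NA") {
  format <- match.arg(format)
  df <- if (format == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.delim(path, sep = if (format == "tsv") "\t" else ",",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      na.strings = na_token)
  }
  need <- c("mirna_id", "gene_symbol", "tissue", "condition", "n_used",
            "p_mirna_gene", "sign_mirna_gene", "p_gene_protein",
            "sign_gene_protein", "interaction_type")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("characterization table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("p_mirna_gene", "p_gene_protein"))
    df[[col]] <- as.numeric(df[[col]])
  df$n_used <- as.integer(df$n_used)
  df
}

#' Write a comparison view as a wide TSV
#'
#' @param rows output of [compare_runs()].
#' @param path output path.
#' @param na_token missing-value token.
#' @export
write_comparison_table <- function(rows, path, na_token = "NA") {
  df <- as.data.frame(rows)
  pcols <- grep("\\.p_(mirna_gene|gene_protein)$", names(df))
  for (j in pcols)
    df[[j]] <- ifelse(is.na(df[[j]]), NA_character_,
                      formatC(df[[j]], format = "e", digits = 2))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = na_token)
  invisible(path)
}
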