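#' Characterize all catalog pairs in one tissue cohort
#'
#' For every validated (miRNA, gene) pair of the catalog whose features are
#' present in the cohort's matrices, computes the miRNA-gene association
#' (gene expression as response), the gene-protein association (protein as
#' response) when the cohort has protein data covering the gene, and the
#' resulting interaction call. Pairs whose features are absent are reported
#' in the `skipped` attribute with a reason, so that catalog pairs are
#' conserved: results plus skipped rows cover the catalog exactly.
#'
#' @param cohort a [cohort_view()] with at least mirna and gene assays.
#' @param catalog an [interaction_catalog()].
#' @param config a [gt_config()].
#' @param class_config a [classification_config()]. With
#'   `mt_correction = "bh"`, the miRNA-gene and gene-protein families are
#'   adjusted separately before classification and the adjusted p-values are
#'   reported.
#' @return data.frame of class `characterization` with columns `mirna_id`,
#'   `gene_symbol`, `tissue`, `condition`, `n_used`, `p_mirna_gene`,
#'   `sign_mirna_gene`, `p_gene_protein`, `sign_gene_protein`,
#'   `interaction_type`, sorted by `p_mirna_gene` ascending with
#'   lexicographic (mirna_id, gene_symbol) tie-break; attribute `skipped` is
#'   a data.frame (mirna_id, gene_symbol, reason).
#' @export
characterize_cohort <- function(cohort, catalog, config = gt_config(),
                                class_config = classification_config()) {
  stopifnot(inherits(cohort, "cohort_view"),
            inherits(catalog, "interaction_catalog"))
  rec <- catalog$records
  if (nrow(rec) == 0) stop("catalog is empty", call. = FALSE)
  for (a in c("mirna", "gene"))
    if (!a %in% names(cohort$matrices))
      stop("cohort lacks required assay: ", a, call. = FALSE)
  mir <- cohort$matrices$mirna
  gen <- cohort$matrices$gene
  prot <- if (cohort$has_protein) cohort$matrices$protein else NULL

  skipped <- list()
  mg_list <- list()
  gp_list <- list()
  keep <- integer()
  for (i in seq_len(nrow(rec))) {
    mid <- rec$mirna_id[i]; gid <- rec$gene_symbol[i]
    if (!mid %in% mir$feature_ids) {
      skipped[[length(skipped) + 1]] <- data.frame(
        mirna_id = mid, gene_symbol = gid,
        reason = "miRNA absent from mirna matrix", stringsAsFactors = FALSE)
      next
    }
    if (!gid %in% gen$feature_ids) {
      skipped[[length(skipped) + 1]] <- data.frame(
        mirna_id = mid, gene_symbol = gid,
        reason = "gene absent from gene matrix", stringsAsFactors = FALSE)
      next
    }
    mg <- pair_association(gen$values[gid, ], mir$values[mid, ], config,
                           response_id = gid, covariate_id = mid,
                           response_assay = "gene", covariate_assay = "mirna")
    gp <- NULL
    if (!is.null(prot) && gid %in% prot$feature_ids)
      gp <- pair_association(prot$values[gid, ], gen$values[gid, ], config,
                             response_id = gid, covariate_id = gid,
                             response_assay = "protein",
                             covariate_assay = "gene")
    keep <- c(keep, i)
    mg_list[[length(mg_list) + 1]] <- mg
    gp_list[length(gp_list) + 1] <- list(gp)  # list(NULL) keeps the slot
  }
  if (length(keep) == 0)
    stop("no catalog pair is testable in this cohort (feature namespaces do not overlap)",
         call. = FALSE)
  if (class_config$mt_correction != "none") {
    mg_list <- apply_multiple_testing(mg_list, class_config$mt_correction)
    has_gp <- !vapply(gp_list, is.null, logical(1))
    if (any(has_gp)) {
      adj <- apply_multiple_testing(gp_list[has_gp], class_config$mt_correction)
      gp_list[has_gp] <- adj
    }
  }
  rows <- lapply(seq_along(keep), function(k) {
    i <- keep[k]; mg <- mg_list[[k]]; gp <- gp_list[[k]]
    data.frame(mirna_id = rec$mirna_id[i], gene_symbol = rec$gene_symbol[i],
               tissue = cohort$tissue, condition = cohort$condition,
               n_used = mg$n_used,
               p_mirna_gene = mg$p_value, sign_mirna_gene = mg$sign,
               p_gene_protein = if (is.null(gp)) NA_real_ else gp$p_value,
               sign_gene_protein = if (is.null(gp)) NA_character_ else gp$sign,
               interaction_type = classify_interaction(mg, gp, class_config),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_mirna_gene, out$mirna_id, out$gene_symbol,
                   na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped) > 0) do.call(rbind, skipped) else
    data.frame(mirna_id = character(), gene_symbol = character(),
               reason = character(), stringsAsFactors = FALSE)
  class(out) <- c("characterization", "data.frame")
  out
}

#' Join characterization runs into a comparison view
#'
#' Outer-joins two or more runs (e.g. tumor vs normal, or two tissues) on
#' the (mirna_id, gene_symbol) pair key. Each run contributes a column block
#' `<label>.p_mirna_gene`, `<label>.sign_mirna_gene`,
#' `<label>.p_gene_protein`, `<label>.sign_gene_protein`,
#' `<label>.interaction_type`; pairs missing from a run have NA cells.
#'
#' @param runs named list of characterization data.frames (>= 2).
#' @return data.frame with one row per pair in the union of pair keys.
#' @export
compare_runs <- function(runs) {
  stopifnot(is.list(runs), length(runs) >= 2)
  if (is.null(names(runs)) || any(!nzchar(names(runs))))
    names(runs) <- paste0("run", seq_along(runs))
  cols <- c("p_mirna_gene", "sign_mirna_gene", "p_gene_protein",
            "sign_gene_protein", "interaction_type")
  out <- NULL
  for (lab in names(runs)) {
    r <- as.data.frame(runs[[lab]])[, c("mirna_id", "gene_symbol", cols)]
    names(r)[-(1:2)] <- paste(lab, cols, sep = ".")
    out <- if (is.null(out)) r else
      merge(out, r, by = c("mirna_id", "gene_symbol"), all = TRUE)
  }
  out <- out[order(out$mirna_id, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter and sort a characterization view
#'
#' Conjunctive selectors over a characterization table; the result is
#' stably sorted by miRNA-gene p-value ascending.
#'
#' @param rows a characterization data.frame.
#' @param mirna_ids,gene_symbols,calls optional character vectors to keep.
#' @param max_p optional upper bound on `p_mirna_gene`.
#' @param protein_only keep only rows with a gene-protein test (default
#'   FALSE).
#' @return The filtered, sorted data.frame.
#' @export
filter_view <- function(rows, mirna_ids = NULL, gene_symbols = NULL,
                        calls = NULL, max_p = NULL, protein_only = FALSE) {
  keep <- rep(TRUE, nrow(rows))
  if (!is.null(mirna_ids)) keep <- keep & rows$mirna_id %in% mirna_ids
  if (!is.null(gene_symbols)) keep <- keep & rows$gene_symbol %in% gene_symbols
  if (!is.null(calls)) keep <- keep & rows$interaction_type %in% calls
  if (!is.null(max_p)) keep <- keep & !is.na(rows$p_mirna_gene) &
      rows$p_mirna_gene <= max_p
  if (isTRUE(protein_only)) keep <- keep & !is.na(rows$p_gene_protein)
  out <- rows[keep, , drop = FALSE]
  out <- out[order(out$p_mirna_gene, out$mirna_id, out$gene_symbol,
                   na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a characterization run
#'
#' @param rows a characterization data.frame.
#' @return list with `counts` (named integer vector over
#'   [interaction_calls]) and `fraction_typed`, the fraction of rows called
#'   degradation or inhibition — the pairs the typing keeps for downstream
#'   analysis.
#' @export
summarize_run <- function(rows) {
  counts <- table(factor(rows$interaction_type, levels = interaction_calls))
  counts <- stats::setNames(as.integer(counts), names(counts))
  typed <- sum(counts[c("degradation", "inhibition")])
  list(counts = counts,
       fraction_typed = if (nrow(rows) == 0) 0 else typed / nrow(rows))
}
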