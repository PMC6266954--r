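#' Synthetic-cohort simulation configuration
#'
#' Describes a TCGA-like cohort: log-normal FPKM-style miRNA and gene
#' abundances (log2-scale normal marginals), an RPPA-style normalized
#' protein assay covering a fraction of genes, and a set of planted
#' (miRNA, gene) dependencies with chosen interaction type and strength.
#'
#' Planted structure, on the log2 scale (so the pipeline's log2(v+1)
#' transform approximately recovers it):
#' * `degradation` — gene = -b * miRNA + noise, protein = +c * gene + noise;
#' * `inhibition`  — gene = +b * miRNA + noise, protein = -c * gene + noise;
#' * `null`        — miRNA, gene and protein mutually independent (decoy
#'   catalog pairs, so specificity is measurable).
#'
#' b and c are set so the population correlation magnitude equals
#' `strength`.
#'
#' @param n_samples matched samples per assay (default 150, the order of a
#'   TCGA tissue cohort).
#' @param n_mirna,n_gene number of miRNA / gene features.
#' @param planted data.frame with columns `mirna_idx`, `gene_idx`, `type`
#'   (degradation/inhibition/null) and `strength` in (0,1); at most one
#'   record per (miRNA, gene), indices within range.
#' @param noise_sd residual noise sd on the log2 scale (default 1).
#' @param fpkm_log_mean,fpkm_log_sd log2-scale mean and sd of the FPKM
#'   marginals (defaults 3 and 1.5: right-skewed abundances with median ~8
#'   FPKM).
#' @param protein_coverage fraction of genes with a protein row (default
#'   0.8). Genes of planted degradation/inhibition pairs are always covered;
#'   0 disables the protein assay entirely (e.g. a normal-tissue cohort).
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 150L, n_mirna = 30L, n_gene = 150L,
                              planted = NULL, noise_sd = 1,
                              fpkm_log_mean = 3, fpkm_log_sd = 1.5,
                              protein_coverage = 0.8, seed = 1L) {
  if (is.null(planted))
    planted <- data.frame(mirna_idx = integer(), gene_idx = integer(),
                          type = character(), strength = numeric(),
                          stringsAsFactors = FALSE)
  stopifnot(is.data.frame(planted),
            all(c("mirna_idx", "gene_idx", "type", "strength") %in%
                  names(planted)))
  if (nrow(planted) > 0) {
    stopifnot(all(planted$mirna_idx >= 1 & planted$mirna_idx <= n_mirna),
              all(planted$gene_idx >= 1 & planted$gene_idx <= n_gene),
              all(planted$type %in% c("degradation", "inhibition", "null")))
    if (anyDuplicated(planted[, c("mirna_idx", "gene_idx")]))
      stop("at most one planted record per (miRNA, gene)", call. = FALSE)
    typed <- planted$type != "null"
    if (any(typed & (planted$strength <= 0 | planted$strength >= 1)))
      stop("infeasible strength: planted correlations must lie in (0, 1) ",
           "for finite noise", call. = FALSE)
    if (anyDuplicated(planted$gene_idx[typed]))
      stop("a gene can carry at most one typed planted dependency", call. = FALSE)
  }
  stopifnot(noise_sd > 0, fpkm_log_sd > 0,
            protein_coverage >= 0, protein_coverage <= 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_mirna = as.integer(n_mirna), n_gene = as.integer(n_gene),
                 planted = planted, noise_sd = noise_sd,
                 fpkm_log_mean = fpkm_log_mean, fpkm_log_sd = fpkm_log_sd,
                 protein_coverage = protein_coverage,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default planted design: typed and decoy pairs
#'
#' Convenience builder: `n_degradation` + `n_inhibition` planted pairs at a
#' common strength, plus `n_null` independent decoy pairs, assigned to
#' distinct (miRNA, gene) slots round-robin over the miRNA range.
#'
#' @param n_degradation,n_inhibition,n_null pair counts.
#' @param strength planted correlation magnitude (default 0.6).
#' @param n_mirna number of miRNA features available.
#' @return data.frame suitable for [simulation_config()]`$planted`.
#' @export
planted_design <- function(n_degradation = 10L, n_inhibition = 10L,
                           n_null = 30L, strength = 0.6, n_mirna = 30L) {
  k <- n_degradation + n_inhibition + n_null
  data.frame(
    mirna_idx = ((seq_len(k) - 1L) %% n_mirna) + 1L,
    gene_idx = seq_len(k),
    type = rep(c("degradation", "inhibition", "null"),
               c(n_degradation, n_inhibition, n_null)),
    strength = strength, stringsAsFactors = FALSE)
}

#' Simulate a TCGA-like cohort with planted interaction types
#'
#' @param config a [simulation_config()].
#' @param tissue,condition labels for the cohort.
#' @return list of class `synthetic_cohort`: `matrices` (named list of
#'   [expression_matrix]; `protein` absent when `protein_coverage = 0`),
#'   `truth` (data.frame mirna_id, gene_symbol, type), `catalog` (an
#'   [interaction_catalog] over all planted + decoy pairs) and `config`.
#' @export
simulate_cohort <- function(config = simulation_config(), tissue = "SYNTH",
                            condition = "tumor") {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_samples
  sids <- sprintf("S%03d", seq_len(n))
  mids <- sprintf("hsa-mir-%04d", seq_len(config$n_mirna))
  gids <- sprintf("GENE%04d", seq_len(config$n_gene))
  pl <- config$planted
  slope <- function(strength) # log-scale coefficient giving |cor| = strength
    strength / sqrt(1 - strength^2) * config$noise_sd / config$fpkm_log_sd

  with_seed(config$seed, {
    mir_log <- matrix(stats::rnorm(config$n_mirna * n, config$fpkm_log_mean,
                                   config$fpkm_log_sd),
                      nrow = config$n_mirna, dimnames = list(mids, sids))
    gene_log <- matrix(stats::rnorm(config$n_gene * n, config$fpkm_log_mean,
                                    config$fpkm_log_sd),
                       nrow = config$n_gene, dimnames = list(gids, sids))
    typed <- which(pl$type != "null")
    for (i in typed) {
      b <- slope(pl$strength[i])
      if (pl$type[i] == "degradation") b <- -b
      mc <- mir_log[pl$mirna_idx[i], ] - config$fpkm_log_mean
      gene_log[pl$gene_idx[i], ] <- config$fpkm_log_mean + b * mc +
        stats::rnorm(n, 0, config$noise_sd)
    }
    matrices <- list(mirna = expression_matrix(2^mir_log, "mirna"),
                     gene = expression_matrix(2^gene_log, "gene"))
    if (config$protein_coverage > 0) {
      n_cov <- max(round(config$protein_coverage * config$n_gene),
                   length(typed))
      forced <- pl$gene_idx[typed]
      pool <- setdiff(seq_len(config$n_gene), forced)
      extra <- if (n_cov > length(forced))
        sort(sample(pool, n_cov - length(forced))) else integer()
      covered <- sort(unique(c(forced, extra)))
      prot <- matrix(stats::rnorm(length(covered) * n),
                     nrow = length(covered),
                     dimnames = list(gids[covered], sids))
      for (i in typed) {
        gsd <- sqrt((slope(pl$strength[i]) * config$fpkm_log_sd)^2 +
                      config$noise_sd^2)
        cc <- pl$strength[i] / sqrt(1 - pl$strength[i]^2) *
          config$noise_sd / gsd
        if (pl$type[i] == "inhibition") cc <- -cc
        gc <- gene_log[pl$gene_idx[i], ] - config$fpkm_log_mean
        prot[gids[pl$gene_idx[i]], ] <- cc * gc +
          stats::rnorm(n, 0, config$noise_sd)
      }
      matrices$protein <- expression_matrix(prot, "protein")
    }
    truth <- data.frame(mirna_id = mids[pl$mirna_idx],
                        gene_symbol = gids[pl$gene_idx],
                        type = pl$type, stringsAsFactors = FALSE)
    catalog <- interaction_catalog(data.frame(
      mirna_id = truth$mirna_id, gene_symbol = truth$gene_symbol,
      support_type = "synthetic", source_id = sprintf("SYN%04d", seq_len(nrow(truth))),
      stringsAsFactors = FALSE))
    structure(list(matrices = matrices, truth = truth, catalog = catalog,
                   config = config, tissue = tissue, condition = condition),
              class = "synthetic_cohort")
  })
}

#' Materialize a synthetic cohort as files
#'
#' Writes the assay TSVs (`mirna.tsv`, `gene.tsv`, and `protein.tsv` when
#' present), `catalog.csv`, `truth.json` and `config.json` into a directory,
#' immediately consumable by the command-line interface.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (a in names(cohort$matrices))
    write_expression_matrix(cohort$matrices[[a]],
                            file.path(dir, paste0(a, ".tsv")))
  write_interaction_catalog(cohort$catalog, file.path(dir, "catalog.csv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", pretty = TRUE)
  cfg <- unclass(cohort$config)
  cfg$tissue <- cohort$tissue
  cfg$condition <- cohort$condition
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       dataframe = "rows", pretty = TRUE)
  invisible(dir)
}

#' Score recovered interaction types against the planted truth
#'
#' @param results a characterization data.frame over the synthetic catalog.
#' @param truth data.frame (mirna_id, gene_symbol, type) from
#'   [simulate_cohort()].
#' @return list with `confusion` (planted type x interaction call table),
#'   `recall` (named vector: fraction of planted degradation / inhibition
#'   pairs receiving their planted call) and `false_typing_rate` (fraction
#'   of null pairs receiving any typed call: degradation, inhibition,
#'   no_interaction or no_interaction_star).
#' @export
evaluate_recovery <- function(results, truth) {
  if (nrow(results) == 0) stop("empty results", call. = FALSE)
  key <- function(d) paste(d$mirna_id, d$gene_symbol, sep = "\r")
  idx <- match(key(results), key(truth))
  if (anyNA(idx))
    stop("result pair(s) missing from truth: ",
         paste(utils::head(results$mirna_id[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  planted_type <- truth$type[idx]
  call <- factor(results$interaction_type, levels = interaction_calls)
  confusion <- table(planted = factor(planted_type,
                                      levels = c("degradation", "inhibition", "null")),
                     call = call)
  recall <- vapply(c("degradation", "inhibition"), function(tp) {
    is_tp <- planted_type == tp
    if (!any(is_tp)) return(NA_real_)
    mean(results$interaction_type[is_tp] == tp)
  }, numeric(1))
  typed <- c("degradation", "inhibition", "no_interaction",
             "no_interaction_star")
  is_null <- planted_type == "null"
  ftr <- if (!any(is_null)) NA_real_ else
    mean(results$interaction_type[is_null] %in% typed)
  list(confusion = confusion, recall = recall, false_typing_rate = ftr)
}
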