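test_that("simulation is bit-identical under a fixed seed", {
  cfg <- simulation_config(n_samples = 40, planted = planted_design(2, 2, 2),
                           seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$matrices$mirna$values, b$matrices$mirna$values)
  expect_identical(a$matrices$gene$values, b$matrices$gene$values)
  expect_identical(a$matrices$protein$values, b$matrices$protein$values)
  expect_identical(a$truth, b$truth)
})

test_that("planted dependencies realize their target correlations", {
  cfg <- simulation_config(
    n_samples = 500,
    planted = data.frame(mirna_idx = 1:2, gene_idx = 1:2,
                         type = c("degradation", "inhibition"),
                         strength = 0.8),
    seed = 88)
  co <- simulate_cohort(cfg)
  lm_ <- log2(co$matrices$mirna$values + 1)
  lg <- log2(co$matrices$gene$values + 1)
  r_deg <- cor(lm_[1, ], lg[1, ])
  r_inh <- cor(lm_[2, ], lg[2, ])
  expect_gt(r_deg, -0.9); expect_lt(r_deg, -0.7)
  expect_gt(r_inh, 0.7); expect_lt(r_inh, 0.9)
  # protein side: positive for degradation, negative for inhibition
  prot <- co$matrices$protein$values
  expect_gt(cor(lg[1, ], prot["GENE0001", ]), 0.7)
  expect_lt(cor(lg[2, ], prot["GENE0002", ]), -0.7)
})

test_that("FPKM marginals are non-negative and right-skewed; protein normalized", {
  co <- simulate_cohort(simulation_config(n_samples = 100, seed = 5,
                                          planted = planted_design(1, 1, 1)))
  expect_true(all(co$matrices$mirna$values >= 0))
  expect_true(all(co$matrices$gene$values >= 0))
  g <- co$matrices$gene$values
  expect_gt(mean(g), median(g))  # heavy right tail on the FPKM scale
  expect_lt(min(co$matrices$protein$values), 0)
})

test_that("protein_coverage = 0 yields a protein-free cohort", {
  co <- simulate_cohort(simulation_config(n_samples = 40, seed = 9,
                                          planted = planted_design(2, 2, 2),
                                          protein_coverage = 0))
  expect_null(co$matrices$protein)
  cv <- cohort_view(co$matrices, "SYNTH", "normal")
  expect_false(cv$has_protein)
  rows <- characterize_cohort(cv, co$catalog, gt_config(n_perm = 999, seed = 1))
  expect_true(all(rows$interaction_type %in%
                    c("degradation", "no_interaction_star", "no_evidence",
                      "untestable")))
})

test_that("infeasible planted configurations are rejected", {
  bad <- data.frame(mirna_idx = 1, gene_idx = 1, type = "degradation",
                    strength = 1)
  expect_error(simulation_config(planted = bad), "infeasible strength")
  dup <- data.frame(mirna_idx = c(1, 1), gene_idx = c(1, 1),
                    type = c("degradation", "null"), strength = 0.5)
  expect_error(simulation_config(planted = dup), "at most one planted")
})

test_that("evaluate_recovery scores a pass-through of the truth as identity", {
  truth <- data.frame(mirna_id = c("m1", "m2", "m3"),
                      gene_symbol = c("g1", "g2", "g3"),
                      type = c("degradation", "inhibition", "null"),
                      stringsAsFactors = FALSE)
  results <- data.frame(mirna_id = truth$mirna_id,
                        gene_symbol = truth$gene_symbol,
                        interaction_type = c("degradation", "inhibition",
                                             "no_evidence"),
                        stringsAsFactors = FALSE)
  ev <- evaluate_recovery(results, truth)
  expect_equal(unname(ev$recall), c(1, 1))
  expect_equal(ev$false_typing_rate, 0)
  expect_equal(ev$confusion["degradation", "degradation"], 1,
               ignore_attr = TRUE)
  expect_error(evaluate_recovery(results[0, ], truth), "empty")
  stranger <- results; stranger$gene_symbol[1] <- "gX"
  expect_error(evaluate_recovery(stranger, truth), "missing from truth")
})

test_that("per-type recall is non-decreasing in sample size", {
  recalls <- vapply(c(50, 150, 500), function(n) {
    cfg <- simulation_config(n_samples = n, n_mirna = 10, n_gene = 20,
                             planted = planted_design(3, 3, 4, 0.6, 10),
                             seed = 123)
    co <- simulate_cohort(cfg)
    cv <- cohort_view(co$matrices, "SYNTH", "tumor")
    rows <- characterize_cohort(cv, co$catalog, gt_config(n_perm = 999, seed = 1))
    mean(evaluate_recovery(rows, co$truth)$recall)
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
  expect_equal(recalls[3], 1)
})

test_that("a cohort bundle round-trips through the file system", {
  co <- simulate_cohort(simulation_config(n_samples = 30, seed = 44,
                                          planted = planted_design(1, 1, 2)))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir,
    c("mirna.tsv", "gene.tsv", "protein.tsv", "catalog.csv", "truth.json",
      "config.json")))))
  m <- read_expression_matrix(file.path(dir, "mirna.tsv"), "mirna")
  expect_identical(m$values, co$matrices$mirna$values)
  cat_back <- read_interaction_catalog(file.path(dir, "catalog.csv"))
  expect_identical(cat_back$records$mirna_id, co$catalog$records$mirna_id)
})
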