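# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: permutations come from Heap's algorithm (the
# package enumerates recursively in lexicographic-ish order) and the test
# statistic is the squared Pearson correlation via stats::cor.

# all permutations of seq_len(n), Heap's algorithm (iterative)
heap_permutations <- function(n) {
  a <- seq_len(n)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  out[1, ] <- a
  k <- 1L
  c_ <- integer(n)
  i <- 1L
  while (i <= n) {
    if (c_[i] < i - 1L) {
      if (i %% 2L == 1L) {
        tmp <- a[1]; a[1] <- a[i]; a[i] <- tmp
      } else {
        tmp <- a[c_[i] + 1L]; a[c_[i] + 1L] <- a[i]; a[i] <- tmp
      }
      k <- k + 1L
      out[k, ] <- a
      c_[i] <- c_[i] + 1L
      i <- 1L
    } else {
      c_[i] <- 0L
      i <- i + 1L
    }
  }
  out
}

# exact two-sided permutation p-value of the squared Pearson correlation
exhaustive_cor2_p <- function(y, x) {
  P <- heap_permutations(length(y))
  obs <- stats::cor(x, y)^2
  mean(apply(P, 1, function(idx) stats::cor(x, y[idx])^2) >= obs)
}

# tiny two-assay expression matrix pair sharing samples
toy_matrices <- function(n = 10, seed = 42) {
  set.seed(seed)
  sids <- sprintf("S%02d", seq_len(n))
  m <- matrix(rexp(3 * n, 0.1), nrow = 3,
              dimnames = list(c("hsa-mir-1", "hsa-mir-2", "hsa-mir-3"), sids))
  g <- matrix(rexp(4 * n, 0.1), nrow = 4,
              dimnames = list(c("GA", "GB", "GC", "GD"), sids))
  list(mirna = expression_matrix(m, "mirna"),
       gene = expression_matrix(g, "gene"))
}

make_pa <- function(p, sign, untestable = FALSE, n_used = 50L) {
  structure(list(response_id = "g", covariate_id = "m", p_value = p,
                 sign = sign, n_used = n_used, untestable = untestable,
                 reason = NA_character_),
            class = "pair_association")
}
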