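#' Global test of association between expression profiles
#'
#' The global test asks whether any of a group of covariate profiles is
#' associated with a response profile. In its linear score form, with
#' centered response residuals r = y - mean(y) and standardized covariate
#' columns x_j, the statistic is
#'
#'   Q = sum_j (x_j' r)^2 / (m * s^2),   s^2 = r'r / n
#'
#' i.e. the mean squared covariance between the residuals and each
#' covariate, scaled by the residual variance. Q decomposes additively into
#' per-covariate contributions whose signs (sign of x_j' r) give the
#' direction of association. The null distribution is obtained by permuting
#' the response across samples (exhaustively for small n, Monte-Carlo
#' otherwise) or by a moment-matched gamma approximation.
#'
#' @name globaltest
NULL

# run expr with a private, seeded RNG stream; the caller's stream is untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Global-test configuration
#'
#' @param method null-distribution method: `"permutation"` (default,
#'   Monte-Carlo with `n_perm` draws), `"exhaustive"` (all n! permutations,
#'   n <= 9), or `"gamma"` (moment-matched analytic approximation).
#' @param n_perm number of Monte-Carlo permutations (>= 999).
#' @param seed integer seed for the permutation stream.
#' @param transform expression transform applied per assay before testing:
#'   `"auto"` (log2(v+1) for mirna/gene FPKM, none for normalized protein
#'   intensities), `"log2p1"`, or `"none"`.
#' @param standardize center/scale covariate columns to unit variance
#'   (default TRUE; makes Q scale-free).
#' @param min_samples minimum complete-case n per test (default 8).
#' @return list of class `gt_config`.
#' @export
gt_config <- function(method = c("permutation", "exhaustive", "gamma"),
                      n_perm = 10000L, seed = 1L,
                      transform = c("auto", "log2p1", "none"),
                      standardize = TRUE, min_samples = 8L) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  if (method == "permutation" && n_perm < 999)
    stop("n_perm must be >= 999", call. = FALSE)
  structure(list(method = method, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), transform = transform,
                 standardize = isTRUE(standardize),
                 min_samples = as.integer(min_samples)),
            class = "gt_config")
}

#' Prepare a global-test input
#'
#' Applies the expression transform, drops samples with any missing value in
#' the response or covariates (complete-case filtering, count recorded), and
#' optionally standardizes covariate columns.
#'
#' @param y numeric response profile (length n).
#' @param X numeric covariate matrix (n x m) or vector (m = 1).
#' @param transform `"log2p1"` or `"none"`, applied to both y and X columns
#'   (use [pair_association()] / [group_target_test()] for per-assay
#'   transforms).
#' @param standardize standardize covariate columns (mean 0, unit sample
#'   variance).
#' @param min_samples minimum complete-case n.
#' @return list of class `gt_input` with elements `y`, `X`, `n`, `m`,
#'   `n_removed`, `standardize`.
#' @export
gt_input <- function(y, X, transform = c("none", "log2p1"),
                     standardize = TRUE, min_samples = 8L) {
  transform <- match.arg(transform)
  if (is.vector(X)) X <- matrix(X, ncol = 1, dimnames = list(NULL, "x1"))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(y) == nrow(X), ncol(X) >= 1)
  if (transform == "log2p1") {
    y <- log2(y + 1)
    X <- log2(X + 1)
  }
  ok <- is.finite(y) & rowSums(!is.finite(X)) == 0
  n_removed <- sum(!ok)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  n <- length(y)
  if (n < min_samples)
    stop(sprintf("untestable: %d complete case(s) < min_samples=%d", n,
                 min_samples), call. = FALSE)
  structure(list(y = y, X = X, n = n, m = ncol(X), n_removed = n_removed,
                 standardize = isTRUE(standardize)),
            class = "gt_input")
}

# center response, standardize covariates, validate non-degeneracy;
# shared by the statistic and all p-value methods
.gt_core <- function(input) {
  stopifnot(inherits(input, "gt_input"))
  y <- input$y; X <- input$X
  n <- input$n; m <- input$m
  r <- y - mean(y)
  s2 <- sum(r^2) / n
  if (s2 == 0) stop("untestable: constant response profile", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("untestable: constant covariate profile: ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  Xs <- if (input$standardize)
    scale(X, center = TRUE, scale = sds) else X
  list(r = r, Xs = Xs, s2 = s2, n = n, m = m)
}

#' Global-test statistic and per-covariate contributions
#'
#' @param input a [gt_input()].
#' @return list with `statistic` (Q >= 0) and `contributions`, a data.frame
#'   with columns `covariate_id`, `contribution` (summing to Q) and `sign`
#'   (`"positive"`/`"negative"`/`"zero"`, the sign of the centered
#'   cross-product with the response).
#' @export
global_statistic <- function(input) {
  core <- .gt_core(input)
  cross <- drop(crossprod(core$Xs, core$r))
  contrib <- cross^2 / (core$m * core$s2)
  sgn <- ifelse(cross > 0, "positive", ifelse(cross < 0, "negative", "zero"))
  list(statistic = sum(contrib),
       contributions = data.frame(covariate_id = colnames(input$X),
                                  contribution = unname(contrib),
                                  sign = unname(sgn),
                                  stringsAsFactors = FALSE))
}

# all permutations of 1..n as an n! x n integer matrix (n <= 9)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(rep(i, nrow(sub)), matrix(rest[sub], nrow(sub)))
  }))
}

# Q for each column-permutation of r held in index matrix P (n x k)
.gt_perm_Q <- function(core, P) {
  R <- matrix(core$r[P], nrow = core$n)
  colSums(crossprod(core$Xs, R)^2) / (core$m * core$s2)
}

.gt_result <- function(statistic, p_value, method, core, input,
                       n_perm = NA_integer_, seed = NA_integer_) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n_used = core$n, m = core$m, n_removed = input$n_removed,
                 n_perm = n_perm, seed = seed),
            class = "gt_result")
}

#' @export
print.gt_result <- function(x, ...) {
  cat(sprintf("<gt_result> Q=%.4g, p=%.3g (%s), n=%d, m=%d\n",
              x$statistic, x$p_value, x$method, x$n_used, x$m))
  invisible(x)
}

#' Exact permutation p-value by exhaustive enumeration
#'
#' Enumerates all n! permutations of the response (feasible for n <= 9) and
#' returns p = #(Q_perm >= Q_obs) / n!. The identity permutation is
#' included, so p >= 1/n! and a zero statistic yields p = 1.
#'
#' @param input a [gt_input()] with `n <= 9`.
#' @return A `gt_result` with `method = "exhaustive"`.
#' @export
p_value_exhaustive <- function(input) {
  core <- .gt_core(input)
  if (core$n > 9)
    stop("exhaustive enumeration limited to n <= 9; use p_value_permutation",
         call. = FALSE)
  obs <- sum(drop(crossprod(core$Xs, core$r))^2) / (core$m * core$s2)
  P <- t(all_permutations(core$n))
  Qp <- .gt_perm_Q(core, P)
  # relative tolerance so the identity permutation always counts despite
  # summation-order rounding in the batched null computation
  p <- mean(Qp >= obs * (1 - 1e-12))
  .gt_result(obs, p, "exhaustive", core, input)
}

#' Monte-Carlo permutation p-value
#'
#' Draws B seeded permutations of the response and returns the standard
#' upper-bounded estimate p = (b + 1)/(B + 1) with
#' b = #(Q_perm >= Q_obs); identical (input, n_perm, seed) give
#' bit-identical p-values.
#'
#' @param input a [gt_input()].
#' @param n_perm number of permutations B (>= 999).
#' @param seed integer seed.
#' @return A `gt_result` with `method = "permutation"`.
#' @export
p_value_permutation <- function(input, n_perm = 10000L, seed = 1L) {
  if (n_perm < 999) stop("n_perm must be >= 999", call. = FALSE)
  core <- .gt_core(input)
  obs <- sum(drop(crossprod(core$Xs, core$r))^2) / (core$m * core$s2)
  b <- with_seed(seed, {
    total <- 0L
    B <- as.integer(n_perm)
    chunk <- 20000L
    done <- 0L
    while (done < B) {
      k <- min(chunk, B - done)
      P <- vapply(seq_len(k), function(i) sample.int(core$n), integer(core$n))
      total <- total + sum(.gt_perm_Q(core, P) >= obs * (1 - 1e-12))
      done <- done + k
    }
    total
  })
  p <- (b + 1) / (n_perm + 1)
  .gt_result(obs, p, "permutation", core, input,
             n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Gamma-approximated p-value
#'
#' Analytic approximation to the permutation null of Q: under permutation
#' the centered response has covariance (S2/(n-1)) (I - J/n) with
#' S2 = r'r, so Q = r'Ar with A the centered covariate cross-product
#' operator X X'/(m s^2) behaves like sum(lambda_k chi^2_1), lambda_k =
#' (S2/(n-1)) * eigenvalues of X'X/(m s^2). A gamma distribution is matched
#' to the mean sum(lambda) — which equals the exact permutation mean of Q —
#' and variance 2 sum(lambda^2), and the upper tail evaluated at Q_obs.
#'
#' @param input a [gt_input()].
#' @return A `gt_result` with `method = "gamma"`.
#' @export
p_value_gamma <- function(input) {
  core <- .gt_core(input)
  obs <- sum(drop(crossprod(core$Xs, core$r))^2) / (core$m * core$s2)
  if (obs == 0) return(.gt_result(0, 1, "gamma", core, input))
  S2 <- sum(core$r^2)
  M <- crossprod(core$Xs) / (core$m * core$s2)
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > max(lam) * 1e-12] * S2 / (core$n - 1)
  mu <- sum(lam)
  v <- 2 * sum(lam^2)
  p <- stats::pgamma(obs, shape = mu^2 / v, rate = mu / v, lower.tail = FALSE)
  .gt_result(obs, p, "gamma", core, input)
}

.gt_p <- function(input, config) {
  switch(config$method,
         permutation = p_value_permutation(input, config$n_perm, config$seed),
         exhaustive = p_value_exhaustive(input),
         gamma = p_value_gamma(input))
}

.assay_transform <- function(assay, transform) {
  if (transform != "auto") return(transform)
  if (assay %in% c("mirna", "gene")) "log2p1" else "none"
}

.untestable_pair <- function(response_id, covariate_id, n_used, reason) {
  structure(list(response_id = response_id, covariate_id = covariate_id,
                 p_value = NA_real_, sign = "zero", n_used = n_used,
                 untestable = TRUE, reason = reason),
            class = "pair_association")
}

#' Pairwise association between two expression profiles
#'
#' Runs the m = 1 global test for one (response, covariate) profile pair
#' over a shared ordered sample set. The regulatory target is the response:
#' gene expression is the response to the miRNA covariate, protein abundance
#' the response to the gene covariate. Per-assay transforms are applied
#' (log2(v+1) for FPKM-scaled mirna/gene, none for normalized protein) and
#' samples missing either value are dropped per pair. Degenerate pairs
#' (constant profile after filtering, or fewer complete cases than
#' `min_samples`) are flagged untestable rather than dropped.
#'
#' @param y response profile (named numeric vector).
#' @param x covariate profile over the same ordered samples.
#' @param config a [gt_config()].
#' @param response_id,covariate_id feature labels stored on the result.
#' @param response_assay,covariate_assay assay tags controlling the `"auto"`
#'   transform.
#' @return Object of class `pair_association` with fields `response_id`,
#'   `covariate_id`, `p_value`, `sign`, `n_used`, `untestable`.
#' @export
pair_association <- function(y, x, config = gt_config(),
                             response_id = "response",
                             covariate_id = "covariate",
                             response_assay = "gene",
                             covariate_assay = "mirna") {
  stopifnot(length(y) == length(x))
  ty <- .assay_transform(response_assay, config$transform)
  tx <- .assay_transform(covariate_assay, config$transform)
  y2 <- if (ty == "log2p1") log2(y + 1) else as.numeric(y)
  x2 <- if (tx == "log2p1") log2(x + 1) else as.numeric(x)
  ok <- is.finite(y2) & is.finite(x2)
  n_used <- sum(ok)
  if (n_used < config$min_samples)
    return(.untestable_pair(response_id, covariate_id, n_used,
                            sprintf("only %d complete case(s)", n_used)))
  input <- gt_input(y2[ok], matrix(x2[ok], ncol = 1,
                                   dimnames = list(NULL, covariate_id)),
                    transform = "none", standardize = config$standardize,
                    min_samples = config$min_samples)
  stat <- tryCatch(global_statistic(input), error = function(e) e)
  if (inherits(stat, "error"))
    return(.untestable_pair(response_id, covariate_id, n_used,
                            conditionMessage(stat)))
  res <- .gt_p(input, config)
  structure(list(response_id = response_id, covariate_id = covariate_id,
                 p_value = res$p_value, sign = stat$contributions$sign[1],
                 n_used = n_used, untestable = FALSE, reason = NA_character_),
            class = "pair_association")
}

#' @export
print.pair_association <- function(x, ...) {
  if (x$untestable)
    cat(sprintf("<pair_association> %s ~ %s: untestable (%s)\n",
                x$response_id, x$covariate_id, x$reason))
  else
    cat(sprintf("<pair_association> %s ~ %s: p=%.3g, sign=%s, n=%d\n",
                x$response_id, x$covariate_id, x$p_value, x$sign, x$n_used))
  invisible(x)
}

#' Global test of a miRNA against the group of its target genes
#'
#' Tests the association between one miRNA expression profile (response)
#' and the expression profiles of a group of its target genes (covariates),
#' returning the group p-value and the per-gene contributions sorted with
#' the strongest anti-correlated targets first (anti-correlation between a
#' miRNA and a target is the signature of an active interaction).
#'
#' @param mirna_profile named numeric vector (FPKM scale).
#' @param target_matrix an [expression_matrix] slice (gene assay) whose
#'   samples are ordered like `mirna_profile`.
#' @param config a [gt_config()].
#' @return list with `result` (a `gt_result`) and `contributions`
#'   (data.frame, negative-sign contributions first, then by decreasing
#'   contribution).
#' @export
group_target_test <- function(mirna_profile, target_matrix,
                              config = gt_config()) {
  stopifnot(inherits(target_matrix, "expression_matrix"))
  stopifnot(length(mirna_profile) == length(target_matrix$sample_ids))
  tm <- .assay_transform("mirna", config$transform)
  tg <- .assay_transform(target_matrix$assay, config$transform)
  y <- if (tm == "log2p1") log2(mirna_profile + 1) else as.numeric(mirna_profile)
  X <- t(target_matrix$values)
  if (tg == "log2p1") X <- log2(X + 1)
  ok <- is.finite(y) & rowSums(!is.finite(X)) == 0
  if (sum(ok) < config$min_samples)
    stop(sprintf("untestable: %d complete case(s) < min_samples=%d", sum(ok),
                 config$min_samples), call. = FALSE)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  const <- apply(X, 2, stats::sd) == 0
  if (all(const))
    stop("untestable: all target profiles are constant", call. = FALSE)
  if (any(const)) {
    warning("dropping constant target profile(s): ",
            paste(colnames(X)[const], collapse = ", "), call. = FALSE)
    X <- X[, !const, drop = FALSE]
  }
  input <- gt_input(y, X, transform = "none", standardize = config$standardize,
                    min_samples = config$min_samples)
  stat <- global_statistic(input)
  res <- .gt_p(input, config)
  contrib <- stat$contributions
  ord <- order(factor(contrib$sign, levels = c("negative", "zero", "positive")),
               -contrib$contribution)
  list(result = res, contributions = contrib[ord, , drop = FALSE])
}
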