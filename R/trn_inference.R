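## Per-gene lasso regression over TF features, lambda tuning by 10-fold CV,
## R-squared filtering, coefficient thresholding, and treatment-specific
## networks matched to a reference density.
##
## Objective convention (documented because the cutoff alpha and penalty
## lambda are only meaningful relative to it):
##   (1 / (2m)) * ||Y_j - X A_j||^2 + lambda * sum_i |a_i|
## with a free intercept, response used as-is, TF features NOT rescaled by
## default (coefficients stay comparable across TFs on the common log
## scale, which is what a single global cutoff assumes). glmnet implements
## exactly this objective when standardize = FALSE.

col_vars <- function(x) {
  mu <- colMeans(x)
  colMeans(x^2) - mu^2
}

# Shared glmnet call: descending lambda path ending at the target so the
# warm-started solution at `lambda` is fully converged.
lasso_fit <- function(x, y, lambda, standardize = FALSE, thresh = 1e-12) {
  if (all(col_vars(x) == 0) || var(y) == 0) return(numeric(ncol(x)))
  path <- sort(unique(lambda * c(64, 16, 4, 1)), decreasing = TRUE)
  if (all(lambda == 0)) path <- c(1e-3, 0)
  fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                        lambda = path, standardize = standardize,
                        intercept = TRUE, thresh = thresh,
                        maxit = 1e7)
  as.numeric(coef(fit, s = lambda))[-1L]
}

#' Fit the lasso model for one gene
#'
#' Models the expression of `gene` as a sparse linear combination of TF
#' expression levels, minimizing
#' `(1/(2m)) * ||Y_j - X A_j||^2 + lambda * sum |a_i|` with a free
#' intercept. If the gene is itself a TF its own feature column is zeroed
#' before fitting (self-masking), so the returned self-coefficient is
#' exactly 0.
#'
#' @param expr An [expression_matrix()].
#' @param gene Gene identifier.
#' @param lambda Nonnegative L1 penalty.
#' @param standardize Standardize TF features internally (coefficients are
#'   always returned on the original scale). Default `FALSE`.
#' @return Named numeric vector of coefficients, one per TF.
#' @export
fit_gene_model <- function(expr, gene, lambda, standardize = FALSE) {
  if (lambda < 0) stop("lambda must be nonnegative")
  if (!gene %in% expr$gene_ids) stop("gene not found: ", gene)
  X <- t(expr$values[expr$tf_ids, , drop = FALSE])
  if (gene %in% expr$tf_ids) X[, gene] <- 0
  y <- expr$values[gene, ]
  beta <- lasso_fit(X, y, lambda, standardize = standardize)
  setNames(beta, expr$tf_ids)
}

#' Fit lasso models for every gene
#'
#' @inheritParams fit_gene_model
#' @param genes Genes to fit (default: all genes in `expr`).
#' @param r2 Optional named vector of per-gene CV R-squared to attach.
#' @return A [coefficient_matrix()] (TFs x genes).
#' @export
fit_coefficients <- function(expr, lambda, genes = expr$gene_ids,
                             standardize = FALSE, r2 = NULL) {
  X <- t(expr$values[expr$tf_ids, , drop = FALSE])
  n_tf <- length(expr$tf_ids)
  cols <- vector("list", length(genes))
  for (jj in seq_along(genes)) {
    g <- genes[jj]
    Xg <- X
    if (g %in% expr$tf_ids) Xg[, g] <- 0
    cols[[jj]] <- lasso_fit(Xg, expr$values[g, ], lambda,
                            standardize = standardize)
  }
  A <- do.call(cbind, cols)
  dimnames(A) <- list(expr$tf_ids, genes)
  A <- Matrix::Matrix(A, sparse = TRUE)
  coefficient_matrix(A, lambda_used = lambda, r2 = r2)
}

# Fold assignment: random partition by default; contiguous = TRUE gives
# deterministic contiguous blocks (alternating tenths of the sample order).
make_folds <- function(m, folds, seed, contiguous = FALSE) {
  stopifnot(folds >= 2L)
  if (m < folds) stop("fewer samples than folds")
  if (contiguous) {
    sort(rep_len(seq_len(folds), m))
  } else {
    withr::local_seed(seed)
    sample(rep_len(seq_len(folds), m))
  }
}

# Mean out-of-fold R^2 per gene for each lambda in `grid`.
# Returns genes x lambdas matrix. R^2 of a fold is
# 1 - SSE / SST with SST around the held-out mean.
cv_r2 <- function(expr, grid, folds = 10L, seed = 1L, contiguous = FALSE,
                  standardize = FALSE, genes = expr$gene_ids) {
  grid <- sort(unique(grid), decreasing = TRUE)
  fold_id <- make_folds(length(expr$sample_ids), folds, seed, contiguous)
  Xall <- t(expr$values[expr$tf_ids, , drop = FALSE])
  r2 <- array(0, dim = c(length(genes), length(grid), folds),
              dimnames = list(genes, as.character(grid), NULL))
  hi <- max(max(grid), 1e-3)
  path <- sort(unique(c(grid, hi * c(64, 16, 4))), decreasing = TRUE)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    for (jj in seq_along(genes)) {
      g <- genes[jj]
      Xg <- Xall
      if (g %in% expr$tf_ids) Xg[, g] <- 0
      y <- expr$values[g, ]
      if (all(col_vars(Xg[!test, , drop = FALSE]) == 0) ||
          var(y[!test]) == 0) {
        # no usable features: the model is the training mean
        yt <- y[test]
        sst <- sum((yt - mean(yt))^2)
        r2[jj, , f] <- if (sst > 0) 1 - sum((yt - mean(y[!test]))^2) / sst else NA_real_
        next
      }
      fit <- glmnet::glmnet(Xg[!test, , drop = FALSE], y[!test],
                            family = "gaussian", alpha = 1, lambda = path,
                            standardize = standardize, intercept = TRUE,
                            thresh = 1e-9, maxit = 1e7)
      pred <- predict(fit, newx = Xg[test, , drop = FALSE], s = grid)
      yt <- y[test]
      sst <- sum((yt - mean(yt))^2)
      sse <- colSums((yt - pred)^2)
      r2[jj, , f] <- if (sst > 0) 1 - sse / sst else NA_real_
    }
  }
  apply(r2, c(1L, 2L), mean, na.rm = TRUE)
}

#' Tune the L1 penalty by cross-validated R-squared
#'
#' For each candidate lambda, fits every gene on the training folds and
#' records the mean out-of-fold R-squared (10-fold cross-validation by
#' default); the chosen lambda maximizes the mean over genes of the per-gene
#' mean R-squared.
#'
#' @param expr An [expression_matrix()].
#' @param grid Numeric vector of candidate lambda values (all >= 0).
#' @param folds Number of CV folds.
#' @param seed Seed for the random fold partition.
#' @param contiguous Use contiguous sample blocks instead of a random
#'   partition.
#' @param standardize Passed to the lasso fit.
#' @return A list: `lambda_star`, and `report` (class `FitReport`) holding
#'   the per-gene mean R-squared at `lambda_star` (`r2`), the full
#'   gene x lambda R-squared matrix (`r2_by_lambda`), the grid, fold seed
#'   and per-lambda summary.
#' @export
tune_lambda <- function(expr, grid, folds = 10L, seed = 1L,
                        contiguous = FALSE, standardize = FALSE) {
  stopifnot(length(grid) >= 1L, all(grid >= 0))
  r2m <- cv_r2(expr, grid, folds = folds, seed = seed,
               contiguous = contiguous, standardize = standardize)
  mean_by_lambda <- colMeans(r2m)
  best <- which.max(mean_by_lambda)
  lambda_star <- as.numeric(colnames(r2m)[best])
  report <- structure(list(
    r2 = r2m[, best],
    r2_by_lambda = r2m,
    grid = as.numeric(colnames(r2m)),
    mean_r2_by_lambda = mean_by_lambda,
    lambda_star = lambda_star,
    folds = folds, fold_seed = seed, contiguous = contiguous),
    class = "FitReport")
  list(lambda_star = lambda_star, report = report)
}

#' @export
print.FitReport <- function(x, ...) {
  cat(sprintf("FitReport: %d genes, %d-fold CV, lambda* = %g (mean R2 = %.3f)\n",
              length(x$r2), x$folds, x$lambda_star,
              x$mean_r2_by_lambda[as.character(x$lambda_star)]))
  invisible(x)
}

#' Filter genes by cross-validated R-squared percentile
#'
#' Removes genes whose mean CV R-squared falls strictly below the given
#' percentile of the R-squared distribution. The percentile uses linear
#' interpolation between order statistics (R's default quantile type 7).
#'
#' @param report A `FitReport` from [tune_lambda()], or a named numeric
#'   vector of per-gene R-squared values.
#' @param percentile Percentile in \[0, 100).
#' @return List with `retained` (gene ids) and `cutoff` (the R-squared value
#'   used).
#' @export
filter_by_r2 <- function(report, percentile = 25) {
  stopifnot(percentile >= 0, percentile < 100)
  r2 <- if (inherits(report, "FitReport")) report$r2 else report
  cutoff <- as.numeric(quantile(r2, percentile / 100, type = 7))
  list(retained = names(r2)[r2 >= cutoff], cutoff = cutoff)
}

#' Threshold a coefficient matrix into a regulatory network
#'
#' An edge (i, j) with weight `a_ij` is kept iff `|a_ij| >= alpha`. The sign
#' of the weight is preserved (positive = up-regulation). Nodes without any
#' surviving edge (singletons) are absent from the result by construction.
#'
#' @param A A [coefficient_matrix()].
#' @param alpha Nonnegative coefficient cutoff.
#' @return A [regulatory_network()].
#' @export
threshold_network <- function(A, alpha = 0.075) {
  stopifnot(alpha >= 0)
  M <- A$entries
  idx <- Matrix::which(abs(M) >= alpha & M != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warning("threshold alpha exceeds every |coefficient|; empty network")
    return(regulatory_network())
  }
  regulatory_network(rownames(M)[idx[, 1L]], colnames(M)[idx[, 2L]], M[idx])
}

#' Find the cutoff matching a target network density
#'
#' Edge count is a step function of alpha, so the smallest alpha whose
#' thresholded network has at most `target_edge_count` edges is one of the
#' distinct |coefficient| values; it is located by scanning the sorted
#' magnitudes.
#'
#' @param A A [coefficient_matrix()].
#' @param target_edge_count Desired maximum edge count (>= 1).
#' @return The cutoff alpha.
#' @export
match_density_alpha <- function(A, target_edge_count) {
  stopifnot(target_edge_count >= 1L)
  mags <- abs(A$entries@x)
  mags <- mags[mags > 0]
  if (target_edge_count >= length(mags)) {
    if (target_edge_count > length(mags))
      warning("target edge count exceeds the number of nonzero coefficients; returning 0")
    return(0)
  }
  vals <- sort(unique(mags))
  counts <- length(mags) - findInterval(vals, sort(mags)) + 1L
  # counts[v] = #{|a| >= v}; pick the smallest v with count <= target
  ok <- which(counts <= target_edge_count)
  vals[ok[1L]]
}

#' Infer treatment-specific networks
#'
#' Refits the per-gene lasso models on each treatment category's samples
#' only, then thresholds each category's coefficient matrix with
#' [match_density_alpha()] so every network has (at most) the reference
#' edge count, making densities comparable across categories.
#'
#' @param expr An [expression_matrix()] with `sample_category` set.
#' @param lambda L1 penalty (shared across categories).
#' @param reference_density Target edge count for every category network.
#' @param min_samples Categories with fewer samples are skipped with a
#'   warning.
#' @param genes Genes to fit (default all).
#' @param standardize Passed to the lasso fit.
#' @return Named list of [regulatory_network()] objects, one per category,
#'   each carrying the chosen cutoff as attribute `"alpha"`.
#' @export
infer_treatment_networks <- function(expr, lambda, reference_density,
                                     min_samples = 10L,
                                     genes = expr$gene_ids,
                                     standardize = FALSE) {
  if (is.null(expr$sample_category))
    stop("expression matrix has no sample_category")
  cats <- unique(expr$sample_category[!is.na(expr$sample_category)])
  nets <- list()
  for (cc in cats) {
    keep <- which(!is.na(expr$sample_category) & expr$sample_category == cc)
    if (length(keep) < min_samples) {
      warning(sprintf("category '%s' has %d samples (< %d); skipped",
                      cc, length(keep), min_samples))
      next
    }
    sub <- expression_matrix(expr$values[, keep, drop = FALSE],
                             gene_ids = expr$gene_ids, tf_ids = expr$tf_ids,
                             sample_ids = expr$sample_ids[keep])
    A <- fit_coefficients(sub, lambda, genes = genes,
                          standardize = standardize)
    alpha <- match_density_alpha(A, reference_density)
    net <- threshold_network(A, alpha)
    attr(net, "alpha") <- alpha
    nets[[cc]] <- net
  }
  nets
}
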