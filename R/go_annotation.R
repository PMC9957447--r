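## TF annotation from target pools: EASE-style enrichment, sampling-based
## null curves and z-scores, term specificity, and comparison with reference
## annotations via Wang semantic similarity.

#' EASE score: conservative hypergeometric enrichment p-value
#'
#' Upper-tail hypergeometric probability with the observed overlap penalized
#' by one gene: `P(X >= overlap - 1)` where X counts term-annotated genes in
#' a random draw of `pool` genes from a `universe` containing `term_total`
#' annotated genes. Overlaps of 0 or 1 return exactly 1 (the penalty removes
#' all evidence). Always at least as large as the plain hypergeometric
#' upper tail at `overlap`.
#'
#' @param overlap Number of pool genes annotated with the term.
#' @param pool Pool (target-pool) size.
#' @param term_total Genes annotated with the term in the universe.
#' @param universe Universe size.
#' @return p-value in (0, 1]. Vectorized over its arguments.
#' @export
ease_score <- function(overlap, pool, term_total, universe) {
  n <- max(length(overlap), length(pool), length(term_total), length(universe))
  overlap <- rep_len(overlap, n); pool <- rep_len(pool, n)
  term_total <- rep_len(term_total, n); universe <- rep_len(universe, n)
  if (any(overlap < 0 | overlap > pmin(pool, term_total) |
          pmax(pool, term_total) > universe))
    stop("inconsistent counts: need 0 <= overlap <= min(pool, term_total) <= universe")
  p <- phyper(overlap - 2L, term_total, universe - term_total, pool,
              lower.tail = FALSE)
  p[overlap <= 1L] <- 1
  pmin(p, 1)
}

# gene -> propagated term index restricted to the universe, cached on the
# corpus the first time it is needed
universe_term_index <- function(corpus) {
  corpus$ann_closed[intersect(names(corpus$ann_closed), corpus$universe)]
}

#' Enrichment analysis of a gene pool
#'
#' Tests every biological-process term annotated (after DAG propagation) to
#' at least `min_overlap` pool genes, using the EASE score against the
#' corpus universe. Records at or below `threshold` are returned sorted by
#' ascending p-value, with fold enrichment `(l/k)/(L/n)` and
#' Benjamini-Hochberg adjusted p-values (computed over all tested terms)
#' reported alongside.
#'
#' @param pool Character vector of gene ids (intersected with the universe).
#' @param corpus A [go_corpus()].
#' @param threshold Raw EASE-score cutoff (default 0.05).
#' @param min_overlap Minimum pool overlap for a term to be tested
#'   (default 2).
#' @return Data frame with columns term, overlap, pool_size, term_size,
#'   universe, ease_p, bh_adjusted, fold_enrichment.
#' @export
enrich_pool <- function(pool, corpus, threshold = 0.05, min_overlap = 2L) {
  empty <- data.frame(term = character(), overlap = integer(),
                      pool_size = integer(), term_size = integer(),
                      universe = integer(), ease_p = numeric(),
                      bh_adjusted = numeric(), fold_enrichment = numeric(),
                      stringsAsFactors = FALSE)
  pool <- intersect(unique(pool), corpus$universe)
  if (length(pool) == 0L) {
    warning("empty pool (no genes in the enrichment universe)")
    return(empty)
  }
  idx <- universe_term_index(corpus)
  hits <- table(unlist(idx[intersect(pool, names(idx))], use.names = FALSE))
  hits <- hits[hits >= min_overlap]
  if (length(hits) == 0L) return(empty)
  terms <- names(hits)
  l <- as.integer(hits)
  L <- as.integer(corpus$term_counts[terms])
  k <- length(pool)
  n <- length(corpus$universe)
  p <- ease_score(l, k, L, n)
  bh <- p.adjust(p, method = "BH")
  fold <- (l / k) / (L / n)
  out <- data.frame(term = terms, overlap = l, pool_size = k, term_size = L,
                    universe = n, ease_p = p, bh_adjusted = bh,
                    fold_enrichment = fold, stringsAsFactors = FALSE)
  out <- out[out$ease_p <= threshold, , drop = FALSE]
  out[order(out$ease_p, out$term), , drop = FALSE]
}

#' Annotate every TF in a network from its target pool
#'
#' @param net A [regulatory_network()].
#' @param corpus A [go_corpus()].
#' @inheritParams enrich_pool
#' @return Data frame of enrichment records with a leading `tf` column
#'   (one row per significant TF-term pair).
#' @export
annotate_tfs <- function(net, corpus, threshold = 0.05, min_overlap = 2L) {
  tfs <- network_tfs(net)
  res <- lapply(tfs, function(tf) {
    rec <- enrich_pool(out_targets(net, tf), corpus,
                       threshold = threshold, min_overlap = min_overlap)
    if (nrow(rec)) cbind(tf = tf, rec, stringsAsFactors = FALSE) else NULL
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res))
    return(data.frame(tf = character(), term = character(),
                      overlap = integer(), pool_size = integer(),
                      term_size = integer(), universe = integer(),
                      ease_p = numeric(), bh_adjusted = numeric(),
                      fold_enrichment = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Default null-curve sample sizes
#'
#' `floor(2^e)` for e = 1.5, 2, 2.5, ..., 10: eighteen sizes from 2 to 1024.
#' @return Integer vector of length 18.
#' @export
null_sizes <- function() as.integer(floor(2^seq(1.5, 10, by = 0.5)))

#' Build sampling-based null curves for annotation counts
#'
#' For each pool size k, draws `reps` uniform random gene samples (without
#' replacement) from the universe, runs the same enrichment analysis applied
#' to real target pools, and records the mean and standard deviation of the
#' number of significant terms. Both moments are then fitted as linear
#' functions of k by ordinary least squares, so the null mean and spread can
#' be predicted at any pool size.
#'
#' @param corpus A [go_corpus()].
#' @param sizes Pool sizes to sample (default [null_sizes()]).
#' @param reps Draws per size (default 100).
#' @param threshold Raw EASE-score significance cutoff.
#' @param seed Integer seed.
#' @param min_overlap Passed to [enrich_pool()].
#' @return Object of class `NullCurves`: `table` (size, mu, sigma),
#'   `mu_fit` and `sigma_fit` (intercept, slope), `reps`, `threshold`,
#'   `counts` (reps x sizes matrix of raw significant-term counts).
#' @export
build_null_curves <- function(corpus, sizes = null_sizes(), reps = 100L,
                              threshold = 0.05, seed, min_overlap = 2L) {
  stopifnot(reps >= 2L)
  n <- length(corpus$universe)
  if (any(sizes > n)) stop("sample size exceeds the universe size")
  withr::local_seed(seed)
  counts <- matrix(0L, nrow = reps, ncol = length(sizes),
                   dimnames = list(NULL, as.character(sizes)))
  for (j in seq_along(sizes)) {
    for (r in seq_len(reps)) {
      pool <- sample(corpus$universe, sizes[j])
      counts[r, j] <- nrow(enrich_pool(pool, corpus, threshold = threshold,
                                       min_overlap = min_overlap))
    }
  }
  mu <- colMeans(counts)
  sigma <- apply(counts, 2L, sd)
  mu_fit <- stats::lm.fit(cbind(1, sizes), mu)$coefficients
  sigma_fit <- stats::lm.fit(cbind(1, sizes), sigma)$coefficients
  structure(list(table = data.frame(size = sizes, mu = mu, sigma = sigma),
                 mu_fit = setNames(mu_fit, c("intercept", "slope")),
                 sigma_fit = setNames(sigma_fit, c("intercept", "slope")),
                 reps = reps, threshold = threshold, counts = counts),
            class = "NullCurves")
}

#' @export
print.NullCurves <- function(x, ...) {
  cat(sprintf("NullCurves: %d sizes x %d reps; mu = %.3f + %.4f k; sigma = %.3f + %.4f k\n",
              nrow(x$table), x$reps, x$mu_fit[1L], x$mu_fit[2L],
              x$sigma_fit[1L], x$sigma_fit[2L]))
  invisible(x)
}

#' Predicted null mean and spread at a pool size
#' @param curves A `NullCurves` object.
#' @param pool_size Pool size(s) k.
#' @return List with `mu` and `sigma` vectors.
#' @export
predict_null <- function(curves, pool_size) {
  list(mu = curves$mu_fit[1L] + curves$mu_fit[2L] * pool_size,
       sigma = curves$sigma_fit[1L] + curves$sigma_fit[2L] * pool_size)
}

#' z-score for an observed annotation count
#'
#' `z = (t(k) - mu_hat(k)) / sigma_hat(k)` using the fitted null curves.
#' Pools with `z >= 2` are flagged as having significantly more annotations
#' than random gene sets of the same size. If the predicted sigma is not
#' positive the z-score is undefined and reported as `NaN` with a warning.
#'
#' @param t_observed Observed number of significant terms.
#' @param pool_size Pool size k.
#' @param curves A `NullCurves` object.
#' @return Data frame with columns t_observed, pool_size, mu, sigma, z,
#'   significant.
#' @export
annotation_zscore <- function(t_observed, pool_size, curves) {
  pred <- predict_null(curves, pool_size)
  sigma <- pred$sigma
  bad <- sigma <= 0
  if (any(bad)) {
    warning("nonpositive predicted sigma; z-score undefined for ",
            sum(bad), " pool(s)")
    sigma[bad] <- NA_real_
  }
  z <- (t_observed - pred$mu) / sigma
  z[bad] <- NaN
  data.frame(t_observed = t_observed, pool_size = pool_size,
             mu = unname(pred$mu), sigma = unname(pred$sigma), z = unname(z),
             significant = !is.na(z) & z >= 2)
}

#' Specificity of a term or term set
#'
#' For a single term, the reciprocal of the number of universe genes
#' annotated with it (after DAG propagation); for a set, the maximum over
#' members — the most specific term represents the set. Strictly decreasing
#' in a term's annotated-gene count; the root of a fully annotated universe
#' attains the minimum 1/n.
#'
#' @param terms Character vector of term ids (length >= 1).
#' @param corpus A [go_corpus()].
#' @return Specificity value in (0, 1].
#' @export
specificity <- function(terms, corpus) {
  counts <- corpus$term_counts[terms]
  if (anyNA(counts) || any(counts == 0))
    stop("specificity undefined for unannotated term(s): ",
         paste(terms[is.na(counts) | counts == 0], collapse = ", "))
  max(1 / as.numeric(counts))
}

# Wang S-values: semantic contribution of every ancestor of `term`,
# decaying multiplicatively along parent edges (max over paths), with
# S(term) = 1. Edge weights by type: is_a 0.8, part_of 0.6 by default.
wang_svalues <- function(term, corpus, weights = c(is_a = 0.8, part_of = 0.6)) {
  if (!term %in% names(corpus$ancestors))
    stop("term not in the ontology DAG: ", term)
  anc <- corpus$ancestors[[term]]
  ed <- corpus$edges[corpus$edges$child %in% anc &
                     corpus$edges$parent %in% anc, , drop = FALSE]
  s <- setNames(rep(-Inf, length(anc)), anc)
  s[term] <- 1
  # relax edges until fixpoint (ancestor sub-DAG is acyclic and small)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(ed))) {
      cand <- weights[[ed$type[i]]] * s[ed$child[i]]
      if (cand > s[ed$parent[i]]) { s[ed$parent[i]] <- cand; changed <- TRUE }
    }
    if (!changed) break
  }
  s
}

#' Wang graph-based semantic similarity between term sets
#'
#' Each term's semantic value is the sum of S-values over its ancestors
#' (multiplicative decay 0.8 per `is_a` edge and 0.6 per `part_of` edge,
#' max over paths, 1 for the term itself). Similarity of two terms is the
#' summed S-values of their shared ancestors, taken from both sides, over
#' the sum of the two semantic values; set similarity is the best-match
#' average. Symmetric, in \[0, 1\], and 1 exactly for identical terms.
#'
#' @param terms_a,terms_b Nonempty character vectors of term ids.
#' @param corpus A [go_corpus()].
#' @param weights Named semantic contribution factors per edge type.
#' @return Similarity in \[0, 1\].
#' @export
wang_similarity <- function(terms_a, terms_b, corpus,
                            weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(length(terms_a) >= 1L, length(terms_b) >= 1L)
  sv_a <- lapply(terms_a, wang_svalues, corpus = corpus, weights = weights)
  sv_b <- lapply(terms_b, wang_svalues, corpus = corpus, weights = weights)
  pair_sim <- function(sa, sb) {
    common <- intersect(names(sa), names(sb))
    if (!length(common)) return(0)
    (sum(sa[common]) + sum(sb[common])) / (sum(sa) + sum(sb))
  }
  M <- matrix(0, length(terms_a), length(terms_b))
  for (i in seq_along(terms_a))
    for (j in seq_along(terms_b))
      M[i, j] <- pair_sim(sv_a[[i]], sv_b[[j]])
  (sum(apply(M, 1L, max)) + sum(apply(M, 2L, max))) /
    (length(terms_a) + length(terms_b))
}

#' Compare predicted TF annotations with a reference
#'
#' Per TF shared between the two annotation maps: the exact term overlap,
#' Wang best-match-average set similarity, the specificity of each side's
#' term set, term counts, and a flag for TFs whose reference annotation
#' consists only of trivial terms (e.g. the bare regulation-of-transcription
#' annotation every TF carries).
#'
#' @param predicted,reference Named lists mapping TF id -> character vector
#'   of term ids.
#' @param corpus A [go_corpus()].
#' @param trivial_terms Term ids regarded as trivial reference annotations.
#' @return Data frame with one row per TF present in both maps.
#' @export
compare_with_reference <- function(predicted, reference, corpus,
                                   trivial_terms = character()) {
  tfs <- intersect(names(predicted), names(reference))
  rows <- lapply(tfs, function(tf) {
    p <- unique(predicted[[tf]]); r <- unique(reference[[tf]])
    both <- length(p) > 0L && length(r) > 0L
    data.frame(
      tf = tf,
      n_predicted = length(p), n_reference = length(r),
      overlap = length(intersect(p, r)),
      wang = if (both) wang_similarity(p, r, corpus) else NA_real_,
      specificity_predicted = if (length(p)) specificity(p, corpus) else NA_real_,
      specificity_reference = if (length(r)) specificity(r, corpus) else NA_real_,
      trivial_reference = length(r) > 0L && all(r %in% trivial_terms),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
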