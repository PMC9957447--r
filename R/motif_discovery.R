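## k-mer over-representation in target-pool promoters, BH correction,
## degree-preserving rewiring null, and information-content alignment of
## enriched k-mers against reference PWMs.

#' Enumerate all k-mers
#'
#' All strings over ACGT of each requested length, lexicographic within
#' length, lengths in the given order. k = 6, 7, 8 yields 86,016 motifs.
#'
#' @param ks Integer vector of k-mer lengths (each >= 1).
#' @return Character vector of length `sum(4^ks)`.
#' @export
enumerate_kmers <- function(ks) {
  stopifnot(length(ks) >= 1L, all(ks >= 1L))
  bases <- c("A", "C", "G", "T")
  one <- function(k) {
    v <- ""
    for (i in seq_len(k))
      v <- paste0(rep(v, each = 4L), rep(bases, times = length(v)))
    v
  }
  unlist(lapply(as.integer(ks), one), use.names = FALSE)
}

#' Index promoter sequences by k-mer presence
#'
#' Records, for every k-mer of each requested length, which promoters
#' contain it as an exact forward-strand substring (windows containing N
#' never match). Presence is binary per gene: multiple occurrences count
#' once. With `both_strands = TRUE` a gene is also marked present when the
#' reverse complement of its promoter contains the k-mer.
#'
#' @param seqs Named character vector of promoter sequences (ACGTN).
#' @param ks Integer vector of k-mer lengths.
#' @param both_strands Also match the reverse complement (default FALSE).
#' @return Object of class `PromoterIndex`: `gene_ids`, `n`, `ks`, and per-k
#'   sparse presence matrices (`presence[[as.character(k)]]`, motifs x genes)
#'   with the full lexicographic motif set as row names.
#' @export
index_promoters <- function(seqs, ks, both_strands = FALSE) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("promoter sequences must carry unique names")
  genes <- names(seqs)
  seqs <- toupper(seqs)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs)))
  }
  presence <- list()
  for (k in as.integer(ks)) {
    if (any(nchar(seqs) < k))
      stop("k exceeds the shortest promoter length")
    motifs <- enumerate_kmers(k)
    midx <- seq_along(motifs)
    names(midx) <- motifs
    ii <- list(); jj <- list()
    for (g in seq_along(genes)) {
      s <- seqs[[g]]
      subs <- unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
      if (both_strands) {
        r <- rc[[g]]
        subs <- unique(c(subs, substring(r, 1:(nchar(r) - k + 1L), k:nchar(r))))
      }
      hit <- midx[subs]
      hit <- hit[!is.na(hit)]  # windows containing N are absent from the dictionary
      ii[[g]] <- hit
      jj[[g]] <- rep.int(g, length(hit))
    }
    presence[[as.character(k)]] <- Matrix::sparseMatrix(
      i = unlist(ii, use.names = FALSE), j = unlist(jj, use.names = FALSE),
      x = 1, dims = c(length(motifs), length(genes)),
      dimnames = list(motifs, genes))
  }
  structure(list(gene_ids = genes, n = length(genes), ks = as.integer(ks),
                 presence = presence, both_strands = both_strands),
            class = "PromoterIndex")
}

#' @export
print.PromoterIndex <- function(x, ...) {
  cat(sprintf("PromoterIndex: %d promoters, k = {%s}%s\n", x$n,
              paste(x$ks, collapse = ", "),
              if (x$both_strands) ", both strands" else ""))
  invisible(x)
}

# number of universe genes containing each k-mer
motif_universe_counts <- function(index, k) {
  Matrix::rowSums(index$presence[[as.character(k)]])
}

#' Hypergeometric enrichment of one motif in a target pool
#'
#' Upper-tail hypergeometric test: with L universe genes containing motif
#' `f`, the probability that a random pool of size k_i contains at least the
#' observed number of motif-bearing genes.
#'
#' @param pool Character vector of gene ids (subset of the index universe).
#' @param f Motif string.
#' @param index A [index_promoters()] result.
#' @return One-row data frame (class `MotifHit` columns): motif, overlap,
#'   pool_size, motif_total, universe, p_value.
#' @export
motif_enrichment <- function(pool, f, index) {
  k <- nchar(f)
  P <- index$presence[[as.character(k)]]
  if (is.null(P)) stop("k-mer length ", k, " is not indexed")
  pool <- unique(pool)
  if (!all(pool %in% index$gene_ids)) stop("pool contains genes outside the promoter universe")
  L <- sum(P[f, ])
  l <- sum(P[f, pool])
  n <- index$n
  ki <- length(pool)
  p <- phyper(l - 1, L, n - L, ki, lower.tail = FALSE)
  data.frame(motif = f, overlap = as.integer(l), pool_size = ki,
             motif_total = as.integer(L), universe = n,
             p_value = min(p, 1), stringsAsFactors = FALSE)
}

#' Enrichment of every indexed k-mer in a target pool
#'
#' Vectorized version of [motif_enrichment()] over the full motif set of one
#' k-mer length.
#'
#' @inheritParams motif_enrichment
#' @param k k-mer length to test.
#' @return Data frame with one row per motif (unfiltered, uncorrected).
#' @export
enrich_motifs <- function(pool, index, k) {
  P <- index$presence[[as.character(k)]]
  if (is.null(P)) stop("k-mer length ", k, " is not indexed")
  pool <- unique(pool)
  if (!all(pool %in% index$gene_ids)) stop("pool contains genes outside the promoter universe")
  L <- Matrix::rowSums(P)
  l <- Matrix::rowSums(P[, pool, drop = FALSE])
  n <- index$n
  ki <- length(pool)
  p <- phyper(l - 1, L, n - L, ki, lower.tail = FALSE)
  data.frame(motif = rownames(P), overlap = as.integer(l), pool_size = ki,
             motif_total = as.integer(L), universe = n,
             p_value = pmin(p, 1), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg correction for motif hits
#'
#' Step-up adjusted p-values with monotonicity enforced, and a significance
#' flag at FDR `q`. The family is the supplied set of hits — by convention
#' one TF's tested motifs (use [discover_motifs()]'s `global_fdr` to pool
#' families).
#'
#' @param hits Data frame with a `p_value` column.
#' @param q FDR level in (0, 1).
#' @return `hits` with `bh_adjusted` and `significant` columns added.
#' @export
bh_correct <- function(hits, q = 0.05) {
  stopifnot(q > 0, q < 1)
  if (nrow(hits) == 0L) {
    hits$bh_adjusted <- numeric(0); hits$significant <- logical(0)
    return(hits)
  }
  hits$bh_adjusted <- p.adjust(hits$p_value, method = "BH")
  hits$significant <- hits$bh_adjusted <= q
  hits
}

#' Discover enriched motifs for every TF of a network
#'
#' Runs the hypergeometric enrichment of every indexed k-mer against each
#' TF's target-pool promoters and applies BH correction per TF (or globally
#' across all TF-motif tests with `global_fdr = TRUE`).
#'
#' @param net A [regulatory_network()].
#' @param index A [index_promoters()] result.
#' @param k k-mer length to test (default 7).
#' @param q FDR level.
#' @param global_fdr Pool all TF-motif tests into one BH family.
#' @param keep_all Return all tested motifs instead of significant ones only.
#' @return Data frame of TF-motif records with `bh_adjusted` and
#'   `significant` columns.
#' @export
discover_motifs <- function(net, index, k = 7L, q = 0.05,
                            global_fdr = FALSE, keep_all = FALSE) {
  tfs <- network_tfs(net)
  res <- lapply(tfs, function(tf) {
    pool <- intersect(out_targets(net, tf), index$gene_ids)
    if (length(pool) == 0L) return(NULL)
    hits <- enrich_motifs(pool, index, k)
    if (!global_fdr) hits <- bh_correct(hits, q)
    cbind(tf = tf, hits, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(res)) return(res)
  if (global_fdr) res <- bh_correct(res, q)
  if (!keep_all) res <- res[res$significant, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Degree-preserving rewiring null for motif enrichment
#'
#' Each rewiring replaces every TF's target pool with a uniform random gene
#' set of identical size drawn from the promoter universe (pool
#' cardinalities `|out_i|`, and hence their sum, are preserved exactly),
#' reruns the full enrichment + BH pipeline, and records the number of
#' significant TF-motif pairs. The empirical exceedance of the observed
#' count over the null counts measures whether the network's motif signal
#' could arise from pool sizes alone.
#'
#' @param net A [regulatory_network()].
#' @param index A [index_promoters()] result.
#' @param k k-mer length.
#' @param reps Number of rewirings (default 100).
#' @param q FDR level.
#' @param seed Integer seed.
#' @param global_fdr Passed through to [discover_motifs()].
#' @param permute_targets Alternative shuffle: permute the concatenated
#'   target multiset across TFs instead of drawing fresh uniform pools.
#' @return List with `observed` (significant pair count in `net`),
#'   `null_counts` (length `reps`), and `exceedance`
#'   (fraction of null counts >= observed).
#' @export
rewire_null <- function(net, index, k = 7L, reps = 100L, q = 0.05, seed,
                        global_fdr = FALSE, permute_targets = FALSE) {
  stopifnot(reps >= 1L)
  observed <- nrow(discover_motifs(net, index, k = k, q = q,
                                   global_fdr = global_fdr))
  sizes <- pool_sizes(net)
  withr::local_seed(seed)
  null_counts <- integer(reps)
  for (r in seq_len(reps)) {
    if (permute_targets) {
      df <- unique(data.frame(tf = net$tf, target = sample(net$target),
                              stringsAsFactors = FALSE))
      df <- df[df$tf != df$target, , drop = FALSE]
      rnet <- regulatory_network(df$tf, df$target, rep(1, nrow(df)))
    } else {
      pools <- lapply(names(sizes), function(tf)
        sample(setdiff(index$gene_ids, tf), sizes[[tf]]))
      names(pools) <- names(sizes)
      rnet <- regulatory_network(
        tf = rep(names(pools), lengths(pools)),
        target = unlist(pools, use.names = FALSE),
        weight = rep(1, sum(lengths(pools))))
    }
    null_counts[r] <- nrow(discover_motifs(rnet, index, k = k, q = q,
                                           global_fdr = global_fdr))
  }
  list(observed = observed, null_counts = null_counts,
       exceedance = mean(null_counts >= observed))
}

## ---------------------------------------------------------------------------
## Information-content alignment against reference PWMs
## ---------------------------------------------------------------------------

# per-column, per-symbol information contribution p*log2(p/b), with
# 0*log2(0/b) := 0. convention = "literal" negates it (the flattened
# rendering of the column score carries a leading minus; the positive
# convention makes conserved, over-background symbols score highest and is
# the default).
pwm_contributions <- function(p, convention = c("conserved", "literal")) {
  convention <- match.arg(convention)
  M <- p$matrix
  B <- matrix(p$background, nrow = 4L, ncol = ncol(M))
  C <- ifelse(M > 0, M * log2(M / B), 0)
  if (convention == "literal") -C else C
}

#' Information-content alignment score of a 7-mer against a PWM
#'
#' Each PWM column contributes `max_k p_ck * log2(p_ck / b_k)` to the
#' unmasked column score; a motif masked onto a window selects instead the
#' contribution of its own symbol at each of 7 consecutive columns. The
#' score is the best masked window sum divided by the best unmasked window
#' sum `s_max(p, 7)`, so a motif tracing the PWM's most conserved stretch
#' scores 1 and no motif can exceed 1. Window ties resolve to the smallest
#' start.
#'
#' @param pwm A [pwm()] of width >= 7.
#' @param motif A 7-character string over ACGT.
#' @param convention `"conserved"` (default) or `"literal"` (negated column
#'   scores as in the flattened formula rendering).
#' @return List of class `ICAlignment`: `pwm_id`, `motif`, `ic_score`,
#'   `window_score`, `s_max`, `best_start` (1-based column of the best
#'   masked window).
#' @export
ic_score <- function(pwm, motif, convention = c("conserved", "literal")) {
  convention <- match.arg(convention)
  w <- 7L
  if (nchar(motif) != w || !grepl("^[ACGT]+$", motif))
    stop("motif must be a 7-mer over ACGT")
  if (pwm$width < w) stop("PWM shorter than motif")
  C <- pwm_contributions(pwm, convention)
  col_best <- apply(C, 2L, max)
  q <- match(strsplit(motif, "")[[1L]], c("A", "C", "G", "T"))
  nwin <- pwm$width - w + 1L
  masked <- numeric(nwin); unmasked <- numeric(nwin)
  for (c0 in seq_len(nwin)) {
    cols <- c0:(c0 + w - 1L)
    masked[c0] <- sum(C[cbind(q, cols)])
    unmasked[c0] <- sum(col_best[cols])
  }
  s_max <- max(unmasked)
  best <- which.max(masked)   # smallest index on ties
  score <- if (s_max > 0) masked[best] / s_max else NaN
  if (is.nan(score)) warning("PWM carries no information (s_max = 0)")
  structure(list(pwm_id = pwm$id, motif = motif, ic_score = score,
                 window_score = masked[best], s_max = s_max,
                 best_start = as.integer(best)),
            class = "ICAlignment")
}

#' Score each TF's motifs against its PWM, with a shuffled baseline
#'
#' Computes the IC alignment score of every assigned motif against the
#' corresponding TF's reference PWM, then permutes the motif sets across
#' TFs (fixed seed) and rescores, reporting an independent two-sample
#' t-test between the two score distributions. TFs without a PWM, and PWMs
#' shorter than 7 columns, are skipped with a warning.
#'
#' @param assignments Named list mapping TF id -> character vector of
#'   enriched 7-mers.
#' @param pwms Named list of [pwm()] objects keyed by TF id.
#' @param seed Integer seed for the shuffle.
#' @param convention Passed to [ic_score()].
#' @return List with `true_scores`, `shuffled_scores`, `t_statistic`,
#'   `p_value`.
#' @export
score_shuffle_baseline <- function(assignments, pwms, seed,
                                   convention = "conserved") {
  usable <- intersect(names(assignments), names(pwms))
  short <- usable[vapply(pwms[usable], function(p) p$width < 7L, TRUE)]
  if (length(short)) {
    warning("PWM shorter than motif; skipped: ", paste(short, collapse = ", "))
    usable <- setdiff(usable, short)
  }
  if (length(usable) < 2L) stop("need at least 2 TFs with usable PWMs")
  score_set <- function(assign) {
    unlist(lapply(usable, function(tf) {
      vapply(assign[[tf]], function(m)
        ic_score(pwms[[tf]], m, convention)$ic_score, numeric(1L))
    }), use.names = FALSE)
  }
  true_scores <- score_set(assignments[usable])
  withr::local_seed(seed)
  perm <- sample(length(usable))
  shuffled <- setNames(assignments[usable][perm], usable)
  shuffled_scores <- score_set(shuffled)
  tt <- t.test(true_scores, shuffled_scores, var.equal = FALSE)
  list(true_scores = true_scores, shuffled_scores = shuffled_scores,
       t_statistic = unname(tt$statistic), p_value = tt$p.value)
}
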