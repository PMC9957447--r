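## Synthetic fixtures with the statistical structure the pipeline assumes:
## sparse linear regulation with Gaussian noise, promoters with planted
## motifs in the targets of chosen TFs, and a toy biological-process DAG
## whose terms concentrate in those targets.

#' Generate a synthetic expression compendium with planted regulation
#'
#' TF expression rows are drawn i.i.d. standard normal per sample. Each
#' non-TF gene is assigned `ceiling(density * n_tf)` regulators whose
#' coefficients are drawn uniformly from +/- \[0.2, 1.0\] (bounded away from
#' zero so a coefficient cutoff can separate signal from shrinkage noise),
#' and its expression row is the coefficient-weighted combination of its
#' regulators' rows plus `Normal(0, noise_sd^2)` noise. TF self-coefficients
#' are structurally zero and, by default, no TF -> TF edges are planted, so
#' an ordinary-least-squares refit on the true support is an exact oracle
#' for the planted weights.
#'
#' @param n_tf Number of transcription factors.
#' @param n_genes Total number of genes (TFs included); must be >= `n_tf`.
#' @param m Number of samples.
#' @param density Fraction of the TF set regulating each target.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed; the generator is a pure function of it.
#' @param tf_tf_edges If `TRUE`, TFs (except the first) also receive planted
#'   regulators among earlier TFs.
#' @param sample_category Optional named character vector of sample
#'   categories to attach.
#' @return A list with `expr` (an [expression_matrix()]) and `model` (a
#'   `PlantedModel`: `true_A` sparse TF x gene matrix, `noise_sd`,
#'   `motif_plants`, `go_plants`, `seed`).
#' @export
generate_expression <- function(n_tf, n_genes, m, density = 0.1,
                                noise_sd = 0.1, seed,
                                tf_tf_edges = FALSE,
                                sample_category = NULL) {
  stopifnot(n_genes >= n_tf, n_tf >= 1L, m >= 2L, density > 0, density <= 1)
  n_reg <- ceiling(density * n_tf)
  if (n_reg < 1L) stop("each target needs >=1 regulator")
  withr::local_seed(seed)
  tf_ids <- sprintf("TF%03d", seq_len(n_tf))
  tgt_ids <- if (n_genes > n_tf) sprintf("G%05d", seq_len(n_genes - n_tf)) else character()
  gene_ids <- c(tf_ids, tgt_ids)
  sample_ids <- sprintf("S%04d", seq_len(m))

  X_tf <- matrix(rnorm(n_tf * m), nrow = n_tf,
                 dimnames = list(tf_ids, sample_ids))
  true_A <- Matrix::Matrix(0, nrow = n_tf, ncol = n_genes, sparse = TRUE,
                           dimnames = list(tf_ids, gene_ids))
  values <- matrix(0, nrow = n_genes, ncol = m,
                   dimnames = list(gene_ids, sample_ids))
  values[tf_ids, ] <- X_tf

  plant <- function(j, allowed) {
    reg <- sample(allowed, min(n_reg, length(allowed)))
    w <- runif(length(reg), 0.2, 1.0) * sample(c(-1, 1), length(reg), replace = TRUE)
    true_A[reg, j] <<- w
    drop(w %*% X_tf[reg, , drop = FALSE]) + rnorm(m, sd = noise_sd)
  }
  if (tf_tf_edges && n_tf > 1L) {
    # regenerate TF rows in topological order (earlier TFs regulate later
    # ones) before any targets are drawn, keeping the planted model exact
    for (idx in 2:n_tf) {
      j <- tf_ids[idx]
      values[j, ] <- plant(j, tf_ids[seq_len(idx - 1L)])
      X_tf[j, ] <- values[j, ]
    }
  }
  for (j in tgt_ids) values[j, ] <- plant(j, tf_ids)
  expr <- expression_matrix(values, gene_ids = gene_ids, tf_ids = tf_ids,
                            sample_ids = sample_ids,
                            sample_category = sample_category)
  model <- structure(list(true_A = true_A, noise_sd = noise_sd,
                          motif_plants = list(), go_plants = list(),
                          seed = seed),
                     class = "PlantedModel")
  list(expr = expr, model = model)
}

#' Planted edge list of a synthetic model
#'
#' Applies the same absolute-value thresholding used downstream to the true
#' coefficient matrix, so the planted edge set is recovered exactly for any
#' cutoff below the minimum planted magnitude (0.2).
#'
#' @param model A `PlantedModel`.
#' @param alpha Coefficient cutoff (entries kept iff `|a| >= alpha`).
#' @return A [regulatory_network()] of the planted edges.
#' @export
planted_edges <- function(model, alpha = 0) {
  A <- model$true_A
  idx <- Matrix::which(abs(A) >= alpha & A != 0, arr.ind = TRUE)
  regulatory_network(rownames(A)[idx[, 1L]], colnames(A)[idx[, 2L]],
                     A[idx])
}

#' Attach motif plants to a model
#'
#' @param model A `PlantedModel`.
#' @param motifs Named character vector (TF id -> motif string over ACGT).
#' @param pi Insertion probability per target promoter (recycled).
#' @return The updated model.
#' @export
plant_motifs <- function(model, motifs, pi = 1) {
  stopifnot(all(grepl("^[ACGT]+$", motifs)), all(pi >= 0 & pi <= 1))
  pi <- rep_len(pi, length(motifs))
  model$motif_plants <- Map(function(m, p) list(motif = m, pi = p),
                            motifs, pi)
  model
}

#' Attach GO-term plants to a model
#'
#' Regulons are typically engaged in several related processes, so each TF
#' may be planted with one term or a small set of terms.
#'
#' @param model A `PlantedModel`.
#' @param terms Named character vector (TF id -> term id) or named list
#'   (TF id -> character vector of term ids).
#' @param rho Annotation probability per target gene and term (recycled).
#' @return The updated model.
#' @export
plant_go_terms <- function(model, terms, rho = 1) {
  stopifnot(all(rho >= 0 & rho <= 1))
  if (!is.list(terms)) terms <- as.list(terms)
  rho <- rep_len(rho, length(terms))
  model$go_plants <- Map(function(t, r) list(term = t, rho = r), terms, rho)
  model
}

#' Generate promoter sequences with planted motifs
#'
#' Background sequence is i.i.d. over ACGT (uniform by default). For every
#' TF with a motif plant, each gene in its target pool receives one copy of
#' the motif, overwriting the background at a uniformly random position, with
#' probability `pi`. One record is emitted per gene in the universe.
#'
#' @param model A `PlantedModel` carrying `motif_plants` (see
#'   [plant_motifs()]).
#' @param net A [regulatory_network()] defining each TF's target pool.
#' @param universe Character vector of gene ids to emit promoters for.
#' @param length Promoter length in base pairs. The default, 1577 bp, is a
#'   typical median promoter length for a compact plant genome.
#' @param seed Integer seed.
#' @param base_probs Background nucleotide probabilities (ACGT order).
#' @return Named character vector of promoter sequences.
#' @export
generate_promoters <- function(model, net, universe, length = 1577, seed,
                               base_probs = rep(0.25, 4)) {
  stopifnot(length >= 1L, base_probs > 0)
  plants <- model$motif_plants
  if (length(plants) &&
      any(nchar(vapply(plants, `[[`, "", "motif")) >= length))
    stop("planted motifs must be shorter than the promoter length")
  withr::local_seed(seed)
  bases <- c("A", "C", "G", "T")
  n <- base::length(universe)
  mat <- matrix(sample(bases, n * length, replace = TRUE,
                       prob = base_probs / sum(base_probs)),
                nrow = n)
  rownames(mat) <- universe
  for (tf in names(plants)) {
    motif <- strsplit(plants[[tf]]$motif, "")[[1L]]
    w <- base::length(motif)
    for (g in intersect(out_targets(net, tf), universe)) {
      if (runif(1L) <= plants[[tf]]$pi) {
        pos <- sample.int(length - w + 1L, 1L)
        mat[g, pos:(pos + w - 1L)] <- motif
      }
    }
  }
  setNames(apply(mat, 1L, paste, collapse = ""), universe)
}

#' Generate a toy biological-process corpus with planted terms
#'
#' Builds a small DAG — one root, three branches, and leaf terms split
#' across the branches (`is_a` edges, with a minority of `part_of` edges) —
#' then annotates genes: targets of each TF carrying a GO plant receive each
#' planted leaf term with probability `rho`, and every gene receives each
#' non-planted leaf term independently at a background rate. Background
#' rates follow a Zipf profile across leaves (rate of the j-th leaf
#' proportional to 1/j, scaled so the mean equals `background_rate` and
#' capped at 0.5), emulating the heavy-tailed term-size distribution of real
#' ontologies in which a few broad terms annotate many genes and most terms
#' are specific. With `uniform_background = TRUE` every leaf instead uses
#' `background_rate` directly. Annotations are propagated to ancestors by
#' [go_corpus()].
#'
#' @param model A `PlantedModel` carrying `go_plants` (see
#'   [plant_go_terms()]); planted term ids must name leaves that exist, i.e.
#'   be among `sprintf("TOY:%04d", 5:(n_terms))`.
#' @param net A [regulatory_network()].
#' @param universe Character vector of gene ids forming the background.
#' @param n_terms Total number of terms including root and 3 branches.
#' @param background_rate Mean per-gene, per-leaf probability of a
#'   background annotation.
#' @param seed Integer seed.
#' @param part_of_fraction Fraction of leaf -> branch edges typed `part_of`.
#' @param uniform_background Use a flat rate for every leaf instead of the
#'   Zipf profile.
#' @return A [go_corpus()] whose universe is the supplied gene list.
#' @export
generate_go_corpus <- function(model, net, universe, n_terms = 124,
                               background_rate = 0.05, seed,
                               part_of_fraction = 0.2,
                               uniform_background = FALSE) {
  stopifnot(n_terms >= 5L)
  withr::local_seed(seed)
  ids <- sprintf("TOY:%04d", seq_len(n_terms))
  root <- ids[1L]; branches <- ids[2:4]; leaves <- ids[-(1:4)]
  planted_terms <- unique(unlist(lapply(model$go_plants, `[[`, "term"),
                                 use.names = FALSE))
  if (length(planted_terms) && !all(planted_terms %in% leaves))
    stop("planted terms must be leaf ids within the generated DAG")
  edges <- data.frame(child = branches, parent = root, type = "is_a",
                      stringsAsFactors = FALSE)
  leaf_parent <- branches[1L + (seq_along(leaves) %% 3L)]
  leaf_type <- ifelse(runif(length(leaves)) < part_of_fraction,
                      "part_of", "is_a")
  edges <- rbind(edges, data.frame(child = leaves, parent = leaf_parent,
                                   type = leaf_type, stringsAsFactors = FALSE))
  terms <- data.frame(id = ids, name = paste("toy term", ids),
                      stringsAsFactors = FALSE)

  ann <- setNames(vector("list", length(universe)), universe)
  # background annotations on non-planted leaves
  bg_leaves <- setdiff(leaves, planted_terms)
  if (background_rate > 0 && length(bg_leaves)) {
    j <- seq_along(bg_leaves)
    rates <- if (uniform_background) rep(background_rate, length(bg_leaves))
             else pmin(0.5, background_rate * length(j) / (sum(1 / j) * j))
    hits <- matrix(runif(length(universe) * length(bg_leaves)) <
                     rep(rates, each = length(universe)),
                   nrow = length(universe))
    for (i in seq_along(universe))
      if (any(hits[i, ])) ann[[i]] <- bg_leaves[hits[i, ]]
  }
  for (tf in names(model$go_plants)) {
    pl <- model$go_plants[[tf]]
    for (g in intersect(out_targets(net, tf), universe))
      for (tm in pl$term)
        if (runif(1L) <= pl$rho) ann[[g]] <- unique(c(ann[[g]], tm))
  }
  ann <- ann[lengths(ann) > 0L]
  go_corpus(terms, edges, ann, universe = universe)
}
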