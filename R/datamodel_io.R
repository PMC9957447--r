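#' @importFrom stats coef cor cor.test phyper predict quantile rnorm runif sd
#'   t.test var p.adjust setNames
#' @importFrom utils read.delim write.table head tail
#' @importFrom graphics hist
#' @importFrom methods as is
NULL

## ---------------------------------------------------------------------------
## ExpressionMatrix
## ---------------------------------------------------------------------------

#' Construct an ExpressionMatrix
#'
#' Container for a genes x samples expression matrix (log-scale arbitrary
#' units) with a designated transcription-factor subset and optional
#' per-sample treatment categories.
#'
#' @param values Numeric matrix, one row per gene, one column per sample.
#'   Row and column names are taken as gene and sample identifiers when
#'   `gene_ids`/`sample_ids` are not given.
#' @param gene_ids Character vector of unique gene identifiers (row order).
#' @param tf_ids Character vector, subset of `gene_ids`, the TF feature set.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param sample_category Optional named character vector mapping samples to a
#'   treatment category (e.g. `"abiotic stress"`, `"development"`).
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              tf_ids, sample_ids = colnames(values),
                              sample_category = NULL) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(ncol(values)))
  if (is.null(gene_ids))
    stop("gene_ids are required (or set rownames on 'values')")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  tf_ids <- as.character(tf_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (!all(tf_ids %in% gene_ids)) stop("tf_ids must be a subset of gene_ids")
  if (length(tf_ids) < 1L) stop("no usable TF features")
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stop("dimensions of 'values' do not match id vectors")
  if (ncol(values) < 2L) stop("need at least 2 samples")
  if (anyNA(values)) stop("missing expression values; apply a missing policy before construction")
  storage.mode(values) <- "double"
  dimnames(values) <- list(gene_ids, sample_ids)
  if (!is.null(sample_category)) {
    sample_category <- sample_category[sample_ids]
    names(sample_category) <- sample_ids
  }
  structure(list(values = values, gene_ids = gene_ids, tf_ids = tf_ids,
                 sample_ids = sample_ids, sample_category = sample_category),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes (%d TFs) x %d samples\n",
              length(x$gene_ids), length(x$tf_ids), length(x$sample_ids)))
  if (!is.null(x$sample_category)) {
    tab <- table(x$sample_category, useNA = "ifany")
    cat("sample categories:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read an expression table and TF list
#'
#' The table must have a header row of sample identifiers and gene
#' identifiers in the first column; tab- and comma-separated files are both
#' accepted (sniffed from the header line). The TF list file has one
#' identifier per line. TFs absent from the expression table are dropped with
#' a warning; identifier matching is case-sensitive and exact.
#'
#' @param path Path to the delimited expression table.
#' @param tf_list_path Path to the plain-text TF list.
#' @param impute_missing If `TRUE`, missing cells are replaced by the gene's
#'   row mean; the default rejects missing values.
#' @param sample_category Optional named character vector of sample categories.
#' @return An [expression_matrix()] object. Gene order equals file order.
#' @export
read_expression <- function(path, tf_list_path, impute_missing = FALSE,
                            sample_category = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1L]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in expression table: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & nzchar(col))
      if (length(bad))
        stop(sprintf("non-numeric cell at row '%s', column '%s'",
                     gene_ids[bad[1L]], colnames(vals)[j]))
      vals[[j]] <- num
    }
  }
  values <- as.matrix(vals)
  rownames(values) <- gene_ids
  if (anyNA(values)) {
    if (!impute_missing)
      stop("expression table contains missing values (set impute_missing = TRUE to impute row means)")
    for (i in which(rowSums(is.na(values)) > 0L)) {
      mu <- mean(values[i, ], na.rm = TRUE)
      values[i, is.na(values[i, ])] <- mu
    }
  }
  tfs <- readLines(tf_list_path)
  tfs <- trimws(tfs)
  tfs <- unique(tfs[nzchar(tfs)])
  if (length(tfs) == 0L) stop("no usable TF features")
  missing_tfs <- setdiff(tfs, gene_ids)
  if (length(missing_tfs)) {
    warning(sprintf("%d of %d TFs have no expression data and were dropped",
                    length(missing_tfs), length(tfs)))
    tfs <- setdiff(tfs, missing_tfs)
  }
  if (length(tfs) == 0L) stop("no usable TF features")
  expression_matrix(values, gene_ids = gene_ids, tf_ids = tfs,
                    sample_ids = colnames(values),
                    sample_category = sample_category)
}

#' Write an expression table
#'
#' Tab-separated, header row of sample ids, gene ids in the first column.
#' Round-trips losslessly through [read_expression()].
#'
#' @param expr An [expression_matrix()] object.
#' @param path Output path.
#' @param tf_list_path Optional path for the matching TF list file.
#' @export
write_expression <- function(expr, path, tf_list_path = NULL) {
  df <- data.frame(gene_id = expr$gene_ids, expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(tf_list_path)) writeLines(expr$tf_ids, tf_list_path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## CoefficientMatrix
## ---------------------------------------------------------------------------

#' Construct a CoefficientMatrix
#'
#' Sparse TF x gene matrix of lasso coefficients `a_ij`. Self entries
#' (a TF regressed on itself) are structurally zero.
#'
#' @param entries A (sparse) numeric matrix with TF ids as row names and gene
#'   ids as column names.
#' @param lambda_used Nonnegative L1 penalty used for the fit.
#' @param r2 Optional named numeric vector of per-gene mean cross-validated
#'   R-squared values.
#' @param alpha Threshold applied (or `NA` if unthresholded).
#' @return An object of class `CoefficientMatrix`.
#' @export
coefficient_matrix <- function(entries, lambda_used, r2 = NULL, alpha = NA_real_) {
  entries <- methods::as(methods::as(entries, "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(entries)) || is.null(colnames(entries)))
    stop("entries must carry TF row names and gene column names")
  stopifnot(lambda_used >= 0)
  self <- intersect(rownames(entries), colnames(entries))
  if (length(self)) {
    d <- entries[cbind(match(self, rownames(entries)), match(self, colnames(entries)))]
    if (any(d != 0)) stop("self coefficients a_jj must be exactly zero")
  }
  structure(list(entries = entries, lambda_used = lambda_used,
                 alpha = alpha, r2 = r2),
            class = "CoefficientMatrix")
}

#' @export
print.CoefficientMatrix <- function(x, ...) {
  cat(sprintf("CoefficientMatrix: %d TFs x %d genes, %d nonzero, lambda = %g\n",
              nrow(x$entries), ncol(x$entries),
              Matrix::nnzero(x$entries), x$lambda_used))
  invisible(x)
}

## ---------------------------------------------------------------------------
## RegulatoryNetwork
## ---------------------------------------------------------------------------

#' Construct a RegulatoryNetwork
#'
#' A weighted directed TF -> target edge list. Zero-weight edges and
#' self-loops are disallowed; nodes exist only by virtue of incident edges,
#' so singletons are absent by construction.
#'
#' @param tf,target Character vectors of equal length.
#' @param weight Numeric edge weights (signed regression coefficients;
#'   positive = up-regulation, negative = down-regulation).
#' @return A `RegulatoryNetwork`, a data frame with columns tf/target/weight.
#' @export
regulatory_network <- function(tf = character(), target = character(),
                               weight = numeric()) {
  stopifnot(length(tf) == length(target), length(tf) == length(weight))
  tf <- as.character(tf); target <- as.character(target)
  if (any(weight == 0)) stop("zero-weight edges are not allowed")
  if (any(tf == target)) stop("self-loops are not allowed")
  if (anyDuplicated(paste0(tf, "\r", target)))
    stop("duplicate edges")
  net <- data.frame(tf = tf, target = target, weight = as.numeric(weight),
                    stringsAsFactors = FALSE)
  class(net) <- c("RegulatoryNetwork", "data.frame")
  net
}

#' Target pool of a TF
#'
#' `out_i`: the set of genes receiving an edge from TF `i`.
#' @param net A `RegulatoryNetwork`.
#' @param tf TF identifier.
#' @return Character vector of target gene ids.
#' @export
out_targets <- function(net, tf) unique(net$target[net$tf == tf])

#' Regulators of a gene
#'
#' `in_j`: the set of TFs with an edge into gene `j`.
#' @param net A `RegulatoryNetwork`.
#' @param gene Gene identifier.
#' @return Character vector of TF ids.
#' @export
in_regulators <- function(net, gene) unique(net$tf[net$target == gene])

#' TFs present in a network (nonempty target pool)
#' @param net A `RegulatoryNetwork`.
#' @return Character vector of TF ids.
#' @export
network_tfs <- function(net) unique(net$tf)

#' All node identifiers of a network
#' @param net A `RegulatoryNetwork`.
#' @return Character vector of node ids (TFs and targets).
#' @export
network_nodes <- function(net) unique(c(net$tf, net$target))

#' Target-pool sizes for every TF
#' @param net A `RegulatoryNetwork`.
#' @return Named integer vector `k_i = |out_i|`.
#' @export
pool_sizes <- function(net) {
  k <- table(net$tf)
  setNames(as.integer(k), names(k))
}

#' Write a network as a TSV edge list
#'
#' Three tab-separated columns (tf, target, weight) plus a header row, edges
#' in lexicographic (tf, target) order so output is deterministic.
#'
#' @param net A `RegulatoryNetwork`.
#' @param path Output path.
#' @export
write_network <- function(net, path) {
  if (nrow(net) == 0L) warning("writing an empty network")
  ord <- order(net$tf, net$target)
  df <- as.data.frame(net)[ord, , drop = FALSE]
  df$weight <- formatC(df$weight, format = "g", digits = 17)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV edge list written by [write_network()]
#' @param path Path to the edge-list file.
#' @return A `RegulatoryNetwork`.
#' @export
read_network <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric"))
  regulatory_network(df$tf, df$target, df$weight)
}

#' Export a network as GraphML
#' @param net A `RegulatoryNetwork`.
#' @param path Output path.
#' @export
write_network_graphml <- function(net, path) {
  g <- network_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a RegulatoryNetwork to an igraph object
#' @param net A `RegulatoryNetwork`.
#' @param directed Keep edge direction (default) or project to undirected.
#' @return An igraph graph with a `weight` edge attribute.
#' @export
network_igraph <- function(net, directed = TRUE) {
  g <- igraph::graph_from_data_frame(as.data.frame(net), directed = TRUE)
  if (!directed) g <- igraph::as_undirected(g, mode = "collapse",
                                            edge.attr.comb = list(weight = "first"))
  g
}

## ---------------------------------------------------------------------------
## PWMs (MEME minimal format)
## ---------------------------------------------------------------------------

#' Construct a PWM
#'
#' @param matrix A 4 x t column-stochastic matrix of nucleotide frequencies,
#'   rows in ACGT order.
#' @param id Identifier of the TF the PWM belongs to.
#' @param background Length-4 background probabilities (ACGT), default uniform.
#' @return An object of class `PWM`.
#' @export
pwm <- function(matrix, id = NA_character_, background = rep(0.25, 4)) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(matrix) < 1L) stop("PWM must have at least one column")
  if (any(matrix < 0)) stop("PWM frequencies must be nonnegative")
  cs <- colSums(matrix)
  if (any(abs(cs - 1) > 1e-6)) stop("PWM columns must sum to 1 (within 1e-6)")
  stopifnot(length(background) == 4L, all(background > 0))
  rownames(matrix) <- c("A", "C", "G", "T")
  structure(list(matrix = matrix, background = background / sum(background),
                 id = id, width = ncol(matrix)),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d\n", x$id, x$width))
  invisible(x)
}

#' Read PWMs from a MEME minimal-format file
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections over the
#' ACGT alphabet; the background model is taken from a
#' `Background letter frequencies` section when present, else uniform.
#' Columns whose probabilities do not sum to 1 within 1e-3 are renormalized
#' with a warning.
#'
#' @param path Path to the MEME minimal file.
#' @return A named list of [pwm()] objects, in file order.
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  alph <- grep("^ALPHABET", lines, value = TRUE)
  if (length(alph) && !grepl("ACGT", alph[1L]))
    stop("only the ACGT alphabet is supported")
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    bg_line <- lines[bg_at[1L] + 1L]
    toks <- strsplit(trimws(bg_line), "\\s+")[[1L]]
    if (length(toks) >= 8L) {
      freq <- as.numeric(toks[seq(2L, 8L, by = 2L)])
      lett <- toks[seq(1L, 7L, by = 2L)]
      background <- freq[match(c("A", "C", "G", "T"), lett)]
      if (anyNA(background)) stop("only the ACGT alphabet is supported")
    }
  }
  motif_at <- grep("^MOTIF", lines)
  if (!length(motif_at)) stop("no MOTIF blocks found in ", path)
  out <- list()
  for (s in motif_at) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1L]][2L]
    hdr <- grep("letter-probability matrix", lines[seq(s, length(lines))])[1L]
    if (is.na(hdr)) stop("MOTIF block without letter-probability matrix: ", id)
    hdr <- s + hdr - 1L
    rows <- list()
    i <- hdr + 1L
    while (i <= length(lines)) {
      tl <- trimws(lines[i])
      if (!nzchar(tl) || !grepl("^[0-9.eE+-]", tl)) break
      rows[[length(rows) + 1L]] <- as.numeric(strsplit(tl, "\\s+")[[1L]])
      i <- i + 1L
    }
    if (!length(rows)) stop("empty letter-probability matrix for motif ", id)
    if (any(lengths(rows) != 4L)) stop("only the ACGT alphabet is supported")
    m <- t(do.call(rbind, rows))  # rows of file = positions -> 4 x t
    cs <- colSums(m)
    if (any(abs(cs - 1) > 1e-3)) {
      warning(sprintf("motif '%s': %d column(s) renormalized to sum 1",
                      id, sum(abs(cs - 1) > 1e-3)))
    }
    m <- sweep(m, 2L, cs, "/")
    out[[id]] <- pwm(m, id = id, background = background)
  }
  out
}

#' Write PWMs in MEME minimal format
#' @param pwms A list of [pwm()] objects.
#' @param path Output path.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: +", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", c("A", "C", "G", "T"),
                             pwms[[1L]]$background), collapse = " "), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d", p$width), con)
    for (c in seq_len(p$width))
      writeLines(paste(formatC(p$matrix[, c], format = "f", digits = 6),
                       collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Promoters (FASTA)
## ---------------------------------------------------------------------------

#' Read promoter sequences from a FASTA file
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_promoters <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs))) stop("duplicate record ids in ", path)
  seqs
}

#' Write promoter sequences to a FASTA file
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_promoters <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Gene Ontology corpus
## ---------------------------------------------------------------------------

#' Construct a GOCorpus
#'
#' Bundles a term DAG (typed `is_a`/`part_of` edges), gene -> term
#' annotations restricted to the biological-process aspect, and the
#' enrichment universe. Annotations are propagated to all ancestors
#' (true-path rule) at construction; the universe defaults to all genes with
#' at least one annotation.
#'
#' @param terms Data frame with columns `id` and (optionally) `name`.
#' @param edges Data frame with columns `child`, `parent`, `type`
#'   (`"is_a"` or `"part_of"`).
#' @param annotations Named list mapping gene id -> character vector of
#'   directly annotated term ids.
#' @param universe Optional character vector of background genes; default is
#'   all annotated genes.
#' @return An object of class `GOCorpus` with precomputed ancestor closures
#'   (`ancestors`, including the term itself), propagated annotations
#'   (`ann_closed`), and the term -> annotated-gene-count table
#'   (`term_counts`).
#' @export
go_corpus <- function(terms, edges, annotations, universe = NULL) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  if (!"name" %in% names(terms)) terms$name <- terms$id
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) && !all(edges$type %in% c("is_a", "part_of")))
    stop("edge types must be 'is_a' or 'part_of'")
  if (nrow(edges) && !all(c(edges$child, edges$parent) %in% terms$id))
    stop("edges reference unknown terms")
  bad <- setdiff(unique(unlist(annotations, use.names = FALSE)), terms$id)
  if (length(bad))
    stop("annotations reference terms absent from the DAG: ",
         paste(head(bad, 5L), collapse = ", "))
  anc <- term_ancestors(terms$id, edges)  # errors on cycles
  ann_closed <- lapply(annotations, function(ts)
    unique(unlist(anc[unique(ts)], use.names = FALSE)))
  if (is.null(universe)) universe <- names(ann_closed)
  universe <- unique(as.character(universe))
  counts <- table(unlist(lapply(ann_closed[intersect(names(ann_closed), universe)],
                                unique), use.names = FALSE))
  structure(list(terms = terms, edges = edges,
                 annotations = annotations, ann_closed = ann_closed,
                 ancestors = anc, universe = universe,
                 term_counts = counts),
            class = "GOCorpus")
}

#' @export
print.GOCorpus <- function(x, ...) {
  cat(sprintf("GOCorpus: %d terms, %d typed edges, %d annotated genes, universe %d\n",
              nrow(x$terms), nrow(x$edges), length(x$annotations),
              length(x$universe)))
  invisible(x)
}

# Ancestor closure (including self) for every term, via memoized DFS over the
# child -> parent edge list. Errors on cycles.
term_ancestors <- function(term_ids, edges) {
  parents <- split(edges$parent, edges$child)
  anc <- new.env(parent = emptyenv())
  visiting <- new.env(parent = emptyenv())
  visit <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    if (!is.null(visiting[[t]])) stop("cycle in ontology at term ", t)
    visiting[[t]] <- TRUE
    ps <- parents[[t]]
    res <- t
    for (p in ps) res <- c(res, visit(p))
    res <- unique(res)
    anc[[t]] <- res
    rm(list = t, envir = visiting)
    res
  }
  out <- lapply(term_ids, visit)
  names(out) <- term_ids
  out
}

#' Read an OBO ontology file (biological-process terms)
#'
#' Minimal reader for the OBO flat-file format: `[Term]` stanzas with `id`,
#' `name`, `namespace`, `is_a` and `relationship: part_of` tags. Obsolete
#' terms are skipped. When namespaces are present only
#' `biological_process` terms are kept.
#'
#' @param path Path to the `.obo` file.
#' @return A list with data frames `terms` (id, name) and `edges`
#'   (child, parent, type), suitable for [go_corpus()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  starts <- grep("^\\[Term\\]$", lines)
  stanza_end <- c(grep("^\\[", lines)[-1L] - 1L, length(lines))
  terms <- list(); edges <- list()
  for (s in starts) {
    e <- min(stanza_end[stanza_end >= s])
    block <- lines[seq(s + 1L, e)]
    get1 <- function(tag) {
      v <- sub(paste0("^", tag, ":\\s*"), "", grep(paste0("^", tag, ":"), block, value = TRUE))
      if (length(v)) v else NA_character_
    }
    id <- get1("id")[1L]
    if (is.na(id)) next
    if (any(grepl("^is_obsolete:\\s*true", block))) next
    ns <- get1("namespace")[1L]
    if (!is.na(ns) && ns != "biological_process") next
    nm <- get1("name")[1L]
    isa <- sub("\\s*!.*$", "", get1("is_a"))
    isa <- isa[!is.na(isa)]
    rel <- grep("^relationship:\\s*part_of\\s", block, value = TRUE)
    po <- sub("\\s*!.*$", "", sub("^relationship:\\s*part_of\\s+", "", rel))
    terms[[id]] <- nm
    if (length(isa))
      edges[[length(edges) + 1L]] <- data.frame(child = id, parent = isa,
                                                type = "is_a", stringsAsFactors = FALSE)
    if (length(po))
      edges[[length(edges) + 1L]] <- data.frame(child = id, parent = po,
                                                type = "part_of", stringsAsFactors = FALSE)
  }
  ed <- if (length(edges)) do.call(rbind, edges)
        else data.frame(child = character(), parent = character(),
                        type = character(), stringsAsFactors = FALSE)
  td <- data.frame(id = names(terms), name = unlist(terms, use.names = FALSE),
                   stringsAsFactors = FALSE)
  # drop edges pointing outside the BP namespace
  ed <- ed[ed$parent %in% td$id & ed$child %in% td$id, , drop = FALSE]
  list(terms = td, edges = ed)
}

#' Read gene -> GO term annotations
#'
#' Accepts either GAF 2.x (17 columns, `!` comments; column 2 = gene id,
#' column 5 = term, column 9 = aspect, only aspect `P` kept) or a headerless
#' 2-column TSV (gene, term).
#'
#' @param path Path to the annotation file.
#' @return Named list mapping gene id -> character vector of term ids.
#' @export
read_gene_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (all(ncols >= 15L)) {           # GAF
    gene <- vapply(fields, `[[`, "", 2L)
    term <- vapply(fields, `[[`, "", 5L)
    aspect <- vapply(fields, `[[`, "", 9L)
    keep <- aspect == "P"
    gene <- gene[keep]; term <- term[keep]
  } else if (all(ncols == 2L)) {     # 2-column TSV
    gene <- vapply(fields, `[[`, "", 1L)
    term <- vapply(fields, `[[`, "", 2L)
  } else stop("unrecognized annotation format (need GAF or 2-column TSV)")
  lapply(split(term, gene), unique)
}

#' Write gene -> term annotations as a 2-column TSV
#' @param annotations Named list mapping gene -> term ids.
#' @param path Output path.
#' @export
write_gene_annotations <- function(annotations, path) {
  df <- data.frame(
    gene = rep(names(annotations), lengths(annotations)),
    term = unlist(annotations, use.names = FALSE), stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a toy ontology in OBO format
#' @param terms,edges Data frames as accepted by [go_corpus()].
#' @param path Output path.
#' @export
write_obo <- function(terms, edges, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(terms))) {
    id <- terms$id[i]
    writeLines(c("", "[Term]", paste0("id: ", id),
                 paste0("name: ", terms$name[i]),
                 "namespace: biological_process"), con)
    sub <- edges[edges$child == id, , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      if (sub$type[j] == "is_a")
        writeLines(paste0("is_a: ", sub$parent[j]), con)
      else
        writeLines(paste0("relationship: part_of ", sub$parent[j]), con)
    }
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Gene architecture
## ---------------------------------------------------------------------------

#' Read a gene length table
#'
#' Accepts a 2+ column TSV with a header (`gene_id`, `length`) or a GFF3 file
#' (lengths derived as end - start + 1 of `gene` features, id from the
#' `ID=`/`Name=` attribute).
#'
#' @param path Path to the table or GFF3 file.
#' @return Data frame with columns `gene_id` and `length`.
#' @export
read_gene_lengths <- function(path) {
  first <- readLines(path, n = 20L)
  if (any(grepl("^##gff-version", first)) ||
      all(lengths(strsplit(first[!startsWith(first, "#")], "\t")) == 9L)) {
    g <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
    g <- g[g[[3L]] == "gene", , drop = FALSE]
    attr_id <- sub(".*(?:ID|Name)=([^;]+).*", "\\1", g[[9L]])
    out <- data.frame(gene_id = attr_id,
                      length = g[[5L]] - g[[4L]] + 1L,
                      stringsAsFactors = FALSE)
  } else {
    out <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    names(out)[1:2] <- c("gene_id", "length")
    out <- out[, c("gene_id", "length")]
  }
  if (any(out$length <= 0)) stop("gene lengths must be positive")
  out
}
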