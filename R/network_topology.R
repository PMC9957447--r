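## Graph statistics of the inferred network and the gene-architecture /
## expression correlation analyses.

#' Summarize network topology
#'
#' Computes the standard descriptive statistics of a TF -> target network:
#' node/edge counts, TF and target counts, mean and largest (undirected)
#' degree, mean and median out-degree of TFs and in-degree of targets,
#' the diameter of the largest connected component of the undirected
#' projection, the average local clustering coefficient (nodes of degree
#' < 2 contribute 0), and the degree coefficient — the Pearson correlation
#' between the undirected degrees at the two endpoints of each edge,
#' computed over both orientations of every edge. For a degree-regular
#' graph the endpoint degrees have zero variance and the degree coefficient
#' is reported as `NaN` with a warning, never 0.
#'
#' @param net A [regulatory_network()].
#' @return A list of class `TopologySummary`.
#' @export
summarize_topology <- function(net) {
  if (nrow(net) == 0L) stop("empty network")
  g <- network_igraph(net)                       # directed
  gu <- igraph::as_undirected(g, mode = "collapse")
  deg_u <- igraph::degree(gu)
  out_deg <- igraph::degree(g, mode = "out")
  in_deg <- igraph::degree(g, mode = "in")
  tfs <- names(out_deg)[out_deg > 0L]
  targets <- names(in_deg)[in_deg > 0L]

  comp <- igraph::components(gu)
  big <- which.max(comp$csize)
  gbig <- igraph::induced_subgraph(gu, which(comp$membership == big))

  # degree coefficient: Pearson over the 2|E| (source deg, sink deg) pairs
  el <- igraph::as_edgelist(gu, names = TRUE)
  d1 <- deg_u[el[, 1L]]; d2 <- deg_u[el[, 2L]]
  xs <- c(d1, d2); ys <- c(d2, d1)
  if (var(xs) == 0 || var(ys) == 0) {
    warning("endpoint degrees have zero variance; degree coefficient undefined")
    degree_coeff <- NaN
  } else {
    degree_coeff <- cor(xs, ys)
  }

  structure(list(
    n_nodes = igraph::vcount(gu),
    n_edges = nrow(net),
    n_tfs = length(tfs),
    n_targets = length(targets),
    mean_degree = mean(deg_u),
    largest_degree = max(deg_u),
    mean_out_degree = mean(out_deg[tfs]),
    median_out_degree = as.numeric(stats::median(out_deg[tfs])),
    mean_in_degree = mean(in_deg[targets]),
    median_in_degree = as.numeric(stats::median(in_deg[targets])),
    diameter = igraph::diameter(gbig, directed = FALSE, unconnected = FALSE,
                                weights = NA),
    clustering_coefficient = igraph::transitivity(gu, type = "localaverage",
                                                  isolates = "zero"),
    clustering_variant = "average local (degree < 2 counted as 0)",
    degree_coefficient = degree_coeff),
    class = "TopologySummary")
}

#' @export
print.TopologySummary <- function(x, ...) {
  cat("Network topology summary\n")
  for (f in setdiff(names(x), "clustering_variant"))
    cat(sprintf("  %-24s %s\n", f, format(x[[f]], digits = 4)))
  invisible(x)
}

#' Per-node degree table and log-binned histogram
#'
#' @param net A [regulatory_network()].
#' @param bins Number of logarithmic bins for the histogram.
#' @return List with `degrees` (data frame: node, in_degree, out_degree,
#'   degree) and `histogram` (data frame of log-binned undirected-degree
#'   counts for plotting). No distributional fit is performed.
#' @export
degree_distribution <- function(net, bins = 10L) {
  if (nrow(net) == 0L) stop("empty network")
  g <- network_igraph(net)
  nodes <- igraph::V(g)$name
  out_deg <- igraph::degree(g, mode = "out")
  in_deg <- igraph::degree(g, mode = "in")
  deg <- igraph::degree(igraph::as_undirected(g, mode = "collapse"))[nodes]
  tab <- data.frame(node = nodes, in_degree = as.integer(in_deg[nodes]),
                    out_degree = as.integer(out_deg[nodes]),
                    degree = as.integer(deg), stringsAsFactors = FALSE)
  brks <- unique(c(0, exp(seq(0, log(max(deg) + 1), length.out = bins + 1L))))
  h <- hist(deg, breaks = brks, plot = FALSE)
  list(degrees = tab,
       histogram = data.frame(lower = head(h$breaks, -1L),
                              upper = tail(h$breaks, -1L),
                              count = h$counts))
}

#' Dispersion index of expression
#'
#' `dispersion_i = sd(Y_i) / mean(Y_i)` per gene (sample standard deviation,
#' denominator n - 1). Scale-invariant. Genes with nonpositive mean are
#' excluded with a warning, as the index is undefined there.
#'
#' @param expr An [expression_matrix()].
#' @return Named numeric vector of dispersions for genes with positive mean.
#' @export
dispersion_index <- function(expr) {
  mu <- rowMeans(expr$values)
  s <- apply(expr$values, 1L, sd)
  bad <- mu <= 0
  if (any(bad))
    warning(sprintf("%d gene(s) with nonpositive mean excluded from dispersion",
                    sum(bad)))
  (s / mu)[!bad]
}

#' Correlations among gene architecture, regulation, and expression
#'
#' Pearson correlation and two-sided p-value for every pair among gene
#' length, number of regulators `|in_j|`, mean expression, and dispersion of
#' expression, over the genes shared by all three inputs.
#'
#' @param expr An [expression_matrix()].
#' @param net A [regulatory_network()].
#' @param lengths Data frame with columns `gene_id` and `length` (see
#'   [read_gene_lengths()]).
#' @return Data frame with columns var1, var2, r, p_value, n.
#' @export
architecture_correlations <- function(expr, net, lengths) {
  in_deg <- table(net$target)
  genes <- intersect(intersect(expr$gene_ids, lengths$gene_id),
                     names(in_deg))
  if (length(genes) < 3L) stop("fewer than 3 genes shared across inputs")
  mu <- rowMeans(expr$values[genes, , drop = FALSE])
  disp <- apply(expr$values[genes, , drop = FALSE], 1L, sd) / mu
  vars <- list(
    gene_length = lengths$length[match(genes, lengths$gene_id)],
    n_regulators = as.numeric(in_deg[genes]),
    mean_expression = mu,
    dispersion = disp)
  pairs <- utils::combn(names(vars), 2L)
  rows <- apply(pairs, 2L, function(pp) {
    x <- vars[[pp[1L]]]; y <- vars[[pp[2L]]]
    ok <- is.finite(x) & is.finite(y)
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    data.frame(var1 = pp[1L], var2 = pp[2L],
               r = unname(ct$estimate), p_value = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
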