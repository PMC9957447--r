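# Brute-force graph statistics used as an independent oracle for
# summarize_topology(): adjacency-matrix algorithms only, no igraph.

bf_undirected_adj <- function(net) {
  nodes <- sort(unique(c(net$tf, net$target)))
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(net))) {
    A[net$tf[e], net$target[e]] <- 1L
    A[net$target[e], net$tf[e]] <- 1L
  }
  diag(A) <- 0L
  A
}

# all-pairs shortest paths by Floyd-Warshall; diameter of largest component
bf_diameter <- function(A) {
  n <- nrow(A)
  D <- ifelse(A == 1L, 1, Inf); diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n))
    D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
  # largest component = the component with most members
  comp <- rep(NA_integer_, n); cid <- 0L
  for (i in seq_len(n)) if (is.na(comp[i])) {
    cid <- cid + 1L
    comp[is.finite(D[i, ])] <- cid
  }
  big <- which(comp == which.max(tabulate(comp)))
  max(D[big, big])
}

# mean local clustering, degree < 2 counted as 0
bf_clustering <- function(A) {
  n <- nrow(A)
  loc <- numeric(n)
  deg <- rowSums(A)
  for (i in seq_len(n)) {
    if (deg[i] < 2) { loc[i] <- 0; next }
    nb <- which(A[i, ] == 1L)
    links <- sum(A[nb, nb]) / 2
    loc[i] <- links / choose(deg[i], 2)
  }
  mean(loc)
}

# Pearson correlation of endpoint degrees over both orientations of the
# undirected edges
bf_degree_coefficient <- function(A) {
  deg <- rowSums(A)
  idx <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  xs <- c(deg[idx[, 1]], deg[idx[, 2]])
  ys <- c(deg[idx[, 2]], deg[idx[, 1]])
  if (stats::var(xs) == 0) return(NaN)
  stats::cor(xs, ys)
}

random_small_network <- function(seed) {
  set.seed(seed)
  n_tf <- sample(2:5, 1)
  n_tg <- sample(3:10, 1)
  tfs <- paste0("t", seq_len(n_tf))
  tgs <- paste0("g", seq_len(n_tg))
  pairs <- expand.grid(tf = tfs, target = tgs, stringsAsFactors = FALSE)
  keep <- sample(nrow(pairs), max(2, rbinom(1, nrow(pairs), 0.4)))
  regulatory_network(pairs$tf[keep], pairs$target[keep],
                     runif(length(keep), 0.1, 1))
}
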