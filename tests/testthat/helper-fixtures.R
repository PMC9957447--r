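# Shared fixtures, built in code.

# A small hand-built BP-style DAG:
#   ROOT
#    |- BR1 (is_a)         |- BR2 (is_a)        |- BR3 (is_a)
#       |- L1, L2 (is_a)      |- L3 (part_of)      |- L4 -(is_a)- L5 (is_a chain)
tiny_dag <- function() {
  terms <- data.frame(
    id = c("ROOT", "BR1", "BR2", "BR3", "L1", "L2", "L3", "L4", "L5"),
    name = c("root", "branch 1", "branch 2", "branch 3",
             "leaf 1", "leaf 2", "leaf 3", "leaf 4", "leaf 5"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    child  = c("BR1", "BR2", "BR3", "L1", "L2", "L3",     "L4", "L5"),
    parent = c("ROOT", "ROOT", "ROOT", "BR1", "BR1", "BR2", "BR3", "L4"),
    type   = c("is_a", "is_a", "is_a", "is_a", "is_a", "part_of", "is_a", "is_a"),
    stringsAsFactors = FALSE)
  list(terms = terms, edges = edges)
}

tiny_corpus <- function(annotations = list(
                          g1 = "L1", g2 = "L1", g3 = c("L1", "L2"),
                          g4 = "L2", g5 = "L3", g6 = "L5", g7 = "L4",
                          g8 = "L1"),
                        universe = NULL) {
  d <- tiny_dag()
  go_corpus(d$terms, d$edges, annotations, universe = universe)
}

# planted regulatory fixture shared by several tests
small_planted <- function(seed = 3, n_tf = 5, n_genes = 60, m = 30,
                          density = 0.2, noise_sd = 0.1) {
  sim <- generate_expression(n_tf, n_genes, m, density = density,
                             noise_sd = noise_sd, seed = seed)
  sim$truth <- planted_edges(sim$model)
  sim
}

edge_key <- function(net) paste(net$tf, net$target)
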