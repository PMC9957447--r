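test_that("read_expression parses tables, keeps order, and applies the TF policy", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "AT1G01010\t1.0\t2.0\t3.0\t4.0",
               "AT1G01020\t0.5\t0.5\t0.5\t0.5",
               "AT1G01030\t2.0\t1.0\t2.0\t1.0"), tsv)
  tfl <- tempfile()
  writeLines("AT1G01020", tfl)
  ex <- read_expression(tsv, tfl)
  expect_s3_class(ex, "ExpressionMatrix")
  expect_equal(length(ex$gene_ids), 3L)
  expect_equal(length(ex$tf_ids), 1L)
  expect_equal(length(ex$sample_ids), 4L)
  # order equals file order, never silently reordered
  expect_equal(ex$gene_ids, c("AT1G01010", "AT1G01020", "AT1G01030"))

  # TFs without expression data are dropped with a warning
  writeLines(c("AT1G01020", "AT9G99999"), tfl)
  expect_warning(ex2 <- read_expression(tsv, tfl), "dropped")
  expect_equal(ex2$tf_ids, "AT1G01020")

  # degenerate TF lists are an error
  writeLines(character(), tfl)
  expect_error(read_expression(tsv, tfl), "no usable TF")
  writeLines("AT9G99999", tfl)
  expect_error(suppressWarnings(read_expression(tsv, tfl)), "no usable TF")
})

test_that("read_expression rejects duplicates and non-numeric cells by name", {
  tsv <- tempfile(fileext = ".tsv")
  tfl <- tempfile(); writeLines("g1", tfl)
  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), tsv)
  expect_error(read_expression(tsv, tfl), "duplicate gene ids")
  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g2\tNOPE\t4"), tsv)
  expect_error(read_expression(tsv, tfl), "row 'g2', column 's1'")
})

test_that("expression tables round-trip and CSV is sniffed", {
  sim <- small_planted()
  p <- tempfile(fileext = ".tsv"); ptf <- tempfile()
  write_expression(sim$expr, p, ptf)
  back <- read_expression(p, ptf)
  expect_equal(back$gene_ids, sim$expr$gene_ids)
  expect_equal(back$tf_ids, sim$expr$tf_ids)
  expect_equal(back$values, sim$expr$values, tolerance = 1e-12)

  csv <- tempfile(fileext = ".csv")
  writeLines(c("gene,s1,s2", "g1,1,2", "g2,3,4"), csv)
  tfl <- tempfile(); writeLines("g1", tfl)
  expect_equal(read_expression(csv, tfl)$values["g2", 2], 4)
})

test_that("MEME minimal PWMs parse, renormalize, and round-trip", {
  f <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               "A 0.3 C 0.2 G 0.2 T 0.3", "",
               "MOTIF M1",
               "letter-probability matrix: alength= 4 w= 9",
               rep("0.25 0.25 0.25 0.25", 8),
               "0.97 0.01 0.01 0.01", ""), f)
  ps <- read_pwms(f)
  expect_length(ps, 1L)
  expect_equal(ps[["M1"]]$width, 9L)
  expect_equal(ps[["M1"]]$background, c(0.3, 0.2, 0.2, 0.3))

  # two blocks preserve order; bad column renormalized with warning
  writeLines(c("MEME version 4", "",
               "MOTIF A1", "letter-probability matrix:",
               "0.5 0.5 0.1 0.1", "",
               "MOTIF B2", "letter-probability matrix:",
               "0.25 0.25 0.25 0.25", ""), f)
  expect_warning(ps2 <- read_pwms(f), "renormalized")
  expect_equal(names(ps2), c("A1", "B2"))
  expect_equal(sum(ps2[["A1"]]$matrix[, 1]), 1)
  expect_equal(unname(ps2[["A1"]]$matrix[1, 1]), 0.5 / 1.2)

  out <- tempfile(fileext = ".meme")
  write_pwms(ps2, out)
  back <- read_pwms(out)
  expect_equal(back[["A1"]]$matrix, ps2[["A1"]]$matrix, tolerance = 1e-5)
})

test_that("PWM validation enforces the column-stochastic contract", {
  expect_error(pwm(matrix(0.2, 3, 5)), "4 rows")
  expect_error(pwm(matrix(c(0.5, 0.5, 0.2, 0.1), 4, 1)), "sum to 1")
  expect_error(pwm(matrix(c(-0.1, 0.6, 0.3, 0.2), 4, 1)), "nonnegative")
})

test_that("network edge lists write deterministically and round-trip to 1e-12", {
  net <- regulatory_network(c("tfB", "tfA"), c("g2", "g1"),
                            c(-0.123456789012345, 0.5))
  p <- tempfile(fileext = ".tsv")
  write_network(net, p)
  lines <- readLines(p)
  expect_equal(lines[1], "tf\ttarget\tweight")
  expect_length(lines, 3L)                      # header + 2 edges
  expect_true(startsWith(lines[2], "tfA"))      # lexicographic order
  back <- read_network(p)
  expect_setequal(edge_key(back), edge_key(net))
  m <- merge(as.data.frame(net), as.data.frame(back), by = c("tf", "target"))
  expect_equal(m$weight.x, m$weight.y, tolerance = 1e-12)

  expect_warning(write_network(regulatory_network(), p), "empty")
  expect_equal(readLines(p), "tf\ttarget\tweight")
})

test_that("network constructor rejects zero weights, self-loops, duplicates", {
  expect_error(regulatory_network("a", "b", 0), "zero-weight")
  expect_error(regulatory_network("a", "a", 1), "self-loop")
  expect_error(regulatory_network(c("a", "a"), c("b", "b"), c(1, 2)),
               "duplicate")
})

test_that("network accessors report pools, regulators, and sizes", {
  net <- regulatory_network(c("t1", "t1", "t2"), c("g1", "g2", "g1"),
                            c(1, -1, 2))
  expect_setequal(out_targets(net, "t1"), c("g1", "g2"))
  expect_setequal(in_regulators(net, "g1"), c("t1", "t2"))
  expect_equal(pool_sizes(net), c(t1 = 2L, t2 = 1L))
  expect_setequal(network_nodes(net), c("t1", "t2", "g1", "g2"))
})

test_that("FASTA promoters round-trip and duplicate ids error", {
  seqs <- c(gA = "ACGTACGT", gB = "TTTTAAAA")
  p <- tempfile(fileext = ".fasta")
  write_promoters(seqs, p)
  expect_equal(read_promoters(p), seqs)
  writeLines(c(">x", "ACGT", ">x", "TTTT"), p)
  expect_error(read_promoters(p), "duplicate record ids")
})

test_that("OBO and annotation files round-trip into a corpus", {
  d <- tiny_dag()
  obo <- tempfile(fileext = ".obo")
  write_obo(d$terms, d$edges, obo)
  parsed <- read_obo(obo)
  expect_setequal(parsed$terms$id, d$terms$id)
  expect_equal(nrow(parsed$edges), nrow(d$edges))
  expect_setequal(parsed$edges$type[parsed$edges$child == "L3"], "part_of")

  ann <- list(g1 = c("L1", "L2"), g2 = "L5")
  annp <- tempfile(fileext = ".tsv")
  write_gene_annotations(ann, annp)
  expect_equal(read_gene_annotations(annp), ann)

  # GAF: only aspect P rows kept
  gaf <- tempfile()
  row <- function(gene, term, aspect)
    paste(c("DB", gene, gene, "", term, "REF", "IEA", "", aspect,
            "", "", "protein", "taxon:3702", "20230101", "DB", "", ""),
          collapse = "\t")
  writeLines(c("!gaf-version: 2.2", row("g1", "L1", "P"),
               row("g1", "L2", "F"), row("g2", "L5", "P")), gaf)
  expect_equal(read_gene_annotations(gaf), list(g1 = "L1", g2 = "L5"))
})

test_that("go_corpus propagates annotations and counts terms in the universe", {
  corp <- tiny_corpus()
  # g6 -> L5 propagates through L4, BR3 to ROOT
  expect_setequal(corp$ann_closed$g6, c("L5", "L4", "BR3", "ROOT"))
  # root is annotated to every annotated gene
  expect_equal(as.integer(corp$term_counts["ROOT"]),
               length(corp$annotations))
  expect_error(go_corpus(tiny_dag()$terms, tiny_dag()$edges,
                         list(g1 = "NOPE")), "absent from the DAG")
  # cycles are rejected
  bad <- data.frame(child = c("A", "B"), parent = c("B", "A"),
                    type = "is_a", stringsAsFactors = FALSE)
  expect_error(go_corpus(data.frame(id = c("A", "B")), bad,
                         list(g1 = "A")), "cycle")
})

test_that("gene length tables load from TSV and GFF3", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlength", "g1\t1500", "g2\t800"), p)
  gl <- read_gene_lengths(p)
  expect_equal(gl$length, c(1500, 800))

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "Chr1\tsrc\tgene\t100\t1099\t.\t+\t.\tID=g1;Name=g1",
               "Chr1\tsrc\tmRNA\t100\t1099\t.\t+\t.\tID=g1.1;Parent=g1",
               "Chr1\tsrc\tgene\t2000\t2499\t.\t-\t.\tID=g2"), gff)
  gg <- read_gene_lengths(gff)
  expect_equal(gg$gene_id, c("g1", "g2"))
  expect_equal(gg$length, c(1000, 500))
})
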