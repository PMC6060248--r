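test_that("genomes round-trip through GFF3 + FASTA field by field", {
  ps <- shared_panel()
  for (org in c("clustered", "dispersed")) {
    gg <- generate_genome(sim_profile(org, seed = 21,
                                      fragmentation = if (org == "clustered")
                                        2 else 0), ps)
    g <- gg$genome
    d <- withr::local_tempdir()
    write_genome(g, file.path(d, "g.gff3"), file.path(d, "g.faa"))
    g2 <- read_genome(file.path(d, "g.gff3"), file.path(d, "g.faa"),
                      genome_id = g$genome_id)
    expect_setequal(g2$contigs$contig_id, g$contigs$contig_id)
    expect_equal(
      g2$contigs$length[match(g$contigs$contig_id, g2$contigs$contig_id)],
      g$contigs$length)
    cols <- c("gene_id", "contig_id", "start", "end", "strand", "product",
              "locus_index")
    a <- g$genes[order(g$genes$gene_id), cols]
    b <- g2$genes[order(g2$genes$gene_id), cols]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(b, a)
    nm <- sort(names(g$proteins))
    expect_equal(g2$proteins[nm], g$proteins[nm])
  }
})

test_that("locus_index ranks genes by start regardless of record order", {
  genes <- data.frame(gene_id = c("b", "c", "a"), contig_id = "c1",
                      start = c(500, 900, 100), end = c(600, 1000, 200),
                      strand = "+", product = "", stringsAsFactors = FALSE)
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    g <- new_genome("p", contigs = data.frame(contig_id = "c1", length = 2000),
                    genes = genes[perm, ])
    got <- setNames(g$genes$locus_index, g$genes$gene_id)
    expect_equal(got[c("a", "b", "c")], c(a = 0L, b = 1L, c = 2L))
  }
})

test_that("header-only GFF3 yields an empty genome and a 0-gene genome writes only the pragma", {
  d <- withr::local_tempdir()
  writeLines("##gff-version 3", file.path(d, "empty.gff3"))
  g <- read_genome(file.path(d, "empty.gff3"))
  expect_equal(nrow(g$contigs), 0L)
  expect_equal(nrow(g$genes), 0L)
  g0 <- new_genome("none", contigs = data.frame(contig_id = character(0),
                                                length = integer(0)),
                   genes = data.frame(gene_id = character(0),
                                      contig_id = character(0),
                                      start = integer(0), end = integer(0),
                                      strand = character(0),
                                      product = character(0)))
  write_genome(g0, file.path(d, "zero.gff3"))
  expect_identical(readLines(file.path(d, "zero.gff3")), "##gff-version 3")
})

test_that("malformed GFF3 lines and duplicate gene ids are rejected with diagnostics", {
  d <- withr::local_tempdir()
  writeLines(c("##gff-version 3",
               "c1\tsrc\tgene\t1\t90\t.\t+\t.\tID=g1",
               "c1\tsrc\tgene\tbroken-line"),
             file.path(d, "bad.gff3"))
  expect_error(read_genome(file.path(d, "bad.gff3")), "line 3")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tgene\t1\t90\t.\t+\t.\tID=g1",
               "c1\tsrc\tgene\t200\t290\t.\t+\t.\tID=g1"),
             file.path(d, "dup.gff3"))
  expect_error(read_genome(file.path(d, "dup.gff3")), "duplicate")
  expect_error(new_genome("x", contigs = data.frame(contig_id = "c1",
                                                    length = 100),
                          genes = data.frame(gene_id = c("g", "g"),
                                             contig_id = "c1",
                                             start = c(1, 20),
                                             end = c(10, 30), strand = "+",
                                             product = "")),
               "duplicate")
})

test_that("genes without a translation are kept with empty sequence", {
  d <- withr::local_tempdir()
  writeLines(c("##gff-version 3",
               "##sequence-region c1 1 5000",
               "c1\tsrc\tgene\t100\t400\t.\t+\t.\tID=g1",
               "c1\tsrc\tgene\t600\t900\t.\t-\t.\tID=g2"),
             file.path(d, "g.gff3"))
  writeLines(c(">g1", "MKTEST"), file.path(d, "g.faa"))
  expect_warning(g <- read_genome(file.path(d, "g.gff3"),
                                  file.path(d, "g.faa")),
                 "lack a protein")
  expect_equal(nrow(g$genes), 2L)
  expect_identical(unname(g$proteins["g2"]), "")
  expect_identical(unname(g$proteins["g1"]), "MKTEST")
})

test_that("iTOL binary dataset round-trips and rejects bad entries", {
  d <- withr::local_tempdir()
  m <- matrix(c(1L, -1L, 1L, 1L, -1L, -1L), nrow = 2, byrow = TRUE,
              dimnames = list(c("gen1", "gen2"),
                              c("pilA", "pilB", "pilT")))
  p <- file.path(d, "itol.txt")
  write_itol_binary(m, p)
  lines <- readLines(p)
  expect_true("DATASET_BINARY" %in% lines)
  expect_true(any(lines == "SEPARATOR TAB"))
  expect_identical(read_itol_binary(p), m)
  # single present family renders the forced DATA line
  write_itol_binary(matrix(1L, 1, 1, dimnames = list("g1", "pilA")), p)
  expect_true("g1\t1" %in% readLines(p))
  # no genomes: header only, no DATA rows
  write_itol_binary(matrix(integer(0), 0, 2,
                           dimnames = list(NULL, c("pilA", "pilB"))), p)
  lines <- readLines(p)
  expect_identical(lines[length(lines)], "DATA")
  expect_error(write_itol_binary(matrix(0L, 1, 1,
                                        dimnames = list("g", "f")), p),
               "1 .present. or -1")
})
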