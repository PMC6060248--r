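test_that("self-alignment is perfect and empty input errors", {
  seq <- rand_peptide(50)
  aln <- local_align(seq, seq)
  h <- score_hit("pilA", "g1", aln, nchar(seq))
  expect_equal(h$identity_pct, 100)
  expect_equal(h$similarity_pct, 100)
  expect_equal(h$query_coverage_pct, 100)
  expect_error(local_align("", "ACDE"), "empty")
})

test_that("local alignment scores match the hand-coded DP oracle on random short peptides", {
  set.seed(11)
  mat <- bl62()
  for (k in seq_len(60)) {
    a <- rand_peptide(sample(1:12, 1))
    b <- rand_peptide(sample(1:12, 1))
    expect_equal(local_align(a, b)$score_raw, sw_score_oracle(a, b, mat),
                 info = paste(a, b))
  }
})

test_that("the DP oracle agrees with exhaustive alignment enumeration on tiny strings", {
  set.seed(12)
  mat <- bl62()
  for (k in seq_len(15)) {
    a <- rand_peptide(sample(2:5, 1))
    b <- rand_peptide(sample(2:5, 1))
    enum <- sw_enum_oracle(a, b, mat)
    expect_equal(sw_score_oracle(a, b, mat), max(enum, 0),
                 info = paste(a, b))
  }
})

test_that("all-negative residue pairings give the empty local alignment, a single positive pair is found by hand", {
  # every pairing of ACDE against W scores negative under BLOSUM62
  aln <- local_align("ACDE", "WWWW")
  expect_equal(aln$score_raw, 0)
  expect_identical(aln$pattern_aligned, "")
  # best nonempty alignment: the C-C pair, worth BLOSUM62[C,C] = 9
  aln2 <- local_align("ACDE", "WWCW")
  expect_equal(aln2$score_raw, bl62()["C", "C"])
  expect_identical(aln2$pattern_aligned, "C")
})

test_that("the simplified E-value follows its closed form and monotonicities", {
  expect_equal(estimate_evalue(40, 100, 100), 1e4 * 2^-40)
  expect_equal(estimate_evalue(40, 100, 200) / estimate_evalue(40, 100, 100),
               2)
  e <- estimate_evalue(seq(10, 60, by = 5), 300, 300)
  expect_true(all(diff(e) < 0))
  expect_identical(estimate_evalue(33.25, 217, 512),
                   estimate_evalue(33.25, 217, 512))
  expect_error(estimate_evalue(40, 0, 10), "positive")
})

test_that("coverage is reference-relative and similarity recomputable from the alignment", {
  set.seed(13)
  core <- rand_peptide(100)
  ref <- paste0(core, rand_peptide(100))  # reference twice the aligned span
  aln <- local_align(ref, core)
  h <- score_hit("pilB", "g1", aln, nchar(ref))
  expect_equal(h$query_coverage_pct, 50, tolerance = 0.02)
  # self-consistency on random long pairs: recompute similarity from the
  # emitted alignment strings
  mat <- bl62()
  for (k in 1:5) {
    a <- rand_peptide(200)
    b <- local({  # correlated sequence so a real alignment exists
      ch <- strsplit(a, "")[[1]]
      idx <- sample(200, 60)
      ch[idx] <- sample(AA20, 60, replace = TRUE)
      paste(ch, collapse = "")
    })
    aln <- local_align(a, b)
    h <- score_hit("f", "g", aln, nchar(a))
    pa <- strsplit(aln$pattern_aligned, "")[[1]]
    sa <- strsplit(aln$subject_aligned, "")[[1]]
    both <- pa != "-" & sa != "-"
    pos <- logical(length(pa))
    pos[both] <- mat[cbind(pa[both], sa[both])] > 0
    expect_equal(h$similarity_pct, 100 * sum(pos) / length(pa))
    expect_equal(h$identity_pct, 100 * sum(both & pa == sa) / length(pa))
  }
})

test_that("family assignment is correct, decoy-exclusive and order-invariant", {
  ps <- shared_panel()
  panel <- ps$panel
  # gene identical to the pilB reference is assigned pilB
  pilb <- panel$seq[panel$family == "pilB"]
  genes <- data.frame(gene_id = c("gB", "gDecoy", "gBg"), contig_id = "c1",
                      start = c(100, 2000, 4000), end = c(1000, 3000, 4500),
                      strand = "+", product = "", stringsAsFactors = FALSE)
  set.seed(14)
  prot <- c(gB = pilb,
            gDecoy = panel$seq[panel$name == "t2ssE_1"],
            gBg = rand_peptide(150))
  g <- new_genome("hx", contigs = data.frame(contig_id = "c1", length = 1e4),
                  genes = genes, proteins = prot)
  asg <- assign_families(g, panel)
  expect_identical(asg$family[asg$gene_id == "gB"], "pilB")
  # gene matching the T2SS paralog best (pilB second-best) is excluded
  row <- asg[asg$gene_id == "gDecoy", ]
  expect_identical(row$family, "UNASSIGNED")
  expect_true(row$excluded_as_decoy)
  expect_identical(row$hit_family, "t2ssE")
  expect_identical(asg$family[asg$gene_id == "gBg"], "UNASSIGNED")
  # iteration order must not matter
  g2 <- new_genome("hx2", contigs = g$contigs, genes = genes[c(3, 1, 2), ],
                   proteins = prot)
  asg2 <- assign_families(g2, panel)
  asg2 <- asg2[match(asg$gene_id, asg2$gene_id), ]
  rownames(asg2) <- NULL
  expect_equal(asg2, asg)
  expect_error(assign_families(g, panel[panel$role == "decoy", ]),
               "non-decoy")
})

test_that("the three filters are conjunctive: losing any one removes the hit", {
  ps <- shared_panel()
  panel <- ps$panel[ps$panel$family == "pilC", , drop = FALSE]
  gene_seq <- mutate_protein(panel$seq[1], 0.2)
  g <- new_genome("cj", contigs = data.frame(contig_id = "c1", length = 5000),
                  genes = data.frame(gene_id = "g1", contig_id = "c1",
                                     start = 100, end = 1000, strand = "+",
                                     product = ""),
                  proteins = c(g1 = gene_seq))
  base <- default_thresholds()
  asg <- assign_families(g, panel, base)
  expect_identical(asg$family, "pilC")
  hit <- asg[1, ]
  for (tweak in list(
    list(max_evalue = hit$evalue / 10),
    list(min_query_coverage_pct = min(hit$query_coverage_pct + 1, 100)),
    list(min_similarity_pct = min(hit$similarity_pct + 1, 100)))) {
    th <- utils::modifyList(base, tweak)
    expect_identical(assign_families(g, panel, th)$family, "UNASSIGNED")
  }
})

test_that("panels round-trip through FASTA with family|role headers", {
  ps <- shared_panel()
  d <- withr::local_tempdir()
  p <- file.path(d, "panel.faa")
  write_panel(ps$panel, p)
  got <- read_panel(p)
  expect_equal(got[order(got$name), ], ps$panel[order(ps$panel$name), ],
               ignore_attr = TRUE)
})
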