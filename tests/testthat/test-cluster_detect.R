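test_that("no assigned genes yields no clusters; anchors never join", {
  toy <- toy_genome(rep("", 8))
  expect_length(detect_clusters(toy$genome, toy$assignments), 0)
  toy2 <- toy_genome(c("pilB", "ribF", "", "", ""))
  cl <- detect_clusters(toy2$genome, toy2$assignments)
  expect_length(cl, 1)
  expect_identical(cl[[1]]$members$family, "pilB")
})

test_that("gap rule: members join iff intervening unassigned genes <= max_gap", {
  toy <- toy_genome(c("pilB", "", "", "pilT", rep("", 6), "pilC"))
  cl <- detect_clusters(toy$genome, toy$assignments, max_gap = 2)
  expect_length(cl, 2)
  expect_equal(cl[[1]]$gaps, 2L)
  expect_identical(cl[[1]]$architecture, "pilB-[2]-pilT")
  cl5 <- detect_clusters(toy$genome, toy$assignments, max_gap = 6)
  expect_length(cl5, 1)
  expect_equal(cl5[[1]]$gaps, c(2L, 6L))
  expect_error(detect_clusters(toy$genome,
                               data.frame(gene_id = "ghost",
                                          family = "pilB")),
               "absent")
})

test_that("cluster detection equals the independent union-find oracle on random contigs", {
  set.seed(21)
  fams <- c("pilA", "pilB", "pilC", "pilM", "pilT", "fimU")
  for (k in seq_len(120)) {
    n <- sample(3:20, 1)
    tokens <- ifelse(runif(n) < 0.4, sample(fams, n, replace = TRUE), "")
    max_gap <- sample(0:5, 1)
    toy <- toy_genome(tokens)
    got <- detect_clusters(toy$genome, toy$assignments, max_gap = max_gap)
    got_idx <- lapply(got, function(cl) cl$members$locus_index + 1L)
    want <- cluster_oracle(which(tokens != ""), max_gap)
    expect_equal(length(got_idx), length(want))
    expect_setequal(vapply(got_idx, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
  }
})

test_that("clusters partition assigned genes and reverse with the contig", {
  set.seed(22)
  tokens <- c("pilB", "", "pilT", "pilC", "", "", "", "", "", "fimU", "pilW")
  toy <- toy_genome(tokens)
  cl <- detect_clusters(toy$genome, toy$assignments)
  all_members <- unlist(lapply(cl, function(x) x$members$gene_id))
  expect_false(anyDuplicated(all_members) > 0)
  expect_setequal(all_members,
                  toy$assignments$gene_id[toy$assignments$family !=
                                          "UNASSIGNED"])
  # reverse the contig: same clusters, reversed architectures
  g <- toy$genome
  L <- g$contigs$length
  rev_genes <- g$genes
  tmp <- L - rev_genes$end + 1
  rev_genes$end <- L - rev_genes$start + 1
  rev_genes$start <- tmp
  rev_genes$strand <- ifelse(rev_genes$strand == "+", "-", "+")
  g_rev <- new_genome("rev", contigs = g$contigs, genes = rev_genes)
  cl_rev <- detect_clusters(g_rev, toy$assignments)
  archs <- sort(vapply(cl, `[[`, "", "architecture"))
  archs_rev <- sort(vapply(cl_rev, function(x) {
    p <- parse_architecture(x$architecture)
    architecture_string(rev(p$families), rev(p$gaps))
  }, ""))
  expect_identical(archs_rev, archs)
})

test_that("architecture strings parse back losslessly", {
  set.seed(23)
  fams <- c("pilA", "pilB", "pilQ", "fimU", "pilY1", "tsaP", "pilRS")
  for (k in seq_len(50)) {
    nf <- sample(1:8, 1)
    f <- sample(fams, nf, replace = TRUE)
    gp <- sample(0:6, max(nf - 1, 0), replace = TRUE)
    arch <- architecture_string(f, gp)
    back <- parse_architecture(arch)
    expect_identical(back$families, f)
    expect_equal(back$gaps, as.integer(gp))
  }
})

test_that("classification reproduces the field's architecture labels", {
  mk <- function(tokens) {
    toy <- toy_genome(tokens)
    classify_clusters(detect_clusters(toy$genome, toy$assignments))
  }
  cl <- mk(c("fimU", "pilW", "pilV", "pilY1", "pilX"))
  expect_identical(cl[[1]]$label, "minor_pilin")
  expect_identical(cl[[1]]$architecture, "fimU-pilW-pilV-pilY1-pilX")
  cl <- mk(c("pilW", "", "pilY1"))
  expect_identical(cl[[1]]$label, "minor_pilin")
  expect_identical(cl[[1]]$architecture, "pilW-x-pilY1")
  cl <- mk(c("pilM", "pilN", "pilO", "pilP", "pilQ"))
  expect_identical(cl[[1]]$label, "mnopq")
  # a lone minor pilin is not a minor-pilin locus
  cl <- mk(c("pilE"))
  expect_identical(cl[[1]]$label, "other")
})

test_that("organization calls follow the clustered/dispersed dichotomy", {
  ps <- shared_panel()
  gg <- generate_genome(sim_profile("clustered", divergence = 0, seed = 31),
                        ps)
  cl <- classify_clusters(detect_clusters(gg$genome,
                                          truth_assignments(gg$truth)))
  org <- call_organization(gg$genome, cl)
  expect_identical(org$call, "clustered")
  expect_equal(org$main_cluster_size, 17L)
  gg2 <- generate_genome(sim_profile("dispersed", divergence = 0, seed = 32),
                         ps)
  cl2 <- classify_clusters(detect_clusters(gg2$genome,
                                           truth_assignments(gg2$truth)))
  expect_identical(call_organization(gg2$genome, cl2)$call, "dispersed")
  # no T4aP genes at all: ambiguous
  toy <- toy_genome(rep("", 5))
  expect_identical(call_organization(toy$genome, list())$call, "ambiguous")
})

test_that("split main loci across contig ends are flagged and upgrade the call", {
  ps <- shared_panel()
  gg <- generate_genome(sim_profile("clustered", divergence = 0, seed = 33),
                        ps)
  truth <- gg$truth
  main_idx <- gg$genome$genes$locus_index[
    gg$genome$genes$gene_id %in% truth$gene_id[truth$locus == "main"]]
  cut_at <- sort(main_idx)[9]  # split the 17-gene locus 9/8
  frag <- fragment_genome(gg$genome,
                          data.frame(contig_id = "c1",
                                     after_locus_index = cut_at - 1L))
  asg <- truth_assignments(truth)
  cl <- classify_clusters(detect_clusters(frag, asg))
  expect_false(any(vapply(cl, `[[`, "", "label") == "main"))
  cl <- flag_split_clusters(frag, cl)
  expect_true(any(vapply(cl, `[[`, logical(1), "split_candidate")))
  org <- call_organization(frag, cl)
  expect_identical(org$call, "clustered")
  expect_true(org$split_candidate)
  expect_equal(org$main_cluster_size, 17L)
  # the same two fragments mid-contig must not be flagged
  cl_far <- flag_split_clusters(frag, classify_clusters(
    detect_clusters(frag, asg)), edge_window = 0)
  expect_false(any(vapply(cl_far, `[[`, logical(1), "split_candidate")))
})

test_that("pilA paralog counting is exact and permutation-invariant", {
  ps <- shared_panel()
  for (k in c(1, 4, 7)) {
    gg <- generate_genome(sim_profile("clustered", n_pila_paralogs = k,
                                      divergence = 0, seed = 40 + k), ps)
    asg <- truth_assignments(gg$truth)
    expect_equal(count_paralogs(asg, "pilA"), k)
    expect_equal(count_paralogs(asg[sample(nrow(asg)), ], "pilA"), k)
  }
  expect_equal(count_paralogs(data.frame(gene_id = "g", family = "pilB"),
                              "pilA"), 0)
})

test_that("pilRS members resolve into numbered pairs by locus order", {
  toy <- toy_genome(c("pilB", "pilRS", "pilRS", "pilRS", "pilRS", "pilT",
                      "pilC", "pilA", "pilM", "pilN", "pilO", "pilP"))
  cl <- classify_clusters(detect_clusters(toy$genome, toy$assignments))
  expect_identical(cl[[1]]$label, "main")
  rs <- resolve_pilrs(cl[[1]])
  expect_equal(nrow(rs), 4)
  expect_identical(unique(rs$pair_label), c("pilR1S1", "pilR2S2"))
  expect_true(all(rs$complete))
  # odd pilRS count: trailing singleton flagged incomplete
  toy2 <- toy_genome(c("pilRS", "pilRS", "pilRS"))
  cl2 <- detect_clusters(toy2$genome, toy2$assignments)
  rs2 <- resolve_pilrs(cl2[[1]])
  expect_identical(rs2$complete, c(TRUE, TRUE, FALSE))
})
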