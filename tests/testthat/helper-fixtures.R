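# shared fixtures and independent oracles, built in code at test time

# one panel per test run (panel generation involves alignment checks)
shared_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_panel(seed = 42)
    cache
  }
})

bl62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
          "S","T","W","Y","V")

rand_peptide <- function(n) paste(sample(AA20, n, replace = TRUE),
                                  collapse = "")

# ground-truth assignment table from a generator truth table (bypasses the
# homology stage so cluster logic is tested in isolation)
truth_assignments <- function(truth) {
  fam <- truth$true_family
  fam[fam == "background" | grepl("^t2ss", fam)] <- "UNASSIGNED"
  data.frame(gene_id = truth$gene_id, family = fam,
             stringsAsFactors = FALSE)
}

# hand-built single-contig genome from a token vector ("" = unassigned
# background, anything else = the assigned family); returns genome +
# assignments
toy_genome <- function(tokens, contig = "c1", genome_id = "toy",
                       strand = NULL) {
  n <- length(tokens)
  if (is.null(strand)) strand <- rep("+", n)
  start <- seq(100, by = 1000, length.out = n)
  genes <- data.frame(gene_id = sprintf("t%03d", seq_len(n)),
                      contig_id = contig, start = start,
                      end = start + 800, strand = strand,
                      product = ifelse(tokens == "", "hypothetical protein",
                                       tokens),
                      stringsAsFactors = FALSE)
  genome <- new_genome(genome_id,
                       contigs = data.frame(contig_id = contig,
                                            length = max(start) + 1000,
                                            stringsAsFactors = FALSE),
                       genes = genes)
  asg <- data.frame(gene_id = genes$gene_id,
                    family = ifelse(tokens == "", "UNASSIGNED", tokens),
                    stringsAsFactors = FALSE)
  list(genome = genome, assignments = asg)
}

# independent Smith-Waterman oracle: plain-R Gotoh DP, score clamped at 0
# (empty local alignment allowed), gap of length L costs go + ge * L
sw_score_oracle <- function(a, b, mat, go = 11, ge = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- mat[A[i], B[j]]
    M[i + 1, j + 1] <- s + max(0, M[i, j], Ix[i, j], Iy[i, j])
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, Ix[i, j + 1] - ge)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, Iy[i + 1, j] - ge)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# exhaustive enumeration of every nonempty local alignment path for tiny
# strings (exponential; used to validate the DP oracle itself at small n);
# local alignments start and end on an aligned pair, a gap of length L
# costs go + ge * L
sw_enum_oracle <- function(a, b, mat, go = 11, ge = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  best <- 0
  extend <- function(i, j, score, last) {
    if (last == "m") best <<- max(best, score)
    if (i < na && j < nb)
      extend(i + 1, j + 1, score + mat[A[i + 1], B[j + 1]], "m")
    if (i < na)
      extend(i + 1, j, score - ge - (last != "ga") * go, "ga")
    if (j < nb)
      extend(i, j + 1, score - ge - (last != "gb") * go, "gb")
  }
  for (i in seq_len(na)) for (j in seq_len(nb))
    extend(i, j, mat[A[i], B[j]], "m")
  best
}

# independent cluster oracle: union-find over pairs of assigned loci with
# no assigned gene between them and at most max_gap intervening genes
cluster_oracle <- function(assigned_idx, max_gap) {
  if (length(assigned_idx) == 0) return(list())
  assigned_idx <- sort(assigned_idx)
  parent <- seq_along(assigned_idx)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (p in seq_along(assigned_idx)) for (q in seq_along(assigned_idx)) {
    if (p >= q) next
    i <- assigned_idx[p]; j <- assigned_idx[q]
    between <- assigned_idx[assigned_idx > i & assigned_idx < j]
    if (length(between) == 0 && (j - i - 1) <= max_gap)
      parent[find(q)] <- find(p)
  }
  comp <- vapply(seq_along(assigned_idx), find, integer(1))
  unname(lapply(split(assigned_idx, comp), as.integer))
}

# independent monophyly oracle: cut each internal edge of the phylo and
# collect tip descendants by recursive traversal of the child side
monophyly_oracle <- function(tree, subset) {
  ntip <- length(tree$tip.label)
  subset <- unique(subset)
  if (length(subset) <= 1 || length(subset) == ntip) return(TRUE)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips_under <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tips_under))
  }
  for (e in seq_len(nrow(tree$edge))) {
    side <- tips_under(tree$edge[e, 2])
    other <- setdiff(tree$tip.label, side)
    if (setequal(side, subset) || setequal(other, subset)) return(TRUE)
  }
  FALSE
}
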