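#' Construct a multiple-alignment object
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   (gap character `-`).
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return Object of class `t4_msa`: `labels`, `seqs`, `alphabet`.
#' @export
new_msa <- function(seqs, alphabet = "protein") {
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)),
            !anyDuplicated(names(seqs)))
  if (length(unique(nchar(seqs))) != 1)
    stop("aligned sequences must have equal length")
  structure(list(labels = names(seqs), seqs = unname(seqs),
                 alphabet = alphabet), class = "t4_msa")
}

# profile = list(rows = character matrix of aligned residues)
profile_freq <- function(rows, letters) {
  L <- ncol(rows)
  f <- matrix(0, nrow = length(letters), ncol = L, dimnames = list(letters))
  for (i in seq_len(nrow(rows))) {
    idx <- match(rows[i, ], letters)
    ok <- !is.na(idx)
    f[cbind(idx[ok], which(ok))] <- f[cbind(idx[ok], which(ok))] + 1
  }
  f / nrow(rows)
}

#' Progressive multiple alignment
#'
#' Deterministic progressive aligner: pairwise global-alignment identity
#' distances feed an average-linkage guide tree; profiles are merged
#' leaf-to-root by profile-profile global alignment (expected BLOSUM62
#' column score, affine gaps, end gaps penalised).  For two sequences the
#' result is exactly the optimal pairwise global alignment.  Intended for
#' the desk-scale protein sets this package analyses (tens of sequences); it
#' is a progressive stand-in for a full MSA program, adequate for the
#' conservation and distance summaries built on top of it.
#'
#' @param sequences Named character vector (>= 2 nonempty sequences).
#' @param gap_open,gap_extend Affine gap penalties (defaults 11, 1; a gap of
#'   length L costs `gap_open + gap_extend * L`).
#' @return A `t4_msa` with rows in input order.
#' @export
progressive_align <- function(sequences, gap_open = 11, gap_extend = 1) {
  n <- length(sequences)
  if (n < 2) stop("need at least 2 sequences to align")
  if (any(!nzchar(sequences))) stop("empty sequence")
  nm <- names(sequences)
  if (is.null(nm)) nm <- paste0("seq", seq_len(n))
  mat <- blosum62()
  letters20 <- rownames(mat)
  # guide distances: 1 - fractional identity of global alignments
  D <- matrix(0, n, n)
  if (n > 2) {
    for (i in seq_len(n - 1)) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(rep(sequences[i], n - i)),
        Biostrings::AAStringSet(sequences[(i + 1):n]),
        substitutionMatrix = mat, gapOpening = gap_open,
        gapExtension = gap_extend, type = "global")
      p <- Biostrings::pid(al, type = "PID1") / 100
      D[i, (i + 1):n] <- D[(i + 1):n, i] <- 1 - p
    }
  }
  profiles <- lapply(seq_len(n), function(i)
    matrix(strsplit(sequences[[i]], "")[[1]], nrow = 1,
           dimnames = list(nm[i])))
  merge_two <- function(pa, pb) {
    fa <- profile_freq(pa, letters20)
    fb <- profile_freq(pb, letters20)
    colscore <- t(fa) %*% mat %*% fb
    path <- .nw_profile_path(colscore, gap_open, gap_extend)
    ga <- matrix("-", nrow(pa), length(path$a), dimnames = list(rownames(pa)))
    gb <- matrix("-", nrow(pb), length(path$b), dimnames = list(rownames(pb)))
    ga[, path$a > 0] <- pa[, path$a[path$a > 0], drop = FALSE]
    gb[, path$b > 0] <- pb[, path$b[path$b > 0], drop = FALSE]
    rbind(ga, gb)
  }
  if (n == 2) {
    merged <- merge_two(profiles[[1]], profiles[[2]])
  } else {
    hc <- hclust(as.dist(D), method = "average")
    store <- vector("list", n - 1)
    for (s in seq_len(n - 1)) {
      get_prof <- function(k) if (k < 0) profiles[[-k]] else store[[k]]
      store[[s]] <- merge_two(get_prof(hc$merge[s, 1]),
                              get_prof(hc$merge[s, 2]))
    }
    merged <- store[[n - 1]]
  }
  aligned <- apply(merged, 1, paste, collapse = "")
  new_msa(aligned[nm], alphabet = "protein")
}

#' Pairwise evolutionary distances from an alignment
#'
#' p-distances over ungapped shared columns, optionally corrected:
#' `poisson` (protein): d = -ln(1 - p); `jc69` (nucleotide):
#' d = -(3/4) ln(1 - 4p/3); `p` leaves the raw proportion.
#'
#' @param msa A `t4_msa`.
#' @param correction `"p"`, `"poisson"` or `"jc69"`.
#' @param column_range Optional integer vector of alignment columns to use
#'   (e.g. the first 60 mature columns for an N-terminal-only pilin
#'   phylogeny).
#' @return Symmetric distance matrix with taxa labels.
#' @export
distance_matrix <- function(msa, correction = c("poisson", "p", "jc69"),
                            column_range = NULL) {
  correction <- match.arg(correction)
  m <- do.call(rbind, strsplit(msa$seqs, ""))
  rownames(m) <- msa$labels
  if (!is.null(column_range)) {
    column_range <- intersect(column_range, seq_len(ncol(m)))
    m <- m[, column_range, drop = FALSE]
  }
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(msa$labels, msa$labels))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    shared <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(shared)) stop("no shared ungapped columns for pair ",
                           msa$labels[i], " / ", msa$labels[j])
    p <- mean(m[i, shared] != m[j, shared])
    d <- switch(correction,
      p = p,
      poisson = {
        if (p >= 1) stop("saturated distance (p >= 1) for pair ",
                         msa$labels[i], " / ", msa$labels[j])
        -log(1 - p)
      },
      jc69 = {
        if (p >= 0.75) stop("saturated distance (p >= 3/4) for pair ",
                            msa$labels[i], " / ", msa$labels[j])
        -0.75 * log(1 - 4 * p / 3)
      })
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou–Nei neighbor joining on a symmetric nonnegative distance matrix;
#' for additive matrices the tree's path-length distances reproduce the
#' input exactly.  Negative branch lengths (a known NJ artefact on
#' non-additive input) are clamped to zero.
#'
#' @param d Symmetric distance matrix (>= 3 taxa) or `dist`.
#' @return An `ape::phylo` (unrooted).
#' @export
neighbor_joining <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(m < 0)) stop("distances must be nonnegative")
  tr <- ape::nj(m)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# canonical nontrivial bipartitions of an unrooted tree: each split is
# keyed by the sorted tip set on the side NOT containing the reference tip
tree_splits <- function(tree, ref = NULL) {
  tips <- tree$tip.label
  if (is.null(ref)) ref <- sort(tips)[1]
  pp <- ape::prop.part(tree)
  keys <- character(0)
  nodes <- integer(0)
  for (k in seq_along(pp)) {
    side <- tips[pp[[k]]]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) == 0 || length(side) >= length(tips) - 1) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, length(tips) + k)  # prop.part order = internal nodes
  }
  data.frame(key = keys, node = nodes, stringsAsFactors = FALSE)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the tree from the full alignment, then resamples alignment
#' columns with replacement `n_replicates` times; the support of an internal
#' edge is the percentage of replicate NJ trees containing its bipartition.
#' All replicate column draws come from one seeded stream drawn up front, so
#' results depend only on `seed` (100 replicates by default).
#'
#' @param msa A `t4_msa` with >= 4 taxa.
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param correction Distance correction (see [distance_matrix()]).
#' @param column_range Optional column restriction applied to the base tree
#'   and every replicate (resampling is within the restricted columns).
#' @return The base `phylo` with `node.label` carrying support percentages
#'   (root/trivial nodes `NA`).
#' @export
bootstrap_support <- function(msa, n_replicates = 100, seed = 1,
                              correction = "poisson", column_range = NULL) {
  if (length(msa$labels) < 4) stop("bootstrap needs at least 4 taxa")
  cols <- if (is.null(column_range)) seq_len(nchar(msa$seqs[1])) else
    intersect(column_range, seq_len(nchar(msa$seqs[1])))
  base <- neighbor_joining(distance_matrix(msa, correction,
                                           column_range = cols))
  splits <- tree_splits(base)
  counts <- setNames(numeric(nrow(splits)), splits$key)
  chars <- do.call(rbind, strsplit(msa$seqs, ""))[, cols, drop = FALSE]
  rownames(chars) <- msa$labels
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  L <- length(cols)
  draws <- matrix(sample.int(L, n_replicates * L, replace = TRUE),
                  nrow = n_replicates)
  ok_reps <- 0L
  for (r in seq_len(n_replicates)) {
    rep_m <- chars[, draws[r, ], drop = FALSE]
    rep_msa <- new_msa(setNames(apply(rep_m, 1, paste, collapse = ""),
                                msa$labels))
    tr <- tryCatch(neighbor_joining(distance_matrix(rep_msa, correction)),
                   error = function(e) NULL)
    if (is.null(tr)) next  # saturated replicate: skipped, not counted
    ok_reps <- ok_reps + 1L
    rk <- tree_splits(tr, ref = sort(msa$labels)[1])$key
    hit <- splits$key %in% rk
    counts[hit] <- counts[hit] + 1
  }
  support <- if (ok_reps > 0) 100 * counts / ok_reps else counts * NA
  nl <- rep(NA_real_, base$Nnode)
  nl[splits$node - length(base$tip.label)] <- support
  base$node.label <- ifelse(is.na(nl), "", format(round(nl, 1), trim = TRUE))
  attr(base, "support") <- setNames(as.numeric(support), splits$key)
  base
}

#' Test monophyly of a taxon subset on an unrooted tree
#'
#' True iff some internal edge's bipartition isolates exactly the subset.
#' Singletons and the full tip set are trivially monophyletic.  When the
#' tree carries bootstrap supports (from [bootstrap_support()]) the defining
#' edge's support is attached.
#'
#' @param tree An `ape::phylo`.
#' @param taxon_subset Nonempty character vector of tip labels.
#' @return List: `is_monophyletic`, `support_pct` (`NA` when unavailable or
#'   trivial).
#' @export
test_monophyly <- function(tree, taxon_subset) {
  stopifnot(length(taxon_subset) >= 1)
  unknown <- setdiff(taxon_subset, tree$tip.label)
  if (length(unknown) > 0)
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  taxon_subset <- unique(taxon_subset)
  n <- length(tree$tip.label)
  if (length(taxon_subset) <= 1 || length(taxon_subset) == n)
    return(list(is_monophyletic = TRUE, support_pct = NA_real_))
  ref <- sort(tree$tip.label)[1]
  side <- if (ref %in% taxon_subset) setdiff(tree$tip.label, taxon_subset)
  else taxon_subset
  key <- paste(sort(side), collapse = "|")
  # pendant-edge bipartitions (1 vs n-1 tips) are always present
  if (length(side) <= 1 || length(side) >= n - 1)
    return(list(is_monophyletic = TRUE, support_pct = NA_real_))
  splits <- tree_splits(tree)
  hit <- match(key, splits$key)
  if (is.na(hit)) return(list(is_monophyletic = FALSE,
                              support_pct = NA_real_))
  sup <- attr(tree, "support")
  list(is_monophyletic = TRUE,
       support_pct = if (!is.null(sup)) unname(sup[key]) else NA_real_)
}

#' Write a tree with supports to Newick
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tree_newick <- function(tree, path) {
  con <- file(path, open = "wb")
  writeLines(ape::write.tree(tree), con)
  close(con)
  invisible(path)
}

#' Write an alignment to FASTA
#' @param msa A `t4_msa`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_msa_fasta <- function(msa, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(msa$seqs, msa$labels)), path)
  invisible(path)
}

#' Read an aligned FASTA into a `t4_msa`
#' @param path FASTA file of equal-length aligned sequences.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return A `t4_msa`.
#' @export
read_msa_fasta <- function(path, alphabet = "protein") {
  aa <- Biostrings::readAAStringSet(path)
  new_msa(setNames(as.character(aa),
                   vapply(strsplit(names(aa), "\\s+"), `[`, "", 1)),
          alphabet = alphabet)
}
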