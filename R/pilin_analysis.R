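#' Locate the prepilin (PilD) cleavage site
#'
#' Pilins are made as prepilins whose class-III signal peptide is removed by
#' the PilD peptidase just before a conserved glycine-phenylalanine motif.
#' The default motif `G[FY][ST]L[ILMV]E` is the canonical prepilin consensus;
#' cleavage occurs after the motif's glycine, so the mature sequence begins
#' with the residue following it.  Only the leftmost motif match starting
#' within the first `search_window` residues counts.
#'
#' @param sequence Amino-acid sequence (prepilin).
#' @param motif Regular expression; its first character class must cover the
#'   glycine (default `"G[FY][ST]L[ILMV]E"`).
#' @param search_window Motif must start at or before this 1-based position
#'   (default 50).
#' @return 1-based position of the cleaved glycine, or `NA_integer_` when no
#'   motif is found in the window.  The mature sequence is
#'   `substring(sequence, pos + 1)`.
#' @export
find_cleavage_site <- function(sequence, motif = "G[FY][ST]L[ILMV]E",
                               search_window = 50) {
  m <- regexpr(motif, sequence)
  pos <- as.integer(m)
  if (pos < 1 || pos > search_window) return(NA_integer_)
  pos
}

#' Mature pilin sequence after cleavage
#' @param sequence Prepilin sequence.
#' @param cleavage_pos Result of [find_cleavage_site()]; `NA` returns the
#'   sequence unchanged.
#' @return Mature amino-acid sequence.
#' @export
mature_sequence <- function(sequence, cleavage_pos) {
  if (is.na(cleavage_pos)) return(sequence)
  substring(sequence, cleavage_pos + 1)
}

#' N-terminal conservation profile of mature pilins
#'
#' Aligns the mature sequences ([progressive_align()]), then computes the
#' per-column modal-residue fraction: the count of the most frequent
#' non-gap residue divided by the number of sequences.  `window_mean` is the
#' mean over the first `window` columns — mature pilins are strongly
#' conserved over roughly their first 60 residues (the filament-core
#' alpha-helix) while C-terminal domains diverge.
#'
#' @param mature_sequences Named character vector (>= 2 sequences).
#' @param window Number of leading alignment columns (default 60).
#' @return List of class `t4_conservation`: `column_fraction` (numeric per
#'   column), `window_mean`, `rest_mean` (mean over remaining columns, `NA`
#'   if none), `alignment` (the `t4_msa`).
#' @export
nterm_conservation <- function(mature_sequences, window = 60) {
  if (length(mature_sequences) < 2)
    stop("need at least 2 sequences for a conservation profile")
  msa <- progressive_align(mature_sequences)
  m <- do.call(rbind, strsplit(msa$seqs, ""))
  frac <- apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return(0)
    max(table(col)) / nrow(m)
  })
  w <- seq_len(min(window, length(frac)))
  structure(list(column_fraction = as.numeric(frac),
                 window_mean = mean(frac[w]),
                 rest_mean = if (length(frac) > length(w))
                   mean(frac[-w]) else NA_real_,
                 alignment = msa),
            class = "t4_conservation")
}

#' Detect the disulfide-bonded loop (DSL) cysteine pair
#'
#' Major pilins typically terminate in a Cys-bounded loop (the D-region)
#' mediating surface attachment; some lineages instead carry the Cys pair in
#' the middle of the C-terminal domain.  Cysteines in the C-terminal
#' `cterm_fraction` of the mature sequence are considered; among pairs whose
#' separation (index difference) lies in `[min_loop, max_loop]`, the last
#' such pair defines the loop.  The class is `terminal_dsl` when the
#' downstream Cys lies within `terminal_window` residues of the C-terminus,
#' `mid_cterm_pair` otherwise, and `none` without a qualifying pair.
#'
#' @param mature_seq Nonempty mature amino-acid sequence.
#' @param cterm_fraction Fraction of the sequence scanned from the C-terminus
#'   (default 0.5).
#' @param min_loop,max_loop Allowed Cys separation (defaults 6, 60).
#' @param terminal_window Distance from the C-terminus defining a terminal
#'   loop (default 15).
#' @return List: `cys_positions` (all Cys in the scanned region, 1-based on
#'   the mature sequence), `loop` (the defining pair, or `NULL`),
#'   `dsl_class` in `{"terminal_dsl", "mid_cterm_pair", "none"}`.
#' @export
find_dsl <- function(mature_seq, cterm_fraction = 0.5, min_loop = 6,
                     max_loop = 60, terminal_window = 15) {
  stopifnot(nzchar(mature_seq))
  L <- nchar(mature_seq)
  region_start <- floor(L * (1 - cterm_fraction)) + 1L
  chars <- strsplit(mature_seq, "")[[1]]
  cys <- which(chars == "C")
  cys <- cys[cys >= region_start]
  loop <- NULL
  if (length(cys) >= 2) {
    best <- NULL
    for (j in rev(seq_along(cys))) {
      for (i in rev(seq_len(j - 1))) {
        sep <- cys[j] - cys[i]
        if (sep >= min_loop && sep <= max_loop) { best <- c(cys[i], cys[j]); break }
      }
      if (!is.null(best)) break
    }
    loop <- best
  }
  cls <- if (is.null(loop)) "none"
  else if (L - loop[2] <= terminal_window) "terminal_dsl"
  else "mid_cterm_pair"
  list(cys_positions = cys, loop = loop, dsl_class = cls)
}

#' Pairwise identity and similarity among pilin paralogs
#'
#' Global (Needleman–Wunsch) alignment of every pair under BLOSUM62 with
#' affine gaps; identity and similarity are percentages of alignment columns
#' (gaps included), diagonals are 100.  Used to read off signatures such as
#' tandem duplicates sharing high similarity versus distantly related
#' paralogs.
#'
#' @param pilin_sequences Named character vector (>= 2 sequences).
#' @param gap_open,gap_extend Affine gap penalties (defaults 11, 1).
#' @return List of symmetric matrices `identity` and `similarity`.
#' @export
paralog_matrix <- function(pilin_sequences, gap_open = 11, gap_extend = 1) {
  n <- length(pilin_sequences)
  if (n < 2) stop("need at least 2 sequences")
  nm <- names(pilin_sequences)
  if (is.null(nm)) nm <- paste0("seq", seq_len(n))
  mat <- blosum62()
  idm <- simm <- matrix(100, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(pilin_sequences[[i]]),
      Biostrings::AAString(pilin_sequences[[j]]),
      substitutionMatrix = mat, gapOpening = gap_open,
      gapExtension = gap_extend, type = "global")
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    cols <- length(pa)
    both <- pa != "-" & sa != "-"
    pos <- logical(cols)
    pos[both] <- mat[cbind(pa[both], sa[both])] > 0
    idm[i, j] <- idm[j, i] <- 100 * sum(both & pa == sa) / cols
    simm[i, j] <- simm[j, i] <- 100 * sum(pos) / cols
  }
  list(identity = idm, similarity = simm)
}

#' Pilin feature table for a genome
#'
#' Runs cleavage-site detection and DSL classification on every gene
#' assigned to a pilin family (default: pilA) and records whether the gene
#' sits inside a main T4aP cluster.  DSL classification operates on the
#' mature sequence, so it is invariant to the signal peptide.
#'
#' @param genome A `t4_genome`.
#' @param assignments Assignment table.
#' @param clusters Classified clusters of the genome.
#' @param family Pilin family to profile (default `"pilA"`).
#' @param motif,search_window Cleavage parameters (see
#'   [find_cleavage_site()]).
#' @param cterm_fraction,min_loop,max_loop,terminal_window DSL parameters
#'   (see [find_dsl()]).
#' @return `data.frame`: `gene_id`, `cleavage_pos`, `nterm_extension_len`
#'   (residues preceding the cleaved glycine), `n_cys`, `dsl_class`,
#'   `in_t4ap_cluster`.
#' @export
pilin_features <- function(genome, assignments, clusters, family = "pilA",
                           motif = "G[FY][ST]L[ILMV]E", search_window = 50,
                           cterm_fraction = 0.5, min_loop = 6, max_loop = 60,
                           terminal_window = 15) {
  ids <- assignments$gene_id[assignments$family == family]
  main_ids <- unlist(lapply(clusters, function(cl)
    if (identical(cl$label, "main")) cl$members$gene_id else character(0)))
  rows <- lapply(ids, function(gid) {
    seq <- genome$proteins[[gid]]
    if (is.null(seq) || !nzchar(seq))
      return(data.frame(gene_id = gid, cleavage_pos = NA_integer_,
                        nterm_extension_len = NA_integer_, n_cys = NA_integer_,
                        dsl_class = NA_character_,
                        in_t4ap_cluster = gid %in% main_ids,
                        stringsAsFactors = FALSE))
    cp <- find_cleavage_site(seq, motif, search_window)
    mat <- mature_sequence(seq, cp)
    dsl <- find_dsl(mat, cterm_fraction, min_loop, max_loop, terminal_window)
    data.frame(gene_id = gid, cleavage_pos = cp,
               nterm_extension_len = if (is.na(cp)) NA_integer_ else cp - 1L,
               n_cys = length(dsl$cys_positions), dsl_class = dsl$dsl_class,
               in_t4ap_cluster = gid %in% main_ids, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    gene_id = character(0), cleavage_pos = integer(0),
    nterm_extension_len = integer(0), n_cys = integer(0),
    dsl_class = character(0), in_t4ap_cluster = logical(0),
    stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}
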