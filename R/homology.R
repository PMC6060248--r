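#' The T4aP family roster
#'
#' Families searched by the pipeline and their roles.  The core set
#' (pilA, pilB, pilC, pilD, pilM, pilN, pilO, pilP, pilQ, pilT) encodes the
#' main machinery components; fimU/pilV/pilW/pilX/pilE are the minor pilins
#' that form a priming subcomplex with the adhesin PilY1; pilRS is the
#' two-component regulator pair detected as one combined family (it resembles
#' the genome's many other regulators — positional resolution into
#' pilR1S1/pilR2S2 happens inside detected clusters); ribF (riboflavin
#' kinase) is a synteny anchor, never a cluster member; decoy families are
#' T2SS-like paralogs used competitively and are never reportable
#' assignments.
#'
#' @param decoys Include the T2SS decoy families (default `TRUE`).
#' @return `data.frame` with columns `family`, `role`.
#' @export
family_roster <- function(decoys = TRUE) {
  core <- c("pilA", "pilB", "pilC", "pilD", "pilM", "pilN", "pilO", "pilP",
            "pilQ", "pilT")
  minor <- c("fimU", "pilV", "pilW", "pilX", "pilE")
  noncore <- c("pilF", "pilG", "pilH", "pilI", "pilY1", "tsaP")
  df <- rbind(
    data.frame(family = core, role = "core", stringsAsFactors = FALSE),
    data.frame(family = minor, role = "minor_pilin", stringsAsFactors = FALSE),
    data.frame(family = noncore, role = "noncore", stringsAsFactors = FALSE),
    data.frame(family = "pilRS", role = "regulatory", stringsAsFactors = FALSE),
    data.frame(family = "ribF", role = "anchor", stringsAsFactors = FALSE))
  if (decoys)
    df <- rbind(df, data.frame(family = c("t2ssE", "t2ssF", "t2ssO"),
                               role = "decoy", stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

#' Families considered core T4aP genes
#' @return Character vector of the ten core family names.
#' @export
core_families <- function() {
  r <- family_roster(decoys = FALSE)
  r$family[r$role == "core"]
}

#' Default homology filter thresholds
#'
#' Hits must satisfy all three: E-value at most `max_evalue`, query coverage
#' (relative to the reference/query sequence) at least
#' `min_query_coverage_pct`, and similarity (percent positive-scoring aligned
#' pairs over alignment columns, gaps included) at least
#' `min_similarity_pct`.  Defaults: 1e-5 / 35 / 35.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(max_evalue = 1e-5, min_query_coverage_pct = 35, min_similarity_pct = 35)
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Optimal local alignment of two protein sequences
#'
#' Smith–Waterman local alignment under BLOSUM62 with affine gaps (a gap of
#' length L costs `gap_open + gap_extend * L`).  A score of 0 means no
#' positive-scoring alignment exists (the empty alignment).  The bit score is
#' a configurable linear rescaling of the raw score used only by the
#' simplified E-value model.
#'
#' @param seq_a,seq_b Nonempty amino-acid sequences (seq_a is the
#'   query/reference).
#' @param substitution_matrix Scoring matrix (default BLOSUM62).
#' @param gap_open,gap_extend Affine gap penalties (defaults 11, 1).
#' @param bits_per_raw Raw-score to bit-score factor (default 0.5).
#' @return List with `score_raw`, `score_bits`, aligned strings
#'   `pattern_aligned`/`subject_aligned` and 1-based span coordinates
#'   `pattern_start`/`pattern_end`/`subject_start`/`subject_end` (0 when the
#'   optimal alignment is empty).
#' @export
local_align <- function(seq_a, seq_b, substitution_matrix = blosum62(),
                        gap_open = 11, gap_extend = 1, bits_per_raw = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "local")
  sc <- Biostrings::score(al)
  if (sc <= 0) {
    return(list(score_raw = max(sc, 0), score_bits = 0,
                pattern_aligned = "", subject_aligned = "",
                pattern_start = 0L, pattern_end = 0L,
                subject_start = 0L, subject_end = 0L))
  }
  pa <- Biostrings::pattern(al)
  sa <- Biostrings::subject(al)
  list(score_raw = sc, score_bits = sc * bits_per_raw,
       pattern_aligned = as.character(Biostrings::alignedPattern(al)),
       subject_aligned = as.character(Biostrings::alignedSubject(al)),
       pattern_start = Biostrings::start(pa), pattern_end = Biostrings::end(pa),
       subject_start = Biostrings::start(sa), subject_end = Biostrings::end(sa))
}

#' Simplified E-value for a local alignment score
#'
#' `E = query_len * db_len * 2^(-score_bits)`: the expected number of chance
#' hits at this bit score in a search space of that size.  A deliberate
#' simplification of Karlin–Altschul statistics — only relative cutoff
#' behaviour matters at panel scale; the bit scaling is configurable in
#' [local_align()].
#'
#' @param score_bits Bit score.
#' @param query_len,db_len Positive sequence lengths.
#' @return E-value (monotone decreasing in `score_bits`).
#' @export
estimate_evalue <- function(score_bits, query_len, db_len) {
  if (any(query_len <= 0) || any(db_len <= 0))
    stop("query_len and db_len must be positive")
  query_len * db_len * 2^(-score_bits)
}

#' Score a local alignment as a homology hit
#'
#' Similarity is the percentage of alignment columns (gaps included) whose
#' aligned pair has a positive substitution score; identity is the analogous
#' percentage of exact matches; query coverage is the aligned span on the
#' reference divided by the reference length.
#'
#' @param family Family of the reference sequence.
#' @param gene_id Gene whose protein was the subject.
#' @param aln Result of [local_align()] (reference as `seq_a`).
#' @param reference_length Full length of the reference sequence.
#' @param query_len,db_len Lengths for the E-value model (default: reference
#'   and subject lengths).
#' @param substitution_matrix Matrix used to define positive pairs.
#' @return One-row `data.frame` (a HomologyHit).
#' @export
score_hit <- function(family, gene_id, aln, reference_length,
                      query_len = reference_length, db_len = NULL,
                      substitution_matrix = blosum62()) {
  pa <- strsplit(aln$pattern_aligned, "")[[1]]
  sa <- strsplit(aln$subject_aligned, "")[[1]]
  cols <- length(pa)
  if (cols == 0) {
    idp <- simp <- cov <- 0
  } else {
    both <- pa != "-" & sa != "-"
    pos <- logical(cols)
    pos[both] <- substitution_matrix[cbind(pa[both], sa[both])] > 0
    idp <- 100 * sum(both & pa == sa) / cols
    simp <- 100 * sum(pos) / cols
    cov <- 100 * (aln$pattern_end - aln$pattern_start + 1) / reference_length
  }
  if (is.null(db_len)) db_len <- max(aln$subject_end, 1L)
  data.frame(query_family = family, gene_id = gene_id,
             bitscore = aln$score_bits,
             evalue = estimate_evalue(aln$score_bits, query_len, db_len),
             identity_pct = idp, similarity_pct = simp,
             query_coverage_pct = cov,
             stringsAsFactors = FALSE)
}

#' Assign genes to T4aP families against a reference panel
#'
#' Every reference is locally aligned to every translated gene; hits passing
#' all three thresholds (conjunctively) are collected and the winner per gene
#' is the highest bit score (ties: lower E-value, then alphabetical family).
#' If the winning family is a decoy (T2SS-like paralog) the gene is reported
#' UNASSIGNED with `excluded_as_decoy = TRUE` — decoys compete but are never
#' reportable.  Genes with no passing hit (including untranslated genes) are
#' UNASSIGNED.  Assignment is deterministic and independent of gene order.
#'
#' A fast score-only pass computes all raw scores first; full alignments are
#' only made for references whose score could pass the E-value cutoff.
#'
#' @param genome A `t4_genome`.
#' @param panel Reference panel `data.frame` with columns `name`, `family`,
#'   `role`, `seq` (see [generate_panel()], [read_panel()]).
#' @param thresholds List as [default_thresholds()].
#' @param gap_open,gap_extend,bits_per_raw Alignment parameters.
#' @return `data.frame` with one row per gene: `gene_id`, `family`
#'   (`"UNASSIGNED"` when none), `excluded_as_decoy`, `hit_family` (winning
#'   family before decoy exclusion, `NA` if none), `bitscore`, `evalue`,
#'   `identity_pct`, `similarity_pct`, `query_coverage_pct`.
#' @export
assign_families <- function(genome, panel, thresholds = default_thresholds(),
                            gap_open = 11, gap_extend = 1, bits_per_raw = 0.5) {
  if (nrow(panel) == 0 || !any(panel$role != "decoy"))
    stop("reference panel must contain at least one non-decoy family")
  mat <- blosum62()
  refs <- Biostrings::AAStringSet(setNames(panel$seq, panel$name))
  ref_len <- nchar(panel$seq)
  genes <- genome$genes$gene_id
  empty_hit <- function(gid) data.frame(
    gene_id = gid, family = "UNASSIGNED", excluded_as_decoy = FALSE,
    hit_family = NA_character_, bitscore = NA_real_, evalue = NA_real_,
    identity_pct = NA_real_, similarity_pct = NA_real_,
    query_coverage_pct = NA_real_, stringsAsFactors = FALSE)
  rows <- lapply(genes, function(gid) {
    prot <- genome$proteins[[gid]]
    if (is.null(prot) || is.na(prot) || !nzchar(prot)) return(empty_hit(gid))
    # coverage feasibility screen: a reference whose required aligned span
    # (min coverage) exceeds 1.5x the protein length can never pass the
    # conjunctive filter, so its alignment is skipped outright
    feasible <- ref_len * (thresholds$min_query_coverage_pct / 100) <=
      nchar(prot) * 1.5
    if (!any(feasible)) return(empty_hit(gid))
    scores <- rep(-Inf, length(ref_len))
    scores[feasible] <- Biostrings::pairwiseAlignment(
      refs[feasible], Biostrings::AAString(prot), substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend,
      type = "local", scoreOnly = TRUE)
    bits <- pmax(scores, 0) * bits_per_raw
    ev <- estimate_evalue(bits, ref_len, nchar(prot))
    cand <- which(scores > 0 & ev <= thresholds$max_evalue)
    if (length(cand) == 0) return(empty_hit(gid))
    # winner = highest bitscore among passing hits (ties: lower E-value,
    # then alphabetical family).  Bitscores are already known from the
    # score-only pass, so walking candidates in winner order and stopping at
    # the first one that passes the coverage/similarity thresholds yields
    # the same assignment without aligning every candidate in full.
    cand <- cand[order(-scores[cand], ev[cand], panel$family[cand],
                       panel$name[cand])]
    w <- NULL
    for (i in cand) {
      aln <- local_align(panel$seq[i], prot, mat, gap_open, gap_extend,
                         bits_per_raw)
      h <- score_hit(panel$family[i], gid, aln, ref_len[i],
                     query_len = ref_len[i], db_len = nchar(prot),
                     substitution_matrix = mat)
      if (h$evalue <= thresholds$max_evalue &&
          h$query_coverage_pct >= thresholds$min_query_coverage_pct &&
          h$similarity_pct >= thresholds$min_similarity_pct) {
        h$role <- panel$role[i]
        w <- h
        break
      }
    }
    if (is.null(w)) return(empty_hit(gid))
    decoy <- w$role == "decoy"
    data.frame(gene_id = gid,
               family = if (decoy) "UNASSIGNED" else w$query_family,
               excluded_as_decoy = decoy,
               hit_family = w$query_family, bitscore = w$bitscore,
               evalue = w$evalue, identity_pct = w$identity_pct,
               similarity_pct = w$similarity_pct,
               query_coverage_pct = w$query_coverage_pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(empty_hit("..template..")[0, ])))
  rownames(out) <- NULL
  out
}

#' Read a reference panel from FASTA
#'
#' Headers carry `family|role|name` as the first whitespace-delimited token.
#'
#' @param path FASTA file.
#' @return Panel `data.frame` (`name`, `family`, `role`, `seq`).
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel FASTA not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  tok <- strsplit(vapply(strsplit(names(aa), "\\s+"), `[`, "", 1), "|",
                  fixed = TRUE)
  if (any(lengths(tok) < 2))
    stop("panel FASTA headers must be 'family|role' or 'family|role|name'")
  data.frame(
    name = vapply(tok, function(x) if (length(x) >= 3) x[3] else
      paste0(x[1], "_1"), ""),
    family = vapply(tok, `[`, "", 1),
    role = vapply(tok, `[`, "", 2),
    seq = as.character(aa), stringsAsFactors = FALSE)
}

#' Write a reference panel to FASTA
#' @param panel Panel `data.frame`.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  aa <- Biostrings::AAStringSet(setNames(
    panel$seq, paste(panel$family, panel$role, panel$name, sep = "|")))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
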