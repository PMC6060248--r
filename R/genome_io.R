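#' Construct an annotated genome object
#'
#' The coordinate and identity model used throughout pilarch.  A genome is a
#' set of contigs carrying stranded gene features (1-based inclusive
#' coordinates, GFF3 convention) plus a table of translated protein sequences.
#' All neighbourhood computations in the package use `locus_index` — the
#' 0-based rank of a gene on its contig ordered by start — never nucleotide
#' distance: cluster membership is defined by counts of intervening genes.
#'
#' @param genome_id Unique genome identifier.
#' @param taxon_label Display label used in tree/annotation exports
#'   (defaults to `genome_id`).
#' @param contigs `data.frame` with columns `contig_id`, `length` (nt).
#' @param genes `data.frame` with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`), `product` (free text, may be `""`).
#'   `locus_index` is (re)computed here.
#' @param proteins Named character vector of amino-acid sequences; names are
#'   gene ids.  Genes may lack a translation (they still occupy a locus and
#'   count as intervening genes).
#' @return An object of class `t4_genome`.
#' @export
new_genome <- function(genome_id, taxon_label = genome_id, contigs, genes,
                       proteins = character(0)) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  contigs <- as.data.frame(contigs, stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(genes) > 0 && anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in genome '", genome_id, "': ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  genes <- assign_locus_index(genes, contigs$contig_id)
  g <- structure(list(genome_id = genome_id, taxon_label = taxon_label,
                      contigs = contigs, genes = genes,
                      proteins = proteins),
                 class = "t4_genome")
  validate_genome(g)
  g
}

# order genes by (contig in declared order, start) and assign 0-based rank
assign_locus_index <- function(genes, contig_order) {
  if (nrow(genes) == 0) {
    genes$locus_index <- integer(0)
    return(genes)
  }
  genes$contig_id <- as.character(genes$contig_id)
  ord <- order(match(genes$contig_id, contig_order), genes$start)
  genes <- genes[ord, , drop = FALSE]
  genes$locus_index <- stats::ave(seq_len(nrow(genes)), genes$contig_id,
                                  FUN = seq_along) - 1L
  rownames(genes) <- NULL
  genes
}

#' Validate a genome object's invariants
#'
#' Checks coordinate sanity (start <= end, ends within contig length),
#' consecutive per-contig locus indices, unique gene ids, and that every
#' protein key matches a gene feature and uses the 20-letter amino-acid
#' alphabet plus X.
#'
#' @param genome A `t4_genome`.
#' @return `genome`, invisibly; errors on violation.
#' @export
validate_genome <- function(genome) {
  stopifnot(inherits(genome, "t4_genome"))
  g <- genome$genes
  if (nrow(g) > 0) {
    if (any(g$start > g$end)) stop("gene with start > end")
    if (!all(g$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (anyDuplicated(g$gene_id)) stop("duplicate gene_id")
    if (!all(g$contig_id %in% genome$contigs$contig_id))
      stop("gene on undeclared contig")
    len <- setNames(genome$contigs$length, genome$contigs$contig_id)
    if (any(g$end > len[g$contig_id])) stop("gene end exceeds contig length")
    for (ct in unique(g$contig_id)) {
      li <- sort(g$locus_index[g$contig_id == ct])
      if (!identical(as.integer(li), seq_along(li) - 1L))
        stop("locus_index not consecutive on contig ", ct)
    }
  }
  if (length(genome$proteins) > 0) {
    if (!all(names(genome$proteins) %in% g$gene_id))
      stop("protein without matching gene feature")
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]",
                 genome$proteins[nzchar(genome$proteins)])
    if (any(bad)) stop("protein sequence outside amino-acid alphabet (20 + X)")
  }
  invisible(genome)
}

#' Read an annotated genome from GFF3 + protein FASTA
#'
#' Gene features are taken from rows of type `gene` (or `CDS` when no `gene`
#' rows are present); the `ID` attribute is the gene id and must be unique.
#' Contigs come from `##sequence-region` pragmas plus any contig carrying a
#' feature (length then defaults to the last gene end).  FASTA headers carry
#' the gene id as the first whitespace-delimited token.  Genes lacking a
#' protein sequence are retained with an empty sequence and a warning.
#'
#' @param gff3_path Path to a GFF3 file.
#' @param protein_fasta_path Path to the matching protein FASTA (optional).
#' @param genome_id Genome identifier; defaults to the GFF3 basename.
#' @param taxon_label Taxon display label; defaults to `genome_id`.
#' @return A `t4_genome`.
#' @export
read_genome <- function(gff3_path, protein_fasta_path = NULL,
                        genome_id = sub("\\.gff3?$", "", basename(gff3_path)),
                        taxon_label = genome_id) {
  lines <- readLines(gff3_path)
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1]]
    stop("malformed GFF3 line ", bad, " in ", gff3_path,
         ": expected 9 tab-separated fields")
  }
  sr <- lines[grepl("^##sequence-region", lines)]
  contigs <- data.frame(contig_id = character(0), length = integer(0),
                        stringsAsFactors = FALSE)
  if (length(sr) > 0) {
    tok <- strsplit(trimws(sr), "\\s+")
    contigs <- data.frame(contig_id = vapply(tok, `[`, "", 2),
                          length = as.integer(vapply(tok, `[`, "", 4)),
                          stringsAsFactors = FALSE)
  }
  genes <- data.frame(gene_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), product = character(0),
                      stringsAsFactors = FALSE)
  if (any(body)) {
    gr <- rtracklayer::import(gff3_path, format = "gff3")
    type <- as.character(gr$type)
    keep <- if (any(type == "gene")) type == "gene" else type == "CDS"
    gr <- gr[keep]
    if (length(gr) > 0) {
      ids <- as.character(gr$ID)
      if (anyNA(ids) || any(!nzchar(ids)))
        stop("GFF3 feature without ID attribute in ", gff3_path)
      if (anyDuplicated(ids))
        stop("duplicate gene_id in ", gff3_path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
      prod <- if (!is.null(gr$product)) as.character(gr$product) else
        rep("", length(gr))
      prod[is.na(prod)] <- ""
      genes <- data.frame(gene_id = ids,
                          contig_id = as.character(GenomicRanges::seqnames(gr)),
                          start = GenomicRanges::start(gr),
                          end = GenomicRanges::end(gr),
                          strand = as.character(GenomicRanges::strand(gr)),
                          product = prod, stringsAsFactors = FALSE)
    }
  }
  # contigs seen only through features: length defaults to last gene end
  extra <- setdiff(unique(genes$contig_id), contigs$contig_id)
  if (length(extra) > 0) {
    lens <- vapply(extra, function(ct) max(genes$end[genes$contig_id == ct]), 0)
    contigs <- rbind(contigs, data.frame(contig_id = extra, length = as.integer(lens),
                                         stringsAsFactors = FALSE))
  }
  proteins <- character(0)
  if (!is.null(protein_fasta_path) && file.exists(protein_fasta_path)) {
    aa <- Biostrings::readAAStringSet(protein_fasta_path)
    proteins <- as.character(aa)
    names(proteins) <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1)
    unknown <- setdiff(names(proteins), genes$gene_id)
    if (length(unknown) > 0) {
      warning("dropping ", length(unknown),
              " protein sequence(s) without a gene feature")
      proteins <- proteins[!names(proteins) %in% unknown]
    }
  }
  missing_prot <- setdiff(genes$gene_id, names(proteins))
  if (length(missing_prot) > 0 && nrow(genes) > 0) {
    if (length(proteins) > 0 || !is.null(protein_fasta_path))
      warning(length(missing_prot), " gene(s) lack a protein sequence; ",
              "kept with empty sequence")
    proteins <- c(proteins, setNames(rep("", length(missing_prot)), missing_prot))
  }
  new_genome(genome_id, taxon_label, contigs, genes, proteins)
}

#' Write a genome to GFF3 + protein FASTA
#'
#' Emits a `##gff-version 3` pragma, one `##sequence-region` pragma per
#' contig, and one `gene` line per feature (attributes carry `ID` and
#' `product`), ordered by contig (input order) then start.  Output is
#' deterministic.  Empty protein sequences are omitted from the FASTA.
#'
#' @param genome A `t4_genome`.
#' @param gff3_path Output GFF3 path.
#' @param protein_fasta_path Output protein FASTA path (optional).
#' @return Invisibly, the GFF3 path.
#' @export
write_genome <- function(genome, gff3_path, protein_fasta_path = NULL) {
  validate_genome(genome)
  g <- genome$genes
  out <- "##gff-version 3"
  if (nrow(genome$contigs) > 0 && nrow(g) > 0) {
    used <- genome$contigs[genome$contigs$contig_id %in% g$contig_id, ,
                           drop = FALSE]
    out <- c(out, sprintf("##sequence-region %s 1 %d", used$contig_id,
                          used$length))
    gr <- GenomicRanges::GRanges(
      seqnames = g$contig_id,
      ranges = IRanges::IRanges(start = g$start, end = g$end),
      strand = g$strand)
    gr$type <- "gene"
    gr$ID <- g$gene_id
    gr$product <- g$product
    tmp <- tempfile(fileext = ".gff3")
    rtracklayer::export(gr, tmp, format = "gff3")
    feat <- readLines(tmp)
    unlink(tmp)
    feat <- feat[!grepl("^#", feat) & nzchar(feat)]
    out <- c(out, feat)
  }
  con <- file(gff3_path, open = "wb")  # binary: stable newlines
  writeLines(out, con)
  close(con)
  if (!is.null(protein_fasta_path)) {
    pr <- genome$proteins[g$gene_id]
    pr <- pr[!is.na(pr) & nzchar(pr)]
    Biostrings::writeXStringSet(Biostrings::AAStringSet(pr),
                                protein_fasta_path)
  }
  invisible(gff3_path)
}

#' Write an iTOL DATASET_BINARY presence/absence annotation
#'
#' Maps per-genome family presence onto a phylogenetic-tree visualisation in
#' the iTOL binary-dataset text format.  Entries must be `1` (present) or
#' `-1` (absent).  Rows are emitted in table order; ordering is stable.
#'
#' @param presence Integer matrix (or data.frame) with one row per genome and
#'   one column per family; rownames are genome ids, colnames family names.
#' @param path Output path.
#' @param genomes Optional list of `t4_genome` objects used to map genome ids
#'   to taxon labels; otherwise rownames are used as labels.
#' @param label Dataset label shown in iTOL.
#' @return Invisibly, `path`.
#' @export
write_itol_binary <- function(presence, path, genomes = NULL,
                              label = "T4aP families") {
  m <- as.matrix(presence)
  if (length(m) > 0 && !all(m %in% c(1L, -1L)))
    stop("presence entries must be 1 (present) or -1 (absent)")
  fams <- colnames(m)
  labs <- rownames(m)
  if (!is.null(genomes)) {
    tl <- vapply(genomes, function(g) g$taxon_label, "")
    names(tl) <- vapply(genomes, function(g) g$genome_id, "")
    hit <- labs %in% names(tl)
    labs[hit] <- tl[labs[hit]]
  }
  out <- c("DATASET_BINARY", "SEPARATOR TAB",
           paste0("DATASET_LABEL\t", label),
           "COLOR\t#1f78b4",
           paste0("FIELD_SHAPES\t", paste(rep("1", length(fams)), collapse = "\t")),
           paste0("FIELD_LABELS\t", paste(fams, collapse = "\t")),
           "DATA")
  if (nrow(m) > 0)
    out <- c(out, paste(labs, apply(m, 1, paste, collapse = "\t"), sep = "\t"))
  con <- file(path, open = "wb")
  writeLines(out, con)
  close(con)
  invisible(path)
}

#' Re-read an iTOL DATASET_BINARY file into a presence matrix
#'
#' Inverse of [write_itol_binary()]; used for round-trip validation.
#'
#' @param path iTOL annotation file.
#' @return Integer matrix with taxon labels as rownames.
#' @export
read_itol_binary <- function(path) {
  lines <- readLines(path)
  fl <- lines[grepl("^FIELD_LABELS\t", lines)]
  fams <- strsplit(sub("^FIELD_LABELS\t", "", fl), "\t")[[1]]
  di <- which(lines == "DATA")
  rows <- lines[seq_len(length(lines)) > di]
  rows <- rows[nzchar(rows)]
  m <- matrix(integer(0), nrow = 0, ncol = length(fams),
              dimnames = list(NULL, fams))
  if (length(rows) > 0) {
    tok <- strsplit(rows, "\t", fixed = TRUE)
    m <- t(vapply(tok, function(x) as.integer(x[-1]), integer(length(fams))))
    if (length(fams) == 1L) m <- matrix(m, ncol = 1L)
    dimnames(m) <- list(vapply(tok, `[`, "", 1), fams)
  }
  m
}

# deterministic TSV writer used by all report stages
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  close(con)
  invisible(path)
}
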