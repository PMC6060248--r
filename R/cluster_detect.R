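#' Detect T4aP gene clusters on each contig
#'
#' Scans genes by locus index per contig; consecutive family-assigned genes
#' (anchor families excluded — ribF never counts as a member) join the same
#' cluster when the number of intervening non-assigned genes is at most
#' `max_gap`.  Singleton assigned genes are emitted as size-1 clusters.
#' Strand is recorded but never affects membership; membership is purely
#' positional.
#'
#' @param genome A `t4_genome`.
#' @param assignments Assignment table from [assign_families()] (only
#'   `gene_id` and `family` are required; `family == "UNASSIGNED"` rows are
#'   ignored).
#' @param max_gap Maximum intervening non-assigned genes between consecutive
#'   members (default 5).
#' @param anchor_families Families never taken as members (default `"ribF"`).
#' @return List of `t4_cluster` objects: `contig_id`, `members` (data.frame
#'   `gene_id`, `family`, `strand`, `locus_index`), `gaps` (intervening gene
#'   counts between consecutive members, length `nrow(members) - 1`),
#'   `label` (`NA` until [classify_cluster()]), `architecture`.
#' @export
detect_clusters <- function(genome, assignments, max_gap = 5,
                            anchor_families = "ribF") {
  stopifnot(max_gap >= 0)
  asg <- assignments[assignments$family != "UNASSIGNED", , drop = FALSE]
  missing <- setdiff(asg$gene_id, genome$genes$gene_id)
  if (length(missing) > 0)
    stop("assignment references gene absent from genome: ",
         paste(missing, collapse = ", "))
  asg <- asg[!asg$family %in% anchor_families, , drop = FALSE]
  g <- merge(genome$genes, asg[, c("gene_id", "family")], by = "gene_id")
  clusters <- list()
  for (ct in unique(genome$genes$contig_id)) {
    m <- g[g$contig_id == ct, , drop = FALSE]
    if (nrow(m) == 0) next
    m <- m[order(m$locus_index), , drop = FALSE]
    gap_before <- c(Inf, diff(m$locus_index) - 1L)
    grp <- cumsum(gap_before > max_gap)
    for (k in unique(grp)) {
      mm <- m[grp == k, , drop = FALSE]
      members <- data.frame(gene_id = mm$gene_id, family = mm$family,
                            strand = mm$strand, locus_index = mm$locus_index,
                            stringsAsFactors = FALSE)
      gaps <- if (nrow(mm) > 1) as.integer(diff(mm$locus_index) - 1L) else
        integer(0)
      clusters[[length(clusters) + 1L]] <- structure(
        list(contig_id = ct, members = members, gaps = gaps,
             label = NA_character_,
             architecture = architecture_string(members$family, gaps),
             split_candidate = FALSE),
        class = "t4_cluster")
    }
  }
  clusters
}

#' Render a cluster architecture string
#'
#' Family names joined by `-`; a run of k intervening genes between two
#' members is rendered as `x` when k = 1 and `[k]` when k > 1 (the digits in
#' the white boxes of the field's cluster diagrams).
#'
#' @param families Member family names in locus order.
#' @param gaps Intervening-gene counts between consecutive members.
#' @return Architecture string, e.g. `"pilW-x-pilY1"`.
#' @export
architecture_string <- function(families, gaps) {
  stopifnot(length(gaps) == max(length(families) - 1L, 0L))
  if (length(families) == 0) return("")
  parts <- families[1]
  for (i in seq_along(gaps)) {
    if (gaps[i] == 1) parts <- c(parts, "x")
    else if (gaps[i] > 1) parts <- c(parts, paste0("[", gaps[i], "]"))
    parts <- c(parts, families[i + 1])
  }
  paste(parts, collapse = "-")
}

#' Parse an architecture string back to families and gaps
#'
#' Lossless inverse of [architecture_string()].
#'
#' @param arch Architecture string.
#' @return List with `families` and `gaps`.
#' @export
parse_architecture <- function(arch) {
  if (!nzchar(arch)) return(list(families = character(0), gaps = integer(0)))
  tok <- strsplit(arch, "-", fixed = TRUE)[[1]]
  families <- character(0)
  gaps <- integer(0)
  pending <- 0L
  for (t in tok) {
    if (t == "x") {
      pending <- 1L
    } else if (grepl("^\\[[0-9]+\\]$", t)) {
      pending <- as.integer(sub("^\\[([0-9]+)\\]$", "\\1", t))
    } else {
      if (length(families) > 0) gaps <- c(gaps, pending)
      families <- c(families, t)
      pending <- 0L
    }
  }
  list(families = families, gaps = gaps)
}

#' Classify a detected cluster
#'
#' `main` when the cluster has at least `main_min_size` members covering at
#' least `min_core_families` distinct core families; `minor_pilin` when it
#' has at least two members, all from the minor-pilin set (fimU, pilV, pilW,
#' pilX, pilE, pilY1); `mnopq` when the family set is a subset of
#' pilM/N/O/P/Q with at least 4 distinct; otherwise `other` (scattered
#' singletons fall here — a lone minor pilin is not a minor-pilin locus).
#'
#' @param cluster A `t4_cluster`.
#' @param main_min_size,min_core_families Main-cluster thresholds (defaults
#'   10 and 5: large clustered loci carry 15+ genes while the biggest locus
#'   of dispersed genomes is pilMNOPQ, so the defaults sit safely between).
#' @return The cluster with `label` filled in.
#' @export
classify_cluster <- function(cluster, main_min_size = 10,
                             min_core_families = 5) {
  fams <- cluster$members$family
  minor_set <- c("fimU", "pilV", "pilW", "pilX", "pilE", "pilY1")
  mnopq_set <- c("pilM", "pilN", "pilO", "pilP", "pilQ")
  n_core <- length(intersect(unique(fams), core_families()))
  label <-
    if (length(fams) >= main_min_size && n_core >= min_core_families) "main"
    else if (length(fams) >= 2 && all(fams %in% minor_set)) "minor_pilin"
    else if (all(fams %in% mnopq_set) && length(unique(fams)) >= 4) "mnopq"
    else "other"
  cluster$label <- label
  cluster
}

#' Classify every cluster in a list
#' @inheritParams classify_cluster
#' @param clusters List of `t4_cluster`.
#' @return The list with labels filled in.
#' @export
classify_clusters <- function(clusters, main_min_size = 10,
                              min_core_families = 5) {
  lapply(clusters, classify_cluster, main_min_size = main_min_size,
         min_core_families = min_core_families)
}

#' Flag main clusters split across draft-assembly contigs
#'
#' In draft assemblies the main locus can be cut by a contig break.  Two
#' clusters on different contigs — each with at least 3 members, disjoint
#' family sets, each within `edge_window` genes of a contig end — whose
#' pooled members would qualify as a main cluster are both flagged as split
#' candidates; [call_organization()] then upgrades the genome to `clustered`.
#'
#' @param genome A `t4_genome`.
#' @param clusters Classified clusters.
#' @param edge_window Maximum distance (in genes) from a contig end
#'   (default 5).
#' @inheritParams classify_cluster
#' @return The cluster list with `split_candidate` set.
#' @export
flag_split_clusters <- function(genome, clusters, edge_window = 5,
                                main_min_size = 10, min_core_families = 5) {
  if (length(clusters) < 2) return(clusters)
  ngenes <- table(genome$genes$contig_id)
  near_edge <- vapply(clusters, function(cl) {
    n <- as.integer(ngenes[[cl$contig_id]])
    first <- min(cl$members$locus_index)
    last <- max(cl$members$locus_index)
    first < edge_window || last > n - 1L - edge_window
  }, logical(1))
  eligible <- which(vapply(clusters, function(cl) nrow(cl$members) >= 3,
                           logical(1)) & near_edge)
  if (length(eligible) >= 2) {
    for (a in eligible) for (b in eligible) {
      if (a >= b) next
      ca <- clusters[[a]]; cb <- clusters[[b]]
      if (ca$contig_id == cb$contig_id) next
      if (length(intersect(ca$members$family, cb$members$family)) > 0) next
      pooled <- structure(list(
        contig_id = NA_character_,
        members = rbind(ca$members, cb$members),
        gaps = integer(nrow(ca$members) + nrow(cb$members) - 1L),
        label = NA_character_, architecture = "", split_candidate = FALSE),
        class = "t4_cluster")
      pooled <- classify_cluster(pooled, main_min_size, min_core_families)
      if (pooled$label == "main") {
        clusters[[a]]$split_candidate <- TRUE
        clusters[[b]]$split_candidate <- TRUE
      }
    }
  }
  clusters
}

#' Call a genome's T4aP organization type
#'
#' `clustered` when any main cluster exists (or a flagged split pair jointly
#' qualifies — then `split_candidate` is set and the pooled size reported);
#' `dispersed` when there is no main cluster but a pilMNOPQ cluster exists;
#' otherwise `ambiguous`.
#'
#' @param genome A `t4_genome` (or a genome id string).
#' @param clusters Classified clusters (after [flag_split_clusters()] if
#'   draft assemblies are in play).
#' @return One-row `data.frame`: `genome_id`, `call`, `main_cluster_size`,
#'   `evidence` (comma-joined cluster labels), `split_candidate`.
#' @export
call_organization <- function(genome, clusters) {
  gid <- if (inherits(genome, "t4_genome")) genome$genome_id else genome
  labels <- vapply(clusters, `[[`, "", "label")
  sizes <- vapply(clusters, function(cl) nrow(cl$members), integer(1))
  split <- vapply(clusters, `[[`, logical(1), "split_candidate")
  if (any(labels == "main")) {
    call <- "clustered"
    size <- max(sizes[labels == "main"])
    split_flag <- any(split)
  } else if (any(split)) {
    call <- "clustered"
    size <- sum(sizes[split])
    split_flag <- TRUE
  } else if (any(labels == "mnopq")) {
    call <- "dispersed"; size <- 0L; split_flag <- FALSE
  } else {
    call <- "ambiguous"; size <- 0L; split_flag <- FALSE
  }
  data.frame(genome_id = gid, call = call,
             main_cluster_size = as.integer(size),
             evidence = paste(labels, collapse = ","),
             split_candidate = split_flag, stringsAsFactors = FALSE)
}

#' Count paralogs of a family in a genome
#'
#' @param assignments Assignment table.
#' @param family Family name (e.g. `"pilA"`).
#' @return Number of genes assigned to the family.
#' @export
count_paralogs <- function(assignments, family) {
  sum(assignments$family == family)
}

#' Resolve pilRS regulator pairs inside a cluster
#'
#' The two-component pair pilR/pilS is detected as one combined family
#' because the proteins resemble the genome's many other regulators;
#' inside a cluster, successive pilRS members are chunked into pairs by
#' locus order and numbered pilR1S1, pilR2S2, ...  Incomplete trailing
#' singletons are labelled with the next pair number and flagged.
#'
#' @param cluster A `t4_cluster`.
#' @return `data.frame` with `gene_id`, `pair_label`, `complete` (logical);
#'   zero rows when the cluster has no pilRS members.
#' @export
resolve_pilrs <- function(cluster) {
  m <- cluster$members[cluster$members$family == "pilRS", , drop = FALSE]
  if (nrow(m) == 0)
    return(data.frame(gene_id = character(0), pair_label = character(0),
                      complete = logical(0), stringsAsFactors = FALSE))
  m <- m[order(m$locus_index), , drop = FALSE]
  pair <- ceiling(seq_len(nrow(m)) / 2)
  sizes <- table(pair)
  data.frame(gene_id = m$gene_id,
             pair_label = sprintf("pilR%dS%d", pair, pair),
             complete = as.integer(sizes[as.character(pair)]) == 2L,
             stringsAsFactors = FALSE)
}

#' Tabulate clusters for reporting
#'
#' @param genome_id Genome identifier.
#' @param clusters Classified clusters.
#' @return `data.frame` with one row per cluster: genome, contig, label,
#'   architecture, size, member gene ids, gaps, split flag.
#' @export
clusters_table <- function(genome_id, clusters) {
  if (length(clusters) == 0)
    return(data.frame(genome_id = character(0), contig_id = character(0),
                      label = character(0), architecture = character(0),
                      n_members = integer(0), members = character(0),
                      gaps = character(0), split_candidate = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(clusters, function(cl) data.frame(
    genome_id = genome_id, contig_id = cl$contig_id, label = cl$label,
    architecture = cl$architecture, n_members = nrow(cl$members),
    members = paste(cl$members$gene_id, collapse = ","),
    gaps = paste(cl$gaps, collapse = ","),
    split_candidate = cl$split_candidate, stringsAsFactors = FALSE)))
}
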