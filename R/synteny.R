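#' Flanking-gene context of a cluster
#'
#' The `k` genes before the first member and after the last member of the
#' cluster on its contig (truncated at contig ends).  Genes lying between
#' members (interior gap occupants) are never part of the flanking context.
#'
#' @param genome A `t4_genome`.
#' @param cluster A `t4_cluster` belonging to `genome`.
#' @param k Number of flanking genes per side (default 5).
#' @param assignments Optional assignment table; when given, flanking genes
#'   are annotated with their family (else with the free-text product).
#' @return List of class `t4_synteny_context`: `contig_id`, `upstream` and
#'   `downstream` data.frames (`offset`, `gene_id`, `token`), where offsets
#'   are -k..-1 and +1..+k relative to the cluster span.
#' @export
flanking_context <- function(genome, cluster, k = 5, assignments = NULL) {
  g <- genome$genes[genome$genes$contig_id == cluster$contig_id, ,
                    drop = FALSE]
  g <- g[order(g$locus_index), , drop = FALSE]
  if (!all(cluster$members$gene_id %in% g$gene_id))
    stop("cluster does not belong to this genome/contig")
  first <- min(cluster$members$locus_index)
  last <- max(cluster$members$locus_index)
  token_of <- function(rows) {
    tok <- rows$product
    if (!is.null(assignments)) {
      fam <- assignments$family[match(rows$gene_id, assignments$gene_id)]
      use <- !is.na(fam) & fam != "UNASSIGNED"
      tok[use] <- fam[use]
    }
    tok
  }
  up <- g[g$locus_index >= first - k & g$locus_index < first, , drop = FALSE]
  down <- g[g$locus_index > last & g$locus_index <= last + k, , drop = FALSE]
  structure(list(
    contig_id = cluster$contig_id,
    upstream = data.frame(offset = up$locus_index - first,
                          gene_id = up$gene_id, token = token_of(up),
                          stringsAsFactors = FALSE),
    downstream = data.frame(offset = down$locus_index - last,
                            gene_id = down$gene_id, token = token_of(down),
                            stringsAsFactors = FALSE)),
    class = "t4_synteny_context")
}

#' Test whether one family lies just downstream of another
#'
#' True iff some gene of `family_a` has a gene of `family_b` downstream on
#' the same contig — downstream in `family_a`'s transcription direction —
#' with at most `max_intervening` genes between them.  The canonical use is
#' the riboflavin-kinase anchor: `anchor_adjacent(genome, asg, "pilB",
#' "ribF")`, which holds in clustered-organization genomes and fails where
#' pilB and ribF are genetically unlinked.  The verdict is strand-consistent:
#' reversing a contig (coordinates and strands together) leaves it unchanged.
#'
#' @param genome A `t4_genome`.
#' @param assignments Assignment table.
#' @param family_a Upstream family (direction donor).
#' @param family_b Family sought downstream.
#' @param max_intervening Maximum genes strictly between the pair
#'   (default 1).
#' @return List: `adjacent` (logical) and `evidence` data.frame
#'   (`gene_a`, `gene_b`, `intervening`) of all qualifying pairs.
#' @export
anchor_adjacent <- function(genome, assignments, family_a, family_b,
                            max_intervening = 1) {
  a_ids <- assignments$gene_id[assignments$family == family_a]
  b_ids <- assignments$gene_id[assignments$family == family_b]
  ev <- data.frame(gene_a = character(0), gene_b = character(0),
                   intervening = integer(0), stringsAsFactors = FALSE)
  if (length(a_ids) > 0 && length(b_ids) > 0) {
    g <- genome$genes
    for (ga in a_ids) {
      ra <- g[g$gene_id == ga, ]
      cand <- g[g$contig_id == ra$contig_id & g$gene_id %in% b_ids, ,
                drop = FALSE]
      if (nrow(cand) == 0) next
      delta <- cand$locus_index - ra$locus_index
      if (ra$strand == "-") delta <- -delta
      ok <- delta >= 1 & delta - 1 <= max_intervening
      if (any(ok))
        ev <- rbind(ev, data.frame(gene_a = ga, gene_b = cand$gene_id[ok],
                                   intervening = as.integer(delta[ok] - 1L),
                                   stringsAsFactors = FALSE))
    }
  }
  list(adjacent = nrow(ev) > 0, evidence = ev)
}

#' Flanking-family frequency across genomes
#'
#' For each flanking offset (-k..-1, +1..+k), the frequency of each
#' family/annotation token among the supplied contexts.  Frequencies are
#' counts divided by the number of contexts, so they sum to at most 1 per
#' offset (short contigs truncate contexts).
#'
#' @param contexts List of `t4_synteny_context`.
#' @return `data.frame` with `offset`, `token`, `count`, `frequency`, sorted
#'   by offset then decreasing frequency then token.
#' @export
synteny_conservation <- function(contexts) {
  stopifnot(length(contexts) >= 1)
  all_rows <- do.call(rbind, lapply(contexts, function(cx)
    rbind(cx$upstream[, c("offset", "token")],
          cx$downstream[, c("offset", "token")])))
  if (is.null(all_rows) || nrow(all_rows) == 0)
    return(data.frame(offset = integer(0), token = character(0),
                      count = integer(0), frequency = numeric(0),
                      stringsAsFactors = FALSE))
  tab <- as.data.frame(table(offset = all_rows$offset, token = all_rows$token),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  out <- data.frame(offset = as.integer(tab$offset), token = tab$token,
                    count = as.integer(tab$Freq),
                    frequency = tab$Freq / length(contexts),
                    stringsAsFactors = FALSE)
  out <- out[order(out$offset, -out$frequency, out$token), , drop = FALSE]
  rownames(out) <- NULL
  out
}
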