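#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its default: homology thresholds
#' (E-value 1e-5, query coverage 35%, similarity 35%), clustering
#' (`max_gap` 5 intervening genes, main cluster at least 10 members covering
#' at least 5 core families, split-candidate `edge_window` 5), synteny
#' (`flank_k` 5 genes per side, ribF anchor within `anchor_max_intervening`
#' 1 gene of pilB), pilin diagnostics (prepilin motif within the first 50
#' residues, DSL parameters), and phylogenetics (100 bootstrap replicates,
#' N-terminal window of 60 columns).
#'
#' @return Named list (a RunConfig).
#' @export
default_config <- function() {
  list(max_evalue = 1e-5, min_query_coverage_pct = 35,
       min_similarity_pct = 35, gap_open = 11, gap_extend = 1,
       max_gap = 5, main_min_size = 10, min_core_families = 5,
       edge_window = 5, anchor_max_intervening = 1, flank_k = 5,
       cleavage_motif = "G[FY][ST]L[ILMV]E", cleavage_window = 50,
       cterm_fraction = 0.5, min_loop = 6, max_loop = 60,
       terminal_window = 15, nterm_window = 60, bootstrap_n = 100,
       seed = 1)
}

#' Validate a configuration file
#'
#' Reads a flat `key: value` text file (blank lines and `#` comments
#' ignored), applies defaults for absent keys, rejects unknown keys and
#' non-numeric or out-of-range values.
#'
#' @param path Config file path; `NULL` returns the defaults.
#' @return A validated RunConfig list.
#' @export
validate_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !grepl("^#", lines)]
    for (ln in lines) {
      if (!grepl(":", ln, fixed = TRUE))
        stop("config line without 'key: value': '", ln, "'")
      key <- trimws(sub(":.*$", "", ln))
      val <- trimws(sub("^[^:]*:", "", ln))
      if (!key %in% names(cfg)) stop("unknown config key: ", key)
      if (is.numeric(cfg[[key]])) {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) stop("non-numeric value for key ", key, ": ", val)
        cfg[[key]] <- num
      } else {
        cfg[[key]] <- val
      }
    }
  }
  check_pos <- function(k) if (cfg[[k]] <= 0)
    stop("config key ", k, " must be positive")
  check_nonneg <- function(k) if (cfg[[k]] < 0)
    stop("config key ", k, " must be nonnegative")
  lapply(c("max_evalue", "main_min_size", "min_core_families", "flank_k",
           "cleavage_window", "min_loop", "max_loop", "terminal_window",
           "nterm_window", "bootstrap_n"), check_pos)
  lapply(c("max_gap", "edge_window", "anchor_max_intervening", "gap_open",
           "gap_extend"), check_nonneg)
  if (cfg$min_query_coverage_pct <= 0 || cfg$min_query_coverage_pct > 100 ||
      cfg$min_similarity_pct <= 0 || cfg$min_similarity_pct > 100)
    stop("coverage/similarity thresholds must be in (0, 100]")
  if (cfg$cterm_fraction <= 0 || cfg$cterm_fraction > 1)
    stop("cterm_fraction must be in (0, 1]")
  cfg
}

#' Write the effective configuration as `key: value` lines
#' @param config A RunConfig.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  fmt <- vapply(config, function(v)
    if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE,
                              digits = 15) else as.character(v), "")
  con <- file(path, open = "wb")
  writeLines(paste0(names(config), ": ", fmt), con)
  close(con)
  invisible(path)
}

config_thresholds <- function(cfg) {
  list(max_evalue = cfg$max_evalue,
       min_query_coverage_pct = cfg$min_query_coverage_pct,
       min_similarity_pct = cfg$min_similarity_pct)
}

#' Analyse one genome end to end
#'
#' Homology scan, cluster detection and classification, split-cluster
#' flagging, organization call, pilRS resolution, pilin features, and the
#' pilB-ribF anchor test, under one configuration.
#'
#' @param genome A `t4_genome`.
#' @param panel Reference panel `data.frame` (or a `t4_panel_set`).
#' @param config RunConfig (default [default_config()]).
#' @return List: `assignments`, `clusters` (classified, split-flagged),
#'   `organization` (one-row data.frame), `pilrs` (pair table of the main
#'   cluster), `pilin` (feature table), `anchor` (pilB-ribF verdict),
#'   `contexts` (flanking contexts of main/mnopq clusters).
#' @export
analyze_genome <- function(genome, panel, config = default_config()) {
  if (inherits(panel, "t4_panel_set")) panel <- panel$panel
  asg <- assign_families(genome, panel, config_thresholds(config),
                         gap_open = config$gap_open,
                         gap_extend = config$gap_extend)
  cl <- detect_clusters(genome, asg, max_gap = config$max_gap)
  cl <- classify_clusters(cl, main_min_size = config$main_min_size,
                          min_core_families = config$min_core_families)
  cl <- flag_split_clusters(genome, cl, edge_window = config$edge_window,
                            main_min_size = config$main_min_size,
                            min_core_families = config$min_core_families)
  org <- call_organization(genome, cl)
  main_cl <- Filter(function(x) identical(x$label, "main"), cl)
  pilrs <- if (length(main_cl) > 0) resolve_pilrs(main_cl[[1]]) else
    resolve_pilrs(structure(list(members = data.frame(
      gene_id = character(0), family = character(0), strand = character(0),
      locus_index = integer(0))), class = "t4_cluster"))
  pil <- pilin_features(genome, asg, cl, motif = config$cleavage_motif,
                        search_window = config$cleavage_window,
                        cterm_fraction = config$cterm_fraction,
                        min_loop = config$min_loop,
                        max_loop = config$max_loop,
                        terminal_window = config$terminal_window)
  anchor <- anchor_adjacent(genome, asg, "pilB", "ribF",
                            max_intervening = config$anchor_max_intervening)
  focal <- Filter(function(x) x$label %in% c("main", "mnopq"), cl)
  contexts <- lapply(focal, function(x)
    flanking_context(genome, x, k = config$flank_k, assignments = asg))
  list(assignments = asg, clusters = cl, organization = org, pilrs = pilrs,
       pilin = pil, anchor = anchor, contexts = contexts)
}

#' Run the full pipeline over a cohort and write all reports
#'
#' Stages: scan (homology), cluster, pilin, synteny, phylo, report.  Writes
#' tab-separated tables (`assignments.tsv`, `clusters.tsv`,
#' `organization.tsv`, `pilin_features.tsv`, `synteny.tsv`, `anchors.tsv`,
#' `summary.tsv`), the family presence/absence matrix with its iTOL
#' annotation (`presence.tsv`, `itol_presence.txt`), the effective config
#' echo (`config_effective.txt`), and — when at least four pilT genes exist
#' across the cohort — a bootstrap NJ tree of pilT proteins
#' (`pilT_tree.nwk`) with a monophyly verdict for cluster-resident homologs
#' (`monophyly.tsv`).  All outputs are deterministic given the config seed;
#' any stage failure raises an error naming the stage.
#'
#' @param genomes List of `t4_genome` (e.g. a cohort's `genomes`).
#' @param panel Reference panel `data.frame` or `t4_panel_set`.
#' @param out_dir Output directory (created if needed).
#' @param config RunConfig.
#' @return Invisibly, a named list of written paths plus the per-genome
#'   result list (`results`).
#' @export
run_all <- function(genomes, panel, out_dir, config = default_config()) {
  if (inherits(panel, "t4_panel_set")) panel <- panel$panel
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }
  paths <- list()
  message("[config] ", length(genomes), " genome(s), seed ", config$seed)
  paths$config <- write_config(config, file.path(out_dir,
                                                 "config_effective.txt"))
  message("[scan] homology scan + per-genome analysis")
  res <- stage("scan", lapply(genomes, analyze_genome, panel = panel,
                              config = config))
  message("[report] writing tables to ", out_dir)
  stage("report", {
    asg_tab <- do.call(rbind, lapply(names(res), function(id) {
      a <- res[[id]]$assignments
      cbind(genome_id = id, a)
    }))
    paths$assignments <- write_tsv(asg_tab,
                                   file.path(out_dir, "assignments.tsv"))
    cl_tab <- do.call(rbind, lapply(names(res), function(id)
      clusters_table(id, res[[id]]$clusters)))
    paths$clusters <- write_tsv(cl_tab, file.path(out_dir, "clusters.tsv"))
    org_tab <- do.call(rbind, lapply(res, `[[`, "organization"))
    paths$organization <- write_tsv(org_tab,
                                    file.path(out_dir, "organization.tsv"))
    pil_tab <- do.call(rbind, lapply(names(res), function(id)
      if (nrow(res[[id]]$pilin) > 0) cbind(genome_id = id, res[[id]]$pilin)))
    if (is.null(pil_tab)) pil_tab <- data.frame(genome_id = character(0))
    paths$pilin <- write_tsv(pil_tab,
                             file.path(out_dir, "pilin_features.tsv"))
    syn_tab <- do.call(rbind, lapply(names(res), function(id) {
      cxs <- res[[id]]$contexts
      if (length(cxs) == 0) return(NULL)
      do.call(rbind, lapply(cxs, function(cx)
        cbind(genome_id = id, contig_id = cx$contig_id,
              rbind(cx$upstream, cx$downstream))))
    }))
    if (is.null(syn_tab))
      syn_tab <- data.frame(genome_id = character(0), contig_id = character(0),
                            offset = integer(0), gene_id = character(0),
                            token = character(0))
    paths$synteny <- write_tsv(syn_tab, file.path(out_dir, "synteny.tsv"))
    anchor_tab <- do.call(rbind, lapply(names(res), function(id)
      data.frame(genome_id = id, pair = "pilB-ribF",
                 adjacent = res[[id]]$anchor$adjacent,
                 n_evidence = nrow(res[[id]]$anchor$evidence),
                 stringsAsFactors = FALSE)))
    paths$anchors <- write_tsv(anchor_tab, file.path(out_dir, "anchors.tsv"))
    fams <- sort(unique(family_roster(decoys = FALSE)$family))
    pres <- t(vapply(res, function(r)
      ifelse(fams %in% r$assignments$family, 1L, -1L),
      integer(length(fams))))
    colnames(pres) <- fams
    rownames(pres) <- names(res)
    paths$presence <- write_tsv(cbind(genome_id = rownames(pres),
                                      as.data.frame(pres)),
                                file.path(out_dir, "presence.tsv"))
    paths$itol <- write_itol_binary(pres,
                                    file.path(out_dir, "itol_presence.txt"),
                                    genomes = genomes)
    summ <- do.call(rbind, lapply(names(res), function(id) {
      r <- res[[id]]
      data.frame(genome_id = id, call = r$organization$call,
                 main_cluster_size = r$organization$main_cluster_size,
                 split_candidate = r$organization$split_candidate,
                 n_pilA = count_paralogs(r$assignments, "pilA"),
                 n_pilRS_pairs = sum(r$pilrs$complete) / 2,
                 anchor_pilB_ribF = r$anchor$adjacent,
                 stringsAsFactors = FALSE)
    }))
    paths$summary <- write_tsv(summ, file.path(out_dir, "summary.tsv"))
  })
  message("[phylo] cohort pilT tree")
  stage("phylo", {
    pilt <- unlist(lapply(names(res), function(id) {
      ids <- res[[id]]$assignments$gene_id[
        res[[id]]$assignments$family == "pilT"]
      setNames(unlist(genomes[[id]]$proteins[ids]),
               paste0(id, ".", ids))
    }))
    pilt <- pilt[nzchar(pilt)]
    if (length(pilt) >= 4) {
      msa <- progressive_align(pilt)
      tr <- bootstrap_support(msa, n_replicates = config$bootstrap_n,
                              seed = config$seed)
      paths$pilt_tree <- write_tree_newick(tr,
                                           file.path(out_dir,
                                                     "pilT_tree.nwk"))
      in_main <- unlist(lapply(names(res), function(id) {
        main_ids <- unlist(lapply(res[[id]]$clusters, function(cl)
          if (identical(cl$label, "main")) cl$members$gene_id))
        ids <- res[[id]]$assignments$gene_id[
          res[[id]]$assignments$family == "pilT"]
        setNames(ids %in% main_ids, paste0(id, ".", ids))
      }))
      subset <- names(in_main)[in_main]
      subset <- intersect(subset, tr$tip.label)
      if (length(subset) >= 1 && length(subset) < length(tr$tip.label)) {
        mono <- test_monophyly(tr, subset)
        paths$monophyly <- write_tsv(
          data.frame(subset = "pilT_in_main_cluster",
                     n_taxa = length(subset),
                     is_monophyletic = mono$is_monophyletic,
                     support_pct = mono$support_pct,
                     stringsAsFactors = FALSE),
          file.path(out_dir, "monophyly.tsv"))
      }
    }
  })
  invisible(c(paths, list(results = res)))
}

#' Write a synthetic cohort to disk as GFF3 + protein FASTA
#'
#' @param cohort A `t4_cohort` from [generate_cohort()].
#' @param dir Output directory.
#' @return Invisibly, the directory; writes `<genome_id>.gff3` /
#'   `<genome_id>.faa` per genome, the panel FASTA and a truth table TSV.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in cohort$genomes)
    write_genome(g, file.path(dir, paste0(g$genome_id, ".gff3")),
                 file.path(dir, paste0(g$genome_id, ".faa")))
  write_panel(cohort$panel_set$panel, file.path(dir, "panel.faa"))
  write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
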