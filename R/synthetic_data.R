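# amino-acid background frequencies (approximate natural composition)
aa_letters <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
                "S","T","W","Y","V")
aa_freq <- c(A = 0.083, R = 0.057, N = 0.044, D = 0.055, C = 0.014,
             Q = 0.040, E = 0.067, G = 0.071, H = 0.022, I = 0.059,
             L = 0.096, K = 0.058, M = 0.024, F = 0.039, P = 0.046,
             S = 0.066, T = 0.054, W = 0.011, Y = 0.029, V = 0.071)

# distinct RNG streams for distinct purposes: a panel and a genome built
# from the same user seed must not replay the same draws (identical streams
# would plant panel subsequences inside background genes).  Linear-
# congruential scramble keeps everything in 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 69069 + 101 * stream) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

random_protein <- function(n, exclude = character(0)) {
  p <- aa_freq
  p[exclude] <- 0
  paste(sample(aa_letters, n, replace = TRUE, prob = p / sum(p)),
        collapse = "")
}

# BLOSUM62-biased replacement weights: exchanges with positive substitution
# scores are favoured, so percent similarity degrades more slowly than
# percent identity under mutation, as in real proteins.  New cysteines are
# never introduced: Cys exist only where the generator plants them, keeping
# DSL ground truth stable.
replacement_weights <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- blosum62()[aa_letters, aa_letters]
      w <- exp(m / 2)
      diag(w) <- 0
      w[, "C"] <- 0
      cache <<- w
    }
    cache
  }
})

#' Mutate a protein sequence at a per-site substitution rate
#'
#' Each unprotected site is substituted with probability `divergence`; the
#' replacement residue is drawn with BLOSUM62-biased weights (see package
#' vignette).  Cysteines are never created.
#'
#' @param seq Amino-acid sequence.
#' @param divergence Per-site substitution probability in `[0, 0.6]`.
#' @param protect Integer positions never mutated.
#' @return Mutated sequence.
#' @export
mutate_protein <- function(seq, divergence, protect = integer(0)) {
  stopifnot(divergence >= 0, divergence <= 0.6)
  if (divergence == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < divergence)
  hit <- setdiff(hit, protect)
  w <- replacement_weights()
  for (i in hit) {
    a <- chars[i]
    if (!a %in% aa_letters) next
    chars[i] <- sample(aa_letters, 1, prob = w[a, ])
  }
  paste(chars, collapse = "")
}

# positions that must survive mutation in a pilin: the prepilin cleavage
# motif and any planted cysteines
pilin_protected <- function(seq, motif = "G[FY][ST]L[ILMV]E") {
  pos <- find_cleavage_site(seq, motif, search_window = 50)
  prot <- if (is.na(pos)) integer(0) else seq.int(pos, pos + 5L)
  c(prot, which(strsplit(seq, "")[[1]] == "C"))
}

# pilins: conserved N-terminus (through the first ~60 mature residues)
# mutates at a fifth of the nominal rate, the divergent C-terminal domain at
# 1.5x (capped at 0.6)
mutate_pilin <- function(seq, divergence, motif = "G[FY][ST]L[ILMV]E") {
  prot <- pilin_protected(seq, motif)
  pos <- find_cleavage_site(seq, motif, search_window = 50)
  n_end <- if (is.na(pos)) 60L else pos + 60L
  n_end <- min(n_end, nchar(seq))
  n_part <- substring(seq, 1, n_end)
  c_part <- substring(seq, n_end + 1)
  n_mut <- mutate_protein(n_part, divergence * 0.2, protect = prot)
  c_mut <- if (nzchar(c_part))
    mutate_protein(c_part, min(divergence * 1.5, 0.6),
                   protect = prot[prot > n_end] - n_end)
  else ""
  paste0(n_mut, c_mut)
}

pilin_families <- function() c("pilA", "fimU", "pilV", "pilW", "pilX", "pilE")

# one random pilin ancestor: signal prefix + prepilin motif + conserved-N
# region + variable C-terminal domain; pilA additionally carries the
# planted terminal Cys pair (separation 15, second Cys 5 from the end)
random_pilin_ancestor <- function(family) {
  prefix <- paste0("M", random_protein(4, exclude = c("C", "G")))
  motif <- paste0("G", sample(c("F", "Y"), 1), sample(c("S", "T"), 1),
                  "L", sample(c("I", "L", "M", "V"), 1), "E")
  n_region <- random_protein(54, exclude = "C")
  c_len <- sample(90:160, 1)
  c_region <- random_protein(c_len, exclude = "C")
  if (family == "pilA") {
    cc <- strsplit(c_region, "")[[1]]
    cc[c_len - 4L] <- "C"
    cc[c_len - 19L] <- "C"
    c_region <- paste(cc, collapse = "")
  }
  paste0(prefix, motif, n_region, c_region)
}

#' Generate a reference panel with family ancestors
#'
#' Builds one random ancestor per T4aP family (pilins 140-230 aa, pilQ
#' 600-900 aa, others 200-500 aa; the pilRS regulator pair gets a
#' sensor-kinase-like and a response-regulator-like ancestor).  Decoy
#' families mimic T2SS paralogy: they are derived from the pilB/pilC/pilD
#' ancestors at ~50% divergence and accepted only when their global identity
#' to the source lies in (35%, 65%) (regenerated otherwise).  Deterministic
#' for a given seed.
#'
#' @param seed Integer seed.
#' @param families Family roster as [family_roster()]; must include all core
#'   families.
#' @return List of class `t4_panel_set`: `panel` (reference data.frame with
#'   `name`, `family`, `role`, `seq`) and `ancestors` (named list of named
#'   character vectors, one per family).
#' @export
generate_panel <- function(seed = 1, families = family_roster()) {
  missing_core <- setdiff(core_families(), families$family)
  if (length(missing_core) > 0)
    stop("family roster missing core families: ",
         paste(missing_core, collapse = ", "))
  with_seed(seed, {
    ancestors <- list()
    fams <- families[order(match(families$role, c(
      "core", "minor_pilin", "noncore", "regulatory", "anchor", "decoy")),
      families$family), , drop = FALSE]
    for (k in seq_len(nrow(fams))) {
      fam <- fams$family[k]
      role <- fams$role[k]
      if (role == "decoy") next
      seqs <- if (fam %in% pilin_families()) {
        c(anc = random_pilin_ancestor(fam))
      } else if (fam == "pilQ") {
        c(anc = random_protein(sample(600:900, 1)))
      } else if (fam == "pilRS") {
        c(S = random_protein(sample(400:500, 1)),
          R = random_protein(sample(210:280, 1)))
      } else {
        c(anc = random_protein(sample(200:500, 1)))
      }
      ancestors[[fam]] <- seqs
    }
    decoy_src <- c(t2ssE = "pilB", t2ssF = "pilC", t2ssO = "pilD")
    for (dec in intersect(fams$family[fams$role == "decoy"],
                          names(decoy_src))) {
      src <- ancestors[[decoy_src[[dec]]]][[1]]
      for (try in 1:25) {
        cand <- mutate_protein(src, 0.5)
        al <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(src), Biostrings::AAString(cand),
          substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
          type = "global")
        idp <- Biostrings::pid(al, type = "PID1")
        if (idp > 35 && idp < 65) break
      }
      ancestors[[dec]] <- c(anc = cand)
    }
    rows <- lapply(names(ancestors), function(fam) {
      role <- families$role[match(fam, families$family)]
      data.frame(name = paste0(fam, "_", seq_along(ancestors[[fam]])),
                 family = fam, role = role,
                 seq = unname(ancestors[[fam]]), stringsAsFactors = FALSE)
    })
    panel <- do.call(rbind, rows)
    rownames(panel) <- NULL
    structure(list(panel = panel, ancestors = ancestors),
              class = "t4_panel_set")
  })
}

#' Simulation profile for one synthetic genome
#'
#' @param organization `"clustered"` (17-gene main locus + ribF anchor +
#'   minor-pilin loci) or `"dispersed"` (contiguous pilMNOPQ only,
#'   everything else scattered, ribF unlinked).
#' @param n_pila_paralogs Total pilA genes, 1..7.
#' @param divergence Per-site substitution rate versus family ancestors,
#'   in `[0, 0.6]`.
#' @param decoy_families Number of T2SS-like decoy genes planted (0..3).
#' @param fragmentation Expected number of contig breaks (Poisson); 0 keeps
#'   one contig.
#' @param tandem_pila Place a second pilA gene in tandem inside the main
#'   cluster (the *S. aurantiaca*-style architecture).
#' @param seed Integer seed.
#' @return List of class `t4_sim_profile`.
#' @export
sim_profile <- function(organization = c("clustered", "dispersed"),
                        n_pila_paralogs = 1, divergence = 0.1,
                        decoy_families = 3, fragmentation = 0,
                        tandem_pila = FALSE, seed = 1) {
  organization <- match.arg(organization)
  stopifnot(n_pila_paralogs >= 1, n_pila_paralogs <= 7,
            divergence >= 0, divergence <= 0.6,
            decoy_families >= 0, fragmentation >= 0)
  if (tandem_pila && n_pila_paralogs < 2)
    stop("tandem_pila requires n_pila_paralogs >= 2")
  structure(list(organization = organization,
                 n_pila_paralogs = as.integer(n_pila_paralogs),
                 divergence = divergence,
                 decoy_families = as.integer(decoy_families),
                 fragmentation = fragmentation,
                 tandem_pila = tandem_pila, seed = as.integer(seed)),
            class = "t4_sim_profile")
}

#' Read the packaged main-locus layout
#'
#' @param path Layout file (defaults to the packaged one); one family per
#'   line, `#` comments, genomic left-to-right order.
#' @return Character vector of family names.
#' @export
main_locus_layout <- function(path = system.file("extdata",
                                                 "main_locus_layout.txt",
                                                 package = "pilarch")) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !grepl("^#", lines)]
}

product_for_family <- function(fam) {
  map <- c(pilA = "type IV pilus major pilin PilA",
           pilB = "type IV pilus assembly ATPase PilB",
           pilC = "type IV pilus platform protein PilC",
           pilD = "prepilin peptidase PilD",
           pilM = "type IV pilus alignment protein PilM",
           pilN = "type IV pilus alignment protein PilN",
           pilO = "type IV pilus alignment protein PilO",
           pilP = "type IV pilus alignment protein PilP",
           pilQ = "type IV pilus secretin PilQ",
           pilT = "type IV pilus retraction ATPase PilT",
           fimU = "type IV minor pilin FimU",
           pilV = "type IV minor pilin PilV",
           pilW = "type IV minor pilin PilW",
           pilX = "type IV minor pilin PilX",
           pilE = "type IV minor pilin PilE",
           pilY1 = "type IV pilus adhesin PilY1",
           pilF = "pilotin lipoprotein PilF",
           pilG = "pil cluster ABC-transporter-like protein PilG",
           pilH = "pil cluster ABC-transporter-like protein PilH",
           pilI = "pil cluster ABC-transporter-like protein PilI",
           tsaP = "secretin-associated protein TsaP",
           pilRS = "two-component regulator PilR/PilS",
           ribF = "riboflavin kinase",
           t2ssE = "type II secretion system ATPase GspE",
           t2ssF = "type II secretion system protein GspF",
           t2ssO = "type II secretion system prepilin peptidase GspO")
  ifelse(fam %in% names(map), map[fam], "hypothetical protein")
}

background_vocab <- c(
  "hypothetical protein", "ABC transporter permease", "MFS transporter",
  "TonB-dependent receptor", "acyl-CoA dehydrogenase",
  "sensor histidine kinase", "DNA-binding response regulator",
  "serine/threonine protein kinase", "glycosyltransferase",
  "outer membrane protein")

#' Generate a synthetic annotated genome with planted T4aP architecture
#'
#' Clustered organization plants the 17-gene main locus (layout file order,
#' pilB at the anchor-proximal end with ribF immediately downstream), two
#' fimU-pilWVY1X minor-pilin loci, one pilW-x-pilY1 locus, and scattered
#' singletons (pilD, pilF, pilE, extra pilA paralogs, decoys) between
#' background genes.  Dispersed organization plants a contiguous pilMNOPQ
#' run and scatters every other family as singletons with ribF unlinked from
#' pilB.  Orthologs are mutated from the panel ancestors at the profile's
#' divergence (pilins with a conserved-N / divergent-C model).  Positive
#' `fragmentation` cuts contigs at random intergenic points.
#'
#' @param profile A [sim_profile()].
#' @param panel_set A `t4_panel_set` from [generate_panel()].
#' @return List: `genome` (`t4_genome`), `truth` (per-gene data.frame:
#'   `gene_id`, `true_family`, `locus`, `in_main_cluster`), plus attributes
#'   `organization` and `cuts` on the truth.
#' @export
generate_genome <- function(profile, panel_set) {
  stopifnot(inherits(profile, "t4_sim_profile"),
            inherits(panel_set, "t4_panel_set"))
  anc <- panel_set$ancestors
  with_seed(derive_seed(profile$seed, 2L), {
    plan <- list()  # rows: family ("" = background), variant, locus
    add <- function(fam, locus, variant = 1L)
      plan[[length(plan) + 1L]] <<- list(fam = fam, locus = locus,
                                         variant = variant)
    bg <- function(k, locus = "background")
      for (i in seq_len(k)) add("", locus)
    if (profile$organization == "clustered") {
      bg(4)
      for (f in c("fimU", "pilW", "pilV", "pilY1", "pilX")) add(f, "minor1")
      bg(6)
      for (f in c("fimU", "pilW", "pilV", "pilY1", "pilX")) add(f, "minor2")
      bg(6)
      add("pilW", "wx"); bg(1, "wx_gap"); add("pilY1", "wx")
      bg(6)
      rs_seen <- 0L
      for (f in main_locus_layout()) {
        if (f == "pilRS") {
          rs_seen <- rs_seen + 1L
          add("pilRS", "main", variant = if (rs_seen %% 2L == 1L) 2L else 1L)
        } else {
          add(f, "main")
          if (f == "pilA" && profile$tandem_pila) add("pilA", "main")
        }
      }
      add("ribF", "anchor")
      bg(6)
      extra_pila <- profile$n_pila_paralogs - 1L -
        (if (profile$tandem_pila) 1L else 0L)
      singles <- c("pilD", "pilF", "pilE", rep("pilA", max(extra_pila, 0L)),
                   head(c("t2ssE", "t2ssF", "t2ssO"),
                        profile$decoy_families))
      for (f in singles) { add(f, "singleton"); bg(6) }
      bg(3)
    } else {
      bg(4)
      for (f in c("pilM", "pilN", "pilO", "pilP", "pilQ")) add(f, "mnopq")
      bg(6)
      singles <- c("pilB", "pilT", "pilC", "pilD",
                   rep("pilA", profile$n_pila_paralogs), "tsaP", "ribF",
                   "fimU", "pilV", "pilW", "pilX", "pilE", "pilY1", "pilF",
                   head(c("t2ssE", "t2ssF", "t2ssO"),
                        profile$decoy_families))
      for (f in singles) { add(f, "singleton"); bg(6) }
      add("pilRS", "singleton", 1L); bg(6)
      add("pilRS", "singleton", 2L); bg(3)
    }
    n <- length(plan)
    gid <- sprintf("g%04d", seq_len(n))
    fams <- vapply(plan, `[[`, "", "fam")
    locus <- vapply(plan, `[[`, "", "locus")
    variant <- vapply(plan, function(p) as.integer(p$variant), integer(1))
    proteins <- character(n)
    products <- character(n)
    for (i in seq_len(n)) {
      f <- fams[i]
      if (f == "") {
        proteins[i] <- random_protein(sample(80:160, 1))
        products[i] <- sample(background_vocab, 1)
      } else {
        src <- anc[[f]][[min(variant[i], length(anc[[f]]))]]
        proteins[i] <- if (f %in% pilin_families())
          mutate_pilin(src, profile$divergence)
        else mutate_protein(src, profile$divergence)
        products[i] <- unname(product_for_family(f))
      }
    }
    glen <- 3L * (nchar(proteins) + 1L)
    inter <- sample(50:250, n, replace = TRUE)
    start <- cumsum(c(inter[1], glen[-n] + inter[-1])) + 1L
    end <- start + glen - 1L
    strand <- ifelse(fams == "", sample(c("+", "-"), n, replace = TRUE), "+")
    gid_name <- paste0("sim", profile$seed, "_",
                       substr(profile$organization, 1, 4))
    genome <- new_genome(
      gid_name,
      contigs = data.frame(contig_id = "c1",
                           length = max(end) + 100L,
                           stringsAsFactors = FALSE),
      genes = data.frame(gene_id = gid, contig_id = "c1", start = start,
                         end = end, strand = strand, product = products,
                         stringsAsFactors = FALSE),
      proteins = setNames(proteins, gid))
    cuts <- data.frame(contig_id = character(0),
                       after_locus_index = integer(0))
    if (profile$fragmentation > 0) {
      ncut <- min(rpois(1, profile$fragmentation), n - 2L)
      if (ncut > 0) {
        after <- sort(sample(seq_len(n - 1L) - 1L, ncut))
        cuts <- data.frame(contig_id = "c1", after_locus_index = after,
                           stringsAsFactors = FALSE)
        genome <- fragment_genome(genome, cuts)
      }
    }
    truth <- data.frame(gene_id = gid,
                        true_family = ifelse(fams == "", "background", fams),
                        locus = locus,
                        in_main_cluster = locus == "main",
                        stringsAsFactors = FALSE)
    attr(truth, "organization") <- profile$organization
    attr(truth, "cuts") <- cuts
    list(genome = genome, truth = truth)
  })
}

#' Split genome contigs at given intergenic points
#'
#' Emulates draft-assembly fragmentation: each cut after `after_locus_index`
#' (0-based, cut lies between that gene and the next) splits the contig into
#' pieces named `<contig>_p1`, `<contig>_p2`, ...; coordinates are rebased
#' per piece and locus indices recomputed.  Deterministic.
#'
#' @param genome A `t4_genome`.
#' @param cuts `data.frame` with `contig_id`, `after_locus_index`.
#' @return The fragmented `t4_genome`.
#' @export
fragment_genome <- function(genome, cuts) {
  g <- genome$genes
  new_genes <- list()
  new_contigs <- list()
  for (ct in genome$contigs$contig_id) {
    rows <- g[g$contig_id == ct, , drop = FALSE]
    cc <- sort(cuts$after_locus_index[cuts$contig_id == ct])
    if (length(cc) == 0 || nrow(rows) == 0) {
      new_genes[[length(new_genes) + 1L]] <- rows
      new_contigs[[length(new_contigs) + 1L]] <-
        genome$contigs[genome$contigs$contig_id == ct, , drop = FALSE]
      next
    }
    rows <- rows[order(rows$locus_index), , drop = FALSE]
    piece <- findInterval(rows$locus_index, cc + 0.5) + 1L
    for (p in sort(unique(piece))) {
      pr <- rows[piece == p, , drop = FALSE]
      base <- min(pr$start) - 51L
      pr$start <- pr$start - base
      pr$end <- pr$end - base
      pid <- paste0(ct, "_p", p)
      pr$contig_id <- pid
      new_genes[[length(new_genes) + 1L]] <- pr
      new_contigs[[length(new_contigs) + 1L]] <-
        data.frame(contig_id = pid, length = max(pr$end) + 50L,
                   stringsAsFactors = FALSE)
    }
  }
  new_genome(genome$genome_id, genome$taxon_label,
             do.call(rbind, new_contigs), do.call(rbind, new_genes),
             genome$proteins)
}

#' Generate a cohort of synthetic genomes
#'
#' Per-genome seeds are derived from the master seed, so the whole cohort is
#' reproducible from one integer.  The first `round(n * mix)` genomes are
#' clustered, the rest dispersed; pilA paralog counts are drawn 1..7 and
#' divergence uniformly from `divergence_range`.
#'
#' @param n Number of genomes (>= 1).
#' @param mix Fraction of clustered genomes in `[0, 1]` (default 0.5).
#' @param seed Master integer seed.
#' @param panel_set Panel from [generate_panel()]; generated from `seed`
#'   when omitted.
#' @param divergence_range Length-2 numeric (default `c(0.05, 0.35)`).
#' @param fragmentation Expected contig breaks per genome (default 0).
#' @return List of class `t4_cohort`: `genomes` (list of `t4_genome`),
#'   `gene_truth` (named list of per-gene truth tables), `truth`
#'   (per-genome data.frame: `genome_id`, `seed`, `organization`,
#'   `n_pila_paralogs`, `divergence`), `panel_set`.
#' @export
generate_cohort <- function(n, mix = 0.5, seed = 1, panel_set = NULL,
                            divergence_range = c(0.05, 0.35),
                            fragmentation = 0) {
  stopifnot(n >= 1, mix >= 0, mix <= 1)
  if (is.null(panel_set)) panel_set <- generate_panel(seed)
  pars <- with_seed(seed, {
    data.frame(seed = sample.int(.Machine$integer.max - 1L, n),
               organization = rep(c("clustered", "dispersed"),
                                  c(round(n * mix), n - round(n * mix))),
               n_pila = sample(1:7, n, replace = TRUE),
               divergence = runif(n, divergence_range[1],
                                  divergence_range[2]),
               stringsAsFactors = FALSE)
  })
  genomes <- vector("list", n)
  gene_truth <- vector("list", n)
  ids <- character(n)
  for (i in seq_len(n)) {
    pf <- sim_profile(pars$organization[i], n_pila_paralogs = pars$n_pila[i],
                      divergence = pars$divergence[i],
                      fragmentation = fragmentation, seed = pars$seed[i])
    gg <- generate_genome(pf, panel_set)
    gg$genome$genome_id <- sprintf("sim%03d_%s", i,
                                   substr(pars$organization[i], 1, 4))
    gg$genome$taxon_label <- gg$genome$genome_id
    genomes[[i]] <- gg$genome
    gene_truth[[i]] <- gg$truth
    ids[i] <- gg$genome$genome_id
  }
  names(genomes) <- names(gene_truth) <- ids
  truth <- data.frame(genome_id = ids, seed = pars$seed,
                      organization = pars$organization,
                      n_pila_paralogs = pars$n_pila,
                      divergence = pars$divergence, stringsAsFactors = FALSE)
  structure(list(genomes = genomes, gene_truth = gene_truth, truth = truth,
                 panel_set = panel_set), class = "t4_cohort")
}
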