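#' Configuration for the OBP family simulator
#'
#' Defines the generative model behind [simulate_family()]: a random
#' rooted gene tree whose root sequence carries the six-cysteine scaffold,
#' background substitutions that never create cysteines, branch-placed
#' cysteine-loss events whose rate for the disulphide partner of an
#' already-lost cysteine is multiplied by `partner_multiplier` (the
#' relaxed-constraint hypothesis; `1` gives the random-loss null), and
#' tandem fusion events that duplicate the mature domain once per lineage.
#'
#' @param n_leaves Number of genes (tree leaves), >= 2.
#' @param seed Integer seed; the simulation is deterministic given the
#'   full configuration.
#' @param loss_rate Expected losses per branch per extant cysteine.
#' @param partner_multiplier Rate multiplier (>= 1) for a cysteine whose
#'   bond partner is already lost.
#' @param fusion_probability Per-branch probability of a tandem fusion.
#' @param substitution_rate Per-site per-branch replacement probability at
#'   non-canonical sites.
#' @param scaffold_spacings Inter-cysteine gap ranges,
#'   see [default_scaffold_spacings()].
#' @param domain_length Total root protein length in residues, including
#'   the signal-like leader before `mature_start`.
#' @param mature_start First residue of the mature protein (default 25).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_leaves = 20L, seed = 1L,
                              loss_rate = 0.02, partner_multiplier = 1,
                              fusion_probability = 0,
                              substitution_rate = 0.02,
                              scaffold_spacings = default_scaffold_spacings(),
                              domain_length = 160L, mature_start = 25L) {
  cfg <- list(n_leaves = as.integer(n_leaves), seed = as.integer(seed),
              loss_rate = loss_rate, partner_multiplier = partner_multiplier,
              fusion_probability = fusion_probability,
              substitution_rate = substitution_rate,
              scaffold_spacings = scaffold_spacings,
              domain_length = as.integer(domain_length),
              mature_start = as.integer(mature_start))
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  if (cfg$n_leaves < 2L) stop("n_leaves must be >= 2")
  if (cfg$loss_rate < 0 || cfg$substitution_rate < 0) {
    stop("rates must be >= 0")
  }
  if (cfg$partner_multiplier < 1) stop("partner_multiplier must be >= 1")
  if (cfg$fusion_probability < 0 || cfg$fusion_probability > 1) {
    stop("fusion_probability must lie in [0, 1]")
  }
  sp <- cfg$scaffold_spacings
  if (!is.matrix(sp) || nrow(sp) != 5L || ncol(sp) != 2L ||
      any(sp[, 1] > sp[, 2]) || any(sp < 0)) {
    stop("scaffold_spacings must be a 5 x 2 matrix of valid gap ranges")
  }
  max_c6 <- cfg$mature_start + 6L + sum(sp[, 2] + 1L)
  if (cfg$domain_length < max_c6 + 10L) {
    stop("domain_length too short for the scaffold: need >= ",
         max_c6 + 10L)
  }
  invisible(cfg)
}

# disulphide partner index for cysteine i under C1-C3, C2-C5, C4-C6
BOND_PARTNER <- c(3L, 5L, 1L, 6L, 2L, 4L)

#' Simulate an OBP gene family with known ground truth
#'
#' Generates a rooted random gene tree, evolves a scaffold-bearing root
#' protein along it, places cysteine-loss and tandem-fusion events, and
#' returns the family together with the true event log, the true residue
#' homology (as an alignment) and per-gene exon/intron structures. Since
#' the model has no indels, single-domain genes align without gaps and the
#' true canonical columns equal the root cysteine positions; fusion genes
#' carry the duplicated mature region in an appended alignment block.
#'
#' @param config A [simulation_config()].
#' @return Object of class `obp_synthetic_family`: list with `tree`
#'   (`phylo`, node-labelled), `sequences` (named character), `alignment`
#'   (`obp_alignment` of the true homology), `structures` (named list of
#'   [gene_structure()]), `truth_events` (`obp_loss_events`),
#'   `truth_fusions` (data.frame `branch`, `junction`),
#'   `scaffold_columns` (true canonical columns) and `config`.
#' @export
simulate_family <- function(config = simulation_config()) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_leaves
  tree <- ape::rtree(n, rooted = TRUE)
  tree$tip.label <- sprintf("gene%02d", seq_len(n))
  tree$node.label <- paste0("n", (n + 1L):(n + tree$Nnode))

  L0 <- config$domain_length
  ms <- config$mature_start
  sp <- config$scaffold_spacings
  # root scaffold: lead-in after the mature start, then sampled gaps
  pos <- integer(6)
  pos[1] <- ms + sample(2:6, 1L)
  for (k in 1:5) {
    gap <- if (sp[k, 1] == sp[k, 2]) sp[k, 1] else
      sample(sp[k, 1]:sp[k, 2], 1L)
    pos[k + 1] <- pos[k] + gap + 1L
  }
  root_seq <- sample(AA_NO_C, L0, replace = TRUE)
  root_seq[pos] <- "C"

  root <- tree_root(tree)
  n_nodes <- max(tree$edge)
  states <- vector("list", n_nodes)
  states[[root]] <- list(seq = root_seq, present = rep(TRUE, 6L),
                         fused = FALSE)
  event_log <- list()    # per-branch lost cysteine indices
  fusion_log <- list()
  edges <- ape::reorder.phylo(tree, "cladewise")$edge  # preorder

  for (k in seq_len(nrow(edges))) {
    parent <- edges[k, 1]; child <- edges[k, 2]
    st <- states[[parent]]
    seqv <- st$seq; present <- st$present; fused <- st$fused
    # background substitutions (never create or protect-break cysteines
    # at extant canonical positions; replacements are never cysteine)
    protected <- pos[present]
    hit <- which(runif(length(seqv)) < config$substitution_rate)
    hit <- setdiff(hit, protected)
    if (length(hit)) {
      seqv[hit] <- sample(AA_NO_C, length(hit), replace = TRUE)
    }
    # cysteine losses; within-branch order is random so the partner
    # multiplier can act on same-branch double losses
    lost_here <- integer(0)
    for (ci in sample.int(6L)) {
      if (!present[ci]) next
      mult <- if (!present[BOND_PARTNER[ci]]) config$partner_multiplier
              else 1
      if (runif(1) < 1 - exp(-config$loss_rate * mult)) {
        present[ci] <- FALSE
        seqv[pos[ci]] <- sample(AA_NO_C, 1L)
        lost_here <- c(lost_here, ci)
      }
    }
    if (length(lost_here)) {
      event_log[[length(event_log) + 1L]] <-
        list(node = child, lost = sort(lost_here))
    }
    # at most one tandem fusion per lineage
    if (!fused && runif(1) < config$fusion_probability) {
      junction <- length(seqv) + 1L
      seqv <- c(seqv, seqv[ms:length(seqv)])
      fused <- TRUE
      fusion_log[[length(fusion_log) + 1L]] <-
        list(node = child, junction = junction)
    }
    states[[child]] <- list(seq = seqv, present = present, fused = fused)
  }

  tips <- seq_len(n)
  sequences <- vapply(tips, function(i)
    paste(states[[i]]$seq, collapse = ""), character(1))
  names(sequences) <- tree$tip.label

  # true-homology alignment: base block plus one fusion block
  M <- L0 - ms + 1L
  any_fused <- any(vapply(tips, function(i) states[[i]]$fused, TRUE))
  aligned <- vapply(tips, function(i) {
    s <- sequences[[i]]
    if (!any_fused) return(s)
    if (states[[i]]$fused) s else
      paste0(s, strrep("-", M))
  }, character(1))
  alignment <- new_alignment(tree$tip.label, aligned)

  below <- descendant_leaves(tree)
  truth_events <- structure(lapply(event_log, function(ev) {
    lv <- below[[ev$node]]
    list(branch = node_label(tree, ev$node), node = ev$node,
         lost = CYS_LABELS[ev$lost],
         affected_genes = sort(tree$tip.label[lv[lv <= n]]))
  }), class = "obp_loss_events")
  truth_fusions <- if (length(fusion_log)) {
    data.frame(branch = vapply(fusion_log, function(f)
                 node_label(tree, f$node), character(1)),
               junction = vapply(fusion_log, `[[`, 0L, "junction"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(branch = character(0), junction = integer(0))
  }

  structures <- lapply(tips, function(i)
    make_structure(tree$tip.label[i], states[[i]], L0, ms))
  names(structures) <- tree$tip.label

  structure(list(tree = tree, sequences = sequences,
                 alignment = alignment, structures = structures,
                 truth_events = truth_events,
                 truth_fusions = truth_fusions,
                 scaffold_columns = stats::setNames(pos, CYS_LABELS),
                 config = config),
            class = "obp_synthetic_family")
}

# two exons per domain with an internal phase-1 intron; fused genes add a
# phase-0 inter-domain intron at the junction
make_structure <- function(gene_id, st, L0, ms) {
  Ltot <- length(st$seq)
  k0 <- L0 %/% 2L
  if (!st$fused) {
    exons <- rbind(c(1L, 3L * k0 + 1L), c(3L * k0 + 2L, 3L * L0))
    return(gene_structure(gene_id, exons, 1L))
  }
  junction <- L0 + 1L
  M <- Ltot - L0
  k2 <- L0 + M %/% 2L
  exons <- rbind(c(1L, 3L * k0 + 1L),
                 c(3L * k0 + 2L, 3L * L0),
                 c(3L * L0 + 1L, 3L * k2 + 1L),
                 c(3L * k2 + 2L, 3L * Ltot))
  gene_structure(gene_id, exons, c(1L, 0L, 1L))
}

#' @export
print.obp_synthetic_family <- function(x, ...) {
  cat("obp_synthetic_family:", length(x$sequences), "genes,",
      length(x$truth_events), "loss event(s),",
      nrow(x$truth_fusions), "fusion(s)\n")
  invisible(x)
}

#' Write a simulated family to disk
#'
#' Emits unaligned and aligned FASTA, a Newick tree, the gene structures
#' and the ground-truth logs as plain-text files that round-trip through
#' the package readers.
#'
#' @param family An `obp_synthetic_family`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_family <- function(family, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    sequences = file.path(out_dir, "sequences.fasta"),
    alignment = file.path(out_dir, "alignment.fasta"),
    tree = file.path(out_dir, "tree.nwk"),
    structures = file.path(out_dir, "structures.tsv"),
    truth_events = file.path(out_dir, "truth_events.tsv"),
    truth_fusions = file.path(out_dir, "truth_fusions.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(family$sequences), paths[["sequences"]])
  writeLines(paste0(">", family$alignment$ids, "\n",
                    family$alignment$seqs), paths[["alignment"]])
  ape::write.tree(family$tree, paths[["tree"]])
  write_structures(family$structures, paths[["structures"]])
  ev <- family$truth_events
  df <- data.frame(
    branch = vapply(ev, `[[`, character(1), "branch"),
    lost_set = vapply(ev, function(e) paste(e$lost, collapse = "/"),
                      character(1)),
    affected_genes = vapply(ev, function(e)
      paste(e$affected_genes, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  write.table(df, paths[["truth_events"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(family$truth_fusions, paths[["truth_fusions"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write gene structures as a GFF-like TSV
#'
#' One row per exon: `gene_id`, `exon_index`, `start`, `end`,
#' `phase_after` (intron phase following the exon; `NA` for the last).
#'
#' @param structures Named list of [gene_structure()] objects.
#' @param path Output path.
#' @export
write_structures <- function(structures, path) {
  rows <- lapply(structures, function(st) {
    ne <- nrow(st$exons)
    data.frame(gene_id = st$gene_id, exon_index = seq_len(ne),
               start = st$exons[, 1], end = st$exons[, 2],
               phase_after = c(st$intron_phases, NA),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read gene structures written by [write_structures()]
#'
#' @param path TSV path.
#' @return Named list of [gene_structure()] objects.
#' @export
read_structures <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$gene_id), function(g) {
    g <- g[order(g$exon_index), ]
    gene_structure(g$gene_id[1], cbind(g$start, g$end),
                   head(g$phase_after, -1L))
  })
  out[unique(df$gene_id)]
}

#' Read a truth-event TSV written by [write_family()]
#'
#' @param path TSV path.
#' @return An `obp_loss_events` list.
#' @export
read_truth_events <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  structure(lapply(seq_len(nrow(df)), function(i) {
    list(branch = df$branch[i], node = NA_integer_,
         lost = strsplit(df$lost_set[i], "/", fixed = TRUE)[[1]],
         affected_genes = strsplit(df$affected_genes[i], ",",
                                   fixed = TRUE)[[1]])
  }), class = "obp_loss_events")
}
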