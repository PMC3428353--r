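#' Gene structure on the coding sequence
#'
#' @param gene_id Gene name.
#' @param exons Two-column matrix (or data.frame) of 1-based inclusive
#'   exon start/end coordinates on the coding sequence, ascending and
#'   non-overlapping.
#' @param intron_phases Integer vector in {0,1,2}, one per intron
#'   (i.e. one fewer than the number of exons).
#' @return List of class `gene_structure`.
#' @export
gene_structure <- function(gene_id, exons, intron_phases = integer(0)) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  if (ncol(exons) != 2L) stop("exons must have two columns (start, end)")
  if (any(exons[, 1] > exons[, 2])) stop("exon start after end")
  if (nrow(exons) > 1L) {
    if (any(diff(exons[, 1]) <= 0) ||
        any(exons[-1, 1] <= exons[-nrow(exons), 2])) {
      stop("exons must be ascending and non-overlapping")
    }
  }
  intron_phases <- as.integer(intron_phases)
  if (length(intron_phases) != nrow(exons) - 1L) {
    stop("need one intron phase per intron (exons - 1)")
  }
  if (length(intron_phases) && !all(intron_phases %in% 0:2)) {
    stop("intron phases must be 0, 1 or 2")
  }
  structure(list(gene_id = gene_id, exons = unname(exons),
                 intron_phases = intron_phases),
            class = "gene_structure")
}

# protein residues at which splice sites fall: the residue containing the
# splice (phase 1/2) or the first residue of the next exon (phase 0)
splice_residues <- function(structure) {
  if (is.null(structure)) return(integer(0))
  ends <- structure$exons[, 2]
  if (length(ends) < 2L) return(integer(0))
  e <- head(ends, -1L)
  as.integer(ifelse(e %% 3L == 0L, e %/% 3L + 1L, e %/% 3L + 1L))
}

#' Default inter-cysteine spacing ranges of the OBP scaffold
#'
#' Number of residues strictly between consecutive canonical cysteines.
#' The C2-C3 gap of exactly three residues is the hallmark of the fold;
#' the other ranges are generous envelopes around typical classic-OBP
#' spacings.
#'
#' @return 5 x 2 integer matrix of (min, max) gaps, rows C1-C2 .. C5-C6.
#' @export
default_scaffold_spacings <- function() {
  m <- rbind(c(20L, 32L),   # C1-C2
             c(3L, 3L),     # C2-C3
             c(28L, 42L),   # C3-C4
             c(8L, 14L),    # C4-C5
             c(8L, 14L))    # C5-C6
  rownames(m) <- c("C1-C2", "C2-C3", "C3-C4", "C4-C5", "C5-C6")
  colnames(m) <- c("min", "max")
  m
}

#' Find canonical cysteine scaffold matches in a protein sequence
#'
#' Scans left to right for chains of six cysteines whose consecutive gaps
#' fall within the scaffold spacing ranges; matches are non-overlapping
#' (greedy from the left, with backtracking within a chain).
#'
#' @param sequence Protein string.
#' @param spacings Gap ranges as from [default_scaffold_spacings()].
#' @return List of integer vectors of length 6 (residue positions of
#'   C1..C6 per match); empty list if none.
#' @export
find_scaffold_matches <- function(sequence,
                                  spacings = default_scaffold_spacings()) {
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  cpos <- which(s == "C")
  matches <- list()
  from <- 1L
  extend <- function(chain, depth) {
    if (depth == 6L) return(chain)
    last <- chain[depth]
    lo <- last + spacings[depth, 1] + 1L
    hi <- last + spacings[depth, 2] + 1L
    for (p in cpos[cpos >= lo & cpos <= hi]) {
      res <- extend(c(chain, p), depth + 1L)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  repeat {
    starts <- cpos[cpos >= from]
    found <- NULL
    for (p in starts) {
      found <- extend(p, 1L)
      if (!is.null(found)) break
    }
    if (is.null(found)) break
    matches[[length(matches) + 1L]] <- found
    from <- found[6] + 1L
  }
  matches
}

#' Call the domain architecture of an OBP sequence
#'
#' Classifies a protein as a single-domain OBP, a tandem double-domain OBP,
#' or a vestigial double (one intact domain plus the remnant of a former
#' second domain). A double call requires either two non-overlapping
#' cysteine-scaffold matches, or exceptional length combined with an
#' off-diagonal self-dotplot run. A vestigial call requires one intact
#' scaffold plus at least two of three remnant evidence types: a stray
#' remnant cysteine, a splice site in the remnant, and an exon count
#' exceeding a single domain's.
#'
#' @param sequence Protein string.
#' @param gene_id Optional gene name carried through to the result.
#' @param profile_hits Optional precomputed scaffold matches (list of
#'   six-position vectors); computed with [find_scaffold_matches()] when
#'   `NULL`.
#' @param structure Optional [gene_structure()].
#' @param min_double_length Length (aa) above which a gene is exceptionally
#'   long for a single OBP domain (default 250).
#' @param window,min_run,min_mean Dotplot parameters, see [self_dotplot()].
#' @param spacings Scaffold spacing ranges for the matcher.
#' @return Object of class `obp_architecture`: list with `gene_id`, `call`
#'   (`"single"`, `"double"`, `"vestigial_double"`), `boundary` (first
#'   residue of domain 2, `NA` unless double/vestigial), `domain_profiles`,
#'   `evidence` (logical flags `dotplot`, `splice`, `cysteine`, `length`),
#'   plus the scaffold `hits` and the `dotplot` used.
#' @export
detect_architecture <- function(sequence, gene_id = NA_character_,
                                profile_hits = NULL, structure = NULL,
                                min_double_length = 250L, window = 15L,
                                min_run = 30L, min_mean = 1.0,
                                spacings = default_scaffold_spacings()) {
  s <- toupper(sequence)
  n <- nchar(s)
  hits <- if (is.null(profile_hits)) {
    find_scaffold_matches(s, spacings)
  } else {
    profile_hits
  }
  dp <- NULL
  if (n >= window + min_run) {
    dp <- self_dotplot(s, window = window, min_run = min_run,
                       min_mean = min_mean)
  }
  run <- best_run(dp)
  has_run <- !is.null(run)

  call <- "single"
  boundary <- NA_integer_
  ev_splice <- FALSE
  ev_cys <- FALSE
  if (length(hits) >= 2L || (n > min_double_length && has_run)) {
    call <- "double"
    # the dotplot run pins the junction directly (start of the second
    # repeat copy); scaffold-hit arithmetic assumes an equal lead-in
    # before each domain copy and is only a fallback
    boundary <- if (has_run) {
      run_boundary(run, window)
    } else {
      max(2L, hits[[2]][1] - (hits[[1]][1] - 1L))
    }
  } else if (length(hits) == 1L) {
    hit <- hits[[1]]
    # remnant = sequence clearly outside the matched domain
    margin_n <- max(1L, hit[1] - 30L)
    margin_c <- min(n, hit[6] + 25L)
    cys_all <- gregexpr("C", s, fixed = TRUE)[[1]]
    cys_all <- cys_all[cys_all > 0]
    ev_cys <- any(cys_all < margin_n) || any(cys_all > margin_c)
    spl <- splice_residues(structure)
    ev_splice <- any(spl < margin_n) || any(spl > margin_c)
    ev_exons <- !is.null(structure) && nrow(structure$exons) > 2L
    if (sum(c(ev_cys, ev_splice, ev_exons)) >= 2L) {
      call <- "vestigial_double"
      boundary <- if (any(cys_all > margin_c)) {
        as.integer(margin_c + 1L)
      } else {
        hit[1]
      }
    }
  }
  profiles <- domain_cys_profiles(s, call, boundary, spacings)
  structure(list(gene_id = gene_id, call = call,
                 boundary = boundary,
                 domain_profiles = profiles,
                 evidence = c(dotplot = has_run,
                              splice = ev_splice,
                              cysteine = ev_cys || length(hits) >= 2L,
                              length = n > min_double_length),
                 hits = hits, dotplot = dp,
                 sequence = s),
            class = "obp_architecture")
}

best_run <- function(dp) {
  if (is.null(dp) || nrow(dp$diagonals) == 0L) return(NULL)
  d <- dp$diagonals
  d[order(-d$length, -d$mean_score), ][1, , drop = FALSE]
}

# junction estimate from a dotplot run: start of the second repeat copy.
# A window passes the threshold once roughly half its residues are
# homologous, so a run whose start is interior begins about half a window
# before the true junction; a run at the diagonal's left edge is bounded
# by the matrix, not by fading homology, and needs no correction.
run_boundary <- function(run, window) {
  corr <- if (run$start > 1L) window %/% 2L else 0L
  as.integer(run$start + run$offset + corr)
}

# crude per-domain cysteine profile: count + scaffold positions if found
domain_cys_profiles <- function(s, call, boundary, spacings) {
  count_cys <- function(str) {
    lengths(regmatches(str, gregexpr("C", str, fixed = TRUE)))
  }
  one <- function(str, offset = 0L) {
    m <- find_scaffold_matches(str, spacings)
    list(n_cysteines = unname(count_cys(str)),
         scaffold = if (length(m)) m[[1]] + offset else NULL)
  }
  if (call %in% c("double", "vestigial_double") && !is.na(boundary)) {
    d1 <- substr(s, 1L, boundary - 1L)
    d2 <- substr(s, boundary, nchar(s))
    list(domain1 = one(d1), domain2 = one(d2, offset = boundary - 1L))
  } else {
    list(domain1 = one(s))
  }
}

#' @export
print.obp_architecture <- function(x, ...) {
  cat("obp_architecture:", x$gene_id, "-", x$call)
  if (!is.na(x$boundary)) cat(" (domain 2 from residue", x$boundary, ")")
  cat("\n  evidence:",
      paste(names(x$evidence)[x$evidence], collapse = ", "), "\n")
  invisible(x)
}

#' Pinpoint the boundary between two tandem OBP domains
#'
#' Refines the domain boundary of a double (or vestigial-double) call:
#' the raw boundary is the start of the second copy of the best
#' off-diagonal dotplot run (or the scaffold-derived boundary when no run
#' exists), then snapped to the nearest splice-site residue within
#' `snap_radius`, subject to the constraint that each domain contains its
#' cysteine scaffold in order. If no candidate boundary separates the two
#' scaffolds the boundary is ambiguous and an error lists the candidates.
#'
#' @param arch An `obp_architecture` with call `double` or
#'   `vestigial_double`.
#' @param dotplot Dotplot to use (defaults to the one stored in `arch`).
#' @param structure Optional [gene_structure()] supplying splice sites.
#' @param snap_radius Maximum snapping distance in residues (default 10).
#' @return The architecture with `boundary` finalised, `domains` (the two
#'   residue strings) and refreshed `domain_profiles`; splice evidence flag
#'   updated when snapping was applied.
#' @export
delimit_domains <- function(arch, dotplot = arch$dotplot, structure = NULL,
                            snap_radius = 10L) {
  if (!arch$call %in% c("double", "vestigial_double")) {
    stop("delimit_domains requires a double or vestigial_double call")
  }
  s <- arch$sequence
  n <- nchar(s)
  run <- best_run(dotplot)
  raw <- if (!is.null(run)) {
    run_boundary(run, dotplot$window)
  } else {
    arch$boundary
  }
  if (is.na(raw)) stop("no boundary evidence: neither dotplot run nor ",
                       "scaffold-derived boundary available")
  raw <- as.integer(min(max(raw, 2L), n))

  ok <- function(b) {
    if (length(arch$hits) < 2L) return(TRUE)
    all(arch$hits[[1]] < b) && all(arch$hits[[2]] >= b)
  }
  spl <- splice_residues(structure)
  snapped <- NA_integer_
  if (length(spl)) {
    near <- spl[abs(spl - raw) <= snap_radius]
    if (length(near)) {
      near <- near[order(abs(near - raw), near)]
      near <- near[vapply(near, ok, TRUE)]
      if (length(near)) snapped <- near[1]
    }
  }
  boundary <- if (!is.na(snapped)) snapped else raw
  if (!ok(boundary)) {
    cand <- unique(c(raw, spl))
    cand <- cand[vapply(cand, ok, TRUE)]
    if (length(cand) == 0L) {
      stop("ambiguous boundary: scaffolds interleave; candidates tried: ",
           paste(unique(c(raw, spl)), collapse = ", "))
    }
    boundary <- cand[order(abs(cand - raw))][1]
  }
  arch$boundary <- as.integer(boundary)
  arch$domains <- split_domains(s, boundary)
  arch$domain_profiles <- domain_cys_profiles(s, arch$call, boundary,
                                              default_scaffold_spacings())
  arch$evidence["splice"] <- arch$evidence["splice"] || !is.na(snapped)
  arch
}

#' Split a protein at a domain boundary
#'
#' @param sequence Protein string.
#' @param boundary First residue of domain 2 (1-based).
#' @return Character vector `c(domain1, domain2)`; concatenating the two
#'   reproduces the input exactly.
#' @export
split_domains <- function(sequence, boundary) {
  n <- nchar(sequence)
  boundary <- as.integer(boundary)
  if (boundary < 2L || boundary > n) {
    stop("boundary must lie in [2, sequence length]")
  }
  c(substr(sequence, 1L, boundary - 1L), substr(sequence, boundary, n))
}

#' Write architecture calls as TSV
#'
#' @param archs List of `obp_architecture` objects.
#' @param path Output path.
#' @export
write_architecture_table <- function(archs, path) {
  df <- data.frame(
    gene_id = vapply(archs, `[[`, character(1), "gene_id"),
    call = vapply(archs, `[[`, character(1), "call"),
    boundary = vapply(archs, function(a) as.integer(a$boundary), 0L),
    evidence_dotplot = vapply(archs, function(a) a$evidence[["dotplot"]],
                              TRUE),
    evidence_splice = vapply(archs, function(a) a$evidence[["splice"]],
                             TRUE),
    evidence_cysteine = vapply(archs, function(a) a$evidence[["cysteine"]],
                               TRUE),
    evidence_length = vapply(archs, function(a) a$evidence[["length"]],
                             TRUE),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
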