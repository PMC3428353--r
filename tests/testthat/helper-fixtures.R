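# Builders for tiny in-memory fixtures used across the tests.

# write an aligned FASTA and return the path
write_fasta <- function(seqs, ids = names(seqs)) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), tf)
  tf
}

# toy alignment whose six cysteine columns are 10, 40, 44, 80, 92, 101
# (C2 at 40 and C3 at 44 are separated by exactly three residues)
toy_scaffold_alignment <- function(n_seq = 4L, ncol = 110L, mutate = NULL) {
  cols <- c(10L, 40L, 44L, 80L, 92L, 101L)
  base <- rep("A", ncol)
  seqs <- vapply(seq_len(n_seq), function(i) {
    s <- base
    s[setdiff(seq(2, ncol, by = 7), cols)] <- "G"  # some variety
    s[cols] <- "C"
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("seq", seq_len(n_seq))
  if (!is.null(mutate)) {
    for (m in mutate) {
      s <- strsplit(seqs[[m$id]], "")[[1]]
      s[m$pos] <- m$res
      seqs[[m$id]] <- paste(s, collapse = "")
    }
  }
  aln <- obpscaffold:::new_alignment(names(seqs), seqs)
  list(aln = aln, cols = obpscaffold:::new_canonical_columns(cols, ncol))
}

# four-leaf tree ((A,B),(C,D)); with node labels
quartet_tree <- function() {
  tr <- ape::read.tree(text = "((A,B)ab,(C,D)cd)r;")
  tr
}

# profile data.frame in the P/A/U layout for given absence patterns;
# `absent` is a named list id -> character vector of lost cysteines,
# `unknown` likewise
make_profiles <- function(ids, absent = list(), unknown = list()) {
  codes <- matrix("P", length(ids), 6,
                  dimnames = list(ids, paste0("C", 1:6)))
  for (id in names(absent)) codes[id, absent[[id]]] <- "A"
  for (id in names(unknown)) codes[id, unknown[[id]]] <- "U"
  data.frame(sequence_id = ids, codes, extra_cysteines = 0L,
             subfamily = NA_character_, row.names = NULL,
             stringsAsFactors = FALSE)
}

# random rooted tree with n leaves labelled t1..tn
random_tree <- function(n) {
  tr <- ape::rtree(n, rooted = TRUE)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# a protein with a single canonical scaffold and a fixed spacing draw
scaffold_protein <- function(domain_length = 160L, mature_start = 25L,
                             lead = 4L, gaps = c(26L, 3L, 35L, 11L, 11L),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa_no_c <- setdiff(c("A","R","N","D","Q","E","G","H","I","L","K","M",
                       "F","P","S","T","W","Y","V"), "C")
  s <- sample(aa_no_c, domain_length, replace = TRUE)
  pos <- integer(6)
  pos[1] <- mature_start + lead
  for (k in 1:5) pos[k + 1] <- pos[k] + gaps[k] + 1L
  s[pos] <- "C"
  list(seq = paste(s, collapse = ""), pos = pos)
}
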