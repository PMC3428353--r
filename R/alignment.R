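#' Read a protein multiple sequence alignment
#'
#' Reads an aligned protein FASTA or Clustal file into a light-weight
#' alignment object. Residues are upper-cased and `.` gap characters are
#' normalised to `-`.
#'
#' @param path Path to the alignment file.
#' @param format Either `"fasta"` or `"clustal"`.
#' @return An object of class `obp_alignment`: a list with elements
#'   `ids` (character), `seqs` (named character vector of aligned rows) and
#'   `length` (number of alignment columns).
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "MK-CW", ">b", "MKACW"), tf)
#' aln <- read_alignment(tf)
#' aln$length
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("alignment file not found: ", path)
  }
  if (format == "fasta") {
    set <- Biostrings::readAAStringSet(path)
    ids <- names(set)
    seqs <- as.character(set)
  } else {
    a <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    seqs <- as.character(a)
    ids <- names(seqs)
  }
  if (length(seqs) == 0L) {
    stop("no records in alignment file: ", path)
  }
  # first token of the FASTA header is the id
  ids <- vapply(strsplit(ids, "[ \t]+"), `[`, character(1), 1L)
  new_alignment(ids, seqs)
}

new_alignment <- function(ids, seqs) {
  if (any(!nzchar(ids))) stop("empty sequence id in alignment")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L) {
    mode_w <- as.integer(names(sort(table(widths), decreasing = TRUE))[1])
    bad <- ids[widths != mode_w]
    stop("unequal lengths in alignment: record(s) ",
         paste(bad, collapse = ", "), " differ from ", mode_w, " columns")
  }
  names(seqs) <- ids
  structure(list(ids = ids, seqs = seqs, length = unname(widths[1])),
            class = "obp_alignment")
}

#' @export
print.obp_alignment <- function(x, ...) {
  cat("obp_alignment:", length(x$ids), "sequences x", x$length, "columns\n")
  invisible(x)
}

# alignment as a character matrix (rows = sequences, columns = positions)
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

#' Locate the six canonical cysteine columns of an OBP alignment
#'
#' Finds the alignment columns carrying the six conserved cysteines (C1..C6)
#' of the classic OBP scaffold. In `majority` mode, columns are candidate
#' positions when at least `min_fraction` of the sequences carry a cysteine
#' there; the C2/C3 pair is anchored by the scaffold hallmark that exactly
#' three (ungapped) residues separate them in a majority of sequences, and
#' the remaining columns are the highest-occupancy candidates in order. In
#' `reference` mode the columns are read off named reference sequences that
#' carry exactly six cysteines.
#'
#' @param aln An `obp_alignment`.
#' @param mode `"majority"` or `"reference"`.
#' @param reference_ids Sequence ids used in reference mode.
#' @param min_fraction Minimum fraction of sequences with a cysteine for a
#'   column to be a candidate (default 0.5).
#' @return Integer vector of six strictly increasing 1-based column indices,
#'   named C1..C6, of class `canonical_columns`.
#' @export
locate_canonical_columns <- function(aln, mode = c("majority", "reference"),
                                     reference_ids = NULL,
                                     min_fraction = 0.5) {
  mode <- match.arg(mode)
  m <- alignment_matrix(aln)
  if (mode == "reference") {
    if (is.null(reference_ids) || length(reference_ids) == 0L) {
      stop("reference mode requires reference_ids")
    }
    missing_ids <- setdiff(reference_ids, aln$ids)
    if (length(missing_ids)) {
      stop("reference id(s) not in alignment: ",
           paste(missing_ids, collapse = ", "))
    }
    col_sets <- lapply(reference_ids, function(id) which(m[id, ] == "C"))
    bad <- reference_ids[vapply(col_sets, length, 1L) != 6L]
    if (length(bad)) {
      stop("reference sequence(s) without exactly six cysteines: ",
           paste(bad, collapse = ", "))
    }
    votes <- table(unlist(col_sets))
    cols <- sort(as.integer(names(votes[votes >= length(reference_ids) / 2])))
    if (length(cols) != 6L) {
      stop("reference sequences disagree: ", length(cols),
           " consensus cysteine columns found, need 6")
    }
    return(new_canonical_columns(cols, aln$length))
  }

  occupancy <- colMeans(m == "C")
  cand <- which(occupancy >= min_fraction)
  if (length(cand) < 6L) {
    stop("scaffold not found: only ", length(cand),
         " columns reach cysteine occupancy >= ", min_fraction)
  }
  pair <- find_c2c3_pair(m, cand, occupancy, min_fraction)
  if (is.null(pair)) {
    # no hallmark pair: fall back to the six highest-occupancy columns
    keep <- cand[order(-occupancy[cand], cand)][1:6]
    return(new_canonical_columns(sort(keep), aln$length))
  }
  left <- cand[cand < pair[1]]
  right <- cand[cand > pair[2]]
  if (length(left) < 1L || length(right) < 3L) {
    stop("scaffold not found: C2/C3 anchor at columns ", pair[1], "/",
         pair[2], " leaves ", length(left), " candidate(s) upstream and ",
         length(right), " downstream")
  }
  c1 <- left[order(-occupancy[left], left)][1]
  c456 <- sort(right[order(-occupancy[right], right)][1:3])
  new_canonical_columns(c(c1, pair[1], pair[2], c456), aln$length)
}

# Hallmark search: among candidate columns, the (i, j) pair with exactly
# three non-gap residues between them in >= min_fraction of the sequences
# spanning both; best-supported pair (highest summed occupancy) wins.
find_c2c3_pair <- function(m, cand, occupancy, min_fraction) {
  best <- NULL
  best_score <- -Inf
  for (i in cand) {
    for (j in cand[cand > i]) {
      if (j - i < 4L) next   # need at least 3 residues between
      rows <- m[, i] != "-" & m[, j] != "-"
      if (!any(rows)) next
      between <- if (j - i == 1L) {
        integer(nrow(m))
      } else {
        mm <- m[, (i + 1):(j - 1), drop = FALSE]
        rowSums(mm != "-")
      }
      frac3 <- mean(between[rows] == 3L)
      if (frac3 >= min_fraction) {
        score <- occupancy[i] + occupancy[j]
        if (score > best_score) {
          best_score <- score
          best <- c(i, j)
        }
      }
    }
  }
  best
}

new_canonical_columns <- function(cols, aln_length) {
  cols <- as.integer(cols)
  stopifnot(length(cols) == 6L)
  if (any(diff(cols) <= 0L)) stop("canonical columns must strictly increase")
  if (any(cols < 1L) || any(cols > aln_length)) {
    stop("canonical column outside alignment (length ", aln_length, ")")
  }
  names(cols) <- CYS_LABELS
  structure(cols, class = "canonical_columns")
}

#' Build the cysteine profile of one aligned sequence
#'
#' Records presence/absence of each canonical cysteine, distinguishing
#' genuinely absent (substituted or internally deleted) from unknown
#' (the canonical column falls in a leading/trailing gap run of an
#' incomplete sequence), and counts extra cysteines in the mature region
#' outside the canonical columns.
#'
#' @param aln An `obp_alignment`.
#' @param cols `canonical_columns` for the alignment.
#' @param sequence_id Sequence to profile.
#' @param mature_start 1-based alignment column where the mature protein
#'   starts (default 25, i.e. after a typical signal peptide); cysteines
#'   before it are ignored when counting extras.
#' @return An object of class `cysteine_profile`: list with `sequence_id`,
#'   logical vectors `present` and `unknown` (named C1..C6), and
#'   `extra_cysteines`.
#' @export
profile_sequence <- function(aln, cols, sequence_id, mature_start = 25L) {
  if (!sequence_id %in% aln$ids) {
    stop("unknown sequence id: ", sequence_id)
  }
  s <- strsplit(aln$seqs[[sequence_id]], "", fixed = TRUE)[[1]]
  nongap <- which(s != "-")
  if (length(nongap) == 0L) {
    stop("sequence ", sequence_id, " is all gaps")
  }
  first <- nongap[1]
  last <- nongap[length(nongap)]
  res <- s[cols]
  present <- res == "C"
  unknown <- res == "-" & (cols < first | cols > last)
  names(present) <- names(unknown) <- CYS_LABELS
  mature_start <- max(1L, as.integer(mature_start))
  extra_idx <- setdiff(which(s == "C"), as.integer(cols))
  extra <- sum(extra_idx >= mature_start)
  structure(list(sequence_id = sequence_id,
                 present = present,
                 unknown = unknown,
                 extra_cysteines = extra),
            class = "cysteine_profile")
}

#' Classify a cysteine profile into an OBP subfamily
#'
#' Classic OBPs carry all six canonical cysteines; minus-C OBPs have lost at
#' least one; plus-C OBPs carry additional conserved cysteines beyond the
#' six. Profiles with unknown canonical positions (incomplete sequences)
#' are reported as `"incomplete"` rather than forced into a subfamily.
#'
#' @param p A `cysteine_profile`.
#' @param plus_c_min_extra Minimum number of extra mature-region cysteines
#'   for a plus-C call (default 2, i.e. enough for one additional bond).
#' @return List with `sequence_id` and `subfamily`, one of
#'   `"classic"`, `"minus-C"`, `"plus-C"`, `"incomplete"`.
#' @export
classify_subfamily <- function(p, plus_c_min_extra = 2L) {
  stopifnot(inherits(p, "cysteine_profile"))
  subfamily <- if (any(p$unknown)) {
    "incomplete"
  } else if (any(!p$present)) {
    "minus-C"
  } else if (p$extra_cysteines >= plus_c_min_extra) {
    "plus-C"
  } else {
    "classic"
  }
  list(sequence_id = p$sequence_id, subfamily = subfamily)
}

#' Profile and classify every sequence of an alignment
#'
#' @inheritParams profile_sequence
#' @inheritParams classify_subfamily
#' @return A data.frame with one row per sequence: `sequence_id`, `C1`..`C6`
#'   coded `P` (present) / `A` (absent) / `U` (unknown), `extra_cysteines`
#'   and `subfamily`. The list of `cysteine_profile` objects is attached as
#'   attribute `"profiles"`.
#' @export
profile_alignment <- function(aln, cols, mature_start = 25L,
                              plus_c_min_extra = 2L) {
  profiles <- lapply(aln$ids, function(id)
    profile_sequence(aln, cols, id, mature_start = mature_start))
  names(profiles) <- aln$ids
  code <- function(p) {
    ifelse(p$unknown, "U", ifelse(p$present, "P", "A"))
  }
  codes <- do.call(rbind, lapply(profiles, code))
  df <- data.frame(sequence_id = aln$ids, codes,
                   extra_cysteines = vapply(profiles, `[[`, 0L,
                                            "extra_cysteines"),
                   subfamily = vapply(profiles, function(p)
                     classify_subfamily(p, plus_c_min_extra)$subfamily,
                     character(1)),
                   row.names = NULL, stringsAsFactors = FALSE)
  attr(df, "profiles") <- profiles
  df
}

#' Write a per-sequence profile table as TSV
#'
#' @param profile_df Data frame from [profile_alignment()].
#' @param path Output path.
#' @export
write_profile_table <- function(profile_df, path) {
  write.table(profile_df, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a per-sequence profile table written by [write_profile_table()]
#'
#' @param path TSV path.
#' @return Data frame in the layout of [profile_alignment()].
#' @export
read_profile_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
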