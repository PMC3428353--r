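#' Self-comparison dotplot of a protein sequence
#'
#' Computes the windowed mean substitution score of a protein against
#' itself for every pair of window start positions, and scans the
#' off-main diagonals for high-scoring runs — the signature of a tandem
#' domain duplication, which appears as a parallel diagonal at an offset
#' equal to the repeat length.
#'
#' @param sequence Protein sequence (single string, one-letter code).
#' @param window Odd window width in residues (default 15).
#' @param score_matrix Substitution matrix name (default `"BLOSUM62"`,
#'   taken from Biostrings).
#' @param min_run Minimum run length in window positions for a reported
#'   diagonal (default 30).
#' @param min_mean Minimum windowed mean score per residue for a position
#'   to belong to a run (default 1.0).
#' @return An object of class `obp_dotplot`: list with `window`, `scores`
#'   (symmetric matrix over window start positions) and `diagonals`
#'   (data.frame of off-diagonal runs: `offset`, `start`, `length`,
#'   `mean_score`).
#' @export
self_dotplot <- function(sequence, window = 15L, score_matrix = "BLOSUM62",
                         min_run = 30L, min_mean = 1.0) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(s)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  if (n < window) {
    stop("sequence (", n, " aa) shorter than window (", window, ")")
  }
  sub <- if (identical(score_matrix, "BLOSUM62")) {
    blosum62()
  } else {
    e <- new.env()
    utils::data(list = score_matrix, package = "Biostrings", envir = e)
    get(score_matrix, envir = e)
  }
  if (!all(s %in% rownames(sub))) {
    bad <- unique(s[!s %in% rownames(sub)])
    stop("residue(s) not in ", score_matrix, ": ",
         paste(bad, collapse = ", "))
  }
  n_start <- n - window + 1L
  scores <- matrix(NA_real_, n_start, n_start)
  # windowed means per diagonal via cumulative sums
  for (d in 0:(n_start - 1L)) {
    len <- n - d                       # residues on this diagonal
    v <- sub[cbind(match(s[seq_len(len)], rownames(sub)),
                   match(s[seq_len(len) + d], colnames(sub)))]
    if (len < window) next
    cs <- c(0, cumsum(v))
    w <- (cs[(window + 1):(len + 1)] - cs[1:(len - window + 1L)]) / window
    idx <- seq_len(len - window + 1L)
    scores[cbind(idx, idx + d)] <- w
    scores[cbind(idx + d, idx)] <- w
  }
  diagonals <- scan_diagonal_runs(scores, n_start, min_run, min_mean)
  structure(list(window = window, scores = scores, diagonals = diagonals),
            class = "obp_dotplot")
}

# maximal stretches of above-threshold windows on each off-main diagonal
scan_diagonal_runs <- function(scores, n_start, min_run, min_mean) {
  out <- list()
  for (d in seq_len(n_start - 1L)) {
    idx <- seq_len(n_start - d)
    w <- scores[cbind(idx, idx + d)]
    ok <- !is.na(w) & w >= min_mean
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      seg <- starts[k]:ends[k]
      out[[length(out) + 1L]] <- data.frame(
        offset = d, start = seg[1], length = length(seg),
        mean_score = mean(w[seg]))
    }
  }
  if (length(out) == 0L) {
    return(data.frame(offset = integer(0), start = integer(0),
                      length = integer(0), mean_score = numeric(0)))
  }
  do.call(rbind, out)
}

#' @export
print.obp_dotplot <- function(x, ...) {
  cat("obp_dotplot: window", x$window, "-",
      nrow(x$diagonals), "off-diagonal run(s)\n")
  if (nrow(x$diagonals)) print(x$diagonals, row.names = FALSE)
  invisible(x)
}

#' Write dotplot runs as BED-like intervals on the protein
#'
#' Each off-diagonal run is written twice, once per repeat copy, as
#' 0-based half-open intervals on the protein coordinate system.
#'
#' @param dotplot An `obp_dotplot`.
#' @param sequence_id Name used in the first column.
#' @param path Output path.
#' @export
write_dotplot_bed <- function(dotplot, sequence_id, path) {
  d <- dotplot$diagonals
  w <- dotplot$window
  if (nrow(d)) {
    bed <- data.frame(
      chrom = sequence_id,
      start = c(d$start - 1L, d$start + d$offset - 1L),
      end = c(d$start + d$length + w - 2L,
              d$start + d$offset + d$length + w - 2L),
      name = rep(sprintf("repeat_offset_%d", d$offset), 2L),
      score = rep(round(d$mean_score, 3), 2L))
  } else {
    bed <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0))
  }
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
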