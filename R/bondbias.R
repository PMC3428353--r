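#' Disulphide-bond topology of the classic OBP fold
#'
#' The six canonical cysteines form three disulphide bonds with the
#' connectivity C1-C3, C2-C5, C4-C6.
#'
#' @param pairs List of two-element character vectors; must partition
#'   C1..C6 into three disjoint pairs.
#' @return A list of class `bond_topology`.
#' @export
bond_topology <- function(pairs = list(c("C1", "C3"),
                                       c("C2", "C5"),
                                       c("C4", "C6"))) {
  flat <- unlist(pairs)
  if (length(pairs) != 3L || any(vapply(pairs, length, 0L) != 2L) ||
      !setequal(flat, CYS_LABELS) || anyDuplicated(flat)) {
    stop("bond topology must partition C1..C6 into three disjoint pairs")
  }
  structure(list(pairs = lapply(pairs, sort)), class = "bond_topology")
}

#' Does a two-cysteine loss hit a disulphide-bond pair?
#'
#' @param lost Character vector of exactly two canonical cysteines.
#' @param topology A [bond_topology()].
#' @return `TRUE` iff the two lost cysteines are bond partners.
#' @export
is_bond_pair <- function(lost, topology = bond_topology()) {
  if (length(lost) != 2L) {
    stop("is_bond_pair needs exactly two cysteines, got ", length(lost))
  }
  key <- paste(sort(lost), collapse = "/")
  key %in% vapply(topology$pairs, paste, character(1), collapse = "/")
}

#' Binomial tail test for preferential loss of bond partners
#'
#' After one canonical cysteine is lost, one of the five remaining
#' cysteines is its disulphide partner, so under random loss the second
#' cysteine of a two-loss event hits the partner with probability
#' q = 1/5. Given `x` two-cysteine loss events of which `y` hit a bond
#' pair, the upper-tail probability of observing `y` or more is
#' P = sum_{k=y}^{x} C(x,k) q^k (1-q)^(x-k).
#'
#' @param x Number of events losing exactly two cysteines.
#' @param y Number of those events hitting a bond pair.
#' @param q Null probability that a second loss hits the partner
#'   (default 1/5).
#' @return A list of class `bond_bias_result` with `x`, `y`, `q` and
#'   `p_value`.
#' @examples
#' bond_bias_pvalue(13, 11)$p_value  # 1.065779e-06
#' @export
bond_bias_pvalue <- function(x, y, q = 0.2) {
  x <- as.integer(x); y <- as.integer(y)
  if (is.na(x) || is.na(y) || x < 0L || y < 0L || y > x) {
    stop("need 0 <= y <= x")
  }
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("q must lie strictly between 0 and 1")
  }
  p <- if (y == 0L) 1 else pbinom(y - 1L, x, q, lower.tail = FALSE)
  structure(list(x = x, y = y, q = q, p_value = p),
            class = "bond_bias_result")
}

#' @export
print.bond_bias_result <- function(x, ...) {
  cat(sprintf("bond-bias test: y = %d of x = %d two-cysteine events hit a bond pair (q = %g)\n",
              x$y, x$x, x$q))
  cat(sprintf("  upper-tail binomial p = %.6e\n", x$p_value))
  invisible(x)
}

#' Count two-cysteine events and bond-pair hits in an event table
#'
#' @param table An [obp_event_table][tabulate_events()].
#' @param topology A [bond_topology()].
#' @return Named integer vector `c(x = ..., y = ...)`: the number of
#'   events losing exactly two cysteines and, of those, the number hitting
#'   a disulphide-bond pair. Events losing one or three cysteines are
#'   excluded.
#' @export
count_bond_events <- function(table, topology = bond_topology()) {
  two <- table[table$n_cysteines == 2L, , drop = FALSE]
  x <- sum(two$event_count)
  if (x == 0L) return(c(x = 0L, y = 0L))
  bond <- vapply(strsplit(two$lost_set, "/", fixed = TRUE),
                 is_bond_pair, TRUE, topology = topology)
  y <- sum(two$event_count[bond])
  c(x = as.integer(x), y = as.integer(y))
}

#' Chi-square p-value for a likelihood-ratio test
#'
#' Upper-tail chi-square probability for a likelihood-ratio statistic, as
#' used to compare nested codon site models (e.g. M7 vs M8). For
#' `df = 2` this equals `exp(-statistic / 2)`.
#'
#' @param statistic Non-negative likelihood-ratio statistic
#'   (2 * delta lnL).
#' @param df Positive integer degrees of freedom.
#' @return The p-value.
#' @examples
#' lrt_pvalue(11.07, 2)  # 0.0039, printed as 0.004
#' @export
lrt_pvalue <- function(statistic, df) {
  if (!is.numeric(statistic) || length(statistic) != 1L ||
      is.na(statistic) || statistic < 0) {
    stop("statistic must be a non-negative number")
  }
  df <- as.integer(df)
  if (is.na(df) || df < 1L) stop("df must be a positive integer")
  pchisq(statistic, df = df, lower.tail = FALSE)
}

#' Evaluate a table of site-model likelihood-ratio comparisons
#'
#' Takes reported log-likelihoods and reported likelihood-ratio statistics
#' for nested model pairs, computes the chi-square p-value from the
#' reported statistic, and independently recomputes the statistic as
#' 2 * (lnL_alt - lnL_null). When the two disagree beyond `tol` the row is
#' flagged rather than silently resolved, since published model tables
#' sometimes print inconsistent statistics.
#'
#' @param comparisons Data frame with columns `model_null`, `model_alt`,
#'   `lnL_null`, `lnL_alt`, `statistic`, `df`.
#' @param tol Absolute tolerance before a reported statistic is flagged as
#'   inconsistent with the log-likelihoods (default 0.01).
#' @return The input with added columns `p_value` (from the reported
#'   statistic), `statistic_recomputed` and logical `flag_inconsistent`.
#' @export
lrt_table <- function(comparisons, tol = 0.01) {
  needed <- c("model_null", "model_alt", "lnL_null", "lnL_alt",
              "statistic", "df")
  if (!all(needed %in% names(comparisons))) {
    stop("comparisons must have columns ", paste(needed, collapse = ", "))
  }
  comparisons$p_value <- mapply(lrt_pvalue, comparisons$statistic,
                                comparisons$df)
  comparisons$statistic_recomputed <-
    2 * (comparisons$lnL_alt - comparisons$lnL_null)
  comparisons$flag_inconsistent <-
    abs(comparisons$statistic_recomputed - comparisons$statistic) > tol
  comparisons
}

#' Read a TSV of site-model comparisons
#'
#' @param path TSV with the columns required by [lrt_table()]; defaults to
#'   the packaged table of reported codon site-model fits for the wasp
#'   double-domain OBP expansion.
#' @return Data frame ready for [lrt_table()].
#' @export
read_lrt_table <- function(path = system.file("extdata",
                                              "site_model_lrt.tsv",
                                              package = "obpscaffold")) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
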