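# Independent oracles, kept deliberately naive.

# Brute-force minimum number of loss branches under no-regain semantics:
# smallest set of nodes whose pooled leaf descendants equal the absent set.
brute_min_loss_events <- function(tree, absent_tips) {
  n_tip <- length(tree$tip.label)
  below <- obpscaffold:::descendant_leaves(tree)
  absent_idx <- sort(match(absent_tips, tree$tip.label))
  if (length(absent_idx) == 0L) return(0L)
  nodes <- seq_len(max(tree$edge))
  leafsets <- lapply(nodes, function(nd) sort(below[[nd]]))
  # only nodes whose leaves are all absent can carry a loss
  admissible <- nodes[vapply(leafsets, function(lv)
    all(lv %in% absent_idx), TRUE)]
  for (k in seq_len(length(admissible))) {
    combos <- utils::combn(admissible, k, simplify = FALSE)
    for (s in combos) {
      covered <- sort(unique(unlist(leafsets[s])))
      if (identical(covered, absent_idx)) return(k)
    }
  }
  stop("no covering found")  # cannot happen: singleton leaves admissible
}

# Exhaustive binomial tail: enumerate all bond/non-bond outcome strings.
enumerate_tail_probability <- function(x, y, q) {
  if (x == 0L) return(as.numeric(y <= 0L))
  total <- 0
  for (code in 0:(2^x - 1)) {
    bits <- as.integer(intToBits(code))[1:x]
    k <- sum(bits)
    if (k >= y) total <- total + q^k * (1 - q)^(x - k)
  }
  total
}
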