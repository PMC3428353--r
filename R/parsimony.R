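#' Infer cysteine-loss events on a gene tree by parsimony
#'
#' Maps the loss of each canonical cysteine onto a rooted gene tree,
#' minimising the number of loss events. The default `dollo` mode assumes
#' the cysteine was present in the family ancestor and is never regained
#' once lost, so each character's events are the maximal subtrees in which
#' every scored leaf lacks the cysteine (the root-most minimal placement).
#' `fitch` mode allows regain and reports the loss branches of one
#' most-parsimonious Fitch reconstruction (root state preferring presence,
#' parent state retained on ties). Losses of different cysteines assigned to
#' the same branch are merged into a single multi-cysteine event. Leaves
#' whose profile is unknown at a cysteine are excluded for that character
#' only.
#'
#' @param tree A rooted `phylo` gene tree; leaf labels must match the
#'   profiled sequence ids. Multifurcations are allowed; branch lengths are
#'   ignored.
#' @param profiles A list of [cysteine_profile][profile_sequence()] objects
#'   or a data.frame from [profile_alignment()] / [read_profile_table()]
#'   (columns C1..C6 coded P/A/U).
#' @param mode `"dollo"` (default) or `"fitch"`.
#' @return A list of class `obp_loss_events`; each element has `branch`
#'   (label of the child node of the branch carrying the event), `node`
#'   (its node number), `lost` (character vector of cysteines lost there)
#'   and `affected_genes` (scored descendant leaves lacking them).
#' @export
infer_losses <- function(tree, profiles, mode = c("dollo", "fitch")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  st <- profile_states(profiles)
  leaves <- tree$tip.label
  if (!setequal(leaves, rownames(st$present))) {
    only_tree <- setdiff(leaves, rownames(st$present))
    only_prof <- setdiff(rownames(st$present), leaves)
    stop("leaf/profile mismatch; only in tree: [",
         paste(only_tree, collapse = ", "), "]; only in profiles: [",
         paste(only_prof, collapse = ", "), "]")
  }
  present <- st$present[leaves, , drop = FALSE]
  unknown <- st$unknown[leaves, , drop = FALSE]

  assignments <- list()  # per (cysteine, branch) loss with affected genes
  for (cys in CYS_LABELS) {
    known <- !unknown[, cys]
    absent <- known & !present[, cys]
    if (!any(absent)) next
    hits <- if (mode == "dollo") {
      dollo_losses(tree, known, absent)
    } else {
      fitch_losses(tree, known, absent)
    }
    for (h in hits) {
      assignments[[length(assignments) + 1L]] <-
        list(node = h$node, lost = cys, affected = h$affected)
    }
  }
  merge_assignments(tree, assignments)
}

# P/A/U data.frame or profile list -> logical matrices (rows = sequence ids)
profile_states <- function(profiles) {
  if (is.data.frame(profiles)) {
    stopifnot(all(c("sequence_id", CYS_LABELS) %in% names(profiles)))
    codes <- as.matrix(profiles[, CYS_LABELS])
    present <- codes == "P"
    unknown <- codes == "U"
    rownames(present) <- rownames(unknown) <- profiles$sequence_id
  } else {
    stopifnot(all(vapply(profiles, inherits, TRUE, "cysteine_profile")))
    present <- do.call(rbind, lapply(profiles, `[[`, "present"))
    unknown <- do.call(rbind, lapply(profiles, `[[`, "unknown"))
    rownames(present) <- rownames(unknown) <-
      vapply(profiles, `[[`, character(1), "sequence_id")
  }
  colnames(present) <- colnames(unknown) <- CYS_LABELS
  list(present = present, unknown = unknown)
}

# children indexed by parent node, computed once per call
tree_children <- function(tree) {
  n_nodes <- max(tree$edge)
  kids <- vector("list", n_nodes)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[k, 2])
  }
  kids
}

tree_root <- function(tree) {
  setdiff(tree$edge[, 1], tree$edge[, 2])[1]
}

node_label <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  if (!is.null(tree$node.label) &&
      nzchar(tree$node.label[node - n_tip])) {
    return(tree$node.label[node - n_tip])
  }
  paste0("n", node)
}

# leaves below each node (node numbers), as list over all nodes
descendant_leaves <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_nodes <- max(tree$edge)
  below <- vector("list", n_nodes)
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(n_tip)) below[[i]] <- i
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]
    ch <- ord$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

# Dollo placement for one binary character: maximal subtrees whose scored
# leaves are all absent. known/absent are logical vectors over tip labels.
dollo_losses <- function(tree, known, absent) {
  n_tip <- length(tree$tip.label)
  below <- descendant_leaves(tree)
  n_nodes <- max(tree$edge)
  n_known <- vapply(below, function(lv) sum(known[lv]), 0L)
  n_absent <- vapply(below, function(lv) sum(absent[lv]), 0L)
  eligible <- n_known > 0L & n_absent == n_known
  parent <- integer(n_nodes)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- tree_root(tree)
  parent[root] <- NA_integer_
  maximal <- which(eligible &
                   (is.na(parent) | !eligible[ifelse(is.na(parent), root,
                                                     parent)]))
  lapply(maximal, function(nd) {
    lv <- below[[nd]]
    list(node = nd,
         affected = tree$tip.label[lv[absent[lv]]])
  })
}

# Fitch reconstruction for one binary character (1 = present, 0 = absent);
# unknown leaves get the full state set. Returns loss edges (1 -> 0) with
# the absent scored leaves they explain.
fitch_losses <- function(tree, known, absent) {
  n_tip <- length(tree$tip.label)
  n_nodes <- max(tree$edge)
  kids <- tree_children(tree)
  root <- tree_root(tree)
  # state sets coded as 1 = {absent}, 2 = {present}, 3 = {both}
  setv <- integer(n_nodes)
  for (i in seq_len(n_tip)) {
    lbl <- tree$tip.label[i]
    setv[i] <- if (!known[lbl]) 3L else if (absent[lbl]) 1L else 2L
  }
  ord <- ape::reorder.phylo(tree, "postorder")
  inner <- unique(ord$edge[, 1])
  for (p in inner) {
    sets <- setv[kids[[p]]]
    inter <- Reduce(bitwAnd, sets)
    setv[p] <- if (inter != 0L) inter else Reduce(bitwOr, sets)
  }
  # uppass: prefer presence at the root, parent state on ties
  state <- integer(n_nodes)
  state[root] <- if (bitwAnd(setv[root], 2L) != 0L) 1L else 0L
  preorder <- rev(c(unique(ord$edge[, 2]), root))
  for (nd in preorder) {
    for (ch in kids[[nd]]) {
      ps_bit <- if (state[nd] == 1L) 2L else 1L
      state[ch] <- if (bitwAnd(setv[ch], ps_bit) != 0L) {
        state[nd]
      } else if (bitwAnd(setv[ch], 2L) != 0L) 1L else 0L
    }
  }
  # walk down carrying the governing loss edge; a regain clears it
  affected <- vector("list", n_nodes)
  loss_nodes <- integer(0)
  walk <- function(nd, loss_at) {
    for (ch in kids[[nd]]) {
      child_loss <- loss_at
      if (state[nd] == 1L && state[ch] == 0L) child_loss <- ch
      if (state[nd] == 0L && state[ch] == 1L) child_loss <- NA_integer_
      if (ch <= n_tip) {
        lbl <- tree$tip.label[ch]
        if (known[lbl] && absent[lbl] && !is.na(child_loss)) {
          affected[[child_loss]] <<- c(affected[[child_loss]], lbl)
          loss_nodes <<- union(loss_nodes, child_loss)
        }
      } else {
        walk(ch, child_loss)
      }
    }
  }
  walk(root, NA_integer_)
  out <- lapply(sort(loss_nodes), function(nd)
    list(node = nd, affected = affected[[nd]]))
  # total state changes in this reconstruction (losses + regains), kept
  # for cross-checks against generic parsimony scorers
  n_changes <- sum(vapply(seq_len(nrow(tree$edge)), function(k) {
    state[tree$edge[k, 1]] != state[tree$edge[k, 2]]
  }, TRUE))
  attr(out, "n_changes") <- n_changes
  out
}

# group per-cysteine branch assignments into one event per branch
merge_assignments <- function(tree, assignments) {
  if (length(assignments) == 0L) {
    return(structure(list(), class = "obp_loss_events"))
  }
  nodes <- vapply(assignments, `[[`, 0L, "node")
  events <- lapply(sort(unique(nodes)), function(nd) {
    sel <- assignments[nodes == nd]
    lost <- sort(unique(vapply(sel, `[[`, character(1), "lost")))
    lost <- CYS_LABELS[CYS_LABELS %in% lost]
    affected <- sort(unique(unlist(lapply(sel, `[[`, "affected"))))
    list(branch = node_label(tree, nd), node = nd,
         lost = lost, affected_genes = affected)
  })
  structure(events, class = "obp_loss_events")
}

#' @export
print.obp_loss_events <- function(x, ...) {
  cat("obp_loss_events:", length(x), "event(s)\n")
  for (e in x) {
    cat("  ", e$branch, ": ", paste(e$lost, collapse = "/"),
        " [", length(e$affected_genes), " gene(s)]\n", sep = "")
  }
  invisible(x)
}

#' Tabulate loss events by lost-cysteine set
#'
#' Groups loss events into table rows keyed by the set of cysteines lost
#' (e.g. `"C2/C5"`), with event and affected-gene counts, ordered by
#' lost-set size and then cysteine index.
#'
#' @param events An `obp_loss_events` list (from [infer_losses()] or
#'   [load_event_fixture()]).
#' @return A data.frame of class `obp_event_table` with columns `lost_set`,
#'   `n_cysteines`, `event_count`, `gene_count`, plus a list column
#'   `gene_lists` holding one gene vector per event.
#' @export
tabulate_events <- function(events) {
  if (length(events) == 0L) {
    out <- data.frame(lost_set = character(0), n_cysteines = integer(0),
                      event_count = integer(0), gene_count = integer(0),
                      stringsAsFactors = FALSE)
    out$gene_lists <- list()
    class(out) <- c("obp_event_table", "data.frame")
    return(out)
  }
  keys <- vapply(events, function(e) paste(e$lost, collapse = "/"),
                 character(1))
  sizes <- vapply(events, function(e) length(e$lost), 0L)
  # order rows by lost-set cardinality, then first cysteine index
  uk <- unique(keys)
  first_idx <- function(k) {
    idx <- match(strsplit(k, "/", fixed = TRUE)[[1]], CYS_LABELS)
    sum(idx * 7^(rev(seq_along(idx)) - 1))  # lexicographic on C-indices
  }
  uk <- uk[order(vapply(uk, function(k)
    length(strsplit(k, "/", fixed = TRUE)[[1]]), 0L),
    vapply(uk, first_idx, 0))]
  rows <- lapply(uk, function(k) {
    sel <- events[keys == k]
    list(lost_set = k,
         n_cysteines = length(strsplit(k, "/", fixed = TRUE)[[1]]),
         event_count = length(sel),
         gene_count = length(unique(unlist(lapply(sel, `[[`,
                                                  "affected_genes")))),
         gene_lists = lapply(sel, `[[`, "affected_genes"))
  })
  out <- data.frame(lost_set = vapply(rows, `[[`, character(1), "lost_set"),
                    n_cysteines = vapply(rows, `[[`, 0L, "n_cysteines"),
                    event_count = vapply(rows, `[[`, 0L, "event_count"),
                    gene_count = vapply(rows, `[[`, 0L, "gene_count"),
                    stringsAsFactors = FALSE)
  out$gene_lists <- lapply(rows, `[[`, "gene_lists")
  class(out) <- c("obp_event_table", "data.frame")
  out
}

#' @export
print.obp_event_table <- function(x, ...) {
  df <- as.data.frame(x)[, c("lost_set", "event_count", "gene_count")]
  print(df, row.names = FALSE)
  cat("total events:", sum(x$event_count),
      " total genes:", sum(x$gene_count), "\n")
  invisible(x)
}

#' Write an event table as TSV or JSON
#'
#' @param table An `obp_event_table`.
#' @param path Output path; format chosen by extension (`.json` for JSON,
#'   otherwise TSV with comma-separated per-event gene lists).
#' @export
write_event_table <- function(table, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- lapply(seq_len(nrow(table)), function(i) {
      list(lost_set = table$lost_set[i],
           event_count = table$event_count[i],
           gene_count = table$gene_count[i],
           gene_lists = table$gene_lists[[i]])
    })
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    flat <- data.frame(
      lost_set = rep(table$lost_set,
                     vapply(table$gene_lists, length, 0L)),
      event_id = unlist(lapply(table$gene_lists, seq_along)),
      affected_genes = unlist(lapply(table$gene_lists, function(gl)
        vapply(gl, paste, character(1), collapse = ","))),
      stringsAsFactors = FALSE)
    write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Load the packaged loss-event reference table
#'
#' Reads the packaged transcription of the published cysteine-loss event
#' table for insect OBP families (22 events across wasp, bee, fly, beetle,
#' mosquito, aphid and louse OBPs) and returns it as an event list. The
#' loader validates the fixture's marginal totals and refuses a corrupted
#' file.
#'
#' @param path Fixture path; defaults to the copy shipped with the package.
#' @return An `obp_loss_events` list; branches are synthetic labels since
#'   the published table reports events, not tree branches.
#' @export
load_event_fixture <- function(path = system.file("extdata",
                                                  "loss_events.tsv",
                                                  package = "obpscaffold")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("loss-event fixture not found")
  }
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("lost_set", "event_id", "affected_genes")
  if (!all(needed %in% names(df))) {
    stop("loss-event fixture malformed: need columns ",
         paste(needed, collapse = ", "))
  }
  events <- lapply(seq_len(nrow(df)), function(i) {
    lost <- strsplit(df$lost_set[i], "/", fixed = TRUE)[[1]]
    genes <- strsplit(df$affected_genes[i], ",", fixed = TRUE)[[1]]
    genes <- trimws(genes)
    list(branch = paste0(df$lost_set[i], ".", df$event_id[i]),
         node = NA_integer_, lost = lost, affected_genes = genes)
  })
  n_genes <- sum(vapply(events, function(e) length(e$affected_genes), 0L))
  if (length(events) != 22L || n_genes != 74L) {
    stop("loss-event fixture checksum mismatch: expected 22 events / 74 ",
         "gene entries, found ", length(events), " / ", n_genes)
  }
  structure(events, class = "obp_loss_events")
}
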