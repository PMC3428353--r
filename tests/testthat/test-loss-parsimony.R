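test_that("a loss shared by one clade maps to its stem branch", {
  tr <- quartet_tree()
  prof <- make_profiles(c("A", "B", "C", "D"),
                        absent = list(A = "C2", B = "C2"))
  ev <- infer_losses(tr, prof)
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$branch, "ab")
  expect_equal(ev[[1]]$lost, "C2")
  expect_setequal(ev[[1]]$affected_genes, c("A", "B"))
})

test_that("losses in non-sister leaves need two events", {
  tr <- quartet_tree()
  prof <- make_profiles(c("A", "B", "C", "D"),
                        absent = list(A = "C2", C = "C2"))
  ev <- infer_losses(tr, prof)
  expect_length(ev, 2L)
  expect_equal(brute_min_loss_events(tr, c("A", "C")), 2L)
  expect_setequal(vapply(ev, `[[`, character(1), "branch"), c("A", "C"))
})

test_that("joint losses on one branch merge into one event", {
  tr <- quartet_tree()
  prof <- make_profiles(c("A", "B", "C", "D"),
                        absent = list(A = c("C2", "C5"),
                                      B = c("C2", "C5")))
  ev <- infer_losses(tr, prof)
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$lost, c("C2", "C5"))
  expect_setequal(ev[[1]]$affected_genes, c("A", "B"))
})

test_that("leaf/profile mismatches are reported with the difference", {
  tr <- quartet_tree()
  prof <- make_profiles(c("A", "B", "C", "E"))
  expect_error(infer_losses(tr, prof), "only in tree.*D.*only in profiles.*E")
})

test_that("unknown states are excluded per character, not per sequence", {
  tr <- quartet_tree()
  # A is 3'-truncated: C5/C6 unknown; C absent at C2
  prof <- make_profiles(c("A", "B", "C", "D"),
                        absent = list(A = "C2", B = "C2", C = "C5"),
                        unknown = list(A = c("C5", "C6")))
  ev <- infer_losses(tr, prof)
  keys <- vapply(ev, function(e) paste(e$lost, collapse = "/"), character(1))
  expect_setequal(keys, c("C2", "C5"))
  # the C5 event must not claim the unknown leaf A
  c5 <- ev[[which(keys == "C5")]]
  expect_equal(c5$affected_genes, "C")
})

test_that("dollo event counts match the brute-force minimum", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(4:8, 1)
    tr <- random_tree(n)
    absent <- sample(tr$tip.label, sample.int(n, 1))
    prof <- make_profiles(tr$tip.label,
                          absent = stats::setNames(
                            rep(list("C4"), length(absent)), absent))
    ev <- infer_losses(tr, prof)
    expect_equal(length(ev), brute_min_loss_events(tr, absent),
                 info = paste("rep", rep))
  }
})

test_that("dollo placement is root-most: one event absorbs a whole clade", {
  tr <- ape::read.tree(text = "(((A,B)ab,C)abc,D)r;")
  prof <- make_profiles(c("A", "B", "C", "D"),
                        absent = list(A = "C1", B = "C1", C = "C1"))
  ev <- infer_losses(tr, prof)
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$branch, "abc")
  expect_setequal(ev[[1]]$affected_genes, c("A", "B", "C"))
})

test_that("adding an absent leaf never decreases the event count", {
  set.seed(7)
  for (rep in 1:20) {
    tr <- random_tree(7)
    absent <- sample(tr$tip.label, 3)
    extra <- sample(setdiff(tr$tip.label, absent), 1)
    mk <- function(ab) make_profiles(tr$tip.label,
      absent = stats::setNames(rep(list("C2"), length(ab)), ab))
    n0 <- length(infer_losses(tr, mk(absent)))
    n1 <- length(infer_losses(tr, mk(c(absent, extra))))
    expect_gte(n1, n0)
  }
})

test_that("fitch reconstruction matches phangorn's parsimony score", {
  skip_if_not_installed("phangorn")
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    tr$tip.label <- paste0("t", seq_len(n))
    states <- sample(c("p", "a"), n, replace = TRUE)
    if (!any(states == "a")) states[1] <- "a"
    prof <- make_profiles(tr$tip.label,
      absent = stats::setNames(
        rep(list("C3"), sum(states == "a")),
        tr$tip.label[states == "a"]))
    st <- obpscaffold:::profile_states(prof)
    known <- !st$unknown[tr$tip.label, "C3"]
    absent <- known & !st$present[tr$tip.label, "C3"]
    hits <- obpscaffold:::fitch_losses(tr, known, absent)
    dat <- phangorn::phyDat(matrix(states, ncol = 1,
                                   dimnames = list(tr$tip.label, NULL)),
                            type = "USER", levels = c("p", "a"))
    expect_equal(attr(hits, "n_changes"),
                 phangorn::parsimony(tr, dat), info = paste("rep", rep))
  }
})

test_that("merging groups assignments without changing their number", {
  set.seed(5)
  tr <- random_tree(8)
  prof <- make_profiles(tr$tip.label,
    absent = list(t1 = c("C2", "C5"), t2 = c("C2", "C5"), t5 = "C1"))
  ev <- infer_losses(tr, prof)
  n_assign_merged <- sum(vapply(ev, function(e) length(e$lost), 0L))
  n_assign_single <- 0L
  for (cys in paste0("C", 1:6)) {
    sub <- prof
    for (other in setdiff(paste0("C", 1:6), cys)) sub[[other]] <- "P"
    n_assign_single <- n_assign_single + length(infer_losses(tr, sub))
  }
  expect_equal(n_assign_merged, n_assign_single)
})

test_that("event tables group, order and count deterministically", {
  ev <- structure(list(
    list(branch = "b1", node = 1L, lost = c("C2", "C5"),
         affected_genes = c("g1", "g2")),
    list(branch = "b2", node = 2L, lost = "C1", affected_genes = "g3"),
    list(branch = "b3", node = 3L, lost = c("C2", "C5"),
         affected_genes = "g4"),
    list(branch = "b4", node = 4L, lost = c("C1", "C3"),
         affected_genes = "g5")), class = "obp_loss_events")
  tab <- tabulate_events(ev)
  expect_equal(tab$lost_set, c("C1", "C1/C3", "C2/C5"))
  expect_equal(tab$event_count, c(1L, 1L, 2L))
  expect_equal(tab$gene_count, c(1L, 1L, 3L))

  empty <- tabulate_events(structure(list(), class = "obp_loss_events"))
  expect_equal(nrow(empty), 0L)
  expect_equal(sum(empty$event_count), 0L)
})

test_that("the packaged event fixture matches its published marginals", {
  ev <- load_event_fixture()
  expect_length(ev, 22L)
  tab <- tabulate_events(ev)
  expect_equal(sum(tab$event_count), 22L)
  # the three-cysteine row and the C2/C6 row carry exactly one gene each
  c456 <- ev[vapply(ev, function(e)
    identical(e$lost, c("C4", "C5", "C6")), TRUE)]
  expect_length(c456, 1L)
  expect_equal(c456[[1]]$affected_genes, "AgamOBP16")
  c26 <- ev[vapply(ev, function(e)
    identical(e$lost, c("C2", "C6")), TRUE)]
  expect_equal(c26[[1]]$affected_genes, "NvitOBP69")
  # genes across single-cysteine rows
  singles <- tab[tab$n_cysteines == 1L, ]
  expect_equal(sum(singles$gene_count), 15L)
})

test_that("a corrupted event fixture is refused", {
  src <- system.file("extdata", "loss_events.tsv", package = "obpscaffold")
  lines <- readLines(src)
  tf <- tempfile(fileext = ".tsv")
  writeLines(head(lines, -2L), tf)  # drop two events
  expect_error(load_event_fixture(tf), "checksum mismatch")
})

test_that("event tables round-trip to TSV and JSON", {
  tab <- tabulate_events(load_event_fixture())
  tsv <- tempfile(fileext = ".tsv")
  write_event_table(tab, tsv)
  flat <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(nrow(flat), 22L)
  js <- tempfile(fileext = ".json")
  write_event_table(tab, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(sum(vapply(parsed, `[[`, 0, "event_count")), 22)
})
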