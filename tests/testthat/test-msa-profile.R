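test_that("read_alignment reads well-formed FASTA and normalises residues", {
  tf <- write_fasta(c(a = "mk.cw", b = "MKACW", c = "MK-CW"))
  aln <- read_alignment(tf)
  expect_s3_class(aln, "obp_alignment")
  expect_equal(aln$length, 5L)
  expect_equal(unname(aln$seqs[["a"]]), "MK-CW")  # upper-cased, '.' -> '-'
  expect_equal(aln$ids, c("a", "b", "c"))
})

test_that("read_alignment rejects ragged, empty and duplicated input", {
  ragged <- write_fasta(c(a = strrep("A", 240), b = strrep("A", 240),
                          shorty = strrep("A", 239)))
  expect_error(read_alignment(ragged), "unequal lengths.*shorty")
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_alignment(empty), "no records")
  dup <- write_fasta(c("AC", "AG"), ids = c("x", "x"))
  expect_error(read_alignment(dup), "duplicate")
})

test_that("read_alignment reads Clustal format", {
  tf <- tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               "s1              MKCW-A",
               "s2              MKCWGA",
               "                ****  ",
               ""), tf)
  aln <- read_alignment(tf, format = "clustal")
  expect_equal(aln$length, 6L)
  expect_setequal(aln$ids, c("s1", "s2"))
})

test_that("canonical columns are found by unanimity and by majority", {
  fx <- toy_scaffold_alignment()
  cols <- locate_canonical_columns(fx$aln)
  expect_equal(unname(unclass(cols)), c(10L, 40L, 44L, 80L, 92L, 101L))

  # one sequence carries serine at the C2 column: occupancy 3/4 >= 0.5
  fx2 <- toy_scaffold_alignment(mutate = list(list(id = "seq1", pos = 40L,
                                                   res = "S")))
  cols2 <- locate_canonical_columns(fx2$aln)
  expect_equal(unclass(cols2), unclass(cols))
})

test_that("column search is invariant to record order and all-gap columns", {
  fx <- toy_scaffold_alignment()
  ref <- unclass(locate_canonical_columns(fx$aln))
  shuffled <- obpscaffold:::new_alignment(rev(fx$aln$ids),
                                          rev(fx$aln$seqs))
  expect_equal(unclass(locate_canonical_columns(shuffled)), ref)
  padded <- obpscaffold:::new_alignment(fx$aln$ids,
                                        paste0(fx$aln$seqs, "-"))
  expect_equal(unclass(locate_canonical_columns(padded)), ref)
})

test_that("column search errors when the scaffold is not present", {
  aln <- obpscaffold:::new_alignment(c("a", "b"),
                                     c(strrep("A", 50), strrep("G", 50)))
  expect_error(locate_canonical_columns(aln), "scaffold not found")
})

test_that("reference mode reads columns off named references", {
  fx <- toy_scaffold_alignment()
  cols <- locate_canonical_columns(fx$aln, mode = "reference",
                                   reference_ids = c("seq1", "seq2"))
  expect_equal(unname(unclass(cols)), c(10L, 40L, 44L, 80L, 92L, 101L))
  expect_error(
    locate_canonical_columns(fx$aln, mode = "reference",
                             reference_ids = "nope"),
    "not in alignment")
})

test_that("majority mode recovers the simulator's true columns", {
  fam <- simulate_family(simulation_config(n_leaves = 50, seed = 11,
                                           loss_rate = 0.01,
                                           substitution_rate = 0.03))
  cols <- locate_canonical_columns(fam$alignment)
  expect_equal(unname(unclass(cols)), unname(fam$scaffold_columns))
})

test_that("profile_sequence distinguishes present, absent and unknown", {
  fx <- toy_scaffold_alignment(
    mutate = list(list(id = "seq2", pos = c(40L, 92L), res = "A")))
  p1 <- profile_sequence(fx$aln, fx$cols, "seq1")
  expect_true(all(p1$present))
  expect_false(any(p1$unknown))
  expect_equal(p1$extra_cysteines, 0L)

  p2 <- profile_sequence(fx$aln, fx$cols, "seq2")
  expect_equal(unname(p2$present), c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_false(any(p2$unknown))

  # trailing gap run covering C5 and C6 -> unknown, not absent
  trunc <- toy_scaffold_alignment(
    mutate = list(list(id = "seq3", pos = 85:110, res = "-")))
  p3 <- profile_sequence(trunc$aln, trunc$cols, "seq3")
  expect_equal(unname(p3$unknown), c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(unname(p3$present[1:4]), rep(TRUE, 4))

  # an internal gap at a canonical column is a deletion: absent
  gap <- toy_scaffold_alignment(
    mutate = list(list(id = "seq4", pos = 44L, res = "-")))
  p4 <- profile_sequence(gap$aln, gap$cols, "seq4")
  expect_false(p4$present[["C3"]])
  expect_false(p4$unknown[["C3"]])

  expect_error(profile_sequence(fx$aln, fx$cols, "ghost"), "unknown sequence")
})

test_that("extra cysteines are counted from the mature start only", {
  fx <- toy_scaffold_alignment(
    mutate = list(list(id = "seq1", pos = c(5L, 30L, 60L), res = "C")))
  p <- profile_sequence(fx$aln, fx$cols, "seq1", mature_start = 25L)
  expect_equal(p$extra_cysteines, 2L)  # the cysteine at column 5 is signal
  p_all <- profile_sequence(fx$aln, fx$cols, "seq1", mature_start = 1L)
  expect_equal(p_all$extra_cysteines, 3L)
})

test_that("subfamily classification partitions complete profiles", {
  fx <- toy_scaffold_alignment(
    n_seq = 6L,
    mutate = list(list(id = "seq2", pos = c(40L, 92L), res = "A"),
                  list(id = "seq3", pos = c(30L, 60L, 70L), res = "C"),
                  list(id = "seq4", pos = 95:110, res = "-")))
  df <- profile_alignment(fx$aln, fx$cols)
  expect_equal(df$subfamily[df$sequence_id == "seq1"], "classic")
  expect_equal(df$subfamily[df$sequence_id == "seq2"], "minus-C")
  expect_equal(df$subfamily[df$sequence_id == "seq3"], "plus-C")
  expect_equal(df$subfamily[df$sequence_id == "seq4"], "incomplete")
  complete <- df$subfamily != "incomplete"
  expect_true(all(df$subfamily[complete] %in%
                  c("classic", "minus-C", "plus-C")))

  # a single stray cysteine stays classic under the default threshold
  one_extra <- toy_scaffold_alignment(
    mutate = list(list(id = "seq1", pos = 60L, res = "C")))
  p <- profile_sequence(one_extra$aln, one_extra$cols, "seq1")
  expect_equal(classify_subfamily(p)$subfamily, "classic")
  expect_equal(classify_subfamily(p, plus_c_min_extra = 1L)$subfamily,
               "plus-C")
})

test_that("simulated families without losses are all classic", {
  fam <- simulate_family(simulation_config(n_leaves = 15, seed = 4,
                                           loss_rate = 0,
                                           fusion_probability = 0))
  cols <- obpscaffold:::new_canonical_columns(fam$scaffold_columns,
                                              fam$alignment$length)
  df <- profile_alignment(fam$alignment, cols)
  expect_true(all(df$subfamily == "classic"))
  expect_length(fam$truth_events, 0L)
})

test_that("profile tables round-trip through TSV", {
  fx <- toy_scaffold_alignment()
  df <- profile_alignment(fx$aln, fx$cols)
  tf <- tempfile(fileext = ".tsv")
  write_profile_table(df, tf)
  back <- read_profile_table(tf)
  expect_equal(back$sequence_id, df$sequence_id)
  expect_equal(back$C2, df$C2)
  expect_equal(back$subfamily, df$subfamily)
})
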