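test_that("reference position mapping handles gaps, identity and errors", {
  aln <- aln_of(ref = "ME-D", other = "MEAD")
  map <- map_reference_positions(aln, "ref")
  expect_equal(unname(map[2]), 1L)          # E is 0-based column 1
  expect_equal(unname(map), c(0L, 1L, 3L))  # gap column skipped

  ungapped <- aln_of(ref = "MKLVQE", x = "MKLVQD")
  expect_equal(unname(map_reference_positions(ungapped, "ref")), 0:5)

  lead <- aln_of(ref = "-----MKLV", x = "AAAAAMKLV")
  expect_equal(unname(map_reference_positions(lead, "ref")[1]), 5L)

  expect_error(map_reference_positions(aln, "absent"), "not present")
})

test_that("column states distinguish residues, internal gaps and termination", {
  aln <- aln_of(a = "ACD---", b = "A-CD-E", c = "---DEF", d = "ACDDEF")
  expect_equal(unname(classify_column_states(aln, 3)["a"]), "terminated")
  expect_equal(unname(classify_column_states(aln, 1)["b"]), "internal_gap")
  expect_equal(unname(classify_column_states(aln, 1)["c"]), "terminated")
  expect_equal(unname(classify_column_states(aln, 0)["d"]), "residue")
  expect_error(classify_column_states(aln, 6), "out of range")

  # 10 records, 2 truncated before column 55 -> occupancy 0.8 there
  base <- paste(rep("A", 60), collapse = "")
  trunc <- paste(c(rep("A", 50), rep("-", 10)), collapse = "")
  seqs <- setNames(c(rep(base, 8), rep(trunc, 2)), sprintf("r%d", 1:10))
  states <- classify_column_states(alignment(seqs), 55)
  expect_equal(sum(states == "residue") / 10, 0.8)
  expect_equal(sum(states == "terminated"), 2L)
})

test_that("key-residue scoring reports occupancy, both PIDs and substitutions", {
  # 10 records at one scored column: 6 match E, 2 substituted Q, 2 terminated
  seqs <- setNames(c(
    "MAE", rep("MAE", 5), "MAQ", "MAQ", "MA-", "MA-"
  ), sprintf("r%02d", 1:10))
  aln <- alignment(seqs)
  spec <- key_residue_spec("toy", "r01", positions = 3L, expected = "E")
  rep <- score_key_residues(aln, spec)
  expect_equal(rep$occupancy, 0.8)
  expect_equal(rep$pid_all, 0.6)
  expect_equal(rep$pid_occupied, 0.75)
  expect_equal(rep$n_terminated, 2L)
  subs <- attr(rep, "substitutions")[["E3"]]
  expect_equal(as.integer(subs[["Q"]]), 2L)

  # full conservation
  all_match <- alignment(setNames(rep("MAE", 4), sprintf("r%d", 1:4)))
  rep2 <- score_key_residues(all_match,
                             key_residue_spec("toy", "r1", 3L, "E"))
  expect_equal(rep2$pid_all, 1)
  expect_equal(rep2$occupancy, 1)

  # degenerate: all scored records terminated -> occupancy 0, pid_occupied NA
  meta <- data.frame(id = c("ref", "y", "z"),
                     record_class = c("isolate", "MAG", "MAG"))
  aln4 <- alignment(setNames(c("MAE", "MA-", "MA-"), c("ref", "y", "z")),
                    meta = meta)
  rep4 <- score_key_residues(aln4, key_residue_spec("toy", "ref", 3L, "E"),
                             record_class = "MAG")
  expect_equal(rep4$occupancy, 0)
  expect_equal(rep4$pid_all, 0)
  expect_true(is.na(rep4$pid_occupied))
  expect_equal(rep4$n_terminated, 2L)

  expect_error(
    score_key_residues(aln, key_residue_spec("toy", "r01", 9L, "E")),
    "beyond reference length")
})

test_that("X counts toward occupancy but never identity; '.' and case fold", {
  aln <- alignment(setNames(c("mae", "MAX", "MA."), c("a", "b", "c")))
  rep <- score_key_residues(aln, key_residue_spec("toy", "a", 3L, "E"))
  expect_equal(rep$occupancy, 2 / 3)       # X occupies, '.' is a gap
  expect_equal(rep$pid_all, 1 / 3)
  expect_equal(rep$pid_occupied, 0.5)
})

test_that("scores equal a brute-force recount and obey the PID identity", {
  set.seed(402)
  for (i in 1:25) {
    aln <- random_alignment(n = sample(5:20, 1), L = sample(20:60, 1))
    ids <- rownames(aln$seq)
    # pick a reference without leading/trailing gaps so mapping is stable
    full <- ids[apply(aln$seq, 1, function(s) s[1] != "-" &&
                                              s[length(s)] != "-")]
    if (length(full) == 0L) next
    ref <- full[1L]
    npos <- sum(aln$seq[ref, ] != "-")
    pos <- sort(sample(seq_len(npos), min(3L, npos)))
    expected <- sample(AA20, length(pos), replace = TRUE)
    spec <- key_residue_spec("rand", ref, pos, expected)
    rep <- score_key_residues(aln, spec)
    for (k in seq_len(nrow(rep))) {
      oracle <- recount_column(aln, rep$column_index[k], rep$expected[k])
      expect_equal(rep$occupancy[k], oracle$occupancy)
      expect_equal(rep$pid_all[k], oracle$pid_all)
      expect_equal(rep$pid_occupied[k], oracle$pid_occupied)
      expect_equal(rep$n_terminated[k], oracle$n_terminated)
    }
    # identity pid_all = pid_occupied * occupancy, and reorder invariance
    occ_part <- ifelse(is.na(rep$pid_occupied), 0, rep$pid_occupied)
    expect_equal(rep$pid_all, occ_part * rep$occupancy)
    shuffled <- subset_alignment(aln, sample(ids))
    # reference must stay present; scores must not depend on record order
    rep_sh <- score_key_residues(shuffled, spec)
    expect_equal(rep_sh$pid_all, rep$pid_all)
    expect_equal(rep_sh$occupancy, rep$occupancy)
  }
})

test_that("logo information content matches closed forms", {
  single <- alignment(setNames(rep("E", 8), sprintf("r%d", 1:8)))
  lm1 <- logo_matrix(single)
  expect_equal(lm1$information_content, log2(20), tolerance = 1e-12)

  half <- alignment(setNames(c(rep("E", 4), rep("Q", 4)), sprintf("r%d", 1:8)))
  lm2 <- logo_matrix(half)
  expect_equal(lm2$information_content, log2(20) - 1, tolerance = 1e-12)

  unif <- alignment(setNames(AA20, sprintf("r%02d", 1:20)))
  lm3 <- logo_matrix(unif)
  expect_equal(lm3$information_content, 0, tolerance = 1e-12)

  # zero-occupancy column -> NA frequencies and IC; X excluded from freqs
  gappy <- alignment(setNames(c("-E", "-X", "-Q"), c("a", "b", "c")))
  lm4 <- logo_matrix(gappy)
  expect_true(is.na(lm4$information_content[1]))
  expect_equal(lm4$n_occupied, c(0L, 2L))
  expect_equal(sum(lm4$freq[2, ]), 1)
})

test_that("reports and logo matrices write to disk and read back", {
  fam <- generate_family(family_config(
    n_groups = 2, records_per_group = 5, seq_length = 40,
    key_sites = data.frame(position = 10, residue = "E", conservation = 1),
    seed = 9))
  ref <- rownames(fam$aln$seq)[1]
  rep <- score_key_residues(fam$aln, key_residue_spec("fam", ref, 10L, "E"))
  path <- tempfile(fileext = ".csv")
  write_conservation_report(rep, path)
  back <- read.csv(path)
  expect_equal(back$pid_all, rep$pid_all)

  lpath <- tempfile(fileext = ".tsv")
  write_logo_matrix(logo_matrix(fam$aln, columns = c(0, 9)), lpath)
  tab <- read.delim(lpath, check.names = FALSE)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$column, c(0, 9))
})
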