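small_spec <- function(seed = 3) {
  synthetic_spec(n_canonical_pts1 = 15, n_twilight_pts1 = 8, n_pts2 = 8,
                 n_tm_pts1_decoy = 12, n_er_pts1_decoy = 12,
                 n_background = 45, seed = seed)
}

test_that("motif planting anchors correctly and respects bounds", {
  out <- plant_motif(strrep("A", 30), "SKL", "C_TERM")
  expect_equal(nchar(out), 30L)
  expect_equal(substr(out, 28, 30), "SKL")

  out <- plant_motif(strrep("A", 30), "RLQHIRGHI", "AT_OFFSET", 0L)
  expect_equal(substr(out, 1, 9), "RLQHIRGHI")
  expect_equal(nchar(out), 30L)

  expect_error(plant_motif(strrep("A", 30), strrep("L", 31), "C_TERM"),
               "longer")
  expect_error(plant_motif(strrep("A", 30), "SKL", "AT_OFFSET", 28L),
               "out of range")
})

test_that("generation is deterministic under the spec seed", {
  p1 <- generate_proteome(small_spec())
  p2 <- generate_proteome(small_spec())
  expect_identical(p1$records$sequence, p2$records$sequence)
  expect_identical(p1$truth, p2$truth)

  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(p1$records, f1)
  write_fasta(p2$records, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("different seeds change sequences but preserve class counts", {
  p1 <- generate_proteome(small_spec(seed = 3))
  p2 <- generate_proteome(small_spec(seed = 4))
  expect_identical(table(p1$truth$label), table(p2$truth$label))
  expect_false(identical(p1$records$sequence, p2$records$sequence))
})

test_that("single-class specs honour their construction guarantees", {
  only_can <- generate_proteome(synthetic_spec(
    n_canonical_pts1 = 10, n_twilight_pts1 = 0, n_pts2 = 0,
    n_tm_pts1_decoy = 0, n_er_pts1_decoy = 0, n_background = 0, seed = 5))
  expect_equal(nrow(only_can$records), 10L)
  expect_true(all(match_consensus(extract_cterm12(only_can$records)$tripeptide)))

  only_bg <- generate_proteome(synthetic_spec(
    n_canonical_pts1 = 0, n_twilight_pts1 = 0, n_pts2 = 0,
    n_tm_pts1_decoy = 0, n_er_pts1_decoy = 0, n_background = 100, seed = 5))
  rep <- run_cascade(only_bg$records)
  expect_equal(rep$n_consensus, 0L)
  expect_true(all(rep$table$final_fate == "DROP_NO_CONSENSUS"))
})

test_that("planted motifs are confirmed by the matching detector", {
  p <- generate_proteome(small_spec(seed = 6))
  model <- pts1_default_model()
  recs <- p$records
  truth <- p$truth
  for (i in seq_len(nrow(recs))) {
    seq <- recs$sequence[i]
    label <- truth$label[i]
    if (label %in% c("canonical_pts1", "twilight_pts1")) {
      cat_i <- as.character(predict(model, seq)$category)
      expect_equal(cat_i,
                   if (label == "canonical_pts1") "TARGETED" else "TWILIGHT")
      expect_equal(substr(seq, truth$start[i] + 1, truth$end[i]),
                   truth$motif[i])
    } else if (label == "pts2") {
      hits <- find_pts2(seq)
      expect_true(truth$start[i] %in% hits$offset)
      expect_false(match_consensus(extract_cterm12(seq)$tripeptide))
    } else if (label == "tm_pts1_decoy") {
      prof <- tm_profile(seq)
      expect_equal(prof$topology, "TM")
      expect_false(apply_tm_rule(prof))
    } else if (label == "er_pts1_decoy") {
      expect_true(detect_secretory_signal(seq)$secretory_signal)
    } else {
      expect_false(match_consensus(extract_cterm12(seq)$tripeptide))
    }
  }
})

test_that("the early-core decoy variant exercises the signal-peptide exemption", {
  p <- generate_proteome(synthetic_spec(
    n_canonical_pts1 = 0, n_twilight_pts1 = 0, n_pts2 = 0,
    n_tm_pts1_decoy = 10, n_er_pts1_decoy = 0, n_background = 0,
    seed = 7, tm_decoy_early = TRUE))
  for (seq in p$records$sequence) {
    prof <- tm_profile(seq)
    expect_equal(prof$topology, "TM")
    expect_true(apply_tm_rule(prof))  # core confined to the first 60 residues
  }
})

test_that("spec validation rejects impossible compositions", {
  expect_error(synthetic_spec(n_background = -1), ">= 0")
  expect_error(synthetic_spec(n_canonical_pts1 = 0, n_twilight_pts1 = 0,
                              n_pts2 = 0, n_tm_pts1_decoy = 0,
                              n_er_pts1_decoy = 0, n_background = 0),
               "at least one")
  expect_error(synthetic_spec(length_range = c(10, 50)), "min >= 30")
})

test_that("truth tables serialise with 0-based half-open coordinates", {
  p <- generate_proteome(synthetic_spec(
    n_canonical_pts1 = 3, n_twilight_pts1 = 0, n_pts2 = 2,
    n_tm_pts1_decoy = 0, n_er_pts1_decoy = 0, n_background = 2, seed = 8))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth_table(p$truth, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 7L)
  can <- back[back$label == "canonical_pts1", ]
  lens <- nchar(p$records$sequence[match(can$accession,
                                         p$records$accession)])
  expect_equal(can$end - can$start, rep(12L, 3))
  expect_equal(can$end, lens)
})
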