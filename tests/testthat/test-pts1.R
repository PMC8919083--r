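test_that("C-terminal 12-mer extraction pads short sequences and slices reporters", {
  ctx <- extract_cterm12("DLHSIVLSDIQTKL")     # Urad reporter insert
  expect_equal(ctx$dodecamer, "HSIVLSDIQTKL")
  expect_equal(ctx$tripeptide, "TKL")

  ctx <- extract_cterm12("DLLMLDKQTLSSKI")     # Cdc5l reporter insert
  expect_equal(ctx$dodecamer, "LMLDKQTLSSKI")
  expect_equal(ctx$tripeptide, "SKI")

  ctx <- extract_cterm12("MSKL")
  expect_equal(ctx$dodecamer, "XXXXXXXXMSKL")
  expect_equal(ctx$tripeptide, "SKL")
})

test_that("consensus matcher agrees with brute-force set membership on all 8000 tripeptides", {
  all_tri <- apply(expand.grid(AA20, AA20, AA20, stringsAsFactors = FALSE),
                   1, paste, collapse = "")
  expected <- vapply(all_tri, consensus_oracle, logical(1))
  got <- match_consensus(all_tri)
  expect_equal(unname(got), unname(expected))
  # 8 x 7 x 5 admissible residue combinations
  expect_identical(sum(got), 280L)

  expect_true(match_consensus("SKL"))
  expect_true(match_consensus("SKM"))
  expect_false(match_consensus("QKL"))
  expect_false(match_consensus("GGG"))
  expect_false(match_consensus("XKL"))
  expect_false(match_consensus("SUL"))
  expect_error(match_consensus("SK"), "3 residues")
})

test_that("model fitting concentrates weight on observed residues and validates input", {
  m <- pts1_model(rep("AAAAAAAAASKL", 10))
  expect_equal(names(which.max(coef(m)[12, ])), "L")
  expect_equal(names(which.max(coef(m)[1, ])), "A")
  expect_equal(unname(coef(m)[, "X"]), rep(0, 12))

  expect_error(pts1_model(rep("AAAAAAAAASKL", 9)), "at least 10")
  expect_error(pts1_model(rep("AAAAAAAAAQKL", 10)), "consensus")
  expect_error(pts1_model(rep("AAAAAAAAASKL", 10),
                          background = rep(0.1, 20)), "sum to 1")
  expect_error(
    pts1_model(rep("AAAAAAAAASKL", 10),
               calibration = c(AAAAAAAAASKL = "TARGETED",
                               AAAAAAAAASKL = "REJECTED")),
    "unsatisfiable")
})

test_that("scores are additive in single-residue substitutions", {
  m <- pts1_default_model()
  set.seed(41)
  for (k in 1:25) {
    base <- paste0(random_seq(9), "SKL")
    pos <- sample(1:9, 1)
    sub <- sample(AA20, 1)
    mutated <- base
    substr(mutated, pos, pos) <- sub
    delta <- score_pts1(m, mutated)$score - score_pts1(m, base)$score
    expected <- coef(m)[pos, sub] - coef(m)[pos, substr(base, pos, pos)]
    expect_equal(delta, unname(expected), tolerance = 1e-12)
  }
})

test_that("every consensus-matching 12-mer falls in exactly one score category", {
  m <- pts1_default_model()
  set.seed(42)
  tails <- c("SKL", "TKL", "GNF", "AQM", "PLV", "GGG", "QKL")
  dode <- paste0(replicate(80, random_seq(9)), sample(tails, 80, TRUE))
  res <- score_pts1(m, dode)
  gate <- match_consensus(substring(dode, 10, 12))
  expect_equal(res$category == "NO_MATCH", !gate)
  expect_true(all(res$score[!gate] == -Inf))
  on_gate <- res[gate, ]
  expect_true(all(on_gate$category %in% c("TARGETED", "TWILIGHT", "REJECTED")))
  expect_equal(on_gate$category == "TARGETED", on_gate$score > 0)
  expect_equal(on_gate$category == "TWILIGHT",
               on_gate$score <= 0 & on_gate$score > -10)
})

test_that("the bundled model reproduces the reporter classifications", {
  m <- pts1_default_model()
  rep5 <- pts1_reporters()
  res <- predict(m, rep5$insert)
  expect_equal(res$tripeptide, c("TKL", "AHL", "SKI", "SRM", "SKF"))
  expect_true(all(match_consensus(res$tripeptide)))
  got <- as.character(res$category[match(c("Cdc5l", "Meox2a", "Kctd5a"),
                                         rep5$name)])
  expect_equal(got, c("TARGETED", "TWILIGHT", "TWILIGHT"))
})

test_that("SKL outscores SKM in an identical context on the bundled model", {
  m <- pts1_default_model()
  ctxs <- c("AAAAAAAAA", "LVYHTSPER", "TGLLSVAAG")
  for (ctx in ctxs) {
    expect_gt(score_pts1(m, paste0(ctx, "SKL"))$score,
              score_pts1(m, paste0(ctx, "SKM"))$score)
  }
})

test_that("rebuilding the bundled model is bit-identical and JSON round-trips", {
  a <- pts1_model(pts1_training_set(), calibration = pts1_default_calibration())
  b <- pts1_model(pts1_training_set(), calibration = pts1_default_calibration())
  expect_identical(a$weights, b$weights)
  expect_identical(a$offset, b$offset)

  f <- withr::local_tempfile(fileext = ".json")
  write_pts1_model(a, f)
  back <- read_pts1_model(f)
  probe <- paste0(replicate(10, random_seq(9)), "SKL")
  expect_equal(score_pts1(back, probe)$score, score_pts1(a, probe)$score,
               tolerance = 1e-12)
})

test_that("padding X and selenocysteine U score neutrally", {
  m <- pts1_default_model()
  expect_equal(score_pts1(m, "XXXXXXXXXSKL")$score,
               score_pts1(m, "UUUUUUUUUSKL")$score)
  expect_equal(score_pts1(m, "XXXXXXXXXSKL")$score,
               sum(coef(m)[cbind(10:12, match(c("S", "K", "L"),
                                              colnames(coef(m))))]) - m$offset)
})

test_that("an uncalibrated model anchors its offset at the training 5th percentile", {
  set.seed(7)
  train <- paste0(replicate(40, random_seq(9)), "SKL")
  m <- pts1_model(train)
  res <- score_pts1(m, train)
  # by construction ~95% of the training set scores above 0
  expect_gte(mean(res$score > 0), 0.9)
  expect_lte(mean(res$score > 0), 1.0)
})
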