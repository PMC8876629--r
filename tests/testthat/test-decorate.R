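test_that("the worked example decorates to the printed structure", {
  dec <- decorate(WX_SEQ, WX_CAND)
  expect_identical(dec$stem2_ext,
                   cbind(i = c(8L, 7L), j = c(17L, 18L)))
  expect_identical(dec$stem1_ext,
                   cbind(i = c(4L, 3L), j = c(11L, 12L)))
  expect_identical(dec$pair_count, 6L)
  expect_identical(to_dotbracket(WX_SEQ, dec), WX_FINAL_DB)
  # undecorated core renders the parser-output row
  expect_identical(to_dotbracket(WX_SEQ, WX_CAND), WX_CORE_DB)
  # decoration never moves the core stems
  expect_identical(dec$candidate[c("i1", "i2", "j1", "j2")], WX_CAND)
})

test_that("non-complementary flanks stop decoration immediately", {
  # all-A surroundings: no extension possible
  dec <- decorate("AACAUGAAAA", list(i1 = 3, i2 = 5, j1 = 6, j2 = 9))
  expect_identical(dec$pair_count, 2L)
  expect_identical(nrow(dec$stem1_ext), 0L)
  expect_identical(nrow(dec$stem2_ext), 0L)
  # minimal 6-mer: one bracket of each kind
  db <- to_dotbracket("CAGGAC",
                      decorate("CAGGAC", list(i1 = 1, i2 = 3, j1 = 4,
                                              j2 = 6)))
  expect_identical(db, "[.(].)")
  counts <- table(strsplit(db, "")[[1]])
  expect_true(all(counts[c("[", "]", "(", ")")] == 1))
})

test_that("the wobble option extends by exactly the G-U run", {
  #             123456789|
  s <-         "AACGUGAAAU"   # (4,10) = G-U at the stem-2 boundary
  cand <- list(i1 = 3, i2 = 5, j1 = 6, j2 = 9)
  off <- decorate(s, cand, allow_gu = FALSE)
  on <- decorate(s, cand, allow_gu = TRUE)
  expect_identical(nrow(off$stem2_ext), 0L)
  expect_identical(nrow(on$stem2_ext), 1L)
  expect_identical(on$pair_count, off$pair_count + 1L)
})

test_that("min_loop reserves unpaired loop bases", {
  dec <- decorate(WX_SEQ, WX_CAND, min_loop = 3)
  expect_identical(nrow(dec$stem2_ext), 0L)   # left loop len 3: all reserved
  expect_identical(nrow(dec$stem1_ext), 2L)   # right loop len 5: 2 spendable
  expect_identical(dec$pair_count, 4L)
})

test_that("invalid candidates are rejected", {
  expect_error(decorate(WX_SEQ, list(i1 = 9, i2 = 5, j1 = 10, j2 = 16)),
               "i1 < i2")
  expect_error(decorate(WX_SEQ, list(i1 = 5, i2 = 6, j1 = 7, j2 = 16)),
               "loop")
  expect_error(decorate("AAAAAAAA", list(i1 = 1, i2 = 3, j1 = 5, j2 = 7)),
               "Watson-Crick")
})

test_that("dot-bracket round-trips the pair set", {
  check_roundtrip <- function(seq, dec) {
    m <- dotbracket_pairs(to_dotbracket(seq, dec))
    got <- m[order(m[, "i"]), c("i", "j"), drop = FALSE]
    want <- pkscan:::decorated_pairs(dec)
    want <- want[order(want[, "i"]), , drop = FALSE]
    dimnames(got) <- dimnames(want) <- NULL
    expect_identical(got, want)
    expect_identical(nrow(m), dec$pair_count)   # brackets == pair_count
  }
  check_roundtrip(WX_SEQ, decorate(WX_SEQ, WX_CAND))
  set.seed(43)
  for (k in 1:20) {
    s <- rna_sequence(random_rna(30))
    cands <- detect_bruteforce(s)
    if (!nrow(cands)) next
    check_roundtrip(s, decorate(s, cands[sample(nrow(cands), 1), ]))
  }
})

test_that("dotbracket_pairs validates its input", {
  expect_error(dotbracket_pairs("((."), "unbalanced '\\('")
  expect_error(dotbracket_pairs(".)"), "unbalanced '\\)'")
  expect_error(dotbracket_pairs("]["), "unbalanced")
  expect_error(dotbracket_pairs(".x."), "position 2")
  expect_identical(nrow(dotbracket_pairs("....")), 0L)
})
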