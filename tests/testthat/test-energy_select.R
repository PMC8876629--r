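test_that("the energy of the worked example is 10.2", {
  sc <- pseudoknot_energy(WX_SEQ, decorate(WX_SEQ, WX_CAND))
  expect_identical(sc$bp, 2L)
  expect_identical(sc$up, 4L)           # positions 6, 13, 14, 15
  expect_equal(sc$g_pseudo, 9.6 + 0.1 * 2 + 0.1 * 4)
})

test_that("the energy formula holds for arbitrary structures", {
  # Up recomputed independently from the rendered string: dots strictly
  # inside the outermost bracketed span
  up_from_db <- function(db) {
    ch <- strsplit(db, "")[[1]]
    paired <- which(ch != ".")
    sum(ch[(min(paired) + 1):(max(paired) - 1)] == ".")
  }
  set.seed(53)
  degenerate <- energy_params(beta2 = 0, beta3 = 0)
  for (k in 1:15) {
    s <- rna_sequence(random_rna(35))
    cands <- detect_bruteforce(s)
    if (!nrow(cands)) next
    dec <- decorate(s, cands[sample(nrow(cands), 1), ])
    sc <- pseudoknot_energy(s, dec)
    expect_identical(sc$up, up_from_db(to_dotbracket(s, dec)))
    expect_equal(sc$g_pseudo, 9.6 + 0.2 + 0.1 * sc$up)
    expect_equal(pseudoknot_energy(s, dec, degenerate)$g_pseudo, 9.6)
  }
})

test_that("Bp can optionally count all pairs", {
  dec <- decorate(WX_SEQ, WX_CAND)
  sc <- pseudoknot_energy(WX_SEQ, dec, energy_params(count_pairs = TRUE))
  expect_identical(sc$bp, 6L)
  expect_equal(sc$g_pseudo, 9.6 + 0.1 * 6 + 0.1 * 4)
})

test_that("an optional stacking table adds to the energy", {
  dec <- decorate(WX_SEQ, WX_CAND)
  # stem 1 pairs (5,10),(4,11),(3,12): stacks CU/GA? keys from the sequence
  st <- c("UC/GA" = -1.5)
  sc <- pseudoknot_energy(WX_SEQ, dec, energy_params(stack_table = st))
  base <- pseudoknot_energy(WX_SEQ, dec)
  expect_equal(sc$g_pseudo - base$g_pseudo, sc$stack_energy)
})

test_that("selection maximizes pairs, then minimizes energy", {
  cands <- detect_bruteforce(WX_SEQ)
  decs <- lapply(seq_len(nrow(cands)), function(k)
    decorate(WX_SEQ, cands[k, ]))
  best <- select_best(WX_SEQ, decs)
  pcs <- vapply(decs, `[[`, integer(1), "pair_count")
  expect_identical(best$dec$pair_count, max(pcs))
  expect_identical(best$dec$candidate[c("i1", "i2", "j1", "j2")], WX_CAND)
  # invariant under permutation of the candidate list
  best2 <- select_best(WX_SEQ, rev(decs))
  expect_identical(to_dotbracket(WX_SEQ, best$dec),
                   to_dotbracket(WX_SEQ, best2$dec))
  # a 6-pair structure beats any 4-pair structure regardless of energy
  few <- decs[pcs < max(pcs)]
  expect_gt(best$dec$pair_count, max(vapply(few, `[[`, integer(1),
                                            "pair_count")))
  expect_null(select_best(WX_SEQ, list()))
})

test_that("equal pair count: lower Up wins; full ties break by leftmost i1", {
  s <- "CAGGACCAGGAC"       # two copies of the same minimal motif
  left <- decorate(s, list(i1 = 1, i2 = 3, j1 = 4, j2 = 6))
  right <- decorate(s, list(i1 = 7, i2 = 9, j1 = 10, j2 = 12))
  expect_identical(left$pair_count, right$pair_count)
  expect_identical(pseudoknot_energy(s, left)$g_pseudo,
                   pseudoknot_energy(s, right)$g_pseudo)
  best <- select_best(s, list(right, left))
  expect_identical(best$dec$candidate$i1, 1L)

  # differing Up at equal pair count: smaller Up has lower energy and wins
  scored <- lapply(list(left, right), function(d) pseudoknot_energy(s, d))
  fake_up <- scored
  fake_up[[2]]$up <- fake_up[[2]]$up + 2L
  fake_up[[2]]$g_pseudo <- fake_up[[2]]$g_pseudo + 0.2
  expect_identical(select_best(s, fake_up)$dec$candidate$i1, 1L)
  expect_identical(select_best(s, rev(fake_up))$dec$candidate$i1, 1L)
})

test_that("end-to-end prediction reproduces the worked example", {
  p <- predict_structure(WX_SEQ)
  expect_identical(p$dot_bracket, WX_FINAL_DB)
  expect_identical(predict_structure("AAAAAAAAAA")$dot_bracket,
                   "..........")
  expect_identical(predict_structure("")$dot_bracket, "")
})

test_that("planted structures are recovered when uniquely maximal", {
  ok <- 0L
  for (k in 1:20) {
    fx <- generate_planted(varied_spec(k, base_seed = 9L))
    p <- predict_structure(fx$seq)
    if (core_stem_match(p$best$dec$candidate,
                        as.list(fx$candidate[1, ]), slip = 1))
      ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("the candidate table carries the stable schema", {
  tab <- candidates_table(rna_sequence(WX_SEQ, "wx"))
  expect_named(tab, c("seq_id", "i1", "i2", "j1", "j2", "rule_id",
                      "pair_count", "up", "g_pseudo", "dot_bracket"))
  expect_identical(max(tab$pair_count), 6L)
  expect_true(WX_FINAL_DB %in% tab$dot_bracket)
})
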