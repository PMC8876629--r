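test_that("per-base confusion counts classify the worked example", {
  c1 <- confusion_counts(WX_FINAL_DB, WX_FINAL_DB)
  expect_identical(c1[c("tp", "tn", "fp", "fn")],
                   list(tp = 12L, tn = 7L, fp = 0L, fn = 0L))
  c2 <- confusion_counts(strrep(".", 19), WX_FINAL_DB)
  expect_identical(c2[c("tp", "tn", "fp", "fn")],
                   list(tp = 0L, tn = 7L, fp = 0L, fn = 12L))
  expect_identical(c1$tp + c1$tn + c1$fp + c1$fn, 19L)
  expect_error(confusion_counts("...", WX_FINAL_DB), "equal length")
  expect_error(confusion_counts("((..", "...."), "unbalanced")
})

test_that("strict mode requires identical partners", {
  ref <- "((..))"                       # pairs (1,6), (2,5)
  pred <- "(()).."                      # pairs (1,4), (2,3)
  loose <- confusion_counts(pred, ref)
  expect_identical(loose[c("tp", "tn", "fp", "fn")],
                   list(tp = 2L, tn = 0L, fp = 2L, fn = 2L))
  strict <- confusion_counts(pred, ref, strict = TRUE)
  expect_identical(strict[c("tp", "tn", "fp", "fn")],
                   list(tp = 0L, tn = 0L, fp = 4L, fn = 2L))
})

test_that("every printed metric row reproduces at 3 decimals", {
  rows <- PRINTED_METRIC_ROWS
  for (r in seq_len(nrow(rows))) {
    m <- confusion_metrics(rows[r, c("tp", "tn", "fp", "fn")])
    lbl <- paste(rows$table[r], rows$platform[r])
    expect_identical(round3up(m$ppv), rows$ppv[r], info = lbl)
    expect_identical(round3up(m$recall), rows$recall[r], info = lbl)
    expect_identical(round3up(m$f1), rows$f1[r], info = lbl)
    expect_identical(round3up(m$mcc), rows$mcc[r], info = lbl)
  }
})

test_that("metric identities hold", {
  set.seed(61)
  for (k in 1:50) {
    cts <- as.list(sample(0:500, 4))
    names(cts) <- c("tp", "tn", "fp", "fn")
    m <- suppressWarnings(confusion_metrics(cts))
    if (m$ppv > 0 && m$recall > 0)
      expect_equal(m$f1, 2 / (1 / m$ppv + 1 / m$recall))
    swapped <- suppressWarnings(confusion_metrics(
      list(tp = cts$tn, tn = cts$tp, fp = cts$fn, fn = cts$fp)))
    expect_equal(m$mcc, swapped$mcc)
    expect_true(m$ppv >= 0 && m$ppv <= 1)
    expect_true(m$recall >= 0 && m$recall <= 1)
    expect_true(m$mcc >= -1 && m$mcc <= 1)
  }
  expect_warning(z <- confusion_metrics(list(tp = 0, tn = 5, fp = 0,
                                             fn = 0)),
                 "zero denominator")
  expect_identical(z$ppv, 0)
  expect_true(z$degenerate)
  perfect <- confusion_metrics(list(tp = 1, tn = 1, fp = 0, fn = 0))
  expect_equal(unlist(perfect[c("ppv", "recall", "f1", "mcc")]),
               c(ppv = 1, recall = 1, f1 = 1, mcc = 1))
})

test_that("core-stem matching applies per-pair slippage", {
  p <- list(i1 = 5, i2 = 9, j1 = 10, j2 = 16)
  expect_true(core_stem_match(p, p, slip = 1))
  expect_true(core_stem_match(p, list(i1 = 4, i2 = 9, j1 = 10, j2 = 17),
                              slip = 1))
  expect_false(core_stem_match(p, list(i1 = 7, i2 = 9, j1 = 10, j2 = 16),
                               slip = 1))
  # both coordinates of one pair shifted: not in the equivalence set
  expect_false(core_stem_match(p, list(i1 = 4, i2 = 9, j1 = 11, j2 = 16),
                               slip = 1))
  expect_false(core_stem_match(p, list(i1 = 4, i2 = 9, j1 = 10, j2 = 16),
                               slip = 0))
})

test_that("dataset evaluation sums counts before computing metrics", {
  recs <- data.frame(
    seq_id = c("a", "b"),
    pred_db = c(WX_FINAL_DB, strrep(".", 19)),
    ref_db = c(WX_FINAL_DB, WX_FINAL_DB))
  rep <- evaluate_dataset(recs, bins = c(30, 40, 50))
  all_row <- rep$table[rep$table$bin == "all", ]
  expect_identical(all_row$tp, 12)                # summed component-wise
  expect_identical(all_row$fn, 12)
  expect_identical(all_row$tn, 14)
  hand <- confusion_metrics(list(tp = 12, tn = 14, fp = 0, fn = 12))
  expect_identical(all_row$f1, round3up(hand$f1))
  expect_identical(all_row$exact, 1L)

  perfect <- evaluate_dataset(recs[1, ], bins = 30)
  expect_identical(perfect$overall$exact, 1L)
  expect_identical(perfect$overall$exact_pct, 100)
})

test_that("length bins use the closed-left convention", {
  mk <- function(n) strrep(".", n)
  recs <- data.frame(seq_id = c("x", "y", "z"),
                     pred_db = c(mk(29), mk(30), mk(50)),
                     ref_db = c(mk(29), mk(30), mk(50)))
  rep <- suppressWarnings(evaluate_dataset(recs, bins = c(30, 40, 50)))
  tab <- rep$table
  expect_identical(tab$n[tab$bin == "L<30"], 1L)
  expect_identical(tab$n[tab$bin == "30<=L<40"], 1L)  # length 30: 2nd bin
  expect_identical(tab$n[tab$bin == "40<=L<50"], 0L)
  expect_identical(tab$n[tab$bin == "L>=50"], 1L)
})

test_that("records with a missing reference are skipped with a message", {
  recs <- data.frame(seq_id = c("a", "b"),
                     pred_db = c(WX_FINAL_DB, WX_FINAL_DB),
                     ref_db = c(WX_FINAL_DB, NA))
  expect_message(rep <- evaluate_dataset(recs), "skipped")
  expect_identical(rep$overall$n, 1L)
})
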