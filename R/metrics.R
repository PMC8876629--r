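# Evaluation toolkit: per-base confusion counts, PPV / recall / F1 / MCC,
# core-stem matching with slippage, and dataset-level aggregation.

#' Per-base confusion counts between two structures
#'
#' Each position is classified paired/unpaired in the prediction and in the
#' reference: `tp` = paired in both, `fp` = paired in the prediction only,
#' `fn` = paired in the reference only, `tn` = unpaired in both.  In strict
#' mode a position only counts as `tp` when its partner is identical in both
#' structures (otherwise it contributes to both `fp` and `fn` denominators
#' as a misprediction: it is counted as `fp`).
#'
#' @param pred_db,ref_db extended dot-bracket strings of equal length; both
#'   must parse as balanced two-layer structures.
#' @param strict require identical partners for `tp`.
#' @return object of class `pk_confusion`: list with `tp`, `tn`, `fp`, `fn`
#'   (their sum is the number of evaluated bases).
#' @examples
#' confusion_counts("..[[[.(((]]]...))).", "..[[[.(((]]]...))).")
#' @export
confusion_counts <- function(pred_db, ref_db, strict = FALSE) {
  if (nchar(pred_db) != nchar(ref_db))
    stop("prediction and reference must have equal length")
  pp <- partner_vector(pred_db)
  rp <- partner_vector(ref_db)
  if (strict) {
    tp <- sum(pp > 0 & rp > 0 & pp == rp)
    fp <- sum(pp > 0 & !(rp > 0 & pp == rp))
  } else {
    tp <- sum(pp > 0 & rp > 0)
    fp <- sum(pp > 0 & rp == 0)
  }
  fn <- sum(pp == 0 & rp > 0)
  tn <- sum(pp == 0 & rp == 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "pk_confusion")
}

# partner position per base (0 = unpaired); validates balance
partner_vector <- function(db) {
  m <- dotbracket_pairs(db)
  out <- integer(nchar(db))
  out[m[, 1]] <- m[, 2]
  out[m[, 2]] <- m[, 1]
  out
}

#' PPV, recall, F1 and MCC from confusion counts
#'
#' PPV = tp/(tp+fp); recall = tp/(tp+fn); F1 is their harmonic mean;
#' MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)).  Any metric
#' with a zero denominator is reported as 0 and flagged.
#'
#' @param counts a `pk_confusion` object or list with `tp`, `tn`, `fp`,
#'   `fn`.
#' @return object of class `pk_metrics`: list with `ppv`, `recall`, `f1`,
#'   `mcc` (raw, unrounded) and `degenerate` (flag: some denominator was
#'   zero).
#' @examples
#' m <- confusion_metrics(list(tp = 4212, tn = 4102, fp = 1162, fn = 1300))
#' round(m$mcc, 3)   # 0.543
#' @export
confusion_metrics <- function(counts) {
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  degenerate <- FALSE
  safe <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  ppv <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f1 <- safe(2 * ppv * recall, ppv + recall)
  mcc <- safe(tp * tn - fp * fn,
              sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
  if (degenerate)
    warning("zero denominator: affected metrics reported as 0")
  structure(list(ppv = ppv, recall = recall, f1 = f1, mcc = mcc,
                 degenerate = degenerate),
            class = "pk_metrics")
}

# 3-decimal round-half-up, the tables' rounding convention
round3 <- function(x) floor(x * 1000 + 0.5) / 1000

#' @export
print.pk_metrics <- function(x, ...) {
  cat(sprintf("PPV %.3f  recall %.3f  F1 %.3f  MCC %.3f%s\n",
              round3(x$ppv), round3(x$recall), round3(x$f1), round3(x$mcc),
              if (x$degenerate) "  (degenerate)" else ""))
  invisible(x)
}

#' Core-stem match with slippage
#'
#' Compares the two predicted core-stem pairs `(i1, j1)` and `(i2, j2)`
#' with the reference pairs under the slippage equivalence: a pair `(i, j)`
#' matches `(i', j')` when one coordinate shifts by at most `slip` while the
#' other is exact.  Both stems must match for the prediction to count.
#'
#' @param pred,ref candidates (one-row `pk_candidates` or lists with `i1`,
#'   `i2`, `j1`, `j2`).
#' @param slip maximum single-coordinate shift (>= 0; the standard
#'   evaluation uses 1).
#' @return logical scalar.
#' @examples
#' a <- list(i1 = 5, i2 = 9, j1 = 10, j2 = 16)
#' b <- list(i1 = 4, i2 = 9, j1 = 10, j2 = 17)
#' core_stem_match(a, b, slip = 1)   # TRUE
#' @export
core_stem_match <- function(pred, ref, slip = 1) {
  stopifnot(slip >= 0)
  pred <- as_candidate(pred); ref <- as_candidate(ref)
  pair_match <- function(i, j, ri, rj) {
    (abs(i - ri) <= slip && j == rj) || (i == ri && abs(j - rj) <= slip)
  }
  pair_match(pred$i1, pred$j1, ref$i1, ref$j1) &&
    pair_match(pred$i2, pred$j2, ref$i2, ref$j2)
}

#' Evaluate a set of predictions against references
#'
#' Sums per-base confusion counts over all records (micro-averaging) and
#' reports metrics overall and per length bin, plus exact-match counts
#' (identical dot-bracket strings).  Records with a missing reference are
#' skipped with a message.
#'
#' @param records data frame with columns `seq_id`, `pred_db`, `ref_db`,
#'   and optionally `length` (defaults to `nchar(ref_db)`).
#' @param bins increasing numeric cut points; lengths bin with the
#'   closed-left convention, e.g. `c(30, 40, 50)` gives `L<30`, `30<=L<40`,
#'   `40<=L<50`, `L>=50`.
#' @param strict strict-partner `tp` (see [confusion_counts()]).
#' @return object of class `pk_report`: list with `overall` (counts,
#'   metrics, exact matches) and `table` (one row per bin plus an `all`
#'   row: n, tp, tn, fp, fn, ppv, recall, f1, mcc, exact, exact_pct).
#' @export
evaluate_dataset <- function(records, bins = c(30, 40, 50),
                             strict = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("seq_id", "pred_db", "ref_db") %in% names(records)))
  if (is.unsorted(bins, strictly = TRUE))
    stop("`bins` must be strictly increasing")
  keep <- !is.na(records$ref_db) & nzchar(records$ref_db)
  if (any(!keep))
    message(sum(!keep), " record(s) skipped: missing reference")
  records <- records[keep, , drop = FALSE]
  len <- if ("length" %in% names(records)) records$length else
    nchar(records$ref_db)

  counts <- lapply(seq_len(nrow(records)), function(k)
    confusion_counts(records$pred_db[k], records$ref_db[k],
                     strict = strict))
  exact <- records$pred_db == records$ref_db
  bin_idx <- findInterval(len, bins)           # 0..length(bins), left-closed
  labels <- c(paste0("L<", bins[1]),
              if (length(bins) > 1)
                paste0(bins[-length(bins)], "<=L<", bins[-1]),
              paste0("L>=", bins[length(bins)]))

  row_for <- function(sel, label) {
    tp <- sum(vapply(counts[sel], `[[`, numeric(1), "tp"))
    tn <- sum(vapply(counts[sel], `[[`, numeric(1), "tn"))
    fp <- sum(vapply(counts[sel], `[[`, numeric(1), "fp"))
    fn <- sum(vapply(counts[sel], `[[`, numeric(1), "fn"))
    m <- if (sum(sel)) suppressWarnings(
      confusion_metrics(list(tp = tp, tn = tn, fp = fp, fn = fn)))
      else list(ppv = NA_real_, recall = NA_real_, f1 = NA_real_,
                mcc = NA_real_)
    data.frame(bin = label, n = sum(sel), tp = tp, tn = tn, fp = fp,
               fn = fn, ppv = round3(m$ppv), recall = round3(m$recall),
               f1 = round3(m$f1), mcc = round3(m$mcc),
               exact = sum(exact[sel]),
               exact_pct = if (sum(sel)) round3(100 * sum(exact[sel]) /
                                                  sum(sel)) else NA_real_)
  }

  tab <- do.call(rbind, c(
    lapply(seq_along(labels), function(bi)
      row_for(bin_idx == bi - 1L, labels[bi])),
    list(row_for(rep(TRUE, nrow(records)), "all"))))
  rownames(tab) <- NULL
  overall <- as.list(tab[tab$bin == "all", ])
  structure(list(overall = overall, table = tab, strict = strict),
            class = "pk_report")
}

#' @export
print.pk_report <- function(x, ...) {
  cat("pseudoknot prediction evaluation",
      if (x$strict) "(strict partners)" else "", "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' @param report a [evaluate_dataset()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "pk_report"))
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
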