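# Earley chart parsing of pseudoknot strings.
#
# The chart is the classical array of n+1 state sets; a state is the triple
# (rule, dot, origin).  Chart construction runs in compiled code; this file
# is the R-facing API plus chart-walking derivation extraction.

encode_input <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  m <- match(ch, RNA_BASES)
  if (anyNA(m)) {
    p <- which(is.na(m))[1]
    stop(sprintf("invalid character '%s' at position %d: alphabet is A,C,G,U",
                 ch[p], p))
  }
  m - 1L
}

#' Parse a terminal string with the Earley algorithm
#'
#' Builds the full Earley chart for `s` under `grammar`: `n + 1` state sets
#' closed under the Predictor/Scanner/Completer operations, with the usual
#' fixpoint re-scan of the current set so that epsilon completions (the gap
#' nonterminals derive the empty string) are not missed.
#'
#' @param grammar a [build_grammar()] object.
#' @param s string over A, C, G, U.  Characters outside the alphabet raise an
#'   error naming the offending position.
#' @return an object of class `pk_chart`: list with `sets` (list of `n + 1`
#'   integer matrices with columns `rule`, `dot`, `origin`; rule ids are
#'   0-based, the augmented rule `Start -> S` has id `length(grammar$rules)`),
#'   `input`, `n`, `grammar`, `aug_rule`.
#' @examples
#' g <- build_grammar(2)
#' ch <- earley_parse(g, "CGCCUGAUUUGA")
#' length(ch$sets)        # 13 sets for a 12-nt input
#' @seealso [recognize()], [extract_splits()]
#' @export
earley_parse <- function(grammar, s) {
  stopifnot(inherits(grammar, "pk_grammar"))
  u <- encode_input(s)
  enc <- encode_grammar(grammar)
  sets <- cpp_earley_chart(enc$lhs, enc$rhs, enc$start, enc$nsym, u)
  structure(list(sets = sets, input = s, n = length(u), grammar = grammar,
                 aug_rule = length(grammar$rules)),
            class = "pk_chart")
}

chart_accepts <- function(chart) {
  fin <- chart$sets[[chart$n + 1L]]
  any(fin[, 1] == chart$aug_rule & fin[, 2] == 1L & fin[, 3] == 0L)
}

#' Recognize a pseudoknot core string
#'
#' `TRUE` iff `s` is derivable from the start symbol, i.e. iff the final
#' chart set holds a completed `Start -> S .` state with origin 0.
#'
#' @inheritParams earley_parse
#' @return logical scalar.
#' @examples
#' g <- build_grammar(2)
#' recognize(g, "CGCCUGAUUUGA")   # TRUE (rule-6 core)
#' recognize(g, "AAAA")           # FALSE
#' @export
recognize <- function(grammar, s) {
  chart_accepts(earley_parse(grammar, s))
}

#' Extract all pseudoknot decompositions from a chart
#'
#' Every derivation of an accepted string under an S-rule is identified by
#' the triple (rule id, left-loop length, gap length); the second loop length
#' is implied by the total length.  The decompositions are read off the
#' chart: completed L and D constituents give the admissible spans and the
#' S-rule letters fix the four core-stem positions.
#'
#' @inheritParams earley_parse
#' @param chart optionally a precomputed [earley_parse()] chart for `s`.
#' @return data frame with columns `rule_id`, `l1_len`, `d_len`, one row per
#'   distinct derivation, sorted; zero rows when `s` is not accepted.
#' @examples
#' g <- build_grammar(2)
#' extract_splits(g, "CGCCUGAUUUGA")   # contains (6, 3, 0)
#' @export
extract_splits <- function(grammar, s, chart = NULL) {
  stopifnot(inherits(grammar, "pk_grammar"))
  if (is.null(chart)) chart <- earley_parse(grammar, s)
  stopifnot(inherits(chart, "pk_chart"), identical(chart$input, s))
  n <- chart$n
  empty <- data.frame(rule_id = integer(0), l1_len = integer(0),
                      d_len = integer(0))
  if (n < 6L || !chart_accepts(chart)) return(empty)

  lhs_vec <- vapply(chart$grammar$rules, function(r) r$lhs, character(1))
  rlen <- vapply(chart$grammar$rules, function(r) length(r$rhs), integer(1))

  # span[o + 1, k + 1]: a completed constituent derives s[(o+1)..k] (1-based)
  Lspan <- matrix(FALSE, n + 1L, n + 1L)
  Dspan <- matrix(FALSE, n + 1L, n + 1L)
  for (k in seq_len(n + 1L)) {
    m <- chart$sets[[k]]
    if (!nrow(m)) next
    real <- m[, 1] < chart$aug_rule
    comp <- real & m[, 2] == rlen[m[, 1] + 1L]
    for (row in which(comp)) {
      lh <- lhs_vec[m[row, 1] + 1L]
      if (lh == "L") Lspan[m[row, 3] + 1L, k] <- TRUE
      else if (lh == "D") Dspan[m[row, 3] + 1L, k] <- TRUE
    }
  }

  u <- strsplit(s, "", fixed = TRUE)[[1]]
  letters <- core_stem_letter_pairs(grammar)
  out <- list()
  for (r in seq_len(nrow(letters))) {
    if (u[1] != letters$x[r] || u[n] != letters$w[r]) next
    for (l1 in 1:(n - 5L)) {
      if (!Lspan[2L, l1 + 2L]) next            # l1 spans positions 2..(1+l1)
      if (u[l1 + 2L] != letters$y[r]) next     # y at position l1 + 2
      for (d in 0:grammar$max_dd) {
        pz <- l1 + 3L + d                      # position of z
        if (pz > n - 2L) break                 # l2 must be nonempty
        if (!Dspan[l1 + 3L, pz]) next          # gap spans (l1+3)..(pz-1)
        if (u[pz] != letters$z[r]) next
        if (!Lspan[pz + 1L, n]) next           # l2 spans (pz+1)..(n-1)
        out[[length(out) + 1L]] <-
          c(letters$rule_id[r], l1, d)
      }
    }
  }
  if (!length(out)) return(empty)
  m <- do.call(rbind, out)
  res <- data.frame(rule_id = m[, 1], l1_len = m[, 2], d_len = m[, 3])
  res <- unique(res[order(res$rule_id, res$l1_len, res$d_len), , drop = FALSE])
  rownames(res) <- NULL
  res
}

#' @export
print.pk_chart <- function(x, ...) {
  cat(sprintf("Earley chart for %d-nt input \"%s\": %d sets, %d states\n",
              x$n, x$input, length(x$sets),
              sum(vapply(x$sets, nrow, integer(1)))))
  invisible(x)
}
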