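# Pseudoknot grammar construction.
#
# The grammar recognizes H-type pseudoknot cores: strings that decompose as
# x . l1 . y . d . z . l2 . w where (x,z) and (y,w) are Watson-Crick pairs,
# l1 and l2 are nonempty loop runs, and d is a bounded gap between the two
# crossing stem halves.  One S-rule per ordered pair of Watson-Crick core
# stems (16 rules), loop rules on L, and a chain of optional-terminal
# nonterminals deriving the gap D.

#' RNA alphabet and Watson-Crick complements
#'
#' `RNA_BASES` fixes the terminal order used throughout the package
#' (A, U, C, G — the order the grammar rules enumerate bases in).
#' `WC_PARTNER` maps each base to its Watson-Crick complement.
#'
#' @keywords internal
#' @name alphabet
NULL

RNA_BASES <- c("A", "U", "C", "G")
WC_PARTNER <- c(A = "U", U = "A", C = "G", G = "C")

#' Test base pairing
#'
#' @param x,y character vectors of single bases (recycled).
#' @param allow_gu also accept the G-U wobble pair.
#' @return logical vector: `TRUE` where `(x, y)` is an admissible pair.
#' @examples
#' is_base_pair("G", "C")
#' is_base_pair("G", "U")               # FALSE
#' is_base_pair("G", "U", allow_gu = TRUE)
#' @export
is_base_pair <- function(x, y, allow_gu = FALSE) {
  wc <- !is.na(WC_PARTNER[x]) & WC_PARTNER[x] == y
  if (allow_gu)
    wc <- wc | (x == "G" & y == "U") | (x == "U" & y == "G")
  unname(wc)
}

#' Build the pseudoknot context-free grammar
#'
#' Constructs the core-stem grammar parameterized by `max_dd`, the maximum
#' number of bases allowed between the two crossing core-stem halves.  The
#' grammar has exactly 16 S-rules (one per ordered pair of Watson-Crick core
#' stems), rules making L derive every nonempty terminal string, and a chain
#' of `max_dd` optional-terminal nonterminals (named K, N, N3, ...) making D
#' derive terminal strings of length 0 to `max_dd`.  With `max_dd = 2` the
#' rule set is the standard 35-rule table (ids 0-34).
#'
#' @param max_dd integer >= 0, maximum gap length derivable from D.
#' @return an object of class `pk_grammar`: a list with elements `rules`
#'   (list of rules, each `list(id, lhs, rhs)`; `rhs` is a character vector of
#'   symbols, empty for an epsilon rule), `max_dd`, `start`, `terminals`,
#'   `nonterminals`.
#' @examples
#' g <- build_grammar(2)
#' length(g$rules)                      # 35
#' format_grammar(g)[7]                 # rule 6, the C..U..G..A core
#' @seealso [core_stem_letter_pairs()], [earley_parse()]
#' @export
build_grammar <- function(max_dd = 2) {
  if (!is.numeric(max_dd) || length(max_dd) != 1L || is.na(max_dd) ||
      max_dd < 0 || max_dd != floor(max_dd))
    stop("`max_dd` must be a single non-negative integer")
  max_dd <- as.integer(max_dd)

  rules <- list()
  add <- function(lhs, rhs)
    rules[[length(rules) + 1L]] <<- list(id = length(rules), lhs = lhs,
                                         rhs = rhs)
  # S-rules: id = 4 * index(y) + index(x) over the base order A, U, C, G
  for (y in RNA_BASES)
    for (x in RNA_BASES)
      add("S", c(x, "L", y, "D",
                 unname(WC_PARTNER[x]), "L", unname(WC_PARTNER[y])))
  # L derives every nonempty terminal string
  for (t in RNA_BASES) add("L", c(t, "L"))
  for (t in RNA_BASES) add("L", t)
  # D derives terminal strings of length 0..max_dd
  if (max_dd == 0L) {
    gap_nts <- character(0)
    add("D", character(0))
  } else {
    gap_nts <- c("K", "N", if (max_dd > 2L) paste0("N", 3:max_dd))[1:max_dd]
    add("D", gap_nts)
    for (g in gap_nts) {
      for (t in RNA_BASES) add(g, t)
      add(g, character(0))
    }
  }

  structure(list(rules = rules, max_dd = max_dd, start = "S",
                 terminals = RNA_BASES,
                 nonterminals = c("S", "L", "D", gap_nts)),
            class = "pk_grammar")
}

#' Core-stem letter tuples of the 16 S-rules
#'
#' @param grammar a `pk_grammar`.
#' @return a 16-row data frame with columns `rule_id`, `x`, `y`, `z`, `w`:
#'   the S-rule pattern is `S -> x L y D z L w`, with (x,z) and (y,w) each
#'   Watson-Crick complements.  Row order matches rule id.
#' @examples
#' core_stem_letter_pairs(build_grammar(2))[7, ]   # rule 6: C, U, G, A
#' @export
core_stem_letter_pairs <- function(grammar) {
  stopifnot(inherits(grammar, "pk_grammar"))
  srules <- Filter(function(r) r$lhs == "S", grammar$rules)
  out <- data.frame(
    rule_id = vapply(srules, function(r) r$id, integer(1)),
    x = vapply(srules, function(r) r$rhs[1], character(1)),
    y = vapply(srules, function(r) r$rhs[3], character(1)),
    z = vapply(srules, function(r) r$rhs[5], character(1)),
    w = vapply(srules, function(r) r$rhs[7], character(1)))
  out[order(out$rule_id), , drop = FALSE]
}

#' Plain-text grammar dump
#'
#' One rule per line in the table notation, e.g.
#' `6: S -> "C" L "U" D "G" L "A"`; epsilon rules render as `eps`.
#'
#' @param grammar a `pk_grammar`.
#' @return character vector, one rule per line, in id order.
#' @export
format_grammar <- function(grammar) {
  stopifnot(inherits(grammar, "pk_grammar"))
  vapply(grammar$rules, function(r) {
    rhs <- if (!length(r$rhs)) "eps" else
      paste(ifelse(r$rhs %in% grammar$terminals,
                   paste0("\"", r$rhs, "\""), r$rhs),
            collapse = " ")
    sprintf("%d: %s -> %s", r$id, r$lhs, rhs)
  }, character(1))
}

#' @export
print.pk_grammar <- function(x, ...) {
  cat(sprintf("H-type pseudoknot grammar: %d rules, max gap %d\n",
              length(x$rules), x$max_dd))
  cat(format_grammar(x), sep = "\n")
  invisible(x)
}

# Integer encoding handed to the C++ engine: terminals 0..3 in RNA_BASES
# order, nonterminals 4.. in grammar$nonterminals order.
encode_grammar <- function(grammar) {
  syms <- c(grammar$terminals, grammar$nonterminals)
  code <- stats::setNames(seq_along(syms) - 1L, syms)
  list(lhs = vapply(grammar$rules, function(r) code[[r$lhs]], integer(1)),
       rhs = lapply(grammar$rules, function(r) unname(code[r$rhs])),
       start = code[["S"]],
       nsym = length(syms))
}
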