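# Core-stem decoration: greedy outward extension of the two crossing stems
# by contiguous stacked base pairs, and extended dot-bracket rendering.

as_candidate <- function(cand) {
  if (inherits(cand, "pk_candidates") || is.data.frame(cand)) {
    if (nrow(cand) != 1L)
      stop("expected a single candidate (one row)")
    cand <- as.list(cand)
  }
  stopifnot(all(c("i1", "i2", "j1", "j2") %in% names(cand)))
  cand$i1 <- as.integer(cand$i1); cand$i2 <- as.integer(cand$i2)
  cand$j1 <- as.integer(cand$j1); cand$j2 <- as.integer(cand$j2)
  if (is.null(cand$rule_id)) cand$rule_id <- NA_integer_
  cand
}

#' Decorate a candidate's core stems with stacked base pairs
#'
#' Each stem is extended outward greedily one pair at a time, stopping at
#' the first non-complementary pair or region boundary.  Stem 2 (the
#' `(i2, j2)` pair) pairs left-loop bases `i2-1, i2-2, ...` with bases
#' beyond `j2`; stem 1 (the `(i1, j1)` pair) pairs bases before `i1` with
#' right-loop bases `j1+1, j1+2, ...`.  Extensions are strictly contiguous;
#' bulges and interior loops are not modeled.
#'
#' @param seq an [rna_sequence()] or raw base string.
#' @param cand a single candidate: one row of a `pk_candidates` frame or a
#'   list with `i1`, `i2`, `j1`, `j2` (and optionally `rule_id`).
#' @param allow_gu also accept G-U wobble pairs in the extensions (never in
#'   the core stems).
#' @param min_loop minimum number of unpaired bases to leave in each loop
#'   (default 0: loops may be consumed entirely).
#' @return object of class `pk_decorated`: list with `candidate`,
#'   `stem1_ext` and `stem2_ext` (k x 2 matrices of pairs, outward order),
#'   `pair_count` (2 + total extensions), `allow_gu`.
#' @examples
#' dec <- decorate("CCAUCGCCUGAUUUGAGGA",
#'                 list(i1 = 5, i2 = 9, j1 = 10, j2 = 16))
#' dec$stem2_ext          # (8,17), (7,18)
#' dec$pair_count         # 6
#' @export
decorate <- function(seq, cand, allow_gu = FALSE, min_loop = 0) {
  seq <- as_rna(seq)
  cand <- as_candidate(cand)
  validate_candidate(seq, cand)
  b <- seq_chars(seq)

  extend <- function(left0, right0, kmax) {
    k <- 0L
    while (k < kmax &&
           is_base_pair(b[left0 - k - 1L], b[right0 + k + 1L], allow_gu))
      k <- k + 1L
    if (k == 0L) return(matrix(integer(0), 0L, 2L,
                               dimnames = list(NULL, c("i", "j"))))
    cbind(i = left0 - seq_len(k), j = right0 + seq_len(k))
  }

  # stem 2: left halves stay inside the left loop, right halves inside the
  # 3' tail; stem 1: left halves in the 5' tail, right halves inside the
  # right loop.  min_loop reserves unpaired bases in the consumed loop.
  e2max <- min(cand$i2 - cand$i1 - 1L - min_loop, seq$n - cand$j2)
  e1max <- min(cand$i1 - 1L, cand$j2 - cand$j1 - 1L - min_loop)
  stem2_ext <- extend(cand$i2, cand$j2, max(0L, e2max))
  stem1_ext <- extend(cand$i1, cand$j1, max(0L, e1max))

  structure(list(candidate = cand,
                 stem1_ext = stem1_ext, stem2_ext = stem2_ext,
                 pair_count = 2L + nrow(stem1_ext) + nrow(stem2_ext),
                 allow_gu = allow_gu),
            class = "pk_decorated")
}

decorated_pairs <- function(dec) {
  rbind(cbind(i = dec$candidate$i1, j = dec$candidate$j1), dec$stem1_ext,
        cbind(i = dec$candidate$i2, j = dec$candidate$j2), dec$stem2_ext)
}

#' Render a structure in extended dot-bracket notation
#'
#' Stem 1 and its extensions are written with square brackets, stem 2 and
#' its extensions with round brackets, unpaired positions as dots; the two
#' layers are each individually balanced and nested, and together encode the
#' crossing.
#'
#' @param seq an [rna_sequence()] or raw base string.
#' @param x a `pk_decorated` structure, or a bare candidate (rendered with
#'   no extensions).
#' @return a string of length `n` over `. ( ) [ ]`.
#' @examples
#' s <- "CCAUCGCCUGAUUUGAGGA"
#' to_dotbracket(s, decorate(s, list(i1 = 5, i2 = 9, j1 = 10, j2 = 16)))
#' @export
to_dotbracket <- function(seq, x) {
  seq <- as_rna(seq)
  if (!inherits(x, "pk_decorated")) {
    cand <- as_candidate(x)
    x <- list(candidate = cand,
              stem1_ext = matrix(integer(0), 0, 2),
              stem2_ext = matrix(integer(0), 0, 2))
  }
  db <- rep(".", seq$n)
  db[c(x$candidate$i1, x$stem1_ext[, 1])] <- "["
  db[c(x$candidate$j1, x$stem1_ext[, 2])] <- "]"
  db[c(x$candidate$i2, x$stem2_ext[, 1])] <- "("
  db[c(x$candidate$j2, x$stem2_ext[, 2])] <- ")"
  paste(db, collapse = "")
}

#' Parse an extended dot-bracket string into its base pairs
#'
#' @param db string over `. ( ) [ ]` (a layer may be absent).
#' @return integer matrix with columns `i`, `j`, `layer` (1 for the square
#'   layer, 2 for the round layer), rows sorted by `i`.  Unbalanced input
#'   is an error.
#' @examples
#' dotbracket_pairs("..[[[.(((]]]...))).")
#' @export
dotbracket_pairs <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  bad <- which(!(ch %in% c(".", "(", ")", "[", "]")))
  if (length(bad))
    stop(sprintf("invalid structure character '%s' at position %d",
                 ch[bad[1]], bad[1]))
  pairs <- list()
  for (layer in 1:2) {
    open <- c("[", "(")[layer]; close <- c("]", ")")[layer]
    stack <- integer(0)
    for (p in seq_along(ch)) {
      if (ch[p] == open) stack <- c(stack, p)
      else if (ch[p] == close) {
        if (!length(stack))
          stop(sprintf("unbalanced '%s' at position %d", close, p))
        pairs[[length(pairs) + 1L]] <- c(stack[length(stack)], p, layer)
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack))
      stop(sprintf("unbalanced '%s' at position %d", open,
                   stack[length(stack)]))
  }
  if (!length(pairs))
    return(matrix(integer(0), 0, 3, dimnames = list(NULL,
                                                    c("i", "j", "layer"))))
  m <- do.call(rbind, pairs)
  colnames(m) <- c("i", "j", "layer")
  m[order(m[, 1]), , drop = FALSE]
}

#' @export
print.pk_decorated <- function(x, ...) {
  cat(sprintf(
    "decorated pseudoknot: core (%d,%d)/(%d,%d), %d pairs (%d + %d ext)\n",
    x$candidate$i1, x$candidate$j1, x$candidate$i2, x$candidate$j2,
    x$pair_count, nrow(x$stem1_ext), nrow(x$stem2_ext)))
  invisible(x)
}
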