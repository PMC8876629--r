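# Candidate core-stem detection: grammar engine (sliding windows over the
# Earley parser) and brute-force engine (direct quadruple enumeration).
# Both emit the same canonical candidate table.

#' Construct an RNA sequence object
#'
#' Validates and normalizes a raw base string: lower case is folded to upper
#' case and the DNA letter T is converted to U, each with a warning; any
#' other character raises an error naming the offending position.
#'
#' @param bases single string over A, C, G, U (case-insensitive; T accepted).
#' @param seq_id sequence identifier.
#' @return object of class `rna_sequence`: list with `seq_id`, `bases`
#'   (normalized string), `n` (length), `normalized` (flag).
#' @examples
#' rna_sequence("CCAUCGCCUGAUUUGAGGA", "wx")
#' @export
rna_sequence <- function(bases, seq_id = "seq") {
  stopifnot(is.character(bases), length(bases) == 1L, !is.na(bases))
  up <- toupper(bases)
  normalized <- !identical(up, bases)
  if (grepl("T", up, fixed = TRUE)) {
    up <- gsub("T", "U", up, fixed = TRUE)
    normalized <- TRUE
  }
  ch <- strsplit(up, "", fixed = TRUE)[[1]]
  bad <- which(!(ch %in% RNA_BASES))
  if (length(bad))
    stop(sprintf("sequence '%s': invalid base '%s' at position %d",
                 seq_id, ch[bad[1]], bad[1]))
  if (normalized)
    warning(sprintf("sequence '%s' normalized (case folded / T -> U)",
                    seq_id))
  structure(list(seq_id = seq_id, bases = up, n = nchar(up),
                 normalized = normalized),
            class = "rna_sequence")
}

as_rna <- function(x, seq_id = "seq") {
  if (inherits(x, "rna_sequence")) x else rna_sequence(x, seq_id)
}

seq_chars <- function(seq) strsplit(seq$bases, "", fixed = TRUE)[[1]]

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf(">%s (%d nt)\n%s\n", x$seq_id, x$n, x$bases))
  invisible(x)
}

# rule id determined by the four core bases: id = 4 * index(y) + index(x)
# over the base order A, U, C, G (matches the S-rule table).
rule_id_for <- function(x, y) {
  4L * (match(y, RNA_BASES) - 1L) + (match(x, RNA_BASES) - 1L)
}

empty_candidates <- function() {
  structure(data.frame(seq_id = character(0), i1 = integer(0),
                       i2 = integer(0), j1 = integer(0), j2 = integer(0),
                       rule_id = integer(0)),
            class = c("pk_candidates", "data.frame"))
}

canonical_candidates <- function(df) {
  if (!nrow(df)) return(empty_candidates())
  df <- unique(df)
  df <- df[order(df$i1, df$i2, df$j1, df$j2, df$rule_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("pk_candidates", "data.frame"))
}

# re-validate the candidate invariants against the sequence
validate_candidate <- function(seq, cand, max_dd = NULL, allow_gu = FALSE) {
  b <- seq_chars(seq)
  with(cand, {
    if (!(1 <= i1 && i1 < i2 && i2 < j1 && j1 < j2 && j2 <= seq$n))
      stop("candidate positions must satisfy 1 <= i1 < i2 < j1 < j2 <= n")
    if (i2 - i1 - 1L < 1L) stop("left loop must be nonempty")
    if (j2 - j1 - 1L < 1L) stop("right loop must be nonempty")
    if (!is.null(max_dd) && (j1 - i2 - 1L < 0L || j1 - i2 - 1L > max_dd))
      stop("gap length outside [0, max_dd]")
    if (!is_base_pair(b[i1], b[j1]) || !is_base_pair(b[i2], b[j2]))
      stop("core stems must be Watson-Crick pairs")
  })
  invisible(TRUE)
}

# one chart per start position covers every window end (the Earley chart
# for the suffix at `a` is prefix-incremental)
scan_starts <- function(seq, grammar, starts, min_window) {
  enc <- encode_grammar(grammar)
  u <- encode_input(seq$bases)
  m <- cpp_scan_starts(enc$lhs, enc$rhs, enc$start, enc$nsym, u,
                       as.integer(starts), as.integer(min_window),
                       grammar$max_dd)
  data.frame(seq_id = rep.int(seq$seq_id, nrow(m)),
             i1 = m[, 1], i2 = m[, 2], j1 = m[, 3], j2 = m[, 4],
             rule_id = m[, 5])
}

#' Detect pseudoknot candidates with the grammar engine
#'
#' Runs the Earley parser over every substring window of length at least
#' `min_window` (the window endpoints are the outermost core-stem bases);
#' every derivation is mapped to full-sequence coordinates.
#'
#' @param seq an [rna_sequence()] or a raw base string.
#' @param max_dd maximum gap between the crossing stem halves (default 2).
#' @param min_window minimum window length, at least 6 (the analytic minimum
#'   pseudoknot core length).
#' @param grammar optionally a prebuilt [build_grammar()] (must match
#'   `max_dd`).
#' @return a `pk_candidates` data frame with columns `seq_id`, `i1`, `i2`,
#'   `j1`, `j2` (1-based inclusive core-stem positions, `i1 < i2 < j1 < j2`;
#'   stem 1 pairs `(i1, j1)`, stem 2 pairs `(i2, j2)`), `rule_id`; candidates
#'   are deduplicated and sorted by `(i1, i2, j1, j2, rule_id)`.
#' @examples
#' detect_grammar("CGCCUGAUUUGA")
#' @seealso [detect_bruteforce()], [detect_parallel()]
#' @export
detect_grammar <- function(seq, max_dd = 2, min_window = 6,
                           grammar = NULL) {
  seq <- as_rna(seq)
  if (min_window < 6) stop("`min_window` must be at least 6")
  if (is.null(grammar)) grammar <- build_grammar(max_dd)
  stopifnot(inherits(grammar, "pk_grammar"), grammar$max_dd == max_dd)
  if (seq$n < min_window) return(empty_candidates())
  starts <- seq_len(seq$n - as.integer(min_window) + 1L)
  canonical_candidates(scan_starts(seq, grammar, starts, min_window))
}

#' Detect pseudoknot candidates by brute force
#'
#' Enumerates all Watson-Crick base pairs, then all ordered pairs of pairs
#' `(i1, j1)`, `(i2, j2)` with `i1 < i2 < j1 < j2`, nonempty loops, and a
#' gap `j1 - i2 - 1` between 0 and `max_dd`.  Produces exactly the grammar
#' engine's candidate set, in the same canonical order.
#'
#' @inheritParams detect_grammar
#' @return a `pk_candidates` data frame (see [detect_grammar()]).
#' @examples
#' detect_bruteforce("CGCCUGAUUUGA")   # contains (1, 5, 6, 12)
#' @export
detect_bruteforce <- function(seq, max_dd = 2) {
  seq <- as_rna(seq)
  b <- seq_chars(seq)
  n <- seq$n
  if (n < 6L) return(empty_candidates())
  pair_ok <- outer(b, b, is_base_pair)
  idx <- which(pair_ok & upper.tri(pair_ok), arr.ind = TRUE)
  if (!nrow(idx)) return(empty_candidates())
  P <- data.frame(i = idx[, 1], j = idx[, 2])
  out <- vector("list", max_dd + 1L)
  for (d in 0:max_dd) {
    P2 <- data.frame(i2 = P$i, j2 = P$j, k = P$i + 1L + d)
    m <- merge(data.frame(i1 = P$i, j1 = P$j), P2,
               by.x = "j1", by.y = "k")
    m <- m[m$i2 >= m$i1 + 2L & m$j2 >= m$j1 + 2L, , drop = FALSE]
    out[[d + 1L]] <- m
  }
  m <- do.call(rbind, out)
  if (!nrow(m)) return(empty_candidates())
  canonical_candidates(data.frame(
    seq_id = rep.int(seq$seq_id, nrow(m)),
    i1 = m$i1, i2 = m$i2, j1 = m$j1, j2 = m$j2,
    rule_id = rule_id_for(b[m$i1], b[m$i2])))
}

#' Parallel grammar-engine detection
#'
#' Windows are independent, so they are chunked across `workers` forked
#' processes and the joined result is canonically sorted: the output is
#' bit-identical to [detect_grammar()] for any worker count.
#'
#' @inheritParams detect_grammar
#' @param workers number of worker processes (>= 1).
#' @return a `pk_candidates` data frame (see [detect_grammar()]).
#' @export
detect_parallel <- function(seq, max_dd = 2, min_window = 6, workers = 1L) {
  seq <- as_rna(seq)
  if (workers < 1) stop("`workers` must be >= 1")
  if (min_window < 6) stop("`min_window` must be at least 6")
  grammar <- build_grammar(max_dd)
  if (seq$n < min_window) return(empty_candidates())
  starts <- seq_len(seq$n - as.integer(min_window) + 1L)
  workers <- min(as.integer(workers), length(starts))
  chunk <- sort(rep_len(seq_len(workers), length(starts)))
  parts <- if (workers == 1L || .Platform$OS.type == "windows") {
    lapply(split(starts, chunk), function(k)
      scan_starts(seq, grammar, k, min_window))
  } else {
    parallel::mclapply(split(starts, chunk), function(k)
      scan_starts(seq, grammar, k, min_window), mc.cores = workers)
  }
  canonical_candidates(do.call(rbind, parts))
}
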