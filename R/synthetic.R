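# Seeded generator of synthetic RNA sequences with one planted H-type
# pseudoknot and its ground-truth structure.  A stand-in for curated
# benchmark sets: two crossing Watson-Crick stems of chosen depth, loops,
# bounded gap and optional flanks, with rejection sampling so the planted
# structure is the unique maximal-pair candidate.

#' Specification of a planted pseudoknot
#'
#' Segment layout (5' to 3'): flank5, stem1 left half (`stem1_len` bases),
#' loop1 (`loop1_len` unpaired), stem2 left half, gap (`gap_len` bases),
#' stem1 right half, loop2, stem2 right half, flank3.  The generated length
#' is the segment sum with both stems counted twice.
#'
#' @param stem1_len,stem2_len full stem depths (core pair + decoration),
#'   >= 1.
#' @param loop1_len,loop2_len unpaired loop lengths, >= 1.
#' @param gap_len bases between the crossing stem halves, in `[0, max_dd]`
#'   of the intended detector.
#' @param flank5_len,flank3_len unpaired flank lengths, >= 0.
#' @param seed integer seed; generation is reproducible.
#' @return object of class `pk_plant_spec`.
#' @export
plant_spec <- function(stem1_len = 3, stem2_len = 3, loop1_len = 1,
                       loop2_len = 5, gap_len = 0, flank5_len = 2,
                       flank3_len = 1, seed = 1L) {
  v <- list(stem1_len = stem1_len, stem2_len = stem2_len,
            loop1_len = loop1_len, loop2_len = loop2_len,
            gap_len = gap_len, flank5_len = flank5_len,
            flank3_len = flank3_len, seed = seed)
  v <- lapply(v, function(x) {
    stopifnot(is.numeric(x), length(x) == 1L, !is.na(x), x == floor(x))
    as.integer(x)
  })
  with(v, {
    stopifnot(stem1_len >= 1L, stem2_len >= 1L, loop1_len >= 1L,
              loop2_len >= 1L, gap_len >= 0L, flank5_len >= 0L,
              flank3_len >= 0L)
  })
  structure(v, class = "pk_plant_spec")
}

# run code under a private RNG stream, leaving global state untouched
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

rand_bases <- function(k) sample(RNA_BASES, k, replace = TRUE)
revcomp <- function(x) rev(unname(WC_PARTNER[x]))

#' Generate a sequence with one planted pseudoknot
#'
#' Draws stem, loop, gap and flank bases uniformly, forces the bases just
#' outside each stem to be non-pairing (so greedy decoration stops exactly
#' at the planted depth), and rejects draws in which the planted structure
#' is not the unique maximal-pair candidate (verified with the brute-force
#' detector).  Reproducible under the spec's seed.
#'
#' @param spec a [plant_spec()].
#' @param max_dd detector gap bound the fixture targets (default 2); must
#'   be >= `spec$gap_len`.
#' @param max_tries rejection-sampling budget.
#' @return list with `seq` (an [rna_sequence()]), `dot_bracket` (ground
#'   truth), `candidate` (the planted core stems as a one-row candidate
#'   frame), `spec`, `tries`.
#' @examples
#' fx <- generate_planted(plant_spec(seed = 7))
#' fx$dot_bracket
#' @export
generate_planted <- function(spec, max_dd = 2, max_tries = 200) {
  stopifnot(inherits(spec, "pk_plant_spec"), max_dd >= spec$gap_len)
  s1 <- spec$stem1_len; s2 <- spec$stem2_len
  f5 <- spec$flank5_len; f3 <- spec$flank3_len
  l1 <- spec$loop1_len; l2 <- spec$loop2_len; g <- spec$gap_len

  i1 <- f5 + s1
  i2 <- i1 + l1 + s2
  j1 <- i2 + g + 1L
  j2 <- j1 + s1 + l2
  n <- f5 + s1 + l1 + s2 + g + s1 + l2 + s2 + f3

  build <- function() {
    stem1 <- rand_bases(s1)            # 5'->3' left half, ends at i1
    stem2 <- rand_bases(s2)            # 5'->3' left half, ends at i2
    b <- c(rand_bases(f5), stem1, rand_bases(l1), stem2, rand_bases(g),
           revcomp(stem1), rand_bases(l2), revcomp(stem2), rand_bases(f3))
    # stop decoration exactly at the planted depth: the pair just outside
    # each stem must not form (not even G-U, so fixtures are robust to the
    # wobble option)
    no_pair <- function(fix_pos, against) {
      while (is_base_pair(b[fix_pos], b[against], allow_gu = TRUE) ||
             is_base_pair(b[against], b[fix_pos], allow_gu = TRUE))
        b[fix_pos] <<- sample(RNA_BASES, 1)
    }
    if (f5 >= 1L && j1 + s1 <= j2 - 1L) no_pair(i1 - s1, j1 + s1)
    if (f3 >= 1L && i2 - s2 >= i1 + 1L) no_pair(j2 + s2, i2 - s2)
    b
  }

  planted <- list(i1 = i1, i2 = i2, j1 = j1, j2 = j2)

  res <- with_seed(spec$seed, {
    out <- NULL
    for (t in seq_len(max_tries)) {
      b <- build()
      seq <- rna_sequence(paste(b, collapse = ""),
                          sprintf("planted_s%d", spec$seed))
      cands <- detect_bruteforce(seq, max_dd)
      hit <- which(cands$i1 == i1 & cands$i2 == i2 &
                     cands$j1 == j1 & cands$j2 == j2)
      if (!length(hit)) next                      # cannot happen, defensive
      pc <- vapply(seq_len(nrow(cands)), function(k)
        decorate(seq, cands[k, ])$pair_count, integer(1))
      if (pc[hit] == max(pc) && sum(pc == max(pc)) == 1L &&
          pc[hit] == s1 + s2) {
        out <- list(seq = seq, tries = t)
        break
      }
    }
    out
  })
  if (is.null(res))
    stop("rejection sampling exhausted after ", max_tries,
         " tries; relax the spec (shorter flanks/loops or deeper stems)")

  db <- rep(".", n)
  db[i1 - seq_len(s1) + 1L] <- "["; db[j1 + seq_len(s1) - 1L] <- "]"
  db[i2 - seq_len(s2) + 1L] <- "("; db[j2 + seq_len(s2) - 1L] <- ")"
  cand <- canonical_candidates(data.frame(
    seq_id = res$seq$seq_id, i1 = i1, i2 = i2, j1 = j1, j2 = j2,
    rule_id = rule_id_for(substr(res$seq$bases, i1, i1),
                          substr(res$seq$bases, i2, i2))))
  list(seq = res$seq, dot_bracket = paste(db, collapse = ""),
       candidate = cand, spec = spec, tries = res$tries)
}
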