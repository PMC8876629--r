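# Pseudoknot free-energy heuristic and optimal-structure selection.
#
# G_pseudo = beta1 + beta2 * Bp + beta3 * Up, where beta1 is the cost of
# forming the pseudoknot, Bp the number of core stems (2 for H-type) and Up
# the number of unpaired bases inside the pseudoknot span.  Selection first
# maximizes the pair count and applies the energy only to the top-ranked
# structures.

#' Energy model parameters
#'
#' @param beta1 pseudoknot-existence weight (default 9.6).
#' @param beta2 per-core-stem weight (default 0.1).
#' @param beta3 per-unpaired-base weight (default 0.1).
#' @param stack_table optional named numeric vector of stacking energies,
#'   keyed `"XY/ZW"` for adjacent pairs `(i, j)` and `(i-1, j+1)` with
#'   `X = base[i-1]`, `Y = base[i]`, `Z = base[j]`, `W = base[j+1]`; summed
#'   over all stacked adjacencies and added to the energy.
#' @param count_pairs count all base pairs as `Bp` instead of the literal
#'   "number of core stems" (= 2).
#' @return object of class `pk_energy_params`.
#' @export
energy_params <- function(beta1 = 9.6, beta2 = 0.1, beta3 = 0.1,
                          stack_table = NULL, count_pairs = FALSE) {
  stopifnot(is.numeric(beta1), is.numeric(beta2), is.numeric(beta3))
  if (!is.null(stack_table))
    stopifnot(is.numeric(stack_table), !is.null(names(stack_table)))
  structure(list(beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 stack_table = stack_table, count_pairs = count_pairs),
            class = "pk_energy_params")
}

stack_term <- function(seq, dec, stack_table) {
  if (is.null(stack_table)) return(0)
  b <- seq_chars(seq)
  term <- 0
  for (ext in list(rbind(cbind(i = dec$candidate$i1, j = dec$candidate$j1),
                         dec$stem1_ext),
                   rbind(cbind(i = dec$candidate$i2, j = dec$candidate$j2),
                         dec$stem2_ext))) {
    if (nrow(ext) < 2L) next
    for (k in 2:nrow(ext)) {
      # ext[k, ] = (i - 1, j + 1) stacked under ext[k - 1, ] = (i, j)
      key <- paste0(b[ext[k, 1]], b[ext[k - 1, 1]], "/",
                    b[ext[k - 1, 2]], b[ext[k, 2]])
      if (!is.na(stack_table[key])) term <- term + stack_table[[key]]
    }
  }
  term
}

#' Score a decorated structure with the pseudoknot energy
#'
#' `Up` counts the positions strictly inside the outermost paired span that
#' remain unpaired after decoration; `Bp` is 2 (the number of core stems)
#' unless `count_pairs` is set in the parameters.
#'
#' @param seq an [rna_sequence()] or raw base string (needed only when a
#'   stacking table is configured; pass the candidate's sequence).
#' @param dec a [decorate()]d structure.
#' @param params an [energy_params()] object.
#' @return object of class `pk_scored`: list with `dec`, `bp`, `up`,
#'   `g_pseudo`, `stack_energy`.
#' @examples
#' s <- "CCAUCGCCUGAUUUGAGGA"
#' dec <- decorate(s, list(i1 = 5, i2 = 9, j1 = 10, j2 = 16))
#' pseudoknot_energy(s, dec)$g_pseudo   # 9.6 + 0.1*2 + 0.1*4 = 10.2
#' @export
pseudoknot_energy <- function(seq, dec, params = energy_params()) {
  stopifnot(inherits(dec, "pk_decorated"),
            inherits(params, "pk_energy_params"))
  pr <- decorated_pairs(dec)
  paired <- sort(c(pr[, 1], pr[, 2]))
  span <- range(paired)
  inside <- seq.int(span[1] + 1L, span[2] - 1L)
  up <- sum(!(inside %in% paired))
  bp <- if (isTRUE(params$count_pairs)) dec$pair_count else 2L
  st <- if (is.null(params$stack_table)) 0 else
    stack_term(as_rna(seq), dec, params$stack_table)
  structure(list(dec = dec, bp = bp, up = up,
                 g_pseudo = params$beta1 + params$beta2 * bp +
                   params$beta3 * up + st,
                 stack_energy = st),
            class = "pk_scored")
}

#' Select the optimal structure
#'
#' Among the structures with the maximal pair count, returns the one with
#' minimal pseudoknot energy; the energy is only computed for that maximal
#' subset.  Remaining ties break deterministically by smallest `i1`, then
#' smallest `j2`, then smallest `i2`.
#'
#' @param seq the common [rna_sequence()] (or raw string) of the structures.
#' @param structures list of `pk_decorated` (scored lazily) or `pk_scored`
#'   objects.
#' @param params an [energy_params()] object.
#' @return the winning `pk_scored` structure, or `NULL` for an empty list
#'   ("no pseudoknot found").
#' @export
select_best <- function(seq, structures, params = energy_params()) {
  if (!length(structures)) return(NULL)
  dec_of <- function(s) if (inherits(s, "pk_scored")) s$dec else s
  pc <- vapply(structures, function(s) dec_of(s)$pair_count, integer(1))
  top <- structures[pc == max(pc)]
  scored <- lapply(top, function(s)
    if (inherits(s, "pk_scored")) s else pseudoknot_energy(seq, s, params))
  g <- vapply(scored, function(s) s$g_pseudo, numeric(1))
  i1 <- vapply(scored, function(s) s$dec$candidate$i1, integer(1))
  j2 <- vapply(scored, function(s) s$dec$candidate$j2, integer(1))
  i2 <- vapply(scored, function(s) s$dec$candidate$i2, integer(1))
  scored[[order(g, i1, j2, i2)[1]]]
}

#' Predict the pseudoknot structure of a sequence
#'
#' End-to-end pipeline: enumerate candidate core stems (grammar or
#' brute-force engine), decorate each candidate, and select the optimal
#' structure by maximum pairing then minimum energy.  When no candidate
#' exists the all-dots structure is returned.
#'
#' @param seq an [rna_sequence()] or raw base string.
#' @param engine `"bruteforce"` (default, the faster engine) or `"grammar"`.
#' @param max_dd maximum gap between the crossing stem halves.
#' @param min_window minimum window length for the grammar engine.
#' @param allow_gu allow G-U wobble pairs in decoration.
#' @param min_loop minimum unpaired bases left in each loop by decoration.
#' @param params an [energy_params()] object.
#' @param workers worker processes for the grammar engine (ignored by the
#'   brute-force engine).
#' @return object of class `pk_prediction`: list with `seq`, `best` (the
#'   winning `pk_scored`, or `NULL`), `dot_bracket`, `n_candidates`.
#' @examples
#' p <- predict_structure("CCAUCGCCUGAUUUGAGGA")
#' p$dot_bracket          # "..[[[.(((]]]...)))."
#' @export
predict_structure <- function(seq, engine = c("bruteforce", "grammar"),
                              max_dd = 2, min_window = 6, allow_gu = FALSE,
                              min_loop = 0, params = energy_params(),
                              workers = 1L) {
  seq <- as_rna(seq)
  engine <- match.arg(engine)
  cands <- switch(engine,
    bruteforce = detect_bruteforce(seq, max_dd),
    grammar = if (workers > 1L)
      detect_parallel(seq, max_dd, min_window, workers)
    else detect_grammar(seq, max_dd, min_window))
  decs <- lapply(seq_len(nrow(cands)), function(k)
    decorate(seq, cands[k, ], allow_gu = allow_gu, min_loop = min_loop))
  best <- select_best(seq, decs, params)
  db <- if (is.null(best)) strrep(".", seq$n) else
    to_dotbracket(seq, best$dec)
  structure(list(seq = seq, best = best, dot_bracket = db,
                 n_candidates = nrow(cands), engine = engine),
            class = "pk_prediction")
}

#' Score every candidate of a sequence as a table
#'
#' Detects, decorates and scores all candidates; one row per candidate with
#' the stable CSV schema `seq_id,i1,i2,j1,j2,rule_id,pair_count,up,
#' g_pseudo,dot_bracket`.
#'
#' @inheritParams predict_structure
#' @return data frame in the schema above, canonically ordered.
#' @export
candidates_table <- function(seq, engine = c("bruteforce", "grammar"),
                             max_dd = 2, min_window = 6, allow_gu = FALSE,
                             min_loop = 0, params = energy_params(),
                             workers = 1L) {
  seq <- as_rna(seq)
  engine <- match.arg(engine)
  cands <- switch(engine,
    bruteforce = detect_bruteforce(seq, max_dd),
    grammar = if (workers > 1L)
      detect_parallel(seq, max_dd, min_window, workers)
    else detect_grammar(seq, max_dd, min_window))
  rows <- lapply(seq_len(nrow(cands)), function(k) {
    dec <- decorate(seq, cands[k, ], allow_gu = allow_gu,
                    min_loop = min_loop)
    sc <- pseudoknot_energy(seq, dec, params)
    data.frame(seq_id = seq$seq_id, i1 = dec$candidate$i1,
               i2 = dec$candidate$i2, j1 = dec$candidate$j1,
               j2 = dec$candidate$j2, rule_id = dec$candidate$rule_id,
               pair_count = dec$pair_count, up = sc$up,
               g_pseudo = sc$g_pseudo,
               dot_bracket = to_dotbracket(seq, dec))
  })
  if (!length(rows))
    return(data.frame(seq_id = character(0), i1 = integer(0),
                      i2 = integer(0), j1 = integer(0), j2 = integer(0),
                      rule_id = integer(0), pair_count = integer(0),
                      up = integer(0), g_pseudo = numeric(0),
                      dot_bracket = character(0)))
  do.call(rbind, rows)
}

#' @export
print.pk_prediction <- function(x, ...) {
  cat(sprintf(">%s (%d nt, %s engine, %d candidates)\n%s\n%s\n",
              x$seq$seq_id, x$seq$n, x$engine, x$n_candidates,
              x$seq$bases, x$dot_bracket))
  if (!is.null(x$best))
    cat(sprintf("core stems (%d,%d)/(%d,%d), %d pairs, G = %.3f\n",
                x$best$dec$candidate$i1, x$best$dec$candidate$j1,
                x$best$dec$candidate$i2, x$best$dec$candidate$j2,
                x$best$dec$pair_count, x$best$g_pseudo))
  else cat("no pseudoknot found\n")
  invisible(x)
}
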