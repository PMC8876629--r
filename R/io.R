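# FASTA / structure-record / CSV input and output.

#' Read RNA sequences from a FASTA file
#'
#' Multi-line FASTA; case is folded and T is converted to U, each with a
#' warning (see [rna_sequence()]).
#'
#' @param path FASTA file.
#' @return named list of [rna_sequence()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  if (is.null(ids)) ids <- character(length(set))
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1)
  blank <- is.na(ids) | !nzchar(ids)
  ids[blank] <- paste0("seq", which(blank))
  out <- lapply(seq_along(set), function(k)
    rna_sequence(as.character(set[[k]]), ids[k]))
  stats::setNames(out, ids)
}

#' Write predictions as FASTA-like structure records
#'
#' Each record is three lines: `>id`, the sequence, and the dot-bracket
#' structure.
#'
#' @param path output file.
#' @param records a list of `pk_prediction` objects, or a data frame with
#'   columns `seq_id`, `sequence`, `dot_bracket`.
#' @return `path`, invisibly.
#' @export
write_prediction <- function(path, records) {
  if (is.data.frame(records)) {
    stopifnot(all(c("seq_id", "sequence", "dot_bracket") %in%
                    names(records)))
    df <- records
  } else {
    df <- do.call(rbind, lapply(records, function(p) {
      stopifnot(inherits(p, "pk_prediction"))
      data.frame(seq_id = p$seq$seq_id, sequence = p$seq$bases,
                 dot_bracket = p$dot_bracket)
    }))
  }
  lines <- as.vector(rbind(paste0(">", df$seq_id), df$sequence,
                           df$dot_bracket))
  writeLines(lines, path)
  invisible(path)
}

#' Read structure records
#'
#' Accepts either the three-line record format written by
#' [write_prediction()] (`>id` / sequence / dot-bracket) or a CSV file with
#' header `seq_id,sequence,dot_bracket` (selected by the `.csv` extension).
#'
#' @param path input file.
#' @return data frame with columns `seq_id`, `sequence`, `dot_bracket`.
#' @export
read_structures <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("seq_id", "sequence", "dot_bracket")
    if (!all(need %in% names(df)))
      stop("CSV must have header seq_id,sequence,dot_bracket")
    return(df[need])
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads) || any(diff(heads) != 3L) ||
      heads[1] != 1L || length(lines) %% 3L != 0L)
    stop("malformed structure file (expected 3-line >id/sequence/structure ",
         "records); first problem near line ",
         if (length(heads)) heads[which(diff(heads) != 3L)[1] + 1L] else 1L)
  df <- data.frame(seq_id = sub("^>\\s*", "", lines[heads]),
                   sequence = lines[heads + 1L],
                   dot_bracket = lines[heads + 2L])
  bad <- which(nchar(df$sequence) != nchar(df$dot_bracket))
  if (length(bad))
    stop(sprintf("record '%s' (line %d): structure length != sequence length",
                 df$seq_id[bad[1]], heads[bad[1]]))
  df
}

#' Write a candidate table as CSV
#'
#' Stable schema, versioned in a leading comment line:
#' `seq_id,i1,i2,j1,j2,rule_id,pair_count,up,g_pseudo,dot_bracket`.
#'
#' @param path output file.
#' @param table a [candidates_table()] data frame (tables for several
#'   sequences may be `rbind`ed).
#' @return `path`, invisibly.
#' @export
write_candidates_csv <- function(path, table) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pkscan candidates v1", con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Read a candidate CSV written by [write_candidates_csv()]
#'
#' @param path input file.
#' @return data frame in the candidate-table schema.
#' @export
read_candidates_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
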