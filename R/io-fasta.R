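#' Read a FASTA file into a tibble
#'
#' Sequences are uppercased and validated against the DNA alphabet
#' `{A,C,G,T,N}`; any other residue is an error naming the record and the
#' offending character. The first whitespace-delimited token of each header
#' is the record id, the remainder its description.
#'
#' @param path path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("malformed FASTA in %s: %s",
                                      path, conditionMessage(e)))
  )
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  if (any(ids == "" | is.na(ids))) {
    abort(sprintf("malformed FASTA header (record %d) in %s",
                  which(ids == "" | is.na(ids))[1], path))
  }
  if (any(nchar(seqs) == 0L)) {
    abort(sprintf("empty sequence for record '%s' in %s",
                  ids[nchar(seqs) == 0L][1], path))
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort(sprintf(
      "invalid residue '%s' at position %d of record '%s' in %s",
      substr(seqs[i], bad[i], bad[i]), bad[i], ids[i], path
    ))
  }
  if (anyDuplicated(ids)) abort(sprintf("duplicated record id in %s", path))
  tibble(id = ids, description = desc, seq = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param x a tibble with columns `id`, `seq` and optionally `description`,
#'   or a named character vector.
#' @param path output path.
#' @param width line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    x <- tibble(id = names(x), description = "", seq = unname(x))
  }
  stopifnot(all(c("id", "seq") %in% names(x)))
  desc <- if ("description" %in% names(x)) x$description else rep("", nrow(x))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    hdr <- if (nzchar(desc[i])) paste(x$id[i], desc[i]) else x$id[i]
    writeLines(paste0(">", hdr), con)
    s <- x$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

revcomp <- function(x) {
  if (!length(x)) return(character())
  unname(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x))))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}
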