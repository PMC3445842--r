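#' Match scaffold ends against bridging contigs
#'
#' Aligns a window from each scaffold end against every contig and retains
#' matches at the manual-curation thresholds (99% identity over at least
#' 100 bp by default). A match is assigned to a contig end (`left`/`right`)
#' when it reaches a contig terminus within 10 bp; interior-only matches
#' carry `contig_end = NA`.
#'
#' @param scaffolds,contigs tibbles with `id`, `seq`.
#' @param params [analysis_params()].
#' @param end_window scaffold end window length (bp).
#' @return tibble `scaffold_id`, `end`, `contig_id`, `contig_end`,
#'   `identity`, `aln_len`, plus match coordinates on the scaffold
#'   (`scf_start`, `scf_end`) and contig (`ctg_start`, `ctg_end`).
#' @export
find_end_matches <- function(scaffolds, contigs, params = analysis_params(),
                             end_window = 1000L) {
  out <- list()
  for (i in seq_len(nrow(scaffolds))) {
    slen <- nchar(scaffolds$seq[i])
    win <- min(end_window, slen)
    ends <- list(
      left = list(seq = substring(scaffolds$seq[i], 1L, win), offset = 0L),
      right = list(seq = substring(scaffolds$seq[i], slen - win + 1L, slen),
                   offset = slen - win)
    )
    for (endname in names(ends)) {
      for (j in seq_len(nrow(contigs))) {
        hits <- align_local(ends[[endname]]$seq, contigs$seq[j], params,
                            both_strands = FALSE,
                            query_id = scaffolds$id[i],
                            subject_id = contigs$id[j])
        hits <- filter(hits,
                       .data$identity >= params$merge_min_identity,
                       .data$aln_len >= params$merge_min_len)
        if (!nrow(hits)) next
        h <- hits[1, ]
        clen <- nchar(contigs$seq[j])
        contig_end <- if (h$s_start <= 10L) "left"
          else if (clen - h$s_end <= 10L) "right"
          else NA_character_
        out[[length(out) + 1L]] <- tibble(
          scaffold_id = scaffolds$id[i], end = endname,
          contig_id = contigs$id[j], contig_end = contig_end,
          identity = h$identity, aln_len = h$aln_len,
          scf_start = h$q_start + ends[[endname]]$offset,
          scf_end = h$q_end + ends[[endname]]$offset,
          ctg_start = h$s_start, ctg_end = h$s_end
        )
      }
    }
  }
  rbind_or(out,
           tibble(scaffold_id = character(), end = character(),
                  contig_id = character(), contig_end = character(),
                  identity = numeric(), aln_len = integer(),
                  scf_start = integer(), scf_end = integer(),
                  ctg_start = integer(), ctg_end = integer()))
}

#' Merge scaffolds bridged by a shared contig (one pass)
#'
#' When the right end of one scaffold and the left end of another match the
#' two ends of the same contig, the scaffolds are concatenated with the
#' contig's unmatched interior filling the gap; overlapping stretches are
#' kept from the scaffolds (higher consensus depth). A contig matched by
#' more than two scaffold ends is refused and logged as a conflict.
#'
#' @param scaffolds tibble with `id`, `seq`.
#' @param contigs tibble with `id`, `seq` (provides gap-filling interiors).
#' @param end_matches output of [find_end_matches()].
#' @param risky_ends optional tibble (`scaffold_id`, `end`) of repeat-flagged
#'   ends (see [screen_end_repeats()]); a risky end merges only when it has
#'   at least two independent end matches.
#' @return list with `scaffolds` (post-merge), `log` tibble and `merged`
#'   (logical: anything merged this pass).
#' @export
merge_scaffolds <- function(scaffolds, contigs, end_matches,
                            risky_ends = NULL) {
  contig_seqs <- setNames(as.list(contigs$seq), contigs$id)
  log <- list()
  em <- filter(end_matches, !is.na(.data$contig_end))
  if (!is.null(risky_ends) && nrow(risky_ends)) {
    n_support <- end_matches |>
      count(.data$scaffold_id, .data$end, name = "n_matches")
    em <- left_join(em, n_support, by = c("scaffold_id", "end"))
    risky <- paste(risky_ends$scaffold_id, risky_ends$end)
    em <- filter(em,
                 !(paste(.data$scaffold_id, .data$end) %in% risky) |
                   .data$n_matches >= 2L)
  }
  merged_any <- FALSE
  done <- character()
  seqs <- setNames(scaffolds$seq, scaffolds$id)
  for (ctg in unique(em$contig_id)) {
    m <- filter(em, .data$contig_id == ctg)
    if (nrow(m) > 2L) {
      log[[length(log) + 1L]] <- tibble(
        contig_id = ctg, action = "conflict",
        detail = sprintf("%d scaffold ends match one contig", nrow(m)))
      next
    }
    if (nrow(m) != 2L) next
    if (length(unique(m$scaffold_id)) != 2L) next
    if (setequal(m$contig_end, c("left", "right"))) {
      left_m <- m[m$contig_end == "left", ]    # matches contig start
      right_m <- m[m$contig_end == "right", ]  # matches contig end
      # the scaffold whose RIGHT end carries the contig's left end goes first
      if (left_m$end != "right" || right_m$end != "left") next
      if (any(c(left_m$scaffold_id, right_m$scaffold_id) %in% done)) next
      # contig interior between the two matched terminal stretches; the
      # overlapping stretches themselves come from the scaffolds
      interior <- substring(contig_seqs[[ctg]],
                            left_m$ctg_end + 1L, right_m$ctg_start)
      out_seq <- paste0(seqs[[left_m$scaffold_id]], interior,
                        seqs[[right_m$scaffold_id]])
      seqs[[left_m$scaffold_id]] <- out_seq
      seqs <- seqs[names(seqs) != right_m$scaffold_id]
      done <- c(done, left_m$scaffold_id, right_m$scaffold_id)
      merged_any <- TRUE
      log[[length(log) + 1L]] <- tibble(
        contig_id = ctg, action = "merge",
        detail = sprintf("%s + %s via %s", left_m$scaffold_id,
                         right_m$scaffold_id, ctg))
    }
  }
  list(
    scaffolds = tibble(id = names(seqs), seq = unname(seqs)),
    log = rbind_or(log, tibble(contig_id = character(),
                               action = character(),
                               detail = character())),
    merged = merged_any
  )
}

#' Screen scaffold ends for repetitive sequence
#'
#' Flags scaffold ends carrying a repeat-database hit of at least
#' `repeat_screen_min_len` bp above `repeat_screen_min_identity` percent
#' identity — such ends risk misassembly if merged on sequence identity
#' alone.
#'
#' @param scaffolds tibble with `id`, `seq`.
#' @param repeat_db tibble with `id`, `seq` of known repeats.
#' @param params [analysis_params()].
#' @param end_window end window length (bp).
#' @return tibble with one row per scaffold end: `scaffold_id`, `end`,
#'   `flagged`, `best_identity`, `best_len`.
#' @export
screen_end_repeats <- function(scaffolds, repeat_db,
                               params = analysis_params(),
                               end_window = 1000L) {
  if (!nrow(repeat_db)) abort("`repeat_db` is empty")
  out <- list()
  for (i in seq_len(nrow(scaffolds))) {
    slen <- nchar(scaffolds$seq[i])
    win <- min(end_window, slen)
    ends <- list(left = substring(scaffolds$seq[i], 1L, win),
                 right = substring(scaffolds$seq[i], slen - win + 1L, slen))
    for (endname in names(ends)) {
      best_id <- 0; best_len <- 0L; flagged <- FALSE
      for (j in seq_len(nrow(repeat_db))) {
        hits <- align_local(ends[[endname]], repeat_db$seq[j], params,
                            query_id = scaffolds$id[i],
                            subject_id = repeat_db$id[j])
        ok <- filter(hits,
                     .data$aln_len >= params$repeat_screen_min_len,
                     .data$identity > params$repeat_screen_min_identity)
        if (nrow(ok)) {
          flagged <- TRUE
          if (ok$identity[1] > best_id) {
            best_id <- ok$identity[1]
            best_len <- ok$aln_len[1]
          }
        }
      }
      out[[length(out) + 1L]] <- tibble(
        scaffold_id = scaffolds$id[i], end = endname, flagged = flagged,
        best_identity = ifelse(flagged, best_id, NA_real_),
        best_len = ifelse(flagged, best_len, NA_integer_))
    }
  }
  list_rbind(out)
}

#' Iterated scaffold curation
#'
#' Repeats end matching and merging to a fixed point: whenever two scaffolds
#' match opposite ends of one contig they are merged with the contig
#' interior closing the gap, so a locus fragmented into scaffolds plus
#' bridging contigs is reconstructed exactly.
#'
#' @param scaffolds,contigs tibbles with `id`, `seq`.
#' @param params [analysis_params()].
#' @param repeat_db optional repeat database for end screening.
#' @param end_window end window (bp).
#' @return list with final `scaffolds` and the accumulated `log`.
#' @export
curate_assembly <- function(scaffolds, contigs, params = analysis_params(),
                            repeat_db = NULL, end_window = 1000L) {
  logs <- list()
  risky <- NULL
  repeat {
    em <- find_end_matches(scaffolds, contigs, params, end_window)
    if (!is.null(repeat_db) && nrow(repeat_db)) {
      flags <- screen_end_repeats(scaffolds, repeat_db, params, end_window)
      risky <- filter(flags, .data$flagged)[, c("scaffold_id", "end")]
    }
    res <- merge_scaffolds(scaffolds, contigs, em, risky_ends = risky)
    logs[[length(logs) + 1L]] <- res$log
    scaffolds <- res$scaffolds
    if (!res$merged) break
  }
  list(scaffolds = scaffolds, log = list_rbind(logs))
}
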