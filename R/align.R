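sub_matrix <- function(params) {
  b <- c(DNA_BASES, "N")
  m <- matrix(-params$mismatch_penalty, 5, 5, dimnames = list(b, b))
  diag(m) <- params$match_reward
  m["N", ] <- -params$mismatch_penalty
  m[, "N"] <- -params$mismatch_penalty
  m
}

#' Karlin-Altschul lambda for a match/mismatch scoring scheme
#'
#' Solves `sum_ij p_i p_j exp(lambda * s_ij) = 1` for uniform base
#' composition (ungapped approximation). Used with the configurable `K`
#' constant to convert local alignment scores to E-values,
#' `E = K m n exp(-lambda S)`.
#'
#' @param params [analysis_params()].
#' @return lambda (numeric scalar).
#' @export
karlin_lambda <- function(params = analysis_params()) {
  r <- params$match_reward
  q <- params$mismatch_penalty
  f <- function(l) 0.25 * exp(l * r) + 0.75 * exp(-l * q) - 1
  uniroot(f, c(1e-8, 10), tol = 1e-12)$root
}

hit_evalue <- function(score, m, n, params, lambda = karlin_lambda(params)) {
  params$karlin_k * as.numeric(m) * as.numeric(n) * exp(-lambda * score)
}

aln_stats <- function(pa) {
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  len <- length(ap)
  nmatch <- sum(ap == as_ & ap != "-")
  # indel runs with positions in pattern/subject coordinates (0-based,
  # position of the base following the gap)
  qi <- cumsum(ap != "-")
  si <- cumsum(as_ != "-")
  gaps <- ap == "-" | as_ == "-"
  indels <- NULL
  if (any(gaps)) {
    r <- rle(ifelse(ap == "-", "query_gap", ifelse(as_ == "-", "subject_gap", "m")))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != "m"
    indels <- tibble(
      side = r$values[keep],
      len = r$lengths[keep],
      q_pos = qi[starts[keep]] - as.integer(r$values[keep] == "query_gap"),
      s_pos = si[starts[keep]] - as.integer(r$values[keep] == "subject_gap")
    )
  } else {
    indels <- tibble(side = character(), len = integer(),
                     q_pos = integer(), s_pos = integer())
  }
  list(aln_len = len, nmatch = nmatch,
       gaps = sum(gaps), indels = indels)
}

#' Optimal local alignment between two sequences
#'
#' Exact Smith-Waterman dynamic programming with affine gaps (via
#' Biostrings), reported with identity, alignment length and a
#' Karlin-Altschul E-value for the configured scoring. Both strands of the
#' query are searched by default; coordinates are always reported on the
#' forward strands (0-based, half-open) with a `strand` flag for the query.
#' One optimal hit per searched strand is returned, sorted by score
#' (ties by query then subject start).
#'
#' @param query,subject DNA strings over `A,C,G,T,N`.
#' @param params [analysis_params()].
#' @param both_strands also search the reverse complement of the query.
#' @param query_id,subject_id identifiers copied into the result.
#' @param subject_kind `"cds"` or `"locus"`.
#' @return tibble of hits: ids, `strand`, spans, `identity` (percent),
#'   `aln_len`, `score`, `evalue`.
#' @export
align_local <- function(query, subject, params = analysis_params(),
                        both_strands = TRUE,
                        query_id = "query", subject_id = "subject",
                        subject_kind = "cds") {
  if (!nzchar(query) || !nzchar(subject)) abort("empty sequence")
  lambda <- karlin_lambda(params)
  mat <- sub_matrix(params)
  qlen <- nchar(query)
  one <- function(qseq, strand) {
    pa <- Biostrings::pairwiseAlignment(
      qseq, subject, type = "local", substitutionMatrix = mat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend
    )
    sc <- Biostrings::score(pa)
    if (sc <= 0) return(NULL)
    st <- aln_stats(pa)
    qs <- Biostrings::start(Biostrings::pattern(pa)) - 1L
    qe <- Biostrings::end(Biostrings::pattern(pa))
    if (strand == "-") {
      tmp <- qs
      qs <- qlen - qe
      qe <- qlen - tmp
    }
    tibble(
      query_id = query_id, subject_id = subject_id, strand = strand,
      q_start = qs, q_end = qe,
      s_start = Biostrings::start(Biostrings::subject(pa)) - 1L,
      s_end = Biostrings::end(Biostrings::subject(pa)),
      identity = 100 * st$nmatch / st$aln_len,
      aln_len = st$aln_len, gaps = st$gaps,
      mismatches = st$aln_len - st$gaps - st$nmatch,
      score = sc,
      evalue = hit_evalue(sc, qlen, nchar(subject), params, lambda),
      subject_kind = subject_kind
    )
  }
  hits <- list(one(query, "+"))
  if (both_strands) hits <- c(hits, list(one(revcomp(query), "-")))
  hits <- list_rbind(hits)
  if (is.null(hits) || !nrow(hits)) {
    return(tibble(query_id = character(), subject_id = character(),
                  strand = character(), q_start = integer(),
                  q_end = integer(), s_start = integer(), s_end = integer(),
                  identity = numeric(), aln_len = integer(), gaps = integer(),
                  mismatches = integer(), score = numeric(),
                  evalue = numeric(), subject_kind = character()))
  }
  arrange(hits, desc(.data$score), .data$q_start, .data$s_start)
}

kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Best homolog of a query among a set of subject sequences
#'
#' The highest-scoring local alignment with E-value at or below
#' `params$evalue_max`; ties are broken by higher identity, then by
#' lexicographically smaller subject id. Returns a zero-row tibble when no
#' subject passes the threshold.
#'
#' @param query query DNA string.
#' @param subjects tibble with columns `gene_id` (or `id`) and `seq`.
#' @param params [analysis_params()].
#' @param both_strands search both query strands.
#' @return one-row tibble (`subject_id`, `score`, `identity`, `evalue`,
#'   `aln_len`), or zero rows.
#' @export
find_best_homolog <- function(query, subjects, params = analysis_params(),
                              both_strands = TRUE) {
  res <- score_against(query, subjects, params, both_strands)
  res <- filter(res, .data$evalue <= params$evalue_max)
  if (!nrow(res)) return(res[0, c("subject_id", "score", "identity",
                                  "evalue", "aln_len")])
  res <- arrange(res, desc(.data$score), desc(.data$identity),
                 .data$subject_id)
  res[1, c("subject_id", "score", "identity", "evalue", "aln_len")]
}

# scores of one query against a set of subjects (both strands in one
# alignment batch: aligning the reverse complement of each subject is
# equivalent to aligning the reverse complement of the query)
score_against <- function(query, subjects, params, both_strands = TRUE) {
  idcol <- if ("gene_id" %in% names(subjects)) "gene_id" else "id"
  if (!nrow(subjects)) abort("`subjects` is empty")
  lambda <- karlin_lambda(params)
  mat <- sub_matrix(params)
  patterns <- subjects$seq
  ids <- subjects[[idcol]]
  if (both_strands) {
    patterns <- c(patterns, revcomp(subjects$seq))
    ids <- c(ids, ids)
  }
  pa <- Biostrings::pairwiseAlignment(
    patterns, query, type = "local", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  res <- tibble(
    subject_id = ids,
    score = Biostrings::score(pa),
    nmatch = Biostrings::nmatch(pa),
    aln_len = Biostrings::nchar(pa)
  )
  if (both_strands) {
    res <- res |>
      group_by(.data$subject_id) |>
      slice(which.max(.data$score)) |>
      ungroup()
  }
  mutate(res,
         identity = 100 * .data$nmatch / pmax(.data$aln_len, 1L),
         evalue = hit_evalue(.data$score, nchar(query),
                             nchar(subjects$seq[match(.data$subject_id,
                                                      subjects[[idcol]])]),
                             params, lambda))
}

#' Best-homolog map between two gene sets
#'
#' Runs [find_best_homolog()] for every query gene. An optional shared
#' k-mer prefilter skips subject sequences with no exact `k`-mer in common
#' with the query; retained hits at the default E-value cutoff require long
#' exact stretches, so the prefilter does not change results above
#' threshold.
#'
#' @param queries,subjects tibbles with `gene_id`, `seq` (e.g. from
#'   [cds_table()]).
#' @param params [analysis_params()].
#' @param prefilter use the shared k-mer prefilter.
#' @param k prefilter k-mer size.
#' @return tibble with one row per query that has a retained best hit:
#'   `query_id`, `subject_id`, `score`, `identity`, `evalue`.
#' @export
homology_search <- function(queries, subjects, params = analysis_params(),
                            prefilter = TRUE, k = 12L) {
  all <- all_pair_scores(queries, subjects, params, prefilter, k)
  all <- filter(all, .data$evalue <= params$evalue_max)
  if (!nrow(all)) {
    return(tibble(query_id = character(), subject_id = character(),
                  score = numeric(), identity = numeric(), evalue = numeric(),
                  aln_len = integer()))
  }
  all |>
    arrange(.data$query_id, desc(.data$score), desc(.data$identity),
            .data$subject_id) |>
    group_by(.data$query_id) |>
    slice(1L) |>
    ungroup() |>
    select("query_id", "subject_id", "score", "identity", "evalue", "aln_len")
}

# scores for every (query, subject) pair passing the shared k-mer prefilter
all_pair_scores <- function(queries, subjects, params, prefilter = TRUE,
                            k = 12L) {
  stopifnot(nrow(subjects) > 0)
  index <- NULL
  if (prefilter) {
    index <- new.env(parent = emptyenv(), hash = TRUE)
    for (i in seq_len(nrow(subjects))) {
      for (km in kmer_set(subjects$seq[i], k)) {
        index[[km]] <- c(index[[km]], i)
      }
    }
  }
  out <- map(seq_len(nrow(queries)), function(qi) {
    q <- queries$seq[qi]
    cand <- subjects
    if (prefilter) {
      kms <- unique(c(kmer_set(q, k), kmer_set(revcomp(q), k)))
      idx <- unique(unlist(lapply(kms, function(km) index[[km]])))
      if (!length(idx)) return(NULL)
      cand <- subjects[sort(idx), , drop = FALSE]
    }
    sc <- score_against(q, cand, params)
    mutate(sc, query_id = queries$gene_id[qi], .before = 1)
  })
  rbind_or(out,
           tibble(query_id = character(), subject_id = character(),
                  score = numeric(), nmatch = integer(), aln_len = integer(),
                  identity = numeric(), evalue = numeric()))
}

#' Reciprocal best hit pairs between two gene sets
#'
#' A pair is retained when each gene is the other's best homolog at the
#' configured E-value cutoff. This is how "homoeolog" pairs between the two
#' wheat loci (and wheat-model ortholog anchors) are operationalized.
#'
#' @inheritParams homology_search
#' @return tibble with `gene_a`, `gene_b`, `identity`, `score` (query-side
#'   values from the a-vs-b search).
#' @export
reciprocal_best_pairs <- function(queries, subjects,
                                  params = analysis_params(),
                                  prefilter = TRUE, k = 12L) {
  # local alignment scores are symmetric in the two sequences and the k-mer
  # prefilter is symmetric, so one all-pairs pass yields both directions
  all <- all_pair_scores(queries, subjects, params, prefilter, k)
  all <- filter(all, .data$evalue <= params$evalue_max)
  if (!nrow(all)) {
    return(tibble(gene_a = character(), gene_b = character(),
                  identity = numeric(), score = numeric()))
  }
  best_a <- all |>
    arrange(.data$query_id, desc(.data$score), desc(.data$identity),
            .data$subject_id) |>
    group_by(.data$query_id) |> slice(1L) |> ungroup()
  best_b <- all |>
    arrange(.data$subject_id, desc(.data$score), desc(.data$identity),
            .data$query_id) |>
    group_by(.data$subject_id) |> slice(1L) |> ungroup()
  back <- setNames(best_b$query_id, best_b$subject_id)
  keep <- !is.na(back[best_a$subject_id]) &
    back[best_a$subject_id] == best_a$query_id
  tibble(gene_a = best_a$query_id[keep], gene_b = best_a$subject_id[keep],
         identity = best_a$identity[keep], score = best_a$score[keep])
}

#' Search an orphan CDS against another locus' full sequence
#'
#' For genes with no CDS-level homolog, searches the complete DNA of the
#' other locus; retained hits are labelled `"annotated"` when they overlap
#' an annotated gene there and `"candidate_fragment"` otherwise (possible
#' un-annotated gene remnants, e.g. a ~500 bp fragment of a truncated copy).
#'
#' @param orphan_id,orphan_seq the orphan gene and its CDS.
#' @param other_locus a [locus_annotation()].
#' @param params [analysis_params()].
#' @return hits tibble from [align_local()] plus a `label` column.
#' @export
rescue_against_locus <- function(orphan_id, orphan_seq, other_locus,
                                 params = analysis_params()) {
  hits <- align_local(orphan_seq, other_locus$seq, params,
                      query_id = orphan_id,
                      subject_id = other_locus$locus_id,
                      subject_kind = "locus")
  hits <- filter(hits, .data$evalue <= params$evalue_max)
  if (!nrow(hits)) return(mutate(hits, label = character()))
  g <- other_locus$genes
  lab <- map_chr(seq_len(nrow(hits)), function(i) {
    ov <- nrow(g) > 0 && any(g$start < hits$s_end[i] & g$end > hits$s_start[i])
    if (ov) "annotated" else "candidate_fragment"
  })
  mutate(hits, label = lab)
}

#' Merge two gene fragments into a single gene model
#'
#' Two CDS fragments that best-match the same homolog on disjoint intervals
#' (for instance, the two halves of a frameshifted pseudogene that were
#' annotated separately) are merged into one model: the union of their
#' exons under the id of the coding-strand 5'-most fragment.
#'
#' @param locus a [locus_annotation()] containing both fragments.
#' @param frag_a,frag_b fragment gene ids.
#' @param evidence tibble with one row per fragment: `gene_id`,
#'   `subject_id` (shared homolog), `s_start`, `s_end` (matched homolog
#'   interval, 0-based half-open).
#' @return A list with the updated `locus` and the merged gene `model` row.
#' @export
merge_fragments <- function(locus, frag_a, frag_b, evidence) {
  ga <- locus_gene(locus, frag_a)
  gb <- locus_gene(locus, frag_b)
  if (ga$strand != gb$strand) abort("fragments must be on the same strand")
  if (ga$start < gb$end && gb$start < ga$end) {
    abort("fragments overlap on the locus")
  }
  ev <- evidence[match(c(frag_a, frag_b), evidence$gene_id), ]
  if (anyNA(ev$gene_id)) abort("evidence must cover both fragments")
  if (length(unique(ev$subject_id)) != 1L) {
    abort("fragments match different homologs")
  }
  ov <- max(0, min(ev$s_end) - max(ev$s_start))
  if (ov > 0.10 * min(ev$s_end - ev$s_start)) {
    abort("homolog intervals overlap by more than 10%")
  }
  five_prime_first <- if (ga$strand == "+") ga$start <= gb$start else
    ga$end >= gb$end
  keep_id <- if (five_prime_first) frag_a else frag_b
  exons <- arrange(bind_rows(ga$exons[[1]], gb$exons[[1]]), .data$start)
  model <- tibble(
    gene_id = keep_id, strand = ga$strand,
    start = min(ga$start, gb$start), end = max(ga$end, gb$end),
    status = ga$status,
    exons = list(exons),
    notes = sprintf("merged:%s", if (five_prime_first) frag_b else frag_a)
  )
  genes <- filter(locus$genes, !.data$gene_id %in% c(frag_a, frag_b))
  locus <- locus_annotation(locus$locus_id, locus$genome_tag, locus$seq,
                            bind_rows(genes, model), locus$repeats)
  list(locus = locus, model = model)
}

#' Multiple local alignment blocks by iterative masking
#'
#' Repeats optimal local alignment, masking the matched subject interval
#' after each round, to recover the separate high-scoring blocks that a
#' single optimal alignment cannot represent (e.g. the two flanks around a
#' large transposon insertion).
#'
#' @param query,subject DNA strings (aligned on their forward strands).
#' @param params [analysis_params()].
#' @param min_score stop when the best remaining block scores below this.
#' @param max_blocks maximum number of blocks.
#' @return tibble of blocks (`q_start`, `q_end`, `s_start`, `s_end`,
#'   `score`, `identity`) with a list-column `indels` of per-block indel runs.
#' @export
local_blocks <- function(query, subject, params = analysis_params(),
                         min_score = 40, max_blocks = 4L) {
  lambda <- karlin_lambda(params)
  mat <- sub_matrix(params)
  blocks <- list()
  cur <- subject
  for (i in seq_len(max_blocks)) {
    pa <- Biostrings::pairwiseAlignment(
      query, cur, type = "local", substitutionMatrix = mat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend
    )
    sc <- Biostrings::score(pa)
    if (sc < min_score) break
    st <- aln_stats(pa)
    s0 <- Biostrings::start(Biostrings::subject(pa)) - 1L
    e0 <- Biostrings::end(Biostrings::subject(pa))
    blocks[[length(blocks) + 1L]] <- tibble(
      q_start = Biostrings::start(Biostrings::pattern(pa)) - 1L,
      q_end = Biostrings::end(Biostrings::pattern(pa)),
      s_start = s0, s_end = e0,
      score = sc, identity = 100 * st$nmatch / st$aln_len,
      indels = list(st$indels)
    )
    cur <- paste0(substring(cur, 1L, s0),
                  strrep("N", e0 - s0),
                  substring(cur, e0 + 1L))
  }
  out <- list_rbind(blocks)
  if (is.null(out) || !nrow(out)) {
    return(tibble(q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  score = numeric(), identity = numeric(), indels = list()))
  }
  arrange(out, .data$q_start)
}
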