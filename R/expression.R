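#' Exact EST-to-CDS matches
#'
#' Finds all maximal exact common substrings of length at least
#' `params$est_min_len` between each EST (both strands) and each CDS — the
#' stringent expression criterion of 100% identity over at least 100 bp. No
#' mismatches are tolerated: matching is by merged k-mer diagonals with
#' `k = est_min_len`, which enumerates exactly the maximal common substrings
#' of at least that length.
#'
#' @param cds tibble with `gene_id`, `seq`.
#' @param ests tibble with `id`, `seq` (e.g. from [read_fasta()]).
#' @param params [analysis_params()]; `est_min_identity` must be 100.
#' @return tibble `est_id`, `gene_id`, `strand`, `match_len`, `est_start`,
#'   `cds_start` (0-based), `identity`.
#' @export
match_ests <- function(cds, ests, params = analysis_params()) {
  if (params$est_min_identity != 100) {
    abort("EST matching is exact: `est_min_identity` must be 100")
  }
  k <- as.integer(params$est_min_len)
  empty <- tibble(est_id = character(), gene_id = character(),
                  strand = character(), match_len = integer(),
                  est_start = integer(), cds_start = integer(),
                  identity = numeric())
  if (!nrow(cds) || !nrow(ests)) return(empty)

  # k-mer -> (cds index, 0-based offset) index over all CDS
  index <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(cds))) {
    s <- cds$seq[i]
    n <- nchar(s)
    if (n < k) next
    kms <- substring(s, 1:(n - k + 1L), k:n)
    for (p in seq_along(kms)) {
      index[[kms[p]]] <- rbind(index[[kms[p]]], c(i, p - 1L))
    }
  }

  scan_one <- function(est_seq, est_id, strand) {
    n <- nchar(est_seq)
    if (n < k) return(NULL)
    kms <- substring(est_seq, 1:(n - k + 1L), k:n)
    hits <- list()
    for (p in seq_along(kms)) {
      m <- index[[kms[p]]]
      if (is.null(m)) next
      hits[[length(hits) + 1L]] <-
        cbind(est_pos = p - 1L, cds_i = m[, 1], cds_pos = m[, 2])
    }
    if (!length(hits)) return(NULL)
    h <- do.call(rbind, hits)
    df <- as_tibble(h) |>
      mutate(diag = .data$cds_pos - .data$est_pos) |>
      arrange(.data$cds_i, .data$diag, .data$est_pos)
    # merge runs of consecutive k-mer hits on one diagonal: a maximal exact
    # match of length L contributes exactly L - k + 1 consecutive hits
    runs <- df |>
      group_by(.data$cds_i, .data$diag) |>
      mutate(brk = cumsum(c(1L, diff(.data$est_pos) != 1L))) |>
      group_by(.data$cds_i, .data$diag, .data$brk) |>
      summarise(est_start = min(.data$est_pos),
                cds_start = min(.data$cds_pos),
                match_len = dplyr::n() + k - 1L, .groups = "drop")
    tibble(
      est_id = est_id,
      gene_id = cds$gene_id[runs$cds_i],
      strand = strand,
      match_len = as.integer(runs$match_len),
      est_start = as.integer(runs$est_start),
      cds_start = as.integer(runs$cds_start),
      identity = 100
    )
  }

  out <- list_rbind(map(seq_len(nrow(ests)), function(j) {
    bind_rows(
      scan_one(ests$seq[j], ests$id[j], "+"),
      scan_one(revcomp(ests$seq[j]), ests$id[j], "-")
    )
  }))
  if (is.null(out) || !nrow(out)) return(empty)
  arrange(out, .data$est_id, .data$gene_id, .data$est_start)
}

#' Remove ESTs that hit both members of a homoeologous pair
#'
#' Such ESTs cannot be assigned to either gene copy and are removed from the
#' analysis entirely (every hit of the EST, not just the paired ones).
#'
#' @param hits output of [match_ests()].
#' @param pairs tibble with `gene_a`, `gene_b` homoeologous pairs.
#' @return list with `hits` (filtered) and `removed` (EST ids).
#' @export
drop_shared_ests <- function(hits, pairs) {
  if (!nrow(hits) || !nrow(pairs)) return(list(hits = hits,
                                               removed = character()))
  by_est <- split(hits$gene_id, hits$est_id)
  shared <- names(by_est)[map_lgl(by_est, function(g) {
    any(pairs$gene_a %in% g & pairs$gene_b %in% g)
  })]
  list(hits = filter(hits, !.data$est_id %in% shared), removed = shared)
}

#' Expressed fractions per locus and collinearity group
#'
#' A gene is expressed when it has at least one retained EST hit. Fractions
#' (one decimal, half-up) are reported per wheat locus for collinear genes
#' (`COLLINEAR_ALL`, `COLLINEAR_RICE_WHEAT`) and non-collinear genes
#' (`SHARED_WHEAT_NC`, `LOCUS_SPECIFIC_NC`, `TANDEM_DUP_NC`); excluded genes
#' are omitted.
#'
#' @param hits retained EST hits.
#' @param profiles classified profiles.
#' @param wheat_tags genome tags of the wheat loci; defaults to the tags
#'   that carry homoeologous pairs.
#' @return tibble `genome_tag`, `group`, `n_genes`, `n_expressed`,
#'   `pct_expressed`.
#' @export
expression_summary <- function(hits, profiles, wheat_tags = NULL) {
  wheat_tags <- wheat_tags %||%
    unique(profiles$genome_tag[!is.na(profiles$pair_id)])
  wheat <- filter(profiles, !is.na(.data$category),
                  .data$category != "EXCLUDED",
                  .data$genome_tag %in% wheat_tags)
  expressed <- unique(hits$gene_id)
  wheat |>
    mutate(group = ifelse(.data$category %in% COLLINEAR_CATEGORIES,
                          "collinear", "non_collinear"),
           expressed = .data$gene_id %in% expressed) |>
    group_by(.data$genome_tag, .data$group) |>
    summarise(n_genes = dplyr::n(), n_expressed = sum(.data$expressed),
              pct_expressed = round_half_up(
                100 * sum(.data$expressed) / dplyr::n(), 1),
              .groups = "drop")
}

#' Two-tailed exact binomial contrast of per-gene EST counts
#'
#' Tests whether the EST hits of a homoeologous pair are split evenly
#' (H0: p = 0.5 over `hits_a + hits_b` trials); the two-tailed p-value sums
#' point probabilities no larger than that of the observed count.
#'
#' @param hits_a,hits_b EST hit counts of the two genes.
#' @return tibble with `n`, `p_value` and an `undefined` flag (both counts
#'   zero).
#' @export
binomial_contrast <- function(hits_a, hits_b) {
  stopifnot(hits_a >= 0, hits_b >= 0)
  n <- hits_a + hits_b
  if (n == 0) return(tibble(n = 0L, p_value = NA_real_, undefined = TRUE))
  p <- binom.test(hits_a, n, p = 0.5, alternative = "two.sided")$p.value
  tibble(n = as.integer(n), p_value = p, undefined = FALSE)
}
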