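#' Assess the integrity of a CDS against an intact homolog
#'
#' Flags the three defect types used to define pseudogenes: a premature
#' in-frame stop codon (before the final 5% of the homolog ORF, so minor
#' C-terminal truncations are not called), a frameshift (an aligned indel
#' run whose length is not a multiple of 3), and a deletion (aligned
#' coverage of the homolog below `1 - pseudo_deletion_frac`, i.e. < 70% by
#' default). A model is a `pseudogene` if any defect is present, and a
#' `fragment` when coverage is below `fragment_coverage_max` (50%) with no
#' other defect evidence. Without a homolog (`homolog_cds = NULL`) only the
#' intrinsic premature-stop check against the model's own length runs.
#'
#' @param cds the spliced CDS under assessment (coding strand).
#' @param homolog_cds the intact homolog CDS, or `NULL`.
#' @param params [analysis_params()].
#' @param gene_id id copied into the call.
#' @return one-row tibble: `gene_id`, `status`, `coverage`, `n_defects` and a
#'   list-column `defects` (tibble of `type`, `at`, `value`).
#' @export
assess_integrity <- function(cds, homolog_cds = NULL,
                             params = analysis_params(),
                             gene_id = "gene") {
  defects <- list()
  coverage <- NA_real_
  if (!is.null(homolog_cds)) {
    hs <- first_stop_codon(homolog_cds)
    h_codons <- nchar(homolog_cds) %/% 3L
    if (!is.na(hs) && hs < h_codons) {
      abort("homolog CDS carries a premature stop; not a valid reference")
    }
    ref_codons <- h_codons
    # multiple alignment blocks: one optimal local alignment cannot bridge
    # large insertions (e.g. a transposon inside an exon) or deletions
    blocks <- local_blocks(cds, homolog_cds, params, min_score = 60)
    if (nrow(blocks)) {
      covered <- sum(map_dbl(seq_len(nrow(blocks)), function(i) {
        ind <- blocks$indels[[i]]
        (blocks$s_end[i] - blocks$s_start[i]) -
          sum(ind$len[ind$side == "query_gap"])
      }))
      coverage <- min(1, covered / nchar(homolog_cds))
      # indel evidence: within-block runs plus net between-block gaps
      indel_lens <- unlist(map(blocks$indels, "len"))
      indel_pos <- unlist(map(seq_len(nrow(blocks)), function(i) {
        blocks$q_start[i] + blocks$indels[[i]]$q_pos
      }))
      if (nrow(blocks) > 1L) {
        consistent <- all(diff(blocks$s_start) > 0)
        if (consistent) {
          for (i in seq_len(nrow(blocks) - 1L)) {
            q_gap <- max(0L, blocks$q_start[i + 1L] - blocks$q_end[i])
            s_gap <- max(0L, blocks$s_start[i + 1L] - blocks$s_end[i])
            net <- abs(q_gap - s_gap)
            if (net > 0L) {
              indel_lens <- c(indel_lens, net)
              indel_pos <- c(indel_pos, blocks$q_end[i])
            }
          }
        }
      }
      bad <- which(indel_lens %% 3L != 0L)
      if (length(bad)) {
        defects[[length(defects) + 1L]] <- tibble(
          type = "frameshift", at = as.integer(indel_pos[bad[1]]),
          value = as.numeric(indel_lens[bad[1]])
        )
      }
    } else {
      coverage <- 0
    }
    if (coverage < 1 - params$pseudo_deletion_frac) {
      defects[[length(defects) + 1L]] <- tibble(
        type = "deletion", at = NA_integer_, value = coverage
      )
    }
  } else {
    ref_codons <- nchar(cds) %/% 3L
  }
  stop_at <- first_stop_codon(cds)
  if (!is.na(stop_at) && stop_at <= floor(0.95 * ref_codons) &&
      stop_at < nchar(cds) %/% 3L) {
    defects[[length(defects) + 1L]] <- tibble(
      type = "premature_stop", at = stop_at, value = NA_real_
    )
  }
  d <- rbind_or(defects,
                tibble(type = character(), at = integer(), value = numeric()))
  status <- if (!nrow(d)) {
    "intact"
  } else if (!is.na(coverage) && coverage < params$fragment_coverage_max &&
             all(d$type == "deletion")) {
    "fragment"
  } else {
    "pseudogene"
  }
  tibble(gene_id = gene_id, status = status, coverage = coverage,
         n_defects = nrow(d), defects = list(d))
}

MECHANISMS <- c("TE_INSERTION", "POINT_FRAMESHIFT", "INTERNAL_DELETION",
                "TERMINAL_TRUNCATION", "UNKNOWN")

#' Attribute the pseudogenization mechanism of a gene-pseudogene pair
#'
#' Compares the region of the intact gene (CDS plus flanks) with the region
#' of its defective homolog and the repeat annotation there, and returns
#' exactly one mechanism, in priority order: `TE_INSERTION` (a repeat
#' feature fills an insertion that interrupts an exon-aligned block),
#' `POINT_FRAMESHIFT` (the indel evidence is a single 1-2 bp event),
#' `INTERNAL_DELETION` (an internal gene block is missing with both ends
#' anchored), `TERMINAL_TRUNCATION` (5' or 3' gene homology is absent), and
#' `UNKNOWN`.
#'
#' @param gene_region intact-gene region with flanks (forward strand of the
#'   gene; e.g. CDS plus 1 kb each side).
#' @param gene_cds_span 0-based half-open span of the CDS within
#'   `gene_region` (integer length-2 vector).
#' @param pseudo_region corresponding region containing the pseudogene.
#' @param pseudo_repeats tibble of repeat spans (`start`, `end`) in
#'   `pseudo_region` coordinates (may be empty).
#' @param params [analysis_params()].
#' @param min_insertion,min_deletion,min_truncation event-size thresholds (bp).
#' @return a single mechanism string.
#' @export
attribute_mechanism <- function(gene_region, gene_cds_span, pseudo_region,
                                pseudo_repeats = empty_repeats(),
                                params = analysis_params(),
                                min_insertion = 50L, min_deletion = 30L,
                                min_truncation = 60L) {
  blocks <- local_blocks(gene_region, pseudo_region, params, min_score = 60)
  if (!nrow(blocks)) return("UNKNOWN")
  cds_lo <- gene_cds_span[1]
  cds_hi <- gene_cds_span[2]

  insertions <- list()   # extra sequence in the pseudo region
  deletions <- list()    # gene sequence missing from the pseudo region
  small_indels <- 0L
  n_small_events <- 0L

  # within-block indel runs ("query_gap" = gap in the gene row, i.e. extra
  # pseudo sequence; "subject_gap" = gene bases missing from the pseudo)
  for (i in seq_len(nrow(blocks))) {
    ind <- blocks$indels[[i]]
    for (j in seq_len(nrow(ind))) {
      q_abs <- blocks$q_start[i] + ind$q_pos[j]
      s_abs <- blocks$s_start[i] + ind$s_pos[j]
      if (ind$len[j] <= 2L) {
        small_indels <- small_indels + ind$len[j]
        n_small_events <- n_small_events + 1L
      } else if (ind$side[j] == "query_gap") {
        insertions[[length(insertions) + 1L]] <-
          c(s_start = s_abs, s_end = s_abs + ind$len[j], q_at = q_abs)
      } else {
        deletions[[length(deletions) + 1L]] <-
          c(q_start = q_abs, q_end = q_abs + ind$len[j])
      }
    }
  }
  # between-block gaps (events too large for one optimal alignment)
  if (nrow(blocks) > 1L) {
    for (i in seq_len(nrow(blocks) - 1L)) {
      q_gap <- blocks$q_start[i + 1L] - blocks$q_end[i]
      s_gap <- blocks$s_start[i + 1L] - blocks$s_end[i]
      if (s_gap >= min_insertion && q_gap <= min_deletion) {
        insertions[[length(insertions) + 1L]] <-
          c(s_start = blocks$s_end[i], s_end = blocks$s_start[i + 1L],
            q_at = blocks$q_end[i])
      } else if (q_gap >= min_deletion && s_gap < min_insertion) {
        deletions[[length(deletions) + 1L]] <-
          c(q_start = blocks$q_end[i], q_end = blocks$q_start[i + 1L])
      }
    }
  }

  # 1. TE insertion interrupting the exon-aligned part of the pseudo region
  for (ins in insertions) {
    if (ins["s_end"] - ins["s_start"] < min_insertion) next
    if (ins["q_at"] < cds_lo || ins["q_at"] > cds_hi) next
    if (nrow(pseudo_repeats) &&
        any(pseudo_repeats$start < ins["s_end"] &
            pseudo_repeats$end > ins["s_start"])) {
      return("TE_INSERTION")
    }
  }
  # 2. a single small (1-2 bp) indel event, with the CDS otherwise covered
  # (a truncation boundary can also induce a spurious 1 bp alignment gap)
  cov_lo <- min(blocks$q_start)
  cov_hi <- max(blocks$q_end)
  ends_covered <- cov_lo - cds_lo < min_truncation &&
    cds_hi - cov_hi < min_truncation
  if (n_small_events == 1L && small_indels %% 3L != 0L &&
      !length(insertions) && !length(deletions) && ends_covered) {
    return("POINT_FRAMESHIFT")
  }
  # 3. internal deletion: missing gene block with anchors on both sides
  for (del in deletions) {
    if (del["q_end"] - del["q_start"] < min_deletion) next
    if (del["q_start"] > cov_lo && del["q_end"] < cov_hi) {
      return("INTERNAL_DELETION")
    }
  }
  # 4. terminal truncation: CDS end uncovered by any block
  if (cov_lo - cds_lo >= min_truncation || cds_hi - cov_hi >= min_truncation) {
    return("TERMINAL_TRUNCATION")
  }
  if (n_small_events >= 1L && small_indels %% 3L != 0L) {
    return("POINT_FRAMESHIFT")
  }
  "UNKNOWN"
}

#' Pseudogene census across classified loci
#'
#' Per-locus totals of pseudogenes and gene fragments, cross-tabulated
#' against collinearity categories. The "non-collinear pseudogene" count
#' excludes `TANDEM_DUP_NC` copies of collinear genes: a defective tandem
#' copy of a gene that is itself collinear reflects duplication of an
#' already-broken gene, not pseudogenization of an inserted gene.
#'
#' @param calls tibble of [assess_integrity()] calls (one row per wheat gene)
#'   with a `genome_tag` column.
#' @param profiles classified profiles ([classify_genes()]).
#' @return list with `by_locus` totals and the `cross_tab` tibble.
#' @export
pseudogene_census <- function(calls, profiles) {
  if (nrow(calls)) {
    missing <- setdiff(calls$gene_id, profiles$gene_id)
    if (length(missing)) {
      abort(sprintf("calls contain genes absent from profiles: %s",
                    paste(head(missing, 3), collapse = ", ")))
    }
  }
  joined <- left_join(
    select(calls, -dplyr::any_of(c("category"))),
    select(profiles, "gene_id", profile_tag = "genome_tag", "category"),
    by = "gene_id"
  )
  defective <- filter(joined, .data$status %in% c("pseudogene", "fragment"))
  by_locus <- joined |>
    group_by(genome_tag = .data$profile_tag) |>
    summarise(
      n_assessed = dplyr::n(),
      n_pseudo = sum(.data$status %in% c("pseudogene", "fragment")),
      n_noncollinear_pseudo = sum(
        .data$status %in% c("pseudogene", "fragment") &
          .data$category %in% c("SHARED_WHEAT_NC", "LOCUS_SPECIFIC_NC")),
      .groups = "drop"
    )
  cross_tab <- defective |>
    count(genome_tag = .data$profile_tag, .data$category, .data$status)
  list(by_locus = by_locus, cross_tab = cross_tab)
}
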