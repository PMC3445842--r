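#' Maximum-weight order-preserving anchor chain
#'
#' Given best-homolog anchor pairs between two loci (each gene in at most
#' one pair), finds the maximum-weight chain that is strictly increasing in
#' both gene orders (longest-increasing-subsequence dynamic programming,
#' weight = alignment score). "Collinear position" is operationalized as
#' membership in this chain. Ties are broken toward the chain containing
#' the earlier query gene.
#'
#' @param anchors tibble with integer columns `a_index`, `b_index` (gene
#'   order indices in the two loci) and optionally `weight` (default 1).
#' @return `anchors` with a logical `in_chain` column.
#' @export
chain_anchors <- function(anchors) {
  n <- nrow(anchors)
  if (!n) return(mutate(anchors, in_chain = logical(0)))
  if (anyDuplicated(anchors$a_index) || anyDuplicated(anchors$b_index)) {
    abort("each gene may appear in at most one anchor pair")
  }
  w <- if ("weight" %in% names(anchors)) anchors$weight else rep(1, n)
  ord <- order(anchors$a_index)
  a <- anchors$a_index[ord]
  b <- anchors$b_index[ord]
  wt <- w[ord]
  best <- numeric(n)
  prev <- integer(n)
  for (i in seq_len(n)) {
    best[i] <- wt[i]
    prev[i] <- 0L
    for (j in seq_len(i - 1L)) {
      if (b[j] < b[i] && best[j] + wt[i] > best[i]) {
        best[i] <- best[j] + wt[i]
        prev[i] <- j
      }
    }
  }
  end <- which.max(best)  # first maximum -> earliest query gene on ties
  sel <- logical(n)
  while (end > 0L) {
    sel[end] <- TRUE
    end <- prev[end]
  }
  in_chain <- logical(n)
  in_chain[ord] <- sel
  mutate(anchors, in_chain = in_chain)
}

pair_anchors <- function(pairs, genes_a, genes_b) {
  if (!nrow(pairs)) {
    return(tibble(gene_a = character(), gene_b = character(),
                  a_index = integer(), b_index = integer(),
                  weight = numeric(), in_chain = logical()))
  }
  anchors <- tibble(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    a_index = match(pairs$gene_a, genes_a),
    b_index = match(pairs$gene_b, genes_b),
    weight = pairs$score
  )
  if (anyNA(anchors$a_index) || anyNA(anchors$b_index)) {
    abort("anchor gene not present in locus gene order")
  }
  chain_anchors(anchors)
}

#' Resolve tandem duplications among classified genes
#'
#' A tandem pair is two nearby genes (at most `params$tandem_max_intervening`
#' genes between them) of one locus whose best homolog in a model genome (or,
#' failing that, in the other wheat locus) is the same gene. The copy with
#' higher identity to that homolog keeps its collinear eligibility; the
#' other copy is re-categorized `TANDEM_DUP_NC` with `tandem_partner`
#' recorded on both. Identity ties go to the 5'-most copy. In arrays of
#' three or more copies only the single best copy is kept.
#'
#' @param profiles profile tibble for one locus (see [classify_genes()]).
#' @param params [analysis_params()].
#' @return updated profiles.
#' @export
resolve_tandem <- function(profiles, params = analysis_params()) {
  pr <- arrange(profiles, .data$order_index)
  key <- dplyr::coalesce(pr$best_model_id, pr$pair_id)
  key_identity <- dplyr::coalesce(pr$best_model_identity, pr$pair_identity)
  groups <- split(seq_len(nrow(pr)), key)
  for (idx in groups) {
    if (length(idx) < 2L) next
    idx <- sort(idx)
    # require adjacency within the allowed window along the whole array
    if (any(diff(idx) > params$tandem_max_intervening + 1L)) next
    ids <- key_identity[idx]
    keep <- idx[order(-ids, idx)][1]  # best identity, then 5'-most
    drop <- setdiff(idx, keep)
    pr$category[drop] <- "TANDEM_DUP_NC"
    pr$tandem_partner[drop] <- pr$gene_id[keep]
    pr$tandem_partner[keep] <- pr$gene_id[drop[1]]
  }
  pr
}

#' Classify genes of two wheat loci against two model genomes
#'
#' Builds per-gene collinearity profiles from reciprocal-best homolog pairs
#' and anchor chains. Categories: `COLLINEAR_ALL` (in-chain homoeolog pair
#' plus in-chain homologs in both model genomes), `COLLINEAR_RICE_WHEAT`
#' (in-chain pair and in-chain rice homolog, absent from Brachypodium),
#' `SHARED_WHEAT_NC` (homoeolog pair but no in-chain model-genome homolog),
#' `LOCUS_SPECIFIC_NC` (no homoeolog pair), `TANDEM_DUP_NC` (extra tandem
#' copy, via [resolve_tandem()]) and `EXCLUDED` (annotation-flagged genes,
#' e.g. a gene falling in an assembly gap, withheld from pairing).
#'
#' @param loci named list of four [locus_annotation()] objects.
#' @param wheat_tags genome tags of the two wheat loci (D first).
#' @param model_tags genome tags of the model genomes, Brachypodium then rice.
#' @param pairs wheat-wheat reciprocal best pairs ([reciprocal_best_pairs()]).
#' @param model_pairs named list (per wheat tag, per model tag) of
#'   reciprocal best pairs wheat-vs-model.
#' @param params [analysis_params()].
#' @param best_model named list (per wheat tag) of best-hit maps against the
#'   pooled model gene sets (used for tandem resolution), or `NULL`.
#' @return tibble with one row per gene of all four loci.
#' @export
classify_genes <- function(loci, wheat_tags, model_tags, pairs, model_pairs,
                           params = analysis_params(), best_model = NULL) {
  tag_of <- map_chr(loci, "genome_tag")
  locus_by_tag <- setNames(loci, tag_of)
  wd <- wheat_tags[1]; wb <- wheat_tags[2]
  bd <- model_tags[1]; os <- model_tags[2]
  gorder <- map(locus_by_tag, ~ .x$genes$gene_id)

  chains <- list()
  chains[[paste(wd, wb)]] <- pair_anchors(pairs, gorder[[wd]], gorder[[wb]])
  for (wt in wheat_tags) {
    for (mt in model_tags) {
      chains[[paste(wt, mt)]] <-
        pair_anchors(model_pairs[[wt]][[mt]], gorder[[wt]], gorder[[mt]])
    }
  }

  wheat_profile <- function(wt, other_wt) {
    lc <- locus_by_tag[[wt]]
    g <- lc$genes
    wp <- chains[[paste(wd, wb)]]
    side <- if (wt == wd) "gene_a" else "gene_b"
    oside <- if (wt == wd) "gene_b" else "gene_a"
    pair_id <- wp[[oside]][match(g$gene_id, wp[[side]])]
    pair_in_chain <- wp$in_chain[match(g$gene_id, wp[[side]])]
    pair_identity <- if (nrow(wp)) {
      pid <- pairs$identity[match(
        if (wt == wd) g$gene_id else pair_id,
        pairs$gene_a)]
      pid
    } else rep(NA_real_, nrow(g))
    model_cols <- map(model_tags, function(mt) {
      ch <- chains[[paste(wt, mt)]]
      tibble(
        id = ch$gene_b[match(g$gene_id, ch$gene_a)],
        in_chain = dplyr::coalesce(ch$in_chain[match(g$gene_id, ch$gene_a)],
                                   FALSE)
      )
    })
    names(model_cols) <- model_tags
    bm <- best_model[[wt]]
    best_model_id <- if (!is.null(bm)) {
      bm$subject_id[match(g$gene_id, bm$query_id)]
    } else {
      dplyr::coalesce(model_cols[[os]]$id, model_cols[[bd]]$id)
    }
    best_model_identity <- if (!is.null(bm)) {
      bm$identity[match(g$gene_id, bm$query_id)]
    } else rep(NA_real_, nrow(g))

    pr <- tibble(
      gene_id = g$gene_id, locus_id = lc$locus_id, genome_tag = wt,
      order_index = seq_len(nrow(g)),
      start = g$start, end = g$end, status = g$status,
      pair_id = pair_id,
      pair_identity = pair_identity,
      pair_in_chain = dplyr::coalesce(pair_in_chain, FALSE),
      bd_id = model_cols[[bd]]$id, bd_in_chain = model_cols[[bd]]$in_chain,
      os_id = model_cols[[os]]$id, os_in_chain = model_cols[[os]]$in_chain,
      best_model_id = best_model_id,
      best_model_identity = best_model_identity,
      tandem_partner = NA_character_
    )
    pr <- mutate(pr, category = dplyr::case_when(
      status == "excluded" ~ "EXCLUDED",
      pair_in_chain & bd_in_chain & os_in_chain ~ "COLLINEAR_ALL",
      pair_in_chain & os_in_chain & is.na(bd_id) ~ "COLLINEAR_RICE_WHEAT",
      !is.na(pair_id) ~ "SHARED_WHEAT_NC",
      TRUE ~ "LOCUS_SPECIFIC_NC"
    ))
    resolve_tandem(pr, params)
  }

  model_profile <- function(mt) {
    lc <- locus_by_tag[[mt]]
    g <- lc$genes
    flags <- map(wheat_tags, function(wt) {
      ch <- chains[[paste(wt, mt)]]
      dplyr::coalesce(ch$in_chain[match(g$gene_id, ch$gene_b)], FALSE)
    })
    tibble(
      gene_id = g$gene_id, locus_id = lc$locus_id, genome_tag = mt,
      order_index = seq_len(nrow(g)),
      start = g$start, end = g$end, status = g$status,
      pair_id = NA_character_, pair_identity = NA_real_,
      pair_in_chain = FALSE,
      bd_id = NA_character_, bd_in_chain = FALSE,
      os_id = NA_character_, os_in_chain = FALSE,
      best_model_id = NA_character_, best_model_identity = NA_real_,
      tandem_partner = NA_character_,
      category = ifelse(flags[[1]] & flags[[2]], "COLLINEAR_ALL",
                        "LOCUS_SPECIFIC_NC")
    )
  }

  out <- bind_rows(
    wheat_profile(wd, wb),
    wheat_profile(wb, wd),
    model_profile(bd),
    model_profile(os)
  )
  attr(out, "chains") <- chains
  out
}

NC_CATEGORIES <- c("SHARED_WHEAT_NC", "LOCUS_SPECIFIC_NC", "TANDEM_DUP_NC")
COLLINEAR_CATEGORIES <- c("COLLINEAR_ALL", "COLLINEAR_RICE_WHEAT")

#' Per-genome collinearity summary
#'
#' Counts and printed-style fractions per genome: the collinear percentage
#' (one decimal, half-up), the homoeolog percentage of each wheat locus
#' (whole percent; the denominator keeps annotation-excluded genes), counts
#' of wheat-shared and locus-specific non-collinear genes (the latter
#' includes tandem extra copies, which exist at only one locus) and tandem
#' counts.
#'
#' @param profiles output of [classify_genes()].
#' @return one row per genome tag.
#' @export
summarize_collinearity <- function(profiles) {
  if (!nrow(profiles)) return(tibble())
  profiles |>
    group_by(.data$genome_tag) |>
    summarise(
      n_genes = dplyr::n(),
      n_collinear = sum(.data$category %in% COLLINEAR_CATEGORIES),
      pct_collinear = round_half_up(100 * .data$n_collinear / .data$n_genes, 1),
      n_pairs = sum(!is.na(.data$pair_id)),
      pct_homoeolog = round_half_up(100 * .data$n_pairs / .data$n_genes, 0),
      n_shared_nc = sum(.data$category == "SHARED_WHEAT_NC"),
      n_locus_specific = sum(.data$category %in%
                               c("LOCUS_SPECIFIC_NC", "TANDEM_DUP_NC")),
      n_tandem = sum(.data$category == "TANDEM_DUP_NC"),
      n_excluded = sum(.data$category == "EXCLUDED"),
      .groups = "drop"
    )
}

#' Distances between consecutive genes of a locus
#'
#' Distance is measured from the end of one gene span to the start of the
#' next (bp). The median of an even count is the mean of the central pair.
#'
#' @param locus a [locus_annotation()].
#' @return list with `mean`, `median` and the `distances` vector.
#' @export
gene_distances <- function(locus) {
  g <- locus$genes
  if (nrow(g) < 2L) {
    abort(sprintf("locus %s has fewer than 2 genes; gene distances undefined",
                  locus$locus_id))
  }
  d <- g$start[-1] - g$end[-nrow(g)]
  list(mean = mean(d), median = median(d), distances = d)
}

#' Repeat composition summary
#'
#' Per class/order/superfamily element counts, cumulative lengths and the
#' percentage of total repeat length (one decimal, half-up), in the style of
#' a repetitive-landscape classification table.
#'
#' @param repeats repeats tibble of a locus (or several, row-bound).
#' @param total_repeat_len denominator for percentages; defaults to the sum
#'   of all repeat lengths in `repeats`.
#' @return tibble grouped by `class`, `order`, `superfamily`.
#' @export
repeat_composition <- function(repeats, total_repeat_len = NULL) {
  if (!nrow(repeats)) {
    return(tibble(class = character(), order = character(),
                  superfamily = character(), n_elements = integer(),
                  cumulative_len = integer(), pct = numeric()))
  }
  lens <- repeats$end - repeats$start
  total <- total_repeat_len %||% sum(lens)
  repeats |>
    mutate(len = lens) |>
    group_by(.data$class, .data$order, .data$superfamily) |>
    summarise(n_elements = dplyr::n(),
              cumulative_len = sum(.data$len), .groups = "drop") |>
    mutate(pct = round_half_up(100 * .data$cumulative_len / total, 1)) |>
    arrange(desc(.data$cumulative_len))
}
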