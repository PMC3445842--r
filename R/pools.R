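#' Design three-dimensional BAC pools
#'
#' Assigns clones to wells of `n_plates` 384-well plates (rows `A`-`P`,
#' columns 1-24 by default), filled plate-major, then row-major, then by
#' column, and derives the three pooling dimensions: plate pools (all clones
#' of one plate), row pools (one row across all plates) and column pools
#' (one column across all plates). Every clone belongs to exactly one pool
#' per dimension.
#'
#' @param clones character vector of clone ids.
#' @param n_plates,n_rows,n_cols pool-grid dimensions.
#' @return object of class `pool_design`: list with `wells` tibble
#'   (`clone`, `plate`, `row`, `col`) and the dimensions.
#' @export
design_pools <- function(clones, n_plates = 10L, n_rows = 16L, n_cols = 24L) {
  n <- length(clones)
  capacity <- n_plates * n_rows * n_cols
  if (n > capacity) {
    abort(sprintf("%d clones exceed pool capacity %d", n, capacity))
  }
  if (anyDuplicated(clones)) abort("duplicated clone ids")
  i <- seq_len(n) - 1L
  wells <- tibble(
    clone = clones,
    plate = i %/% (n_rows * n_cols) + 1L,
    row = LETTERS[(i %% (n_rows * n_cols)) %/% n_cols + 1L],
    col = (i %% n_cols) + 1L
  )
  structure(list(wells = wells, n_plates = n_plates, n_rows = n_rows,
                 n_cols = n_cols),
            class = "pool_design")
}

#' @export
print.pool_design <- function(x, ...) {
  cat(sprintf("<pool_design> %d clones in %d x %d x %d wells (%d empty)\n",
              nrow(x$wells), x$n_plates, x$n_rows, x$n_cols,
              x$n_plates * x$n_rows * x$n_cols - nrow(x$wells)))
  invisible(x)
}

#' Positive pools of a marker given its true clone set
#'
#' @param design a [design_pools()] object.
#' @param clones clone ids carrying the marker.
#' @return list with `plates`, `rows`, `cols` of positive pools.
#' @export
positive_pools <- function(design, clones) {
  w <- design$wells[design$wells$clone %in% clones, ]
  list(plates = sort(unique(w$plate)), rows = sort(unique(w$row)),
       cols = sort(unique(w$col)))
}

#' Deconvolve a pool-screening result to candidate clone addresses
#'
#' The candidate set is the Cartesian product of the positive pools of the
#' three dimensions intersected with occupied wells; with `p`, `r`, `c`
#' positives the candidate count is at most `p*r*c`. An empty dimension
#' yields a no-call.
#'
#' @param design a [design_pools()] object.
#' @param positives list with `plates`, `rows`, `cols` (as from
#'   [positive_pools()]).
#' @param marker_id id copied into the result.
#' @return tibble of candidate clones with an `ambiguity` column (candidate
#'   count; zero rows with `no_call` attribute when a dimension is empty).
#' @export
deconvolve <- function(design, positives, marker_id = "marker") {
  empty <- tibble(marker_id = character(), clone = character(),
                  plate = integer(), row = character(), col = integer(),
                  ambiguity = integer())
  if (!length(positives$plates) || !length(positives$rows) ||
      !length(positives$cols)) {
    attr(empty, "no_call") <- TRUE
    return(empty)
  }
  w <- design$wells
  cand <- w[w$plate %in% positives$plates & w$row %in% positives$rows &
              w$col %in% positives$cols, ]
  mutate(cand, marker_id = marker_id, ambiguity = nrow(cand), .before = 1)
}

#' Infer physical-map contig overlaps from multi-clone markers
#'
#' A marker whose positive clones fall in two different contigs indicates
#' that those contigs overlap. Edges are deduplicated with the number of
#' supporting markers; markers hitting more than two contigs are flagged
#' unusual (all pairs still reported).
#'
#' @param assignments tibble with `marker_id`, `clone`.
#' @param clone_contigs tibble with `clone`, `contig`.
#' @return tibble `contig_a`, `contig_b`, `support`, `markers`, `unusual`.
#' @export
infer_contig_overlaps <- function(assignments, clone_contigs) {
  joined <- left_join(assignments, clone_contigs, by = "clone")
  if (anyNA(joined$contig)) abort("clone without contig assignment")
  edges <- rbind_or(map(split(joined, joined$marker_id), function(d) {
    ctgs <- sort(unique(d$contig))
    if (length(ctgs) < 2L) return(NULL)
    cmb <- utils::combn(ctgs, 2L)
    tibble(marker_id = d$marker_id[1],
           contig_a = cmb[1, ], contig_b = cmb[2, ],
           unusual = length(ctgs) > 2L)
  }), tibble(marker_id = character(), contig_a = character(),
             contig_b = character(), unusual = logical()))
  if (is.null(edges) || !nrow(edges)) {
    return(tibble(contig_a = character(), contig_b = character(),
                  support = integer(), markers = list(), unusual = logical()))
  }
  edges |>
    group_by(.data$contig_a, .data$contig_b) |>
    summarise(support = dplyr::n(),
              markers = list(sort(unique(.data$marker_id))),
              unusual = any(.data$unusual), .groups = "drop")
}

#' Build a synthetic pool-screening fixture
#'
#' Emulates the published screen: a minimum tiling path of 3,827 clones in
#' ten 384-well plates screened with twelve EST-derived markers, four of
#' which identify single clones and the rest two clones each; clones are
#' spread over eight physical-map contigs so that five markers bridge
#' contigs, supporting three distinct overlaps (one of them by three
#' markers).
#'
#' @param n_clones number of clones.
#' @param n_plates,n_rows,n_cols pool-grid dimensions.
#' @param n_markers total markers.
#' @param n_single markers hitting a single clone.
#' @param seed RNG seed.
#' @return list with `design`, `truth` (marker to clone tibble), `screen`
#'   (positive pools per marker) and `clone_contigs`.
#' @export
build_pool_fixture <- function(n_clones = 3827L, n_plates = 10L,
                               n_rows = 16L, n_cols = 24L,
                               n_markers = 12L, n_single = 4L, seed = 1L) {
  withr::with_seed(seed, {
    clones <- sprintf("clone%04d", seq_len(n_clones))
    design <- design_pools(clones, n_plates, n_rows, n_cols)
    # eight contigs along the tiling path
    breaks <- sort(sample(seq(50L, n_clones - 50L), 7L))
    contig <- sprintf("ctg%02d",
                      findInterval(seq_len(n_clones), breaks + 1L) + 1L)
    clone_contigs <- tibble(clone = clones, contig = contig)
    # markers: n_single single-clone, the rest two clones; five of the
    # two-clone markers straddle a contig boundary (three distinct
    # boundaries, the first supported by three markers)
    truth <- list()
    singles <- sample(n_clones, n_single)
    for (i in seq_len(n_single)) {
      truth[[i]] <- tibble(marker_id = sprintf("mk%02d", i),
                           clone = clones[singles[i]])
    }
    n_double <- n_markers - n_single
    bridge_breaks <- c(breaks[1], breaks[1], breaks[1], breaks[3], breaks[5])
    for (j in seq_len(n_double)) {
      id <- sprintf("mk%02d", n_single + j)
      picked <- if (j <= length(bridge_breaks)) {
        b <- bridge_breaks[j]
        c(clones[b], clones[b + 1L])  # adjacent clones across the boundary
      } else {
        # adjacent pair inside one contig
        k <- sample(setdiff(seq_len(n_clones - 1L), breaks), 1L)
        c(clones[k], clones[k + 1L])
      }
      truth[[n_single + j]] <- tibble(marker_id = id, clone = picked)
    }
    truth <- list_rbind(truth)
    screen <- map(split(truth$clone, truth$marker_id),
                  ~ positive_pools(design, .x))
    list(design = design, truth = truth, screen = screen,
         clone_contigs = clone_contigs)
  })
}
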