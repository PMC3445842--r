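# Independent plain-R implementations used as oracles. These deliberately
# share no code with the package internals.

# affine-gap local alignment score (Gotoh recursion)
sw_oracle_score <- function(a, b, match = 2, mismatch = -3,
                            gap_open = 5, gap_ext = 2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_ext, E[i, j - 1] - gap_ext)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_ext, F[i - 1, j] - gap_ext)
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# exhaustive maximum-weight strictly increasing chain over <= ~10 anchors
chain_oracle_weight <- function(a_idx, b_idx, w) {
  n <- length(a_idx)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (!length(sel)) next
    sel <- sel[order(a_idx[sel])]
    if (length(sel) > 1 &&
        (any(diff(a_idx[sel]) <= 0) || any(diff(b_idx[sel]) <= 0))) next
    best <- max(best, sum(w[sel]))
  }
  best
}

# all maximal exact common substrings of length >= k (naive enumeration)
mcs_oracle <- function(est, cds, k) {
  out <- list()
  for (i in 1:nchar(est)) {
    for (j in 1:nchar(cds)) {
      left_ext <- i > 1 && j > 1 &&
        substr(est, i - 1, i - 1) == substr(cds, j - 1, j - 1)
      if (left_ext) next
      l <- 0
      while (i + l <= nchar(est) && j + l <= nchar(cds) &&
             substr(est, i + l, i + l) == substr(cds, j + l, j + l)) {
        l <- l + 1
      }
      if (l >= k) out[[length(out) + 1]] <- c(i - 1, j - 1, l)
    }
  }
  if (!length(out)) return(character())
  m <- do.call(rbind, out)
  sort(sprintf("%d:%d:%d", m[, 1], m[, 2], m[, 3]))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# minimal single-exon locus builder for unit tests
toy_locus <- function(seq, genes, tag = "T", id = "toy") {
  if (!"status" %in% names(genes)) genes$status <- rep("intact", nrow(genes))
  genes$exons <- lapply(seq_len(nrow(genes)), function(i) {
    tibble::tibble(start = genes$start[i], end = genes$end[i])
  })
  genes$notes <- rep("", nrow(genes))
  locus_annotation(id, tag, seq, genes)
}
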