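test_that("exact-match rule: length and identity thresholds", {
  p <- analysis_params()
  set.seed(50)
  core <- rand_seq(150)
  cds <- tibble::tibble(gene_id = "g",
                        seq = paste0(rand_seq(60), core, rand_seq(60)))
  hit <- match_ests(cds, tibble::tibble(id = "e", seq = core), p)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$match_len, 150L)
  expect_equal(hit$identity, 100)

  # one mismatch in 150 bp (99.3% identity): rejected
  near <- core
  substr(near, 75, 75) <- setdiff(c("A", "C", "G", "T"),
                                  substr(near, 75, 75))[1]
  expect_equal(nrow(match_ests(cds, tibble::tibble(id = "e", seq = near), p)),
               0L)

  # exact but only 80 bp: rejected
  expect_equal(nrow(match_ests(cds, tibble::tibble(
    id = "e", seq = substring(core, 1, 80)), p)), 0L)

  # reverse-complement ESTs are matched (orientation is arbitrary)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(core)))
  hrc <- match_ests(cds, tibble::tibble(id = "e", seq = rc), p)
  expect_equal(hrc$strand, "-")

  expect_error(match_ests(cds, tibble::tibble(id = "e", seq = core),
                          analysis_params(est_min_identity = 99)),
               "exact")
})

test_that("match_ests equals the naive all-substring oracle", {
  p <- analysis_params(est_min_len = 6L)
  set.seed(51)
  for (r in 1:30) {
    cds <- rand_seq(sample(40:120, 1))
    est <- paste0(rand_seq(10), substring(cds, 15, 45), rand_seq(8))
    hits <- match_ests(tibble::tibble(gene_id = "g", seq = cds),
                       tibble::tibble(id = "e", seq = est), p)
    fw <- hits[hits$strand == "+", ]
    got <- sort(sprintf("%d:%d:%d", fw$est_start, fw$cds_start, fw$match_len))
    expect_equal(got, mcs_oracle(est, cds, 6))
  }
})

test_that("shared-EST removal drops whole ESTs, pair-specifically", {
  expect_equal(length(paper_expr$removed), 4L)
  expect_false(any(paper_expr$hits$est_id %in% paper_expr$removed))

  # an EST hitting two unpaired genes is retained
  hits <- tibble::tibble(est_id = "e1", gene_id = c("u1", "u2"),
                         strand = "+", match_len = 150L,
                         est_start = 0L, cds_start = 0L, identity = 100)
  pairs <- tibble::tibble(gene_a = "a", gene_b = "b")
  res <- drop_shared_ests(hits, pairs)
  expect_equal(nrow(res$hits), 2L)
  expect_equal(res$removed, character(0))

  # no pairs: the filter is the identity
  res2 <- drop_shared_ests(hits, pairs[0, ])
  expect_equal(res2$hits, hits)

  # never remove one hit of an EST without removing all of them
  both <- tibble::tibble(est_id = c("e1", "e1", "e2"),
                         gene_id = c("a", "b", "a"),
                         strand = "+", match_len = 150L,
                         est_start = 0L, cds_start = 0L, identity = 100)
  res3 <- drop_shared_ests(both, pairs)
  expect_equal(unique(res3$hits$est_id), "e2")
})

test_that("expressed fractions per category match the planted design", {
  s <- paper_expr$summary
  get <- function(tag, grp, col) {
    s[[col]][s$genome_tag == tag & s$group == grp]
  }
  expect_equal(get("3DS", "non_collinear", "pct_expressed"), 41.7)
  expect_equal(get("3DS", "collinear", "pct_expressed"), 53.3)
  expect_equal(get("3B", "collinear", "pct_expressed"), 33.3)
  expect_equal(get("3B", "non_collinear", "pct_expressed"), 22.7)
  expect_equal(get("3DS", "non_collinear", "n_genes"), 24L)
  expect_equal(get("3B", "non_collinear", "n_genes"), 22L)

  none <- expression_summary(paper_expr$hits[0, ], paper_cmp$profiles)
  expect_true(all(none$pct_expressed == 0))
})

test_that("two-tailed binomial p-values match closed forms", {
  expect_equal(binomial_contrast(0, 8)$p_value, 2 * 0.5^8)
  expect_equal(binomial_contrast(1, 7)$p_value, 18 / 256)
  expect_equal(binomial_contrast(3, 3)$p_value, 1)
  expect_true(binomial_contrast(0, 0)$undefined)
  # symmetry
  set.seed(52)
  for (i in 1:20) {
    n <- sample(1:15, 1)
    k <- sample(0:n, 1)
    expect_equal(binomial_contrast(k, n - k)$p_value,
                 binomial_contrast(n - k, k)$p_value)
  }
})
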