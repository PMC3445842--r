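test_that("identical sequences give a full-length perfect hit", {
  p <- analysis_params()
  set.seed(10)
  s <- rand_seq(200)
  h <- align_local(s, s, p)
  expect_equal(h$score[1], 400)
  expect_equal(h$identity[1], 100)
  expect_equal(h$aln_len[1], 200L)
  expect_lt(h$evalue[1], 1e-50)
})

test_that("optimal local score matches the independent DP oracle", {
  p <- analysis_params()
  set.seed(11)
  for (i in 1:150) {
    a <- rand_seq(sample(4:12, 1))
    b <- rand_seq(sample(4:12, 1))
    got <- align_local(a, b, p, both_strands = FALSE)
    expect_equal(if (nrow(got)) got$score[1] else 0,
                 sw_oracle_score(a, b))
  }
})

test_that("reverse-complement hits are found only with both strands", {
  p <- analysis_params()
  set.seed(12)
  s <- rand_seq(120)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  fw <- align_local(s, rc, p, both_strands = FALSE)
  expect_true(!nrow(fw) || fw$score[1] < 240)
  both <- align_local(s, rc, p, both_strands = TRUE)
  expect_equal(both$strand[1], "-")
  expect_equal(both$score[1], 240)
})

test_that("E-value decreases monotonically in score for fixed m, n", {
  p <- analysis_params()
  ev <- sapply(seq(10, 400, by = 10),
               function(s) homeolocus:::hit_evalue(s, 450, 450, p))
  expect_true(all(diff(ev) < 0))
})

test_that("find_best_homolog applies the E-value cutoff and tie-breaks", {
  p <- analysis_params()
  set.seed(13)
  q <- rand_seq(450)
  unrelated <- tibble::tibble(gene_id = c("x", "y", "z"),
                              seq = replicate(3, rand_seq(1000)))
  expect_equal(nrow(find_best_homolog(q, unrelated, p)), 0L)

  # two identical subjects: lexicographically smaller id wins
  twin <- tibble::tibble(gene_id = c("b", "a"), seq = c(q, q))
  expect_equal(find_best_homolog(q, twin, p)$subject_id, "a")
})

test_that("all 32 planted homoeologous pairs are reciprocal best hits", {
  expect_equal(nrow(paper_cmp$pairs), 32L)
  truth <- paper_fx$truth
  fam_of <- setNames(truth$family, truth$gene_id)
  expect_true(all(fam_of[paper_cmp$pairs$gene_a] ==
                    fam_of[paper_cmp$pairs$gene_b]))
  expect_true(all(paper_cmp$pairs$identity > 88))
})

test_that("the k-mer prefilter does not change retained best hits", {
  cds <- paper_cmp$cds
  d <- dplyr::filter(cds, genome_tag == "3DS")[1:8, ]
  b <- dplyr::filter(cds, genome_tag == "3B")[1:12, ]
  p <- analysis_params()
  with_f <- homology_search(d, b, p, prefilter = TRUE)
  without <- homology_search(d, b, p, prefilter = FALSE)
  expect_equal(with_f, without)
})

test_that("rescue against a locus labels annotated and un-annotated hits", {
  p <- analysis_params()
  set.seed(14)
  orphan <- rand_seq(600)
  frag <- substring(orphan, 101, 600)  # a ~500 bp remnant
  lseq <- paste0(rand_seq(2000), frag, rand_seq(1500))
  genes <- tibble::tibble(gene_id = "other", strand = "+",
                          start = 3900L, end = 3990L)
  lc <- toy_locus(paste0(lseq, rand_seq(100)), genes, tag = "B", id = "lb")
  hits <- rescue_against_locus("orphan", orphan, lc, p)
  expect_equal(hits$label[1], "candidate_fragment")
  expect_gte(hits$s_end[1] - hits$s_start[1], 490)

  # no counterpart anywhere
  lc2 <- toy_locus(rand_seq(3000),
                   tibble::tibble(gene_id = "g", strand = "+",
                                  start = 10L, end = 100L))
  expect_equal(nrow(rescue_against_locus("orphan", orphan, lc2, p)), 0L)

  # hit inside an annotated gene is labelled, not a fragment
  lseq3 <- paste0(rand_seq(1000), frag, rand_seq(1000))
  lc3 <- toy_locus(lseq3, tibble::tibble(gene_id = "ann", strand = "+",
                                         start = 1000L, end = 1500L))
  hits3 <- rescue_against_locus("orphan", orphan, lc3, p)
  expect_equal(hits3$label[1], "annotated")
})

test_that("merge_fragments unifies split gene models under the 5' id", {
  set.seed(15)
  full <- rand_seq(900)
  lseq <- paste0(rand_seq(500), substring(full, 1, 400), rand_seq(80),
                 substring(full, 401, 900), rand_seq(500))
  genes <- tibble::tibble(
    gene_id = c("fA", "fB"), strand = "+",
    start = c(500L, 980L), end = c(900L, 1480L))
  lc <- toy_locus(lseq, genes)
  ev <- tibble::tibble(gene_id = c("fA", "fB"), subject_id = "homolog",
                       s_start = c(0L, 400L), s_end = c(400L, 900L))
  res <- merge_fragments(lc, "fA", "fB", ev)
  expect_equal(res$model$gene_id, "fA")
  expect_equal(res$model$start, 500L)
  expect_equal(res$model$end, 1480L)
  expect_equal(nrow(res$model$exons[[1]]), 2L)
  expect_equal(nrow(res$locus$genes), 1L)
  # homolog coverage of the merged model exceeds 90%
  cov <- sum(ev$s_end - ev$s_start) / 900
  expect_gt(cov, 0.9)

  ev_bad <- ev
  ev_bad$subject_id <- c("h1", "h2")
  expect_error(merge_fragments(lc, "fA", "fB", ev_bad), "different homologs")

  ev_ov <- ev
  ev_ov$s_start <- c(0L, 100L)
  ev_ov$s_end <- c(400L, 900L)
  expect_error(merge_fragments(lc, "fA", "fB", ev_ov), "overlap")
})
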