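test_that("chain_anchors keeps order-consistent anchors", {
  a <- tibble::tibble(a_index = 1:3, b_index = 1:3, weight = 1)
  expect_true(all(chain_anchors(a)$in_chain))

  single <- tibble::tibble(a_index = 5L, b_index = 9L, weight = 2)
  expect_true(chain_anchors(single)$in_chain)

  # crossing pair with equal weights: chain of length 3
  x <- tibble::tibble(a_index = 1:4, b_index = c(1L, 3L, 2L, 4L), weight = 1)
  ch <- chain_anchors(x)
  expect_equal(sum(ch$in_chain), 3L)
  expect_equal(sum(ch$weight[ch$in_chain]),
               chain_oracle_weight(x$a_index, x$b_index, x$weight))
})

test_that("chain_anchors equals exhaustive search on random anchor sets", {
  set.seed(20)
  for (i in 1:60) {
    n <- sample(2:8, 1)
    a <- tibble::tibble(a_index = sample(20L, n), b_index = sample(20L, n),
                        weight = sample(1:5, n, replace = TRUE))
    ch <- chain_anchors(a)
    expect_equal(sum(ch$weight[ch$in_chain]),
                 chain_oracle_weight(a$a_index, a$b_index, a$weight))
  }
})

test_that("reversing one locus' gene order collapses the chain", {
  a <- tibble::tibble(a_index = 1:6, b_index = 6:1, weight = 1)
  expect_equal(sum(chain_anchors(a)$in_chain), 1L)
})

test_that("tandem resolution demotes the less conserved copy", {
  base <- tibble::tibble(
    gene_id = c("g1", "g1c", "g2"), locus_id = "L", genome_tag = "W",
    order_index = 1:3, start = c(0L, 100L, 200L), end = c(50L, 150L, 250L),
    status = "intact", pair_id = c("p1", NA, "p2"),
    pair_identity = c(95, NA, 95), pair_in_chain = c(TRUE, FALSE, TRUE),
    bd_id = NA_character_, bd_in_chain = FALSE,
    os_id = NA_character_, os_in_chain = FALSE,
    best_model_id = c("os1", "os1", "os2"),
    best_model_identity = c(90, 84, 88),
    tandem_partner = NA_character_,
    category = c("COLLINEAR_ALL", "LOCUS_SPECIFIC_NC", "COLLINEAR_ALL")
  )
  out <- resolve_tandem(base, analysis_params())
  expect_equal(out$category[out$gene_id == "g1c"], "TANDEM_DUP_NC")
  expect_equal(out$tandem_partner[out$gene_id == "g1c"], "g1")
  expect_equal(out$category[out$gene_id == "g1"], "COLLINEAR_ALL")

  # identity tie: the 5'-most copy keeps collinear standing
  tie <- base
  tie$best_model_identity <- c(90, 90, 88)
  out2 <- resolve_tandem(tie, analysis_params())
  expect_equal(out2$category[out2$gene_id == "g1"], "COLLINEAR_ALL")
  expect_equal(out2$category[out2$gene_id == "g1c"], "TANDEM_DUP_NC")

  # adjacent genes with different model homologs are untouched
  diffh <- base
  diffh$best_model_id <- c("os1", "os9", "os2")
  out3 <- resolve_tandem(diffh, analysis_params())
  expect_equal(out3$category, base$category)
})

test_that("fixture genes are classified into the planted categories", {
  pr <- paper_cmp$profiles
  truth <- paper_fx$truth
  joined <- dplyr::left_join(pr, truth[, c("gene_id", "category_truth")],
                             by = "gene_id")
  expect_equal(joined$category, joined$category_truth)
  # partition: per-locus category counts sum to the gene counts
  sums <- dplyr::count(pr, genome_tag)
  expect_equal(sums$n[match(c("3DS", "3B", "Bd2", "Os1"), sums$genome_tag)],
               c(39L, 38L, 22L, 21L))
})

test_that("tandem copies are flagged on both wheat loci", {
  pr <- paper_cmp$profiles
  expect_equal(sum(pr$category == "TANDEM_DUP_NC" & pr$genome_tag == "3DS"), 3L)
  expect_equal(sum(pr$category == "TANDEM_DUP_NC" & pr$genome_tag == "3B"), 2L)
  td <- dplyr::filter(pr, category == "TANDEM_DUP_NC")
  expect_true(all(!is.na(td$tandem_partner)))
})

test_that("summarize_collinearity handles empty input", {
  expect_equal(nrow(summarize_collinearity(paper_cmp$profiles[0, ])), 0L)
})

test_that("gene distances use consecutive span gaps", {
  lc <- toy_locus(rand_seq(1100),
                  tibble::tibble(gene_id = c("a", "b", "c"), strand = "+",
                                 start = c(0L, 300L, 900L),
                                 end = c(100L, 400L, 1000L)))
  d <- gene_distances(lc)
  expect_equal(d$distances, c(200L, 500L))
  expect_equal(d$mean, 350)
  expect_equal(d$median, 350)

  lc2 <- toy_locus(rand_seq(500),
                   tibble::tibble(gene_id = c("a", "b"), strand = "+",
                                  start = c(0L, 300L), end = c(100L, 400L)))
  d2 <- gene_distances(lc2)
  expect_equal(d2$mean, d2$median)

  lc1 <- toy_locus(rand_seq(200),
                   tibble::tibble(gene_id = "a", strand = "+",
                                  start = 0L, end = 100L))
  expect_error(gene_distances(lc1), "fewer than 2")
})

test_that("repeat composition reproduces printed-style percentages", {
  # counts and cumulative lengths as in a repetitive-landscape table
  reps <- tibble::tibble(
    start = 0L,
    end = c(236440L, 354331L, 16607L, 256633L, 433L, 3609L, 5096L, 128095L),
    class = c("Retrotransposons", "Retrotransposons", "Retrotransposons",
              "DNA_transposons", "DNA_transposons", "DNA_transposons",
              "DNA_transposons", "Unclassified"),
    order = c("LTR_retrotransposons", "LTR_retrotransposons", "LINE",
              "TIR", "TIR", "TIR", "TIR", "unclassified"),
    superfamily = c("Copia", "Gypsy", "LINE", "CACTA", "Harbinger",
                    "Mutator", "Mariner", "unclassified"),
    complete = FALSE
  )
  # the printed total repeat length includes order-level unclassified mass
  comp <- repeat_composition(reps, total_repeat_len = 1059398L)
  expect_equal(comp$pct[comp$superfamily == "Gypsy"], 33.4)
  expect_equal(comp$pct[comp$superfamily == "Copia"], 22.3)
  expect_equal(comp$pct[comp$superfamily == "CACTA"], 24.2)

  one <- repeat_composition(reps[1, ])
  expect_equal(one$pct, 100)

  two <- repeat_composition(tibble::tibble(
    start = 0L, end = 500L, class = c("A", "B"), order = c("x", "y"),
    superfamily = c("Gypsy", "Copia"), complete = FALSE))
  expect_equal(two$pct, c(50, 50))
})
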