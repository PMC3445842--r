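make_orf <- function(n_codons = 150, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  homeolocus:::make_cds(n_codons * 3)
}

test_that("a CDS identical to its homolog is intact", {
  cds <- make_orf(seed = 30)
  call <- assess_integrity(cds, cds)
  expect_equal(call$status, "intact")
  expect_equal(call$n_defects, 0L)
  expect_equal(call$coverage, 1)
})

test_that("a single inserted base is flagged as a frameshift", {
  cds <- make_orf(seed = 31)
  mid <- nchar(cds) %/% 2
  shifted <- paste0(substring(cds, 1, mid), "A", substring(cds, mid + 1))
  call <- assess_integrity(shifted, cds)
  expect_equal(call$status, "pseudogene")
  expect_true("frameshift" %in% call$defects[[1]]$type)
})

test_that("deletion coverage uses the 70% threshold", {
  cds <- make_orf(200, seed = 32)   # 600 bp
  # remove 40% internally (multiple of 3): coverage 0.60 < 0.70
  del <- paste0(substring(cds, 1, 180), substring(cds, 421))
  call <- assess_integrity(del, cds)
  expect_equal(call$status, "pseudogene")
  expect_true("deletion" %in% call$defects[[1]]$type)
  expect_lt(call$coverage, 0.70)
  expect_gt(call$coverage, 0.50)
})

test_that("severe truncation without other defects is a fragment", {
  cds <- make_orf(400, seed = 33)   # 1200 bp
  frag <- substring(cds, nchar(cds) - 479)  # 3' 480 bp, in frame
  call <- assess_integrity(frag, cds)
  expect_equal(call$status, "fragment")
  expect_lt(call$coverage, 0.5)
})

test_that("premature stops are detected, sparing the final 5%", {
  cds <- make_orf(200, seed = 34)
  early <- cds
  substr(early, 301, 303) <- "TAA"   # codon 101 of 200
  call <- assess_integrity(early, cds)
  expect_equal(call$status, "pseudogene")
  expect_true("premature_stop" %in% call$defects[[1]]$type)

  # a stop in the final 5% of the homolog ORF is not premature
  late <- cds
  substr(late, 592, 594) <- "TAA"    # codon 198 of 200
  expect_equal(assess_integrity(late, cds)$status, "intact")

  expect_error(assess_integrity(cds, early), "premature stop")
})

test_that("intrinsic mode flags internal stops without a reference", {
  cds <- make_orf(seed = 35)
  expect_equal(assess_integrity(cds, NULL)$status, "intact")
  broken <- cds
  substr(broken, 202, 204) <- "TGA"   # codon 68, in frame
  expect_equal(assess_integrity(broken, NULL)$status, "pseudogene")
})

test_that("every planted fixture defect is recovered with its mechanism", {
  truth <- paper_fx$truth
  joined <- dplyr::left_join(
    paper_calls,
    truth[, c("gene_id", "status_truth", "mechanism_truth")],
    by = "gene_id")
  expect_equal(joined$status, joined$status_truth)
  mech <- dplyr::filter(joined, !is.na(mechanism_truth))
  expect_equal(nrow(mech), 4L)
  expect_equal(mech$mechanism, mech$mechanism_truth)
})

test_that("pseudogene census matches the planted per-locus totals", {
  by_locus <- paper_census$by_locus
  get <- function(tag, col) by_locus[[col]][match(tag, by_locus$genome_tag)]
  expect_equal(get("3DS", "n_pseudo"), 2L)
  expect_equal(get("3B", "n_pseudo"), 6L)
  expect_equal(get("3DS", "n_noncollinear_pseudo"), 0L)
  expect_equal(get("3B", "n_noncollinear_pseudo"), 5L)
})

test_that("census is invariant to gene input order and checks ids", {
  shuffled <- paper_calls[sample(nrow(paper_calls)), ]
  cen2 <- pseudogene_census(shuffled, paper_cmp$profiles)
  expect_equal(dplyr::arrange(cen2$by_locus, genome_tag),
               dplyr::arrange(paper_census$by_locus, genome_tag))
  bogus <- paper_calls
  bogus$gene_id[1] <- "not_a_gene"
  expect_error(pseudogene_census(bogus, paper_cmp$profiles), "absent")
})
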