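# The bundled multi-genome fixture and its full pipeline run, computed once
# and shared across test files (helpers are sourced a single time per run).
paper_fx <- build_paper_fixture(seed = 101L)
paper_cmp <- compare_loci(paper_fx$loci)
paper_ests <- generate_ests(paper_fx, seed = 101L)
paper_expr <- score_expression(paper_cmp, paper_ests)
paper_calls <- call_pseudogenes(paper_cmp, paper_fx$loci)
paper_census <- pseudogene_census(paper_calls, paper_cmp$profiles)
summary_of <- function(tag, col) {
  s <- paper_cmp$summary
  s[[col]][match(tag, s$genome_tag)]
}
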