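test_that("compute_tpm normalizes length-corrected rates to one million", {
  expect_equal(compute_tpm(c(10, 10), c(1000, 500)),
               c(1e6 / 3, 2e6 / 3))
  expect_equal(compute_tpm(5, 200), 1e6)
  expect_warning(z <- compute_tpm(c(0, 0), c(100, 100)), "all-zero")
  expect_equal(z, c(0, 0))
  expect_error(compute_tpm(c(1, 2), c(0, 10)), "lengths")
})

ref_for_codes <- function() {
  make_ann(list(
    tx_model("r1.1", "rg1", "+", c(1001, 1601), c(1400, 2200),
             bt = "protein_coding"),
    tx_model("r2.1", "rg2", "-", c(10001, 10901), c(10400, 11500),
             bt = "protein_coding")))
}

test_that("class codes follow the u/x/i semantics", {
  ref <- ref_for_codes()
  cand <- make_ann(list(
    tx_model("far", "cg1", "+", 50001, 50500),          # no gene nearby
    tx_model("anti", "cg2", "-", 1101, 1700),           # exon overlap, - vs +
    tx_model("intr", "cg3", "+", 10451, 10850),         # inside rg2 intron
    tx_model("same", "cg4", "+", 1201, 1900)))          # same-strand overlap
  cc <- class_codes(cand, ref)
  codes <- setNames(cc$class_code, cc$transcript_id)
  expect_identical(unname(codes[c("far", "anti", "intr", "same")]),
                   c("u", "x", "i", "other"))
  expect_identical(cc$evidence[cc$transcript_id == "anti"], "rg1")
  expect_identical(cc$evidence[cc$transcript_id == "intr"], "rg2")
})

test_that("class codes agree with a brute-force overlap oracle", {
  # oracle: direct coordinate arithmetic against every reference transcript
  oracle_code <- function(s, e, strand, ref_models) {
    same_ex <- FALSE; opp_ex <- FALSE; span_ov <- FALSE; in_intron <- FALSE
    for (m in ref_models) {
      g_s <- min(m$starts); g_e <- max(m$ends)
      if (s <= g_e && e >= g_s) span_ov <- TRUE
      ex_ov <- any(m$starts <= e & m$ends >= s)
      if (ex_ov && m$strand == strand) same_ex <- TRUE
      if (ex_ov && m$strand != strand) opp_ex <- TRUE
      if (length(m$starts) > 1) {
        for (k in seq_len(length(m$starts) - 1)) {
          i_s <- m$ends[k] + 1; i_e <- m$starts[k + 1] - 1
          if (s >= i_s && e <= i_e) in_intron <- TRUE
        }
      }
    }
    if (opp_ex && !same_ex) return("x")
    if (!same_ex && !opp_ex && in_intron) return("i")
    if (!span_ov) return("u")
    "other"
  }
  ref_models <- list(
    list(starts = c(1001, 1601), ends = c(1400, 2200), strand = "+"),
    list(starts = c(10001, 10901), ends = c(10400, 11500), strand = "-"))
  ref <- ref_for_codes()
  set.seed(301)
  for (i in 1:400) {
    s <- sample(1:13000, 1)
    len <- sample(50:900, 1)
    strand <- sample(c("+", "-"), 1)
    cand <- make_ann(list(tx_model("q", "qg", strand, s, s + len - 1)))
    got <- class_codes(cand, ref)$class_code
    expect_identical(got, oracle_code(s, s + len - 1, strand, ref_models),
                     label = sprintf("placement %d:%d %s", s, s + len - 1,
                                     strand))
  }
})

test_that("coding potential flags long ORFs and spares random sequences", {
  # 400-codon ORF covering ~90% of the transcript
  set.seed(77)
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  nonstop <- setdiff(codons, stops)
  orf <- paste0("ATG", paste(sample(nonstop, 399, TRUE), collapse = ""),
                "TAA")
  seq <- paste0(random_dna(60), orf, random_dna(60))
  res <- coding_potential_score(seq)
  expect_true(res$is_coding)
  expect_gte(res$orf_codons, 100L)

  # no start codon at all
  no_atg <- gsub("A", "C", random_dna(300))
  res2 <- coding_potential_score(no_atg)
  expect_false(res2$is_coding)
  expect_identical(res2$score, -Inf)

  # random uniform 300-nt sequences are almost never called coding
  ncalled <- sum(vapply(1:100, function(i)
    coding_potential_score(random_dna(300))$is_coding, logical(1)))
  expect_lte(ncalled, 1L)
})

test_that("identification cascade reproduces the engineered fixture exactly", {
  fx <- load_filter_fixture()
  res <- run_identification(fx$candidates, fx$reference, fx$expr,
                            fx$sequences)
  expect_equal(unname(res$report$n_removed_by), c(3L, 4L, 2L, 2L, 1L))
  expect_equal(length(res$lncrna_ids), 8L)
  expect_equal(res$report$n_input,
               length(res$lncrna_ids) + sum(res$report$n_removed_by))
  # annotated lncRNA matches are retained, coding matches dropped
  expect_true(all(c("C04", "C05") %in% res$lncrna_ids))
  expect_false(any(c("C01", "C02", "C03") %in% res$lncrna_ids))
})

test_that("boundary rules: <150 nt is short, TPMmax < 1 is low abundance", {
  fx <- load_filter_fixture()
  res <- run_identification(fx$candidates, fx$reference, fx$expr,
                            fx$sequences)
  fate <- setNames(res$table$fate, res$table$transcript_id)
  expect_identical(unname(fate["C10"]), "short")       # 149 nt
  expect_identical(unname(fate["C12"]), "low_abundance")
  expect_identical(unname(fate["C14"]), "coding_potential")
})

test_that("a transcript failing several rules is attributed to the first", {
  # short AND zero-abundance AND novel class u -> reported as short
  ref <- ref_for_codes()
  cand <- make_ann(list(
    tx_model("both", "bg", "+", 50001, 50100),
    tx_model("keep", "kg", "+", 60001, 60500)))
  cnt <- matrix(c(0L, 0L, 50L, 50L), 2, 2, byrow = TRUE,
                dimnames = list(c("both", "keep"), c("d4_r1", "d30_r1")))
  expr <- make_expr(cnt, cand)
  seqs <- setNames(c(random_dna(100), random_dna(500)), c("both", "keep"))
  res <- run_identification(cand, ref, expr, seqs)
  fate <- setNames(res$table$fate, res$table$transcript_id)
  expect_identical(unname(fate["both"]), "short")
  expect_identical(unname(fate["keep"]), "retained_novel")
})

test_that("missing sequences or expression rows are reported by name", {
  ref <- ref_for_codes()
  cand <- make_ann(list(tx_model("t1", "g1", "+", 50001, 50500)))
  cnt <- matrix(10L, 1, 2, dimnames = list("t1", c("d4_r1", "d30_r1")))
  expr <- make_expr(cnt, cand)
  expect_error(run_identification(cand, ref, expr, character(0)), "t1")
})
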