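coding_ref <- function() {
  make_ann(list(
    tx_model("h1.1", "hg1", "+", c(5001, 5601), c(5400, 6200),
             bt = "protein_coding"),
    tx_model("h2.1", "hg2", "-", c(20001, 20901), c(20400, 21500),
             bt = "protein_coding")))
}

test_that("genomic location: antisense, intronic, intergenic and flags", {
  ref <- coding_ref()
  lncs <- make_ann(list(
    tx_model("anti", "l1", "-", 5101, 5700),     # overlaps hg1 exon on -
    tx_model("intr", "l2", "+", 20451, 20850),   # inside hg2 intron
    tx_model("far", "l3", "+", 50001, 50800),    # 5 kb from everything
    tx_model("div", "l4", "-", 4301, 4700),      # TSS 4700, 300 bp from hg1
    tx_model("conv", "l5", "-", 6500, 6900)))    # TES 6500, 300 bp from hg1
  loc <- classify_genomic_location(lncs$transcripts$transcript_id, lncs, ref)
  got <- setNames(loc$location, loc$transcript_id)
  expect_identical(unname(got[c("anti", "intr", "far")]),
                   c("antisense", "intronic", "intergenic"))
  expect_true(loc$divergent[loc$transcript_id == "div"])
  expect_false(loc$convergent[loc$transcript_id == "div"])
  expect_true(loc$convergent[loc$transcript_id == "conv"])
  expect_false(loc$divergent[loc$transcript_id == "conv"])
  expect_false(loc$divergent[loc$transcript_id == "far"])
})

test_that("location agrees with a brute-force geometric oracle", {
  ref <- coding_ref()
  genes <- list(list(s = 5001, e = 6200, strand = "+"),
                list(s = 20001, e = 21500, strand = "-"))
  exons <- list(list(starts = c(5001, 5601), ends = c(5400, 6200),
                     strand = "+"),
                list(starts = c(20001, 20901), ends = c(20400, 21500),
                     strand = "-"))
  introns <- list(c(5401, 5600), c(20401, 20900))
  oracle <- function(s, e, strand) {
    anti <- FALSE; intr <- FALSE; div <- FALSE; conv <- FALSE
    for (k in seq_along(genes)) {
      g <- genes[[k]]; ex <- exons[[k]]
      ex_ov <- any(ex$starts <= e & ex$ends >= s)
      if (ex_ov && g$strand != strand) anti <- TRUE
      if (s >= introns[[k]][1] && e <= introns[[k]][2] && !ex_ov)
        intr <- TRUE
      ov <- g$s <= e && g$e >= s
      if (!ov && g$strand != strand) {
        g_tss <- if (g$strand == "+") g$s else g$e
        g_tes <- if (g$strand == "+") g$e else g$s
        l_tss <- if (strand == "+") s else e
        l_tes <- if (strand == "+") e else s
        h2h <- if (strand == "+") g_tss < l_tss else g_tss > l_tss
        if (h2h && abs(g_tss - l_tss) <= 1000) div <- TRUE
        t2t <- if (strand == "+") g_tes > l_tes else g_tes < l_tes
        if (t2t && abs(g_tes - l_tes) <= 1000) conv <- TRUE
      }
    }
    primary <- if (anti) "antisense" else if (intr) "intronic"
               else "intergenic"
    list(primary = primary, div = div, conv = conv)
  }
  set.seed(302)
  for (i in 1:400) {
    s <- sample(3000:23000, 1)
    len <- sample(100:900, 1)
    strand <- sample(c("+", "-"), 1)
    lncs <- make_ann(list(tx_model("q", "ql", strand, s, s + len - 1)))
    loc <- classify_genomic_location("q", lncs, ref)
    want <- oracle(s, s + len - 1, strand)
    expect_identical(loc$location, want$primary,
                     label = sprintf("primary at %d-%d %s", s, s + len - 1,
                                     strand))
    expect_identical(loc$divergent, want$div,
                     label = sprintf("div flag at %d-%d %s", s, s + len - 1,
                                     strand))
    expect_identical(loc$convergent, want$conv,
                     label = sprintf("conv flag at %d-%d %s", s, s + len - 1,
                                     strand))
  }
})

test_that("sORF enumeration respects the 10-aa boundary and 5'-most starts", {
  nonstop9 <- paste(rep("GCA", 9), collapse = "")
  one <- paste0("ATG", nonstop9, "TAA")         # 33 nt, 10 aa
  expect_equal(nchar(one), 33L)
  calls <- enumerate_sorfs(one)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$peptide_aa, 10L)
  expect_equal(calls$start, 1L)
  expect_equal(calls$stop, 33L)

  below <- paste0("ATG", paste(rep("GCA", 8), collapse = ""), "TAA") # 9 aa
  expect_equal(nrow(enumerate_sorfs(below)), 0L)

  # two in-frame ATGs sharing one stop: only the 5'-most is reported
  two <- paste0("ATG", "GCA", "ATG", paste(rep("GCA", 9), collapse = ""),
                "TAA")
  calls2 <- enumerate_sorfs(two)
  expect_equal(nrow(calls2), 1L)
  expect_equal(calls2$start, 1L)
})

test_that("sORF enumeration matches a brute-force codon walk", {
  brute <- function(seq) {
    n <- nchar(seq)
    out <- list()
    for (frame in 0:2) {
      pos <- 1 + frame
      cods <- character(0); idx <- integer(0)
      while (pos + 2 <= n) {
        cods <- c(cods, substr(seq, pos, pos + 2))
        idx <- c(idx, pos)
        pos <- pos + 3
      }
      last_stop <- 0
      for (ci in seq_along(cods)) {
        if (cods[ci] %in% c("TAA", "TAG", "TGA")) {
          starts <- which(cods == "ATG")
          starts <- starts[starts > last_stop & starts < ci]
          if (length(starts)) {
            s <- starts[1]
            if (ci - s >= 10)
              out[[length(out) + 1]] <- c(idx[s], idx[ci] + 2, ci - s)
          }
          last_stop <- ci
        }
      }
    }
    if (!length(out)) return(data.frame(start = integer(),
                                        stop = integer(),
                                        peptide_aa = integer()))
    m <- do.call(rbind, out)
    d <- data.frame(start = m[, 1], stop = m[, 2], peptide_aa = m[, 3])
    d[order(d$start, d$stop), , drop = FALSE]
  }
  set.seed(303)
  for (i in 1:100) {
    s <- random_dna(500)
    got <- enumerate_sorfs(s)
    want <- brute(s)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, label = paste("sequence", i))
  }
})

test_that("RRS contrasts ORF and downstream footprint densities", {
  cov <- rep(2, 200)
  expect_equal(compute_rrs(31, 90, cov), 0.5)          # uniform -> 0.5
  cov2 <- c(rep(0.5, 30), rep(9, 57), rep(0, 3), rep(1, 110))
  expect_equal(compute_rrs(31, 90, cov2), 0.9)         # 9 / (9 + 1)
  cov3 <- c(rep(0, 30), rep(4, 60), rep(0, 110))
  expect_equal(compute_rrs(31, 90, cov3), 1.0)
  expect_equal(compute_rrs(31, 90, rep(0, 200)), 0)    # 0/0 -> 0
})

test_that("RRS is invariant under uniform coverage scaling", {
  set.seed(304)
  cov <- rpois(300, 3) + runif(300)
  base <- compute_rrs(61, 150, cov)
  for (c in c(0.1, 2, 117)) {
    expect_equal(compute_rrs(61, 150, c * cov), base)
  }
})

test_that("sRNA precursor calls need depth and 21-22-nt dominance", {
  mk <- function(v) setNames(v, 18:26)
  x <- rep(0, 9); x[4:5] <- 40                       # 80 of 100 at 21-22
  x[c(1, 2, 3, 6, 7)] <- 4
  expect_true(detect_srna_precursor(mk(x)))
  u <- rep(100 / 9, 9)                               # uniform: 2/9 < 0.5
  expect_false(detect_srna_precursor(mk(u)))
  few <- rep(0, 9); few[4] <- 5                      # below min_reads
  expect_false(detect_srna_precursor(mk(few)))
})

test_that("functional classification is non-exclusive and gated correctly", {
  nonstop <- paste(rep("GCC", 18), collapse = "")
  seq <- paste0(random_dna(99), "TAAATG", nonstop, "TAA", random_dna(138))
  L <- nchar(seq)
  cov <- rep(0.1, L)
  cov[103:(103 + 53)] <- 12                          # ORF body hot
  srna_hot <- setNames(c(0, 0, 0, 40, 40, 0, 0, 0, 0), 18:26)
  srna_cold <- setNames(rep(1, 9), 18:26)
  res <- classify_functional(
    c("both", "plain"),
    ribo = list(both = cov, plain = rep(0, L)),
    srna = list(both = srna_hot, plain = srna_cold),
    sequences = c(both = seq, plain = random_dna(L)))
  both <- res[res$transcript_id == "both", ]
  expect_true(both$ribo_lncRNA)
  expect_true(both$sorf)
  expect_gte(both$best_rrs, 0.9)
  expect_true(both$srna_precursor)
  expect_false(both$canonical)
  plain <- res[res$transcript_id == "plain", ]
  expect_false(plain$ribo_lncRNA)
  expect_true(plain$canonical)
})

test_that("feature summaries use exact rank-sum tests on small sets", {
  ann <- make_ann(c(
    lapply(1:3, function(i) tx_model(paste0("l", i), paste0("lg", i), "+",
                                     10000 * i, 10000 * i + c(100, 200,
                                                              300)[i] - 1)),
    lapply(1:3, function(i) tx_model(paste0("c", i), paste0("cg", i), "+",
                                     100000 + 10000 * i,
                                     100000 + 10000 * i +
                                       c(400, 500, 600)[i] - 1,
                                     bt = "protein_coding"))))
  cnt <- matrix(10L, 6, 4, dimnames = list(
    c(paste0("l", 1:3), paste0("c", 1:3)),
    c("d4_r1", "d4_r2", "d30_r1", "d30_r2")))
  expr <- make_expr(cnt, ann)
  res <- summarize_features(ann, paste0("l", 1:3), paste0("c", 1:3), expr)
  lt <- res$tests[res$tests$feature == "length", ]
  expect_equal(lt$U, 0)
  expect_equal(lt$p, 0.1)      # 2 / C(6,3)
  self <- summarize_features(ann, paste0("l", 1:3), paste0("l", 1:3), expr)
  expect_true(all(self$tests$p == 1))
  expect_error(summarize_features(ann, character(0), paste0("c", 1:3), expr),
               "empty")
})
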