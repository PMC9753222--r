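test_that("config validation catches impossible designs", {
  expect_error(sim_config(duplex_segment_len = 14L), "15 nt")
  expect_error(sim_config(timepoints = c(4, 4, 8)), "increasing")
  expect_error(sim_config(n_coding_genes = 10L), "not enough single")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("annotation generation is deterministic and labels are planted", {
  cfg <- sim_config(seed = 7,
                    n_lncrnas_per_category = c(intergenic = 5L,
                                               antisense = 5L,
                                               intronic = 5L,
                                               divergent = 5L,
                                               convergent = 5L))
  sim1 <- simulate_annotation(cfg)
  sim2 <- simulate_annotation(cfg)
  p1 <- tempfile(); p2 <- tempfile()
  write_gtf(sim1$annotation, p1)
  write_gtf(sim2$annotation, p2)
  expect_identical(readLines(p1), readLines(p2))     # byte-identical

  # the classifier recovers 100% of planted location categories
  loc <- classify_genomic_location(sim1$truth$lnc$transcript_id,
                                   sim1$annotation, sim1$reference)
  expect_identical(location_label(loc), sim1$truth$lnc$category)

  # novel lncRNAs carry XLOC_ identifiers
  novel <- sim1$truth$lnc$transcript_id[!sim1$truth$lnc$annotated]
  expect_true(all(grepl("^XLOC_", novel)))
})

test_that("a config without lncRNAs yields coding genes only", {
  cfg <- sim_config(seed = 3,
                    n_lncrnas_per_category = c(intergenic = 0L,
                                               antisense = 0L,
                                               intronic = 0L,
                                               divergent = 0L,
                                               convergent = 0L),
                    n_planted_sorf = 0L, n_planted_srna = 0L, n_dual = 0L,
                    n_planted_cerna_triplets = 0L,
                    n_planted_duplex_pairs = 0L)
  sim <- simulate_annotation(cfg)
  expect_equal(nrow(sim$truth$lnc), 0L)
  expect_true(all(sim$annotation$transcripts$biotype == "protein_coding"))
})

test_that("counts approach their means in the small-dispersion limit", {
  cfg <- sim_config(seed = 5, dispersion = 1e-8, libsize_sd = 0,
                    baseline_log_sd = 0, baseline_log_mean = log(5e4),
                    ar_frac_lnc = 0, ar_frac_coding = 0,
                    n_planted_cerna_triplets = 0L,
                    n_planted_duplex_pairs = 0L)
  sim <- simulate_annotation(cfg)
  sim <- simulate_sequences(sim, cfg)
  sim <- simulate_expression(sim, cfg)
  flat_ids <- names(sim$truth$archetype)[sim$truth$archetype == "flat"]
  cnt <- sim$expr$counts[flat_ids, ]
  rel_dev <- abs(cnt - 5e4) / 5e4
  expect_lt(mean(rel_dev), 0.01)                    # Poisson-degenerate
})

test_that("planted temporal signals have the right direction and coupling", {
  cfg <- sim_config(seed = 11)
  base <- simulate_annotation(cfg)
  base <- simulate_sequences(base, cfg)
  n_up_ok <- 0L; n_pcc_ok <- 0L; n <- 60L
  u1 <- names(base$truth$archetype)[base$truth$archetype == "U1"][1]
  pair1 <- base$truth$pairs[1, ]
  for (s in seq_len(n)) {
    cfg2 <- cfg; cfg2$seed <- 20000L + s
    sim <- simulate_expression(base, cfg2)
    prof <- mean_tpm_profiles(sim$expr)
    lfc <- log2((prof[u1, ncol(prof)] + 0.5) / (prof[u1, 1] + 0.5))
    if (lfc > 0) n_up_ok <- n_up_ok + 1L
    pcc <- pearson_cc(prof[pair1$lncRNA_id, ], prof[pair1$mRNA_id, ])
    if (pcc >= 0.9) n_pcc_ok <- n_pcc_ok + 1L
  }
  expect_gte(n_up_ok / n, 0.95)
  expect_gte(n_pcc_ok / n, 0.95)
})

test_that("footprint and sRNA layers encode the planted functional labels", {
  bundle <- default_bundle()
  truth <- bundle$truth
  # every planted sORF reaches RRS >= 0.9 on its own profile
  for (i in seq_len(nrow(truth$sorf))) {
    id <- truth$sorf$transcript_id[i]
    rrs <- compute_rrs(truth$sorf$start[i], truth$sorf$stop[i],
                       bundle$ribo[[id]])
    expect_gte(rrs, 0.9)
  }
  # uniform-coverage transcripts sit near 0.5
  plain <- setdiff(truth$lnc$transcript_id, truth$sorf$transcript_id)[1]
  L <- length(bundle$ribo[[plain]])
  flat_cov <- rep(2, L)
  sorfs <- enumerate_sorfs(as.character(bundle$sequences[[plain]]))
  sorfs <- sorfs[sorfs$stop + 10 <= L, , drop = FALSE]
  if (nrow(sorfs))
    expect_equal(compute_rrs(sorfs$start[1], sorfs$stop[1], flat_cov), 0.5)
  # planted sRNA precursors are detected, others are not
  for (i in seq_len(nrow(truth$lnc))) {
    id <- truth$lnc$transcript_id[i]
    got <- detect_srna_precursor(
      setNames(as.numeric(bundle$srna[id, ]), colnames(bundle$srna)))
    expect_identical(got, truth$lnc$srna[i], label = id)
  }
})

test_that("planted duplex segments are reverse complements with GC >= 0.5", {
  bundle <- default_bundle()
  dup <- bundle$truth$pairs[bundle$truth$pairs$kind == "duplex", ]
  for (i in seq_len(nrow(dup))) {
    lseq <- as.character(bundle$sequences[[dup$lncRNA_id[i]]])
    mseq <- as.character(bundle$sequences[[dup$mRNA_id[i]]])
    seg <- substr(lseq, dup$lnc_start[i] + 1, dup$lnc_end[i])
    mseg <- substr(mseq, dup$mrna_start[i] + 1, dup$mrna_end[i])
    expect_identical(mseg, reverse_complement(seg))
    gc <- mean(strsplit(seg, "")[[1]] %in% c("G", "C"))
    expect_gte(gc, 0.5)
    # energy bound: 20 nt at GC fraction >= 0.5 is at most -33 kcal/mol
    hits <- scan_pair(lseq, mseq)
    expect_lte(min(hits$energy), -33)
  }
})

test_that("target tables make planted junctions hypergeometrically significant", {
  bundle <- default_bundle()
  targets <- bundle$targets
  N <- length(unique(targets$mirna_id))
  by_t <- split(targets$mirna_id, targets$target_id)
  cer <- bundle$truth$pairs[bundle$truth$pairs$kind == "cerna", ]
  for (i in seq_len(nrow(cer))) {
    mi_l <- by_t[[cer$lncRNA_id[i]]]
    mi_m <- by_t[[cer$mRNA_id[i]]]
    k <- length(intersect(mi_l, mi_m))
    p <- hypergeom_pvalue(N, length(mi_m), length(mi_l), k)
    expect_lt(p, 0.05)
  }
  # determinism of the full study under a fixed seed
  s1 <- simulate_target_tables(simulate_annotation(sim_config(seed = 2)),
                               sim_config(seed = 2))
  s2 <- simulate_target_tables(simulate_annotation(sim_config(seed = 2)),
                               sim_config(seed = 2))
  expect_identical(s1$targets, s2$targets)
})

test_that("bundles round-trip through disk", {
  bundle <- default_bundle()
  dir <- file.path(tempdir(), "bundle_rt")
  write_bundle(bundle, dir)
  back <- load_bundle(dir)
  expect_equal(sort(back$annotation$transcripts$transcript_id),
               sort(bundle$annotation$transcripts$transcript_id))
  expect_equal(back$expr$counts[rownames(bundle$expr$counts), ],
               bundle$expr$counts)
  expect_equal(back$ribo[["foo"]], NULL)
  id1 <- bundle$truth$lnc$transcript_id[1]
  expect_equal(back$ribo[[id1]], bundle$ribo[[id1]])
  expect_identical(as.character(back$sequences[[id1]]),
                   as.character(bundle$sequences[[id1]]))
})
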