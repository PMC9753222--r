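#' Configuration of the synthetic study generator
#'
#' Defaults emulate the study design the pipeline targets: a 4-30 d leaf-age
#' time course sampled every 2 d with 2 replicates, negative-binomial counts
#' with shared dispersion 0.1, six temporal archetypes (three up, three
#' down), lncRNAs planted in every genomic-location category, translated
#' sORFs, 21-22-nt sRNA precursors, ceRNA triplets and complementary
#' sequence pairs.
#'
#' @param seed integer RNG seed; a fixed seed makes every generated artifact
#'   byte-identical.
#' @param n_coding_genes number of protein-coding genes.
#' @param n_lncrnas_per_category named counts for categories `intergenic`,
#'   `antisense`, `intronic`, `divergent`, `convergent`.
#' @param n_app_pairs,n_dpp_pairs,n_cpp_pairs planted coding-gene pair
#'   geometries (overlapping antisense, divergent, convergent).
#' @param frac_annotated_lncrna fraction of lncRNAs present in the reference
#'   annotation (the rest are novel `XLOC_` transcripts).
#' @param timepoints days after emergence.
#' @param replicates biological replicates per timepoint.
#' @param dispersion shared negative-binomial dispersion.
#' @param amplitude terminal `|log2FC|` of the non-flat archetypes.
#' @param ar_frac_lnc,ar_frac_coding fraction of lncRNAs / coding genes
#'   assigned a non-flat archetype.
#' @param baseline_log_mean,baseline_log_sd log-normal baseline mean counts.
#' @param libsize_sd log-normal sd of per-sample library size factors.
#' @param n_mirnas miRNA universe size.
#' @param targets_per_transcript background miRNA targets per transcript.
#' @param n_planted_cerna_triplets planted ceRNA triplets.
#' @param junction_size shared junction miRNAs per planted triplet.
#' @param n_planted_duplex_pairs planted complementary lncRNA-mRNA pairs.
#' @param duplex_segment_len planted complementary segment length (>= 15 nt).
#' @param n_planted_sorf lncRNAs carrying a translated sORF.
#' @param n_planted_srna lncRNAs acting as 21-22-nt sRNA precursors (the
#'   first `n_dual` of them also carry a translated sORF).
#' @param n_dual lncRNAs carrying both the sORF and sRNA-precursor labels.
#' @param sorf_orf_nt planted ORF length including the stop codon.
#' @param coupling_dispersion residual NB dispersion of the mRNA partner in
#'   planted ceRNA/duplex pairs, which tracks the realized profile of its
#'   lncRNA (the co-regulation the downstream screens look for).
#' @param nuclear_frac fraction of lncRNAs with nuclear-biased localization.
#' @param stress_conditions names of simulated stress-response sets.
#' @param stress_set_size lncRNAs per stress set.
#' @param stress_ar_frac fraction of each stress set drawn from planted
#'   (non-flat) lncRNAs.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_coding_genes = 120L,
                       n_lncrnas_per_category = c(intergenic = 8L,
                                                  antisense = 8L,
                                                  intronic = 8L,
                                                  divergent = 8L,
                                                  convergent = 8L),
                       n_app_pairs = 6L, n_dpp_pairs = 6L, n_cpp_pairs = 6L,
                       frac_annotated_lncrna = 0.5,
                       timepoints = seq(4L, 30L, 2L),
                       replicates = 2L,
                       dispersion = 0.1,
                       amplitude = 3,
                       ar_frac_lnc = 0.7,
                       ar_frac_coding = 0.4,
                       baseline_log_mean = log(150),
                       baseline_log_sd = 1,
                       libsize_sd = 0.15,
                       n_mirnas = 80L,
                       targets_per_transcript = 5L,
                       n_planted_cerna_triplets = 8L,
                       junction_size = 4L,
                       n_planted_duplex_pairs = 8L,
                       duplex_segment_len = 20L,
                       n_planted_sorf = 6L,
                       n_planted_srna = 6L,
                       n_dual = 2L,
                       sorf_orf_nt = 60L,
                       coupling_dispersion = 0.01,
                       nuclear_frac = 0.7,
                       stress_conditions = c("ABA", "drought", "cold"),
                       stress_set_size = 30L,
                       stress_ar_frac = 0.6) {
  cfg <- as.list(environment())
  cats <- c("intergenic", "antisense", "intronic", "divergent", "convergent")
  if (!all(cats %in% names(n_lncrnas_per_category)))
    stop_lncage("sim_config: n_lncrnas_per_category needs counts for ",
                paste(cats, collapse = ", "))
  counts <- unlist(cfg[grep("^n_", names(cfg))])
  if (any(counts < 0)) stop_lncage("sim_config: counts must be >= 0")
  if (any(diff(timepoints) <= 0))
    stop_lncage("sim_config: timepoints must be strictly increasing")
  if (duplex_segment_len < 15L)
    stop_lncage("sim_config: duplex_segment_len below the reportable ",
                "duplex length (15 nt)")
  if (replicates < 1L) stop_lncage("sim_config: replicates must be >= 1")
  n_singles <- n_coding_genes - 2L * (n_app_pairs + n_dpp_pairs + n_cpp_pairs)
  n_hosts <- sum(n_lncrnas_per_category[c("antisense", "intronic",
                                          "divergent", "convergent")])
  if (n_singles < n_hosts)
    stop_lncage("sim_config: not enough single coding genes (", n_singles,
                ") to host ", n_hosts, " gene-proximal lncRNAs")
  structure(cfg, class = "sim_config")
}

# the six temporal archetypes: piecewise-linear log2FC trajectories relative
# to the first timepoint (early / mid / late ramps, up and mirrored down)
archetype_log2fc <- function(archetype, timepoints, amplitude) {
  ramp <- function(t0, t1) pmin(pmax((timepoints - t0) / (t1 - t0), 0), 1)
  switch(archetype,
         U1 = amplitude * ramp(4, 12),
         U2 = amplitude * ramp(12, 20),
         U3 = amplitude * ramp(20, 30),
         D1 = -amplitude * ramp(4, 12),
         D2 = -amplitude * ramp(12, 20),
         D3 = -amplitude * ramp(20, 30),
         flat = rep(0, length(timepoints)),
         stop_lncage("unknown archetype ", archetype))
}

random_seq <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Simulate the genome annotation with planted location categories
#'
#' Lays out gene "blocks" along two chromosomes with at least 3 kb between
#' blocks, so that no unintended neighbor falls within the classification
#' window: overlapping / divergent / convergent coding-gene pairs, single
#' coding genes (some hosting a gene-proximal lncRNA), and isolated
#' intergenic lncRNAs. Every lncRNA is placed to satisfy exactly its
#' intended category under [classify_genomic_location()]; the placement is
#' verified and redrawn when violated.
#'
#' @param config [sim_config()].
#' @return list with `annotation` (all transcripts), `reference` (coding
#'   genes + annotated lncRNAs), `truth` (see Details).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  for (attempt in 1:5) {
    out <- with_seed(config$seed + 1000L * attempt,
                     simulate_annotation_once(config))
    if (!nrow(out$truth$lnc)) return(out)
    loc <- classify_genomic_location(out$truth$lnc$transcript_id,
                                     out$annotation, out$reference)
    want <- out$truth$lnc$category
    got <- ifelse(loc$location != "intergenic", loc$location,
                  ifelse(loc$divergent & loc$convergent,
                         "divergent_convergent",
                         ifelse(loc$divergent, "divergent",
                                ifelse(loc$convergent, "convergent",
                                       "intergenic"))))
    if (all(got == want)) return(out)
  }
  stop_lncage("simulate_annotation: could not realize all planted location",
              " categories; use longer gene spacing or fewer lncRNAs")
}

simulate_annotation_once <- function(config) {
  cfg <- config
  blocks <- list()
  nlc <- cfg$n_lncrnas_per_category
  add <- function(type, n) {
    if (n > 0) for (i in seq_len(n)) blocks[[length(blocks) + 1L]] <<- type
  }
  add("app", cfg$n_app_pairs)
  add("dpp", cfg$n_dpp_pairs)
  add("cpp", cfg$n_cpp_pairs)
  n_singles <- cfg$n_coding_genes -
    2L * (cfg$n_app_pairs + cfg$n_dpp_pairs + cfg$n_cpp_pairs)
  host_types <- c(rep("antisense", nlc[["antisense"]]),
                  rep("intronic", nlc[["intronic"]]),
                  rep("divergent", nlc[["divergent"]]),
                  rep("convergent", nlc[["convergent"]]),
                  rep("single", n_singles - sum(nlc[c("antisense",
                      "intronic", "divergent", "convergent")])))
  for (h in host_types) blocks[[length(blocks) + 1L]] <- paste0("host_", h)
  add("lnc_intergenic", nlc[["intergenic"]])
  blocks <- sample(unlist(blocks))

  tx_rows <- list(); ex_rows <- list(); lnc_rows <- list()
  gene_i <- 0L; lnc_i <- 0L; novel_i <- 0L; annot_i <- 0L
  n_lnc_total <- sum(nlc)
  annotated_flags <- sample(rep(c(TRUE, FALSE),
    c(round(cfg$frac_annotated_lncrna * n_lnc_total),
      n_lnc_total - round(cfg$frac_annotated_lncrna * n_lnc_total))))

  emit_tx <- function(gene_id, tx_id, chrom, strand, exon_starts,
                      exon_ends, biotype) {
    tx_rows[[length(tx_rows) + 1L]] <<- data.frame(
      transcript_id = tx_id, gene_id = gene_id, chrom = chrom,
      strand = strand, biotype = biotype, stringsAsFactors = FALSE)
    ex_rows[[length(ex_rows) + 1L]] <<- data.frame(
      chrom = chrom, start = exon_starts, end = exon_ends,
      transcript_id = tx_id, stringsAsFactors = FALSE)
  }

  # returns list(start, end, tss, tes) of the emitted gene
  emit_coding <- function(chrom, pos, strand, long_intron = FALSE,
                          second_isoform = FALSE) {
    gene_i <<- gene_i + 1L
    gid <- sprintf("G%04d", gene_i)
    n_ex <- if (long_intron) 3L else sample(2:5, 1L)
    ex_len <- sample(150:400, n_ex, replace = TRUE)
    int_len <- if (long_intron) c(900L, sample(100:250, 1L))
               else sample(100:250, max(n_ex - 1L, 0L), replace = TRUE)
    starts <- integer(n_ex); ends <- integer(n_ex)
    p <- pos
    for (e in seq_len(n_ex)) {
      starts[e] <- p; ends[e] <- p + ex_len[e] - 1L
      p <- ends[e] + 1L + if (e < n_ex) int_len[e] else 0L
    }
    emit_tx(gid, paste0(gid, ".1"), chrom, strand, starts, ends,
            "protein_coding")
    if (second_isoform && n_ex >= 3L)
      emit_tx(gid, paste0(gid, ".2"), chrom, strand, starts[-2L], ends[-2L],
              "protein_coding")
    list(gene_id = gid, start = starts[1L], end = ends[n_ex],
         exon1 = c(starts[1L], ends[1L]),
         intron1 = if (n_ex >= 2L) c(ends[1L] + 1L, starts[2L] - 1L)
                   else NULL)
  }

  emit_lnc <- function(chrom, start, strand, len, category, host_gene,
                       n_exons = 1L) {
    lnc_i <<- lnc_i + 1L
    annotated <- annotated_flags[lnc_i]
    if (annotated) {
      annot_i <<- annot_i + 1L
      tid <- sprintf("ATLNC%04d", annot_i)
      bt <- "annotated_noncoding"
    } else {
      novel_i <<- novel_i + 1L
      tid <- sprintf("XLOC_%05d", novel_i)
      bt <- "novel"
    }
    gid <- sprintf("LG%04d", lnc_i)
    if (n_exons == 2L && len >= 300L) {
      e1 <- floor(len * 0.4); gap <- 120L
      starts <- c(start, start + e1 + gap)
      ends <- c(start + e1 - 1L, start + len + gap - 1L)
    } else {
      starts <- start; ends <- start + len - 1L
    }
    emit_tx(gid, tid, chrom, strand, starts, ends, bt)
    lnc_rows[[length(lnc_rows) + 1L]] <<- data.frame(
      transcript_id = tid, gene_id = gid, category = category,
      annotated = annotated, host_gene = host_gene %||% NA_character_,
      stringsAsFactors = FALSE)
    tid
  }

  chroms <- c("chr1", "chr2")
  cursor <- c(chr1 = 10000L, chr2 = 10000L)
  half <- ceiling(length(blocks) / 2)
  for (bi in seq_along(blocks)) {
    chrom <- chroms[[if (bi <= half) 1L else 2L]]
    pos <- cursor[[chrom]]
    type <- blocks[[bi]]
    flip <- sample(c("+", "-"), 1L)
    other <- setdiff(c("+", "-"), flip)
    block_end <- pos
    if (type == "app") {
      a <- emit_coding(chrom, pos, flip)
      ov_start <- a$start + sample(100:300, 1L)
      b <- emit_coding(chrom, ov_start, other)
      block_end <- max(a$end, b$end)
    } else if (type == "dpp") {
      # head-to-head: left gene transcribed away (TSS at its right end)
      a <- emit_coding(chrom, pos, "-")
      gap <- sample(200:800, 1L)
      b <- emit_coding(chrom, a$end + gap, "+")
      block_end <- b$end
    } else if (type == "cpp") {
      # tail-to-tail: left gene on +, right gene on -
      a <- emit_coding(chrom, pos, "+")
      gap <- sample(200:800, 1L)
      b <- emit_coding(chrom, a$end + gap, "-")
      block_end <- b$end
    } else if (type == "host_single") {
      a <- emit_coding(chrom, pos, flip,
                       second_isoform = runif(1) < 0.15)
      block_end <- a$end
    } else if (type == "host_antisense") {
      a <- emit_coding(chrom, pos, flip)
      len <- sample(300:700, 1L)
      lstart <- a$exon1[1L] + sample(20:80, 1L)
      emit_lnc(chrom, lstart, other, len, "antisense", a$gene_id)
      block_end <- max(a$end, lstart + len + 150L)
    } else if (type == "host_intronic") {
      a <- emit_coding(chrom, pos, flip, long_intron = TRUE)
      len <- sample(250:500, 1L)
      margin <- a$intron1[2L] - a$intron1[1L] + 1L - len
      lstart <- a$intron1[1L] + sample(20:max(21L, margin - 20L), 1L)
      emit_lnc(chrom, lstart, sample(c("+", "-"), 1L), len, "intronic",
               a$gene_id)
      block_end <- a$end
    } else if (type == "host_divergent") {
      # lncRNA head-to-head upstream of the host TSS
      len <- sample(300:700, 1L)
      gap <- sample(100:900, 1L)
      if (flip == "+") {
        lstart <- pos
        a <- emit_coding(chrom, lstart + len + gap, "+")
        emit_lnc(chrom, lstart, "-", len, "divergent", a$gene_id)
        block_end <- a$end
      } else {
        a <- emit_coding(chrom, pos, "-")
        lstart <- a$end + gap
        emit_lnc(chrom, lstart, "+", len, "divergent", a$gene_id)
        block_end <- lstart + len
      }
    } else if (type == "host_convergent") {
      # lncRNA tail-to-tail downstream of the host TES
      len <- sample(300:700, 1L)
      gap <- sample(100:900, 1L)
      if (flip == "+") {
        a <- emit_coding(chrom, pos, "+")
        lstart <- a$end + gap
        emit_lnc(chrom, lstart, "-", len, "convergent", a$gene_id)
        block_end <- lstart + len
      } else {
        lstart <- pos
        a <- emit_coding(chrom, lstart + len + gap, "-")
        emit_lnc(chrom, lstart, "+", len, "convergent", a$gene_id)
        block_end <- a$end
      }
    } else if (type == "lnc_intergenic") {
      len <- sample(300:1200, 1L)
      emit_lnc(chrom, pos, flip, len, "intergenic", NULL,
               n_exons = sample(c(1L, 2L), 1L, prob = c(.8, .2)))
      block_end <- pos + len + 150L
    }
    cursor[[chrom]] <- block_end + sample(3000:6000, 1L)
  }

  tx <- do.call(rbind, tx_rows)
  exdf <- do.call(rbind, ex_rows)
  chrom_lengths <- cursor + 10000L
  gr <- GRanges(exdf$chrom, IRanges(exdf$start, exdf$end))
  mcols(gr)$transcript_id <- exdf$transcript_id
  ann <- genome_annotation(tx, gr, chrom_lengths)
  ref_ids <- tx$transcript_id[tx$biotype %in%
                                c("protein_coding", "annotated_noncoding")]
  reference <- subset_annotation(ann, ref_ids)

  lnc <- if (length(lnc_rows)) do.call(rbind, lnc_rows) else
    data.frame(transcript_id = character(), gene_id = character(),
               category = character(), annotated = logical(),
               host_gene = character(), stringsAsFactors = FALSE)
  truth <- build_truth(ann, lnc, cfg)
  list(annotation = ann, reference = reference, truth = truth)
}

# assigns archetypes, functional labels, planted pairs and localization;
# called inside the seeded annotation draw
build_truth <- function(ann, lnc, cfg) {
  tx <- ann$transcripts
  arch_pool <- c("U1", "U2", "U3", "D1", "D2", "D3")

  # archetypes: cycle through the six shapes for the AR fraction
  assign_arch <- function(ids, frac) {
    n_ar <- round(frac * length(ids))
    ar_ids <- sample(ids, n_ar)
    a <- setNames(rep("flat", length(ids)), ids)
    a[ar_ids] <- rep(arch_pool, length.out = n_ar)
    a
  }
  lnc_arch <- assign_arch(lnc$transcript_id, cfg$ar_frac_lnc)
  coding_ids <- tx$transcript_id[tx$biotype == "protein_coding"]
  coding_arch <- assign_arch(coding_ids, cfg$ar_frac_coding)

  # antisense lncRNAs are co-expressed with their host gene: the host
  # inherits the lncRNA's archetype (the cis-regulation the neighbor
  # co-expression analysis is designed to detect)
  anti <- lnc[lnc$category == "antisense", , drop = FALSE]
  for (i in seq_len(nrow(anti))) {
    a <- lnc_arch[[anti$transcript_id[i]]]
    if (a == "flat") next
    host_tx <- tx$transcript_id[tx$gene_id == anti$host_gene[i]]
    coding_arch[host_tx[host_tx %in% names(coding_arch)]] <- a
  }

  # functional labels
  lnc$sorf <- logical(nrow(lnc)); lnc$srna <- logical(nrow(lnc))
  eligible <- lnc$transcript_id[
    transcript_lengths(ann)[lnc$transcript_id] >= cfg$sorf_orf_nt + 160L]
  n_sorf <- min(cfg$n_planted_sorf, length(eligible))
  sorf_ids <- sample(eligible, n_sorf)
  lnc$sorf[lnc$transcript_id %in% sorf_ids] <- TRUE
  dual_ids <- head(sorf_ids, cfg$n_dual)
  rest <- setdiff(lnc$transcript_id, sorf_ids)
  srna_ids <- c(dual_ids,
                sample(rest, min(max(0L, cfg$n_planted_srna -
                                       length(dual_ids)), length(rest))))
  lnc$srna[lnc$transcript_id %in% srna_ids] <- TRUE

  # planted ceRNA and duplex pairs: AR lncRNAs coupled to single-host coding
  # transcripts sharing their archetype
  lnc_ar <- lnc$transcript_id[lnc_arch[lnc$transcript_id] != "flat"]
  host_used <- unique(lnc$host_gene[!is.na(lnc$host_gene)])
  free_coding <- setdiff(coding_ids,
                         tx$transcript_id[tx$gene_id %in% host_used])
  free_coding <- free_coding[!duplicated(tx$gene_id[
    match(free_coding, tx$transcript_id)])]
  n_pairs <- cfg$n_planted_cerna_triplets + cfg$n_planted_duplex_pairs
  lnc_pick <- sample(lnc_ar, min(n_pairs, length(lnc_ar)))
  mrna_pick <- sample(free_coding, length(lnc_pick))
  kind <- rep(c("cerna", "duplex"),
              c(cfg$n_planted_cerna_triplets,
                cfg$n_planted_duplex_pairs))[seq_along(lnc_pick)]
  pairs <- data.frame(kind = kind, lncRNA_id = lnc_pick, mRNA_id = mrna_pick,
                      stringsAsFactors = FALSE)

  # localization: two-component mixture of log-ratios
  nuc <- runif(nrow(lnc)) < cfg$nuclear_frac
  lnc$loc_logratio <- ifelse(nuc, rnorm(nrow(lnc), 1.5, 0.5),
                             rnorm(nrow(lnc), -1.5, 0.5))
  lnc$localization <- ifelse(lnc$loc_logratio > 0, "nuclear", "cytosolic")

  archetype <- c(lnc_arch, coding_arch)
  other <- setdiff(tx$transcript_id, names(archetype))
  archetype[other] <- "flat"

  list(lnc = lnc, archetype = archetype, pairs = pairs,
       sorf = data.frame(transcript_id = sorf_ids,
                         start = rep(NA_integer_, length(sorf_ids)),
                         stop = rep(NA_integer_, length(sorf_ids)),
                         stringsAsFactors = FALSE))
}

#' Simulate transcript sequences with planted sORFs and duplex segments
#'
#' Background sequences are i.i.d. uniform nucleotides. sORF-planted lncRNAs
#' receive an in-frame `ATG`..`TAA` open reading frame (preceded by an
#' in-frame stop so the planted ORF is the one enumerated); planted duplex
#' pairs receive an exact reverse-complementary segment of the configured
#' length with GC fraction at least 0.5.
#'
#' @param sim output of [simulate_annotation()].
#' @param config [sim_config()].
#' @return `sim` with `sequences` (`DNAStringSet`) added and the truth tables
#'   updated with planted coordinates.
#' @export
simulate_sequences <- function(sim, config) {
  with_seed(config$seed + 7001L, {
    lens <- transcript_lengths(sim$annotation)
    seqs <- vapply(lens, random_seq, character(1))

    # sORFs: TAA | ATG | non-stop codons | TAA, centred in the transcript
    stops <- c("TAA", "TAG", "TGA")
    codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                c("A","C","G","T")), 1, paste, collapse = "")
    nonstop <- setdiff(codons, stops)
    for (i in seq_len(nrow(sim$truth$sorf))) {
      id <- sim$truth$sorf$transcript_id[i]
      L <- lens[[id]]
      orf_nt <- config$sorf_orf_nt
      inner <- paste(sample(nonstop, orf_nt / 3L - 2L, replace = TRUE),
                     collapse = "")
      cassette <- paste0("TAA", "ATG", inner, "TAA")
      at <- max(1L, floor((L - nchar(cassette)) / 2))
      s <- seqs[[id]]
      seqs[[id]] <- paste0(substr(s, 1, at - 1), cassette,
                           substr(s, at + nchar(cassette), L))
      sim$truth$sorf$start[i] <- at + 3L          # the ATG
      sim$truth$sorf$stop[i] <- at + 3L + orf_nt - 1L
    }

    # duplex segments: GC-rich exact reverse complements
    dup <- sim$truth$pairs$kind == "duplex"
    nNA <- rep(NA_integer_, nrow(sim$truth$pairs))
    sim$truth$pairs$lnc_start <- nNA
    sim$truth$pairs$lnc_end <- nNA
    sim$truth$pairs$mrna_start <- nNA
    sim$truth$pairs$mrna_end <- nNA
    for (i in which(dup)) {
      ln <- sim$truth$pairs$lncRNA_id[i]
      mr <- sim$truth$pairs$mRNA_id[i]
      k <- config$duplex_segment_len
      seg <- random_seq(k, c(A = .2, C = .3, G = .3, T = .2))
      while (mean(strsplit(seg, "")[[1]] %in% c("G", "C")) < 0.5)
        seg <- random_seq(k, c(A = .2, C = .3, G = .3, T = .2))
      place <- function(seq, insert) {
        at <- sample(seq_len(nchar(seq) - nchar(insert) + 1L), 1L)
        list(seq = paste0(substr(seq, 1, at - 1), insert,
                          substr(seq, at + nchar(insert), nchar(seq))),
             start0 = at - 1L, end0 = at - 1L + nchar(insert))
      }
      pl <- place(seqs[[ln]], seg)
      seqs[[ln]] <- pl$seq
      pm <- place(seqs[[mr]], reverse_complement(seg))
      seqs[[mr]] <- pm$seq
      sim$truth$pairs$lnc_start[i] <- pl$start0
      sim$truth$pairs$lnc_end[i] <- pl$end0
      sim$truth$pairs$mrna_start[i] <- pm$start0
      sim$truth$pairs$mrna_end[i] <- pm$end0
    }
    sim$sequences <- DNAStringSet(seqs)
    sim
  })
}

#' Simulate the time-course count matrix
#'
#' Counts are negative binomial with mean
#' `baseline x 2^(archetype log2FC at t) x library size` and shared
#' dispersion. The mRNA member of every planted ceRNA/duplex pair instead
#' tracks the realized replicate-mean profile of its lncRNA with a small
#' residual dispersion, emulating the co-regulation (miRNA sharing, RNA
#' stabilization) that the downstream screens detect.
#'
#' @param sim output of [simulate_annotation()] (sequences not required).
#' @param config [sim_config()].
#' @return `sim` with `expr` (`lnc_expression`), `fractions` and
#'   `stress_sets` added.
#' @export
simulate_expression <- function(sim, config) {
  with_seed(config$seed + 7002L, {
    tx <- sim$annotation$transcripts
    ids <- tx$transcript_id
    tp <- config$timepoints
    nrep <- config$replicates
    samples <- paste0("d", rep(tp, each = nrep), "_r",
                      rep(seq_len(nrep), length(tp)))
    libsize <- rlnorm(length(samples), 0, config$libsize_sd)
    size <- 1 / config$dispersion

    baseline <- setNames(rlnorm(length(ids), config$baseline_log_mean,
                                config$baseline_log_sd), ids)
    planted <- unique(unlist(sim$truth$pairs[, c("lncRNA_id", "mRNA_id")]))
    baseline[planted] <- pmax(baseline[planted], 150)

    counts <- matrix(0L, length(ids), length(samples),
                     dimnames = list(ids, samples))
    day_of <- rep(tp, each = nrep)
    coupled <- setNames(sim$truth$pairs$lncRNA_id, sim$truth$pairs$mRNA_id)
    free_ids <- setdiff(ids, names(coupled))
    for (id in free_ids) {
      lfc <- archetype_log2fc(sim$truth$archetype[[id]], tp,
                              config$amplitude)
      mu <- baseline[[id]] * 2^lfc[match(day_of, tp)] * libsize
      counts[id, ] <- rnbinom(length(mu), mu = mu, size = size)
    }
    for (id in names(coupled)) {
      src <- counts[coupled[[id]], ] / libsize
      src_day <- vapply(tp, function(d) mean(src[day_of == d]), numeric(1))
      mu <- pmax(src_day[match(day_of, tp)], 0.5) *
        (baseline[[id]] / baseline[[coupled[[id]]]]) * libsize
      counts[id, ] <- rnbinom(length(mu), mu = mu,
                              size = 1 / config$coupling_dispersion)
    }
    sim$expr <- expression_matrix(counts, sim$annotation)

    # nuclear/cytosolic fractions for the lncRNAs
    base_tpm <- rowMeans(sim$expr$tpm)[sim$truth$lnc$transcript_id]
    lr <- sim$truth$lnc$loc_logratio
    sim$fractions <- data.frame(
      transcript_id = sim$truth$lnc$transcript_id,
      nuclear_tpm = base_tpm * 2^(lr / 2),
      cytosolic_tpm = base_tpm * 2^(-lr / 2),
      stringsAsFactors = FALSE)

    # stress-responsive sets partially overlapping the planted AR set
    lnc_ids <- sim$truth$lnc$transcript_id
    is_ar <- sim$truth$archetype[lnc_ids] != "flat"
    sim$stress_sets <- lapply(
      setNames(nm = config$stress_conditions), function(cond) {
        n_ar <- round(config$stress_ar_frac * config$stress_set_size)
        n_ar <- min(n_ar, sum(is_ar))
        n_fl <- min(config$stress_set_size - n_ar, sum(!is_ar))
        c(sample(lnc_ids[is_ar], n_ar), sample(lnc_ids[!is_ar], n_fl))
      })
    sim
  })
}

#' Simulate ribosome-footprint and small-RNA coverage
#'
#' Translated sORFs receive footprint density inside the ORF far above the
#' density downstream of the stop codon; other lncRNAs receive uniform low
#' coverage. sRNA-precursor lncRNAs receive 80% of their small-RNA reads at
#' lengths 21-22 nt; others get sparse length-uniform noise.
#'
#' @param sim output of [simulate_sequences()].
#' @param config [sim_config()].
#' @return `sim` with `ribo` (named list of coverage vectors) and `srna`
#'   (matrix transcript x read length 18-26) added.
#' @export
simulate_ribo_and_srna <- function(sim, config) {
  with_seed(config$seed + 7003L, {
    lens <- transcript_lengths(sim$annotation)
    lnc <- sim$truth$lnc
    ribo <- list()
    for (i in seq_len(nrow(lnc))) {
      id <- lnc$transcript_id[i]
      L <- lens[[id]]
      cov <- rpois(L, 0.05)
      if (lnc$sorf[i]) {
        cov <- rpois(L, 0.2)
        srow <- sim$truth$sorf[sim$truth$sorf$transcript_id == id, ]
        cov[srow$start:(srow$stop - 3L)] <- rpois(srow$stop - 2L - srow$start,
                                                  12)
      }
      ribo[[id]] <- cov
    }
    lengths <- 18:26
    srna <- matrix(0L, nrow(lnc), length(lengths),
                   dimnames = list(lnc$transcript_id, lengths))
    for (i in seq_len(nrow(lnc))) {
      if (lnc$srna[i]) {
        main <- c(40L, 40L)
        restn <- 20L
        row <- rep(0L, length(lengths))
        row[lengths %in% c(21L, 22L)] <- main
        row[!(lengths %in% c(21L, 22L))] <-
          as.integer(stats::rmultinom(1, restn, rep(1, 7))[, 1])
        srna[i, ] <- row
      } else {
        srna[i, ] <- as.integer(stats::rmultinom(
          1, rpois(1, 8), rep(1, length(lengths)))[, 1])
      }
    }
    sim$ribo <- ribo
    sim$srna <- srna
    sim
  })
}

#' Simulate miRNA-target interaction tables with planted ceRNA triplets
#'
#' Every participating transcript receives `targets_per_transcript`
#' background miRNAs drawn uniformly from the universe (so background
#' sharing follows the hypergeometric null by construction); planted ceRNA
#' triplets add `junction_size` shared miRNAs to both members.
#'
#' @param sim output of [simulate_annotation()] (or later stage).
#' @param config [sim_config()].
#' @return `sim` with `targets` (data.frame `mirna_id`, `target_id`,
#'   `target_class`) added; planted junctions recorded in
#'   `sim$truth$pairs$junction`.
#' @export
simulate_target_tables <- function(sim, config) {
  with_seed(config$seed + 7004L, {
    universe <- sprintf("miR%03d", seq_len(config$n_mirnas))
    tx <- sim$annotation$transcripts
    lnc_ids <- sim$truth$lnc$transcript_id
    cerna <- sim$truth$pairs[sim$truth$pairs$kind == "cerna", , drop = FALSE]
    coding_ids <- tx$transcript_id[tx$biotype == "protein_coding"]
    mrna_ids <- unique(c(cerna$mRNA_id,
                         sample(coding_ids,
                                min(60L, length(coding_ids)))))
    edges <- list()
    tgt <- function(id, cls, mirnas) {
      edges[[length(edges) + 1L]] <<- data.frame(
        mirna_id = mirnas, target_id = id, target_class = cls,
        stringsAsFactors = FALSE)
    }
    for (id in lnc_ids)
      tgt(id, "lncRNA", sample(universe, config$targets_per_transcript))
    for (id in mrna_ids)
      tgt(id, "mRNA", sample(universe, config$targets_per_transcript))
    targets <- unique(do.call(rbind, edges))

    sim$truth$pairs$junction <- NA_character_
    for (i in seq_len(nrow(sim$truth$pairs))) {
      if (sim$truth$pairs$kind[i] != "cerna") next
      junction <- sample(universe, config$junction_size)
      add <- rbind(
        data.frame(mirna_id = junction,
                   target_id = sim$truth$pairs$lncRNA_id[i],
                   target_class = "lncRNA", stringsAsFactors = FALSE),
        data.frame(mirna_id = junction,
                   target_id = sim$truth$pairs$mRNA_id[i],
                   target_class = "mRNA", stringsAsFactors = FALSE))
      targets <- unique(rbind(targets, add))
      sim$truth$pairs$junction[i] <- paste(sort(junction), collapse = ",")
    }
    sim$targets <- targets
    sim
  })
}

#' Generate the complete synthetic study
#'
#' Runs all generators in order (annotation, sequences, expression,
#' footprints and sRNA coverage, target tables). Fixed seed implies
#' byte-identical outputs.
#'
#' @param config [sim_config()].
#' @return list with `annotation`, `reference`, `truth`, `sequences`,
#'   `expr`, `fractions`, `stress_sets`, `ribo`, `srna`, `targets`,
#'   `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  sim <- simulate_annotation(config)
  sim <- simulate_sequences(sim, config)
  sim <- simulate_expression(sim, config)
  sim <- simulate_ribo_and_srna(sim, config)
  sim <- simulate_target_tables(sim, config)
  sim$config <- config
  sim
}

#' Write a synthetic study as a fixture bundle
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gtf(sim$annotation, p("annotation.gtf"))
  write_gtf(sim$reference, p("reference.gtf"))
  writeXStringSet(sim$sequences, p("transcripts.fa"), width = 70L)
  counts <- data.frame(transcript_id = rownames(sim$expr$counts),
                       sim$expr$counts, check.names = FALSE)
  write_table(counts, p("counts.tsv"))
  ribo <- data.frame(
    transcript_id = rep(names(sim$ribo), lengths(sim$ribo)),
    pos = unlist(lapply(sim$ribo, seq_along), use.names = FALSE),
    depth = unlist(sim$ribo, use.names = FALSE))
  write_table(ribo, p("ribo.tsv"))
  srna <- data.frame(transcript_id = rownames(sim$srna), sim$srna,
                     check.names = FALSE)
  write_table(srna, p("srna.tsv"))
  write_table(sim$targets, p("targets.tsv"))
  write_table(sim$fractions, p("fractions.tsv"))
  stress <- do.call(rbind, lapply(names(sim$stress_sets), function(cond)
    data.frame(condition = cond, transcript_id = sim$stress_sets[[cond]],
               stringsAsFactors = FALSE)))
  write_table(stress, p("stress_sets.tsv"))
  truth <- sim$truth$lnc
  truth$archetype <- sim$truth$archetype[truth$transcript_id]
  write_table(truth, p("truth.tsv"))
  write_table(sim$truth$pairs, p("truth_pairs.tsv"))
  invisible(list.files(dir, full.names = TRUE))
}
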