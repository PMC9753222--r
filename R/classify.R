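#' Classify lncRNAs by genomic location
#'
#' Primary category: `antisense` when at least 1 bp of exonic overlap with a
#' protein-coding gene on the opposite strand exists; `intronic` when the
#' transcript lies entirely within a single intron of a coding isoform with
#' no exon overlap; otherwise `intergenic`. Two non-exclusive flags are added:
#' `divergent` when a coding TSS on the opposite strand lies within `window`
#' bp of the lncRNA TSS in head-to-head orientation without overlap, and
#' `convergent` when the 3' ends are within `window` bp tail-to-tail.
#'
#' @param lncrna_ids transcript ids to classify (must be in `ann`).
#' @param ann `lnc_annotation` holding the lncRNA models.
#' @param reference `lnc_annotation` containing protein-coding gene models.
#' @param window neighborhood window in bp (default 1000).
#' @return data.frame `transcript_id`, `location` (primary), `divergent`,
#'   `convergent` (logical flags).
#' @export
classify_genomic_location <- function(lncrna_ids, ann, reference,
                                      window = 1000L) {
  sub <- subset_annotation(ann, lncrna_ids)
  sp <- transcript_spans(sub)
  sp <- sp[match(lncrna_ids, mcols(sp)$transcript_id)]

  rtx <- reference$transcripts
  coding_tx <- rtx$transcript_id[rtx$biotype == "protein_coding"]
  rex <- reference$exons
  rex <- rex[mcols(rex)$transcript_id %in% coding_tx]
  rstr <- rtx$strand[match(mcols(rex)$transcript_id, rtx$transcript_id)]
  rex_str <- GRanges(seqnames(rex), ranges(rex), strand = rstr)
  mcols(rex_str)$gene_id <-
    rtx$gene_id[match(mcols(rex)$transcript_id, rtx$transcript_id)]

  cex <- sub$exons
  cstr <- sub$transcripts$strand[match(mcols(cex)$transcript_id,
                                       sub$transcripts$transcript_id)]
  cex_str <- GRanges(seqnames(cex), ranges(cex), strand = cstr)
  mcols(cex_str)$transcript_id <- mcols(cex)$transcript_id

  hits <- findOverlaps(cex_str, rex_str, ignore.strand = TRUE)
  opp <- as.character(strand(cex_str))[queryHits(hits)] !=
    as.character(strand(rex_str))[subjectHits(hits)]
  tx_antisense <- unique(mcols(cex_str)$transcript_id[queryHits(hits)[opp]])
  tx_exonic <- unique(mcols(cex_str)$transcript_id[queryHits(hits)])

  cod_ref <- subset_annotation(reference, coding_tx)
  introns <- transcript_introns(cod_ref)
  within_i <- findOverlaps(sp, introns, type = "within", ignore.strand = TRUE)
  tx_intronic <- unique(mcols(sp)$transcript_id[queryHits(within_i)])

  location <- rep("intergenic", length(lncrna_ids))
  location[lncrna_ids %in% tx_intronic &
             !(lncrna_ids %in% tx_exonic)] <- "intronic"
  location[lncrna_ids %in% tx_antisense] <- "antisense"

  # flags from gene-level coding spans
  gsp <- gene_spans(reference, biotype = "protein_coding")
  gplus <- as.character(strand(gsp)) == "+"
  g_tss <- ifelse(gplus, start(gsp), end(gsp))
  g_tes <- ifelse(gplus, end(gsp), start(gsp))
  l_plus <- as.character(strand(sp)) == "+"
  l_tss <- ifelse(l_plus, start(sp), end(sp))
  l_tes <- ifelse(l_plus, end(sp), start(sp))

  divergent <- logical(length(lncrna_ids))
  convergent <- logical(length(lncrna_ids))
  for (i in seq_along(lncrna_ids)) {
    same_chr <- as.character(seqnames(gsp)) ==
      as.character(seqnames(sp))[i]
    oppstr <- gplus != l_plus[i]
    no_ov <- !(start(gsp) <= end(sp)[i] & end(gsp) >= start(sp)[i])
    cand <- same_chr & oppstr & no_ov
    if (!any(cand)) next
    # head-to-head: TSSs face each other, gene lies on the 5' side of the lnc
    d_tss <- abs(g_tss - l_tss[i])
    head2head <- if (l_plus[i]) g_tss[cand] < l_tss[i] & !gplus[cand]
                 else g_tss[cand] > l_tss[i] & gplus[cand]
    divergent[i] <- any(head2head & d_tss[cand] <= window)
    # tail-to-tail: TESs face each other, gene lies on the 3' side of the lnc
    d_tes <- abs(g_tes - l_tes[i])
    tail2tail <- if (l_plus[i]) g_tes[cand] > l_tes[i] & !gplus[cand]
                 else g_tes[cand] < l_tes[i] & gplus[cand]
    convergent[i] <- any(tail2tail & d_tes[cand] <= window)
  }
  data.frame(transcript_id = lncrna_ids, location = location,
             divergent = divergent, convergent = convergent,
             stringsAsFactors = FALSE)
}

#' Enumerate small open reading frames
#'
#' Scans the three forward frames of the (transcript-stranded) sequence for
#' `ATG`..stop spans with a coding span of at least `3 * (min_aa + 1) - 3`
#' nt, i.e. peptides of at least `min_aa` amino acids. For several in-frame
#' ATGs sharing a stop, only the 5'-most (longest ORF) is reported.
#'
#' @param sequence nucleotide string.
#' @param min_aa minimum peptide length (amino acids), default 10.
#' @return data.frame `start`, `stop` (1-based; `stop` = last base of the stop
#'   codon), `peptide_aa`.
#' @export
enumerate_sorfs <- function(sequence, min_aa = 10L) {
  seq <- chartr("U", "T", toupper(sequence))
  n <- nchar(seq)
  out <- list()
  if (n >= 6L) {
    chars <- strsplit(seq, "")[[1L]]
    for (frame in 0:2) {
      idx <- seq.int(1L + frame, n, by = 3L)
      idx <- idx[idx + 2L <= n]
      if (length(idx) < 2L) next
      codons <- paste0(chars[idx], chars[idx + 1L], chars[idx + 2L])
      stops <- which(codons %in% c("TAA", "TAG", "TGA"))
      starts <- which(codons == "ATG")
      prev_stop <- 0L
      for (st in stops) {
        cand <- starts[starts > prev_stop & starts < st]
        prev_stop <- st
        if (!length(cand)) next
        s <- cand[[1L]]                    # 5'-most ATG for this stop
        aa <- st - s                       # codons from ATG up to the stop
        if (aa < min_aa) next
        out[[length(out) + 1L]] <- data.frame(
          start = idx[[s]], stop = idx[[st]] + 2L, peptide_aa = aa)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), stop = integer(),
                      peptide_aa = integer()))
  res <- do.call(rbind, out)
  res[order(res$start, res$stop), , drop = FALSE]
}

#' Ribosome release score of an sORF
#'
#' `rrs = d_orf / (d_orf + d_down)` where `d_orf` is the mean footprint
#' coverage over the coding span (start up to, excluding, the stop codon) and
#' `d_down` the mean coverage over the `downstream_window` nt after the stop
#' codon (shrunk to what remains of the transcript, minimum 10 nt). A
#' coverage-free transcript (0/0) yields 0. Values near 1 indicate ribosome
#' release at the stop codon, i.e. genuine translation.
#'
#' @param start,stop 1-based sORF coordinates on the transcript (as returned
#'   by [enumerate_sorfs()]; `stop` = last base of the stop codon).
#' @param coverage per-nucleotide footprint depth along the transcript.
#' @param downstream_window nt downstream of the stop codon, default 100.
#' @return RRS in `[0, 1]`.
#' @export
compute_rrs <- function(start, stop, coverage, downstream_window = 100L) {
  n <- length(coverage)
  stopifnot(start >= 1L, stop <= n, start < stop)
  orf_end <- stop - 3L                      # exclude the stop codon
  d_orf <- mean(coverage[start:orf_end])
  down_from <- stop + 1L
  down_to <- min(n, stop + downstream_window)
  if (down_to - down_from + 1L < 10L)
    stop_lncage("compute_rrs: fewer than 10 nt downstream of the stop codon")
  d_down <- mean(coverage[down_from:down_to])
  if (d_orf + d_down == 0) return(0)
  d_orf / (d_orf + d_down)
}

#' Detect small-RNA precursor lncRNAs
#'
#' A transcript is called an sRNA precursor when its total small-RNA read
#' count reaches `min_reads` and at least `min_frac` of those reads have
#' lengths of 21-22 nt.
#'
#' @param length_counts named numeric vector of read counts per read length
#'   (names "18".."26", or any subset).
#' @param min_reads minimum total reads, default 20.
#' @param min_frac minimum 21-22-nt fraction, default 0.5.
#' @return logical flag.
#' @export
detect_srna_precursor <- function(length_counts, min_reads = 20,
                                  min_frac = 0.5) {
  total <- sum(length_counts)
  if (total < min_reads) return(FALSE)
  frac2122 <- sum(length_counts[names(length_counts) %in% c("21", "22")]) /
    total
  frac2122 >= min_frac
}

#' Functional classification of lncRNAs
#'
#' Assigns non-exclusive functional labels from the orthogonal evidence
#' layers: `ribo_lncRNA` when mean footprint coverage reaches `ribo_min`
#' reads/nt (with `sorf = TRUE` when some sORF attains `rrs >= rrs_min`),
#' `srna_precursor` per [detect_srna_precursor()], and `canonical` when
#' neither label applies. A transcript may carry both the ribo and sRNA
#' labels.
#'
#' @param ids transcript ids to classify.
#' @param ribo named list of per-nucleotide coverage vectors.
#' @param srna named list (or matrix rows) of per-read-length count vectors.
#' @param sequences named character vector of transcript sequences.
#' @param ribo_min mean-coverage gate for ribo-lncRNAs (reads/nt), default 1.
#' @param rrs_min RRS gate for translated sORFs, default 0.9.
#' @param min_aa minimum sORF peptide length, default 10.
#' @return data.frame `transcript_id`, `ribo_lncRNA`, `sorf`, `best_rrs`,
#'   `srna_precursor`, `canonical`.
#' @export
classify_functional <- function(ids, ribo, srna, sequences,
                                ribo_min = 1, rrs_min = 0.9, min_aa = 10L) {
  res <- lapply(ids, function(id) {
    cov <- ribo[[id]]
    is_ribo <- !is.null(cov) && mean(cov) >= ribo_min
    best_rrs <- NA_real_
    has_sorf <- FALSE
    if (is_ribo) {
      sorfs <- enumerate_sorfs(sequences[[id]], min_aa = min_aa)
      rrs <- rep(NA_real_, nrow(sorfs))
      for (j in seq_len(nrow(sorfs))) {
        if (sorfs$stop[j] + 10L <= length(cov))
          rrs[j] <- compute_rrs(sorfs$start[j], sorfs$stop[j], cov)
      }
      if (any(!is.na(rrs))) best_rrs <- max(rrs, na.rm = TRUE)
      has_sorf <- !is.na(best_rrs) && best_rrs >= rrs_min
    }
    is_srna <- !is.null(srna[[id]]) && detect_srna_precursor(srna[[id]])
    data.frame(transcript_id = id, ribo_lncRNA = is_ribo, sorf = has_sorf,
               best_rrs = best_rrs, srna_precursor = is_srna,
               canonical = !is_ribo && !is_srna, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Compare structural and expression features of two transcript sets
#'
#' Summarizes spliced length, exons per transcript, isoforms per gene and
#' mean TPM for a lncRNA set and a coding set, with a two-tailed
#' Mann-Whitney U test per feature (exact when both sets have at most 20
#' members, normal approximation with tie correction otherwise).
#'
#' @param ann `lnc_annotation` holding both sets.
#' @param lnc_ids,coding_ids transcript id vectors (both non-empty).
#' @param expr `lnc_expression`.
#' @return list with `summary` (per set x feature medians/means) and
#'   `tests` (feature, U, p).
#' @export
summarize_features <- function(ann, lnc_ids, coding_ids, expr) {
  if (!length(lnc_ids) || !length(coding_ids))
    stop_lncage("summarize_features: empty transcript set")
  feat <- function(ids) {
    tx <- ann$transcripts[match(ids, ann$transcripts$transcript_id), ]
    exn <- table(mcols(ann$exons)$transcript_id)[ids]
    iso <- table(ann$transcripts$gene_id)[tx$gene_id]
    mtpm <- rowMeans(expr$tpm[ids, , drop = FALSE])
    list(length = as.numeric(tx$length), exons = as.numeric(exn),
         isoforms = as.numeric(iso), mean_tpm = as.numeric(mtpm))
  }
  a <- feat(lnc_ids); b <- feat(coding_ids)
  features <- names(a)
  summary <- do.call(rbind, lapply(features, function(f) {
    data.frame(feature = f,
               lnc_median = median(a[[f]]), lnc_mean = mean(a[[f]]),
               coding_median = median(b[[f]]), coding_mean = mean(b[[f]]))
  }))
  tests <- do.call(rbind, lapply(features, function(f) {
    mw <- mann_whitney(a[[f]], b[[f]])
    data.frame(feature = f, U = mw$U, p = mw$p)
  }))
  list(summary = summary, tests = tests)
}

# two-tailed Mann-Whitney U; exact when both n <= 20 and no ties
mann_whitney <- function(x, y, exact_max = 20L) {
  exact <- length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = !exact))
  p <- wt$p.value
  if (is.na(p)) p <- 1        # fully tied groups carry no evidence
  list(U = unname(wt$statistic), p = min(1, p))
}
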