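#' Transcripts-per-million from raw counts
#'
#' `tpm_t = (count_t / length_t) / sum_s(count_s / length_s) * 1e6`. An
#' all-zero sample yields all-zero TPM with a warning rather than an error.
#'
#' @param counts nonnegative counts for one sample.
#' @param lengths effective transcript lengths (bp), same order.
#' @return TPM vector summing to 1e6 (or all zeros).
#' @export
compute_tpm <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths))
  if (any(lengths < 1)) stop_lncage("compute_tpm: lengths must be >= 1")
  if (any(counts < 0)) stop_lncage("compute_tpm: negative count")
  rate <- counts / lengths
  tot <- sum(rate)
  if (tot == 0) {
    warning("compute_tpm: all-zero sample; TPM set to zero")
    return(rep(0, length(counts)))
  }
  rate / tot * 1e6
}

#' Assign class codes to candidate transcripts
#'
#' Reproduces the class-code semantics used to select novel lncRNA
#' candidates: `u` for transcripts with no overlap with any reference gene
#' span (intergenic), `x` for exonic overlap with a reference transcript on
#' the opposite strand, `i` for transcripts entirely contained within an
#' intron of a reference isoform (either strand), and `other` for everything
#' else (notably same-strand exonic overlap, a candidate for known-transcript
#' matching).
#'
#' @param candidates `lnc_annotation` (or a single transcript id within it).
#' @param reference `lnc_annotation` of reference gene models.
#' @return data.frame with `transcript_id`, `class_code`, `evidence`
#'   (reference gene id for `x`/`i`, `NA` for `u`).
#' @export
class_codes <- function(candidates, reference) {
  sp <- transcript_spans(candidates)
  rex <- reference$exons
  rtx <- reference$transcripts
  rex_str <- GRanges(seqnames(rex), ranges(rex),
                     strand = rtx$strand[match(mcols(rex)$transcript_id,
                                               rtx$transcript_id)])
  mcols(rex_str)$gene_id <-
    rtx$gene_id[match(mcols(rex)$transcript_id, rtx$transcript_id)]
  cex <- candidates$exons
  ctx <- candidates$transcripts
  cex_str <- GRanges(seqnames(cex), ranges(cex),
                     strand = ctx$strand[match(mcols(cex)$transcript_id,
                                               ctx$transcript_id)])
  mcols(cex_str)$transcript_id <- mcols(cex)$transcript_id

  # exon-exon overlaps, same and opposite strand
  hits_any <- findOverlaps(cex_str, rex_str, ignore.strand = TRUE)
  same <- as.character(strand(cex_str))[queryHits(hits_any)] ==
    as.character(strand(rex_str))[subjectHits(hits_any)]
  tx_same <- unique(mcols(cex_str)$transcript_id[queryHits(hits_any)[same]])
  opp_q <- queryHits(hits_any)[!same]
  opp_s <- subjectHits(hits_any)[!same]
  tx_opp <- mcols(cex_str)$transcript_id[opp_q]
  opp_gene <- tapply(mcols(rex_str)$gene_id[opp_s], tx_opp,
                     function(g) g[[1L]])

  # intron containment: candidate span within a single reference intron,
  # with no exonic overlap at all
  introns <- transcript_introns(reference)
  tx_exonic <- unique(mcols(cex_str)$transcript_id[queryHits(hits_any)])
  within_i <- findOverlaps(sp, introns, type = "within", ignore.strand = TRUE)
  tx_intronic <- mcols(sp)$transcript_id[queryHits(within_i)]
  intron_gene <- tapply(mcols(introns)$gene_id[subjectHits(within_i)],
                        tx_intronic, function(g) g[[1L]])

  # gene-span overlap (for 'u': zero overlap with any reference gene span)
  gsp <- gene_spans(reference)
  span_hit <- overlapsAny(sp, gsp, ignore.strand = TRUE)
  tx_span <- mcols(sp)$transcript_id[span_hit]

  ids <- ctx$transcript_id
  code <- rep("other", length(ids))
  evidence <- rep(NA_character_, length(ids))
  is_x <- ids %in% names(opp_gene) & !(ids %in% tx_same)
  code[is_x] <- "x"
  evidence[is_x] <- unlist(opp_gene[ids[is_x]])
  is_i <- !is_x & !(ids %in% tx_same) & !(ids %in% tx_exonic) &
    ids %in% names(intron_gene)
  code[is_i] <- "i"
  evidence[is_i] <- unlist(intron_gene[ids[is_i]])
  is_u <- !(ids %in% tx_span)
  code[is_u] <- "u"
  evidence[is_u] <- NA_character_
  data.frame(transcript_id = ids, class_code = code, evidence = evidence,
             stringsAsFactors = FALSE)
}

#' @rdname class_codes
#' @param transcript_id single transcript id within `candidates`.
#' @export
assign_class_code <- function(candidates, reference, transcript_id) {
  cc <- class_codes(subset_annotation(candidates, transcript_id), reference)
  cc[cc$transcript_id == transcript_id, ]
}

# ---- coding potential ------------------------------------------------------

orf_scan_frames <- function(seq) {
  # longest forward-frame ORF (ATG..stop, stop included in span)
  n <- nchar(seq)
  best <- list(len = 0L, start = NA_integer_, end = NA_integer_)
  chars <- strsplit(seq, "")[[1L]]
  for (frame in 0:2) {
    idx <- seq.int(1L + frame, n - 2L, by = 3L)
    if (!length(idx) || idx[[length(idx)]] + 2L > n)
      idx <- idx[idx + 2L <= n]
    if (!length(idx)) next
    codons <- paste0(chars[idx], chars[idx + 1L], chars[idx + 2L])
    starts <- which(codons == "ATG")
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    for (s in starts) {
      st <- stops[stops > s]
      if (!length(st)) next
      e <- st[[1L]]
      len <- (e - s) * 3L            # coding span excluding the stop codon
      if (len > best$len)
        best <- list(len = len, start = idx[[s]], end = idx[[e]] + 2L)
    }
  }
  best
}

#' Train a hexamer log-odds model for coding-potential scoring
#'
#' In-frame hexamer frequencies are tabulated from a set of coding sequences
#' and contrasted (log odds, with add-one smoothing) against hexamer
#' frequencies of noncoding sequences. The packaged training fixtures are used
#' when no sequences are supplied.
#'
#' @param coding `DNAStringSet` (or character) of coding sequences.
#' @param noncoding `DNAStringSet` (or character) of noncoding sequences.
#' @return named numeric vector of 4096 hexamer log-odds.
#' @export
hexamer_model <- function(coding = NULL, noncoding = NULL) {
  if (is.null(coding)) {
    coding <- readDNAStringSet(system.file("extdata",
      "hexamer_train_coding.fa", package = "lncage"))
    noncoding <- readDNAStringSet(system.file("extdata",
      "hexamer_train_noncoding.fa", package = "lncage"))
  }
  count_hex <- function(seqs) {
    seqs <- as.character(seqs)
    tab <- integer(4096)
    kmers <- mkAllStrings_hex()
    for (s in seqs) {
      n <- nchar(s)
      if (n < 6L) next
      subs <- substring(s, 1:(n - 5L), 6:n)
      subs <- subs[!grepl("[^ACGT]", subs)]
      t2 <- table(factor(subs, levels = kmers))
      tab <- tab + as.integer(t2)
    }
    setNames(tab, kmers)
  }
  fc <- count_hex(coding)
  fn <- count_hex(noncoding)
  pc <- (fc + 1) / sum(fc + 1)
  pn <- (fn + 1) / sum(fn + 1)
  log(pc / pn)
}

mkAllStrings_hex <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- c("A", "C", "G", "T")
      g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
      cache <<- do.call(paste0, g)
    }
    cache
  }
})

.lncage_cache <- new.env(parent = emptyenv())

default_hexamer_model <- function() {
  if (is.null(.lncage_cache$hex)) .lncage_cache$hex <- hexamer_model()
  .lncage_cache$hex
}

#' Coding-potential score of a transcript sequence
#'
#' A transcript is flagged coding when its longest forward-frame ORF reaches
#' 100 codons, or when that ORF covers at least half of the transcript and its
#' mean in-frame hexamer log-odds (coding vs noncoding background) is
#' positive. Sequences without any ATG are noncoding with score `-Inf`.
#'
#' @param sequence nucleotide string (T or U alphabet).
#' @param model hexamer log-odds vector from [hexamer_model()]; the packaged
#'   model by default.
#' @param min_codons ORF-length rule threshold (codons), default 100.
#' @param min_coverage ORF-coverage rule threshold, default 0.5.
#' @return list with `score` (mean hexamer log-odds of the longest ORF),
#'   `is_coding`, `orf_start`, `orf_end` (1-based, stop codon included),
#'   `orf_codons`.
#' @export
coding_potential_score <- function(sequence, model = default_hexamer_model(),
                                   min_codons = 100L, min_coverage = 0.5) {
  stopifnot(nchar(sequence) >= 1L)
  seq <- chartr("U", "T", toupper(sequence))
  orf <- orf_scan_frames(seq)
  if (orf$len == 0L)
    return(list(score = -Inf, is_coding = FALSE, orf_start = NA_integer_,
                orf_end = NA_integer_, orf_codons = 0L))
  orf_seq <- substr(seq, orf$start, orf$end)
  n <- nchar(orf_seq)
  starts <- seq.int(1L, n - 5L, by = 3L)
  hex <- substring(orf_seq, starts, starts + 5L)
  hex <- hex[!grepl("[^ACGT]", hex)]
  score <- if (length(hex)) mean(model[hex]) else -Inf
  codons <- orf$len / 3L
  coverage <- (orf$len + 3L) / nchar(seq)
  is_coding <- codons >= min_codons || (coverage >= min_coverage && score > 0)
  list(score = score, is_coding = is_coding, orf_start = orf$start,
       orf_end = orf$end, orf_codons = as.integer(codons))
}

# ---- identification cascade ------------------------------------------------

# same strand + identical intron chain (single-exon: reciprocal overlap >= .5)
match_annotated <- function(candidates, reference) {
  csp <- transcript_spans(candidates)
  rsp <- transcript_spans(reference)
  cint <- transcript_introns(candidates)
  rint <- transcript_introns(reference)
  chain <- function(introns, ids) {
    key <- setNames(rep("", length(ids)), ids)
    if (length(introns)) {
      k <- tapply(sprintf("%s:%d-%d", as.character(seqnames(introns)),
                          start(introns), end(introns)),
                  mcols(introns)$transcript_id,
                  function(x) paste(sort(x), collapse = ";"))
      key[names(k)] <- k
    }
    key
  }
  ckey <- chain(cint, candidates$transcripts$transcript_id)
  rkey <- chain(rint, reference$transcripts$transcript_id)

  hits <- findOverlaps(csp, rsp, ignore.strand = FALSE)
  out <- setNames(rep(NA_character_, length(csp)), mcols(csp)$transcript_id)
  for (h in seq_along(hits)) {
    qi <- queryHits(hits)[h]; si <- subjectHits(hits)[h]
    cid <- mcols(csp)$transcript_id[qi]
    rid <- mcols(rsp)$transcript_id[si]
    if (!is.na(out[cid])) next
    multi_c <- nzchar(ckey[cid]); multi_r <- nzchar(rkey[rid])
    if (multi_c || multi_r) {
      if (identical(ckey[[cid]], rkey[[rid]]) && multi_c && multi_r)
        out[cid] <- rid
    } else {
      ov <- width(pintersect(ranges(csp[qi]), ranges(rsp[si])))
      if (ov >= 0.5 * width(csp[qi]) && ov >= 0.5 * width(rsp[si]))
        out[cid] <- rid
    }
  }
  out
}

#' Run the lncRNA identification cascade
#'
#' Filters candidate transcripts in a fixed order, each transcript being
#' attributed to the first rule that removes it: (1) same-strand matches to
#' annotated reference transcripts (matches to annotated noncoding transcripts
#' are retained as annotated lncRNAs; matches to coding transcripts are
#' dropped); (2) novel transcripts must have class code `u`, `x` or `i`;
#' (3) spliced length must be at least `min_length` nt; (4) maximum TPM over
#' all samples must reach `min_tpmmax`; (5) transcripts with protein-coding
#' potential are dropped.
#'
#' @param candidates `lnc_annotation` of assembled transcripts.
#' @param reference `lnc_annotation` of reference gene models.
#' @param expr `lnc_expression` covering all candidates.
#' @param sequences named character vector or `DNAStringSet` of candidate
#'   transcript sequences.
#' @param min_length minimum spliced length (nt), default 150.
#' @param min_tpmmax minimum TPMmax, default 1.
#' @param hex_model hexamer model for [coding_potential_score()].
#' @return list with `lncrna_ids` (retained, annotated + novel), `report`
#'   (the filter report), and `table` (per-transcript fate).
#' @export
run_identification <- function(candidates, reference, expr, sequences,
                               min_length = 150L, min_tpmmax = 1,
                               hex_model = default_hexamer_model()) {
  ids <- candidates$transcripts$transcript_id
  sequences <- setNames(as.character(sequences), names(sequences))
  miss_seq <- setdiff(ids, names(sequences))
  if (length(miss_seq))
    stop_lncage("run_identification: missing sequence for ", miss_seq[[1L]])
  miss_expr <- setdiff(ids, rownames(expr$counts))
  if (length(miss_expr))
    stop_lncage("run_identification: missing expression for ",
                miss_expr[[1L]])

  fate <- setNames(rep(NA_character_, length(ids)), ids)

  # rule 1: matches to annotated transcripts
  matched <- match_annotated(candidates, reference)
  ref_bt <- setNames(reference$transcripts$biotype,
                     reference$transcripts$transcript_id)
  is_match <- !is.na(matched[ids])
  match_bt <- ref_bt[matched[ids]]
  fate[is_match & match_bt == "protein_coding"] <- "annotated_known"
  annotated_lnc <- ids[is_match & match_bt != "protein_coding"]
  fate[annotated_lnc] <- "retained_annotated"

  # rule 2: class codes for the remaining (novel) transcripts
  open <- ids[is.na(fate[ids])]
  cc <- class_codes(candidates, reference)
  code <- setNames(cc$class_code, cc$transcript_id)
  fate[open[!(code[open] %in% c("u", "x", "i"))]] <- "class_code"

  # rule 3: length
  open <- ids[is.na(fate[ids])]
  lens <- transcript_lengths(candidates)
  fate[open[lens[open] < min_length]] <- "short"

  # rule 4: abundance
  open <- ids[is.na(fate[ids])]
  tpmmax <- apply(expr$tpm[open, , drop = FALSE], 1, max)
  fate[open[tpmmax < min_tpmmax]] <- "low_abundance"

  # rule 5: coding potential
  open <- ids[is.na(fate[ids])]
  coding <- vapply(open, function(id)
    coding_potential_score(sequences[[id]], hex_model)$is_coding,
    logical(1))
  fate[open[coding]] <- "coding_potential"
  fate[open[!coding]] <- "retained_novel"

  retained <- ids[fate[ids] %in% c("retained_annotated", "retained_novel")]
  removed <- c(annotated_known = sum(fate == "annotated_known"),
               class_code = sum(fate == "class_code"),
               short = sum(fate == "short"),
               low_abundance = sum(fate == "low_abundance"),
               coding_potential = sum(fate == "coding_potential"))
  report <- list(n_input = length(ids), n_removed_by = removed,
                 retained_ids = retained)
  stopifnot(report$n_input == length(retained) + sum(removed))
  list(lncrna_ids = retained, report = report,
       table = data.frame(transcript_id = ids, fate = unname(fate[ids]),
                          class_code = unname(code[ids]),
                          stringsAsFactors = FALSE))
}
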