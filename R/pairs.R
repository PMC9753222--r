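#' Pearson correlation coefficient of two expression profiles
#'
#' Standard product-moment correlation; a constant profile has no defined
#' correlation and yields `NA`.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return correlation in `[-1, 1]`, or `NA` when either vector is constant.
#' @export
pearson_cc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

# gene-level replicate-mean TPM profile: sum of isoform TPM per gene
gene_profiles <- function(ann, expr) {
  prof <- mean_tpm_profiles(expr)
  gid <- ann$transcripts$gene_id[match(rownames(prof),
                                       ann$transcripts$transcript_id)]
  keep <- !is.na(gid)
  rowsum(prof[keep, , drop = FALSE], gid[keep])
}

#' Enumerate neighbor pair categories
#'
#' Builds the gene-pair categories compared in the co-expression analysis.
#' Protein-coding baselines: `APP` (coding genes overlapping on opposite
#' strands), `IPP` (each coding gene with its nearest non-overlapping coding
#' neighbor), `DPP`/`CPP` (coding pairs head-to-head / tail-to-tail within
#' `window` bp). LncRNA categories mirror them with an AR-lncRNA member:
#' `ALP` (antisense AR-lncRNA with exonic overlap of a coding gene), `ILP`
#' (intergenic AR-lncRNA with its nearest non-overlapping coding gene),
#' `DLP`/`CLP` (divergent/convergent AR-lncRNA within `window` bp of a coding
#' gene). `Random` pairs are uniformly sampled lncRNA-coding pairs (seeded).
#' A pair appears once per qualifying category; the Pearson correlation uses
#' gene-level replicate-mean TPM over all timepoints.
#'
#' @param ann `lnc_annotation` of all gene models.
#' @param ar_lnc_ids AR-lncRNA transcript ids.
#' @param expr `lnc_expression`.
#' @param window distance window in bp, default 1000.
#' @param n_random number of random pairs, default 100.
#' @param seed RNG seed for the random pairs.
#' @return data.frame `a_id`, `b_id` (gene ids; `a_id` is the lncRNA gene in
#'   L categories), `category`, `pcc`.
#' @export
enumerate_pairs <- function(ann, ar_lnc_ids, expr, window = 1000L,
                            n_random = 100L, seed = 1L) {
  tx <- ann$transcripts
  coding_g <- gene_spans(ann, biotype = "protein_coding")
  lnc_tx <- tx[tx$transcript_id %in% ar_lnc_ids, ]
  lnc_ann <- subset_annotation(ann, lnc_tx$transcript_id)
  lnc_g <- gene_spans(lnc_ann)
  prof <- gene_profiles(ann, expr)
  pcc_of <- function(a, b) {
    if (!(a %in% rownames(prof)) || !(b %in% rownames(prof))) return(NA_real_)
    pearson_cc(prof[a, ], prof[b, ])
  }
  pair_df <- function(a, b, category) {
    if (!length(a)) return(NULL)
    data.frame(a_id = a, b_id = b, category = category,
               pcc = mapply(pcc_of, a, b, USE.NAMES = FALSE),
               stringsAsFactors = FALSE)
  }

  res <- list()
  gid <- mcols(coding_g)$gene_id
  gplus <- as.character(strand(coding_g)) == "+"
  tss <- ifelse(gplus, start(coding_g), end(coding_g))
  tes <- ifelse(gplus, end(coding_g), start(coding_g))

  # coding/coding categories (unordered pairs, i < j)
  ov <- findOverlaps(coding_g, coding_g, ignore.strand = TRUE)
  ii <- queryHits(ov); jj <- subjectHits(ov)
  sel <- ii < jj & gplus[ii] != gplus[jj]
  res$APP <- pair_df(gid[ii[sel]], gid[jj[sel]], "APP")

  near <- nearest_nonoverlapping(coding_g, coding_g)
  res$IPP <- pair_df(gid[!is.na(near)], gid[near[!is.na(near)]], "IPP")

  dconv <- head_tail_pairs(coding_g, coding_g, window, self = TRUE)
  res$DPP <- pair_df(gid[dconv$div$i], gid[dconv$div$j], "DPP")
  res$CPP <- pair_df(gid[dconv$conv$i], gid[dconv$conv$j], "CPP")

  # lncRNA categories
  if (length(lnc_g)) {
    lid <- mcols(lnc_g)$gene_id
    loc <- classify_genomic_location(lnc_tx$transcript_id, ann, ann, window)
    loc_g <- loc[match(lid, tx$gene_id[match(loc$transcript_id,
                                             tx$transcript_id)]), ]
    # ALP: exonic overlap with a coding gene, opposite strand
    lex <- lnc_ann$exons
    lstr <- lnc_ann$transcripts$strand[
      match(mcols(lex)$transcript_id, lnc_ann$transcripts$transcript_id)]
    lex_str <- GRanges(seqnames(lex), ranges(lex), strand = lstr)
    lgene <- lnc_ann$transcripts$gene_id[
      match(mcols(lex)$transcript_id, lnc_ann$transcripts$transcript_id)]
    cex <- ann$exons
    ctx_bt <- tx$biotype[match(mcols(cex)$transcript_id, tx$transcript_id)]
    cex <- cex[ctx_bt == "protein_coding"]
    cstr <- tx$strand[match(mcols(cex)$transcript_id, tx$transcript_id)]
    cgene <- tx$gene_id[match(mcols(cex)$transcript_id, tx$transcript_id)]
    cex_str <- GRanges(seqnames(cex), ranges(cex), strand = cstr)
    h <- findOverlaps(lex_str, cex_str, ignore.strand = TRUE)
    opp <- as.character(strand(lex_str))[queryHits(h)] !=
      as.character(strand(cex_str))[subjectHits(h)]
    alp <- unique(data.frame(a = lgene[queryHits(h)[opp]],
                             b = cgene[subjectHits(h)[opp]],
                             stringsAsFactors = FALSE))
    res$ALP <- pair_df(alp$a, alp$b, "ALP")

    near_l <- nearest_nonoverlapping(lnc_g, coding_g)
    ok <- !is.na(near_l)
    res$ILP <- pair_df(lid[ok], gid[near_l[ok]], "ILP")

    dc <- head_tail_pairs(lnc_g, coding_g, window, self = FALSE)
    res$DLP <- pair_df(lid[dc$div$i], gid[dc$div$j], "DLP")
    res$CLP <- pair_df(lid[dc$conv$i], gid[dc$conv$j], "CLP")

    rnd <- with_seed(seed, data.frame(
      a = lid[sample.int(length(lid), n_random, replace = TRUE)],
      b = gid[sample.int(length(gid), n_random, replace = TRUE)],
      stringsAsFactors = FALSE))
    res$Random <- pair_df(rnd$a, rnd$b, "Random")
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out[!is.na(out$pcc) | out$category == "Random", , drop = FALSE]
}

# index of nearest non-overlapping range in `subject` for each range of
# `query`; ties broken toward the smaller start coordinate
nearest_nonoverlapping <- function(query, subject) {
  out <- rep(NA_integer_, length(query))
  qs <- as.character(seqnames(query)); ss <- as.character(seqnames(subject))
  for (i in seq_along(query)) {
    same <- which(ss == qs[i])
    if (identical(query, subject)) same <- setdiff(same, i)
    if (!length(same)) next
    ov <- start(subject)[same] <= end(query)[i] &
      end(subject)[same] >= start(query)[i]
    cand <- same[!ov]
    if (!length(cand)) next
    gap <- pmax(start(subject)[cand] - end(query)[i],
                start(query)[i] - end(subject)[cand])
    best <- cand[gap == min(gap)]
    out[i] <- best[order(start(subject)[best])][[1L]]
  }
  out
}

# divergent (TSS-TSS head-to-head) and convergent (TES-TES tail-to-tail)
# pairs within `window` bp on opposite strands, no overlap
head_tail_pairs <- function(a, b, window, self = FALSE) {
  ap <- as.character(strand(a)) == "+"
  bp <- as.character(strand(b)) == "+"
  a_tss <- ifelse(ap, start(a), end(a)); a_tes <- ifelse(ap, end(a), start(a))
  b_tss <- ifelse(bp, start(b), end(b)); b_tes <- ifelse(bp, end(b), start(b))
  div <- list(i = integer(), j = integer())
  conv <- list(i = integer(), j = integer())
  for (i in seq_along(a)) {
    cand <- which(as.character(seqnames(b)) ==
                    as.character(seqnames(a))[i] & bp != ap[i])
    if (self) cand <- cand[cand > i]
    if (!length(cand)) next
    no_ov <- !(start(b)[cand] <= end(a)[i] & end(b)[cand] >= start(a)[i])
    cand <- cand[no_ov]
    if (!length(cand)) next
    h2h <- if (ap[i]) b_tss[cand] < a_tss[i] else b_tss[cand] > a_tss[i]
    d <- abs(b_tss[cand] - a_tss[i])
    jj <- cand[h2h & d <= window]
    div$i <- c(div$i, rep(i, length(jj))); div$j <- c(div$j, jj)
    t2t <- if (ap[i]) b_tes[cand] > a_tes[i] else b_tes[cand] < a_tes[i]
    d2 <- abs(b_tes[cand] - a_tes[i])
    jj <- cand[t2t & d2 <= window]
    conv$i <- c(conv$i, rep(i, length(jj))); conv$j <- c(conv$j, jj)
  }
  list(div = div, conv = conv)
}

#' Compare correlation distributions across pair categories
#'
#' Per-category summaries (n, median, quartiles) of the pair correlations,
#' and two-tailed Mann-Whitney U tests for each lncRNA category against its
#' protein-coding baseline (ALP vs APP, ILP vs IPP, DLP vs DPP, CLP vs CPP)
#' and for every category against Random. Comparisons with fewer than
#' `min_n` pairs on either side are skipped with a warning.
#'
#' @param pairs data.frame from [enumerate_pairs()].
#' @param min_n minimum pairs per compared category, default 3.
#' @return list with `summary` and `tests` data.frames.
#' @export
compare_categories <- function(pairs, min_n = 3L) {
  pairs <- pairs[!is.na(pairs$pcc), , drop = FALSE]
  cats <- split(pairs$pcc, pairs$category)
  summary <- do.call(rbind, lapply(names(cats), function(cc) {
    x <- cats[[cc]]
    data.frame(category = cc, n = length(x), median = median(x),
               q25 = unname(quantile(x, 0.25)),
               q75 = unname(quantile(x, 0.75)), stringsAsFactors = FALSE)
  }))
  cmp <- rbind(
    data.frame(a = c("ALP", "ILP", "DLP", "CLP"),
               b = c("APP", "IPP", "DPP", "CPP")),
    data.frame(a = setdiff(names(cats), "Random"), b = "Random"))
  tests <- list()
  for (i in seq_len(nrow(cmp))) {
    a <- cmp$a[i]; b <- cmp$b[i]
    if (is.null(cats[[a]]) || is.null(cats[[b]])) next
    if (length(cats[[a]]) < min_n || length(cats[[b]]) < min_n) {
      warning("compare_categories: skipping ", a, " vs ", b,
              " (undersized category)")
      next
    }
    mw <- mann_whitney(cats[[a]], cats[[b]])
    tests[[length(tests) + 1L]] <-
      data.frame(category = a, baseline = b, U = mw$U, p = mw$p)
  }
  list(summary = summary,
       tests = if (length(tests)) do.call(rbind, tests)
               else data.frame(category = character(), baseline = character(),
                               U = numeric(), p = numeric()))
}

#' Select correlated antisense pairs
#'
#' ALP pairs whose correlation strictly exceeds the threshold, sorted by
#' decreasing correlation.
#'
#' @param pairs data.frame from [enumerate_pairs()].
#' @param threshold correlation gate, default 0.7 (strict `>`).
#' @return subset of `pairs`.
#' @export
select_correlated_antisense <- function(pairs, threshold = 0.7) {
  sel <- pairs$category == "ALP" & !is.na(pairs$pcc) & pairs$pcc > threshold
  out <- pairs[sel, , drop = FALSE]
  out[order(-out$pcc), , drop = FALSE]
}
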