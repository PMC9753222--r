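#' Genome annotation container
#'
#' Holds transcript models: one row per transcript (id, gene, chromosome,
#' strand, biotype) plus the exon structure of every transcript as a
#' `GRanges`. Exons are stored in the usual 1-based inclusive genomic
#' convention of GenomicRanges; exported tables use 0-based half-open
#' coordinates (see [exon_table()]).
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand` (`+`/`-`), `biotype` (one of `protein_coding`,
#'   `annotated_noncoding`, `novel`).
#' @param exons `GRanges` with metadata column `transcript_id`; one range per
#'   exon.
#' @param chrom_lengths optional named vector of chromosome lengths (bp).
#' @return An object of class `lnc_annotation`.
#' @export
genome_annotation <- function(transcripts, exons, chrom_lengths = NULL) {
  stopifnot(is.data.frame(transcripts), is(exons, "GRanges"))
  need <- c("transcript_id", "gene_id", "chrom", "strand", "biotype")
  miss <- setdiff(need, names(transcripts))
  if (length(miss))
    stop_lncage("annotation: missing transcript columns: ",
                paste(miss, collapse = ", "))
  if (anyDuplicated(transcripts$transcript_id))
    stop_lncage("annotation: duplicate transcript ids")
  if (!all(transcripts$strand %in% c("+", "-")))
    stop_lncage("annotation: transcript strand must be '+' or '-'")
  if (is.null(mcols(exons)$transcript_id))
    stop_lncage("annotation: exons lack a transcript_id column")
  unknown <- setdiff(mcols(exons)$transcript_id, transcripts$transcript_id)
  if (length(unknown))
    stop_lncage("annotation: exon without parent transcript: ", unknown[[1L]])
  if (!all(transcripts$transcript_id %in% mcols(exons)$transcript_id))
    stop_lncage("annotation: transcript without exons")

  # sort exons within transcript, check disjointness
  o <- order(match(mcols(exons)$transcript_id, transcripts$transcript_id),
             start(exons))
  exons <- exons[o]
  byTx <- split(ranges(exons), mcols(exons)$transcript_id)
  bad <- sum(width(IRanges::reduce(byTx, min.gapwidth = 0L))) !=
    sum(width(byTx))
  if (any(bad))
    stop_lncage("annotation: overlapping exons within transcript ",
                names(byTx)[bad][[1L]])
  if (!is.null(chrom_lengths)) {
    sl <- chrom_lengths[as.character(seqnames(exons))]
    if (any(is.na(sl)) || any(end(exons) > sl) || any(start(exons) < 1L))
      stop_lncage("annotation: exon outside chromosome bounds")
  }
  lens <- vapply(byTx, function(r) sum(width(r)), numeric(1))
  transcripts$length <- as.integer(lens[transcripts$transcript_id])
  rownames(transcripts) <- NULL
  structure(list(transcripts = transcripts, exons = exons,
                 chrom_lengths = chrom_lengths),
            class = "lnc_annotation")
}

#' @export
print.lnc_annotation <- function(x, ...) {
  cat("lnc_annotation:", nrow(x$transcripts), "transcripts,",
      length(unique(x$transcripts$gene_id)), "genes,",
      length(x$exons), "exons\n")
  tab <- table(x$transcripts$biotype)
  cat(paste0("  ", names(tab), ": ", tab, collapse = "\n"), "\n")
  invisible(x)
}

#' Exon table in 0-based half-open coordinates
#'
#' @param ann `lnc_annotation`.
#' @return data.frame with `transcript_id`, `chrom`, `strand`, `start`
#'   (0-based), `end` (exclusive).
#' @export
exon_table <- function(ann) {
  ex <- ann$exons
  tx <- ann$transcripts
  i <- match(mcols(ex)$transcript_id, tx$transcript_id)
  data.frame(transcript_id = mcols(ex)$transcript_id,
             chrom = as.character(seqnames(ex)),
             strand = tx$strand[i],
             start = start(ex) - 1L,
             end = end(ex),
             stringsAsFactors = FALSE)
}

#' Genomic span of every transcript
#'
#' @param ann `lnc_annotation`.
#' @return `GRanges`, one range per transcript (strand-aware), with
#'   `transcript_id`, `gene_id` and `biotype` metadata.
#' @export
transcript_spans <- function(ann) {
  ex <- ann$exons
  byTx <- split(ex, mcols(ex)$transcript_id)
  sp <- unlist(range(byTx))
  tx <- ann$transcripts
  i <- match(names(sp), tx$transcript_id)
  strand(sp) <- tx$strand[i]
  mcols(sp)$transcript_id <- names(sp)
  mcols(sp)$gene_id <- tx$gene_id[i]
  mcols(sp)$biotype <- tx$biotype[i]
  unname(sp)
}

#' Genomic span of every gene (union of its transcripts)
#'
#' @param ann `lnc_annotation`.
#' @param biotype optional biotype filter (e.g. `"protein_coding"`).
#' @return `GRanges` with `gene_id` metadata.
#' @export
gene_spans <- function(ann, biotype = NULL) {
  tx <- ann$transcripts
  keep <- if (is.null(biotype)) rep(TRUE, nrow(tx)) else tx$biotype %in% biotype
  sp <- transcript_spans(ann)
  sp <- sp[mcols(sp)$transcript_id %in% tx$transcript_id[keep]]
  byGene <- split(sp, mcols(sp)$gene_id)
  g <- unlist(range(byGene))
  st <- vapply(split(as.character(strand(sp)), mcols(sp)$gene_id),
               function(s) s[[1L]], character(1))
  strand(g) <- st[names(g)]
  mcols(g)$gene_id <- names(g)
  unname(g)
}

#' Spliced (exonic) transcript lengths
#'
#' @param ann `lnc_annotation`.
#' @return named integer vector of exonic lengths.
#' @export
transcript_lengths <- function(ann) {
  setNames(ann$transcripts$length, ann$transcripts$transcript_id)
}

#' Introns of every transcript
#'
#' @param ann `lnc_annotation`.
#' @return `GRanges` of introns with `transcript_id`, `gene_id` metadata.
#' @keywords internal
transcript_introns <- function(ann) {
  ex <- ann$exons
  byTx <- split(ranges(ex), mcols(ex)$transcript_id)
  sp <- range(byTx)
  gaps <- IRanges::setdiff(sp, byTx)
  n <- lengths(gaps)
  txid <- rep(names(gaps), n)
  if (!length(txid))
    return(GRanges(transcript_id = character(), gene_id = character()))
  chr <- ann$transcripts$chrom[match(txid, ann$transcripts$transcript_id)]
  gid <- ann$transcripts$gene_id[match(txid, ann$transcripts$transcript_id)]
  gr <- GRanges(chr, unlist(gaps, use.names = FALSE))
  mcols(gr)$transcript_id <- txid
  mcols(gr)$gene_id <- gid
  gr
}

#' Subset an annotation to a set of transcripts
#'
#' @param ann `lnc_annotation`.
#' @param transcript_ids character vector of ids to keep.
#' @return `lnc_annotation`.
#' @export
subset_annotation <- function(ann, transcript_ids) {
  keep <- ann$transcripts$transcript_id %in% transcript_ids
  genome_annotation(ann$transcripts[keep, setdiff(names(ann$transcripts), "length")],
             ann$exons[mcols(ann$exons)$transcript_id %in% transcript_ids],
             ann$chrom_lengths)
}

#' Read a GTF file into an annotation
#'
#' Coordinates on disk follow the GTF standard (1-based inclusive). Only
#' `exon` features are required; `gene`/`transcript` features are accepted and
#' used for biotype metadata when present. Transcripts on strand `.` are
#' rejected: every classification rule in the pipeline is strand-dependent.
#'
#' @param path GTF file.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return `lnc_annotation`.
#' @export
read_gtf <- function(path, chrom_lengths = NULL) {
  if (!file.exists(path)) stop_lncage("read_gtf: no such file: ", path)
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(regmatches(lines[body], gregexpr("\t", lines[body]))) + 1L
  if (any(nf != 9L)) {
    lineno <- which(body)[which(nf != 9L)[[1L]]]
    stop_lncage("read_gtf: malformed GTF line ", lineno, " in ", path,
                " (expected 9 tab-separated fields)")
  }
  if (!any(body)) {
    empty <- data.frame(transcript_id = character(), gene_id = character(),
                        chrom = character(), strand = character(),
                        biotype = character(), stringsAsFactors = FALSE)
    gr <- GRanges()
    mcols(gr)$transcript_id <- character()
    return(genome_annotation(empty, gr, chrom_lengths))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop_lncage("read_gtf: no exon features in ", path)
  if (any(is.na(ex$transcript_id)))
    stop_lncage("read_gtf: exon without transcript_id attribute")
  if (any(is.na(ex$gene_id)))
    stop_lncage("read_gtf: exon without gene_id attribute")
  if (any(as.character(strand(ex)) == "*"))
    stop_lncage("read_gtf: unstranded ('.') transcripts are not supported")
  first <- !duplicated(ex$transcript_id)
  bt <- if (!is.null(ex$biotype)) as.character(ex$biotype[first])
        else rep(NA_character_, sum(first))
  bt[is.na(bt)] <- "novel"
  tx <- data.frame(transcript_id = as.character(ex$transcript_id[first]),
                   gene_id = as.character(ex$gene_id[first]),
                   chrom = as.character(seqnames(ex[first])),
                   strand = as.character(strand(ex[first])),
                   biotype = bt, stringsAsFactors = FALSE)
  gene_of <- split(tx$gene_id, tx$transcript_id)
  ex2 <- GRanges(seqnames(ex), ranges(ex), strand = strand(ex))
  mcols(ex2)$transcript_id <- as.character(ex$transcript_id)
  genome_annotation(tx, ex2, chrom_lengths)
}

#' Write an annotation as GTF
#'
#' Emits `transcript` and `exon` features with 1-based inclusive coordinates
#' and `gene_id`/`transcript_id`/`biotype` attributes, in a fixed deterministic
#' order, so that identical annotations produce byte-identical files.
#'
#' @param ann `lnc_annotation`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gtf <- function(ann, path) {
  tx <- ann$transcripts[order(ann$transcripts$chrom,
                              ann$transcripts$transcript_id), ]
  ex <- ann$exons
  sp <- transcript_spans(ann)
  spi <- match(tx$transcript_id, mcols(sp)$transcript_id)
  lines <- character(0)
  exTx <- split(seq_along(ex), mcols(ex)$transcript_id)
  out <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    attr1 <- sprintf('gene_id "%s"; transcript_id "%s"; biotype "%s";',
                     t$gene_id, t$transcript_id, t$biotype)
    s <- sp[spi[i]]
    head <- sprintf("%s\tlncage\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                    t$chrom, start(s), end(s), t$strand, attr1)
    ei <- exTx[[t$transcript_id]]
    exl <- sprintf("%s\tlncage\texon\t%d\t%d\t.\t%s\t.\t%s",
                   t$chrom, start(ex[ei]), end(ex[ei]), t$strand, attr1)
    out[[i]] <- c(head, exl)
  }
  writeLines(unlist(out), path)
  invisible(path)
}
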