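# small in-code fixture builders shared across the test files

make_ann <- function(models, chrom_lengths = NULL) {
  txdf <- do.call(rbind, lapply(models, function(m)
    data.frame(transcript_id = m$id, gene_id = m$gid,
               chrom = m$chrom %||% "chr1", strand = m$strand,
               biotype = m$bt %||% "novel", stringsAsFactors = FALSE)))
  exdf <- do.call(rbind, lapply(models, function(m)
    data.frame(chrom = m$chrom %||% "chr1", start = m$starts, end = m$ends,
               transcript_id = m$id, stringsAsFactors = FALSE)))
  gr <- GenomicRanges::GRanges(exdf$chrom,
                               IRanges::IRanges(exdf$start, exdf$end))
  S4Vectors::mcols(gr)$transcript_id <- exdf$transcript_id
  genome_annotation(txdf, gr, chrom_lengths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tx_model <- function(id, gid, strand, starts, ends, bt = "novel",
                     chrom = "chr1") {
  list(id = id, gid = gid, strand = strand, starts = starts, ends = ends,
       bt = bt, chrom = chrom)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# expression object from a plain counts matrix and an annotation
make_expr <- function(counts, ann) expression_matrix(counts, ann)

# packaged filter-cascade fixture, loaded once per test run
load_filter_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ext <- function(f) system.file("extdata", f, package = "lncage")
    cand <- read_gtf(ext("filter_candidates.gtf"))
    ref <- read_gtf(ext("filter_reference.gtf"))
    expr <- read_expression(ext("filter_counts.tsv"), cand)
    seqs <- Biostrings::readDNAStringSet(ext("filter_sequences.fa"))
    cache <<- list(candidates = cand, reference = ref, expr = expr,
                   sequences = setNames(as.character(seqs), names(seqs)))
    cache
  }
})

# default synthetic bundle, simulated once and reused across test files
default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(sim_config(seed = 1))
    cache
  }
})

# map a location + flags row to the planted truth category labels
location_label <- function(loc) {
  ifelse(loc$location != "intergenic", loc$location,
         ifelse(loc$divergent & loc$convergent, "divergent_convergent",
                ifelse(loc$divergent, "divergent",
                       ifelse(loc$convergent, "convergent", "intergenic"))))
}
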