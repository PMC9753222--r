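#' Pipeline thresholds
#'
#' One flat list of every tunable threshold, with the screening values used
#' throughout the study as defaults: minimum lncRNA length 150 nt, TPMmax 1,
#' neighborhood window 1000 bp, ribo-lncRNA gate 1 read/nt, RRS gate 0.9,
#' sRNA precursor gates (20 reads, 50% at 21-22 nt), AR gates
#' (|log2FC| >= 1, adjusted p <= 0.05), 6 temporal clusters, antisense-pair
#' correlation 0.7, ceRNA gates (p < 0.05, PCC > 0.7), duplex gates
#' (E < -16 kcal/mol, >= 15 paired nt, |PCC| >= 0.9).
#'
#' @param ... overrides of the defaults (named).
#' @return list of thresholds.
#' @export
pipeline_config <- function(...) {
  cfg <- list(min_length = 150L, min_tpmmax = 1, window = 1000L,
              ribo_min = 1, rrs_min = 0.9,
              srna_min_reads = 20, srna_min_frac = 0.5,
              lfc_min = 1, padj_max = 0.05, k_clusters = 6L,
              pcc_alp = 0.7, cerna_p_max = 0.05, cerna_pcc_min = 0.7,
              duplex_max_energy = -16, duplex_min_len = 15L,
              duplex_pcc_min = 0.9, n_random_pairs = 100L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop_lncage("pipeline_config: unknown threshold ", bad[[1L]])
  cfg[names(over)] <- over
  cfg
}

#' Load a fixture bundle from disk
#'
#' Reads the files written by [write_bundle()] back into the in-memory
#' layout used by [run_pipeline()].
#'
#' @param dir bundle directory.
#' @return list with `annotation`, `reference`, `sequences`, `expr`,
#'   `ribo`, `srna`, `targets`, `fractions`, `stress_sets`.
#' @export
load_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  ann <- read_gtf(p("annotation.gtf"))
  reference <- read_gtf(p("reference.gtf"))
  expr <- read_expression(p("counts.tsv"), ann)
  sequences <- readDNAStringSet(p("transcripts.fa"))
  ribo_tab <- read_table(p("ribo.tsv"))
  ribo <- lapply(split(ribo_tab, ribo_tab$transcript_id),
                 function(d) d$depth[order(d$pos)])
  srna_tab <- read_table(p("srna.tsv"))
  srna <- as.matrix(srna_tab[, -1L, drop = FALSE])
  rownames(srna) <- srna_tab$transcript_id
  targets <- read_table(p("targets.tsv"))
  fractions <- read_table(p("fractions.tsv"))
  stress_tab <- read_table(p("stress_sets.tsv"))
  stress_sets <- split(stress_tab$transcript_id, stress_tab$condition)
  list(annotation = ann, reference = reference, sequences = sequences,
       expr = expr, ribo = ribo, srna = srna, targets = targets,
       fractions = fractions, stress_sets = stress_sets)
}

srna_as_list <- function(srna) {
  lapply(setNames(nm = rownames(srna)), function(id)
    setNames(as.numeric(srna[id, ]), colnames(srna)))
}

#' Run the complete analysis pipeline on a study bundle
#'
#' Executes identification, classification, AR calling, clustering,
#' localization and stress overlap, neighbor co-expression, ceRNA discovery
#' and the duplex screen, writing one TSV (or GTF) per stage into
#' `out_dir`. All outputs are deterministic given `seed`.
#'
#' @param bundle study as returned by [simulate_study()] or [load_bundle()].
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @param params [pipeline_config()].
#' @param seed RNG seed for k-means restarts and random pair sampling.
#' @return list with each stage's result.
#' @export
run_pipeline <- function(bundle, out_dir = NULL, params = pipeline_config(),
                         seed = 1L) {
  sequences <- setNames(as.character(bundle$sequences),
                        names(bundle$sequences))

  ident <- run_identification(bundle$annotation, bundle$reference,
                              bundle$expr, sequences,
                              min_length = params$min_length,
                              min_tpmmax = params$min_tpmmax)
  lnc_ids <- ident$lncrna_ids

  loc <- classify_genomic_location(lnc_ids, bundle$annotation,
                                   bundle$reference, params$window)
  func <- classify_functional(lnc_ids, bundle$ribo,
                              srna_as_list(bundle$srna), sequences,
                              ribo_min = params$ribo_min,
                              rrs_min = params$rrs_min)
  classification <- merge(loc, func, by = "transcript_id", sort = TRUE)

  ar <- call_ar_lncrnas(bundle$expr, lnc_ids,
                        lfc_min = params$lfc_min,
                        padj_max = params$padj_max)

  clusters <- NULL
  if (length(ar$ar_ids) >= params$k_clusters) {
    prof <- log2fc_profiles(bundle$expr, ar$ar_ids)
    clusters <- kmeans_clusters(prof, k = params$k_clusters, seed = seed)
  }

  loc_enrich <- localization_enrichment(
    bundle$fractions[bundle$fractions$transcript_id %in% lnc_ids, ,
                     drop = FALSE])
  stress <- stress_overlap(ar$ar_ids, bundle$stress_sets)

  pairs <- enumerate_pairs(bundle$annotation, ar$ar_ids, bundle$expr,
                           window = params$window,
                           n_random = params$n_random_pairs, seed = seed)
  pair_stats <- compare_categories(pairs)
  alp_sel <- select_correlated_antisense(pairs, params$pcc_alp)

  cerna <- find_cerna_sets(bundle$targets, bundle$expr,
                           p_max = params$cerna_p_max,
                           pcc_min = params$cerna_pcc_min)
  network <- build_network(cerna[cerna$retained, , drop = FALSE])

  tx <- bundle$annotation$transcripts
  mrna_ids <- tx$transcript_id[tx$biotype == "protein_coding"]
  duplex <- screen_and_filter(ar$ar_ids, mrna_ids, sequences, bundle$expr,
                              pcc_min = params$duplex_pcc_min,
                              max_energy = params$duplex_max_energy,
                              min_len = params$duplex_min_len)

  res <- list(identification = ident, classification = classification,
              ar = ar, clusters = clusters, localization = loc_enrich,
              stress = stress, pairs = pairs, pair_stats = pair_stats,
              alp_selected = alp_sel, cerna = cerna, network = network,
              duplex = duplex, lnc_ids = lnc_ids)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_gtf(subset_annotation(bundle$annotation, lnc_ids),
              p("lncrnas.gtf"))
    rep_df <- data.frame(rule = c("input", names(ident$report$n_removed_by),
                                  "retained"),
                         n = c(ident$report$n_input,
                               unname(ident$report$n_removed_by),
                               length(lnc_ids)))
    write_table(rep_df, p("filter_report.tsv"))
    write_table(classification, p("classification.tsv"))
    write_table(ar$results, p("de_results.tsv"))
    if (!is.null(clusters))
      write_table(clusters$assignment, p("clusters.tsv"))
    write_table(loc_enrich, p("localization.tsv"))
    write_table(stress, p("stress_overlap.tsv"))
    write_table(pairs, p("pairs.tsv"))
    write_table(pair_stats$tests, p("category_stats.tsv"))
    write_table(cerna, p("cerna_sets.tsv"))
    write_table(network$edges, p("network_edges.tsv"))
    write_table(duplex, p("duplex_hits.tsv"))
  }
  res
}
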