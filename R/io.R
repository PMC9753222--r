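#' Write a result table as TSV
#'
#' Tab-separated UTF-8 with a header row; numeric columns are written with 12
#' significant digits so values round-trip through [read_table()] within 1e-9.
#' Formatting is locale-independent and deterministic.
#'
#' @param records data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  cols <- lapply(records, function(x) {
    if (is.double(x)) {
      out <- sprintf("%.12g", x)
      out[is.na(x)] <- "NA"
      out
    } else as.character(x)
  })
  header <- paste(names(records), collapse = "\t")
  body <- if (nrow(records)) do.call(paste, c(cols, sep = "\t")) else character()
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop_lncage("write_table: cannot open ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(header, body), con, useBytes = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path input file.
#' @return data.frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop_lncage("read_table: no such file: ", path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Reverse complement of a nucleotide sequence
#'
#' Accepts the DNA or RNA alphabet (`A C G T U N`); `T` and `U` are treated
#' as equivalent and the output uses the alphabet of the input.
#'
#' @param sequence single nucleotide string.
#' @return the reverse complement, same length and alphabet.
#' @export
reverse_complement <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "")[[1L]]
  ok <- chars %in% c("A", "C", "G", "T", "U", "N")
  if (!all(ok))
    stop_lncage("reverse_complement: invalid character '",
                chars[!ok][[1L]], "'")
  is_rna <- any(chars == "U")
  dna <- chartr("U", "T", sequence)
  rc <- as.character(reverseComplement(DNAString(dna)))
  if (is_rna) rc <- chartr("T", "U", rc)
  rc
}

#' Expression matrix over a (timepoint x replicate) design
#'
#' Wraps a counts matrix (transcripts x samples) whose column names follow the
#' `d{day}_r{replicate}` convention, together with TPM values recomputed from
#' the counts with the spliced transcript lengths of the annotation.
#'
#' @param counts integer matrix, rownames = transcript ids, colnames =
#'   `d{day}_r{rep}`.
#' @param annotation `lnc_annotation` providing transcript lengths.
#' @return object of class `lnc_expression` with elements `counts`, `tpm`,
#'   `samples` (data.frame `day`, `replicate`), `transcript_ids`.
#' @export
expression_matrix <- function(counts, annotation) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (anyDuplicated(rownames(counts)))
    stop_lncage("expression_matrix: duplicate transcript id")
  if (any(counts < 0))
    stop_lncage("expression_matrix: negative count")
  if (any(counts != round(counts)))
    stop_lncage("expression_matrix: non-integer count")
  m <- regmatches(colnames(counts),
                  regexec("^d([0-9]+)_r([0-9]+)$", colnames(counts)))
  bad <- lengths(m) != 3L
  if (any(bad))
    stop_lncage("expression_matrix: malformed sample name '",
                colnames(counts)[bad][[1L]], "' (expected d{day}_r{rep})")
  samples <- data.frame(
    sample = colnames(counts),
    day = as.integer(vapply(m, `[[`, character(1), 2L)),
    replicate = as.integer(vapply(m, `[[`, character(1), 3L)),
    stringsAsFactors = FALSE)
  lens <- transcript_lengths(annotation)
  miss <- setdiff(rownames(counts), names(lens))
  if (length(miss))
    stop_lncage("expression_matrix: transcript absent from annotation: ",
                miss[[1L]])
  tpm <- apply(counts, 2, compute_tpm, lengths = lens[rownames(counts)])
  if (!is.matrix(tpm)) tpm <- matrix(tpm, nrow = nrow(counts))
  dimnames(tpm) <- dimnames(counts)
  structure(list(counts = counts, tpm = tpm, samples = samples,
                 transcript_ids = rownames(counts)),
            class = "lnc_expression")
}

#' @export
print.lnc_expression <- function(x, ...) {
  cat("lnc_expression:", nrow(x$counts), "transcripts x",
      ncol(x$counts), "samples (days",
      paste(range(x$samples$day), collapse = "-"), ",",
      max(x$samples$replicate), "replicates)\n")
  invisible(x)
}

#' Read a count table into an expression matrix
#'
#' The first column must hold transcript ids; remaining columns must be named
#' `d{day}_r{replicate}`. Rows whose transcript is absent from the annotation
#' are dropped with a warning reporting the number dropped. TPM is recomputed
#' from the counts.
#'
#' @param path TSV file of counts.
#' @param annotation `lnc_annotation`.
#' @return `lnc_expression` with attribute `dropped` = number of dropped rows.
#' @export
read_expression <- function(path, annotation) {
  tab <- read_table(path)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop_lncage("read_expression: duplicate transcript id '",
                ids[duplicated(ids)][[1L]], "'")
  cnt <- as.matrix(tab[, -1L, drop = FALSE])
  if (any(cnt < 0))
    stop_lncage("read_expression: negative count for transcript '",
                ids[which(rowSums(cnt < 0) > 0)[[1L]]], "'")
  rownames(cnt) <- ids
  known <- ids %in% annotation$transcripts$transcript_id
  dropped <- sum(!known)
  if (dropped)
    warning("read_expression: dropped ", dropped,
            " rows absent from annotation")
  expr <- expression_matrix(cnt[known, , drop = FALSE], annotation)
  attr(expr, "dropped") <- dropped
  expr
}

#' Replicate-mean TPM profiles
#'
#' Averages TPM over replicates within each timepoint, giving one profile
#' column per day. These profiles are the "average TPM" convention used by
#' every co-expression computation in the pipeline.
#'
#' @param expr `lnc_expression`.
#' @param ids optional subset of transcript ids.
#' @return numeric matrix, transcripts x timepoints (columns named by day).
#' @export
mean_tpm_profiles <- function(expr, ids = NULL) {
  tpm <- expr$tpm
  if (!is.null(ids)) {
    miss <- setdiff(ids, rownames(tpm))
    if (length(miss))
      stop_lncage("mean_tpm_profiles: no expression for ", miss[[1L]])
    tpm <- tpm[ids, , drop = FALSE]
  }
  days <- sort(unique(expr$samples$day))
  out <- vapply(days, function(d) {
    rowMeans(tpm[, expr$samples$day == d, drop = FALSE])
  }, numeric(nrow(tpm)))
  out <- matrix(out, nrow = nrow(tpm),
                dimnames = list(rownames(tpm), days))
  out
}
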