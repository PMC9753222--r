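#' Additive per-pair duplex energy model
#'
#' A fully specified additive stand-in for thermodynamic duplex scoring:
#' every paired position contributes its base-pair energy (kcal/mol), every
#' mismatch a fixed penalty, and extension stops once the running energy
#' exceeds the best seen by `xdrop`. The defaults place the reporting gate
#' (-16 kcal/mol at >= 15 paired nt) exactly at a 15-nt AU-only perfect
#' duplex (15 x -1.1 = -16.5). The mismatch penalty is on the scale of an
#' internal-loop destabilization (+4 kcal/mol): a substantially weaker
#' penalty would let extensions accumulate stability through interleaved
#' mismatches, and unrelated sequences of a few hundred nt would pass the
#' reporting gate more often than not, destroying the specificity the screen
#' exists for.
#'
#' @param eGC,eAU,eGU pairing energies (kcal/mol), defaults -2.2, -1.1, -0.6.
#' @param mismatch mismatch penalty (kcal/mol), default +4.0.
#' @param xdrop x-drop extension cutoff (kcal/mol), default 3.0.
#' @return list of model parameters.
#' @export
energy_model <- function(eGC = -2.2, eAU = -1.1, eGU = -0.6,
                         mismatch = 4.0, xdrop = 3.0) {
  stopifnot(eGC < 0, eAU < 0, eGU < 0, mismatch > 0, xdrop > 0)
  list(eGC = eGC, eAU = eAU, eGU = eGU, mismatch = mismatch, xdrop = xdrop)
}

encode_seq <- function(sequence) {
  seq <- chartr("U", "T", toupper(sequence))
  chars <- strsplit(seq, "")[[1L]]
  code <- match(chars, c("A", "C", "G", "T", "N")) - 1L
  if (any(is.na(code)))
    stop_lncage("invalid nucleotide '", chars[is.na(code)][[1L]], "'")
  code[code == 4L] <- -1L
  code
}

#' Find exact Watson-Crick seed matches between two sequences
#'
#' All positions at which a `seed_len`-mer of the lncRNA is the exact
#' reverse complement (Watson-Crick only, no G:U) of an mRNA `seed_len`-mer,
#' located through a k-mer index of the mRNA.
#'
#' @param lnc_seq,mrna_seq nucleotide strings (T/U equivalent).
#' @param seed_len seed length, default 6.
#' @return data.frame `lnc_pos`, `mrna_pos` (1-based window starts).
#' @export
find_seeds <- function(lnc_seq, mrna_seq, seed_len = 6L) {
  stopifnot(nchar(lnc_seq) >= seed_len, nchar(mrna_seq) >= seed_len)
  m <- find_seeds_cpp(encode_seq(lnc_seq), encode_seq(mrna_seq),
                      as.integer(seed_len))
  data.frame(lnc_pos = m[, 1L] + 1L, mrna_pos = m[, 2L] + 1L)
}

#' Extend one seed into a duplex candidate
#'
#' Ungapped antiparallel x-drop extension of a seed in both directions under
#' the energy model; G:U pairs are allowed during extension (not in seeds).
#' The candidate is trimmed to its best-energy span.
#'
#' @param lnc_seq,mrna_seq nucleotide strings.
#' @param lnc_pos,mrna_pos 1-based seed start positions (one row of
#'   [find_seeds()]).
#' @param model [energy_model()].
#' @param seed_len seed length, default 6.
#' @return one-row data.frame `lnc_start`, `lnc_end`, `mrna_start`,
#'   `mrna_end` (0-based half-open, on the respective transcript),
#'   `paired_len` (non-mismatch positions), `energy` (kcal/mol).
#' @export
extend_duplex <- function(lnc_seq, mrna_seq, lnc_pos, mrna_pos,
                          model = energy_model(), seed_len = 6L) {
  r <- extend_duplex_cpp(encode_seq(lnc_seq), encode_seq(mrna_seq),
                         as.integer(lnc_pos) - 1L, as.integer(mrna_pos) - 1L,
                         as.integer(seed_len), model$eGC, model$eAU,
                         model$eGU, model$mismatch, model$xdrop)
  as.data.frame(r)
}

#' Scan one lncRNA-mRNA pair for duplex hits
#'
#' Every seed is extended, overlapping candidates are merged keeping the
#' best-energy hit per overlapping group, and hits are reported when
#' `energy < max_energy` and `paired_len >= min_len`, sorted by energy
#' (most stable first).
#'
#' @param lnc_seq,mrna_seq nucleotide strings.
#' @param model [energy_model()].
#' @param max_energy reporting gate (kcal/mol, strict `<`), default -16.
#' @param min_len minimum paired positions, default 15.
#' @param seed_len seed length, default 6.
#' @return data.frame as in [extend_duplex()], zero or more rows.
#' @export
scan_pair <- function(lnc_seq, mrna_seq, model = energy_model(),
                      max_energy = -16, min_len = 15L, seed_len = 6L) {
  df <- scan_pair_cpp(encode_seq(lnc_seq), encode_seq(mrna_seq),
                      as.integer(seed_len), model$eGC, model$eAU, model$eGU,
                      model$mismatch, model$xdrop, max_energy,
                      as.integer(min_len))
  as.data.frame(df)
}

#' Screen AR-lncRNAs against mRNAs and filter by co-expression
#'
#' All lncRNA x mRNA pairs are scanned with [scan_pair()]; pairs with at
#' least one hit are annotated with the Pearson correlation of their
#' replicate-mean TPM profiles over the lifespan and retained when
#' `|pcc| >= pcc_min` (non-strict). Pairs without a sequence or expression
#' profile are skipped with a warning.
#'
#' @param lnc_ids,mrna_ids transcript id vectors.
#' @param sequences named character vector (or `DNAStringSet`) covering both
#'   sets.
#' @param expr `lnc_expression`.
#' @param model [energy_model()].
#' @param pcc_min absolute-correlation gate, default 0.9.
#' @param max_energy,min_len duplex reporting gates (see [scan_pair()]).
#' @return data.frame: one row per hit with ids, 0-based half-open intervals,
#'   `paired_len`, `energy`, `pcc`, `retained`.
#' @export
screen_and_filter <- function(lnc_ids, mrna_ids, sequences, expr,
                              model = energy_model(), pcc_min = 0.9,
                              max_energy = -16, min_len = 15L) {
  sequences <- setNames(as.character(sequences), names(sequences))
  prof <- mean_tpm_profiles(expr)
  skipped <- 0L
  rows <- list()
  for (ln in lnc_ids) {
    if (is.na(sequences[ln]) || !(ln %in% rownames(prof))) {
      skipped <- skipped + length(mrna_ids)
      next
    }
    lcode <- sequences[[ln]]
    for (mr in mrna_ids) {
      if (is.na(sequences[mr]) || !(mr %in% rownames(prof))) {
        skipped <- skipped + 1L
        next
      }
      hits <- scan_pair(lcode, sequences[[mr]], model,
                        max_energy = max_energy, min_len = min_len)
      if (!nrow(hits)) next
      pcc <- pearson_cc(prof[ln, ], prof[mr, ])
      hits$lncRNA_id <- ln
      hits$mRNA_id <- mr
      hits$pcc <- pcc
      rows[[length(rows) + 1L]] <- hits
    }
  }
  if (skipped)
    warning("screen_and_filter: skipped ", skipped,
            " pairs without sequence or expression")
  if (!length(rows))
    return(data.frame(lncRNA_id = character(), mRNA_id = character(),
                      lnc_start = integer(), lnc_end = integer(),
                      mrna_start = integer(), mrna_end = integer(),
                      paired_len = integer(), energy = numeric(),
                      pcc = numeric(), retained = logical()))
  out <- do.call(rbind, rows)
  out$retained <- !is.na(out$pcc) & abs(out$pcc) >= pcc_min
  cols <- c("lncRNA_id", "mRNA_id", "lnc_start", "lnc_end", "mrna_start",
            "mrna_end", "paired_len", "energy", "pcc", "retained")
  out <- out[order(out$energy, out$lncRNA_id, out$mRNA_id), cols]
  rownames(out) <- NULL
  out
}
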