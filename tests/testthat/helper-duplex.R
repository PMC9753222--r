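# brute-force oracle: best (minimum-energy) ungapped antiparallel alignment
# over all substring pairs, via per-diagonal prefix sums; optionally
# restricted to the reporting gates
brute_best <- function(lnc, mrna, model = energy_model(),
                       max_energy = Inf, min_len = 0L) {
  code <- function(s) match(strsplit(chartr("U", "T", s), "")[[1]],
                            c("A", "C", "G", "T")) - 1L
  a <- code(lnc); b <- code(mrna)
  pe <- function(x, y) {
    if (x + y == 3 && x != y) {
      if (x == 1 || x == 2) model$eGC else model$eAU
    } else if ((x == 2 && y == 3) || (x == 3 && y == 2)) {
      model$eGU
    } else model$mismatch
  }
  paired <- function(x, y) (x + y == 3 && x != y) ||
    (x == 2 && y == 3) || (x == 3 && y == 2)
  best <- Inf
  for (d in 0:(length(a) + length(b) - 2)) {
    ps <- max(0, d - length(b) + 1)
    pend <- min(length(a) - 1, d)
    if (ps > pend) next
    p <- ps:pend
    e <- vapply(p, function(pp) pe(a[pp + 1], b[d - pp + 1]), numeric(1))
    m <- vapply(p, function(pp) paired(a[pp + 1], b[d - pp + 1]),
                logical(1))
    n <- length(e)
    cs <- cumsum(e); cm <- cumsum(m)
    for (i in 1:n) for (j in i:n) {
      en <- cs[j] - if (i > 1) cs[i - 1] else 0
      np <- cm[j] - if (i > 1) cm[i - 1] else 0
      if (np >= min_len && en < max_energy && en < best) best <- en
    }
  }
  best
}

plant_pair <- function(seg_len = 18, flank = 15, gc = TRUE,
                       hard_flanks = FALSE) {
  seg <- paste(sample(if (gc) c("G", "C") else c("A", "C", "G", "T"),
                      seg_len, TRUE), collapse = "")
  fl <- function(n) if (hard_flanks) strrep("A", n) else random_dna(n)
  list(lnc = paste0(fl(flank), seg, fl(flank)),
       mrna = paste0(fl(flank), reverse_complement(seg), fl(flank)),
       seg = seg)
}

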