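#' Upper-tail hypergeometric p-value for shared miRNAs
#'
#' With a universe of `N` miRNAs of which `K` target the mRNA, and `n`
#' targeting the lncRNA, the probability of sharing at least `k` miRNAs by
#' chance is the upper tail `P(X >= k)` of `Hypergeometric(N, K, n)`,
#' evaluated in log space for numerical stability.
#'
#' @param N universe size (all distinct miRNAs).
#' @param K miRNAs targeting the mRNA.
#' @param n miRNAs targeting the lncRNA.
#' @param k shared (junction) miRNAs.
#' @return `P(X >= k)`.
#' @export
hypergeom_pvalue <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n) ||
      k < max(0, K + n - N))
    stop_lncage("hypergeom_pvalue: invalid (N, K, n, k) = (",
                paste(c(N, K, n, k), collapse = ", "), ")")
  if (k == 0) return(1)
  # sum P(X = j) for j = k..min(K, n) in log space
  j <- k:min(K, n)
  logp <- dhyper(j, K, N - K, n, log = TRUE)
  m <- max(logp)
  min(1, exp(m + log(sum(exp(logp - m)))))
}

#' Read a miRNA-target interaction table
#'
#' @param path TSV with columns `mirna_id`, `target_id`, `target_class`
#'   (`mRNA` or `lncRNA`).
#' @return deduplicated data.frame (a `TargetTable`).
#' @export
read_targets <- function(path) {
  tab <- read_table(path)
  need <- c("mirna_id", "target_id", "target_class")
  if (!all(need %in% names(tab)))
    stop_lncage("read_targets: expected columns ",
                paste(need, collapse = ", "))
  unique(tab[, need])
}

#' Discover ceRNA sets by shared-miRNA testing and co-expression
#'
#' Candidate (lncRNA, mRNA) pairs are all pairs sharing at least one
#' targeting miRNA. Each candidate is scored with [hypergeom_pvalue()]
#' (universe = all distinct miRNAs in the table) and with the Pearson
#' correlation of replicate-mean TPM profiles. Retained ceRNA sets satisfy
#' `p < p_max` (strict; optionally BH-adjusted) and `pcc > pcc_min` (strict,
#' signed: only positively correlated pairs qualify). The shared miRNAs form
#' the junction of the set.
#'
#' @param targets data.frame as from [read_targets()].
#' @param expr `lnc_expression` covering the targets (pairs with missing
#'   expression are skipped with a warning).
#' @param p_max p-value gate, default 0.05.
#' @param pcc_min correlation gate, default 0.7.
#' @param adjust apply BH adjustment across candidate pairs (default FALSE:
#'   the screen uses raw p-values).
#' @return data.frame `lncRNA_id`, `mRNA_id`, `n_shared`, `junction`
#'   (comma-separated miRNA ids), `p`, `pcc`, `retained`; ordered by `p` then
#'   ids. The retained subset is the ceRNA set list.
#' @export
find_cerna_sets <- function(targets, expr, p_max = 0.05, pcc_min = 0.7,
                            adjust = FALSE) {
  targets <- unique(targets)
  if (!nrow(targets)) stop_lncage("find_cerna_sets: empty target table")
  universe <- unique(targets$mirna_id)
  N <- length(universe)
  by_target <- split(targets$mirna_id, targets$target_id)
  cls <- tapply(targets$target_class, targets$target_id,
                function(x) x[[1L]])
  lncs <- names(cls)[cls == "lncRNA"]
  mrnas <- names(cls)[cls == "mRNA"]
  if (!length(lncs) || !length(mrnas))
    stop_lncage("find_cerna_sets: need both lncRNA and mRNA targets")

  prof <- mean_tpm_profiles(expr)
  skipped <- 0L
  rows <- list()
  for (ln in lncs) {
    mi_l <- unique(by_target[[ln]])
    for (mr in mrnas) {
      mi_m <- unique(by_target[[mr]])
      shared <- intersect(mi_l, mi_m)
      if (!length(shared)) next
      if (!(ln %in% rownames(prof)) || !(mr %in% rownames(prof))) {
        skipped <- skipped + 1L
        next
      }
      p <- hypergeom_pvalue(N, length(mi_m), length(mi_l), length(shared))
      pcc <- pearson_cc(prof[ln, ], prof[mr, ])
      rows[[length(rows) + 1L]] <- data.frame(
        lncRNA_id = ln, mRNA_id = mr, n_shared = length(shared),
        junction = paste(sort(shared), collapse = ","),
        p = p, pcc = pcc, stringsAsFactors = FALSE)
    }
  }
  if (skipped)
    warning("find_cerna_sets: skipped ", skipped,
            " candidate pairs without expression")
  if (!length(rows))
    return(data.frame(lncRNA_id = character(), mRNA_id = character(),
                      n_shared = integer(), junction = character(),
                      p = numeric(), pcc = numeric(), p_eff = numeric(),
                      retained = logical()))
  out <- do.call(rbind, rows)
  out$p_eff <- if (adjust) bh_adjust(out$p) else out$p
  out$retained <- out$p_eff < p_max & !is.na(out$pcc) & out$pcc > pcc_min
  out <- out[order(out$p, out$lncRNA_id, out$mRNA_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the tripartite ceRNA network
#'
#' Every retained ceRNA set contributes a lncRNA-miRNA and a miRNA-mRNA edge
#' for each junction miRNA.
#'
#' @param sets data.frame of retained ceRNA sets (rows of
#'   [find_cerna_sets()] output with `retained = TRUE`, or any subset).
#' @return list with `edges` (`from`, `to`, `from_type`, `to_type`),
#'   `degrees` (`node`, `type`, `degree`) and `n_nodes` (named counts of
#'   distinct lncRNAs, miRNAs, mRNAs).
#' @export
build_network <- function(sets) {
  if (!nrow(sets)) {
    return(list(edges = data.frame(from = character(), to = character(),
                                   from_type = character(),
                                   to_type = character()),
                degrees = data.frame(node = character(), type = character(),
                                     degree = integer()),
                n_nodes = c(lncRNA = 0L, miRNA = 0L, mRNA = 0L)))
  }
  edges <- list()
  for (i in seq_len(nrow(sets))) {
    mirnas <- strsplit(sets$junction[i], ",")[[1L]]
    edges[[length(edges) + 1L]] <- data.frame(
      from = sets$lncRNA_id[i], to = mirnas,
      from_type = "lncRNA", to_type = "miRNA", stringsAsFactors = FALSE)
    edges[[length(edges) + 1L]] <- data.frame(
      from = mirnas, to = sets$mRNA_id[i],
      from_type = "miRNA", to_type = "mRNA", stringsAsFactors = FALSE)
  }
  edges <- unique(do.call(rbind, edges))
  rownames(edges) <- NULL
  nodes <- rbind(data.frame(node = edges$from, type = edges$from_type),
                 data.frame(node = edges$to, type = edges$to_type))
  deg <- as.data.frame(table(node = nodes$node), stringsAsFactors = FALSE)
  names(deg)[2L] <- "degree"
  deg$type <- nodes$type[match(deg$node, nodes$node)]
  deg <- deg[order(-deg$degree, deg$node), c("node", "type", "degree")]
  rownames(deg) <- NULL
  utype <- unique(nodes)
  list(edges = edges, degrees = deg,
       n_nodes = c(lncRNA = sum(utype$type == "lncRNA"),
                   miRNA = sum(utype$type == "miRNA"),
                   mRNA = sum(utype$type == "mRNA")))
}
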