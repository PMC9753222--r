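#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over transcripts (those
#' with nonzero counts in every sample) of the ratio of the sample's count to
#' the transcript's geometric mean count. When no transcript is nonzero in
#' all samples, total-count ratios (normalized to geometric mean 1) are used
#' with a warning.
#'
#' @param counts matrix, transcripts x samples.
#' @return positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts))
  allpos <- rowSums(counts == 0) == 0
  if (!any(allpos)) {
    warning("size_factors: no transcript with nonzero counts in all samples;",
            " falling back to total-count ratios")
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  m <- counts[allpos, , drop = FALSE]
  geo <- exp(rowMeans(log(m)))
  apply(m / geo, 2, median)
}

#' Negative-binomial Wald test between two endpoint groups
#'
#' A self-contained two-group test on raw counts: counts are normalized by
#' size factors; group means get a pseudo-count of 0.5; the log2 fold change
#' is tested with a Wald statistic whose standard error comes from the
#' delta method under an NB(mean, dispersion) model. The NB dispersion is
#' estimated by the method of moments within each group, pooled across the
#' two groups, and then pooled across all tested transcripts (mean of the
#' positive per-transcript estimates, floored at 1e-8): with few replicates a
#' per-transcript estimate is far too unstable to calibrate the test, while
#' the count model assumes a shared dispersion in the first place.
#'
#' @param counts1,counts2 count matrices (transcripts x replicates) at the
#'   two endpoints; vectors are treated as one transcript.
#' @param sf1,sf2 size factors for the columns of `counts1` / `counts2`.
#' @return data.frame `log2fc`, `se`, `p` (two-sided normal), one row per
#'   transcript; transcripts with all-zero counts at both endpoints get
#'   `log2fc = 0, p = 1`.
#' @export
nb_wald_test <- function(counts1, counts2, sf1 = NULL, sf2 = NULL) {
  if (!is.matrix(counts1)) counts1 <- matrix(counts1, nrow = 1)
  if (!is.matrix(counts2)) counts2 <- matrix(counts2, nrow = 1)
  stopifnot(nrow(counts1) == nrow(counts2))
  n1 <- ncol(counts1); n2 <- ncol(counts2)
  sf1 <- sf1 %||% rep(1, n1); sf2 <- sf2 %||% rep(1, n2)
  q1 <- sweep(counts1, 2, sf1, "/")
  q2 <- sweep(counts2, 2, sf2, "/")
  mu1 <- rowMeans(q1); mu2 <- rowMeans(q2)
  m1 <- mu1 + 0.5; m2 <- mu2 + 0.5
  log2fc <- log2(m2 / m1)

  disp_mom <- function(q, mu, n) {
    if (n < 2) return(rep(NA_real_, length(mu)))
    v <- rowSums((q - mu)^2) / (n - 1)
    (v - mu) / mu^2
  }
  a1 <- disp_mom(q1, mu1, n1)
  a2 <- disp_mom(q2, mu2, n2)
  w1 <- if (n1 >= 2) n1 - 1 else 0
  w2 <- if (n2 >= 2) n2 - 1 else 0
  araw <- (w1 * ifelse(is.na(a1), 0, a1) + w2 * ifelse(is.na(a2), 0, a2)) /
    max(w1 + w2, 1)
  araw[!is.finite(araw)] <- NA
  pooled <- mean(pmax(araw, 0), na.rm = TRUE)
  alpha <- max(if (is.finite(pooled)) pooled else 0, 1e-8)

  se <- sqrt((m1 + alpha * m1^2) / (n1 * m1^2) +
             (m2 + alpha * m2^2) / (n2 * m2^2)) / log(2)
  z <- log2fc / se
  p <- 2 * pnorm(-abs(z))
  zero <- rowSums(counts1) + rowSums(counts2) == 0
  log2fc[zero] <- 0
  p[zero] <- 1
  data.frame(log2fc = log2fc, se = se, p = pmin(p, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' preserving the input order.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted values, same order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop_lncage("bh_adjust: p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Default developmental window contrasts
#'
#' Growth-to-maturation (4 to 18 d), maturation-to-senescence (16 to 30 d)
#' and the full lifespan (4 to 30 d).
#'
#' @return data.frame `name`, `start_day`, `end_day`.
#' @export
default_contrasts <- function() {
  data.frame(name = c("G_to_M", "M_to_S", "G_to_S"),
             start_day = c(4L, 16L, 4L),
             end_day = c(18L, 30L, 30L),
             stringsAsFactors = FALSE)
}

#' Call age-related transcripts over developmental windows
#'
#' For each contrast the endpoint timepoints are tested with
#' [nb_wald_test()] (size factors computed once over all samples), p-values
#' are BH-adjusted within the contrast across the tested transcripts, and a
#' transcript is age-related (AR) in a contrast when `|log2fc| >= lfc_min`
#' and `p_adj <= padj_max`. The AR set is the union over contrasts.
#'
#' @param expr `lnc_expression`.
#' @param ids transcript ids to test (e.g. the identified lncRNAs).
#' @param contrasts data.frame as from [default_contrasts()].
#' @param lfc_min absolute log2 fold-change gate, default 1.
#' @param padj_max adjusted-p gate, default 0.05.
#' @return list with `results` (per transcript x contrast: `log2fc`, `p`,
#'   `p_adj`, `is_AR`), `ar_ids` (union), and `summary` (per-contrast up/down
#'   counts).
#' @export
call_ar_lncrnas <- function(expr, ids, contrasts = default_contrasts(),
                            lfc_min = 1, padj_max = 0.05) {
  miss <- setdiff(ids, rownames(expr$counts))
  if (length(miss))
    stop_lncage("call_ar_lncrnas: no expression for ", miss[[1L]])
  sf <- size_factors(expr$counts)
  res <- list()
  for (i in seq_len(nrow(contrasts))) {
    ct <- contrasts[i, ]
    i1 <- which(expr$samples$day == ct$start_day)
    i2 <- which(expr$samples$day == ct$end_day)
    if (!length(i1) || !length(i2))
      stop_lncage("call_ar_lncrnas: contrast ", ct$name,
                  " endpoint missing from samples")
    wt <- nb_wald_test(expr$counts[ids, i1, drop = FALSE],
                       expr$counts[ids, i2, drop = FALSE],
                       sf[i1], sf[i2])
    p_adj <- bh_adjust(wt$p)
    res[[ct$name]] <- data.frame(
      transcript_id = ids, contrast = ct$name, log2fc = wt$log2fc,
      p = wt$p, p_adj = p_adj,
      is_AR = abs(wt$log2fc) >= lfc_min & p_adj <= padj_max,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  ar_ids <- unique(results$transcript_id[results$is_AR])
  summary <- do.call(rbind, lapply(split(results, results$contrast),
    function(d) data.frame(contrast = d$contrast[[1L]],
                           n_AR = sum(d$is_AR),
                           n_up = sum(d$is_AR & d$log2fc > 0),
                           n_down = sum(d$is_AR & d$log2fc < 0))))
  rownames(summary) <- NULL
  list(results = results, ar_ids = ar_ids, summary = summary)
}

#' Temporal log2 fold-change profiles
#'
#' Replicate-mean TPM with a pseudo-count of 0.5, expressed as log2 ratio to
#' the first timepoint — the representation used for temporal clustering.
#'
#' @param expr `lnc_expression`.
#' @param ids transcript ids.
#' @return matrix transcripts x timepoints of log2 ratios (first column 0).
#' @export
log2fc_profiles <- function(expr, ids) {
  prof <- mean_tpm_profiles(expr, ids)
  log2((prof + 0.5) / (prof[, 1L] + 0.5))
}

#' k-means clustering of temporal profiles
#'
#' Profiles are z-scored per transcript, clustered with `stats::kmeans`
#' (fixed seed, `nstart` restarts), and the clusters are relabelled from
#' their mean unstandardized profiles: clusters whose terminal log2
#' fold-change is positive become `U*`, negative become `D*`; within each
#' direction, clusters are numbered by the time at which half the terminal
#' change is reached (earliest first). The relabelling is a pure function of
#' the cluster centroids, so it does not depend on k-means' internal label
#' permutation.
#'
#' @param profiles matrix of log2 fold-change profiles (see
#'   [log2fc_profiles()]).
#' @param k number of clusters, default 6.
#' @param seed RNG seed for the restarts.
#' @param nstart random restarts, default 50.
#' @return list with `assignment` (data.frame `transcript_id`, `cluster`),
#'   `centroids` (cluster x timepoint mean log2FC matrix).
#' @export
kmeans_clusters <- function(profiles, k = 6L, seed = 1L, nstart = 50L) {
  if (nrow(profiles) < k)
    stop_lncage("kmeans_clusters: fewer profiles than clusters")
  z <- t(apply(profiles, 1, function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  km <- with_seed(seed, kmeans(z, centers = k, nstart = nstart,
                               iter.max = 100L))
  centroids <- do.call(rbind, lapply(seq_len(k), function(cl) {
    colMeans(profiles[km$cluster == cl, , drop = FALSE])
  }))
  labels <- relabel_clusters(centroids)
  data.frame(transcript_id = rownames(profiles),
             cluster = labels[km$cluster], stringsAsFactors = FALSE) -> asg
  rownames(centroids) <- labels
  list(assignment = asg, centroids = centroids[order(labels), , drop = FALSE])
}

# direction from terminal mean log2FC; rank within direction by the first
# (interpolated) time index at which half the terminal change is reached
relabel_clusters <- function(centroids) {
  term <- centroids[, ncol(centroids)]
  half_time <- apply(centroids, 1, function(p) {
    tgt <- p[[length(p)]] / 2
    if (tgt == 0) return(Inf)
    cross <- if (tgt > 0) which(p >= tgt) else which(p <= tgt)
    if (!length(cross)) return(Inf)
    i <- cross[[1L]]
    if (i == 1L) return(1)
    i - 1 + (tgt - p[[i - 1L]]) / (p[[i]] - p[[i - 1L]])
  })
  up <- which(term >= 0)
  down <- which(term < 0)
  labels <- character(nrow(centroids))
  labels[up[order(half_time[up])]] <- paste0("U", seq_along(up))
  labels[down[order(half_time[down])]] <- paste0("D", seq_along(down))
  labels
}

#' Nuclear/cytosolic localization call
#'
#' A transcript is `nuclear` when its nuclear TPM strictly exceeds its
#' cytosolic TPM; ties go to `cytosolic` (an arbitrary but fixed break).
#' Transcripts absent (zero) from both fractions are excluded.
#'
#' @param fractions data.frame `transcript_id`, `nuclear_tpm`,
#'   `cytosolic_tpm`.
#' @return data.frame `transcript_id`, `localization`.
#' @export
localization_enrichment <- function(fractions) {
  keep <- fractions$nuclear_tpm > 0 | fractions$cytosolic_tpm > 0
  f <- fractions[keep, , drop = FALSE]
  data.frame(transcript_id = f$transcript_id,
             localization = ifelse(f$nuclear_tpm > f$cytosolic_tpm,
                                   "nuclear", "cytosolic"),
             stringsAsFactors = FALSE)
}

#' Overlap of the AR set with stress-responsive sets
#'
#' @param ar_ids AR transcript ids.
#' @param stress_sets named list of transcript id vectors (one per
#'   condition).
#' @return data.frame `condition`, `n_stress`, `n_overlap`, `fraction`.
#' @export
stress_overlap <- function(ar_ids, stress_sets) {
  do.call(rbind, lapply(names(stress_sets), function(cond) {
    s <- unique(stress_sets[[cond]])
    ov <- sum(s %in% ar_ids)
    data.frame(condition = cond, n_stress = length(s), n_overlap = ov,
               fraction = if (length(s)) ov / length(s) else 0,
               stringsAsFactors = FALSE)
  }))
}
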