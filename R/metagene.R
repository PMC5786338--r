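#' Metagene ramp profile of normalized footprint density
#'
#' Each gene's profile is divided by its own mean over informative
#' positions (positions with at least one footprint), aligned from the
#' start codon (positive positions, 1 = start) or from the stop codon
#' (negative positions, -1 = stop), and averaged with equal gene weight
#' at every aligned position covered by the gene.
#'
#' @param profiles named list of per-codon count vectors.
#' @param align `"start"` or `"stop"`.
#' @param max_pos number of aligned positions returned.
#' @return a data.frame (class `metagene_curve`) with `position`,
#'   `value` and `n_genes`.
#' @export
ramp_profile <- function(profiles, align = c("start", "stop"),
                         max_pos = 500L) {
  align <- match.arg(align)
  stopifnot(is.list(profiles), length(profiles) > 0L)
  acc <- numeric(max_pos); n <- integer(max_pos)
  for (p in profiles) {
    inf_pos <- p > 0
    if (!any(inf_pos)) next
    v <- p / mean(p[inf_pos])
    if (align == "stop") v <- rev(v)
    m <- min(length(v), max_pos)
    acc[1:m] <- acc[1:m] + v[1:m]
    n[1:m] <- n[1:m] + 1L
  }
  pos <- if (align == "start") seq_len(max_pos) else -seq_len(max_pos)
  out <- data.frame(position = pos,
                    value = ifelse(n > 0, acc / pmax(n, 1L), NA_real_),
                    n_genes = n)
  class(out) <- c("metagene_curve", "data.frame")
  out
}

# truncated moving average over +/- window positions
.smooth_ma <- function(x, window) {
  if (window <= 0) return(x)
  n <- length(x)
  ok <- !is.na(x)
  xs <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xs)); cn <- c(0, cumsum(as.numeric(ok)))
  lo <- pmax(seq_len(n) - window, 1L); hi <- pmin(seq_len(n) + window, n)
  s <- cs[hi + 1L] - cs[lo]; k <- cn[hi + 1L] - cn[lo]
  ifelse(k > 0, s / k, NA_real_)
}

#' Positional frequencies of codon groups binned by mean elongation rate
#'
#' Codons (stop codons excluded) are grouped by their codon-specific mean
#' elongation rate (MER) into half-open bins `[a, b)`; at each position
#' the fraction of genes whose codon falls in each group is reported,
#' optionally smoothed by a truncated moving average over
#' `i - smooth .. i + smooth`.
#'
#' @param sequences named list of codon vectors.
#' @param mer_by_codon named numeric vector of MERs for the 61 sense
#'   codons.
#' @param bin_edges increasing MER bin edges; the default
#'   `c(4, 6, 8, 10, 12, Inf)` yields five groups.
#' @param max_pos number of start-aligned positions.
#' @param smooth moving-average half-width in codons (0 = raw).
#' @return a data.frame with `position`, `group` (factor), `freq`, `n`.
#' @export
codon_group_frequencies <- function(sequences, mer_by_codon,
                                    bin_edges = c(4, 6, 8, 10, 12, Inf),
                                    max_pos = 300L, smooth = 0L) {
  stop_codons <- c("TAA", "TAG", "TGA")
  groups <- cut(mer_by_codon, breaks = bin_edges, right = FALSE,
                include.lowest = FALSE)
  n_grp <- nlevels(groups)
  counts <- matrix(0, nrow = max_pos, ncol = n_grp)
  n <- integer(max_pos)
  for (s in sequences) {
    m <- min(length(s), max_pos)
    idx <- seq_len(m)
    cod <- s[idx]
    sense <- !(cod %in% stop_codons) & cod %in% names(mer_by_codon)
    g <- as.integer(groups[match(cod[sense], names(mer_by_codon))])
    at <- idx[sense]
    for (k in seq_len(n_grp))
      counts[at[g == k], k] <- counts[at[g == k], k] + 1L
    n[at] <- n[at] + 1L
  }
  freq <- counts / pmax(n, 1L)
  if (smooth > 0)
    for (k in seq_len(n_grp)) freq[, k] <- .smooth_ma(freq[, k], smooth)
  data.frame(position = rep(seq_len(max_pos), n_grp),
             group = factor(rep(levels(groups), each = max_pos),
                            levels = levels(groups)),
             freq = as.vector(freq), n = rep(n, n_grp))
}

#' Positional mean elongation rates per codon type
#'
#' For each codon type, the mean inferred rate around each position
#' (averaging positions `i - window .. i + window` across genes), plus
#' the frequency-weighted overall curve and the codon-frequency-only
#' counterfactual obtained by replacing every rate with its codon-type
#' MER (which isolates how much of a positional trend is explained by
#' codon usage alone).
#'
#' @param rates_by_gene named list of per-position rate vectors.
#' @param codons_by_gene matching list of codon vectors.
#' @param window smoothing half-width in codons.
#' @param max_pos number of start-aligned positions.
#' @return a list with `per_codon` (position x codon matrix of smoothed
#'   means), `weighted_mean` (frequency-weighted curve),
#'   `counterfactual` (codon-usage-only curve) and `mer` (codon MERs).
#' @export
positional_mer <- function(rates_by_gene, codons_by_gene, window = 20L,
                           max_pos = 300L) {
  stopifnot(length(rates_by_gene) == length(codons_by_gene))
  stop_codons <- c("TAA", "TAG", "TGA")
  all_cod <- unique(unlist(lapply(codons_by_gene, unique)))
  all_cod <- sort(setdiff(all_cod, stop_codons))
  sum_m <- matrix(0, max_pos, length(all_cod),
                  dimnames = list(NULL, all_cod))
  cnt_m <- matrix(0, max_pos, length(all_cod),
                  dimnames = list(NULL, all_cod))
  mer_sum <- setNames(numeric(length(all_cod)), all_cod)
  mer_n <- setNames(numeric(length(all_cod)), all_cod)
  for (g in seq_along(rates_by_gene)) {
    r <- rates_by_gene[[g]]; cod <- codons_by_gene[[g]]
    m <- min(length(r), max_pos)
    for (i in seq_len(m)) {
      cj <- cod[i]
      if (cj %in% stop_codons) next
      sum_m[i, cj] <- sum_m[i, cj] + r[i]
      cnt_m[i, cj] <- cnt_m[i, cj] + 1
    }
    keep <- !(cod %in% stop_codons)
    tab <- tapply(r[keep], cod[keep], sum)
    mer_sum[names(tab)] <- mer_sum[names(tab)] + tab
    tabn <- table(cod[keep])
    mer_n[names(tabn)] <- mer_n[names(tabn)] + tabn
  }
  mer <- ifelse(mer_n > 0, mer_sum / mer_n, NA_real_)
  # windowed positional means per codon type
  sm_sum <- apply(sum_m, 2, function(x) {
    cs <- c(0, cumsum(x))
    lo <- pmax(seq_len(max_pos) - window, 1L)
    hi <- pmin(seq_len(max_pos) + window, max_pos)
    cs[hi + 1L] - cs[lo]
  })
  sm_cnt <- apply(cnt_m, 2, function(x) {
    cs <- c(0, cumsum(x))
    lo <- pmax(seq_len(max_pos) - window, 1L)
    hi <- pmin(seq_len(max_pos) + window, max_pos)
    cs[hi + 1L] - cs[lo]
  })
  per_codon <- ifelse(sm_cnt > 0, sm_sum / sm_cnt, NA_real_)
  w <- sm_cnt / pmax(rowSums(sm_cnt), 1)
  weighted_mean <- rowSums(per_codon * w, na.rm = TRUE)
  # counterfactual: every rate replaced by its codon MER
  cf_num <- sweep(sm_cnt, 2, mer, `*`)
  counterfactual <- rowSums(cf_num, na.rm = TRUE) /
    pmax(rowSums(sm_cnt), 1)
  list(per_codon = per_codon, weighted_mean = weighted_mean,
       counterfactual = counterfactual, mer = mer)
}

#' Aligned unobstructed and observed rate curves and their gap
#'
#' Averages the unobstructed rate (`lambda`) and the observed rate
#' (inverse mean dwell time) across genes at each aligned position; the
#' gap between them quantifies the positional impact of ribosomal
#' interference (it peaks one footprint upstream of a strong stall, e.g.
#' at position -10 relative to a slow stop codon).
#'
#' @param sims list of `tasep_sim` objects.
#' @param align `"start"` or `"stop"`.
#' @param max_pos number of aligned positions.
#' @return a data.frame with `position`, `unobstructed`, `observed`,
#'   `gap` and `n_genes`.
#' @export
rate_gap_curves <- function(sims, align = c("start", "stop"),
                            max_pos = 300L) {
  align <- match.arg(align)
  acc_u <- numeric(max_pos); acc_o <- numeric(max_pos)
  n <- integer(max_pos)
  for (s in sims) {
    stopifnot(inherits(s, "tasep_sim"))
    u <- s$unobstructed_rate; o <- s$observed_rate
    if (align == "stop") { u <- rev(u); o <- rev(o) }
    m <- min(length(u), max_pos)
    ok <- !is.na(o[1:m])
    acc_u[1:m][ok] <- acc_u[1:m][ok] + u[1:m][ok]
    acc_o[1:m][ok] <- acc_o[1:m][ok] + o[1:m][ok]
    n[1:m][ok] <- n[1:m][ok] + 1L
  }
  pos <- if (align == "start") seq_len(max_pos) else -seq_len(max_pos)
  data.frame(position = pos,
             unobstructed = ifelse(n > 0, acc_u / pmax(n, 1L), NA_real_),
             observed = ifelse(n > 0, acc_o / pmax(n, 1L), NA_real_),
             gap = ifelse(n > 0, (acc_u - acc_o) / pmax(n, 1L), NA_real_),
             n_genes = n)
}

#' Positional frequencies of charged amino acids
#'
#' The fraction of sequences carrying a positively charged residue (K or
#' R) and a negatively charged residue (D or E) at each position, raw and
#' smoothed over a `window`-codon moving average.  Ambiguous residues are
#' excluded from both counts (and from the denominator at that position).
#'
#' @param protein_sequences character vector (or list) of one-letter
#'   amino-acid sequences; only sequences of at least `max_pos` residues
#'   enter the curves.
#' @param max_pos number of positions.
#' @param window smoothing half-width... the smoothed value at `i`
#'   averages positions within `window`/2 either side (truncated at the
#'   ends).
#' @param min_len minimal sequence length to be included.
#' @return a data.frame with `position`, `freq_positive`,
#'   `freq_negative`, `smooth_positive`, `smooth_negative`, `n`.
#' @export
charge_frequency_metagene <- function(protein_sequences, max_pos = 200L,
                                      window = 10L, min_len = 200L) {
  seqs <- vapply(protein_sequences, paste, "", collapse = "")
  seqs <- seqs[nchar(seqs) >= min_len]
  if (!length(seqs)) stop("no sequence of length >= ", min_len)
  pos_cnt <- integer(max_pos); neg_cnt <- integer(max_pos)
  n <- integer(max_pos)
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  for (s in seqs) {
    aa <- strsplit(s, "")[[1L]]
    m <- min(length(aa), max_pos)
    a <- aa[1:m]
    known <- a %in% std
    pos_cnt[1:m] <- pos_cnt[1:m] + (known & a %in% c("K", "R"))
    neg_cnt[1:m] <- neg_cnt[1:m] + (known & a %in% c("D", "E"))
    n[1:m] <- n[1:m] + known
  }
  fp <- ifelse(n > 0, pos_cnt / pmax(n, 1L), NA_real_)
  fn <- ifelse(n > 0, neg_cnt / pmax(n, 1L), NA_real_)
  half <- max(1L, as.integer(round(window / 2)))
  data.frame(position = seq_len(max_pos), freq_positive = fp,
             freq_negative = fn,
             smooth_positive = .smooth_ma(fp, half),
             smooth_negative = .smooth_ma(fn, half), n = n)
}

#' Write a metagene curve as TSV
#'
#' @param curve a data.frame from one of the metagene operators.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(curve, path) {
  write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
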