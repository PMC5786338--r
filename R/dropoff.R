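#' Binned log-mean normalized footprint coverage
#'
#' Divides the region into consecutive bins of `bin_size` codons,
#' normalizes each gene's per-codon counts by the gene mean, averages the
#' normalized counts within each bin across genes and positions, and
#' returns the logarithm of the bin averages.  A constant drop-off rate
#' produces a linear decay of these log-means in the bin index.
#'
#' @param profiles named list of per-codon count vectors; only genes
#'   covering the full region are used.
#' @param bin_size bin width in codons (default 25).
#' @param region inclusive codon interval `c(from, to)` (default
#'   `c(25, 225)`).
#' @return a data.frame with `bin` (1-based index), `log_mean`, `n_obs`;
#'   empty bins are dropped with a warning.
#' @export
bin_log_means <- function(profiles, bin_size = 25L, region = c(25L, 225L)) {
  stopifnot(bin_size >= 1L, region[2L] > region[1L])
  use <- Filter(function(p) length(p) >= region[2L], profiles)
  if (!length(use)) stop("no gene covers the region")
  edges <- seq(region[1L], region[2L], by = bin_size)
  n_bins <- length(edges) - 1L
  if (n_bins < 1L) stop("region shorter than one bin")
  sums <- numeric(n_bins); cnts <- numeric(n_bins)
  for (p in use) {
    v <- p / mean(p)
    for (b in seq_len(n_bins)) {
      i <- seq(edges[b], edges[b + 1L] - 1L)
      sums[b] <- sums[b] + sum(v[i])
      cnts[b] <- cnts[b] + length(i)
    }
  }
  keep <- cnts > 0 & sums > 0
  if (!all(keep)) warning(sum(!keep), " empty bin(s) dropped")
  data.frame(bin = seq_len(n_bins)[keep],
             log_mean = log(sums[keep] / cnts[keep]),
             n_obs = cnts[keep])
}

#' Fit an exponential decay A e^(-Q X) to bin averages
#'
#' Ordinary least squares of the log bin means on the (1-based) bin
#' index: `Q` is minus the slope, `A = exp(intercept)` (evaluated at
#' X = 0 by convention; the indexing base affects only `A`, never `Q`).
#'
#' @param bins data.frame from [bin_log_means()] (columns `bin`,
#'   `log_mean`), or a bare numeric vector of positive bin means.
#' @return a list with `A`, `Q` and the `lm` fit.
#' @export
fit_decay <- function(bins) {
  if (is.numeric(bins)) {
    if (any(bins <= 0)) stop("bin values must be positive")
    bins <- data.frame(bin = seq_along(bins), log_mean = log(bins))
  }
  if (nrow(bins) < 3L) stop("need at least 3 bins")
  fit <- lm(log_mean ~ bin, data = bins)
  list(A = exp(unname(coef(fit)[1L])), Q = -unname(coef(fit)[2L]),
       lm = fit)
}

#' Convert a per-bin decay coefficient to a per-codon drop-off rate
#'
#' The per-codon survival `1 - r` compounds over a bin to `e^{-Q}`, so
#' the rate is `1 - exp(-Q / bin_size)`.  A negative `Q` (coverage increasing
#' along the region) yields a rate of 0 with a warning.
#'
#' @param Q per-bin decay coefficient.
#' @param bin_size bin width in codons.
#' @return drop-off probability per codon and per elongation event.
#' @export
q_to_rate <- function(Q, bin_size = 25L) {
  if (Q < 0) {
    warning("negative decay coefficient; drop-off rate set to 0")
    return(0)
  }
  1 - exp(-Q / bin_size)
}

#' Survival probability after translating n codons
#'
#' @param r per-codon drop-off probability (`0 <= r < 1`).
#' @param n_codons number of codons translated.
#' @return `(1 - r)^n_codons`.
#' @export
dropoff_survival <- function(r, n_codons) {
  stopifnot(r >= 0, r < 1, n_codons >= 0)
  (1 - r)^n_codons
}

#' Estimate the drop-off rate from footprint profiles
#'
#' Orchestrates [bin_log_means()], [fit_decay()] and [q_to_rate()], with
#' an optional bootstrap over genes (resampling genes with replacement
#' and refitting) for the distribution of `Q`.
#'
#' @param profiles named list of per-codon count vectors.
#' @param bin_size bin width in codons.
#' @param region codon interval fitted.
#' @param n_boot bootstrap replicates (0 = none).
#' @param seed seed for the bootstrap resampling.
#' @return a list of class `dropoff_fit` with `A`, `Q`, `r`, `bin_size`,
#'   `region`, `bins` and (optionally) `bootstrap_Q`.
#' @export
estimate_dropoff <- function(profiles, bin_size = 25L,
                             region = c(25L, 225L), n_boot = 0L,
                             seed = 1L) {
  bins <- bin_log_means(profiles, bin_size, region)
  dec <- fit_decay(bins)
  boot <- NULL
  if (n_boot > 0L) {
    use <- Filter(function(p) length(p) >= region[2L], profiles)
    set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(i) {
      res <- use[sample.int(length(use), replace = TRUE)]
      fit_decay(bin_log_means(res, bin_size, region))$Q
    }, 0)
  }
  structure(list(A = dec$A, Q = dec$Q, r = q_to_rate(dec$Q, bin_size),
                 bin_size = bin_size, region = region, bins = bins,
                 bootstrap_Q = boot),
            class = "dropoff_fit")
}

#' @export
print.dropoff_fit <- function(x, ...) {
  cat(sprintf(
    "<dropoff_fit> region [%d, %d], bin %d: Q = %.4g, r = %.3g per codon\n",
    x$region[1L], x$region[2L], x$bin_size, x$Q, x$r))
  invisible(x)
}
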