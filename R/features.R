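#' Kyte-Doolittle hydropathy scale
#'
#' Named numeric vector of hydropathy values for the 20 standard amino
#' acids (positive = hydrophobic).
#'
#' @return named numeric vector.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Windowed nascent-chain / mRNA feature specification
#'
#' A feature is defined by its kind, an inclusive window `[a:b]` of codon
#' offsets, and its side relative to the A-site.  Charge features
#' (`positive_charge` = K/R, `negative_charge` = D/E) are counts over an
#' upstream window (positions `i - b .. i - a` for A-site `i`);
#' `hydropathy` is the Kyte-Doolittle mean over an upstream window; and
#' `pars` is the mean per-codon PARS score over a downstream window
#' (positions `i + a .. i + b`).  Windows extending past the ORF are
#' truncated to the available positions (an empty truncated window
#' contributes a count of 0, or `NA` for mean-type features).
#'
#' @param kind one of `"negative_charge"`, `"positive_charge"`,
#'   `"hydropathy"`, `"pars"`.
#' @param window integer `c(a, b)` with `0 <= a <= b`.
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(kind = c("negative_charge", "positive_charge",
                                  "hydropathy", "pars"),
                         window) {
  kind <- match.arg(kind)
  window <- as.integer(window)
  if (length(window) != 2L || window[1L] < 0L || window[2L] < window[1L])
    stop("`window` must be c(a, b) with 0 <= a <= b")
  structure(list(
    kind = kind, window = window,
    side = if (kind == "pars") "downstream" else "upstream",
    aggregation = if (kind %in% c("hydropathy", "pars")) "mean"
                  else "count"),
    class = "feature_spec")
}

# per-gene windowed aggregate of `values` at positions 1..L for every
# A-site position 1..L; count features sum, mean features average; empty
# windows give 0 (count) or NA (mean).
.window_aggregate <- function(values, a, b, side, aggregation) {
  L <- length(values)
  i <- seq_len(L)
  if (side == "upstream") { lo <- i - b; hi <- i - a }
  else                    { lo <- i + a; hi <- i + b }
  lo <- pmax(lo, 1L); hi <- pmin(hi, L)
  width <- pmax(hi - lo + 1L, 0L)
  cs <- c(0, cumsum(ifelse(is.na(values), 0, values)))
  cn <- c(0, cumsum(as.numeric(!is.na(values))))
  s <- ifelse(width > 0, cs[pmax(hi, 1L) + 1L] - cs[pmin(lo, L)], 0)
  k <- ifelse(width > 0, cn[pmax(hi, 1L) + 1L] - cn[pmin(lo, L)], 0)
  if (aggregation == "count") s
  else ifelse(k > 0, s / k, NA_real_)
}

# per-gene raw value track for a feature kind
.feature_track <- function(gene, kind) {
  switch(kind,
    positive_charge = as.numeric(gene$aa %in% c("K", "R")),
    negative_charge = as.numeric(gene$aa %in% c("D", "E")),
    hydropathy = unname(kyte_doolittle()[gene$aa]),
    pars = gene$pars,
    stop("unknown feature kind: ", kind))
}

#' Position-wise feature covariate averaged over a gene set
#'
#' Computes, for every position `i`, the mean over genes of the per-gene
#' window aggregate defined by the spec (see [feature_spec()]).  Genes
#' are lists with components `aa` (one-letter amino-acid vector, one per
#' codon) and, for PARS features, `pars` (per-codon scores).
#'
#' @param genes list of gene objects.
#' @param spec a [feature_spec()].
#' @param max_pos number of positions returned.
#' @return numeric vector `x` of length `max_pos` (`NA` where no gene
#'   contributes a defined aggregate).
#' @export
compute_feature <- function(genes, spec, max_pos = 300L) {
  stopifnot(inherits(spec, "feature_spec"))
  acc <- numeric(max_pos); n <- numeric(max_pos)
  for (g in genes) {
    v <- .feature_track(g, spec$kind)
    agg <- .window_aggregate(v, spec$window[1L], spec$window[2L],
                             spec$side, spec$aggregation)
    m <- min(length(agg), max_pos)
    ok <- !is.na(agg[1:m])
    acc[1:m][ok] <- acc[1:m][ok] + agg[1:m][ok]
    n[1:m][ok] <- n[1:m][ok] + 1
  }
  ifelse(n > 0, acc / pmax(n, 1), NA_real_)
}

#' Position-wise mean deviation of elongation rates from codon means
#'
#' The dependent variable of the feature regression: at each position
#' `i`, the mean over genes of the inferred rate minus the codon-type
#' mean elongation rate (the latter averaged over all transcripts and
#' positions).
#'
#' @param rates_by_gene list of per-position rate vectors.
#' @param codons_by_gene matching list of codon vectors.
#' @param max_pos number of positions.
#' @return a list with `y` (deviation curve), `n_genes` (support) and
#'   `codon_means`.
#' @export
mean_rate_deviation <- function(rates_by_gene, codons_by_gene,
                                max_pos = 300L) {
  stopifnot(length(rates_by_gene) == length(codons_by_gene))
  all_r <- unlist(rates_by_gene)
  all_c <- unlist(codons_by_gene)
  codon_means <- tapply(all_r, all_c, mean)
  acc <- numeric(max_pos); n <- integer(max_pos)
  for (g in seq_along(rates_by_gene)) {
    r <- rates_by_gene[[g]]; cod <- codons_by_gene[[g]]
    m <- min(length(r), max_pos)
    dev <- r[1:m] - codon_means[cod[1:m]]
    acc[1:m] <- acc[1:m] + dev
    n[1:m] <- n[1:m] + 1L
  }
  list(y = ifelse(n > 0, acc / pmax(n, 1L), NA_real_), n_genes = n,
       codon_means = codon_means)
}

#' Ordinary least squares fit of the positional deviation curve
#'
#' Fits `y_i = sum_k beta_k x_{i,k} + eps` over a position region by OLS
#' with an intercept (reported separately; the deviations need not be
#' mean-zero over a sub-region).  Near-collinear feature columns trigger
#' a condition-number warning.
#'
#' @param y deviation curve (full-length vector).
#' @param x_table matrix or data.frame of feature columns (full-length).
#' @param region integer `c(start, end)` of codon positions to fit.
#' @param intercept include an intercept (default TRUE).
#' @return a list of class `feature_fit` with `betas`, `intercept`,
#'   `r_squared`, `fitted`, `region` and the `lm` object.
#' @export
fit_linear <- function(y, x_table, region, intercept = TRUE) {
  x_table <- as.matrix(x_table)
  idx <- seq(region[1L], region[2L])
  yy <- y[idx]; X <- x_table[idx, , drop = FALSE]
  ok <- complete.cases(cbind(yy, X))
  yy <- yy[ok]; X <- X[ok, , drop = FALSE]
  if (ncol(X) > 1L) {
    sv <- svd(scale(X, scale = FALSE))$d
    if (sv[length(sv)] < 1e-10 * sv[1L])
      warning("feature columns are (near-)collinear; condition number ",
              format(sv[1L] / max(sv[length(sv)], 1e-300), digits = 3))
  }
  fml <- if (intercept) yy ~ X else yy ~ X - 1
  fit <- lm(fml)
  cf <- coef(fit)
  tss <- if (intercept) sum((yy - mean(yy))^2) else sum(yy^2)
  r2 <- if (tss > 0) 1 - sum(residuals(fit)^2) / tss else NA_real_
  betas <- cf[grep("^X", names(cf))]
  names(betas) <- colnames(X)
  structure(list(
    betas = betas,
    intercept = if (intercept) unname(cf["(Intercept)"]) else 0,
    r_squared = r2, fitted = fitted(fit), region = region, lm = fit),
    class = "feature_fit")
}

#' @export
print.feature_fit <- function(x, ...) {
  cat(sprintf("<feature_fit> region [%d:%d], R^2 = %.4f\n",
              x$region[1L], x$region[2L], x$r_squared))
  print(round(x$betas, 4))
  invisible(x)
}

#' Exhaustive window scan maximizing the linear-model fit
#'
#' For each requested feature kind, candidate inclusive windows `[a:b]`
#' with `a` in `bounds$a` and `b` in `a .. bounds$b_max` are generated;
#' the combination of one window per kind maximizing the OLS R-squared
#' over the region is returned, with ties broken toward smaller windows
#' (smaller total width, then smaller `a`).  One and two kinds are
#' scanned exhaustively by correlation algebra; three or more kinds are
#' optimized by coordinate ascent over the same grids.
#'
#' @param y deviation curve.
#' @param genes gene list (see [compute_feature()]).
#' @param kinds character vector of feature kinds to scan.
#' @param region integer `c(start, end)`.
#' @param bounds list with `a` (candidate values of `a`) and `b_max`.
#' @param max_pos length of the position axis.
#' @return a list with `specs` (best [feature_spec()] per kind), `fit`
#'   (the corresponding [fit_linear()] result) and `r_squared`.
#' @export
scan_windows <- function(y, genes, kinds, region,
                         bounds = list(a = 0:15, b_max = 45L),
                         max_pos = 300L) {
  stopifnot(length(kinds) >= 1L)
  idx <- seq(region[1L], region[2L])
  yy <- y[idx]
  if (anyNA(yy)) stop("deviation curve undefined inside the region")
  wins <- do.call(rbind, lapply(bounds$a, function(a) {
    bs <- seq.int(a, bounds$b_max)
    cbind(a = a, b = bs)
  }))
  if (!nrow(wins)) stop("empty window grid")
  # feature matrix per kind: rows = region positions, cols = windows
  feats <- lapply(kinds, function(kind) {
    F <- vapply(seq_len(nrow(wins)), function(w) {
      x <- compute_feature(genes,
                           feature_spec(kind, wins[w, ]), max_pos)
      x[idx]
    }, numeric(length(idx)))
    keep <- colSums(is.na(F)) == 0L &
      apply(F, 2, function(z) sd(z, na.rm = TRUE) > 0)
    list(F = F[, keep, drop = FALSE], wins = wins[keep, , drop = FALSE])
  })
  names(feats) <- kinds
  width <- function(w) w[2L] - w[1L]

  pick <- if (length(kinds) == 1L) {
    r <- as.vector(stats::cor(feats[[1L]]$F, yy))
    .best_window(r^2, list(feats[[1L]]$wins))
  } else if (length(kinds) == 2L) {
    F1 <- feats[[1L]]$F; F2 <- feats[[2L]]$F
    r1 <- as.vector(stats::cor(F1, yy))
    r2v <- as.vector(stats::cor(F2, yy))
    r12 <- stats::cor(F1, F2)
    R2 <- (outer(r1^2, r2v^2, `+`) - 2 * outer(r1, r2v) * r12) /
      pmax(1 - r12^2, 1e-12)
    R2[abs(r12) > 1 - 1e-10] <- -Inf   # collinear pairs are degenerate
    best <- .best_window(R2, list(feats[[1L]]$wins, feats[[2L]]$wins))
    best
  } else {
    # coordinate ascent over the per-kind grids
    cur <- lapply(feats, function(f) 1L)
    Xcur <- vapply(seq_along(kinds),
                   function(k) feats[[k]]$F[, cur[[k]]],
                   numeric(length(idx)))
    r2_of <- function(X) summary(lm(yy ~ X))$r.squared
    repeat {
      changed <- FALSE
      for (k in seq_along(kinds)) {
        scores <- vapply(seq_len(ncol(feats[[k]]$F)), function(w) {
          X <- Xcur; X[, k] <- feats[[k]]$F[, w]
          r2_of(X)
        }, 0)
        w_best <- which.max(scores)
        if (w_best != cur[[k]] &&
            scores[w_best] > r2_of(Xcur) + 1e-12) {
          cur[[k]] <- w_best
          Xcur[, k] <- feats[[k]]$F[, w_best]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    lapply(seq_along(kinds), function(k) cur[[k]])
  }

  specs <- lapply(seq_along(kinds), function(k)
    feature_spec(kinds[k], feats[[k]]$wins[pick[[k]], ]))
  names(specs) <- kinds
  X <- vapply(specs, function(sp) compute_feature(genes, sp, max_pos),
              numeric(max_pos))
  colnames(X) <- kinds
  fit <- fit_linear(y, X, region)
  list(specs = specs, fit = fit, r_squared = fit$r_squared)
}

# choose the maximal-R2 cell of a vector (1 kind) or matrix (2 kinds),
# breaking near-ties (within 1e-9) toward smaller windows
.best_window <- function(R2, wins_list) {
  best <- max(R2, na.rm = TRUE)
  cand <- which(R2 >= best - 1e-9, arr.ind = length(wins_list) == 2L)
  if (length(wins_list) == 1L) {
    w <- wins_list[[1L]][cand, , drop = FALSE]
    ord <- order(w[, 2L] - w[, 1L], w[, 1L])
    list(cand[ord[1L]])
  } else {
    w1 <- wins_list[[1L]][cand[, 1L], , drop = FALSE]
    w2 <- wins_list[[2L]][cand[, 2L], , drop = FALSE]
    tot <- (w1[, 2L] - w1[, 1L]) + (w2[, 2L] - w2[, 1L])
    ord <- order(tot, w1[, 1L], w2[, 1L])
    list(cand[ord[1L], 1L], cand[ord[1L], 2L])
  }
}
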