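# shared fixture builders (all generated in code; no stored data)

toy_model <- function(L, alpha, lambdas, footprint = 1L, id = "toy") {
  codons <- c("ATG", rep("AAA", L - 2L), "TAA")
  gene_model(id, codons, alpha, lambdas, footprint = footprint,
             asite_offset = 1L)
}

random_small_model <- function(L, footprint) {
  toy_model(L, alpha = runif(1, 0.05, 1.5),
            lambdas = runif(L, 0.3, 2.5), footprint = footprint,
            id = "rand")
}

# batch-means standard error of per-position occupancy over snapshots
occupancy_se <- function(snapshots, n_batches = 30L) {
  lst <- snapshot_list(snapshots)
  L <- snapshots$L
  n <- length(lst)
  batch <- cut(seq_len(n), n_batches, labels = FALSE)
  bm <- vapply(seq_len(n_batches), function(b) {
    idx <- which(batch == b)
    tabulate(unlist(lst[idx]), nbins = L) / length(idx)
  }, numeric(L))
  apply(bm, 1, sd) / sqrt(n_batches)
}

# independent brute-force stationary distribution for tiny systems:
# states built by filtering all position subsets, generator assembled
# densely, solved with base R only (no shared code with the package
# implementation beyond the model definition).
brute_force_steady <- function(L, ell, alpha, lam) {
  cand <- list(integer(0))
  for (k in 1:floor((L - 2) / max(ell, 1) + 1)) {
    combs <- utils::combn(2:L, k, simplify = FALSE)
    ok <- Filter(function(s) all(diff(s) >= ell), combs)
    cand <- c(cand, ok)
  }
  n <- length(cand)
  keyf <- function(s) paste0("s", paste(s, collapse = "-"))
  lut <- setNames(seq_len(n), vapply(cand, keyf, ""))
  Q <- matrix(0, n, n)
  for (s in seq_len(n)) {
    st <- cand[[s]]
    if (alpha > 0 && (!length(st) || st[1] >= 2 + ell))
      Q[s, lut[[keyf(sort(c(2L, st)))]] ] <-
        Q[s, lut[[keyf(sort(c(2L, st)))]] ] + alpha
    for (k in seq_along(st)) {
      p <- st[k]
      if (p == L) {
        Q[s, lut[[keyf(st[-k])]] ] <- Q[s, lut[[keyf(st[-k])]] ] + lam[L]
      } else if (k == length(st) || st[k + 1] - p > ell) {
        nw <- st; nw[k] <- p + 1L
        Q[s, lut[[keyf(nw)]] ] <- Q[s, lut[[keyf(nw)]] ] + lam[p]
      }
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  A <- t(Q); A[n, ] <- 1
  p <- solve(A, c(rep(0, n - 1), 1))
  occ <- numeric(L)
  for (s in seq_len(n))
    if (length(cand[[s]])) occ[cand[[s]]] <- occ[cand[[s]]] + p[s]
  flux <- sum(p[vapply(cand, function(st)
    length(st) > 0 && st[length(st)] == L, TRUE)]) * lam[L]
  list(occ = occ, flux = flux, n_states = n)
}
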