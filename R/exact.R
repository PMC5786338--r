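#' Exact steady state of the exclusion process by full enumeration
#'
#' Enumerates every admissible ribosome configuration (A-sites
#' `2 <= p_1 < ... < p_k <= L` with consecutive gaps `>= footprint`),
#' builds the full master-equation rate matrix of the jump process used by
#' [simulate_tasep()] (drop-off excluded), and solves the stationary
#' distribution exactly with a sparse linear solve.  Intended as an
#' independent oracle for small systems.
#'
#' @param model a [gene_model()]; `alpha = 0` is permitted here (empty
#'   lattice is then absorbing) by passing `alpha` explicitly.
#' @param alpha optional override of the initiation rate (may be 0).
#' @param max_states guard on the configuration count (default 2e4); the
#'   state space is counted first and the call refuses with the size
#'   estimate when it exceeds the guard.
#' @return a list with `site_occupancy` (marginal A-site occupancy per
#'   position), `flux` (stationary termination rate), `n_states` and the
#'   stationary probabilities `pi` alongside the enumerated `states`.
#' @export
exact_steady_state <- function(model, alpha = NULL, max_states = 2e4) {
  stopifnot(inherits(model, "gene_model"))
  L <- length(model$codons)
  ell <- model$footprint
  lam <- model$lambdas
  a <- if (is.null(alpha)) model$alpha else alpha
  if (a < 0) stop("alpha must be >= 0")

  n_est <- .count_states(L, ell)
  if (n_est > max_states)
    stop(sprintf(
      "state space too large for exact solve: %.0f configurations (guard %.0f)",
      n_est, max_states))

  states <- .enum_states(L, ell)
  n <- length(states)
  key <- vapply(states, function(st) paste0("s", paste(st, collapse = "_")), "")
  idx <- setNames(seq_len(n), key)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(from, to, rate) {
    ii[[length(ii) + 1L]] <<- from
    jj[[length(jj) + 1L]] <<- to
    xx[[length(xx) + 1L]] <<- rate
  }
  for (s in seq_len(n)) {
    st <- states[[s]]
    # initiation
    if (a > 0 && (!length(st) || st[1L] >= 2L + ell))
      add(s, idx[[paste0("s", paste(c(2L, st), collapse = "_"))]], a)
    # hops and termination
    for (k in seq_along(st)) {
      p <- st[k]
      if (p == L) {
        add(s, idx[[paste0("s", paste(st[-k], collapse = "_"))]], lam[L])
      } else if (k == length(st) || st[k + 1L] - p > ell) {
        new <- st; new[k] <- p + 1L
        add(s, idx[[paste0("s", paste(new, collapse = "_"))]], lam[p])
      }
    }
  }

  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  # solve pi Q = 0, sum(pi) = 1: replace the last column of t(Q) system
  A <- Matrix::t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  pi_hat <- as.numeric(Matrix::solve(A, b))
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  pi_hat <- pi_hat / sum(pi_hat)

  occ <- numeric(L)
  flux <- 0
  for (s in seq_len(n)) {
    st <- states[[s]]
    if (length(st)) {
      occ[st] <- occ[st] + pi_hat[s]
      if (st[length(st)] == L) flux <- flux + pi_hat[s] * lam[L]
    }
  }
  list(site_occupancy = occ, flux = flux, n_states = n,
       pi = pi_hat, states = states)
}

# number of admissible configurations, by dynamic programming
.count_states <- function(L, ell) {
  # f(p) = number of configurations whose 5'-most ribosome is at p
  f <- numeric(L + 1L)
  for (p in seq(L, 2L)) {
    f[p] <- 1
    q0 <- p + ell
    if (q0 <= L) f[p] <- f[p] + sum(f[seq(q0, L)])
  }
  1 + sum(f)
}

.enum_states <- function(L, ell) {
  out <- list(integer(0))
  grow <- function(prefix, minpos) {
    for (p in seq.int(minpos, L)) {
      st <- c(prefix, p)
      out[[length(out) + 1L]] <<- st
      if (p + ell <= L) grow(st, p + ell)
    }
  }
  if (L >= 2L) grow(integer(0), 2L)
  out
}
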