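#' Fit a straight centerline through tunnel coordinates
#'
#' Total least squares via the first principal axis of the 3-D point
#' cloud; the reported R-squared is the fraction of total variance
#' explained by that axis (1 for collinear points, about 1/3 for an
#' isotropic cloud).  The arc coordinate of each point is its projection
#' onto the axis, shifted and oriented so that the first point (the
#' peptidyl transferase center end) maps to 0 and the coordinate
#' increases toward the exit.
#'
#' @param points numeric matrix or data.frame with 3 columns (x, y, z),
#'   ordered from the PTC to the exit.
#' @return a list with `center`, `direction` (unit vector), `r_squared`
#'   and `arc` (per-point arc coordinate, first point at 0).
#' @export
fit_centerline <- function(points) {
  P <- as.matrix(points)[, 1:3, drop = FALSE]
  if (nrow(P) < 3L) stop("need at least 3 points")
  ctr <- colMeans(P)
  C <- sweep(P, 2, ctr)
  if (all(abs(C) < 1e-12)) stop("degenerate input: all points coincide")
  sv <- svd(C)
  dir <- sv$v[, 1L]
  r2 <- sv$d[1L]^2 / sum(sv$d^2)
  proj <- as.vector(C %*% dir)
  if (proj[length(proj)] < proj[1L]) { dir <- -dir; proj <- -proj }
  list(center = ctr, direction = dir, r_squared = r2,
       arc = proj - proj[1L])
}

#' Tunnel radius profile along the arc coordinate
#'
#' @param x strictly increasing arc coordinates (Angstrom), PTC at 0.
#' @param radius positive radii r(x) (Angstrom).
#' @param centerline optional matrix of the 3-D centerline samples
#'   matching `x` (needed for [coulomb_potential()]).
#' @return an object of class `tunnel_profile`.
#' @export
tunnel_profile <- function(x, radius, centerline = NULL) {
  if (is.unsorted(x, strictly = TRUE))
    stop("arc coordinates must be strictly increasing")
  if (any(radius <= 0)) stop("all radii must be positive")
  if (!is.null(centerline)) {
    centerline <- as.matrix(centerline)
    stopifnot(nrow(centerline) == length(x), ncol(centerline) == 3L)
  }
  structure(list(x = as.numeric(x), radius = as.numeric(radius),
                 centerline = centerline),
            class = "tunnel_profile")
}

#' Read a tunnel centerline export (CSV with x, y, z, radius)
#'
#' Consumes the centerline sampling produced by tunnel-detection
#' software; the arc coordinate is rebuilt by [fit_centerline()].
#'
#' @param path CSV path with columns `x`, `y`, `z`, `radius`.
#' @return a [tunnel_profile()] (with `centerline` attached) plus the
#'   centerline fit in attribute `"fit"`.
#' @export
read_centerline_csv <- function(path) {
  tab <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "z", "radius") %in% names(tab)))
  fit <- fit_centerline(tab[, c("x", "y", "z")])
  ord <- order(fit$arc)
  prof <- tunnel_profile(fit$arc[ord], tab$radius[ord],
                         as.matrix(tab[ord, c("x", "y", "z")]))
  attr(prof, "fit") <- fit
  prof
}

#' Assign point charges from structure atom records
#'
#' Places -1 e at every nucleotide phosphorus atom (the backbone
#' phosphate), +1 e at lysine NZ and arginine CZ, and -1 e at aspartate
#' CG and glutamate CD (one representative side-chain atom per charged
#' group; histidine is treated as neutral at physiological pH).  All
#' other atoms carry no charge.  Residue names outside the standard
#' amino acids and nucleotides are skipped and counted.
#'
#' @param atoms a `bio3d` pdb object, a PDB file path, or a data.frame
#'   with columns `resid`, `elety`, `x`, `y`, `z`.
#' @return a data.frame (class `charge_set`) with `x`, `y`, `z`,
#'   `charge`, `resid`, `elety`; the number of skipped unknown-residue
#'   atoms is in attribute `"n_skipped"`.
#' @export
charges_from_structure <- function(atoms) {
  if (is.character(atoms) && length(atoms) == 1L)
    atoms <- bio3d::read.pdb(atoms)
  if (inherits(atoms, "pdb")) atoms <- atoms$atom
  stopifnot(all(c("resid", "elety", "x", "y", "z") %in% names(atoms)))
  aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  nts <- c("A", "U", "G", "C", "DA", "DT", "DG", "DC",
           "RA", "RU", "RG", "RC")
  resid <- toupper(trimws(atoms$resid))
  elety <- toupper(trimws(atoms$elety))
  known <- resid %in% c(aa3, nts)
  n_skipped <- sum(!known)
  if (n_skipped > 0)
    message(n_skipped, " atom(s) with unknown residue names skipped")
  q <- numeric(nrow(atoms))
  q[resid %in% nts & elety == "P"] <- -1
  q[resid == "LYS" & elety == "NZ"] <- 1
  q[resid == "ARG" & elety == "CZ"] <- 1
  q[resid == "ASP" & elety == "CG"] <- -1
  q[resid == "GLU" & elety == "CD"] <- -1
  q[!known] <- 0
  keep <- q != 0
  out <- data.frame(x = atoms$x[keep], y = atoms$y[keep],
                    z = atoms$z[keep], charge = q[keep],
                    resid = resid[keep], elety = elety[keep])
  class(out) <- c("charge_set", "data.frame")
  attr(out, "n_skipped") <- n_skipped
  out
}

# central finite differences on a (possibly non-uniform) grid
.gradient <- function(y, x) {
  n <- length(y)
  g <- numeric(n)
  if (n < 2L) return(g * NA_real_)
  g[1L] <- (y[2L] - y[1L]) / (x[2L] - x[1L])
  g[n] <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
  if (n > 2L) {
    i <- 2:(n - 1L)
    g[i] <- (y[i + 1L] - y[i - 1L]) / (x[i + 1L] - x[i - 1L])
  }
  g
}

# moving average over a window of `width` length units centred on each x
.smooth_x <- function(v, x, width) {
  if (width <= 0) return(v)
  half <- width / 2
  vapply(seq_along(x), function(i)
    mean(v[abs(x - x[i]) <= half], na.rm = TRUE), 0)
}

#' Entropic potential of the tunnel cross-section
#'
#' The one-dimensional reduction of diffusion in a varying cross-section
#' carries an entropic potential `S(x) = ln(pi r(x)^2)`; its negative
#' gradient (the entropic force, positive when the tunnel narrows toward
#' the exit) is computed by central finite differences on the arc
#' coordinate and smoothed by a moving average over a `smooth` Angstrom
#' window.
#'
#' @param profile a [tunnel_profile()].
#' @param smooth smoothing window in Angstrom (default 10).
#' @return a data.frame with `x`, `S`, `dS` (gradient), `neg_dS_smooth`.
#' @export
entropic_potential <- function(profile, smooth = 10) {
  stopifnot(inherits(profile, "tunnel_profile"))
  S <- log(pi * profile$radius^2)
  dS <- .gradient(S, profile$x)
  data.frame(x = profile$x, S = S, dS = dS,
             neg_dS_smooth = .smooth_x(-dS, profile$x, smooth))
}

#' Coulomb potential along the tunnel centerline
#'
#' Approximates the electrostatic potential at each centerline point by
#' the unscreened Coulomb sum `V(x) = sum_j q_j / d(x, j)` (unitless
#' prefactor 1) over the charges within `cutoff` Angstrom of that point;
#' charges coincident with a centerline point are excluded with a
#' warning.  The negative gradient is computed and smoothed as in
#' [entropic_potential()].
#'
#' @param profile a [tunnel_profile()] with a `centerline`.
#' @param charges a `charge_set` (see [charges_from_structure()]) or a
#'   data.frame with `x`, `y`, `z`, `charge`.
#' @param cutoff inclusion radius in Angstrom (default 20).
#' @param smooth smoothing window in Angstrom (default 10).
#' @return a data.frame with `x`, `V`, `dV`, `neg_dV_smooth`.
#' @export
coulomb_potential <- function(profile, charges, cutoff = 20, smooth = 10) {
  stopifnot(inherits(profile, "tunnel_profile"))
  if (is.null(profile$centerline))
    stop("the tunnel profile has no 3-D centerline samples")
  if (!nrow(charges)) stop("empty charge set")
  Q <- as.matrix(charges[, c("x", "y", "z")])
  q <- charges$charge
  P <- profile$centerline
  V <- vapply(seq_len(nrow(P)), function(i) {
    d <- sqrt(colSums((t(Q) - P[i, ])^2))
    zero <- d == 0
    if (any(zero))
      warning("charge coincident with a centerline point excluded")
    use <- d <= cutoff & !zero
    sum(q[use] / d[use])
  }, 0)
  dV <- .gradient(V, profile$x)
  data.frame(x = profile$x, V = V, dV = dV,
             neg_dV_smooth = .smooth_x(-dV, profile$x, smooth))
}
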