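#' Detection scenario for closely stacked ribosomes
#'
#' Standard ribosome-profiling libraries select ~28-30 nt fragments, so
#' footprints of closely stacked ribosomes (inter-A-site distance at most
#' `stack_threshold` codons; default 12, i.e. a free gap of at most 2
#' codons for a 10-codon footprint) may be missing.  A scenario assigns
#' each stacked ribosome an independent detection probability: 1 for full
#' detection, 0.5 for partial, 0 for none.  Isolated ribosomes are always
#' detected.
#'
#' @param detect_prob probability in `[0, 1]` that a stacked ribosome is
#'   detected.
#' @param stack_threshold maximal inter-A-site distance (codons) counted
#'   as stacked; must be at least the footprint.
#' @return an object of class `detection_scenario`.
#' @export
detection_scenario <- function(detect_prob = 0, stack_threshold = 12L) {
  if (detect_prob < 0 || detect_prob > 1)
    stop("`detect_prob` must be in [0, 1]")
  structure(list(detect_prob = detect_prob,
                 stack_threshold = as.integer(stack_threshold)),
            class = "detection_scenario")
}

#' Classify which ribosomes of one snapshot are detected
#'
#' A ribosome is closely stacked iff its distance to at least one
#' neighbouring A-site is `<= stack_threshold`; both members of a stacked
#' pair are candidates for non-detection.  Stacked ribosomes are flagged
#' detected independently with probability `detect_prob`; all others are
#' always detected.  Draws use the current R RNG stream.
#'
#' @param a_sites strictly increasing integer A-site positions.
#' @param scenario a [detection_scenario()].
#' @return logical vector, `TRUE` where detected.
#' @export
classify_detected <- function(a_sites, scenario = detection_scenario()) {
  stopifnot(inherits(scenario, "detection_scenario"))
  if (length(a_sites) == 0L) return(logical(0))
  if (is.unsorted(a_sites, strictly = TRUE))
    stop("`a_sites` must be strictly increasing")
  gap <- diff(a_sites)
  stacked <- c(gap <= scenario$stack_threshold, FALSE) |
    c(FALSE, gap <= scenario$stack_threshold)
  det <- !stacked
  if (any(stacked))
    det[stacked] <- runif(sum(stacked)) < scenario$detect_prob
  det
}

# vectorised detection over a flattened snapshot stream
.classify_flat <- function(pos, len, stack_threshold, detect_prob) {
  if (!length(pos)) return(logical(0))
  id <- rep.int(seq_along(len), len)
  n <- length(pos)
  same_prev <- c(FALSE, id[-1L] == id[-n])
  gap_prev <- c(NA_integer_, diff(pos))
  close_prev <- same_prev & gap_prev <= stack_threshold
  stacked <- close_prev | c(close_prev[-1L], FALSE)
  det <- !stacked
  if (any(stacked)) {
    if (detect_prob <= 0) det[stacked] <- FALSE
    else if (detect_prob >= 1) det[stacked] <- TRUE
    else det[stacked] <- runif(sum(stacked)) < detect_prob
  }
  det
}

#' Sample footprint profiles from a snapshot stream
#'
#' Mirrors the profile sampling scheme of the simulation protocol: for
#' each snapshot, detection flags are drawn under the scenario, one A-site
#' is picked uniformly from the detected set (if non-empty) and added to
#' the detected profile, and independently one A-site is picked uniformly
#' over all ribosomes for the total profile.  One footprint (at most) per
#' snapshot and per profile is recorded.
#'
#' @param snapshots the `snapshots` component of a `tasep_sim` (or an
#'   object built by [as_snapshots()]).
#' @param scenario a [detection_scenario()].
#' @param seed optional integer seed for the detection and sampling draws.
#' @return a list with integer count vectors `detected` and `total`
#'   (length `L`), class `ribo_profile_pair`.
#' @export
sample_profile <- function(snapshots, scenario = detection_scenario(),
                           seed = NULL) {
  stopifnot(inherits(snapshots, "tasep_snapshots"))
  if (!is.null(seed)) set.seed(seed)
  L <- snapshots$L
  pos <- snapshots$pos
  len <- snapshots$len
  if (!length(len) || !length(pos)) {
    warning("empty snapshot stream: returning empty profiles")
    return(structure(list(detected = integer(L), total = integer(L)),
                     class = "ribo_profile_pair"))
  }
  det <- .classify_flat(pos, len, scenario$stack_threshold,
                        scenario$detect_prob)
  nonempty <- len > 0L
  start <- cumsum(len) - len + 1L
  # total profile: one uniform pick among all ribosomes of each snapshot
  pick_tot <- start[nonempty] +
    floor(runif(sum(nonempty)) * len[nonempty])
  total <- tabulate(pos[pick_tot], nbins = L)
  # detected profile: one uniform pick among the detected ribosomes
  cum <- cumsum(det)
  before <- ifelse(start > 1L, cum[pmax(start - 1L, 1L)], 0L)
  ends <- cumsum(len)
  d_len <- ifelse(ends > 0L, cum[pmax(ends, 1L)], 0L) - before
  d_len[!nonempty] <- 0L
  has_det <- nonempty & d_len > 0L
  rank <- before[has_det] +
    pmax(1L, ceiling(runif(sum(has_det)) * d_len[has_det]))
  gidx <- which(det)
  detected <- tabulate(pos[gidx[rank]], nbins = L)
  structure(list(detected = detected, total = total),
            class = "ribo_profile_pair")
}

#' Total and detected ribosome densities of a snapshot stream
#'
#' @param snapshots the `snapshots` component of a `tasep_sim`.
#' @param scenario a [detection_scenario()].
#' @param seed optional seed for the detection draws.
#' @return a list with `rho_total` and `rho_detected` (mean ribosomes per
#'   codon) and their per-100-codon scales `rho_total_per100`,
#'   `rho_detected_per100`.
#' @export
ribo_densities <- function(snapshots, scenario = detection_scenario(),
                           seed = NULL) {
  stopifnot(inherits(snapshots, "tasep_snapshots"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(snapshots$len)
  L <- snapshots$L
  if (n == 0L)
    return(list(rho_total = 0, rho_detected = 0,
                rho_total_per100 = 0, rho_detected_per100 = 0))
  det <- .classify_flat(snapshots$pos, snapshots$len,
                        scenario$stack_threshold, scenario$detect_prob)
  rho_t <- sum(snapshots$len) / (n * L)
  rho_d <- sum(det) / (n * L)
  list(rho_total = rho_t, rho_detected = rho_d,
       rho_total_per100 = 100 * rho_t, rho_detected_per100 = 100 * rho_d)
}

#' Build a snapshot stream from a list of A-site position vectors
#'
#' @param positions list of strictly increasing integer vectors.
#' @param L transcript length in codons.
#' @param footprint exclusion length (for bookkeeping).
#' @return a `tasep_snapshots` object.
#' @export
as_snapshots <- function(positions, L, footprint = 10L) {
  stopifnot(is.list(positions))
  structure(list(pos = as.integer(unlist(positions)),
                 len = vapply(positions, length, 1L),
                 L = as.integer(L), footprint = as.integer(footprint)),
            class = "tasep_snapshots")
}
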