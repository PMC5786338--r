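#' Simulate the extended exclusion process for one transcript
#'
#' Runs a continuous-time Markov jump process by the next reaction method:
#' initiation places a ribosome with its A-site at codon 2 at exponential
#' rate `alpha` whenever no other A-site lies within `footprint` codons
#' downstream of codon 2; a ribosome with A-site at `i < L` hops to
#' `i + 1` at rate `lambda[i]` iff the next ribosome's A-site is beyond
#' `i + footprint`; at the stop codon it unbinds at rate `lambda[L]`,
#' which counts toward the protein production flux.  With a positive
#' drop-off rate each completed elongation step is followed by premature
#' unbinding with that probability.
#'
#' After `burn_in` reaction events, a snapshot of all A-site positions is
#' recorded every `sample_interval` events until `n_samples` snapshots
#' exist.  Dwell times are taken from the exact event log (entry and exit
#' time per position), not from snapshots, so observed rates are unbiased.
#' Flux is the number of terminations divided by the simulated time after
#' burn-in.
#'
#' @param model a [gene_model()].
#' @param config a [sim_config()]; its `seed` makes the run reproducible
#'   and its `detect_prob`/`stack_threshold` define the detection scenario
#'   used for the detected-ribosome density.
#' @return an object of class `tasep_sim` with components
#'   `snapshots` (flattened snapshot stream: integer vectors `pos`, `len`),
#'   `site_occupancy` (per-position mean A-site occupancy),
#'   `rho_total`/`rho_detected` (mean ribosomes per codon; multiply by 100
#'   for the per-100-codon scale), `dwell_time` (per-position mean dwell,
#'   s), `observed_rate` (1/dwell, codons/s; `NA` where never visited),
#'   `unobstructed_rate` (copy of `lambda`), `flux` (proteins/s) and
#'   `interference_prob` (probability that a ribosome at `i` co-occurs
#'   with a trailing ribosome at the minimal distance `i - footprint`).
#' @seealso [exact_steady_state()] for an exact small-system oracle.
#' @export
simulate_tasep <- function(model, config = sim_config()) {
  stopifnot(inherits(model, "gene_model"), inherits(config, "sim_config"))
  L <- length(model$codons)
  set.seed(config$seed)
  raw <- .tasep_simulate(L, model$alpha, model$lambdas, model$footprint,
                         config$burn_in, config$n_samples,
                         config$sample_interval, config$dropoff_rate)
  n <- raw$n_snapshots
  occ <- if (n > 0) raw$occupancy_counts / n else rep(0, L)
  snapshots <- structure(
    list(pos = raw$snap_pos, len = raw$snap_len, L = L,
         footprint = model$footprint),
    class = "tasep_snapshots")
  det <- .classify_flat(raw$snap_pos, raw$snap_len,
                        config$stack_threshold, config$detect_prob)
  rho_total <- if (n > 0) sum(raw$snap_len) / (n * L) else 0
  rho_detected <- if (n > 0) sum(det) / (n * L) else 0
  structure(
    list(model = model, config = config, snapshots = snapshots,
         site_occupancy = occ, rho_total = rho_total,
         rho_detected = rho_detected,
         dwell_time = ifelse(raw$dwell_n > 0,
                             raw$dwell_sum / raw$dwell_n, NA_real_),
         dwell_n = raw$dwell_n, observed_rate = raw$observed_rate,
         unobstructed_rate = model$lambdas,
         flux = if (raw$sim_time > 0) raw$terminations / raw$sim_time else 0,
         terminations = raw$terminations, sim_time = raw$sim_time,
         interference_prob = .interference_prob(raw$snap_pos, raw$snap_len,
                                                model$footprint, L)),
    class = "tasep_sim")
}

#' @export
print.tasep_sim <- function(x, ...) {
  cat(sprintf(
    "<tasep_sim> %s: %d snapshots, rho = %.3g (detected %.3g) ribosomes/codon, flux = %.3g /s\n",
    x$model$gene_id, length(x$snapshots$len), x$rho_total, x$rho_detected,
    x$flux))
  invisible(x)
}

#' Per-position observed elongation rates
#'
#' The observed rate at a position is the inverse of the mean time a
#' ribosome's A-site spends there, including time spent blocked by a
#' ribosome downstream; it is therefore at most the unobstructed rate
#' `lambda` up to sampling error.  Positions never visited are `NA`.
#'
#' @param sim a `tasep_sim` from [simulate_tasep()].
#' @return a data.frame with `position`, `observed_rate`,
#'   `unobstructed_rate`, `gap` (unobstructed minus observed) and
#'   `n_visits`.
#' @export
observed_rates <- function(sim) {
  stopifnot(inherits(sim, "tasep_sim"))
  data.frame(position = seq_along(sim$observed_rate),
             observed_rate = sim$observed_rate,
             unobstructed_rate = sim$unobstructed_rate,
             gap = sim$unobstructed_rate - sim$observed_rate,
             n_visits = sim$dwell_n)
}

#' Mean observed translation speed over a transcript region
#'
#' The global average speed over positions `from .. L` is defined as the
#' number of positions divided by the summed mean dwell times, i.e. the
#' average speed of a ribosome traversing the region (a time-weighted
#' speed, dominated by slow sites as a real transit is).
#'
#' @param sim a `tasep_sim`.
#' @param from first codon position of the region (default 150).
#' @param to last position (default the stop codon).
#' @return speed in codons/s.
#' @export
region_speed <- function(sim, from = 150L, to = NULL) {
  stopifnot(inherits(sim, "tasep_sim"))
  L <- length(sim$dwell_time)
  if (is.null(to)) to <- L
  if (from >= to) stop("`from` must be < `to`")
  d <- sim$dwell_time[from:to]
  keep <- !is.na(d)
  if (!any(keep)) stop("no visited positions in the region")
  if (!all(keep))
    warning(sum(!keep), " never-visited positions excluded from the speed")
  sum(keep) / sum(d[keep])
}

#' Convert a flattened snapshot stream to a list of position vectors
#'
#' @param snapshots the `snapshots` component of a `tasep_sim`.
#' @return a list of integer vectors of A-site positions (one per
#'   snapshot, possibly empty).
#' @export
snapshot_list <- function(snapshots) {
  stopifnot(inherits(snapshots, "tasep_snapshots"))
  f <- rep.int(seq_along(snapshots$len), snapshots$len)
  out <- rep(list(integer(0)), length(snapshots$len))
  out[unique(f)] <- split(snapshots$pos, f)
  out
}

#' Export a snapshot stream as TSV
#'
#' Columns `sample_index` and `a_sites` (comma-joined A-site positions;
#' empty string for an empty lattice).
#'
#' @param snapshots the `snapshots` component of a `tasep_sim`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(snapshots, path) {
  lst <- snapshot_list(snapshots)
  df <- data.frame(sample_index = seq_along(lst),
                   a_sites = vapply(lst, paste, "", collapse = ","))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# interference probability: P(trailing ribosome at i - footprint | ribosome
# at i), estimated over snapshots.  With exclusion >= footprint only
# adjacent pairs can sit at the minimal distance.
.interference_prob <- function(pos, len, footprint, L) {
  n_at <- tabulate(pos, nbins = L)
  if (!length(pos)) return(rep(NA_real_, L))
  id <- rep.int(seq_along(len), len)
  same <- c(FALSE, id[-1L] == id[-length(id)])
  gap <- c(NA_integer_, diff(pos))
  lead <- pos[which(same & gap == footprint)]
  co <- tabulate(lead, nbins = L)
  ifelse(n_at > 0, co / n_at, NA_real_)
}
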