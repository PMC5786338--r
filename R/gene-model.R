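#' Transcript-level translation model
#'
#' A `gene_model` bundles everything the exclusion-process simulator needs
#' for one transcript: the codon sequence, the initiation rate `alpha`
#' (events/s; the rate at which a ribosome's A-site enters codon 2 when
#' the 5' end is clear) and the per-position unobstructed elongation rates
#' `lambdas` (events/s; `lambdas[L]` is the termination/unbinding rate at
#' the stop codon).  Positions are 1-based codons; position 1 is the start
#' codon and position `L` the stop codon.  The ribosome occupies
#' `footprint` codons (default 10, i.e. 30 nt) with its A-site at codon
#' `asite_offset` of the footprint (default 6), so a ribosome with A-site
#' at `i` covers codons `i - 5 .. i + 4`; overhangs past the 5' end at
#' initiation impose no constraint.
#'
#' @param gene_id character identifier.
#' @param codons character vector of codon identifiers (e.g. "ATG"),
#'   length `L`.
#' @param alpha initiation rate (> 0), events/s.
#' @param lambdas numeric vector of per-position elongation rates (> 0),
#'   length `L`.
#' @param footprint exclusion length in codons (>= 1).
#' @param asite_offset A-site index within the footprint
#'   (`1 <= asite_offset <= footprint`).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, codons, alpha, lambdas,
                       footprint = 10L, asite_offset = 6L) {
  stopifnot(is.character(codons), length(codons) >= 2L)
  L <- length(codons)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("`alpha` must be a single positive number")
  if (length(lambdas) != L)
    stop("`lambdas` must have one rate per codon (length ", L, ")")
  if (any(!is.finite(lambdas)) || any(lambdas <= 0))
    stop("all elongation rates must be positive and finite")
  footprint <- as.integer(footprint)
  asite_offset <- as.integer(asite_offset)
  if (footprint < 1L) stop("`footprint` must be >= 1")
  if (asite_offset < 1L || asite_offset > footprint)
    stop("`asite_offset` must lie within the footprint")
  structure(
    list(gene_id = as.character(gene_id)[1L], codons = codons,
         alpha = alpha, lambdas = as.numeric(lambdas),
         footprint = footprint, asite_offset = asite_offset),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s: L = %d codons, alpha = %.4g, footprint = %d\n",
    x$gene_id, length(x$codons), x$alpha, x$footprint))
  cat(sprintf("  lambda: mean %.3g, range [%.3g, %.3g]\n",
              mean(x$lambdas), min(x$lambdas), max(x$lambdas)))
  invisible(x)
}

#' Rescale all rates of a model by a constant
#'
#' Multiplies the initiation rate and every elongation rate by `k`.  The
#' exclusion-process occupancies and sampled profiles are invariant under
#' this scaling (only the time unit changes), which is the degree of
#' freedom removed by [normalize_rates()].
#'
#' @param model a [gene_model()].
#' @param k positive scaling constant.
#' @return the rescaled `gene_model`.
#' @export
scale_rates <- function(model, k) {
  stopifnot(inherits(model, "gene_model"), is.numeric(k), k > 0)
  model$alpha <- model$alpha * k
  model$lambdas <- model$lambdas * k
  model
}

#' Simulation settings for the exclusion-process sampler
#'
#' Defaults follow the simulation protocol used throughout: about 10^4
#' reaction events of burn-in and 3 x 10^4 sampled ribosome snapshots.
#' The snapshot interval (reaction events between recorded states) is not
#' fixed by that protocol and defaults to 50 events, which makes
#' consecutive snapshots approximately independent for transcript-scale
#' systems.
#'
#' @param burn_in reaction events discarded before sampling.
#' @param n_samples number of snapshots recorded.
#' @param sample_interval reaction events between snapshots (>= 1).
#' @param seed integer seed used for the simulation RNG.
#' @param detect_prob probability that a closely stacked ribosome is
#'   detected (1 = full detection, 0.5 = partial, 0 = none).
#' @param stack_threshold maximal inter-A-site distance (codons) counted
#'   as closely stacked.
#' @param dropoff_rate probability per completed elongation event that the
#'   ribosome unbinds prematurely (`0 <= r < 1`).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(burn_in = 1e4, n_samples = 3e4, sample_interval = 50,
                       seed = 1L, detect_prob = 1, stack_threshold = 12L,
                       dropoff_rate = 0) {
  burn_in <- as.integer(burn_in); n_samples <- as.integer(n_samples)
  sample_interval <- as.integer(sample_interval)
  if (burn_in < 0L || n_samples < 0L) stop("counts must be >= 0")
  if (sample_interval < 1L) stop("`sample_interval` must be >= 1")
  if (detect_prob < 0 || detect_prob > 1)
    stop("`detect_prob` must be in [0, 1]")
  if (dropoff_rate < 0 || dropoff_rate >= 1)
    stop("`dropoff_rate` must be in [0, 1)")
  structure(
    list(burn_in = burn_in, n_samples = n_samples,
         sample_interval = sample_interval, seed = as.integer(seed),
         detect_prob = detect_prob,
         stack_threshold = as.integer(stack_threshold),
         dropoff_rate = dropoff_rate),
    class = "sim_config")
}

#' Write / read a gene model as TSV
#'
#' The format has a header line `#alpha=<value>` (plus `#footprint=` and
#' `#asite_offset=` lines) followed by tab-separated columns `gene_id`,
#' `position`, `codon`, `lambda`.  Round-trips are bit-exact up to the
#' full precision of `%.17g`.
#'
#' @param model a [gene_model()].
#' @param path file path.
#' @return `write_gene_model()` returns `path` invisibly;
#'   `read_gene_model()` returns a [gene_model()].
#' @export
write_gene_model <- function(model, path) {
  stopifnot(inherits(model, "gene_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#alpha=%.17g", model$alpha),
               sprintf("#footprint=%d", model$footprint),
               sprintf("#asite_offset=%d", model$asite_offset),
               "gene_id\tposition\tcodon\tlambda"), con)
  writeLines(sprintf("%s\t%d\t%s\t%.17g", model$gene_id,
                     seq_along(model$codons), model$codons, model$lambdas),
             con)
  invisible(path)
}

#' @rdname write_gene_model
#' @export
read_gene_model <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (!length(ln)) stop("missing header line #", key, "=")
    as.numeric(sub(paste0("^#", key, "="), "", ln[1L]))
  }
  tab <- read.delim(text = lines[!grepl("^#", lines)],
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$position), , drop = FALSE]
  gene_model(tab$gene_id[1L], tab$codon, get("alpha"), tab$lambda,
             footprint = as.integer(get("footprint")),
             asite_offset = as.integer(get("asite_offset")))
}
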