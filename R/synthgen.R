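#' Default codon-specific base elongation rates
#'
#' A fixed assignment of the 61 sense codons to five rate groups of sizes
#' 4, 13, 13, 16 and 15 with rates spread evenly inside the intervals
#' [4,6), [6,8), [8,10), [10,12) and [12,14) codons/s, emulating the
#' reported distribution of codon-specific mean elongation rates in
#' yeast.  The assignment of codons to groups is deterministic
#' (alphabetical order), so the table is a pure constant.
#'
#' @return named numeric vector of length 61 (codons/s).
#' @export
default_codon_rates <- function() {
  stop_codons <- c("TAA", "TAG", "TGA")
  codons <- sort(setdiff(names(Biostrings::GENETIC_CODE), stop_codons))
  sizes <- c(4L, 13L, 13L, 16L, 15L)
  lo <- c(4, 6, 8, 10, 12); hi <- c(6, 8, 10, 12, 14)
  rates <- unlist(lapply(seq_along(sizes), function(g)
    lo[g] + (hi[g] - lo[g]) * (seq_len(sizes[g]) - 0.5) / sizes[g]))
  setNames(rates, codons)
}

#' Specification of a synthetic gene set
#'
#' Defines the study conditions the generator emulates: per-codon base
#' elongation rates (codon identity effect), a 5' ramp multiplier rising
#' linearly from `ramp_start` at codon 1 to 1 at codon `ramp_len`,
#' multiplicative position-specific lognormal rate noise (mean one,
#' `position_sdlog` on the log scale) standing in for the unmodelled
#' sequence-context modulation, lognormal gene-specific initiation rates
#' (median `exp(alpha_meanlog)`, about 0.1/s, i.e. a 10 s median time
#' between initiations), a slow termination rate at the stop codon, and
#' optional planted multiplicative nascent-peptide feature effects
#' `exp(beta * feature)` for end-to-end regression tests.
#'
#' @param n_genes number of genes.
#' @param length transcript length(s) in codons (recycled).
#' @param codon_weights named sampling weights for the 61 sense codons
#'   (default uniform).
#' @param codon_rates named base rates, codons/s
#'   (default [default_codon_rates()]).
#' @param ramp_start multiplier at codon 1 (default 0.85).
#' @param ramp_len position where the ramp reaches 1 (default 200).
#' @param position_sdlog sdlog of the mean-one positional rate noise.
#' @param alpha_meanlog,alpha_sdlog lognormal parameters of the
#'   initiation rate (events/s).
#' @param stop_rate termination rate at the stop codon (events/s;
#'   termination is not fast).
#' @param features list of planted effects, each a list with `kind`,
#'   `window` (see [feature_spec()]) and `beta` (per-unit log-rate
#'   effect).
#' @param dropoff_rate per-codon drop-off probability passed to the
#'   simulations.
#' @param te_scale proportionality constant between TE and detected
#'   density per 100 codons (default 0.83).
#' @param seed mandatory integer seed.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_genes = 20L, length = 300L,
                       codon_weights = NULL,
                       codon_rates = default_codon_rates(),
                       ramp_start = 0.85, ramp_len = 200L,
                       position_sdlog = 0.7,
                       alpha_meanlog = log(0.1), alpha_sdlog = 0.3,
                       stop_rate = 2, features = list(),
                       dropoff_rate = 0, te_scale = 0.83, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (any(codon_rates <= 0)) stop("codon rates must be positive")
  if (is.null(codon_weights))
    codon_weights <- setNames(rep(1, length(codon_rates)),
                              names(codon_rates))
  if (all(codon_weights == 0)) stop("all codon weights are zero")
  if (any(codon_weights < 0)) stop("codon weights must be >= 0")
  structure(list(
    n_genes = as.integer(n_genes), length = as.integer(length),
    codon_weights = codon_weights, codon_rates = codon_rates,
    ramp_start = ramp_start, ramp_len = as.integer(ramp_len),
    position_sdlog = position_sdlog, alpha_meanlog = alpha_meanlog,
    alpha_sdlog = alpha_sdlog, stop_rate = stop_rate,
    features = features, dropoff_rate = dropoff_rate,
    te_scale = te_scale, seed = as.integer(seed)),
    class = "synth_spec")
}

.ramp_multiplier <- function(L, start, ramp_len) {
  i <- seq_len(L)
  pmin(start + (1 - start) * (i - 1) / max(ramp_len - 1, 1), 1)
}

#' Generate a synthetic gene set
#'
#' Draws codon sequences from the usage weights (position 1 = ATG,
#' position L = TAA), builds per-position elongation rates as
#' base rate x ramp x mean-one lognormal noise x planted feature
#' effects, draws gene-specific initiation rates, and derives protein
#' sequences and per-codon PARS scores (mean of three iid standard
#' normal per-nucleotide scores).  Deterministic given the spec seed.
#'
#' @param spec a [synth_spec()].
#' @return a list of class `synth_gene_set`; each element has `model`
#'   (a [gene_model()]), `aa`, `pars` and the true `alpha`/`lambdas`.
#' @export
generate_gene_set <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  code <- Biostrings::GENETIC_CODE
  sense <- names(spec$codon_rates)
  w <- spec$codon_weights[sense]
  Ls <- rep_len(spec$length, spec$n_genes)
  out <- vector("list", spec$n_genes)
  for (g in seq_len(spec$n_genes)) {
    L <- Ls[g]
    codons <- c("ATG",
                sample(sense, L - 2L, replace = TRUE, prob = w),
                "TAA")
    aa <- unname(code[codons])
    aa[L] <- "*"
    pars <- colMeans(matrix(rnorm(3L * L), nrow = 3L))
    ramp <- .ramp_multiplier(L, spec$ramp_start, spec$ramp_len)
    noise <- rlnorm(L, meanlog = -spec$position_sdlog^2 / 2,
                    sdlog = spec$position_sdlog)
    # winsorise at two log-sd: physiological per-site rates span roughly
    # 1-40 codons/s, and heavier tails would plant rates no finite
    # footprint profile can constrain
    s2 <- spec$position_sdlog
    noise <- pmin(pmax(noise, exp(-2 * s2 - s2^2 / 2)),
                  exp(2 * s2 - s2^2 / 2))
    lam <- spec$codon_rates[codons] * ramp * noise
    lam[1L] <- mean(spec$codon_rates)          # start codon, never decoded
    lam[L] <- spec$stop_rate                   # termination
    gene <- list(aa = aa, pars = pars)
    if (length(spec$features)) {
      eff <- numeric(L)
      for (f in spec$features) {
        sp <- feature_spec(f$kind, f$window)
        x <- .window_aggregate(.feature_track(gene, sp$kind),
                               sp$window[1L], sp$window[2L], sp$side,
                               sp$aggregation)
        x[is.na(x)] <- 0
        eff <- eff + f$beta * x
      }
      lam <- lam * exp(eff)
    }
    alpha <- rlnorm(1L, spec$alpha_meanlog, spec$alpha_sdlog)
    out[[g]] <- list(
      model = gene_model(sprintf("synth_%03d", g), codons, alpha,
                         unname(lam)),
      aa = aa, pars = pars, alpha = alpha, lambdas = unname(lam))
  }
  names(out) <- vapply(out, function(x) x$model$gene_id, "")
  class(out) <- c("synth_gene_set", "list")
  out
}

#' Simulate footprint profiles and TE values for a synthetic gene set
#'
#' Runs the exclusion-process simulator for each gene, samples detected
#' and total footprint profiles under the detection scenario, and
#' computes TE as the detected density per 100 codons times the
#' calibration constant `te_scale`, so the TE calibration and the full
#' inference pipeline can be closed end-to-end.  Per-gene seeds are
#' derived deterministically from `config$seed`.
#'
#' @param genes a `synth_gene_set` from [generate_gene_set()].
#' @param scenario a [detection_scenario()].
#' @param config a [sim_config()]; `n_samples` is the number of
#'   footprints sampled per profile (default 1e5, a deep-coverage
#'   setting: about 330 footprints per codon for a 300-codon gene,
#'   typical of the high-coverage genes retained by the
#'   `> 10` reads/codon selection).
#' @param te_scale overrides the spec's TE calibration constant.
#' @return a list of class `synth_profiles` with `profiles` (detected
#'   counts), `totals`, `te` (data.frame `gene_id`, `te`, `density`),
#'   `sims` (the `tasep_sim` objects) and `scenario`.
#' @export
generate_profiles <- function(genes, scenario = detection_scenario(),
                              config = sim_config(n_samples = 1e5),
                              te_scale = 0.83) {
  stopifnot(inherits(genes, "synth_gene_set"))
  profiles <- list(); totals <- list(); sims <- list()
  te <- data.frame(gene_id = character(0), te = numeric(0),
                   density = numeric(0))
  for (g in seq_along(genes)) {
    gene <- genes[[g]]
    cfg_g <- config
    cfg_g$seed <-
      as.integer((as.numeric(config$seed) * 1009 + g) %% 2147483647)
    cfg_g$detect_prob <- scenario$detect_prob
    cfg_g$stack_threshold <- scenario$stack_threshold
    sim <- simulate_tasep(gene$model, cfg_g)
    prof <- sample_profile(sim$snapshots, scenario)
    id <- gene$model$gene_id
    profiles[[id]] <- prof$detected
    totals[[id]] <- prof$total
    sims[[id]] <- sim
    te <- rbind(te, data.frame(
      gene_id = id, te = 100 * sim$rho_detected * te_scale,
      density = 100 * sim$rho_total))
  }
  structure(list(profiles = profiles, totals = totals, te = te,
                 sims = sims, scenario = scenario, te_scale = te_scale),
            class = "synth_profiles")
}
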