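#' Configuration of the two-step rate inference
#'
#' Controls the naive inverse-density estimate, the initiation-rate
#' search, the error-site correction loop, and the global speed
#' calibration.  Rates are handled internally in "naive units" in which
#' the mean finite naive rate is `mean_rate` (10); `lambda_max` (50, i.e.
#' five times the mean) caps rates at sites with few or no footprints.
#' The error-site threshold defaults to 30% of the mean normalized
#' density of the gene, lifted per site by a counting-noise floor (see
#' [detect_error_sites()]).  [normalize_rates()] rescales all
#' rates so that the simulated mean observed speed between
#' `speed_region_start` and the stop codon equals `target_speed`
#' (5.6 codons/s, the experimentally measured global average).
#'
#' @param lambda_max cap for naive rates, in units of `mean_rate`.
#' @param mean_rate reference mean of the finite naive rates.
#' @param error_threshold scalar absolute normalized-density difference
#'   above which a site is flagged; `NULL` (default) uses the adaptive
#'   per-site rule of [detect_error_sites()].
#' @param correction_window half-width (codons) of the neighbourhood
#'   jointly re-optimized around an error-site.
#' @param max_rounds cap on correction rounds.
#' @param target_speed calibration speed in codons/s.
#' @param speed_region_start first codon of the calibration region.
#' @param alpha_tol relative tolerance of the initiation-rate bisection.
#' @param search_samples,search_interval snapshot count and interval used
#'   inside the initiation search and the local optimizer (smaller than
#'   the final simulation for speed).
#' @param final_samples,final_interval snapshot count and interval of the
#'   full simulations used for error-site detection and normalization.
#' @param burn_in burn-in reaction events for every simulation.
#' @param opt_maxit iteration cap of the derivative-free local optimizer.
#' @return an object of class `inference_config`.
#' @export
inference_config <- function(lambda_max = 50, mean_rate = 10,
                             error_threshold = NULL, correction_window = 2L,
                             max_rounds = 10L, target_speed = 5.6,
                             speed_region_start = 150L, alpha_tol = 0.02,
                             search_samples = 1e4, search_interval = 50L,
                             final_samples = 3e4, final_interval = 50L,
                             burn_in = 1e4, opt_maxit = 150L) {
  stopifnot(lambda_max > 0, mean_rate > 0, correction_window >= 1L,
            max_rounds >= 1L, target_speed > 0, alpha_tol > 0)
  structure(list(
    lambda_max = lambda_max, mean_rate = mean_rate,
    error_threshold = error_threshold,
    correction_window = as.integer(correction_window),
    max_rounds = as.integer(max_rounds), target_speed = target_speed,
    speed_region_start = as.integer(speed_region_start),
    alpha_tol = alpha_tol, search_samples = as.integer(search_samples),
    search_interval = as.integer(search_interval),
    final_samples = as.integer(final_samples),
    final_interval = as.integer(final_interval),
    burn_in = as.integer(burn_in), opt_maxit = as.integer(opt_maxit)),
    class = "inference_config")
}

#' Naive elongation rates by inverting the footprint profile
#'
#' With negligible ribosomal interference the steady-state A-site density
#' at a position is proportional to `alpha / lambda_i`, so the inverse of
#' the observed footprint count estimates the elongation rate up to a
#' global constant.  Rates are rescaled so the mean over sites with
#' footprints equals `cfg$mean_rate`; zero-count sites are set to
#' `cfg$lambda_max`, and all rates are capped there.
#'
#' @param counts integer per-codon footprint counts.
#' @param cfg an [inference_config()].
#' @return numeric rate vector (naive units).
#' @export
naive_rates <- function(counts, cfg = inference_config()) {
  if (all(counts == 0)) stop("profile has no footprints")
  lam <- rep(NA_real_, length(counts))
  pos <- counts > 0
  lam[pos] <- 1 / counts[pos]
  lam[pos] <- lam[pos] * cfg$mean_rate / mean(lam[pos])
  lam[!pos] <- cfg$lambda_max
  pmin(lam, cfg$lambda_max)
}

# simulation shorthand used by the search and correction steps
.sim_for <- function(model, cfg, seed, n_samples, interval,
                     scenario) {
  config <- sim_config(burn_in = cfg$burn_in, n_samples = n_samples,
                       sample_interval = interval, seed = seed,
                       detect_prob = scenario$detect_prob,
                       stack_threshold = scenario$stack_threshold)
  simulate_tasep(model, config)
}

#' Search the initiation rate matching a target detected density
#'
#' The simulated detected-ribosome density increases with the initiation
#' rate until the transcript starts to jam; under partial or no detection
#' of stacked ribosomes it then falls again as stacked ribosomes drop out
#' of the detected pool.  The search expands a geometric bracket along
#' the rising branch and then bisects, with common random numbers across
#' evaluations (the same seed for every candidate `alpha`).  If the
#' target density lies above the reachable peak the search reports
#' non-convergence and returns the best-achieving rate.
#'
#' @param model a [gene_model()] with the elongation rates fixed.
#' @param target_density target detected density in ribosomes per codon.
#' @param scenario a [detection_scenario()].
#' @param cfg an [inference_config()].
#' @param seed seed shared by all objective evaluations.
#' @param alpha_bounds search bracket for `alpha` (naive-rate units).
#' @return a list with `alpha`, `achieved_density`, `converged` and the
#'   evaluation count `n_eval`.
#' @export
fit_initiation <- function(model, target_density,
                           scenario = detection_scenario(),
                           cfg = inference_config(), seed = 1L,
                           alpha_bounds = c(1e-6, 64)) {
  stopifnot(target_density >= 0)
  n_eval <- 0L
  f <- function(a) {
    n_eval <<- n_eval + 1L
    m <- model; m$alpha <- a
    s <- .sim_for(m, cfg, seed, cfg$search_samples, cfg$search_interval,
                  scenario)
    s$rho_detected
  }
  lo <- alpha_bounds[1L]
  if (target_density <= 0)
    return(list(alpha = lo, achieved_density = 0, converged = TRUE,
                n_eval = 0L))
  # Geometric bracket expansion restricted to the rising branch: under
  # partial or no detection of stacked ribosomes the detected density
  # peaks and then falls once the transcript jams (stacked ribosomes
  # vanish from the detected pool), so expansion stops either when the
  # target is bracketed or when the density has clearly passed its peak.
  hi <- max(0.01, 2 * lo)
  f_hi <- f(hi)
  best_alpha <- hi; best_f <- f_hi
  expanded <- FALSE
  while (f_hi < target_density && hi < alpha_bounds[2L]) {
    expanded <- TRUE
    if (f_hi < 0.9 * best_f) {
      # past the jamming peak without reaching the target
      return(list(alpha = best_alpha, achieved_density = best_f,
                  converged = FALSE, n_eval = n_eval))
    }
    if (f_hi > best_f) { best_f <- f_hi; best_alpha <- hi }
    hi <- min(2 * hi, alpha_bounds[2L])
    f_hi <- f(hi)
  }
  if (f_hi < target_density * 0.995)
    return(list(alpha = max(best_alpha, hi),
                achieved_density = max(best_f, f_hi), converged = FALSE,
                n_eval = n_eval))
  if (expanded) lo <- max(lo, hi / 2)
  while ((hi - lo) / (hi + lo) > cfg$alpha_tol / 2) {
    mid <- sqrt(lo * hi)  # bisect on the log scale; alpha spans decades
    if (f(mid) < target_density) lo <- mid else hi <- mid
  }
  alpha <- sqrt(lo * hi)
  list(alpha = alpha, achieved_density = f(alpha), converged = TRUE,
       n_eval = n_eval)
}

#' Detect error-sites between a simulated and an experimental profile
#'
#' Both profiles are normalized to sum to one; positions where the
#' absolute difference exceeds the threshold are returned in 5' to 3'
#' order.
#'
#' @param sim_profile,exp_profile per-codon counts (equal length).
#' @param cfg an [inference_config()]; a scalar `error_threshold` is used
#'   as given, while the default (`NULL`) applies
#'   `max(0.3 / L, 4 * se)` per site, where `se` is the binomial
#'   sampling noise of the normalized density difference implied by the
#'   two profiles' total counts.  The noise floor keeps finite-depth
#'   simulated profiles from flagging pure sampling fluctuations at
#'   high-occupancy sites as model errors.
#' @return integer vector of positions, possibly empty.
#' @export
detect_error_sites <- function(sim_profile, exp_profile,
                               cfg = inference_config()) {
  if (length(sim_profile) != length(exp_profile))
    stop("profiles have different lengths")
  th <- .error_threshold(sim_profile, exp_profile, cfg)
  d <- abs(.norm1(sim_profile) - .norm1(exp_profile))
  sort(which(d > th))
}

# per-site flagging threshold (vector): flat 30%-of-mean-density floor,
# lifted where binomial counting noise alone could exceed it
.error_threshold <- function(sim_profile, exp_profile, cfg) {
  L <- length(exp_profile)
  if (!is.null(cfg$error_threshold)) return(rep(cfg$error_threshold, L))
  n1 <- sum(sim_profile); n2 <- sum(exp_profile)
  p <- pmax(.norm1(sim_profile), .norm1(exp_profile))
  se <- sqrt(p * (1 / max(n1, 1) + 1 / max(n2, 1)))
  pmax(0.3 / L, 4 * se)
}

.norm1 <- function(x) if ((s <- sum(x)) > 0) x / s else x

#' Jointly re-optimize the initiation rate and rates around an error-site
#'
#' Runs a bounded derivative-free simplex search (Nelder-Mead on log
#' rates) over `alpha` and the elongation rates within
#' `cfg$correction_window` codons of the flagged site, minimizing the
#' summed squared difference between the normalized simulated and
#' experimental detected profiles.  Common random numbers (one fixed seed
#' for all objective evaluations) make the stochastic objective
#' quasi-deterministic, so the best-objective sequence is monotone.  If
#' the objective fails to improve the input model is kept and the site is
#' flagged unresolved.
#'
#' @param model current [gene_model()].
#' @param exp_profile experimental per-codon counts.
#' @param site flagged codon position.
#' @param scenario a [detection_scenario()].
#' @param cfg an [inference_config()].
#' @param seed common-random-number seed.
#' @return a list with the updated `model`, `improvement` (error after /
#'   error before), `resolved` (error at the site now under threshold)
#'   and `improved`.
#' @export
correct_error_site <- function(model, exp_profile, site,
                               scenario = detection_scenario(),
                               cfg = inference_config(), seed = 1L) {
  L <- length(model$lambdas)
  idx <- seq(max(2L, site - cfg$correction_window),
             min(L, site + cfg$correction_window))
  expn <- .norm1(exp_profile)
  obj <- function(theta) {
    m <- model
    m$alpha <- exp(theta[1L])
    m$lambdas[idx] <- pmin(exp(theta[-1L]), cfg$lambda_max)
    s <- .sim_for(m, cfg, seed, cfg$search_samples, cfg$search_interval,
                  scenario)
    prof <- sample_profile(s$snapshots, scenario)$detected
    sum((.norm1(prof) - expn)^2)
  }
  theta0 <- log(c(model$alpha, model$lambdas[idx]))
  e0 <- obj(theta0)
  fit <- optim(theta0, obj, method = "Nelder-Mead",
               control = list(maxit = cfg$opt_maxit))
  improved <- fit$value < e0
  out_model <- model
  if (improved) {
    out_model$alpha <- exp(fit$par[1L])
    out_model$lambdas[idx] <- pmin(exp(fit$par[-1L]), cfg$lambda_max)
  }
  s <- .sim_for(out_model, cfg, seed, cfg$final_samples,
                cfg$final_interval, scenario)
  prof <- sample_profile(s$snapshots, scenario)$detected
  th <- .error_threshold(prof, exp_profile, cfg)
  resolved <- abs(.norm1(prof)[site] - expn[site]) <= th[site]
  list(model = out_model,
       improvement = if (e0 > 0) fit$value / e0 else 1,
       resolved = resolved, improved = improved)
}

#' Calibrate the global rate scale to a target speed
#'
#' The exclusion-process occupancies and profiles are invariant under a
#' common scaling of `alpha` and all `lambda`, so the scale must be fixed
#' externally: all rates are multiplied by one constant `k` such that the
#' simulated mean observed speed (see [region_speed()]) between
#' `cfg$speed_region_start` and the stop codon equals `cfg$target_speed`.
#' Requires `L > speed_region_start` (in practice genes longer than 200
#' codons, so the calibration is not biased by the 5' ramp).
#'
#' @param model a [gene_model()].
#' @param scenario a [detection_scenario()].
#' @param cfg an [inference_config()].
#' @param seed simulation seed.
#' @return a list with the rescaled `model`, the scaling constant `k` and
#'   the pre-scaling `measured_speed`.
#' @export
normalize_rates <- function(model, scenario = detection_scenario(),
                            cfg = inference_config(), seed = 1L) {
  L <- length(model$lambdas)
  if (L <= cfg$speed_region_start)
    stop("transcript shorter than the speed calibration region")
  s <- .sim_for(model, cfg, seed, cfg$final_samples, cfg$final_interval,
                scenario)
  v <- region_speed(s, from = cfg$speed_region_start)
  k <- cfg$target_speed / v
  list(model = scale_rates(model, k), k = k, measured_speed = v)
}

#' Infer initiation and elongation rates for one gene
#'
#' Orchestrates the full two-step procedure: naive inverse-density rates,
#' initiation-rate search against the TE-derived detected density,
#' iterative error-site correction (starting from the 5'-most flagged
#' site, re-detecting strictly downstream after each accepted correction)
#' and, optionally, the global speed normalization.
#'
#' @param exp_profile experimental per-codon footprint counts.
#' @param codons codon sequence of the transcript.
#' @param te translation efficiency of the gene.
#' @param te_scaling a `te_scaling` fit (or bare constant) converting TE
#'   to detected density per 100 codons.
#' @param scenario a [detection_scenario()].
#' @param cfg an [inference_config()].
#' @param seed integer seed driving every simulation of the fit.
#' @param gene_id identifier for the returned model.
#' @param normalize apply [normalize_rates()] at the end (default TRUE).
#' @return a list of class `tasep_fit` with the inferred `model` and a
#'   `diagnostics` list (initial error-site count, corrections attempted,
#'   improvement ratios, unresolved sites, interference probability at
#'   corrected sites, convergence flag, the initiation search summary and
#'   the normalization constant).
#' @export
infer_gene <- function(exp_profile, codons, te, te_scaling,
                       scenario = detection_scenario(),
                       cfg = inference_config(), seed = 1L,
                       gene_id = "gene", normalize = TRUE) {
  L <- length(codons)
  if (length(exp_profile) != L)
    stop("profile and codon sequence have different lengths")
  lam <- naive_rates(exp_profile, cfg)
  target <- density_from_te(te, te_scaling) / 100  # per codon
  model <- gene_model(gene_id, codons, alpha = 1e-3, lambdas = lam)
  init <- fit_initiation(model, target, scenario, cfg, seed = seed)
  model$alpha <- init$alpha

  sim <- .sim_for(model, cfg, seed, cfg$final_samples, cfg$final_interval,
                  scenario)
  prof <- sample_profile(sim$snapshots, scenario)$detected
  sites <- detect_error_sites(prof, exp_profile, cfg)
  n_initial <- length(sites)
  improvements <- numeric(0)
  unresolved <- integer(0)
  corrected <- integer(0)
  rounds <- 0L
  while (length(sites) && rounds < cfg$max_rounds) {
    rounds <- rounds + 1L
    site <- sites[1L]
    res <- correct_error_site(model, exp_profile, site, scenario, cfg,
                              seed = seed)
    model <- res$model
    improvements <- c(improvements, res$improvement)
    corrected <- c(corrected, site)
    if (!res$resolved) unresolved <- c(unresolved, site)
    sim <- .sim_for(model, cfg, seed, cfg$final_samples,
                    cfg$final_interval, scenario)
    prof <- sample_profile(sim$snapshots, scenario)$detected
    sites <- detect_error_sites(prof, exp_profile, cfg)
    sites <- sites[sites > site]   # strictly downstream
  }
  converged <- init$converged &&
    (length(sites) == 0L ||
       (length(improvements) >= 2L &&
          all(tail(improvements, 2L) > 0.95)))
  k <- NA_real_
  if (normalize) {
    nr <- normalize_rates(model, scenario, cfg, seed = seed)
    model <- nr$model
    k <- nr$k
  }
  structure(list(
    model = model,
    diagnostics = list(
      n_error_sites = n_initial, corrected_sites = corrected,
      improvements = improvements, unresolved_sites = unresolved,
      interference_at_corrected =
        if (length(corrected)) sim$interference_prob[corrected]
        else numeric(0),
      converged = converged, initiation = init, scale_k = k)),
    class = "tasep_fit")
}

#' @export
print.tasep_fit <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "<tasep_fit> %s: alpha = %.4g, %d error site(s), %d correction(s), converged: %s\n",
    x$model$gene_id, x$model$alpha, d$n_error_sites,
    length(d$corrected_sites), d$converged))
  invisible(x)
}
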