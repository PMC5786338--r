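test_that("invalid models and configs are rejected", {
  expect_error(gene_model("g", c("ATG", "TAA"), alpha = 0,
                          lambdas = c(1, 1)), "positive")
  expect_error(gene_model("g", c("ATG", "TAA"), alpha = 1,
                          lambdas = c(1, -1)), "positive")
  expect_error(gene_model("g", c("ATG", "AAA", "TAA"), alpha = 1,
                          lambdas = c(1, 1)), "length")
  expect_error(sim_config(sample_interval = 0), "sample_interval")
  expect_error(sim_config(dropoff_rate = 1), "dropoff_rate")
  expect_error(gene_model("g", c("ATG", "TAA"), 1, c(1, 1),
                          footprint = 2, asite_offset = 3), "footprint")
})

test_that("exact steady state solves degenerate and symmetric cases", {
  # single decoded site: enter at alpha, leave at lambda; alpha = lambda
  m <- toy_model(2, alpha = 1, lambdas = c(1, 1))
  ex <- exact_steady_state(m)
  expect_equal(ex$site_occupancy, c(0, 0.5))
  expect_equal(ex$flux, 0.5)
  # alpha = 0: empty lattice is absorbing
  ex0 <- exact_steady_state(m, alpha = 0)
  expect_equal(ex0$site_occupancy, c(0, 0))
  expect_equal(ex0$flux, 0)
  # detailed-balance check on a non-uniform single-site system
  m2 <- toy_model(2, alpha = 0.3, lambdas = c(1, 0.7))
  ex2 <- exact_steady_state(m2)
  expect_equal(ex2$site_occupancy[2], 0.3 / (0.3 + 0.7))
})

test_that("exact solver agrees with an independent brute-force oracle", {
  set.seed(42)
  for (ell in 1:2) {
    L <- 6L
    lam <- runif(L, 0.4, 2)
    alpha <- runif(1, 0.1, 1)
    m <- toy_model(L, alpha, lam, footprint = ell)
    ex <- exact_steady_state(m)
    bf <- brute_force_steady(L, ell, alpha, lam)
    expect_equal(ex$n_states, bf$n_states)
    expect_equal(ex$site_occupancy, bf$occ, tolerance = 1e-10)
    expect_equal(ex$flux, bf$flux, tolerance = 1e-10)
  }
})

test_that("state-space guard refuses with a size estimate", {
  m <- gene_model("big", c("ATG", rep("AAA", 298), "TAA"), 0.1,
                  rep(1, 300))
  expect_error(exact_steady_state(m), "configurations")
})

test_that("simulated occupancies match alpha/lambda in the sparse limit", {
  L <- 50L
  m <- toy_model(L, alpha = 1e-4, lambdas = rep(1, L), footprint = 10L)
  s <- simulate_tasep(m, sim_config(burn_in = 5e3, n_samples = 3e4,
                                    sample_interval = 20, seed = 101))
  interior <- 5:45
  se <- occupancy_se(s$snapshots)
  pooled <- mean(s$site_occupancy[interior])
  pooled_se <- sqrt(mean(se[interior]^2) / length(interior))
  expect_lt(abs(pooled - 1e-4), 3 * pooled_se + 1e-12)
})

test_that("simulation matches the exact oracle within 3 standard errors", {
  set.seed(7)
  for (i in 1:3) {
    ell <- sample(1:2, 1)
    L <- sample(5:8, 1)
    m <- random_small_model(L, ell)
    ex <- exact_steady_state(m)
    s <- simulate_tasep(m, sim_config(burn_in = 2e3, n_samples = 3e4,
                                      sample_interval = 10,
                                      seed = 500 + i))
    se <- occupancy_se(s$snapshots)
    dev <- abs(s$site_occupancy - ex$site_occupancy)
    expect_true(all(dev <= 3 * se + 0.01 * ex$site_occupancy + 1e-9))
  }
})

test_that("flux balances against stop-codon occupancy and termination rate", {
  m <- toy_model(30, alpha = 0.5, lambdas = c(rep(2, 29), 0.8),
                 footprint = 5L)
  s <- simulate_tasep(m, sim_config(burn_in = 5e3, n_samples = 3e4,
                                    sample_interval = 20, seed = 11))
  expect_equal(s$flux, s$site_occupancy[30] * 0.8, tolerance = 0.06)
})

test_that("total density is monotone in the initiation rate", {
  L <- 40L
  lam <- rep(2, L)
  rho <- vapply(c(0.05, 0.3, 1.5), function(a) {
    m <- toy_model(L, a, lam, footprint = 10L)
    simulate_tasep(m, sim_config(burn_in = 5e3, n_samples = 1e4,
                                 sample_interval = 20,
                                 seed = 21))$rho_total
  }, 0)
  expect_true(all(diff(rho) > 0))
})

test_that("identical model, config and seed give identical snapshots", {
  m <- toy_model(25, 0.4, runif(25, 0.5, 2), footprint = 5L)
  cfg <- sim_config(burn_in = 1e3, n_samples = 2e3, sample_interval = 10,
                    seed = 99)
  s1 <- simulate_tasep(m, cfg)
  s2 <- simulate_tasep(m, cfg)
  expect_identical(s1$snapshots$pos, s2$snapshots$pos)
  expect_identical(s1$snapshots$len, s2$snapshots$len)
  expect_identical(s1$flux, s2$flux)
})

test_that("drop-off thins the ribosome current geometrically", {
  L <- 60L
  r <- 0.02
  m <- toy_model(L, alpha = 0.02, lambdas = rep(1, L), footprint = 10L)
  s <- simulate_tasep(m, sim_config(burn_in = 5e3, n_samples = 4e4,
                                    sample_interval = 20, seed = 31,
                                    dropoff_rate = r))
  # visits at position k relative to position 2 approach (1-r)^(k-2)
  ks <- c(20L, 40L, 59L)
  ratio <- s$dwell_n[ks] / s$dwell_n[2L]
  expected <- (1 - r)^(ks - 2L)
  expect_equal(ratio, expected, tolerance = 0.08)
})

test_that("observed rates equal lambda without interference and drop below it behind a stall", {
  L <- 40L
  lam <- rep(2, L)
  m <- toy_model(L, alpha = 0.005, lambdas = lam, footprint = 10L)
  s <- simulate_tasep(m, sim_config(burn_in = 5e3, n_samples = 3e4,
                                    sample_interval = 20, seed = 41))
  rates <- observed_rates(s)
  visited <- rates$n_visits > 50
  expect_equal(rates$observed_rate[visited],
               rates$unobstructed_rate[visited], tolerance = 0.1)
  # now jam the lattice behind a slow site
  lam2 <- lam; lam2[30] <- 0.1
  m2 <- toy_model(L, alpha = 1, lambdas = lam2, footprint = 10L)
  s2 <- simulate_tasep(m2, sim_config(burn_in = 5e3, n_samples = 3e4,
                                      sample_interval = 20, seed = 42))
  r2 <- observed_rates(s2)
  trailing <- 15:19   # one footprint behind the queue position
  expect_true(all(r2$observed_rate[trailing] <
                    r2$unobstructed_rate[trailing] * 0.8))
  expect_true(all(r2$gap > -0.2, na.rm = TRUE))
  # never-visited positions are NA, not zero
  expect_true(is.na(r2$observed_rate[1]))
})

test_that("interference probability concentrates one footprint behind a stall", {
  L <- 40L
  lam <- rep(2, L); lam[30] <- 0.05
  m <- toy_model(L, alpha = 1.5, lambdas = lam, footprint = 10L)
  s <- simulate_tasep(m, sim_config(burn_in = 5e3, n_samples = 2e4,
                                    sample_interval = 20, seed = 43))
  # the stalled site at 30 almost always has a trailing ribosome at 20
  expect_gt(s$interference_prob[30], 0.5)
})

test_that("gene model and snapshot TSV round-trips are exact", {
  m <- toy_model(12, 0.123456789, runif(12, 0.5, 2), footprint = 3L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_model(m, path)
  m2 <- read_gene_model(path)
  expect_identical(m2$lambdas, m$lambdas)
  expect_identical(m2$alpha, m$alpha)
  expect_identical(m2$codons, m$codons)
  snaps <- as_snapshots(list(c(2L, 7L), integer(0), 5L), L = 12)
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_snapshots(snaps, sp)
  tab <- read.delim(sp, colClasses = c("integer", "character"))
  expect_equal(tab$a_sites, c("2,7", "", "5"))
})
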