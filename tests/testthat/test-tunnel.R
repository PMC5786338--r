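test_that("centerline fit explains collinear, helical and isotropic clouds", {
  t <- seq(0, 50, length.out = 100)
  line <- cbind(1 + 2 * t, 3 - t, 0.5 * t)
  fit <- fit_centerline(line)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$arc[1], 0)
  expect_true(all(diff(fit$arc) > 0))
  # helical perturbation: R^2 -> 1 as the amplitude shrinks
  r2_at <- function(eps) {
    helix <- cbind(t, eps * cos(t), eps * sin(t))
    fit_centerline(helix)$r_squared
  }
  expect_gt(r2_at(0.01), r2_at(1))
  expect_gt(r2_at(0.01), 0.999)
  # isotropic cloud: the first principal axis explains about 1/3
  set.seed(500)
  cloud <- matrix(rnorm(1500), ncol = 3)
  expect_lt(abs(fit_centerline(cloud)$r_squared - 1 / 3), 0.05)
  expect_error(fit_centerline(matrix(1, 5, 3)), "degenerate")
  expect_error(fit_centerline(line[1:2, ]), "3 points")
})

test_that("charge assignment places unit charges on representative atoms", {
  atoms <- data.frame(
    resid = c("LYS", "LYS", "ARG", "ASP", "GLU", "A", "G", "HIS", "XXX"),
    elety = c("NZ", "CA", "CZ", "CG", "CD", "P", "P", "NE2", "ZN"),
    x = 1:9, y = 1:9, z = 1:9)
  cs <- suppressMessages(charges_from_structure(atoms))
  # +1 (LYS NZ) +1 (ARG CZ) -1 (ASP CG) -1 (GLU CD) -2 (two phosphates)
  expect_equal(sum(cs$charge), -2)
  expect_equal(attr(cs, "n_skipped"), 1L)
})

test_that("a mixed residue fixture has the expected net charge", {
  # 3 lysines, 2 aspartates, 4 nucleotide phosphates: net 3 - 2 - 4 = -3
  atoms <- data.frame(
    resid = c(rep("LYS", 3), rep("ASP", 2), rep("A", 2), rep("U", 2)),
    elety = c(rep("NZ", 3), rep("CG", 2), rep("P", 4)),
    x = seq(1, 9), y = 0, z = 0)
  cs <- charges_from_structure(atoms)
  expect_equal(sum(cs$charge), -3)
  expect_equal(nrow(cs), 9L)
  # histidine stays neutral
  his <- data.frame(resid = "HIS", elety = "ND1", x = 0, y = 0, z = 0)
  expect_equal(nrow(charges_from_structure(his)), 0L)
})

test_that("PDB text records are parsed through the structure reader", {
  pdb_lines <- c(
    sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            "ATOM", 1, " NZ", "LYS", "A", 1, 1.0, 2.0, 3.0, 1, 0),
    sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            "ATOM", 2, " P", "A", "B", 2, 4.0, 5.0, 6.0, 1, 0),
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines, f)
  cs <- charges_from_structure(f)
  expect_equal(sort(cs$charge), c(-1, 1))
  expect_equal(cs$x[cs$charge == 1], 1.0)
})

test_that("entropic potential has the closed-form increments and gradient", {
  prof <- tunnel_profile(x = c(0, 1), radius = c(2, 4))
  ep <- entropic_potential(prof, smooth = 0)
  expect_equal(diff(ep$S), log(4))            # r doubling: ln 4
  flat <- tunnel_profile(x = 0:20, radius = rep(3, 21))
  ef <- entropic_potential(flat, smooth = 10)
  expect_equal(ef$neg_dS_smooth, rep(0, 21))
  expect_equal(ef$S, rep(log(pi * 9), 21))
  # cone r = a x on x in [1, 10]: dS/dx = 2/x, central differences
  x <- seq(1, 10, by = 0.05)
  cone <- tunnel_profile(x, radius = 0.7 * x)
  ec <- entropic_potential(cone, smooth = 0)
  interior <- 10:170
  expect_equal(ec$dS[interior], 2 / x[interior], tolerance = 0.01)
  expect_error(tunnel_profile(x, radius = -x), "positive")
})

test_that("Coulomb potential sums 1/d within the cutoff", {
  x <- seq(0, 30, by = 1)
  P <- cbind(x, 0, 0)
  prof <- tunnel_profile(x, radius = rep(5, length(x)), centerline = P)
  q1 <- data.frame(x = 0, y = 5, z = 0, charge = 1)
  v <- coulomb_potential(prof, q1, cutoff = 20, smooth = 0)
  expect_equal(v$V[1], 0.2)                   # +1 at 5 Angstrom
  # opposite charges equidistant cancel exactly
  q2 <- rbind(q1, data.frame(x = 0, y = -5, z = 0, charge = -1))
  v2 <- coulomb_potential(prof, q2, cutoff = 20, smooth = 0)
  expect_equal(v2$V[1], 0)
  # a charge beyond the cutoff adds nothing
  q3 <- rbind(q1, data.frame(x = 0, y = 21, z = 0, charge = 5))
  v3 <- coulomb_potential(prof, q3, cutoff = 20, smooth = 0)
  expect_equal(v3$V, v$V)
  # linearity in the charge set
  qa <- data.frame(x = 3, y = 4, z = 0, charge = 1)
  qb <- data.frame(x = 8, y = -6, z = 1, charge = -1)
  va <- coulomb_potential(prof, qa, smooth = 0)$V
  vb <- coulomb_potential(prof, qb, smooth = 0)$V
  vab <- coulomb_potential(prof, rbind(qa, qb), smooth = 0)$V
  expect_equal(vab, va + vb)
  # coincident charge excluded with a warning
  q0 <- data.frame(x = 0, y = 0, z = 0, charge = 1)
  expect_warning(coulomb_potential(prof, q0, smooth = 0), "coincident")
})

test_that("potentials are invariant under rigid-body transforms", {
  set.seed(501)
  x <- seq(0, 20, by = 0.5)
  P <- cbind(x, sin(x / 5), cos(x / 7))
  charges <- data.frame(x = runif(30, -5, 25), y = runif(30, -8, 8),
                        z = runif(30, -8, 8),
                        charge = sample(c(-1, 1), 30, TRUE))
  prof <- tunnel_profile(x, radius = 2 + 0.1 * x, centerline = P)
  v0 <- coulomb_potential(prof, charges, smooth = 0)$V
  # random rotation + translation applied to both
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(3, -2, 5)
  Pr <- sweep(P %*% t(R), 2, -shift)
  Cr <- sweep(as.matrix(charges[, 1:3]) %*% t(R), 2, -shift)
  charges_r <- data.frame(Cr, charge = charges$charge)
  names(charges_r)[1:3] <- c("x", "y", "z")
  prof_r <- tunnel_profile(x, radius = 2 + 0.1 * x, centerline = Pr)
  vr <- coulomb_potential(prof_r, charges_r, smooth = 0)$V
  expect_equal(vr, v0, tolerance = 1e-10)
})

test_that("smoothing preserves a uniformly one-signed gradient", {
  x <- seq(0, 40, by = 0.5)
  prof <- tunnel_profile(x, radius = 2 + 0.2 * x)   # monotone widening
  ep <- entropic_potential(prof, smooth = 10)
  expect_true(all(ep$neg_dS_smooth < 0))            # force uniformly inward
})

test_that("centerline CSV round-trips into a tunnel profile", {
  t <- seq(0, 40, length.out = 50)
  df <- data.frame(x = t + rnorm(50, 0, 0.01), y = 0.3 * t, z = -0.1 * t,
                   radius = 2 + t / 20)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  prof <- read_centerline_csv(f)
  expect_s3_class(prof, "tunnel_profile")
  expect_gt(attr(prof, "fit")$r_squared, 0.999)
  expect_equal(length(prof$x), 50)
  expect_true(all(diff(prof$x) > 0))
})
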