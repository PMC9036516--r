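# ESP sample lattices, charge fitting, solvent charge maps, thresholding.

test_that("chelpg lattice matches brute-force enumeration for one atom", {
  one <- solute_model("C", matrix(0, 1, 3), 0, 3.4, 1.0)
  pts <- chelpg_points(one, radii = c(C = 1.5), shell_spacing = 1.0,
                       r_max = 2.8)
  # oracle: enumerate the documented lattice (anchored at multiples of the
  # spacing) and count shell members
  ax <- (floor(-2.8):ceiling(2.8)) * 1.0
  lat <- as.matrix(expand.grid(ax, ax, ax))
  d <- sqrt(rowSums(lat^2))
  expect_identical(nrow(pts), sum(d >= 1.5 & d <= 2.8))
  # all points respect the shell
  dp <- sqrt(rowSums(pts^2))
  expect_true(all(dp >= 1.5 & dp <= 2.8))
})

test_that("chelpg lattice mirrors with the molecule and validates input", {
  s <- solute_model(c("C", "O"), rbind(c(0.4, 0.2, 0), c(1.6, 0.2, 0)),
                    c(0, 0), c(3.4, 3.0), c(0.5, 0.6))
  sm <- solute_model(c("C", "O"), rbind(c(-0.4, 0.2, 0), c(-1.6, 0.2, 0)),
                     c(0, 0), c(3.4, 3.0), c(0.5, 0.6))
  p <- chelpg_points(s, shell_spacing = 0.7)
  pm <- chelpg_points(sm, shell_spacing = 0.7)
  # mirror through x = 0: same points with x negated (as sets)
  key <- function(m) sort(apply(round(m, 9), 1, paste, collapse = "/"))
  pm_ref <- p; pm_ref[, 1] <- -pm_ref[, 1]
  expect_identical(key(pm), key(pm_ref))
  expect_error(chelpg_points(s, radii = c(C = 1.7)), "O")
  expect_error(chelpg_points(s, r_max = 1.0), "degenerate shell")
})

test_that("ESP fit is an exact inverse of the forward model", {
  # two known charges, analytic sample, recovery to 1e-10
  pos <- rbind(c(0, 0, 0), c(0, 0, 1.1))
  q_true <- c(0.4, -0.4)
  sol <- solute_model(c("N", "O"), pos, q_true, c(3, 3), c(0.5, 0.5))
  pts <- chelpg_points(sol, shell_spacing = 0.8)
  phi <- direct_esp(q_true, pos, pts, units = "au")
  fit <- fit_esp_charges(pts, phi, pos, total_charge = 0)
  expect_lt(max(abs(fit$values - q_true)), 1e-10)
  expect_lt(fit$rms, 1e-12)
  # symmetric diatomic with symmetric sample: opposite equal charges
  expect_equal(fit$values[1], -fit$values[2], tolerance = 1e-10)
  # seeded random configurations: property holds whenever points > atoms
  for (seed in 1:4) {
    fx <- make_fixture("random_cluster", seed = seed)
    s <- fx$solute
    pts <- chelpg_points(s, radii = c(C = 1.5), shell_spacing = 0.9)
    phi <- direct_esp(s$charge, s$xyz, pts, units = "au")
    fit <- fit_esp_charges(pts, phi, s$xyz, total_charge = sum(s$charge))
    expect_lt(max(abs(fit$values - s$charge)), 1e-9)
  }
})

test_that("fit respects the total-charge constraint and flags degeneracy", {
  pos <- rbind(c(0, 0, 0), c(0, 0, 1.1))
  sol <- solute_model(c("N", "O"), pos, c(0.2, 0.3), c(3, 3), c(0.5, 0.5))
  pts <- chelpg_points(sol, shell_spacing = 0.9)
  phi <- direct_esp(c(0.2, 0.3), pos, pts, units = "au")
  fit <- fit_esp_charges(pts, phi, pos, total_charge = 0.5)
  expect_equal(sum(fit$values), 0.5, tolerance = 1e-12)
  # collinear degeneracy: two atoms at the same position
  expect_error(fit_esp_charges(pts, phi, rbind(c(0, 0, 0), c(0, 0, 0)),
                               total_charge = 0.5), "ill-conditioned")
  expect_error(fit_esp_charges(pts[1:2, ], phi[1:2], pos, 0), "sample points")
})

test_that("production fitter agrees with the substitution-route oracle", {
  set.seed(7)
  pos <- matrix(rnorm(9), 3, 3)
  pts <- matrix(rnorm(60, sd = 4), 20, 3)
  phi <- direct_esp(c(0.3, -0.5, 0.2), pos, pts, units = "au")
  phi <- phi + rnorm(20, sd = 0.01)     # noisy so the fit is non-trivial
  A <- matrix(0, 20, 3)
  for (a in 1:3)
    A[, a] <- 1 / (sqrt(rowSums(sweep(pts, 2, pos[a, ])^2)) /
                   rism_constants()$bohr_angstrom)
  fit <- fit_esp_charges(pts, phi, pos, total_charge = 0)
  oracle <- naive_constrained_lsq(A, phi, total = 0)
  expect_lt(max(abs(fit$values - oracle)), 1e-10)
})

test_that("solvent charge map: bulk neutrality and single-voxel arithmetic", {
  chi <- test_chi("cSPC/E", closure_spec("KH"))
  corr <- test_lj_corr()
  map <- solvent_charge_map(corr)
  dims <- corr$grid$dims
  dv <- corr$grid$voxel_volume
  rho <- corr$site_densities
  qs <- corr$site_charges
  # a bulk voxel (g = 1 for both sites) carries zero net charge
  g1 <- which(abs(corr$g$O - 1) < 1e-9 & abs(corr$g$H - 1) < 1e-9)
  if (length(g1) > 0) expect_lt(max(abs(map$charges[g1])), 1e-12)
  # hand computation at the voxel of maximum g_O
  i <- which.max(corr$g$O)
  expect_equal(map$charges[i],
               (qs[["O"]] * rho[["O"]] * corr$g$O[i] +
                qs[["H"]] * rho[["H"]] * corr$g$H[i]) * dv,
               tolerance = 1e-14)
  # bulk-subtracted variant differs by exactly the (zero) bulk term
  mapb <- solvent_charge_map(corr, bulk_subtract = TRUE)
  expect_equal(map$charges, mapb$charges, tolerance = 1e-12)
  # map points follow R's array linearization of the grid
  expect_equal(map$points[1, ], sapply(corr$grid$axes, `[`, 1))
})

test_that("charge map scales linearly with voxel volume", {
  # same g fields, coarser grid: per-point charges double when dV doubles
  z <- array(1.5, c(4, 4, 4))
  mk <- function(vv) {
    grid <- structure(list(origin = c(0, 0, 0),
                           spacing = rep(vv^(1 / 3), 3), dims = c(4L, 4L, 4L),
                           voxel_volume = vv,
                           axes = lapply(1:3, function(i)
                             (0:3) * vv^(1 / 3))), class = "grid3d")
    structure(list(grid = grid, sites = c("O", "H"),
                   site_densities = c(O = 0.03, H = 0.06),
                   site_charges = c(O = -0.8, H = 0.4),
                   g = list(O = z, H = array(1, c(4, 4, 4)))),
              class = "correlations3d")
  }
  m1 <- solvent_charge_map(mk(0.125))
  m2 <- solvent_charge_map(mk(0.25))
  expect_equal(m2$charges, 2 * m1$charges, tolerance = 1e-12)
})

test_that("drop_small thresholds, records fractions, and is idempotent", {
  m <- charge_map(matrix(0, 3, 3), c(1e-7, 5e-6, 2e-3))
  # threshold 0 is the identity
  m0 <- drop_small(m, 0)
  expect_identical(m0$charges, m$charges)
  d <- drop_small(m, 1e-6)
  expect_identical(length(d$charges), 2L)
  expect_equal(d$dropped_fraction, 1 / 3)
  # idempotence
  d2 <- drop_small(d, 1e-6)
  expect_identical(d2$charges, d$charges)
  expect_identical(d2$dropped_fraction, d$dropped_fraction)
  # threshold above everything empties the map
  e <- drop_small(m, 1)
  expect_identical(length(e$charges), 0L)
  expect_equal(e$dropped_fraction, 1)
  expect_error(drop_small(m, -1), ">= 0")
})
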