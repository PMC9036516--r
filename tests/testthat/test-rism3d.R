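# 3D grid construction, site potentials, spectral solver.

test_that("build_grid respects buffer, rounding, and monotonicity", {
  one <- solute_model("C", matrix(0, 1, 3), 0, 3.4, 1.0)
  g <- build_grid(one, buffer = 15, spacing = 0.3)
  expect_true(all(g$dims * g$spacing >= 30))
  expect_true(all(g$dims >= 100))
  # realized clearance from the atom to every face is >= buffer
  lo <- g$origin
  hi <- g$origin + g$dims * g$spacing
  expect_true(all(-lo >= 15) && all(hi >= 15))
  # larger buffer, strictly larger volume
  g5 <- build_grid(one, buffer = 5, spacing = 0.3)
  expect_lt(prod(g5$dims), prod(g$dims))
  # two atoms 4 A apart on x, buffer 10, spacing 0.5: x edge >= 24 A and
  # dims rounded up to an FFT-friendly composite >= 48
  two <- solute_model(c("C", "C"), rbind(c(-2, 0, 0), c(2, 0, 0)),
                      c(0, 0), c(3, 3), c(0.5, 0.5))
  g2 <- build_grid(two, buffer = 10, spacing = 0.5)
  expect_gte(g2$dims[1] * 0.5, 24)
  expect_identical(g2$dims[1], 48L)    # 48 = 2^4 * 3 is already smooth
  expect_error(build_grid(one, buffer = 1, spacing = 10), "degenerate")
})

test_that("fft-friendly rounding produces 2,3,5,7-smooth sizes", {
  smooth <- function(n) {
    for (p in c(2, 3, 5, 7)) while (n %% p == 0) n <- n / p
    n == 1
  }
  for (n in c(11, 13, 31, 97, 101, 211)) {
    m <- ecrism:::.fft_friendly(n)
    expect_gte(m, n)
    expect_true(smooth(m))
  }
})

test_that("solute potentials: superposition and exact Coulomb split", {
  th <- thermo_state()
  solv <- list(O = site("O", -0.8476, 3.1658, 0.64978),
               H = site("H", 0.4238, 1.1658, 0.064978))
  two <- solute_model(c("N", "O"), rbind(c(0, 0, 0), c(0, 0, 1.2)),
                      c(0.35, -0.35), c(3.1, 2.9), c(0.5, 0.45))
  grid <- build_grid(two, buffer = 6, spacing = 0.5)
  pot <- solute_site_potentials(two, solv, grid, th)
  # superposition: two one-atom solutes sum to the two-atom field exactly
  for (a in 1:2) {
    onea <- solute_model(two$element[a], two$xyz[a, , drop = FALSE],
                         two$charge[a], two$sigma[a], two$epsilon[a])
    assign(paste0("p", a), solute_site_potentials(onea, solv, grid, th))
  }
  expect_identical(pot$u_sr$O, p1$u_sr$O + p2$u_sr$O)
  expect_equal(pot$u$H, p1$u$H + p2$u$H, tolerance = 1e-15)
  # all charges zero leaves the pure LJ sum
  neut <- set_charges(two, c(0, 0))
  pn <- solute_site_potentials(neut, solv, grid, th)
  expect_equal(pn$u_lr$O, array(0, grid$dims))
  expect_identical(pn$u$O, pn$u_sr$O)
  # total real-space Coulomb of a unit charge at an off-axis grid point
  # 5 A away equals k_e/5 (short + long split reconstructs 1/r exactly)
  probe <- solute_model("H", matrix(0, 1, 3), 1, 0, 0)
  gridp <- build_grid(probe, buffer = 8, spacing = 0.5)
  potp <- solute_site_potentials(probe, list(O = site("p", 1, 0, 0),
                                             H = site("h", 0, 0, 0)), gridp, th)
  idx <- vapply(1:3, function(d) which.min(abs(gridp$axes[[d]] -
                                               c(3, 4, 0)[d])), integer(1))
  r <- sqrt(sum((c(gridp$axes[[1]][idx[1]], gridp$axes[[2]][idx[2]],
                   gridp$axes[[3]][idx[3]]))^2))
  u_here <- potp$u$O[idx[1], idx[2], idx[3]]
  expect_equal(u_here, rism_constants()$coulomb / r, tolerance = 1e-6)
  # invalid solvent parameters are rejected
  expect_error(solute_site_potentials(two, list(O = site("bad", 0, 0, 0.5)),
                                      grid, th), "invalid solvent site")
})

test_that("spectral convolution matches the brute-force oracle on 8^3", {
  set.seed(11)
  d <- c(8L, 8L, 8L)
  c_arr <- array(rnorm(prod(d)), d)
  kernel <- array(exp(-as.vector(ecrism:::.k_squared(
    structure(list(dims = d, spacing = rep(0.5, 3)), class = "grid3d")))), d)
  K_real <- Re(fft(kernel, inverse = TRUE)) / prod(d)
  expect_lt(max(abs(spectral_convolve(c_arr, kernel) -
                    direct_convolution(c_arr, K_real))), 1e-10)
  # delta-function input returns the kernel
  delta <- array(0, d); delta[1, 1, 1] <- 1
  expect_lt(max(abs(direct_convolution(delta, K_real) - K_real)), 1e-14)
  expect_error(direct_convolution(array(0, c(32, 32, 32)),
                                  array(0, c(32, 32, 32))), "too large")
})

test_that("zero potential gives the trivial fixed point h = c = 0", {
  chi <- test_chi("cSPC/E", closure_spec("KH"))
  neut <- solute_model("C", matrix(0, 1, 3), 0, 0, 0)
  grid <- build_grid(neut, buffer = 5, spacing = 0.5)
  pot <- solute_site_potentials(neut, chi$solvent_sites, grid, thermo_state())
  corr <- solve_3drism(pot, chi, closure_spec("KH"))
  expect_equal(max(abs(corr$h$O)), 0)
  expect_equal(max(abs(corr$c$O)), 0)
  expect_lte(corr$niter, 2)
})

test_that("LJ sphere solution is spherically symmetric and physical", {
  corr <- test_lj_corr()
  grid <- corr$grid
  # sample g_O at equal radii in different directions
  ctr <- grid$origin + grid$dims * grid$spacing / 2
  # axis directions at lattice radii are exact symmetry images: they must
  # agree to solver tolerance
  axes6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  for (rad in c(3.5, 5.0)) {
    vals <- trilinear_sample(corr$g$O, grid, sweep(axes6 * rad, 2, ctr, "+"))
    expect_lt(diff(range(vals)), 1e-6)
  }
  # off-lattice directions agree up to trilinear interpolation error
  diag3 <- rbind(c(1, 1, 1) / sqrt(3), c(-1, 1, 0) / sqrt(2), c(1, 0, 0))
  vals <- trilinear_sample(corr$g$O, grid, sweep(diag3 * 5.0, 2, ctr, "+"))
  expect_lt(diff(range(vals)), 5e-2)
  # pointwise KH linearization regions: linear branch wherever g > 1
  t_arg <- -corr$thermo$beta * corr$u_sr$O + corr$gamma$O
  up <- corr$g$O > 1
  expect_equal(corr$g$O[up], 1 + t_arg[up], tolerance = 1e-12)
  expect_equal(corr$g$O[!up], exp(t_arg[!up]), tolerance = 1e-12)
  # core exclusion: h <= 0 where the potential is strongly repulsive
  expect_true(all(corr$h$O[corr$u_sr$O > 50] <= 0))
  # g >= 0 everywhere, boundary near bulk (8 A buffer: LJ tail ~ 1e-2)
  expect_true(all(corr$g$O >= 0) && all(corr$g$H >= 0))
  expect_lt(max(abs(corr$g$O[1, , ] - 1)), 5e-2)
  # at the recommended 15 A buffer the boundary is bulk-like within 5e-3
  c15 <- test_lj_corr(buffer = 15, spacing = 0.5)
  expect_lt(max(abs(c15$g$O[1, , ] - 1)), 5e-3)
  expect_lt(max(abs(c15$g$H[, 1, ] - 1)), 5e-3)
})

test_that("solution tightness: halving the tolerance moves dG < 0.01 kJ/mol", {
  c1 <- test_lj_corr(tol = 1e-6)
  c2 <- test_lj_corr(tol = 5e-7)
  dg1 <- excess_mu(c1, "KH")
  dg2 <- excess_mu(c2, "KH")
  expect_lt(abs(dg1 - dg2), 0.01)
})
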