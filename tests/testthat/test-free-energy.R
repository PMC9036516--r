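# Free-energy functionals, PMV, UC / PC / PC+ corrections.

# hand-built correlations3d carrier for synthetic-field tests
fake_corr <- function(h, cc, gamma = NULL, u_sr = NULL,
                      spacing = 0.5, closure = closure_spec("KH"),
                      rho = c(O = 0.0333, H = 0.0666),
                      kappa_T = 0.8, p_rism = 0.76, rho_kT = 0.0826) {
  d <- dim(h)
  grid <- structure(list(origin = c(0, 0, 0), spacing = rep(spacing, 3),
                         dims = d, voxel_volume = spacing^3,
                         axes = lapply(1:3, function(i)
                           (seq_len(d[i]) - 1) * spacing)),
                    class = "grid3d")
  if (is.null(gamma)) gamma <- h - cc
  if (is.null(u_sr)) u_sr <- array(0, d)
  structure(list(
    grid = grid, closure = closure, thermo = thermo_state(),
    sites = c("O", "H"),
    site_densities = rho, site_charges = c(O = -0.8476, H = 0.4238),
    rho_molecular = unname(rho["O"]),
    kappa_T = kappa_T,
    pressure = list(p_rism = p_rism, rho_kT = rho_kT, ideal = 2 * rho_kT),
    u = list(O = u_sr, H = u_sr), u_sr = list(O = u_sr, H = u_sr),
    gamma = list(O = gamma, H = gamma),
    h = list(O = h, H = h), c = list(O = cc, H = cc),
    g = list(O = h + 1, H = h + 1),
    residual = 0, niter = 0, converged = TRUE,
    solvent = "synthetic", chi_closure = "KH"
  ), class = "correlations3d")
}

test_that("all functionals vanish on bulk fields (h = c = 0)", {
  z <- array(0, c(6, 6, 6))
  corr <- fake_corr(z, z)
  for (f in c("KH", "HNC", "GF"))
    expect_identical(excess_mu(corr, f, override = TRUE), 0)
  expect_identical(excess_mu(corr, "PSE", n = 3, override = TRUE), 0)
})

test_that("KH equals HNC on h < 0 fields and GF on h >= 0 fields", {
  set.seed(42)
  d <- c(5, 5, 5)
  cc <- array(rnorm(prod(d), sd = 0.1), d)
  h_neg <- -abs(array(rnorm(prod(d), sd = 0.3), d))
  corr_n <- fake_corr(h_neg, cc)
  expect_identical(excess_mu(corr_n, "KH"),
                   excess_mu(corr_n, "HNC", override = TRUE))
  h_pos <- abs(array(rnorm(prod(d), sd = 0.3), d))
  corr_p <- fake_corr(h_pos, cc)
  expect_identical(excess_mu(corr_p, "KH"),
                   excess_mu(corr_p, "GF", override = TRUE))
  # independent integrand evaluation for the h < 0 case
  kT <- 1 / thermo_state()$beta
  byhand <- kT * sum((0.0333 + 0.0666) *
                     (h_neg^2 / 2 - cc - h_neg * cc / 2)) * 0.5^3
  expect_equal(excess_mu(corr_n, "KH"), byhand, tolerance = 1e-12)
})

test_that("functional/closure mismatch is signalled unless overridden", {
  z <- array(0, c(4, 4, 4))
  corr <- fake_corr(z, z, closure = closure_spec("KH"))
  expect_error(excess_mu(corr, "HNC"), "does not match")
  expect_silent(excess_mu(corr, "GF"))   # GF is closure-agnostic
})

test_that("functionals are additive over disjoint spatial decompositions", {
  corr <- test_lj_corr()
  integ <- excess_mu(corr, "KH", integrand = TRUE)
  total <- excess_mu(corr, "KH")
  half <- corr$grid$dims[1] %/% 2
  left <- sum(integ[seq_len(half), , ]) * corr$grid$voxel_volume
  right <- sum(integ[(half + 1):corr$grid$dims[1], , ]) *
    corr$grid$voxel_volume
  expect_equal(left + right, total, tolerance = 1e-12)
})

test_that("partial molar volume follows the Kirkwood-Buff route", {
  d <- c(10, 10, 10)
  z <- array(0, d)
  kT <- 1 / thermo_state()$beta
  corr0 <- fake_corr(z, z, kappa_T = 0.8)
  expect_equal(partial_molar_volume(corr0), kT * 0.8)
  # toy field: c constant inside the whole 5 A cube, closed-form value
  cval <- -0.02
  cc <- array(cval, d)
  corr1 <- fake_corr(z, cc, kappa_T = 0.8)
  vol <- prod(d) * 0.5^3
  expected <- kT * 0.8 * (1 - (0.0333 + 0.0666) * cval * vol)
  expect_equal(partial_molar_volume(corr1), expected, tolerance = 1e-12)
  # linearity in c: scaling c by lambda scales (V - kT kappa) by lambda
  corr2 <- fake_corr(z, 3 * cc, kappa_T = 0.8)
  expect_equal(partial_molar_volume(corr2) - kT * 0.8,
               3 * (partial_molar_volume(corr1) - kT * 0.8),
               tolerance = 1e-12)
})

test_that("UC fit recovers constructed parameters and applies exactly", {
  dpmv <- c(0.2, 0.5, 0.9, 1.4, 2.0)
  dg_calc <- c(-3, 5, 1, -7, 2)
  # exact linear error: err = 2 dpmv - 3
  dg_exp <- dg_calc + 2 * dpmv - 3
  p <- fit_uc(dg_calc, dpmv, dg_exp)
  expect_equal(p$a1, 2, tolerance = 1e-10)
  expect_equal(p$a0, -3, tolerance = 1e-10)
  corrected <- correct_uc(dg_calc, dpmv, p)
  expect_equal(corrected, dg_exp, tolerance = 1e-10)
  # constant error: zero slope, intercept = the constant
  p2 <- fit_uc(dg_calc, dpmv, dg_calc + 4.5)
  expect_equal(p2$a1, 0, tolerance = 1e-10)
  expect_equal(p2$a0, 4.5, tolerance = 1e-10)
  # pinned variant matches the closed-form constrained solution
  p3 <- fit_uc(dg_calc, dpmv, dg_calc + 4.5, pin_intercept = TRUE)
  expect_equal(p3$a1, sum(4.5 * dpmv) / sum(dpmv^2), tolerance = 1e-12)
  expect_identical(p3$a0, 0)
  # identity and degenerate cases
  expect_equal(correct_uc(-10, 1.3, uc_params(0, 0)), -10)
  expect_equal(correct_uc(-10, 0, uc_params(-0.43269, 7)), -3)
  expect_error(fit_uc(c(1, 2), c(0.5, 0.5), c(1, 2)), "rank-deficient")
})

test_that("pressure corrections obey their algebraic identities", {
  pt <- list(p_rism = 0.76, rho_kT = 0.0826)
  # V = 0: both schemes are the identity
  expect_equal(correct_pressure(-5, 0, pt, "PC"), -5)
  expect_equal(correct_pressure(-5, 0, pt, "PC+"), -5)
  # PC(x) - PC+(x) = -rho kT V for any x, V
  for (v in c(10, 42.5, -3)) {
    expect_equal(correct_pressure(1.5, v, pt, "PC") -
                 correct_pressure(1.5, v, pt, "PC+"),
                 -pt$rho_kT * v, tolerance = 1e-12)
  }
  # P = rho kT makes PC+ the identity
  pt2 <- list(p_rism = 0.0826, rho_kT = 0.0826)
  expect_equal(correct_pressure(-8, 33, pt2, "PC+"), -8)
})

test_that("grid refinement: dG(0.15 A) within 0.5 kJ/mol of dG(0.3 A)", {
  chi <- test_chi("cSPC/E", closure_spec("KH"))
  fx <- make_fixture("lj_sphere")
  run <- function(spacing) {
    grid <- build_grid(fx$solute, buffer = 8, spacing = spacing)
    pot <- solute_site_potentials(fx$solute, chi$solvent_sites, grid,
                                  thermo_state())
    excess_mu(solve_3drism(pot, chi, closure_spec("KH"), tol = 1e-7), "KH")
  }
  expect_lt(abs(run(0.15) - run(0.3)), 0.5)
})

test_that("report invariants: dpmv scaling and bitwise corrected = base + term", {
  corr <- test_lj_corr()
  rep <- free_energy_report(corr, uc = uc_params(-0.5, 0.2))
  expect_identical(rep$dpmv, corr$rho_molecular * rep$pmv)
  for (s in c("PC", "PC+"))
    expect_identical(rep$corrected[[s]],
                     rep$delta_g[[rep$base]] + rep$correction_terms[[s]])
  expect_identical(rep$corrected[["UC"]],
                   rep$delta_g[["GF"]] + rep$correction_terms[["UC"]])
})
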