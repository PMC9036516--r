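# Dielectrically consistent 1D-RISM for bulk three-site water.
#
# Site-site functions are stored as the three unique pairs (OO, OH, HH); the
# two hydrogens are equivalent by construction, and the full 3x3 site matrix
# is rebuilt wherever the matrix algebra needs it.  Coulomb tails are
# renormalized analytically (erf/erfc splitting) so all transforms act on
# short-ranged remainders.

.pkg_cache <- new.env(parent = emptyenv())

#' Radial grid for 1D-RISM
#'
#' Uses the type-I discrete sine transform convention: r_j = j dr
#' (j = 1..n-1), k_m = m dk with dk = pi/(n dr).
#'
#' @param n_points Grid size n (power of two times small primes).
#' @param dr Radial spacing, Angstrom (default 0.025).
#' @return Object of class `radial_grid` with fields `n`, `dr`, `dk`,
#'   `r`, `k`.
#' @export
radial_grid <- function(n_points = 1024L, dr = 0.025) {
  n <- as.integer(n_points)
  stopifnot(n >= 8L, dr > 0)
  dk <- pi / (n * dr)
  j <- seq_len(n - 1L)
  structure(list(n = n, dr = dr, dk = dk, r = j * dr, k = j * dk),
            class = "radial_grid")
}

# cached DST-I matrix S[j, m] = sin(pi j m / n)
.sine_matrix <- function(n) {
  key <- paste0("dst", n)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  j <- seq_len(n - 1L)
  S <- sin(pi * outer(j, j) / n)
  .pkg_cache[[key]] <- S
  S
}

# radial Fourier pair:
#   fhat(k) = 4 pi / k * int r f(r) sin(kr) dr
#   f(r)    = 1 / (2 pi^2 r) * int k fhat(k) sin(kr) dk
# Columns of `f` are transformed together.
.fbt_fwd <- function(f, grid) {
  S <- .sine_matrix(grid$n)
  (4 * pi * grid$dr / grid$k) * (S %*% (grid$r * f))
}
.fbt_inv <- function(fhat, grid) {
  S <- .sine_matrix(grid$n)
  (grid$dk / (2 * pi^2 * grid$r)) * (S %*% (grid$k * fhat))
}

# spherical Bessel functions used by the dielectric bridge
.j0 <- function(x) ifelse(abs(x) < 1e-6, 1 - x^2 / 6, sin(x) / x)
.j1 <- function(x) ifelse(abs(x) < 1e-4, x / 3 - x^3 / 30,
                          sin(x) / x^2 - cos(x) / x)

#' Intramolecular correlation functions of rigid water
#'
#' omega_hat(k) = sin(k l)/(k l) for distinct sites at fixed distance l,
#' and 1 for a site with itself.  The H-H distance follows from r_OH and
#' theta_HOH.
#'
#' @param model A `water_model`.
#' @param grid A `radial_grid`.
#' @return Array of dimension (n_k, 3, 3) over sites (O, H1, H2).
#' @export
intramolecular_omega <- function(model, grid) {
  k <- grid$k
  l_OH <- model$r_OH
  l_HH <- hh_distance(model)
  nk <- length(k)
  w <- array(0, c(nk, 3L, 3L),
             dimnames = list(NULL, c("O", "H1", "H2"), c("O", "H1", "H2")))
  oh <- .j0(k * l_OH)
  hh <- .j0(k * l_HH)
  w[, 1, 1] <- w[, 2, 2] <- w[, 3, 3] <- 1
  w[, 1, 2] <- w[, 2, 1] <- w[, 1, 3] <- w[, 3, 1] <- oh
  w[, 2, 3] <- w[, 3, 2] <- hh
  w
}

# site coordinates in the molecular (dipole-along-z) frame, relative to the
# |q|-weighted charge center; returned as 3 x 3 matrix with rows O, H1, H2
.water_frame <- function(model) {
  th <- model$theta_HOH * pi / 180
  xh <- model$r_OH * sin(th / 2)
  zh <- model$r_OH * cos(th / 2)
  pos <- rbind(O = c(0, 0, 0), H1 = c(xh, 0, zh), H2 = c(-xh, 0, zh))
  qa <- abs(c(model$O$charge, model$H$charge, model$H$charge))
  ctr <- colSums(pos * qa) / sum(qa)
  sweep(pos, 2, ctr)
}

# dielectric-consistency bridge (Perkyns-Pettitt construction):
# zeta_ab(k) = A j0(k x_a) j0(k y_a) j1(k z_a) (same for b) exp(-s^2 k^2 / 4)
.drism_zeta <- function(model, thermo, grid, smear = 0.5) {
  q <- c(model$O$charge, model$H$charge, model$H$charge)
  pos <- .water_frame(model)
  dvec <- colSums(pos * q)
  d <- sqrt(sum(dvec^2))            # dipole moment, e Angstrom
  nk <- length(grid$k)
  if (d < 1e-10 || all(q == 0)) return(array(0, c(nk, 3L, 3L)))
  rho <- number_density(model)
  y <- (4 * pi / 9) * thermo$beta * rho * d^2 * .k$coulomb
  A <- (model$dielectric - 1 - 3 * y) / (rho * y)
  dk_site <- sapply(1:3, function(a) {
    .j0(grid$k * pos[a, 1]) * .j0(grid$k * pos[a, 2]) * .j1(grid$k * pos[a, 3])
  })
  env <- exp(-(smear^2) * grid$k^2 / 4)
  z <- array(0, c(nk, 3L, 3L))
  for (a in 1:3) for (b in 1:3) z[, a, b] <- A * dk_site[, a] * dk_site[, b] * env
  z
}

# site pair table for the three unique water pairs
.water_pairs <- function(model) {
  list(OO = list(a = model$O, b = model$O),
       OH = list(a = model$O, b = model$H),
       HH = list(a = model$H, b = model$H))
}

#' Solve the dielectrically consistent 1D-RISM equations for bulk water
#'
#' Fixed-point iteration on the renormalized indirect correlation function
#' with MDIIS acceleration; the long-ranged Coulomb parts of u and c are
#' handled analytically.  If the full-charge problem fails to converge the
#' solver restarts along a charge-scaling continuation path.
#'
#' @param model A `water_model` (must be neutral).
#' @param thermo A `thermo_state`.
#' @param grid A `radial_grid`.
#' @param closure A `closure_spec`.
#' @param tol RMS residual tolerance (default 1e-7).
#' @param max_iter Maximum iterations per continuation stage (default 2000).
#' @param mdiis_depth,mdiis_step MDIIS history depth and mixing step.
#' @param kappa Coulomb splitting parameter, 1/Angstrom.
#' @param dielectric_correction Apply the dielectric-consistency bridge
#'   (default TRUE).  Disable for plain site-site RISM, e.g. in low-density
#'   limits where forcing the liquid dielectric constant is unphysical.
#' @param verbose Print residuals every 50 iterations.
#' @return Object of class `bulk_solution`: unique-pair functions `h`, `c`
#'   (full direct correlation), `c_short`, `g` on `grid$r`; `h_hat` on
#'   `grid$k`; convergence metadata.
#' @export
solve_drism <- function(model, thermo = thermo_state(),
                        grid = radial_grid(), closure = closure_spec("KH"),
                        tol = 1e-7, max_iter = 2000L,
                        mdiis_depth = 10L, mdiis_step = 0.3,
                        kappa = 1.0, dielectric_correction = TRUE,
                        verbose = FALSE) {
  stopifnot(inherits(model, "water_model"), inherits(grid, "radial_grid"))
  rho <- number_density(model)
  r <- grid$r; k <- grid$k
  nk <- length(k)
  pairs <- .water_pairs(model)
  pnames <- names(pairs)

  omega <- intramolecular_omega(model, grid)
  zeta <- if (dielectric_correction) .drism_zeta(model, thermo, grid) else
    array(0, c(length(k), 3L, 3L))

  # expand unique-pair columns (nk x 3) to a full 3x3 stack
  expand33 <- function(m) {
    a <- array(0, c(nk, 3L, 3L))
    a[, 1, 1] <- m[, 1]
    a[, 1, 2] <- a[, 2, 1] <- a[, 1, 3] <- a[, 3, 1] <- m[, 2]
    a[, 2, 2] <- a[, 3, 3] <- a[, 2, 3] <- a[, 3, 2] <- m[, 3]
    a
  }

  run_stage <- function(lambda, gamma0) {
    # potentials at charge scaling lambda
    u_sr <- u_lr_hat <- matrix(0, nk, 3L)
    for (p in 1:3) {
      a <- pairs[[p]]$a; b <- pairs[[p]]$b
      m <- mix_lj(a, b)
      qq <- lambda^2 * a$charge * b$charge
      x6 <- if (m$sigma > 0) (m$sigma / r)^6 else numeric(nk)
      erf_r <- 2 * pnorm(kappa * r * sqrt(2)) - 1
      u_sr[, p] <- 4 * m$epsilon * (x6^2 - x6) +
        .k$coulomb * qq * (1 - erf_r) / r
      u_lr_hat[, p] <- .k$coulomb * qq * 4 * pi *
        exp(-k^2 / (4 * kappa^2)) / k^2
    }
    c_lr_hat <- -thermo$beta * u_lr_hat

    gamma <- gamma0
    acc <- mdiis_new(mdiis_depth, mdiis_step)
    res_hist <- numeric(0)
    wtilde <- omega + rho * zeta * lambda^2
    for (it in seq_len(max_iter)) {
      g <- matrix(0, nk, 3L)
      for (p in 1:3) {
        g[, p] <- .closure_g_of_t(-thermo$beta * u_sr[, p] + gamma[, p], closure)
      }
      h <- g - 1
      cs <- h - gamma
      cs_hat <- .fbt_fwd(cs, grid)
      c_hat_full <- expand33(cs_hat + c_lr_hat)
      hp_hat <- matrix(0, nk, 3L)
      I3 <- diag(3)
      singular <- FALSE
      for (m_ in seq_len(nk)) {
        W <- wtilde[m_, , ]
        C <- c_hat_full[m_, , ]
        WC <- W %*% C
        Hp <- tryCatch(solve(I3 - rho * WC, WC %*% W),
                       error = function(e) NULL)
        if (is.null(Hp)) { singular <- TRUE; break }
        Hp <- (Hp + t(Hp)) / 2
        hp_hat[m_, ] <- c(Hp[1, 1], Hp[1, 2], Hp[2, 3])
      }
      if (singular) return(list(ok = FALSE, gamma = gamma0,
                                res_hist = res_hist))
      h_hat <- hp_hat + lambda^2 *
        cbind(zeta[, 1, 1], zeta[, 1, 2], zeta[, 2, 3])
      gamma_new_hat <- h_hat - cs_hat
      gamma_new <- .fbt_inv(gamma_new_hat, grid)
      resid <- gamma_new - gamma
      rms <- sqrt(mean(resid^2))
      res_hist <- c(res_hist, rms)
      if (verbose && (it %% 50 == 0 || it < 8))
        message(sprintf("  drism lambda=%.2f iter %d rms %.3e", lambda, it, rms))
      if (!is.finite(rms)) return(list(ok = FALSE, gamma = gamma0,
                                       res_hist = res_hist))
      # bail out of stalled stages instead of burning the iteration budget
      if (it >= 300L && it %% 100L == 0L &&
          min(res_hist) > 0.5 * min(res_hist[seq_len(it - 200L)]))
        return(list(ok = FALSE, gamma = gamma0, res_hist = res_hist))
      if (rms < tol) {
        return(list(ok = TRUE, gamma = gamma, h = h, g = g, cs = cs,
                    h_hat = h_hat, u_sr = u_sr, res_hist = res_hist,
                    niter = it, rms = rms,
                    u_lr_r = {
                      erf_r <- 2 * pnorm(kappa * r * sqrt(2)) - 1
                      sapply(1:3, function(p) {
                        a <- pairs[[p]]$a; b <- pairs[[p]]$b
                        .k$coulomb * lambda^2 * a$charge * b$charge * erf_r / r
                      })
                    }))
      }
      gamma <- mdiis_update(acc, gamma, resid)
    }
    list(ok = FALSE, gamma = gamma, res_hist = res_hist)
  }

  gamma <- matrix(0, nk, 3L)
  st <- run_stage(1.0, gamma)
  if (!st$ok && !(closure$kind %in% c("KH", "PLHNC"))) {
    # seed hard closures (PSE-n, HNC) from the robust KH solution
    kh <- tryCatch(
      solve_drism(model, thermo, grid, closure_spec("KH"), tol = 1e-4,
                  max_iter = max_iter, mdiis_depth = mdiis_depth,
                  mdiis_step = mdiis_step, kappa = kappa,
                  dielectric_correction = dielectric_correction),
      error = function(e) NULL)
    if (!is.null(kh)) st <- run_stage(1.0, kh$gamma)
  }
  if (!st$ok) {
    # charge-scaling continuation fallback
    gamma <- matrix(0, nk, 3L)
    for (lambda in c(0.25, 0.5, 0.75, 1.0)) {
      st <- run_stage(lambda, gamma)
      if (!st$ok)
        stop("1D-RISM failed to converge (closure ", closure_label(closure),
             ", stage lambda=", lambda, "); last rms residuals: ",
             paste(signif(utils::tail(st$res_hist, 5), 3), collapse = ", "))
      gamma <- st$gamma
    }
  }

  c_full <- st$cs - thermo$beta * st$u_lr_r
  structure(list(
    model = model, thermo = thermo, grid = grid, closure = closure,
    pair_names = pnames,
    h = st$h, g = st$g, c = c_full, c_short = st$cs, gamma = st$gamma,
    h_hat = st$h_hat, rho = rho,
    residual = st$rms, niter = st$niter, residual_history = st$res_hist,
    converged = TRUE
  ), class = "bulk_solution")
}

#' @export
print.bulk_solution <- function(x, ...) {
  cat(sprintf("<bulk_solution> %s, %s closure, %d pts x %.4g A, rms %.2e (%d iters)\n",
              x$model$name, closure_label(x$closure), x$grid$n, x$grid$dr,
              x$residual, x$niter))
  invisible(x)
}

# k = 0 value of the radial transform of the short-ranged direct correlations
.c_short_hat0 <- function(sol) {
  4 * pi * sol$grid$dr * colSums(sol$grid$r^2 * sol$c_short)
}

# sum over the full 3x3 site matrix of c_hat(0); long-range Coulomb parts
# cancel exactly by molecular neutrality
.c_hat0_sum <- function(sol) {
  c0 <- .c_short_hat0(sol)
  c0[1] + 4 * c0[2] + 4 * c0[3]
}

#' Assemble the reduced solvent susceptibility
#'
#' chi_hat(k) = omega_hat(k) + rho h_hat(k) per site pair (dimensionless
#' convention; multiplying by the site density gives the full
#' susceptibility).
#'
#' @param sol A converged `bulk_solution`.
#' @param model The `water_model` used (defaults to the one in `sol`).
#' @param grid The `radial_grid` used (defaults to the one in `sol`).
#' @return Object of class `solvent_susceptibility` with the k-grid, the
#'   unique-pair chi matrix, geometry, densities, and provenance.
#' @export
susceptibility <- function(sol, model = sol$model, grid = sol$grid) {
  stopifnot(inherits(sol, "bulk_solution"), isTRUE(sol$converged))
  rho <- number_density(model)
  rho_h <- rho * sol$h_hat      # nk x 3 (OO, OH, HH)
  colnames(rho_h) <- c("OO", "OH", "HH")
  structure(list(
    k = grid$k,
    rho_h_hat = rho_h,
    l_OH = model$r_OH,
    l_HH = hh_distance(model),
    rho_molecular = rho,
    site_densities = c(O = rho, H = 2 * rho),
    site_charges = c(O = model$O$charge, H = model$H$charge),
    solvent_sites = list(O = model$O, H = model$H),
    thermo = sol$thermo,
    model_name = model$name,
    closure = closure_label(sol$closure),
    kappa_T = isothermal_compressibility(sol, model, sol$thermo),
    pressure = rism_pressure(sol, model, sol$thermo),
    grid = list(n = grid$n, dr = grid$dr)
  ), class = "solvent_susceptibility")
}

#' @export
print.solvent_susceptibility <- function(x, ...) {
  cat(sprintf("<solvent_susceptibility> %s (%s), %d k-points, rho = %.5f A^-3\n",
              x$model_name, x$closure, length(x$k), x$rho_molecular))
  invisible(x)
}

#' Evaluate the unique-pair chi matrix at arbitrary k
#'
#' The intramolecular part is evaluated analytically; the rho*h part is
#' linearly interpolated from the stored 1D solution.
#'
#' @param chi A `solvent_susceptibility`.
#' @param kq Wavenumbers (1/Angstrom) at which to evaluate.
#' @return Matrix with columns OO, OH, HH.
#' @export
chi_at_k <- function(chi, kq) {
  interp <- function(y) {
    stats::approx(c(0, chi$k), c(2 * y[1] - y[2], y), xout = kq, rule = 2)$y
  }
  cbind(OO = 1 + interp(chi$rho_h_hat[, "OO"]),
        OH = .j0(kq * chi$l_OH) + interp(chi$rho_h_hat[, "OH"]),
        HH = .j0(kq * chi$l_HH) + interp(chi$rho_h_hat[, "HH"]))
}

#' RISM pressure of the bulk solvent (free-energy route)
#'
#' P = rho k_B T (n_sites + 1)/2 - (k_B T / 2) rho^2 sum_ab c_hat_ab(0),
#' with rho the molecular number density.  For water n_sites = 3, so the
#' ideal/molecular term is 2 rho k_B T.
#'
#' @param sol A converged `bulk_solution`.
#' @param model,thermo Defaults taken from `sol`.
#' @return List with `p_rism` (kJ/mol/A^3), `rho_kT`, `ideal`, and the
#'   direct-correlation sum `c0_sum` (A^3).
#' @export
rism_pressure <- function(sol, model = sol$model, thermo = sol$thermo) {
  rho <- number_density(model)
  rism_pressure_from_c0sum(.c_hat0_sum(sol), rho, 3L, thermo)
}

#' RISM pressure from a precomputed direct-correlation k=0 sum
#'
#' @param c0_sum sum over all site pairs of c_hat(k=0), A^3.
#' @param rho_molecular Molecular number density, A^-3.
#' @param n_sites Number of sites per solvent molecule.
#' @param thermo A `thermo_state`.
#' @return Same structure as [rism_pressure()].
#' @export
rism_pressure_from_c0sum <- function(c0_sum, rho_molecular, n_sites,
                                     thermo = thermo_state()) {
  kT <- 1 / thermo$beta
  ideal <- rho_molecular * kT * (n_sites + 1) / 2
  list(p_rism = ideal - kT / 2 * rho_molecular^2 * c0_sum,
       rho_kT = rho_molecular * kT,
       ideal = ideal,
       c0_sum = c0_sum)
}

#' Isothermal compressibility from the k = 0 structure
#'
#' kappa_T = beta / (rho (1 - rho sum_ab c_hat_ab(0))), the compressibility
#' route for a site model; with c = 0 this reduces to the ideal-gas value
#' 1/(rho k_B T).
#'
#' @param sol A converged `bulk_solution`.
#' @param model,thermo Defaults taken from `sol`.
#' @return kappa_T in A^3 mol / kJ.
#' @export
isothermal_compressibility <- function(sol, model = sol$model,
                                       thermo = sol$thermo) {
  rho <- number_density(model)
  thermo$beta / (rho * (1 - rho * .c_hat0_sum(sol)))
}
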