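# 3D-RISM: grid construction, solute-solvent potentials, and the spectral
# fixed-point solver.
#
# The supercell is treated as periodic for the FFT; the buffer is the
# mitigation for image interactions.  Coulomb potentials are split with an
# erf/erfc scheme: the total real-space potential is exact (erfc part +
# erf part evaluated by direct summation over atoms), while the analytic
# reciprocal-space form of the erf part renormalizes the long-ranged tails
# of c inside the solver.

# round up to an even 2,3,5,7-smooth integer (FFT-friendly; even so the
# box center -- where the solute bounding-box center sits -- falls on a
# lattice point, keeping discretization consistent across buffer sizes)
.fft_friendly <- function(n) {
  n <- max(4L, as.integer(ceiling(n)))
  if (n %% 2L == 1L) n <- n + 1L
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 2L
  }
}

#' Build a rectangular 3D grid around a solute
#'
#' Each box face is at least `buffer` away from every solute atom; the box is
#' centered on the solute bounding box and dimensions are rounded up to
#' FFT-friendly composites, so the realized clearance is >= `buffer`.
#'
#' @param solute A `solute_model`.
#' @param buffer Minimum solute-to-face distance, Angstrom (> 0).
#' @param spacing Grid spacing, Angstrom (> 0; applied per axis).
#' @return Object of class `grid3d` with `origin`, `spacing` (length 3),
#'   `dims`, `voxel_volume`, and per-axis coordinate vectors `axes`.
#' @export
build_grid <- function(solute, buffer = 15, spacing = 0.3) {
  stopifnot(inherits(solute, "solute_model"))
  if (buffer <= 0) stop("buffer must be > 0")
  if (spacing <= 0) stop("spacing must be > 0")
  lo <- apply(solute$xyz, 2, min)
  hi <- apply(solute$xyz, 2, max)
  edge <- (hi - lo) + 2 * buffer
  if (any(spacing >= edge)) stop("degenerate grid: spacing >= box edge")
  dims <- vapply(edge / spacing, .fft_friendly, integer(1))
  center <- (hi + lo) / 2
  origin <- center - dims * spacing / 2
  axes <- lapply(1:3, function(d) origin[d] + (seq_len(dims[d]) - 1L) * spacing)
  structure(list(origin = origin, spacing = rep(spacing, 3), dims = dims,
                 voxel_volume = spacing^3, axes = axes),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("<grid3d> %d x %d x %d @ %.3g A (%.1f x %.1f x %.1f A box)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing[1],
              x$dims[1] * x$spacing[1], x$dims[2] * x$spacing[2],
              x$dims[3] * x$spacing[3]))
  invisible(x)
}

# reciprocal-space wavevector magnitudes (and per-axis components on demand)
.k_axis <- function(n, delta) {
  f <- c(0:(n %/% 2), -((n - (n %/% 2 + 1L)):1)) / (n * delta)
  2 * pi * f
}

.k_squared <- function(grid) {
  kx <- .k_axis(grid$dims[1], grid$spacing[1])
  ky <- .k_axis(grid$dims[2], grid$spacing[2])
  kz <- .k_axis(grid$dims[3], grid$spacing[3])
  outer(outer(kx^2, ky^2, "+"), kz^2, "+")
}

# distance arrays from one point to every voxel, via outer sums of squares
.dist2_to_point <- function(grid, p) {
  dx2 <- (grid$axes[[1]] - p[1])^2
  dy2 <- (grid$axes[[2]] - p[2])^2
  dz2 <- (grid$axes[[3]] - p[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}

.erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

#' Solute-site potentials on a 3D grid
#'
#' For every solvent site type, sums the Lennard-Jones (Lorentz-Berthelot)
#' and Coulomb contributions of all solute atoms.  The Coulomb part is split
#' into a short-ranged erfc term and a long-ranged erf term; both are
#' evaluated exactly in real space (their sum is the plain 1/r Coulomb sum),
#' and the analytic reciprocal-space representation of the erf part is
#' returned for the solver's tail renormalization.
#'
#' @param solute A `solute_model` with charges assigned.
#' @param solvent_sites Named list of `site` objects (e.g. O and H of a
#'   water model).
#' @param grid A `grid3d`.
#' @param thermo A `thermo_state`.
#' @param kappa Splitting parameter, 1/Angstrom (default 1).
#' @return Object of class `site_potentials`: lists `u_sr`, `u_lr`, `u`
#'   (kJ/mol arrays per solvent site), complex array `phi_lr_hat`
#'   (reciprocal-space long-range electrostatic potential per unit solvent
#'   charge), and metadata.
#' @export
solute_site_potentials <- function(solute, solvent_sites, grid,
                                   thermo = thermo_state(), kappa = 1.0) {
  stopifnot(inherits(solute, "solute_model"), inherits(grid, "grid3d"))
  for (s in solvent_sites) {
    if (s$sigma == 0 && s$epsilon > 0)
      stop("invalid solvent site parameters: zero sigma with nonzero epsilon")
  }
  nat <- nrow(solute$xyz)
  u_sr <- u_lr <- vector("list", length(solvent_sites))
  names(u_sr) <- names(u_lr) <- names(solvent_sites)
  # per-atom distance fields are shared across solvent sites
  dist <- vector("list", nat)
  for (a in seq_len(nat)) dist[[a]] <- sqrt(.dist2_to_point(grid, solute$xyz[a, ]))
  for (sname in names(solvent_sites)) {
    sv <- solvent_sites[[sname]]
    usr <- array(0, grid$dims)
    ulr <- array(0, grid$dims)
    for (a in seq_len(nat)) {
      asite <- site(solute$element[a], solute$charge[a],
                    solute$sigma[a], solute$epsilon[a])
      m <- mix_lj(asite, sv)
      r <- dist[[a]]
      # floor at half a voxel: keeps the (capped) repulsive core dominant
      # over the attractive Coulomb singularity when an atom sits exactly
      # on a grid point
      rs <- pmax(r, 0.5 * min(grid$spacing))
      # one combined contribution per atom so superposition over atoms is
      # bitwise exact (same floating-point grouping as single-atom fields)
      contrib <- 0
      if (m$epsilon > 0 && m$sigma > 0) {
        x6 <- (m$sigma / rs)^6
        contrib <- contrib + pmin(4 * m$epsilon * (x6^2 - x6), 1e8)
      }
      qq <- .k$coulomb * solute$charge[a] * sv$charge
      if (qq != 0) {
        e <- .erf(kappa * rs)
        contrib <- contrib + pmin(qq * (1 - e) / rs, 1e8)
        # erf(kr)/r is finite (2 kappa/sqrt(pi)) at r = 0
        ulr <- ulr + ifelse(r < 1e-9, qq * 2 * kappa / sqrt(pi), qq * e / rs)
      }
      usr <- usr + contrib
    }
    u_sr[[sname]] <- usr
    u_lr[[sname]] <- ulr
  }
  # reciprocal-space long-range potential per unit solvent charge:
  # phi_lr_hat(k) = k_e 4 pi exp(-k^2/(4 kappa^2))/k^2 sum_a q_a e^{-i k r_a}
  k2 <- .k_squared(grid)
  kx <- .k_axis(grid$dims[1], grid$spacing[1])
  ky <- .k_axis(grid$dims[2], grid$spacing[2])
  kz <- .k_axis(grid$dims[3], grid$spacing[3])
  S <- array(0 + 0i, grid$dims)
  for (a in seq_len(nat)) {
    if (solute$charge[a] == 0) next
    rel <- solute$xyz[a, ] - grid$origin
    ph <- outer(outer(exp(-1i * kx * rel[1]), exp(-1i * ky * rel[2])),
                exp(-1i * kz * rel[3]))
    S <- S + solute$charge[a] * ph
  }
  env <- array(0, grid$dims)
  nz <- k2 > 0
  env[nz] <- 4 * pi * exp(-k2[nz] / (4 * kappa^2)) / k2[nz]
  phi_lr_hat <- .k$coulomb * env * S   # k = 0 term dropped (neutralizing bg)
  u <- mapply(function(a, b) a + b, u_sr, u_lr, SIMPLIFY = FALSE)
  structure(list(u_sr = u_sr, u_lr = u_lr, u = u,
                 phi_lr_hat = phi_lr_hat, kappa = kappa,
                 solvent_sites = solvent_sites, grid = grid, thermo = thermo),
            class = "site_potentials")
}

#' Spectral periodic convolution with a reciprocal-space kernel
#'
#' h = IFFT( FFT(c) * K ), with K the (dimensionless) kernel sampled on the
#' grid's reciprocal lattice.  This is the production convolution route used
#' inside [solve_3drism()]; the brute-force counterpart for testing is
#' [direct_convolution()].
#'
#' @param c_arr Real 3D array.
#' @param kernel_hat Kernel values on the reciprocal lattice (array of the
#'   same dimensions, real or complex).
#' @return Real array of the same dimensions.
#' @export
spectral_convolve <- function(c_arr, kernel_hat) {
  stopifnot(identical(dim(c_arr), dim(kernel_hat)))
  Re(stats::fft(stats::fft(c_arr) * kernel_hat, inverse = TRUE)) / length(c_arr)
}

#' Solve the 3D-RISM equations around a fixed solute
#'
#' Fixed point of {closure; h_a = sum_xi c_xi * chi_xi,a} with the
#' convolution evaluated spectrally and MDIIS acceleration.  Hydrogen sites
#' are collapsed to one field by symmetry.
#'
#' @param pot A `site_potentials` (solvent sites O and H).
#' @param chi A `solvent_susceptibility` from [susceptibility()].
#' @param closure A `closure_spec`.
#' @param thermo A `thermo_state`.
#' @param tol RMS residual tolerance (default 1e-6).
#' @param max_iter Maximum iterations (default 1000).
#' @param mdiis_depth,mdiis_step MDIIS parameters.
#' @param verbose Print residuals every 10 iterations.
#' @return Object of class `correlations3d` with per-site fields `u`, `h`,
#'   `c`, `g` (arrays), the grid, closure and solvent metadata, and the
#'   residual history.
#' @export
solve_3drism <- function(pot, chi, closure = closure_spec("KH"),
                         thermo = pot$thermo, tol = 1e-6, max_iter = 1000L,
                         mdiis_depth = 10L, mdiis_step = 0.7,
                         verbose = FALSE) {
  stopifnot(inherits(pot, "site_potentials"),
            inherits(chi, "solvent_susceptibility"))
  if (!all(c("O", "H") %in% names(pot$u_sr)))
    stop("potentials must carry O and H solvent sites matching the ",
         "susceptibility")
  grid <- pot$grid
  dims <- grid$dims
  kq <- sqrt(.k_squared(grid))
  # collapsed susceptibility kernels on the reciprocal lattice
  cc <- chi_at_k(chi, as.vector(kq))
  rho_h_HH <- cc[, "HH"] - .j0(as.vector(kq) * chi$l_HH)
  K_OO <- array(cc[, "OO"], dims)                 # c_O -> h_O
  K_HO <- array(2 * cc[, "OH"], dims)             # c_H -> h_O
  K_OH <- array(cc[, "OH"], dims)                 # c_O -> h_H
  K_HH <- array(1 + .j0(as.vector(kq) * chi$l_HH) + 2 * rho_h_HH, dims)
  rm(cc, rho_h_HH, kq)

  beta <- thermo$beta
  qs <- chi$site_charges
  c_lr_hat <- list(O = -beta * qs[["O"]] * pot$phi_lr_hat,
                   H = -beta * qs[["H"]] * pot$phi_lr_hat)
  u_sr <- pot$u_sr

  nvox <- prod(dims)
  gamma <- list(O = array(0, dims), H = array(0, dims))
  step_now <- mdiis_step
  acc <- mdiis_new(mdiis_depth, step_now)
  res_hist <- numeric(0)
  g <- h <- cs <- list()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (s in c("O", "H")) {
      g[[s]] <- .closure_g_of_t(-beta * u_sr[[s]] + gamma[[s]], closure)
      h[[s]] <- g[[s]] - 1
      cs[[s]] <- h[[s]] - gamma[[s]]
    }
    cs_hat <- lapply(cs, function(x) stats::fft(x) * grid$voxel_volume)
    c_hat <- list(O = cs_hat$O + c_lr_hat$O, H = cs_hat$H + c_lr_hat$H)
    h_hat <- list(O = c_hat$O * K_OO + c_hat$H * K_HO,
                  H = c_hat$O * K_OH + c_hat$H * K_HH)
    gamma_new <- list(
      O = Re(stats::fft(h_hat$O - cs_hat$O, inverse = TRUE)) /
        (nvox * grid$voxel_volume),
      H = Re(stats::fft(h_hat$H - cs_hat$H, inverse = TRUE)) /
        (nvox * grid$voxel_volume)
    )
    resid <- c(gamma_new$O - gamma$O, gamma_new$H - gamma$H)
    rms <- sqrt(mean(resid^2))
    res_hist <- c(res_hist, rms)
    if (verbose && it %% 10 == 0)
      message(sprintf("  3drism iter %d rms %.3e", it, rms))
    if (!is.finite(rms))
      stop("3D-RISM diverged (non-finite residual) at iteration ", it,
           " with closure ", closure_label(closure),
           "; consider the KH closure or stronger damping. Residual history: ",
           paste(signif(utils::tail(res_hist, 5), 3), collapse = ", "))
    if (rms < tol) { converged <- TRUE; break }
    # stall guard: if 60 iterations bring < 20% improvement, restart the
    # accelerator with a halved mixing step (plateaus come from an
    # over-aggressive step, not from the fixed point itself)
    if (it >= 120L && it %% 60L == 0L && step_now > 0.05 &&
        min(res_hist) > 0.8 * min(res_hist[seq_len(it - 60L)])) {
      step_now <- step_now / 2
      acc <- mdiis_new(mdiis_depth, step_now)
    }
    xnew <- mdiis_update(acc, c(gamma$O, gamma$H), resid)
    gamma <- list(O = array(xnew[seq_len(nvox)], dims),
                  H = array(xnew[nvox + seq_len(nvox)], dims))
  }
  if (!converged)
    stop("3D-RISM did not converge in ", max_iter, " iterations (rms ",
         signif(utils::tail(res_hist, 1), 3), ", closure ",
         closure_label(closure), "); residual trace tail: ",
         paste(signif(utils::tail(res_hist, 5), 3), collapse = ", "))
  c_full <- list(O = cs$O - beta * pot$u_lr$O,
                 H = cs$H - beta * pot$u_lr$H)
  structure(list(
    grid = grid, closure = closure, thermo = thermo,
    sites = c("O", "H"),
    site_densities = chi$site_densities,
    site_charges = chi$site_charges,
    rho_molecular = chi$rho_molecular,
    kappa_T = chi$kappa_T, pressure = chi$pressure,
    u = pot$u, u_sr = pot$u_sr, gamma = gamma,
    h = h, c = c_full, g = g,
    residual = utils::tail(res_hist, 1), niter = it,
    residual_history = res_hist, converged = TRUE,
    solvent = chi$model_name, chi_closure = chi$closure
  ), class = "correlations3d")
}

#' @export
print.correlations3d <- function(x, ...) {
  cat(sprintf("<correlations3d> %s on %d x %d x %d grid, %s closure, rms %.2e (%d iters)\n",
              x$solvent, x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              closure_label(x$closure), x$residual, x$niter))
  invisible(x)
}

#' Trilinear interpolation of a 3D field
#'
#' @param field Array on `grid`.
#' @param grid A `grid3d`.
#' @param points n x 3 matrix of coordinates, Angstrom.
#' @return Numeric vector of interpolated values.
#' @export
trilinear_sample <- function(field, grid, points) {
  points <- matrix(points, ncol = 3)
  fr <- sweep(points, 2, grid$origin)
  fr <- sweep(fr, 2, grid$spacing, "/")
  i0 <- pmin(pmax(floor(fr), 0), matrix(rep(grid$dims - 2L, each = nrow(fr)),
                                        ncol = 3))
  t <- fr - i0
  out <- numeric(nrow(points))
  for (p in seq_len(nrow(points))) {
    v <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, t[p, ], 1 - t[p, ]))
      v <- v + w * field[i0[p, 1] + dx + 1L, i0[p, 2] + dy + 1L,
                         i0[p, 3] + dz + 1L]
    }
    out[p] <- v
  }
  out
}
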