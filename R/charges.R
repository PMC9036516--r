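# ESP-fitted solute charges (CHELPG-style) and the solvent background
# point-charge map with thresholding.

#' Default van der Waals radii for ESP fitting
#'
#' Bondi radii with a Br override of 1.75 A; the 1.3 A Br variant used by
#' older ESP-fitting setups is available via `br_radius`.
#'
#' @param br_radius Radius for Br, Angstrom (default 1.75).
#' @return Named numeric vector of radii, Angstrom.
#' @export
chelpg_radii <- function(br_radius = 1.75) {
  c(H = 1.20, He = 1.40, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
    Ne = 1.54, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88,
    Br = br_radius, I = 1.98)
}

#' CHELPG-style sample-point lattice
#'
#' Regular cubic lattice of spacing `shell_spacing` clipped to the shell
#' between the van der Waals surface (per-element radii) and `r_max` around
#' the molecule.  Point ordering is deterministic (x fastest).
#'
#' @param solute A `solute_model`.
#' @param radii Named radii table, Angstrom (see [chelpg_radii()]).
#' @param shell_spacing Lattice spacing, Angstrom (default 0.3).
#' @param r_max Outer shell radius, Angstrom (default 2.8).
#' @return n x 3 matrix of sample coordinates.
#' @export
chelpg_points <- function(solute, radii = chelpg_radii(),
                          shell_spacing = 0.3, r_max = 2.8) {
  stopifnot(inherits(solute, "solute_model"))
  missing <- setdiff(unique(solute$element), names(radii))
  if (length(missing) > 0)
    stop("no ESP-fitting radius for element(s): ",
         paste(missing, collapse = ", "))
  rv <- radii[solute$element]
  if (r_max < min(rv))
    stop("degenerate shell: r_max (", r_max,
         ") is smaller than the smallest vdW radius (", min(rv), ")")
  # lattice anchored at absolute multiples of the spacing, so congruent
  # molecules (translations by lattice vectors, mirrors) sample congruent
  # point sets
  lo <- floor((apply(solute$xyz, 2, min) - r_max) / shell_spacing)
  hi <- ceiling((apply(solute$xyz, 2, max) + r_max) / shell_spacing)
  ax <- lapply(1:3, function(d) (lo[d]:hi[d]) * shell_spacing)
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- NULL
  # keep points outside every vdW sphere and within r_max of some atom
  mind <- rep(Inf, nrow(pts))
  ok_out <- rep(TRUE, nrow(pts))
  for (a in seq_len(nrow(solute$xyz))) {
    d <- sqrt((pts[, 1] - solute$xyz[a, 1])^2 +
              (pts[, 2] - solute$xyz[a, 2])^2 +
              (pts[, 3] - solute$xyz[a, 3])^2)
    ok_out <- ok_out & (d >= rv[a])
    mind <- pmin(mind, d)
  }
  out <- pts[ok_out & mind <= r_max, , drop = FALSE]
  if (nrow(out) == 0) stop("degenerate shell: no sample points survive")
  out
}

#' Fit atomic charges to an electrostatic potential sample
#'
#' Least-squares minimization of sum_i (phi_i - sum_a q_a / r_ia)^2 subject
#' to sum_a q_a = total_charge, via the Lagrange-multiplier normal
#' equations.  Potentials are in atomic units; distances are converted to
#' Bohr internally.
#'
#' @param points n x 3 matrix of sample coordinates, Angstrom.
#' @param values Electrostatic potential at the points, atomic units.
#' @param atom_positions m x 3 matrix, Angstrom.
#' @param total_charge Molecular total charge, e.
#' @param method Tag recorded on the result ("CHELPG", "MK", or "input").
#' @return Object of class `atomic_charges`: `values` (e), `rms` residual
#'   (a.u.), `method`, `condition` estimate.
#' @export
fit_esp_charges <- function(points, values, atom_positions, total_charge = 0,
                            method = "CHELPG") {
  points <- matrix(points, ncol = 3)
  atom_positions <- matrix(atom_positions, ncol = 3)
  np <- nrow(points); na <- nrow(atom_positions)
  stopifnot(length(values) == np, na >= 1)
  if (np < na + 1L)
    stop("need at least n_atoms + 1 sample points (have ", np, ")")
  A <- matrix(0, np, na)
  for (a in seq_len(na)) {
    d <- sqrt((points[, 1] - atom_positions[a, 1])^2 +
              (points[, 2] - atom_positions[a, 2])^2 +
              (points[, 3] - atom_positions[a, 3])^2) / .k$bohr_angstrom
    A[, a] <- 1 / d
  }
  # KKT system for min |A q - phi|^2 s.t. 1' q = Q
  M <- rbind(cbind(2 * crossprod(A), rep(1, na)),
             c(rep(1, na), 0))
  rhs <- c(2 * crossprod(A, values), total_charge)
  cond <- kappa(M, exact = FALSE)
  if (!is.finite(cond) || cond > 1e12)
    stop("ill-conditioned ESP fit (condition estimate ",
         format(cond, digits = 3), "); sample geometry is degenerate")
  sol <- solve(M, rhs)
  q <- sol[seq_len(na)]
  rms <- sqrt(mean((A %*% q - values)^2))
  structure(list(values = q, rms = rms, method = method, condition = cond),
            class = "atomic_charges")
}

#' @export
print.atomic_charges <- function(x, ...) {
  cat(sprintf("<atomic_charges> %s: %s (sum %+.6f e, rms %.3e a.u.)\n",
              x$method, paste(sprintf("%+.4f", x$values), collapse = " "),
              sum(x$values), x$rms))
  invisible(x)
}

#' Solvent background point-charge map from a 3D-RISM solution
#'
#' Per grid point r_i, charge = sum_g q_g rho_g g_g(r_i) dV over solvent
#' site types (site density and voxel volume included so the charges come
#' out in elementary-charge units).  With `bulk_subtract = TRUE` the bulk
#' contribution is removed (g - 1 instead of g); for a neutral solvent the
#' two agree because the bulk term sums to zero charge at every point.
#'
#' @param corr A converged `correlations3d`.
#' @param bulk_subtract Use g - 1 instead of g (default FALSE).
#' @return Object of class `charge_map`: `points` (n x 3, Angstrom),
#'   `charges` (e), `threshold` (0 = none), `dropped_fraction`,
#'   `voxel_volume`.
#' @export
solvent_charge_map <- function(corr, bulk_subtract = FALSE) {
  stopifnot(inherits(corr, "correlations3d"))
  grid <- corr$grid
  qv <- array(0, grid$dims)
  for (s in corr$sites) {
    gf <- if (bulk_subtract) corr$g[[s]] - 1 else corr$g[[s]]
    qv <- qv + corr$site_charges[[s]] * corr$site_densities[[s]] * gf
  }
  qv <- qv * grid$voxel_volume
  pts <- as.matrix(expand.grid(x = grid$axes[[1]], y = grid$axes[[2]],
                               z = grid$axes[[3]], KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- NULL
  # expand.grid varies x fastest, matching R's array linearization
  structure(list(points = pts, charges = as.vector(qv),
                 threshold = 0, dropped_fraction = 0,
                 n_original = length(qv),
                 voxel_volume = grid$voxel_volume,
                 bulk_subtracted = bulk_subtract),
            class = "charge_map")
}

#' Construct a charge map directly
#'
#' Mostly useful for tests and for loading externally produced maps; the
#' production route is [solvent_charge_map()].
#'
#' @param points n x 3 matrix, Angstrom.
#' @param charges Charges, e (length n).
#' @param voxel_volume Voxel volume the charges were integrated over, A^3.
#' @return A `charge_map`.
#' @export
charge_map <- function(points, charges, voxel_volume = NA_real_) {
  points <- matrix(points, ncol = 3)
  stopifnot(nrow(points) == length(charges))
  structure(list(points = points, charges = as.numeric(charges),
                 threshold = 0, dropped_fraction = 0,
                 n_original = length(charges),
                 voxel_volume = voxel_volume, bulk_subtracted = FALSE),
            class = "charge_map")
}

#' @export
print.charge_map <- function(x, ...) {
  cat(sprintf("<charge_map> %d points, total %+.6e e, threshold %g (dropped %.1f%%)\n",
              length(x$charges), sum(x$charges), x$threshold,
              100 * x$dropped_fraction))
  invisible(x)
}

#' Drop insignificant background charges
#'
#' Retains points with |q| >= threshold (in elementary-charge units, which
#' coincide with atomic units of charge); records the dropped fraction
#' relative to the input map.  Ordering is preserved and the operation is
#' idempotent.
#'
#' @param map A `charge_map`.
#' @param threshold Magnitude threshold, a.u. (>= 0; default 1e-6).
#' @return A filtered `charge_map`.
#' @export
drop_small <- function(map, threshold = 1e-6) {
  stopifnot(inherits(map, "charge_map"))
  if (threshold < 0) stop("threshold must be >= 0")
  keep <- if (threshold == 0) rep(TRUE, length(map$charges)) else
    abs(map$charges) >= threshold
  n0 <- if (is.null(map$n_original)) length(map$charges) else map$n_original
  map$points <- map$points[keep, , drop = FALSE]
  map$charges <- map$charges[keep]
  map$threshold <- threshold
  map$n_original <- n0
  map$dropped_fraction <- if (n0 == 0) 0 else 1 - length(map$charges) / n0
  map
}
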