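# Deterministic toy solutes and brute-force oracles.  All seeded
# pseudo-randomness in the package lives here; production code paths
# contain none.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Deterministic toy solute fixtures
#'
#' @param kind One of "lj_sphere" (one neutral site), "dipolar_diatomic"
#'   (+q/-q pair at fixed bond length), "ammonia_like" (4 sites with C3v
#'   symmetry), "random_cluster" (seeded neutral cluster).
#' @param seed Seed for "random_cluster" (ignored otherwise).
#' @return Object of class `fixture`: `name`, `solute` (a `solute_model`),
#'   `seed`.
#' @export
make_fixture <- function(kind = c("lj_sphere", "dipolar_diatomic",
                                  "ammonia_like", "random_cluster"),
                         seed = 1L) {
  kind <- match.arg(kind)
  solute <- switch(kind,
    lj_sphere = solute_model("Ar", matrix(0, 1, 3),
                             charge = 0, sigma = 3.4, epsilon = 1.0),
    dipolar_diatomic = solute_model(
      c("N", "O"),
      rbind(c(0, 0, 0), c(0, 0, 1.2)),
      charge = c(0.35, -0.35), sigma = c(3.1, 2.9), epsilon = c(0.5, 0.45)),
    ammonia_like = {
      r_NH <- 1.012; theta <- 106.7 * pi / 180
      # C3v: N on the axis, 3 equivalent H on a cone
      zH <- -r_NH * cos(theta * 0.6)     # fixed pyramidal geometry
      rxy <- sqrt(r_NH^2 - zH^2)
      ang <- 2 * pi * (0:2) / 3
      solute_model(
        c("N", "H", "H", "H"),
        rbind(c(0, 0, 0),
              cbind(rxy * cos(ang), rxy * sin(ang), zH)),
        charge = c(-0.9, 0.3, 0.3, 0.3),
        sigma = c(3.25, 1.07, 1.07, 1.07),
        epsilon = c(0.711, 0.0657, 0.0657, 0.0657))
    },
    random_cluster = .with_seed(seed, {
      n <- sample(3:6, 1)
      xyz <- matrix(stats::runif(3 * n, -1.5, 1.5), n, 3)
      q <- stats::runif(n, -0.5, 0.5)
      q <- q - mean(q)                    # neutral overall
      solute_model(rep("C", n), xyz, charge = q,
                   sigma = stats::runif(n, 2.5, 3.5),
                   epsilon = stats::runif(n, 0.2, 1.0))
    })
  )
  structure(list(name = kind, solute = solute, seed = seed),
            class = "fixture")
}

#' Brute-force periodic convolution oracle
#'
#' Direct O(N^2) evaluation of h[i] = sum_j c[j] K[i - j] with periodic
#' wrap-around, for comparison against the spectral route of
#' [spectral_convolve()].  Deliberately slow; refuses grids above 16^3.
#'
#' @param c_arr Real 3D array.
#' @param kernel_real Real-space kernel on the same (periodic) grid, with
#'   the kernel origin at index (1,1,1).
#' @return Real array of the same dimensions.
#' @export
direct_convolution <- function(c_arr, kernel_real) {
  d <- dim(c_arr)
  stopifnot(identical(d, dim(kernel_real)), length(d) == 3L)
  if (prod(d) > 16^3)
    stop("oracle instance too large (> 16^3); use spectral_convolve")
  out <- array(0, d)
  for (i1 in seq_len(d[1])) for (i2 in seq_len(d[2])) for (i3 in seq_len(d[3])) {
    s <- 0
    for (j1 in seq_len(d[1])) for (j2 in seq_len(d[2])) for (j3 in seq_len(d[3])) {
      k1 <- ((i1 - j1) %% d[1]) + 1L
      k2 <- ((i2 - j2) %% d[2]) + 1L
      k3 <- ((i3 - j3) %% d[3]) + 1L
      s <- s + c_arr[j1, j2, j3] * kernel_real[k1, k2, k3]
    }
    out[i1, i2, i3] <- s
  }
  out
}

#' Brute-force electrostatic potential oracle
#'
#' Plain double loop over charges and points.
#'
#' @param charges Charges, e.
#' @param positions n x 3 matrix, Angstrom.
#' @param points m x 3 matrix, Angstrom.
#' @param units "au" (Hartree/e, distances converted to Bohr) or "kJmol"
#'   (kJ/mol per unit probe charge).
#' @return Potential at the points.
#' @export
direct_esp <- function(charges, positions, points, units = c("au", "kJmol")) {
  units <- match.arg(units)
  positions <- matrix(positions, ncol = 3)
  points <- matrix(points, ncol = 3)
  if (nrow(points) > 4096) stop("oracle instance too large")
  out <- numeric(nrow(points))
  for (p in seq_len(nrow(points))) {
    for (a in seq_len(nrow(positions))) {
      r <- sqrt(sum((points[p, ] - positions[a, ])^2))
      out[p] <- out[p] + if (units == "au")
        charges[a] / (r / .k$bohr_angstrom)
      else .k$coulomb * charges[a] / r
    }
  }
  out
}

#' Constrained least-squares oracle (substitution route)
#'
#' Solves min |A q - b|^2 subject to sum(q) = total by eliminating the last
#' unknown (q_n = total - sum of the others) and solving the reduced
#' unconstrained problem by QR.  Independent of the Lagrange-multiplier
#' route used by [fit_esp_charges()].
#'
#' @param A Design matrix (m x n).
#' @param b Right-hand side (length m).
#' @param total Constraint value for sum(q).
#' @return Solution vector q (length n).
#' @export
naive_constrained_lsq <- function(A, b, total = 0) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (nrow(A) > 4096 || n > 64) stop("oracle instance too large")
  if (n == 1L) return(total)
  # q = e_n * total + N y with N mapping the first n-1 free variables
  N <- rbind(diag(n - 1L), rep(-1, n - 1L))
  q0 <- c(rep(0, n - 1L), total)
  y <- qr.solve(A %*% N, b - A %*% q0)
  as.vector(q0 + N %*% y)
}
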