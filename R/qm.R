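# Quantum-backend contract, embedding energy ledger, and a closed-form
# polarizable mock engine.
#
# Contract: a `qm_backend` returns the total energy in atomic units
# EXCLUDING the point-charge self-energy (E_qq is never computed anywhere in
# this package; backends must exclude it), and the electrostatic potential
# of the solute at requested points.  The QM side works in atomic units;
# conversion to kJ/mol happens only in the ledger / driver.

# pairwise 1/r potential and field of external charges at target positions
# (everything in Bohr / e / a.u.)
.ext_potential_field <- function(targets_bohr, src_bohr, src_q) {
  nt <- nrow(targets_bohr)
  phi <- numeric(nt)
  Ef <- matrix(0, nt, 3)
  if (length(src_q) == 0) return(list(phi = phi, E = Ef))
  for (t in seq_len(nt)) {
    dx <- targets_bohr[t, 1] - src_bohr[, 1]
    dy <- targets_bohr[t, 2] - src_bohr[, 2]
    dz <- targets_bohr[t, 3] - src_bohr[, 3]
    r2 <- dx * dx + dy * dy + dz * dz
    r <- sqrt(r2)
    phi[t] <- sum(src_q / r)
    w <- src_q / (r2 * r)
    Ef[t, ] <- c(sum(w * dx), sum(w * dy), sum(w * dz))
  }
  list(phi = phi, E = Ef)
}

#' Closed-form polarizable mock quantum engine
#'
#' A test double satisfying the backend contract: fixed core charges plus
#' isotropic, non-interacting induced dipoles mu_a = alpha_a E_a responding
#' to the external point-charge field.  With zero polarizability the engine
#' is pure fixed-charge electrostatics.  Total energy (a.u., excluding
#' point-charge self-energy):
#'   E = E_core-core + sum_a q_a phi_ext(r_a) - 1/2 sum_a alpha_a |E_a|^2.
#'
#' @param solute A `solute_model`; its charges are the core charges.
#' @param polarizability Isotropic polarizability per atom, Angstrom^3
#'   (scalar recycled, default 0).
#' @param method,basis Labels recorded in ledgers.
#' @return Object of class `c("mock_engine", "qm_backend")` with functions
#'   `energy(map)`, `esp(points, map)`, `charge_interaction(map)` and fields
#'   `method`, `basis`, `total_charge`, `includes_nuclear_point_charge`.
#' @export
mock_polarizable_engine <- function(solute, polarizability = 0,
                                    method = "MOCK", basis = "POINT") {
  stopifnot(inherits(solute, "solute_model"))
  b <- .k$bohr_angstrom
  pos <- solute$xyz / b
  q <- solute$charge
  alpha <- rep(polarizability, length.out = length(q)) / b^3   # Bohr^3
  na <- length(q)
  e_core <- 0
  if (na > 1) {
    for (a in seq_len(na - 1)) for (b2 in (a + 1):na) {
      e_core <- e_core + q[a] * q[b2] / sqrt(sum((pos[a, ] - pos[b2, ])^2))
    }
  }
  map_src <- function(map) {
    if (is.null(map) || length(map$charges) == 0)
      return(list(pos = matrix(0, 0, 3), q = numeric(0)))
    list(pos = map$points / b, q = map$charges)
  }
  induced <- function(map) {
    s <- map_src(map)
    pf <- .ext_potential_field(pos, s$pos, s$q)
    list(phi = pf$phi, E = pf$E, mu = alpha * pf$E)
  }
  energy <- function(map = NULL) {
    ind <- induced(map)
    e_core + sum(q * ind$phi) - 0.5 * sum(alpha * rowSums(ind$E^2))
  }
  esp <- function(points, map = NULL) {
    pts <- matrix(points, ncol = 3) / b
    ind <- induced(map)
    out <- numeric(nrow(pts))
    for (a in seq_len(na)) {
      dx <- pts[, 1] - pos[a, 1]
      dy <- pts[, 2] - pos[a, 2]
      dz <- pts[, 3] - pos[a, 3]
      r2 <- dx * dx + dy * dy + dz * dz
      r <- sqrt(r2)
      out <- out + q[a] / r +
        (ind$mu[a, 1] * dx + ind$mu[a, 2] * dy + ind$mu[a, 3] * dz) / (r2 * r)
    }
    out
  }
  # independent route to E_q: evaluated on the atom side (potential and
  # field of the map at the atoms) rather than the map side
  charge_interaction <- function(map = NULL) {
    ind <- induced(map)
    sum(q * ind$phi) - sum(alpha * rowSums(ind$E^2))
  }
  structure(list(energy = energy, esp = esp,
                 charge_interaction = charge_interaction,
                 method = method, basis = basis,
                 total_charge = sum(q),
                 includes_nuclear_point_charge = TRUE),
            class = c("mock_engine", "qm_backend"))
}

#' Interaction energy of background charges with the solute ESP
#'
#' E_q = sum_i q_i phi(r_i), atomic units.
#'
#' @param map A `charge_map` (or anything with a `charges` field).
#' @param esp_at_points Solute electrostatic potential at the map points,
#'   a.u., 1:1 with the map.
#' @return Energy in atomic units.
#' @export
eq_energy <- function(map, esp_at_points) {
  q <- if (inherits(map, "charge_map")) map$charges else as.numeric(map)
  if (length(q) != length(esp_at_points))
    stop("length mismatch: ", length(q), " charges vs ",
         length(esp_at_points), " potential values")
  if (length(q) == 0) return(0)
  sum(q * esp_at_points)
}

#' One embedded quantum step
#'
#' Runs the backend in the field of the background charges, assembles the
#' energy ledger (E_qq omitted by policy: the contract requires backends to
#' exclude it), and returns ESP-fitted charges for the next 3D-RISM call.
#'
#' @param backend A `qm_backend`.
#' @param solute A `solute_model` (geometry and total charge).
#' @param map A `charge_map` (may be empty / NULL for the gas phase).
#' @param esp_points Sample points for the charge fit (default: CHELPG
#'   lattice around the solute).
#' @param method Charge-fit method tag.
#' @return List with `ledger` (class `qm_energy_ledger`) and `charges`
#'   (an `atomic_charges`).
#' @export
embedded_step <- function(backend, solute, map = NULL,
                          esp_points = chelpg_points(solute),
                          method = "CHELPG") {
  stopifnot(inherits(backend, "qm_backend"), inherits(solute, "solute_model"))
  e_tot <- backend$energy(map)
  e_q <- if (is.null(map) || length(map$charges) == 0) 0 else
    eq_energy(map, backend$esp(map$points, map))
  ledger <- structure(list(
    e_tot = e_tot, e_q = e_q, e_1 = e_tot - e_q,
    e_qq_omitted = TRUE,
    method = backend$method, basis = backend$basis
  ), class = "qm_energy_ledger")
  phi_fit <- backend$esp(esp_points, map)
  ch <- fit_esp_charges(esp_points, phi_fit, solute$xyz,
                        total_charge = backend$total_charge, method = method)
  list(ledger = ledger, charges = ch)
}

#' @export
print.qm_energy_ledger <- function(x, ...) {
  cat(sprintf("<qm_energy_ledger> %s/%s: E_tot %.8f, E_q %.8f, E_1 %.8f a.u.%s\n",
              x$method, x$basis, x$e_tot, x$e_q, x$e_1,
              if (isTRUE(x$e_qq_omitted)) " (E_qq omitted)" else ""))
  invisible(x)
}

#' Electronic solvation energy change
#'
#' Delta E_QM = (E_1(solvated) - E_1(gas)) converted to kJ/mol.  When
#' ledgers are supplied their method/basis tags must agree.
#'
#' @param e1_solv,e1_gas Either `qm_energy_ledger` objects or energies in
#'   atomic units.
#' @return Energy change in kJ/mol.
#' @export
delta_e_qm <- function(e1_solv, e1_gas) {
  pick <- function(x) {
    if (inherits(x, "qm_energy_ledger")) x$e_1 else as.numeric(x)
  }
  if (inherits(e1_solv, "qm_energy_ledger") &&
      inherits(e1_gas, "qm_energy_ledger")) {
    if (!identical(e1_solv$method, e1_gas$method) ||
        !identical(e1_solv$basis, e1_gas$basis))
      stop("inconsistent ledgers: ", e1_solv$method, "/", e1_solv$basis,
           " vs ", e1_gas$method, "/", e1_gas$basis)
  }
  (pick(e1_solv) - pick(e1_gas)) * .k$hartree_kjmol
}

#' Total embedded-cluster solvation free energy
#'
#' Delta G = Delta G_RISM(corrected) + Delta E_QM.
#'
#' @param delta_g_rism_corrected Corrected RISM solvation free energy,
#'   kJ/mol.
#' @param delta_e Electronic energy change from [delta_e_qm()], kJ/mol.
#' @return Total solvation free energy, kJ/mol.
#' @export
ecrism_total <- function(delta_g_rism_corrected, delta_e) {
  delta_g_rism_corrected + delta_e
}

#' Backend contract conformance checks
#'
#' Verifies, for any backend: (i) with an empty charge list all results
#' equal the gas-phase calculation; (ii) the ledger's E_q equals the
#' backend's own charge-interaction energy within `tol` a.u. when the
#' backend reports one; (iii) ESP superposition over point sets.
#'
#' @param backend A `qm_backend`.
#' @param solute The `solute_model` the backend describes.
#' @param map A nonempty `charge_map` used for the interaction check.
#' @param tol Tolerance in a.u. (default 1e-8).
#' @return Invisibly TRUE; signals an error on contract violation.
#' @export
check_backend_contract <- function(backend, solute, map, tol = 1e-8) {
  empty <- charge_map(matrix(0, 0, 3), numeric(0))
  if (abs(backend$energy(empty) - backend$energy(NULL)) > tol)
    stop("contract violation: empty charge list differs from gas phase")
  pts <- chelpg_points(solute)[1:5, , drop = FALSE]
  if (max(abs(backend$esp(pts, empty) - backend$esp(pts, NULL))) > tol)
    stop("contract violation: ESP with empty charges differs from gas phase")
  if (!is.null(backend$charge_interaction)) {
    e_q <- eq_energy(map, backend$esp(map$points, map))
    if (abs(e_q - backend$charge_interaction(map)) > tol)
      stop("contract violation: ledger E_q (", e_q,
           ") differs from backend charge interaction (",
           backend$charge_interaction(map), ")")
  }
  invisible(TRUE)
}
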