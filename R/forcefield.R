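#' Interaction site
#'
#' A Lennard-Jones + point-charge interaction site.
#'
#' @param label Site label (e.g. "O", "H").
#' @param charge Partial charge in elementary charge units.
#' @param sigma LJ diameter in Angstrom (>= 0).
#' @param epsilon LJ well depth in kJ/mol (>= 0).
#' @return Object of class `site`.
#' @export
site <- function(label, charge, sigma, epsilon) {
  stopifnot(is.character(label), length(label) == 1L)
  if (sigma < 0)   stop("sigma must be >= 0")
  if (epsilon < 0) stop("epsilon must be >= 0")
  structure(list(label = label, charge = charge,
                 sigma = sigma, epsilon = epsilon),
            class = "site")
}

#' Rigid three-site water model
#'
#' The hydrogen site is stored once and replicated by symmetry, which
#' guarantees that both H sites are identical by construction.
#'
#' @param name Model name.
#' @param r_OH O-H bond length, Angstrom.
#' @param theta_HOH H-O-H angle, degrees.
#' @param O,H `site` objects for oxygen and (one) hydrogen.
#' @param density Molecular number density, mol/dm^3 (default 55.343).
#' @param dielectric Target dielectric constant (default 78.375).
#' @return Object of class `water_model`.
#' @export
water_model <- function(name, r_OH, theta_HOH, O, H,
                        density = 55.343, dielectric = 78.375) {
  stopifnot(inherits(O, "site"), inherits(H, "site"))
  if (abs(O$charge + 2 * H$charge) > 1e-12)
    stop("water model is not neutral: q_O + 2 q_H = ",
         O$charge + 2 * H$charge)
  structure(list(name = name, r_OH = r_OH, theta_HOH = theta_HOH,
                 O = O, H = H, density = density, dielectric = dielectric),
            class = "water_model")
}

#' @export
print.water_model <- function(x, ...) {
  cat(sprintf("<water_model> %s: r_OH=%.4f A, theta=%.2f deg\n",
              x$name, x$r_OH, x$theta_HOH))
  cat(sprintf("  O: q=%+.4f e, sigma=%.4f A, eps=%.6f kJ/mol\n",
              x$O$charge, x$O$sigma, x$O$epsilon))
  cat(sprintf("  H: q=%+.4f e, sigma=%.4f A, eps=%.6f kJ/mol (x2)\n",
              x$H$charge, x$H$sigma, x$H$epsilon))
  cat(sprintf("  density=%.3f mol/dm^3, dielectric=%.3f\n",
              x$density, x$dielectric))
  invisible(x)
}

#' Molecular number density in Angstrom^-3
#' @param model A `water_model`.
#' @return Number density in A^-3.
#' @export
number_density <- function(model) {
  model$density * .k$avogadro / 1e27
}

#' H-H distance of a rigid water geometry
#' @param model A `water_model`.
#' @return Distance in Angstrom.
#' @export
hh_distance <- function(model) {
  2 * model$r_OH * sin(model$theta_HOH * pi / 360)
}

#' Derive a coincident water model
#'
#' Resizes the hydrogen LJ sphere so that its surface coincides with the
#' oxygen sphere (sigma_H = sigma_O - 2 r_OH) and sets eps_H = 0.1 eps_O.
#' This keeps the H site buried exactly at the oxygen surface, which is what
#' makes three-site waters tractable for 1D-RISM.
#'
#' @param base A `water_model` whose O site carries the LJ parameters.
#' @param name Optional name for the derived model (default "c<base name>").
#' @return A `water_model` with modified H LJ parameters.
#' @export
make_coincident_water <- function(base, name = paste0("c", base$name)) {
  stopifnot(inherits(base, "water_model"))
  sigma_H <- base$O$sigma - 2 * base$r_OH
  if (sigma_H < 0)
    stop("invalid geometry: sigma_O <= 2 r_OH gives negative sigma_H (",
         sigma_H, ")")
  H <- site(base$H$label, base$H$charge, sigma_H, 0.1 * base$O$epsilon)
  water_model(name, base$r_OH, base$theta_HOH, base$O, H,
              density = base$density, dielectric = base$dielectric)
}

# Base (uncorrected) parameter sets; H has no LJ sphere of its own.
.base_water <- function(name, r_OH, theta, q_O, sigma_O, eps_O) {
  water_model(name, r_OH, theta,
              O = site("O", q_O, sigma_O, eps_O),
              H = site("H", -q_O / 2, 0, 0))
}

#' Built-in water model registry
#'
#' The coincident models cSPC/E, cTIP3P, cOPC3 and cPOL3 are derived from
#' their parent parameter sets with [make_coincident_water()]; mSPC/E is a
#' literal parameter set (sigma_H = 1.0 A, eps_H = 0.234304 kJ/mol) that does
#' not follow the coincident rule.
#'
#' @param name One of "cSPC/E", "cTIP3P", "cOPC3", "cPOL3", "mSPC/E".
#' @return A `water_model`.
#' @examples
#' water_registry("cSPC/E")$H$sigma   # 1.1658
#' @export
water_registry <- function(name) {
  base <- switch(name,
    "cSPC/E" = .base_water("SPC/E", 1.0000, 109.47, -0.8476, 3.1658, 0.64978),
    "cTIP3P" = .base_water("TIP3P", 0.9572, 104.52, -0.8340, 3.1507, 0.63597),
    "cOPC3"  = .base_water("OPC3",  1.0000, 109.47, -0.7300, 3.2037, 0.65270),
    "cPOL3"  = .base_water("POL3",  0.9789, 109.47, -0.8952, 3.1743, 0.68369),
    "mSPC/E" = NULL,
    stop("unknown water model: ", name,
         " (available: cSPC/E, cTIP3P, cOPC3, cPOL3, mSPC/E)")
  )
  if (name == "mSPC/E") {
    return(water_model("mSPC/E", 1.0000, 109.47,
                       O = site("O", -0.8476, 3.1658, 0.64978),
                       H = site("H",  0.4238, 1.0000, 0.234304)))
  }
  make_coincident_water(base, name = name)
}

#' Lorentz-Berthelot combination of two LJ sites
#'
#' @param a,b `site` objects.
#' @return List with `sigma` = (sigma_a + sigma_b)/2 and
#'   `epsilon` = sqrt(eps_a eps_b).
#' @export
mix_lj <- function(a, b) {
  list(sigma = (a$sigma + b$sigma) / 2,
       epsilon = sqrt(a$epsilon * b$epsilon))
}

#' Site-site pair potential
#'
#' Lennard-Jones (Lorentz-Berthelot mixed) plus Coulomb:
#' u(r) = 4 eps [ (s/r)^12 - (s/r)^6 ] + k_e q_a q_b / r.
#'
#' @param r Separation(s), Angstrom, > 0.
#' @param a,b `site` objects.
#' @param thermo A `thermo_state` (unused by the potential itself; accepted so
#'   call sites can thread one state object through, and validated).
#' @return Energy in kJ/mol, same length as `r`.
#' @export
pair_potential <- function(r, a, b, thermo = thermo_state()) {
  stopifnot(inherits(thermo, "thermo_state"))
  if (any(r <= 0)) stop("singular separation: r must be > 0")
  m <- mix_lj(a, b)
  x6 <- (m$sigma / r)^6
  4 * m$epsilon * (x6^2 - x6) + .k$coulomb * a$charge * b$charge / r
}

#' Solute model: atoms with coordinates and interaction sites
#'
#' @param element Character vector of element symbols.
#' @param xyz Numeric matrix (n x 3) of coordinates, Angstrom.
#' @param charge,sigma,epsilon Per-atom site parameters (e, Angstrom, kJ/mol).
#' @return Object of class `solute_model`.
#' @export
solute_model <- function(element, xyz, charge, sigma, epsilon) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  if (n < 1L) stop("solute must contain at least one atom")
  if (!all(is.finite(xyz))) stop("solute coordinates must be finite")
  stopifnot(length(element) == n, length(charge) == n,
            length(sigma) == n, length(epsilon) == n)
  if (any(sigma < 0) || any(epsilon < 0))
    stop("sigma and epsilon must be >= 0")
  structure(list(element = as.character(element), xyz = xyz,
                 charge = as.numeric(charge), sigma = as.numeric(sigma),
                 epsilon = as.numeric(epsilon)),
            class = "solute_model")
}

#' @export
print.solute_model <- function(x, ...) {
  cat(sprintf("<solute_model> %d atoms, total charge %+.4f e\n",
              nrow(x$xyz), sum(x$charge)))
  invisible(x)
}

#' Replace the partial charges of a solute
#' @param solute A `solute_model`.
#' @param charge New per-atom charges, e.
#' @return Updated `solute_model`.
#' @export
set_charges <- function(solute, charge) {
  stopifnot(inherits(solute, "solute_model"),
            length(charge) == nrow(solute$xyz))
  solute$charge <- as.numeric(charge)
  solute
}
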