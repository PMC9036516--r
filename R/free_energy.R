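# Excess chemical potential functionals, partial molar volume, and the
# UC / PC / PC+ corrections.
#
# Functional forms (voxel-sum quadrature, Theta(0) = 0):
#   HNC:   kT sum_a rho_a int [ h^2/2 - c - h c/2 ]
#   KH:    kT sum_a rho_a int [ h^2/2 Theta(-h) - c - h c/2 ]
#   GF:    kT sum_a rho_a int [ - c - h c/2 ]          (Gaussian fluctuations)
#   PSE-n: kT sum_a rho_a int [ h^2/2 - c - h c/2 - Theta(t) t^{n+1}/(n+1)! ]
# with t the closure argument; PSE-1 reduces to KH and PSE-(n->inf) to HNC.

.functional_tag <- function(functional, n) {
  if (functional == "PSE") sprintf("PSE-%d", n) else functional
}

# does a functional request match the closure the solution was produced with
.functional_matches_closure <- function(functional, n, closure) {
  if (functional == "GF") return(TRUE)   # closure-agnostic
  lbl <- closure_label(closure)
  want <- .functional_tag(functional, n)
  if (want == "KH") return(lbl %in% c("KH", "PSE-1"))
  if (want == "PSE-1") return(lbl %in% c("KH", "PSE-1"))
  want == lbl
}

#' Excess chemical potential from a 3D-RISM solution
#'
#' @param corr A converged `correlations3d`.
#' @param functional One of "HNC", "KH", "GF", "PSE".
#' @param n PSE order (used when `functional = "PSE"`).
#' @param thermo A `thermo_state` (defaults to the solution's).
#' @param override Allow a functional that does not match the closure the
#'   solution was converged with (GF is always allowed).
#' @param integrand If TRUE, return the per-voxel integrand (kJ/mol per A^3,
#'   summed over solvent sites) instead of the integral.
#' @return Solvation free energy contribution in kJ/mol (or the integrand
#'   array).
#' @export
excess_mu <- function(corr, functional = c("KH", "HNC", "GF", "PSE"),
                      n = 1L, thermo = corr$thermo, override = FALSE,
                      integrand = FALSE) {
  functional <- match.arg(functional)
  stopifnot(inherits(corr, "correlations3d"))
  if (!override && !.functional_matches_closure(functional, n, corr$closure))
    stop("functional ", .functional_tag(functional, n),
         " does not match the solution's closure ",
         closure_label(corr$closure),
         "; pass override = TRUE to force the evaluation")
  kT <- 1 / thermo$beta
  acc <- 0
  for (s in corr$sites) {
    h <- corr$h[[s]]
    cc <- corr$c[[s]]
    base <- -cc - h * cc / 2
    term <- switch(functional,
      HNC = h^2 / 2 + base,
      KH  = { out <- base; neg <- h < 0; out[neg] <- out[neg] + h[neg]^2 / 2; out },
      GF  = base,
      PSE = {
        t <- -thermo$beta * corr$u_sr[[s]] + corr$gamma[[s]]
        out <- h^2 / 2 + base
        up <- t > 0                        # Theta(0) = 0
        out[up] <- out[up] - t[up]^(n + 1) / factorial(n + 1)
        out
      })
    acc <- acc + kT * corr$site_densities[[s]] * term
  }
  if (integrand) return(acc)
  sum(acc) * corr$grid$voxel_volume
}

#' Partial molar volume (Kirkwood-Buff route)
#'
#' V = k_B T kappa_T (1 - sum_a rho_a int c_a dr), the expression used by
#' 3D-RISM single-point codes; the integral is a voxel sum over the full
#' direct correlation functions.
#'
#' @param corr A converged `correlations3d`.
#' @param kappa_T Isothermal compressibility (A^3 mol/kJ); defaults to the
#'   value carried from the matching susceptibility.
#' @param thermo A `thermo_state`.
#' @return Partial molar volume in A^3.
#' @export
partial_molar_volume <- function(corr, kappa_T = corr$kappa_T,
                                 thermo = corr$thermo) {
  stopifnot(inherits(corr, "correlations3d"))
  kT <- 1 / thermo$beta
  cint <- 0
  for (s in corr$sites)
    cint <- cint + corr$site_densities[[s]] *
      sum(corr$c[[s]]) * corr$grid$voxel_volume
  kT * kappa_T * (1 - cint)
}

#' Universal-correction parameters
#' @param a1 Slope, kJ/mol per unit of dimensionless partial molar volume.
#' @param a0 Intercept, kJ/mol.
#' @return Object of class `uc_params`.
#' @export
uc_params <- function(a1, a0 = 0) {
  stopifnot(is.finite(a1), is.finite(a0))
  structure(list(a1 = a1, a0 = a0), class = "uc_params")
}

#' Apply the universal correction
#'
#' delta_g + a1 * dpmv + a0, where dpmv is the dimensionless partial molar
#' volume (molecular density times PMV).  Usable with any free-energy
#' functional; the parameters must be fitted or supplied (none are shipped).
#'
#' @param delta_g Base solvation free energy, kJ/mol.
#' @param dpmv Dimensionless partial molar volume.
#' @param params A `uc_params`.
#' @return Corrected free energy, kJ/mol.
#' @export
correct_uc <- function(delta_g, dpmv, params) {
  stopifnot(inherits(params, "uc_params"))
  delta_g + params$a1 * dpmv + params$a0
}

#' Fit universal-correction parameters by least squares
#'
#' Ordinary least squares of the error (delta_g_exp - delta_g_calc) on the
#' dimensionless partial molar volume.  With `pin_intercept = TRUE` the
#' intercept is constrained to zero and the slope is the closed-form
#' constrained solution.
#'
#' @param delta_g_calc,dpmv,delta_g_exp Equal-length numeric vectors.
#' @param pin_intercept Constrain a0 = 0.
#' @return A `uc_params`.
#' @export
fit_uc <- function(delta_g_calc, dpmv, delta_g_exp, pin_intercept = FALSE) {
  stopifnot(length(delta_g_calc) == length(dpmv),
            length(dpmv) == length(delta_g_exp))
  err <- delta_g_exp - delta_g_calc
  if (pin_intercept) {
    if (all(dpmv == 0)) stop("rank-deficient fit: all dpmv values are zero")
    return(uc_params(a1 = sum(err * dpmv) / sum(dpmv^2), a0 = 0))
  }
  if (length(unique(dpmv)) < 2L)
    stop("rank-deficient fit: need at least 2 distinct dpmv values")
  co <- stats::coef(stats::lm(err ~ dpmv))
  uc_params(a1 = unname(co["dpmv"]), a0 = unname(co["(Intercept)"]))
}

#' Apply a pressure correction (PC or PC+)
#'
#' PC subtracts the full pressure-volume work term P_RISM * V; PC+ subtracts
#' (P_RISM - rho k_B T) * V, i.e. it additionally cancels the ideal
#' molecular contribution.  The two schemes differ by exactly rho k_B T V.
#'
#' @param delta_g Base solvation free energy, kJ/mol.
#' @param pmv Partial molar volume, A^3.
#' @param pressure_terms List with `p_rism` and `rho_kT` (from
#'   [rism_pressure()]).
#' @param scheme "PC" or "PC+".
#' @param extra_constant Optional additive constant, kJ/mol (default 0).
#' @return Corrected free energy, kJ/mol.
#' @export
correct_pressure <- function(delta_g, pmv, pressure_terms,
                             scheme = c("PC+", "PC"), extra_constant = 0) {
  scheme <- match.arg(scheme)
  p <- pressure_terms$p_rism
  if (scheme == "PC+") p <- p - pressure_terms$rho_kT
  delta_g - p * pmv + extra_constant
}

#' Assemble a free-energy report from a 3D-RISM solution
#'
#' Evaluates the requested functionals, the partial molar volume and its
#' dimensionless form, and the PC / PC+ (and optionally UC) corrections of a
#' chosen base functional.  Corrected values satisfy
#' `corrected == base + term` bitwise.
#'
#' @param corr A converged `correlations3d`.
#' @param functionals Character vector of functionals to evaluate; "PSE"
#'   entries use the closure's own order.  Defaults to the functional
#'   matching the closure plus "GF".
#' @param base Functional whose value the corrections are applied to
#'   (default: the one matching the closure).
#' @param uc A `uc_params` or NULL (UC omitted).
#' @param uc_base Functional the UC is applied to (default "GF").
#' @return Object of class `free_energy_report`.
#' @export
free_energy_report <- function(corr, functionals = NULL, base = NULL,
                               uc = NULL, uc_base = "GF") {
  stopifnot(inherits(corr, "correlations3d"))
  lbl <- closure_label(corr$closure)
  own <- if (grepl("^PSE", lbl)) "PSE" else if (lbl == "KH") "KH" else lbl
  if (is.null(functionals)) functionals <- unique(c(own, "GF"))
  if (is.null(base)) base <- own
  n_own <- if (corr$closure$kind == "PSE") corr$closure$n else 1L
  # an explicit functional request in the report is itself the override
  dg <- vapply(functionals, function(f)
    excess_mu(corr, functional = f, n = n_own, override = TRUE), numeric(1))
  names(dg) <- vapply(functionals, .functional_tag, character(1), n = n_own)
  pmv <- partial_molar_volume(corr)
  dpmv <- corr$rho_molecular * pmv
  base_tag <- .functional_tag(base, n_own)
  base_val <- dg[[base_tag]]
  terms <- c("PC"  = -corr$pressure$p_rism * pmv,
             "PC+" = -(corr$pressure$p_rism - corr$pressure$rho_kT) * pmv)
  corrected <- base_val + terms
  if (!is.null(uc)) {
    stopifnot(inherits(uc, "uc_params"))
    uc_tag <- .functional_tag(uc_base, n_own)
    if (!uc_tag %in% names(dg))
      dg[[uc_tag]] <- excess_mu(corr, functional = uc_base, n = n_own)
    terms[["UC"]] <- uc$a1 * dpmv + uc$a0
    corrected[["UC"]] <- dg[[uc_tag]] + terms[["UC"]]
  }
  structure(list(
    delta_g = dg, pmv = pmv, dpmv = dpmv,
    pressure = corr$pressure$p_rism, rho_kT = corr$pressure$rho_kT,
    base = base_tag, correction_terms = terms, corrected = corrected,
    closure = lbl, solvent = corr$solvent,
    grid = list(dims = corr$grid$dims, spacing = corr$grid$spacing)
  ), class = "free_energy_report")
}

#' @export
print.free_energy_report <- function(x, ...) {
  cat(sprintf("<free_energy_report> %s / %s\n", x$solvent, x$closure))
  for (f in names(x$delta_g))
    cat(sprintf("  dG[%s] = %10.4f kJ/mol\n", f, x$delta_g[[f]]))
  cat(sprintf("  PMV = %.4f A^3 (dpmv %.4f); P_RISM = %.6f kJ/mol/A^3\n",
              x$pmv, x$dpmv, x$pressure))
  for (s in names(x$corrected))
    cat(sprintf("  dG[%s, %s] = %10.4f kJ/mol\n", x$base, s, x$corrected[[s]]))
  invisible(x)
}
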