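# The self-consistent embedded-cluster loop: charges -> 3D-RISM -> solvent
# charge map -> embedded QM -> charges, repeated until both the QM and the
# RISM energy change fall below the convergence criterion.

#' Embedded-cluster RISM configuration
#'
#' The defaults reproduce the recommended setup: PSE-3 closure with cTIP3P
#' water, 15 A buffer, 0.3 A grid spacing, PC+ correction, CHELPG charges,
#' a 1e-6 a.u. point-charge threshold, and a 0.01 kJ/mol self-consistency
#' criterion.
#'
#' @param buffer Buffer, Angstrom.
#' @param spacing Grid spacing, Angstrom.
#' @param closure A `closure_spec` (default PSE-3).
#' @param water Water model name for [water_registry()].
#' @param correction "PC+", "PC", "UC" or "none".
#' @param uc A `uc_params`, required when `correction = "UC"`.
#' @param charge_method Charge-fit tag (default "CHELPG").
#' @param threshold Point-charge drop threshold, a.u.
#' @param convergence Self-consistency criterion, kJ/mol.
#' @param max_cycles Maximum embedding cycles.
#' @param temperature Temperature, K.
#' @param closure_1d Closure for the bulk 1D-RISM solvent (default: same as
#'   `closure`; pass e.g. `closure_spec("HNC")` for a split setup).
#' @param mix Optional linear charge mixing between cycles (0 = off).
#' @param rism_tol 3D-RISM residual tolerance.
#' @return Object of class `ecrism_config`.
#' @export
ecrism_config <- function(buffer = 15, spacing = 0.3,
                          closure = closure_spec("PSE", n = 3),
                          water = "cTIP3P",
                          correction = c("PC+", "PC", "UC", "none"),
                          uc = NULL, charge_method = "CHELPG",
                          threshold = 1e-6, convergence = 0.01,
                          max_cycles = 30L, temperature = 298.15,
                          closure_1d = NULL, mix = 0, rism_tol = 1e-6) {
  correction <- match.arg(correction)
  if (correction == "UC" && is.null(uc))
    stop("correction = \"UC\" requires explicit uc_params; ",
         "no default fit parameters are shipped")
  structure(list(buffer = buffer, spacing = spacing, closure = closure,
                 water = water, correction = correction, uc = uc,
                 charge_method = charge_method, threshold = threshold,
                 convergence = convergence, max_cycles = as.integer(max_cycles),
                 temperature = temperature,
                 closure_1d = if (is.null(closure_1d)) closure else closure_1d,
                 mix = mix, rism_tol = rism_tol),
            class = "ecrism_config")
}

# corrected RISM free energy according to the configured scheme
.corrected_dg <- function(report, config) {
  switch(config$correction,
    "none" = report$delta_g[[report$base]],
    "UC"   = report$corrected[["UC"]],
    report$corrected[[config$correction]]
  )
}

#' Run the self-consistent embedded-cluster RISM loop
#'
#' Initialized by a gas-phase backend calculation; then iterates (i) charge
#' fit, (ii) 3D-RISM with the fitted charges, (iii) embedded backend
#' calculation in the solvent point-charge field, until the changes of both
#' Delta E_QM and the corrected Delta G_RISM are below the criterion.
#'
#' @param solute A `solute_model` carrying LJ parameters (charges are
#'   replaced by the fitted ones each cycle).
#' @param backend A `qm_backend`.
#' @param config An `ecrism_config`.
#' @param chi Optional precomputed `solvent_susceptibility` (computed from
#'   the config's water model and 1D closure when omitted).
#' @param verbose Print a per-cycle energy table.
#' @return Object of class `ecrism_result`: final `delta_g_total` (kJ/mol),
#'   `delta_e_qm`, `delta_g_rism`, the final `report` and `corr`, the cycle
#'   `history`, and `converged`.
#' @export
run_ecrism <- function(solute, backend, config = ecrism_config(),
                       chi = NULL, verbose = FALSE) {
  stopifnot(inherits(solute, "solute_model"), inherits(backend, "qm_backend"),
            inherits(config, "ecrism_config"))
  thermo <- thermo_state(config$temperature)
  model <- water_registry(config$water)
  if (is.null(chi)) {
    sol1d <- solve_drism(model, thermo, closure = config$closure_1d)
    chi <- susceptibility(sol1d)
  }
  grid <- build_grid(solute, buffer = config$buffer, spacing = config$spacing)
  esp_pts <- chelpg_points(solute)

  gas <- embedded_step(backend, solute, map = NULL, esp_points = esp_pts,
                       method = config$charge_method)
  charges <- gas$charges$values
  history <- list()
  prev <- list(de = NA_real_, dg = NA_real_, charges = charges)
  converged <- FALSE
  de <- dg_rism <- NA_real_
  report <- corr <- emb <- NULL
  for (cyc in seq_len(config$max_cycles)) {
    work <- set_charges(solute, charges)
    pot <- solute_site_potentials(work, chi$solvent_sites, grid, thermo)
    corr <- solve_3drism(pot, chi, closure = config$closure, thermo = thermo,
                         tol = config$rism_tol)
    report <- free_energy_report(corr, uc = config$uc)
    dg_rism <- .corrected_dg(report, config)
    map <- drop_small(solvent_charge_map(corr), config$threshold)
    emb <- embedded_step(backend, work, map, esp_points = esp_pts,
                         method = config$charge_method)
    de <- delta_e_qm(emb$ledger, gas$ledger)
    new_charges <- emb$charges$values
    if (config$mix > 0)
      new_charges <- (1 - config$mix) * new_charges + config$mix * charges
    rec <- list(cycle = cyc, delta_g_rism = dg_rism, delta_e_qm = de,
                delta_g_total = ecrism_total(dg_rism, de),
                ledger = emb$ledger, charges = new_charges,
                max_dq = max(abs(new_charges - prev$charges)),
                d_delta_e = abs(de - prev$de),
                d_delta_g = abs(dg_rism - prev$dg),
                map_points = length(map$charges),
                map_dropped_fraction = map$dropped_fraction)
    history[[cyc]] <- rec
    if (verbose)
      message(sprintf(
        "cycle %d: dG_RISM %.4f, dE_QM %.4f, total %.4f kJ/mol, max|dq| %.2e",
        cyc, dg_rism, de, rec$delta_g_total, rec$max_dq))
    if (cyc > 1 && rec$d_delta_e < config$convergence &&
        rec$d_delta_g < config$convergence) {
      converged <- TRUE
      break
    }
    prev <- list(de = de, dg = dg_rism, charges = new_charges)
    charges <- new_charges
  }
  structure(list(
    delta_g_total = ecrism_total(dg_rism, de),
    delta_g_rism = dg_rism, delta_e_qm = de,
    report = report, corr = corr, final_ledger = emb$ledger,
    gas_ledger = gas$ledger, charges = emb$charges,
    history = history, n_cycles = length(history),
    converged = converged, config = config
  ), class = "ecrism_result")
}

#' @export
print.ecrism_result <- function(x, ...) {
  cat(sprintf("<ecrism_result> %s after %d cycle(s)\n",
              if (x$converged) "converged" else "NOT converged", x$n_cycles))
  cat(sprintf("  dG_RISM(%s) = %.4f kJ/mol\n", x$config$correction,
              x$delta_g_rism))
  cat(sprintf("  dE_QM       = %.4f kJ/mol\n", x$delta_e_qm))
  cat(sprintf("  dG_total    = %.4f kJ/mol\n", x$delta_g_total))
  invisible(x)
}

#' Boltzmann conformer averaging
#'
#' Conformers with reference energies more than `window` above the minimum
#' are excluded; the remaining solvation free energies are averaged with
#' weights proportional to exp(-beta E_rel).
#'
#' @param energy Per-conformer reference energies, kJ/mol (gas-phase
#'   energies in the standard workflow).
#' @param delta_g Per-conformer solvation free energies, kJ/mol.
#' @param thermo A `thermo_state`.
#' @param window Energy window above the minimum, kJ/mol (default 10).
#' @return Weighted mean solvation free energy, kJ/mol.
#' @export
boltzmann_average <- function(energy, delta_g, thermo = thermo_state(),
                              window = 10) {
  stopifnot(length(energy) == length(delta_g), length(energy) >= 1)
  e_rel <- energy - min(energy)
  keep <- e_rel <= window
  w <- exp(-thermo$beta * e_rel[keep])
  sum(w * delta_g[keep]) / sum(w)
}
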