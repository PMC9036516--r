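# Session-level cache for expensive solvent solutions shared across test
# files (testthat sources helpers once per test_dir run).

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

# converged bulk solution + susceptibility, keyed by model/closure
test_bulk <- function(model = "cSPC/E", closure = closure_spec("KH"),
                      n_points = 1024L, dr = 0.025) {
  key <- paste("bulk", model, closure_label(closure), n_points, dr)
  cached(key, solve_drism(water_registry(model), thermo_state(),
                          radial_grid(n_points, dr), closure))
}

test_chi <- function(model = "cSPC/E", closure = closure_spec("KH")) {
  key <- paste("chi", model, closure_label(closure))
  cached(key, susceptibility(test_bulk(model, closure)))
}

# small converged 3D solution on the LJ-sphere fixture
test_lj_corr <- function(buffer = 8, spacing = 0.5,
                         closure = closure_spec("KH"), tol = 1e-6) {
  key <- paste("ljcorr", buffer, spacing, closure_label(closure), tol)
  cached(key, {
    fx <- make_fixture("lj_sphere")
    chi <- test_chi("cSPC/E", closure)
    grid <- build_grid(fx$solute, buffer = buffer, spacing = spacing)
    pot <- solute_site_potentials(fx$solute, chi$solvent_sites, grid,
                                  thermo_state())
    solve_3drism(pot, chi, closure, tol = tol)
  })
}
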