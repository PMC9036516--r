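# Readers and writers: solute geometries (XYZ, whitespace site table, PDB
# subset), OpenDX volumetric fields, 4-column charge maps, JSON reports,
# and the self-describing plain-text (JSON) susceptibility container.
#
# All writers are deterministic: stable ordering and fixed float formatting
# (17 significant digits, enough for exact double round-trips in text).

.fmt <- function(x) formatC(x, format = "g", digits = 17)

.known_elements <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Fe", "Zn", "Se", "Br", "Kr",
  "I", "Xe")

.check_element <- function(el, line = NULL) {
  bad <- !(el %in% .known_elements)
  if (any(bad))
    stop("unknown element symbol: ", paste(unique(el[bad]), collapse = ", "),
         if (!is.null(line)) paste0(" (line ", line[bad][1], ")") else "")
  el
}

#' Read a solute structure
#'
#' Formats: `"xyz"` (standard XYZ; coordinates only, site parameters from
#' `defaults`), `"site_table"` (whitespace-delimited
#' `element x y z q sigma epsilon`, one atom per line, `#` comments), and
#' `"pdb"` (ATOM/HETATM coordinates and elements only; first altloc kept
#' with a warning).
#'
#' @param path File path.
#' @param format One of "auto", "xyz", "site_table", "pdb" ("auto" guesses
#'   from the extension).
#' @param defaults Optional data.frame with columns `element`, `charge`,
#'   `sigma`, `epsilon` supplying per-element site parameters for xyz/pdb.
#' @return A `solute_model`.
#' @export
read_solute <- function(path, format = c("auto", "xyz", "site_table", "pdb"),
                        defaults = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyz = "xyz", pdb = "pdb", "site_table")
  }
  lookup_params <- function(el) {
    if (is.null(defaults))
      return(list(q = rep(0, length(el)), s = rep(0, length(el)),
                  e = rep(0, length(el))))
    idx <- match(el, defaults$element)
    if (anyNA(idx))
      stop("no default site parameters for element(s): ",
           paste(unique(el[is.na(idx)]), collapse = ", "))
    list(q = defaults$charge[idx], s = defaults$sigma[idx],
         e = defaults$epsilon[idx])
  }
  if (format == "xyz") {
    lines <- readLines(path)
    n <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(n)) stop("malformed XYZ header (line 1): ", lines[1])
    body <- lines[3:(2 + n)]
    tok <- strsplit(trimws(body), "\\s+")
    el <- character(n); xyz <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      t <- tok[[i]]
      if (length(t) < 4) stop("malformed XYZ line ", i + 2, ": ", body[i])
      el[i] <- t[1]
      v <- suppressWarnings(as.numeric(t[2:4]))
      if (anyNA(v)) stop("malformed XYZ line ", i + 2, ": ", body[i])
      xyz[i, ] <- v
    }
    .check_element(el)
    p <- lookup_params(el)
    return(solute_model(el, xyz, p$q, p$s, p$e))
  }
  if (format == "site_table") {
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    body <- lines[keep]
    lineno <- which(keep)
    tok <- strsplit(trimws(body), "\\s+")
    n <- length(body)
    if (n == 0) stop("empty site table: ", path)
    el <- character(n); m <- matrix(0, n, 6)
    for (i in seq_len(n)) {
      t <- tok[[i]]
      if (length(t) != 7)
        stop("malformed site-table line ", lineno[i], " (need 7 fields): ",
             body[i])
      el[i] <- t[1]
      v <- suppressWarnings(as.numeric(t[2:7]))
      if (anyNA(v)) stop("malformed site-table line ", lineno[i], ": ", body[i])
      m[i, ] <- v
    }
    .check_element(el, lineno)
    return(solute_model(el, m[, 1:3], m[, 4], m[, 5], m[, 6]))
  }
  # pdb subset
  lines <- readLines(path)
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(rec) == 0) stop("no ATOM/HETATM records in ", path)
  altloc <- substr(rec, 17, 17)
  if (any(!altloc %in% c(" ", "", "A"))) {
    warning("alternate locations present; keeping first altloc only")
    rec <- rec[altloc %in% c(" ", "", "A")]
  }
  xyz <- cbind(as.numeric(substr(rec, 31, 38)),
               as.numeric(substr(rec, 39, 46)),
               as.numeric(substr(rec, 47, 54)))
  el <- trimws(substr(rec, 77, 78))
  if (any(el == "")) {
    nm <- trimws(substr(rec, 13, 16))
    el[el == ""] <- sub("^([A-Za-z]+).*", "\\1", nm[el == ""])
    el <- sub("^([A-Z])([a-z]?).*", "\\1\\2", el)
  }
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
  el <- trimws(el)
  .check_element(el)
  p <- lookup_params(el)
  solute_model(el, xyz, p$q, p$s, p$e)
}

#' Write a solute as a whitespace site table
#' @param solute A `solute_model`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_site_table <- function(solute, path) {
  lines <- c("# element x y z q sigma epsilon",
             vapply(seq_len(nrow(solute$xyz)), function(i) {
               paste(solute$element[i],
                     .fmt(solute$xyz[i, 1]), .fmt(solute$xyz[i, 2]),
                     .fmt(solute$xyz[i, 3]), .fmt(solute$charge[i]),
                     .fmt(solute$sigma[i]), .fmt(solute$epsilon[i]))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a solute in XYZ format
#' @param solute A `solute_model`.
#' @param path Output path.
#' @param comment Comment line.
#' @return Invisibly `path`.
#' @export
write_xyz <- function(solute, path, comment = "") {
  n <- nrow(solute$xyz)
  lines <- c(as.character(n), comment,
             vapply(seq_len(n), function(i) {
               paste(solute$element[i], .fmt(solute$xyz[i, 1]),
                     .fmt(solute$xyz[i, 2]), .fmt(solute$xyz[i, 3]))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a 3D field in OpenDX regular-grid format
#'
#' @param field 3D array on `grid`.
#' @param grid A `grid3d`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_dx <- function(field, grid, path) {
  stopifnot(identical(dim(field), as.integer(grid$dims)) ||
            identical(dim(field), grid$dims))
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %s %s %s", .fmt(grid$origin[1]), .fmt(grid$origin[2]),
            .fmt(grid$origin[3])),
    sprintf("delta %s 0 0", .fmt(grid$spacing[1])),
    sprintf("delta 0 %s 0", .fmt(grid$spacing[2])),
    sprintf("delta 0 0 %s", .fmt(grid$spacing[3])),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))
  ), con)
  # DX order: z fastest
  vals <- .fmt(as.vector(aperm(field, c(3, 2, 1))))
  # write in rows of 3
  n <- length(vals)
  pad <- (3 - n %% 3) %% 3
  vals <- c(vals, rep("", pad))
  rows <- apply(matrix(vals, ncol = 3, byrow = TRUE), 1, paste, collapse = " ")
  writeLines(trimws(rows), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Read an OpenDX regular-grid file written by [write_dx()]
#' @param path File path.
#' @return List with `field` (3D array), `origin`, `spacing`, `dims`.
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  cnt <- as.integer(strsplit(sub(".*counts ", "", lines[1]), "\\s+")[[1]])
  origin <- as.numeric(strsplit(sub("^origin ", "", lines[2]), "\\s+")[[1]])
  d1 <- as.numeric(strsplit(sub("^delta ", "", lines[3]), "\\s+")[[1]])[1]
  d2 <- as.numeric(strsplit(sub("^delta ", "", lines[4]), "\\s+")[[1]])[2]
  d3 <- as.numeric(strsplit(sub("^delta ", "", lines[5]), "\\s+")[[1]])[3]
  first <- 8L
  last <- length(lines)
  while (grepl("^attribute", lines[last])) last <- last - 1L
  vals <- as.numeric(unlist(strsplit(trimws(lines[first:last]), "\\s+")))
  vals <- vals[!is.na(vals)]
  stopifnot(length(vals) == prod(cnt))
  field <- aperm(array(vals, rev(cnt)), c(3, 2, 1))
  list(field = field, origin = origin, spacing = c(d1, d2, d3), dims = cnt)
}

#' Write a charge map as a 4-column text table
#' @param map A `charge_map`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "charge_map"))
  hdr <- sprintf("# x y z q  (n=%d threshold=%s dropped=%s)",
                 length(map$charges), .fmt(map$threshold),
                 .fmt(map$dropped_fraction))
  body <- if (length(map$charges) == 0) character(0) else
    vapply(seq_along(map$charges), function(i) {
      paste(.fmt(map$points[i, 1]), .fmt(map$points[i, 2]),
            .fmt(map$points[i, 3]), .fmt(map$charges[i]))
    }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a 4-column charge-map table written by [write_map()]
#' @param path File path.
#' @return A `charge_map`.
#' @export
read_map <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(body) == 0) return(charge_map(matrix(0, 0, 3), numeric(0)))
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  charge_map(m[, 1:3, drop = FALSE], m[, 4])
}

#' Save a solvent susceptibility as self-describing JSON
#'
#' Plain-text container holding the k-grid, the unique-pair chi components,
#' densities, geometry, thermodynamic state and provenance at full numeric
#' precision.
#'
#' @param chi A `solvent_susceptibility`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_susceptibility <- function(chi, path) {
  stopifnot(inherits(chi, "solvent_susceptibility"))
  obj <- list(
    format = "ecrism-susceptibility-1",
    model_name = chi$model_name, closure = chi$closure,
    temperature = chi$thermo$temperature,
    rho_molecular = chi$rho_molecular,
    site_densities = as.list(chi$site_densities),
    site_charges = as.list(chi$site_charges),
    solvent_sites = lapply(chi$solvent_sites, unclass),
    l_OH = chi$l_OH, l_HH = chi$l_HH,
    kappa_T = chi$kappa_T, pressure = chi$pressure,
    grid = chi$grid,
    k = chi$k,
    rho_h_hat = list(OO = chi$rho_h_hat[, "OO"],
                     OH = chi$rho_h_hat[, "OH"],
                     HH = chi$rho_h_hat[, "HH"])
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a solvent susceptibility saved by [write_susceptibility()]
#' @param path File path.
#' @return A `solvent_susceptibility`.
#' @export
read_susceptibility <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$format, "ecrism-susceptibility-1"))
    stop("not an ecrism susceptibility container: ", path)
  sites <- lapply(o$solvent_sites, function(s)
    site(s$label, s$charge, s$sigma, s$epsilon))
  structure(list(
    k = o$k,
    rho_h_hat = cbind(OO = o$rho_h_hat$OO, OH = o$rho_h_hat$OH,
                      HH = o$rho_h_hat$HH),
    l_OH = o$l_OH, l_HH = o$l_HH,
    rho_molecular = o$rho_molecular,
    site_densities = unlist(o$site_densities),
    site_charges = unlist(o$site_charges),
    solvent_sites = sites,
    thermo = thermo_state(o$temperature),
    model_name = o$model_name, closure = o$closure,
    kappa_T = o$kappa_T,
    pressure = o$pressure,
    grid = o$grid
  ), class = "solvent_susceptibility")
}

#' Write a result bundle (report or EC-RISM result) as JSON
#'
#' @param x A `free_energy_report` or `ecrism_result`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_report <- function(x, path) {
  strip <- function(r) {
    list(delta_g = as.list(r$delta_g), pmv = r$pmv, dpmv = r$dpmv,
         pressure = r$pressure, rho_kT = r$rho_kT, base = r$base,
         correction_terms = as.list(r$correction_terms),
         corrected = as.list(r$corrected),
         closure = r$closure, solvent = r$solvent, grid = r$grid)
  }
  obj <- if (inherits(x, "free_energy_report")) {
    c(list(format = "ecrism-report-1", kind = "free_energy_report"), strip(x))
  } else if (inherits(x, "ecrism_result")) {
    list(format = "ecrism-report-1", kind = "ecrism_result",
         delta_g_total = x$delta_g_total, delta_g_rism = x$delta_g_rism,
         delta_e_qm = x$delta_e_qm, converged = x$converged,
         n_cycles = x$n_cycles,
         charges = x$charges$values,
         config = list(buffer = x$config$buffer, spacing = x$config$spacing,
                       closure = closure_label(x$config$closure),
                       water = x$config$water,
                       correction = x$config$correction,
                       threshold = x$config$threshold,
                       convergence = x$config$convergence),
         history = lapply(x$history, function(h)
           list(cycle = h$cycle, delta_g_rism = h$delta_g_rism,
                delta_e_qm = h$delta_e_qm, delta_g_total = h$delta_g_total,
                max_dq = h$max_dq, map_points = h$map_points,
                map_dropped_fraction = h$map_dropped_fraction)),
         report = strip(x$report))
  } else stop("unsupported object for write_report: ", class(x)[1])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
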