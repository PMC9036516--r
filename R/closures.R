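#' Closure specification
#'
#' Describes the closure relation used to complement the RISM equations:
#' hypernetted chain (HNC), partially linearized HNC (PLHNC, with constant
#' `C`; `C = 0` is the Kovalenko-Hirata closure), KH, or the partial series
#' expansion of order n of HNC (PSE-n; PSE-1 is identical to KH).
#'
#' @param kind One of "KH", "PLHNC", "PSE", "HNC".
#' @param n Expansion order for PSE (positive integer).
#' @param C Linearization threshold for PLHNC (dimensionless, default 0).
#' @return Object of class `closure_spec`.
#' @examples
#' closure_spec("PSE", n = 3)
#' @export
closure_spec <- function(kind = c("KH", "PLHNC", "PSE", "HNC"),
                         n = 1L, C = 0) {
  kind <- match.arg(kind)
  if (kind == "PSE") {
    if (n < 1 || n != round(n)) stop("PSE order n must be a positive integer")
  }
  structure(list(kind = kind, n = as.integer(n), C = C),
            class = "closure_spec")
}

#' @export
print.closure_spec <- function(x, ...) {
  lbl <- switch(x$kind,
                PSE = sprintf("PSE-%d", x$n),
                PLHNC = sprintf("PLHNC(C=%g)", x$C),
                x$kind)
  cat("<closure_spec>", lbl, "\n")
  invisible(x)
}

#' Human-readable closure label
#' @param closure A `closure_spec`.
#' @return Character scalar such as "PSE-3".
#' @export
closure_label <- function(closure) {
  switch(closure$kind,
         PSE = sprintf("PSE-%d", closure$n),
         PLHNC = if (closure$C == 0) "KH" else sprintf("PLHNC(%g)", closure$C),
         closure$kind)
}

# g(t) for closure argument t = -beta*u + gamma, elementwise on arrays.
# Branch selection uses the Heaviside convention Theta(0) = 0: the
# exponential branch is taken at the switching point itself.
.closure_g_of_t <- function(t, closure) {
  if (closure$kind == "HNC") {
    if (any(t > 500, na.rm = TRUE))
      stop("HNC closure overflow: exp argument exceeds 500; ",
           "use a damped iteration or a partially linearized closure")
    return(exp(t))
  }
  if (closure$kind %in% c("KH", "PLHNC")) {
    C <- if (closure$kind == "KH") 0 else closure$C
    up <- t > C                      # Theta(t - C) with Theta(0) = 0
    g <- exp(pmin(t, C))
    g[up] <- exp(C) * (1 + t[up] - C)
    return(g)
  }
  # PSE-n: exponential below 0, order-n partial Taylor sum above
  up <- t > 0
  g <- exp(pmin(t, 0))
  if (any(up)) {
    tu <- t[up]
    s <- 1
    term <- rep(1, length(tu))
    for (m in seq_len(closure$n)) {
      term <- term * tu / m
      s <- s + term
    }
    g[up] <- s
  }
  g
}

#' Apply a closure relation
#'
#' Computes the distribution function g from the interaction potential and
#' the indirect correlation function gamma = h - c.  The closure argument is
#' t = -beta u + gamma.
#'
#' @param u Potential (kJ/mol), array of any shape.
#' @param gamma Indirect correlation function, same shape as `u`.
#' @param closure A `closure_spec`.
#' @param thermo A `thermo_state`.
#' @return g, same shape as the inputs.
#' @export
apply_closure <- function(u, gamma, closure, thermo = thermo_state()) {
  stopifnot(inherits(closure, "closure_spec"), inherits(thermo, "thermo_state"))
  if (!identical(dim(u), dim(gamma)) || length(u) != length(gamma))
    stop("u and gamma must live on the same grid")
  t <- -thermo$beta * u + gamma
  out <- .closure_g_of_t(t, closure)
  if (!is.null(dim(u))) dim(out) <- dim(u)
  out
}
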