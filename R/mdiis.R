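# Modified direct inversion in the iterative subspace (MDIIS).
#
# Generic accelerator for fixed-point iterations x -> F(x).  The caller
# supplies, per step, the current trial x and its residual r = F(x) - x;
# the accelerator returns the next trial as the DIIS-optimal linear
# combination of stored vectors plus `step` times the combined residual.
# Restarts (keeping only the best stored vector) when the current residual
# exceeds `restart_factor` times the smallest residual seen in the store.

mdiis_new <- function(depth = 10L, step = 0.7, restart_factor = 10) {
  env <- new.env(parent = emptyenv())
  env$depth <- as.integer(depth)
  env$step <- step
  env$restart_factor <- restart_factor
  env$x <- list()
  env$r <- list()
  env$rnorm <- numeric(0)
  env
}

mdiis_update <- function(m, x, r) {
  rn <- sqrt(mean(r * r))
  if (length(m$rnorm) > 0 && rn > m$restart_factor * min(m$rnorm)) {
    # restart: keep only the best stored pair
    best <- which.min(m$rnorm)
    m$x <- m$x[best]
    m$r <- m$r[best]
    m$rnorm <- m$rnorm[best]
    x <- m$x[[1L]]
    r <- m$r[[1L]]
    rn <- m$rnorm[[1L]]
  }
  m$x[[length(m$x) + 1L]] <- x
  m$r[[length(m$r) + 1L]] <- r
  m$rnorm <- c(m$rnorm, rn)
  if (length(m$x) > m$depth) {
    m$x <- m$x[-1L]
    m$r <- m$r[-1L]
    m$rnorm <- m$rnorm[-1L]
  }
  n <- length(m$x)
  if (n == 1L) return(x + m$step * r)
  # DIIS system: minimize |sum c_i r_i|^2 subject to sum c_i = 1
  B <- matrix(0, n + 1L, n + 1L)
  for (i in seq_len(n)) for (j in i:n) {
    B[i, j] <- B[j, i] <- sum(m$r[[i]] * m$r[[j]])
  }
  B[n + 1L, seq_len(n)] <- 1
  B[seq_len(n), n + 1L] <- 1
  rhs <- c(rep(0, n), 1)
  co <- tryCatch(solve(B, rhs)[seq_len(n)], error = function(e) NULL)
  if (is.null(co) || any(!is.finite(co))) {
    # ill-conditioned history: fall back to damped Picard on latest pair
    return(x + m$step * r)
  }
  xn <- 0
  for (i in seq_len(n)) xn <- xn + co[i] * (m$x[[i]] + m$step * m$r[[i]])
  xn
}
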