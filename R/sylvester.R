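#' Solve the Sylvester equation P X + X Q = R
#'
#' Eigendecomposes `Q = V S V^-1` (possibly complex), solves the resulting
#' shifted systems `(P + s_j I) y_j = (R V)_j` column by column, and maps
#' back.  The solution is unique exactly when no eigenvalue of `P` equals
#' the negative of an eigenvalue of `Q`; an overlap aborts with the shared
#' eigenvalue named.
#'
#' @param P square matrix (`m x m`).
#' @param Q square matrix (`k x k`).
#' @param R right-hand side (`m x k`).
#' @return the `m x k` solution `X`, with
#'   `norm(P X + X Q - R, "F") <= 1e-8 * norm(R, "F")` for well-conditioned
#'   inputs.
#' @export
solve_sylvester <- function(P, Q, R) {
  P <- as.matrix(P); Q <- as.matrix(Q); R <- as.matrix(R)
  stopifnot(nrow(P) == ncol(P), nrow(Q) == ncol(Q),
            nrow(R) == nrow(P), ncol(R) == ncol(Q))

  ep <- eigen(P, only.values = TRUE)$values
  eq <- eigen(Q)
  sep <- outer(ep, eq$values, `+`)
  scale <- max(1, max(abs(ep)), max(abs(eq$values)))
  if (min(abs(sep)) < 1e-12 * scale) {
    bad <- which(abs(sep) == min(abs(sep)), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "spectra of P and -Q overlap: eigenvalue %s of P matches -(%s) of Q",
      format(ep[bad[1]]), format(eq$values[bad[2]])))
  }

  V <- eq$vectors
  RV <- R %*% V
  Y <- matrix(0i, nrow(R), ncol(R))
  I_m <- diag(nrow(P))
  for (j in seq_len(ncol(R))) {
    Y[, j] <- solve(P + eq$values[j] * I_m, RV[, j])
  }
  X <- Y %*% solve(V)
  if (is.complex(X)) {
    if (max(abs(Im(X))) > 1e-6 * max(1, max(abs(Re(X))))) {
      warning("solve_sylvester: dropping non-negligible imaginary part")
    }
    X <- Re(X)
  }
  X
}
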