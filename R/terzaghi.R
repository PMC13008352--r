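#' Classical one-dimensional consolidation (Terzaghi) series solution
#'
#' Excess pore pressure in a laterally confined column of height `h`,
#' loaded at t = 0 by a constant axial stress `q`, drained at the top and
#' impermeable at the base:
#' \deqn{p(z,t) = q \sum_{m \ge 0} \frac{2}{M} \sin\!\Big(M \frac{h - z}{h}\Big)
#'   e^{-M^2 T_v}, \quad M = \tfrac{\pi}{2}(2m+1), \; T_v = \frac{D t}{h^2},}
#' with `z` measured upward from the impermeable base (so `z = h` is the
#' drained surface) and `D` the consolidation (poroelastic diffusion)
#' coefficient. At \eqn{t = 0^+} the undrained response carries the full
#' load (`p = q`); as \eqn{t \to \infty} the column drains completely.
#'
#' Serves as the independent closed-form oracle for the finite element
#' solver.
#'
#' @param q Applied axial stress, Pa.
#' @param h Column height, um.
#' @param D Consolidation coefficient, um^2/s.
#' @param z Heights above the impermeable base, um (vectorised).
#' @param t Time, s (scalar).
#' @param tol Series truncation tolerance on the term magnitude.
#' @return Pore pressure at each `z`, Pa.
#' @examples
#' terzaghi_reference(100, 20, 10, z = 0, t = 1)
#' @export
terzaghi_reference <- function(q, h, D, z, t, tol = 1e-12) {
  stopifnot(h > 0, D > 0, all(z >= -1e-9), all(z <= h + 1e-9), t >= 0)
  if (t == 0) return(rep(q, length(z)))
  Tv <- D * t / h^2
  p <- numeric(length(z))
  m <- 0
  repeat {
    M <- pi / 2 * (2 * m + 1)
    term <- (2 / M) * sin(M * (h - z) / h) * exp(-M^2 * Tv)
    p <- p + term
    if (max(abs((2 / M) * exp(-M^2 * Tv))) < tol || m > 2000) break
    m <- m + 1
  }
  q * p
}

#' Average degree of consolidation of the Terzaghi column
#'
#' \eqn{U(T_v) = 1 - \sum (2/M^2) e^{-M^2 T_v}}; U = 0.5 at
#' \eqn{T_v \approx 0.197}.
#'
#' @param Tv Dimensionless time factor \eqn{D t / h^2}.
#' @return Degree of consolidation in (0, 1).
#' @export
consolidation_degree <- function(Tv) {
  vapply(Tv, function(tv) {
    if (tv <= 0) return(0)
    s <- 0
    for (m in 0:2000) {
      M <- pi / 2 * (2 * m + 1)
      term <- (2 / M^2) * exp(-M^2 * tv)
      s <- s + term
      if (term < 1e-14) break
    }
    1 - s
  }, numeric(1))
}
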