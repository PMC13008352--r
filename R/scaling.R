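# Closed-form scaling estimates for poroelastic relaxation in cells.

#' Pore-size scaling of the poroelastic relaxation time with volume change
#'
#' A cell losing volume compresses its hydraulic pores. If intracellular
#' water sits in pores of size \eqn{\xi_0} and the solid fraction is
#' incompressible, a relative volume \eqn{\alpha = V/V_0} changes the pore
#' size by
#' \deqn{\xi/\xi_0 = \big(\alpha + \phi(\alpha - 1)\big)^{1/3},}
#' with \eqn{\phi} the solid-to-fluid volume ratio (0.42-0.6 for typical
#' fluid fractions of 65-75%). Since the poroelastic diffusion constant
#' scales as \eqn{D_p \sim \xi^2}, the fluid efflux time scales as
#' \deqn{t_p/t_{p0} = (\xi/\xi_0)^{-2}.}
#'
#' Note on conventions: \eqn{\alpha} is the *remaining* volume fraction, so
#' a 40% volume decrease means \eqn{\alpha = 0.6}. (Published brackets of
#' 0.72-0.77 for the pore-size ratio correspond to this formula evaluated
#' near \eqn{\alpha = 0.6}, even where the shrinkage magnitude 0.4 is
#' quoted as "alpha"; the formula here is implemented exactly as printed
#' and the ambiguity is documented rather than silently patched.)
#'
#' @param alpha Volume ratio \eqn{V/V_0}, in (0, 1].
#' @param phi Solid-to-fluid volume ratio, > 0.
#' @return A one-row tibble: `xi_ratio`, `tp_ratio`.
#' @examples
#' pore_scaling(alpha = 0.6, phi = 0.42)   # xi ratio ~0.756
#' @export
pore_scaling <- function(alpha, phi) {
  stopifnot(length(alpha) == length(phi) || length(alpha) == 1L ||
              length(phi) == 1L)
  if (any(alpha <= 0) || any(alpha > 1)) abort("`alpha` must lie in (0, 1].")
  if (any(phi <= 0)) abort("`phi` must be positive.")
  arg <- alpha + phi * (alpha - 1)
  if (any(arg <= 0))
    abort("Fully collapsed pores: alpha + phi*(alpha - 1) must be positive.")
  xi <- arg^(1 / 3)
  tibble(alpha = alpha, phi = phi, xi_ratio = xi, tp_ratio = xi^(-2))
}

#' Relaxation-time ratio from a pore-size ratio
#'
#' \eqn{t_p/t_{p0} = (\xi/\xi_0)^{-2}}, the diffusive scaling
#' \eqn{D_p \sim \xi^2}.
#'
#' @param xi_ratio Pore-size ratio \eqn{\xi/\xi_0}, > 0.
#' @return The relaxation-time ratio.
#' @examples
#' tp_ratio_from_xi(c(0.72, 0.77))   # ~1.93, ~1.69
#' @export
tp_ratio_from_xi <- function(xi_ratio) {
  if (any(xi_ratio <= 0)) abort("`xi_ratio` must be positive.")
  xi_ratio^(-2)
}

#' Order-of-magnitude scaling estimates for poroelastic cell mechanics
#'
#' Computes any of the four closed-form estimates used to interpret
#' indentation and injection experiments; only the outputs whose inputs are
#' supplied are returned, and requesting an output without its inputs is an
#' error.
#' \describe{
#'   \item{`L_um`}{indentation-affected length \eqn{L = \sqrt{d\delta}}
#'     (`d` contact diameter, `delta` depth, um).}
#'   \item{`t_p_s`}{fluid efflux time \eqn{t_p = d\delta/D}
#'     (`D` poroelastic diffusion constant, um^2/s).}
#'   \item{`l_um`}{surface-tension screening length \eqn{l = \gamma/E}
#'     (`gamma` cortical tension, N/m; `E` cytoplasm modulus, Pa).}
#'   \item{`tau_z_s`}{vertical relaxation time
#'     \eqn{\tau_z = l\,\delta_z/(kE)} with \eqn{L^2 \sim l\,\delta_z}
#'     (`delta_z` displacement amplitude, um; `kE = D_p`, um^2/s).}
#' }
#'
#' @param d Indentation diameter, um.
#' @param delta Indentation depth, um.
#' @param D Poroelastic diffusion constant, um^2/s.
#' @param gamma Cortical surface tension, N/m.
#' @param E Cytoplasmic Young's modulus, Pa.
#' @param delta_z Vertical displacement amplitude, um.
#' @param k Hydraulic permeability, um^2/(Pa s) (used with `E` as
#'   \eqn{D_p = kE} when `D` is not given for `tau_z_s`).
#' @param outputs Which estimates to compute; default: all whose inputs
#'   are present.
#' @return A one-row tibble with the requested estimates.
#' @examples
#' scaling_estimates(d = 4, delta = 2, D = 40)          # t_p = 0.2 s
#' scaling_estimates(gamma = 1e-3, E = 100)             # l = 10 um
#' @export
scaling_estimates <- function(d = NULL, delta = NULL, D = NULL, gamma = NULL,
                              E = NULL, delta_z = NULL, k = NULL,
                              outputs = NULL) {
  for (nm in c("d", "delta", "D", "gamma", "E", "delta_z", "k")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || v <= 0))
      abort(sprintf("`%s` must be a single positive number.", nm))
  }
  have <- function(...) all(!vapply(list(...), is.null, logical(1)))
  Dp <- if (!is.null(D)) D else if (have(k, E)) k * E else NULL
  avail <- c(L_um = have(d, delta),
             t_p_s = have(d, delta) && !is.null(Dp),
             l_um = have(gamma, E),
             tau_z_s = have(gamma, E, delta_z) && !is.null(Dp))
  if (is.null(outputs)) {
    outputs <- names(avail)[avail]
    if (length(outputs) == 0L)
      abort("No estimate is computable from the supplied inputs.")
  } else {
    bad <- setdiff(outputs, names(avail))
    if (length(bad) > 0L)
      abort(sprintf("Unknown output(s): %s.", paste(bad, collapse = ", ")))
    missing <- outputs[!avail[outputs]]
    if (length(missing) > 0L)
      abort(sprintf("Missing inputs for: %s.", paste(missing, collapse = ", ")))
  }
  out <- list()
  if ("L_um" %in% outputs) out$L_um <- sqrt(d * delta)
  if ("t_p_s" %in% outputs) out$t_p_s <- d * delta / Dp
  if ("l_um" %in% outputs) out$l_um <- gamma / E * 1e6   # m -> um
  if ("tau_z_s" %in% outputs) out$tau_z_s <- (gamma / E * 1e6) * delta_z / Dp
  as_tibble(out)
}
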