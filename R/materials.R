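#' Convert between hydraulic permeability and poroelastic diffusion constant
#'
#' The poroelastic diffusion constant \eqn{D} and the hydraulic permeability
#' \eqn{k} of a linear poroelastic medium are linked through the confined
#' (oedometric) modulus of the drained skeleton,
#' \deqn{D = k \, E \frac{1-\nu}{(1+\nu)(1-2\nu)},}
#' the consolidation coefficient of classical soil mechanics. The literature
#' on cell poroelasticity usually only quotes the scaling \eqn{D \sim kE};
#' this package fixes the oedometric convention and uses it consistently in
#' both directions, so every parameter-recovery result is
#' convention-independent.
#'
#' Units: `k` in um^2/(Pa s), `E` in Pa, `D` in um^2/s. The SI permeability
#' often quoted in m^2/(Pa s) converts as
#' 1 um^2/(Pa s) = 1e-12 m^2/(Pa s) (see [k_si_to_um2()]).
#'
#' @param k Hydraulic permeability, um^2/(Pa s).
#' @param D Poroelastic diffusion constant, um^2/s.
#' @param E Drained Young's modulus, Pa.
#' @param nu Drained Poisson ratio (default 0.3).
#' @return A numeric scalar (or vector, the functions vectorise).
#' @examples
#' poro_D_from_k(0.125, E = 1000)     # um^2/s
#' poro_k_from_D(13, E = 1200)        # um^2/(Pa s)
#' @export
poro_D_from_k <- function(k, E, nu = 0.3) {
  stopifnot(all(k > 0), all(E > 0), all(nu > 0 & nu < 0.5))
  k * oedometric_modulus(E, nu)
}

#' @rdname poro_D_from_k
#' @export
poro_k_from_D <- function(D, E, nu = 0.3) {
  stopifnot(all(D > 0), all(E > 0), all(nu > 0 & nu < 0.5))
  D / oedometric_modulus(E, nu)
}

#' @rdname poro_D_from_k
#' @export
oedometric_modulus <- function(E, nu = 0.3) {
  E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
}

#' Convert hydraulic permeability between SI and package units
#'
#' The package works in um^2/(Pa s); experimental papers usually print
#' m^2/(Pa s). The factor is 1e12: 1.25e-13 m^2/(Pa s) = 0.125 um^2/(Pa s).
#'
#' @param k_si Permeability in m^2/(Pa s).
#' @param k_um2 Permeability in um^2/(Pa s).
#' @return The converted value.
#' @export
k_si_to_um2 <- function(k_si) k_si * 1e12

#' @rdname k_si_to_um2
#' @export
k_um2_to_si <- function(k_um2) k_um2 * 1e-12

#' Define a poroelastic material region
#'
#' A labelled subdomain (cytoplasm or cortex) with drained elastic constants
#' and a transport parameter. Exactly one of `D` (poroelastic diffusion
#' constant, um^2/s) or `k` (hydraulic permeability, um^2/(Pa s)) is given;
#' the other is derived through the oedometric mapping of [poro_D_from_k()].
#'
#' @param label `"cytoplasm"` or `"cortex"`.
#' @param E Drained Young's modulus, Pa.
#' @param nu Drained Poisson ratio, in (0, 0.5).
#' @param D Poroelastic diffusion constant, um^2/s.
#' @param k Hydraulic permeability, um^2/(Pa s).
#' @return A one-row tibble of class `material_region` with columns
#'   `label`, `E_Pa`, `nu`, `D_um2_s`, `k_um2_Pa_s`.
#' @examples
#' material_region("cytoplasm", E = 1800, nu = 0.3, D = 28)
#' @export
material_region <- function(label = c("cytoplasm", "cortex"), E, nu = 0.3,
                            D = NULL, k = NULL) {
  label <- match.arg(label)
  if (!is.numeric(E) || length(E) != 1L || E <= 0)
    abort("`E` must be a single positive number (Pa).")
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0 || nu >= 0.5)
    abort("`nu` must lie strictly between 0 and 0.5.")
  if (is.null(D) == is.null(k))
    abort("Give exactly one of `D` (um^2/s) or `k` (um^2/(Pa s)).")
  if (is.null(D)) {
    if (k <= 0) abort("`k` must be positive.")
    D <- poro_D_from_k(k, E, nu)
  } else {
    if (D <= 0) abort("`D` must be positive.")
    k <- poro_k_from_D(D, E, nu)
  }
  out <- tibble(label = label, E_Pa = E, nu = nu, D_um2_s = D, k_um2_Pa_s = k)
  class(out) <- c("material_region", class(out))
  out
}

#' Bind material regions into a material set
#'
#' @param ... `material_region` rows.
#' @return A tibble with one row per region; labels must be unique.
#' @export
material_set <- function(...) {
  out <- dplyr::bind_rows(...)
  if (anyDuplicated(out$label))
    abort("Material labels must be unique.")
  out
}
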