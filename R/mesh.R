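# Structured axisymmetric meshes: 9-node biquadratic quadrilaterals for
# displacement sharing corner nodes with a 4-node bilinear pressure field
# (Q2-Q1 Taylor-Hood pairing, inf-sup stable for Biot consolidation).

# Geometrically graded 1D breaks covering [0, L]: element size h_fine on the
# `fine` end growing by `ratio` towards h_coarse, never exceeding it.
graded_breaks <- function(L, h_fine, h_coarse = h_fine, fine = c("start", "end"),
                          ratio = 1.4) {
  fine <- match.arg(fine)
  if (h_fine >= L) return(c(0, L))
  sizes <- h_fine
  while (sum(sizes) < L) {
    nxt <- min(tail(sizes, 1) * ratio, h_coarse)
    sizes <- c(sizes, nxt)
  }
  sizes <- sizes * (L / sum(sizes))
  br <- cumsum(c(0, sizes))
  br[length(br)] <- L
  if (fine == "end") br <- L - rev(br)
  br
}

#' Build a finite element mesh for an axisymmetric cell geometry
#'
#' Generates a conforming structured mesh of 9-node quadrilaterals on the
#' (r, z) section of the geometry, with region labels (`cytoplasm` /
#' `cortex`) and tagged boundary segments (`axis`, `bottom`, `side`,
#' `surface`). Meshes are graded: finer near the axis and the top surface,
#' where indenters, pipettes and sinks act. When a cortex layer is present
#' it is resolved by at least two element layers through its thickness.
#'
#' For the `elliptical_cap` shape the dome profile
#' \eqn{h(r) = h_0\sqrt{1 - (r/a)^2}} collapses to zero thickness at the
#' rim; the mesh is clipped at the radius where the local height falls
#' below a minimum (three cortex thicknesses, or 8% of the apex height),
#' which avoids degenerate elements while leaving the mechanically active
#' footprint intact.
#'
#' @param geometry A [scenario_geometry()].
#' @param resolution Target element size away from refinement zones, um.
#' @param fine_fraction Ratio of the fine element size (near axis/surface)
#'   to `resolution`; default 1/3.
#' @return A list of class `poro_mesh`: node coordinates, displacement and
#'   pressure connectivity, element regions, boundary edge table.
#' @examples
#' m <- build_mesh(scenario_geometry("disk", 20, 20), resolution = 2)
#' mesh_area(m)   # 400 um^2 section area
#' @export
build_mesh <- function(geometry, resolution, fine_fraction = 1 / 3) {
  stopifnot(inherits(geometry, "scenario_geometry"))
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    abort("`resolution` must be a single positive number (um).")
  if (resolution > 2 * min(geometry$radius, geometry$thickness))
    abort("`resolution` exceeds twice the smallest feature size.")
  tc <- geometry$cortex_thickness
  if (tc >= geometry$thickness)
    abort("Degenerate geometry: cortex thickness >= total thickness.")

  h_fine <- resolution * fine_fraction
  if (geometry$shape == "column") {
    r_br <- c(0, geometry$radius)
    z_br <- graded_breaks(geometry$thickness, h_fine, resolution, fine = "end")
  } else {
    fine_r <- max(geometry$contact_radius,
                  sqrt(geometry$indenter_radius * 2))  # typical contact patch
    r_core <- seq(0, fine_r, by = h_fine)
    if (tail(r_core, 1) < fine_r) r_core <- c(r_core, fine_r)
    r_rest <- graded_breaks(geometry$radius - fine_r, h_fine, resolution,
                            fine = "start")
    r_br <- c(r_core, fine_r + r_rest[-1])
  }

  if (geometry$shape == "disk") {
    z_br <- graded_breaks(geometry$thickness, h_fine, resolution, fine = "end")
  } else if (geometry$shape == "elliptical_cap") {
    h_min <- max(3 * tc, 0.08 * geometry$thickness)
    r_max <- geometry$radius * sqrt(1 - (h_min / geometry$thickness)^2)
    r_br <- r_br[r_br < r_max]
    r_br <- c(r_br, r_max)
    # relative breaks through the (local) cytoplasm height; cortex appended
    nz_c <- max(3, ceiling(geometry$thickness / resolution) + 1)
    s_br <- seq(0, 1, length.out = nz_c + 1)
    if (tc > 0) {
      nz_k <- max(2, ceiling(tc / h_fine))
      z_br <- list(s_cyto = s_br, n_cortex = nz_k)
    } else {
      z_br <- list(s_cyto = s_br, n_cortex = 0L)
    }
  }

  if (geometry$shape %in% c("disk", "column")) {
    if (tc > 0) {
      # peel the cortex off the top of the uniform stack
      z_br <- z_br[z_br < geometry$thickness - tc]
      z_br <- c(z_br, geometry$thickness - tc)
      nk <- max(2, ceiling(tc / h_fine))
      z_br <- c(z_br, geometry$thickness - tc + seq_len(nk) * tc / nk)
      cortex_from <- length(z_br) - nk  # first cortex element layer index
    } else cortex_from <- Inf
    mesh <- structured_mesh_rect(r_br, z_br, cortex_from)
  } else {
    mesh <- structured_mesh_cap(geometry, r_br, z_br$s_cyto, z_br$n_cortex)
  }
  mesh$geometry <- geometry
  mesh$resolution <- resolution
  class(mesh) <- "poro_mesh"
  mesh
}

# Rectangular (disk/column) structured mesh from break vectors; element rows
# with layer index >= cortex_from are labelled cortex.
structured_mesh_rect <- function(r_br, z_br, cortex_from = Inf) {
  nr <- length(r_br) - 1L; nz <- length(z_br) - 1L
  rg <- midpoint_refine(r_br); zg <- midpoint_refine(z_br)
  ni <- length(rg); nj <- length(zg)
  nodes <- cbind(r = rep(rg, times = nj), z = rep(zg, each = ni))
  finish_structured(nodes, ni, nj, nr, nz,
                    region_fun = function(a, b) ifelse(b >= cortex_from,
                                                       "cortex", "cytoplasm"))
}

# Elliptical cap: radial breaks r_br; per column the cytoplasm occupies
# [0, h(r) - tc] split at relative breaks s_cyto, the cortex (n_cortex
# element layers) occupies [h(r) - tc, h(r)].
structured_mesh_cap <- function(geometry, r_br, s_cyto, n_cortex) {
  tc <- geometry$cortex_thickness
  nr <- length(r_br) - 1L
  nz1 <- length(s_cyto) - 1L
  nz <- nz1 + n_cortex
  rg <- midpoint_refine(r_br)
  ni <- length(rg); nj <- 2L * nz + 1L
  zmat <- matrix(0, ni, nj)
  for (ii in seq_len(ni)) {
    h <- cap_height(geometry, min(rg[ii], geometry$radius))
    h_cyto <- h - tc
    z_cy <- h_cyto * s_cyto
    z_all <- if (n_cortex > 0) {
      c(z_cy, h_cyto + seq_len(n_cortex) * tc / n_cortex)
    } else z_cy
    zmat[ii, ] <- midpoint_refine(z_all)
  }
  nodes <- cbind(r = rep(rg, times = nj), z = as.vector(zmat))
  finish_structured(nodes, ni, nj, nr, nz,
                    region_fun = function(a, b) ifelse(b > nz1,
                                                       "cortex", "cytoplasm"))
}

midpoint_refine <- function(br) {
  out <- numeric(2L * length(br) - 1L)
  out[seq(1, length(out), by = 2)] <- br
  out[seq(2, length(out), by = 2)] <- (br[-1] + br[-length(br)]) / 2
  out
}

# Shared connectivity/boundary construction for an ni x nj node grid holding
# nr x nz biquadratic elements. Q9 local order: corners (bl, br, tr, tl),
# mid-edges (bottom, right, top, left), centre.
finish_structured <- function(nodes, ni, nj, nr, nz, region_fun) {
  idx <- function(i, j) (j - 1L) * ni + i
  conn <- matrix(0L, nr * nz, 9L)
  region <- character(nr * nz)
  e <- 0L
  for (b in seq_len(nz)) {
    for (a in seq_len(nr)) {
      e <- e + 1L
      i0 <- 2L * a - 1L; j0 <- 2L * b - 1L
      conn[e, ] <- c(idx(i0, j0), idx(i0 + 2L, j0), idx(i0 + 2L, j0 + 2L),
                     idx(i0, j0 + 2L), idx(i0 + 1L, j0), idx(i0 + 2L, j0 + 1L),
                     idx(i0 + 1L, j0 + 2L), idx(i0, j0 + 1L),
                     idx(i0 + 1L, j0 + 1L))
      region[e] <- region_fun(a, b)
    }
  }
  # pressure nodes = corner grid nodes (odd i, odd j)
  odd_i <- seq(1L, ni, by = 2L); odd_j <- seq(1L, nj, by = 2L)
  pnode <- as.vector(outer(odd_i, (odd_j - 1L) * ni, `+`))
  pmap <- integer(nrow(nodes)); pmap[pnode] <- seq_along(pnode)
  pconn <- matrix(pmap[conn[, 1:4]], ncol = 4L)

  eidx <- function(a, b) (b - 1L) * nr + a
  bnd <- dplyr::bind_rows(
    tibble(elem = eidx(seq_len(nr), 1L), edge = 1L, tag = "bottom"),
    tibble(elem = eidx(nr, seq_len(nz)), edge = 2L, tag = "side"),
    tibble(elem = eidx(seq_len(nr), nz), edge = 3L, tag = "surface"),
    tibble(elem = eidx(1L, seq_len(nz)), edge = 4L, tag = "axis"))

  list(nodes = nodes, conn = conn, region = region,
       pnode = pnode, pmap = pmap, pconn = pconn,
       boundary = bnd, nr = nr, nz = nz, ni = ni, nj = nj)
}

#' Mesh section area by region
#'
#' Integrates the (r, z) cross-section area of the mesh with the element
#' quadrature rule (no axisymmetric weight), per region.
#'
#' @param mesh A `poro_mesh`.
#' @return A tibble with `region` and `area_um2`.
#' @export
mesh_area <- function(mesh) {
  qd <- quad_q9()
  areas <- vapply(seq_len(nrow(mesh$conn)), function(e) {
    X <- mesh$nodes[mesh$conn[e, ], , drop = FALSE]
    sum(vapply(seq_len(nrow(qd$pts)), function(g) {
      J <- t(qd$dN[[g]]) %*% X
      qd$w[g] * abs(det(J))
    }, numeric(1)))
  }, numeric(1))
  out <- tibble(region = mesh$region, area = areas) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(area_um2 = sum(.data$area), .groups = "drop") |>
    dplyr::rename(region = "region")
  if (nrow(out) == 1 && out$region[1] == "cytoplasm") return(out)
  out
}

#' @export
print.poro_mesh <- function(x, ...) {
  cat(sprintf("<poro_mesh> %s: %d elements (%d x %d), %d nodes, %d pressure nodes\n",
              x$geometry$shape, nrow(x$conn), x$nr, x$nz,
              nrow(x$nodes), length(x$pnode)))
  invisible(x)
}

# Edge-local node triples per edge id.
edge_local_nodes <- function(edge) {
  switch(edge, `1` = c(1L, 5L, 2L), `2` = c(2L, 6L, 3L),
         `3` = c(4L, 7L, 3L), `4` = c(1L, 8L, 4L))
}

#' Nodes on a tagged boundary segment
#'
#' @param mesh A `poro_mesh`.
#' @param tag One of `"axis"`, `"bottom"`, `"side"`, `"surface"`.
#' @return Node indices ordered by radius then height.
#' @export
boundary_nodes <- function(mesh, tag) {
  bnd <- mesh$boundary[mesh$boundary$tag == tag, ]
  ids <- unique(unlist(lapply(seq_len(nrow(bnd)), function(i) {
    mesh$conn[bnd$elem[i], edge_local_nodes(bnd$edge[i])]
  })))
  ids[order(mesh$nodes[ids, 1], mesh$nodes[ids, 2])]
}
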