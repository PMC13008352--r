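# Transient Biot solver: implicit (backward Euler) time stepping of the
# coupled effective-stress / Darcy continuity system, with a tiny specific
# storage regularisation so that the pure-constant pressure mode stays
# well-posed when every boundary is impermeable.

#' Specify boundary conditions for an axisymmetric solve
#'
#' Each tagged boundary segment (`bottom`, `side`, `surface`) carries one
#' mechanical and one hydraulic condition; the symmetry axis automatically
#' gets \eqn{u_r = 0} and no-flux. Mechanical conditions: `"fixed"` (no
#' slip), `"free"`, `"roller_r"` / `"roller_z"` (single-component
#' constraint), or a list
#' `list(type = "indent", depth, ramp_time, radius)` prescribing a ramped
#' vertical displacement over the contact patch \eqn{r \le} `radius`
#' (frictionless), or `list(type = "traction", value, ramp_time = 0)`
#' applying a vertical surface traction (Pa, positive upward). Hydraulic
#' conditions: `"impermeable"` or
#' `list(type = "pressure", value, ramp_time = 0, where, radius)` with
#' `where` one of `"all"`, `"within_radius"`, `"outside_radius"`.
#'
#' @param mech Named list of mechanical conditions keyed by boundary tag.
#' @param hyd Named list of hydraulic conditions keyed by boundary tag.
#' @return A list of class `boundary_spec`.
#' @examples
#' boundary_spec(
#'   mech = list(bottom = "fixed", side = "free",
#'               surface = list(type = "indent", depth = 2,
#'                              ramp_time = 0.01, radius = 2)),
#'   hyd = list(surface = list(type = "pressure", value = 0,
#'                             where = "outside_radius", radius = 2)))
#' @export
boundary_spec <- function(mech = list(), hyd = list()) {
  known <- c("bottom", "side", "surface")
  for (nm in names(mech)) if (!nm %in% known)
    abort(sprintf("Unknown boundary tag '%s'.", nm))
  for (nm in names(hyd)) if (!nm %in% known)
    abort(sprintf("Unknown boundary tag '%s'.", nm))
  for (tag in known) {
    if (is.null(mech[[tag]])) mech[[tag]] <- "free"
    if (is.null(hyd[[tag]])) hyd[[tag]] <- "impermeable"
  }
  structure(list(mech = mech, hyd = hyd), class = "boundary_spec")
}

ramp_factor <- function(t, ramp_time) {
  if (ramp_time <= 0) as.numeric(t > 0) else pmin(t / ramp_time, 1)
}

#' Ramp-and-hold time grid
#'
#' Uniform steps through the ramp phase followed by geometrically growing
#' steps through the hold, the standard schedule for consolidation problems
#' whose dynamics slow down as pressure gradients decay.
#'
#' @param ramp_time Ramp duration, s (0 for a step load).
#' @param t_end Final time, s.
#' @param n_ramp Number of ramp steps.
#' @param dt0 First hold step, s (default: ramp step or `t_end/200`).
#' @param growth Geometric growth factor of hold steps.
#' @return Strictly increasing numeric vector starting at 0.
#' @export
time_grid_ramp_hold <- function(ramp_time, t_end, n_ramp = 8, dt0 = NULL,
                                growth = 1.35) {
  stopifnot(t_end > ramp_time, ramp_time >= 0)
  tg <- if (ramp_time > 0) seq(0, ramp_time, length.out = n_ramp + 1) else 0
  if (is.null(dt0)) dt0 <- if (ramp_time > 0) ramp_time / n_ramp else t_end / 200
  t <- ramp_time
  dt <- dt0
  while (t < t_end) {
    t <- min(t + dt, t_end)
    tg <- c(tg, t)
    dt <- dt * growth
  }
  tg
}

#' Solve the transient Biot consolidation problem
#'
#' Backward-Euler integration of the coupled momentum balance (drained
#' effective stress minus pore pressure) and fluid continuity (Darcy flux)
#' equations on an axisymmetric mesh. Biot coefficient 1, incompressible
#' constituents; a small specific storage (`storage`, 1/Pa) regularises the
#' constant-pressure mode. Stiffness scales linearly in each region's `E`
#' and the mobility in each region's `k`, so repeated solves on one mesh
#' (as in parameter fitting) reuse a cached unit-parameter assembly.
#'
#' @param mesh A [build_mesh()] result.
#' @param materials A tibble from [material_set()] (or one
#'   [material_region()]); must cover every region label of the mesh.
#' @param bcs A [boundary_spec()].
#' @param time_grid Strictly increasing times starting at 0, s.
#' @param initial_pressure Initial uniform pore pressure, Pa.
#' @param cache Optional precomputed assembly from a previous solve on the
#'   same mesh (retrieved via `attr(solution, "cache")`).
#' @param ptol Optional maximum pore-pressure change per increment, Pa;
#'   when set, steps exceeding it are bisected (up to 6 levels).
#' @param storage Specific storage regularisation, 1/Pa.
#' @return A `poro_solution`: times, displacement field `U` (2 x nodes by
#'   time), pressure `P` (pressure nodes by time), `force` (indenter
#'   reaction, nN), mesh and material references.
#' @export
solve_transient <- function(mesh, materials, bcs, time_grid,
                            initial_pressure = 0, cache = NULL,
                            ptol = NULL, storage = 1e-9) {
  stopifnot(inherits(mesh, "poro_mesh"), inherits(bcs, "boundary_spec"))
  if (!all(sort(unique(mesh$region)) %in% materials$label))
    abort("`materials` must cover every region present in the mesh.")
  if (length(time_grid) < 2L || time_grid[1] != 0 ||
      any(diff(time_grid) <= 0))
    abort("`time_grid` must be strictly increasing and start at 0.")

  nu_by_region <- setNames(as.list(materials$nu), materials$label)
  if (is.null(cache)) cache <- fem_cache(mesh, nu_by_region)
  nn <- cache$nn; np <- cache$np
  E_by <- setNames(materials$E_Pa, materials$label)
  k_by <- setNames(materials$k_um2_Pa_s, materials$label)
  K <- Reduce(`+`, lapply(cache$mesh_regions,
                          function(rg) E_by[[rg]] * cache$K1[[rg]]))
  H <- Reduce(`+`, lapply(cache$mesh_regions,
                          function(rg) k_by[[rg]] * cache$H1[[rg]]))
  Q <- cache$Q
  Mp <- cache$Mp

  con <- collect_constraints(mesh, bcs)
  if (length(con$udof) == 0L)
    abort("Singular system: no mechanical constraint anywhere (rigid-body motion).")
  loads <- collect_loads(mesh, bcs)

  ndof <- 2L * nn + np
  cdof <- c(con$udof, 2L * nn + con$pdof)
  free <- setdiff(seq_len(ndof), cdof)

  nt <- length(time_grid)
  U <- matrix(0, 2L * nn, nt)
  P <- matrix(initial_pressure, np, nt)
  force <- numeric(nt)
  max_dp <- numeric(nt)

  x_prev <- c(U[, 1], P[, 1])
  fact_cache <- new.env(parent = emptyenv())
  Afull_cache <- new.env(parent = emptyenv())

  get_system <- function(dt) {
    key <- sprintf("%.12g", dt)
    if (!is.null(Afull_cache[[key]])) return(Afull_cache[[key]])
    A <- rbind(cbind(K, -Q), cbind(-Matrix::t(Q), -(dt * H + storage * Mp)))
    A <- methods::as(A, "CsparseMatrix")
    sys <- list(A = A, Aff = A[free, free, drop = FALSE],
                Afc = A[free, cdof, drop = FALSE])
    Afull_cache[[key]] <- sys
    sys
  }
  get_fact <- function(dt, Aff) {
    key <- sprintf("%.12g", dt)
    if (is.null(fact_cache[[key]])) {
      f <- tryCatch(Matrix::lu(Aff), error = function(e)
        abort(paste0("Singular system: ", conditionMessage(e))))
      fact_cache[[key]] <- f
    }
    fact_cache[[key]]
  }

  step_once <- function(x_prev, t0, t1) {
    dt <- t1 - t0
    sys <- get_system(dt)
    u_prev <- x_prev[seq_len(2L * nn)]
    p_prev <- x_prev[2L * nn + seq_len(np)]
    f <- load_vector(loads, t1, 2L * nn)
    b <- c(f, as.vector(-(Matrix::crossprod(Q, u_prev))) -
             storage * as.vector(Mp %*% p_prev))
    xc <- c(constraint_values(con, t1, "u"), constraint_values(con, t1, "p"))
    x <- numeric(ndof)
    x[cdof] <- xc
    rhs <- b[free] - as.vector(sys$Afc %*% xc)
    x[free] <- as.vector(Matrix::solve(get_fact(dt, sys$Aff), rhs))
    resid_c <- as.vector(sys$A[cdof, , drop = FALSE] %*% x) - b[cdof]
    list(x = x, resid_c = resid_c)
  }

  for (n in 2:nt) {
    t0 <- time_grid[n - 1]; t1 <- time_grid[n]
    nsub <- 1L
    repeat {
      xp <- x_prev
      tt <- t0
      ok <- TRUE
      for (s in seq_len(nsub)) {
        tn <- t0 + (t1 - t0) * s / nsub
        st <- step_once(xp, tt, tn)
        dp <- max(abs(st$x[2L * nn + seq_len(np)] - xp[2L * nn + seq_len(np)]))
        if (!is.null(ptol) && dp > ptol && nsub < 64L) { ok <- FALSE; break }
        xp <- st$x; tt <- tn
      }
      if (ok) break
      nsub <- nsub * 2L
    }
    x_prev <- xp
    U[, n] <- x_prev[seq_len(2L * nn)]
    P[, n] <- x_prev[2L * nn + seq_len(np)]
    max_dp[n] <- max(abs(P[, n] - P[, n - 1]))
    # reaction force on prescribed-displacement (indenter) dofs
    if (length(con$indent_dofs) > 0L) {
      ri <- match(con$indent_dofs, cdof)
      force[n] <- -sum(st$resid_c[ri]) * .PA_UM2_TO_NN
    }
  }

  out <- list(times = time_grid, U = U, P = P, force = force,
              mesh = mesh, materials = materials, bcs = bcs,
              k_by_region = as.list(k_by), E_by_region = as.list(E_by),
              max_dp = max_dp, initial_pressure = initial_pressure)
  class(out) <- "poro_solution"
  attr(out, "cache") <- cache
  out
}

# ---- constraint bookkeeping -------------------------------------------------

collect_constraints <- function(mesh, bcs) {
  nn <- nrow(mesh$nodes)
  udof <- integer(0); uval <- numeric(0); uramp <- numeric(0)
  pdof <- integer(0); pval <- numeric(0); pramp <- numeric(0)
  indent_dofs <- integer(0)

  axis_nodes <- boundary_nodes(mesh, "axis")
  udof <- c(udof, 2L * axis_nodes - 1L)
  uval <- c(uval, numeric(length(axis_nodes)))
  uramp <- c(uramp, numeric(length(axis_nodes)))

  for (tag in c("bottom", "side", "surface")) {
    nodes <- boundary_nodes(mesh, tag)
    mc <- bcs$mech[[tag]]
    if (is.character(mc)) {
      add <- switch(mc,
        fixed = list(dofs = c(2L * nodes - 1L, 2L * nodes)),
        roller_r = list(dofs = 2L * nodes - 1L),
        roller_z = list(dofs = 2L * nodes),
        free = list(dofs = integer(0)),
        abort(sprintf("Unknown mechanical condition '%s'.", mc)))
      udof <- c(udof, add$dofs)
      uval <- c(uval, numeric(length(add$dofs)))
      uramp <- c(uramp, numeric(length(add$dofs)))
    } else if (identical(mc$type, "indent")) {
      sel <- nodes[mesh$nodes[nodes, 1] <= mc$radius + 1e-9]
      if (length(sel) < 2L)
        abort("Indenter contact patch resolved by fewer than 2 nodes; refine the mesh.")
      d <- 2L * sel
      udof <- c(udof, d)
      uval <- c(uval, rep(-abs(mc$depth), length(d)))
      uramp <- c(uramp, rep(mc$ramp_time, length(d)))
      indent_dofs <- c(indent_dofs, d)
    } else if (identical(mc$type, "traction")) {
      # natural condition, handled by collect_loads()
    } else abort("Unknown mechanical condition.")

    hc <- bcs$hyd[[tag]]
    if (is.list(hc) && identical(hc$type, "pressure")) {
      pn <- nodes[mesh$pmap[nodes] > 0L]
      r <- mesh$nodes[pn, 1]
      where <- if (is.null(hc$where)) "all" else hc$where
      keep <- switch(where,
        all = rep(TRUE, length(pn)),
        within_radius = r <= hc$radius + 1e-9,
        outside_radius = r > hc$radius + 1e-9,
        abort(sprintf("Unknown hydraulic restriction '%s'.", where)))
      pn <- pn[keep]
      pdof <- c(pdof, mesh$pmap[pn])
      pval <- c(pval, rep(hc$value, length(pn)))
      pramp <- c(pramp, rep(if (is.null(hc$ramp_time)) 0 else hc$ramp_time,
                            length(pn)))
    } else if (is.list(hc) && identical(hc$type, "pressure_split")) {
      # sink value inside the contact radius, reservoir value outside
      pn <- nodes[mesh$pmap[nodes] > 0L]
      r <- mesh$nodes[pn, 1]
      inner <- r <= hc$radius + 1e-9
      pdof <- c(pdof, mesh$pmap[pn])
      pval <- c(pval, ifelse(inner, hc$inner_value, hc$outer_value))
      pramp <- c(pramp, rep(if (is.null(hc$ramp_time)) 0 else hc$ramp_time,
                            length(pn)))
    } else if (!identical(hc, "impermeable"))
      abort("Unknown hydraulic condition.")
  }
  # de-duplicate displacement constraints (axis corner shared etc.)
  dd <- !duplicated(udof)
  list(udof = udof[dd], uval = uval[dd], uramp = uramp[dd],
       pdof = pdof, pval = pval, pramp = pramp,
       indent_dofs = unique(indent_dofs))
}

constraint_values <- function(con, t, which = c("u", "p")) {
  which <- match.arg(which)
  if (which == "u") {
    if (length(con$udof) == 0L) return(numeric(0))
    con$uval * vapply(con$uramp, function(rt) ramp_factor(t, rt), numeric(1))
  } else {
    if (length(con$pdof) == 0L) return(numeric(0))
    con$pval * vapply(con$pramp, function(rt) ramp_factor(t, rt), numeric(1))
  }
}

collect_loads <- function(mesh, bcs) {
  loads <- list()
  for (tag in c("bottom", "side", "surface")) {
    mc <- bcs$mech[[tag]]
    if (is.list(mc) && identical(mc$type, "traction")) {
      f <- traction_load(mesh, tag, mc$value, direction = "z")
      loads[[length(loads) + 1L]] <-
        list(f = f, ramp_time = if (is.null(mc$ramp_time)) 0 else mc$ramp_time)
    }
  }
  loads
}

load_vector <- function(loads, t, ndof_u) {
  f <- numeric(ndof_u)
  for (ld in loads) f <- f + ld$f * ramp_factor(t, ld$ramp_time)
  f
}

# ---- solution accessors -----------------------------------------------------

#' @export
print.poro_solution <- function(x, ...) {
  cat(sprintf("<poro_solution> %d nodes, %d times (0 to %g s), max |u_z| %.4g um\n",
              nrow(x$mesh$nodes), length(x$times), max(x$times),
              max(abs(x$U[seq(2, nrow(x$U), by = 2), ]))))
  invisible(x)
}

#' Surface displacement profile of a transient solution
#'
#' @param solution A `poro_solution`.
#' @param time Time at which to report, s (default: final); the closest
#'   stored time is used.
#' @return Tibble with `r_um`, `u_r_um`, `u_z_um`, `t_s`.
#' @export
surface_displacement <- function(solution, time = NULL) {
  idx <- time_index(solution, time)
  sn <- boundary_nodes(solution$mesh, "surface")
  tibble(r_um = solution$mesh$nodes[sn, 1],
         u_r_um = solution$U[2L * sn - 1L, idx],
         u_z_um = solution$U[2L * sn, idx],
         t_s = solution$times[idx])
}

#' Probe displacement time courses
#'
#' Interpolates the vertical surface displacement at given radial distances
#' from the stimulus axis, at every stored time.
#'
#' @param solution A `poro_solution`.
#' @param probes Radial probe positions, um (undeformed configuration).
#' @return Long tibble with `probe_um`, `t_s`, `u_z_um`.
#' @export
probe_displacement <- function(solution, probes) {
  sn <- boundary_nodes(solution$mesh, "surface")
  r <- solution$mesh$nodes[sn, 1]
  if (any(probes < min(r) - 1e-9 | probes > max(r) + 1e-9))
    abort("Probe distances fall outside the meshed surface footprint.")
  purrr::map_dfr(seq_along(solution$times), function(i) {
    uz <- solution$U[2L * sn, i]
    tibble(probe_um = probes, t_s = solution$times[i],
           u_z_um = approx(r, uz, xout = probes, rule = 2)$y)
  })
}

#' Pore pressure profile along a horizontal line
#'
#' @param solution A `poro_solution`.
#' @param z Height of the sampling line, um; default mid-height of the
#'   pressure nodes. The closest row of pressure nodes is used.
#' @param time Reporting time, s (default final).
#' @return Tibble with `r_um`, `z_um`, `p_Pa`, `t_s`.
#' @export
pressure_profile <- function(solution, z = NULL, time = NULL) {
  idx <- time_index(solution, time)
  mesh <- solution$mesh
  coords <- mesh$nodes[mesh$pnode, , drop = FALSE]
  if (is.null(z)) z <- stats::median(coords[, 2])
  # snap to the nearest structured row of pressure nodes per radial column
  out <- tibble(r_um = coords[, 1], z_um = coords[, 2],
                p_Pa = solution$P[, idx]) |>
    dplyr::mutate(col = round(.data$r_um, 6)) |>
    dplyr::group_by(.data$col) |>
    dplyr::slice_min(abs(.data$z_um - z), n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-"col") |>
    dplyr::arrange(.data$r_um)
  out$t_s <- solution$times[idx]
  out
}

time_index <- function(solution, time = NULL) {
  if (is.null(time)) return(length(solution$times))
  which.min(abs(solution$times - time))
}

#' Element-wise Darcy flux field
#'
#' Evaluates \eqn{q = -k \nabla p} at element centroids.
#'
#' @param solution A `poro_solution`.
#' @param time Reporting time, s (default final).
#' @return Tibble with centroid `r_um`, `z_um`, flux components
#'   `q_r_um_s`, `q_z_um_s` and `region`.
#' @export
darcy_flux <- function(solution, time = NULL) {
  idx <- time_index(solution, time)
  mesh <- solution$mesh
  pvals <- solution$P[, idx]
  ne <- nrow(mesh$conn)
  out <- purrr::map_dfr(seq_len(ne), function(e) {
    X <- mesh$nodes[mesh$conn[e, ], , drop = FALSE]
    J <- t(dshape_q9(0, 0)) %*% X
    dNpdx <- dshape_q4(0, 0) %*% solve(t(J))
    gradp <- as.vector(t(dNpdx) %*% pvals[mesh$pconn[e, ]])
    k <- solution$k_by_region[[mesh$region[e]]]
    ctr <- as.vector(shape_q9(0, 0) %*% X)
    tibble(r_um = ctr[1], z_um = ctr[2],
           q_r_um_s = -k * gradp[1], q_z_um_s = -k * gradp[2],
           region = mesh$region[e])
  })
  out$t_s <- solution$times[idx]
  out
}

#' Net Darcy outflux through a tagged boundary segment
#'
#' Integrates the normal Darcy flux over the boundary (axisymmetric
#' measure), giving the volumetric rate leaving the domain, um^3/s.
#'
#' @param solution A `poro_solution`.
#' @param tag Boundary tag (`"bottom"`, `"side"`, `"surface"`).
#' @param time Reporting time, s (default final).
#' @param within_radius,outside_radius Optional radial restriction of the
#'   segment, um.
#' @return Volumetric outflux, um^3/s (positive = leaving).
#' @export
boundary_outflux <- function(solution, tag, time = NULL,
                             within_radius = NULL, outside_radius = NULL) {
  idx <- time_index(solution, time)
  boundary_flux_restricted(solution, tag, idx, within_radius, outside_radius)
}
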