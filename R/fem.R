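# Axisymmetric Biot consolidation FEM kernel.
#
# Weak form (u = solid displacement, p = pore pressure above ambient,
# Biot coefficient 1, incompressible constituents):
#   momentum:   int eps(w):C:eps(u) dV - int p div(w) dV = int t.w dA
#   continuity: int div(du/dt) q dV + int k grad(p).grad(q) dV = boundary flux
# Effective stress sigma' = C:eps acts on the drained skeleton; total stress
# sigma = sigma' - p I. All volume integrals carry the 2*pi*r axisymmetric
# measure; strain components ordered (e_rr, e_zz, g_rz, e_tt).

# 1D quadratic Lagrange shapes on [-1, 1] and derivatives
shape1q <- function(x) c(x * (x - 1) / 2, 1 - x^2, x * (x + 1) / 2)
dshape1q <- function(x) c(x - 0.5, -2 * x, x + 0.5)
shape1l <- function(x) c((1 - x) / 2, (1 + x) / 2)
dshape1l <- function(x) c(-0.5, 0.5)

# Q9 node order: corners (-1,-1),(1,-1),(1,1),(-1,1); mid-edges bottom,
# right, top, left; centre. Tensor index (i along xi, j along eta).
.q9_ix <- c(1L, 3L, 3L, 1L, 2L, 3L, 2L, 1L, 2L)
.q9_jx <- c(1L, 1L, 3L, 3L, 1L, 2L, 3L, 2L, 2L)
.q4_ix <- c(1L, 2L, 2L, 1L)
.q4_jx <- c(1L, 1L, 2L, 2L)

shape_q9 <- function(xi, eta) {
  sx <- shape1q(xi); sy <- shape1q(eta)
  sx[.q9_ix] * sy[.q9_jx]
}
dshape_q9 <- function(xi, eta) {
  sx <- shape1q(xi); sy <- shape1q(eta)
  dx <- dshape1q(xi); dy <- dshape1q(eta)
  cbind(dx[.q9_ix] * sy[.q9_jx], sx[.q9_ix] * dy[.q9_jx])
}
shape_q4 <- function(xi, eta) {
  sx <- shape1l(xi); sy <- shape1l(eta)
  sx[.q4_ix] * sy[.q4_jx]
}
dshape_q4 <- function(xi, eta) {
  sx <- shape1l(xi); sy <- shape1l(eta)
  dx <- dshape1l(xi); dy <- dshape1l(eta)
  cbind(dx[.q4_ix] * sy[.q4_jx], sx[.q4_ix] * dy[.q4_jx])
}

# 3x3 Gauss rule with pre-evaluated shape data (memoised per session)
quad_q9 <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g1 <- c(-sqrt(3 / 5), 0, sqrt(3 / 5)); w1 <- c(5, 8, 5) / 9
    pts <- as.matrix(expand.grid(xi = g1, eta = g1))
    w <- as.vector(outer(w1, w1))
    N <- lapply(seq_len(nrow(pts)), function(i) shape_q9(pts[i, 1], pts[i, 2]))
    dN <- lapply(seq_len(nrow(pts)), function(i) dshape_q9(pts[i, 1], pts[i, 2]))
    Np <- lapply(seq_len(nrow(pts)), function(i) shape_q4(pts[i, 1], pts[i, 2]))
    dNp <- lapply(seq_len(nrow(pts)), function(i) dshape_q4(pts[i, 1], pts[i, 2]))
    cache <<- list(pts = pts, w = w, N = N, dN = dN, Np = Np, dNp = dNp)
    cache
  }
})

# Isotropic drained elasticity matrix for (e_rr, e_zz, g_rz, e_tt), E = 1.
elastic_matrix_unit <- function(nu) {
  lam <- nu / ((1 + nu) * (1 - 2 * nu))
  mu <- 1 / (2 * (1 + nu))
  D <- matrix(lam, 4, 4)
  D[3, ] <- 0; D[, 3] <- 0
  diag(D) <- c(lam + 2 * mu, lam + 2 * mu, mu, lam + 2 * mu)
  D
}

# Assemble unit-parameter global matrices once per mesh:
#   K1[[region]]: stiffness for E = 1 (given region nu)
#   H1[[region]]: pressure Laplacian for k = 1
#   Q: displacement-pressure coupling (independent of material)
# Stored as sparse dgCMatrix; K(E) = sum_r E_r K1_r etc.
fem_cache <- function(mesh, nu_by_region) {
  qd <- quad_q9()
  ne <- nrow(mesh$conn)
  nn <- nrow(mesh$nodes)
  np <- length(mesh$pnode)
  regions <- unique(mesh$region)
  Dm <- lapply(regions, function(rg) elastic_matrix_unit(nu_by_region[[rg]]))
  names(Dm) <- regions

  trip <- function() list(i = vector("list", ne), j = vector("list", ne),
                          x = vector("list", ne))
  tK <- setNames(lapply(regions, function(r) trip()), regions)
  tH <- setNames(lapply(regions, function(r) trip()), regions)
  tQ <- trip()
  tM <- trip()

  for (e in seq_len(ne)) {
    en <- mesh$conn[e, ]
    X <- mesh$nodes[en, , drop = FALSE]
    rg <- mesh$region[e]
    pdof <- mesh$pconn[e, ]
    Ke <- matrix(0, 18, 18)
    He <- matrix(0, 4, 4)
    Qe <- matrix(0, 18, 4)
    Me <- matrix(0, 4, 4)
    for (g in seq_along(qd$w)) {
      J <- t(qd$dN[[g]]) %*% X
      detJ <- det(J)
      if (detJ <= 0) abort(sprintf("Degenerate element %d (non-positive Jacobian).", e))
      Jinv_t <- solve(t(J))
      dNdx <- qd$dN[[g]] %*% Jinv_t          # 9 x 2 (d/dr, d/dz)
      dNpdx <- qd$dNp[[g]] %*% Jinv_t        # 4 x 2
      Nv <- qd$N[[g]]
      r <- sum(Nv * X[, 1])
      wgt <- qd$w[g] * detJ * 2 * pi * r
      B <- matrix(0, 4, 18)
      iur <- seq(1, 18, by = 2); iuz <- seq(2, 18, by = 2)
      B[1, iur] <- dNdx[, 1]
      B[2, iuz] <- dNdx[, 2]
      B[3, iur] <- dNdx[, 2]; B[3, iuz] <- dNdx[, 1]
      B[4, iur] <- Nv / r
      Ke <- Ke + wgt * (t(B) %*% Dm[[rg]] %*% B)
      divu <- numeric(18)
      divu[iur] <- dNdx[, 1] + Nv / r
      divu[iuz] <- dNdx[, 2]
      Qe <- Qe + wgt * (divu %*% t(qd$Np[[g]]))
      He <- He + wgt * (dNpdx %*% t(dNpdx))
      Me <- Me + wgt * (qd$Np[[g]] %*% t(qd$Np[[g]]))
    }
    udof <- as.vector(rbind(2L * en - 1L, 2L * en))
    tK[[rg]]$i[[e]] <- rep(udof, times = 18L)
    tK[[rg]]$j[[e]] <- rep(udof, each = 18L)
    tK[[rg]]$x[[e]] <- as.vector(Ke)
    tH[[rg]]$i[[e]] <- rep(pdof, times = 4L)
    tH[[rg]]$j[[e]] <- rep(pdof, each = 4L)
    tH[[rg]]$x[[e]] <- as.vector(He)
    tQ$i[[e]] <- rep(udof, times = 4L)
    tQ$j[[e]] <- rep(pdof, each = 18L)
    tQ$x[[e]] <- as.vector(Qe)
    tM$i[[e]] <- rep(pdof, times = 4L)
    tM$j[[e]] <- rep(pdof, each = 4L)
    tM$x[[e]] <- as.vector(Me)
  }
  mk <- function(tr, nrow, ncol) {
    keep <- !vapply(tr$i, is.null, logical(1))
    Matrix::sparseMatrix(i = unlist(tr$i[keep]), j = unlist(tr$j[keep]),
                         x = unlist(tr$x[keep]), dims = c(nrow, ncol))
  }
  K1 <- lapply(regions, function(rg) mk(tK[[rg]], 2L * nn, 2L * nn))
  H1 <- lapply(regions, function(rg) mk(tH[[rg]], np, np))
  names(K1) <- names(H1) <- regions
  Q <- mk(tQ, 2L * nn, np)
  Mp <- mk(tM, np, np)
  list(K1 = K1, H1 = H1, Q = Q, Mp = Mp, nn = nn, np = np,
       nu_by_region = nu_by_region, mesh_regions = regions)
}

# Consistent nodal load for a constant normal traction on a tagged boundary
# (traction > 0 pulls along +n? here: value applied on the z component for
# horizontal surfaces; `direction` selects the global component).
traction_load <- function(mesh, tag, value, direction = c("z", "r")) {
  direction <- match.arg(direction)
  g1 <- c(-sqrt(3 / 5), 0, sqrt(3 / 5)); w1 <- c(5, 8, 5) / 9
  f <- numeric(2L * nrow(mesh$nodes))
  bnd <- mesh$boundary[mesh$boundary$tag == tag, ]
  for (i in seq_len(nrow(bnd))) {
    loc <- edge_local_nodes(bnd$edge[i])
    en <- mesh$conn[bnd$elem[i], loc]
    X <- mesh$nodes[en, , drop = FALSE]
    for (g in seq_along(g1)) {
      N <- shape1q(g1[g]); dN <- dshape1q(g1[g])
      tangent <- as.vector(t(dN) %*% X)           # d(x)/d(s)
      ds <- sqrt(sum(tangent^2))
      r <- sum(N * X[, 1])
      wgt <- w1[g] * ds * 2 * pi * r
      comp <- if (direction == "z") 2L * en else 2L * en - 1L
      f[comp] <- f[comp] + wgt * value * N
    }
  }
  f
}

# Boundary integral of the Darcy flux -k dp/dn (outward normal) over a
# tagged segment at one time index; returns volumetric rate in um^3/s.
# Optional radial window restricts the integral to r <= within_radius or
# r > outside_radius (per quadrature point).
boundary_flux_restricted <- function(solution, tag, time_index = NULL,
                                     within_radius = NULL,
                                     outside_radius = NULL) {
  mesh <- solution$mesh
  if (is.null(time_index)) time_index <- length(solution$times)
  pvals <- solution$P[, time_index]
  g1 <- c(-sqrt(3 / 5), 0, sqrt(3 / 5)); w1 <- c(5, 8, 5) / 9
  bnd <- mesh$boundary[mesh$boundary$tag == tag, ]
  total <- 0
  kmap <- solution$k_by_region
  # local edge -> (xi, eta) parametrisation of the parent square
  edge_param <- function(edge, s) switch(edge,
    `1` = c(s, -1), `2` = c(1, s), `3` = c(s, 1), `4` = c(-1, s))
  # outward normal sign per edge in parent coords
  for (i in seq_len(nrow(bnd))) {
    e <- bnd$elem[i]; edge <- bnd$edge[i]
    en <- mesh$conn[e, ]
    X <- mesh$nodes[en, , drop = FALSE]
    pe <- pvals[mesh$pconn[e, ]]
    k <- kmap[[mesh$region[e]]]
    for (g in seq_along(g1)) {
      xe <- edge_param(edge, g1[g])
      dN <- dshape_q9(xe[1], xe[2])
      N <- shape_q9(xe[1], xe[2])
      J <- t(dN) %*% X
      dNpdx <- dshape_q4(xe[1], xe[2]) %*% solve(t(J))
      gradp <- as.vector(t(dNpdx) %*% pe)
      # tangent along the edge in physical space
      dpar <- switch(edge, `1` = c(1, 0), `2` = c(0, 1),
                     `3` = c(1, 0), `4` = c(0, 1))
      tangent <- as.vector(t(J) %*% dpar)
      ds <- sqrt(sum(tangent^2))
      nrm <- c(tangent[2], -tangent[1]) / ds
      # orient outward: edges 1 (bottom) -> -z, 2 (right) -> +r,
      # 3 (top) -> +z-ish, 4 (left) -> -r
      want <- switch(edge, `1` = c(0, -1), `2` = c(1, 0),
                     `3` = c(0, 1), `4` = c(-1, 0))
      if (sum(nrm * want) < 0) nrm <- -nrm
      r <- sum(N * X[, 1])
      if (!is.null(within_radius) && r > within_radius) next
      if (!is.null(outside_radius) && r <= outside_radius) next
      qn <- -k * sum(gradp * nrm)
      total <- total + w1[g] * ds * 2 * pi * r * qn
    }
  }
  total
}
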