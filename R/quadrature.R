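## Quadrature rules and quadratic (P2) basis functions on tetrahedra and
## triangles.  The tetrahedral rule is a collapsed (conical-product) rule
## built from Gauss-Jacobi lines, exact for polynomials up to degree
## 2n-1 per direction; n = 3 (27 points) covers the degree-4 quadrature
## used for the quadratic elements with margin.

## Golub-Welsch: nodes/weights of the n-point Gauss rule for the Jacobi
## weight (1-x)^alpha on [-1, 1] (beta = 0), via the symmetric tridiagonal
## Jacobi matrix of the monic recurrence.
gauss_jacobi <- function(n, alpha) {
  stopifnot(n >= 1)
  k <- seq_len(n) - 1
  a <- ifelse(k == 0, -alpha / (alpha + 2),
              -alpha^2 / ((2 * k + alpha) * (2 * k + alpha + 2)))
  k1 <- seq_len(n - 1)
  ## beta = 0: b_n = 4 n^2 (n+alpha)^2 / ((2n+alpha)^2 ((2n+alpha)^2 - 1))
  b <- 4 * k1^2 * (k1 + alpha)^2 /
    ((2 * k1 + alpha)^2 * (2 * k1 + alpha + 1) * (2 * k1 + alpha - 1))
  J <- diag(a, n, n)
  if (n > 1) {
    sb <- sqrt(b)
    J[cbind(k1, k1 + 1)] <- sb
    J[cbind(k1 + 1, k1)] <- sb
  }
  e <- eigen(J, symmetric = TRUE)
  mu0 <- 2^(alpha + 1) / (alpha + 1) # int_{-1}^{1} (1-x)^alpha dx
  idx <- order(e$values)
  list(x = e$values[idx], w = (mu0 * e$vectors[1, ]^2)[idx])
}

## map a Gauss-Jacobi rule for (1-x)^alpha from [-1,1] to weight
## (1-t)^alpha on [0,1]
jacobi01 <- function(n, alpha) {
  g <- gauss_jacobi(n, alpha)
  list(x = (1 + g$x) / 2, w = g$w / 2^(alpha + 1))
}

#' Quadrature rule on the reference tetrahedron
#'
#' Conical-product rule on the unit tetrahedron (vertices at the origin and
#' the three unit points).  With \code{n} points per direction the rule is
#' exact for polynomials of total degree at least \code{2n - 1}.
#'
#' @param n points per collapsed direction (default 3, 27 points).
#' @return list with \code{points} (m x 3 local coordinates) and
#'   \code{weights} (summing to 1/6).
#' @export
tet_quadrature <- function(n = 3) {
  gu <- jacobi01(n, 2) # weight (1-u)^2
  gv <- jacobi01(n, 1) # weight (1-v)
  gw <- jacobi01(n, 0)
  pts <- matrix(0, n^3, 3)
  wts <- numeric(n^3)
  m <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    m <- m + 1
    u <- gu$x[i]; v <- gv$x[j]; w <- gw$x[k]
    pts[m, ] <- c(u, v * (1 - u), w * (1 - u) * (1 - v))
    wts[m] <- gu$w[i] * gv$w[j] * gw$w[k]
  }
  list(points = pts, weights = wts)
}

#' Degree-4 14-point rule on the reference tetrahedron
#'
#' Keast's symmetric 14-point rule (all weights positive); exact through
#' total degree 4.  Preferred for assembly (half the points of the
#' collapsed rule at the same order).
#'
#' @return list with \code{points} (14 x 3) and \code{weights} (sum 1/6).
#' @export
tet_quadrature14 <- function() {
  perm4 <- function(a, b) { # barycentric (b,b,b,a) permutations
    rbind(c(b, b, b), c(a, b, b), c(b, a, b), c(b, b, a))
  }
  g1 <- 0.0673422422100983; h1 <- 0.3108859192633005
  g2 <- 0.7217942490673264; h2 <- 0.0927352503108912
  a3 <- 0.0455037041256497; b3 <- 0.4544962958743503
  ## 6 permutations of (a,a,b,b) in barycentric coordinates
  p6 <- rbind(c(a3, b3, b3), c(b3, a3, b3), c(b3, b3, a3),
              c(b3, a3, a3), c(a3, b3, a3), c(a3, a3, b3))
  ## convert barycentric (l1,l2,l3,l4) -> local (x,y,z) = (l2,l3,l4)
  pts <- rbind(perm4(g1, h1), perm4(g2, h2), p6)
  w <- c(rep(0.1126879257180162, 4), rep(0.0734930431163619, 4),
         rep(0.0425460207770812, 6)) / 6
  list(points = pts, weights = w)
}

#' Degree-4 quadrature on the reference triangle
#'
#' The standard symmetric 6-point rule (weights sum to 1/2).
#'
#' @return list with \code{points} (6 x 2) and \code{weights}.
#' @export
tri_quadrature <- function() {
  a <- 0.445948490915965; wa <- 0.223381589678011
  b <- 0.091576213509771; wb <- 0.109951743655322
  pts <- rbind(c(a, a), c(1 - 2 * a, a), c(a, 1 - 2 * a),
               c(b, b), c(1 - 2 * b, b), c(b, 1 - 2 * b))
  list(points = pts, weights = c(wa, wa, wa, wb, wb, wb) / 2)
}

## P2 tetrahedron: nodes 1-4 vertices, 5-10 midside nodes on edges
## (1,2),(2,3),(1,3),(1,4),(2,4),(3,4)
TET_EDGES <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))

#' P2 shape functions on the reference tetrahedron
#'
#' @param xi m x 3 local coordinates.
#' @return list with \code{N} (m x 10) and \code{dN} (m x 10 x 3 array of
#'   gradients with respect to local coordinates).
#' @export
tet10_shape <- function(xi) {
  xi <- rbind(xi)
  m <- nrow(xi)
  l <- cbind(1 - rowSums(xi), xi) # barycentric: lambda1..lambda4
  dl <- rbind(c(-1, -1, -1), diag(3)) # dlambda_i / dxi_j
  N <- matrix(0, m, 10)
  dN <- array(0, c(m, 10, 3))
  for (i in 1:4) {
    N[, i] <- l[, i] * (2 * l[, i] - 1)
    for (j in 1:3) dN[, i, j] <- (4 * l[, i] - 1) * dl[i, j]
  }
  for (e in 1:6) {
    i <- TET_EDGES[e, 1]; k <- TET_EDGES[e, 2]
    N[, 4 + e] <- 4 * l[, i] * l[, k]
    for (j in 1:3)
      dN[, 4 + e, j] <- 4 * (dl[i, j] * l[, k] + l[, i] * dl[k, j])
  }
  list(N = N, dN = dN)
}

#' P2 shape functions on the reference triangle
#'
#' Nodes 1-3 vertices, 4-6 midside nodes on edges (1,2),(2,3),(1,3).
#'
#' @param xi m x 2 local coordinates.
#' @return list with \code{N} (m x 6) and \code{dN} (m x 6 x 2).
#' @export
tri6_shape <- function(xi) {
  xi <- rbind(xi)
  m <- nrow(xi)
  l <- cbind(1 - rowSums(xi), xi)
  dl <- rbind(c(-1, -1), diag(2))
  edges <- rbind(c(1, 2), c(2, 3), c(1, 3))
  N <- matrix(0, m, 6)
  dN <- array(0, c(m, 6, 2))
  for (i in 1:3) {
    N[, i] <- l[, i] * (2 * l[, i] - 1)
    for (j in 1:2) dN[, i, j] <- (4 * l[, i] - 1) * dl[i, j]
  }
  for (e in 1:3) {
    i <- edges[e, 1]; k <- edges[e, 2]
    N[, 3 + e] <- 4 * l[, i] * l[, k]
    for (j in 1:2)
      dN[, 3 + e, j] <- 4 * (dl[i, j] * l[, k] + l[, i] * dl[k, j])
  }
  list(N = N, dN = dN)
}

## P1 (linear) shape functions of the 4 vertices at local coordinates
tet4_shape <- function(xi) {
  xi <- rbind(xi)
  cbind(1 - rowSums(xi), xi)
}
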