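## Idealized truncated-ellipsoid left-ventricle mesh with quadratic (P2)
## tetrahedra.
##
## The wall is the region between two half-ellipsoids truncated by the
## basal plane z = 0 (apex toward negative z).  A structured parametric
## grid (circumferential theta, apex angle phi, transmural m) is split into
## tetrahedra; midside nodes are placed with parametric midpoints, so
## surface nodes lie exactly on the bounding ellipsoids and elements are
## curved.  The parametric transmural coordinate m in [0 (endo), 1 (epi)]
## is carried on every node and serves as the transmural coordinate field
## for the rule-based fiber architecture.

#' Left-ventricle geometry specification
#'
#' Dimensions of the truncated-ellipsoid wall.  Defaults follow a healthy
#' adult LV: 7.3 cm base-to-apex outer length, 7.2 cm basal outer diameter,
#' 1.3 cm basal wall thickness, apical thickness half of basal; the
#' enclosed unloaded cavity volume is then ~74 mL (about 75 mL).
#'
#' @param length_cm outer base-to-apex length.
#' @param outer_diameter_cm basal outer diameter.
#' @param wall_thickness_cm basal wall thickness.
#' @param apical_thickness_cm apical wall thickness (default half basal).
#' @return object of class \code{lv_geometry} with SI semi-axes
#'   \code{a_endo}, \code{c_endo}, \code{a_epi}, \code{c_epi} (m).
#' @export
lv_geometry <- function(length_cm = 7.3, outer_diameter_cm = 7.2,
                        wall_thickness_cm = 1.3,
                        apical_thickness_cm = wall_thickness_cm / 2) {
  if (any(c(length_cm, outer_diameter_cm, wall_thickness_cm,
            apical_thickness_cm) <= 0)) stop("dimensions must be positive")
  a_epi <- outer_diameter_cm / 2
  a_endo <- a_epi - wall_thickness_cm
  c_epi <- length_cm
  c_endo <- c_epi - apical_thickness_cm
  if (a_endo <= 0 || c_endo <= 0) stop("wall thicker than the chamber")
  structure(list(a_endo = a_endo / 100, c_endo = c_endo / 100,
                 a_epi = a_epi / 100, c_epi = c_epi / 100,
                 length_cm = length_cm, outer_diameter_cm = outer_diameter_cm,
                 wall_thickness_cm = wall_thickness_cm,
                 apical_thickness_cm = apical_thickness_cm),
            class = "lv_geometry")
}

## parametric wall map; m transmural in [0,1], phi in [0, pi/2], theta
## circumferential
lv_wall_point <- function(geom, theta, phi, m) {
  a <- geom$a_endo + (geom$a_epi - geom$a_endo) * m
  cc <- geom$c_endo + (geom$c_epi - geom$c_endo) * m
  cbind(a * cos(phi) * cos(theta), a * cos(phi) * sin(theta),
        -cc * sin(phi))
}

#' Mesh resolution presets
#'
#' \code{mini} ~90 elements (fast closed-loop tests), \code{coarse} ~170
#' elements (property-test fixture), \code{paper} ~1250 elements
#' (full-resolution geometry).
#'
#' @param resolution preset name or a list with \code{n_theta},
#'   \code{n_phi}, \code{n_trans}.
#' @return list with the three grid counts.
#' @export
mesh_resolution <- function(resolution = "coarse") {
  if (is.list(resolution)) return(resolution)
  switch(resolution,
         mini = list(n_theta = 6L, n_phi = 3L, n_trans = 1L),
         coarse = list(n_theta = 8L, n_phi = 4L, n_trans = 1L),
         paper = list(n_theta = 16L, n_phi = 7L, n_trans = 2L),
         stop("unknown mesh resolution: ", resolution))
}

#' Build the truncated-ellipsoid LV mesh
#'
#' @param geom \code{lv_geometry}.
#' @param resolution preset name or list, see \code{\link{mesh_resolution}}.
#' @return object of class \code{lv_mesh}: P2 nodes (vertices first),
#'   10-node element table, tagged endocardial/epicardial/basal surface
#'   triangles (6-node, outward-oriented), basal node set, per-node
#'   transmural coordinate \code{t_node} and parametric coordinates.
#' @export
build_ellipsoid_mesh <- function(geom = lv_geometry(), resolution = "coarse") {
  res <- mesh_resolution(resolution)
  nt <- res$n_theta; np <- res$n_phi; nr <- res$n_trans
  stopifnot(nt >= 4, np >= 2, nr >= 1)

  ## ---- vertex grid ----
  per_layer <- np * nt + 1L
  vid <- function(it, ip, ir) {
    it <- it %% nt
    ir * per_layer + ifelse(ip >= np, np * nt, ip * nt + it) + 1L
  }
  nv <- per_layer * (nr + 1L)
  vpar <- matrix(0, nv, 3) # theta, phi, m (theta NA-free; apex theta = 0)
  for (ir in 0:nr) for (ip in 0:np) {
    if (ip < np) {
      for (it in 0:(nt - 1L)) {
        vpar[vid(it, ip, ir), ] <- c(2 * pi * it / nt, (pi / 2) * ip / np,
                                     ir / nr)
      }
    } else {
      vpar[vid(0L, np, ir), ] <- c(0, pi / 2, ir / nr)
    }
  }
  apex_ids <- vid(0L, np, 0:nr)

  ## ---- tetrahedra from hexes and apex prisms ----
  tets <- list()
  hex_split <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                     c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  for (ir in 0:(nr - 1L)) {
    for (ip in 0:(np - 2L)) for (it in 0:(nt - 1L)) {
      h <- c(vid(it, ip, ir), vid(it + 1L, ip, ir),
             vid(it + 1L, ip + 1L, ir), vid(it, ip + 1L, ir),
             vid(it, ip, ir + 1L), vid(it + 1L, ip, ir + 1L),
             vid(it + 1L, ip + 1L, ir + 1L), vid(it, ip + 1L, ir + 1L))
      for (k in 1:6) tets[[length(tets) + 1L]] <- h[hex_split[k, ]]
    }
    for (it in 0:(nt - 1L)) { # prisms: ring (np-1) to apex
      p0 <- vid(it, np - 1L, ir); p1 <- vid(it + 1L, np - 1L, ir)
      A <- apex_ids[ir + 1L]
      q0 <- vid(it, np - 1L, ir + 1L); q1 <- vid(it + 1L, np - 1L, ir + 1L)
      A2 <- apex_ids[ir + 2L]
      tets[[length(tets) + 1L]] <- c(p0, p1, A, A2)
      tets[[length(tets) + 1L]] <- c(p0, p1, A2, q1)
      tets[[length(tets) + 1L]] <- c(p0, q1, A2, q0)
    }
  }
  tv <- do.call(rbind, tets)

  ## straight-vertex positions to orient elements
  vx <- lv_wall_point(geom, vpar[, 1], vpar[, 2], vpar[, 3])
  for (e in seq_len(nrow(tv))) {
    a <- vx[tv[e, 1], ]
    d <- det(cbind(vx[tv[e, 2], ] - a, vx[tv[e, 3], ] - a,
                   vx[tv[e, 4], ] - a))
    if (d < 0) tv[e, c(3, 4)] <- tv[e, c(4, 3)]
  }

  ## ---- P2 midside nodes (parametric midpoints) ----
  edge_key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  edge_env <- new.env(hash = TRUE)
  mid_par <- list()
  n_mid <- 0L
  get_mid <- function(i, j) {
    k <- edge_key(i, j)
    id <- edge_env[[k]]
    if (!is.null(id)) return(id)
    pi_ <- vpar[i, ]; pj <- vpar[j, ]
    ## circumferential wrap-aware midpoint; apex nodes adopt partner theta
    th_i <- pi_[1]; th_j <- pj[1]
    i_apex <- abs(pi_[2] - pi / 2) < 1e-12
    j_apex <- abs(pj[2] - pi / 2) < 1e-12
    if (i_apex && !j_apex) th_i <- th_j
    if (j_apex && !i_apex) th_j <- th_i
    dth <- ((th_j - th_i + pi) %% (2 * pi)) - pi
    par <- c(th_i + dth / 2, (pi_[2] + pj[2]) / 2, (pi_[3] + pj[3]) / 2)
    n_mid <<- n_mid + 1L
    id <- nv + n_mid
    mid_par[[n_mid]] <<- par
    edge_env[[k]] <- id
    id
  }
  elems <- matrix(0L, nrow(tv), 10)
  elems[, 1:4] <- tv
  for (e in seq_len(nrow(tv))) {
    for (ed in 1:6) {
      elems[e, 4L + ed] <- get_mid(tv[e, TET_EDGES[ed, 1]],
                                   tv[e, TET_EDGES[ed, 2]])
    }
  }
  node_par <- rbind(vpar, do.call(rbind, mid_par))
  nodes <- lv_wall_point(geom, node_par[, 1], node_par[, 2], node_par[, 3])

  ## ---- boundary faces ----
  face_local <- rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
  nf <- 4L * nrow(tv)
  fv <- matrix(0L, nf, 3)
  for (f in 1:4) fv[seq(f, nf, by = 4L), ] <- tv[, face_local[f, ]]
  key <- apply(fv, 1, function(r) paste(sort(r), collapse = "_"))
  bnd <- fv[key %in% names(which(table(key) == 1L)), , drop = FALSE]

  phi_v <- vpar[, 2]; m_v <- vpar[, 3]
  on_base <- matrix(phi_v[bnd] < 1e-12, nrow(bnd))
  on_endo <- matrix(m_v[bnd] < 1e-12, nrow(bnd))
  on_epi <- matrix(m_v[bnd] > 1 - 1e-12, nrow(bnd))
  classify <- function(mask) bnd[rowSums(mask) == 3L, , drop = FALSE]
  base_faces <- classify(on_base)
  endo_faces <- classify(on_endo)
  epi_faces <- classify(on_epi)

  add_face_mids <- function(fm) {
    if (nrow(fm) == 0) return(matrix(0L, 0, 6))
    cbind(fm,
          mapply(function(i, j) edge_env[[edge_key(i, j)]], fm[, 1], fm[, 2]),
          mapply(function(i, j) edge_env[[edge_key(i, j)]], fm[, 2], fm[, 3]),
          mapply(function(i, j) edge_env[[edge_key(i, j)]], fm[, 1], fm[, 3]))
  }

  mesh <- structure(list(
    nodes = nodes, n_vert = nv, elems = elems,
    endo_faces = add_face_mids(endo_faces),
    epi_faces = add_face_mids(epi_faces),
    base_faces = add_face_mids(base_faces),
    base_nodes = which(abs(node_par[, 2]) < 1e-12),
    t_node = node_par[, 3],
    node_par = node_par,
    geometry = geom, resolution = res), class = "lv_mesh")
  mesh
}

#' Wall (myocardial) volume of the mesh
#'
#' Sum of element volumes by quadrature; useful for region-fraction
#' accounting and mesh QA.
#'
#' @param mesh \code{lv_mesh}.
#' @return volume in m^3.
#' @export
mesh_wall_volume <- function(mesh) {
  qr <- tet_quadrature()
  sh <- tet10_shape(qr$points)
  total <- 0
  for (e in seq_len(nrow(mesh$elems))) {
    xe <- mesh$nodes[mesh$elems[e, ], ]
    for (q in seq_along(qr$weights)) {
      Jm <- t(xe) %*% sh$dN[q, , ] # 3x3 dx/dxi
      total <- total + qr$weights[q] * det(Jm)
    }
  }
  total
}

#' @export
print.lv_mesh <- function(x, ...) {
  cat("LV truncated-ellipsoid mesh:", nrow(x$elems), "P2 tetrahedra,",
      nrow(x$nodes), "nodes (", x$n_vert, "vertices )\n")
  cat("  surfaces: endo", nrow(x$endo_faces), "| epi", nrow(x$epi_faces),
      "| base", nrow(x$base_faces), "faces\n")
  invisible(x)
}
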