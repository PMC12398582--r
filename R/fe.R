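## Mixed finite-element mechanics of the LV wall.
##
## Unknowns: quadratic displacement u (3 per node), linear hydrostatic
## pressure p (1 per vertex), the cavity-pressure Lagrange multiplier P_LV
## enforcing V_LV(u) = V_target, and three rigid-body multipliers removing
## in-plane translation and rotation about the long axis.  The basal plane
## carries the Dirichlet condition u . n = 0 (u_z = 0 at z = 0).

#' Set up the finite-element workspace for a mesh
#'
#' Precomputes quadrature geometry (global shape gradients, weighted
#' Jacobians, quadrature positions), the transmural coordinate at
#' quadrature points, dof bookkeeping and rigid-body constraint vectors.
#'
#' @param mesh \code{lv_mesh}.
#' @param penalty augmented-Lagrangian volumetric penalty modulus (Pa).
#'   The pressure multiplier enforces the element-mean incompressibility
#'   constraint exactly; the penalty additionally suppresses pointwise
#'   J - 1 oscillations that the piecewise-linear multiplier space cannot
#'   control on coarse meshes.
#' @return object of class \code{lv_fe}.
#' @export
fe_setup <- function(mesh, penalty = 1e6) {
  qr <- tet_quadrature14()
  sh <- tet10_shape(qr$points)
  nq <- length(qr$weights)
  elems0 <- mesh$elems - 1L
  pre <- fe_precompute_cpp(mesh$nodes, elems0, sh$N, sh$dN, qr$weights)
  pN <- tet4_shape(qr$points)

  ne <- nrow(mesh$elems)
  n <- nrow(mesh$nodes)
  nv <- mesh$n_vert

  ## transmural coordinate and shape integrals at quadrature points
  t_qp <- numeric(ne * nq)
  intN <- numeric(3 * n) # placeholder for rigid vectors
  gx <- numeric(3 * n); gy <- numeric(3 * n); grot <- numeric(3 * n)
  for (e in seq_len(ne)) {
    idx <- (e - 1L) * nq + seq_len(nq)
    conn <- mesh$elems[e, ]
    t_qp[idx] <- drop(sh$N %*% mesh$t_node[conn])
    w <- pre$wdet[idx]
    a_int <- colSums(sh$N * w)                    # int N_a dV
    ax_int <- colSums(sh$N * (w * pre$pos[idx, 1])) # int N_a X dV
    ay_int <- colSums(sh$N * (w * pre$pos[idx, 2])) # int N_a Y dV
    gx[3 * (conn - 1L) + 1L] <- gx[3 * (conn - 1L) + 1L] + a_int
    gy[3 * (conn - 1L) + 2L] <- gy[3 * (conn - 1L) + 2L] + a_int
    ## rotation about z: int (z x X) . u dV -> x-dofs get -Y, y-dofs get +X
    grot[3 * (conn - 1L) + 1L] <- grot[3 * (conn - 1L) + 1L] - ay_int
    grot[3 * (conn - 1L) + 2L] <- grot[3 * (conn - 1L) + 2L] + ax_int
  }

  ## surface quadrature for the cavity-volume integral
  trq <- tri_quadrature()
  trsh <- tri6_shape(trq$points)

  ## consistent mass-type matrix (per scalar component) for the viscous
  ## wall-damping term of the backward-Euler time discretization
  mi <- integer(0); mj <- integer(0); mx <- numeric(0)
  for (e in seq_len(ne)) {
    idx <- (e - 1L) * nq + seq_len(nq)
    Me <- crossprod(sh$N * sqrt(pre$wdet[idx]))
    conn <- mesh$elems[e, ]
    mi <- c(mi, rep(conn, each = 10L))
    mj <- c(mj, rep(conn, times = 10L))
    mx <- c(mx, as.numeric(Me))
  }
  Mu <- Matrix::sparseMatrix(i = mi, j = mj, x = mx, dims = c(n, n))
  M3 <- Mu %x% Matrix::Diagonal(3) # u-dof ordering is node-major
  M3t <- Matrix::mat2triplet(M3)

  fixed_u <- 3 * (mesh$base_nodes - 1L) + 3L # u_z on the basal plane
  ndof <- 3 * n + nv + 4L
  fixed <- fixed_u
  free <- setdiff(seq_len(ndof), fixed)
  free_map <- integer(ndof)
  free_map[free] <- seq_along(free)
  ufree <- setdiff(seq_len(3 * n), fixed_u)
  umap <- integer(3 * n)
  umap[ufree] <- seq_along(ufree)

  fe <- list(mesh = mesh, qr = qr, sh = sh, nq = nq, elems0 = elems0,
             dNg = pre$dNg, wdet = pre$wdet, pos = pre$pos, pN = pN,
             t_qp = t_qp, gx = gx, gy = gy, grot = grot,
             tri_qw = trq$weights, tri_N = trsh$N,
             tri_dN1 = trsh$dN[, , 1], tri_dN2 = trsh$dN[, , 2],
             n_nodes = n, n_vert = nv, n_qp = ne * nq,
             ndof = ndof, free = free, fixed = fixed, free_map = free_map,
             ufree = ufree, umap = umap,
             penalty = penalty,
             M3 = M3, m3i = M3t$i, m3j = M3t$j, m3x = M3t$x,
             i_plv = 3 * n + nv + 1L, i_cx = 3 * n + nv + 2L,
             i_cy = 3 * n + nv + 3L, i_cz = 3 * n + nv + 4L)
  class(fe) <- "lv_fe"
  fe
}

#' Cavity volume enclosed by the (deformed) endocardial surface
#'
#' Evaluates V = -1/3 surface integral of x . n over the endocardial P2
#' triangles (closed by the basal plane at z = 0, which contributes
#' nothing).
#'
#' @param fe \code{lv_fe} (or \code{lv_mesh}, for the undeformed volume).
#' @param u displacement vector (length 3 * n_nodes); default undeformed.
#' @param grad if TRUE also return dV/du.
#' @return volume (m^3), or list with \code{V} and \code{grad}.
#' @export
cavity_volume <- function(fe, u = NULL, grad = FALSE, hess = FALSE) {
  if (inherits(fe, "lv_mesh")) fe <- fe_setup(fe)
  mesh <- fe$mesh
  if (is.null(u)) u <- numeric(3 * fe$n_nodes)
  out <- cavity_volume_cpp(mesh$nodes, mesh$endo_faces - 1L, u,
                           fe$tri_N, fe$tri_dN1, fe$tri_dN2, fe$tri_qw,
                           grad, hess)
  if (grad || hess) out else out$V
}

## per-quadrature-point material parameter arrays from region labels
qp_materials <- function(fe, labels = NULL, table = material_table()) {
  nqp <- fe$n_qp
  pick <- rep("normal", nqp)
  if (!is.null(labels)) pick[labels$perturbed] <- labels$material
  nb <- table$normal$bulk; fb <- table$fibrous$bulk
  nm <- table$normal$myofiber; fm <- table$fibrous$myofiber
  fib <- pick == "fibrous"
  list(Cb = ifelse(fib, fb$C, nb$C),
       bff = ifelse(fib, fb$b_ff, nb$b_ff),
       bxx = ifelse(fib, fb$b_xx, nb$b_xx),
       bfs = ifelse(fib, fb$b_fs, nb$b_fs),
       C1 = ifelse(fib, fm$C_1, nm$C_1),
       C2 = ifelse(fib, fm$C_2, nm$C_2),
       xb_scale = ifelse(fib, table$fibrous$xb_density, table$normal$xb_density) /
         table$normal$xb_density)
}

## assemble residual blocks and (optionally) the tangent triplets
fe_assemble <- function(fe, frames, mats, Sact, u, p,
                        want_matrix = TRUE, want_fields = FALSE) {
  assemble_cpp(fe$elems0, fe$n_nodes, fe$n_vert, fe$dNg, fe$wdet, fe$pN,
               u, p, frames$f0, frames$s0, frames$n0,
               mats$Cb, mats$bff, mats$bxx, mats$bfs, mats$C1, mats$C2,
               Sact, fe$penalty, want_matrix, want_fields)
}

## full residual vector of the saddle problem
fe_residual <- function(fe, asm, cav, u, plv, cvec, v_target) {
  r <- numeric(fe$ndof)
  r[seq_len(3 * fe$n_nodes)] <- asm$Ru - plv * cav$grad -
    cvec[1] * fe$gx - cvec[2] * fe$gy - cvec[3] * fe$grot
  r[3 * fe$n_nodes + seq_len(fe$n_vert)] <- asm$Rp
  r[fe$i_plv] <- -(cav$V - v_target)
  r[fe$i_cx] <- -sum(fe$gx * u)
  r[fe$i_cy] <- -sum(fe$gy * u)
  r[fe$i_cz] <- -sum(fe$grot * u)
  r
}

#' Solve one quasi-static mechanics step
#'
#' Newton iteration on the coupled system: momentum residual with total
#' stress (active stress frozen at the sarcomere value for this step),
#' pointwise incompressibility via the pressure field, cavity volume
#' constrained to \code{v_target} through the P_LV multiplier, and
#' rigid-body constraints.
#'
#' @param fe \code{lv_fe}.
#' @param frames list of quadrature-point frame matrices \code{f0},
#'   \code{s0}, \code{n0} (each n_qp x 3).
#' @param mats per-quadrature-point material arrays from
#'   \code{qp_materials}.
#' @param Sact active fiber stress per quadrature point (Pa).
#' @param state list with current \code{u}, \code{p}, \code{plv},
#'   \code{cvec} (initial guess and multipliers).
#' @param v_target target cavity volume (m^3).
#' @param control list: \code{rtol}, \code{atol}, \code{maxit},
#'   \code{vol_tol} (m^3).
#' @param cache optional environment carrying the factorized tangent of a
#'   nearby solve (simplified-Newton warm start).
#' @param visc optional viscous wall damping for time stepping: list with
#'   \code{gamma} (damping coefficient / dt, N s m^-4 / s) and
#'   \code{u_ref} (displacement of the previous time step).  NULL for
#'   quasi-static solves.
#' @return updated state list with convergence info and per-point fields
#'   (\code{J}, \code{alpha}, \code{Sff_myo}, \code{S}, \code{E},
#'   \code{F}).
#' @export
solve_mechanics_step <- function(fe, frames, mats, Sact, state, v_target,
                                 control = list(), cache = NULL,
                                 visc = NULL) {
  ctl <- modifyList(list(rtol = 1e-9, atol = 1e-11, maxit = 50,
                         vol_tol = 1e-3 * lv_units$mL), control)
  u <- state$u; p <- state$p; plv <- state$plv; cvec <- state$cvec
  nU <- 3 * fe$n_nodes
  iu <- seq_len(nU)

  resid <- function(u, p, plv, cvec) {
    if (!is.null(cache)) cache$n_resid <- c(cache$n_resid, 0)[1] + 1
    asm <- fe_assemble(fe, frames, mats, Sact, u, p, want_matrix = FALSE)
    cav <- cavity_volume(fe, u, grad = TRUE)
    r <- fe_residual(fe, asm, cav, u, plv, cvec, v_target)
    if (!is.null(visc))
      r[iu] <- r[iu] +
        visc$gamma * as.numeric(fe$M3 %*% (u - visc$u_ref))
    list(r = r, cav = cav)
  }

  finish <- function(u, p, plv, cvec, V, it) {
    fields <- fe_assemble(fe, frames, mats, Sact, u, p,
                          want_matrix = FALSE, want_fields = TRUE)
    list(u = u, p = p, plv = plv, cvec = cvec, V = V,
         iterations = it, converged = TRUE, fields = fields)
  }

  ## assemble the bordered tangent at the current state and factorize.
  ## The four scalar constraints (P_LV, c_x, c_y, c_z) couple densely to
  ## all displacement dofs; factoring them inside the sparse matrix causes
  ## massive fill-in, so they are eliminated by a 4x4 Schur complement
  ## around the sparse (u, p) core.
  factorize <- function(u, p, plv) {
    if (!is.null(cache)) cache$n_fact <- c(cache$n_fact, 0)[1] + 1
    asm <- fe_assemble(fe, frames, mats, Sact, u, p, want_matrix = TRUE)
    cav <- cavity_volume(fe, u, grad = TRUE, hess = TRUE)
    lu_bordered <- function() {
      ## full bordered sparse LU: robust fallback (also the quasi-static
      ## path, where the (u, p) core alone is singular because the rigid
      ## modes are only fixed by the borders)
      gam <- if (is.null(visc)) 0 else visc$gamma
      bi <- c(asm$ti + 1L, cav$hi + 1L, fe$m3i,
              iu, rep(fe$i_plv, nU), iu, rep(fe$i_cx, nU),
              iu, rep(fe$i_cy, nU), iu, rep(fe$i_cz, nU))
      bj <- c(asm$tj + 1L, cav$hj + 1L, fe$m3j,
              rep(fe$i_plv, nU), iu, rep(fe$i_cx, nU), iu,
              rep(fe$i_cy, nU), iu, rep(fe$i_cz, nU), iu)
      bv <- c(asm$tv, -plv * cav$hv, gam * fe$m3x,
              -cav$grad, -cav$grad, -fe$gx, -fe$gx,
              -fe$gy, -fe$gy, -fe$grot, -fe$grot)
      fm <- fe$free_map
      ib <- fm[bi]; jb <- fm[bj]
      keep <- ib > 0L & jb > 0L & bv != 0
      Kf <- Matrix::sparseMatrix(i = ib[keep], j = jb[keep], x = bv[keep],
                                 dims = c(length(fe$free), length(fe$free)))
      sc <- 1 / sqrt(sqrt(Matrix::colSums(Kf^2)) + 1e-300)
      Ks <- Matrix::Diagonal(x = sc) %*% Kf %*% Matrix::Diagonal(x = sc)
      function(b) sc * as.numeric(Matrix::solve(Ks, sc * b))
    }
    if (is.null(visc)) return(lu_bordered())
    bi <- c(asm$ti + 1L, cav$hi + 1L, fe$m3i)
    bj <- c(asm$tj + 1L, cav$hj + 1L, fe$m3j)
    bv <- c(asm$tv, -plv * cav$hv, visc$gamma * fe$m3x)
    nuf <- length(fe$ufree)
    nb <- fe$n_vert + 4L
    ## displacement block: symmetric positive definite thanks to the
    ## viscous mass term; factorized with CHOLMOD so the symbolic
    ## analysis is reused across refactorizations
    sel <- bi <= nU & bj <= nU
    iub <- fe$umap[bi[sel]]; jub <- fe$umap[bj[sel]]; vub <- bv[sel]
    keep <- iub > 0L & jub > 0L & vub != 0
    Auu <- Matrix::sparseMatrix(i = iub[keep], j = jub[keep], x = vub[keep],
                                dims = c(nuf, nuf), symmetric = FALSE)
    Auu <- Matrix::forceSymmetric(Auu, uplo = "U")
    ## CHOLMOD warns (and modifies the factor) when the block is locally
    ## indefinite; the modified factor still works as a quasi-Newton
    ## operator, and the residual-based acceptance test guards correctness
    quiet <- function(expr)
      tryCatch(suppressWarnings(expr), error = function(e) NULL)
    CH <- NULL
    if (!is.null(cache) && !is.null(cache$chol))
      CH <- quiet(Matrix::update(cache$chol, Auu))
    if (is.null(CH))
      CH <- quiet(Matrix::Cholesky(Auu, LDL = FALSE, super = TRUE))
    if (is.null(CH)) return(lu_bordered()) # hard breakdown: robust path
    if (!is.null(cache)) cache$chol <- CH
    ## border columns: pressure coupling plus the four scalar constraints
    selp <- bi <= nU & bj > 3 * fe$n_nodes
    ipu <- fe$umap[bi[selp]]
    jpc <- bj[selp] - 3L * fe$n_nodes
    ok <- ipu > 0L
    B <- cbind(
      as.matrix(Matrix::sparseMatrix(i = ipu[ok], j = jpc[ok],
                                     x = bv[selp][ok],
                                     dims = c(nuf, fe$n_vert))),
      -cav$grad[fe$ufree], -fe$gx[fe$ufree], -fe$gy[fe$ufree],
      -fe$grot[fe$ufree])
    W <- as.matrix(Matrix::solve(CH, B))
    SB <- crossprod(B, W) # (nv + 4) dense Schur complement
    SB_lu <- qr(SB)
    function(b) {
      b1 <- b[seq_len(nuf)]
      b2 <- b[nuf + seq_len(nb)]
      z <- as.numeric(Matrix::solve(CH, b1))
      y <- solve(SB_lu, crossprod(B, z) - b2)
      c(as.numeric(z - W %*% y), as.numeric(y))
    }
  }

  ## damped quasi-Newton with lazy refactorization: the factorized tangent
  ## of a nearby state (cached across time steps) is reused as long as the
  ## natural (affine-invariant) monotonicity test contracts; it is rebuilt
  ## when contraction stalls.  The preconditioned norm |K^-1 r| makes the
  ## displacement, pressure and constraint rows commensurate.
  lin_solve <- if (!is.null(cache)) cache$lin_solve else NULL
  fresh <- FALSE
  rr <- resid(u, p, plv, cvec) # errors on an inadmissible start state
  r0n <- max(sqrt(sum(rr$r[fe$free]^2)), ctl$atol)
  for (it in seq_len(ctl$maxit)) {
    rn <- sqrt(sum(rr$r[fe$free]^2))
    if (rn <= ctl$rtol * r0n + ctl$atol &&
        abs(rr$cav$V - v_target) <= ctl$vol_tol)
      return(finish(u, p, plv, cvec, rr$cav$V, it - 1L))
    if (is.null(lin_solve)) {
      lin_solve <- factorize(u, p, plv)
      fresh <- TRUE
      if (!is.null(cache)) cache$lin_solve <- lin_solve
    }
    du <- tryCatch(lin_solve(-rr$r[fe$free]), error = function(e) NULL)
    if (is.null(du) || !all(is.finite(du))) {
      if (fresh)
        stop("linear solve failed in Newton step (singular tangent)")
      lin_solve <- NULL # stale factorization: rebuild and retry
      next
    }
    ndu <- sqrt(sum(du^2))
    full <- numeric(fe$ndof)
    full[fe$free] <- du
    step <- 1
    accepted <- FALSE
    for (ls in 1:11) {
      u2 <- u + step * full[iu]
      p2 <- p + step * full[nU + seq_len(fe$n_vert)]
      plv2 <- plv + step * full[fe$i_plv]
      cv2 <- cvec + step * full[c(fe$i_cx, fe$i_cy, fe$i_cz)]
      rr2 <- tryCatch(resid(u2, p2, plv2, cv2), error = function(e) NULL)
      nd2 <- if (is.null(rr2)) Inf else
        tryCatch(sqrt(sum(lin_solve(rr2$r[fe$free])^2)),
                 error = function(e) Inf)
      if (is.finite(nd2) && nd2 <= (1 - step / 2) * ndu) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      if (fresh)
        stop("Newton damping failed (increment outside the convergence ",
             "basin)")
      lin_solve <- NULL # blame the stale tangent first
      next
    }
    u <- u2; p <- p2; plv <- plv2; cvec <- cv2
    rr <- rr2
    fresh <- FALSE # the factorization ages once the state moves
    ## refactorize next iteration only if contraction is genuinely weak
    ## (cheap resid-only iterations beat a refactorization)
    if (step < 0.5 || nd2 > 0.8 * ndu) lin_solve <- NULL
  }
  stop("Newton did not converge in ", ctl$maxit,
       " iterations (last residual ", signif(rn, 3), ", volume gap ",
       signif(abs(rr$cav$V - v_target) / lv_units$mL, 3), " mL)")
}

#' Mechanics step with incremental-load continuation
#'
#' Wraps \code{\link{solve_mechanics_step}}: if the Newton solve fails for
#' the full increment (large active-stress or volume jump), the active
#' stress and target volume are ramped from their values at the last
#' converged state in recursively bisected sub-increments.
#'
#' @param fe,frames,mats,state,control as in
#'   \code{\link{solve_mechanics_step}}.
#' @param sact_from active stress field at which \code{state} was
#'   converged.
#' @param sact_to new active stress field.
#' @param v_from,v_to previous and target cavity volumes (m^3).
#' @param max_depth maximum bisection depth.
#' @return converged state (see \code{\link{solve_mechanics_step}}).
#' @export
solve_mechanics_ramp <- function(fe, frames, mats, sact_from, sact_to,
                                 v_from, v_to, state, control = list(),
                                 max_depth = 6, cache = NULL, visc = NULL) {
  recurse <- function(s0, s1, v0, v1, st, depth) {
    out <- tryCatch(
      solve_mechanics_step(fe, frames, mats, s1, st, v1, control, cache,
                           visc),
      error = function(e) e)
    if (!inherits(out, "error")) return(out)
    if (depth >= max_depth)
      stop("mechanics step failed even after load bisection: ",
           conditionMessage(out))
    sm <- (s0 + s1) / 2
    vm <- (v0 + v1) / 2
    mid <- recurse(s0, sm, v0, vm, st, depth + 1)
    recurse(sm, s1, vm, v1, mid, depth + 1)
  }
  recurse(sact_from, sact_to, v_from, v_to, state, 0)
}

#' Initial (stress-free) mechanics state
#'
#' @param fe \code{lv_fe}.
#' @return list with zero displacement, pressure, multipliers.
#' @export
mechanics_state_init <- function(fe) {
  list(u = numeric(3 * fe$n_nodes), p = numeric(fe$n_vert), plv = 0,
       cvec = c(0, 0, 0))
}

#' Quasi-static passive inflation sweep
#'
#' Inflates the passive ventricle to a sequence of cavity volumes and
#' records the cavity pressure at each, continuing from the previous
#' solution.
#'
#' @param fe \code{lv_fe}.
#' @param frames quadrature-point frames.
#' @param volumes_ml target cavity volumes (mL, increasing).
#' @param mats material arrays (default homogeneous normal myocardium).
#' @return data.frame with \code{volume_ml} and \code{p_lv_mmhg}.
#' @export
passive_inflation <- function(fe, frames, volumes_ml,
                              mats = qp_materials(fe)) {
  st <- mechanics_state_init(fe)
  Sact <- numeric(fe$n_qp)
  out <- data.frame(volume_ml = volumes_ml, p_lv_mmhg = NA_real_)
  for (i in seq_along(volumes_ml)) {
    st <- solve_mechanics_step(fe, frames, mats, Sact, st,
                               volumes_ml[i] * lv_units$mL)
    out$p_lv_mmhg[i] <- convert_pressure(st$plv, "mmHg")
  }
  attr(out, "state") <- st
  out
}
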