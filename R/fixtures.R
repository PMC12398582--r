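## Deterministic test fixtures.
##
## Every module can be exercised without a full coupled run: a coarse
## mesh, a synthetic symmetric stress-tensor field with a known
## eigen-structure, a canned calcium transient, and a small circulation
## parameter set.  All fixtures are pure functions of a seed.

#' Build a named test fixture
#'
#' @param kind one of "coarse-mesh" (a ~170-element ellipsoid mesh plus FE
#'   workspace), "synthetic-stress-field" (per-quadrature-point symmetric
#'   stress tensors whose dominant eigenvectors are a known smooth field),
#'   "canned-calcium" (a one-cycle calcium trace), "toy-circulation"
#'   (small circulation parameter set plus an initialized state).
#' @param seed RNG seed stamped into the fixture.
#' @return fixture object (kind-specific list).
#' @export
make_fixtures <- function(kind = c("coarse-mesh", "synthetic-stress-field",
                                   "canned-calcium", "toy-circulation"),
                          seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    "coarse-mesh" = {
      mesh <- build_ellipsoid_mesh(lv_geometry(), "coarse")
      fe <- fe_setup(mesh)
      list(kind = kind, seed = seed, mesh = mesh, fe = fe)
    },
    "synthetic-stress-field" = {
      fx <- make_fixtures("coarse-mesh", seed)
      fe <- fx$fe
      set.seed(seed)
      ## dominant direction: smooth position-dependent unit field;
      ## eigenvalues (3, 1, 0.5) * scale
      pos <- fe$pos / max(abs(fe$pos))
      d <- cbind(cos(2 * pos[, 3]), sin(2 * pos[, 3]),
                 0.5 + pos[, 1])
      d <- d / sqrt(rowSums(d^2))
      scale <- 1e3
      S <- matrix(0, fe$n_qp, 6) # Voigt 11,22,33,23,13,12
      dom <- matrix(0, fe$n_qp, 3)
      for (iq in seq_len(fe$n_qp)) {
        v1 <- d[iq, ]
        h <- if (abs(v1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        v2 <- h - sum(h * v1) * v1
        v2 <- v2 / sqrt(sum(v2^2))
        v3 <- cross3(v1, v2)
        Sm <- scale * (3 * tcrossprod(v1) + 1 * tcrossprod(v2) +
                         0.5 * tcrossprod(v3))
        S[iq, ] <- Sm[cbind(c(1, 2, 3, 2, 1, 1), c(1, 2, 3, 3, 3, 2))]
        dom[iq, ] <- v1
      }
      list(kind = kind, seed = seed, fe = fe, S_voigt = S,
           dominant = dom, eigenvalues = scale * c(3, 1, 0.5))
    },
    "canned-calcium" = {
      p <- calcium_params()
      tt <- seq(0, p$period, by = 1e-3)
      list(kind = kind, seed = seed, params = p,
           trace = data.frame(time_s = tt,
                              ca_M = calcium_transient(tt, p)))
    },
    "toy-circulation" = {
      p <- default_circulation_params()
      st <- circulation_init(p, default_initial_pressures(),
                             v_lv = 75 * lv_units$mL)
      list(kind = kind, seed = seed, params = p, state = st)
    })
}
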