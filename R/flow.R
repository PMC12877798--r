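## Steady/quasi-steady incompressible Brinkman flow on the masked
## Cartesian staggered (MAC) grid.
##
## Momentum:  rho (V.grad)V = -grad p + mu lap V - mu invG V   (+ optional
## transient term), continuity div V = 0. The clot enters through the
## per-cell inverse permeability invG (Darcy drag). Discretization:
## finite volume, first-order implicit upwind advection with a deferred
## second-order upwind correction, central diffusion, exact discrete
## continuity. The monolithic (u, v, p) system is solved by sparse LU at
## each Picard iteration.

lin_idx <- function(i, j, m) (j - 1L) * m + i

## classify neighbor positions in a staggered-variable layout
## typ: 1 unknown, 2 Dirichlet, 3 out-of-bounds, 4 excluded (solid-solid)
nb_info <- function(ii, jj, idm, dirm, valm) {
  m <- nrow(idm); n <- ncol(idm)
  len <- length(ii)
  typ <- integer(len); id <- integer(len); val <- numeric(len)
  oob <- ii < 1L | ii > m | jj < 1L | jj > n
  typ[oob] <- 3L
  k <- which(!oob)
  if (length(k)) {
    li <- lin_idx(ii[k], jj[k], m)
    idk <- idm[li]; dirk <- dirm[li]
    unk <- idk > 0L
    typ[k[unk]] <- 1L; id[k[unk]] <- idk[unk]
    typ[k[dirk]] <- 2L; val[k[dirk]] <- valm[li][dirk]
    typ[k[!unk & !dirk]] <- 4L
  }
  list(typ = typ, id = id, val = val)
}

#' Inlet/outlet boundary conditions for the flow solve
#'
#' The volumetric flow rate is given for the equivalent circular vessel;
#' the planar model preserves its mean velocity, i.e. the per-unit-depth
#' flow is `Q / (pi D^2 / 4) * w` with `w` the inlet channel width.
#'
#' @param flow_rate inlet volumetric flow rate, m3/s
#' @param profile inlet velocity profile
#' @param outlet_pressure gauge pressure at the outlets, Pa
#' @return list of class `boundary_conditions`
#' @export
boundary_conditions <- function(flow_rate = 2e-6,
                                profile = c("parabolic", "plug"),
                                outlet_pressure = 0) {
  profile <- match.arg(profile)
  stopifnot(flow_rate >= 0)
  structure(list(flow_rate = flow_rate, profile = profile,
                 outlet_pressure = outlet_pressure),
            class = "boundary_conditions")
}

## staggered-variable layouts: ids, Dirichlet masks and values
velocity_layout <- function(mesh, bc) {
  nx <- mesh$nx; ny <- mesh$ny; fl <- mesh$fluid
  dy <- mesh$dy

  uid <- matrix(0L, nx + 1L, ny); udir <- matrix(FALSE, nx + 1L, ny)
  uval <- matrix(0, nx + 1L, ny)
  both <- fl[1:(nx - 1), , drop = FALSE] & fl[2:nx, , drop = FALSE]
  one <- xor(fl[1:(nx - 1), , drop = FALSE], fl[2:nx, , drop = FALSE])
  uid[2:nx, ][both] <- 1L              # placeholder, renumbered below
  udir[2:nx, ][one] <- TRUE            # staircase wall faces, u = 0
  udir[1, fl[1, ]] <- TRUE             # inlet (profile set below)
  uid[nx + 1L, fl[nx, ]] <- 1L         # pressure outlets
  nu <- sum(uid > 0L)
  uid[uid > 0L] <- seq_len(nu)

  vid <- matrix(0L, nx, ny + 1L); vdir <- matrix(FALSE, nx, ny + 1L)
  vval <- matrix(0, nx, ny + 1L)
  bothv <- fl[, 1:(ny - 1), drop = FALSE] & fl[, 2:ny, drop = FALSE]
  onev <- xor(fl[, 1:(ny - 1), drop = FALSE], fl[, 2:ny, drop = FALSE])
  vid[, 2:ny][bothv] <- 1L
  vdir[, 2:ny][onev] <- TRUE
  vdir[, 1][fl[, 1]] <- TRUE           # bottom box wall
  vdir[, ny + 1L][fl[, ny]] <- TRUE    # top box wall
  nv <- sum(vid > 0L)
  vid[vid > 0L] <- seq_len(nv)

  ## inlet profile over the left-edge fluid faces, scaled to the exact
  ## per-depth flow rate
  geom <- mesh$geom
  j_in <- which(fl[1, ])
  w_in <- geom$branches[[geom$inlet_branch]]$base_width * MM
  d_circ <- w_in
  u_mean <- bc$flow_rate / (pi * d_circ^2 / 4)
  qbar <- u_mean * w_in
  yj <- (j_in - 0.5) * dy
  ycm <- geom$yc * MM
  prof <- if (bc$profile == "plug") rep(1, length(j_in))
          else pmax(0, 1 - ((yj - ycm) / (w_in / 2))^2)
  if (sum(prof) * dy <= 0) stop("empty inlet")
  uval[1, j_in] <- prof * qbar / (sum(prof) * dy)

  list(uid = uid, udir = udir, uval = uval, nu = nu,
       vid = vid, vdir = vdir, vval = vval, nv = nv, qbar = qbar)
}

## fill unknown + Dirichlet values into full staggered matrices
full_field <- function(id, dir, val, x) {
  out <- val
  out[id > 0L] <- x[id[id > 0L]]
  out
}

## first- and second-order upwind advection of one velocity component,
## evaluated explicitly on a full field (for the deferred correction)
explicit_advection <- function(F, valid, ua, va, rows_i, rows_j, h1, h2, rho) {
  m <- nrow(F)
  P <- lin_idx(rows_i, rows_j, m)
  gv <- function(di, dj) {
    ii <- rows_i + di; jj <- rows_j + dj
    ok <- ii >= 1L & ii <= m & jj >= 1L & jj <= ncol(F)
    v <- numeric(length(ii)); vl <- logical(length(ii))
    li <- lin_idx(ii[ok], jj[ok], m)
    v[ok] <- F[li]; vl[ok] <- valid[li]
    list(v = v, ok = vl)
  }
  W <- gv(-1L, 0L); E <- gv(1L, 0L); WW <- gv(-2L, 0L); EE <- gv(2L, 0L)
  S <- gv(0L, -1L); N <- gv(0L, 1L); SS <- gv(0L, -2L); NN <- gv(0L, 2L)
  fP <- F[P]
  a1x <- pmax(ua, 0) * (fP - W$v) / h1 + pmin(ua, 0) * (E$v - fP) / h1
  a1y <- pmax(va, 0) * (fP - S$v) / h2 + pmin(va, 0) * (N$v - fP) / h2
  ## second order where the two upstream values exist
  a2x <- a1x
  up <- ua > 0 & W$ok & WW$ok
  a2x[up] <- ua[up] * (3 * fP[up] - 4 * W$v[up] + WW$v[up]) / (2 * h1)
  dn <- ua < 0 & E$ok & EE$ok
  a2x[dn] <- ua[dn] * (-3 * fP[dn] + 4 * E$v[dn] - EE$v[dn]) / (2 * h1)
  a2y <- a1y
  up <- va > 0 & S$ok & SS$ok
  a2y[up] <- va[up] * (3 * fP[up] - 4 * S$v[up] + SS$v[up]) / (2 * h2)
  dn <- va < 0 & N$ok & NN$ok
  a2y[dn] <- va[dn] * (-3 * fP[dn] + 4 * N$v[dn] - NN$v[dn]) / (2 * h2)
  rho * (a2x + a2y - a1x - a1y)
}

#' Solve steady (or quasi-steady) Brinkman flow
#'
#' @param mesh a `clot_mesh`
#' @param inv_perm per-cell inverse permeability 1/m2: `NULL` (clot-free),
#'   a numeric vector over fluid cells, or a `resistance_field`
#' @param bc a [boundary_conditions()]
#' @param props a [fluid_properties()]
#' @param tol Picard convergence tolerance on the relative velocity change
#' @param advection include the inertial term (Picard-iterated); with
#'   `FALSE` the linear Stokes-Brinkman problem is solved in one step
#' @param second_order use the deferred-correction second-order upwind
#'   advection scheme
#' @param max_iter Picard iteration cap
#' @param relax Picard under-relaxation factor
#' @param warm_start a previous `flow_field` on the same mesh
#' @param dt optional physical time-step: adds the transient term
#'   `rho (V - V_old)/dt` with `V_old` from `warm_start` (quasi-steady
#'   runs leave this `NULL`)
#' @return list of class `flow_field` with staggered `u`, `v`, cell
#'   pressure `p`, cell-centered velocities, divergence residual and the
#'   Picard history
#' @export
solve_flow <- function(mesh, inv_perm = NULL, bc = boundary_conditions(),
                       props = fluid_properties(), tol = 1e-4,
                       advection = TRUE, second_order = TRUE,
                       max_iter = 60L, relax = 0.85,
                       warm_start = NULL, dt = NULL) {
  nx <- mesh$nx; ny <- mesh$ny
  dx <- mesh$dx; dy <- mesh$dy
  mu <- props$viscosity; rho <- props$density
  fl <- mesh$fluid; cid <- mesh$cell_id; nc <- mesh$n_cells

  invg <- matrix(0, nx, ny)
  if (!is.null(inv_perm)) {
    if (inherits(inv_perm, "resistance_field")) inv_perm <- inv_perm$inv_g_clot
    if (any(inv_perm < 0)) stop("negative inverse permeability")
    invg[fl] <- inv_perm[mesh$cells$id]
  }

  lay <- velocity_layout(mesh, bc)
  uid <- lay$uid; udir <- lay$udir; uval <- lay$uval
  vid <- lay$vid; vdir <- lay$vdir; vval <- lay$vval
  nu <- lay$nu; nv <- lay$nv
  ntot <- nu + nv + nc
  vol <- dx * dy

  Upos <- which(uid > 0L)
  u_i <- ((Upos - 1L) %% (nx + 1L)) + 1L
  u_j <- ((Upos - 1L) %/% (nx + 1L)) + 1L
  Vpos <- which(vid > 0L)
  v_i <- ((Vpos - 1L) %% nx) + 1L
  v_j <- ((Vpos - 1L) %/% nx) + 1L
  uvalid <- uid > 0L | udir
  vvalid <- vid > 0L | vdir

  u_prev <- full_field(uid, udir, uval, numeric(nu))
  v_prev <- full_field(vid, vdir, vval, numeric(nv))
  if (!is.null(warm_start)) { u_prev <- warm_start$u; v_prev <- warm_start$v }
  u_old <- u_prev; v_old <- v_prev   # transient reference

  ## neighbor tables (fixed over Picard iterations)
  uW <- nb_info(u_i - 1L, u_j, uid, udir, uval)
  uE <- nb_info(u_i + 1L, u_j, uid, udir, uval)
  uS <- nb_info(u_i, u_j - 1L, uid, udir, uval)
  uN <- nb_info(u_i, u_j + 1L, uid, udir, uval)
  vW <- nb_info(v_i - 1L, v_j, vid, vdir, vval)
  vE <- nb_info(v_i + 1L, v_j, vid, vdir, vval)
  vS <- nb_info(v_i, v_j - 1L, vid, vdir, vval)
  vN <- nb_info(v_i, v_j + 1L, vid, vdir, vval)

  ## inverse permeability at u/v faces (average of adjacent fluid cells)
  cell_invg <- function(ii, jj) {
    ok <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny
    g <- numeric(length(ii)); f <- logical(length(ii))
    li <- lin_idx(ii[ok], jj[ok], nx)
    g[ok] <- invg[li]; f[ok] <- fl[li]
    list(g = g, f = f)
  }
  gl <- cell_invg(u_i - 1L, u_j); gr <- cell_invg(u_i, u_j)
  u_invg <- ifelse(gl$f & gr$f, (gl$g + gr$g) / 2, pmax(gl$g, gr$g))
  gb <- cell_invg(v_i, v_j - 1L); gt <- cell_invg(v_i, v_j)
  v_invg <- ifelse(gb$f & gt$f, (gb$g + gt$g) / 2, pmax(gb$g, gt$g))

  ## pressure columns for momentum rows
  pcol <- function(ii, jj) {
    ok <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny
    id <- integer(length(ii))
    id[ok] <- cid[lin_idx(ii[ok], jj[ok], nx)]
    id
  }
  u_pW <- pcol(u_i - 1L, u_j); u_pE <- pcol(u_i, u_j)
  v_pS <- pcol(v_i, v_j - 1L); v_pN <- pcol(v_i, v_j)

  ## One momentum component. Sides: "stream" = the component's own axis
  ## (W/E for u, S/N for v; spacing h1), "cross" = the other axis (h2).
  ## adv_stream/adv_cross are the advecting velocities along those axes.
  ## Out-of-bounds cross neighbors: minus side and, for u, both sides are
  ## solid walls (no-slip at half a cell); the plus-side x-neighbor of v
  ## in the last column is the outlet plane (zero gradient).
  assemble_momentum <- function(rows, off, stream_m, stream_p, cross_m, cross_p,
                                h1, h2, adv_stream, adv_cross, face_invg,
                                pA, pB, cross_p_oob_wall, trip) {
    cs <- mu * vol / h1^2; cc <- mu * vol / h2^2
    n <- length(rows)
    diag <- rep(0, n); bw <- rep(0, n)
    add <- function(cols, vals, keep) {
      trip$i <- c(trip$i, rows[keep]); trip$j <- c(trip$j, cols[keep])
      trip$x <- c(trip$x, vals[keep]); trip
    }
    ## -- streamwise viscous: neighbors present (1/2) or zero-gradient (3)
    for (tt in list(stream_m, stream_p)) {
      pres <- tt$typ <= 2L
      diag[pres] <- diag[pres] + cs
      trip <- add(tt$id + off, rep(-cs, n), tt$typ == 1L)
      isdir <- tt$typ == 2L
      bw[isdir] <- bw[isdir] + cs * tt$val[isdir]
    }
    ## -- cross viscous: per-side class present / wall-at-half-cell / zerograd
    wall_m <- cross_m$typ == 4L | cross_m$typ == 3L   # minus oob is always a wall
    wall_p <- cross_p$typ == 4L | (cross_p$typ == 3L & cross_p_oob_wall)
    zg_p <- cross_p$typ == 3L & !cross_p_oob_wall
    pres_m <- cross_m$typ <= 2L; pres_p <- cross_p$typ <= 2L
    diag[pres_m] <- diag[pres_m] + cc
    diag[pres_p] <- diag[pres_p] + cc
    diag[wall_m] <- diag[wall_m] + 2 * cc
    diag[wall_p] <- diag[wall_p] + 2 * cc
    ## quadratic no-slip fit (exact for parabolic profiles): when exactly
    ## one side is a wall and the other carries a value, the pair
    ## (diag 4cc, neighbor -4/3 cc) replaces the linear one-sided fluxes
    q_m <- wall_m & pres_p   # wall below/left, value above/right
    q_p <- wall_p & pres_m
    diag[q_m | q_p] <- diag[q_m | q_p] + cc
    cmcoef <- rep(-cc, n); cmcoef[q_p] <- -(4 / 3) * cc
    cpcoef <- rep(-cc, n); cpcoef[q_m] <- -(4 / 3) * cc
    trip <- add(cross_m$id + off, cmcoef, cross_m$typ == 1L)
    isd <- cross_m$typ == 2L
    bw[isd] <- bw[isd] - cmcoef[isd] * cross_m$val[isd]
    trip <- add(cross_p$id + off, cpcoef, cross_p$typ == 1L)
    isd <- cross_p$typ == 2L
    bw[isd] <- bw[isd] - cpcoef[isd] * cross_p$val[isd]
    ## -- advection, first-order upwind (Picard-linearized)
    if (!is.null(adv_stream)) {
      for (ax in list(list(a = adv_stream, m = stream_m, p = stream_p,
                           h = h1, zg_p = stream_p$typ == 3L),
                      list(a = adv_cross, m = cross_m, p = cross_p,
                           h = h2, zg_p = zg_p))) {
        pos <- pmax(ax$a, 0) * vol / ax$h
        neg <- pmin(ax$a, 0) * vol / ax$h
        diag <- diag + rho * pos + rho * (-neg) * !ax$zg_p
        trip <- add(ax$m$id + off, -rho * pos, ax$m$typ == 1L & pos > 0)
        isd <- ax$m$typ == 2L & pos > 0
        bw[isd] <- bw[isd] + rho * pos[isd] * ax$m$val[isd]
        trip <- add(ax$p$id + off, rho * neg, ax$p$typ == 1L & neg < 0)
        isd <- ax$p$typ == 2L & neg < 0
        bw[isd] <- bw[isd] - rho * neg[isd] * ax$p$val[isd]
      }
    }
    ## -- Brinkman drag
    diag <- diag + mu * face_invg * vol
    ## -- pressure gradient: (p_plus - p_minus)/h1 * vol
    gp <- vol / h1
    trip <- add(pA + nu + nv, rep(-gp, n), pA > 0L)
    trip <- add(pB + nu + nv, rep(gp, n), pB > 0L)
    bw[pB == 0L] <- bw[pB == 0L] - gp * bc$outlet_pressure  # outlet ghost
    trip$i <- c(trip$i, rows); trip$j <- c(trip$j, rows); trip$x <- c(trip$x, diag)
    list(trip = trip, b = bw)
  }

  hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    ## advecting velocities at faces from the previous iterate
    if (advection) {
      g0 <- function(M, ii, jj) {
        ok <- ii >= 1L & ii <= nrow(M) & jj >= 1L & jj <= ncol(M)
        out <- numeric(length(ii))
        out[ok] <- M[lin_idx(ii[ok], jj[ok], nrow(M))]
        out
      }
      ua_u <- u_prev[Upos]
      va_u <- (g0(v_prev, u_i - 1L, u_j) + g0(v_prev, u_i, u_j) +
               g0(v_prev, u_i - 1L, u_j + 1L) + g0(v_prev, u_i, u_j + 1L)) / 4
      va_v <- v_prev[Vpos]
      ua_v <- (g0(u_prev, v_i, v_j - 1L) + g0(u_prev, v_i + 1L, v_j - 1L) +
               g0(u_prev, v_i, v_j) + g0(u_prev, v_i + 1L, v_j)) / 4
    } else {
      ua_u <- va_u <- ua_v <- va_v <- NULL
    }

    trip <- list(i = integer(0), j = integer(0), x = numeric(0))
    b <- numeric(ntot)

    ru <- uid[Upos]
    res_u <- assemble_momentum(ru, 0L, uW, uE, uS, uN, dx, dy,
                               ua_u, va_u, u_invg, u_pW, u_pE,
                               cross_p_oob_wall = TRUE, trip)
    trip <- res_u$trip; b[ru] <- res_u$b
    rv <- vid[Vpos] + nu
    res_v <- assemble_momentum(rv, nu, vS, vN, vW, vE, dy, dx,
                               va_v, ua_v, v_invg, v_pS, v_pN,
                               cross_p_oob_wall = FALSE, trip)
    trip <- res_v$trip; b[rv] <- res_v$b

    ## transient term
    if (!is.null(dt)) {
      trip$i <- c(trip$i, ru, rv); trip$j <- c(trip$j, ru, rv)
      trip$x <- c(trip$x, rep(rho * vol / dt, nu + nv))
      b[ru] <- b[ru] + rho * vol / dt * u_old[Upos]
      b[rv] <- b[rv] + rho * vol / dt * v_old[Vpos]
    }

    ## deferred second-order upwind correction (explicit, previous
    ## iterate; zero on a cold start where the previous field is zero)
    if (advection && second_order) {
      cu <- explicit_advection(u_prev, uvalid, ua_u, va_u, u_i, u_j, dx, dy, rho)
      cv <- explicit_advection(v_prev, vvalid, ua_v, va_v, v_i, v_j, dx, dy, rho)
      b[ru] <- b[ru] - cu * vol
      b[rv] <- b[rv] - cv * vol
    }

    ## continuity rows: (uE - uW) dy + (vN - vS) dx = 0 per fluid cell
    ci <- mesh$cells$i; cj <- mesh$cells$j
    rp <- mesh$cells$id + nu + nv
    for (fc in list(list(m = "u", ii = ci + 1L, jj = cj, s = +dy),
                    list(m = "u", ii = ci, jj = cj, s = -dy),
                    list(m = "v", ii = ci, jj = cj + 1L, s = +dx),
                    list(m = "v", ii = ci, jj = cj, s = -dx))) {
      if (fc$m == "u") {
        nb <- nb_info(fc$ii, fc$jj, uid, udir, uval); offm <- 0L
      } else {
        nb <- nb_info(fc$ii, fc$jj, vid, vdir, vval); offm <- nu
      }
      unk <- nb$typ == 1L
      trip$i <- c(trip$i, rp[unk]); trip$j <- c(trip$j, nb$id[unk] + offm)
      trip$x <- c(trip$x, rep(fc$s, sum(unk)))
      isd <- nb$typ == 2L
      b[rp[isd]] <- b[rp[isd]] - fc$s * nb$val[isd]
    }

    A <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                              dims = c(ntot, ntot))
    ## row equilibration: the Brinkman-penalized momentum rows are many
    ## orders larger than the continuity rows; scaling each row by its
    ## largest entry keeps the sparse LU well-pivoted without changing
    ## the solution
    rs <- 1 / pmax(Matrix::rowSums(abs(A)), 1e-300)
    A <- Matrix::Diagonal(x = rs) %*% A
    sol <- as.numeric(Matrix::solve(A, rs * b))
    u_new <- full_field(uid, udir, uval, sol[seq_len(nu)])
    v_new <- full_field(vid, vdir, vval, sol[nu + seq_len(nv)])
    p_new <- sol[nu + nv + seq_len(nc)]

    uscale <- max(abs(u_new), abs(v_new), 1e-30)
    delta <- max(abs(u_new - u_prev), abs(v_new - v_prev)) / uscale
    hist <- c(hist, delta)
    if (!advection) { u_prev <- u_new; v_prev <- v_new; p <- p_new; break }
    a <- if (it == 1L) 1 else relax
    u_prev <- a * u_new + (1 - a) * u_prev
    v_prev <- a * v_new + (1 - a) * v_prev
    p <- p_new
    if (delta < tol) { u_prev <- u_new; v_prev <- v_new; break }
    if (it == max_iter) {
      err <- simpleError(sprintf(
        "flow solve did not converge in %d Picard iterations (last change %.3g)",
        max_iter, delta))
      err$residual_history <- hist
      stop(err)
    }
  }

  u <- u_prev; v <- v_prev
  ## cell-centered fields and divergence residual
  uc <- (u[1:nx, , drop = FALSE] + u[2:(nx + 1), , drop = FALSE]) / 2
  vc <- (v[, 1:ny, drop = FALSE] + v[, 2:(ny + 1), drop = FALSE]) / 2
  div <- (u[2:(nx + 1), , drop = FALSE] - u[1:nx, , drop = FALSE]) / dx +
         (v[, 2:(ny + 1), drop = FALSE] - v[, 1:ny, drop = FALSE]) / dy
  div[!fl] <- 0
  pm <- matrix(NA_real_, nx, ny); pm[fl] <- p[cid[fl]]

  structure(list(
    u = u, v = v, p = pm, uc = uc, vc = vc,
    div_residual = max(abs(div)),
    picard_history = hist, iterations = length(hist),
    bc = bc, props = props, qbar = lay$qbar,
    inv_perm = invg
  ), class = "flow_field")
}

#' Wall shear stress and shear rate along the channel walls
#'
#' The shear stress at each wall boundary face is obtained from a
#' quadratic fit of the wall-tangential velocity through the two nearest
#' cell centers along the wall normal (with the no-slip value at the
#' wall), which is exact for locally parabolic profiles. The shear rate is
#' `gamma_dot = tau / mu`.
#'
#' @param flow a `flow_field`
#' @param mesh the `clot_mesh` it was solved on
#' @param props the [fluid_properties()]
#' @return data.frame: wall faces with `tau_pa`, `gamma_dot`,
#'   `arclength_mm`, branch and band/segment annotation
#' @export
wall_shear <- function(flow, mesh, props = fluid_properties()) {
  mu <- props$viscosity
  f <- mesh$faces[mesh$faces$label == "wall", , drop = FALSE]
  nx <- mesh$nx; ny <- mesh$ny; fl <- mesh$fluid
  uc <- flow$uc; vc <- flow$vc
  tang <- function(ii, jj, horiz) {
    ok <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny
    v <- numeric(length(ii)); have <- logical(length(ii))
    li <- lin_idx(ii[ok], jj[ok], nx)
    v[ok] <- if (horiz) uc[li] else vc[li]
    have[ok] <- fl[li]
    list(v = v, ok = have)
  }
  horiz <- f$norm_y != 0     # wall normal along y => tangential velocity u
  di <- as.integer(-f$norm_x); dj <- as.integer(-f$norm_y)  # into the fluid
  s1 <- tang(f$i, f$j, TRUE); s1v <- tang(f$i, f$j, FALSE)
  u1 <- ifelse(horiz, s1$v, s1v$v)
  s2 <- tang(f$i + di, f$j + dj, TRUE); s2v <- tang(f$i + di, f$j + dj, FALSE)
  u2 <- ifelse(horiz, s2$v, s2v$v)
  ok2 <- ifelse(horiz, s2$ok, s2v$ok)
  h <- ifelse(horiz, mesh$dy, mesh$dx)
  tau <- ifelse(ok2, mu * abs(9 * u1 - u2) / (3 * h), mu * abs(u1) * 2 / h)
  out <- data.frame(
    face_id = f$id, arclength_mm = f$s_mm, tau_pa = tau,
    gamma_dot = tau / mu, branch = f$branch,
    in_band = f$in_band, segment = f$segment,
    i = f$i, j = f$j, side = f$side, x_mm = f$x_mm, y_mm = f$y_mm
  )
  class(out) <- c("wall_shear_profile", "data.frame")
  out
}

#' Per-outlet flow rates and fractions of the inlet flow
#'
#' @param flow a `flow_field`
#' @param mesh the `clot_mesh`
#' @return list with per-depth inlet flow, per-outlet flows, and fractions
#' @export
branch_flow_rates <- function(flow, mesh) {
  f <- mesh$faces
  dy <- mesh$dy
  q_in <- sum(flow$u[1, mesh$fluid[1, ]]) * dy
  outs <- sort(unique(f$label[grepl("^outlet", f$label)]))
  q_out <- vapply(outs, function(lb) {
    jj <- f$j[f$label == lb]
    sum(flow$u[mesh$nx + 1L, jj]) * dy
  }, numeric(1))
  list(inlet = q_in, outlet = q_out,
       fractions = if (q_in > 0) q_out / q_in else q_out * 0,
       balance = (sum(q_out) - q_in) / max(abs(q_in), 1e-300))
}

#' Reynolds number of a circular vessel
#'
#' `Re = rho U D / mu` with `U = Q / (pi D^2 / 4)`.
#'
#' @param Q volumetric flow rate, m3/s
#' @param D vessel diameter, m
#' @param props a [fluid_properties()]
#' @return dimensionless Reynolds number
#' @export
#' @examples
#' reynolds_number(10 / 6e7, 2e-3)  # ~ 33.5 for blood at 10 ml/min in 2 mm
reynolds_number <- function(Q, D, props = fluid_properties()) {
  stopifnot(D > 0)
  U <- Q / (pi * D^2 / 4)
  props$density * U * D / props$viscosity
}
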