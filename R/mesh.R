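## Mask-based Cartesian meshing of channel geometries.
##
## The mesh is a uniform structured grid over the geometry bounding box;
## cells whose centers fall outside the lumen are masked solid. Walls are
## therefore staircase except along axis-aligned straight sections, which
## are resolved exactly. Mesh coordinates are SI meters; arclength labels
## on faces are kept in mm for reporting.

MM <- 1e-3

#' Generate a structured mask-based mesh for a channel geometry
#'
#' @param geom a `channel_geometry` from [build_stenosed_tube()] or
#'   [build_bifurcation()]
#' @param resolution target cell size, mm
#' @return list of class `clot_mesh`; key members:
#'   \describe{
#'     \item{nx, ny, dx, dy}{grid shape and spacings (m)}
#'     \item{fluid}{`nx x ny` logical mask}
#'     \item{cell_id}{`nx x ny` integer matrix, 0 for solid, else 1..n_cells}
#'     \item{cells}{data.frame of fluid cells (centers in m, branch, s_mm, area_m2)}
#'     \item{faces}{data.frame of boundary faces with labels
#'       `inlet`/`outlet_1`/`outlet_2`/`wall`, unit normals, arclength and
#'       thrombogenic-band/segment annotation}
#'   }
#' @export
generate_mesh <- function(geom, resolution) {
  stopifnot(inherits(geom, "channel_geometry"), resolution > 0)
  Lx <- geom$box[1]; Ly <- geom$box[2]
  nx <- max(4L, as.integer(round(Lx / resolution)))
  ny <- max(4L, as.integer(round(Ly / resolution)))
  if (ny %% 2 == 1) ny <- ny + 1L   # keep the centerline on a face: preserves mirror symmetry
  dx <- Lx / nx; dy <- Ly / ny      # mm for classification
  ## throat must be resolved
  sb <- geom$stenosed_branch
  if (!is.null(sb) && !is.null(geom$band)) {
    ss <- seq(geom$band[1], geom$band[2], length.out = 201)
    throat <- min(vapply(sb, function(b) min(branch_width(geom, b, ss)),
                         numeric(1)))
    if (throat / max(dx, dy) < 4)
      stop("resolution too coarse: the stenosis throat must span at least 4 cells")
  }
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dy
  pts <- expand.grid(x = xc, y = yc)            # i fastest
  loc <- locate_points(geom, pts$x, pts$y)
  fluid <- matrix(loc$inside, nx, ny)
  branch_m <- matrix(loc$branch, nx, ny)
  s_m <- matrix(loc$s, nx, ny)

  ## keep only cells connected to the inlet (flood fill)
  fluid <- flood_from_inlet(fluid)
  n_cells <- sum(fluid)
  if (n_cells == 0) stop("empty mesh: no fluid cells connected to the inlet")
  cell_id <- matrix(0L, nx, ny)
  cell_id[fluid] <- seq_len(n_cells)

  idx <- which(fluid, arr.ind = TRUE)
  cells <- data.frame(
    id = cell_id[fluid],
    i = idx[, 1], j = idx[, 2],
    x = xc[idx[, 1]] * MM, y = yc[idx[, 2]] * MM,
    branch = branch_m[fluid], s_mm = s_m[fluid],
    area = dx * dy * MM^2
  )
  cells <- cells[order(cells$id), ]

  faces <- boundary_faces(geom, fluid, cell_id, branch_m, s_m, xc, yc, dx, dy)

  structure(list(
    geom = geom, resolution = resolution,
    nx = nx, ny = ny, dx = dx * MM, dy = dy * MM,
    fluid = fluid, cell_id = cell_id, n_cells = n_cells,
    cells = cells, faces = faces,
    area_total = n_cells * dx * dy * MM^2
  ), class = "clot_mesh")
}

flood_from_inlet <- function(fluid) {
  nx <- nrow(fluid); ny <- ncol(fluid)
  seen <- matrix(FALSE, nx, ny)
  frontier <- which(fluid[1, ])
  seen[1, frontier] <- TRUE
  active <- cbind(rep(1L, length(frontier)), frontier)
  while (nrow(active) > 0) {
    nb <- rbind(
      cbind(active[, 1] + 1L, active[, 2]),
      cbind(active[, 1] - 1L, active[, 2]),
      cbind(active[, 1], active[, 2] + 1L),
      cbind(active[, 1], active[, 2] - 1L)
    )
    ok <- nb[, 1] >= 1 & nb[, 1] <= nx & nb[, 2] >= 1 & nb[, 2] <= ny
    nb <- nb[ok, , drop = FALSE]
    ok <- fluid[nb] & !seen[nb]
    nb <- unique(nb[ok, , drop = FALSE])
    if (nrow(nb) == 0) break
    seen[nb] <- TRUE
    active <- nb
  }
  fluid & seen
}

boundary_faces <- function(geom, fluid, cell_id, branch_m, s_m, xc, yc, dx, dy) {
  nx <- nrow(fluid); ny <- ncol(fluid)
  rows <- list()
  solid_at <- function(i, j) {
    out <- i < 1 | i > nx | j < 1 | j > ny
    res <- rep(TRUE, length(i))
    res[!out] <- !fluid[cbind(i[!out], j[!out])]
    res
  }
  idx <- which(fluid, arr.ind = TRUE)
  sides <- list(W = c(-1L, 0L), E = c(1L, 0L), S = c(0L, -1L), N = c(0L, 1L))
  for (sd in names(sides)) {
    off <- sides[[sd]]
    bdry <- solid_at(idx[, 1] + off[1], idx[, 2] + off[2])
    if (!any(bdry)) next
    ii <- idx[bdry, 1]; jj <- idx[bdry, 2]
    on_left <- sd == "W" & ii == 1L
    on_right <- sd == "E" & ii == nx
    lbl <- rep("wall", length(ii))
    lbl[on_left] <- "inlet"
    if (geom$type == "tube") {
      lbl[on_right] <- "outlet_1"
    } else {
      up <- branch_m[cbind(ii, jj)] == geom$outlet_branches[["outlet_1"]]
      lbl[on_right & up] <- "outlet_1"
      lbl[on_right & !up] <- "outlet_2"
    }
    fx <- xc[ii] + if (off[1] != 0) off[1] * dx / 2 else 0
    fy <- yc[jj] + if (off[2] != 0) off[2] * dy / 2 else 0
    rows[[sd]] <- data.frame(
      cell = cell_id[cbind(ii, jj)], i = ii, j = jj, side = sd,
      label = lbl, branch = branch_m[cbind(ii, jj)],
      s_mm = s_m[cbind(ii, jj)],
      x_mm = fx, y_mm = fy,
      norm_x = off[1], norm_y = off[2],
      len = (if (off[1] != 0) dy else dx) * MM
    )
  }
  faces <- do.call(rbind, rows)
  faces <- faces[order(faces$cell, faces$side), ]
  faces$id <- seq_len(nrow(faces))
  rownames(faces) <- NULL

  ## thrombogenic-candidate band + equal-arclength segments
  faces$in_band <- faces$label == "wall" &
    !is.na(faces$branch) & faces$branch %in% geom$stenosed_branch &
    faces$s_mm >= geom$band[1] & faces$s_mm <= geom$band[2]
  faces$segment <- NA_integer_
  nseg <- geom$n_segments
  if (!is.null(nseg) && nseg >= 1 && any(faces$in_band)) {
    edges <- seq(geom$band[1], geom$band[2], length.out = nseg + 1)
    k <- findInterval(faces$s_mm[faces$in_band], edges,
                      rightmost.closed = TRUE, all.inside = TRUE)
    faces$segment[faces$in_band] <- as.integer(k)
  }
  faces
}
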