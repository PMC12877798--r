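## Synthetic 2D vessel geometries: stenosed tubes and Y-bifurcations.
## All geometric quantities are in mm; the mesh converts to SI meters.

#' Stenosis specification
#'
#' @param degree fractional diameter (or area) reduction, in \[0, 1)
#' @param length axial extent of the stenosis, mm
#' @param center_position arclength of the stenosis center along its branch,
#'   mm; `NULL` means mid-branch (resolved when the geometry is built)
#' @param basis `"diameter"` (default) or `"area"`; an area degree `g` is
#'   converted to the equivalent diameter degree `1 - sqrt(1 - g)`
#' @return list of class `stenosis_spec`
#' @export
stenosis_spec <- function(degree, length, center_position = NULL,
                          basis = c("diameter", "area")) {
  basis <- match.arg(basis)
  if (degree < 0 || degree >= 1)
    stop("stenosis degree must be in [0, 1): full occlusion of the unclotted lumen is non-physical")
  stopifnot(length > 0)
  dd <- if (basis == "area") 1 - sqrt(1 - degree) else degree
  structure(list(degree = degree, length = length,
                 center_position = center_position, basis = basis,
                 degree_by_diameter = dd),
            class = "stenosis_spec")
}

#' Local diameter along a stenosed branch
#'
#' Smooth cosine diameter-reduction bump: the diameter equals
#' `base_diameter` outside `[center - length/2, center + length/2]` and
#' dips to `base_diameter * (1 - degree_by_diameter)` at the center.
#'
#' @param s arclength coordinate(s) along the branch, mm
#' @param base_diameter unstenosed diameter, mm
#' @param spec a [stenosis_spec()]; its `center_position` must be set
#' @return local diameter(s), mm
#' @export
stenosis_profile <- function(s, base_diameter, spec) {
  stopifnot(base_diameter > 0, inherits(spec, "stenosis_spec"))
  ctr <- spec$center_position
  if (is.null(ctr)) stop("stenosis center_position is not set")
  dd <- spec$degree_by_diameter
  w <- rep(base_diameter, length(s))
  inside <- abs(s - ctr) < spec$length / 2
  if (any(inside)) {
    xi <- (s[inside] - ctr) / spec$length          # in (-1/2, 1/2)
    w[inside] <- base_diameter * (1 - dd * 0.5 * (1 + cos(2 * pi * xi)))
  }
  w
}

new_branch <- function(name, origin, dir, length, base_width,
                       stenosis = NULL, eccentric = FALSE) {
  dir <- dir / sqrt(sum(dir^2))
  if (!is.null(stenosis) && is.null(stenosis$center_position))
    stenosis$center_position <- length / 2
  if (!is.null(stenosis) &&
      (stenosis$center_position - stenosis$length / 2 < 0 ||
       stenosis$center_position + stenosis$length / 2 > length))
    stop("stenosis extent exceeds the branch length")
  list(name = name, origin = origin, dir = dir,
       normal = c(-dir[2], dir[1]), length = length,
       base_width = base_width, stenosis = stenosis, eccentric = eccentric)
}

#' Local channel width of a branch
#'
#' @param geom a `channel_geometry`
#' @param branch branch name
#' @param s arclength coordinate(s), mm
#' @return local width(s), mm
#' @export
branch_width <- function(geom, branch, s) {
  br <- geom$branches[[branch]]
  if (is.null(br)) stop("unknown branch: ", branch)
  if (is.null(br$stenosis)) rep(br$base_width, length(s))
  else stenosis_profile(s, br$base_width, br$stenosis)
}

## For each point, (s, t) coordinates in each branch frame and an
## inside test. Returns the containing branch (smallest normalized
## centerline offset wins near the junction) or NA.
locate_points <- function(geom, x, y) {
  n <- length(x)
  best <- rep(NA_character_, n)
  best_q <- rep(Inf, n)
  best_s <- rep(NA_real_, n)
  for (br in geom$branches) {
    rx <- x - br$origin[1]; ry <- y - br$origin[2]
    s <- rx * br$dir[1] + ry * br$dir[2]
    t <- rx * br$normal[1] + ry * br$normal[2]
    w <- if (is.null(br$stenosis)) rep(br$base_width, n)
         else stenosis_profile(pmin(pmax(s, 0), br$length), br$base_width, br$stenosis)
    if (br$eccentric) t <- t + (br$base_width - w) / 2   # one-sided bump
    ok <- s >= 0 & s <= br$length & abs(t) <= w / 2
    q <- abs(t) / (w / 2)
    take <- ok & q < best_q
    best[take] <- br$name
    best_q[take] <- q[take]
    best_s[take] <- s[take]
  }
  list(branch = best, s = best_s, inside = !is.na(best))
}

#' Build a single stenosed tube geometry
#'
#' A straight channel of the given diameter with a cosine stenosis bump,
#' whose axial extent is the thrombogenic-candidate band, partitioned into
#' `n_segments` equal-arclength labeled segments.
#'
#' @param diameter unstenosed channel diameter, mm
#' @param spec a [stenosis_spec()]
#' @param upstream_length,downstream_length channel length before/after the
#'   stenosis band, mm
#' @param n_segments number of equal segments the band is divided into
#' @param eccentric if `TRUE` the lumen narrows from one wall only
#' @return list of class `channel_geometry`
#' @export
#' @examples
#' g <- build_stenosed_tube(2, stenosis_spec(0.35, 4))
#' min(branch_width(g, "tube", seq(0, g$length, by = 0.01)))  # 1.3 mm
build_stenosed_tube <- function(diameter, spec, upstream_length = 2 * diameter,
                                downstream_length = 4 * diameter,
                                n_segments = 5, eccentric = FALSE) {
  stopifnot(diameter > 0, inherits(spec, "stenosis_spec"), n_segments >= 1)
  total <- upstream_length + spec$length + downstream_length
  ctr <- upstream_length + spec$length / 2
  sp <- spec; sp$center_position <- ctr
  yc <- diameter / 2
  br <- new_branch("tube", c(0, yc), c(1, 0), total, diameter, sp, eccentric)
  band <- c(ctr - spec$length / 2, ctr + spec$length / 2)
  structure(list(
    type = "tube", branches = list(tube = br),
    box = c(total, diameter), yc = yc, length = total,
    inlet_branch = "tube", outlet_branches = c(outlet_1 = "tube"),
    stenosed_branch = "tube", band = band, n_segments = n_segments
  ), class = "channel_geometry")
}

#' Build an idealized planar coronary bifurcation
#'
#' A parent (LMCA) channel along the x axis splitting into two straight
#' daughter branches (LAD above, LCX below) at equal and opposite angles.
#' The stenosis bump is applied to the branch named in `params`; its axial
#' extent is recorded as the thrombogenic-candidate band.
#'
#' @param params one row of a [patient_table()] (or a list with fields
#'   `d_lmca`, `d_lad`, `d_lcx`, `stenosed_branch`, `stenosis_degree`,
#'   `stenosis_length`)
#' @param half_angle angle between each daughter and the parent axis, degrees
#' @param length_factor branch length as a multiple of the local diameter
#'   (lengths are extended automatically so the stenosis fits; both
#'   daughters share the longer of the two requirements so that they end on
#'   a common outlet plane)
#' @param parent_length override of the parent length, mm
#' @param branch_length override of the daughter length, mm
#' @param basis stenosis degree convention, `"diameter"` or `"area"`
#' @return list of class `channel_geometry`
#' @export
build_bifurcation <- function(params, half_angle = 30, length_factor = 10,
                              parent_length = NULL, branch_length = NULL,
                              basis = "diameter") {
  p <- as.list(params)
  stopifnot(p$d_lmca > 0, p$d_lad > 0, p$d_lcx > 0,
            p$stenosis_degree >= 0, p$stenosis_degree < 1,
            p$stenosis_length > 0)
  stenosed <- match.arg(toupper(p$stenosed_branch), c("LAD", "LCX", "BOTH"))
  th <- half_angle * pi / 180
  if (half_angle <= 0 || half_angle >= 90) stop("half_angle must be in (0, 90)")
  wl <- p$d_lad; wc <- p$d_lcx
  Lp <- if (is.null(parent_length)) length_factor * p$d_lmca else parent_length
  d_st <- if (stenosed == "LCX") wc else wl
  need_st <- p$stenosis_length * 1.25 + d_st
  Ld <- if (is.null(branch_length)) max(length_factor * max(wl, wc), need_st)
        else branch_length
  if (Ld < need_st)
    stop("branch_length too short for the requested stenosis length")
  ## daughters must separate faster than their walls approach each other
  if (2 * sin(th) * Ld / 2 < (wl + wc) / 4)
    stop("daughter branches overlap at the requested half_angle")
  sp <- stenosis_spec(p$stenosis_degree, p$stenosis_length, basis = basis)
  sp$center_position <- Ld / 2
  yc_off <- Ld * sin(th) + max(wl, wc)          # box half-height
  yc <- yc_off
  junction <- c(Lp, yc)
  ## daughters overshoot the outlet plane by a width so the full aperture
  ## where the slanted channel crosses the box edge stays open
  lad <- new_branch("LAD", junction, c(cos(th),  sin(th)), Ld + wl, wl,
                    if (stenosed %in% c("LAD", "BOTH")) sp else NULL)
  lcx <- new_branch("LCX", junction, c(cos(th), -sin(th)), Ld + wc, wc,
                    if (stenosed %in% c("LCX", "BOTH")) sp else NULL)
  parent <- new_branch("LMCA", c(0, yc), c(1, 0), Lp, p$d_lmca)
  ctr <- sp$center_position
  band <- c(ctr - sp$length / 2, ctr + sp$length / 2)
  structure(list(
    type = "bifurcation",
    branches = list(LMCA = parent, LAD = lad, LCX = lcx),
    box = c(Lp + Ld * cos(th), 2 * yc), yc = yc,
    inlet_branch = "LMCA",
    outlet_branches = c(outlet_1 = "LAD", outlet_2 = "LCX"),
    stenosed_branch = if (stenosed == "BOTH") c("LAD", "LCX") else stenosed,
    band = band, n_segments = 1L,
    half_angle = half_angle
  ), class = "channel_geometry")
}

#' Analytic area of a channel geometry
#'
#' For a tube this is the exact integral of the width; for a bifurcation it
#' is evaluated by dense midpoint sampling of the bounding box.
#'
#' @param geom a `channel_geometry`
#' @param n sampling density per direction (bifurcation only)
#' @return area in mm2
#' @export
geometry_area <- function(geom, n = 800) {
  if (geom$type == "tube") {
    br <- geom$branches$tube
    a <- br$base_width * br$length
    if (!is.null(br$stenosis))
      a <- a - br$base_width * br$stenosis$degree_by_diameter * br$stenosis$length / 2
    return(a)
  }
  hx <- geom$box[1] / n; hy <- geom$box[2] / n
  xs <- (seq_len(n) - 0.5) * hx
  ys <- (seq_len(n) - 0.5) * hy
  pts <- expand.grid(x = xs, y = ys)
  sum(locate_points(geom, pts$x, pts$y)$inside) * hx * hy
}
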