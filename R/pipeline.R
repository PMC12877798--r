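## Coupled clot-growth pipeline: flow -> shear -> species transport ->
## deposition -> resistance -> flow, with cessation detection.

#' Simulation configuration
#'
#' @param geometry a `channel_geometry`
#' @param resolution mesh resolution, mm (`NULL`: stenosis throat / 4.5)
#' @param dt coupling time step, s
#' @param t_max maximum physical time, s
#' @param kinetics_scale multiplier on every reaction/deposition rate; a
#'   factor `k` compresses the clot-growth timeline by about `k` so that
#'   scaled-down runs finish quickly (ordering and mechanism are
#'   preserved; absolute times are reported on the compressed clock)
#' @param flow_rate inlet flow, m3/s
#' @param thrombogenic_rule `"shear_threshold"`: deposition acts on
#'   in-band wall faces whose baseline shear exceeds `tau_thresh`;
#'   `"whole_band"`: every in-band wall face is an injury site
#' @param tau_thresh thrombogenic shear threshold, Pa
#' @param cessation_threshold stenosed-branch flow fraction treated as
#'   "zero flow"
#' @param cessation_sustain time the fraction must stay below the
#'   threshold, s (`NULL`: `1 / kinetics_scale`)
#' @param dep_stop_frac stop once the total deposition rate has fallen
#'   below this fraction of its running peak (`NULL` disables)
#' @param flow_tol,max_picard,advection flow-solver controls
#' @param flow_every re-solve the flow every this many coupling steps
#' @param output_every log the time series every this many steps
#' @param kinetics,clot,props,inlet parameter objects
#' @param seed integer seed recorded for synthetic-noise utilities (the
#'   pipeline itself is deterministic)
#' @return list of class `simulation_config`
#' @export
simulation_config <- function(geometry, resolution = NULL, dt = 0.05,
                              t_max = 60, kinetics_scale = 25,
                              flow_rate = 2e-6,
                              thrombogenic_rule = c("shear_threshold",
                                                    "whole_band"),
                              tau_thresh = 7,
                              cessation_threshold = 0.01,
                              cessation_sustain = NULL,
                              dep_stop_frac = 1e-4,
                              flow_tol = 1e-3, max_picard = 40L,
                              advection = TRUE, flow_every = 1L,
                              output_every = 1L,
                              kinetics = kinetic_parameters(),
                              clot = clot_parameters(),
                              props = fluid_properties(),
                              inlet = blood_concentrations(),
                              seed = 1L) {
  thrombogenic_rule <- match.arg(thrombogenic_rule)
  stopifnot(inherits(geometry, "channel_geometry"), dt > 0, t_max > 0,
            kinetics_scale >= 0, cessation_threshold > 0,
            cessation_threshold < 1)
  if (is.null(cessation_sustain))
    cessation_sustain <- max(if (kinetics_scale > 0) 1 / kinetics_scale else 0,
                             2 * dt)
  if (is.null(resolution)) {
    sb <- geometry$stenosed_branch
    ss <- seq(geometry$band[1], geometry$band[2], length.out = 201)
    throat <- min(vapply(sb, function(b) min(branch_width(geometry, b, ss)),
                         numeric(1)))
    resolution <- throat / 4.5
  }
  structure(list(
    geometry = geometry, resolution = resolution, dt = dt, t_max = t_max,
    kinetics_scale = kinetics_scale, flow_rate = flow_rate,
    thrombogenic_rule = thrombogenic_rule, tau_thresh = tau_thresh,
    cessation_threshold = cessation_threshold,
    cessation_sustain = cessation_sustain, dep_stop_frac = dep_stop_frac,
    flow_tol = flow_tol, max_picard = max_picard, advection = advection,
    flow_every = as.integer(flow_every), output_every = as.integer(output_every),
    kinetics = kinetics, clot = clot, props = props, inlet = inlet,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

## Open-channel status of the stenosed branch: connectivity of non-clot
## fluid cells from upstream of the band to downstream of it, plus the
## narrowest open cross-section (as a fraction of the local width).
open_channel_status <- function(mesh, resist, geom) {
  sb <- geom$stenosed_branch[1]
  cells <- mesh$cells
  in_br <- cells$branch == sb & !is.na(cells$branch)
  open <- in_br & !resist$clot
  band <- geom$band
  ## connectivity by BFS over the grid restricted to open branch cells
  nx <- mesh$nx; ny <- mesh$ny
  openm <- matrix(FALSE, nx, ny)
  openm[cbind(cells$i[open], cells$j[open])] <- TRUE
  src <- open & cells$s_mm < band[1]
  dst <- open & cells$s_mm > band[2]
  reached <- matrix(FALSE, nx, ny)
  if (any(src)) {
    front <- cbind(cells$i[src], cells$j[src])
    reached[front] <- TRUE
    while (nrow(front) > 0) {
      nb <- rbind(cbind(front[, 1] + 1L, front[, 2]),
                  cbind(front[, 1] - 1L, front[, 2]),
                  cbind(front[, 1], front[, 2] + 1L),
                  cbind(front[, 1], front[, 2] - 1L))
      ok <- nb[, 1] >= 1 & nb[, 1] <= nx & nb[, 2] >= 1 & nb[, 2] <= ny
      nb <- nb[ok, , drop = FALSE]
      ok <- openm[nb] & !reached[nb]
      nb <- unique(nb[ok, , drop = FALSE])
      if (nrow(nb) == 0) break
      reached[nb] <- TRUE
      front <- nb
    }
  }
  connected <- any(reached[cbind(cells$i[dst], cells$j[dst])])
  ## narrowest open cross-section across the band
  bin <- 2 * mesh$dx / MM
  inb <- in_br & cells$s_mm >= band[1] & cells$s_mm <= band[2]
  min_frac <- NA_real_
  if (any(inb)) {
    sbin <- floor(cells$s_mm[inb] / bin)
    n_open <- tapply(open[inb], sbin, sum)
    smid <- (as.numeric(names(n_open)) + 0.5) * bin
    w <- branch_width(geom, sb, smid)
    frac <- as.numeric(n_open) * (mesh$dx * mesh$dy / MM^2) / (w * bin)
    min_frac <- max(0, min(frac))
  }
  list(connected = connected, min_open_frac = min_frac)
}

#' Run the coupled clot-growth simulation
#'
#' Per coupling step: solve Brinkman flow with the current clot
#' resistance; update wall shear and the shear-enhanced platelet
#' diffusivity; advance the nine species; integrate wall deposition on
#' the active thrombogenic faces; map coverage to cell resistance and
#' propagate the clot surface; log the branch-flow time series. Stops at
#' sustained flow cessation, at deposition-rate exhaustion or at `t_max`.
#'
#' @param config a [simulation_config()]
#' @param resume a previous `simulation_result` to continue from
#' @param quiet suppress progress messages
#' @return list of class `simulation_result`: `series` (time series
#'   data.frame), `report` (cessation report), `mesh`, `baseline`
#'   (clot-free flow and shear), final `state`, and per-segment
#'   deposition totals `segment_deposit`
#' @export
run_simulation <- function(config, resume = NULL, quiet = TRUE) {
  cf <- config
  geom <- cf$geometry
  ks <- cf$kinetics_scale
  bc <- boundary_conditions(cf$flow_rate)

  if (is.null(resume)) {
    mesh <- generate_mesh(geom, cf$resolution)
    stencil <- transport_stencil(mesh)
    ## clot-free baseline: thrombogenic area identification
    base_flow <- solve_flow(mesh, NULL, bc, cf$props, tol = 1e-4,
                            advection = cf$advection,
                            max_iter = max(cf$max_picard, 60L))
    base_ws <- wall_shear(base_flow, mesh, cf$props)
    base_ws <- equivalent_tube_shear(base_ws, base_flow, mesh, cf$flow_rate,
                                     cf$props)
    fcols <- c("cell", "i", "j", "side", "s_mm", "branch", "segment", "len")
    wallf <- mesh$faces
    if (cf$thrombogenic_rule == "whole_band") {
      active <- wallf[wallf$in_band, fcols]
    } else {
      sel <- thrombogenic_area(base_ws, cf$tau_thresh, measure = "equivalent")
      active <- wallf[wallf$id %in% sel$face_ids, fcols]
    }
    rownames(active) <- NULL
    dep <- wall_deposition_state(nrow(active))
    resist <- resistance_field(mesh)
    C <- species_state(mesh, cf$inlet)
    flow <- base_flow
    t <- 0
    series <- list()
    seg_dep <- rep(0, max(1L, geom$n_segments))
    total_dep <- 0
    peak_rate <- 0
    step0 <- 0L
  } else {
    mesh <- resume$mesh; stencil <- resume$stencil
    base_flow <- resume$baseline$flow; base_ws <- resume$baseline$wall_shear
    st <- resume$state
    active <- st$active; dep <- st$dep; resist <- st$resist
    C <- st$C; flow <- st$flow; t <- st$t
    series <- list(resume$series)
    seg_dep <- resume$segment_deposit
    total_dep <- st$total_dep; peak_rate <- st$peak_rate
    step0 <- st$step
  }
  n_outlets <- sum(grepl("^outlet", unique(mesh$faces$label)))
  sb <- geom$stenosed_branch[1]
  sten_outlet <- if (geom$type == "tube") "outlet_1"
                 else names(geom$outlet_branches)[geom$outlet_branches == sb]
  band_edges <- seq(geom$band[1], geom$band[2],
                    length.out = max(1L, geom$n_segments) + 1)

  n_steps <- ceiling((cf$t_max - t) / cf$dt)
  stopped <- NA_character_
  steps_done <- 0L
  for (step in seq_len(max(0L, n_steps))) {
    gstep <- step0 + step
    steps_done <- step
    ## 1. flow with current resistance
    if (gstep == 1L || (gstep - 1L) %% cf$flow_every == 0L) {
      flow <- solve_flow(mesh, resist$inv_g_clot, bc, cf$props,
                         tol = cf$flow_tol, advection = cf$advection,
                         max_iter = cf$max_picard, warm_start = flow)
    }
    gam <- cell_shear_rate(flow, mesh)
    ws_now <- wall_shear(flow, mesh, cf$props)
    ## wall-profile shear rate at the active faces (NA for clot-front
    ## faces not on the original boundary -> cell estimate used there)
    gam_face <- ws_now$gamma_dot[match(paste(active$i, active$j, active$side),
                                       paste(ws_now$i, ws_now$j, ws_now$side))]
    ## 2. species transport + reactions
    C <- advance_species(C, flow, mesh, cf$dt, cf$kinetics,
                         active = active, dep = dep, inlet = cf$inlet,
                         gamma_dot = gam, gamma_face = gam_face,
                         kinetics_scale = ks, stencil = stencil)
    ## 3. deposition on active faces (boundary-layer-limited capture)
    if (nrow(active)) {
      cw <- lapply(species_names(), function(s) C[active$cell, s])
      names(cw) <- species_names()
      keff <- face_capture_keff(active, gam, mesh, cf$kinetics, gam_face)
      dep <- update_deposition(dep, cw, cf$dt, cf$kinetics, rate_scale = ks,
                               k_eff = keff)
      inc <- dep$rate * active$len * cf$dt
      total_dep <- total_dep + sum(inc)
      ## per-segment deposit: per-unit-area flux over equal-arclength
      ## segments (independent of the staircase face count)
      seg <- findInterval(active$s_mm, band_edges, rightmost.closed = TRUE,
                          all.inside = TRUE)
      sd <- tapply(inc, seg, sum) / tapply(active$len, seg, sum)
      seg_dep[as.integer(names(sd))] <- seg_dep[as.integer(names(sd))] +
        as.numeric(sd) * diff(band_edges)[1] * MM
      rate_now <- sum(dep$rate * active$len)
    } else rate_now <- 0
    peak_rate <- max(peak_rate, rate_now)
    ## 4. resistance + clot propagation
    pc <- propagate_clot(resist, active, dep, mesh, c_f = C[, "f"],
                         c_fg_ref = cf$inlet[["fg"]], params = cf$clot)
    resist <- pc$resist; active <- pc$active; dep <- pc$dep
    ## 5. diagnostics
    t <- t + cf$dt
    br <- branch_flow_rates(flow, mesh)
    fr <- br$fractions
    if (gstep %% cf$output_every == 0L || step == n_steps) {
      series[[length(series) + 1L]] <- data.frame(
        t_s = t,
        frac_branch1 = fr[["outlet_1"]],
        frac_branch2 = if (n_outlets > 1) fr[["outlet_2"]] else 0,
        n_clot_cells = sum(resist$clot),
        tau_max_pa = max(ws_now$tau_pa),
        total_dep_plt = total_dep,
        dep_rate = rate_now
      )
    }
    if (!quiet && gstep %% 10L == 0L)
      message(sprintf("t=%.3f s  frac=%.4f  clot=%d", t,
                      fr[[sten_outlet]], sum(resist$clot)))
    ## stopping rules
    ser <- do.call(rbind, series)
    frac_col <- if (sten_outlet == "outlet_1") "frac_branch1" else "frac_branch2"
    cess <- detect_cessation(ser$t_s, ser[[frac_col]],
                             cf$cessation_threshold, cf$cessation_sustain)
    if (!is.na(cess)) { stopped <- "cessation"; break }
    if (!is.null(cf$dep_stop_frac) && peak_rate > 0 &&
        rate_now < cf$dep_stop_frac * peak_rate) {
      stopped <- "deposition_exhausted"; break
    }
  }
  series <- do.call(rbind, series)
  rownames(series) <- NULL
  frac_col <- if (sten_outlet == "outlet_1") "frac_branch1" else "frac_branch2"
  cess <- detect_cessation(series$t_s, series[[frac_col]],
                           cf$cessation_threshold, cf$cessation_sustain)
  oc <- open_channel_status(mesh, resist, geom)
  report <- list(
    cessation_time_s = cess,
    stop_reason = if (is.na(stopped)) "t_max" else stopped,
    final_fraction = series[[frac_col]][nrow(series)],
    stenosed_outlet = sten_outlet,
    open_channel = oc$connected,
    min_open_frac = oc$min_open_frac,
    n_clot_cells = sum(resist$clot),
    kinetics_scale = ks
  )
  structure(list(
    series = series, report = report, mesh = mesh, stencil = stencil,
    baseline = list(flow = base_flow, wall_shear = base_ws),
    state = list(C = C, dep = dep, active = active, resist = resist,
                 flow = flow, t = t, total_dep = total_dep,
                 peak_rate = peak_rate, step = step0 + steps_done),
    segment_deposit = seg_dep,
    config = cf
  ), class = "simulation_result")
}

#' Detect sustained flow cessation in a branch-flow series
#'
#' Earliest time from which the flow fraction stays below the threshold
#' for at least the sustain window; `NA` if never.
#'
#' @param t time points, s (sorted)
#' @param fraction branch flow fraction at those times
#' @param threshold cessation threshold (fraction of inlet flow)
#' @param sustain required below-threshold duration, s
#' @return cessation time, s, or `NA`
#' @export
detect_cessation <- function(t, fraction, threshold = 0.01, sustain = 1) {
  stopifnot(length(t) == length(fraction), !is.unsorted(t))
  below <- fraction < threshold
  if (!any(below)) return(NA_real_)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    dur <- t[ends[k]] - t[starts[k]]
    if (dur >= sustain) return(t[starts[k]])
  }
  NA_real_
}

#' Run the stenosed-tube perfusion experiment
#'
#' Whole blood perfused through a stenosed tube whose stenosis band is
#' the injury site, divided into equal segments. Returns the fraction of
#' total platelet deposit per segment and the cumulative deposition
#' series.
#'
#' @param diameter tube diameter, mm
#' @param degree stenosis degree (by diameter unless `basis = "area"`)
#' @param flow_rate inlet flow, m3/s
#' @param duration perfusion time on the simulated clock, s
#' @param stenosis_length stenosis length, mm
#' @param n_segments number of equal thrombogenic segments
#' @param resolution mesh resolution, mm
#' @param kinetics_scale rate multiplier (see [simulation_config()])
#' @param basis stenosis degree convention
#' @param dt coupling step, s
#' @param ... further [simulation_config()] overrides
#' @return list: `segment_fractions`, the full `simulation_result`, and
#'   the wall shear-rate profile of the clot-free baseline
#' @export
run_validation_case <- function(diameter = 2, degree = 0.35,
                                flow_rate = 10 / 6e7, duration = 2,
                                stenosis_length = 4, n_segments = 5,
                                resolution = 0.1, kinetics_scale = 25,
                                basis = "diameter", dt = 0.05, ...) {
  geom <- build_stenosed_tube(
    diameter, stenosis_spec(degree, stenosis_length, basis = basis),
    upstream_length = 2 * diameter, downstream_length = 4 * diameter,
    n_segments = n_segments)
  cfg <- simulation_config(geom, resolution = resolution, dt = dt,
                           t_max = duration, kinetics_scale = kinetics_scale,
                           flow_rate = flow_rate,
                           thrombogenic_rule = "whole_band",
                           dep_stop_frac = NULL, ...)
  res <- run_simulation(cfg)
  segf <- res$segment_deposit / max(sum(res$segment_deposit), 1e-300)
  list(segment_fractions = segf, result = res,
       baseline_shear = res$baseline$wall_shear)
}

#' Export simulation results to files
#'
#' Writes the time series as CSV (schema
#' `t_s,frac_branch1,frac_branch2,n_clot_cells,tau_max_pa,total_dep_plt`),
#' the cessation report as JSON and the final fields as a legacy-ASCII
#' VTK file. Output bytes are deterministic for a fixed configuration.
#'
#' @param result a `simulation_result`
#' @param dir output directory (created if missing)
#' @return invisibly, the written file paths
#' @export
export_results <- function(result, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  cols <- c("t_s", "frac_branch1", "frac_branch2", "n_clot_cells",
            "tau_max_pa", "total_dep_plt")
  f_series <- file.path(dir, "series.csv")
  utils::write.csv(result$series[, cols], f_series, row.names = FALSE)
  f_report <- file.path(dir, "cessation_report.json")
  jsonlite::write_json(result$report, f_report, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  f_vtk <- file.path(dir, "fields.vtk")
  st <- result$state
  fields <- list(
    velocity_u = st$flow$uc[result$mesh$fluid],
    velocity_v = st$flow$vc[result$mesh$fluid],
    pressure = st$flow$p[result$mesh$fluid],
    inv_G_clot = st$resist$inv_g_clot,
    clot_mask = as.numeric(st$resist$clot)
  )
  for (s in species_names()) fields[[paste0("C_", s)]] <- st$C[, s]
  write_vtk(result$mesh, fields, f_vtk)
  invisible(c(f_series, f_report, f_vtk))
}
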