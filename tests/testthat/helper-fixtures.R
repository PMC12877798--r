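## Shared fixtures and a session cache for expensive coupled runs.

.run_cache <- new.env(parent = emptyenv())

## Scaled-down clot-growth run for one packaged patient, cached per
## (patient, kinetics factor) within the test session.
cached_patient_run <- function(i, ks = 10, dt = 0.1, t_max = 60,
                               rule = "whole_band", length_factor = 3) {
  key <- sprintf("p%d_ks%g_dt%g_%s", i, ks, dt, rule)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  pt <- patient_table()
  geom <- build_bifurcation(pt[i, ], length_factor = length_factor)
  cfg <- simulation_config(geom, dt = dt, t_max = t_max,
                           kinetics_scale = ks, flow_rate = 2e-6,
                           thrombogenic_rule = rule)
  res <- run_simulation(cfg)
  .run_cache[[key]] <- res
  res
}

## Small straight-channel mesh for flow oracles.
poiseuille_setup <- function(H_mm = 2, n_across = 20, L_mm = 16) {
  g <- build_stenosed_tube(H_mm, stenosis_spec(0, L_mm / 4),
                           upstream_length = L_mm / 4,
                           downstream_length = L_mm / 2)
  m <- generate_mesh(g, H_mm / n_across)
  list(geom = g, mesh = m)
}

## Independent brute-force evaluation of the nine source terms, written
## directly from the reaction table (kept deliberately separate from the
## package implementation).
oracle_sources <- function(cc, p) {
  omega <- cc$adp / p$c_adp_cri + cc$tx / p$c_tx_cri + cc$t / p$c_t_cri
  k_rpa <- if (omega > 1) omega / p$t_act else 0
  ct_um <- p$beta * cc$t
  gam <- p$k_t * p$c_h * cc$at /
    (p$alpha * (p$c_at_dis * p$c_t_dis + cc$at * p$c_t_dis +
                p$c_at_dis * ct_um + cc$at * ct_um))
  tg <- cc$pt * (p$k_ap_t * cc$ap + p$k_rp_t * cc$rp)
  sf <- 84 * cc$t * cc$fg / (0.0072 + cc$fg)
  c(rp = -k_rpa * cc$rp,
    ap = k_rpa * cc$rp,
    adp = p$lambda_adp * k_rpa * cc$rp - p$k_adp * cc$adp,
    tx = p$s_tx * cc$ap - p$k_tx * cc$tx,
    pt = -p$beta * tg,
    t = -gam * cc$t + tg,
    at = -gam * p$beta * cc$t,
    fg = -sf,
    f = sf)
}

random_state <- function() {
  list(rp = runif(1, 0, 5e8), ap = runif(1, 0, 5e7),
       adp = runif(1, 0, 20), tx = runif(1, 0, 5),
       pt = runif(1, 0, 2), t = runif(1, 0, 2),
       at = runif(1, 0, 5), fg = runif(1, 0, 10), f = runif(1, 0, 10))
}
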