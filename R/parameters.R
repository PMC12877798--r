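#' Kinetic parameters of the coagulation network
#'
#' Returns the rate constants, critical concentrations, surface reaction
#' rates and diffusivities of the nine-species platelet/coagulation model.
#' Values are the standard Sorensen-lineage constants used for whole blood.
#'
#' Unit conventions (kept throughout the package): platelet concentrations
#' in PLT/ml, small chemical species in uM, thrombin in U/ml (converted to
#' uM via `beta` where a molar quantity is required), lengths in m, time
#' in s. With these units every volumetric source term closes without
#' hidden conversion factors because nmol/ml == uM.
#'
#' @param ... named overrides for individual constants.
#' @return A list of class `kinetic_parameters`.
#' @export
#' @examples
#' p <- kinetic_parameters()
#' p$c_adp_cri  # 2 uM
kinetic_parameters <- function(...) {
  p <- list(
    ## platelet activation (agonist index)
    c_adp_cri = 2,        # uM
    c_tx_cri  = 0.6,      # uM
    c_t_cri   = 0.1,      # U/ml
    t_act     = 1,        # s, platelet activation time constant
    ## agonist release / decay
    lambda_adp = 2.4e-8,  # nmol ADP released per activated platelet
    k_adp      = 0.0161,  # 1/s ADP inhibition rate
    k_tx       = 0.0161,  # 1/s TxA2 inhibition rate
    s_tx       = 9.5e-12, # nmol/(PLT s), TxA2 synthesis by activated platelets
    ## thrombin generation / inactivation (Griffith template model)
    k_ap_t   = 3.69e-9,   # U/(PLT s uM), thrombin generation on activated platelets
    k_rp_t   = 6.5e-10,   # U/(PLT s uM), thrombin generation on resting platelets
    beta     = 9.11e-3,   # nmol/U, thrombin U/ml -> uM converter
    k_t      = 13.333,    # 1/s
    c_h      = 0.3,       # uM heparin
    alpha    = 1,         # Griffith denominator scale
    c_t_dis  = 0.035,     # uM
    c_at_dis = 0.1,       # uM
    ## platelet deposition
    m_max  = 7e10,        # PLT/m2 (7e6 PLT/cm2), surface saturation density
    k_rpd  = 3.7e-5,      # m/s, resting platelet deposition rate
    k_apd  = 4.6e-5,      # m/s, activated platelet deposition on collagen
    k_apa  = 4.6e-5,      # m/s, activated platelet adhesion to the plug
    ## diffusivities, m2/s
    d_plt_slope     = 13.61e-13, # shear-enhanced platelet diffusivity slope (m2)
    d_plt_intercept = 1.58e-13,  # m2/s at zero shear
    d_adp = 2.57e-10,
    d_tx  = 2.14e-11,
    d_pt  = 3.32e-11,
    d_t   = 4.16e-11,
    d_at  = 3.49e-11,
    d_fg  = 1e-12,
    ## fibrin generation (Michaelis-Menten FG -> F, constants as used with
    ## C_T in U/ml and C_FG in uM)
    k_fg_vmax = 84,
    k_fg_km   = 0.0072
  )
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(p)))
  p[names(ov)] <- ov
  structure(p, class = "kinetic_parameters")
}

#' Fluid properties of blood
#'
#' @param density kg/m3
#' @param viscosity dynamic viscosity, Pa s
#' @return list of class `fluid_properties`
#' @export
fluid_properties <- function(density = 1106.4, viscosity = 0.0035) {
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Clot constitutive parameters
#'
#' Parameters of the deposition- and fibrin-dependent hydraulic resistance:
#' the half-saturation coverage `phi_cri` of the platelet resistance law,
#' the maximum platelet hydraulic resistance `inv_g_dp_max`, the fibrin
#' fiber radius entering the Davis fibrous-media relation, and the coverage
#' `phi_full` at which a wall face is considered solid and the clot
#' propagates into the adjacent cell.
#'
#' `phi_cri` and `inv_g_dp_max` are not fixed by the core constant table;
#' the defaults follow the continuum clot-growth model lineage this package
#' builds on and are configurable.
#'
#' @param phi_cri coverage at which platelet resistance is half-maximal
#' @param inv_g_dp_max maximum platelet hydraulic resistance, 1/m2
#' @param r_f fibrin fiber radius, m
#' @param phi_full coverage threshold for clot surface propagation
#' @param phi_scaffold minimum platelet coverage for a load-bearing
#'   fibrin network to anchor in a cell
#' @param solidify_frac a cell is also treated as clot once its total
#'   inverse permeability reaches this fraction of `inv_g_dp_max`
#'   (effectively solid, so the deposition surface advances)
#' @return list of class `clot_parameters`
#' @export
clot_parameters <- function(phi_cri = 0.5, inv_g_dp_max = 1e16,
                            r_f = 55e-9, phi_full = 0.9,
                            phi_scaffold = 0.1, solidify_frac = 0.5) {
  stopifnot(phi_cri > 0, phi_cri <= 1, inv_g_dp_max > 0, r_f > 0,
            phi_full > 0, phi_full <= 1, phi_scaffold >= 0,
            solidify_frac > 0)
  structure(list(phi_cri = phi_cri, inv_g_dp_max = inv_g_dp_max,
                 r_f = r_f, phi_full = phi_full,
                 phi_scaffold = phi_scaffold, solidify_frac = solidify_frac),
            class = "clot_parameters")
}

#' Normal blood composition at the inlet
#'
#' Inlet (and initial) concentrations of the nine transported species.
#' Resting platelet count and plasma zymogen levels are standard values for
#' normal whole blood; agonists, thrombin and fibrin are zero upstream.
#'
#' @param rp resting platelets, PLT/ml
#' @param ap_frac activated fraction of the platelet pool at the inlet
#' @param pt prothrombin, uM
#' @param at antithrombin, uM
#' @param fg fibrinogen, uM
#' @return named numeric vector over the nine species
#' @export
blood_concentrations <- function(rp = 2.5e8, ap_frac = 0.005,
                                 pt = 1.1, at = 2.844, fg = 7.0) {
  c(rp = rp * (1 - ap_frac), ap = rp * ap_frac,
    adp = 0, tx = 0, pt = pt, t = 0, at = at, fg = fg, f = 0)
}

#' Species names of the coagulation network
#' @return character vector of the nine species identifiers
#' @export
species_names <- function() {
  c("rp", "ap", "adp", "tx", "pt", "t", "at", "fg", "f")
}

#' Vessel characteristics of the six reference patients
#'
#' The packaged table of coronary bifurcation parameters: left main
#' coronary artery (LMCA) diameter, daughter branch (LAD/LCX) diameters,
#' which branch is stenosed, the stenosis degree (fraction of diameter
#' reduction) and the stenosis length.
#'
#' @return data.frame of class `patient_parameters` with one row per patient
#' @export
#' @examples
#' patient_table()
patient_table <- function() {
  path <- system.file("extdata", "patient_parameters.csv", package = "clotflow")
  read_patient_csv(path)
}

#' Read a patient parameter CSV
#'
#' Expected header:
#' `patient_id,d_lmca_mm,d_lad_mm,d_lcx_mm,stenosed_branch,stenosis_pct,stenosis_len_mm`.
#' Degrees are stored internally as fractions.
#'
#' @param path CSV file path
#' @return data.frame of class `patient_parameters`
#' @export
read_patient_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "d_lmca_mm", "d_lad_mm", "d_lcx_mm",
            "stenosed_branch", "stenosis_pct", "stenosis_len_mm")
  if (!all(need %in% names(df)))
    stop("patient CSV must have columns: ", paste(need, collapse = ","))
  out <- data.frame(
    patient_id = as.character(df$patient_id),
    d_lmca = df$d_lmca_mm, d_lad = df$d_lad_mm, d_lcx = df$d_lcx_mm,
    stenosed_branch = toupper(df$stenosed_branch),
    stenosis_degree = df$stenosis_pct / 100,
    stenosis_length = df$stenosis_len_mm,
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$d_lmca > 0), all(out$d_lad > 0), all(out$d_lcx > 0),
            all(out$stenosis_degree >= 0), all(out$stenosis_degree < 1),
            all(out$stenosis_length > 0),
            all(out$stenosed_branch %in% c("LAD", "LCX")))
  class(out) <- c("patient_parameters", "data.frame")
  out
}
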