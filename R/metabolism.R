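# Deterministic antioxidant-metabolism subsystem.
#
# A minimal GSH/GSSG/NADPH redox cycle: hexokinase supplies
# glucose-6-phosphate, G6PDH regenerates NADPH (the pentose-phosphate entry
# step and the lesion in G6PD deficiency), glutathione reductase (GSSGR)
# reduces GSSG back to GSH, diamide oxidises GSH directly and drives
# S-glutathionylation of protein thiols (PSSG), and oxygenated haemoglobin
# is denatured by diamide to hemichrome, the irreversible band 3 ligand.
# A basal glutathione redox turnover flux keeps the cycle poised so that
# the diamide-free state is an exact fixed point (all net fluxes zero).
#
# Concentrations are molar throughout; the compartment volume converts
# between molecule counts of the particle layer and pool concentrations.

AVOGADRO <- 6.02214076e23
# M -> molecules per m^3
CONC_TO_NUM_M3 <- AVOGADRO * 1e3

#' Antioxidant metabolism parameters
#'
#' Assembles the parameter set of the metabolism subsystem. G6PDH kinetic
#' constants for the healthy and G6PD-deficient cell are the published
#' patient parameter sets (`Vmax` in relative activity units, Michaelis and
#' inhibition constants in micromolar); all remaining constants are
#' calibrated defaults, chosen once so that the control scenario reproduces
#' the transient glutathione depletion-and-recovery shape and the deficient
#' scenario its sustained depletion (they are not printed quantities).
#'
#' @param variant `"control"` or `"g6pd"`.
#' @param volume_L Compartment (cytosol) volume in litres; the full-scale
#'   membrane sheet corresponds to 1e-16 L.
#' @param hematocrit Volume fraction of cells in the treated suspension; an
#'   extracellular dose `c` raises the per-cell diamide concentration by
#'   `c / hematocrit`.
#' @param overrides Named list of parameter overrides.
#' @return A list of class `metabolism_params`.
#' @export
metabolism_params <- function(variant = c("control", "g6pd"),
                              volume_L = 1e-16, hematocrit = 0.3,
                              overrides = list()) {
  variant <- match.arg(variant)
  g6pdh <- if (variant == "control") {
    list(Vmax = 64, KmG6P = 67e-6, KmNADP = 3.7e-6, KiNADPH = 3.1e-6,
         KiATP = 749e-6, Ki23BPG = 2289e-6)
  } else {
    list(Vmax = 1.1, KmG6P = 152e-6, KmNADP = 3.8e-6, KiNADPH = 0.62e-6,
         KiATP = 180e-6, Ki23BPG = 520e-6)
  }
  p <- list(
    variant = variant,
    volume_L = volume_L,
    hematocrit = hematocrit,
    g6pdh = g6pdh,
    # bridge from the published relative Vmax units to flux (M/s); calibrated
    g6pdh_scale = 8.0e-8,
    # glutathione reductase (saturable in GSSG and NADPH); calibrated
    gssgr = list(Vmax = 2.0e-6, KmGSSG = 60e-6, KmNADPH = 10e-6),
    # hexokinase: product-inhibited supply of G6P; Vmax fixed at
    # initialisation so the diamide-free state is a fixed point
    hk = list(Vmax = NA_real_, KmGLC = 1.0e-3, KiG6P = 1.0e-6),
    # diamide chemistry
    k_diamide_gsh = 300,      # M^-1 s^-1, diamide + 2 GSH -> GSSG
    k_pssg = 5,               # M^-1 s^-1, S-glutathionylation; calibrated
    hemichrome = list(KmS = 1.0e-4, KcF = 1.0e-3),
    # basal glutathione redox turnover; fixed at initialisation
    k_ox = NA_real_,
    # hybrid pool-particle coefficients (per-molecule propensities)
    k_band3_ox = 1.0e-23,     # * [diamide] in molecules/m^3 -> s^-1
    k_band3_red = 1.0e-50,    # * [GSH]^2 in (molecules/m^3)^2 -> s^-1
    k_hemi_attach = 1.0e-23,  # * [hemichrome] in molecules/m^3 -> s^-1
    # fixed metabolite levels
    GLC = 5.0e-3, ATP = 1.4e-3, BPG = 5.1e-3,
    # initial concentrations (calibrated)
    init = list(GSH = 1.8e-3, GSSG = 2.0e-6, NADPtot = 62e-6,
                G6P = 38e-6, HbO2 = 7.0e-3, PSSG = 0, hemichrome = 0,
                diamide = 0)
  )
  for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
  class(p) <- "metabolism_params"
  p
}

#' G6PDH reaction rate
#'
#' Two-substrate Michaelis-Menten rate of glucose-6-phosphate
#' dehydrogenase with competitive inhibition of the G6P site by ATP and
#' 2,3-BPG and of the NADP site by NADPH:
#' `v = s * Vmax * g6p * nadp / ((KmG6P * (1 + atp/KiATP + bpg/Ki23BPG) + g6p)
#'  * (KmNADP * (1 + nadph/KiNADPH) + nadp))`.
#'
#' @param pool Named list or vector with `G6P`, `NADP`, `NADPH` (M).
#' @param params A [metabolism_params()] object.
#' @return Flux in M/s (non-negative; zero when G6P or NADP is zero).
#' @export
g6pdh_rate <- function(pool, params) {
  g <- params$g6pdh
  g6p <- max(0, pool[["G6P"]]); nadp <- max(0, pool[["NADP"]])
  nadph <- max(0, pool[["NADPH"]])
  kg <- g$KmG6P * (1 + params$ATP / g$KiATP + params$BPG / g$Ki23BPG)
  kn <- g$KmNADP * (1 + nadph / g$KiNADPH)
  params$g6pdh_scale * g$Vmax * g6p * nadp / ((kg + g6p) * (kn + nadp))
}

#' Hemichrome formation rate
#'
#' Diamide-driven denaturation of oxygenated haemoglobin,
#' `v = KcF * [diamide] * [HbO2] / (KmS + [HbO2])`: saturable in HbO2 with
#' half-saturation `KmS`, first order in diamide with catalytic coefficient
#' `KcF`.
#'
#' @param pool Named list or vector with `diamide` and `HbO2` (M).
#' @param params A [metabolism_params()] object.
#' @return Flux in M/s.
#' @export
hemichrome_formation_rate <- function(pool, params) {
  h <- params$hemichrome
  dia <- max(0, pool[["diamide"]]); hb <- max(0, pool[["HbO2"]])
  h$KcF * dia * hb / (h$KmS + hb)
}

gssgr_rate <- function(pool, params) {
  g <- params$gssgr
  gssg <- max(0, pool[["GSSG"]]); nadph <- max(0, pool[["NADPH"]])
  g$Vmax * gssg / (g$KmGSSG + gssg) * nadph / (g$KmNADPH + nadph)
}

hk_rate <- function(pool, params) {
  h <- params$hk
  g6p <- max(0, pool[["G6P"]])
  h$Vmax * params$GLC / (h$KmGLC + params$GLC) / (1 + g6p / h$KiG6P)
}

#' Initialise the metabolism subsystem at its diamide-free steady state
#'
#' Solves for the NADPH/NADP partition at which G6PDH and glutathione
#' reductase fluxes balance, then fixes the basal glutathione turnover and
#' the hexokinase capacity so that every net flux vanishes: the returned
#' state is an exact fixed point of [metabolism_rhs()] in the absence of
#' diamide.
#'
#' @param params A [metabolism_params()] object.
#' @return A list with `state` (named concentration vector, including the
#'   cumulative exposure integrals `I_dia`, `I_gsh2`, `I_hemi`) and
#'   `params` (with `k_ox` and hexokinase `Vmax` resolved).
#' @export
metabolism_init <- function(params) {
  ini <- params$init
  tot <- ini$NADPtot
  balance <- function(nadph) {
    pool <- list(G6P = ini$G6P, NADP = tot - nadph, NADPH = nadph,
                 GSSG = ini$GSSG)
    g6pdh_rate(pool, params) - gssgr_rate(pool, params)
  }
  # v_g6pdh decreases and v_gssgr increases in NADPH, so the root is unique
  sol <- stats::uniroot(balance, c(tot * 1e-9, tot * (1 - 1e-9)), tol = 1e-18)
  nadph0 <- sol$root
  pool0 <- list(G6P = ini$G6P, NADP = tot - nadph0, NADPH = nadph0,
                GSSG = ini$GSSG)
  v0 <- gssgr_rate(pool0, params)
  params$k_ox <- v0 / ini$GSH
  params$hk$Vmax <- v0 * (1 + ini$G6P / params$hk$KiG6P) /
    (params$GLC / (params$hk$KmGLC + params$GLC))
  state <- c(G6P = ini$G6P, NADPH = nadph0, NADP = tot - nadph0,
             GSH = ini$GSH, GSSG = ini$GSSG, PSSG = ini$PSSG,
             HbO2 = ini$HbO2, hemichrome = ini$hemichrome,
             diamide = ini$diamide,
             I_dia = 0, I_gsh2 = 0, I_hemi = 0)
  list(state = state, params = params)
}

#' Time derivatives of the metabolism subsystem
#'
#' deSolve-compatible right-hand side. Besides the metabolite balance it
#' integrates the exposure integrals `I_dia = int [diamide] dt`,
#' `I_gsh2 = int [GSH]^2 dt` and `I_hemi = int [hemichrome] dt` used by the
#' hybrid pool-particle coupling.
#'
#' @param t Time (unused; the system is autonomous).
#' @param y Named state vector.
#' @param parms A [metabolism_params()] object (with `k_ox` resolved).
#' @return `list(dy)`.
#' @export
metabolism_rhs <- function(t, y, parms) {
  p <- parms
  y <- pmax(y, 0)
  v_hk <- hk_rate(y, p)
  v_g6 <- g6pdh_rate(y, p)
  v_gr <- gssgr_rate(y, p)
  v_ox <- p$k_ox * y[["GSH"]]
  v2 <- p$k_diamide_gsh * y[["diamide"]] * y[["GSH"]]
  v_ps <- p$k_pssg * y[["diamide"]] * y[["GSH"]]
  v_hc <- hemichrome_formation_rate(y, p)
  dy <- c(
    G6P = v_hk - v_g6,
    NADPH = v_g6 - v_gr,
    NADP = v_gr - v_g6,
    GSH = -2 * v2 - v_ps + 2 * v_gr - 2 * v_ox,
    GSSG = v2 + v_ox - v_gr,
    PSSG = v_ps,
    HbO2 = -v_hc,
    hemichrome = v_hc,
    diamide = -v2 - v_ps - v_hc,
    I_dia = y[["diamide"]],
    I_gsh2 = y[["GSH"]]^2,
    I_hemi = y[["hemichrome"]]
  )
  list(dy)
}

#' Integrate the metabolism subsystem over one coupling step
#'
#' Advances the pools by `dt` with an adaptive stiff integrator (lsoda,
#' relative tolerance 1e-6) and reports the exposure-integral increments
#' accumulated over the step.
#'
#' @param state Named state vector (see [metabolism_init()]).
#' @param params Resolved [metabolism_params()].
#' @param dt Step length (s).
#' @return A list with the advanced `state` and `increments` (named vector
#'   `I_dia`, `I_gsh2`, `I_hemi`).
#' @export
integrate_metabolism <- function(state, params, dt) {
  stopifnot(dt > 0)
  out <- deSolve::lsoda(y = state, times = c(0, dt), func = metabolism_rhs,
                        parms = params, rtol = 1e-6, atol = 1e-15)
  new <- out[2, -1]
  inc <- new[c("I_dia", "I_gsh2", "I_hemi")] - state[c("I_dia", "I_gsh2", "I_hemi")]
  new[c("I_dia", "I_gsh2", "I_hemi")] <- state[c("I_dia", "I_gsh2", "I_hemi")] + inc
  list(state = new, increments = inc)
}

#' Convert a pool concentration to a molecule count (and back)
#'
#' @param conc Concentration (M).
#' @param volume_L Compartment volume (L).
#' @return `pool_molecules()`: molecule count; `molecules_conc()`: molar
#'   concentration.
#' @export
pool_molecules <- function(conc, volume_L) conc * AVOGADRO * volume_L

#' @rdname pool_molecules
#' @param count Molecule count.
#' @export
molecules_conc <- function(count, volume_L) count / (AVOGADRO * volume_L)

#' Hybrid pool-particle conversion probabilities over a step
#'
#' Per-molecule conversion probabilities for the three hybrid reactions,
#' computed from the exposure integrals of the deterministic layer so that
#' the fast initial diamide transient is captured exactly even with coarse
#' coupling steps: for a per-molecule propensity `lambda(t) = k * c(t)` the
#' conversion probability over a step is `1 - exp(-k * int c dt)`.
#'
#' @param increments Exposure-integral increments from
#'   [integrate_metabolism()].
#' @param params Resolved [metabolism_params()].
#' @return Named vector of probabilities: `oxidation` (band 3 oxidation by
#'   diamide), `reduction` (band 3 re-reduction by GSH) and `hemi`
#'   (hemichrome attachment).
#' @export
hybrid_probabilities <- function(increments, params) {
  c(oxidation = 1 - exp(-params$k_band3_ox * increments[["I_dia"]] * CONC_TO_NUM_M3),
    reduction = 1 - exp(-params$k_band3_red * increments[["I_gsh2"]] * CONC_TO_NUM_M3^2),
    hemi = 1 - exp(-params$k_hemi_attach * increments[["I_hemi"]] * CONC_TO_NUM_M3))
}
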