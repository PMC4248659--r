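# Model core: the pH switch, the milk buffering curve, Monod growth, the
# nineteen reaction rates and the ODE right-hand side.

.state_names <- c("LAC_out", "LAC_in", "GLU", "PYR", "LA",
                  "M", "LR", "N", "LS", "LZ", "X")

#' pH-induced promoter switch
#'
#' Smoothed step function `F(pH) = 1 - tanh(n * (pH - pH_threshold))`
#' describing activation of a pH-induced promoter (e.g. rcfB) as the medium
#' acidifies.  It is strictly decreasing in pH with range (0, 2): above the
#' threshold it decays towards 0, below the threshold it saturates at 2 (not
#' 1 -- the function is used as printed, so the fully induced transcription
#' term is up to `2 * V1 * GR`), and it equals exactly 1 at the threshold.
#'
#' @param pH pH value(s).
#' @param n switch steepness (> 0); the slope at the threshold is `-n`.
#' @param pH_threshold threshold pH (default 5.5).
#' @return dimensionless activation in (0, 2).
#' @examples
#' switch_F(5.5)        # exactly 1 at the threshold
#' switch_F(4.5)        # 1 - tanh(-1), about 1.762
#' @export
switch_F <- function(pH, n = 1, pH_threshold = 5.5) {
  if (any(!is.finite(pH))) stop("pH must be finite")
  if (!is.finite(n) || n <= 0) stop("n must be a positive finite number")
  1 - tanh(n * (pH - pH_threshold))
}

#' Medium pH as a function of lactic acid
#'
#' Quadratic buffering curve `pH = c0 - c1*LA + c2*LA^2` capturing the
#' buffer capacity of milk.  Warns when the quadratic turns upward (vertex
#' at `LA = c1 / (2*c2)`) inside the evaluated range, since a pH rising with
#' added acid signals constants outside their fitted range.
#'
#' @param LA lactic acid concentration(s), M (>= 0).
#' @param c0 pH at zero lactic acid.
#' @param c1,c2 linear and quadratic coefficients (pH/M and pH/M^2).
#' @return pH value(s).
#' @export
pH_from_LA <- function(LA, c0 = 6.7, c1 = 24, c2 = 30) {
  if (any(!is.finite(LA))) stop("LA must be finite")
  if (any(LA < 0)) stop("LA must be nonnegative")
  pH <- c0 - c1 * LA + c2 * LA^2
  if (any(!is.finite(pH))) stop("pH evaluated to a non-finite value")
  if (c2 > 0 && c1 > 0 && max(LA) > c1 / (2 * c2))
    warning("buffering quadratic is non-monotone over the evaluated range ",
            "(vertex at LA = ", signif(c1 / (2 * c2), 4), " M)")
  pH
}

#' Specific growth rate (Monod with product inhibition)
#'
#' `mu = mu_max * LAC_out / (LAC_out + Ks) * (1 - LA / K_LA)`.  Returned
#' as-is, so the value is negative once `LA > K_LA`; the ODE right-hand side
#' clips it at zero wherever it acts as a dilution or growth term.
#'
#' @param LAC_out extracellular lactose, M.
#' @param LA extracellular lactic acid, M.
#' @param params a [lacferm_params()] object (uses `mu_max`, `Ks`, `K_LA`).
#' @return specific growth rate, 1/h.
#' @export
growth_rate <- function(LAC_out, LA, params) {
  if (any(!is.finite(LAC_out)) || any(!is.finite(LA)))
    stop("inputs must be finite")
  params$mu_max * LAC_out / (LAC_out + params$Ks) * (1 - LA / params$K_LA)
}

#' The nineteen reaction rates
#'
#' Evaluates R1..R19 on a model state: reversible lactose transport (R1/R2),
#' hydrolysis (R3), glycolysis (R4), LDH (R5), lacR transcription basal and
#' pH-induced (R6/R7), lacR mRNA loss (R8), LacR synthesis (R9),
#' LacR-lactose binding (R10), LacR loss (R11), lacSZ basal transcription
#' (R12), repression (R13), lacSZ mRNA loss (R14), LacS/LacZ synthesis
#' (R15/R17), LacS/LacZ loss (R16/R18) and biomass growth (R19).  The
#' growth rate entering the dilution terms and R19 is floored at zero, so
#' all rates are nonnegative on a nonnegative state.
#'
#' @param state named numeric vector with entries
#'   `LAC_out, LAC_in, GLU, PYR, LA, M, LR, N, LS, LZ, X` (concentrations
#'   M, biomass g/L).
#' @param params a [lacferm_params()] object.
#' @param pH current medium pH (default: computed from `state["LA"]`).
#' @param mu current specific growth rate, 1/h (default: computed via
#'   [growth_rate()]).
#' @return named numeric vector `R1`..`R19` (M/h; `R19` in g/(L h)).
#' @export
reaction_rates <- function(state, params, pH = NULL, mu = NULL) {
  s <- as_model_state(state)
  if (is.null(pH))
    pH <- pH_from_LA(s[["LA"]], params$c0, params$c1, params$c2)
  if (is.null(mu)) mu <- growth_rate(s[["LAC_out"]], s[["LA"]], params)
  mu_d <- max(mu, 0)
  p <- params
  Fp <- switch_F(pH, p$n, p$pH_threshold)
  r <- c(
    R1  = p$Kcat_LP * s[["LS"]] * s[["LAC_out"]] / (s[["LAC_out"]] + p$Km_LP),
    R2  = p$Kcat_LP * s[["LS"]] * s[["LAC_in"]] / (s[["LAC_in"]] + p$Km_LP),
    R3  = p$Kcat_GAL * s[["LZ"]] * s[["LAC_in"]] / (s[["LAC_in"]] + p$Km_GAL),
    R4  = p$Vmax_GLYC * s[["GLU"]] / (s[["GLU"]] + p$Km_GLYC),
    R5  = p$Vmax_LDH * s[["PYR"]] / (s[["PYR"]] + p$Km_LDH),
    R6  = p$V0 * p$GR,
    R7  = p$V1 * Fp * p$GR,
    R8  = (p$d_M + mu_d) * s[["M"]],
    R9  = p$K_LR * s[["M"]],
    R10 = p$Kb * s[["LR"]] * s[["LAC_in"]],
    R11 = (p$d_LR + mu_d) * s[["LR"]],
    R12 = p$V2 * p$G,
    R13 = p$T_max * (p$S * s[["LR"]] / (1 + p$S * s[["LR"]])) * p$G,
    R14 = (p$d_N + mu_d) * s[["N"]],
    R15 = p$K_LS * s[["N"]],
    R16 = (p$d_LS + mu_d) * s[["LS"]],
    R17 = p$K_LZ * s[["N"]],
    R18 = (p$d_LZ + mu_d) * s[["LZ"]],
    R19 = mu_d * s[["X"]]
  )
  r
}

# Coerce a (partially) named vector/list to the canonical 11-state vector.
as_model_state <- function(state) {
  if (is.list(state)) state <- unlist(state)
  if (is.null(names(state)) && length(state) == length(.state_names)) {
    names(state) <- .state_names
    return(state)
  }
  unknown <- setdiff(names(state), .state_names)
  if (length(unknown))
    stop("unknown state variable(s): ", paste(unknown, collapse = ", "))
  s <- stats::setNames(numeric(length(.state_names)), .state_names)
  s[names(state)] <- state
  s
}

#' Right-hand side of the fermentation ODE system
#'
#' Time derivatives of the eleven state variables for either model variant.
#' The engineered variant carries the full lacR circuit; the wild-type
#' variant (constitutive lacSZ expression, no lacR gene) drops M and LR and
#' the rates R6--R11 and R13.
#'
#' Net lacSZ transcription: by default `max(R12 - R13, 0) - R14`, i.e.
#' repression can silence transcription but not consume existing mRNA.  With
#' `strict_as_printed = TRUE` the raw `R12 - R13 - R14` is used; with
#' `repression_form = "hill"` production is `T_max*G / (1 + S*LR)`.
#'
#' @param t time, h (unused: the system is autonomous; kept for the
#'   conventional signature).
#' @param state named state vector (see [reaction_rates()]).
#' @param params a [lacferm_params()] object.
#' @param variant `"engineered"` or `"wild_type"`.
#' @return named vector of derivatives, same order as the state.
#' @export
ode_rhs <- function(t, state, params,
                    variant = c("engineered", "wild_type")) {
  variant <- match.arg(variant)
  s <- as_model_state(state)
  if (any(!is.finite(s))) stop("non-finite state")
  s <- pmax(s, 0)
  if (variant == "wild_type") s[c("M", "LR")] <- 0
  pH <- pH_from_LA(s[["LA"]], params$c0, params$c1, params$c2)
  mu <- growth_rate(s[["LAC_out"]], s[["LA"]], params)
  r <- reaction_rates(s, params, pH = pH, mu = mu)
  prod_N <- switch(params$repression_form,
    printed = if (params$strict_as_printed) r[["R12"]] - r[["R13"]]
              else max(r[["R12"]] - r[["R13"]], 0),
    hill = params$T_max * params$G / (1 + params$S * s[["LR"]])
  )
  d <- c(
    LAC_out = -r[["R1"]] + r[["R2"]],
    LAC_in  = r[["R1"]] - r[["R2"]] - r[["R3"]] - r[["R10"]],
    GLU     = r[["R3"]] - r[["R4"]],
    PYR     = params$pyr_per_glc * r[["R4"]] - params$f_conv * r[["R5"]],
    LA      = params$f_conv * r[["R5"]],
    M       = r[["R6"]] + r[["R7"]] - r[["R8"]],
    LR      = r[["R9"]] - r[["R10"]] - r[["R11"]],
    N       = prod_N - r[["R14"]],
    LS      = r[["R15"]] - r[["R16"]],
    LZ      = r[["R17"]] - r[["R18"]],
    X       = r[["R19"]]
  )
  if (variant == "wild_type") {
    d[["M"]] <- 0
    d[["LR"]] <- 0
    d[["LAC_in"]] <- r[["R1"]] - r[["R2"]] - r[["R3"]]  # no R10
    d[["N"]] <- if (params$repression_form == "hill")
      params$T_max * params$G - r[["R14"]] else r[["R12"]] - r[["R14"]]
  }
  d
}

#' Frozen-growth steady state of the expression cascade
#'
#' Closed-form wild-type steady states of the lacSZ expression sub-system at
#' a frozen growth rate `mu_bar`:
#' `N* = V2*G/(d_N+mu_bar)`, `LS* = K_LS*N*/(d_LS+mu_bar)`,
#' `LZ* = K_LZ*N*/(d_LZ+mu_bar)`.  Used as the default pre-culture
#' equilibrium for initial conditions.
#'
#' @param params a [lacferm_params()] object.
#' @param mu_bar frozen specific growth rate, 1/h (>= 0).
#' @return named vector with components `N`, `LS`, `LZ` (M).
#' @export
equilibrate_expression <- function(params, mu_bar = 0) {
  stopifnot(is.finite(mu_bar), mu_bar >= 0)
  Nst <- params$V2 * params$G / (params$d_N + mu_bar)
  c(N = Nst,
    LS = params$K_LS * Nst / (params$d_LS + mu_bar),
    LZ = params$K_LZ * Nst / (params$d_LZ + mu_bar))
}

#' Default initial conditions for a batch fermentation
#'
#' Initial state emulating inoculation of reconstituted skim milk: 0.117 M
#' lactose (about 8\% skim milk solids), no intracellular metabolites or
#' lactic acid, 0.05 g/L biomass (a 4\% inoculum stand-in), lacR circuit off
#' (M = LR = 0), and the lacSZ expression cascade at its wild-type
#' frozen-growth equilibrium ([equilibrate_expression()] at `mu_bar`).
#'
#' @param params a [lacferm_params()] object.
#' @param lactose initial extracellular lactose, M.
#' @param biomass initial biomass, g/L.
#' @param mu_bar growth rate at which the expression cascade is equilibrated
#'   (default 0: stationary pre-culture).
#' @return named 11-component state vector.
#' @export
default_initial_state <- function(params, lactose = 0.117, biomass = 0.05,
                                  mu_bar = 0) {
  eq <- equilibrate_expression(params, mu_bar)
  s <- stats::setNames(numeric(length(.state_names)), .state_names)
  s["LAC_out"] <- lactose
  s["X"] <- biomass
  s[c("N", "LS", "LZ")] <- eq[c("N", "LS", "LZ")]
  s
}
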