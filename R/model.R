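# State vector layout shared by the integrator and all helpers.
.state_fields <- c("G", "R", "X", "I", "C", "P_LR")

#' Construct a system state
#'
#' Concentrations of the six model species: GFP (`G`), RFP (`R`), free
#' excisionase (`X`), free integrase (`I`), the integrase–excisionase complex
#' (`C`) — all in a.u. — and the fraction `P_LR` of promoter copies in the
#' LR (RFP-driving) orientation.
#'
#' @param G,R,X,I,C non-negative concentrations (a.u.).
#' @param P_LR promoter-orientation fraction in `[0, 1]`; the default 1 is
#'   the unflipped LR configuration the circuits start in.
#' @return named numeric vector classed `"system_state"`.
#' @export
system_state <- function(G = 0, R = 0, X = 0, I = 0, C = 0, P_LR = 1) {
  s <- c(G = G, R = R, X = X, I = I, C = C, P_LR = P_LR)
  validate_state(s)
}

#' Validate a state vector
#' @param s named numeric vector with entries `G, R, X, I, C, P_LR`.
#' @return the state, classed `"system_state"`.
#' @export
validate_state <- function(s) {
  s <- unclass(s)
  if (!is.numeric(s) || !all(.state_fields %in% names(s))) {
    stop("state must be numeric with fields ",
         paste(.state_fields, collapse = ", "), call. = FALSE)
  }
  s <- s[.state_fields]
  if (any(!is.finite(s))) stop("non-finite state entries", call. = FALSE)
  if (any(s[c("G", "R", "X", "I", "C")] < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (s["P_LR"] < 0 || s["P_LR"] > 1) {
    stop("P_LR must lie in [0, 1]", call. = FALSE)
  }
  structure(s, class = "system_state")
}

#' Hill activation of the inducible promoter
#'
#' Activity of the arabinose-inducible promoter as a function of inducer
#' dose: `leak + (1 - leak) * dose^n_H / (K_L^n_H + dose^n_H)`. Vectorized
#' over `dose`.
#'
#' @param dose inducer dose(s), % w/v L-arabinose, `>= 0`.
#' @param params a `circuit_parameters` object (uses `K_L`, `n_H`, `leak`).
#' @return activity in `[leak, 1)`, non-decreasing in dose.
#' @examples
#' p <- circuit_parameters()
#' hill_activation(p$K_L, p)  # 0.5 at half-activation when leak = 0
#' @export
hill_activation <- function(dose, params) {
  if (!is.numeric(dose) || any(!is.finite(dose)) || any(dose < 0)) {
    stop("dose must be finite and >= 0", call. = FALSE)
  }
  # dose^n/(K^n + dose^n) via the ratio form; stable for tiny K_L
  frac <- ifelse(dose == 0, 0, 1 / (1 + (params$K_L / dose)^params$n_H))
  params$leak + (1 - params$leak) * frac
}

#' Promoter activities of the three expression modules
#'
#' Dimensionless activities feeding synthesis and resource demand:
#' `u_R = hill(dose) * P_LR` (RFP and, bicistronically, excisionase);
#' `u_G = 1 + beta_FF * hill(dose) * (1 - P_LR)` under the feedforward
#' topology (`RE_NF_FF`), else the constitutive `u_G = 1`;
#' `u_I = 1` whenever recombinase genes are present, 0 for `NO_CONTROLLER`.
#'
#' @param state a `system_state` (only `P_LR` is used).
#' @param dose inducer dose (% w/v).
#' @param params a `circuit_parameters` object.
#' @param topology a topology accepted by [circuit_topology()].
#' @return named list with `u_G`, `u_R`, `u_I`.
#' @export
promoter_activities <- function(state, dose, params, topology) {
  topology <- circuit_topology(topology)
  h <- hill_activation(dose, params)
  p_lr <- unname(unclass(state)["P_LR"])
  u_R <- h * p_lr
  u_G <- if (topology == "RE_NF_FF") 1 + params$beta_FF * h * (1 - p_lr) else 1
  u_I <- if (has_recombinase(topology)) 1 else 0
  list(u_G = u_G, u_R = u_R, u_I = u_I)
}

#' Shared-resource availability factor
#'
#' The fraction of the lumped transcription/translation resource pool
#' available to each promoter: `phi = 1 / (1 + w_G u_G + w_R u_R + w_I u_I)`.
#' Always in `(0, 1]` and strictly decreasing in each weighted activity —
#' induction of one module lowers everyone's synthesis.
#'
#' @param acts list with `u_G`, `u_R`, `u_I` as from [promoter_activities()].
#' @param params a `circuit_parameters` object (uses the weights).
#' @return scalar `phi` in `(0, 1]`.
#' @export
resource_share <- function(acts, params) {
  1 / (1 + params$w_G * acts$u_G + params$w_R * acts$u_R +
         params$w_I * acts$u_I)
}

#' Time derivative of the system state
#'
#' Right-hand side of the circuit ODEs. All synthesis terms share the
#' multiplicative resource factor `phi` ([resource_share()]) and the plasmid
#' copy gain; excisionase is produced from the same promoter activity as RFP
#' (bicistronic). Free integrase and excisionase associate into a complex by
#' mass action; free integrase resets promoters BP->LR at rate
#' `V_on * I` while the complex flips LR->BP at rate `V_off * C` (the
#' negative feedback). The orientation fraction is frozen (`dP_LR = 0`) for
#' the `NO_CONTROLLER` and `OPEN_LOOP_MUT` topologies.
#'
#' The field leaves the physical box forward-invariant: every concentration
#' derivative is non-negative on its zero boundary and `dP_LR` points inward
#' at 0 and 1.
#'
#' @inheritParams promoter_activities
#' @return named numeric vector of derivatives (a.u./h; 1/h for `P_LR`).
#' @export
ode_rhs <- function(state, dose, params, topology) {
  topology <- circuit_topology(topology)
  s <- unclass(state)
  if (any(!is.finite(s))) stop("non-finite state entries", call. = FALSE)
  acts <- promoter_activities(state, dose, params, topology)
  phi <- resource_share(acts, params)
  cg <- params$copy_gain
  X <- s[["X"]]; I <- s[["I"]]; C <- s[["C"]]; P <- s[["P_LR"]]
  assoc <- params$k_on * X * I
  dissoc <- params$k_off * C
  k_X <- if (has_recombinase(topology)) params$k_X else 0
  k_I <- if (has_recombinase(topology)) params$k_I else 0
  dP <- if (flipping_active(topology)) {
    params$V_on * I * (1 - P) - params$V_off * C * P
  } else 0
  c(G = cg * params$k_G * acts$u_G * phi - params$d_G * s[["G"]],
    R = cg * params$k_R * acts$u_R * phi - params$d_R * s[["R"]],
    X = cg * k_X * acts$u_R * phi - params$d_X * X - assoc + dissoc,
    I = cg * k_I * acts$u_I * phi - params$d_I * I - assoc + dissoc,
    C = assoc - (params$k_off + params$d_C) * C,
    P_LR = dP)
}

# Internal fast RHS in deSolve calling convention. Parameters arrive as a
# flat numeric vector (canonical order) plus dose and topology flags, so the
# integrator avoids list dispatch in the inner loop. Kept consistent with
# ode_rhs() by a dedicated test.
.rhs_desolve <- function(t, y, parms) {
  p <- parms$v
  h <- parms$hill
  P <- y[[6L]]
  u_R <- h * P
  u_G <- if (parms$ff) 1 + p[["beta_FF"]] * h * (1 - P) else 1
  u_I <- parms$u_I
  phi <- 1 / (1 + p[["w_G"]] * u_G + p[["w_R"]] * u_R + p[["w_I"]] * u_I)
  cg <- p[["copy_gain"]]
  X <- y[[3L]]; I <- y[[4L]]; C <- y[[5L]]
  assoc <- p[["k_on"]] * X * I
  dissoc <- p[["k_off"]] * C
  dP <- if (parms$flip) {
    p[["V_on"]] * I * (1 - P) - p[["V_off"]] * C * P
  } else 0
  list(c(cg * parms$k_G_eff * u_G * phi - p[["d_G"]] * y[[1L]],
         cg * p[["k_R"]] * u_R * phi - p[["d_R"]] * y[[2L]],
         cg * parms$k_X_eff * u_R * phi - p[["d_X"]] * X - assoc + dissoc,
         cg * parms$k_I_eff * u_I * phi - p[["d_I"]] * I - assoc + dissoc,
         assoc - (p[["k_off"]] + p[["d_C"]]) * C,
         dP))
}

# Precompute the deSolve parameter bundle for one (params, topology, dose).
.rhs_parms <- function(params, topology, dose) {
  topology <- circuit_topology(topology)
  rec <- has_recombinase(topology)
  list(v = unlist(unclass(params)),
       hill = hill_activation(dose, params),
       ff = topology == "RE_NF_FF",
       flip = flipping_active(topology),
       u_I = if (rec) 1 else 0,
       k_G_eff = params$k_G,
       k_X_eff = if (rec) params$k_X else 0,
       k_I_eff = if (rec) params$k_I else 0)
}
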