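# Scaled residual used as the steady-state criterion: the max-norm of the
# RHS relative to state magnitude (a.u./h per unit of 1 + |state|).
.scaled_residual <- function(f, y) max(abs(f) / (1 + abs(y)))

# Numerical Jacobian of the RHS restricted to the active coordinates.
.num_jacobian <- function(y, active, parms) {
  n <- length(active)
  J <- matrix(0, n, n)
  f0 <- unlist(.rhs_desolve(0, y, parms))
  for (j in seq_len(n)) {
    h <- 1e-7 * (1 + abs(y[active[j]]))
    yp <- y; yp[active[j]] <- yp[active[j]] + h
    J[, j] <- (unlist(.rhs_desolve(0, yp, parms))[active] - f0[active]) / h
  }
  J
}

# Damped Newton polish of the integrated end state. Only moves the state if
# it reduces the scaled residual while staying inside the physical box and
# within a small neighbourhood of the integrated state, so the polish can
# never move the answer by more than the integration already allows.
.newton_polish <- function(y, parms, pinned_P, target = 1e-12,
                           max_iter = 20L, max_move_rel = 1e-3) {
  active <- if (pinned_P) 1:5 else 1:6
  y0 <- y
  for (it in seq_len(max_iter)) {
    f <- unlist(.rhs_desolve(0, y, parms))
    res <- .scaled_residual(f, y)
    if (res <= target) break
    J <- .num_jacobian(y, active, parms)
    step <- tryCatch(solve(J, -f[active]), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lambda <- 1
    improved <- FALSE
    for (k in 1:6) {
      cand <- y
      cand[active] <- y[active] + lambda * step
      cand[1:5] <- pmax(cand[1:5], 0)
      cand[6] <- min(max(cand[6], 0), 1)
      if (max(abs(cand - y0) / (1 + abs(y0))) > max_move_rel) {
        lambda <- lambda / 2
        next
      }
      fc <- unlist(.rhs_desolve(0, cand, parms))
      if (.scaled_residual(fc, cand) < res) {
        y <- cand
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  y
}

#' Integrate the circuit ODEs to steady state
#'
#' Integrates the stiff system with [deSolve::lsoda()] in geometrically
#' growing time chunks, declaring steady state when the max-norm of the RHS
#' scaled by state magnitude drops below `ss_tol`, then (by default) applies
#' a damped Newton polish that may only reduce the residual without moving
#' the state appreciably. The physical box (`G,R,X,I,C >= 0`,
#' `P_LR` in `[0,1]`) is asserted on every accepted output point.
#'
#' @param params a `circuit_parameters` object.
#' @param topology a topology accepted by [circuit_topology()].
#' @param dose inducer dose (% w/v).
#' @param init initial `system_state`; defaults to the empty cell with the
#'   promoter in the LR orientation.
#' @param ss_tol steady-state residual tolerance (a.u./h per unit
#'   `1 + |state|`).
#' @param rtol,atol integrator tolerances.
#' @param t_max maximum model time (h) before giving up; flipping dynamics
#'   can be slow, so the default is generous.
#' @param polish apply the Newton polish after integration.
#' @return list classed `"steady_state_result"`: `state` (a `system_state`),
#'   `converged`, `residual`, `elapsed_model_time`.
#' @export
integrate_to_steady_state <- function(params, topology, dose,
                                      init = system_state(),
                                      ss_tol = 1e-8,
                                      rtol = 1e-10, atol = 1e-12,
                                      t_max = 1000, polish = TRUE) {
  params <- validate_parameters(params)
  topology <- circuit_topology(topology)
  init <- validate_state(init)
  parms <- .rhs_parms(params, topology, dose)
  y <- unname(unclass(init))
  names(y) <- .state_fields
  pinned_P <- !flipping_active(topology)

  t_now <- 0
  chunk <- 20
  converged <- FALSE
  repeat {
    t_end <- min(t_now + chunk, t_max)
    times <- seq(t_now, t_end, length.out = 11L)
    sol <- deSolve::lsoda(y, times, .rhs_desolve, parms,
                          rtol = rtol, atol = atol)
    traj <- sol[, 1L + seq_along(y), drop = FALSE]
    if (any(!is.finite(traj))) {
      stop("integration produced non-finite values (dose = ", dose, ")",
           call. = FALSE)
    }
    # forward-invariance assertion with numerical slack, then clamp
    slack <- 1e3 * atol + 1e-9
    if (min(traj[, 1:5]) < -slack || min(traj[, 6]) < -slack ||
        max(traj[, 6]) > 1 + slack) {
      stop("trajectory left the invariant box beyond numerical slack",
           call. = FALSE)
    }
    y <- pmin(pmax(traj[nrow(traj), ], 0), c(Inf, Inf, Inf, Inf, Inf, 1))
    names(y) <- .state_fields
    t_now <- t_end
    res <- .scaled_residual(unlist(.rhs_desolve(0, y, parms)), y)
    if (res <= ss_tol) {
      converged <- TRUE
      break
    }
    if (t_now >= t_max) break
    chunk <- chunk * 2
  }
  if (converged && polish) {
    y <- .newton_polish(y, parms, pinned_P,
                        target = min(1e-12, ss_tol / 100))
  }
  res <- .scaled_residual(unlist(.rhs_desolve(0, y, parms)), y)
  structure(list(state = validate_state(y),
                 converged = converged,
                 residual = res,
                 elapsed_model_time = t_now),
            class = "steady_state_result")
}

#' Steady-state dose–response scan
#'
#' One steady state per inducer dose, warm-starting each dose from the
#' previous steady state (the promoter-orientation fraction carries over,
#' which is also the physical protocol of a dose ladder on a shared
#' pre-culture). Any non-converged dose is an error naming the offending
#' doses.
#'
#' @inheritParams integrate_to_steady_state
#' @param doses sorted non-negative inducer doses (% w/v).
#' @param warm_start warm-start successive doses (default) or integrate each
#'   dose cold from `init`.
#' @param ... passed to [integrate_to_steady_state()].
#' @return data.frame classed `"dose_response"` with columns `dose`, `G_ss`,
#'   `R_ss`, `X_ss`, `I_ss`, `C_ss`, `P_LR_ss`; attributes `topology` and
#'   `params_digest`.
#' @export
dose_response_scan <- function(params, topology, doses = default_dose_ladder(),
                               init = system_state(), warm_start = TRUE, ...) {
  params <- validate_parameters(params)
  topology <- circuit_topology(topology)
  if (!is.numeric(doses) || length(doses) == 0L || any(doses < 0)) {
    stop("doses must be non-negative", call. = FALSE)
  }
  if (is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be strictly increasing", call. = FALSE)
  }
  states <- matrix(NA_real_, length(doses), 6L,
                   dimnames = list(NULL, .state_fields))
  failed <- c()
  cur_init <- init
  for (i in seq_along(doses)) {
    r <- integrate_to_steady_state(params, topology, doses[i],
                                   init = cur_init, ...)
    if (!r$converged) failed <- c(failed, doses[i])
    states[i, ] <- unclass(r$state)
    if (warm_start) cur_init <- r$state
  }
  if (length(failed)) {
    stop("steady state did not converge at dose(s): ",
         paste(signif(failed, 6), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(dose = doses,
                    G_ss = states[, "G"], R_ss = states[, "R"],
                    X_ss = states[, "X"], I_ss = states[, "I"],
                    C_ss = states[, "C"], P_LR_ss = states[, "P_LR"])
  structure(out, class = c("dose_response", "data.frame"),
            topology = unclass(topology), params_digest = params_digest(params))
}

#' Default sweep grid for a parameter
#'
#' The grids used throughout the package: feedback strength `V_off` on a
#' 31-point linear grid over `[0, 1.5]`; excisionase turnover `d_X` on a
#' 25-point log grid over `[1e-2, 1e2]` 1/h; integrase synthesis `k_I` on a
#' 25-point log grid spanning four decades around its default.
#'
#' @param name one of `"V_off"`, `"d_X"`, `"k_I"`.
#' @return numeric vector of swept values.
#' @export
default_sweep_grid <- function(name) {
  switch(name,
    V_off = seq(0, 1.5, length.out = 31L),
    d_X = 10^seq(-2, 2, length.out = 25L),
    k_I = circuit_parameters()$k_I * 10^seq(-2, 2, length.out = 25L),
    stop("no default sweep grid for parameter: ", name, call. = FALSE))
}

#' Parameter sweep of steady-state dose responses
#'
#' Repeats [dose_response_scan()] for each value of one parameter, storing
#' per-row baseline-normalized GFP and the Coupling Index of each row.
#'
#' @inheritParams dose_response_scan
#' @param swept_name name of a `circuit_parameters` field.
#' @param swept_values values for that field (validated per value).
#' @param ci_method CI method passed to [compute_ci()].
#' @param ci_grid_n evaluation grid size for the fitted-curve CI.
#' @return list classed `"sweep_grid"` with `swept_name`, `swept_values`,
#'   `doses`, `G_matrix` and `G_norm_matrix` (rows = swept values, cols =
#'   doses), `ci_per_value`, `scans` (the per-value `dose_response` tables).
#' @export
parameter_sweep <- function(params, topology, swept_name,
                            swept_values = default_sweep_grid(swept_name),
                            doses = default_dose_ladder(),
                            ci_method = "pchip_fit", ci_grid_n = 201L, ...) {
  params <- validate_parameters(params)
  if (!swept_name %in% parameter_fields()) {
    stop("unknown parameter field: ", swept_name, call. = FALSE)
  }
  if (!length(swept_values)) stop("empty sweep grid", call. = FALSE)
  n_v <- length(swept_values)
  G <- matrix(NA_real_, n_v, length(doses))
  Gn <- matrix(NA_real_, n_v, length(doses))
  ci <- numeric(n_v)
  scans <- vector("list", n_v)
  for (i in seq_len(n_v)) {
    p_i <- tryCatch(
      do.call(update_parameters, c(list(params), stats::setNames(
        list(swept_values[i]), swept_name))),
      error = function(e) stop("invalid swept value ", swept_values[i],
                               " for ", swept_name, ": ", conditionMessage(e),
                               call. = FALSE))
    tab <- tryCatch(dose_response_scan(p_i, topology, doses, ...),
                    error = function(e) stop(
                      "scan failed at ", swept_name, " = ", swept_values[i],
                      ": ", conditionMessage(e), call. = FALSE))
    scans[[i]] <- tab
    G[i, ] <- tab$G_ss
    Gn[i, ] <- tab$G_ss / tab$G_ss[tab$dose == 0]
    ci[i] <- compute_ci(normalize_responses(tab), method = ci_method,
                        grid_n = ci_grid_n)$ci
  }
  structure(list(swept_name = swept_name, swept_values = swept_values,
                 doses = doses, G_matrix = G, G_norm_matrix = Gn,
                 ci_per_value = ci, scans = scans,
                 topology = unclass(circuit_topology(topology)),
                 params_digest = params_digest(params)),
            class = "sweep_grid")
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat("<sweep_grid> ", x$swept_name, " over [",
      signif(min(x$swept_values), 4), ", ", signif(max(x$swept_values), 4),
      "] (", length(x$swept_values), " values x ", length(x$doses),
      " doses), topology ", x$topology, "\n", sep = "")
  cat("  CI range: [", signif(min(x$ci_per_value), 4), ", ",
      signif(max(x$ci_per_value), 4), "]\n", sep = "")
  invisible(x)
}

#' Doses that sample the response curve uniformly in normalized RFP
#'
#' Runs a pilot dose-response scan, inverts the monotone dose-to-RFP map
#' with the shape-preserving cubic interpolant, and returns a dose grid
#' whose steady-state RFP values are approximately equally spaced between 0
#' and the maximum. On such a grid the point average of the normalized
#' response is a Riemann sum of the same integral the fitted-curve Coupling
#' Index computes, making the two estimators directly comparable.
#'
#' @inheritParams dose_response_scan
#' @param n number of doses returned (including 0).
#' @param pilot_n pilot grid size for the inversion.
#' @param dose_max top dose of the pilot grid (% w/v).
#' @param ... passed to [dose_response_scan()].
#' @return ascending numeric vector of `n` doses starting at 0.
#' @export
uniform_response_doses <- function(params, topology, n = 200L,
                                   pilot_n = 60L, dose_max = 5e-3, ...) {
  pilot <- c(0, 10^seq(log10(dose_max) - 2.5, log10(dose_max),
                       length.out = pilot_n - 1L))
  tab <- dose_response_scan(params, topology, pilot, ...)
  r <- tab$R_ss / max(tab$R_ss)
  keep <- !duplicated(r)
  inv <- stats::splinefun(r[keep], tab$dose[keep], method = "monoH.FC")
  doses <- pmax(0, inv(seq(0, 1, length.out = n)))
  sort(unique(c(0, doses)))
}
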