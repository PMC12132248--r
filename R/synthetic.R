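#' The plate-reader induction dose ladder
#'
#' The six-step L-arabinose ladder used for circuit induction:
#' 0, 1.25e-4, 2.5e-4, 6.25e-4, 2.5e-3 and 5e-3 % w/v. `extended = TRUE`
#' adds the seventh working dose 8.3e-3 % (the 8.3% stock diluted
#' 1000-fold).
#'
#' @param extended include the top 8.3e-3 % dose.
#' @return ascending numeric vector of doses (% w/v).
#' @export
default_dose_ladder <- function(extended = FALSE) {
  d <- c(0, 1.25e-4, 2.5e-4, 6.25e-4, 2.5e-3, 5e-3)
  if (extended) d <- c(d, 8.3e-3)
  d
}

#' Plate-reader noise model
#'
#' Measurement model applied to model steady states: a multiplicative
#' lognormal factor with coefficient of variation `cv_mult` (unit mean),
#' plus additive Gaussian background `N(bg_mean, bg_sd)`, clipped at zero.
#'
#' @param cv_mult multiplicative coefficient of variation (>= 0).
#' @param bg_mean,bg_sd additive background mean and sd (a.u., `bg_sd >= 0`).
#' @param seed integer RNG seed making a dataset fully reproducible.
#' @return list classed `"noise_model"`.
#' @export
noise_model <- function(cv_mult = 0.10, bg_mean = 0, bg_sd = 0, seed = 1L) {
  if (cv_mult < 0 || bg_sd < 0) {
    stop("cv_mult and bg_sd must be >= 0", call. = FALSE)
  }
  structure(list(cv_mult = cv_mult, bg_mean = bg_mean, bg_sd = bg_sd,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# Unit-mean lognormal multiplicative factors with coefficient of variation cv.
.lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic plate-reader dataset
#'
#' Simulates replicate fluorescence reads of the circuit at each dose of the
#' ladder: the model is driven to steady state per dose
#' ([dose_response_scan()]), then each replicate read is
#' `max(0, S * m + b)` with `S` the steady-state GFP or RFP, `m` a unit-mean
#' lognormal factor with CV `noise$cv_mult`, and `b ~ N(bg_mean, bg_sd)`.
#' Fully reproducible from `noise$seed`.
#'
#' @inheritParams dose_response_scan
#' @param n_reps replicates per dose (the plate protocol uses 3).
#' @param noise a [noise_model()].
#' @param ... passed to [dose_response_scan()].
#' @return data.frame classed `"synthetic_plate_dataset"` with columns
#'   `dose_pct`, `replicate`, `gfp_au`, `rfp_au`; attributes `topology`,
#'   `true_params_digest`, `noise`, and `truth_table` (the generating
#'   `dose_response`).
#' @export
generate_dataset <- function(params, topology, doses = default_dose_ladder(),
                             n_reps = 3L, noise = noise_model(), ...) {
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  if (!inherits(noise, "noise_model")) {
    stop("noise must be a noise_model", call. = FALSE)
  }
  tab <- dose_response_scan(params, topology, doses, ...)
  restore <- .with_seed(noise$seed)
  on.exit(restore(), add = TRUE)
  n_d <- length(doses)
  rows <- expand.grid(replicate = seq_len(n_reps), dose_i = seq_len(n_d))
  draw <- function(signal) {
    s <- signal[rows$dose_i]
    m <- .lognormal_factor(nrow(rows), noise$cv_mult)
    b <- if (noise$bg_sd > 0 || noise$bg_mean != 0) {
      stats::rnorm(nrow(rows), noise$bg_mean, noise$bg_sd)
    } else 0
    pmax(0, s * m + b)
  }
  out <- data.frame(dose_pct = doses[rows$dose_i],
                    replicate = rows$replicate,
                    gfp_au = draw(tab$G_ss),
                    rfp_au = draw(tab$R_ss))
  out <- out[order(out$dose_pct, out$replicate), ]
  rownames(out) <- NULL
  structure(out,
            class = c("synthetic_plate_dataset", "data.frame"),
            topology = unclass(circuit_topology(topology)),
            true_params_digest = params_digest(params),
            noise = noise, truth_table = tab)
}
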