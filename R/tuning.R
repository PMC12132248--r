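#' Tune a controller parameter to the decoupling optimum
#'
#' Finds the value of the excisionase turnover `d_X` or the integrase
#' synthesis rate `k_I` at which the Coupling Index crosses zero, i.e. where
#' the feedforward overcompensation exactly balances the residual negative
#' coupling. Both parameters act multiplicatively over decades, so the root
#' is bracketed and solved on a log scale with [stats::uniroot()].
#'
#' @inheritParams dose_response_scan
#' @param tuned_name `"d_X"` or `"k_I"`.
#' @param bracket length-2 positive vector `(low, high)`; the CI must change
#'   sign across it.
#' @param ci_tol requested |CI| at the returned value.
#' @param ci_method,ci_grid_n Coupling Index options (see [compute_ci()]).
#' @param max_iter maximum root-finder iterations.
#' @param ... passed to [dose_response_scan()].
#' @return list classed `"tuning_result"`: `tuned_name`, `tuned_value`,
#'   `ci_at_value`, `bracket`, `iterations`.
#' @export
find_decoupling_value <- function(params, topology, tuned_name = "d_X",
                                  bracket = c(1e-2, 1e2),
                                  doses = default_dose_ladder(),
                                  ci_tol = 1e-3,
                                  ci_method = "pchip_fit", ci_grid_n = 201L,
                                  max_iter = 100L, ...) {
  if (!tuned_name %in% c("d_X", "k_I")) {
    stop("tuned_name must be \"d_X\" or \"k_I\"", call. = FALSE)
  }
  if (length(bracket) != 2L || any(bracket <= 0) ||
      bracket[1] >= bracket[2]) {
    stop("bracket must be (low, high) with 0 < low < high", call. = FALSE)
  }
  ci_at <- function(value) {
    p <- do.call(update_parameters,
                 c(list(params), stats::setNames(list(value), tuned_name)))
    tab <- dose_response_scan(p, topology, doses, ...)
    compute_ci(normalize_responses(tab), method = ci_method,
               grid_n = ci_grid_n)$ci
  }
  f_lo <- ci_at(bracket[1])
  f_hi <- ci_at(bracket[2])
  if (sign(f_lo) * sign(f_hi) > 0) {
    stop("Coupling Index does not change sign over the bracket [",
         bracket[1], ", ", bracket[2], "] (CI = ", signif(f_lo, 4), " and ",
         signif(f_hi, 4), "); widen the bracket", call. = FALSE)
  }
  root <- stats::uniroot(function(u) ci_at(10^u),
                         lower = log10(bracket[1]), upper = log10(bracket[2]),
                         f.lower = f_lo, f.upper = f_hi,
                         tol = 1e-10, maxiter = max_iter)
  value <- 10^root$root
  ci_val <- ci_at(value)
  if (abs(ci_val) > ci_tol) {
    stop("root finder stalled: |CI| = ", signif(abs(ci_val), 4),
         " > ci_tol at ", tuned_name, " = ", signif(value, 6),
         " (last bracket width ", signif(root$estim.prec, 3), " decades)",
         call. = FALSE)
  }
  structure(list(tuned_name = tuned_name, tuned_value = value,
                 ci_at_value = ci_val, bracket = bracket,
                 iterations = root$iter),
            class = "tuning_result")
}

#' Fit circuit parameters to a plate dataset
#'
#' Least-squares recovery of selected parameters from replicate fluorescence
#' data: minimizes the sum of squared residuals between log-transformed
#' replicate-mean fluorescence and log-transformed model steady states
#' (variance-stabilizing under multiplicative noise), over log-transformed
#' free parameters within bounds, using bounded Levenberg–Marquardt
#' ([minpack.lm::nls.lm()]) from a deterministic list of multi-starts.
#'
#' This is validation machinery for the model (closing the loop
#' simulate -> measure -> re-estimate); the experimental analysis itself
#' fits nothing.
#'
#' @param dataset a [generate_dataset()] result, or any data.frame with
#'   columns `dose_pct`, `replicate`, `gfp_au`, `rfp_au` covering >= 2
#'   doses.
#' @param free_names parameter fields to estimate.
#' @param fixed a `circuit_parameters` object supplying every non-free
#'   field and the nominal values the bounds default around.
#' @param topology circuit topology of the data.
#' @param bounds named list of `(low, high)` per free field; default is
#'   `nominal * c(1e-3, 1e3)`.
#' @param start_seeds integer seeds, one multi-start each; the first start
#'   is always the mid-point of the log bounds.
#' @param ... passed to [dose_response_scan()] (integration tolerances).
#' @return list classed `"fit_result"`: `free_names`, `estimates`,
#'   `relative_errors` (vs `fixed`, as the known truth in recovery studies),
#'   `loss`, `converged`, `n_starts`, `message`.
#' @export
fit_parameters <- function(dataset, free_names, fixed, topology,
                           bounds = NULL, start_seeds = c(1L, 2L, 3L), ...) {
  fixed <- validate_parameters(fixed)
  if (!all(free_names %in% parameter_fields())) {
    stop("free_names must be circuit parameter fields", call. = FALSE)
  }
  obs <- replicate_means(dataset)
  if (nrow(obs) < 2L) stop("dataset must cover >= 2 doses", call. = FALSE)
  flat <- stats::sd(obs$G_ss) < 1e-12 * max(abs(obs$G_ss), 1) &&
    stats::sd(obs$R_ss) < 1e-12 * max(abs(obs$R_ss), 1)
  if (flat) {
    warning("flat data in both channels: parameters not identifiable")
    return(structure(list(free_names = free_names,
                          estimates = unlist(unclass(fixed))[free_names],
                          relative_errors = rep(NA_real_, length(free_names)),
                          loss = NA_real_, converged = FALSE, n_starts = 0L,
                          message = "non-identifiable: flat data"),
                     class = "fit_result"))
  }
  if (is.null(bounds)) {
    bounds <- lapply(free_names, function(nm) {
      unlist(unclass(fixed))[[nm]] * c(1e-3, 1e3)
    })
    names(bounds) <- free_names
  }
  lo <- log(vapply(free_names, function(nm) bounds[[nm]][1], numeric(1)))
  hi <- log(vapply(free_names, function(nm) bounds[[nm]][2], numeric(1)))
  # log-residual floors, fixed from the data scale once
  eps_g <- 1e-3 * max(obs$G_ss)
  eps_r <- 1e-3 * max(obs$R_ss, eps_g)
  resid_fun <- function(theta) {
    p <- do.call(update_parameters,
                 c(list(fixed), stats::setNames(as.list(exp(theta)),
                                                free_names)))
    tab <- tryCatch(dose_response_scan(p, topology, obs$dose, ...),
                    error = function(e) NULL)
    if (is.null(tab)) return(rep(1e3, 2L * nrow(obs)))
    c(log(tab$G_ss + eps_g) - log(obs$G_ss + eps_g),
      log(tab$R_ss + eps_r) - log(obs$R_ss + eps_r))
  }
  mid <- (lo + hi) / 2
  starts <- list(mid)
  for (s in start_seeds) {
    restore <- .with_seed(s)
    starts[[length(starts) + 1L]] <- lo + stats::runif(length(lo)) * (hi - lo)
    restore()
  }
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = lo, upper = hi, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    loss <- sum(fit$fvec^2)
    if (is.null(best) || loss < best$loss) {
      best <- list(theta = fit$par, loss = loss, info = fit$info,
                   message = fit$message)
    }
  }
  if (is.null(best)) {
    stop("all optimizer starts failed", call. = FALSE)
  }
  est <- exp(best$theta)
  names(est) <- free_names
  truth <- unlist(unclass(fixed))[free_names]
  rel_err <- ifelse(truth > 0, abs(est - truth) / truth, NA_real_)
  structure(list(free_names = free_names, estimates = est,
                 relative_errors = rel_err, loss = best$loss,
                 converged = best$info %in% 1:4, n_starts = length(starts),
                 message = best$message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> loss = ", signif(x$loss, 6),
      if (x$converged) " (converged)" else " (NOT converged)", "\n", sep = "")
  for (i in seq_along(x$free_names)) {
    cat("  ", format(x$free_names[i], width = 8), " = ",
        signif(x$estimates[i], 6),
        if (!is.na(x$relative_errors[i]))
          paste0("  (rel. err. ", signif(100 * x$relative_errors[i], 3), "%)"),
        "\n", sep = "")
  }
  invisible(x)
}

#' Parameter-recovery simulation study
#'
#' Repeats generate-then-fit over several noise levels: for each
#' multiplicative CV, `n_datasets` synthetic plate datasets are drawn with
#' distinct seeds derived from `base_seed` and the selected parameters are
#' re-estimated from each. Per-dataset fit failures are counted, not fatal.
#'
#' @inheritParams fit_parameters
#' @param true_params generating (and nominal) `circuit_parameters`.
#' @param cv_levels multiplicative noise CVs to study.
#' @param n_datasets datasets per CV level.
#' @param base_seed integer; dataset seeds are `base_seed + 1000*cv_index +
#'   dataset_index`.
#' @param n_reps replicates per dose in each dataset.
#' @param doses inducer ladder.
#' @param ... passed to [fit_parameters()].
#' @return data.frame classed `"recovery_table"`: one row per (cv, free
#'   parameter) with `median_rel_err`, `iqr_rel_err`, `n_ok`, `n_fail`.
#' @export
recovery_study <- function(true_params, topology, free_names,
                           cv_levels = c(0, 0.05), n_datasets = 20L,
                           base_seed = 1L, n_reps = 3L,
                           doses = default_dose_ladder(), ...) {
  if (n_datasets < 1L) stop("n_datasets must be >= 1", call. = FALSE)
  rows <- list()
  for (ci in seq_along(cv_levels)) {
    cv <- cv_levels[ci]
    errs <- matrix(NA_real_, n_datasets, length(free_names),
                   dimnames = list(NULL, free_names))
    n_fail <- 0L
    for (k in seq_len(n_datasets)) {
      seed <- base_seed + 1000L * ci + k
      ok <- tryCatch({
        ds <- generate_dataset(true_params, topology, doses, n_reps = n_reps,
                               noise = noise_model(cv_mult = cv, seed = seed))
        fit <- fit_parameters(ds, free_names, true_params, topology, ...)
        errs[k, ] <- fit$relative_errors
        TRUE
      }, error = function(e) FALSE)
      if (!ok) n_fail <- n_fail + 1L
    }
    for (nm in free_names) {
      e <- errs[, nm]
      rows[[length(rows) + 1L]] <- data.frame(
        cv = cv, parameter = nm,
        median_rel_err = stats::median(e, na.rm = TRUE),
        iqr_rel_err = stats::IQR(e, na.rm = TRUE),
        n_ok = sum(!is.na(e)), n_fail = n_fail)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("recovery_table", "data.frame"))
}
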