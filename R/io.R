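# All tables are written as long-format CSV with 15 significant digits so a
# round trip preserves at least 12; each CSV gets a JSON sidecar
# (<path>.json) carrying the parameterization, topology and tolerances.

.fmt <- function(x) formatC(x, digits = 15, format = "g")

.write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
}

.read_sidecar <- function(path) {
  side <- paste0(path, ".json")
  if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  else NULL
}

#' Write / read a dose–response table
#'
#' CSV columns `dose, G_ss, R_ss, X_ss, I_ss, C_ss, P_LR_ss`; the JSON
#' sidecar records topology and the parameter digest. Doses are written in
#' % w/v exactly as used.
#'
#' @param table a `dose_response` table.
#' @param path CSV path.
#' @param params optional `circuit_parameters` to embed in the sidecar.
#' @return `path` invisibly (write); the `dose_response` table (read).
#' @export
write_dose_response <- function(table, path, params = NULL) {
  stopifnot(inherits(table, "dose_response"))
  df <- as.data.frame(lapply(table, .fmt), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(type = "dose_response", topology = attr(table, "topology"),
               params_digest = attr(table, "params_digest"))
  if (!is.null(params)) meta$params <- unclass(validate_parameters(params))
  .write_sidecar(path, meta)
  invisible(path)
}

#' @rdname write_dose_response
#' @export
read_dose_response <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  meta <- .read_sidecar(path)
  structure(df, class = c("dose_response", "data.frame"),
            topology = meta$topology, params_digest = meta$params_digest)
}

#' Write / read a parameter-sweep grid
#'
#' Long-format CSV with columns
#' `swept_value, dose, G_ss, R_ss, P_LR_ss, G_norm`; the sidecar holds the
#' swept-parameter name, topology, parameter set and per-value Coupling
#' Index.
#'
#' @param grid a `sweep_grid`.
#' @param path CSV path.
#' @param params optional `circuit_parameters` for the sidecar.
#' @return `path` invisibly (write); a `sweep_grid` (read; the per-value
#'   scans are reconstructed without the auxiliary species columns).
#' @export
write_sweep <- function(grid, path, params = NULL) {
  stopifnot(inherits(grid, "sweep_grid"))
  long <- do.call(rbind, lapply(seq_along(grid$swept_values), function(i) {
    data.frame(swept_value = grid$swept_values[i], dose = grid$doses,
               G_ss = grid$G_matrix[i, ],
               R_ss = grid$scans[[i]]$R_ss,
               P_LR_ss = grid$scans[[i]]$P_LR_ss,
               G_norm = grid$G_norm_matrix[i, ])
  }))
  df <- as.data.frame(lapply(long, .fmt), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(type = "sweep_grid", swept_name = grid$swept_name,
               topology = grid$topology, params_digest = grid$params_digest,
               swept_values = grid$swept_values,
               ci_per_value = grid$ci_per_value)
  if (!is.null(params)) meta$params <- unclass(validate_parameters(params))
  .write_sidecar(path, meta)
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  meta <- .read_sidecar(path)
  if (is.null(meta)) stop("missing sidecar for ", path, call. = FALSE)
  vals <- meta$swept_values
  doses <- sort(unique(df$dose))
  G <- matrix(NA_real_, length(vals), length(doses))
  Gn <- matrix(NA_real_, length(vals), length(doses))
  scans <- vector("list", length(vals))
  for (i in seq_along(vals)) {
    sub <- df[abs(df$swept_value - vals[i]) <=
                1e-12 * max(1, abs(vals[i])), , drop = FALSE]
    sub <- sub[order(sub$dose), ]
    G[i, ] <- sub$G_ss
    Gn[i, ] <- sub$G_norm
    scans[[i]] <- structure(
      data.frame(dose = sub$dose, G_ss = sub$G_ss, R_ss = sub$R_ss,
                 P_LR_ss = sub$P_LR_ss),
      class = c("dose_response", "data.frame"),
      topology = meta$topology, params_digest = meta$params_digest)
  }
  structure(list(swept_name = meta$swept_name, swept_values = vals,
                 doses = doses, G_matrix = G, G_norm_matrix = Gn,
                 ci_per_value = meta$ci_per_value, scans = scans,
                 topology = meta$topology,
                 params_digest = meta$params_digest),
            class = "sweep_grid")
}

#' Write / read a synthetic plate dataset
#'
#' CSV columns `dose_pct, replicate, gfp_au, rfp_au`; the sidecar stores the
#' generating parameters, topology, noise model and seed.
#'
#' @param dataset a `synthetic_plate_dataset`.
#' @param path CSV path.
#' @param params optional generating `circuit_parameters` for the sidecar.
#' @return `path` invisibly (write); a `synthetic_plate_dataset` (read).
#' @export
write_plate_dataset <- function(dataset, path, params = NULL) {
  stopifnot(inherits(dataset, "synthetic_plate_dataset"))
  df <- as.data.frame(lapply(dataset, .fmt), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  nm <- attr(dataset, "noise")
  meta <- list(type = "synthetic_plate_dataset",
               topology = attr(dataset, "topology"),
               true_params_digest = attr(dataset, "true_params_digest"),
               noise = unclass(nm))
  if (!is.null(params)) meta$params <- unclass(validate_parameters(params))
  .write_sidecar(path, meta)
  invisible(path)
}

#' @rdname write_plate_dataset
#' @export
read_plate_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  df$replicate <- as.integer(df$replicate)
  meta <- .read_sidecar(path)
  noise <- if (!is.null(meta$noise)) {
    do.call(noise_model, meta$noise)
  } else NULL
  structure(df, class = c("synthetic_plate_dataset", "data.frame"),
            topology = meta$topology,
            true_params_digest = meta$true_params_digest, noise = noise)
}

#' Write a Coupling Index result to JSON
#' @param result a `coupling_result`.
#' @param path JSON path.
#' @return `path` invisibly.
#' @export
write_coupling_result <- function(result, path) {
  stopifnot(inherits(result, "coupling_result"))
  jsonlite::write_json(list(ci = result$ci, method = result$method,
                            sign = result$sign, grid_n = result$grid_n,
                            tol = result$tol_used),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' A YAML (or JSON) mapping tying a whole pipeline stage together:
#' optional keys `params` (flat mapping of parameter fields), `topology`,
#' `doses`, `sweep` (`name`, `values`), `ci` (`method`, `grid_n`, `tol`),
#' `noise` (`cv_mult`, `bg_mean`, `bg_sd`, `seed`), `seed`, `out_dir`.
#' Every referenced parameter field is validated before any computation;
#' unknown top-level or parameter keys are an error listing the offenders.
#'
#' @param path config file.
#' @return list classed `"run_config"` with fully-resolved `params`
#'   (`circuit_parameters`), `topology`, `doses`, and the optional specs.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config extension: ", ext, call. = FALSE)
  known <- c("params", "topology", "doses", "sweep", "ci", "noise",
             "seed", "out_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p_extra <- setdiff(names(raw$params), parameter_fields())
  if (length(p_extra)) {
    stop("unknown parameter field(s) in config: ",
         paste(p_extra, collapse = ", "), call. = FALSE)
  }
  params <- do.call(circuit_parameters, as.list(raw$params))
  topology <- circuit_topology(raw$topology %||% "RE_NF")
  doses <- raw$doses %||% default_dose_ladder()
  if (!is.null(raw$sweep)) {
    if (is.null(raw$sweep$name) ||
        !raw$sweep$name %in% parameter_fields()) {
      stop("sweep$name must be a circuit parameter field", call. = FALSE)
    }
  }
  if (!is.null(raw$ci) && !is.null(raw$ci$method) &&
      !raw$ci$method %in% c("pchip_fit", "direct")) {
    stop("ci$method must be \"pchip_fit\" or \"direct\"", call. = FALSE)
  }
  noise <- if (!is.null(raw$noise)) do.call(noise_model, raw$noise) else NULL
  structure(list(params = params, topology = topology,
                 doses = as.numeric(doses), sweep = raw$sweep, ci = raw$ci,
                 noise = noise, seed = raw$seed %||% 1L,
                 out_dir = raw$out_dir %||% "."),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
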