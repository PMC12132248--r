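#' Circuit topology variants
#'
#' The four circuit variants modelled by the package, mirroring the
#' experimental constructs:
#'
#' * `NO_CONTROLLER` — reference circuit without recombinase genes: RFP under
#'   the inducible promoter, GFP constitutive; recombinase species carry zero
#'   synthesis and zero resource weight, and the promoter orientation is
#'   frozen.
#' * `OPEN_LOOP_MUT` — open-loop control: integrase and excisionase are
#'   expressed (and consume resources) but the attR central dinucleotide
#'   mutation abolishes recombination, so both flip rates are zero and the
#'   promoter-orientation fraction stays at its initial value.
#' * `RE_NF` — recombinase negative-feedback controller: excisionase is
#'   co-expressed bicistronically with RFP, complexes with constitutive
#'   integrase, and flips the inducible promoter out of the RFP-driving (LR)
#'   orientation as load rises. No feedforward (the flipped promoter is
#'   terminated before GFP).
#' * `RE_NF_FF` — negative feedback plus feedforward: the flipped (BP)
#'   promoter additionally drives GFP with read-through strength `beta_FF`,
#'   compensating the resource-competition loss.
#'
#' @format Character vector of the four variant names.
#' @export
CIRCUIT_TOPOLOGIES <- c("NO_CONTROLLER", "OPEN_LOOP_MUT", "RE_NF", "RE_NF_FF")

#' Validate and normalize a circuit topology
#'
#' @param variant one of [CIRCUIT_TOPOLOGIES] (case-sensitive string).
#' @return The validated topology string, classed `"circuit_topology"`.
#' @export
circuit_topology <- function(variant) {
  if (inherits(variant, "circuit_topology")) return(variant)
  if (!is.character(variant) || length(variant) != 1L ||
      !(variant %in% CIRCUIT_TOPOLOGIES)) {
    stop("topology must be one of: ", paste(CIRCUIT_TOPOLOGIES, collapse = ", "),
         call. = FALSE)
  }
  structure(variant, class = "circuit_topology")
}

#' Does the topology express recombinase genes?
#' @param topology a topology accepted by [circuit_topology()].
#' @return logical
#' @export
has_recombinase <- function(topology) {
  unclass(circuit_topology(topology)) != "NO_CONTROLLER"
}

#' Is the promoter-orientation fraction dynamic for this topology?
#' @inheritParams has_recombinase
#' @return logical; `FALSE` means `P_LR` is pinned at its initial value.
#' @export
flipping_active <- function(topology) {
  unclass(circuit_topology(topology)) %in% c("RE_NF", "RE_NF_FF")
}

# Field order defines the canonical parameter vector layout used everywhere
# (serialization, sweeps, fitting).
.param_fields <- c(
  "k_G", "k_R", "k_X", "k_I",
  "d_G", "d_R", "d_X", "d_I", "d_C",
  "K_L", "n_H", "leak",
  "w_G", "w_R", "w_I",
  "V_on", "V_off", "k_on", "k_off",
  "beta_FF", "copy_gain"
)

#' Kinetic, resource and recombinase parameters of the circuit model
#'
#' Builds a validated parameter set. All concentrations are in arbitrary
#' fluorescence-equivalent units (a.u.), time in hours, inducer dose in
#' % w/v L-arabinose.
#'
#' @param k_G,k_R,k_X,k_I maximal synthesis rates of GFP, RFP, excisionase
#'   and integrase (a.u./h) at full promoter activity and no competition.
#' @param d_G,d_R,d_X,d_I,d_C first-order removal (degradation + dilution)
#'   rates (1/h) of GFP, RFP, excisionase, integrase and the
#'   integrase–excisionase complex. `d_X` is the excisionase turnover the
#'   feedforward controller is tuned by.
#' @param K_L half-activation inducer dose (% w/v) of the arabinose-inducible
#'   promoter; `n_H` its Hill coefficient (>= 1); `leak` basal activity
#'   fraction in `[0, 1)`.
#' @param w_G,w_R,w_I dimensionless resource-demand weights per unit promoter
#'   activity of the GFP, RFP and integrase modules.
#' @param V_on BP->LR reset rate constant per unit free integrase
#'   (1/(a.u. h)); `V_off` LR->BP flip rate constant per unit
#'   integrase–excisionase complex (1/(a.u. h)) — the negative feedback
#'   strength.
#' @param k_on,k_off complex association (1/(a.u. h)) and dissociation (1/h)
#'   rate constants.
#' @param beta_FF flipped-promoter read-through strength toward GFP
#'   (dimensionless); only active in the `RE_NF_FF` topology.
#' @param copy_gain scalar multiplying all synthesis rates, emulating plasmid
#'   copy number (> 0; high-copy variants use a larger value).
#' @return A named list classed `"circuit_parameters"`.
#' @examples
#' p <- circuit_parameters()           # defaults
#' p2 <- circuit_parameters(V_off = 0.75)
#' @export
circuit_parameters <- function(k_G = 100, k_R = 100, k_X = 50, k_I = 10,
                               d_G = 1, d_R = 1, d_X = 1, d_I = 1, d_C = 1,
                               K_L = 6.25e-4, n_H = 2, leak = 0,
                               w_G = 1, w_R = 1, w_I = 0.2,
                               V_on = 0.1, V_off = 0.75,
                               k_on = 1, k_off = 1,
                               beta_FF = 1, copy_gain = 1) {
  p <- mget(.param_fields)
  validate_parameters(p)
}

#' Validate a circuit-parameter list
#'
#' Checks completeness, non-negativity of rates and weights, strict
#' positivity of removal rates and `copy_gain`, `n_H >= 1` and
#' `0 <= leak < 1`.
#'
#' @param p named list (or `circuit_parameters`) with all parameter fields.
#' @return the validated list, classed `"circuit_parameters"`.
#' @export
validate_parameters <- function(p) {
  p <- unclass(p)
  missing <- setdiff(.param_fields, names(p))
  if (length(missing)) {
    stop("missing parameter fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- p[.param_fields]
  bad <- names(p)[!vapply(p, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad)) {
    stop("non-finite or non-scalar parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  v <- unlist(p)
  if (any(v < 0)) {
    stop("negative parameter(s): ",
         paste(names(v)[v < 0], collapse = ", "), call. = FALSE)
  }
  removal <- c("d_G", "d_R", "d_X", "d_I", "d_C")
  if (any(v[removal] <= 0)) stop("removal rates must be > 0", call. = FALSE)
  if (v["copy_gain"] <= 0) stop("copy_gain must be > 0", call. = FALSE)
  if (v["n_H"] < 1) stop("n_H must be >= 1", call. = FALSE)
  if (v["leak"] >= 1) stop("leak must be in [0, 1)", call. = FALSE)
  structure(p, class = "circuit_parameters")
}

#' Replace fields of a parameter set
#' @param p a `circuit_parameters` object.
#' @param ... named scalar replacements, e.g. `V_off = 0.5`.
#' @return validated updated parameter set.
#' @export
update_parameters <- function(p, ...) {
  repl <- list(...)
  if (length(repl)) {
    unknown <- setdiff(names(repl), .param_fields)
    if (length(unknown) || is.null(names(repl)) || any(names(repl) == "")) {
      stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p <- unclass(p)
    p[names(repl)] <- repl
  }
  validate_parameters(p)
}

#' Field names of a circuit-parameter set
#' @return character vector in canonical order.
#' @export
parameter_fields <- function() .param_fields

#' Short digest identifying a parameterization
#'
#' A compact, deterministic identifier of a parameter set used to tag tables
#' and datasets (sum of a simple polynomial hash over the 12-significant-digit
#' text rendering; no cryptographic intent).
#'
#' @param p a `circuit_parameters` object.
#' @return character scalar.
#' @export
params_digest <- function(p) {
  p <- validate_parameters(p)
  txt <- paste(names(p), formatC(unlist(p), digits = 12, format = "g"),
               sep = "=", collapse = ";")
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483647
  sprintf("p%08x", h)
}

#' Serialize parameters to a flat YAML or JSON file
#'
#' @param p a `circuit_parameters` object.
#' @param path output file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  p <- validate_parameters(p)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(unclass(p), path)
  } else if (ext == "json") {
    jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported parameter file extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read parameters from a flat YAML or JSON mapping
#'
#' Missing fields fall back to the package defaults; unknown keys are an
#' error (they usually indicate a typo in a config).
#'
#' @param path a `.yaml`/`.yml` or `.json` file with a flat mapping keyed by
#'   parameter field names.
#' @return a validated `circuit_parameters` object.
#' @export
read_parameters <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported parameter file extension: ", ext, call. = FALSE)
  }
  unknown <- setdiff(names(raw), .param_fields)
  if (length(unknown)) {
    stop("unknown parameter field(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(circuit_parameters, raw)
}

#' @export
print.circuit_parameters <- function(x, ...) {
  cat("<circuit_parameters>\n")
  v <- unlist(unclass(x))
  cat(paste0("  ", format(names(v), width = 10), " ",
             formatC(v, digits = 6, format = "g"), collapse = "\n"), "\n")
  invisible(x)
}
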