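#' Normalize a dose–response for the Coupling Index
#'
#' GFP is normalized to its baseline expression without RFP-module induction
#' (the zero-dose point); RFP is normalized to its maximum. Points are
#' sorted by normalized RFP; ties in normalized RFP average their normalized
#' GFP values.
#'
#' @param table a `dose_response` table, or any data.frame with columns
#'   `dose`, `G_ss`, `R_ss` (replicate-averaged measured tables use the same
#'   columns).
#' @param source label recorded on the result: `"simulation"` or
#'   `"measured"`.
#' @return list classed `"normalized_response"` with sorted `r_norm`
#'   (in `[0, 1]`), `g_norm` (`= 1` at the uninduced point), and `source`.
#' @export
normalize_responses <- function(table, source = "simulation") {
  need <- c("dose", "G_ss", "R_ss")
  if (!all(need %in% names(table))) {
    stop("table must have columns dose, G_ss, R_ss", call. = FALSE)
  }
  if (!any(table$dose == 0)) {
    stop("table must contain the zero-dose (baseline) point", call. = FALSE)
  }
  g0 <- mean(table$G_ss[table$dose == 0])
  if (!is.finite(g0) || g0 <= 0) {
    stop("baseline GFP must be > 0", call. = FALSE)
  }
  r_max <- max(table$R_ss)
  if (r_max <= 0) {
    stop("all-zero RFP: the response curve is degenerate; compute the ",
         "Coupling Index directly on the flat g_norm values instead ",
         "(method = \"direct\" on g_norm = G_ss/baseline)", call. = FALSE)
  }
  g <- table$G_ss / g0
  r <- table$R_ss / r_max
  o <- order(r)
  r <- r[o]; g <- g[o]
  # average g at tied r
  ru <- unique(r)
  gu <- vapply(ru, function(ri) mean(g[r == ri]), numeric(1))
  structure(list(r_norm = ru, g_norm = gu, source = source),
            class = "normalized_response")
}

#' Monotone piecewise-cubic interpolant of a normalized response
#'
#' Shape-preserving piecewise-cubic Hermite interpolant (Fritsch–Carlson
#' derivative limiting) through the (r_norm, g_norm) points: passes through
#' every point exactly, preserves monotonicity on monotone data, and does
#' not overshoot beyond the local data range on monotone segments. This is
#' the sparse-data fit used before averaging the Coupling Index.
#'
#' @param nr a `normalized_response`.
#' @return a function mapping `r` in `[0, 1]` to the fitted normalized GFP.
#' @export
pchip_interpolant <- function(nr) {
  if (!inherits(nr, "normalized_response")) {
    stop("nr must be a normalized_response", call. = FALSE)
  }
  if (length(unique(nr$r_norm)) < 2L) {
    stop("need at least 2 distinct r_norm points to fit a curve",
         call. = FALSE)
  }
  stats::splinefun(nr$r_norm, nr$g_norm, method = "monoH.FC")
}

#' Coupling Index of a normalized response
#'
#' The Coupling Index (CI) is the average deviation of the normalized
#' GFP-vs-RFP response curve from the ideal flat line at 1 that complete
#' resource decoupling would produce. With `method = "pchip_fit"` the curve
#' is the monotone piecewise-cubic fit, averaged over a uniform grid of
#' `grid_n` points on normalized RFP in `[0, 1]` (suitable for sparse
#' measured ladders); with `method = "direct"` the supplied points are
#' averaged without fitting (suitable for dense simulated curves). CI = 0
#' means perfect decoupling; negative and positive values mean under- and
#' over-compensation of GFP.
#'
#' @param nr a `normalized_response`.
#' @param method `"pchip_fit"` or `"direct"`.
#' @param grid_n number of uniform evaluation points for `"pchip_fit"`
#'   (>= 2).
#' @param tol half-width of the decoupled band used for the sign
#'   classification.
#' @return list classed `"coupling_result"`: `ci`, `method`, `grid_n`,
#'   `sign` (`"negative"`, `"decoupled"` or `"positive"`), `tol_used`.
#' @examples
#' nr <- structure(list(r_norm = c(0, 0.5, 1), g_norm = c(1, 0.8, 0.6),
#'                      source = "simulation"),
#'                 class = "normalized_response")
#' compute_ci(nr, method = "direct")$ci  # -0.2
#' @export
compute_ci <- function(nr, method = c("pchip_fit", "direct"),
                       grid_n = 201L, tol = 0.02) {
  method <- match.arg(method)
  if (!inherits(nr, "normalized_response")) {
    stop("nr must be a normalized_response", call. = FALSE)
  }
  if (method == "pchip_fit") {
    if (grid_n < 2L) stop("grid_n must be >= 2", call. = FALSE)
    curve <- pchip_interpolant(nr)
    r_grid <- seq(0, 1, length.out = grid_n)
    ci <- mean(curve(r_grid) - 1)
  } else {
    ci <- mean(nr$g_norm - 1)
    grid_n <- length(nr$g_norm)
  }
  sign <- if (ci < -tol) "negative" else if (ci > tol) "positive" else "decoupled"
  structure(list(ci = ci, method = method, grid_n = as.integer(grid_n),
                 sign = sign, tol_used = tol),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat("<coupling_result> CI = ", signif(x$ci, 6), " (", x$sign, "; ",
      x$method, ", n = ", x$grid_n, ")\n", sep = "")
  invisible(x)
}

#' Bootstrap standard error of the Coupling Index over replicates
#'
#' Resamples plate replicates within each dose, averages per dose,
#' normalizes and recomputes the CI. A convenience for measured or
#' synthetic replicate data; the point estimate always uses the plain
#' replicate mean.
#'
#' @param dataset a `synthetic_plate_dataset` or data.frame with columns
#'   `dose_pct`, `replicate`, `gfp_au`, `rfp_au`.
#' @param n_boot number of bootstrap resamples.
#' @param method,grid_n,tol passed to [compute_ci()].
#' @param seed RNG seed for the resampling.
#' @return list with `ci` (point estimate), `se`, `ci_boot` (the resampled
#'   values).
#' @export
ci_bootstrap <- function(dataset, n_boot = 200L,
                         method = "pchip_fit", grid_n = 201L, tol = 0.02,
                         seed = 1L) {
  tab <- replicate_means(dataset)
  point <- compute_ci(normalize_responses(tab, source = "measured"),
                      method = method, grid_n = grid_n, tol = tol)$ci
  rng <- .with_seed(seed)
  on.exit(rng(), add = TRUE)
  doses <- sort(unique(dataset$dose_pct))
  boots <- vapply(seq_len(n_boot), function(b) {
    rows <- lapply(doses, function(d) {
      sub <- dataset[dataset$dose_pct == d, , drop = FALSE]
      idx <- sample.int(nrow(sub), replace = TRUE)
      data.frame(dose = d, G_ss = mean(sub$gfp_au[idx]),
                 R_ss = mean(sub$rfp_au[idx]))
    })
    tb <- do.call(rbind, rows)
    tryCatch(compute_ci(normalize_responses(tb, source = "measured"),
                        method = method, grid_n = grid_n, tol = tol)$ci,
             error = function(e) NA_real_)
  }, numeric(1))
  list(ci = point, se = stats::sd(boots, na.rm = TRUE), ci_boot = boots)
}

# Save/restore the global RNG state around an internally seeded computation.
.with_seed <- function(seed) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Replicate means of a plate dataset
#'
#' Averages replicate fluorescence per dose and channel, returning the
#' `dose`/`G_ss`/`R_ss` table the normalization and fitting stages consume.
#'
#' @param dataset data.frame with columns `dose_pct`, `replicate`, `gfp_au`,
#'   `rfp_au`.
#' @return data.frame with columns `dose`, `G_ss`, `R_ss`.
#' @export
replicate_means <- function(dataset) {
  need <- c("dose_pct", "gfp_au", "rfp_au")
  if (!all(need %in% names(dataset))) {
    stop("dataset must have columns dose_pct, gfp_au, rfp_au", call. = FALSE)
  }
  g <- tapply(dataset$gfp_au, dataset$dose_pct, mean)
  r <- tapply(dataset$rfp_au, dataset$dose_pct, mean)
  d <- as.numeric(names(g))
  o <- order(d)
  data.frame(dose = d[o], G_ss = unname(g)[o], R_ss = unname(r)[o])
}
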