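#' Ground-truth response surface specification
#'
#' Describes the noiseless LFC surface of one synthetic gene over the
#' normalized dose-time unit square, plus the Gaussian noise added to each
#' pair-sample.  Families:
#' \describe{
#'   \item{constant}{\code{c0}; 1 coefficient.}
#'   \item{linear}{\code{c0 + c1*D + c2*T}; 3 coefficients.}
#'   \item{poly2}{\code{c0 + c1*D^2 + c2*T^2 + c3*D*T + c4*D + c5*T}; 6.}
#'   \item{poly3}{full third-order surface; 10 coefficients in the order
#'     intercept, D^3, D^2 T, D T^2, T^3, D^2, T^2, D T, D, T.}
#'   \item{plateau}{dose-saturating Michaelis-Menten shape
#'     \code{A * D / (D + k)}; coefficients \code{c(A, k)}.  Deliberately
#'     outside the fitted model family.}
#'   \item{adaptive}{dose response decaying with time,
#'     \code{A * D * exp(-r * T)}; coefficients \code{c(A, r)}.}
#' }
#'
#' @param family one of \code{"constant"}, \code{"linear"}, \code{"poly2"},
#'   \code{"poly3"}, \code{"plateau"}, \code{"adaptive"}.
#' @param coefficients numeric vector in normalized dose-time space (log2
#'   LFC units).
#' @param noise_sd standard deviation of i.i.d. Gaussian noise on each
#'   pair-sample LFC (log2 units), >= 0.
#' @param direction "+" or "-"; "-" negates the surface.
#' @return An object of class \code{"surface_spec"}.
#' @export
surface_spec <- function(family, coefficients, noise_sd = 0.05,
                         direction = "+") {
  family <- match.arg(family, c("constant", "linear", "poly2", "poly3",
                                "plateau", "adaptive"))
  need <- c(constant = 1L, linear = 3L, poly2 = 6L, poly3 = 10L,
            plateau = 2L, adaptive = 2L)[[family]]
  if (length(coefficients) != need) {
    stop("family '", family, "' needs ", need, " coefficients, got ",
         length(coefficients))
  }
  stopifnot(is.finite(noise_sd), noise_sd >= 0, direction %in% c("+", "-"))
  structure(list(family = family, coefficients = as.numeric(coefficients),
                 noise_sd = noise_sd, direction = direction),
            class = "surface_spec")
}

# Noiseless surface value at normalized coordinates.
surface_eval <- function(spec, dose_norm, time_norm) {
  co <- spec$coefficients
  v <- switch(spec$family,
    constant = rep(co[1L], length(dose_norm)),
    linear = poly_eval(co, dose_norm, time_norm, 1L),
    poly2 = poly_eval(co, dose_norm, time_norm, 2L),
    poly3 = poly_eval(co, dose_norm, time_norm, 3L),
    plateau = co[1L] * dose_norm / (dose_norm + co[2L]),
    adaptive = co[1L] * dose_norm * exp(-co[2L] * time_norm)
  )
  if (spec$direction == "-") -v else v
}

# Analytic gradient of the noiseless surface (normalized units).
surface_grad <- function(spec, dose_norm, time_norm) {
  co <- spec$coefficients
  g <- switch(spec$family,
    constant = list(grad_dose = numeric(length(dose_norm)),
                    grad_time = numeric(length(dose_norm))),
    linear = poly_grad(co, dose_norm, time_norm, 1L),
    poly2 = poly_grad(co, dose_norm, time_norm, 2L),
    poly3 = poly_grad(co, dose_norm, time_norm, 3L),
    plateau = list(
      grad_dose = co[1L] * co[2L] / (dose_norm + co[2L])^2,
      grad_time = numeric(length(dose_norm))),
    adaptive = list(
      grad_dose = co[1L] * exp(-co[2L] * time_norm),
      grad_time = -co[1L] * co[2L] * dose_norm * exp(-co[2L] * time_norm))
  )
  if (spec$direction == "-") {
    g$grad_dose <- -g$grad_dose
    g$grad_time <- -g$grad_time
  }
  g
}

#' Experiment design for the synthetic generator
#'
#' Defaults emulate a standard in vivo repeat-dose design: 3 dose levels,
#' 4 time points, 3 treated and 3 control animals per dose-time cell, so
#' each cell contributes \code{n_treated * n_control = 9} pairwise LFC
#' columns and the full design has \code{9 * 12 = 108} pair-samples.
#'
#' @param doses numeric vector of dose levels (default 30, 100, 300 mg/kg).
#' @param times numeric vector of time points (default 3, 6, 9, 24 h).
#' @param n_treated,n_control replicates per dose-time cell (defaults 3, 3).
#' @param seed integer seed for reproducible simulation.
#' @return An object of class \code{"experiment_design"}.
#' @export
experiment_design <- function(doses = c(30, 100, 300), times = c(3, 6, 9, 24),
                              n_treated = 3L, n_control = 3L, seed = 1L) {
  stopifnot(length(doses) >= 1, length(times) >= 1,
            n_treated >= 1, n_control >= 1)
  structure(list(doses = sort(as.numeric(doses)),
                 times = sort(as.numeric(times)),
                 n_treated = as.integer(n_treated),
                 n_control = as.integer(n_control),
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' Simulate a log fold-change experiment with known ground truth
#'
#' Generates one gene per surface specification.  Every pair-sample value is
#' the noiseless surface evaluated at the column's normalized design point
#' plus i.i.d. Gaussian noise.  The truth bundle carries, per gene, the
#' generating surface specification, the noiseless surface evaluated on the
#' standard prediction grid, the
#' analytic super-threshold activity mask, its dose-monotone direction, and
#' the most-left POD label of the analytic mask.
#'
#' @param specs list of [surface_spec()] objects (names become gene ids).
#' @param design an [experiment_design()].
#' @param resolution grid resolution for the truth maps (default 50).
#' @param threshold activity threshold (fraction) used for the truth masks
#'   (default 0.10).
#' @param log10_dose passed to [lfc_matrix()].
#' @return list with elements \code{lfc} (an [lfc_matrix()]) and
#'   \code{truth} (per-gene list).
#' @export
simulate_experiment <- function(specs, design = experiment_design(),
                                resolution = 50L, threshold = 0.10,
                                log10_dose = TRUE) {
  stopifnot(inherits(design, "experiment_design"), length(specs) > 0)
  if (inherits(specs, "surface_spec")) specs <- list(specs)
  ok <- vapply(specs, inherits, logical(1L), "surface_spec")
  if (!all(ok)) stop("'specs' must be a list of surface_spec objects")
  ids <- names(specs)
  if (is.null(ids)) ids <- sprintf("gene%04d", seq_along(specs))
  ids[ids == ""] <- sprintf("gene%04d", which(ids == ""))
  names(specs) <- ids

  cells <- expand.grid(time = design$times, dose = design$doses)
  ppc <- design$n_treated * design$n_control
  dose <- rep(cells$dose, each = ppc)
  time <- rep(cells$time, each = ppc)
  nrm <- normalize_axes(dose, time, log10_dose)

  set.seed(design$seed)
  G <- length(specs)
  n <- length(dose)
  mu <- matrix(NA_real_, G, n)
  for (g in seq_len(G)) {
    mu[g, ] <- surface_eval(specs[[g]], nrm$dose_norm, nrm$time_norm)
  }
  sds <- vapply(specs, `[[`, numeric(1L), "noise_sd")
  noise <- matrix(stats::rnorm(G * n), G, n) * sds
  vals <- mu + noise
  rownames(vals) <- ids
  rep_id <- as.integer(stats::ave(seq_len(n), paste(dose, time),
                                  FUN = seq_along))
  colnames(vals) <- sprintf("dose=%g,time=%g,rep=%d", dose, time, rep_id)
  lfc <- lfc_matrix(vals, dose, time, log10_dose = log10_dose)

  gn <- seq(0, 1, length.out = resolution)
  gmat <- expand.grid(dose_norm = gn, time_norm = gn)
  cut <- activity_cut(threshold)
  truth <- lapply(specs, function(sp) {
    surf <- matrix(surface_eval(sp, gmat$dose_norm, gmat$time_norm),
                   resolution, resolution, byrow = TRUE)
    grd <- surface_grad(sp, gmat$dose_norm, gmat$time_norm)
    gd <- matrix(grd$grad_dose, resolution, resolution, byrow = TRUE)
    mask <- abs(surf) >= cut
    dir <- if (any(mask)) {
      s <- sign(gd[mask])
      if (mean(s > 0) >= 0.5) "increasing" else "decreasing"
    } else NA_character_
    lab <- if (any(mask)) mask_most_left_label(mask) else NA_character_
    list(spec = sp, grid_lfc = surf, grid_grad_dose = gd, mask = mask,
         direction = dir, most_left = lab)
  })
  list(lfc = lfc, truth = truth)
}

#' All pairwise treated-vs-control log fold-changes
#'
#' Forms every treated-control difference of log2 expression values for one
#' dose-time cell: \code{n_treated * n_control} pair-sample LFCs per gene.
#'
#' @param treated,control numeric matrices of log2 expression (genes x
#'   replicates) or vectors (single gene).  Gene order must match.
#' @return matrix genes x (n_treated * n_control) of pairwise differences;
#'   column \code{(i-1)*n_control + j} is treated replicate i minus control
#'   replicate j.
#' @export
pairwise_lfc <- function(treated, control) {
  if (is.vector(treated)) treated <- matrix(treated, nrow = 1L)
  if (is.vector(control)) control <- matrix(control, nrow = 1L)
  if (nrow(treated) != nrow(control)) {
    stop("treated and control must have the same number of genes")
  }
  if (ncol(treated) < 1L || ncol(control) < 1L) {
    stop("both groups must be non-empty")
  }
  nt <- ncol(treated); nc <- ncol(control)
  out <- matrix(NA_real_, nrow(treated), nt * nc)
  for (i in seq_len(nt)) {
    out[, (i - 1L) * nc + seq_len(nc)] <- treated[, i] - control
  }
  rownames(out) <- rownames(treated)
  out
}

#' Preset surface specifications for the four fitted model classes
#'
#' Convenience constructor used in simulations and examples: coefficient
#' presets sized so that responsive genes peak around one log2 unit, the
#' scale of a clearly responsive gene.
#'
#' @param family one of "constant", "linear", "poly2", "poly3".
#' @param noise_sd Gaussian noise SD (default 0.05).
#' @param direction "+" or "-".
#' @return a [surface_spec()].
#' @export
preset_spec <- function(family, noise_sd = 0.05, direction = "+") {
  co <- switch(match.arg(family, c("constant", "linear", "poly2", "poly3")),
    constant = 0,
    linear = c(0, 0.8, 0.4),
    poly2 = c(0, 0.9, 0.5, -0.7, 0.3, 0.2),
    #            D^3  D^2T  DT^2  T^3  D^2   T^2  DT    D    T
    poly3 = c(0, 0.0, 1.5, -1.2, 0.8, 0.3, -0.2, 0.2, 0.4, 0.1)
  )
  surface_spec(family, co, noise_sd = noise_sd, direction = direction)
}
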