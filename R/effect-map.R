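#' Predict the dose-time effect map of a fitted gene
#'
#' Evaluates the selected polynomial surface on a dense grid covering the
#' whole tested dose and time range (linear in normalized coordinates, i.e.
#' log-spaced in original dose when log10 dose scaling is on) and attaches
#' the analytic gradient field.  Grid orientation: rows are time (ascending
#' with row index), columns are dose (ascending with column index).
#'
#' @param fit a \code{gene_fit} from [fit_dose_time()].
#' @param resolution grid points per axis (default 50, minimum 4).
#' @param gradient "analytic" (default; exact partial derivatives of the
#'   polynomial) or "finite" (central differences on the grid, retained for
#'   cross-checks).
#' @return An object of class \code{"effect_map"} with elements
#'   \code{lfc}, \code{grad_dose}, \code{grad_time} (resolution x resolution
#'   matrices), \code{dose_norm}, \code{time_norm}, \code{dose}, \code{time}
#'   (axis vectors in normalized and original units) and \code{gene_id}.
#' @export
effect_map <- function(fit, resolution = 50L,
                       gradient = c("analytic", "finite")) {
  stopifnot(inherits(fit, "gene_fit"))
  gradient <- match.arg(gradient)
  resolution <- as.integer(resolution)
  if (resolution < 4L) stop("grid resolution must be >= 4")
  gn <- seq(0, 1, length.out = resolution)
  pts <- expand.grid(dose_norm = gn, time_norm = gn)
  lfc <- matrix(poly_eval(fit$beta, pts$dose_norm, pts$time_norm, fit$order),
                resolution, resolution, byrow = TRUE)
  map <- structure(list(
    gene_id = fit$gene_id, order = fit$order, beta = fit$beta,
    dose_norm = gn, time_norm = gn,
    dose = denormalize_dose(fit$norm, gn),
    time = denormalize_time(fit$norm, gn),
    lfc = lfc, grad_dose = NULL, grad_time = NULL,
    norm = fit$norm, resolution = resolution
  ), class = "effect_map")
  gradient_field(map, method = gradient)
}

#' Fill the gradient field of an effect map
#'
#' Partial derivatives of the fitted log fold-change surface with respect to
#' normalized dose and time at every grid point.  The default is the exact
#' analytic derivative of the polynomial; central finite differences on the
#' grid are available for cross-checking.
#'
#' @param map an [effect_map()].
#' @param method "analytic" or "finite".
#' @return the map with \code{grad_dose} and \code{grad_time} filled
#'   (LFC per normalized axis unit).
#' @export
gradient_field <- function(map, method = c("analytic", "finite")) {
  method <- match.arg(method)
  stopifnot(inherits(map, "effect_map"))
  res <- map$resolution
  if (method == "analytic") {
    pts <- expand.grid(dose_norm = map$dose_norm, time_norm = map$time_norm)
    g <- poly_grad(map$beta, pts$dose_norm, pts$time_norm, map$order)
    map$grad_dose <- matrix(g$grad_dose, res, res, byrow = TRUE)
    map$grad_time <- matrix(g$grad_time, res, res, byrow = TRUE)
  } else {
    h_d <- map$dose_norm[2L] - map$dose_norm[1L]
    h_t <- map$time_norm[2L] - map$time_norm[1L]
    gd <- matrix(NA_real_, res, res)
    gt <- matrix(NA_real_, res, res)
    gd[, 2:(res - 1L)] <- (map$lfc[, 3:res] - map$lfc[, 1:(res - 2L)]) / (2 * h_d)
    gd[, 1L] <- (map$lfc[, 2L] - map$lfc[, 1L]) / h_d
    gd[, res] <- (map$lfc[, res] - map$lfc[, res - 1L]) / h_d
    gt[2:(res - 1L), ] <- (map$lfc[3:res, ] - map$lfc[1:(res - 2L), ]) / (2 * h_t)
    gt[1L, ] <- (map$lfc[2L, ] - map$lfc[1L, ]) / h_t
    gt[res, ] <- (map$lfc[res, ] - map$lfc[res - 1L, ]) / h_t
    map$grad_dose <- gd
    map$grad_time <- gt
  }
  map
}

#' @export
print.effect_map <- function(x, ...) {
  cat("Effect map for gene", x$gene_id, "-", x$resolution, "x", x$resolution,
      "grid, LFC range [", round(min(x$lfc), 3), ",", round(max(x$lfc), 3),
      "]\n")
  invisible(x)
}
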