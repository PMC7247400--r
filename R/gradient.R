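# Relative dose vs time influence from the gradient field of the DDRA.
#
# Every region point contributes the angle (counterclockwise from the
# positive dose axis, in normalized covariate units) and magnitude of the
# local gradient.  The time-dose response score td_s summarizes them as the
# magnitude-weighted mean direction; its quadrant gives the signs of the
# dose and time effects and its sector says which variable dominates.

#' Time-dose response score of a region
#'
#' Per-point gradient angles are taken from \code{(grad_dose, grad_time)}
#' with dose on the x axis, normalized to \code{(0, 360]}.  The default
#' estimator is the direction of the magnitude-weighted mean gradient
#' vector (a weighted circular mean, well defined at the 0/360 wrap); the
#' \code{"literal"} method is the plain magnitude-weighted arithmetic mean
#' of the angles, \code{sum(g_i * mod_i) / sum(mod_i)}, which agrees with
#' the default away from the wrap.  Zero-magnitude points are excluded.
#'
#' @param map an [effect_map()] with gradients.
#' @param ddra a [detect_ddra()] result (or any object with a \code{mask}).
#' @param method "vector" (default) or "literal".
#' @param tol magnitudes below this count as zero.
#' @return An object of class \code{"td_summary"}: \code{td_s} (degrees in
#'   \code{(0, 360]}), \code{quadrant}, \code{sector}, \code{label},
#'   \code{angles}, \code{magnitudes}, \code{n}.
#' @export
time_dose_score <- function(map, ddra, method = c("vector", "literal"),
                            tol = 1e-12) {
  method <- match.arg(method)
  stopifnot(inherits(map, "effect_map"))
  mask <- ddra$mask
  stopifnot(any(mask))
  gd <- map$grad_dose[mask]
  gt <- map$grad_time[mask]
  mod <- sqrt(gd^2 + gt^2)
  keep <- mod > tol
  if (!any(keep)) stop("degenerate gradient field: all magnitudes zero")
  gd <- gd[keep]; gt <- gt[keep]; mod <- mod[keep]
  ang <- (atan2(gt, gd) * 180 / pi) %% 360
  ang[ang == 0] <- 360
  td <- if (method == "vector") {
    a <- (atan2(sum(gt), sum(gd)) * 180 / pi) %% 360
    if (a == 0) 360 else a
  } else {
    sum(ang * mod) / sum(mod)
  }
  cls <- classify_td(td)
  structure(list(td_s = td, quadrant = cls$quadrant, sector = cls$sector,
                 label = cls$label, angles = ang, magnitudes = mod,
                 n = sum(mask), method = method),
            class = "td_summary")
}

#' Quadrant, sector and d/t label of a time-dose response score
#'
#' Quadrants by the half-open intervals (0, 90], (90, 180], (180, 270],
#' (270, 360] give the signs of the dose and time effects (quadrant 1:
#' d+, t+; 2: d-, t+; 3: d-, t-; 4: d+, t-).  Within each quadrant three
#' 30-degree sectors grade dominance: within 30 degrees of the dose axis
#' the dose dominates (capital D), within 30 degrees of the time axis the
#' time dominates (capital T), in between the effects are comparable (both
#' capitals); sector boundaries fall in the "equal" band.  The 0/360 wrap
#' (a pure positive dose effect) resolves to quadrant 1.
#'
#' @param td_s angle in degrees, in \code{(0, 360]}.
#' @return list with \code{quadrant} (1-4), \code{sector} ("dose", "equal",
#'   "time") and \code{label} (e.g. \code{"d+T+"}).
#' @export
classify_td <- function(td_s) {
  stopifnot(is.finite(td_s), td_s > 0, td_s <= 360)
  a0 <- td_s %% 360
  if (a0 == 0) {
    # boundary between quadrants 4 and 1: pure positive dose effect
    quadrant <- 1L
  } else {
    quadrant <- as.integer(ceiling(a0 / 90))
  }
  a_dose <- min(a0 %% 180, 180 - a0 %% 180)   # angular distance to dose axis
  a_time <- 90 - a_dose                       # ... and to time axis
  sector <- if (a_dose < 30) "dose" else if (a_time < 30) "time" else "equal"
  signs <- switch(quadrant,
                  c(d = "+", t = "+"),
                  c(d = "-", t = "+"),
                  c(d = "-", t = "-"),
                  c(d = "+", t = "-"))
  letters_dt <- switch(sector,
                       dose = c("D", "t"),
                       time = c("d", "T"),
                       equal = c("D", "T"))
  label <- paste0(letters_dt[1L], signs[["d"]], letters_dt[2L], signs[["t"]])
  list(quadrant = quadrant, sector = sector, label = label)
}

#' @export
print.td_summary <- function(x, ...) {
  cat(sprintf(
    "Time-dose response score: %.1f deg (quadrant %d, %s-dominant) -> %s over %d points\n",
    x$td_s, x$quadrant,
    if (x$sector == "equal") "no" else x$sector, x$label, x$n))
  invisible(x)
}

#' Tabulate d/t labels per POD category
#'
#' The data behind the per-POD radar summaries: counts of the dose/time
#' influence labels within each joint POD label.
#'
#' @param results results data.frame of a [run_ddr()] object.
#' @return data.frame with columns \code{joint_label},
#'   \code{dose_time_comparison}, \code{n}.
#' @export
td_label_counts <- function(results) {
  if (nrow(results) == 0L) {
    return(data.frame(joint_label = character(),
                      dose_time_comparison = character(), n = integer()))
  }
  agg <- stats::aggregate(list(n = seq_len(nrow(results))),
                          by = list(joint_label = results$joint_label,
                                    dose_time_comparison =
                                      results$dose_time_comparison),
                          FUN = length)
  agg[order(agg$joint_label, agg$dose_time_comparison), ]
}
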