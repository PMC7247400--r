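# Detection of the dynamic dose-responsive area (DDRA): thresholding of the
# effect map, monotone segmentation of the gradient field, candidate scoring,
# region reduction, boundary tracing and front extraction.

# Activity cut on the |LFC| scale.  The default reads a threshold of 0.10 as
# "10% change with respect to controls" on the fold-change scale, i.e.
# |LFC| >= log2(1 + 0.10); scale = "lfc" applies the threshold to |LFC|
# directly.
activity_cut <- function(threshold, scale = c("fold_change", "lfc")) {
  scale <- match.arg(scale)
  stopifnot(threshold > 0)
  if (scale == "fold_change") log2(1 + threshold) else threshold
}

#' Super-threshold activity mask of an effect map
#'
#' A grid point is active when the predicted |LFC| reaches the activity
#' threshold (default 10 percent change relative to controls, i.e.
#' \code{|LFC| >= log2(1.1)}).
#'
#' @param map an [effect_map()].
#' @param threshold activity threshold as a fraction (default 0.10).
#' @param scale "fold_change" (default) or "lfc"; see Details in the package
#'   vignette.
#' @return logical matrix (rows time, columns dose).
#' @export
active_mask <- function(map, threshold = 0.10,
                        scale = c("fold_change", "lfc")) {
  stopifnot(inherits(map, "effect_map"))
  abs(map$lfc) >= activity_cut(threshold, scale)
}

# 8-connected component labelling of a logical mask.  Returns an integer
# matrix (0 = background).  Depth-first flood fill with an explicit stack.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  stack <- integer(nr * nc)
  for (s in which(mask)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    stack[1L] <- s
    top <- 1L
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (dc in -1L:1L) {
        c2 <- cc + dc
        if (c2 < 1L || c2 > nc) next
        base <- (c2 - 1L) * nr
        for (dr in -1L:1L) {
          r2 <- r + dr
          if (r2 < 1L || r2 > nr) next
          q <- base + r2
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            top <- top + 1L
            stack[top] <- q
          }
        }
      }
    }
  }
  lab
}

#' Segment the active area into dose-monotone components
#'
#' Active grid points are split by the sign of the dose gradient (LFC
#' increasing vs decreasing with dose); 8-connected components are computed
#' within each sign class.  Points with |grad_dose| below \code{grad_tol}
#' count as non-monotone and belong to no component.
#'
#' @param map an [effect_map()] with gradients filled.
#' @param mask logical activity mask (from [active_mask()]).
#' @param grad_tol tolerance below which the dose gradient counts as zero.
#' @return list of components, each a list with \code{mask} (logical
#'   matrix), \code{sign} (+1 increasing, -1 decreasing) and
#'   \code{direction} ("increasing"/"decreasing").
#' @export
segment_monotone <- function(map, mask, grad_tol = 1e-9) {
  stopifnot(inherits(map, "effect_map"))
  out <- list()
  for (s in c(1, -1)) {
    m <- mask & (s * map$grad_dose > grad_tol)
    if (!any(m)) next
    lab <- label_components(m)
    for (k in seq_len(max(lab))) {
      out[[length(out) + 1L]] <- list(
        mask = lab == k, sign = s,
        direction = if (s > 0) "increasing" else "decreasing")
    }
  }
  out
}

# Region weight r = n_p + n_tp-md - m_d: points in the region, plus the
# number of grid rows (time points) of the region that reach the highest
# dose column, minus the region's minimum-dose grid column index (1-based).
region_score <- function(mask) {
  nc <- ncol(mask)
  cols <- col(mask)[mask]
  n_p <- length(cols)
  n_tp_md <- sum(mask[, nc])
  m_d <- min(cols)
  list(n_p = n_p, n_tp_md = n_tp_md, m_d = m_d,
       r = n_p + n_tp_md - m_d)
}

#' Select the candidate dose-responsive region
#'
#' Components that do not reach the highest-dose column are discarded (a
#' gene whose responsive area misses the highest tested dose is not
#' responding); among the rest the component maximizing
#' \code{r = n_p + n_tp_md - m_d} wins, ties broken by larger \code{n_p},
#' then lower \code{m_d}.
#'
#' @param components list from [segment_monotone()].
#' @return the winning component with its \code{score} attached, or
#'   \code{NULL} when no component touches the highest dose.
#' @export
select_candidate <- function(components) {
  if (length(components) == 0L) return(NULL)
  keep <- Filter(function(cm) any(cm$mask[, ncol(cm$mask)]), components)
  if (length(keep) == 0L) return(NULL)
  scores <- lapply(keep, function(cm) region_score(cm$mask))
  r <- vapply(scores, `[[`, numeric(1L), "r")
  np <- vapply(scores, `[[`, numeric(1L), "n_p")
  md <- vapply(scores, `[[`, numeric(1L), "m_d")
  ord <- order(-r, -np, md)
  best <- ord[1L]
  out <- keep[[best]]
  out$score <- scores[[best]]
  out
}

#' Reduce the candidate region by auditing rows with opposite behaviour
#'
#' Grid rows (time points) that are still active outside the candidate
#' region but with a dose-gradient sign opposite to the candidate's
#' direction are removed from the candidate mask.  The surviving mask must
#' remain one connected component that still reaches the highest-dose
#' column; otherwise the gene is dropped (\code{NULL}).
#'
#' @param map an [effect_map()].
#' @param candidate component from [select_candidate()].
#' @param active logical activity mask of the full map.
#' @param grad_tol zero-gradient tolerance, as in [segment_monotone()].
#' @return the reduced component (score recomputed), or \code{NULL}.
#' @export
reduce_region <- function(map, candidate, active, grad_tol = 1e-9) {
  stopifnot(!is.null(candidate))
  opp <- active & !candidate$mask &
    (-candidate$sign * map$grad_dose > grad_tol)
  bad_rows <- which(rowSums(opp) > 0L)
  m <- candidate$mask
  if (length(bad_rows) > 0L) m[bad_rows, ] <- FALSE
  if (!any(m)) return(NULL)
  lab <- label_components(m)
  comps <- lapply(seq_len(max(lab)), function(k) {
    list(mask = lab == k, sign = candidate$sign,
         direction = candidate$direction)
  })
  select_candidate(comps)
}

#' Trace the external border of a mask
#'
#' Moore-neighbour boundary tracing (8-connectivity, Jacob's stopping
#' criterion).  Every border point is a mask point with at least one
#' non-mask or grid-edge neighbour; the trace is the ordered closed outer
#' boundary (inner hole boundaries are not traced).
#'
#' @param mask logical matrix, one connected component.
#' @return two-column matrix (row, col) of ordered border grid points; a
#'   point may repeat where the region is one cell wide.
#' @export
trace_border <- function(mask) {
  stopifnot(any(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc
  filled <- function(r, c) inside(r, c) && mask[r, c]
  # clockwise Moore neighbourhood, starting north
  offs <- cbind(r = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
                c = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))
  s <- which(mask)[1L]                  # min column, then min row
  sr <- ((s - 1L) %% nr) + 1L
  sc <- ((s - 1L) %/% nr) + 1L
  if (sum(mask) == 1L) return(cbind(row = sr, col = sc))
  # entered the start pixel from the north during the column-major scan
  path <- matrix(NA_integer_, 4L * sum(mask) + 8L, 2L)
  path[1L, ] <- c(sr, sc)
  npts <- 1L
  prev_dir <- 1L   # neighbour index of the backtrack pixel (north)
  r <- sr; c <- sc
  first_move <- NA_integer_
  repeat {
    found <- FALSE
    for (k in seq_len(8L)) {
      j <- ((prev_dir - 1L + k - 1L) %% 8L) + 1L
      rr <- r + offs[j, 1L]; cc <- c + offs[j, 2L]
      if (filled(rr, cc)) {
        # Jacob's criterion: back at start, about to repeat the first move
        if (r == sr && c == sc && npts > 1L && j == first_move) {
          return(unique_rows_keep_order(path[seq_len(npts), , drop = FALSE]))
        }
        if (r == sr && c == sc && is.na(first_move)) first_move <- j
        npts <- npts + 1L
        if (npts > nrow(path)) path <- rbind(path, path)
        path[npts, ] <- c(rr, cc)
        # backtrack = pixel checked just before the hit, relative to new pixel
        bj <- ((j - 1L + 8L - 1L) %% 8L) + 1L   # previous (background) cell
        br <- r + offs[bj, 1L]; bc <- c + offs[bj, 2L]
        r <- rr; c <- cc
        # direction from new pixel towards the backtrack cell
        prev_dir <- which(offs[, 1L] == br - r & offs[, 2L] == bc - c)
        found <- TRUE
        break
      }
    }
    if (!found) {
      return(cbind(row = sr, col = sc))  # isolated pixel
    }
    if (npts > 8L * sum(mask) + 8L) {
      stop("boundary tracing failed to terminate")
    }
  }
}

# Interior points of a mask: all 8 neighbours exist (not on the grid edge)
# and are themselves mask points.  Border = mask & !erode_all(mask).
erode_all <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  if (nr > 2L && nc > 2L) {
    inner <- matrix(TRUE, nr - 2L, nc - 2L)
    for (dr in -1:1) for (dc in -1:1) {
      inner <- inner & mask[2:(nr - 1L) + dr, 2:(nc - 1L) + dc]
    }
    out[2:(nr - 1L), 2:(nc - 1L)] <- inner
  }
  out
}

unique_rows_keep_order <- function(m) {
  colnames(m) <- c("row", "col")
  m[!duplicated(m), , drop = FALSE]
}

#' Dose-responsive and IC50 fronts of a region
#'
#' Per grid row (time point) inside the region: the dose-responsive front is
#' the smallest dose column of the mask; the IC50 front is the smallest dose
#' in that row's mask where |LFC| reaches 50 percent of the row's maximal
#' |LFC| within the mask.
#'
#' @param map an [effect_map()].
#' @param mask logical region mask.
#' @return data.frame with one row per active time row: \code{row},
#'   \code{time}, \code{dr_col}, \code{dr_dose}, \code{ic50_col},
#'   \code{ic50_dose} (doses in original units).
#' @export
fronts <- function(map, mask) {
  rows <- which(rowSums(mask) > 0L)
  out <- lapply(rows, function(r) {
    cols <- which(mask[r, ])
    a <- abs(map$lfc[r, cols])
    half <- 0.5 * max(a)
    ic <- cols[which(a >= half)[1L]]
    data.frame(row = r, time = map$time[r],
               dr_col = min(cols), dr_dose = map$dose[min(cols)],
               ic50_col = ic, ic50_dose = map$dose[ic])
  })
  do.call(rbind, out)
}

#' Detect the dynamic dose-responsive area of one gene
#'
#' Runs the full region pipeline on an effect map: activity thresholding,
#' monotone segmentation, candidate selection by the region weight, row
#' reduction, boundary tracing and front extraction.
#'
#' @param map an [effect_map()] with gradients.
#' @param threshold activity threshold as a fraction (default 0.10).
#' @param threshold_scale "fold_change" (default) or "lfc".
#' @param grad_tol zero-gradient tolerance.
#' @return An object of class \code{"ddra"} (mask, direction, score, border,
#'   fronts), or an empty drop marker with attribute \code{"reason"} (one of
#'   \code{"below_threshold"}, \code{"non_monotone"},
#'   \code{"highest_dose_not_covered"}) when the gene is not responding;
#'   test with [is_dropped()].
#' @export
detect_ddra <- function(map, threshold = 0.10,
                        threshold_scale = c("fold_change", "lfc"),
                        grad_tol = 1e-9) {
  threshold_scale <- match.arg(threshold_scale)
  act <- active_mask(map, threshold, threshold_scale)
  if (!any(act)) return(NULL_drop("below_threshold"))
  comps <- segment_monotone(map, act, grad_tol)
  if (length(comps) == 0L) return(NULL_drop("non_monotone"))
  cand <- select_candidate(comps)
  if (is.null(cand)) return(NULL_drop("highest_dose_not_covered"))
  red <- reduce_region(map, cand, act, grad_tol)
  if (is.null(red)) return(NULL_drop("highest_dose_not_covered"))
  border <- trace_border(red$mask)
  fr <- fronts(map, red$mask)
  structure(list(
    gene_id = map$gene_id,
    mask = red$mask,
    direction = red$direction,
    sign = red$sign,
    score = red$score,
    border = border,
    dr_front = fr[, c("row", "time", "dr_col", "dr_dose")],
    ic50_front = fr[, c("row", "time", "ic50_col", "ic50_dose")],
    threshold = threshold,
    cut = activity_cut(threshold, threshold_scale),
    mean_fc = mean(map$lfc[red$mask])
  ), class = "ddra")
}

NULL_drop <- function(reason) {
  out <- list()
  attr(out, "reason") <- reason
  attr(out, "dropped") <- TRUE
  out
}

#' Was a gene dropped by the detection stage?
#' @param x a [detect_ddra()] return value.
#' @return logical; the drop reason is in \code{attr(x, "reason")}.
#' @export
is_dropped <- function(x) isTRUE(attr(x, "dropped"))

#' @export
print.ddra <- function(x, ...) {
  cat("DDRA for gene", x$gene_id, "-", x$direction, "with dose;",
      x$score$n_p, "grid points, weight r =", x$score$r, "\n")
  cat("  mean LFC in region:", round(x$mean_fc, 3),
      "| activity cut |LFC| >=", round(x$cut, 4), "\n")
  invisible(x)
}
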