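# Joint dose-time point-of-departure labelling: the dose-time map is
# partitioned into a 3 x 3 grid; dose thirds are named Sensitive /
# Intermediate / Resilient (ascending dose) and time thirds Early / Middle /
# Late (ascending time).

.dose_classes <- c("Sensitive", "Intermediate", "Resilient")
.time_classes <- c("Early", "Middle", "Late")

# Bin index (1..3) of each grid index for a given resolution: equal thirds
# with cutpoints round(res/3) and round(2*res/3) (1-17 / 18-33 / 34-50 at
# resolution 50).
pod_bin <- function(idx, res) {
  c1 <- round(res / 3)
  c2 <- round(2 * res / 3)
  1L + (idx > c1) + (idx > c2)
}

pod_label <- function(dose_bin, time_bin) {
  paste(.dose_classes[dose_bin], .time_classes[time_bin], sep = "-")
}

#' Per-cell statistics of the 3 x 3 POD partition
#'
#' @param ddra a [detect_ddra()] result (needs \code{mask} and
#'   \code{border}).
#' @return list with 3 x 3 matrices \code{coverage} (fraction of each cell
#'   covered by the DDRA; rows = dose class, columns = time class),
#'   \code{border_count} (unique border points per cell) and
#'   \code{cell_size} (grid points per cell).
#' @export
pod_grid <- function(ddra) {
  mask <- ddra$mask
  res_t <- nrow(mask); res_d <- ncol(mask)
  dbin_col <- pod_bin(seq_len(res_d), res_d)
  tbin_row <- pod_bin(seq_len(res_t), res_t)
  cell_size <- outer(tabulate(dbin_col, 3L), tabulate(tbin_row, 3L))
  cover <- matrix(0, 3L, 3L)
  for (db in 1:3) for (tb in 1:3) {
    cover[db, tb] <- sum(mask[tbin_row == tb, dbin_col == db])
  }
  border <- unique_rows_keep_order(ddra$border)
  bcount <- matrix(0L, 3L, 3L)
  bd <- pod_bin(border[, "col"], res_d)
  bt <- pod_bin(border[, "row"], res_t)
  for (i in seq_len(nrow(border))) {
    bcount[bd[i], bt[i]] <- bcount[bd[i], bt[i]] + 1L
  }
  dimnames(cover) <- dimnames(bcount) <- dimnames(cell_size) <-
    list(.dose_classes, .time_classes)
  list(coverage = cover / cell_size, border_count = bcount,
       cell_size = cell_size)
}

# Most-left label straight from a mask (also used for simulation truth).
mask_most_left_label <- function(mask) {
  res_d <- ncol(mask); res_t <- nrow(mask)
  cols <- col(mask)[mask]
  min_col <- min(cols)
  db <- pod_bin(min_col, res_d)
  dose_band <- pod_bin(seq_len(res_d), res_d) == db
  rows_in_band <- which(rowSums(mask[, dose_band, drop = FALSE]) > 0L)
  tb <- pod_bin(min(rows_in_band), res_t)
  pod_label(db, tb)
}

#' Most-left POD label
#'
#' The first available POD: the dose class of the region's lowest active
#' dose, then the earliest active time within that dose band.  This is the
#' default strategy, matching the toxicological convention that a compound
#' is active from the lowest dose and earliest time at which its effect
#' deviates from control.
#'
#' @param ddra a [detect_ddra()] result.
#' @return single label string, e.g. \code{"Sensitive-Early"}.
#' @export
label_most_left <- function(ddra) {
  mask_most_left_label(ddra$mask)
}

#' Presence POD labels
#'
#' All 3 x 3 cells that contain at least one point of the traced DDRA
#' border.
#'
#' @param ddra a [detect_ddra()] result.
#' @return character vector of labels, ordered by dose class then time
#'   class.
#' @export
label_presence <- function(ddra) {
  pg <- pod_grid(ddra)
  cells <- which(pg$border_count > 0L, arr.ind = TRUE)
  cells <- cells[order(cells[, 1L], cells[, 2L]), , drop = FALSE]
  pod_label(cells[, 1L], cells[, 2L])
}

#' Cumulative POD labels
#'
#' Cells ranked by their share of the DDRA border points; the smallest
#' prefix whose cumulative share reaches \code{X} percent is returned.  With
#' \code{X = 100} this equals the presence strategy.
#'
#' @param ddra a [detect_ddra()] result.
#' @param X percentage of the border to cover, in (0, 100].
#' @return character vector of labels (rank order of selection).
#' @export
label_cumulative <- function(ddra, X = 80) {
  stopifnot(X > 0, X <= 100)
  pg <- pod_grid(ddra)
  cnt <- pg$border_count
  cells <- which(cnt > 0L, arr.ind = TRUE)
  counts <- cnt[cells]
  # rank by share, ties towards more sensitive then earlier cells
  ord <- order(-counts, cells[, 1L], cells[, 2L])
  cum <- cumsum(counts[ord])
  total <- sum(counts)
  k <- which(cum * 100 >= X * total)[1L]
  sel <- cells[ord[seq_len(k)], , drop = FALSE]
  pod_label(sel[, 1L], sel[, 2L])
}

#' Mix POD label
#'
#' Scores every 3 x 3 cell by the equal-weight mean of three [0, 1]
#' components: proximity to the Sensitive-Early corner (1 minus the
#' normalized Chebyshev distance of the cell), the fraction of the cell's
#' area covered by the DDRA, and the cell's share of the DDRA border
#' points.  The highest-scoring cell wins; ties go to the more sensitive,
#' then earlier cell.
#'
#' @param ddra a [detect_ddra()] result.
#' @param weights numeric length-3 weights for (proximity, coverage,
#'   border share); default equal.
#' @return single label string.
#' @export
label_mix <- function(ddra, weights = c(1, 1, 1) / 3) {
  stopifnot(length(weights) == 3L, all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  pg <- pod_grid(ddra)
  total_border <- sum(pg$border_count)
  share <- if (total_border > 0) pg$border_count / total_border else
    matrix(0, 3L, 3L)
  prox <- 1 - outer(0:2, 0:2, pmax) / 2
  score <- weights[1L] * prox + weights[2L] * pg$coverage +
    weights[3L] * share
  # argmax with ties to lower dose bin, then lower time bin (column-major
  # which.min ordering is exactly dose-then-time)
  best <- which(score == max(score), arr.ind = TRUE)
  best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
  pod_label(best[1L, 1L], best[1L, 2L])
}

#' POD labels under a chosen strategy
#'
#' @param ddra a [detect_ddra()] result.
#' @param strategy one of "most_left" (default), "presence", "cumulative",
#'   "mix".
#' @param X cumulative border percentage for the cumulative strategy.
#' @param mix_weights weights for [label_mix()].
#' @return character vector of one or more labels.
#' @export
pod_labels <- function(ddra, strategy = c("most_left", "presence",
                                          "cumulative", "mix"),
                       X = 80, mix_weights = c(1, 1, 1) / 3) {
  switch(match.arg(strategy),
    most_left = label_most_left(ddra),
    presence = label_presence(ddra),
    cumulative = label_cumulative(ddra, X),
    mix = label_mix(ddra, mix_weights))
}
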