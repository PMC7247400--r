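#' Log fold-change matrix with dose-time column annotation
#'
#' The sole experimental input of the analysis: a genes x pair-samples matrix
#' of log2 fold-changes, where every column is one treated-vs-control pair
#' annotated with the dose and time of the treated sample.  Doses and times
#' are kept in their original units and additionally min-max normalized to
#' \code{[0, 1]} (dose optionally on the log10 scale first, the default,
#' since tested doses are typically log-spaced); all model fitting and
#' gridding happens on the normalized axes and results are mapped back.
#'
#' @param values numeric matrix, genes as rows (rownames = gene ids),
#'   pair-samples as columns.  All entries must be finite.
#' @param dose,time numeric vectors, one entry per column, in original units
#'   (e.g. mg/kg and hours).  Must be positive.
#' @param log10_dose logical; normalize dose on the log10 scale (default
#'   \code{TRUE}).
#'
#' @return An object of class \code{"lfc_matrix"}: a list with elements
#'   \code{values} (the matrix) and \code{design} (a data.frame with columns
#'   \code{column}, \code{dose}, \code{time}, \code{dose_norm},
#'   \code{time_norm}), plus normalization metadata.
#' @export
lfc_matrix <- function(values, dose, time, log10_dose = TRUE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyNA(rownames(values)) ||
      any(rownames(values) == "")) {
    stop("'values' must have complete, non-empty gene ids as rownames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop("duplicate gene id: ", dup)
  }
  if (!is.numeric(values)) stop("'values' must be numeric")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-finite log fold-change for gene '",
         rownames(values)[bad[1L, 1L]], "' (column ", bad[1L, 2L], ")")
  }
  if (length(dose) != ncol(values) || length(time) != ncol(values)) {
    stop("'dose' and 'time' must have one entry per column of 'values'")
  }
  if (!is.numeric(dose) || !is.numeric(time) || anyNA(dose) || anyNA(time)) {
    stop("doses and times must be numeric and complete")
  }
  if (any(dose <= 0)) stop("all doses must be > 0 (treated samples)")
  if (any(time <= 0)) stop("all times must be > 0")
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("pair%03d", seq_len(ncol(values)))
  }
  nrm <- normalize_axes(dose, time, log10_dose)
  design <- data.frame(
    column = colnames(values),
    dose = dose, time = time,
    dose_norm = nrm$dose_norm, time_norm = nrm$time_norm,
    stringsAsFactors = FALSE
  )
  structure(
    list(values = values, design = design, log10_dose = log10_dose,
         dose_range = nrm$dose_range, time_range = nrm$time_range),
    class = "lfc_matrix"
  )
}

# Min-max normalization of both axes to [0,1]; strictly monotone by
# construction, so ordering is preserved.  dose_range is stored on the
# (possibly log10) fitting scale for back-mapping.
normalize_axes <- function(dose, time, log10_dose) {
  d <- if (log10_dose) log10(dose) else dose
  dr <- range(d)
  tr <- range(time)
  dose_norm <- if (diff(dr) > 0) (d - dr[1L]) / diff(dr) else rep(0, length(d))
  time_norm <- if (diff(tr) > 0) (time - tr[1L]) / diff(tr) else rep(0, length(time))
  list(dose_norm = dose_norm, time_norm = time_norm,
       dose_range = dr, time_range = tr)
}

# Map normalized coordinates back to original units.
denormalize_dose <- function(x, dose_norm) {
  d <- x$dose_range[1L] + dose_norm * diff(x$dose_range)
  if (x$log10_dose) 10^d else d
}

denormalize_time <- function(x, time_norm) {
  x$time_range[1L] + time_norm * diff(x$time_range)
}

#' @export
print.lfc_matrix <- function(x, ...) {
  cat("Log fold-change matrix:", nrow(x$values), "genes x",
      ncol(x$values), "pair-samples\n")
  cat("  doses:", paste(sort(unique(x$design$dose)), collapse = ", "),
      if (x$log10_dose) "(log10-normalized)" else "(linearly normalized)", "\n")
  cat("  times:", paste(sort(unique(x$design$time)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.lfc_matrix <- function(x) dim(x$values)

#' Read a log fold-change table with dose-time annotation
#'
#' Reads a delimited text table (genes as rows, pair-samples as columns).
#' Column doses and times come either from a sidecar annotation file with
#' columns \code{column}, \code{dose}, \code{time} (keyed by column name) or,
#' when \code{annotation} is \code{NULL}, from headers that embed the design
#' point as \code{"dose=<d>,time=<t>[,rep=<k>]"}.
#'
#' @param path path to the LFC table (TSV/CSV; delimiter sniffed from the
#'   header line).
#' @param annotation path to the annotation table, or \code{NULL} to parse
#'   encoded column headers.
#' @param log10_dose passed to [lfc_matrix()].
#' @return An [lfc_matrix()] object; column order is preserved.
#' @export
read_lfc_table <- function(path, annotation = NULL, log10_dose = TRUE) {
  sep <- sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  if (ncol(tab) < 2L) stop("LFC table needs a gene id column plus data columns")
  ids <- tab[[1L]]
  if (anyNA(ids) || any(ids == "")) stop("missing gene id in LFC table")
  if (anyDuplicated(ids)) {
    stop("duplicate gene id: ", ids[duplicated(ids)][1L])
  }
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw),
                                  dimnames = list(ids, colnames(raw))))
  bad <- which(is.na(vals) & !toupper(trimws(raw)) %in% c("NA", "NAN"),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-numeric value '", raw[bad[1L, , drop = FALSE]], "' for gene '",
         ids[bad[1L, 1L]], "', column '", colnames(raw)[bad[1L, 2L]], "'")
  }
  nas <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    stop("missing value for gene '", ids[nas[1L, 1L]], "', column '",
         colnames(raw)[nas[1L, 2L]], "'")
  }
  if (is.null(annotation)) {
    ann <- parse_header_annotation(colnames(vals))
  } else {
    ann <- utils::read.table(annotation, header = TRUE, sep = sniff_sep(annotation),
                             stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("column", "dose", "time")
    if (!all(need %in% names(ann))) {
      stop("annotation must have columns: ", paste(need, collapse = ", "))
    }
    m <- match(colnames(vals), ann$column)
    if (anyNA(m)) {
      stop("column without dose/time annotation: ",
           colnames(vals)[is.na(m)][1L])
    }
    ann <- data.frame(dose = as.numeric(ann$dose[m]),
                      time = as.numeric(ann$time[m]))
    if (anyNA(ann$dose) || anyNA(ann$time)) {
      stop("non-numeric dose or time in annotation")
    }
  }
  lfc_matrix(vals, ann$dose, ann$time, log10_dose = log10_dose)
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
}

parse_header_annotation <- function(cn) {
  dose <- suppressWarnings(as.numeric(sub(".*dose=([0-9.eE+-]+).*", "\\1", cn)))
  time <- suppressWarnings(as.numeric(sub(".*time=([0-9.eE+-]+).*", "\\1", cn)))
  miss <- is.na(dose) | is.na(time) | !grepl("dose=", cn) | !grepl("time=", cn)
  if (any(miss)) {
    stop("column without dose/time annotation: ", cn[miss][1L])
  }
  data.frame(dose = dose, time = time)
}

#' Write a log fold-change matrix (and optional annotation) to disk
#'
#' The design point of each column is encoded in the header
#' (\code{dose=<d>,time=<t>,rep=<k>}) so the file round-trips through
#' [read_lfc_table()] without a sidecar; an annotation file can be written
#' as well.
#'
#' @param x an [lfc_matrix()] object.
#' @param path output path (tab-delimited).
#' @param annotation optional path for a sidecar annotation table.
#' @export
write_lfc_table <- function(x, path, annotation = NULL) {
  stopifnot(inherits(x, "lfc_matrix"))
  key <- paste0("dose=", format(x$design$dose, digits = 15, trim = TRUE),
                ",time=", format(x$design$time, digits = 15, trim = TRUE))
  rep_id <- stats::ave(seq_along(key), key, FUN = seq_along)
  header <- paste0(key, ",rep=", rep_id)
  out <- data.frame(gene_id = rownames(x$values),
                    format(x$values, digits = 15, trim = TRUE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("gene_id", header)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation)) {
    ann <- data.frame(column = header, dose = x$design$dose,
                      time = x$design$time)
    utils::write.table(ann, annotation, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write the per-gene results table
#'
#' One row per dynamic dose-responsive gene with the standard column roster:
#' gene id, dose-time comparison label, joint POD label, gene sign (direction
#' of the dose response), mean log fold-change inside the POD area, and the
#' adjusted p-value of the selected surface model.
#'
#' @param results data.frame as produced by [run_ddr()] (component
#'   \code{results}).
#' @param path output path (tab-delimited).
#' @export
write_results_table <- function(results, path) {
  cols <- c("gene_id", "dose_time_comparison", "joint_label", "gene_sign",
            "MeanFC", "adj.pval")
  if (is.null(results) || nrow(results) == 0L) {
    out <- as.data.frame(matrix(character(), 0, length(cols),
                                dimnames = list(NULL, cols)),
                         check.names = FALSE)
  } else {
    stopifnot(all(cols %in% names(results)))
    out <- results[, cols]
    out$MeanFC <- format(out$MeanFC, digits = 15, trim = TRUE)
    out$adj.pval <- format(out$adj.pval, digits = 15, trim = TRUE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path path to the table.
#' @return data.frame with the six result columns.
#' @export
read_results_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  tab$MeanFC <- as.numeric(tab$MeanFC)
  tab$adj.pval <- as.numeric(tab$adj.pval)
  tab
}
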