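#' Analysis configuration
#'
#' Collects all tunable parameters of the end-to-end analysis.
#'
#' @param activity_threshold activity threshold as a fraction of change
#'   relative to controls (default 0.10, i.e. 10 percent).
#' @param threshold_scale "fold_change" (default; cut at
#'   \code{log2(1 + threshold)} on |LFC|) or "lfc" (cut at the raw value).
#' @param alpha gate on the adjusted goodness-of-fit p-value (default 0.01).
#' @param resolution effect-map grid resolution (default 50, minimum 4).
#' @param log10_dose log10-transform dose before min-max normalization
#'   (default TRUE; tested doses are usually log-spaced).
#' @param strategy POD labelling strategy (default "most_left").
#' @param X cumulative border percentage for the cumulative strategy
#'   (default 80).
#' @param mix_weights weights of the mix strategy components.
#' @param td_method time-dose score estimator, "vector" or "literal".
#' @param selection order-selection p-values, "vs_constant" or
#'   "sequential".
#' @param grad_tol zero-gradient tolerance for monotonicity.
#' @return list of class \code{"ddr_config"}.
#' @export
ddr_config <- function(activity_threshold = 0.10,
                       threshold_scale = c("fold_change", "lfc"),
                       alpha = 0.01,
                       resolution = 50L,
                       log10_dose = TRUE,
                       strategy = c("most_left", "presence", "cumulative",
                                    "mix"),
                       X = 80,
                       mix_weights = c(1, 1, 1) / 3,
                       td_method = c("vector", "literal"),
                       selection = c("vs_constant", "sequential"),
                       grad_tol = 1e-9) {
  stopifnot(activity_threshold > 0, alpha > 0, alpha < 1, resolution >= 4)
  structure(list(
    activity_threshold = activity_threshold,
    threshold_scale = match.arg(threshold_scale),
    alpha = alpha,
    resolution = as.integer(resolution),
    log10_dose = log10_dose,
    strategy = match.arg(strategy),
    X = X,
    mix_weights = mix_weights,
    td_method = match.arg(td_method),
    selection = match.arg(selection),
    grad_tol = grad_tol
  ), class = "ddr_config")
}

#' Run the full dynamic dose-response analysis
#'
#' Orchestrates the end-to-end pipeline for every gene of an LFC matrix:
#' surface fitting with nested-model selection and the adjusted-p gate,
#' effect-map prediction with gradients, DDRA detection, POD labelling,
#' and the time-dose influence score.  Genes leaving the analysis are
#' recorded with the stage and reason.
#'
#' @param lfc an [lfc_matrix()] (its normalization must agree with
#'   \code{config$log10_dose}).
#' @param config a [ddr_config()].
#' @param keep_maps keep per-gene effect maps and DDRAs in the result
#'   (default TRUE; set FALSE for large runs to save memory).
#' @return An object of class \code{"ddr_result"}: \code{results} (one row
#'   per DDR gene: gene_id, dose_time_comparison, joint_label, gene_sign,
#'   MeanFC, adj.pval), \code{drops} (gene, stage, reason), \code{fits}
#'   (the [fit_dose_time()] object), \code{artifacts} (per-gene maps,
#'   regions and scores when \code{keep_maps}), and \code{config}.
#' @export
run_ddr <- function(lfc, config = ddr_config(), keep_maps = TRUE) {
  stopifnot(inherits(lfc, "lfc_matrix"), inherits(config, "ddr_config"))
  if (nrow(lfc$values) == 0L) stop("empty LFC matrix")
  fits <- fit_dose_time(lfc, alpha = config$alpha,
                        selection = config$selection)
  ids <- fits$table$gene_id
  responsive <- fits$table$order != "constant"
  drops <- list()
  for (g in ids[!responsive]) {
    drops[[g]] <- data.frame(gene_id = g, stage = "fitting",
                             reason = "gate_failed")
  }
  rows <- list()
  artifacts <- list()
  for (g in ids[responsive]) {
    fit <- fits$genes[[g]]
    map <- effect_map(fit, resolution = config$resolution)
    ddra <- detect_ddra(map, threshold = config$activity_threshold,
                        threshold_scale = config$threshold_scale,
                        grad_tol = config$grad_tol)
    if (is_dropped(ddra)) {
      drops[[g]] <- data.frame(gene_id = g, stage = "ddra_detection",
                               reason = attr(ddra, "reason"))
      next
    }
    td <- tryCatch(
      time_dose_score(map, ddra, method = config$td_method),
      error = function(e) NULL)
    if (is.null(td)) {
      drops[[g]] <- data.frame(gene_id = g, stage = "gradient_scoring",
                               reason = "degenerate_gradient")
      next
    }
    labels <- pod_labels(ddra, strategy = config$strategy, X = config$X,
                         mix_weights = config$mix_weights)
    rows[[g]] <- data.frame(
      gene_id = g,
      dose_time_comparison = td$label,
      joint_label = paste(labels, collapse = ";"),
      gene_sign = if (ddra$direction == "increasing") "+" else "-",
      MeanFC = ddra$mean_fc,
      `adj.pval` = fit$adj_pval,
      check.names = FALSE, stringsAsFactors = FALSE
    )
    if (keep_maps) {
      artifacts[[g]] <- list(map = map, ddra = ddra, td = td,
                             labels = labels)
    }
  }
  results <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(gene_id = character(), dose_time_comparison = character(),
               joint_label = character(), gene_sign = character(),
               MeanFC = numeric(), `adj.pval` = numeric(),
               check.names = FALSE)
  rownames(results) <- NULL
  drops <- if (length(drops) > 0L) do.call(rbind, drops) else
    data.frame(gene_id = character(), stage = character(),
               reason = character())
  rownames(drops) <- NULL
  structure(list(results = results, drops = drops, fits = fits,
                 artifacts = artifacts, config = config,
                 n_genes = length(ids)),
            class = "ddr_result")
}

#' @export
print.ddr_result <- function(x, ...) {
  cat("Dynamic dose-response analysis:", x$n_genes, "genes in,",
      nrow(x$results), "dynamic dose-responsive,", nrow(x$drops),
      "dropped\n")
  if (nrow(x$drops) > 0L) {
    tb <- table(x$drops$reason)
    cat("  drop reasons:",
        paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  if (nrow(x$results) > 0L) {
    tb <- sort(table(x$results$joint_label), decreasing = TRUE)
    cat("  POD labels:",
        paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.ddr_result <- function(object, ...) {
  list(
    n_genes = object$n_genes,
    n_ddrg = nrow(object$results),
    orders = table(object$fits$table$order),
    drop_reasons = table(object$drops$reason),
    pod_labels = table(object$results$joint_label),
    dt_labels = table(object$results$dose_time_comparison)
  )
}

#' Plot the dose-time effect map of a gene
#'
#' Filled contour map of the predicted log fold-change (dose on x, time on
#' y, both in original units on the normalized spacing), with labelled
#' contour levels, DDRA shading, the traced region border (yellow), the
#' IC50 front (red) and the 3 x 3 POD partition (dashed).
#'
#' @param x a [run_ddr()] result.
#' @param gene gene id to plot (must be a reported DDR gene when overlays
#'   are requested, otherwise the bare map is drawn from its fit).
#' @param file optional path; when given, a PNG is written there.
#' @param ... passed to [graphics::contour()].
#' @return invisibly, the file path (or NULL when drawing to the active
#'   device).
#' @export
plot.ddr_result <- function(x, gene, file = NULL, ...) {
  stopifnot(!missing(gene))
  art <- x$artifacts[[gene]]
  if (is.null(art)) {
    fit <- x$fits$genes[[gene]]
    if (is.null(fit)) stop("unknown gene: ", gene)
    map <- effect_map(fit, resolution = x$config$resolution)
    art <- list(map = map, ddra = NULL)
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 620)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  draw_gene_map(art$map, art$ddra, ...)
  invisible(file)
}

#' @rdname plot.ddr_result
#' @param result a [run_ddr()] result (alias interface used by the CLI).
#' @export
plot_gene_map <- function(result, gene, file = NULL, ...) {
  plot.ddr_result(result, gene = gene, file = file, ...)
}

draw_gene_map <- function(map, ddra = NULL, ...) {
  res <- map$resolution
  xs <- map$dose_norm
  ys <- map$time_norm
  pal <- grDevices::hcl.colors(64, "Blue-Red 2")
  graphics::image(xs, ys, t(map$lfc), col = pal, useRaster = TRUE,
                  xlab = "dose", ylab = "time", axes = FALSE,
                  main = paste("Time-dose effect map:", map$gene_id))
  at <- seq(0, 1, length.out = min(length(unique(map$dose)), 6L))
  graphics::axis(1, at = at,
                 labels = signif(denormalize_dose(map$norm, at), 3))
  graphics::axis(2, at = at,
                 labels = signif(denormalize_time(map$norm, at), 3))
  graphics::box()
  graphics::contour(xs, ys, t(map$lfc), add = TRUE, labcex = 0.8, ...)
  # 3 x 3 POD partition
  c1 <- round(res / 3); c2 <- round(2 * res / 3)
  graphics::abline(v = xs[c(c1, c2)], h = ys[c(c1, c2)], lty = 2,
                   col = "grey40")
  if (!is.null(ddra) && !is_dropped(ddra)) {
    shade <- t(ifelse(ddra$mask, 1, NA))
    graphics::image(xs, ys, shade, col = grDevices::adjustcolor(
      if (ddra$direction == "increasing") "darkgreen" else "firebrick",
      alpha.f = 0.25), add = TRUE, useRaster = TRUE)
    graphics::points(xs[ddra$border[, "col"]], ys[ddra$border[, "row"]],
                     col = "yellow", pch = 16, cex = 0.5)
    graphics::lines(xs[ddra$ic50_front$ic50_col],
                    ys[ddra$ic50_front$row], col = "red", lwd = 2)
  }
}

#' Sweep the activity threshold and count DDR genes
#'
#' Reruns the detection stages (the fits are reused) over a vector of
#' activity thresholds and reports the number of dynamic dose-responsive
#' genes at each; with increasing threshold the count is non-increasing on
#' genes whose mask shrinks below detectability.
#'
#' @param lfc an [lfc_matrix()].
#' @param thresholds numeric vector of activity thresholds (fractions).
#' @param config base configuration (its \code{activity_threshold} is
#'   overridden).
#' @return data.frame with columns \code{threshold}, \code{n_ddrg}.
#' @export
threshold_sweep <- function(lfc, thresholds = c(0.10, 0.20, 0.30, 0.40, 0.50),
                            config = ddr_config()) {
  fits <- fit_dose_time(lfc, alpha = config$alpha,
                        selection = config$selection)
  responsive <- fits$table$gene_id[fits$table$order != "constant"]
  maps <- lapply(responsive, function(g) {
    effect_map(fits$genes[[g]], resolution = config$resolution)
  })
  counts <- vapply(thresholds, function(th) {
    sum(vapply(maps, function(map) {
      d <- detect_ddra(map, threshold = th,
                       threshold_scale = config$threshold_scale,
                       grad_tol = config$grad_tol)
      !is_dropped(d)
    }, logical(1L)))
  }, numeric(1L))
  data.frame(threshold = thresholds, n_ddrg = as.integer(counts))
}
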