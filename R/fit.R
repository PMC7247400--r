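#' Polynomial dose-time design matrix
#'
#' Builds the model matrix of the first-, second- or third-order polynomial
#' surface over normalized dose and time.  Term order (and hence coefficient
#' order) is: order 1 \code{[1, D, T]}; order 2 adds \code{D^2, T^2, D*T}
#' listed as \code{[1, D^2, T^2, D*T, D, T]}; order 3 is
#' \code{[1, D^3, D^2*T, D*T^2, T^3, D^2, T^2, D*T, D, T]} (10 columns).
#'
#' @param dose_norm,time_norm numeric vectors of normalized covariates (or a
#'   data.frame with those columns as first argument).
#' @param order 1, 2 or 3 (or "constant" for the intercept-only column).
#' @return numeric model matrix, one row per observation.
#' @export
build_design <- function(dose_norm, time_norm = NULL, order = 1L) {
  if (is.data.frame(dose_norm)) {
    df <- dose_norm
    stopifnot(all(c("dose_norm", "time_norm") %in% names(df)))
    time_norm <- df$time_norm
    dose_norm <- df$dose_norm
  }
  stopifnot(length(dose_norm) == length(time_norm))
  key <- .order_key(order)
  n <- length(dose_norm)
  # a single point is plain basis evaluation; fitting preconditions apply
  # only to multi-observation designs
  if (key != "constant" && n > 1L) {
    if (length(unique(dose_norm)) < 2L || length(unique(time_norm)) < 2L) {
      stop("need >= 2 distinct doses and >= 2 distinct times to fit order ",
           order)
    }
  }
  X <- poly_basis(dose_norm, time_norm, order)
  if (n > 1L && nrow(X) < ncol(X) + 1L && key != "constant") {
    stop("fewer observations (", nrow(X), ") than required for ", ncol(X),
         " model terms")
  }
  X
}

# Least-squares fit of one order for a genes x observations value matrix.
# Uses pivoting, so aliased columns (e.g. Dose^3 with only 3 dose levels)
# get NA coefficients and the residual df reflects the achieved rank.
ls_fit_order <- function(values, design_df, order) {
  X <- build_design(design_df, order = order)
  Y <- t(values)                       # observations x genes
  fit <- stats::lm.fit(X, Y)
  beta <- fit$coefficients
  if (is.null(dim(beta))) beta <- matrix(beta, ncol = 1L,
                                         dimnames = list(names(beta), NULL))
  res <- fit$residuals
  if (is.null(dim(res))) res <- matrix(res, ncol = 1L)
  rank <- fit$rank
  if (rank < 1L || (.order_key(order) == "order1" && rank < 3L)) {
    aliased <- colnames(X)[is.na(beta[, 1L])]
    stop("rank-deficient design for order ", order, "; collinear terms: ",
         paste(aliased, collapse = ", "))
  }
  df <- nrow(X) - rank
  if (df <= 0L) stop("saturated model: no residual degrees of freedom")
  list(order = order, beta = beta, rss = colSums(res^2), df_resid = df,
       rank = rank, aliased = colnames(X)[is.na(beta[, 1L])],
       n = nrow(X))
}

#' Fit all nested model orders to one or more genes
#'
#' Least-squares fits of the constant, first-, second- and third-order
#' polynomial surfaces.  RSS is non-increasing with order (nested models).
#'
#' @param values numeric matrix (genes x pair-samples) or vector (one gene).
#' @param design data.frame with columns \code{dose_norm}, \code{time_norm}
#'   (e.g. the \code{design} element of an [lfc_matrix()]).
#' @return named list of per-order fits (\code{constant}, \code{order1},
#'   \code{order2}, \code{order3}); each carries coefficients (genes in
#'   columns; aliased terms \code{NA}), per-gene RSS, residual df and rank.
#' @export
fit_all_orders <- function(values, design) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  stopifnot(ncol(values) == nrow(design))
  orders <- list(constant = "constant", order1 = 1L, order2 = 2L,
                 order3 = 3L)
  lapply(orders, function(o) ls_fit_order(values, design, o))
}

# F statistic and p-value for a restricted-vs-full model comparison.
# Returns the p-value on the log scale as well so that astronomically small
# values still rank; the reported p is floored at 1e-300.
nested_f <- function(rss_r, df_r, rss_f, df_f) {
  if (any(df_f <= 0)) stop("full model is saturated (df <= 0)")
  num <- pmax(rss_r - rss_f, 0) / (df_r - df_f)
  den <- rss_f / df_f
  f <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  logp <- stats::pf(f, df_r - df_f, df_f, lower.tail = FALSE, log.p = TRUE)
  logp[f == 0] <- 0
  list(f = f, p = pmax(exp(logp), 1e-300), logp = logp,
       df1 = df_r - df_f, df2 = df_f)
}

#' Nested-model ANOVA over the fitted order sequence
#'
#' For each adjacent (restricted, full) pair along constant -> order 1 ->
#' order 2 -> order 3, computes
#' \code{F = ((RSS_r - RSS_f) / (df_r - df_f)) / (RSS_f / df_f)} and its
#' p-value from the F distribution.  Also returns each order's test against
#' the constant model, which is what the responsiveness gate uses.
#'
#' @param fits result of [fit_all_orders()].
#' @return list with data-frame-like elements \code{steps} (adjacent pairs)
#'   and \code{vs_constant} (each order against the constant model); each
#'   holds per-gene matrices \code{f}, \code{p} and \code{logp} with one row
#'   per comparison.
#' @export
nested_anova <- function(fits) {
  stopifnot(all(c("constant", "order1", "order2", "order3") %in% names(fits)))
  seq_names <- c("constant", "order1", "order2", "order3")
  steps <- list()
  for (k in 2:4) {
    r <- fits[[seq_names[k - 1L]]]
    f <- fits[[seq_names[k]]]
    steps[[paste(seq_names[k - 1L], "->", seq_names[k])]] <-
      nested_f(r$rss, r$df_resid, f$rss, f$df_resid)
  }
  vs_const <- list()
  for (k in 2:4) {
    r <- fits$constant
    f <- fits[[seq_names[k]]]
    vs_const[[seq_names[k]]] <- nested_f(r$rss, r$df_resid, f$rss, f$df_resid)
  }
  list(steps = steps, vs_constant = vs_const)
}

#' Benjamini-Hochberg adjustment of goodness-of-fit p-values
#'
#' @param pvalues numeric vector in \code{[0, 1]}.
#' @return step-up adjusted p-values (monotone, >= raw, <= 1).
#' @export
adjust_pvalues <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Select the optimal dose-time model per gene
#'
#' Each polynomial order is tested against the implicit constant model; a
#' gene with no significant improvement over the constant model is flagged
#' non-responsive, otherwise the order with the lowest test p-value is
#' returned (comparison on the log scale; ties go to the lower order).  With
#' \code{selection = "sequential"} the adjacent-step p-values are used
#' instead.
#'
#' @param anova result of [nested_anova()].
#' @param selection "vs_constant" (default) or "sequential".
#' @return list with per-gene vectors \code{order} (1, 2, 3), \code{pvalue}
#'   (the selected test's p, floored at 1e-300) and \code{logp}.
#'   Responsiveness is decided later, after adjustment across genes.
#' @export
select_model <- function(anova, selection = c("vs_constant", "sequential")) {
  selection <- match.arg(selection)
  tests <- if (selection == "vs_constant") anova$vs_constant else anova$steps
  logp <- do.call(rbind, lapply(tests, `[[`, "logp"))   # 3 x genes
  p <- do.call(rbind, lapply(tests, `[[`, "p"))
  ord <- apply(logp, 2L, which.min)
  idx <- cbind(ord, seq_len(ncol(logp)))
  list(order = as.integer(ord), pvalue = p[idx], logp = logp[idx],
       p_all = p)
}

#' Fit dose-time response surfaces to every gene
#'
#' The central fitting function: for each gene, fits the constant and the
#' three polynomial surface models on the normalized dose-time covariates,
#' runs the nested-model F-tests, selects the optimal order, and adjusts the
#' selected p-values across genes (Benjamini-Hochberg).  Genes whose
#' adjusted p-value fails the gate \code{alpha} are flagged non-responsive
#' (order \code{"constant"}).
#'
#' @param lfc an [lfc_matrix()].
#' @param alpha gate on the adjusted goodness-of-fit p-value (default 0.01).
#' @param selection p-value set used for order selection; see
#'   [select_model()].
#' @return An object of class \code{"dt_fits"}: list with \code{genes}
#'   (named list of per-gene \code{gene_fit} objects), \code{table}
#'   (per-gene summary data.frame), \code{alpha}, and the normalization
#'   metadata needed to map grids back to original units.
#' @export
fit_dose_time <- function(lfc, alpha = 0.01,
                          selection = c("vs_constant", "sequential")) {
  stopifnot(inherits(lfc, "lfc_matrix"), alpha > 0, alpha < 1)
  selection <- match.arg(selection)
  fits <- fit_all_orders(lfc$values, lfc$design)
  an <- nested_anova(fits)
  sel <- select_model(an, selection)
  adj <- adjust_pvalues(sel$pvalue)
  ids <- rownames(lfc$values)
  norm <- list(dose_range = lfc$dose_range, time_range = lfc$time_range,
               log10_dose = lfc$log10_dose)
  responsive <- adj < alpha
  genes <- vector("list", length(ids))
  names(genes) <- ids
  for (g in seq_along(ids)) {
    key <- if (responsive[g]) paste0("order", sel$order[g]) else "constant"
    of <- fits[[key]]
    genes[[g]] <- structure(list(
      gene_id = ids[g],
      order = if (responsive[g]) sel$order[g] else "constant",
      beta = of$beta[, g],
      rss = of$rss[[g]],
      df_resid = of$df_resid,
      pvalue = sel$pvalue[g],
      adj_pval = adj[g],
      p_by_order = sel$p_all[, g],
      norm = norm
    ), class = "gene_fit")
  }
  table <- data.frame(
    gene_id = ids,
    order = ifelse(responsive, as.character(sel$order), "constant"),
    pvalue = sel$pvalue,
    adj_pval = adj,
    stringsAsFactors = FALSE
  )
  structure(list(genes = genes, table = table, alpha = alpha,
                 selection = selection, norm = norm,
                 n_obs = ncol(lfc$values)),
            class = "dt_fits")
}

#' @export
print.dt_fits <- function(x, ...) {
  tab <- table(factor(x$table$order, levels = c("constant", "1", "2", "3")))
  cat("Dose-time surface fits:", nrow(x$table), "genes,",
      sum(x$table$order != "constant"), "responsive at adjusted p <",
      x$alpha, "\n")
  cat("  selected orders: constant", tab[["constant"]], "| linear",
      tab[["1"]], "| poly2", tab[["2"]], "| poly3", tab[["3"]], "\n")
  invisible(x)
}

#' @export
summary.dt_fits <- function(object, ...) {
  out <- object$table
  out$responsive <- out$order != "constant"
  class(out) <- c("summary.dt_fits", "data.frame")
  out
}

#' @export
print.summary.dt_fits <- function(x, ...) {
  print.data.frame(utils::head(x, 20L))
  if (nrow(x) > 20L) cat("... (", nrow(x) - 20L, " more genes)\n", sep = "")
  invisible(x)
}

#' @export
coef.gene_fit <- function(object, ...) object$beta

#' @export
coef.dt_fits <- function(object, ...) {
  lapply(object$genes, coef)
}

#' Predict LFC from a fitted gene surface
#'
#' @param object a \code{gene_fit} (element of a [fit_dose_time()] result).
#' @param dose,time coordinates at which to predict.
#' @param units "original" (default; dose/time in experiment units, mapped
#'   through the stored normalization) or "normalized" (already in
#'   \code{[0, 1]}).
#' @param ... unused.
#' @return numeric vector of predicted log2 fold-changes.
#' @export
predict.gene_fit <- function(object, dose, time,
                             units = c("original", "normalized"), ...) {
  units <- match.arg(units)
  if (units == "original") {
    nr <- object$norm
    d <- if (nr$log10_dose) log10(dose) else dose
    dn <- (d - nr$dose_range[1L]) / diff(nr$dose_range)
    tn <- (time - nr$time_range[1L]) / diff(nr$time_range)
  } else {
    dn <- dose; tn <- time
  }
  poly_eval(object$beta, dn, tn, object$order)
}

#' @export
print.gene_fit <- function(x, ...) {
  cat("Gene", x$gene_id, "- selected model:",
      if (identical(x$order, "constant")) "constant (non-responsive)"
      else paste0("order ", x$order),
      sprintf("(p = %.3g, adjusted = %.3g)\n", x$pvalue, x$adj_pval))
  print(round(x$beta, 4L))
  invisible(x)
}
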