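# Polynomial term bookkeeping shared by the fitting and effect-map stages.
#
# Each model order is a fixed list of monomials Dose^i * Time^j.  The term
# order follows the conventional write-up of the three nested surfaces:
#   order 1: b0 + b1*D + b2*T
#   order 2: b0 + b1*D^2 + b2*T^2 + b3*D*T + b4*D + b5*T
#   order 3: b0 + b1*D^3 + b2*D^2*T + b3*D*T^2 + b4*T^3
#              + b5*D^2 + b6*T^2 + b7*D*T + b8*D + b9*T
# so coefficient vectors have length 3, 6 and 10 (1 for the constant model).

.poly_exponents <- list(
  constant = cbind(d = 0L, t = 0L),
  order1 = cbind(d = c(0L, 1L, 0L),
                 t = c(0L, 0L, 1L)),
  order2 = cbind(d = c(0L, 2L, 0L, 1L, 1L, 0L),
                 t = c(0L, 0L, 2L, 1L, 0L, 1L)),
  order3 = cbind(d = c(0L, 3L, 2L, 1L, 0L, 2L, 0L, 1L, 1L, 0L),
                 t = c(0L, 0L, 1L, 2L, 3L, 0L, 2L, 1L, 0L, 1L))
)

.poly_term_names <- list(
  constant = "(Intercept)",
  order1 = c("(Intercept)", "Dose", "Time"),
  order2 = c("(Intercept)", "Dose2", "Time2", "DoseTime", "Dose", "Time"),
  order3 = c("(Intercept)", "Dose3", "Dose2Time", "DoseTime2", "Time3",
             "Dose2", "Time2", "DoseTime", "Dose", "Time")
)

.order_key <- function(order) {
  if (identical(order, "constant") || identical(order, 0L) || identical(order, 0)) {
    return("constant")
  }
  if (!order %in% c(1, 2, 3)) {
    stop("polynomial order must be 'constant', 1, 2 or 3", call. = FALSE)
  }
  paste0("order", as.integer(order))
}

# Evaluate the monomial basis at (dose, time); rows = points, cols = terms.
poly_basis <- function(dose, time, order) {
  key <- .order_key(order)
  ex <- .poly_exponents[[key]]
  X <- matrix(NA_real_, length(dose), nrow(ex))
  for (k in seq_len(nrow(ex))) {
    X[, k] <- dose^ex[k, "d"] * time^ex[k, "t"]
  }
  colnames(X) <- .poly_term_names[[key]]
  X
}

# Evaluate a fitted polynomial; NA coefficients (aliased terms) contribute 0.
poly_eval <- function(beta, dose, time, order) {
  b <- beta
  b[is.na(b)] <- 0
  drop(poly_basis(dose, time, order) %*% b)
}

# Analytic partial derivatives of the polynomial surface.
poly_grad <- function(beta, dose, time, order) {
  key <- .order_key(order)
  ex <- .poly_exponents[[key]]
  b <- beta
  b[is.na(b)] <- 0
  gd <- numeric(length(dose))
  gt <- numeric(length(dose))
  for (k in seq_len(nrow(ex))) {
    i <- ex[k, "d"]; j <- ex[k, "t"]
    if (i > 0) gd <- gd + b[k] * i * dose^(i - 1L) * time^j
    if (j > 0) gt <- gt + b[k] * j * dose^i * time^(j - 1L)
  }
  list(grad_dose = gd, grad_time = gt)
}
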