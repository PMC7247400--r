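# Shared fixtures and independent oracles used across the test files.

# Normalization metadata of the default design (doses 30/100/300 mg/kg,
# times 3/6/9/24 h, log10 dose scaling).
default_norm <- function() {
  list(dose_range = log10(c(30, 300)), time_range = c(3, 24),
       log10_dose = TRUE)
}

# Manually constructed gene fit, for driving effect_map without data.
make_gene_fit <- function(beta, order, gene_id = "g", norm = default_norm()) {
  structure(list(gene_id = gene_id, order = order, beta = beta,
                 rss = NA_real_, df_resid = NA_integer_, pvalue = NA_real_,
                 adj_pval = NA_real_, norm = norm),
            class = "gene_fit")
}

# Minimal hand-built effect map (for gradient-scoring unit tests).
make_fake_map <- function(grad_dose, grad_time, lfc = NULL) {
  res <- nrow(grad_dose)
  if (is.null(lfc)) lfc <- matrix(0, res, res)
  structure(list(gene_id = "fake", order = 1L, beta = c(0, 0, 0),
                 dose_norm = seq(0, 1, length.out = res),
                 time_norm = seq(0, 1, length.out = res),
                 dose = seq(30, 300, length.out = res),
                 time = seq(3, 24, length.out = res),
                 lfc = lfc, grad_dose = grad_dose, grad_time = grad_time,
                 norm = default_norm(), resolution = res),
            class = "effect_map")
}

# Least-squares oracle via explicit normal equations (independent of the
# package's pivoted-QR path; only valid for full-rank designs).
ne_fit <- function(X, y) {
  b <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% b
  list(beta = drop(b), rss = sum((y - fitted)^2))
}

# Independent F-distribution tail via the incomplete-beta identity
# P(F > f) = pbeta(d2 / (d2 + d1 f), d2/2, d1/2).
f_tail_beta <- function(f, df1, df2) {
  pbeta(df2 / (df2 + df1 * f), df2 / 2, df1 / 2)
}

# Random full-rank continuous design (no dose-level aliasing).
random_design <- function(n = 40L) {
  data.frame(dose_norm = runif(n), time_norm = runif(n))
}

# Random axis-aligned blob components on a res x res grid for the
# region-weight selection tests: disjoint rectangles with random monotone
# direction signs.
random_components <- function(res = 50L, k = NULL) {
  if (is.null(k)) k <- sample(2:5, 1L)
  comps <- list()
  used <- matrix(FALSE, res, res)
  for (i in seq_len(k)) {
    for (try in 1:20) {
      r1 <- sample(res, 1L); r2 <- min(res, r1 + sample(3:20, 1L))
      c1 <- sample(res, 1L); c2 <- min(res, c1 + sample(3:30, 1L))
      m <- matrix(FALSE, res, res)
      m[r1:r2, c1:c2] <- TRUE
      if (!any(m & used)) {
        used <- used | m
        comps[[length(comps) + 1L]] <-
          list(mask = m, sign = sample(c(1, -1), 1L),
               direction = "increasing")
        break
      }
    }
  }
  comps
}

# Brute-force region-weight argmax, written independently of the package:
# enumerate the components reaching the highest-dose column and score each
# by direct counting.
brute_force_select <- function(components) {
  best <- NULL
  best_key <- NULL
  for (cm in components) {
    m <- cm$mask
    if (!any(m[, ncol(m)])) next
    n_p <- sum(m)
    n_tp_md <- sum(m[, ncol(m)])
    m_d <- min(which(colSums(m) > 0L))
    r <- n_p + n_tp_md - m_d
    key <- c(r, n_p, -m_d)
    if (is.null(best_key) ||
        (key[1] > best_key[1]) ||
        (key[1] == best_key[1] && key[2] > best_key[2]) ||
        (key[1] == best_key[1] && key[2] == best_key[2] &&
         key[3] > best_key[3])) {
      best <- cm; best_key <- key
      best$score_r <- r
    }
  }
  best
}

# Random responsive surfaces run through the real detection path; returns
# up to n detected DDRAs together with their maps.
collect_random_ddras <- function(n = 50L, seed = 42L, max_tries = 10L * n) {
  set.seed(seed)
  out <- list()
  tries <- 0L
  while (length(out) < n && tries < max_tries) {
    tries <- tries + 1L
    order <- sample(2:3, 1L)
    p <- if (order == 2L) 6L else 10L
    beta <- runif(p, -1, 1)
    beta[1L] <- runif(1, -0.3, 0.3)
    fit <- make_gene_fit(beta, order, gene_id = sprintf("rand%03d", tries))
    map <- effect_map(fit)
    d <- detect_ddra(map)
    if (!is_dropped(d)) out[[length(out) + 1L]] <- list(map = map, ddra = d)
  }
  out
}

# A mixed synthetic batch with amplitude spread, used by the threshold-sweep
# and end-to-end tests: equal parts constant / linear / poly2 / poly3 genes,
# alternating direction, amplitudes scaled by a random factor.
mixed_batch_specs <- function(n, noise_sd = 0.05, seed = 1L) {
  set.seed(seed)
  fams <- rep(c("constant", "linear", "poly2", "poly3"), length.out = n)
  lapply(seq_len(n), function(i) {
    base <- preset_spec(fams[i], noise_sd = noise_sd,
                        direction = if (i %% 2 == 0) "-" else "+")
    amp <- runif(1, 0.3, 1.5)
    co <- base$coefficients
    if (fams[i] != "constant") co <- co * amp
    surface_spec(fams[i], co, noise_sd = noise_sd,
                 direction = base$direction)
  })
}
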