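# DDRA detection: thresholding, monotone segmentation, region weighting,
# reduction, boundary tracing and fronts.

test_that("activity mask inverts the threshold analytically", {
  weak <- make_gene_fit(c(0, 0.05, 0), 1L)   # max |LFC| = 0.05
  m <- effect_map(weak)
  expect_false(any(active_mask(m, 0.10)))    # cut ~ 0.1375
  d <- detect_ddra(m)
  expect_true(is_dropped(d))
  expect_equal(attr(d, "reason"), "below_threshold")

  plane <- effect_map(make_gene_fit(c(0, 1, 0), 1L))  # LFC = dose_norm
  act <- active_mask(plane, 0.10)
  cut <- log2(1.1)
  expected <- matrix(plane$dose_norm >= cut, 50L, 50L, byrow = TRUE)
  expect_identical(act, expected)

  # raw-LFC threshold scale
  act2 <- active_mask(plane, 0.5, scale = "lfc")
  expect_identical(act2, matrix(plane$dose_norm >= 0.5, 50L, 50L, byrow = TRUE))
})

test_that("mask size is non-increasing in the activity threshold", {
  m <- effect_map(make_gene_fit(c(0, 0.9, 0.5, -0.7, 0.3, 0.2), 2L))
  sizes <- vapply(c(0.10, 0.20, 0.30, 0.40, 0.50),
                  function(th) sum(active_mask(m, th)), numeric(1L))
  expect_true(all(diff(sizes) <= 0))
})

test_that("segmentation splits by dose-gradient sign", {
  plane <- effect_map(make_gene_fit(c(0, 1, 0), 1L))
  comps <- segment_monotone(plane, active_mask(plane))
  expect_length(comps, 1L)
  expect_equal(comps[[1L]]$direction, "increasing")

  # saddle LFC = D*T - 0.5*D: grad_dose = T - 0.5, positive late, negative early
  saddle <- effect_map(make_gene_fit(c(0, 0, 0, 1, -0.5, 0), 2L))
  cs <- segment_monotone(saddle, active_mask(saddle))
  expect_length(cs, 2L)
  expect_setequal(vapply(cs, `[[`, character(1L), "direction"),
                  c("increasing", "decreasing"))
  inc <- cs[[which(vapply(cs, `[[`, character(1L), "direction") ==
                   "increasing")]]
  rows_inc <- unique(row(inc$mask)[inc$mask])
  expect_true(all(saddle$time_norm[rows_inc] > 0.5))

  # active but flat region: no monotone component -> gene removed
  flat <- effect_map(make_gene_fit(0.5, "constant"))
  expect_length(segment_monotone(flat, active_mask(flat)), 0L)
  expect_equal(attr(detect_ddra(flat), "reason"), "non_monotone")
})

test_that("component labelling agrees with an independent graph oracle", {
  set.seed(31)
  for (i in 1:30) {
    mask <- matrix(runif(400) < 0.35, 20L, 20L)
    lab <- ddrmap:::label_components(mask)
    cells <- which(mask)
    # oracle: connected components of the 8-neighbourhood graph
    if (length(cells) == 0L) {
      expect_equal(max(lab), 0L)
      next
    }
    rr <- ((cells - 1L) %% 20L) + 1L
    cc <- ((cells - 1L) %/% 20L) + 1L
    adj <- which(outer(seq_along(cells), seq_along(cells), function(a, b) {
      abs(rr[a] - rr[b]) <= 1L & abs(cc[a] - cc[b]) <= 1L & a < b
    }), arr.ind = TRUE)
    g <- igraph::graph_from_edgelist(cbind(adj[, 1L], adj[, 2L]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, length(cells) - igraph::vcount(g))
    comp <- igraph::components(g)$membership
    # same partition: label pairs agree
    expect_equal(max(lab), max(comp))
    expect_true(all(tapply(comp, lab[cells], function(v) length(unique(v))) == 1L))
  }
})

test_that("region weight follows the published arithmetic", {
  m <- matrix(FALSE, 50L, 50L)
  m[1:20, 5:50] <- TRUE
  sc <- ddrmap:::region_score(m)
  expect_equal(sc$n_p, 20L * 46L)
  expect_equal(sc$n_tp_md, 20L)
  expect_equal(sc$m_d, 5L)
  expect_equal(sc$r, 20L * 46L + 20L - 5L)
})

test_that("candidate selection discards regions missing the highest dose", {
  a <- matrix(FALSE, 50, 50); a[1:30, 20:50] <- TRUE
  b <- matrix(FALSE, 50, 50); b[40:50, 1:15] <- TRUE   # misses column 50
  comps <- list(list(mask = a, sign = 1, direction = "increasing"),
                list(mask = b, sign = -1, direction = "decreasing"))
  sel <- select_candidate(comps)
  expect_identical(sel$mask, a)

  expect_null(select_candidate(list(comps[[2L]])))
  expect_null(select_candidate(list()))
})

test_that("candidate selection equals the brute-force weight argmax", {
  set.seed(47)
  for (i in 1:50) {
    comps <- random_components()
    sel <- select_candidate(comps)
    oracle <- brute_force_select(comps)
    if (is.null(oracle)) {
      expect_null(sel)
    } else {
      expect_equal(sel$score$r, oracle$score_r)
      expect_identical(sel$mask, oracle$mask)
    }
  }
})

test_that("region reduction removes rows with opposite outside behaviour", {
  res <- 50L
  gd <- matrix(1, res, res)
  gd[40:50, 1:10] <- -1
  gt <- matrix(0, res, res)
  lfc <- matrix(0, res, res)
  lfc[, 30:50] <- 1
  lfc[40:50, 1:10] <- -1
  map <- make_fake_map(gd, gt, lfc)
  act <- abs(lfc) >= log2(1.1)
  comps <- segment_monotone(map, act)
  cand <- select_candidate(comps)
  red <- reduce_region(map, cand, act)
  expected <- matrix(FALSE, res, res)
  expected[1:39, 30:50] <- TRUE
  expect_identical(red$mask, expected)
  expect_lte(sum(red$mask), sum(cand$mask))

  # no outside activity -> unchanged
  act2 <- matrix(FALSE, res, res); act2[, 30:50] <- TRUE
  comps2 <- segment_monotone(map, act2)
  cand2 <- select_candidate(comps2)
  red2 <- reduce_region(map, cand2, act2)
  expect_identical(red2$mask, cand2$mask)
})

test_that("boundary tracing honours the perimeter arithmetic", {
  full <- matrix(TRUE, 50L, 50L)
  b <- trace_border(full)
  expect_equal(nrow(b), 4L * 50L - 4L)   # 196 perimeter points
  expect_true(all(b[, "row"] %in% c(1L, 50L) | b[, "col"] %in% c(1L, 50L)))

  single <- matrix(FALSE, 10L, 10L); single[4L, 7L] <- TRUE
  expect_equal(unname(trace_border(single)), cbind(4L, 7L), ignore_attr = TRUE)

  sq <- matrix(FALSE, 10L, 10L); sq[3:5, 3:5] <- TRUE
  bs <- trace_border(sq)
  expect_equal(nrow(bs), 8L)
  expect_false(any(bs[, "row"] == 4L & bs[, "col"] == 4L))
})

test_that("every traced border point touches background or the grid edge", {
  set.seed(53)
  shapes <- list()
  m1 <- matrix(FALSE, 30, 30); m1[5:20, 10:25] <- TRUE
  m2 <- matrix(FALSE, 30, 30); m2[1:30, 1:4] <- TRUE; m2[1:4, 1:30] <- TRUE
  m3 <- matrix(FALSE, 30, 30); m3[10:12, 5:28] <- TRUE; m3[12:25, 26:28] <- TRUE
  for (mask in list(m1, m2, m3)) {
    b <- trace_border(mask)
    for (i in seq_len(nrow(b))) {
      r <- b[i, "row"]; c <- b[i, "col"]
      expect_true(mask[r, c])
      nb <- expand.grid(r = r + (-1:1), c = c + (-1:1))
      edge <- any(nb$r < 1 | nb$r > nrow(mask) | nb$c < 1 | nb$c > ncol(mask))
      inb <- nb[nb$r >= 1 & nb$r <= nrow(mask) & nb$c >= 1 & nb$c <= ncol(mask), ]
      expect_true(edge || any(!mask[cbind(inb$r, inb$c)]))
    }
    # the trace is a subset of the boundary-criterion set; points it may
    # skip are inner diagonal corners (background touches only diagonally)
    crit <- which(mask & !ddrmap:::erode_all(mask), arr.ind = TRUE)
    expect_true(all(paste(b[, 1], b[, 2]) %in% paste(crit[, 1], crit[, 2])))
    missed <- setdiff(paste(crit[, 1], crit[, 2]), paste(b[, 1], b[, 2]))
    for (mcell in missed) {
      rc <- as.integer(strsplit(mcell, " ")[[1L]])
      orth <- rbind(c(rc[1] - 1, rc[2]), c(rc[1] + 1, rc[2]),
                    c(rc[1], rc[2] - 1), c(rc[1], rc[2] + 1))
      ok <- orth[, 1] >= 1 & orth[, 1] <= nrow(mask) &
        orth[, 2] >= 1 & orth[, 2] <= ncol(mask)
      expect_true(all(mask[orth[ok, , drop = FALSE]]))
    }
  }
  # rectangles have no diagonal corners: trace = criterion set exactly
  b1 <- trace_border(m1)
  crit1 <- which(m1 & !ddrmap:::erode_all(m1), arr.ind = TRUE)
  expect_setequal(paste(b1[, 1], b1[, 2]), paste(crit1[, 1], crit1[, 2]))
})

test_that("fronts follow the analytic inversion of a plane", {
  plane <- effect_map(make_gene_fit(c(0, 1, 0), 1L))  # LFC = dose_norm
  d <- detect_ddra(plane)
  expect_false(is_dropped(d))
  cut <- log2(1.1)
  dr_col <- min(which(plane$dose_norm >= cut))
  ic_col <- min(which(plane$dose_norm >= 0.5))  # row max is 1 in every row
  expect_true(all(d$dr_front$dr_col == dr_col))
  expect_true(all(d$ic50_front$ic50_col == ic_col))
  expect_true(all(d$dr_front$dr_col <= d$ic50_front$ic50_col))
  expect_true(all(d$ic50_front$ic50_col <= 50L))
  # fronts are reported in original dose units on the log-spaced grid
  expect_equal(d$dr_front$dr_dose, rep(plane$dose[dr_col], 50L))
})

test_that("noiseless monotone genes recover the analytic region exactly", {
  for (dir in c("+", "-")) {
    sp <- surface_spec("linear", c(0, 1.2, 0.2), noise_sd = 0, direction = dir)
    sim <- simulate_experiment(list(g = sp), experiment_design(seed = 61L))
    fits <- fit_dose_time(sim$lfc)
    map <- effect_map(fits$genes$g)
    d <- detect_ddra(map)
    expect_false(is_dropped(d))
    expect_identical(d$mask, sim$truth$g$mask)
    expect_equal(d$direction,
                 if (dir == "+") "increasing" else "decreasing")
    expect_equal(sign(d$mean_fc), if (dir == "+") 1 else -1)
    # direction agrees with the dose gradient over the whole region
    gsign <- sign(map$grad_dose[d$mask])
    expect_true(mean(gsign == d$sign) >= 0.95)
  }
})

test_that("reported regions always reach the highest-dose column", {
  ddras <- collect_random_ddras(20L, seed = 71L)
  for (x in ddras) {
    expect_true(any(x$ddra$mask[, 50L]))
    expect_true(sum(x$ddra$mask) >= 1L)
  }
})
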