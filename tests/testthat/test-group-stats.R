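# build a group_stack of k-ROI matrices from an edges x subjects matrix
stack_from_edges <- function(E, roi, group, tp, prefix = group) {
  mats <- lapply(seq_len(ncol(E)), function(s) {
    z <- connmri:::edges_to_matrix(E[, s], roi)
    structure(list(z = z, roi_order = roi,
                   meta = list(subject = paste0(prefix, s), group = group,
                               time_point = tp, n = 1L), n_clipped = 0L),
              class = "conn_matrix")
  })
  group_stack(mats, group, tp)
}

roi4 <- paste0("R", 1:4)

test_that("the normality screen behaves like Shapiro-Wilk should", {
  set.seed(10)
  # type-I calibration on normal samples
  rej <- mean(replicate(400, normality_screen(rnorm(50)) < 0.05))
  expect_lt(abs(rej - 0.05), 0.035)
  # power on a heavy-tailed mixture
  pow <- mean(replicate(200, {
    x <- rnorm(50) + rbinom(50, 1, 0.15) * rnorm(50, sd = 8)
    normality_screen(x) < 0.05
  }))
  expect_gte(pow, 0.9)
  expect_error(normality_screen(c(1, 2)), "3 <= n")
  expect_error(normality_screen(rep(1, 10)), "constant")
})

test_that("Friedman k=2 reproduces the closed-form and chi-squared p", {
  # all 7 subjects increase: Q = 7, p = pchisq(7, 1)
  fe <- connmri:::friedman_edge(rep(0, 7), rep(1, 7))
  expect_equal(unname(fe["statistic"]), 7)
  expect_equal(unname(fe["p"]), pchisq(7, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(unname(fe["p"]), 0.00815, tolerance = 1e-3)
  # balanced 4 up / 3 down: weak evidence
  fe2 <- connmri:::friedman_edge(rep(0, 7), c(1, 1, 1, 1, -1, -1, -1),
                                 exact = TRUE)
  expect_gt(unname(fe2["p"]), 0.5)
  # chi-squared track agrees with the base implementation, ties included
  set.seed(11)
  for (i in 1:20) {
    y1 <- rnorm(7); y2 <- rnorm(7)
    if (i %% 3 == 0) y2[1:2] <- y1[1:2]     # inject ties
    fe3 <- connmri:::friedman_edge(y1, y2)
    ft <- friedman.test(cbind(y1, y2))
    expect_equal(unname(fe3["statistic"]), unname(ft$statistic),
                 tolerance = 1e-12)
    expect_equal(unname(fe3["p"]), ft$p.value, tolerance = 1e-12)
  }
})

test_that("exact Friedman p agrees with full sign-flip enumeration", {
  set.seed(12)
  for (n in c(4, 6, 8)) {
    for (i in 1:10) {
      y1 <- rnorm(n); y2 <- rnorm(n)
      if (i > 7) y2[1] <- y1[1]
      p_pkg <- unname(connmri:::friedman_edge(y1, y2, exact = TRUE)["p"])
      p_orc <- oracle_friedman_exact(y1, y2)
      expect_lt(abs(p_pkg - p_orc), 1e-9)
    }
  }
})

test_that("edge-wise Friedman handles pairing, ties and degenerate edges", {
  set.seed(13)
  E1 <- matrix(rnorm(6 * 7), 6, 7)
  E2 <- E1 + matrix(rnorm(6 * 7, mean = 1), 6, 7)
  E2[3, ] <- E1[3, ]                        # fully tied edge
  s1 <- stack_from_edges(E1, roi4, "g", "t1")
  s2 <- stack_from_edges(E2, roi4, "g", "t2")
  sm <- friedman_within_group(s1, s2)
  ut <- upper.tri(sm$p)
  expect_true(is.na(sm$p[2, 3]))            # edge 3 in column-major order
  expect_equal(sum(is.na(sm$p[ut])), 1)
  expect_true(all(sm$p[ut] >= 0 & sm$p[ut] <= 1, na.rm = TRUE))
  expect_equal(sm$p, t(sm$p))
  s2b <- stack_from_edges(E2, roi4, "g", "t2", prefix = "other")
  expect_error(friedman_within_group(s1, s2b), "paired")
})

test_that("Kruskal-Wallis and Dunn match the hand-derivable partition", {
  E <- list(matrix(c(1, 2), 1), matrix(c(3, 4), 1), matrix(c(5, 6), 1))
  stacks <- lapply(1:3, function(i) {
    stack_from_edges(matrix(rep(E[[i]], each = 1), 1), c("A", "B"),
                     c("g1", "g2", "g3")[i], "t1")
  })
  res <- kruskal_dunn_between_groups(stacks)
  expect_equal(res$omnibus$statistic["A", "B"], 4.571, tolerance = 1e-3)
  expect_equal(res$omnibus$p["A", "B"], 0.1017, tolerance = 1e-3)
  zext <- res$pairs[["g1 vs g3"]]$statistic["A", "B"]
  expect_equal(abs(zext), 4 / sqrt(3.5), tolerance = 1e-12)
  expect_equal(abs(zext), 2.138, tolerance = 1e-3)
  expect_equal(res$pairs[["g1 vs g3"]]$p_unadjusted["A", "B"], 0.0325,
               tolerance = 1e-3)
  expect_equal(res$pairs[["g1 vs g3"]]$p["A", "B"], 0.0975,
               tolerance = 1e-3)
})

test_that("Kruskal-Wallis H is invariant under monotone transforms", {
  set.seed(14)
  E <- matrix(rnorm(3 * 18), 3, 18)
  mk <- function(E) lapply(1:3, function(g) {
    stack_from_edges(E[, (g - 1) * 6 + 1:6], roi4, paste0("g", g), "t1")
  })
  res1 <- kruskal_dunn_between_groups(mk(E))
  res2 <- kruskal_dunn_between_groups(mk(exp(3 * E)))   # strictly monotone
  expect_equal(res1$omnibus$statistic, res2$omnibus$statistic,
               tolerance = 1e-10)
  # Dunn adjusted p >= unadjusted, capped at 1
  for (p in res1$pairs) {
    ut <- upper.tri(p$p)
    expect_true(all(p$p[ut] >= p$p_unadjusted[ut] - 1e-15))
    expect_true(all(p$p[ut] <= 1))
  }
})

test_that("edge-wise type-I error of the nonparametric track is calibrated", {
  set.seed(15)
  roi <- sprintf("N%02d", 1:40)              # 780 edges per replicate
  rej <- sapply(1:4, function(rep) {
    stacks <- lapply(1:3, function(g) {
      n <- c(8, 8, 7)[g]
      stack_from_edges(matrix(rnorm(780 * n), 780, n), roi,
                       paste0("g", g), "t1")
    })
    res <- kruskal_dunn_between_groups(stacks)
    p <- res$omnibus$p[upper.tri(res$omnibus$p)]
    mean(p < 0.05)
  })
  expect_lt(abs(mean(rej) - 0.05), 0.015)    # 3120 null edges
})

test_that("significance tiers apply strict thresholds", {
  p <- connmri:::edges_to_matrix(c(0.0498, 0.05, 0.004), c("a", "b", "c"))
  sm <- structure(list(p = p, statistic = p, roi_order = c("a", "b", "c"),
                       test = "t", n = 5, adjustment = "none"),
                  class = "stat_matrix")
  tier <- significance_mask(sm)
  expect_equal(tier["a", "b"], 1L)           # p = 0.0498
  expect_equal(tier["a", "c"], 0L)           # p = 0.05 exactly
  expect_equal(tier["b", "c"], 2L)           # p = 0.004
  expect_equal(attr(tier, "mask")["a", "b"], TRUE)
  expect_equal(attr(tier, "mask")["a", "c"], FALSE)
})
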