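test_that("ROI extraction averages voxels framewise", {
  at <- make_block_atlas(2, c(2, 1, 1), c(2, 1, 1), gap = 1, margin = 0)
  g <- at$geometry
  arr <- array(0, c(g$dims, 4))
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8)
  arr[1, 1, 1, ] <- a
  arr[2, 1, 1, ] <- b
  arr[4, 1, 1, ] <- 5                       # ROI 2, constant
  arr[5, 1, 1, ] <- 5
  bold <- bold4d(arr, g, 1)
  ts <- extract_roi_timeseries(bold, at)
  expect_equal(ts["roi1", ], (a + b) / 2)
  expect_equal(ts["roi2", ], rep(5, 4))     # identical voxels: that series
  ts2 <- extract_roi_timeseries(bold, at, rois = c("roi2", "roi1"))
  expect_identical(rownames(ts2), c("roi2", "roi1"))
  expect_error(extract_roi_timeseries(bold, at, "nope"), "unknown ROI")
})

test_that("ROI extraction matches a brute-force per-voxel oracle", {
  at <- make_block_atlas(24, c(2, 2, 1), c(6, 4, 1))
  g <- at$geometry
  set.seed(4)
  arr <- array(rnorm(prod(g$dims) * 6), c(g$dims, 6))
  ts <- extract_roi_timeseries(bold4d(arr, g, 1), at)
  expect_equal(dim(ts), c(24L, 6L))
  # oracle: loop voxels explicitly for a few ROIs
  for (r in c(1, 13, 24)) {
    idx <- which(at$labels == r, arr.ind = TRUE)
    manual <- colMeans(t(sapply(seq_len(nrow(idx)), function(i) {
      arr[idx[i, 1], idx[i, 2], idx[i, 3], ]
    })))
    expect_equal(unname(ts[r, ]), manual, tolerance = 1e-12)
  }
})

test_that("fisher_z matches the log-form oracle and clips degenerate input", {
  expect_equal(as.numeric(fisher_z(0)), 0)
  expect_equal(as.numeric(fisher_z(0.5)), oracle_atanh(0.5),
               tolerance = 1e-12)
  expect_equal(as.numeric(fisher_z(0.5)), 0.549306, tolerance = 1e-6)
  expect_equal(as.numeric(fisher_z(-0.5)), -as.numeric(fisher_z(0.5)))
  z1 <- fisher_z(1)
  expect_true(is.finite(z1))
  expect_equal(attr(z1, "n_clipped"), 1L)
  expect_error(fisher_z(Inf), "non-finite")
})

test_that("connectivity matrices equal the brute-force double loop", {
  set.seed(5)
  ts <- matrix(rnorm(5 * 60), 5, 60,
               dimnames = list(paste0("R", 1:5), NULL))
  cm <- connectivity_matrix(ts)
  expect_lt(max(abs(cm$z - oracle_conn_z(ts)), na.rm = TRUE), 1e-12)
  expect_equal(cm$z, t(cm$z))
  expect_true(all(is.na(diag(cm$z))))
  # identical and anti-correlated rows are clipped, not infinite
  ts2 <- rbind(a = 1:10, b = 1:10, c = -(1:10)) + 0
  cm2 <- connectivity_matrix(ts2)
  expect_true(all(is.finite(cm2$z[upper.tri(cm2$z)])))
  expect_equal(cm2$z["a", "b"], atanh(1 - 1e-7))
  expect_equal(cm2$z["a", "c"], -atanh(1 - 1e-7))
  expect_gte(cm2$n_clipped, 2)
  ts3 <- rbind(a = rnorm(10), b = rep(2, 10))
  expect_error(connectivity_matrix(ts3), "zero-variance ROI series: b")
})

test_that("connectivity is invariant under affine rescaling of ROI series", {
  set.seed(6)
  ts <- matrix(rnorm(4 * 50), 4, 50, dimnames = list(letters[1:4], NULL))
  cm <- connectivity_matrix(ts)
  ts2 <- ts * c(2, -3, 0.5, 10) + c(1, 0, -5, 100)
  cm2 <- connectivity_matrix(ts2)
  expect_equal(abs(cm2$z), abs(cm$z), tolerance = 1e-10)  # sign flips on b
})

test_that("intra-node strength averages pairwise voxel z-values", {
  at <- make_block_atlas(1, c(3, 1, 1), c(1, 1, 1), margin = 0)
  g <- at$geometry
  set.seed(7)
  Y <- matrix(rnorm(3 * 40), 3, 40)
  arr <- array(0, c(g$dims, 40))
  for (v in 1:3) arr[v, 1, 1, ] <- Y[v, ]
  s <- intra_node_strength(bold4d(arr, g, 1), at, "roi1")
  # oracle: the three pairwise z-values by hand
  zs <- c(atanh(cor(Y[1, ], Y[2, ])), atanh(cor(Y[1, ], Y[3, ])),
          atanh(cor(Y[2, ], Y[3, ])))
  expect_equal(as.numeric(s), mean(zs), tolerance = 1e-12)
  expect_equal(attr(s, "n_pairs"), 3L)
})

test_that("intra-node strength separates coherent from independent nodes", {
  at <- make_block_atlas(1, c(4, 2, 1), c(1, 1, 1), margin = 0)
  g <- at$geometry
  nt <- 400
  base <- rnorm(nt)
  set.seed(8)
  coh <- array(0, c(g$dims, nt))
  ind <- array(0, c(g$dims, nt))
  for (i in 1:4) for (j in 1:2) {
    coh[i, j, 1, ] <- base + rnorm(nt, sd = 0.05)
    ind[i, j, 1, ] <- rnorm(nt)
  }
  s_coh <- intra_node_strength(bold4d(coh, g, 1), at, "roi1")
  expect_gte(as.numeric(s_coh), atanh(0.99))
  expect_equal(attr(s_coh, "n_excluded_voxels"), 0L)
  s_ind <- intra_node_strength(bold4d(ind, g, 1), at, "roi1")
  expect_lt(abs(as.numeric(s_ind)), 4 / sqrt(nt - 3))
  # fewer than two usable voxels errors
  flat <- array(1, c(g$dims, nt))
  expect_error(intra_node_strength(bold4d(flat, g, 1), at, "roi1"),
               "usable voxels")
})

test_that("group averaging is elementwise on z, after the transform", {
  set.seed(9)
  mats <- lapply(1:7, function(i) {
    connectivity_matrix(matrix(rnorm(4 * 50), 4, 50,
                               dimnames = list(letters[1:4], NULL)))
  })
  avg <- group_average_matrix(mats, group = "g", time_point = "t1")
  manual <- Reduce(`+`, lapply(mats, `[[`, "z")) / 7
  expect_equal(avg$z, manual, tolerance = 1e-12)
  expect_equal(avg$meta$n, 7L)
  expect_equal(group_average_matrix(mats[1])$z, mats[[1]]$z)
  m2 <- mats[[2]]; m2$z <- -mats[[1]]$z
  zz <- group_average_matrix(list(mats[[1]], m2))$z
  expect_equal(max(abs(zz), na.rm = TRUE), 0)
  # averaging z first differs from transforming the averaged r (order fixed)
  r <- lapply(mats, function(m) tanh(m$z))
  alt <- atanh(Reduce(`+`, r) / 7)
  expect_gt(max(abs(avg$z - alt), na.rm = TRUE), 1e-6)
  bad <- mats[[3]]; bad$roi_order <- rev(bad$roi_order)
  expect_error(group_average_matrix(list(mats[[1]], bad)), "mismatch")
})
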