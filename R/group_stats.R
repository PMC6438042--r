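#' Bundle per-subject connectivity matrices of one group at one time point
#'
#' @param matrices list of [connectivity_matrix()] results sharing
#'   `roi_order`, one per subject, in subject order.
#' @param group group label.
#' @param time_point time-point label.
#' @param subjects unique subject ids, same order as `matrices` (default:
#'   taken from matrix metadata).
#' @return An object of class `group_stack`.
#' @export
group_stack <- function(matrices, group, time_point, subjects = NULL) {
  if (!length(matrices)) stop("empty stack")
  ord <- matrices[[1]]$roi_order
  for (m in matrices) {
    if (!identical(m$roi_order, ord)) stop("roi_order mismatch in stack")
  }
  if (is.null(subjects)) {
    subjects <- vapply(matrices, function(m) as.character(m$meta$subject),
                       character(1))
  }
  if (anyDuplicated(subjects)) stop("duplicate subject ids in stack")
  structure(list(matrices = matrices, group = group,
                 time_point = time_point, subjects = subjects,
                 roi_order = ord),
            class = "group_stack")
}

# edges x subjects matrix of upper-triangle z values
stack_edge_matrix <- function(stack) {
  ut <- upper.tri(stack$matrices[[1]]$z)
  E <- vapply(stack$matrices, function(m) m$z[ut], numeric(sum(ut)))
  if (is.null(dim(E))) E <- matrix(E, nrow = 1)   # single-edge stacks
  E
}

edge_index_pairs <- function(k) {
  which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
}

# assemble an edge-wise result vector back into a symmetric ROI matrix
edges_to_matrix <- function(values, roi_order) {
  k <- length(roi_order)
  m <- matrix(NA_real_, k, k, dimnames = list(roi_order, roi_order))
  ut <- upper.tri(m)
  m[ut] <- values
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

new_stat_matrix <- function(p, statistic, roi_order, test, n, adjustment) {
  structure(list(p = edges_to_matrix(p, roi_order),
                 statistic = edges_to_matrix(statistic, roi_order),
                 roi_order = roi_order, test = test, n = n,
                 adjustment = adjustment),
            class = "stat_matrix")
}

#' @export
print.stat_matrix <- function(x, ...) {
  p <- x$p[upper.tri(x$p)]
  cat(sprintf("<stat_matrix> %s (n = %s, adjustment: %s)\n", x$test,
              paste(x$n, collapse = "/"), x$adjustment))
  cat(sprintf("  %d edges, %d with p < 0.05, %d with p < 0.005\n",
              sum(!is.na(p)), sum(p < 0.05, na.rm = TRUE),
              sum(p < 0.005, na.rm = TRUE)))
  invisible(x)
}

#' Shapiro-Wilk normality screen
#'
#' Report-level check used to justify the nonparametric testing track (it
#' does not gate individual edges).
#'
#' @param values numeric sample, 3 <= n <= 5000, not constant.
#' @return Shapiro-Wilk p-value.
#' @export
normality_screen <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) stop("normality screen needs 3 <= n <= 5000")
  if (max(values) == min(values)) stop("constant sample")
  stats::shapiro.test(values)$p.value
}

# Friedman test for k = 2 paired conditions on one edge. With ties
# (subjects whose two values are equal) the tie-corrected statistic reduces
# to d^2 / m where d = (#increases - #decreases) and m = #non-tied subjects.
# Exact mode: sign-permutation p over the m non-tied subjects.
friedman_edge <- function(y1, y2, exact = FALSE) {
  diff <- y2 - y1
  s <- sign(diff)
  m <- sum(s != 0)
  if (m == 0) return(c(statistic = NA_real_, p = NA_real_))
  d <- sum(s)
  stat <- d^2 / m
  if (exact) {
    b <- 0:m
    p <- sum(stats::dbinom(b, m, 0.5)[abs(2 * b - m) >= abs(d)])
  } else {
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  c(statistic = stat, p = p)
}

#' Edge-wise Friedman test between two paired time points
#'
#' Within-group treatment effect: for every edge, a Friedman rank test over
#' the two conditions with subjects as blocks. The default p-value comes from
#' the chi-squared (df = 1) reference distribution with tie correction;
#' `exact = TRUE` replaces it with the exact sign-permutation distribution
#' (recommended for small groups). Edges tied in every subject are reported
#' as missing.
#'
#' @param stack_t1,stack_t2 [group_stack()]s of the same subjects in the
#'   same order (paired).
#' @param exact use the exact permutation p (default FALSE).
#' @return A `stat_matrix`.
#' @export
friedman_within_group <- function(stack_t1, stack_t2, exact = FALSE) {
  if (!identical(stack_t1$subjects, stack_t2$subjects)) {
    stop("stacks are not paired by subject")
  }
  if (!identical(stack_t1$roi_order, stack_t2$roi_order)) {
    stop("roi_order mismatch")
  }
  n <- length(stack_t1$subjects)
  if (n < 2) stop("need >= 2 subjects")
  E1 <- stack_edge_matrix(stack_t1)
  E2 <- stack_edge_matrix(stack_t2)
  res <- vapply(seq_len(nrow(E1)),
                function(e) friedman_edge(E1[e, ], E2[e, ], exact),
                numeric(2))
  new_stat_matrix(res["p", ], res["statistic", ], stack_t1$roi_order,
                  test = paste0("Friedman (k = 2",
                                if (exact) ", exact permutation" else "",
                                ")"),
                  n = n, adjustment = "none")
}

# Dunn's pairwise rank comparison following a Kruskal-Wallis test on one
# edge: z = (Rbar_i - Rbar_j) / sqrt(sig2 * (1/n_i + 1/n_j)) with the
# tie-corrected variance sig2 = N(N+1)/12 - T / (12 (N-1)), T = sum(t^3 - t).
dunn_edge <- function(values, groups) {
  rk <- rank(values)
  N <- length(values)
  tt <- table(rk)
  Tie <- sum(tt^3 - tt)
  sig2 <- N * (N + 1) / 12 - Tie / (12 * (N - 1))
  gl <- unique(groups)
  rbar <- tapply(rk, factor(groups, levels = gl), mean)
  ns <- tapply(rk, factor(groups, levels = gl), length)
  pairs <- utils::combn(seq_along(gl), 2)
  z <- apply(pairs, 2, function(ij) {
    (rbar[ij[1]] - rbar[ij[2]]) /
      sqrt(sig2 * (1 / ns[ij[1]] + 1 / ns[ij[2]]))
  })
  names(z) <- apply(pairs, 2, function(ij) paste(gl[ij[1]], gl[ij[2]],
                                                 sep = " vs "))
  z
}

#' Edge-wise Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Between-group effect at one time point: for every edge, the tie-corrected
#' Kruskal-Wallis H with chi-squared (df = groups - 1) p-value, followed by
#' Dunn's pairwise rank comparisons. Pairwise p-values are two-sided normal
#' tail probabilities, adjusted over the family of pairwise comparisons by
#' Bonferroni multiplication (capped at 1); both adjusted and unadjusted
#' values are returned.
#'
#' @param stacks list of >= 2 [group_stack()]s at one time point, each with
#'   >= 2 subjects, sharing `roi_order`.
#' @return list with `omnibus` (a `stat_matrix` of H and p) and `pairs`
#'   (named list of `stat_matrix`; `$p` holds Dunn-adjusted p-values, the
#'   unadjusted ones in field `p_unadjusted`).
#' @export
kruskal_dunn_between_groups <- function(stacks) {
  if (length(stacks) < 2) stop("need >= 2 groups")
  ord <- stacks[[1]]$roi_order
  for (s in stacks) {
    if (!identical(s$roi_order, ord)) stop("roi_order mismatch across groups")
    if (length(s$subjects) < 2) stop("group ", s$group, " has < 2 subjects")
  }
  gl <- vapply(stacks, `[[`, "", "group")
  ns <- vapply(stacks, function(s) length(s$subjects), 0L)
  E <- lapply(stacks, stack_edge_matrix)
  groups <- rep(gl, ns)
  n_edges <- nrow(E[[1]])
  n_pairs <- choose(length(stacks), 2)
  H <- p_om <- numeric(n_edges)
  zp <- matrix(NA_real_, n_edges, n_pairs)
  pp <- matrix(NA_real_, n_edges, n_pairs)
  pair_names <- NULL
  for (e in seq_len(n_edges)) {
    vals <- unlist(lapply(E, function(m) m[e, ]))
    if (max(vals) == min(vals)) {
      H[e] <- NA_real_; p_om[e] <- NA_real_
      next
    }
    kt <- stats::kruskal.test(vals, factor(groups, levels = gl))
    H[e] <- unname(kt$statistic)
    p_om[e] <- kt$p.value
    z <- dunn_edge(vals, groups)
    if (is.null(pair_names)) pair_names <- names(z)
    zp[e, ] <- z
    pp[e, ] <- 2 * stats::pnorm(-abs(z))
  }
  if (is.null(pair_names)) {
    pair_names <- apply(utils::combn(gl, 2), 2, paste, collapse = " vs ")
  }
  omnibus <- new_stat_matrix(p_om, H, ord,
                             test = "Kruskal-Wallis", n = ns,
                             adjustment = "none")
  pairs <- lapply(seq_len(n_pairs), function(j) {
    sm <- new_stat_matrix(pmin(1, pp[, j] * n_pairs), zp[, j], ord,
                          test = paste("Dunn:", pair_names[j]), n = ns,
                          adjustment = sprintf("Bonferroni x %d over pairs",
                                               n_pairs))
    sm$p_unadjusted <- edges_to_matrix(pp[, j], ord)
    sm
  })
  names(pairs) <- pair_names
  list(omnibus = omnibus, pairs = pairs)
}

#' Significance mask and star tiers for an edge-wise p matrix
#'
#' Tier 0: not significant; tier 1: p < 0.05 (one star); tier 2: p < 0.005
#' (two stars). Inequalities are strict.
#'
#' @param stat a `stat_matrix` (or a plain p-value matrix).
#' @param alpha level for the logical mask (default 0.05).
#' @return integer tier matrix with attribute `mask` (logical, `p < alpha`).
#' @export
significance_mask <- function(stat, alpha = 0.05) {
  p <- if (inherits(stat, "stat_matrix")) stat$p else as.matrix(stat)
  tier <- ifelse(is.na(p), NA_integer_,
                 ifelse(p < 0.005, 2L, ifelse(p < 0.05, 1L, 0L)))
  attr(tier, "mask") <- !is.na(p) & p < alpha
  tier
}
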