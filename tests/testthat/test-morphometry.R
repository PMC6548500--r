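test_that("foot index reproduces printed ratios and is scale invariant", {
  expect_equal(round_half_up(foot_index(6, 13)), 0.46)
  expect_equal(round_half_up(foot_index(7, 20.5)), 0.34)
  expect_equal(foot_index(8.2, 8.2), 1)
  expect_equal(foot_index(6, 13), foot_index(60, 130))   # cm -> mm
  expect_equal(foot_index(6, 13, scale100 = TRUE), 100 * 6 / 13)
  expect_error(foot_index(0, 13), "positive")
  expect_error(foot_index(6, -1), "positive")
})

test_that("arch angle matches geometry and is similarity invariant", {
  # border along the y-axis, apex line at 45 degrees from the border point
  border <- rbind(c(0, 0), c(0, 1))
  expect_equal(arch_angle(border, c(1, 2)), 45)

  rot <- function(pts, th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    t(R %*% t(pts))
  }
  oracle <- function(border, apex) {
    u <- border[2, ] - border[1, ]; v <- apex - border[2, ]
    a <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    if (a > 90) 180 - a else a
  }
  set.seed(7)
  for (i in 1:25) {
    b <- matrix(rnorm(4), 2)
    a <- rnorm(2)
    ang <- arch_angle(b, a)
    expect_equal(ang, oracle(b, a), tolerance = 1e-9)
    th <- runif(1, 0, 2 * pi); s <- runif(1, 0.1, 10); sh <- rnorm(2)
    pts <- rot(rbind(b, a), th) * s + rep(sh, each = 3)
    expect_equal(arch_angle(pts[1:2, ], pts[3, ]), ang, tolerance = 1e-6)
  }
  expect_error(arch_angle(rbind(c(0, 0), c(1, 1)), c(2, 2)), "collinear")
  expect_error(arch_angle(rbind(c(0, 0), c(0, 0)), c(1, 1)), "duplicate")
})

test_that("log transform is entrywise natural log and keeps the mask", {
  expect_equal(log_transform(matrix(1)), matrix(0), ignore_attr = TRUE)
  expect_equal(log_transform(matrix(exp(1))), matrix(1), ignore_attr = TRUE)
  M <- measurement_matrix(load_basura_fixtures("table4"))
  L <- log_transform(M)
  expect_equal(dim(L), c(23, 9))
  expect_identical(attr(L, "mask"), is.na(M))
  expect_equal(L[!is.na(M)], log(M[!is.na(M)]))
  expect_error(log_transform(matrix(c(1, -2), 1)), "positive")
})

test_that("iterative imputation recovers structure and leaves data alone", {
  # complete matrix: identity, zero iterations
  M <- rank1_matrix()
  out <- impute_missing(M, k = 1)
  expect_equal(out, M, ignore_attr = TRUE)
  expect_equal(attr(out, "iterations"), 0L)

  # rank-1 completion oracle: deleted cell is scale * profile exactly
  M2 <- M
  M2[3, 4] <- NA
  filled <- impute_missing(M2, k = 1)
  expect_equal(filled[3, 4], M[3, 4], tolerance = 1e-6)
  expect_equal(filled[-3, ], M[-3, ], ignore_attr = TRUE)  # observed untouched
  expect_true(attr(filled, "converged"))

  # fixture completion: imputed values stay within column range +/- 3 SD
  L <- log_transform(measurement_matrix(load_basura_fixtures("table4")))
  C <- impute_missing(L)
  expect_false(anyNA(C))
  mask <- attr(C, "mask")
  for (j in seq_len(ncol(L))) {
    obs <- L[!mask[, j], j]
    imp <- C[mask[, j], j]
    if (!length(imp)) next
    expect_true(all(imp > min(obs) - 3 * sd(obs)))
    expect_true(all(imp < max(obs) + 3 * sd(obs)))
  }

  expect_error(impute_missing(M2, k = 5), "k must")
  M3 <- M
  M3[, 2] <- NA
  expect_error(impute_missing(M3, k = 1), "all-missing")
})

test_that("PCA matches the eigendecomposition oracle and conserves variance", {
  # two mirror-image points: one axis carries all variance
  M <- rbind(c(1, 2, 3), c(3, 2, 1))
  p <- footprint_pca(rbind(M, colMeans(M)))
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:5) {
    X <- matrix(rnorm(40, mean = 5), 10, 4)
    p <- footprint_pca(X)
    ev <- eigen(cov(X), symmetric = TRUE)
    # same sign convention as the implementation
    flip <- apply(ev$vectors, 2, function(l) sign(l[which.max(abs(l))]))
    V <- sweep(ev$vectors, 2, flip, "*")
    expect_equal(unname(p$loadings), unname(V), tolerance = 1e-8)
    S <- sweep(X, 2, colMeans(X)) %*% V
    expect_equal(unname(p$scores), unname(S), tolerance = 1e-8)
    # conservation: component variances sum to total column variance
    expect_equal(sum(p$sdev^2), sum(apply(X, 2, var)), tolerance = 1e-10)
    expect_equal(colMeans(p$scores), rep(0, 4), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_error(footprint_pca(matrix(1, 5, 3)), "zero variance")
  expect_error(footprint_pca(matrix(c(1, NA, 2, 3, 4, 5), 3)), "missing")
})

test_that("PC1 of the log measurement fixture is a common size axis", {
  L <- log_transform(measurement_matrix(load_basura_fixtures("table4")))
  p <- footprint_pca(impute_missing(L))
  expect_true(all(p$loadings[, 1] > 0))
  expect_gt(p$explained_variance[1], 0.5)
})

test_that("morphotype grouping recovers the published partition structure", {
  t4 <- load_basura_fixtures("table4")
  asg <- group_morphotypes(t4)
  expect_equal(asg$n_groups, 5)
  expect_equal(minimum_individuals(asg), 5)
  g <- asg$assignment
  # smallest and largest size classes are unambiguous
  expect_length(unique(g[c("SM3", "SM4", "SM43", "SM17")]), 1)
  expect_length(unique(g[c("C60", "C37", "C35b")]), 1)
  expect_false(g[["SM3"]] == g[["C60"]])
  # labels ordered by size: group 1 smallest
  expect_equal(unname(g[["SM3"]]), 1L)
  expect_equal(unname(g[["C60"]]), 5L)
})

test_that("grouping is order and unit invariant, with degenerate cases", {
  t4 <- load_basura_fixtures("table4")
  ref <- group_morphotypes(t4)$assignment
  set.seed(3)
  perm <- t4[sample(nrow(t4)), ]
  expect_identical(group_morphotypes(perm)$assignment, ref)
  mm <- scale_table(t4, 10)   # cm -> mm
  expect_identical(group_morphotypes(mm)$assignment, ref)

  dup <- tiny_table()
  dup$Dt1 <- dup$Dt2 <- dup$max_FL <- 20
  for (v in c("Dt3", "mtm_BL", "mtl_BL", "ccm_BL", "ctul_BL",
              "mtm_horiz", "ctul_horiz", "max_FW"))
    dup[[v]] <- rep(dup[[v]][1], 3)
  expect_equal(group_morphotypes(dup)$n_groups, 1)

  # two size classes at 1.5x separation: forced split
  a <- as.data.frame(tiny_table())
  b <- a
  b$id <- paste0("B", 1:3)
  for (v in setdiff(names(a), c("id", "side", "Aa")))
    b[[v]] <- a[[v]] * 1.5
  two <- footprint_table(rbind(a, b))
  expect_equal(group_morphotypes(two)$n_groups, 2)

  expect_error(group_morphotypes(tiny_table()[0, ]), "empty")
})
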