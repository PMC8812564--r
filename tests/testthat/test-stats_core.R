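test_that("one-way ANOVA matches the linear-model decomposition", {
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$p, 1)

  # two groups: F equals the square of the pooled t statistic
  set.seed(5)
  g1 <- rnorm(6); g2 <- rnorm(7, 0.5)
  av <- one_way_anova(list(g1, g2))
  tt <- t.test(g2, g1, var.equal = TRUE)
  expect_equal(av$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(av$p, tt$p.value, tolerance = 1e-10)

  # random 3x5 fixture against anova(lm(...)) as oracle
  for (seed in 1:5) {
    set.seed(seed)
    groups <- lapply(1:3, function(i) rnorm(5, i / 2))
    av <- one_way_anova(groups)
    y <- unlist(groups)
    g <- factor(rep(1:3, each = 5))
    ref <- anova(lm(y ~ g))
    expect_equal(av$F, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(av$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(av$mse, ref$`Mean Sq`[2], tolerance = 1e-10)
  }

  # degenerate: zero total variance flags p = 1
  av0 <- one_way_anova(list(c(2, 2), c(2, 2, 2)))
  expect_true(av0$degenerate)
  expect_equal(av0$p, 1)
})

test_that("matrix ANOVA agrees with per-row lm fits", {
  set.seed(9)
  g <- factor(rep(c("a", "b", "c"), each = 4))
  X <- matrix(rnorm(20 * 12), 20, 12)
  av <- reefexo:::.anova_matrix(X, g)
  for (i in c(1, 7, 20)) {
    ref <- anova(lm(X[i, ] ~ g))
    expect_equal(av$F[i], ref$`F value`[1], tolerance = 1e-9)
    expect_equal(av$p[i], ref$`Pr(>F)`[1], tolerance = 1e-9)
  }
  Xc <- rbind(X, 5)   # constant row is degenerate
  avc <- reefexo:::.anova_matrix(Xc, g)
  expect_equal(avc$p[21], 1)
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.03, 5)), rep(0.03, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone step-up transform: sorted inputs give sorted outputs
  set.seed(2)
  p <- sort(runif(50))
  expect_false(is.unsorted(bh_fdr(p)))
  expect_true(all(bh_fdr(p) >= p))
})

test_that("Tukey HSD reduces to the pooled t test for two groups", {
  g <- list(A = c(3, 3.2, 2.8), B = c(3, 3.2, 2.8))
  th <- tukey_hsd(g)
  expect_equal(th$pairs$p_adj, 1)
  expect_equal(unname(th$letters), c("a", "a"))

  set.seed(3)
  g2 <- list(A = rnorm(5), B = rnorm(5, 1))
  th2 <- tukey_hsd(g2)
  tt <- t.test(g2$A, g2$B, var.equal = TRUE)
  expect_equal(th2$pairs$p_adj, tt$p.value, tolerance = 1e-6)

  # planted separation earns distinct letters
  g3 <- list(lo = rnorm(6, 0, 0.1), mid = rnorm(6, 3, 0.1),
             hi = rnorm(6, 6, 0.1))
  th3 <- tukey_hsd(g3)
  expect_equal(length(unique(th3$letters)), 3L)
})

test_that("angular z-score transform matches arcsine values and standardizes", {
  X <- matrix(c(0, 0.5, 1), 1, 3, dimnames = list("f", paste0("s", 1:3)))
  y <- asin(sqrt(c(0, 0.5, 1)))
  expect_equal(y, c(0, pi / 4, pi / 2))
  set.seed(4)
  M <- matrix(runif(60), 6, 10)
  Z <- angular_zscore_transform(M)
  expect_equal(unname(rowMeans(Z)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(apply(Z, 1, sd)), rep(1, 6), tolerance = 1e-9)
  Mc <- rbind(M, 0.3)
  expect_warning(Zc <- angular_zscore_transform(Mc), "constant")
  expect_equal(unname(Zc[7, ]), rep(0, 10))
  expect_error(angular_zscore_transform(matrix(c(0.1, 1.2), 1)), "\\[0, 1\\]")
})

test_that("PCoA recovers Euclidean configurations up to rotation", {
  set.seed(8)
  pts <- matrix(rnorm(24), 12, 2)
  D <- as.matrix(dist(pts))
  fit <- pcoa(D, k = 2)
  pro <- vegan::procrustes(pts, fit$points, symmetric = FALSE)
  expect_lt(sqrt(mean(residuals(pro)^2)), 1e-8)

  # collinear points: second informative axis is null
  line <- cbind(1:5, 2 * (1:5))
  fl <- pcoa(as.matrix(dist(line)))
  expect_lt(abs(fl$eig[2]), 1e-8)

  # duplicate points land on identical coordinates
  dup <- rbind(pts, pts[1, ])
  fd <- pcoa(as.matrix(dist(dup)), k = 2)
  expect_equal(fd$points[13, ], fd$points[1, ], tolerance = 1e-8)

  Da <- D; Da[1, 2] <- Da[1, 2] + 1
  expect_error(pcoa(Da), "symmetric")
})

test_that("PERMANOVA partitions variance and respects reordering", {
  set.seed(10)
  md <- data.frame(treatment = rep(c("A", "B", "C"), each = 8),
                   diel = rep(c("Day", "Night"), 12))
  X <- matrix(rnorm(24 * 4), 24, 4)
  X[md$treatment == "B", ] <- X[md$treatment == "B", ] + 2
  D <- as.matrix(dist(X))
  rownames(D) <- colnames(D) <- paste0("s", 1:24)
  res <- permanova(D, md, n_perm = 199, seed = 3)
  expect_equal(sum(res$R2[1:4]), 1, tolerance = 1e-9)
  expect_true(all(res$R2 >= 0 & res$R2 <= 1))

  # permutation p invariant to consistent row/column reordering
  ord <- sample(24)
  res2 <- permanova(D[ord, ord], md[ord, ], n_perm = 199, seed = 3)
  expect_equal(res2$p[1], res$p[1])

  expect_error(permanova(D, data.frame(treatment = rep("A", 24),
                                       diel = md$diel), n_perm = 199),
               "2 levels")
})

test_that("linear fits reproduce closed-form least squares", {
  x <- c(1, 2, 3, 4)
  f <- linear_fit(x, 2 * x)
  expect_equal(f$slope, 2)
  expect_equal(f$r2, 1)
  f3 <- linear_fit(c(0, 1, 2), c(0, 1, 4))
  expect_equal(f3$slope, 2)
  expect_equal(f3$intercept, -1 / 3, tolerance = 1e-12)
  expect_error(linear_fit(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("congruency is the likelihood-ratio uncertainty coefficient", {
  a <- rep(c("x", "y"), each = 10)
  expect_equal(congruency_r2(a, a)$r2, 1)
  tab22 <- congruency_r2(rep(c("x", "y"), each = 10),
                         rep(c("u", "v"), each = 10))
  expect_equal(tab22$g2, 2 * 20 * log(2), tolerance = 1e-12)
  expect_equal(tab22$r2, 1)

  set.seed(6)
  big <- congruency_r2(sample(letters[1:4], 1e4, TRUE),
                       sample(letters[5:8], 1e4, TRUE))
  expect_lt(big$r2, 0.02)
  expect_error(congruency_r2(rep("x", 5), c("a", "a", "b", "b", "b")),
               "fewer than 2 levels")
})
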