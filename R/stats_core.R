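#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition. With zero total variance the test
#' is undefined; by convention p = 1 is returned with `degenerate = TRUE`.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2
#'   observations).
#' @return List with `F`, `p`, `df1`, `df2`, `mse`, `ss_between`,
#'   `ss_within`, `degenerate`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  gm <- tapply(x, g, mean)
  ss_b <- sum(lengths(groups) * (gm - mean(x))^2)
  ss_w <- sum((x - gm[g])^2)
  df1 <- length(groups) - 1
  df2 <- n - length(groups)
  mse <- ss_w / df2
  if (ss_b + ss_w <= 0 || (ss_w == 0 && ss_b == 0)) {
    return(list(F = 0, p = 1, df1 = df1, df2 = df2, mse = 0,
                ss_between = 0, ss_within = 0, degenerate = TRUE))
  }
  if (ss_w == 0) {
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2, mse = 0,
                ss_between = ss_b, ss_within = 0, degenerate = FALSE))
  }
  Fstat <- (ss_b / df1) / mse
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, mse = mse, ss_between = ss_b, ss_within = ss_w,
       degenerate = FALSE)
}

# Row-wise one-way ANOVA for a feature matrix (features x samples) against a
# grouping factor; the per-feature loop version is far too slow for the
# thousands of features the cascade tests.
.anova_matrix <- function(X, g) {
  g <- as.factor(g)
  n <- ncol(X)
  k <- nlevels(g)
  G <- stats::model.matrix(~ g - 1)          # samples x groups indicator
  colnames(G) <- levels(g)
  ng <- colSums(G)
  sums <- X %*% G
  means <- sweep(sums, 2, ng, "/")
  grand <- rowSums(X) / n
  ss_b <- rowSums(sweep(means, 1, grand, "-")^2 %*% diag(ng, k, k))
  ss_tot <- rowSums(X^2) - n * grand^2
  ss_w <- pmax(ss_tot - ss_b, 0)
  df1 <- k - 1
  df2 <- n - k
  mse <- ss_w / df2
  Fstat <- (ss_b / df1) / mse
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  degen <- ss_tot <= .Machine$double.eps * pmax(rowSums(X^2), 1)
  p[degen] <- 1
  Fstat[degen] <- 0
  zero_w <- !degen & ss_w <= .Machine$double.eps * pmax(ss_tot, 1)
  p[zero_w] <- 0
  Fstat[zero_w] <- Inf
  list(F = Fstat, p = p, mse = mse, df1 = df1, df2 = df2,
       means = means, n_per_group = ng, degenerate = degen)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment, monotone and capped at 1; input order preserved.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Tukey honest significant difference with compact letter display
#'
#' All pairwise comparisons via the studentized range (Tukey-Kramer for
#' unbalanced groups). Groups are assigned display letters greedily from the
#' non-significance graph: groups sharing a letter are not significantly
#' different at `alpha`.
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Significance level for the letter display.
#' @return List with `pairs` (data.frame: group1, group2, estimate, p_adj)
#'   and `letters` (named character vector).
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_along(groups))
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  sizes <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  df <- sum(sizes) - k
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / df
  idx <- utils::combn(k, 2)
  est <- means[idx[2, ]] - means[idx[1, ]]
  if (mse == 0) {
    p <- ifelse(est == 0, 1, 0)
  } else {
    se <- sqrt(mse / 2 * (1 / sizes[idx[1, ]] + 1 / sizes[idx[2, ]]))
    q <- abs(est) / se
    p <- stats::ptukey(q, k, df, lower.tail = FALSE)
  }
  pairs <- data.frame(group1 = names(groups)[idx[1, ]],
                      group2 = names(groups)[idx[2, ]],
                      estimate = unname(est), p_adj = unname(p),
                      stringsAsFactors = FALSE)
  ## compact letter display: insert-and-absorb over groups ordered by mean
  ord <- order(means, decreasing = TRUE)
  sig <- matrix(FALSE, k, k, dimnames = list(names(groups), names(groups)))
  for (j in seq_len(ncol(idx))) {
    if (p[j] < alpha) {
      sig[idx[1, j], idx[2, j]] <- sig[idx[2, j], idx[1, j]] <- TRUE
    }
  }
  blocks <- list()
  for (gi in ord) {
    placed <- FALSE
    for (bi in seq_along(blocks)) {
      if (!any(sig[gi, blocks[[bi]]])) {
        blocks[[bi]] <- c(blocks[[bi]], gi)
        placed <- TRUE
      }
    }
    if (!placed) blocks[[length(blocks) + 1]] <- gi
  }
  ## drop blocks fully contained in another
  keep <- rep(TRUE, length(blocks))
  for (a in seq_along(blocks)) {
    for (b in seq_along(blocks)) {
      if (a != b && keep[b] && all(blocks[[a]] %in% blocks[[b]]) &&
          length(blocks[[a]]) < length(blocks[[b]])) keep[a] <- FALSE
    }
  }
  blocks <- blocks[keep]
  lett <- rep("", k)
  for (bi in seq_along(blocks)) {
    lett[blocks[[bi]]] <- paste0(lett[blocks[[bi]]], letters[bi])
  }
  names(lett) <- names(groups)
  list(pairs = pairs, letters = lett, mse = mse, df = df)
}

#' Angular (arcsine square root) transform followed by per-feature z-scoring
#'
#' Stabilizes proportions toward Gaussian behaviour before ordination:
#' y = arcsin(sqrt(x)) per cell, then each feature row is centred and scaled
#' across samples. Constant features map to all-zero rows with a warning.
#'
#' @param X Numeric matrix of relative abundances in `[0, 1]`
#'   (features x samples).
#' @return Transformed matrix of the same dimensions.
#' @export
angular_zscore_transform <- function(X) {
  if (any(X < 0 | X > 1)) {
    stop("relative abundances must lie in [0, 1]", call. = FALSE)
  }
  Y <- asin(sqrt(X))
  mu <- rowMeans(Y)
  sdv <- apply(Y, 1, stats::sd)
  const <- sdv == 0
  if (any(const)) {
    warning(sum(const), " constant feature(s) mapped to zero rows")
    sdv[const] <- 1
  }
  Z <- sweep(sweep(Y, 1, mu, "-"), 1, sdv, "/")
  Z[const, ] <- 0
  Z
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of the squared distance matrix followed by
#' eigendecomposition (via [stats::cmdscale()]). Axes are ordered by
#' eigenvalue; negative eigenvalues are reported, not corrected.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param k Number of axes to return (default all informative ones).
#' @return List with `points` (samples x axes) and `eig` (all eigenvalues).
#' @export
pcoa <- function(D, k = NULL) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(D)) > 1e-12)) {
    stop("distance matrix must have zero diagonal", call. = FALSE)
  }
  n <- nrow(D)
  if (is.null(k)) k <- n - 1
  fit <- stats::cmdscale(D, k = k, eig = TRUE)
  pts <- fit$points
  if (is.null(rownames(pts))) rownames(pts) <- rownames(D)
  list(points = pts, eig = fit$eig)
}

#' Permutational multivariate analysis of variance
#'
#' Partitions a distance matrix by a crossed two-factor design
#' (treatment, diel, interaction) with sequential sums of squares, the
#' ordering used by `adonis2`. P-values come from free permutation of sample
#' labels under a fixed seed.
#'
#' @param D Distance matrix or `dist` for the samples.
#' @param metadata Data.frame with `treatment` and `diel` columns matching
#'   the rows of `D`.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @return A `permanova_result` data.frame: one row per term with `df`,
#'   `ss`, `R2`, `F`, `p` (NA for the residual row).
#' @export
permanova <- function(D, metadata, n_perm = 999, seed = 1) {
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  md <- data.frame(treatment = factor(metadata$treatment),
                   diel = factor(metadata$diel))
  if (nlevels(md$treatment) < 2 || nlevels(md$diel) < 2) {
    stop("each design factor needs at least 2 levels", call. = FALSE)
  }
  fit <- with_preserved_seed(seed, {
    vegan::adonis2(stats::as.dist(D) ~ treatment * diel, data = md,
                   permutations = n_perm, by = "terms")
  })
  out <- data.frame(term = rownames(fit), df = fit$Df, ss = fit$SumOfSqs,
                    R2 = fit$R2, F = fit$F, p = fit$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  class(out) <- c("permanova_result", "data.frame")
  out
}

#' Pairwise PERMANOVA contrasts for one factor
#'
#' A-posteriori one-factor tests on every pair of levels, reporting raw and
#' BH-adjusted permutation p-values (the correction convention for such
#' contrasts is not standardized, so both are given).
#'
#' @param D Distance matrix for the samples.
#' @param labels Factor of group labels matching the rows of `D`.
#' @param n_perm Permutations per contrast.
#' @param seed Integer seed.
#' @return Data.frame: `level1`, `level2`, `R2`, `F`, `p_raw`, `p_adj`.
#' @export
permanova_pairwise <- function(D, labels, n_perm = 999, seed = 1) {
  D <- as.matrix(D)
  labels <- factor(labels)
  lev <- levels(labels)
  idx <- utils::combn(length(lev), 2)
  res <- lapply(seq_len(ncol(idx)), function(j) {
    keep <- labels %in% lev[idx[, j]]
    md <- data.frame(g = droplevels(labels[keep]))
    fit <- with_preserved_seed(seed + j, {
      vegan::adonis2(stats::as.dist(D[keep, keep]) ~ g, data = md,
                     permutations = n_perm)
    })
    data.frame(level1 = lev[idx[1, j]], level2 = lev[idx[2, j]],
               R2 = fit$R2[1], F = fit$F[1], p_raw = fit$`Pr(>F)`[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_fdr(out$p_raw)
  out
}

#' Ordinary least-squares fit of y on x
#'
#' @param x,y Numeric vectors (n >= 3) with non-zero variance in `x`.
#' @return List with `slope`, `intercept`, `r2`, `p` (slope t-test),
#'   `n`.
#' @export
linear_fit <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations",
                          call. = FALSE)
  if (stats::var(x) == 0) stop("x has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       p = unname(sm$coefficients[2, 4]),
       n = length(x))
}

#' Congruency between two categorical labelings
#'
#' Quantifies how well one nominal variable predicts another with the
#' likelihood-ratio uncertainty coefficient
#' U(category | labels) = G2 / (2 N H(category)), where G2 is the
#' likelihood-ratio statistic of the contingency table and H the natural-log
#' entropy of the category margin (the "R-square (U)" convention of common
#' statistical software). The p-value is the chi-squared tail of G2.
#'
#' @param category Vector of outcome categories (e.g. treatment-association
#'   groups).
#' @param labels Vector of predictor labels (e.g. subnetwork ids).
#' @return List with `r2`, `g2`, `df`, `p`, `cramers_v`, `n`.
#' @export
congruency_r2 <- function(category, labels) {
  ok <- !is.na(category) & !is.na(labels)
  category <- factor(category[ok])
  labels <- factor(labels[ok])
  if (nlevels(category) < 2 || nlevels(labels) < 2) {
    stop("congruency undefined: a vector has fewer than 2 levels",
         call. = FALSE)
  }
  tab <- table(category, labels)
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  pos <- tab > 0
  g2 <- 2 * sum(tab[pos] * log(tab[pos] / expd[pos]))
  pc <- rowSums(tab) / n
  h <- -sum(pc * log(pc))
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  chi2 <- sum((tab - expd)^2 / expd)
  v <- sqrt(chi2 / (n * (min(dim(tab)) - 1)))
  list(r2 = g2 / (2 * n * h), g2 = g2, df = df,
       p = stats::pchisq(g2, df, lower.tail = FALSE),
       cramers_v = v, n = n)
}

# Evaluate an expression under a fixed seed without disturbing the caller's
# RNG stream.
with_preserved_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
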