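## Many-to-one (Dunnett) comparisons against a shared control.
##
## With a pooled variance estimate s^2 on `df` degrees of freedom, the
## statistics T_i = (m_i - m_0) / (s * sqrt(1/n_i + 1/n_0)) follow a
## multivariate t with product-form correlation rho_ij = b_i b_j,
## b_i = 1/sqrt(1 + n_0/n_i). Conditioning on the control mean and on the
## pooled SD makes the k events independent, so the max-T distribution
## reduces to a smooth two-dimensional integral evaluated here by
## Gauss-Legendre quadrature: deterministic, seed-free, and accurate in the
## far tails because the inner product of normal CDFs is accumulated in log
## space.

# Quadrature nodes for the conditioning variables: u ~ N(0,1) (scaled control
# mean) and s ~ sqrt(chisq_df / df) (scale factor of the pooled SD).
.dunnett_nodes <- function(df, n_u = 48, n_s = 48) {
  gu <- pracma::gaussLegendre(n_u, -8.5, 8.5)
  wu <- gu$w * stats::dnorm(gu$x)
  lo <- sqrt(stats::qchisq(1e-12, df) / df)
  hi <- sqrt(stats::qchisq(1e-12, df, lower.tail = FALSE) / df)
  gs <- pracma::gaussLegendre(n_s, lo, hi)
  ## density of S = sqrt(X/df), X ~ chisq_df
  log_fs <- (df / 2) * log(df / 2) - lgamma(df / 2) +
    (df - 1) * log(gs$x) - df * gs$x^2 / 2 + log(2)
  ws <- gs$w * exp(log_fs)
  grid <- expand.grid(u = gu$x, s = gs$x)
  list(u = grid$u, s = grid$s, w = rep(wu, times = n_s) * rep(ws, each = n_u))
}

# P(max_i T_i >= t) (one-sided) or P(max_i |T_i| >= t) (two-sided) for the
# many-to-one design; vectorized over t. n_treat is the vector of treatment
# group sizes (length k), n0 the control size.
.dunnett_tail_exact <- function(t, n_treat, n0, df,
                                sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  nodes <- .dunnett_nodes(df)
  b <- sqrt(n_treat / n0)
  cc <- sqrt(1 + n_treat / n0)
  out <- numeric(length(t))
  balanced <- length(unique(n_treat)) == 1L
  k <- length(n_treat)
  for (j in seq_along(t)) {
    tj <- t[j]
    if (sided == "greater") {
      if (balanced) {
        lp <- k * stats::pnorm(b[1] * nodes$u + cc[1] * nodes$s * tj,
                               log.p = TRUE)
      } else {
        lp <- 0
        for (i in seq_len(k)) {
          lp <- lp + stats::pnorm(b[i] * nodes$u + cc[i] * nodes$s * tj,
                                  log.p = TRUE)
        }
      }
    } else {
      tt <- abs(tj)
      term <- function(i) {
        d <- stats::pnorm(b[i] * nodes$u + cc[i] * nodes$s * tt) -
          stats::pnorm(b[i] * nodes$u - cc[i] * nodes$s * tt)
        log(pmax(d, 1e-320))
      }
      if (balanced) lp <- k * term(1) else {
        lp <- 0
        for (i in seq_len(k)) lp <- lp + term(i)
      }
    }
    out[j] <- sum(nodes$w * -expm1(lp))
  }
  pmin(pmax(out, 0), 1)
}

# Vectorized evaluation over many t sharing one design. For large vectors the
# tail is computed exactly on a dense grid and interpolated monotonically on
# the log scale; interpolation error is far below the quadrature's own ~1e-10.
.dunnett_tail <- function(t, n_treat, n0, df, sided = "greater") {
  if (length(t) <= 512) {
    return(.dunnett_tail_exact(t, n_treat, n0, df, sided))
  }
  rng <- range(t[is.finite(t)])
  knots <- seq(rng[1] - 1e-6, rng[2] + 1e-6, length.out = 513)
  pk <- .dunnett_tail_exact(knots, n_treat, n0, df, sided)
  lpk <- log(pmax(pk, 1e-320))
  f <- stats::splinefun(knots, lpk, method = "hyman")
  out <- exp(f(t))
  pmin(pmax(out, 0), 1)
}

#' Dunnett many-to-one comparisons against a control
#'
#' Compares each treatment group mean with a single shared control using the
#' pooled variance across all groups, adjusting the per-comparison p-values
#' for the family via the max-T distribution of the product-correlated
#' multivariate t. The distribution is evaluated by deterministic
#' two-dimensional Gauss quadrature (no simulation, no seed).
#'
#' @param control Numeric vector of control observations (>= 2).
#' @param treatments Named list of numeric vectors, one per treatment
#'   (each >= 2 observations).
#' @param sided `"greater"` tests treatment > control (the enrichment
#'   direction); `"two.sided"` tests any difference.
#' @return A data.frame with one row per comparison: `comparison`,
#'   `estimate` (mean difference), `t`, `p_raw` (unadjusted single-comparison
#'   t-test p), `p_adj` (family-adjusted). Attributes `df` (error degrees of
#'   freedom) and `mse` (pooled mean squared error).
#' @examples
#' dunnett_many_to_one(c(1, 2, 3), list(A = c(2, 3, 4), B = c(5, 6, 7)))
#' @export
dunnett_many_to_one <- function(control, treatments,
                                sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  if (!is.list(treatments)) treatments <- list(treatment = treatments)
  groups <- c(list(control), treatments)
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  k <- length(treatments)
  n0 <- sizes[1]
  n_treat <- sizes[-1]
  means <- vapply(groups, mean, numeric(1))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df <- sum(sizes) - length(groups)
  mse <- ss_within / df
  est <- means[-1] - means[1]
  se <- sqrt(mse * (1 / n_treat + 1 / n0))
  tstat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, sign(est) * Inf))
  if (mse == 0) {
    ## degenerate: no within-group variance anywhere
    p_raw <- ifelse(est == 0, 1, ifelse(sided == "greater" & est < 0, 1, 0))
    p_adj <- p_raw
  } else {
    p_raw <- if (sided == "greater") {
      stats::pt(tstat, df, lower.tail = FALSE)
    } else {
      2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    }
    p_adj <- .dunnett_tail(tstat, n_treat, n0, df, sided)
    ## numerical guard: family adjustment can never undercut the raw p
    p_adj <- pmax(p_adj, p_raw)
  }
  nm <- names(treatments)
  if (is.null(nm)) nm <- paste0("T", seq_len(k))
  res <- data.frame(comparison = nm, estimate = unname(est),
                    t = unname(tstat), p_raw = unname(p_raw),
                    p_adj = unname(p_adj), stringsAsFactors = FALSE)
  attr(res, "df") <- df
  attr(res, "mse") <- mse
  attr(res, "sided") <- sided
  res
}
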