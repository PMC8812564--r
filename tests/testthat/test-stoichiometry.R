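test_that("Hill-notation parsing handles CHNOPS, charge, and rejection", {
  f <- parse_formula("C6H12O6")
  expect_equal(unlist(f[c("C", "H", "N", "O", "P", "S")]),
               c(C = 6, H = 12, N = 0, O = 6, P = 0, S = 0))
  g <- parse_formula("C5H9NO4")
  expect_equal(g$N, 1L)
  expect_equal(g$O, 4L)
  ch <- parse_formula("C6H13NO2+")
  expect_equal(ch$charge, 1L)
  expect_equal(ch$O, 2L)
  expect_equal(parse_formula("C3H5O3-")$charge, -1L)
  expect_true(parse_formula("C6H5Br")$non_chnops)
  expect_error(parse_formula("6CH12"), "malformed")
})

test_that("the formula quality filter applies the four rules with strict bounds", {
  ann <- data.frame(
    feature_id = paste0("f", 1:4),
    C = 6, H = 12, N = 0, O = 6, P = 0, S = 0, charge = 0,
    non_chnops = FALSE, has_formula = TRUE,
    zodiac_score = c(0.99, 0.98, 0.999, 0.999),
    chimeric = c(FALSE, FALSE, TRUE, FALSE),
    tree_fragments_explained = c(5, 12, 12, 4),
    tree_intensity_explained = c(0.81, 0.95, 0.95, 0.95))
  kept <- suppressMessages(formula_quality_filter(ann))
  expect_identical(kept$feature_id, "f1")   # 0.98 and 4 sit on the boundary

  # pure predicate: order-independent and idempotent
  ann_rev <- ann[4:1, ]
  kept_rev <- suppressMessages(formula_quality_filter(ann_rev))
  expect_setequal(kept_rev$feature_id, kept$feature_id)
  expect_identical(suppressMessages(formula_quality_filter(kept)), kept)
})

test_that("NOSC reproduces the oxidation-state anchors", {
  expect_equal(nosc(parse_formula("C6H12O6")), 0)       # sugars
  expect_equal(nosc(data.frame(C = 1, H = 0, N = 0, O = 2, P = 0, S = 0)), 4)
  expect_equal(nosc(parse_formula("CH4")), -4)
  expect_error(nosc(data.frame(C = 0, H = 2, N = 0, O = 1, P = 0, S = 0)),
               "carbon")
})

test_that("NOSC stays within [-4, 4] for plausible CHNOPS formulas", {
  set.seed(31)
  for (tmpl in c("lipid_like", "sugar_like", "peptide_like", "P_rich",
                 "N_heterocycle")) {
    f <- generate_formula(tmpl, 500)
    v <- nosc(f)
    expect_true(all(v >= -4 & v <= 4), label = tmpl)
  }
})

test_that("Gibbs energy of oxidation decreases strictly with NOSC", {
  expect_equal(gibbs_cox(0), 60.3)
  expect_equal(gibbs_cox(-1.04), 89.94, tolerance = 1e-9)  # fleshy-algae range
  expect_equal(gibbs_cox(-0.77), 82.245, tolerance = 1e-9) # calcifier range
  v <- gibbs_cox(seq(-4, 4, by = 0.25))
  expect_true(all(diff(v) < 0))
})

test_that("carbon-weighted NOSC follows the abundance x carbon rule", {
  A <- matrix(c(10, 10), 2, 1, dimnames = list(c("m", "g"), "s1"))
  ft <- feature_table(A)
  forms <- data.frame(feature_id = c("m", "g"),
                      C = c(1, 6), H = c(4, 12), N = 0, O = c(0, 6),
                      P = 0, S = 0, charge = 0)
  res <- sample_weighted_nosc(ft, forms, "s1")
  expect_equal(res$nosc, -4 / 7, tolerance = 1e-12)  # weights 1:6 on -4 and 0

  single <- sample_weighted_nosc(ft, forms[1, ], "s1")
  expect_equal(single$nosc, -4)

  ft2 <- feature_table(A * 2)
  expect_equal(sample_weighted_nosc(ft2, forms, "s1")$nosc, res$nosc)
})

test_that("weighted means are convex combinations of member values", {
  set.seed(33)
  forms <- generate_formula("peptide_like", 20)
  forms$feature_id <- paste0("f", 1:20)
  A <- matrix(rlnorm(20 * 3, 12, 1), 20, 3,
              dimnames = list(forms$feature_id, c("s1", "s2", "s3")))
  ft <- feature_table(A)
  v <- nosc(forms)
  for (s in colnames(A)) {
    wn <- sample_weighted_nosc(ft, forms, s)$nosc
    expect_gte(wn, min(v))
    expect_lte(wn, max(v))
    st <- sample_stoichiometry(ft, forms, s)
    expect_gte(st$NC, min(forms$N / forms$C))
    expect_lte(st$NC, max(forms$N / forms$C))
    expect_equal(st$share_P + st$share_N_not_P + st$share_CHOS, 1,
                 tolerance = 1e-9)
  }
})

test_that("per-sample stoichiometry matches hand-computed ratios", {
  A <- matrix(c(5, 5), 2, 1, dimnames = list(c("a", "b"), "s1"))
  ft <- feature_table(A)
  forms <- data.frame(feature_id = c("a", "b"), C = 5, H = 10,
                      N = c(0, 1), O = 2, P = 0, S = 0, charge = 0)
  st <- sample_stoichiometry(ft, forms, "s1")
  expect_equal(st$frac_with_N, 0.5)
  expect_equal(st$NC, 0.1)     # mean of 0 and 1/5

  forms$P <- 1
  stp <- sample_stoichiometry(ft, forms, "s1")
  expect_equal(c(stp$share_P, stp$share_N_not_P, stp$share_CHOS), c(1, 0, 0))
})

test_that("feature-standardized weighting removes ionization scale", {
  set.seed(34)
  prof <- rlnorm(4, 13, 0.5)
  A <- rbind(f1 = prof, f2 = prof * 10, f3 = rev(prof))
  colnames(A) <- paste0("s", 1:4)
  forms <- data.frame(feature_id = c("f1", "f2", "f3"),
                      C = c(6, 10, 16), H = c(12, 16, 30),
                      N = c(0, 2, 0), O = c(6, 3, 2), P = 0, S = 0,
                      charge = 0)
  ft <- feature_table(A)
  zw <- feature_standardized_weighting(ft, forms, colnames(A))
  # scaling a feature tenfold changes nothing once z-scored
  Au <- rbind(f1 = prof, f2 = prof, f3 = rev(prof))
  colnames(Au) <- paste0("s", 1:4)
  zw2 <- feature_standardized_weighting(feature_table(Au), forms,
                                        colnames(Au))
  expect_equal(zw$nosc, zw2$nosc, tolerance = 1e-12)

  # identical z-profiles give equal weights, i.e. the unweighted mean
  Aeq <- rbind(f1 = prof, f2 = prof * 3, f3 = prof * 0.2)
  colnames(Aeq) <- paste0("s", 1:4)
  zeq <- feature_standardized_weighting(feature_table(Aeq), forms,
                                        colnames(Aeq))
  expect_equal(zeq$nosc, rep(mean(nosc(forms)), 4), tolerance = 1e-9)

  Ac <- Aeq; Ac["f3", ] <- 5
  expect_warning(feature_standardized_weighting(feature_table(Ac), forms,
                                                colnames(Ac)), "constant")
})

test_that("stoichiometry regression recovers exact proportionality", {
  st <- data.frame(sample_id = paste0("s", 1:6),
                   NC = seq(0.05, 0.3, length.out = 6),
                   PC = seq(0.01, 0.06, length.out = 6))
  bulk <- data.frame(sample_id = st$sample_id,
                     TDN = 5 + 40 * st$NC, TDP = 0.2 + 10 * st$PC)
  fits <- regress_stoichiometry_vs_bulk(st, bulk)
  expect_equal(fits$N$r2, 1, tolerance = 1e-12)
  expect_equal(fits$P$slope, 10, tolerance = 1e-9)
})
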