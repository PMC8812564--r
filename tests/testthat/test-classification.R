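md <- toy_metadata()

make_ft <- function(rows) {
  A <- do.call(rbind, rows)
  rownames(A) <- names(rows)
  colnames(A) <- md$sample_id
  feature_table(A)
}

# a row builder: named cell values on top of a flat base
row_with <- function(base, blanks = 0, cells = list()) {
  v <- rep(base, nrow(md))
  names(v) <- md$sample_id
  v[md$role == "blank"] <- blanks
  for (nm in names(cells)) {
    parts <- strsplit(nm, "\\.")[[1]]
    sel <- md$role == "experimental" & md$treatment == parts[1] &
      !is.na(md$diel) & md$diel == parts[2] & md$timepoint == "end"
    v[sel] <- cells[[nm]]
  }
  v
}

test_that("background rule is the twice-max-blank comparison", {
  ft <- make_ft(list(
    bg = row_with(100, blanks = 60),          # 100 < 2*60 -> background
    keep = row_with(100, blanks = 0),         # absent from blanks
    edge = row_with(120, blanks = 60)))       # 120 !< 120 -> retained
  bg <- suppressMessages(flag_background(ft, md))
  expect_identical(bg, "bg")
  expect_error(flag_background(ft, md[md$role != "blank", ]), "blank")
})

test_that("transient rule counts samples at or above threshold", {
  v2 <- rep(0, nrow(md)); v2[1:2] <- 2e5
  v3 <- rep(0, nrow(md)); v3[1:3] <- 2e5
  A <- rbind(two = v2, three = v3)
  colnames(A) <- md$sample_id
  ft <- feature_table(A)
  tr <- suppressMessages(flag_transient(ft, md))
  expect_identical(tr, "two")                  # "less than three" flags
})

test_that("exudate split applies the floored log2 ratio rule", {
  ft <- make_ft(list(
    exu = row_with(1e6, cells = list(Turf.Day = 2.5e6)),    # log2 = 1.32
    amb = row_with(1e6, cells = list(Turf.Day = 2.0e6)),    # log2 = 1, not >
    floored = row_with(0, cells = list(CCA.Night = 8e5))))  # 0 -> floor 1e5
  sp <- suppressMessages(split_ambient_exudate(ft, md))
  expect_setequal(sp$exudate, c("exu", "floored"))
  expect_setequal(sp$ambient, "amb")
  expect_equal(sp$log2_fold["floored", "CCA.Night"], log2(8e5 / 1e5))
})

test_that("subtype assignment follows the artifact > benthic > planktonic precedence", {
  ft <- make_ft(list(
    art = row_with(1e6, cells = list(Control.Day = 3e6, Control.Night = 3e6,
                                     Turf.Day = 4e6)),
    ben = row_with(1e6, cells = list(Turf.Day = 3e6)),
    pla = row_with(1e6, cells = list(Control.Day = 3e6))))
  sp <- suppressMessages(split_ambient_exudate(ft, md))
  sub <- classify_exudate_subtypes(sp$log2_fold, sp$exudate, character(0))
  expect_equal(unname(sub["art"]), "incubation_artifact")
  expect_equal(unname(sub["ben"]), "benthic_exudate")
  expect_equal(unname(sub["pla"]), "planktonic_exudate")
})

test_that("identical group means are never called exometabolites", {
  # every endpoint group holds the same three values: means identical,
  # within-group variance nonzero
  v <- rep(1e6, nrow(md))
  names(v) <- md$sample_id
  v[md$replicate == 2] <- 1.2e6
  v[md$replicate == 3] <- 0.8e6
  ft <- make_ft(list(flat = v, flat2 = v * 2))
  res <- suppressMessages(test_exometabolites(ft, md))
  expect_length(res$exometabolites, 0)
  expect_true(all(res$cells$t == 0))
  expect_true(all(res$cells$p_fdr >= res$cells$p_dunnett - 1e-12))
})

test_that("classification filters equal brute-force rule evaluation", {
  for (seed in 1:10) {
    ft <- random_feature_table(50, md, seed)
    expect_setequal(suppressMessages(flag_background(ft, md)),
                    oracle_background(ft, md))
    expect_setequal(suppressMessages(flag_transient(ft, md)),
                    oracle_transient(ft, md))
    sp <- suppressMessages(split_ambient_exudate(ft, md))
    or <- oracle_split(ft, md)
    expect_setequal(sp$exudate, or$exudate)
    sub <- classify_exudate_subtypes(sp$log2_fold, sp$exudate, character(0))
    orc <- oracle_subtypes(ft, md, or$exudate, character(0))
    expect_identical(sub[names(orc)], orc)
  }
})

test_that("thresholds act monotonically on the classified sets", {
  ft <- random_feature_table(60, md, 99)
  sp1 <- suppressMessages(split_ambient_exudate(ft, md, log2_threshold = 0.5))
  sp2 <- suppressMessages(split_ambient_exudate(ft, md, log2_threshold = 1))
  sp3 <- suppressMessages(split_ambient_exudate(ft, md, log2_threshold = 2))
  expect_true(all(sp2$exudate %in% sp1$exudate))
  expect_true(all(sp3$exudate %in% sp2$exudate))

  sim <- small_sim(4)
  r1 <- suppressMessages(test_exometabolites(sim$features, sim$metadata,
                                             alpha = 0.05))
  r2 <- suppressMessages(test_exometabolites(sim$features, sim$metadata,
                                             alpha = 0.01))
  expect_true(all(r2$exometabolites %in% r1$exometabolites))
})

test_that("the cascade conserves feature counts at every stage", {
  sim <- small_sim(5)
  cls <- suppressMessages(classify_features(sim$features, sim$metadata))
  counts <- cls$counts
  expect_equal(sum(counts), nrow(sim$features$areas))
  n_exudate <- sum(counts[c("exometabolite", "benthic_exudate",
                            "planktonic_exudate", "incubation_artifact")])
  expect_equal(unname(n_exudate + counts[["ambient"]] +
                        counts[["background"]] + counts[["transient"]]),
               nrow(sim$features$areas))
})

test_that("class peak-area shares sum to one including artifacts", {
  sim <- small_sim(6)
  cls <- suppressMessages(classify_features(sim$features, sim$metadata))
  shares <- class_peak_area_summary(sim$features, cls, sim$metadata)
  cls_cols <- setdiff(names(shares), "sample_id")
  expect_equal(unname(rowSums(shares[cls_cols])), rep(1, nrow(shares)),
               tolerance = 1e-9)
  no_artifact <- setdiff(cls_cols, "incubation_artifact")
  expect_true(all(rowSums(shares[no_artifact]) <= 1 + 1e-12))
})

test_that("treatment-association categories are assembled from significant cells", {
  cells <- data.frame(
    feature_id = c("f1", "f2", "f2", "f3", "f3"),
    treatment = c("Pocillopora", "Turf", "Turf", "CCA", "Dictyota"),
    diel = c("Day", "Day", "Night", "Day", "Day"),
    significant = TRUE, stringsAsFactors = FALSE)
  cats <- treatment_association_categories(list(cells = cells))
  expect_equal(cats$category[cats$feature_id == "f1"], "Pocillopora|day-only")
  expect_equal(cats$category[cats$feature_id == "f2"], "Turf|both")
  expect_equal(cats$category[cats$feature_id == "f3"], "CCA+Dictyota|day-only")
  expect_equal(cats$n_producers, c(1L, 1L, 2L))
})
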