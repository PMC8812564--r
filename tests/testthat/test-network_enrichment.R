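sim <- small_sim(21)
cls <- suppressMessages(classify_features(sim$features, sim$metadata))
common <- cls$labels$feature_id[!cls$labels$class %in%
                                  c("background", "transient")]
ft_common <- subset_features(
  sim$features, features = common,
  samples = sim$metadata$sample_id[sim$metadata$role == "experimental"])
nets <- aggregate_subnetworks(ft_common, sim$annotations, cls, sim$metadata)

test_that("subnetwork aggregation equals brute-force member sums", {
  rel <- relative_abundance(ft_common)$areas
  ann <- sim$annotations
  for (k in sample(rownames(nets$abundance), 5)) {
    mem <- ann$feature_id[!is.na(ann$subnetwork_id) &
                            ann$subnetwork_id == as.integer(k) &
                            ann$feature_id %in% rownames(rel)]
    for (s in sample(colnames(rel), 3)) {
      ref <- 0
      for (f in mem) ref <- ref + rel[f, s]
      expect_equal(nets$abundance[k, s], ref, tolerance = 1e-12)
    }
  }
  expect_true(all(nets$info$n_exudate_nodes <= nets$info$n_members))
})

test_that("subnetworks plus singletons conserve total relative abundance", {
  rel <- relative_abundance(ft_common)$areas
  ann <- sim$annotations
  singleton <- setdiff(rownames(rel),
                       ann$feature_id[!is.na(ann$subnetwork_id)])
  tot <- colSums(nets$abundance) + colSums(rel[singleton, , drop = FALSE])
  expect_equal(unname(tot), rep(1, ncol(rel)), tolerance = 1e-9)
})

test_that("enrichment is the conjunction of significance and fold change", {
  enr <- test_subnetwork_enrichment(nets, sim$metadata)
  expect_true(all(enr$enriched == (enr$p_fdr < 0.05 & enr$fold_change >= 2)))
  # planted producer-specific subnetworks surface as enriched
  expect_gt(sum(enr$enriched), 0)
  truth_exo <- sim$truth[sim$truth$planted_class == "exometabolite", ]
  planted_sn <- unique(truth_exo$subnetwork_id)
  expect_gt(mean(unique(enr$subnetwork_id[enr$enriched]) %in% planted_sn),
            0.8)
})

test_that("focus selection applies the three predicates with strict bounds", {
  info <- data.frame(subnetwork_id = 1:3, n_members = c(10, 10, 10),
                     n_exudate_nodes = c(7, 5, 7),
                     n_exometabolite_nodes = c(7, 5, 7),
                     consensus_class = "x")
  samps <- endpoint_samples(toy_metadata(), diel = "Day")
  ab <- matrix(0.0006, 3, length(samps),
               dimnames = list(1:3, samps))
  ab[3, ] <- 0.0004                        # fails the 0.05% rule
  fake <- list(abundance = ab, info = info,
               members = list(`1` = "a", `2` = "b", `3` = "c"))
  enr <- data.frame(subnetwork_id = c(1, 2, 3), treatment = "Turf",
                    diel = "Day", fold_change = 3, t = 5,
                    p_dunnett = 0.001, p_fdr = 0.005, enriched = TRUE)
  sel <- suppressMessages(select_focus_subnetworks(fake, enr, toy_metadata()))
  expect_identical(sel, 1L)   # 2 fails "> 5 nodes", 3 fails abundance

  # tightening any predicate never grows the set
  sel_tight <- suppressMessages(select_focus_subnetworks(
    fake, enr, toy_metadata(), min_share = 1e-3, alpha = 0.001))
  expect_true(all(sel_tight %in% sel))
})

test_that("focus subnetworks are a subset of enriched ones", {
  enr <- test_subnetwork_enrichment(nets, sim$metadata)
  focus <- suppressMessages(select_focus_subnetworks(nets, enr,
                                                     sim$metadata))
  enriched_day <- unique(enr$subnetwork_id[enr$diel == "Day" &
                                             enr$p_fdr < 0.01 &
                                             enr$fold_change >= 2])
  expect_true(all(focus %in% enriched_day))
})

test_that("feature-level and subnetwork-level enrichment agree on singleton subnetworks", {
  md <- toy_metadata()
  set.seed(77)
  base <- rlnorm(nrow(md), log(1e6), 0.2)
  names(base) <- md$sample_id
  hot <- base
  hot[md$treatment %in% "Turf" & md$timepoint %in% "end"] <- 2e7
  A <- rbind(hot = hot, flat = base,
             pad1 = rlnorm(nrow(md), log(8e5), 0.2),
             pad2 = rlnorm(nrow(md), log(8e5), 0.2))
  colnames(A) <- md$sample_id
  ft <- feature_table(A)
  cls1 <- suppressMessages(classify_features(ft, md))
  ann <- data.frame(feature_id = rownames(A),
                    subnetwork_id = c(1L, 2L, NA, NA),
                    structural_class = NA, stringsAsFactors = FALSE)
  ftx <- subset_features(ft, samples = md$sample_id[md$role == "experimental"])
  nets1 <- aggregate_subnetworks(ftx, ann, cls1, md)
  enr1 <- test_subnetwork_enrichment(nets1, md)
  sn_hot <- enr1$enriched[enr1$subnetwork_id == 1 & enr1$treatment == "Turf"]
  expect_true(any(sn_hot))
  expect_true("hot" %in% cls1$cells$feature_id[cls1$cells$significant])
  expect_false(any(enr1$enriched[enr1$subnetwork_id == 2]))
})

test_that("heatmap rows are standardized within daytime samples", {
  enr <- test_subnetwork_enrichment(nets, sim$metadata)
  focus <- suppressMessages(select_focus_subnetworks(nets, enr,
                                                     sim$metadata))
  skip_if(length(focus) == 0, "no focus subnetworks in this small world")
  H <- heatmap_matrix(focus, nets, ft_common, sim$metadata)
  expect_equal(unname(rowMeans(H)), rep(0, nrow(H)), tolerance = 1e-9)
  expect_equal(unname(apply(H, 1, sd)), rep(1, nrow(H)), tolerance = 1e-9)
  expect_equal(length(attr(H, "subnetwork_id")), nrow(H))
})

test_that("subnetwork identity is more congruent with producers than class labels", {
  congr <- subnetwork_class_congruency(cls, sim$annotations)
  r2 <- setNames(congr$r2, congr$label_set)
  expect_gt(r2[["subnetwork"]], r2[["structural_class"]])
})

test_that("permuted subnetwork ids destroy congruency at large n", {
  set.seed(5)
  n <- 600
  producers <- sample(c("Porites", "Pocillopora", "CCA", "Dictyota", "Turf"),
                      n, replace = TRUE)
  cells <- data.frame(feature_id = sprintf("c%03d", seq_len(n)),
                      treatment = producers, diel = "Day",
                      significant = TRUE, stringsAsFactors = FALSE)
  # subnetworks nested within producers (three per producer)
  sn <- as.integer(factor(producers)) * 10L + sample.int(3, n, TRUE)
  ann <- data.frame(feature_id = cells$feature_id, subnetwork_id = sn,
                    structural_class = sample(letters[1:5], n, TRUE),
                    library_match = NA, stringsAsFactors = FALSE)
  congr <- suppressWarnings(
    subnetwork_class_congruency(list(cells = cells), ann))
  expect_gt(congr$r2[congr$label_set == "subnetwork"], 0.9)
  ann$subnetwork_id <- sample(ann$subnetwork_id)
  congr_perm <- suppressWarnings(
    subnetwork_class_congruency(list(cells = cells), ann))
  expect_lt(congr_perm$r2[congr_perm$label_set == "subnetwork"], 0.05)
})
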