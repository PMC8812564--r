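#' Ordination and PERMANOVA of exometabolite composition
#'
#' Relative abundances of the exometabolite features in each experimental
#' sample are angular transformed and z-scored per feature, ordinated by
#' principal coordinates on Euclidean distances (equivalently, PCA of the
#' transformed matrix), and partitioned by treatment, diel and their
#' interaction with PERMANOVA.
#'
#' @param ft [feature_table()] of retained common features.
#' @param metadata Sample metadata.
#' @param classification A [classify_features()] result.
#' @param n_perm PERMANOVA permutations (default 999).
#' @param seed Permutation seed.
#' @return List with `pcoa` (points, eigenvalues), `permanova`
#'   (per-term table), `pairwise` (pairwise treatment contrasts), and
#'   `distance` (the distance matrix).
#' @export
exometabolome_ordination <- function(ft, metadata, classification,
                                     n_perm = 999, seed = 1) {
  lab <- classification$labels
  exo <- lab$feature_id[lab$class == "exometabolite"]
  if (length(exo) < 2) {
    stop("too few exometabolite features for ordination", call. = FALSE)
  }
  samps <- intersect(experimental_samples(metadata), sample_ids(ft))
  rel <- relative_abundance(subset_features(ft, samples = samps))$areas
  Z <- angular_zscore_transform(rel[exo, , drop = FALSE])
  D <- as.matrix(stats::dist(t(Z)))
  md <- metadata[match(colnames(D), metadata$sample_id), ]
  perm <- permanova(D, md, n_perm = n_perm, seed = seed)
  pair <- permanova_pairwise(D, md$treatment, n_perm = n_perm, seed = seed)
  list(pcoa = pcoa(D), permanova = perm, pairwise = pair, distance = D)
}

#' Run the full exometabolome analysis pipeline
#'
#' Executes the stages in cascade order on supplied inputs (or on a
#' freshly simulated experiment): feature classification, class peak-area
#' summaries, treatment-association categories, ordination + PERMANOVA,
#' energetics and stoichiometry of producer exometabolomes, subnetwork
#' aggregation/enrichment/selection/congruency, and bulk-chemistry
#' couplings. All thresholds default to the study's conventions and are
#' recorded in the run manifest.
#'
#' @param inputs Either a list with `features`, `metadata`, `annotations`,
#'   `bulk` (e.g. from [generate_experiment()]), or NULL to simulate.
#' @param sim Optional [sim_config()] used when `inputs` is NULL.
#' @param alpha Exometabolite significance level.
#' @param log2_threshold Exudate split threshold.
#' @param transient_threshold Transient peak-area threshold.
#' @param noise_floor Noise floor for fold-change means.
#' @param focus_alpha Focus-subnetwork enrichment threshold (default 0.01).
#' @param n_perm PERMANOVA permutations.
#' @param seed Seed for permutation tests (and simulation if `sim` given
#'   without one).
#' @param outdir Optional directory; when given, all stage tables and the
#'   manifest (JSON) are written there.
#' @return List with all stage outputs plus `manifest`.
#' @export
run_pipeline <- function(inputs = NULL, sim = NULL, alpha = 0.05,
                         log2_threshold = 1, transient_threshold = 2e5,
                         noise_floor = 1e5, focus_alpha = 0.01,
                         n_perm = 999, seed = 1, outdir = NULL) {
  if (is.null(inputs)) {
    if (is.null(sim)) sim <- sim_config(seed = seed)
    inputs <- generate_experiment(sim)
  }
  for (nm in c("features", "metadata", "annotations", "bulk")) {
    if (is.null(inputs[[nm]])) stop("missing input: ", nm, call. = FALSE)
  }
  ft <- inputs$features
  md <- inputs$metadata
  ann <- inputs$annotations

  cls <- classify_features(ft, md, alpha = alpha,
                           log2_threshold = log2_threshold,
                           transient_threshold = transient_threshold,
                           noise_floor = noise_floor)
  shares <- class_peak_area_summary(ft, cls, md)
  cats <- treatment_association_categories(cls)

  common <- cls$labels$feature_id[!cls$labels$class %in%
                                    c("background", "transient")]
  ft_common <- subset_features(ft, features = common,
                               samples = intersect(experimental_samples(md),
                                                   sample_ids(ft)))
  ord <- if (sum(cls$labels$class == "exometabolite") >= 2) {
    exometabolome_ordination(ft_common, md, cls, n_perm = n_perm,
                             seed = seed)
  } else NULL

  qf <- formula_quality_filter(ann)
  stoich <- exometabolome_stoichiometry(ft_common, md, cls, qf, diel = "Day")
  stoich_fit <- if (!is.null(stoich) && nrow(stoich) >= 3) {
    regress_stoichiometry_vs_bulk(stoich, inputs$bulk)
  } else NULL

  nets <- aggregate_subnetworks(ft_common, ann, cls, md)
  enr <- test_subnetwork_enrichment(nets, md, alpha = alpha)
  focus <- select_focus_subnetworks(nets, enr, md, alpha = focus_alpha)
  congr <- tryCatch(subnetwork_class_congruency(cls, ann),
                    error = function(e) NULL)
  heat <- if (length(focus)) heatmap_matrix(focus, nets, ft_common, md)
          else NULL

  analytes <- intersect(c("DO", "pH", "DOC", "PO4", "NO3NO2", "NH4",
                          "silicate", "TDN", "TDP", "DON", "DOP"),
                        names(inputs$bulk))
  bulk_tests <- producer_effect_tests(inputs$bulk, md, analytes)
  doc_fit <- doc_metabolome_coupling(ft, cls, inputs$bulk, md)

  manifest <- list(
    package_version = as.character(utils::packageVersion("reefexo")),
    seed = seed,
    thresholds = list(alpha = alpha, log2_threshold = log2_threshold,
                      transient_threshold = transient_threshold,
                      noise_floor = noise_floor, focus_alpha = focus_alpha,
                      n_perm = n_perm),
    counts = c(list(n_features = nrow(ft$areas),
                    n_samples = ncol(ft$areas)),
               as.list(cls$counts),
               list(n_exometabolite_cells = sum(cls$cells$significant),
                    n_subnetworks = nrow(nets$info),
                    n_enriched_subnetworks =
                      length(unique(enr$subnetwork_id[enr$enriched])),
                    n_focus_subnetworks = length(focus))))

  out <- list(inputs = inputs, classification = cls, class_shares = shares,
              categories = cats, ordination = ord, stoichiometry = stoich,
              stoichiometry_fits = stoich_fit, subnetworks = nets,
              enrichment = enr, focus = focus, congruency = congr,
              heatmap = heat, bulk_tests = bulk_tests,
              doc_coupling = doc_fit, manifest = manifest)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(cls$labels, file.path(outdir, "feature_classification.tsv"))
    write_tsv(cls$cells, file.path(outdir, "exometabolite_cells.tsv"))
    write_tsv(shares, file.path(outdir, "class_summary.tsv"))
    if (nrow(cats)) write_tsv(cats, file.path(outdir, "categories.tsv"))
    if (!is.null(ord)) {
      write_tsv(ord$permanova, file.path(outdir, "permanova.tsv"))
      write_tsv(ord$pairwise, file.path(outdir, "permanova_pairwise.tsv"))
    }
    if (!is.null(stoich)) {
      write_tsv(stoich, file.path(outdir, "sample_stoichiometry.tsv"))
    }
    write_tsv(enr, file.path(outdir, "subnetwork_enrichment.tsv"))
    if (!is.null(congr)) {
      write_tsv(congr, file.path(outdir, "congruency.tsv"))
    }
    write_tsv(bulk_tests$anova, file.path(outdir, "bulk_effects.tsv"))
    write_tsv(doc_fit, file.path(outdir, "doc_coupling.tsv"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
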