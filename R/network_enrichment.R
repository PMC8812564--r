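#' Aggregate features into molecular subnetworks
#'
#' Sums per-sample relative abundances of each subnetwork's member features
#' (singletons, i.e. features without a subnetwork id, are excluded) and
#' counts its exudate-class nodes from the classification.
#'
#' @param ft The full [feature_table()] of retained common features
#'   (relative abundances are computed over all of them).
#' @param annotations Annotation data.frame with `subnetwork_id`.
#' @param classification A [classify_features()] result.
#' @param metadata Sample metadata.
#' @return List with `abundance` (subnetworks x experimental-samples matrix
#'   of summed relative abundance), `members` (list of feature-id vectors),
#'   `info` (data.frame: subnetwork_id, n_members, n_exudate_nodes,
#'   n_exometabolite_nodes, consensus_class).
#' @export
aggregate_subnetworks <- function(ft, annotations, classification, metadata) {
  samps <- intersect(experimental_samples(metadata), sample_ids(ft))
  rel <- relative_abundance(subset_features(ft, samples = samps))$areas
  ann <- annotations[!is.na(annotations$subnetwork_id) &
                       annotations$feature_id %in% feature_ids(ft), ]
  if (!nrow(ann)) stop("no subnetwork ids present", call. = FALSE)
  lab <- classification$labels
  exu_classes <- c("exometabolite", "benthic_exudate", "planktonic_exudate")
  ids <- sort(unique(ann$subnetwork_id))
  members <- lapply(ids, function(k) ann$feature_id[ann$subnetwork_id == k])
  names(members) <- as.character(ids)
  ab <- t(vapply(members, function(m) {
    colSums(rel[m, , drop = FALSE])
  }, numeric(ncol(rel))))
  rownames(ab) <- as.character(ids)
  info <- do.call(rbind, lapply(seq_along(ids), function(j) {
    m <- members[[j]]
    cls <- lab$class[match(m, lab$feature_id)]
    sc <- ann$structural_class[match(m, ann$feature_id)]
    sc <- sc[!is.na(sc)]
    consensus <- if (length(sc)) {
      tab <- sort(table(sc), decreasing = TRUE)
      if (length(tab) > 1 && tab[1] == tab[2]) "unclassified" else names(tab)[1]
    } else "unclassified"
    data.frame(subnetwork_id = ids[j], n_members = length(m),
               n_exudate_nodes = sum(cls %in% exu_classes),
               n_exometabolite_nodes = sum(cls == "exometabolite"),
               consensus_class = consensus, stringsAsFactors = FALSE)
  }))
  list(abundance = ab, members = members, info = info)
}

#' Test subnetworks for producer enrichment
#'
#' Per subnetwork and diel period, Dunnett many-to-one comparisons of summed
#' relative abundance in each producer endpoint group against the Control,
#' with BH FDR across the pooled subnetwork x producer x diel family. A
#' subnetwork is enriched in a cell if the adjusted p is below `alpha` and
#' its fold change over the Control is at least `min_fold`.
#'
#' @param subnetworks Output of [aggregate_subnetworks()].
#' @param metadata Sample metadata.
#' @param alpha Significance level (default 0.05).
#' @param min_fold Minimum fold change vs Control (default 2).
#' @param diel Diel periods to test (default both).
#' @return Data.frame: `subnetwork_id`, `treatment`, `diel`, `fold_change`,
#'   `t`, `p_dunnett`, `p_fdr`, `enriched`.
#' @export
test_subnetwork_enrichment <- function(subnetworks, metadata, alpha = 0.05,
                                       min_fold = 2, diel = REEFEXO_DIEL) {
  ab <- subnetworks$abundance
  out <- list()
  for (d in diel) {
    groups <- c("Control", REEFEXO_PRODUCERS)
    samp_by_group <- lapply(groups, function(tr) {
      intersect(endpoint_samples(metadata, tr, d), colnames(ab))
    })
    names(samp_by_group) <- groups
    sizes <- lengths(samp_by_group)
    if (any(sizes < 2)) {
      stop("each endpoint group needs >= 2 replicates (", d, ")",
           call. = FALSE)
    }
    samps <- unlist(samp_by_group, use.names = FALSE)
    g <- factor(rep(groups, sizes), levels = groups)
    av <- .anova_matrix(ab[, samps, drop = FALSE], g)
    n0 <- sizes["Control"]
    df <- length(samps) - length(groups)
    m_ctrl <- av$means[, "Control"]
    for (tr in REEFEXO_PRODUCERS) {
      est <- av$means[, tr] - m_ctrl
      se <- sqrt(av$mse * (1 / sizes[tr] + 1 / n0))
      tstat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, sign(est) * Inf))
      tstat[av$degenerate] <- 0
      fold <- av$means[, tr] / pmax(m_ctrl, .Machine$double.xmin)
      out[[paste(d, tr)]] <- data.frame(
        subnetwork_id = as.integer(rownames(ab)), treatment = tr, diel = d,
        fold_change = unname(fold), t = unname(tstat),
        n_treat = unname(sizes[tr]), n0 = unname(n0), df = df,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$p_dunnett <- NA_real_
  for (d in diel) {
    sel <- res$diel == d
    res$p_dunnett[sel] <- .dunnett_adjust_vector(
      res$t[sel], n_treat = unique(res$n_treat[sel]), n0 = res$n0[sel][1],
      df = res$df[sel][1], sided = "greater")
  }
  res$p_fdr <- bh_fdr(res$p_dunnett)
  res$enriched <- res$p_fdr < alpha & res$fold_change >= min_fold
  res[c("subnetwork_id", "treatment", "diel", "fold_change", "t",
        "p_dunnett", "p_fdr", "enriched")]
}

#' Select focus subnetworks for presentation
#'
#' A subnetwork is selected if it is abundant (maximum per-producer mean
#' summed relative abundance above `min_share`, i.e. 0.05% of at least one
#' exometabolome), diverse (strictly more than `min_exudate_nodes` exudate
#' nodes), and significantly enriched (fold change at least `min_fold` with
#' Dunnett FDR p below `alpha` in at least one producer cell).
#'
#' @param subnetworks Output of [aggregate_subnetworks()].
#' @param enrichment Output of [test_subnetwork_enrichment()].
#' @param metadata Sample metadata.
#' @param min_share Abundance threshold (default `5e-4`).
#' @param min_exudate_nodes Diversity threshold (default 5, exclusive).
#' @param alpha Enrichment significance threshold (default 0.01).
#' @param min_fold Enrichment fold threshold (default 2).
#' @param diel Diel period(s) over which producer means are taken for the
#'   abundance rule (default `"Day"`).
#' @return Integer vector of selected subnetwork ids; per-predicate pass
#'   counts are reported via `message()`.
#' @export
select_focus_subnetworks <- function(subnetworks, enrichment, metadata,
                                     min_share = 5e-4, min_exudate_nodes = 5,
                                     alpha = 0.01, min_fold = 2,
                                     diel = "Day") {
  ab <- subnetworks$abundance
  ids <- as.integer(rownames(ab))
  prod_mean <- vapply(REEFEXO_PRODUCERS, function(tr) {
    s <- intersect(endpoint_samples(metadata, tr, diel), colnames(ab))
    rowMeans(ab[, s, drop = FALSE])
  }, numeric(nrow(ab)))
  abundant <- apply(prod_mean, 1, max) > min_share
  diverse <- subnetworks$info$n_exudate_nodes[
    match(ids, subnetworks$info$subnetwork_id)] > min_exudate_nodes
  enr <- enrichment[enrichment$diel %in% diel, ]
  sig_ids <- unique(enr$subnetwork_id[enr$p_fdr < alpha &
                                        enr$fold_change >= min_fold])
  enriched <- ids %in% sig_ids
  message(sprintf(
    "focus selection: %d abundant, %d diverse, %d enriched, %d selected",
    sum(abundant), sum(diverse), sum(enriched),
    sum(abundant & diverse & enriched)))
  ids[abundant & diverse & enriched]
}

#' Congruency of label sets with treatment-association categories
#'
#' For each available label set (subnetwork id, structural class, library
#' match) computes the likelihood-ratio uncertainty coefficient between
#' the exometabolite features' treatment-association categories and their
#' labels (see [congruency_r2()]). Label sets with fewer than two levels are
#' skipped with a warning.
#'
#' @param classification A [classify_features()] result.
#' @param annotations Annotation data.frame.
#' @return Data.frame: `label_set`, `r2`, `g2`, `df`, `p`, `n_labeled`.
#' @export
subnetwork_class_congruency <- function(classification, annotations) {
  cats <- treatment_association_categories(classification)
  label_sets <- list(
    subnetwork = annotations$subnetwork_id,
    structural_class = annotations$structural_class,
    library_match = annotations$library_match)
  rows <- list()
  for (nm in names(label_sets)) {
    lab <- label_sets[[nm]][match(cats$feature_id, annotations$feature_id)]
    ok <- !is.na(lab)
    if (length(unique(lab[ok])) < 2 || length(unique(cats$category[ok])) < 2) {
      warning("label set '", nm, "' skipped: fewer than 2 levels")
      next
    }
    cr <- congruency_r2(cats$category[ok], lab[ok])
    rows[[nm]] <- data.frame(label_set = nm, r2 = cr$r2, g2 = cr$g2,
                             df = cr$df, p = cr$p, n_labeled = cr$n,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standardized heatmap matrix of focus-subnetwork features
#'
#' Per-feature z-scored relative abundance of the focus subnetworks'
#' members across daytime endpoint samples, rows grouped by subnetwork.
#'
#' @param focus_ids Subnetwork ids from [select_focus_subnetworks()].
#' @param subnetworks Output of [aggregate_subnetworks()].
#' @param ft The [feature_table()] used for aggregation.
#' @param metadata Sample metadata.
#' @param diel Diel period (default `"Day"`).
#' @return Numeric matrix (features x samples) with attribute
#'   `subnetwork_id` giving each row's subnetwork.
#' @export
heatmap_matrix <- function(focus_ids, subnetworks, ft, metadata,
                           diel = "Day") {
  samps <- intersect(endpoint_samples(metadata, diel = diel), sample_ids(ft))
  rel <- relative_abundance(ft)$areas[, samps, drop = FALSE]
  feats <- unlist(subnetworks$members[as.character(focus_ids)],
                  use.names = FALSE)
  sn <- rep(focus_ids, lengths(subnetworks$members[as.character(focus_ids)]))
  X <- rel[feats, , drop = FALSE]
  mu <- rowMeans(X)
  sdv <- apply(X, 1, stats::sd)
  const <- sdv == 0
  if (any(const)) {
    warning(sum(const), " constant feature(s) mapped to zero rows")
    sdv[const] <- 1
  }
  Z <- sweep(sweep(X, 1, mu, "-"), 1, sdv, "/")
  Z[const, ] <- 0
  attr(Z, "subnetwork_id") <- sn
  Z
}
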