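#' Flag background (blank-derived) features
#'
#' A feature is background if its mean peak area across the non-blank sample
#' universe is less than twice its maximum peak area across all blanks.
#'
#' @param ft A [feature_table()] containing blank and experimental samples.
#' @param metadata Sample metadata.
#' @param universe Optional character vector of sample ids over which the
#'   mean is computed (default: all non-blank samples present in `ft`); the
#'   original batch used all field and mesocosm samples.
#' @return Character vector of background feature ids.
#' @export
flag_background <- function(ft, metadata, universe = NULL) {
  blanks <- intersect(blank_samples(metadata), sample_ids(ft))
  if (!length(blanks)) {
    stop("background filter undefined: no blank samples", call. = FALSE)
  }
  if (is.null(universe)) {
    universe <- setdiff(sample_ids(ft), blanks)
  }
  mean_smp <- rowMeans(ft$areas[, universe, drop = FALSE])
  max_blk <- apply(ft$areas[, blanks, drop = FALSE], 1, max)
  bg <- feature_ids(ft)[mean_smp < 2 * max_blk]
  message(length(bg), " background feature(s) flagged")
  bg
}

#' Flag transient (unreplicated) features
#'
#' A feature is transient if it reaches the threshold peak area in fewer
#' than `min_samples` of the experiment's (non-blank) samples. The default
#' threshold is twice the instrument noise threshold.
#'
#' @param ft A [feature_table()].
#' @param metadata Sample metadata.
#' @param threshold Peak-area threshold (default `2e5`).
#' @param min_samples Minimum number of samples at or above the threshold to
#'   be retained (default 3; "fewer than three" flags).
#' @return Character vector of transient feature ids.
#' @export
flag_transient <- function(ft, metadata, threshold = 2e5, min_samples = 3) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  smp <- intersect(experimental_samples(metadata), sample_ids(ft))
  counts <- rowSums(ft$areas[, smp, drop = FALSE] >= threshold)
  tr <- feature_ids(ft)[counts < min_samples]
  message(length(tr), " transient feature(s) flagged")
  tr
}

# log2 fold-change matrix of endpoint-cell means vs the pooled ambient-start
# mean, with means floored at the noise threshold so zero means give finite,
# conservative ratios. Columns are "<treatment>.<diel>" endpoint cells.
.log2_fold_matrix <- function(ft, metadata, floor = 1e5) {
  amb <- intersect(ambient_samples(metadata), sample_ids(ft))
  if (!length(amb)) stop("no ambient (starting water) samples", call. = FALSE)
  amb_mean <- pmax(rowMeans(ft$areas[, amb, drop = FALSE]), floor)
  cells <- expand.grid(treatment = c("Control", REEFEXO_PRODUCERS),
                       diel = REEFEXO_DIEL, stringsAsFactors = FALSE)
  cols <- lapply(seq_len(nrow(cells)), function(j) {
    s <- intersect(endpoint_samples(metadata, cells$treatment[j],
                                    cells$diel[j]), sample_ids(ft))
    if (!length(s)) return(NULL)
    log2(pmax(rowMeans(ft$areas[, s, drop = FALSE]), floor) / amb_mean)
  })
  keep <- !vapply(cols, is.null, logical(1))
  out <- do.call(cbind, cols[keep])
  colnames(out) <- paste(cells$treatment, cells$diel, sep = ".")[keep]
  rownames(out) <- feature_ids(ft)
  out
}

#' Split features into ambient and exudate sets
#'
#' A feature is an exudate if the log2 ratio of its mean endpoint peak area
#' in any incubation treatment (Controls included) to its mean
#' ambient-start peak area exceeds `log2_threshold`; otherwise it is
#' ambient DOM. Means are floored at the noise threshold before the ratio.
#'
#' @param ft A [feature_table()] of retained (non-background, non-transient)
#'   features.
#' @param metadata Sample metadata.
#' @param log2_threshold Fold-change threshold on the log2 scale (default 1,
#'   i.e. twofold).
#' @param floor Noise floor for means (default `1e5`).
#' @return List with `exudate`, `ambient` (feature id vectors) and
#'   `log2_fold` (features x endpoint-cells matrix).
#' @export
split_ambient_exudate <- function(ft, metadata, log2_threshold = 1,
                                  floor = 1e5) {
  lf <- .log2_fold_matrix(ft, metadata, floor)
  mx <- apply(lf, 1, max)
  exu <- feature_ids(ft)[mx > log2_threshold]
  amb <- setdiff(feature_ids(ft), exu)
  message(length(exu), " exudate / ", length(amb), " ambient feature(s)")
  list(exudate = exu, ambient = amb, log2_fold = lf)
}

# Dispatch a vector of Dunnett t statistics sharing one design to the max-T
# tail, handling non-finite entries from degenerate variance rows.
.dunnett_adjust_vector <- function(tstat, n_treat, n0, df, sided) {
  p <- rep(NA_real_, length(tstat))
  fin <- is.finite(tstat)
  if (any(fin)) p[fin] <- .dunnett_tail(tstat[fin], n_treat, n0, df, sided)
  p[!fin & tstat > 0] <- 0
  p[!fin & !(tstat > 0)] <- 1
  p
}

#' Test exudate features for exometabolite status
#'
#' Per diel period, the six endpoint groups (Control plus five producers)
#' are compared by one-way ANOVA on each feature, and each producer is
#' compared with the Control by a one-sided (enrichment) Dunnett many-to-one
#' test. The Dunnett-adjusted p-values are then corrected by
#' Benjamini-Hochberg across the pooled family of all features, producers
#' and diel periods; a feature is an exometabolite if at least one adjusted
#' p falls below `alpha`, and its significant (treatment, diel) cells are
#' recorded.
#'
#' @param ft A [feature_table()] of the retained common features (used to
#'   compute relative abundances).
#' @param metadata Sample metadata.
#' @param features Feature ids to test (the exudate set); default all.
#' @param alpha Significance level (default 0.05).
#' @param sided `"greater"` (default: enrichment over Control) or
#'   `"two.sided"`.
#' @param fdr_family `"pooled"` (default; one BH family across features x
#'   producers x diel) or `"per_diel"`.
#' @param on `"raw"` (default) tests the peak areas whose fold changes
#'   define the exudate classes; `"relative"` tests per-sample relative
#'   abundances (computed over all features of `ft`), which couples features
#'   compositionally.
#' @return List with `cells` (data.frame: feature_id, treatment, diel,
#'   estimate, t, p_dunnett, p_fdr, significant), `anova` (per feature x
#'   diel F and p), and `exometabolites` (feature ids).
#' @export
test_exometabolites <- function(ft, metadata, features = NULL, alpha = 0.05,
                                sided = c("greater", "two.sided"),
                                fdr_family = c("pooled", "per_diel"),
                                on = c("raw", "relative")) {
  sided <- match.arg(sided)
  fdr_family <- match.arg(fdr_family)
  on <- match.arg(on)
  if (is.null(features)) features <- feature_ids(ft)
  X_full <- if (on == "relative") relative_abundance(ft)$areas else ft$areas
  cells_list <- list()
  anova_list <- list()
  for (d in REEFEXO_DIEL) {
    groups <- c("Control", REEFEXO_PRODUCERS)
    samp_by_group <- lapply(groups, function(tr) {
      intersect(endpoint_samples(metadata, tr, d), sample_ids(ft))
    })
    names(samp_by_group) <- groups
    sizes <- lengths(samp_by_group)
    if (any(sizes < 2)) {
      stop("each endpoint group needs >= 2 replicates (", d, ")",
           call. = FALSE)
    }
    samps <- unlist(samp_by_group, use.names = FALSE)
    g <- factor(rep(groups, sizes), levels = groups)
    X <- X_full[features, samps, drop = FALSE]
    av <- .anova_matrix(X, g)
    anova_list[[d]] <- data.frame(feature_id = features, diel = d,
                                  F = av$F, p = av$p,
                                  stringsAsFactors = FALSE)
    n0 <- sizes["Control"]
    n_treat <- sizes[REEFEXO_PRODUCERS]
    df <- length(samps) - length(groups)
    m_ctrl <- av$means[, "Control"]
    for (tr in REEFEXO_PRODUCERS) {
      est <- av$means[, tr] - m_ctrl
      se <- sqrt(av$mse * (1 / sizes[tr] + 1 / n0))
      tstat <- ifelse(se > 0, est / se,
                      ifelse(est == 0, 0, sign(est) * Inf))
      tstat[av$degenerate] <- 0
      cells_list[[paste(d, tr)]] <- data.frame(
        feature_id = features, treatment = tr, diel = d,
        estimate = unname(est), t = unname(tstat),
        n_treat = unname(sizes[tr]), n0 = unname(n0), df = df,
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, cells_list)
  rownames(cells) <- NULL
  cells$p_dunnett <- NA_real_
  for (d in REEFEXO_DIEL) {
    sel <- cells$diel == d
    sub <- cells[sel, ]
    cells$p_dunnett[sel] <- .dunnett_adjust_vector(
      sub$t, n_treat = unique(sub$n_treat), n0 = sub$n0[1], df = sub$df[1],
      sided = sided)
  }
  if (fdr_family == "pooled") {
    cells$p_fdr <- bh_fdr(cells$p_dunnett)
  } else {
    cells$p_fdr <- NA_real_
    for (d in REEFEXO_DIEL) {
      sel <- cells$diel == d
      cells$p_fdr[sel] <- bh_fdr(cells$p_dunnett[sel])
    }
  }
  cells$significant <- cells$p_fdr < alpha
  exo <- unique(cells$feature_id[cells$significant])
  anova_tab <- do.call(rbind, anova_list)
  rownames(anova_tab) <- NULL
  message(length(exo), " exometabolite feature(s) at alpha = ", alpha)
  list(cells = cells[c("feature_id", "treatment", "diel", "estimate", "t",
                       "p_dunnett", "p_fdr", "significant")],
       anova = anova_tab, exometabolites = exo)
}

#' Classify non-exometabolite exudates into subtypes
#'
#' Exudate features that did not meet the exometabolite criteria are, with
#' precedence artifact > benthic > planktonic: incubation artifacts if
#' doubled relative to ambient seawater in both Day and Night Controls
#' (excluded from downstream summaries), benthic exudates if doubled in one
#' or more organismal incubation treatments, and planktonic exudates if
#' doubled in either Control. Doubling reuses the floored-mean fold-change
#' rule of [split_ambient_exudate()].
#'
#' @param log2_fold Fold-change matrix from [split_ambient_exudate()].
#' @param exudate_ids Exudate feature ids.
#' @param exometabolite_ids Features already classified as exometabolites.
#' @return Named character vector (subtype per non-exometabolite exudate
#'   feature): `"benthic_exudate"`, `"planktonic_exudate"` or
#'   `"incubation_artifact"`.
#' @export
classify_exudate_subtypes <- function(log2_fold, exudate_ids,
                                      exometabolite_ids) {
  rest <- setdiff(exudate_ids, exometabolite_ids)
  lf <- log2_fold[rest, , drop = FALSE]
  doubled <- lf >= 1
  ctrl_day <- doubled[, "Control.Day"]
  ctrl_night <- doubled[, "Control.Night"]
  prod_cols <- grep("^Control\\.", colnames(lf), invert = TRUE, value = TRUE)
  any_prod <- apply(doubled[, prod_cols, drop = FALSE], 1, any)
  subtype <- rep(NA_character_, length(rest))
  subtype[ctrl_day & ctrl_night] <- "incubation_artifact"
  subtype[is.na(subtype) & any_prod] <- "benthic_exudate"
  subtype[is.na(subtype) & (ctrl_day | ctrl_night)] <- "planktonic_exudate"
  ## strict-vs-inclusive threshold edge: an exudate exactly at the boundary
  ## in every cell defaults to benthic if any organismal cell led the split
  if (anyNA(subtype)) subtype[is.na(subtype)] <- "benthic_exudate"
  names(subtype) <- rest
  subtype
}

#' Run the full feature-classification cascade
#'
#' Stages, in order: background (blank-derived) removal; transient
#' (unreplicated) removal; ambient/exudate split on floored fold changes;
#' exometabolite testing (ANOVA + one-sided Dunnett vs Control with BH FDR);
#' subtype assignment for the remaining exudates.
#'
#' @param ft A [feature_table()] including blanks.
#' @param metadata Sample metadata.
#' @param alpha Exometabolite significance level (default 0.05).
#' @param log2_threshold Exudate split threshold (default 1).
#' @param transient_threshold Transient peak-area threshold (default `2e5`).
#' @param noise_floor Mean floor for fold changes (default `1e5`).
#' @param background_universe Optional sample universe for the background
#'   filter.
#' @param ... Further arguments passed to [test_exometabolites()].
#' @return A `feature_classification` object: list with `labels`
#'   (data.frame feature_id, class), `cells`, `anova`, `log2_fold`,
#'   `counts`, `params`.
#' @export
classify_features <- function(ft, metadata, alpha = 0.05, log2_threshold = 1,
                              transient_threshold = 2e5, noise_floor = 1e5,
                              background_universe = NULL, ...) {
  all_ids <- feature_ids(ft)
  bg <- flag_background(ft, metadata, universe = background_universe)
  ft1 <- subset_features(ft, features = setdiff(all_ids, bg))
  tr <- flag_transient(ft1, metadata, threshold = transient_threshold)
  common <- setdiff(feature_ids(ft1), tr)
  ft2 <- subset_features(ft1, features = common,
                         samples = intersect(experimental_samples(metadata),
                                             sample_ids(ft1)))
  split <- split_ambient_exudate(ft2, metadata,
                                 log2_threshold = log2_threshold,
                                 floor = noise_floor)
  exo_test <- test_exometabolites(ft2, metadata, features = split$exudate,
                                  alpha = alpha, ...)
  subtype <- classify_exudate_subtypes(split$log2_fold, split$exudate,
                                       exo_test$exometabolites)
  cls <- rep(NA_character_, length(all_ids))
  names(cls) <- all_ids
  cls[bg] <- "background"
  cls[tr] <- "transient"
  cls[split$ambient] <- "ambient"
  cls[exo_test$exometabolites] <- "exometabolite"
  cls[names(subtype)] <- subtype
  labels <- data.frame(feature_id = all_ids, class = unname(cls),
                       stringsAsFactors = FALSE)
  counts <- table(factor(labels$class,
                         levels = c("background", "transient", "ambient",
                                    "exometabolite", "benthic_exudate",
                                    "planktonic_exudate",
                                    "incubation_artifact")))
  out <- list(labels = labels, cells = exo_test$cells, anova = exo_test$anova,
              log2_fold = split$log2_fold, counts = counts,
              params = list(alpha = alpha, log2_threshold = log2_threshold,
                            transient_threshold = transient_threshold,
                            noise_floor = noise_floor))
  class(out) <- "feature_classification"
  out
}

#' @export
print.feature_classification <- function(x, ...) {
  cat("feature_classification:\n")
  print(x$counts)
  invisible(x)
}

#' Per-sample peak-area shares by feature class
#'
#' For each sample, the fraction of total feature peak area held by each
#' class of the cascade. Shares over all classes sum to 1; excluding the
#' incubation-artifact class (as downstream summaries do) they sum to at
#' most 1.
#'
#' @param ft The full [feature_table()].
#' @param classification A [classify_features()] result.
#' @param metadata Sample metadata.
#' @return Data.frame: one row per experimental sample, one column per
#'   class, plus `sample_id`.
#' @export
class_peak_area_summary <- function(ft, classification, metadata) {
  samps <- intersect(experimental_samples(metadata), sample_ids(ft))
  lab <- classification$labels
  classes <- levels(factor(lab$class))
  tot <- colSums(ft$areas[, samps, drop = FALSE])
  out <- data.frame(sample_id = samps, stringsAsFactors = FALSE)
  for (cl in classes) {
    ids <- lab$feature_id[lab$class == cl]
    out[[cl]] <- colSums(ft$areas[ids, samps, drop = FALSE]) / tot
  }
  out
}

#' Treatment-association categories of exometabolite features
#'
#' Groups each exometabolite feature by the set of producers in which it is
#' significantly enriched and by its diel activity (day-only, night-only, or
#' both). "Unique" features are those with exactly one source producer.
#'
#' @param classification A [classify_features()] result (or a
#'   [test_exometabolites()] result).
#' @return Data.frame: `feature_id`, `producers` (collapsed with `+`),
#'   `n_producers`, `diel_activity`, `category`.
#' @export
treatment_association_categories <- function(classification) {
  cells <- classification$cells
  sig <- cells[cells$significant, ]
  if (!nrow(sig)) {
    return(data.frame(feature_id = character(), producers = character(),
                      n_producers = integer(), diel_activity = character(),
                      category = character(), stringsAsFactors = FALSE))
  }
  feats <- unique(sig$feature_id)
  rows <- lapply(feats, function(f) {
    sf <- sig[sig$feature_id == f, ]
    prods <- sort(unique(sf$treatment))
    diel <- sort(unique(sf$diel))
    act <- if (length(diel) == 2) "both" else {
      if (diel == "Day") "day-only" else "night-only"
    }
    data.frame(feature_id = f, producers = paste(prods, collapse = "+"),
               n_producers = length(prods), diel_activity = act,
               category = paste(paste(prods, collapse = "+"), act, sep = "|"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
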