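#' Producer-effect tests on bulk biogeochemistry
#'
#' Per analyte and diel period, a one-way ANOVA across the six endpoint
#' groups (Control plus five producers) with BH FDR across analytes within
#' each diel period, followed by two-sided Dunnett comparisons of each
#' producer against the Control (bulk analytes can move in either
#' direction: oxygen production by day, respiration by night).
#'
#' @param bulk Bulk-chemistry data.frame (see [read_bulk_chemistry()]).
#' @param metadata Sample metadata.
#' @param analytes Character vector of analyte column names.
#' @param alpha ANOVA FDR significance level governing which analytes get
#'   Dunnett follow-up (default 0.05).
#' @param mode `"endpoint"` tests endpoint values; `"delta"` tests
#'   endpoint minus the diel ambient-start mean (production/consumption).
#' @return List with `anova` (analyte x diel F, p, p_fdr) and `dunnett`
#'   (analyte x diel x producer estimates, adjusted p, direction).
#' @export
producer_effect_tests <- function(bulk, metadata, analytes,
                                  alpha = 0.05,
                                  mode = c("endpoint", "delta")) {
  mode <- match.arg(mode)
  missing_a <- setdiff(analytes, names(bulk))
  if (length(missing_a)) {
    stop("analyte(s) absent from bulk table: ",
         paste(missing_a, collapse = ", "), call. = FALSE)
  }
  groups <- c("Control", REEFEXO_PRODUCERS)
  anova_rows <- list()
  dunnett_rows <- list()
  for (d in REEFEXO_DIEL) {
    vals_by_group <- function(a) {
      lapply(groups, function(tr) {
        s <- endpoint_samples(metadata, tr, d)
        v <- bulk[[a]][match(s, bulk$sample_id)]
        if (mode == "delta") {
          amb <- ambient_samples(metadata)
          amb <- amb[metadata$diel[match(amb, metadata$sample_id)] == d]
          v <- v - mean(bulk[[a]][match(amb, bulk$sample_id)])
        }
        v
      })
    }
    per_analyte <- lapply(analytes, function(a) {
      g <- vals_by_group(a)
      names(g) <- groups
      g
    })
    names(per_analyte) <- analytes
    av <- lapply(per_analyte, one_way_anova)
    p_fdr <- bh_fdr(vapply(av, `[[`, numeric(1), "p"))
    for (i in seq_along(analytes)) {
      anova_rows[[paste(d, analytes[i])]] <- data.frame(
        analyte = analytes[i], diel = d, F = av[[i]]$F, p = av[[i]]$p,
        p_fdr = p_fdr[i], degenerate = av[[i]]$degenerate,
        stringsAsFactors = FALSE)
      g <- per_analyte[[i]]
      dn <- dunnett_many_to_one(g[["Control"]], g[REEFEXO_PRODUCERS],
                                sided = "two.sided")
      dunnett_rows[[paste(d, analytes[i])]] <- data.frame(
        analyte = analytes[i], diel = d, producer = dn$comparison,
        estimate = dn$estimate, p_adj = dn$p_adj,
        direction = ifelse(dn$estimate > 0, "increase",
                           ifelse(dn$estimate < 0, "decrease", "none")),
        anova_significant = p_fdr[i] < alpha,
        stringsAsFactors = FALSE)
    }
  }
  anova_tab <- do.call(rbind, anova_rows)
  dunnett_tab <- do.call(rbind, dunnett_rows)
  rownames(anova_tab) <- rownames(dunnett_tab) <- NULL
  list(anova = anova_tab, dunnett = dunnett_tab)
}

#' DOC coupling with the classified metabolite pools
#'
#' Per diel period, regresses DOC concentration on the summed peak area of
#' exudate-class features (exometabolite, benthic, planktonic) and,
#' separately, on the summed peak area of ambient features. A strong
#' exudate coupling with no ambient coupling indicates that the resolved
#' features track freshly produced dissolved organic carbon.
#'
#' @param ft The full [feature_table()].
#' @param classification A [classify_features()] result.
#' @param bulk Bulk-chemistry data.frame with `DOC`.
#' @param metadata Sample metadata.
#' @return Data.frame: `diel`, `pool` (exudate/ambient), `slope`, `r2`,
#'   `p`, `n`.
#' @export
doc_metabolome_coupling <- function(ft, classification, bulk, metadata) {
  lab <- classification$labels
  pools <- list(
    exudate = lab$feature_id[lab$class %in%
                               c("exometabolite", "benthic_exudate",
                                 "planktonic_exudate")],
    ambient = lab$feature_id[lab$class == "ambient"])
  rows <- list()
  for (d in REEFEXO_DIEL) {
    samps <- metadata$sample_id[metadata$role == "experimental" &
                                  !is.na(metadata$diel) & metadata$diel == d]
    samps <- intersect(samps, intersect(sample_ids(ft), bulk$sample_id))
    doc <- bulk$DOC[match(samps, bulk$sample_id)]
    for (pool in names(pools)) {
      s <- colSums(ft$areas[pools[[pool]], samps, drop = FALSE])
      fit <- linear_fit(s, doc)
      rows[[paste(d, pool)]] <- data.frame(
        diel = d, pool = pool, slope = fit$slope, r2 = fit$r2, p = fit$p,
        n = fit$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
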