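#' Parse a Hill-notation molecular formula
#'
#' Accepts formulas over C, H, N, O, P, S with an optional trailing charge
#' (`+`, `-`, `2-`, ...). Formulas containing any other element (halogens,
#' metals, ...) are flagged `non_chnops` and excluded from oxidation-state
#' arithmetic rather than rejected outright.
#'
#' @param text A single formula string, e.g. `"C6H12O6"`.
#' @return List with integer counts `C,H,N,O,P,S`, `charge`, and logical
#'   `non_chnops`.
#' @export
parse_formula <- function(text) {
  res <- parse_formulas(text)
  as.list(res[1, ])
}

#' Parse a vector of Hill-notation formulas
#'
#' Vectorized companion of [parse_formula()]; NA in, NA out.
#'
#' @param texts Character vector of formulas.
#' @return Data.frame with columns `C,H,N,O,P,S`, `charge`, `non_chnops`.
#' @export
parse_formulas <- function(texts) {
  n <- length(texts)
  out <- data.frame(C = rep(NA_integer_, n), H = NA_integer_, N = NA_integer_,
                    O = NA_integer_, P = NA_integer_, S = NA_integer_,
                    charge = 0L, non_chnops = FALSE)
  for (i in seq_len(n)) {
    txt <- texts[i]
    if (is.na(txt) || !nzchar(txt)) next
    body <- txt
    charge <- 0L
    ## a single trailing sign denotes a +/- 1 ion; a digit before the sign
    ## belongs to the last element count
    if (grepl("[+-]$", body)) {
      charge <- if (endsWith(body, "+")) 1L else -1L
      body <- sub("[+-]$", "", body)
    }
    toks <- gregexpr("[A-Z][a-z]?[0-9]*", body)[[1]]
    pieces <- regmatches(body, gregexpr("[A-Z][a-z]?[0-9]*", body))[[1]]
    if (toks[1] == -1 || sum(attr(toks, "match.length")) != nchar(body)) {
      stop("malformed formula: '", txt, "'", call. = FALSE)
    }
    elems <- sub("[0-9]*$", "", pieces)
    counts <- sub("^[A-Z][a-z]?", "", pieces)
    counts <- ifelse(nzchar(counts), suppressWarnings(as.integer(counts)), 1L)
    if (anyNA(counts)) stop("malformed formula: '", txt, "'", call. = FALSE)
    if (anyDuplicated(elems)) {
      agg <- tapply(counts, elems, sum)
      elems <- names(agg); counts <- as.integer(agg)
    }
    known <- c("C", "H", "N", "O", "P", "S")
    if (any(!elems %in% known)) {
      out$non_chnops[i] <- TRUE
      next
    }
    for (j in seq_along(elems)) out[i, elems[j]] <- counts[j]
    out[i, known][is.na(out[i, known])] <- 0L
    out$charge[i] <- charge
  }
  out
}

#' Molecular-formula assignment quality filter
#'
#' Retains annotations whose formula assignment is high quality: ZODIAC
#' score strictly above `zodiac_min`, non-chimeric consensus spectrum, and a
#' fragmentation tree explaining more than `min_fragments` fragments and more
#' than `min_intensity` of the spectral intensity. Rows with missing quality
#' fields are excluded with a warning.
#'
#' @param annotations Annotation data.frame (see [read_annotations()]).
#' @param zodiac_min Minimum (exclusive) ZODIAC score, default 0.98.
#' @param min_fragments Minimum (exclusive) fragments explained, default 4.
#' @param min_intensity Minimum (exclusive) fraction of spectral intensity
#'   explained, default 0.80.
#' @return The retained subset of `annotations`; counts are reported via
#'   `message()`.
#' @export
formula_quality_filter <- function(annotations, zodiac_min = 0.98,
                                   min_fragments = 4, min_intensity = 0.80) {
  with_formula <- annotations[annotations$has_formula %in% TRUE, ]
  qual <- with_formula[c("zodiac_score", "chimeric",
                         "tree_fragments_explained",
                         "tree_intensity_explained")]
  incomplete <- !stats::complete.cases(qual)
  if (any(incomplete)) {
    warning(sum(incomplete),
            " annotation(s) with missing quality fields excluded")
  }
  keep <- !incomplete &
    with_formula$zodiac_score > zodiac_min &
    !with_formula$chimeric &
    with_formula$tree_fragments_explained > min_fragments &
    with_formula$tree_intensity_explained > min_intensity
  message(sprintf("formula quality filter: %d retained, %d excluded",
                  sum(keep), nrow(annotations) - sum(keep)))
  with_formula[keep, ]
}

#' Nominal oxidation state of carbon
#'
#' NOSC = 4 - (-Z + 4 C + H - 3 N - 2 O + 5 P - 2 S) / C for a formula with
#' element counts C,H,N,O,P,S and net charge Z. Ranges from -4 (methane-like)
#' to +4 (carbon dioxide) for chemically plausible molecules.
#'
#' @param formula A data.frame (or list) with columns `C,H,N,O,P,S` and
#'   optionally `charge`; vectorized over rows.
#' @return Numeric vector of NOSC values.
#' @examples
#' nosc(parse_formula("C6H12O6"))  # 0: sugars
#' @export
nosc <- function(formula) {
  f <- as.data.frame(formula)
  if (any(is.na(f$C)) || any(f$C < 1)) {
    stop("NOSC requires at least one carbon atom", call. = FALSE)
  }
  z <- if ("charge" %in% names(f) && !all(is.na(f$charge))) {
    ifelse(is.na(f$charge), 0, f$charge)
  } else 0
  4 - (-z + 4 * f$C + f$H - 3 * f$N - 2 * f$O + 5 * f$P - 2 * f$S) / f$C
}

#' Standard Gibbs energy of the carbon-oxidation half reaction
#'
#' Affine map from NOSC to the energy released per mole of carbon on
#' complete oxidation (kJ (mol C)^-1) at 298 K. More reduced carbon (lower
#' NOSC) yields more catabolic energy, so the relation is strictly
#' decreasing.
#'
#' @param nosc_value Numeric NOSC values.
#' @param intercept,slope Relation constants, exposed for sensitivity
#'   analyses.
#' @return Gibbs energies in kJ per mole of carbon.
#' @export
gibbs_cox <- function(nosc_value, intercept = 60.3, slope = -28.5) {
  intercept + slope * nosc_value
}

# Weighted mean with validation; weights must be non-negative and not all 0.
.weighted_mean <- function(x, w, what = "weighted mean") {
  if (any(w < 0)) stop(what, ": negative weights", call. = FALSE)
  tot <- sum(w)
  if (tot <= 0) stop(what, ": all weights zero", call. = FALSE)
  sum(x * w) / tot
}

#' Carbon-weighted mean NOSC for one sample
#'
#' The sample-level NOSC is weighted by carbon content: each feature's
#' weight is the product of its abundance in the sample and its formula's
#' carbon count. Scale-invariant in the abundances, so raw peak areas and
#' relative abundances give identical values.
#'
#' @param ft A [feature_table()].
#' @param formulas Data.frame with `feature_id` and element counts (only
#'   rows for features to include, typically the quality-filtered enriched
#'   set for the sample's organism).
#' @param sample Sample id.
#' @return List with `nosc` (weighted mean), `gibbs` (from [gibbs_cox()]),
#'   `n_features`.
#' @export
sample_weighted_nosc <- function(ft, formulas, sample) {
  ids <- intersect(formulas$feature_id, feature_ids(ft))
  if (!length(ids)) {
    stop("no features with formulas for sample ", sample, call. = FALSE)
  }
  f <- formulas[match(ids, formulas$feature_id), ]
  ab <- ft$areas[ids, sample]
  nos <- nosc(f)
  w <- ab * f$C
  wn <- .weighted_mean(nos, w, "carbon-weighted NOSC")
  list(nosc = wn, gibbs = gibbs_cox(wn), n_features = length(ids))
}

#' Abundance-weighted elemental stoichiometry for one sample
#'
#' Elemental ratios are abundance-weighted means of per-molecule ratios
#' (N:C = sum_i w_i (N_i / C_i) / sum_i w_i with w_i the feature's
#' abundance), matching a "per molecule" reading; the alternative ratio of
#' weighted element sums is available via `mode = "element_sums"`. The three
#' stoichiometric classes partition molecules by nutrient-element presence:
#' P-containing, N-containing without P, and CHO(S)-only.
#'
#' @param ft A [feature_table()].
#' @param formulas Data.frame with `feature_id` and element counts.
#' @param sample Sample id.
#' @param mode `"per_molecule"` (default) or `"element_sums"`.
#' @return List with weighted `NC`, `PC`, `HC`, `OC`, ternary shares
#'   `share_P`, `share_N_not_P`, `share_CHOS`, fractions `frac_with_N`,
#'   `frac_with_P`, and `n_features`.
#' @export
sample_stoichiometry <- function(ft, formulas, sample,
                                 mode = c("per_molecule", "element_sums")) {
  mode <- match.arg(mode)
  ids <- intersect(formulas$feature_id, feature_ids(ft))
  if (!length(ids)) {
    stop("no features with formulas for sample ", sample, call. = FALSE)
  }
  f <- formulas[match(ids, formulas$feature_id), ]
  w <- ft$areas[ids, sample]
  if (sum(w) <= 0) stop("zero total abundance in sample ", sample,
                        call. = FALSE)
  ratio <- function(num) {
    if (mode == "per_molecule") .weighted_mean(num / f$C, w, "ratio")
    else sum(w * num) / sum(w * f$C)
  }
  cls_P <- f$P >= 1
  cls_N <- !cls_P & f$N >= 1
  cls_C <- !cls_P & !cls_N
  tot <- sum(w)
  list(NC = ratio(f$N), PC = ratio(f$P), HC = ratio(f$H), OC = ratio(f$O),
       share_P = sum(w[cls_P]) / tot,
       share_N_not_P = sum(w[cls_N]) / tot,
       share_CHOS = sum(w[cls_C]) / tot,
       frac_with_N = sum(w[f$N >= 1]) / tot,
       frac_with_P = sum(w[cls_P]) / tot,
       n_features = length(ids))
}

#' Feature-standardized (z-score) weighting for sample NOSC
#'
#' Robustness variant that removes among-feature differences in absolute and
#' relative peak area (ionization bias): each feature's peak areas are
#' z-scored across the supplied samples, and the weight of a feature in a
#' sample is its z-score shifted to be non-negative (z minus the sample
#' minimum plus one SD unit). Features constant across samples are excluded
#' with a warning.
#'
#' @param ft A [feature_table()] restricted to the samples of interest.
#' @param formulas Data.frame with `feature_id` and element counts.
#' @param samples Sample ids over which to z-score and report.
#' @return Data.frame: `sample_id`, `nosc`, `gibbs`, `n_features`.
#' @export
feature_standardized_weighting <- function(ft, formulas, samples) {
  ids <- intersect(formulas$feature_id, feature_ids(ft))
  if (!length(ids)) stop("no features with formulas", call. = FALSE)
  A <- ft$areas[ids, samples, drop = FALSE]
  sdv <- apply(A, 1, stats::sd)
  const <- sdv == 0
  if (all(const)) stop("all features constant across samples", call. = FALSE)
  if (any(const)) {
    warning(sum(const), " constant feature(s) excluded from z-weighting")
    A <- A[!const, , drop = FALSE]
    ids <- ids[!const]
    sdv <- sdv[!const]
  }
  Z <- sweep(sweep(A, 1, rowMeans(A), "-"), 1, sdv, "/")
  f <- formulas[match(ids, formulas$feature_id), ]
  nos <- nosc(f)
  res <- lapply(samples, function(s) {
    z <- Z[, s]
    w <- z - min(z) + 1        # >= 0; equal z-profiles give equal weights
    wn <- .weighted_mean(nos, w, "z-weighted NOSC")
    data.frame(sample_id = s, nosc = wn, gibbs = gibbs_cox(wn),
               n_features = length(z), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-producer exometabolome energetics and stoichiometry
#'
#' For each endpoint sample of each producer treatment, summarizes the
#' features statistically enriched in that treatment (the sample organism's
#' exometabolite set) possessing quality-passing formulas: carbon-weighted
#' NOSC, Gibbs energy, and abundance-weighted elemental stoichiometry.
#'
#' @param ft A [feature_table()] (raw peak areas).
#' @param metadata Sample metadata.
#' @param classification A [classify_features()] result.
#' @param formulas Quality-filtered annotation subset (see
#'   [formula_quality_filter()]).
#' @param diel Diel period to summarize (default `"Day"`, where most
#'   exudation occurs).
#' @param weighting `"area"` for raw abundance weights, `"zscore"` for the
#'   feature-standardized variant.
#' @return Data.frame with one row per producer endpoint sample: treatment,
#'   sample, weighted NOSC, Gibbs energy, elemental ratios, ternary shares.
#' @export
exometabolome_stoichiometry <- function(ft, metadata, classification,
                                        formulas, diel = "Day",
                                        weighting = c("area", "zscore")) {
  weighting <- match.arg(weighting)
  cells <- classification$cells
  rows <- list()
  for (tr in REEFEXO_PRODUCERS) {
    feats <- unique(cells$feature_id[cells$treatment == tr &
                                       cells$diel == diel & cells$significant])
    f <- formulas[formulas$feature_id %in% feats, ]
    if (!nrow(f)) next
    samps <- endpoint_samples(metadata, treatment = tr, diel = diel)
    if (weighting == "zscore") {
      zw <- feature_standardized_weighting(ft, f, samps)
      for (j in seq_len(nrow(zw))) {
        rows[[length(rows) + 1]] <- data.frame(
          treatment = tr, sample_id = zw$sample_id[j], nosc = zw$nosc[j],
          gibbs = zw$gibbs[j], NC = NA, PC = NA, HC = NA, OC = NA,
          share_P = NA, share_N_not_P = NA, share_CHOS = NA,
          frac_with_N = NA, frac_with_P = NA, n_features = zw$n_features[j],
          stringsAsFactors = FALSE)
      }
    } else {
      for (s in samps) {
        wn <- sample_weighted_nosc(ft, f, s)
        st <- sample_stoichiometry(ft, f, s)
        rows[[length(rows) + 1]] <- data.frame(
          treatment = tr, sample_id = s, nosc = wn$nosc, gibbs = wn$gibbs,
          NC = st$NC, PC = st$PC, HC = st$HC, OC = st$OC,
          share_P = st$share_P, share_N_not_P = st$share_N_not_P,
          share_CHOS = st$share_CHOS, frac_with_N = st$frac_with_N,
          frac_with_P = st$frac_with_P, n_features = wn$n_features,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Regress exometabolome stoichiometry on bulk nutrient concentrations
#'
#' Tests whether the weighted N:C and P:C of exometabolite features predict
#' bulk total dissolved nitrogen and phosphorus in the matching samples.
#'
#' @param stoich Output of [exometabolome_stoichiometry()].
#' @param bulk Bulk-chemistry data.frame with `sample_id`, `TDN`, `TDP`.
#' @return List of two [linear_fit()] results: `N` (N:C vs TDN) and `P`
#'   (P:C vs TDP).
#' @export
regress_stoichiometry_vs_bulk <- function(stoich, bulk) {
  m <- match(stoich$sample_id, bulk$sample_id)
  if (anyNA(m)) stop("stoichiometry samples missing from bulk chemistry",
                     call. = FALSE)
  list(N = linear_fit(stoich$NC, bulk$TDN[m]),
       P = linear_fit(stoich$PC, bulk$TDP[m]))
}
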