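#' @keywords internal
"_PACKAGE"

## Controlled vocabularies for the incubation design.
REEFEXO_TREATMENTS <- c("Ambient", "Control", "Porites", "Pocillopora", "CCA",
                        "Dictyota", "Turf")
REEFEXO_PRODUCERS <- c("Porites", "Pocillopora", "CCA", "Dictyota", "Turf")
REEFEXO_DIEL <- c("Day", "Night")
REEFEXO_TIMEPOINTS <- c("start", "end")

#' Construct a feature table
#'
#' A feature table holds XIC MS1 peak areas for a set of aligned features
#' (rows) across samples (columns). Peak areas are non-negative reals in
#' arbitrary ion-count units; gap-filled zeros are meaningful observations,
#' not missing values, because the classification filters compare means that
#' include them.
#'
#' @param areas Numeric matrix, features x samples, with unique rownames
#'   (feature ids) and colnames (sample ids).
#' @param mz Optional numeric vector of feature m/z values (Da).
#' @param rt Optional numeric vector of retention times (minutes).
#' @return An object of class `feature_table`: a list with elements `areas`,
#'   `mz`, `rt`.
#' @export
feature_table <- function(areas, mz = NULL, rt = NULL) {
  if (!is.matrix(areas) || !is.numeric(areas)) {
    stop("`areas` must be a numeric matrix (features x samples)", call. = FALSE)
  }
  if (is.null(rownames(areas)) || is.null(colnames(areas))) {
    stop("`areas` must have feature ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(areas))) {
    stop("duplicate feature ids in feature table", call. = FALSE)
  }
  if (anyDuplicated(colnames(areas))) {
    stop("duplicate sample ids in feature table", call. = FALSE)
  }
  if (anyNA(areas)) {
    stop("feature table contains NA peak areas; use 0 for gap-filled cells",
         call. = FALSE)
  }
  if (any(areas < 0)) {
    stop("peak areas must be non-negative", call. = FALSE)
  }
  if (!is.null(mz) && length(mz) != nrow(areas)) {
    stop("`mz` must have one value per feature", call. = FALSE)
  }
  if (!is.null(rt) && length(rt) != nrow(areas)) {
    stop("`rt` must have one value per feature", call. = FALSE)
  }
  structure(list(areas = areas, mz = mz, rt = rt), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples\n",
              nrow(x$areas), ncol(x$areas)))
  cat(sprintf("  total peak area: %.4g\n", sum(x$areas)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$areas)

feature_ids <- function(ft) rownames(ft$areas)
sample_ids <- function(ft) colnames(ft$areas)

#' Subset a feature table
#'
#' @param ft A `feature_table`.
#' @param features Optional character vector of feature ids to keep.
#' @param samples Optional character vector of sample ids to keep.
#' @return A `feature_table` restricted to the requested rows/columns.
#' @export
subset_features <- function(ft, features = NULL, samples = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  fi <- if (is.null(features)) seq_len(nrow(ft$areas)) else {
    miss <- setdiff(features, feature_ids(ft))
    if (length(miss)) {
      stop("unknown feature ids: ", paste(utils::head(miss, 5), collapse = ", "),
           call. = FALSE)
    }
    match(features, feature_ids(ft))
  }
  si <- if (is.null(samples)) seq_len(ncol(ft$areas)) else {
    miss <- setdiff(samples, sample_ids(ft))
    if (length(miss)) {
      stop("unknown sample ids: ", paste(utils::head(miss, 5), collapse = ", "),
           call. = FALSE)
    }
    match(samples, sample_ids(ft))
  }
  feature_table(ft$areas[fi, si, drop = FALSE],
                mz = ft$mz[fi], rt = ft$rt[fi])
}

#' Convert peak areas to within-sample relative abundances
#'
#' Relative abundance of a feature in a sample is its share of that sample's
#' total feature peak area, so each sample column sums to one. Feature order
#' is preserved.
#'
#' @param ft A `feature_table`.
#' @param samples Optional sample subset to normalize (default: all samples).
#' @return A `feature_table` whose columns each sum to 1.
#' @export
relative_abundance <- function(ft, samples = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  if (!is.null(samples)) ft <- subset_features(ft, samples = samples)
  totals <- colSums(ft$areas)
  zero <- totals <= 0
  if (any(zero)) {
    stop("sample(s) with zero total peak area: ",
         paste(colnames(ft$areas)[zero], collapse = ", "), call. = FALSE)
  }
  feature_table(sweep(ft$areas, 2, totals, "/"), mz = ft$mz, rt = ft$rt)
}

check_samples_covered <- function(ft, metadata) {
  miss <- setdiff(sample_ids(ft), metadata$sample_id)
  if (length(miss)) {
    stop("feature-table sample column(s) absent from metadata: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

## Metadata accessors used throughout the cascade.
blank_samples <- function(metadata) {
  metadata$sample_id[metadata$role == "blank"]
}
experimental_samples <- function(metadata) {
  metadata$sample_id[metadata$role == "experimental"]
}
ambient_samples <- function(metadata) {
  metadata$sample_id[metadata$role == "experimental" &
                       metadata$treatment == "Ambient"]
}
endpoint_samples <- function(metadata, treatment = NULL, diel = NULL) {
  keep <- metadata$role == "experimental" & !is.na(metadata$timepoint) &
    metadata$timepoint == "end"
  if (!is.null(treatment)) keep <- keep & metadata$treatment %in% treatment
  if (!is.null(diel)) keep <- keep & metadata$diel %in% diel
  metadata$sample_id[keep]
}
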