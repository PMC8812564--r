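#' Read an aligned feature-quantification table
#'
#' Two dialects are supported. `"long"` is the package's native interchange:
#' a TSV with columns `feature_id`, `sample_id`, `peak_area` and optionally
#' `mz`, `rt`. `"mzmine"` is the wide quantification-table export style: one
#' row per feature with columns `row ID`, `row m/z`, `row retention time` and
#' one `<sample> Peak area` column per sample. Empty or missing cells become
#' gap-filled zeros with a message reporting the count.
#'
#' @param path File path.
#' @param metadata Sample metadata as returned by [read_sample_metadata()];
#'   every sample column in the file must be present there.
#' @param dialect `"long"` or `"mzmine"`.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, metadata, dialect = c("long", "mzmine")) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
    need <- c("feature_id", "sample_id", "peak_area")
    if (!all(need %in% names(df))) {
      stop("long feature table needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    feats <- unique(df$feature_id)
    samps <- unique(df$sample_id)
    areas <- matrix(0, length(feats), length(samps),
                    dimnames = list(feats, samps))
    n_na <- sum(is.na(df$peak_area))
    df$peak_area[is.na(df$peak_area)] <- 0
    if (anyDuplicated(df[c("feature_id", "sample_id")])) {
      stop("duplicate (feature_id, sample_id) rows in long feature table",
           call. = FALSE)
    }
    areas[cbind(match(df$feature_id, feats), match(df$sample_id, samps))] <-
      df$peak_area
    mz <- rt <- NULL
    if ("mz" %in% names(df)) mz <- df$mz[match(feats, df$feature_id)]
    if ("rt" %in% names(df)) rt <- df$rt[match(feats, df$feature_id)]
    if (n_na > 0) message(n_na, " empty peak-area cell(s) filled with 0")
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!"row ID" %in% names(df)) {
      stop("mzmine dialect expects a 'row ID' column", call. = FALSE)
    }
    if (anyDuplicated(df[["row ID"]])) {
      stop("duplicate feature ids in 'row ID'", call. = FALSE)
    }
    area_cols <- grep(" Peak area$", names(df), value = TRUE)
    if (!length(area_cols)) {
      stop("mzmine dialect expects '<sample> Peak area' columns", call. = FALSE)
    }
    samps <- sub(" Peak area$", "", area_cols)
    areas <- as.matrix(df[area_cols])
    colnames(areas) <- samps
    rownames(areas) <- as.character(df[["row ID"]])
    n_na <- sum(is.na(areas))
    areas[is.na(areas)] <- 0
    mz <- if ("row m/z" %in% names(df)) df[["row m/z"]] else NULL
    rt <- if ("row retention time" %in% names(df)) df[["row retention time"]]
          else NULL
    if (n_na > 0) message(n_na, " empty peak-area cell(s) filled with 0")
  }
  ft <- feature_table(areas, mz = mz, rt = rt)
  check_samples_covered(ft, metadata)
  ft
}

#' Write a feature table in the native long dialect
#'
#' @param ft A [feature_table()].
#' @param path Output TSV path.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  long <- data.frame(
    feature_id = rep(feature_ids(ft), times = ncol(ft$areas)),
    sample_id = rep(sample_ids(ft), each = nrow(ft$areas)),
    peak_area = as.vector(ft$areas),
    stringsAsFactors = FALSE
  )
  if (!is.null(ft$mz)) long$mz <- rep(ft$mz, times = ncol(ft$areas))
  if (!is.null(ft$rt)) long$rt <- rep(ft$rt, times = ncol(ft$areas))
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate sample metadata
#'
#' Expects a TSV with columns `sample_id`, `role`, `treatment`, `diel`,
#' `timepoint`, `replicate`. Blanks carry no treatment/diel/timepoint (empty
#' or NA); Ambient samples must be `timepoint = "start"`. A design summary
#' (cells x replicates) is reported via `message()`.
#'
#' @param path File path.
#' @return A data.frame of validated sample records.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (nrow(df) == 0) stop("no samples in metadata file", call. = FALSE)
  need <- c("sample_id", "role", "treatment", "diel", "timepoint", "replicate")
  if (!all(need %in% names(df))) {
    stop("metadata needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  validate_sample_metadata(df[need])
}

#' Validate a sample-metadata data.frame
#'
#' @param df Data.frame with the metadata columns (see
#'   [read_sample_metadata()]).
#' @return The validated data.frame (invisibly the same object).
#' @export
validate_sample_metadata <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  bad_role <- setdiff(unique(df$role), c("blank", "experimental"))
  if (length(bad_role)) {
    stop("unknown role label(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  exp <- df[df$role == "experimental", ]
  bad_tr <- setdiff(unique(exp$treatment), REEFEXO_TREATMENTS)
  if (length(bad_tr)) {
    stop("unknown treatment label(s): ", paste(bad_tr, collapse = ", "),
         call. = FALSE)
  }
  blanks <- df[df$role == "blank", ]
  if (nrow(blanks) &&
      any(!is.na(blanks$treatment) | !is.na(blanks$diel) |
            !is.na(blanks$timepoint))) {
    stop("blank samples must carry no treatment/diel/timepoint", call. = FALSE)
  }
  if (any(!is.na(exp$diel) & !exp$diel %in% REEFEXO_DIEL)) {
    stop("diel must be one of: ", paste(REEFEXO_DIEL, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(exp$timepoint) & !exp$timepoint %in% REEFEXO_TIMEPOINTS)) {
    stop("timepoint must be one of: ",
         paste(REEFEXO_TIMEPOINTS, collapse = ", "), call. = FALSE)
  }
  amb <- exp[exp$treatment == "Ambient", ]
  if (nrow(amb) && any(amb$timepoint != "start")) {
    stop("Ambient samples must be timepoint = start", call. = FALSE)
  }
  cells <- table(exp$treatment, exp$diel, exp$timepoint)
  message(sprintf("metadata: %d experimental + %d blank samples, %d design cells",
                  nrow(exp), nrow(blanks), sum(cells > 0)))
  df
}

#' Read a feature annotation table
#'
#' TSV keyed by `feature_id` with molecular formulas (Hill notation),
#' formula-assignment quality metrics, molecular-network subnetwork ids and
#' structural classes. Formulas are parsed via [parse_formula()]; a row whose
#' formula cannot be parsed loses its annotation with a warning. Quality
#' metrics must be present if and only if a formula is present.
#'
#' @param path File path.
#' @param feature_ids Optional character vector of known feature ids; rows
#'   whose `feature_id` is not in it produce a warning but are kept
#'   (annotation tables may be supersets).
#' @return A data.frame with columns `feature_id`, element counts
#'   `C,H,N,O,P,S`, `charge`, `has_formula`, `non_chnops`, `zodiac_score`,
#'   `chimeric`, `tree_fragments_explained`, `tree_intensity_explained`,
#'   `subnetwork_id` (NA = singleton), `structural_class`, `library_match`.
#' @export
read_annotations <- function(path, feature_ids = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (!"feature_id" %in% names(df)) {
    stop("annotation table needs a feature_id column", call. = FALSE)
  }
  for (col in c("formula", "zodiac_score", "chimeric",
                "tree_fragments_explained", "tree_intensity_explained",
                "subnetwork_id", "structural_class", "library_match")) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  has_formula <- !is.na(df$formula)
  if (any(!is.na(df$zodiac_score) & !has_formula)) {
    stop("zodiac_score present without a formula", call. = FALSE)
  }
  if (any((!is.na(df$tree_fragments_explained) |
             !is.na(df$tree_intensity_explained)) & !has_formula)) {
    stop("fragment-tree metrics present without a formula", call. = FALSE)
  }
  if (any(has_formula & is.na(df$zodiac_score))) {
    stop("formula present without zodiac_score", call. = FALSE)
  }
  parsed <- parse_formulas(df$formula)
  bad <- has_formula & is.na(parsed$C) & !parsed$non_chnops
  if (any(bad)) {
    warning(sum(bad), " unparsable formula(s) dropped from annotations")
    has_formula[bad] <- FALSE
  }
  if (!is.null(feature_ids)) {
    extra <- setdiff(df$feature_id, feature_ids)
    if (length(extra)) {
      warning(length(extra),
              " annotation row(s) with feature ids absent from feature table",
              " (kept)")
    }
  }
  out <- data.frame(feature_id = as.character(df$feature_id),
                    stringsAsFactors = FALSE)
  out <- cbind(out, parsed)
  out$has_formula <- has_formula & !parsed$non_chnops
  out$zodiac_score <- as.numeric(df$zodiac_score)
  out$chimeric <- as.logical(df$chimeric)
  out$tree_fragments_explained <- as.integer(df$tree_fragments_explained)
  out$tree_intensity_explained <- as.numeric(df$tree_intensity_explained)
  out$subnetwork_id <- suppressWarnings(as.integer(df$subnetwork_id))
  out$structural_class <- as.character(df$structural_class)
  out$library_match <- as.character(df$library_match)
  out
}

#' Read a bulk-chemistry table
#'
#' TSV keyed by `sample_id` with bulk biogeochemical analytes (DO, pH, DOC
#' and nutrient concentrations in micromolar). Derived organic pools are
#' recomputed if absent: DON = TDN - (NO3NO2 + NH4), DOP = TDP - PO4.
#'
#' @param path File path.
#' @param tolerance Tolerance for negative derived DON/DOP before erroring
#'   (measurement noise can push small true values slightly negative).
#' @return A data.frame of bulk-chemistry records.
#' @export
read_bulk_chemistry <- function(path, tolerance = 0.5) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (!"sample_id" %in% names(df)) {
    stop("bulk chemistry table needs a sample_id column", call. = FALSE)
  }
  if (all(c("TDN", "NO3NO2", "NH4") %in% names(df)) && !"DON" %in% names(df)) {
    df$DON <- df$TDN - (df$NO3NO2 + df$NH4)
  }
  if (all(c("TDP", "PO4") %in% names(df)) && !"DOP" %in% names(df)) {
    df$DOP <- df$TDP - df$PO4
  }
  for (col in c("DON", "DOP")) {
    if (col %in% names(df) && any(df[[col]] < -tolerance, na.rm = TRUE)) {
      stop(col, " more negative than measurement tolerance; inconsistent ",
           "total vs inorganic nutrients", call. = FALSE)
    }
  }
  df
}

#' Write a data.frame as TSV
#'
#' @param df Data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
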