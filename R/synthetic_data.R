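#' Configuration for a synthetic exometabolome experiment
#'
#' Defaults encode the incubation study design: triplicate 8-h daytime and
#' nighttime incubations of five benthic producers plus filtered-seawater
#' Controls, ambient starting water sampled before each period, and eight
#' process blanks. Planted exometabolite enrichments are lognormal with a
#' 40-fold geometric mean and a fivefold geometric SD; the transient
#' threshold is twice the instrument noise threshold.
#'
#' @param n_features Named integer vector of planted feature counts per
#'   class.
#' @param replicates Replicates per design cell (>= 2).
#' @param n_blanks Number of process blanks.
#' @param sigma Within-group multiplicative noise (lognormal sdlog) for
#'   replicate peak areas; 0.3 corresponds to a ~30% CV typical of
#'   triplicate incubation LC-MS XIC areas.
#' @param exo_fold_mean,exo_fold_sd_factor Geometric mean and geometric SD
#'   factor of planted exometabolite fold changes (truncated below at 2 so
#'   every planted exometabolite is an exudate).
#' @param noise_floor Instrument noise threshold (peak-area units).
#' @param transient_threshold Transient peak-area threshold.
#' @param blank_fraction Blank intensity of background features as a
#'   fraction of their sample-mean intensity.
#' @param detector_sd SD of the additive detector-floor noise.
#' @param benthic_fold Spike fold-change range of non-exometabolite benthic
#'   exudates; the spike lands in one replicate per source cell (patchy
#'   release), which doubles the cell mean while keeping within-cell
#'   variance too large for statistical enrichment.
#' @param control_fold Fold-change range for planktonic/artifact elevations
#'   in Control incubations.
#' @param doc_baseline Baseline DOC (micromolar C).
#' @param doc_r2 Named target R-squared of the DOC vs summed-exudate-area
#'   coupling per diel period.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_features = c(background = 150, transient = 60,
                                      ambient = 300, exometabolite = 150,
                                      benthic_exudate = 120,
                                      planktonic_exudate = 60,
                                      incubation_artifact = 30),
                       replicates = 3, n_blanks = 8, sigma = 0.3,
                       exo_fold_mean = 40, exo_fold_sd_factor = 5,
                       noise_floor = 1e5, transient_threshold = 2e5,
                       blank_fraction = 0.6, detector_sd = 5e3,
                       benthic_fold = c(6, 12),
                       control_fold = c(3, 6),
                       doc_baseline = 80, doc_r2 = c(Day = 0.84, Night = 0.63),
                       seed = 1) {
  classes <- c("background", "transient", "ambient", "exometabolite",
               "benthic_exudate", "planktonic_exudate", "incubation_artifact")
  full <- stats::setNames(integer(length(classes)), classes)
  full[names(n_features)] <- as.integer(n_features)
  if (any(full < 0)) stop("feature counts must be >= 0", call. = FALSE)
  if (replicates < 2) {
    stop("replicates must be >= 2 (grouped tests undefined)", call. = FALSE)
  }
  if (exo_fold_mean < 1) stop("fold changes must be >= 1", call. = FALSE)
  structure(list(n_features = full, replicates = replicates,
                 n_blanks = n_blanks, sigma = sigma,
                 exo_fold_mean = exo_fold_mean,
                 exo_fold_sd_factor = exo_fold_sd_factor,
                 noise_floor = noise_floor,
                 transient_threshold = transient_threshold,
                 blank_fraction = blank_fraction, detector_sd = detector_sd,
                 benthic_fold = benthic_fold,
                 control_fold = control_fold, doc_baseline = doc_baseline,
                 doc_r2 = doc_r2, seed = seed),
            class = "sim_config")
}

## Producer-specific compound-class template mixes: corals phosphorus-rich,
## the fleshy macroalga lipid-like (reduced, energy-rich), turf nitrogen
## heterocycles, the calcifiers more peptide/sugar-like.
.template_names <- c("lipid_like", "sugar_like", "peptide_like", "P_rich",
                     "N_heterocycle")
.producer_template_mix <- list(
  Porites     = c(lipid_like = .05, sugar_like = .25, peptide_like = .50,
                  P_rich = .15, N_heterocycle = .05),
  Pocillopora = c(lipid_like = .05, sugar_like = .05, peptide_like = .25,
                  P_rich = .50, N_heterocycle = .15),
  CCA         = c(lipid_like = .02, sugar_like = .33, peptide_like = .40,
                  P_rich = .05, N_heterocycle = .20),
  Dictyota    = c(lipid_like = .80, sugar_like = .08, peptide_like = .05,
                  P_rich = .02, N_heterocycle = .05),
  Turf        = c(lipid_like = .10, sugar_like = .05, peptide_like = .25,
                  P_rich = .05, N_heterocycle = .55))

## Hallmark compound class per producer: the most abundantly exuded
## features of a producer preferentially carry its signature chemistry, as
## dominant producer-specific molecular families do in incubation studies.
.producer_signature <- c(Porites = "peptide_like", Pocillopora = "P_rich",
                         CCA = "sugar_like", Dictyota = "lipid_like",
                         Turf = "N_heterocycle")

#' Draw molecular formulas from a compound-class template
#'
#' Templates parameterize marginal elemental ratios: lipid-like formulas
#' have low O:C (~0.15) and high H:C (>1.2), sugar-like formulas sit at
#' NOSC ~ 0, peptide-like formulas carry N at amino-acid-like ratios,
#' P-rich formulas always contain phosphorus, and N-heterocycles carry
#' several nitrogens at moderate saturation.
#'
#' @param template One of `"lipid_like"`, `"sugar_like"`, `"peptide_like"`,
#'   `"P_rich"`, `"N_heterocycle"`.
#' @param n Number of formulas to draw.
#' @return Data.frame with columns `C,H,N,O,P,S`, `charge`, `non_chnops`.
#' @export
generate_formula <- function(template, n = 1) {
  if (!template %in% .template_names) {
    stop("unknown formula template: ", template, call. = FALSE)
  }
  r <- function(lo, hi) stats::runif(n, lo, hi)
  if (template == "lipid_like") {
    C <- sample(14:24, n, replace = TRUE)
    H <- pmax(round(C * r(1.7, 1.95)), 1)
    O <- pmax(round(C * r(0.08, 0.22)), 1)
    N <- stats::rbinom(n, 1, 0.1)
    P <- integer(n)
    S <- stats::rbinom(n, 1, 0.05)
  } else if (template == "sugar_like") {
    C <- sample(5:12, n, replace = TRUE)
    H <- 2L * C
    O <- C + sample(c(-1L, 0L, 1L), n, replace = TRUE,
                    prob = c(0.15, 0.7, 0.15))
    N <- integer(n); P <- integer(n); S <- integer(n)
  } else if (template == "peptide_like") {
    C <- sample(8:20, n, replace = TRUE)
    H <- pmax(round(C * r(1.5, 1.7)), 1)
    O <- pmax(round(C * r(0.25, 0.35)), 1)
    N <- pmax(round(C * r(0.20, 0.35)), 1)
    P <- integer(n)
    S <- stats::rbinom(n, 1, 0.1)
  } else if (template == "P_rich") {
    C <- sample(8:20, n, replace = TRUE)
    P <- 1L + stats::rbinom(n, 1, 0.3)
    H <- pmax(round(C * r(1.4, 1.7)), 1)
    O <- pmax(round(C * r(0.30, 0.45)), 1) + 3L * P
    N <- round(C * r(0.10, 0.25))
    S <- integer(n)
  } else {
    C <- sample(8:16, n, replace = TRUE)
    N <- sample(2:4, n, replace = TRUE)
    H <- pmax(round(C * r(1.0, 1.3)), 1)
    O <- pmax(round(C * r(0.10, 0.30)), 0)
    P <- integer(n); S <- integer(n)
  }
  data.frame(C = C, H = H, N = N, O = O, P = P, S = S, charge = 0L,
             non_chnops = FALSE)
}

# Hill-notation string for an element-count row (C, H, then alphabetical).
.format_formula <- function(f) {
  parts <- character(0)
  add <- function(sym, cnt) {
    if (cnt >= 1) paste0(sym, ifelse(cnt > 1, cnt, "")) else ""
  }
  paste0(add("C", f$C), add("H", f$H), add("N", f$N), add("O", f$O),
         add("P", f$P), add("S", f$S))
}

# Truncated lognormal draw (lower bound by inverse-CDF rejection-free
# sampling).
.rlnorm_trunc <- function(n, meanlog, sdlog, lower) {
  plo <- stats::plnorm(lower, meanlog, sdlog)
  u <- stats::runif(n, plo, 1)
  stats::qlnorm(u, meanlog, sdlog)
}

#' Generate a complete synthetic exometabolome experiment
#'
#' Builds a feature table, sample metadata, annotations, bulk chemistry and
#' ground-truth labels for the incubation design, with planted feature
#' classes recoverable by the classification cascade: background features
#' present in blanks at a fixed fraction of their sample mean; transient
#' features replicated in fewer than three samples; ambient features flat
#' across the experiment; exometabolite features enriched lognormally
#' (geometric mean x geometric SD per config) in their source producer
#' cells; benthic exudates elevated but with high replicate heterogeneity
#' (so not statistically separable from Controls); planktonic exudates
#' elevated in one Control cell; incubation artifacts elevated in every
#' incubated endpoint. Bulk DOC covaries linearly with summed exudate peak
#' area at the configured R-squared per diel period.
#'
#' @param config A [sim_config()].
#' @return List with `features` ([feature_table()]), `metadata`,
#'   `annotations`, `bulk`, `truth` (data.frame of planted labels).
#' @export
generate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_seed(config$seed, .generate_experiment_impl(config))
}

.generate_experiment_impl <- function(cfg) {
  reps <- seq_len(cfg$replicates)
  md <- list()
  for (d in REEFEXO_DIEL) {
    md[[length(md) + 1]] <- data.frame(
      sample_id = sprintf("Ambient.%s.%d", d, reps), role = "experimental",
      treatment = "Ambient", diel = d, timepoint = "start", replicate = reps,
      stringsAsFactors = FALSE)
    for (tr in c("Control", REEFEXO_PRODUCERS)) {
      md[[length(md) + 1]] <- data.frame(
        sample_id = sprintf("%s.%s.end.%d", tr, d, reps),
        role = "experimental", treatment = tr, diel = d, timepoint = "end",
        replicate = reps, stringsAsFactors = FALSE)
    }
  }
  md[[length(md) + 1]] <- data.frame(
    sample_id = sprintf("Blank.%d", seq_len(cfg$n_blanks)), role = "blank",
    treatment = NA, diel = NA, timepoint = NA,
    replicate = seq_len(cfg$n_blanks), stringsAsFactors = FALSE)
  metadata <- do.call(rbind, md)

  nf <- cfg$n_features
  n_tot <- sum(nf)
  classes <- rep(names(nf), nf)
  fid <- sprintf("F%04d", seq_len(n_tot))
  truth <- data.frame(feature_id = fid, planted_class = classes,
                      source_treatments = "", diel_activity = "",
                      planted_fold_change = 1, formula_template = "",
                      subnetwork_id = NA_integer_, stringsAsFactors = FALSE)

  exp_samps <- metadata$sample_id[metadata$role == "experimental"]
  blk_samps <- metadata$sample_id[metadata$role == "blank"]
  all_samps <- c(exp_samps, blk_samps)
  M <- matrix(0, n_tot, length(all_samps), dimnames = list(fid, all_samps))
  SG <- matrix(cfg$sigma, n_tot, length(all_samps),
               dimnames = list(fid, all_samps))

  cell_samples <- function(tr, d) {
    metadata$sample_id[metadata$role == "experimental" &
                         metadata$treatment == tr &
                         !is.na(metadata$diel) & metadata$diel == d &
                         metadata$timepoint == "end"]
  }
  end_samps <- metadata$sample_id[metadata$role == "experimental" &
                                    metadata$timepoint == "end"]

  ## baselines: truncated above the transient threshold so planted common
  ## features are replicated by construction
  is_cls <- function(cl) which(classes == cl)
  base <- numeric(n_tot)
  i <- is_cls("background")
  base[i] <- .rlnorm_trunc(length(i), log(1.5e6), 1.0,
                           2 * cfg$transient_threshold)
  i <- is_cls("ambient")
  base[i] <- .rlnorm_trunc(length(i), log(1.5e6), 1.0,
                           2 * cfg$transient_threshold)
  for (cl in c("exometabolite", "benthic_exudate", "planktonic_exudate",
               "incubation_artifact")) {
    i <- is_cls(cl)
    base[i] <- .rlnorm_trunc(length(i), log(6e5), 0.6,
                             1.25 * cfg$transient_threshold)
  }
  i <- is_cls("transient")
  base[i] <- .rlnorm_trunc(length(i), log(2e6), 0.5, 1e6)

  ## background: everywhere incl. blanks at blank_fraction of sample level
  for (i in is_cls("background")) {
    M[i, exp_samps] <- base[i]
    M[i, blk_samps] <- cfg$blank_fraction * base[i]
  }
  ## ambient: flat in all experimental samples, absent from blanks
  for (i in is_cls("ambient")) M[i, exp_samps] <- base[i]
  ## transient: present in 1-2 random experimental samples only
  for (i in is_cls("transient")) {
    k <- sample(1:2, 1)
    M[i, sample(exp_samps, k)] <- base[i]
  }

  producer_weights <- c(Porites = 0.10, Pocillopora = 0.30, CCA = 0.15,
                        Dictyota = 0.25, Turf = 0.20)
  draw_sources <- function() {
    k <- sample(1:5, 1, prob = c(0.86, 0.10, 0.02, 0.01, 0.01))
    sample(REEFEXO_PRODUCERS, k, prob = producer_weights)
  }
  draw_diel <- function() {
    sample(c("day", "night", "both"), 1, prob = c(0.6, 0.1, 0.3))
  }
  active_diels <- function(act) {
    switch(act, day = "Day", night = "Night", both = REEFEXO_DIEL)
  }

  fold_meanlog <- log(cfg$exo_fold_mean)
  fold_sdlog <- log(cfg$exo_fold_sd_factor)
  for (i in is_cls("exometabolite")) {
    M[i, exp_samps] <- base[i]
    src <- draw_sources()
    act <- draw_diel()
    fold <- .rlnorm_trunc(1, fold_meanlog, fold_sdlog, 2)
    truth$source_treatments[i] <- paste(sort(src), collapse = "+")
    truth$diel_activity[i] <- act
    truth$planted_fold_change[i] <- fold
    for (tr in src) {
      for (d in active_diels(act)) {
        M[i, cell_samples(tr, d)] <- base[i] * fold
      }
    }
  }
  ## benthic exudates: patchy release — one replicate per source cell
  ## carries a large spike, so the cell mean doubles over ambient while the
  ## within-cell variance stays structurally too large for the enrichment
  ## test to separate the cell from the Control
  for (i in is_cls("benthic_exudate")) {
    M[i, exp_samps] <- base[i]
    src <- sample(REEFEXO_PRODUCERS, sample(1:2, 1), prob = producer_weights)
    fold <- stats::runif(1, cfg$benthic_fold[1], cfg$benthic_fold[2])
    truth$source_treatments[i] <- paste(sort(src), collapse = "+")
    truth$diel_activity[i] <- "both"
    truth$planted_fold_change[i] <- (fold + cfg$replicates - 1) /
      cfg$replicates
    for (tr in src) {
      for (d in REEFEXO_DIEL) {
        cs <- cell_samples(tr, d)
        M[i, sample(cs, 1)] <- base[i] * fold
      }
    }
  }
  ## planktonic exudates: elevated in a single Control cell only
  for (i in is_cls("planktonic_exudate")) {
    M[i, exp_samps] <- base[i]
    d <- sample(REEFEXO_DIEL, 1, prob = c(0.7, 0.3))
    fold <- stats::runif(1, cfg$control_fold[1], cfg$control_fold[2])
    truth$diel_activity[i] <- tolower(d)
    truth$planted_fold_change[i] <- fold
    M[i, cell_samples("Control", d)] <- base[i] * fold
  }
  ## incubation artifacts: elevated in every incubated endpoint, both diels
  for (i in is_cls("incubation_artifact")) {
    M[i, exp_samps] <- base[i]
    fold <- stats::runif(1, cfg$control_fold[1], cfg$control_fold[2])
    truth$diel_activity[i] <- "both"
    truth$planted_fold_change[i] <- fold
    M[i, end_samps] <- base[i] * fold
  }

  ## measurement: multiplicative lognormal (mean-one) noise plus additive
  ## detector floor, truncated at zero
  noise <- exp(stats::rnorm(length(M), 0, 1) * SG - SG^2 / 2)
  areas <- M * noise + stats::rnorm(length(M), 0, cfg$detector_sd)
  areas[areas < 0] <- 0
  dim(areas) <- dim(M)
  dimnames(areas) <- dimnames(M)
  ft <- feature_table(areas)

  ## formulas: exudate-type features draw from their primary producer's
  ## template mix; ambient/background features from a seawater-DOM mix
  primary <- vapply(strsplit(truth$source_treatments, "\\+"), function(x) {
    if (length(x) && nzchar(x[1])) x[1] else NA_character_
  }, character(1))
  ambient_mix <- c(lipid_like = 0.1, sugar_like = 0.3, peptide_like = 0.3,
                   P_rich = 0.1, N_heterocycle = 0.2)
  ## exometabolite features in the top abundance quartile of their producer
  ## draw predominantly from that producer's signature template
  exo_set <- is_cls("exometabolite")
  top_tier <- rep(FALSE, n_tot)
  for (tr in REEFEXO_PRODUCERS) {
    mem <- exo_set[primary[exo_set] %in% tr]
    if (length(mem) >= 4) {
      planted_level <- base[mem] * truth$planted_fold_change[mem]
      top_tier[mem[planted_level >=
                     stats::quantile(planted_level, 0.75)]] <- TRUE
    }
  }
  tmpl <- character(n_tot)
  for (i in seq_len(n_tot)) {
    mix <- if (!is.na(primary[i])) {
      m <- .producer_template_mix[[primary[i]]]
      if (top_tier[i]) {
        sig <- .producer_signature[[primary[i]]]
        m <- 0.15 * m
        m[sig] <- m[sig] + 0.85
      }
      m
    } else {
      ambient_mix
    }
    tmpl[i] <- sample(names(mix), 1, prob = mix)
  }
  truth$formula_template <- tmpl
  formulas <- do.call(rbind, lapply(seq_len(n_tot), function(i) {
    generate_formula(tmpl[i], 1)
  }))

  ## subnetworks: chunk exometabolite features per (primary producer,
  ## template); other feature classes get their own looser clusters; ~40%
  ## of ambient features stay singletons
  truth$subnetwork_id <- NA_integer_
  next_id <- 1L
  exo_idx <- is_cls("exometabolite")
  if (length(exo_idx)) {
    key <- paste(primary[exo_idx], tmpl[exo_idx])
    for (k in unique(key)) {
      members <- exo_idx[key == k]
      while (length(members)) {
        size <- min(length(members), 3 + stats::rpois(1, 9))
        truth$subnetwork_id[members[seq_len(size)]] <- next_id
        next_id <- next_id + 1L
        members <- members[-seq_len(size)]
      }
    }
  }
  other_idx <- c(is_cls("benthic_exudate"), is_cls("planktonic_exudate"),
                 is_cls("ambient"))
  other_idx <- other_idx[stats::runif(length(other_idx)) > 0.4]
  while (length(other_idx)) {
    size <- min(length(other_idx), 2 + stats::rpois(1, 6))
    truth$subnetwork_id[other_idx[seq_len(size)]] <- next_id
    next_id <- next_id + 1L
    other_idx <- other_idx[-seq_len(size)]
  }

  ## annotation quality metrics tuned to pass the formula quality filter for
  ## roughly 60% of annotated features
  has_formula <- stats::runif(n_tot) < 0.85
  good <- stats::runif(n_tot) < 0.8
  zodiac <- ifelse(good, stats::runif(n_tot, 0.981, 1),
                   stats::runif(n_tot, 0.5, 0.98))
  chimeric <- stats::runif(n_tot) < 0.08
  frags <- 3L + stats::rpois(n_tot, 9)
  intens <- stats::runif(n_tot, 0.7, 1)
  annotations <- data.frame(
    feature_id = fid, formulas,
    has_formula = has_formula & !formulas$non_chnops,
    zodiac_score = ifelse(has_formula, zodiac, NA),
    chimeric = ifelse(has_formula, chimeric, NA),
    tree_fragments_explained = ifelse(has_formula, frags, NA),
    tree_intensity_explained = ifelse(has_formula, intens, NA),
    subnetwork_id = truth$subnetwork_id,
    structural_class = tmpl,
    library_match = ifelse(stats::runif(n_tot) < 0.15,
                           paste0("lib_", tmpl), NA_character_),
    stringsAsFactors = FALSE)
  annotations$C[!has_formula] <- NA
  annotations$zodiac_score[!has_formula] <- NA

  bulk <- .generate_bulk_impl(ft, metadata, truth, annotations, cfg)
  list(features = ft, metadata = metadata, annotations = annotations,
       bulk = bulk, truth = truth)
}

#' Generate bulk chemistry coupled to the planted exometabolome
#'
#' DOC is a linear function of the summed exudate-class peak area per sample
#' plus Gaussian noise calibrated so the realized coupling R-squared matches
#' the configured per-diel target; total dissolved N and P are proportional
#' to the planted abundance-weighted N:C and P:C of each producer sample's
#' exometabolite features; dissolved oxygen and pH carry the classic diel
#' producer signature (algal daytime oxygenation, nighttime respiration).
#'
#' @param ft Generated [feature_table()].
#' @param metadata Generated sample metadata.
#' @param truth Planted truth labels.
#' @param annotations Generated annotations (element counts for N:C/P:C).
#' @param config The [sim_config()].
#' @return Data.frame of bulk-chemistry records for experimental samples.
#' @export
generate_bulk_chemistry <- function(ft, metadata, truth, annotations,
                                    config) {
  with_preserved_seed(config$seed + 7L,
                      .generate_bulk_impl(ft, metadata, truth, annotations,
                                          config))
}

.generate_bulk_impl <- function(ft, metadata, truth, annotations, cfg) {
  exp_md <- metadata[metadata$role == "experimental", ]
  samps <- exp_md$sample_id
  exudate_cls <- c("exometabolite", "benthic_exudate", "planktonic_exudate",
                   "incubation_artifact")
  exu_ids <- truth$feature_id[truth$planted_class %in% exudate_cls]
  s_exu <- colSums(ft$areas[exu_ids, samps, drop = FALSE])

  doc <- numeric(length(samps))
  names(doc) <- samps
  for (d in REEFEXO_DIEL) {
    in_d <- !is.na(exp_md$diel) & exp_md$diel == d
    s <- s_exu[in_d]
    sd_sig <- stats::sd(s)
    b <- if (sd_sig > 0) 15 / sd_sig else 0
    r2 <- cfg$doc_r2[[d]]
    signal <- b * (s - min(s))
    eps <- stats::rnorm(sum(in_d))
    if (r2 < 1 && b > 0 && stats::sd(eps) > 0) {
      ## orthogonalize the noise to the signal and scale it so the realized
      ## coupling R-squared equals the configured target
      eps <- stats::residuals(stats::lm(eps ~ s))
      ss_sig <- sum((signal - mean(signal))^2)
      eps <- eps * sqrt(ss_sig * (1 / r2 - 1) / sum(eps^2))
    } else {
      eps <- 0 * eps
    }
    doc[in_d] <- cfg$doc_baseline + signal + eps
  }

  ## planted per-sample exometabolite N:C and P:C drive TDN / TDP
  nc <- pc <- numeric(length(samps))
  exo <- truth[truth$planted_class == "exometabolite", ]
  ann <- annotations[match(exo$feature_id, annotations$feature_id), ]
  for (j in seq_along(samps)) {
    tr <- exp_md$treatment[j]
    if (tr %in% REEFEXO_PRODUCERS && exp_md$timepoint[j] == "end") {
      hit <- grepl(tr, exo$source_treatments, fixed = TRUE) & !is.na(ann$C)
      if (any(hit)) {
        w <- ft$areas[exo$feature_id[hit], samps[j]]
        f <- ann[hit, ]
        nc[j] <- sum(w * f$N / f$C) / sum(w)
        pc[j] <- sum(w * f$P / f$C) / sum(w)
      }
    }
  }
  no3no2 <- pmax(stats::rnorm(length(samps), 0.4, 0.08), 0.02)
  nh4 <- pmax(stats::rnorm(length(samps), 0.3, 0.06), 0.02)
  po4 <- pmax(stats::rnorm(length(samps), 0.15, 0.03), 0.01)
  don <- pmax(4 + 25 * nc + stats::rnorm(length(samps), 0, 0.4), 0)
  dop <- pmax(0.15 + 8 * pc + stats::rnorm(length(samps), 0, 0.02), 0)
  tdn <- no3no2 + nh4 + don
  tdp <- po4 + dop

  ## dissolved oxygen / pH: daytime algal oxygenation, nighttime respiration
  do_eff <- c(Ambient = 0, Control = 0, Porites = -3, Pocillopora = -4,
              CCA = 12, Dictyota = 22, Turf = 35)
  o2 <- ph <- numeric(length(samps))
  for (j in seq_along(samps)) {
    tr <- exp_md$treatment[j]
    d <- exp_md$diel[j]
    eff <- if (exp_md$timepoint[j] == "end") {
      if (d == "Day") do_eff[[tr]] else -0.8 * abs(do_eff[[tr]]) - 5
    } else 0
    o2[j] <- 210 + eff + stats::rnorm(1, 0, 2.5)
    ph[j] <- 8.05 + eff / 400 + stats::rnorm(1, 0, 0.01)
  }
  data.frame(sample_id = samps, DO = o2, pH = ph, DOC = doc,
             PO4 = po4, NO3NO2 = no3no2, NH4 = nh4,
             silicate = pmax(stats::rnorm(length(samps), 1.5, 0.2), 0.1),
             TDN = tdn, TDP = tdp, DON = don, DOP = dop,
             stringsAsFactors = FALSE)
}

#' Write a simulated experiment to TSV files
#'
#' Writes the native long feature table, metadata, annotations, bulk
#' chemistry and truth labels.
#'
#' @param sim Output of [generate_experiment()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(sim$features, file.path(dir, "feature_table.tsv"))
  write_tsv(sim$metadata, file.path(dir, "sample_metadata.tsv"))
  ann <- sim$annotations
  ann$formula <- NA_character_
  for (i in which(ann$has_formula)) ann$formula[i] <- .format_formula(ann[i, ])
  keep <- c("feature_id", "formula", "zodiac_score", "chimeric",
            "tree_fragments_explained", "tree_intensity_explained",
            "subnetwork_id", "structural_class", "library_match")
  write_tsv(ann[keep], file.path(dir, "annotations.tsv"))
  write_tsv(sim$bulk, file.path(dir, "bulk_chemistry.tsv"))
  write_tsv(sim$truth, file.path(dir, "truth_labels.tsv"))
  invisible(dir)
}
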