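# Fixture builders and independently coded brute-force oracles for the
# classification rules. The oracles deliberately use plain loops and repeat
# the rule text rather than calling any package internals.

toy_metadata <- function(replicates = 3, n_blanks = 8) {
  rows <- list()
  for (d in c("Day", "Night")) {
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = sprintf("Ambient.%s.%d", d, seq_len(replicates)),
      role = "experimental", treatment = "Ambient", diel = d,
      timepoint = "start", replicate = seq_len(replicates),
      stringsAsFactors = FALSE)
    for (tr in c("Control", "Porites", "Pocillopora", "CCA", "Dictyota",
                 "Turf")) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("%s.%s.end.%d", tr, d, seq_len(replicates)),
        role = "experimental", treatment = tr, diel = d, timepoint = "end",
        replicate = seq_len(replicates), stringsAsFactors = FALSE)
    }
  }
  rows[[length(rows) + 1]] <- data.frame(
    sample_id = sprintf("Blank.%d", seq_len(n_blanks)), role = "blank",
    treatment = NA_character_, diel = NA_character_,
    timepoint = NA_character_, replicate = seq_len(n_blanks),
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

# random feature table over the study design with a mix of magnitudes and
# hard zeros, suitable for exercising every filter branch
random_feature_table <- function(n_feat, metadata, seed) {
  set.seed(seed)
  samps <- metadata$sample_id
  A <- matrix(rlnorm(n_feat * length(samps), log(3e5), 1.5),
              n_feat, length(samps),
              dimnames = list(sprintf("R%03d", seq_len(n_feat)), samps))
  A[runif(length(A)) < 0.25] <- 0
  feature_table(A)
}

oracle_background <- function(ft, metadata) {
  blanks <- metadata$sample_id[metadata$role == "blank"]
  smp <- setdiff(colnames(ft$areas), blanks)
  out <- character(0)
  for (f in rownames(ft$areas)) {
    if (mean(ft$areas[f, smp]) < 2 * max(ft$areas[f, blanks])) {
      out <- c(out, f)
    }
  }
  out
}

oracle_transient <- function(ft, metadata, threshold = 2e5) {
  smp <- intersect(metadata$sample_id[metadata$role == "experimental"],
                   colnames(ft$areas))
  out <- character(0)
  for (f in rownames(ft$areas)) {
    n_above <- 0
    for (s in smp) if (ft$areas[f, s] >= threshold) n_above <- n_above + 1
    if (n_above < 3) out <- c(out, f)
  }
  out
}

oracle_cell_means <- function(ft, metadata) {
  cells <- list()
  for (d in c("Day", "Night")) {
    for (tr in c("Control", "Porites", "Pocillopora", "CCA", "Dictyota",
                 "Turf")) {
      s <- metadata$sample_id[metadata$role == "experimental" &
                                metadata$treatment == tr &
                                !is.na(metadata$diel) & metadata$diel == d &
                                metadata$timepoint == "end"]
      s <- intersect(s, colnames(ft$areas))
      cells[[paste(tr, d, sep = ".")]] <- s
    }
  }
  cells
}

oracle_split <- function(ft, metadata, log2_threshold = 1, floor = 1e5) {
  amb <- metadata$sample_id[metadata$role == "experimental" &
                              metadata$treatment == "Ambient"]
  amb <- intersect(amb, colnames(ft$areas))
  cells <- oracle_cell_means(ft, metadata)
  exu <- character(0)
  for (f in rownames(ft$areas)) {
    amb_mean <- max(mean(ft$areas[f, amb]), floor)
    is_exu <- FALSE
    for (cs in cells) {
      ratio <- log2(max(mean(ft$areas[f, cs]), floor) / amb_mean)
      if (ratio > log2_threshold) is_exu <- TRUE
    }
    if (is_exu) exu <- c(exu, f)
  }
  list(exudate = exu, ambient = setdiff(rownames(ft$areas), exu))
}

oracle_subtypes <- function(ft, metadata, exudate_ids, exometabolite_ids,
                            floor = 1e5) {
  amb <- metadata$sample_id[metadata$role == "experimental" &
                              metadata$treatment == "Ambient"]
  amb <- intersect(amb, colnames(ft$areas))
  cells <- oracle_cell_means(ft, metadata)
  out <- character(0)
  for (f in setdiff(exudate_ids, exometabolite_ids)) {
    amb_mean <- max(mean(ft$areas[f, amb]), floor)
    doubled <- vapply(cells, function(cs) {
      max(mean(ft$areas[f, cs]), floor) / amb_mean >= 2
    }, logical(1))
    ctrl_day <- doubled[["Control.Day"]]
    ctrl_night <- doubled[["Control.Night"]]
    organismal <- any(doubled[setdiff(names(doubled),
                                      c("Control.Day", "Control.Night"))])
    out[f] <- if (ctrl_day && ctrl_night) "incubation_artifact"
      else if (organismal) "benthic_exudate"
      else if (ctrl_day || ctrl_night) "planktonic_exudate"
      else "benthic_exudate"
  }
  out
}

# small simulated experiment for fast module tests
small_sim <- function(seed = 1) {
  generate_experiment(sim_config(
    n_features = c(background = 40, transient = 15, ambient = 80,
                   exometabolite = 50, benthic_exudate = 30,
                   planktonic_exudate = 15, incubation_artifact = 10),
    seed = seed))
}

four_way <- function(x) {
  ifelse(x %in% c("exometabolite", "benthic_exudate", "planktonic_exudate",
                  "incubation_artifact"), "exudate", x)
}
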