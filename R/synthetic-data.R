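#' Specify a synthetic study design
#'
#' Describes a simulated short-term toxicogenomics study mirroring the
#' multi-compound mouse liver design: 14 compounds in four carcinogenicity
#' classes (3 genotoxic carcinogens, one of them dosed at two levels; 3
#' nongenotoxic carcinogens; 4 non-carcinogens; 3 compounds of undefined
#' class), two sexes, dosing durations of 3 and 14 days with time-matched
#' vehicle controls, and 6 replicate animals per treatment group. Three
#' disjoint probeset sets carry planted differential expression:
#' carcinogen-shared, GC-specific and NGC-specific effects; undefined
#' compounds are generated from an explicit GC-like or NGC-like regime so
#' their correct call is known. Effects at day 3 are attenuated relative to
#' day 14.
#'
#' @param n_probesets total probesets (default 2000).
#' @param n_shared,n_gc,n_ngc planted set sizes (defaults 20/20/20).
#' @param effect_size mean log2 shift of planted probesets in units of the
#'   replicate SD (default 2.0).
#' @param replicate_sd within-group log2 SD (default 0.5).
#' @param replicates animals per treatment group (default 6).
#' @param attenuation_day3 multiplier on planted effects at day 3 vs day 14
#'   (default 0.6).
#' @param sex_effect_frac fraction of probesets with a sex-specific baseline
#'   shift in males (default 0.05).
#' @param sex_effect_shift magnitude of that shift in log2 units
#'   (default 0.5).
#' @param seed integer seed.
#' @return list of class `SyntheticDesign`.
#' @export
synthetic_design <- function(n_probesets = 2000, n_shared = 20, n_gc = 20,
                             n_ngc = 20, effect_size = 2.0,
                             replicate_sd = 0.5, replicates = 6,
                             attenuation_day3 = 0.6,
                             sex_effect_frac = 0.05, sex_effect_shift = 0.5,
                             seed = 0L) {
  if (n_shared + n_gc + n_ngc > n_probesets)
    stop("planted sets exceed the number of probesets")
  if (effect_size < 0) stop("effect_size must be >= 0")
  stopifnot(n_probesets > 0, replicates > 0, replicate_sd > 0)
  compounds <- data.frame(
    compound = c("GTXA", "GTXB", "GTXC", "GTXC",
                 "NGXA", "NGXB", "NGXC",
                 "NCA", "NCB", "NCC", "NCD",
                 "UNDA", "UNDB", "UNDC"),
    class_label = c(rep("GC", 4), rep("NGC", 3), rep("NC", 4),
                    rep("UNDEF", 3)),
    vehicle = c("CO", "CO", "CO", "CO", "CMC", "CO", "CMC",
                "CMC", "CMC", "CO", "CMC", "CO", "CMC", "CMC"),
    dose = c(2500, 2, 50, 75, 80, 600, 600, 250, 50, 5, 80, 160, 20, 200),
    regime = c(rep(NA, 11), "NGC", "GC", "GC"),
    stringsAsFactors = FALSE)
  structure(list(n_probesets = n_probesets, n_shared = n_shared,
                 n_gc = n_gc, n_ngc = n_ngc, effect_size = effect_size,
                 replicate_sd = replicate_sd, replicates = replicates,
                 attenuation_day3 = attenuation_day3,
                 sex_effect_frac = sex_effect_frac,
                 sex_effect_shift = sex_effect_shift,
                 compounds = compounds, durations = c(3L, 14L),
                 seed = as.integer(seed)),
            class = "SyntheticDesign")
}

#' Generate a synthetic expression dataset with known ground truth
#'
#' Baseline log2 expression per probeset is drawn from Normal(8, 1); each
#' sample adds Normal(0, replicate_sd) replicate noise; male samples add a
#' sex-specific baseline shift on a random subset of probesets. Treated
#' samples of carcinogenic compounds additionally shift the
#' carcinogen-shared set plus their class-specific planted set (signs fixed
#' per probeset) by `effect_size * replicate_sd` log2 units, multiplied by
#' the day-3 attenuation factor at the short duration; non-carcinogens shift
#' nothing; undefined compounds follow their generative regime. Output is
#' bit-reproducible for a fixed seed.
#'
#' @param design a [SyntheticDesign][synthetic_design].
#' @return list with `dataset` (an
#'   [ExpressionDataset][expression_dataset]), `truth` (a `GroundTruth`:
#'   planted sets, per-compound class, per-undefined-compound regime) and
#'   `design`.
#' @export
generate_synthetic_dataset <- function(design) {
  stopifnot(inherits(design, "SyntheticDesign"))
  set.seed(design$seed)
  P <- design$n_probesets
  ids <- sprintf("ps%05d", seq_len(P))
  planted <- sample.int(P, design$n_shared + design$n_gc + design$n_ngc)
  shared <- planted[seq_len(design$n_shared)]
  gc_set <- planted[design$n_shared + seq_len(design$n_gc)]
  ngc_set <- planted[design$n_shared + design$n_gc + seq_len(design$n_ngc)]
  sign_vec <- numeric(P)
  sign_vec[planted] <- sample(c(-1, 1), length(planted), replace = TRUE)
  baseline <- stats::rnorm(P, mean = 8, sd = 1)
  sex_idx <- sample.int(P, round(design$sex_effect_frac * P))
  sex_shift <- numeric(P)
  sex_shift[sex_idx] <- design$sex_effect_shift *
    sample(c(-1, 1), length(sex_idx), replace = TRUE)
  amp <- design$effect_size * design$replicate_sd

  effect_for <- function(class_label, regime) {
    eff <- numeric(P)
    reg <- if (class_label == "UNDEF") regime else class_label
    if (identical(reg, "GC")) idx <- c(shared, gc_set)
    else if (identical(reg, "NGC")) idx <- c(shared, ngc_set)
    else idx <- integer(0)
    eff[idx] <- amp * sign_vec[idx]
    eff
  }

  ann <- NULL
  cols <- list()
  for (d in design$durations) {
    att <- if (d == 3L) design$attenuation_day3 else 1
    # control groups per vehicle and sex
    for (veh in unique(design$compounds$vehicle)) {
      for (sx in c("F", "M")) {
        gid <- paste0(veh, "_CTRL_", sx, "_D", d)
        for (r in seq_len(design$replicates)) {
          sid <- paste0(gid, "_r", r)
          mu <- baseline + if (sx == "M") sex_shift else 0
          cols[[sid]] <- mu + stats::rnorm(P, 0, design$replicate_sd)
          ann <- rbind(ann, data.frame(
            sample_id = sid, group_id = gid, compound = veh, vehicle = veh,
            dose = 0, sex = sx, duration_days = d, class_label = "CONTROL",
            stringsAsFactors = FALSE))
        }
      }
    }
    for (i in seq_len(nrow(design$compounds))) {
      cm <- design$compounds[i, ]
      eff <- effect_for(cm$class_label, cm$regime) * att
      for (sx in c("F", "M")) {
        gid <- paste0(cm$compound, "_", cm$dose, "_", sx, "_D", d)
        for (r in seq_len(design$replicates)) {
          sid <- paste0(gid, "_r", r)
          mu <- baseline + eff + if (sx == "M") sex_shift else 0
          cols[[sid]] <- mu + stats::rnorm(P, 0, design$replicate_sd)
          ann <- rbind(ann, data.frame(
            sample_id = sid, group_id = gid, compound = cm$compound,
            vehicle = cm$vehicle, dose = cm$dose, sex = sx,
            duration_days = d, class_label = cm$class_label,
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- ids
  truth <- structure(list(
    shared = ids[shared], gc = ids[gc_set], ngc = ids[ngc_set],
    compound_class = stats::setNames(design$compounds$class_label,
                                     design$compounds$compound),
    undef_regime = stats::setNames(
      design$compounds$regime[design$compounds$class_label == "UNDEF"],
      design$compounds$compound[design$compounds$class_label == "UNDEF"])),
    class = "GroundTruth")
  list(dataset = expression_dataset(values, ann), truth = truth,
       design = design)
}

#' Planted probesets relevant to a binary task
#'
#' The carcinogen-shared set is the consistent marker set for
#' carcinogen-vs-non-carcinogen discrimination (class-specific sets are
#' differential in only part of the carcinogen class); the two class-specific
#' sets discriminate GC from NGC; class-vs-NC tasks use the shared set plus
#' that class's specific set.
#'
#' @param truth a `GroundTruth`.
#' @param task one of the four binary task names.
#' @return character vector of probeset ids.
#' @export
relevant_planted <- function(truth, task = TASKS) {
  task <- match.arg(task)
  switch(task,
    C_vs_NC = truth$shared,
    GC_vs_NGC = c(truth$gc, truth$ngc),
    GC_vs_NC = c(truth$shared, truth$gc),
    NGC_vs_NC = c(truth$shared, truth$ngc))
}

#' Fraction of planted task-relevant probesets recovered by a signature
#'
#' @param consensus a `ConsensusSignature` or character vector of probeset
#'   ids.
#' @param truth a `GroundTruth` from [generate_synthetic_dataset()].
#' @param task binary task name.
#' @return |signature intersect relevant| / |relevant| in [0, 1].
#' @export
recovery_score <- function(consensus, truth, task = TASKS) {
  ids <- if (inherits(consensus, "ConsensusSignature"))
    consensus$probeset_ids else as.character(consensus)
  if (!length(ids)) stop("consensus signature is empty")
  rel <- relevant_planted(truth, task)
  length(intersect(ids, rel)) / length(rel)
}

#' Write a synthetic dataset as the tab-delimited input formats
#'
#' Emits `expression.tsv` (probesets x samples, first column `probeset_id`)
#' and `annotations.tsv` (the 7 annotation columns plus `sample_id`) into a
#' directory, exactly as consumed by [read_expression_table()] and
#' [read_annotation_table()].
#'
#' @param sim result of [generate_synthetic_dataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, the two file paths.
#' @export
write_synthetic_tables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ep <- file.path(dir, "expression.tsv")
  ap <- file.path(dir, "annotations.tsv")
  df <- data.frame(probeset_id = rownames(sim$dataset$values),
                   sim$dataset$values, check.names = FALSE)
  utils::write.table(df, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- sim$dataset$annotations
  names(ann)[names(ann) == "duration_days"] <- "duration"
  names(ann)[names(ann) == "class_label"] <- "class"
  utils::write.table(ann, ap, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expression = ep, annotations = ap))
}
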