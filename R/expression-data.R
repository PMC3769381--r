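#' @keywords internal
"_PACKAGE"

CLASS_LEVELS <- c("GC", "NGC", "NC", "UNDEF", "CONTROL")
TASKS <- c("C_vs_NC", "GC_vs_NGC", "GC_vs_NC", "NGC_vs_NC")

#' Construct an expression dataset
#'
#' Bundles a log2 expression matrix (probesets in rows, samples in columns)
#' with per-sample annotations and validates the study design: unique ids,
#' finite values, and a time-matched vehicle control group for every treated
#' sample.
#'
#' @param values numeric matrix of normalized log2 expression, probesets x
#'   samples, with rownames (probeset ids) and colnames (sample ids).
#' @param annotations data.frame with one row per sample and columns
#'   `sample_id`, `group_id`, `compound`, `vehicle`, `dose`, `sex`,
#'   `duration_days`, `class_label`. Class labels must be one of
#'   GC, NGC, NC, UNDEF, CONTROL; durations 3 or 14.
#' @return an object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(values, annotations) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry probeset ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated probeset ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  annotations <- validate_annotations(annotations)
  missing <- setdiff(colnames(values), annotations$sample_id)
  if (length(missing))
    stop("samples without annotation: ", paste(missing, collapse = ", "))
  annotations <- annotations[match(colnames(values), annotations$sample_id), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  # every treated (vehicle, duration) pair needs >= 1 control sample
  ctrl <- annotations[annotations$class_label == "CONTROL", , drop = FALSE]
  trt  <- annotations[annotations$class_label != "CONTROL", , drop = FALSE]
  need <- unique(trt[, c("vehicle", "duration_days")])
  for (i in seq_len(nrow(need))) {
    hit <- ctrl$vehicle == need$vehicle[i] &
      ctrl$duration_days == need$duration_days[i]
    if (!any(hit))
      stop("no time-matched control samples for vehicle ", need$vehicle[i],
           " at duration ", need$duration_days[i], " days")
  }
  structure(list(values = values, annotations = annotations),
            class = "ExpressionDataset")
}

validate_annotations <- function(a) {
  req <- c("sample_id", "group_id", "compound", "vehicle", "dose", "sex",
           "duration_days", "class_label")
  miss <- setdiff(req, names(a))
  if (length(miss))
    stop("annotation table lacks columns: ", paste(miss, collapse = ", "))
  a$duration_days <- as.integer(a$duration_days)
  bad <- !a$duration_days %in% c(3L, 14L)
  if (any(bad))
    stop("duration_days must be 3 or 14; offending rows: ",
         paste(which(bad), collapse = ", "))
  bad <- !a$class_label %in% CLASS_LEVELS
  if (any(bad))
    stop("unknown class label(s): ",
         paste(unique(a$class_label[bad]), collapse = ", "),
         " (must be one of ", paste(CLASS_LEVELS, collapse = "/"), ")")
  ctrl <- a$class_label == "CONTROL"
  if (any(ctrl & a$compound != a$vehicle))
    stop("CONTROL samples must have compound equal to the vehicle name")
  a
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", nrow(x$values), "probesets x",
      ncol(x$values), "samples\n")
  cat("  durations:", paste(sort(unique(x$annotations$duration_days)),
                            collapse = ", "), "days\n")
  cat("  classes:  ",
      paste(names(table(x$annotations$class_label)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a tab-delimited expression table
#'
#' Expects probesets in rows and samples in columns: a header row of sample
#' ids and a first column named `probeset_id`. All cells must be numeric and
#' finite; duplicated ids and non-numeric cells are hard errors naming the
#' offender.
#'
#' @param path path to a tab-separated text file.
#' @return numeric matrix (probesets x samples); combine with annotations via
#'   [expression_dataset()].
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop("expression table needs a probeset column and >=1 sample")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicated probeset ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric or non-finite cell at probeset '", ids[bad[1, 1]],
         "', sample '", colnames(num)[bad[1, 2]], "'")
  }
  if (anyDuplicated(colnames(num)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(num)[duplicated(colnames(num))]), collapse = ", "))
  message("read expression table: ", nrow(num), " probesets x ",
          ncol(num), " samples")
  num
}

#' Read a tab-delimited sample annotation table
#'
#' One row per sample with columns `sample_id`, `group_id`, `compound`,
#' `vehicle`, `dose`, `sex`, `duration` (days, 3 or 14) and `class`
#' (GC/NGC/NC/UNDEF/CONTROL).
#'
#' @param path path to a tab-separated text file.
#' @return data.frame of validated annotations (columns renamed to
#'   `duration_days` / `class_label`).
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  a <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if ("duration" %in% names(a) && !"duration_days" %in% names(a))
    names(a)[names(a) == "duration"] <- "duration_days"
  if ("class" %in% names(a) && !"class_label" %in% names(a))
    names(a)[names(a) == "class"] <- "class_label"
  validate_annotations(a)
}

#' Collapse samples into treatment-group fold-change profiles
#'
#' Each non-control treatment group at the requested dosing duration becomes
#' one profile: the vector over all probesets of mean log2 expression of the
#' treated replicates minus mean log2 expression of the time-matched vehicle
#' control replicates (i.e. a mean log2 fold change). Both sexes are kept as
#' separate groups; controls are matched on vehicle and duration.
#'
#' @param ds an [ExpressionDataset][expression_dataset].
#' @param duration dosing duration in days, 3 or 14.
#' @return an object of class `GroupProfiles`: list with `fold_changes`
#'   (groups x probesets matrix) and `info` (per-group metadata).
#' @export
compute_group_profiles <- function(ds, duration) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  duration <- as.integer(duration)
  if (!duration %in% c(3L, 14L)) stop("duration must be 3 or 14")
  a <- ds$annotations
  at <- a[a$duration_days == duration & a$class_label != "CONTROL", , drop = FALSE]
  ac <- a[a$duration_days == duration & a$class_label == "CONTROL", , drop = FALSE]
  if (!nrow(at)) stop("no treated samples at duration ", duration)
  groups <- unique(at$group_id)
  fc <- matrix(NA_real_, nrow = length(groups), ncol = nrow(ds$values),
               dimnames = list(groups, rownames(ds$values)))
  info <- NULL
  for (g in groups) {
    rows <- at[at$group_id == g, , drop = FALSE]
    ctrl <- ac[ac$vehicle == rows$vehicle[1], , drop = FALSE]
    if (!nrow(ctrl))
      stop("treated group ", g, " has no control samples for vehicle ",
           rows$vehicle[1], " at duration ", duration, " days")
    mt <- rowMeans(ds$values[, rows$sample_id, drop = FALSE])
    mc <- rowMeans(ds$values[, ctrl$sample_id, drop = FALSE])
    fc[g, ] <- mt - mc
    info <- rbind(info, rows[1, c("group_id", "compound", "vehicle", "dose",
                                  "sex", "duration_days", "class_label")])
  }
  rownames(info) <- NULL
  structure(list(fold_changes = fc, info = info), class = "GroupProfiles")
}

#' @export
print.GroupProfiles <- function(x, ...) {
  cat("GroupProfiles:", nrow(x$fold_changes), "treatment groups x",
      ncol(x$fold_changes), "probesets (",
      unique(x$info$duration_days), "days )\n")
  print(table(x$info$class_label))
  invisible(x)
}

#' Subset a GroupProfiles object by group
#'
#' @param profiles a `GroupProfiles` object.
#' @param idx integer or logical index over groups.
#' @return the subsetted `GroupProfiles`.
#' @export
subset_profiles <- function(profiles, idx) {
  structure(list(fold_changes = profiles$fold_changes[idx, , drop = FALSE],
                 info = profiles$info[idx, , drop = FALSE]),
            class = "GroupProfiles")
}

#' Binary labels for a classification task
#'
#' Maps class labels to a two-level factor for one of the four binary tasks.
#' C_vs_NC pools GC and NGC into the carcinogen class. Groups whose class is
#' not part of the task (including UNDEF) get NA.
#'
#' @param class_label character vector of GC/NGC/NC/UNDEF labels.
#' @param task one of "C_vs_NC", "GC_vs_NGC", "GC_vs_NC", "NGC_vs_NC".
#' @return factor with levels c(negative, positive); the positive class is
#'   the first named class of the task (C, GC, GC, NGC respectively).
#' @export
task_labels <- function(class_label, task = TASKS) {
  task <- match.arg(task)
  pos_neg <- switch(task,
    C_vs_NC    = list(pos = c("GC", "NGC"), neg = "NC",
                      names = c("NC", "C")),
    GC_vs_NGC  = list(pos = "GC", neg = "NGC", names = c("NGC", "GC")),
    GC_vs_NC   = list(pos = "GC", neg = "NC",  names = c("NC", "GC")),
    NGC_vs_NC  = list(pos = "NGC", neg = "NC", names = c("NC", "NGC")))
  out <- rep(NA_character_, length(class_label))
  out[class_label %in% pos_neg$pos] <- pos_neg$names[2]
  out[class_label %in% pos_neg$neg] <- pos_neg$names[1]
  factor(out, levels = pos_neg$names)
}

#' Standardize fold-change features with training-set statistics
#'
#' Computes per-feature mean and sample (n-1) standard deviation on the
#' training matrix only and applies the z-score transform to both training
#' and test matrices. A zero-variance training feature gets SD set to 1 (the
#' feature becomes constantly 0) with a warning, so applying a signature
#' never aborts on a flat gene.
#'
#' @param train numeric matrix (profiles x features) or `GroupProfiles`.
#' @param test optional matrix / `GroupProfiles` standardized with the
#'   training statistics (never its own).
#' @param features optional character vector of feature (probeset) ids to
#'   restrict to before standardizing.
#' @return list with `train`, `test` (or NULL), `center`, `scale`.
#' @export
zscore_fit_apply <- function(train, test = NULL, features = NULL) {
  xt <- as_fc_matrix(train)
  xs <- if (!is.null(test)) as_fc_matrix(test)
  if (!is.null(features)) {
    if (!length(features)) stop("'features' must be nonempty")
    miss <- setdiff(features, colnames(xt))
    if (length(miss))
      stop("features absent from training matrix: ",
           paste(utils::head(miss, 5), collapse = ", "))
    xt <- xt[, features, drop = FALSE]
    if (!is.null(xs)) xs <- xs[, features, drop = FALSE]
  }
  if (nrow(xt) < 2) stop("need >= 2 training profiles to estimate SDs")
  ctr <- colMeans(xt)
  scl <- apply(xt, 2, stats::sd)
  flat <- !is.finite(scl) | scl == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance feature(s) on training data; SD set to 1")
    scl[flat] <- 1
  }
  list(train = scale(xt, center = ctr, scale = scl)[, , drop = FALSE],
       test = if (!is.null(xs)) scale(xs, center = ctr, scale = scl)[, , drop = FALSE],
       center = ctr, scale = scl)
}

as_fc_matrix <- function(x) {
  if (inherits(x, "GroupProfiles")) return(x$fold_changes)
  if (is.matrix(x)) return(x)
  stop("expected a GroupProfiles object or a numeric matrix")
}
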