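#' Subject-by-feature table with group labels and feature metadata
#'
#' The container moved through the preprocessing chain. Holds a numeric
#' subjects x features matrix (missing cells permitted), a per-subject group
#' label (\code{"patient"} or \code{"control"}), and per-feature metadata:
#' \code{modality} (structural, task, resting, clinical, functioning or
#' cognitive), a \code{reverse} flag (negate after standardization so higher
#' always means better), and the \code{reference} group whose mean/SD define
#' the z-standardization (control for most features; patient for clinical and
#' daily-functioning scales, whose variability in controls is too limited to
#' serve as a reference).
#'
#' Completed preprocessing stages are tracked in the \code{"stages"}
#' attribute, and each stage validates its position in the fixed order
#' average_hemispheres -> standardize -> winsorize -> reverse_code ->
#' impute -> residualize.
#'
#' @param values numeric matrix, subjects x features; rownames are used as
#'   subject IDs if \code{subject_ids} is not given.
#' @param group character vector of \code{"patient"}/\code{"control"} labels.
#' @param meta data frame with columns \code{name}, \code{modality},
#'   \code{reverse} (logical), \code{reference}; defaults to
#'   control-referenced, non-reversed cognitive features.
#' @param subject_ids optional character vector of unique subject IDs.
#' @return object of class \code{"feature_table"}.
#' @export
feature_table <- function(values, group, meta = NULL, subject_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  subject_ids <- subject_ids %||% rownames(values) %||% sprintf("S%03d", seq_len(n))
  if (anyDuplicated(subject_ids)) stopf("subject IDs must be unique")
  if (length(subject_ids) != n) stopf("subject_ids length %d != %d rows", length(subject_ids), n)
  group <- as.character(group)
  if (length(group) != n) stopf("group length %d != %d rows", length(group), n)
  if (!all(group %in% c("patient", "control"))) {
    stopf("group labels must be 'patient' or 'control'; found: %s",
          paste(setdiff(unique(group), c("patient", "control")), collapse = ", "))
  }
  feat_names <- colnames(values) %||% sprintf("f%02d", seq_len(p))
  if (anyDuplicated(feat_names)) stopf("feature names must be unique")
  if (is.null(meta)) {
    meta <- data.frame(name = feat_names, modality = "cognitive",
                       reverse = FALSE, reference = "control",
                       stringsAsFactors = FALSE)
  }
  req <- c("name", "modality", "reverse", "reference")
  if (!all(req %in% names(meta))) stopf("meta must have columns %s", paste(req, collapse = ", "))
  meta <- meta[match(feat_names, meta$name), req]
  if (anyNA(meta$name)) stopf("meta is missing rows for some features")
  ok_mod <- c("structural", "task", "resting", "clinical", "functioning", "cognitive")
  if (!all(meta$modality %in% ok_mod)) stopf("modality must be one of %s", paste(ok_mod, collapse = ", "))
  if (!all(meta$reference %in% c("control", "patient"))) stopf("reference must be 'control' or 'patient'")
  meta$reverse <- as.logical(meta$reverse)
  rownames(values) <- subject_ids
  colnames(values) <- feat_names
  rownames(meta) <- NULL
  structure(list(values = values, group = group, meta = meta),
            class = "feature_table", stages = character(0))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d subjects (%d patients, %d controls) x %d features\n",
              nrow(x$values), sum(x$group == "patient"), sum(x$group == "control"),
              ncol(x$values)))
  cat(sprintf("  modalities: %s\n", paste(sprintf("%s (%d)", names(table(x$meta$modality)),
                                                  table(x$meta$modality)), collapse = ", ")))
  st <- attr(x, "stages")
  cat(sprintf("  missing cells: %d; stages done: %s\n", sum(is.na(x$values)),
              if (length(st)) paste(st, collapse = " -> ") else "none"))
  invisible(x)
}

stages_done <- function(table) attr(table, "stages") %||% character(0)

mark_stage <- function(table, stage) {
  attr(table, "stages") <- c(stages_done(table), stage)
  table
}

# The fixed chain; `stage` must not already be done and everything mandatory
# before it must be.
check_stage <- function(table, stage) {
  order <- c("average_hemispheres", "standardize", "winsorize", "reverse_code",
             "impute", "residualize")
  optional <- c("average_hemispheres", "impute")  # impute is a no-op without missing cells
  done <- stages_done(table)
  if (stage %in% done) stopf("stage '%s' already applied", stage)
  idx <- match(stage, order)
  needed <- setdiff(order[seq_len(idx - 1)], optional)
  missing_stage <- setdiff(needed, done)
  if (length(missing_stage)) {
    stopf("stage '%s' requires '%s' first (fixed order: %s)", stage,
          missing_stage[1], paste(order, collapse = " -> "))
  }
  invisible(TRUE)
}
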