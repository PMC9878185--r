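#' Schema of the 23 clinical features
#'
#' Defines, for every clinical feature, its kind (`continuous`, `binary`,
#' `ordinal`) and, for categorical kinds, the category vocabulary in
#' encoding order.  Binaries encode N = 0 / Y = 1; ordinals encode
#' consecutive integers from 0 in the listed order.
#'
#' @return data.frame with columns `feature`, `kind` and a list column
#'   `levels`.
#' @export
clinical_schema <- function() {
  bin <- c("N", "Y")
  lv <- list(
    age_y = NULL,
    age_first_onset_y = NULL,
    years_since_onset = NULL,
    gender = c("male", "female"),
    family_history = bin,
    head_surgery_trauma = bin,
    cns_infection = bin,
    perinatal_injury = bin,
    tle = bin,
    mri_abnormal = bin,
    hippocampal_atrophy_sclerosis = bin,
    seizure_type = c("generalized", "focal", "both"),
    status_epilepticus = bin,
    gtcs = bin,
    seizure_frequency = c("rare", "occasional", "frequent"),
    asm_class_ge2 = bin,
    vpa = bin,
    pht = bin,
    tpm = bin,
    aura = bin,
    anxiety = c("none", "possible", "definitely", "definitely_obvious"),
    depression = c("none", "possible", "definitely"),
    education = c("<=6y", "7-9y", "10-12y", ">=13y")
  )
  kind <- vapply(names(lv), function(f) {
    if (is.null(lv[[f]])) "continuous"
    else if (length(lv[[f]]) == 2 && identical(lv[[f]], bin)) "binary"
    else "ordinal"
  }, "")
  kind["gender"] <- "binary"
  data.frame(feature = names(lv), kind = unname(kind),
             levels = I(unname(lv)), stringsAsFactors = FALSE)
}

#' Encode a clinical table to numeric form
#'
#' Maps categorical features to integers per [clinical_schema()] (binaries
#' to 0/1, ordinals to 0-based consecutive integers in vocabulary order)
#' and passes continuous features through.  Missing values and
#' out-of-vocabulary categories are errors, not imputed.
#'
#' @param df data.frame with columns `subject_id`, `group` (CON/CI) and one
#'   column per schema feature holding category strings or numbers.
#' @return data.frame with `subject_id`, `group` and the 23 features as
#'   numerics, class `clinical_encoded`.
#' @export
encode_clinical <- function(df) {
  sch <- clinical_schema()
  need <- c("subject_id", "group", sch$feature)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(df$group %in% c("CON", "CI")))
    stop("group labels must be CON or CI")
  out <- data.frame(subject_id = as.character(df$subject_id),
                    group = as.character(df$group),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sch))) {
    f <- sch$feature[i]
    v <- df[[f]]
    if (anyNA(v)) stop("missing values in clinical feature '", f,
                       "' (no imputation is performed)")
    if (sch$kind[i] == "continuous") {
      out[[f]] <- as.numeric(v)
    } else {
      vocab <- sch$levels[[i]]
      code <- match(as.character(v), vocab) - 1L
      if (anyNA(code)) {
        bad <- unique(as.character(v)[is.na(code)])
        stop("feature '", f, "': unknown category value(s) ",
             paste(sQuote(bad), collapse = ", "))
      }
      out[[f]] <- as.numeric(code)
    }
  }
  if (any(out$age_y < 0) || any(out$age_first_onset_y < 0))
    stop("ages must be non-negative")
  if (any(out$years_since_onset > out$age_y))
    stop("years_since_onset cannot exceed age")
  class(out) <- c("clinical_encoded", "data.frame")
  out
}

#' Decode an encoded clinical table back to category strings
#'
#' Inverse of [encode_clinical()] on the categorical fields (continuous
#' features pass through), so encode-decode is the identity.
#'
#' @param enc a `clinical_encoded` data.frame.
#' @return data.frame in the string form accepted by [encode_clinical()].
#' @export
decode_clinical <- function(enc) {
  sch <- clinical_schema()
  out <- data.frame(subject_id = enc$subject_id, group = enc$group,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sch))) {
    f <- sch$feature[i]
    if (sch$kind[i] == "continuous") out[[f]] <- enc[[f]]
    else out[[f]] <- sch$levels[[i]][enc[[f]] + 1L]
  }
  out
}

#' Assemble the subject feature table
#'
#' Inner-joins encoded clinical rows with per-subject PLV feature vectors
#' by `subject_id` and returns one of three views: clinical only (23
#' columns), PLV only (684), or combined (707).
#'
#' @param clinical a `clinical_encoded` data.frame (see
#'   [encode_clinical()]); may be `NULL` for the `"plv"` view.
#' @param plv named list (by subject id) of PLV feature vectors as from
#'   [extract_plv_features()], or a matrix with subject-id rownames; may be
#'   `NULL` for the `"clinical"` view, in which case `clinical` supplies
#'   the subjects.
#' @param view one of `"combined"`, `"clinical"`, `"plv"`.
#' @param labels optional named group vector (CON/CI by subject id),
#'   required when `clinical` is `NULL`.
#' @return A `subject_table`: data.frame with `subject_id`, `group`, then
#'   feature columns.
#' @export
assemble_table <- function(clinical = NULL, plv = NULL,
                           view = c("combined", "clinical", "plv"),
                           labels = NULL) {
  view <- match.arg(view)
  if (view != "plv" && is.null(clinical))
    stop("view '", view, "' requires clinical data")
  if (view != "clinical" && is.null(plv))
    stop("view '", view, "' requires PLV features")

  if (!is.null(plv) && is.list(plv) && !is.data.frame(plv))
    plv <- do.call(rbind, plv)

  if (is.null(clinical)) {
    if (is.null(labels)) stop("labels required when clinical is NULL")
    ids <- rownames(plv)
    if (!all(ids %in% names(labels)))
      stop("labels missing for subject(s): ",
           paste(setdiff(ids, names(labels)), collapse = ", "))
    base <- data.frame(subject_id = ids, group = unname(labels[ids]),
                       stringsAsFactors = FALSE)
  } else {
    base <- clinical[, c("subject_id", "group")]
  }

  out <- base
  if (view %in% c("combined", "clinical"))
    out <- cbind(out, clinical[, setdiff(names(clinical),
                                         c("subject_id", "group")),
                               drop = FALSE])
  if (view %in% c("combined", "plv")) {
    only_clin <- setdiff(base$subject_id, rownames(plv))
    only_plv <- setdiff(rownames(plv), base$subject_id)
    if (length(only_clin) || length(only_plv))
      stop("subject sets do not match; unmatched: ",
           paste(c(only_clin, only_plv), collapse = ", "))
    out <- cbind(out, as.data.frame(plv[base$subject_id, , drop = FALSE],
                                    optional = TRUE))
  }
  rownames(out) <- NULL
  class(out) <- c("subject_table", "data.frame")
  attr(out, "view") <- view
  out
}

# internal: split a subject_table into feature matrix x and label factor y
# (positive class CI is the second level)
table_xy <- function(tab) {
  stopifnot(inherits(tab, "data.frame"))
  x <- as.matrix(tab[, setdiff(names(tab), c("subject_id", "group")),
                     drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- tab$subject_id
  y <- factor(tab$group, levels = c("CON", "CI"))
  if (anyNA(y)) stop("group labels must be CON or CI")
  list(x = x, y = y)
}
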