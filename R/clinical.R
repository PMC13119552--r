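# Schema, imputation and standardization for the 13 clinical variables.
#
# Nine continuous variables (age, bmi, bun, creatinine, ephedrine,
# op_duration, phenylephrine, potassium, sodium) are z-scored with training
# statistics and median-imputed when missing; four binary variables
# (diabetes, emergency, hypertension, sex) pass through as {0, 1} and are
# mode-imputed. Field order is fixed alphabetically so the standardized
# 13-vector feeding the clinical encoder and retrieval index is stable.
# Vasopressor doses of zero are valid observations, not missing values.

#' Clinical field schema
#'
#' @return List with `fields` (the 13 field names in their fixed order),
#'   `continuous` and `binary` subsets.
#' @export
clinical_fields <- function() {
  list(fields = CLINICAL_FIELDS, continuous = CLINICAL_CONTINUOUS,
       binary = CLINICAL_BINARY)
}

check_clinical_df <- function(profiles) {
  if (inherits(profiles, "clinical_profile")) {
    profiles <- as.data.frame(lapply(unclass(profiles), function(v) v))
  }
  missing_cols <- setdiff(CLINICAL_FIELDS, names(profiles))
  if (length(missing_cols)) {
    stop("missing clinical fields: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(profiles),
                   c(CLINICAL_FIELDS, "patient_id", "dominant_class", "split"))
  if (length(extra)) {
    stop("unknown clinical fields: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  for (f in CLINICAL_BINARY) {
    v <- profiles[[f]]
    if (!all(v[!is.na(v)] %in% c(0, 1))) {
      stop("binary field ", f, " must be in {0, 1}", call. = FALSE)
    }
  }
  profiles
}

#' Fit the clinical scaler on training profiles
#'
#' Stores, per continuous field, the training mean, sample sd and median
#' (for imputation), and per binary field the training mode. Refuses to fit
#' on anything but training-split rows when a `split` column is present
#' (leakage guard), on fewer than two profiles, on all-missing fields, and
#' on zero-variance continuous fields.
#'
#' @param profiles Data frame of clinical profiles (one row per patient).
#' @return Object of class `clinical_scaler`.
#' @export
fit_clinical_scaler <- function(profiles) {
  profiles <- check_clinical_df(profiles)
  if (!is.null(profiles$split) && !all(profiles$split == "train")) {
    stop("clinical scaler must be fitted on training-split profiles only",
         call. = FALSE)
  }
  if (nrow(profiles) < 2L) {
    stop("need at least 2 training profiles", call. = FALSE)
  }
  cont <- lapply(CLINICAL_CONTINUOUS, function(f) {
    v <- profiles[[f]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) stop("field ", f, " is entirely missing", call. = FALSE)
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-12) {
      stop("field ", f, " has zero variance in the training set",
           call. = FALSE)
    }
    list(mean = mean(v), sd = s, median = stats::median(v))
  })
  names(cont) <- CLINICAL_CONTINUOUS
  bin <- lapply(CLINICAL_BINARY, function(f) {
    v <- profiles[[f]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) stop("field ", f, " is entirely missing", call. = FALSE)
    list(mode = as.numeric(sum(v == 1) > sum(v == 0)))
  })
  names(bin) <- CLINICAL_BINARY
  structure(list(continuous = cont, binary = bin), class = "clinical_scaler")
}

#' Standardize clinical profiles to the 13-vector representation
#'
#' Missing continuous values are imputed with the training median and then
#' z-scored with training statistics; missing binary values are imputed
#' with the training mode; binary fields pass through as {0, 1}. Columns
#' follow the fixed schema order.
#'
#' @param profiles Data frame (or single `clinical_profile`).
#' @param scaler A fitted [fit_clinical_scaler()] result.
#' @return Numeric matrix, one row per profile, 13 named columns.
#' @export
clinical_transform <- function(profiles, scaler) {
  stopifnot(inherits(scaler, "clinical_scaler"))
  profiles <- check_clinical_df(profiles)
  n <- nrow(profiles)
  out <- matrix(0, nrow = n, ncol = length(CLINICAL_FIELDS),
                dimnames = list(NULL, CLINICAL_FIELDS))
  for (f in CLINICAL_FIELDS) {
    v <- as.numeric(profiles[[f]])
    if (f %in% CLINICAL_CONTINUOUS) {
      st <- scaler$continuous[[f]]
      v[is.na(v)] <- st$median
      out[, f] <- (v - st$mean) / st$sd
    } else {
      v[is.na(v)] <- scaler$binary[[f]]$mode
      out[, f] <- v
    }
  }
  out
}

#' Persist / restore a clinical scaler as JSON
#'
#' @param scaler A `clinical_scaler`.
#' @param path JSON file path.
#' @return `path` (write) or the restored scaler (read).
#' @export
write_clinical_scaler <- function(scaler, path) {
  jsonlite::write_json(unclass(scaler), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_clinical_scaler
#' @export
read_clinical_scaler <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "clinical_scaler")
}
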