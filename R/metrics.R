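# Classification and segmentation evaluation, improvement arithmetic and
# patient-level splitting.
#
# Zero-denominator conventions (documented and tested): precision, recall
# and F1 are 0 when undefined; Dice and IoU of two empty masks are 1.

#' Confusion matrix over the four rhythm classes
#'
#' @param true,pred Equal-length label vectors (class names or 1-based
#'   indices).
#' @return `4 x 4` integer matrix, rows = true class, columns = predicted,
#'   in [rhythm_classes()] order.
#' @export
confusion_matrix <- function(true, pred) {
  if (length(true) != length(pred)) {
    stop("true and pred must have equal length", call. = FALSE)
  }
  to_f <- function(x) {
    if (is.character(x) || is.factor(x)) {
      x <- as.character(x)
      if (!all(x %in% RHYTHM_CLASSES)) stop("unknown label", call. = FALSE)
      factor(x, levels = RHYTHM_CLASSES)
    } else {
      factor(RHYTHM_CLASSES[x], levels = RHYTHM_CLASSES)
    }
  }
  cm <- table(true = to_f(true), pred = to_f(pred))
  matrix(as.integer(cm), 4, 4,
         dimnames = list(true = RHYTHM_CLASSES, pred = RHYTHM_CLASSES))
}

#' Per-class precision, recall, F1 and overall accuracy
#'
#' `precision_j = cm[j,j] / colsum_j`, `recall_j = cm[j,j] / rowsum_j`,
#' F1 the harmonic mean, accuracy the diagonal fraction; zero denominators
#' yield 0. Values are also reported rounded to 4 decimals.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return List with `per_class` data frame (class, precision, recall, f1)
#'   and `accuracy`.
#' @export
per_class_metrics <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  colsum <- colSums(cm)
  rowsum <- rowSums(cm)
  precision <- ifelse(colsum > 0, tp / colsum, 0)
  recall <- ifelse(rowsum > 0, tp / rowsum, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(per_class = data.frame(class = RHYTHM_CLASSES,
                              precision = unname(precision),
                              recall = unname(recall), f1 = unname(f1),
                              stringsAsFactors = FALSE),
       accuracy = sum(tp) / sum(cm))
}

dice_pair <- function(a, b) {
  inter <- sum(a * b)
  tot <- sum(a) + sum(b)
  if (tot == 0) 1 else 2 * inter / tot
}

iou_pair <- function(a, b) {
  inter <- sum(a * b)
  uni <- sum(pmax(a, b))
  if (uni == 0) 1 else inter / uni
}

#' Segmentation metrics averaged over segments
#'
#' Per segment: pixel accuracy (fraction of matching positions), Dice
#' `2|A∩B| / (|A| + |B|)` and IoU `|A∩B| / |A∪B|`; two empty masks score 1
#' on both overlap metrics. Each metric is then averaged over segments.
#'
#' @param pred,true Binary matrices, one mask per column (or vectors for a
#'   single mask).
#' @return List `pixel_accuracy`, `dice`, `iou` plus the per-segment
#'   vectors.
#' @export
seg_metrics <- function(pred, true) {
  pred <- as.matrix(pred); true <- as.matrix(true)
  if (!all(dim(pred) == dim(true))) {
    stop("mask shapes differ", call. = FALSE)
  }
  if (!is_binary(pred) || !is_binary(true)) {
    stop("masks must be binary", call. = FALSE)
  }
  n <- ncol(pred)
  pa <- colMeans(pred == true)
  dice <- vapply(seq_len(n), function(j) dice_pair(pred[, j], true[, j]),
                 numeric(1))
  iou <- vapply(seq_len(n), function(j) iou_pair(pred[, j], true[, j]),
                numeric(1))
  list(pixel_accuracy = mean(pa), dice = mean(dice), iou = mean(iou),
       per_segment = list(pixel_accuracy = pa, dice = dice, iou = iou))
}

#' Relative and absolute improvement
#'
#' `relative_improvement` returns `100 * (new - old) / old` percent;
#' `absolute_improvement` returns `100 * (new - old)` percentage points
#' (for metrics already on the 0-1 scale).
#'
#' @param new,old Metric values.
#' @return Improvement (percent / percentage points).
#' @export
relative_improvement <- function(new, old) {
  if (old == 0) stop("relative improvement undefined for old = 0",
                     call. = FALSE)
  100 * (new - old) / old
}

#' @rdname relative_improvement
#' @export
absolute_improvement <- function(new, old) 100 * (new - old)

#' Patient-level train/validation/test split
#'
#' Shuffles patient ids deterministically and assigns whole patients to
#' folds by largest-remainder apportionment of `fractions`, so every
#' segment of a patient inherits a single fold and no leakage across folds
#' is possible.
#'
#' @param patient_ids Character vector of unique patient ids.
#' @param fractions Length-3 positive fold fractions summing to 1
#'   (train, validation, test); default 22:8:5.
#' @param seed Integer seed.
#' @param strata Optional named vector (patient id -> stratum, e.g. the
#'   dominant rhythm class); when given, the apportionment is applied
#'   within each stratum so every fold sees every class where the stratum
#'   has at least as many patients as folds.
#' @return List with character vectors `train`, `val`, `test`.
#' @export
patient_level_split <- function(patient_ids, fractions = c(22, 8, 5) / 35,
                                seed = 1L, strata = NULL) {
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions <= 0)) {
    stop("fractions must be positive and sum to 1", call. = FALSE)
  }
  patient_ids <- unique(as.character(patient_ids))
  if (!is.null(strata)) {
    parts <- split(patient_ids, as.character(strata[patient_ids]))
    folds <- list(train = character(0), val = character(0),
                  test = character(0))
    for (i in seq_along(parts)) {
      ids_s <- parts[[i]]
      if (length(ids_s) < 3L) {
        # too few for all folds: strongest claim on the training fold
        folds$train <- c(folds$train, ids_s)
        next
      }
      sub <- patient_level_split(ids_s, fractions,
                                 seed = derive_seed(seed, names(parts)[i]))
      folds$train <- c(folds$train, sub$train)
      folds$val <- c(folds$val, sub$val)
      folds$test <- c(folds$test, sub$test)
    }
    return(folds)
  }
  n <- length(patient_ids)
  if (n < 3L) stop("need at least as many patients as folds", call. = FALSE)
  raw <- fractions * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    order_rem <- order(raw - sizes, decreasing = TRUE)
    sizes[order_rem[seq_len(rem)]] <- sizes[order_rem[seq_len(rem)]] + 1L
  }
  sizes <- pmax(sizes, 1L)
  while (sum(sizes) > n) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  ids <- with_seed(seed, sample(patient_ids))
  ends <- cumsum(sizes)
  list(train = ids[seq_len(ends[1])],
       val = ids[(ends[1] + 1L):ends[2]],
       test = ids[(ends[2] + 1L):ends[3]])
}

#' Split segments by a patient-level fold assignment
#'
#' @param segments Segment list.
#' @param split Result of [patient_level_split()].
#' @return List of segment lists `train`, `val`, `test`.
#' @export
split_segments <- function(segments, split) {
  pids <- vapply(segments, `[[`, "", "patient_id")
  list(train = segments[pids %in% split$train],
       val = segments[pids %in% split$val],
       test = segments[pids %in% split$test])
}
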