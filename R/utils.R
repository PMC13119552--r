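#' @keywords internal
#' @useDynLib ppgrhythm, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Rhythm class vocabulary, fixed order used everywhere (labels, confusion
# matrices, state texts). Index 1..4 maps Normal, AF, Bradycardia, Tachycardia.
RHYTHM_CLASSES <- c("Normal", "AF", "Bradycardia", "Tachycardia")

#' Rhythm classes recognised by the package
#'
#' @return Character vector `c("Normal", "AF", "Bradycardia", "Tachycardia")`,
#'   in the fixed order used for labels, logits and confusion matrices.
#' @export
rhythm_classes <- function() RHYTHM_CLASSES

assert_rhythm_class <- function(x) {
  if (!(is.character(x) && length(x) == 1L && x %in% RHYTHM_CLASSES)) {
    stop("unknown rhythm class: ", paste(x, collapse = ", "), call. = FALSE)
  }
  x
}

class_index <- function(x) {
  i <- match(x, RHYTHM_CLASSES)
  if (anyNA(i)) stop("unknown rhythm class label", call. = FALSE)
  i
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package funnel through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic sub-seed derivation: fold a tag string into a parent seed so
# each pipeline stage gets an independent, reproducible stream. Kept below
# 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, tag) {
  h <- 0
  for (cp in utf8ToInt(tag)) h <- (h * 131 + cp) %% 2147483562
  as.integer((as.numeric(seed) %% 2147483562 + h) %% 2147483562 + 1)
}

# Runs of 1s in a binary vector as half-open [start, end) 0-based intervals.
mask_runs <- function(mask) {
  stopifnot(all(mask %in% c(0, 1)))
  r <- rle(as.integer(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 1L
  data.frame(start = starts[keep], end = ends[keep])
}

is_binary <- function(x) all(x %in% c(0, 1))

`%||%` <- function(a, b) if (is.null(a)) b else a
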