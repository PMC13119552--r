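# Similar-patient retrieval over clinical embeddings and evidence-grounded
# structured report generation.
#
# The retrieval index holds one L2-normalized clinical embedding per
# training patient (same encoder as contrastive pretraining); queries are
# ranked by exact cosine similarity. Reports are rendered from an evidence
# bundle by a fully deterministic template generator (an LLM client can be
# plugged in behind the same interface) and checked by a rule-based
# consistency guard: the diagnosis must match the predicted class and every
# numeral in the report must trace back to the bundle.

# Short neutral rhythm-definition snippets shipped as package data; a
# synthetic stand-in for clinical guideline excerpts (which are not
# redistributable), sufficient to exercise the retrieval-grounded prompt
# and guardrail mechanics.
GUIDELINE_SNIPPETS <- list(
  Normal = paste("Normal sinus rhythm: regular rhythm with a resting heart",
                 "rate of 60-100 bpm; no intervention indicated."),
  AF = paste("Atrial fibrillation: irregularly irregular rhythm without",
             "discernible P waves; assess stroke risk and consider rate or",
             "rhythm control."),
  Bradycardia = paste("Sinus bradycardia: regular rhythm below 60 bpm;",
                      "evaluate for reversible causes and symptoms before",
                      "treatment."),
  Tachycardia = paste("Sinus tachycardia: regular rhythm above 100 bpm;",
                      "identify and treat the underlying driver.")
)

#' Guideline snippet shipped with the package
#'
#' @param rhythm_class Rhythm class.
#' @return Character snippet (synthetic stand-in guideline text).
#' @export
guideline_snippet <- function(rhythm_class) {
  assert_rhythm_class(rhythm_class)
  GUIDELINE_SNIPPETS[[rhythm_class]]
}

#' Build the similar-patient retrieval index
#'
#' Embeds each training patient's standardized clinical vector with the
#' pretrained clinical encoder and stores the L2-normalized embedding with
#' the patient's dominant rhythm label.
#'
#' @param profiles Data frame with `patient_id`, `dominant_class` and the
#'   13 clinical fields (training patients only).
#' @param scaler Fitted [fit_clinical_scaler()].
#' @param enc Encoder set from [clip_encoders()].
#' @return Object of class `retrieval_index`.
#' @export
build_index <- function(profiles, scaler, enc) {
  if (anyDuplicated(profiles$patient_id)) {
    stop("duplicate patient ids in index", call. = FALSE)
  }
  v <- clinical_transform(profiles, scaler)
  z <- encode_clinical(enc, t(v), normalize = TRUE)
  colnames(z) <- profiles$patient_id
  structure(list(embeddings = z,
                 labels = stats::setNames(profiles$dominant_class,
                                          profiles$patient_id)),
            class = "retrieval_index")
}

#' Retrieve the top-k most similar patients
#'
#' Exact cosine ranking (embeddings are unit-norm, so the dot product is
#' the cosine); ties are broken by lexicographic patient id.
#'
#' @param query Standardized 13-vector (or raw profile row with `scaler`),
#'   or, when `enc` is `NULL`, an already-computed embedding of the index's
#'   dimension.
#' @param index A `retrieval_index`.
#' @param enc Encoder set from [clip_encoders()], or `NULL` to rank a
#'   pre-embedded query.
#' @param k Number of neighbours (<= index size).
#' @param scaler Optional scaler when `query` is a raw profile.
#' @return Data frame `patient_id`, `similarity`, `label`, best first.
#' @export
topk_similar <- function(query, index, enc = NULL, k = 10L, scaler = NULL) {
  stopifnot(inherits(index, "retrieval_index"))
  n <- ncol(index$embeddings)
  if (n == 0L) stop("empty retrieval index", call. = FALSE)
  k <- min(k, n)
  if (!is.null(scaler)) query <- clinical_transform(query, scaler)[1, ]
  zq <- if (is.null(enc)) {
    l2_normalize(matrix(as.numeric(query), ncol = 1))
  } else {
    encode_clinical(enc, as.numeric(query), normalize = TRUE)
  }
  sims <- as.numeric(crossprod(index$embeddings, zq))
  ids <- colnames(index$embeddings)
  ord <- order(-sims, ids)[seq_len(k)]
  data.frame(patient_id = ids[ord], similarity = sims[ord],
             label = unname(index$labels[ids[ord]]),
             stringsAsFactors = FALSE)
}

#' Label distribution among retrieved neighbours
#'
#' @param neighbors Data frame from [topk_similar()].
#' @return Named percentages per rhythm class (1 decimal), summing to 100
#'   within rounding.
#' @export
neighbor_stats <- function(neighbors) {
  if (nrow(neighbors) == 0L) stop("no neighbours", call. = FALSE)
  tab <- table(factor(neighbors$label, levels = RHYTHM_CLASSES))
  round(100 * as.numeric(tab) / sum(tab), 1) |>
    stats::setNames(RHYTHM_CLASSES)
}

#' Assemble the evidence bundle for one segment
#'
#' Collects every quantity the report generator may cite: predicted class
#' with per-class probabilities and confidence, the abnormal-interval
#' summary (count, total duration in original-time seconds using the
#' segment's pre-resampling length, locations), the HRV summary, the
#' clinical profile, neighbour statistics and the guideline snippet for the
#' predicted class.
#'
#' @param predicted Predicted class label.
#' @param probs Named per-class probabilities.
#' @param segment The scored segment (needs `mask` length, `raw_length`).
#' @param pred_mask Predicted binary mask (length 286).
#' @param hrv Named HRV vector (hr, sdnn, rmssd, pnn50).
#' @param profile Clinical profile (named list or data frame row).
#' @param neighbors Data frame from [topk_similar()].
#' @param fs Sampling frequency of the raw record.
#' @return Object of class `evidence_bundle`.
#' @export
assemble_evidence <- function(predicted, probs, segment, pred_mask, hrv,
                              profile, neighbors, fs = 100) {
  for (nm in c("predicted", "probs", "segment", "pred_mask", "hrv",
               "profile", "neighbors")) {
    if (is.null(get(nm))) stop("incomplete evidence: missing ", nm,
                               call. = FALSE)
  }
  assert_rhythm_class(predicted)
  L <- length(pred_mask)
  scale_s <- segment$raw_length / L / fs   # seconds per resampled sample
  runs <- mask_runs(pred_mask)
  intervals <- if (nrow(runs)) {
    data.frame(start_s = round(runs$start * scale_s, 2),
               end_s = round(runs$end * scale_s, 2))
  } else {
    data.frame(start_s = numeric(0), end_s = numeric(0))
  }
  structure(list(
    predicted = predicted,
    probs = round(probs, 4),
    confidence = round(max(probs), 4),
    abnormal = list(n_intervals = nrow(runs),
                    total_s = round(sum(pred_mask) * scale_s, 2),
                    intervals = intervals),
    hrv = round(hrv, 1),
    profile = lapply(as.list(profile)[CLINICAL_FIELDS], function(v) {
      if (is.numeric(v)) round(v, 1) else v
    }),
    neighbors = neighbors,
    neighbor_pct = neighbor_stats(neighbors),
    guideline = guideline_snippet(predicted)
  ), class = "evidence_bundle")
}

fmt1 <- function(x) formatC(x, format = "f", digits = 1)

#' Render a structured rhythm report
#'
#' The template generator fills fixed sentences with bundle values and is
#' byte-deterministic; it emits exactly four sections, in order: Diagnosis,
#' Evidence, Interpretation, Recommendations. An LLM client function
#' `function(prompt) -> character` can be supplied for the `"llm"`
#' generator; no client is bundled, and its absence is an explicit error
#' (never a silent fallback). Decoding parameters for the LLM path are
#' constrained to low stochasticity (temperature <= 0.3).
#'
#' @param bundle An `evidence_bundle`.
#' @param generator `"template"` or `"llm"`.
#' @param llm_client Function taking the prompt and returning report text.
#' @param temperature Decoding temperature for the llm generator.
#' @return Object of class `report_document`: `text` (markdown), `sections`
#'   (named list of the four section bodies), `generator`.
#' @export
render_report <- function(bundle, generator = c("template", "llm"),
                          llm_client = NULL, temperature = 0.2) {
  stopifnot(inherits(bundle, "evidence_bundle"))
  generator <- match.arg(generator)
  if (generator == "llm") {
    if (is.null(llm_client)) {
      stop("llm generator requested but no llm_client supplied",
           call. = FALSE)
    }
    if (temperature > 0.3) {
      stop("llm decoding temperature must be <= 0.3", call. = FALSE)
    }
    prompt <- report_prompt(bundle)
    text <- llm_client(prompt)
    doc <- parse_report(text, generator = "llm")
    return(doc)
  }
  hrv <- bundle$hrv
  diag <- sprintf(
    "Predicted rhythm: %s (confidence %s).",
    bundle$predicted, fmt1(100 * bundle$confidence))
  ev <- paste0(
    sprintf("Heart rate %s bpm; SDNN %s ms; RMSSD %s ms; pNN50 %s%%. ",
            fmt1(hrv[["hr"]]), fmt1(hrv[["sdnn"]]), fmt1(hrv[["rmssd"]]),
            fmt1(hrv[["pnn50"]])),
    if (bundle$abnormal$n_intervals > 0) {
      sprintf("Abnormal rhythm detected over %d interval(s) totalling %s s.",
              bundle$abnormal$n_intervals, fmt1(bundle$abnormal$total_s))
    } else {
      "No abnormal intervals were localized in this segment."
    })
  interp <- sprintf(
    paste0("Among the %d most similar patients by clinical profile, ",
           "%s was the dominant rhythm in %s%% of cases. %s"),
    nrow(bundle$neighbors), bundle$predicted,
    fmt1(bundle$neighbor_pct[[bundle$predicted]]), bundle$guideline)
  rec <- if (bundle$predicted == "Normal") {
    "No rhythm-directed action indicated; continue routine monitoring."
  } else {
    sprintf(paste0("Findings are consistent with %s; clinical correlation ",
                   "and expert review are recommended. This report is ",
                   "assistive and not a clinical decision."),
            bundle$predicted)
  }
  sections <- list(Diagnosis = diag, Evidence = ev, Interpretation = interp,
                   Recommendations = rec)
  text <- paste(vapply(names(sections), function(h) {
    paste0("## ", h, "\n", sections[[h]])
  }, ""), collapse = "\n\n")
  structure(list(text = text, sections = sections, generator = "template"),
            class = "report_document")
}

# structured prompt for a pluggable LLM client
report_prompt <- function(bundle) {
  paste0(
    "You are a cardiology reporting assistant. Using ONLY the evidence ",
    "below, write a report with exactly four markdown sections titled ",
    "Diagnosis, Evidence, Interpretation, Recommendations. Do not invent ",
    "numbers.\n\nEVIDENCE\n",
    jsonlite::toJSON(unclass(bundle), auto_unbox = TRUE, digits = 6))
}

parse_report <- function(text, generator) {
  heads <- c("Diagnosis", "Evidence", "Interpretation", "Recommendations")
  lines <- strsplit(text, "\n")[[1]]
  idx <- match(paste0("## ", heads), trimws(lines))
  if (anyNA(idx) || is.unsorted(idx)) {
    stop("unparseable report: expected the four sections in order",
         call. = FALSE)
  }
  bounds <- c(idx, length(lines) + 1L)
  sections <- lapply(seq_along(heads), function(i) {
    paste(lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)], collapse = "\n")
  })
  names(sections) <- heads
  structure(list(text = text, sections = sections, generator = generator),
            class = "report_document")
}

extract_numerals <- function(text) {
  m <- gregexpr("-?[0-9]+\\.?[0-9]*", text)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(text, gregexpr("-?[0-9]+\\.?[0-9]*", text))[[1]]
}

# all numerals a faithful report may contain, in the formatted variants the
# template uses (raw, 1-decimal, percentage forms)
bundle_numerals <- function(bundle) {
  vals <- c(unlist(bundle$probs), bundle$confidence,
            100 * bundle$confidence, unlist(bundle$hrv),
            bundle$abnormal$n_intervals, bundle$abnormal$total_s,
            unlist(bundle$abnormal$intervals),
            unlist(Filter(is.numeric, bundle$profile)),
            bundle$neighbors$similarity, nrow(bundle$neighbors),
            unlist(bundle$neighbor_pct))
  vals <- vals[is.finite(vals)]
  unique(c(
    extract_numerals(paste(vals, collapse = " ")),
    extract_numerals(paste(fmt1(vals), collapse = " ")),
    extract_numerals(paste(round(vals, 2), collapse = " ")),
    extract_numerals(paste(round(vals, 4), collapse = " ")),
    # numerals inside shipped guideline/state texts and fixed template
    # vocabulary (e.g. the metric name pNN50) are package data
    extract_numerals(paste(unlist(GUIDELINE_SNIPPETS), collapse = " ")),
    extract_numerals(paste(unlist(state_texts()), collapse = " ")),
    extract_numerals("pNN50")
  ))
}

#' Consistency guard between a report and its evidence bundle
#'
#' Fails when the Diagnosis section names a different class than the
#' bundle's prediction, or when any numeric token in the report cannot be
#' traced to a bundle quantity (up to the template's formatting variants).
#'
#' @param report A `report_document`.
#' @param bundle The `evidence_bundle` it was generated from.
#' @return List `pass` (logical) and `violations` (character).
#' @export
consistency_check <- function(report, bundle) {
  stopifnot(inherits(report, "report_document"),
            inherits(bundle, "evidence_bundle"))
  violations <- character(0)
  diag <- report$sections$Diagnosis
  mentioned <- RHYTHM_CLASSES[vapply(RHYTHM_CLASSES, grepl, TRUE, x = diag,
                                     fixed = TRUE)]
  if (!(bundle$predicted %in% mentioned)) {
    violations <- c(violations,
                    sprintf("diagnosis does not state predicted class %s",
                            bundle$predicted))
  }
  allowed <- bundle_numerals(bundle)
  nums <- extract_numerals(report$text)
  bad <- setdiff(nums, allowed)
  if (length(bad)) {
    violations <- c(violations,
                    sprintf("numeral %s not present in evidence bundle",
                            bad))
  }
  list(pass = length(violations) == 0L, violations = violations)
}

#' Persist / restore a retrieval index as JSON
#'
#' @param index A `retrieval_index`.
#' @param path JSON file path.
#' @return `path` (write) or the restored index (read).
#' @export
write_index <- function(index, path) {
  jsonlite::write_json(
    list(patient_id = colnames(index$embeddings),
         label = unname(index$labels),
         embeddings = t(index$embeddings)),
    path, digits = NA)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  z <- t(obj$embeddings)
  colnames(z) <- obj$patient_id
  structure(list(embeddings = z,
                 labels = stats::setNames(obj$label, obj$patient_id)),
            class = "retrieval_index")
}
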