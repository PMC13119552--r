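make_index_fixture <- function() {
  cohort <- test_cohort()
  enc <- clip_encoders(test_clip_checkpoint())
  scaler <- fit_clinical_scaler(cohort$clinical)
  list(cohort = cohort, enc = enc, scaler = scaler,
       index = build_index(cohort$clinical, scaler, enc))
}

test_that("the index holds one unit-norm embedding per training patient", {
  fx <- make_index_fixture()
  expect_equal(ncol(fx$index$embeddings), nrow(fx$cohort$clinical))
  expect_lt(max(abs(colSums(fx$index$embeddings^2) - 1)), 1e-6)
  dup <- rbind(fx$cohort$clinical, fx$cohort$clinical[1, ])
  expect_error(build_index(dup, fx$scaler, fx$enc), "duplicate")
})

test_that("top-k retrieval is exact cosine ranking", {
  fx <- make_index_fixture()
  # self-query ranks itself first with similarity 1
  q <- clinical_transform(fx$cohort$clinical, fx$scaler)[4, ]
  top <- topk_similar(q, fx$index, fx$enc, k = 3)
  expect_equal(top$patient_id[1], fx$cohort$clinical$patient_id[4])
  expect_lt(abs(top$similarity[1] - 1), 1e-6)
  expect_true(all(diff(top$similarity) <= 1e-12))

  # hand-set embeddings: brute-force sort oracle, orthogonal similarity 0
  E <- diag(5)[, 1:5]
  E[, 5] <- c(1, 1, 0, 0, 0) / sqrt(2)
  idx <- structure(list(embeddings = E,
                        labels = stats::setNames(rep("AF", 5),
                                                 paste0("Q", 1:5))),
                   class = "retrieval_index")
  colnames(idx$embeddings) <- paste0("Q", 1:5)
  names(idx$labels) <- paste0("Q", 1:5)
  top3 <- topk_similar(c(1, 0, 0, 0, 0), idx, enc = NULL, k = 3)
  sims_all <- as.numeric(crossprod(E, c(1, 0, 0, 0, 0)))
  oracle <- order(-sims_all, paste0("Q", 1:5))[1:3]
  expect_equal(top3$patient_id, paste0("Q", oracle))
  # entries orthogonal to the query score zero
  expect_equal(topk_similar(c(0, 0, 0, 1, 0), idx, enc = NULL,
                            k = 5)$similarity[2:5][4], 0)
  expect_error(topk_similar(c(1, 0), structure(
    list(embeddings = matrix(numeric(0), 2, 0), labels = character(0)),
    class = "retrieval_index"), NULL), "empty")
})

test_that("neighbour label statistics are percentages at one decimal", {
  nb <- data.frame(patient_id = paste0("P", 1:5),
                   similarity = seq(0.9, 0.5, by = -0.1),
                   label = c("AF", "AF", "Normal", "Bradycardia", "Normal"))
  st <- neighbor_stats(nb)
  expect_equal(unname(st[["AF"]]), 40)
  expect_lt(abs(sum(st) - 100), 0.1)
  all_af <- nb; all_af$label <- "AF"
  expect_equal(unname(neighbor_stats(all_af)[["AF"]]), 100)
  expect_error(neighbor_stats(nb[0, ]), "no neighbours")
})

test_that("evidence bundles trace every quantity to the pipeline", {
  fx <- make_index_fixture()
  seg <- test_prep()$segments[[1]]
  nb <- topk_similar(clinical_transform(fx$cohort$clinical, fx$scaler)[1, ],
                     fx$index, fx$enc, k = 5)
  probs <- c(Normal = 0.91, AF = 0.05, Bradycardia = 0.03,
             Tachycardia = 0.01)
  bundle <- assemble_evidence("Normal", probs, seg,
                              pred_mask = rep(0, 286), hrv = seg$hrv,
                              profile = fx$cohort$patients[[1]]$clinical,
                              neighbors = nb)
  expect_equal(bundle$abnormal$total_s, 0)
  expect_equal(bundle$abnormal$n_intervals, 0L)
  # JSON round trip preserves the content
  js <- jsonlite::toJSON(unclass(bundle), auto_unbox = TRUE, digits = 8)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$predicted, "Normal")
  expect_equal(back$confidence, bundle$confidence)
  expect_error(assemble_evidence("Normal", NULL, seg, rep(0, 286),
                                 seg$hrv, fx$cohort$patients[[1]]$clinical,
                                 nb),
               "incomplete evidence")
})

test_that("template reports are structured, deterministic and grounded", {
  fx <- make_index_fixture()
  seg <- test_prep()$segments[[1]]
  nb <- topk_similar(clinical_transform(fx$cohort$clinical, fx$scaler)[2, ],
                     fx$index, fx$enc, k = 5)
  mask <- c(rep(0, 100), rep(1, 100), rep(0, 86))
  probs <- c(Normal = 0.04, AF = 0.02, Bradycardia = 0.92,
             Tachycardia = 0.02)
  bundle <- assemble_evidence("Bradycardia", probs, seg, mask,
                              hrv = c(hr = 52.1, sdnn = 18.2, rmssd = 12.4,
                                      pnn50 = 2.0),
                              profile = fx$cohort$patients[[2]]$clinical,
                              neighbors = nb)
  rep1 <- render_report(bundle)
  rep2 <- render_report(bundle)
  expect_identical(rep1$text, rep2$text)
  heads <- regmatches(rep1$text, gregexpr("## [A-Za-z]+", rep1$text))[[1]]
  expect_identical(heads, c("## Diagnosis", "## Evidence",
                            "## Interpretation", "## Recommendations"))
  expect_match(rep1$sections$Evidence, "52.1", fixed = TRUE)
  expect_match(rep1$sections$Interpretation, "bradycardia",
               ignore.case = TRUE)
  expect_true(consistency_check(rep1, bundle)$pass)
  expect_error(render_report(bundle, generator = "llm"), "llm_client")
  expect_error(render_report(bundle, generator = "llm",
                             llm_client = function(p) "", temperature = 0.9),
               "0.3")
})

test_that("the consistency guard rejects fabricated numerals and classes", {
  fx <- make_index_fixture()
  seg <- test_prep()$segments[[1]]
  nb <- topk_similar(clinical_transform(fx$cohort$clinical, fx$scaler)[1, ],
                     fx$index, fx$enc, k = 4)
  probs <- c(Normal = 0.1, AF = 0.8, Bradycardia = 0.06, Tachycardia = 0.04)
  bundle <- assemble_evidence("AF", probs, seg,
                              c(rep(1, 143), rep(0, 143)),
                              hrv = c(hr = 88.4, sdnn = 95.1, rmssd = 130.7,
                                      pnn50 = 71.2),
                              profile = fx$cohort$patients[[1]]$clinical,
                              neighbors = nb)
  good <- render_report(bundle)
  expect_true(consistency_check(good, bundle)$pass)
  fabricated <- good
  fabricated$text <- paste0(good$text, " An ejection fraction of 37.9 was noted.")
  res <- consistency_check(fabricated, bundle)
  expect_false(res$pass)
  expect_match(res$violations[1], "37.9")
  wrong_class <- good
  wrong_class$sections$Diagnosis <- "Predicted rhythm: Normal."
  expect_false(consistency_check(wrong_class, bundle)$pass)
})

test_that("indices persist as JSON and rank identically after reload", {
  fx <- make_index_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_index(fx$index, path)
  idx2 <- read_index(path)
  q <- clinical_transform(fx$cohort$clinical, fx$scaler)[3, ]
  t1 <- topk_similar(q, fx$index, fx$enc, k = 5)
  t2 <- topk_similar(q, idx2, fx$enc, k = 5)
  expect_equal(t2$patient_id, t1$patient_id)
  expect_equal(t2$similarity, t1$similarity, tolerance = 1e-12)
})
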