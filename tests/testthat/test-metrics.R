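# Four-stage confusion matrices and the staging metric set.

test_that("confusion tallies (truth, predicted) pairs into predicted x true", {
  m <- confusion_from_calls(rep("normal", 3), rep("normal", 3))
  expect_equal(m["normal", "normal"], 3L, ignore_attr = TRUE)
  expect_equal(sum(m), 3)
  # one pair per ordered combination -> all-ones matrix
  grid <- expand.grid(truth = stages(), predicted = stages(),
                      stringsAsFactors = FALSE)
  m16 <- confusion_from_calls(grid$truth, grid$predicted)
  expect_true(all(m16 == 1))
  expect_equal(sum(m16), 16)
  # asymmetric pair lands at [predicted, true]
  m1 <- confusion_from_calls("invasive_cancer", "normal")
  expect_equal(m1["normal", "invasive_cancer"], 1L, ignore_attr = TRUE)
  expect_error(confusion_from_calls(character(0), character(0)), "no")
  expect_error(confusion_from_calls("normal", "benign"), "unknown stage")
})

test_that("pairs reconstructed from a bundled matrix reproduce it", {
  ref <- clinical_confusions("wli_spectrum")
  truth <- character(0); pred <- character(0)
  for (p in stages()) for (t in stages()) {
    k <- ref[p, t]
    truth <- c(truth, rep(t, k)); pred <- c(pred, rep(p, k))
  }
  rebuilt <- confusion_from_calls(truth, pred)
  expect_equal(unclass(rebuilt), unclass(ref), ignore_attr = TRUE)
  expect_equal(sum(rebuilt), 155)
})

test_that("bundled matrices reproduce the published WLI-spectrum metric block", {
  m <- clinical_confusions("wli_spectrum")
  tab <- metrics_table(m)
  expect_equal(tab$per_stage$sensitivity_pct, c(92, 75, 92, 91))
  expect_equal(tab$per_stage$precision_pct, c(85, 84, 88, 92))
  expect_equal(tab$per_stage$f1_pct, c(88, 79, 90, 91))
  expect_equal(tab$accuracy_pct, 88)
  expect_equal(tab$kappa_2dp, 0.84)
})

test_that("remaining bundled matrices reproduce their published metric rows", {
  wli <- metrics_table(clinical_confusions("wli_rgb"))
  expect_equal(wli$per_stage$sensitivity_pct, c(76, 61, 86, 93))
  expect_equal(wli$per_stage$precision_pct, c(72, 85, 86, 85))
  expect_equal(wli$per_stage$f1_pct, c(74, 71, 86, 89))
  expect_equal(wli$total, 112)
  nbi <- metrics_table(clinical_confusions("nbi_rgb"))
  expect_equal(nbi$per_stage$sensitivity_pct, c(68, 83, 88, 98))
  expect_equal(nbi$per_stage$precision_pct, c(89, 88, 86, 84))
  expect_equal(nbi$accuracy_pct, 86)
  expect_equal(nbi$kappa_2dp, 0.81)
  expect_equal(nbi$total, 152)
})

test_that("metric edge cases: perfect, uniform, and undefined", {
  perfect <- staging_confusion(diag(c(5, 6, 7, 8)))
  for (s in stages()) {
    expect_equal(stage_sensitivity(perfect, s), 100)
    expect_equal(stage_precision(perfect, s), 100)
    expect_equal(stage_f1(perfect, s), 100)
  }
  expect_equal(overall_accuracy(perfect), 100)
  expect_equal(cohen_kappa(perfect), 1)
  ones <- staging_confusion(matrix(1, 4, 4))
  expect_equal(vapply(stages(), function(s) stage_sensitivity(ones, s), 1),
               rep(25, 4), ignore_attr = TRUE)
  expect_equal(cohen_kappa(ones), 0)
  # zero column/row -> undefined, reported NA and never 0
  m <- matrix(c(5, 0, 0, 0,
                2, 3, 0, 0,
                0, 0, 4, 0,
                0, 0, 0, 0), 4, 4, byrow = TRUE)
  sc <- staging_confusion(m)
  expect_true(is.na(stage_sensitivity(sc, "invasive_cancer")))
  expect_true(is.na(stage_precision(sc, "invasive_cancer")))
  expect_true(is.na(stage_f1(sc, "invasive_cancer")))
  expect_error(staging_confusion(matrix(-1, 4, 4)), "nonnegative")
})

test_that("relabeling stages permutes per-stage metrics, fixes accuracy/kappa", {
  set.seed(20)
  m <- staging_confusion(matrix(rpois(16, 8) + 1, 4, 4))
  perm <- c(3, 1, 4, 2)
  mp <- staging_confusion(unclass(m)[perm, perm])
  for (i in 1:4) {
    expect_equal(stage_sensitivity(mp, stages()[which(perm == i)]),
                 stage_sensitivity(m, stages()[i]))
    expect_equal(stage_precision(mp, stages()[which(perm == i)]),
                 stage_precision(m, stages()[i]))
  }
  expect_equal(overall_accuracy(mp), overall_accuracy(m))
  expect_equal(cohen_kappa(mp), cohen_kappa(m))
})

test_that("kappa is bounded by 1, equaling 1 only for diagonal matrices", {
  set.seed(21)
  for (i in 1:10) {
    m <- staging_confusion(matrix(rpois(16, 5), 4, 4) + diag(1, 4))
    k <- cohen_kappa(m)
    expect_lte(k, 1)
    offdiag <- sum(m) - sum(diag(m))
    if (offdiag == 0) expect_equal(k, 1) else expect_lt(k, 1)
    # micro-consistency: sum over stages of colsum * sensitivity = trace
    sens <- vapply(stages(), function(s) stage_sensitivity(m, s), 1)
    sens[is.na(sens)] <- 0
    expect_equal(sum(colSums(m) * sens / 100), sum(diag(m)), tolerance = 1e-9)
  }
})

test_that("accuracy and kappa agree with an independent implementation", {
  for (nm in c("wli_rgb", "nbi_rgb", "wli_spectrum")) {
    m <- clinical_confusions(nm)
    cc <- caret::confusionMatrix(as.table(unclass(m)))
    expect_equal(overall_accuracy(m), 100 * unname(cc$overall["Accuracy"]),
                 tolerance = 1e-10)
    expect_equal(cohen_kappa(m), unname(cc$overall["Kappa"]),
                 tolerance = 1e-10)
  }
})

test_that("rounding is half-up, matching the reporting convention", {
  expect_equal(round_half_up(82.5), 83)
  expect_equal(round_half_up(0.835, 2), 0.84)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(92.49), 92)
})

test_that("confusion CSV round-trips and rejects malformed stage rows", {
  m <- clinical_confusions("nbi_rgb")
  f <- tempfile(fileext = ".csv")
  write_confusion_csv(m, f)
  m2 <- read_confusion_csv(f, modality = "nbi", representation = "rgb")
  expect_equal(unclass(m2), unclass(m), ignore_attr = TRUE)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("predicted,a,b,c,d", "x,1,1,1,1"), bad)
  expect_error(read_confusion_csv(bad))
})
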