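# helper: encodings for two perfectly separable composition classes
separable_encodings <- function(n_per = 30, seed = 1) {
  withr::with_seed(seed, {
    cores <- c(
      setNames(replicate(n_per, paste(sample(c("L", "I"), 24, TRUE), collapse = "")),
               paste0("a", seq_len(n_per))),
      setNames(replicate(n_per, paste(sample(c("V", "A"), 24, TRUE), collapse = "")),
               paste0("b", seq_len(n_per)))
    )
    al <- make_aligned(cores, cyt = "KKKK")
    list(x = encode_regions(al),
         labels = rep(c("one", "two"), each = n_per))
  })
}

test_that("region encoding yields 120 inputs with unit block sums", {
  al <- make_aligned(c(p = paste0("AAAA", strrep("L", 20))), cyt = "KRKS")
  enc <- encode_regions(al)
  expect_equal(ncol(enc) - 1, 120)
  m <- as.matrix(enc[, -1])
  # region 2 (positions 1-4) is all alanine
  expect_equal(unname(m[1, "r2_A"]), 1)
  expect_equal(sum(m[1, startsWith(colnames(m), "r2_")]), 1)
  # every populated region block sums to one
  for (r in 1:6) expect_equal(sum(m[1, startsWith(colnames(m), paste0("r", r, "_"))]), 1)
})

test_that("missing positions shrink the block denominator; absent regions warn", {
  # core of 17 residues with no exoplasmic flank: region 6 (18-24) is empty
  al <- make_aligned(c(p = strrep("L", 17)), cyt = "KKKK")
  expect_warning(enc <- encode_regions(al), "empty region")
  m <- as.matrix(enc[, -1])
  expect_equal(sum(m[1, startsWith(colnames(m), "r6_")]), 0)
  # region 5 (16-17) has both residues
  expect_equal(unname(m[1, "r5_L"]), 1)
})

test_that("confusion statistics follow the printed formulas", {
  perfect <- confusion_stats(5, 5, 0, 0)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  hand <- confusion_stats(3, 4, 1, 2)
  expect_equal(hand$mcc, 10 / sqrt(600))
  expect_equal(hand$sensitivity, 3 / 5)
  expect_equal(hand$specificity, 3 / 4)
  expect_equal(confusion_stats(0, 5, 0, 5)$sensitivity, 0)
  # zero denominator factor -> MCC defined as 0
  expect_equal(confusion_stats(0, 10, 0, 0)$mcc, 0)
  expect_error(confusion_stats(0, 0, 0, 0), "all counts zero")
  expect_error(confusion_stats(-1, 1, 1, 1), "negative")
})

test_that("MCC is invariant under the simultaneous Tp/Tn and Fp/Fn swap", {
  set.seed(3)
  for (i in 1:20) {
    k <- sample(0:30, 4, TRUE)
    if (sum(k) == 0) next
    expect_equal(confusion_stats(k[1], k[2], k[3], k[4])$mcc,
                 confusion_stats(k[2], k[1], k[4], k[3])$mcc)
  }
})

test_that("threshold scanning finds separating thresholds and flat curves", {
  scores <- c(runif(40, 0, 0.35), runif(40, 0.65, 1))
  labels <- rep(c(FALSE, TRUE), each = 40)
  sc <- threshold_scan(scores, labels)
  expect_equal(sc$mcc, 1)
  expect_gt(sc$threshold, max(scores[!labels]) - 0.011)
  expect_lte(sc$threshold, min(scores[labels]) + 0.011)
  # equal scores: MCC 0 at every threshold
  flat <- threshold_scan(rep(0.5, 20), rep(c(TRUE, FALSE), 10))
  expect_true(all(flat$curve$mcc == 0))
})

test_that("the scanned threshold is near the exhaustive-threshold optimum", {
  set.seed(9)
  scores <- pmin(pmax(c(rnorm(120, 0.4, 0.12), rnorm(120, 0.62, 0.12)), 0), 1)
  labels <- rep(c(FALSE, TRUE), each = 120)
  sc <- threshold_scan(scores, labels)
  cand <- sort(unique(c(0, scores, 1)))
  mccs <- vapply(cand, function(th) {
    pos <- scores >= th
    confusion_stats(sum(pos & labels), sum(!pos & !labels),
                    sum(pos & !labels), sum(!pos & labels))$mcc
  }, numeric(1))
  expect_gte(sc$mcc, max(mccs) - 0.02)
  expect_lte(abs(sc$threshold - cand[which.max(mccs)]), 0.02)
})

test_that("training separates separable classes deterministically", {
  d <- separable_encodings()
  fit <- ann_train(d$x, d$labels, seed = 7)
  expect_gte(mean(predict(fit, d$x)$.pred == d$labels), 0.99)
  fit2 <- ann_train(d$x, d$labels, seed = 7)
  expect_identical(fit$w_in, fit2$w_in)
  expect_identical(fit$w_out, fit2$w_out)
  expect_error(ann_train(d$x, rep("one", length(d$labels))), "two classes")
})

test_that("training loss is non-increasing on separable data", {
  d <- separable_encodings()
  fit <- ann_train(d$x, d$labels, seed = 11, restarts = 1)
  expect_true(all(diff(fit$loss) <= 1e-8))
  expect_lt(fit$loss[length(fit$loss)], fit$loss[1])
})

test_that("scores lie in (0,1) and argmax defines the prediction", {
  d <- separable_encodings()
  fit <- ann_train(d$x, d$labels, seed = 7)
  pr <- predict(fit, d$x)
  expect_true(all(pr$one > 0 & pr$one < 1 & pr$two > 0 & pr$two < 1))
  expect_equal(pr$.pred, ifelse(pr$one > pr$two, "one", "two"))
})

test_that("cross-validation partitions stratified folds exactly once and is
           perfect on separable data", {
  d <- separable_encodings(25)
  cv <- cross_validate(d$x, d$labels, k = 5, seed = 3)
  expect_equal(cv$accuracy, 1)
  expect_true(all(cv$stats$mcc == 1))
  folds <- cv$scores$fold
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(as.vector(table(folds, cv$scores$label)),
               rep(5, 10))  # 25 per class over 5 folds, stratified
  expect_error(cross_validate(d$x, d$labels, k = 30, seed = 1), "at least k")
})

test_that("cross-validation accuracy is invariant to class relabelling on
           separable data", {
  d <- separable_encodings(25)
  cv1 <- cross_validate(d$x, d$labels, k = 5, seed = 3)
  relab <- c(one = "zz_late", two = "aa_early")[d$labels]
  cv2 <- cross_validate(d$x, unname(relab), k = 5, seed = 3)
  expect_equal(cv1$accuracy, cv2$accuracy)
})

test_that("shuffled labels collapse accuracy to chance", {
  d <- separable_encodings(40)
  shuffled <- withr::with_seed(5, sample(d$labels))
  cv <- cross_validate(d$x, shuffled, k = 5, seed = 5)
  expect_lt(abs(cv$accuracy - 0.5), 0.10)
})

test_that("mirror-symmetric proteins score identically under reversal", {
  core <- "LLLLVVVVLLLL"                      # palindromic core
  p <- make_protein(paste0("KKKNPS", core, "SPNKKK"), id = "pal",
                    tmd_start = 7, tmd_end = 18)
  prot <- sample_dataset("fungal-er", 30, seed = 41)
  enc <- encode_proteins(dplyr::bind_rows(prot, p))
  fit <- ann_train(enc$encodings,
                   c(rep(c("ER", "other"), c(30, 1))), seed = 2, restarts = 1)
  fwd <- predict_organelle(fit, p)
  rev <- predict_organelle(fit, p, reverse = TRUE)
  expect_equal(fwd$ER, rev$ER, tolerance = 1e-12)
})

test_that("reversed PM-like proteins lose their PM signal", {
  sets <- fungal_sets(60, seed = 43)
  enc <- encode_proteins(sets)
  fit <- ann_train(enc$encodings, enc$labels, seed = 6)
  pm <- sets[sets$organelle == "PM", ]
  fwd <- predict_organelle(fit, pm)
  bwd <- predict_organelle(fit, pm, reverse = TRUE)
  expect_gt(mean(fwd$PM), mean(bwd$PM))
  expect_gt(mean(fwd$.pred == "PM"), mean(bwd$.pred == "PM"))
})

test_that("a serialized network predicts identically after reload", {
  d <- separable_encodings()
  fit <- ann_train(d$x, d$labels, seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_ann(fit, path)
  back <- read_ann(path)
  expect_equal(predict(back, d$x)$one, predict(fit, d$x)$one, tolerance = 1e-12)
  expect_equal(back$classes, fit$classes)
})
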