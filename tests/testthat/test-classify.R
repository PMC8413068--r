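test_that("confusion rates reproduce hand-computed arithmetic", {
  m <- confusionMetrics(50, 40, 5, 5)
  expect_equal(m$sensitivity, 50 / 55 * 100)
  expect_equal(m$specificity, 40 / 45 * 100)
  expect_equal(m$accuracy, 90)
  expect_equal(m$f1, 50 / (50 + 5))
  expect_length(m$undefined, 0)

  perfect <- confusionMetrics(10, 10, 0, 0)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$kappa, 1)

  degenerate <- confusionMetrics(0, 10, 0, 10)
  expect_equal(degenerate$sensitivity, 0)
  expect_equal(degenerate$specificity, 100)
  expect_equal(degenerate$accuracy, 50)
  expect_equal(degenerate$f1, 0)

  # undefined rates are NA and flagged, not zero
  u <- confusionMetrics(0, 5, 0, 0)
  expect_true(is.na(u$sensitivity))
  expect_true("sensitivity" %in% u$undefined)
})

test_that("kappa follows (po - pe) / (1 - pe) and the marginal-product rule", {
  expect_equal(cohenKappa(0.9, 0.5), 0.8)
  expect_equal(cohenKappa(0.6, 0.6), 0)
  expect_equal(cohenKappa(1, 0.5), 1)
  expect_true(is.na(cohenKappa(0.9, 1)))

  # marginals: predicted B 55, G 45; actual B 55, G 45 on n = 100
  po <- 0.9
  pe <- (55 * 55 + 45 * 45) / 100^2
  expect_equal(kappaFromConfusion(50, 40, 5, 5), (po - pe) / (1 - pe))
})

test_that("a 70/10/20 split of 360 instances yields 252/36/72", {
  # 180 subjects x 2 trials, balanced classes, split at the subject level
  subs <- sprintf("s%03d", 1:180)
  tab <- data.frame(
    subject_id = rep(subs, each = 2),
    trial = rep(c("baseline", "task"), 180),
    channel = "EEG Fp1", mode = 1, area = 0, m = 0, ctm = 0,
    label = rep(c("G", "B"), each = 180), stringsAsFactors = FALSE)
  parts <- splitSubjects(tab, "percentage", seed = 2)
  nrows <- function(ids) sum(tab$subject_id %in% ids)
  expect_equal(nrows(parts$train), 252)
  expect_equal(nrows(parts$validation), 36)
  expect_equal(nrows(parts$test), 72)
  # stratified: half of each partition per class
  lab_of <- setNames(tab$label[!duplicated(tab$subject_id)],
                     tab$subject_id[!duplicated(tab$subject_id)])
  expect_equal(unname(table(lab_of[parts$train])), c(63L, 63L),
               ignore_attr = TRUE)
  # no subject straddles partitions
  expect_length(intersect(parts$train, parts$test), 0)
  expect_length(intersect(parts$train, parts$validation), 0)
  # deterministic under seed
  expect_identical(parts, splitSubjects(tab, "percentage", seed = 2))
  expect_false(identical(parts, splitSubjects(tab, "percentage", seed = 3)))
})

test_that("k-fold splitting is stratified, exhaustive and guarded", {
  subs <- sprintf("s%02d", 1:40)
  tab <- data.frame(subject_id = subs, trial = "task", channel = "c",
                    mode = 1, area = 0, m = 0, ctm = 0,
                    label = rep(c("G", "B"), 20), stringsAsFactors = FALSE)
  folds <- splitSubjects(tab, "kfold", k = 10, seed = 1)
  expect_length(folds, 10)
  expect_true(all(lengths(folds) == 4))
  expect_setequal(unlist(folds), subs)
  expect_error(splitSubjects(tab[tab$label == "G" | tab$subject_id < "s20", ],
                             "kfold", k = 15),
               "cannot be split")
})

test_that("standardisation statistics come from the training rows only", {
  set.seed(8)
  Xtr <- matrix(rnorm(50), 10, 5)
  sc <- StressVMD:::.fit_scaler(Xtr)
  # planting an extreme test-only outlier cannot move the scaler
  Xte <- matrix(rnorm(10), 2, 5); Xte[1, ] <- 1e6
  sc2 <- StressVMD:::.fit_scaler(Xtr)
  expect_identical(sc, sc2)
  Ztr <- StressVMD:::.apply_scaler(Xtr, sc)
  expect_equal(unname(colMeans(Ztr)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(Ztr, 2, sd)), rep(1, 5), tolerance = 1e-12)
  # the outlier stays an outlier after scaling with training statistics
  expect_true(all(abs(StressVMD:::.apply_scaler(Xte, sc)[1, ]) > 100))
})

test_that("the flattened feature matrix has fixed column order and full cells", {
  ds <- small_dataset(nGood = 2, nBad = 2, K = 8)
  ft <- buildFeatureTable(ds$decomps, ds$labels)
  fm <- featureMatrix(ft, region = "all", modeGroup = "m1_8")
  expect_equal(dim(fm$X), c(4 * 2, 2 * 8 * 3))   # instances x features
  expect_equal(fm$y[order(fm$subjects)], ft$label[match(sort(fm$subjects),
                                                        ft$subject_id)])
  expect_false(anyNA(fm$X))
  # a mode-group subset narrows the columns accordingly
  fm14 <- featureMatrix(ft, region = "all", modeGroup = "m1_4")
  expect_equal(ncol(fm14$X), 2 * 4 * 3)
  # region subsetting by montage prefix
  fmT <- featureMatrix(ft, region = "temporal", modeGroup = "m1_8")
  expect_equal(ncol(fmT$X), 1 * 8 * 3)
  expect_error(featureMatrix(ft, region = "occipital", modeGroup = "m1_8"),
               "empty subset")
})

test_that("evaluation reports satisfy the metric invariants and pool all instances", {
  ds <- small_dataset(nGood = 5, nBad = 5, K = 8, effectSize = 3,
                      durTask = 2, durBase = 2)
  ft <- buildFeatureTable(ds$decomps, ds$labels)
  for (clf in c("mlp", "svm")) {
    rep <- evaluateSubset(ft, "all", "m1_8", classifier = clf,
                          split = "kfold", k = 5, seed = 2)
    expect_equal(rep$TP + rep$TN + rep$FP + rep$FN, nrow(ft) / (2 * 8))
    expect_equal(rep$n_instances, 20)   # 10 subjects x 2 trials
    rates <- c(rep$sensitivity, rep$specificity, rep$accuracy)
    expect_true(all(rates >= 0 & rates <= 100, na.rm = TRUE))
    expect_true(is.na(rep$kappa) || (rep$kappa >= -1 && rep$kappa <= 1))
  }
})

test_that("evaluation is deterministic under seed for both protocols", {
  ds <- small_dataset(nGood = 5, nBad = 5, K = 8)
  ft <- buildFeatureTable(ds$decomps, ds$labels)
  for (sp in c("percentage", "kfold")) {
    r1 <- evaluateSubset(ft, "all", "m1_8", "mlp", split = sp, k = 5,
                         seed = 7)
    r2 <- evaluateSubset(ft, "all", "m1_8", "mlp", split = sp, k = 5,
                         seed = 7)
    expect_identical(r1, r2)
  }
})

test_that("gender subsets filter subjects through the label table", {
  ds <- small_dataset(nGood = 4, nBad = 4, K = 8)
  ft <- buildFeatureTable(ds$decomps, ds$labels)
  labs <- ds$labels
  labs$gender <- rep(c("F", "M"), 4)
  fem <- labs$subject_id[labs$gender == "F"]
  # alternating genders over (4 G then 4 B) subjects leave 2 G + 2 B females
  expect_equal(unname(table(labs$quality[labs$gender == "F"])), c(2L, 2L),
               ignore_attr = TRUE)
  rep <- evaluateSubset(ft, "all", "m1_8", "svm", split = "kfold", k = 2,
                        seed = 1, gender = "F", labels = labs)
  expect_equal(rep$n_instances, 2 * length(fem))
  expect_error(evaluateSubset(ft, "all", "m1_8", "svm", gender = "F"),
               "gender column")
})
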