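#' Confusion-matrix rates
#'
#' Sensitivity, specificity and accuracy as percentages, F1 as a
#' fraction, from raw confusion counts:
#' `SEN = TP/(TP+FN)*100`, `SPE = TN/(TN+FP)*100`,
#' `ACC = (TP+TN)/(TP+TN+FP+FN)*100`, `F1 = TP/(TP + (FP+FN)/2)`.
#' A rate whose denominator is zero is reported as `NA` (undefined, not
#' zero) and listed in the `undefined` element.
#'
#' @param TP,TN,FP,FN nonnegative integer counts.
#' @return list with `TP`, `TN`, `FP`, `FN`, `sensitivity`,
#'   `specificity`, `accuracy` (percent), `f1` (fraction), `kappa`
#'   (chance-corrected agreement from the matrix marginals) and
#'   `undefined` (character vector naming any undefined metrics).
#' @examples
#' confusionMetrics(50, 40, 5, 5)
#' @export
confusionMetrics <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  n <- TP + TN + FP + FN
  undef <- character()
  rate <- function(num, den, what) {
    if (den <= 0) { undef <<- c(undef, what); return(NA_real_) }
    num / den
  }
  sen <- rate(TP, TP + FN, "sensitivity") * 100
  spe <- rate(TN, TN + FP, "specificity") * 100
  acc <- rate(TP + TN, n, "accuracy") * 100
  f1  <- rate(TP, TP + (FP + FN) / 2, "f1")
  kap <- kappaFromConfusion(TP, TN, FP, FN)
  if (is.na(kap)) undef <- c(undef, "kappa")
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       sensitivity = sen, specificity = spe, accuracy = acc, f1 = f1,
       kappa = kap, undefined = undef)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` from observed and
#' expected agreement fractions. `kappaFromConfusion()` derives both from
#' a 2x2 confusion matrix, with expected agreement from the marginal
#' products.
#'
#' @param observed,expected agreement fractions in `[0, 1]`,
#'   `expected < 1`.
#' @return kappa in `[-1, 1]`; `NA` (flagged undefined) when
#'   `expected == 1`.
#' @examples
#' cohenKappa(0.9, 0.5)  # 0.8
#' @export
cohenKappa <- function(observed, expected) {
  stopifnot(observed >= 0, observed <= 1, expected >= 0, expected <= 1)
  if (expected >= 1) return(NA_real_)
  (observed - expected) / (1 - expected)
}

#' @rdname cohenKappa
#' @param TP,TN,FP,FN confusion counts.
#' @export
kappaFromConfusion <- function(TP, TN, FP, FN) {
  n <- TP + TN + FP + FN
  if (n <= 0) return(NA_real_)
  po <- (TP + TN) / n
  pe <- ((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN)) / n^2
  cohenKappa(po, pe)
}

#' Subject-level stratified splits
#'
#' Partitions the subjects of a feature table so that all rows (both
#' trials) of a subject stay on one side of every boundary — the guard
#' against identity leakage. Stratified by class; deterministic under
#' `seed`.
#'
#' @param table feature table (columns `subject_id`, `label`).
#' @param mode `"percentage"` for one train/validation/test partition,
#'   `"kfold"` for k folds.
#' @param fractions named numeric (train, validation, test) summing to 1;
#'   default `c(0.70, 0.10, 0.20)`. Per class the train and validation
#'   counts are `round(n * fraction)` and the remainder is test.
#' @param k number of folds (>= 2) for `mode = "kfold"`; every class
#'   must have at least `k` subjects.
#' @param seed integer shuffle seed.
#' @return for `"percentage"`, list of character vectors `train`,
#'   `validation`, `test` (subject ids); for `"kfold"`, list of `k`
#'   character vectors.
#' @export
splitSubjects <- function(table, mode = c("percentage", "kfold"),
                          fractions = c(train = 0.70, validation = 0.10,
                                        test = 0.20),
                          k = 10L, seed = 1L) {
  mode <- match.arg(mode)
  subj <- unique(table[, c("subject_id", "label")])
  byClass <- split(subj$subject_id, subj$label)
  if (mode == "percentage") {
    stopifnot(abs(sum(fractions) - 1) < 1e-9)
    parts <- list(train = character(), validation = character(),
                  test = character())
    for (ids in byClass) {
      ids <- .with_seed(seed, sample(ids))
      nTr <- round(length(ids) * fractions[["train"]])
      nVa <- round(length(ids) * fractions[["validation"]])
      if (nTr + nVa > length(ids))
        nVa <- length(ids) - nTr
      parts$train <- c(parts$train, ids[seq_len(nTr)])
      parts$validation <- c(parts$validation,
                            ids[nTr + seq_len(nVa)])
      parts$test <- c(parts$test, ids[setdiff(seq_along(ids),
                                              seq_len(nTr + nVa))])
      seed <- seed + 1L   # different shuffle per class
    }
    parts
  } else {
    k <- as.integer(k)
    stopifnot(k >= 2L)
    folds <- vector("list", k)
    for (ids in byClass) {
      if (length(ids) < k)
        stop("class with ", length(ids),
             " subjects cannot be split into k = ", k, " folds")
      ids <- .with_seed(seed, sample(ids))
      f <- rep(seq_len(k), length.out = length(ids))
      for (j in seq_len(k)) folds[[j]] <- c(folds[[j]], ids[f == j])
      seed <- seed + 1L
    }
    folds
  }
}

.mode_groups <- list(m1_4 = 1:4, m5_8 = 5:8, m1_8 = 1:8)

#' Flatten a feature-table subset into an instance matrix
#'
#' Selects rows by channel group and mode group, then pivots to one row
#' per subject-trial instance with columns in fixed
#' (channel, mode, descriptor) order.
#'
#' @param table feature table.
#' @param region channel group name (see [channelGroup()]) or `"all"`.
#' @param modeGroup `"m1_4"`, `"m5_8"` or `"m1_8"`.
#' @param montage optional montage to resolve the region against;
#'   default the channels present in the table.
#' @return list with `X` (numeric matrix), `y` (labels), `subjects`,
#'   `trials` (per instance).
#' @export
featureMatrix <- function(table, region = "all",
                          modeGroup = c("m1_8", "m1_4", "m5_8"),
                          montage = NULL) {
  modeGroup <- match.arg(modeGroup)
  modesWanted <- .mode_groups[[modeGroup]]
  if (is.null(montage)) montage <- unique(table$channel)
  chans <- channelGroup(montage, region)
  sel <- table[table$channel %in% chans & table$mode %in% modesWanted, ,
               drop = FALSE]
  if (nrow(sel) == 0L)
    stop("empty subset: region '", region, "', mode group '", modeGroup, "'")
  key <- paste(sel$subject_id, sel$trial, sep = "\r")
  inst <- unique(data.frame(key = key, subject_id = sel$subject_id,
                            trial = sel$trial, label = sel$label,
                            stringsAsFactors = FALSE))
  inst <- inst[order(inst$subject_id, inst$trial), , drop = FALSE]
  cols <- expand.grid(desc = c("area", "m", "ctm"), mode = modesWanted,
                      channel = chans, stringsAsFactors = FALSE)
  X <- matrix(NA_real_, nrow(inst), nrow(cols))
  rowOf <- match(key, inst$key)
  colBase <- match(paste(sel$channel, sel$mode),
                   paste(cols$channel, cols$mode))
  # cols is desc-fastest, so match() lands on the 'area' column and the
  # (channel, mode) block occupies colBase .. colBase + 2
  for (d in 1:3) {
    X[cbind(rowOf, colBase + d - 1L)] <-
      sel[[c("area", "m", "ctm")[d]]]
  }
  if (anyNA(X))
    stop("incomplete feature table: some (channel, mode) cells are missing")
  colnames(X) <- paste(cols$channel, cols$mode, cols$desc, sep = ".")
  list(X = X, y = inst$label, subjects = inst$subject_id,
       trials = inst$trial)
}

# Standardise columns by training-row statistics only.
.fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}
.apply_scaler <- function(X, s) sweep(sweep(X, 2, s$mu), 2, s$sd, `/`)

.train_predict <- function(Xtr, ytr, Xte, classifier, seed,
                           Xval = NULL, yval = NULL, clfParams = list()) {
  if (classifier == "mlp") {
    args <- utils::modifyList(
      list(X = Xtr, y = ytr, hidden = c(10L, 10L, 10L), lr = 1e-3,
           alpha = 1e-4, epochs = 200L, seed = seed,
           Xval = Xval, yval = yval),
      clfParams)
    fit <- do.call(mlpTrain, args)
    pos <- fit$positive
    pred <- ifelse(predict(fit, Xte, type = "class") == 1,
                   pos, setdiff(sort(unique(ytr)), pos))
    list(pred = pred, converged = fit$converged)
  } else {
    args <- utils::modifyList(
      list(x = Xtr, y = factor(ytr), type = "C-classification",
           kernel = "radial", cost = 0.90, gamma = 0.02,
           tolerance = 0.0010, scale = FALSE),
      clfParams)
    fit <- do.call(e1071::svm, args)
    list(pred = as.character(predict(fit, Xte)), converged = TRUE)
  }
}

.confusion_counts <- function(truth, pred, positive) {
  list(TP = sum(truth == positive & pred == positive),
       TN = sum(truth != positive & pred != positive),
       FP = sum(truth != positive & pred == positive),
       FN = sum(truth == positive & pred != positive))
}

#' Train and evaluate a classifier on a feature subset
#'
#' Selects rows by brain-region channel group and mode group, flattens
#' each subject-trial into a fixed-order feature vector, standardises
#' features with training-set statistics only, trains the configured
#' classifier, and reports confusion counts with the five derived
#' metrics. The positive class is `"B"` (stressed).
#'
#' Under `split = "percentage"` one stratified subject-level 70/10/20
#' partition is drawn: the MLP uses the validation block for best-weight
#' monitoring (the SVM ignores it) and metrics come from the test block.
#' Under `split = "kfold"` the k fold predictions are pooled into one
#' confusion matrix, so every instance is evaluated exactly once.
#'
#' SVM hyperparameters follow the protocol (`cost = 0.90`,
#' RBF kernel `exp(-g |x - y|^2)` with `g = 0.02`, numerical tolerance
#' 0.001); the protocol's epsilon and iteration-limit settings are
#' regression-solver parameters with no effect on C-classification and
#' are not passed through.
#'
#' @param table feature table (balanced or not).
#' @param region channel group name, default `"all"`.
#' @param modeGroup `"m1_4"`, `"m5_8"` or `"m1_8"`.
#' @param classifier `"mlp"` or `"svm"`.
#' @param split `"percentage"` or `"kfold"`.
#' @param k folds for `"kfold"` (default 10).
#' @param fractions percentage-split fractions, default 70/10/20.
#' @param seed integer; drives the split and the MLP initialisation.
#' @param gender optional `"M"`/`"F"`: restrict the comparison to
#'   subjects of one gender (requires `labels`).
#' @param labels label table with a `gender` column; only needed when
#'   `gender` is set.
#' @param clfParams named list overriding classifier arguments.
#' @param montage optional montage for region resolution.
#' @return list (an evaluation report): subset echo plus `TP`, `TN`,
#'   `FP`, `FN`, `sensitivity`, `specificity`, `accuracy` (percent),
#'   `f1`, `kappa`, `n_instances`, `converged`, `undefined`.
#' @export
evaluateSubset <- function(table, region = "all",
                           modeGroup = c("m1_8", "m1_4", "m5_8"),
                           classifier = c("mlp", "svm"),
                           split = c("percentage", "kfold"), k = 10L,
                           fractions = c(train = 0.70, validation = 0.10,
                                         test = 0.20),
                           seed = 1L, gender = NULL, labels = NULL,
                           clfParams = list(), montage = NULL) {
  modeGroup <- match.arg(modeGroup)
  classifier <- match.arg(classifier)
  split <- match.arg(split)
  if (!is.null(gender)) {
    if (is.null(labels) || is.null(labels$gender))
      stop("gender subsets require a label table with a gender column")
    keep <- labels$subject_id[labels$gender == gender]
    table <- table[sub("_dup[0-9]+$", "", table$subject_id) %in% keep, ,
                   drop = FALSE]
  }
  fm <- featureMatrix(table, region = region, modeGroup = modeGroup,
                      montage = montage)
  positive <- "B"
  conv <- TRUE

  if (split == "percentage") {
    parts <- splitSubjects(table, "percentage", fractions = fractions,
                           seed = seed)
    iTr <- fm$subjects %in% parts$train
    iVa <- fm$subjects %in% parts$validation
    iTe <- fm$subjects %in% parts$test
    if (!any(iTe)) stop("test partition is empty; too few subjects")
    sc <- .fit_scaler(fm$X[iTr, , drop = FALSE])
    res <- .train_predict(.apply_scaler(fm$X[iTr, , drop = FALSE], sc),
                          fm$y[iTr],
                          .apply_scaler(fm$X[iTe, , drop = FALSE], sc),
                          classifier, seed,
                          Xval = if (any(iVa))
                            .apply_scaler(fm$X[iVa, , drop = FALSE], sc),
                          yval = if (any(iVa)) fm$y[iVa],
                          clfParams = clfParams)
    conv <- res$converged
    cc <- .confusion_counts(fm$y[iTe], res$pred, positive)
  } else {
    folds <- splitSubjects(table, "kfold", k = k, seed = seed)
    truth <- character(); pred <- character()
    for (j in seq_along(folds)) {
      iTe <- fm$subjects %in% folds[[j]]
      iTr <- !iTe
      sc <- .fit_scaler(fm$X[iTr, , drop = FALSE])
      res <- .train_predict(.apply_scaler(fm$X[iTr, , drop = FALSE], sc),
                            fm$y[iTr],
                            .apply_scaler(fm$X[iTe, , drop = FALSE], sc),
                            classifier, seed + j, clfParams = clfParams)
      conv <- conv && res$converged
      truth <- c(truth, fm$y[iTe])
      pred <- c(pred, res$pred)
    }
    cc <- .confusion_counts(truth, pred, positive)
  }
  met <- confusionMetrics(cc$TP, cc$TN, cc$FP, cc$FN)
  c(list(region = region, mode_group = modeGroup, classifier = classifier,
         split = split, n_instances = with(cc, TP + TN + FP + FN),
         converged = conv),
    met)
}

#' Run the whole stress-classification pipeline
#'
#' Convenience wrapper: per-channel VMD of every recording, Poincare
#' feature extraction for the retained modes, class balancing by
#' replication, Wilcoxon screening, and classifier evaluation on the
#' requested subset.
#'
#' @param recordings list of [Recording-class] (both trials per subject).
#' @param labels label table ([readLabels()] format).
#' @param K modes to extract per channel (default 10).
#' @param modesKept modes retained for features (default 1:8).
#' @param r CTM radius.
#' @param alpha,tau,tol,maxIter [vmd()] parameters.
#' @param balance replicate the minority class to parity first?
#' @param screeningAlpha Wilcoxon screening threshold.
#' @param ... passed to [evaluateSubset()] (`region`, `modeGroup`,
#'   `classifier`, `split`, `k`, `seed`, ...).
#' @return list with `features` (the balanced feature table), `screen`
#'   (the Wilcoxon report) and `report` (the evaluation report).
#' @export
runStressPipeline <- function(recordings, labels, K = 10L, modesKept = 1:8,
                              r = 0.5, alpha = 2000, tau = 0, tol = 1e-7,
                              maxIter = 500L, balance = TRUE,
                              screeningAlpha = 0.05, ...) {
  decomps <- lapply(recordings, decomposeRecording, K = K, alpha = alpha,
                    tau = tau, tol = tol, maxIter = maxIter)
  ft <- buildFeatureTable(decomps, labels, modesKept = modesKept, r = r)
  if (balance) ft <- balanceByReplication(ft, seed = 1L)
  screen <- wilcoxonScreen(ft, alpha = screeningAlpha)
  report <- evaluateSubset(ft, labels = labels, ...)
  list(features = ft, screen = screen, report = report)
}
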