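#' Assemble the per-mode Poincare feature table
#'
#' For every decomposed recording, every channel and every retained mode,
#' computes the three Poincare descriptors (ellipse area, mean radial
#' distance `m`, CTM at radius `r`) and joins the subject's class label.
#' The result is the long-format feature map used throughout the
#' pipeline: one row per (subject, trial, channel, mode), so a
#' subject-trial contributes `channels x modes` rows and, flattened with
#' the 3 descriptors, a `channels x modes x 3`-dimensional feature
#' vector.
#'
#' @param decomps a [DecomposedRecording-class] or a list of them.
#' @param labels data.frame as returned by [readLabels()] (columns
#'   `subject_id`, `quality`); every decomposed subject must appear.
#' @param modesKept integer vector of 1-based mode indices to retain
#'   (default `1:8`: of 10 extracted modes the first eight, counted in
#'   ascending center frequency, carry the discriminative dispersion).
#' @param r CTM radius, default 0.5.
#' @return data.frame with columns `subject_id`, `trial`, `channel`,
#'   `mode`, `area`, `m`, `ctm`, `label`, sorted by (subject, trial,
#'   channel, mode); attribute `"r"` records the CTM radius.
#' @export
buildFeatureTable <- function(decomps, labels, modesKept = 1:8, r = 0.5) {
  if (is(decomps, "DecomposedRecording")) decomps <- list(decomps)
  stopifnot(length(decomps) >= 1L,
            all(vapply(decomps, is, logical(1), "DecomposedRecording")))
  modesKept <- sort(unique(as.integer(modesKept)))
  stopifnot(all(modesKept >= 1L))
  lab <- stats::setNames(labels$quality, labels$subject_id)

  pieces <- lapply(decomps, function(d) {
    sid <- subjectId(d)
    if (is.na(lab[sid]) || is.null(lab[sid]) || !sid %in% names(lab))
      stop("no label for subject '", sid, "'")
    dec <- decompositions(d)
    chunks <- lapply(names(dec), function(ch) {
      M <- modes(dec[[ch]])
      if (max(modesKept) > nrow(M))
        stop("channel '", ch, "' of subject '", sid, "' has ", nrow(M),
             " modes; mode ", max(modesKept), " requested")
      feats <- lapply(modesKept, function(k) ppFeatures(M[k, ], r = r))
      data.frame(
        subject_id = sid, trial = trial(d), channel = ch, mode = modesKept,
        area = vapply(feats, `[[`, 0, "area"),
        m    = vapply(feats, `[[`, 0, "m"),
        ctm  = vapply(feats, `[[`, 0, "ctm"),
        label = unname(lab[sid]),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, chunks)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$subject_id, out$trial, out$channel, out$mode), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "r") <- r
  out
}

#' Balance classes by whole-subject replication
#'
#' Adds "dummy participants": whole-subject, channel-wise copies of
#' randomly chosen minority-class subjects (drawn with replacement under
#' `seed`) with fresh synthetic subject ids, until the two class counts
#' match. Original rows are untouched; an already balanced table is
#' returned unchanged.
#'
#' @param table feature table from [buildFeatureTable()].
#' @param seed integer controlling which subjects are replicated.
#' @return the augmented feature table; replicas carry ids
#'   `<original>_dup<k>`.
#' @export
balanceByReplication <- function(table, seed = 1L) {
  subj <- unique(table[, c("subject_id", "label")])
  counts <- table(subj$label)
  if (length(counts) < 2L)
    stop("balancing requires two classes; found only: ",
         paste(names(counts), collapse = ", "))
  if (counts[1] == counts[2]) return(table)
  minority <- names(counts)[which.min(counts)]
  deficit <- abs(counts[1] - counts[2])
  pool <- subj$subject_id[subj$label == minority]
  picks <- .with_seed(seed, sample(pool, deficit, replace = TRUE))
  extra <- lapply(seq_along(picks), function(i) {
    rows <- table[table$subject_id == picks[i], , drop = FALSE]
    rows$subject_id <- paste0(picks[i], "_dup", i)
    rows
  })
  out <- rbind(table, do.call(rbind, extra))
  rownames(out) <- NULL
  attr(out, "r") <- attr(table, "r", exact = TRUE)
  out
}

#' Screen features with the Wilcoxon signed-rank test
#'
#' Tests each descriptor column (`area`, `m`, `ctm`) for a class
#' difference with the two-sided Wilcoxon signed-rank test. The two class
#' samples are paired positionally: rows of each class are sorted by
#' (subject, trial, channel, mode) and the i-th good-class row is paired
#' with the i-th bad-class row, which is well defined after
#' [balanceByReplication()] has equalised the counts. Zero differences
#' are dropped (Wilcoxon's original rule); the exact null distribution is
#' used for up to 25 nonzero pairs and the normal approximation with
#' continuity correction beyond that. A feature with fewer than 2 nonzero
#' pairs is marked untestable and not retained.
#'
#' @param table balanced feature table.
#' @param alpha significance threshold; default 0.05 (95% confidence).
#' @param exact force (`TRUE`/`FALSE`) the exact test; `NULL` (default)
#'   picks exact for <= 25 nonzero pairs.
#' @return data.frame with one row per feature: `feature`, `statistic`
#'   (the signed-rank V), `p_value`, `retained` (`p < alpha`),
#'   `untestable`; attribute `"alpha"` echoes the threshold.
#' @export
wilcoxonScreen <- function(table, alpha = 0.05, exact = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  cls <- sort(unique(table$label))
  if (length(cls) != 2L)
    stop("screening requires exactly two classes; found: ",
         paste(cls, collapse = ", "))
  ord <- function(d) d[order(d$subject_id, d$trial, d$channel, d$mode), ,
                       drop = FALSE]
  g1 <- ord(table[table$label == cls[1], , drop = FALSE])
  g2 <- ord(table[table$label == cls[2], , drop = FALSE])
  if (nrow(g1) != nrow(g2))
    stop("class row counts differ (", nrow(g1), " vs ", nrow(g2),
         "); balance the table before screening")
  rows <- lapply(c("area", "m", "ctm"), function(f) {
    x <- g1[[f]]; y <- g2[[f]]
    nz <- sum(x != y)
    if (nz < 2L) {
      warning("feature '", f, "' has fewer than 2 nonzero paired ",
              "differences; marked untestable")
      return(data.frame(feature = f, statistic = NA_real_,
                        p_value = NA_real_, retained = FALSE,
                        untestable = TRUE))
    }
    useExact <- if (is.null(exact)) nz <= 25L else isTRUE(exact)
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = useExact,
                         correct = TRUE, alternative = "two.sided"))
    data.frame(feature = f, statistic = unname(wt$statistic),
               p_value = wt$p.value, retained = wt$p.value < alpha,
               untestable = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}
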