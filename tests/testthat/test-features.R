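test_that("the feature table has one row per subject-trial-channel-mode", {
  ds <- small_dataset(nGood = 2, nBad = 1, K = 8)
  ft <- buildFeatureTable(ds$decomps, ds$labels, modesKept = 1:8)
  # 3 subjects x 2 trials x 2 channels x 8 modes
  expect_equal(nrow(ft), 3 * 2 * 2 * 8)
  expect_named(ft, c("subject_id", "trial", "channel", "mode",
                     "area", "m", "ctm", "label"))
  # exactly 8 rows (one per retained mode) per subject-trial-channel
  cnt <- table(paste(ft$subject_id, ft$trial, ft$channel))
  expect_true(all(cnt == 8))
  expect_true(all(ft$mode %in% 1:8))
  # label consistent within subject
  expect_true(all(tapply(ft$label, ft$subject_id,
                         function(l) length(unique(l)) == 1)))
  # deterministic ordering
  expect_false(is.unsorted(order(ft$subject_id, ft$trial, ft$channel, ft$mode)))
  expect_equal(attr(ft, "r"), 0.5)
})

test_that("feature values agree with direct per-mode descriptor computation", {
  ds <- small_dataset(nGood = 1, nBad = 1, K = 8)
  ft <- buildFeatureTable(ds$decomps, ds$labels)
  d1 <- ds$decomps[[1]]
  ch <- channelNames(d1)[1]
  mk <- modes(decompositions(d1)[[ch]])[3, ]
  want <- ppFeatures(mk, r = 0.5)
  row <- ft[ft$subject_id == subjectId(d1) & ft$trial == trial(d1) &
              ft$channel == ch & ft$mode == 3, ]
  expect_equal(row$area, want$area)
  expect_equal(row$m, want$m)
  expect_equal(row$ctm, want$ctm)
})

test_that("unlabeled subjects and missing modes are reported by name", {
  ds <- small_dataset(nGood = 1, nBad = 1, K = 4)
  labs <- ds$labels[ds$labels$subject_id != "sub01", , drop = FALSE]
  expect_error(buildFeatureTable(ds$decomps, labs), "sub01")
  expect_error(buildFeatureTable(ds$decomps, ds$labels, modesKept = 1:8),
               "mode 8")
})

test_that("balancing replicates the minority class to parity, reproducibly", {
  # emulate the real 26 G vs 10 B imbalance at small feature size
  set.seed(10)
  mk <- function(sid, lab) data.frame(
    subject_id = sid, trial = "task", channel = "EEG Fp1", mode = 1,
    area = rnorm(1), m = runif(1), ctm = runif(1), label = lab,
    stringsAsFactors = FALSE)
  tab <- do.call(rbind, c(
    lapply(sprintf("g%02d", 1:26), mk, lab = "G"),
    lapply(sprintf("b%02d", 1:10), mk, lab = "B")))
  bal <- balanceByReplication(tab, seed = 3)
  cnt <- table(unique(bal[, c("subject_id", "label")])$label)
  expect_equal(unname(cnt["G"]), 26)
  expect_equal(unname(cnt["B"]), 26)   # 16 dummies added
  expect_equal(sum(grepl("_dup", bal$subject_id)), 16)
  # originals untouched
  expect_identical(bal[seq_len(nrow(tab)), ], tab)
  # deterministic under seed
  bal2 <- balanceByReplication(tab, seed = 3)
  expect_identical(bal, bal2)
  expect_false(identical(balanceByReplication(tab, seed = 4)$subject_id,
                         bal$subject_id))

  # already balanced input unchanged
  even <- tab[tab$subject_id %in% c(sprintf("g%02d", 1:10),
                                    sprintf("b%02d", 1:10)), ]
  expect_identical(balanceByReplication(even, seed = 1), even)

  single <- tab[tab$label == "G", ]
  expect_error(balanceByReplication(single), "two classes")
})

test_that("Wilcoxon screening reproduces the exact small-sample null", {
  # n = 10 pairs, all differences positive: two-sided exact p = 2/1024,
  # enumerated independently over all 2^10 sign assignments
  enumerate_p <- function(d) {
    n <- length(d)
    ranks <- rank(abs(d))
    v_obs <- sum(ranks[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_null <- signs %*% ranks
    mu <- n * (n + 1) / 4
    mean(abs(v_null - mu) >= abs(v_obs - mu))
  }
  base <- data.frame(
    subject_id = rep(sprintf("s%02d", 1:10), each = 1), trial = "task",
    channel = "EEG Fp1", mode = 1, stringsAsFactors = FALSE)
  g <- transform(base, area = 2 + (1:10) / 10, m = 1, ctm = 0.5, label = "G")
  b <- transform(base, subject_id = sprintf("t%02d", 1:10),
                 area = 1 + (1:10) / 100, m = 1, ctm = 0.5, label = "B")
  tab <- rbind(g, b)
  rep <- suppressWarnings(wilcoxonScreen(tab, alpha = 0.05))
  a <- rep[rep$feature == "area", ]
  expect_equal(a$p_value, 2 / 1024, tolerance = 1e-12)
  expect_equal(a$p_value, enumerate_p(g$area - b$area), tolerance = 1e-12)
  expect_true(a$retained)
  # identical columns are untestable, never retained
  m <- rep[rep$feature == "m", ]
  expect_true(m$untestable)
  expect_false(m$retained)
})

test_that("exact and normal-approximation p-values agree for 15 <= n <= 25", {
  # random screening data with a genuine class shift, as produced upstream
  set.seed(5)
  for (n in c(15, 20, 25)) {
    ids <- sprintf("s%02d", seq_len(n))
    g <- data.frame(subject_id = ids, trial = "task", channel = "c",
                    mode = 1, area = rnorm(n), m = rnorm(n),
                    ctm = runif(n), label = "G", stringsAsFactors = FALSE)
    b <- g; b$label <- "B"; b$area <- g$area + rnorm(n, 1)
    b$m <- g$m + rnorm(n, 1)
    b$ctm <- pmin(1, g$ctm + runif(n, 0.3, 0.6))
    tab <- rbind(g, b)
    pe <- wilcoxonScreen(tab, exact = TRUE)$p_value
    pa <- wilcoxonScreen(tab, exact = FALSE)$p_value
    expect_true(all(abs(pe - pa) < 0.01),
                label = sprintf("exact vs approx at n = %d", n))
  }
  # exhaustive over the whole achievable support of the statistic
  for (n in 15:25) {
    Vmax <- n * (n + 1) / 2
    mu <- Vmax / 2; s2 <- n * (n + 1) * (2 * n + 1) / 24
    V <- 0:Vmax
    pe <- pmin(1, psignrank(pmin(V, Vmax - V), n) +
                 1 - psignrank(pmax(V, Vmax - V) - 1, n))
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(s2)
    pa <- pmin(1, 2 * pnorm(-abs(z)))
    expect_lt(max(abs(pe - pa)), 0.012)
    # anywhere a screening decision could be affected (small exact p) the
    # two routes agree within 0.01; the narrow mid-distribution band at
    # n = 15-16 where they differ by up to 0.0111 has exact p > 0.3
    expect_true(all(abs(pe - pa)[pe < 0.3] < 0.01))
    if (n >= 17) expect_lt(max(abs(pe - pa)), 0.01)
  }
})

test_that("screening is symmetric under label swap and validates balance", {
  ds <- small_dataset(nGood = 2, nBad = 2, K = 8)
  ft <- buildFeatureTable(ds$decomps, ds$labels)
  r1 <- wilcoxonScreen(ft)
  sw <- ft; sw$label <- ifelse(ft$label == "G", "B", "G")
  r2 <- wilcoxonScreen(sw)
  expect_equal(r1$p_value, r2$p_value)

  unb <- ft[!(ft$subject_id == ft$subject_id[1] & ft$trial == "task"), ]
  expect_error(wilcoxonScreen(unb), "balance")
})
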