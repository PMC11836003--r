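mk_labels <- function() {
  l <- array(0L, c(6, 6, 2))
  l[1:2, , 1] <- phantom_labels[["nawm"]]
  l[3, 1:3, 1] <- phantom_labels[["et"]]
  l[3, 4:5, 1] <- phantom_labels[["necrosis"]]
  l[4, 1:2, 1] <- phantom_labels[["edema"]]
  l
}

test_that("region statistics are exact on constructed regions", {
  l <- mk_labels()
  m <- array(NA_real_, dim(l))
  m[l == 1] <- 2                                  # constant NAWM
  m[l == 2] <- c(1, 2, 3)
  m[l == 3] <- c(4, 6)
  m[l == 4] <- c(0, 10)
  st <- extract_region_stats(m, l, "X")
  et <- st[st$region == "ET", ]
  expect_equal(et$mean, 2); expect_equal(et$max, 3); expect_equal(et$n_voxels, 3)
  nawm <- st[st$region == "NAWM", ]
  expect_equal(nawm$mean, 2); expect_equal(nawm$sd, 0)
  expect_equal(nawm$max, nawm$mean)

  # WT equals the pooled union computed independently
  pooled <- m[l %in% 2:4]
  wt <- st[st$region == "WT", ]
  expect_equal(wt$mean, mean(pooled))
  expect_equal(wt$max, max(pooled))
  expect_equal(wt$n_voxels, length(pooled))
  expect_true(wt$max >= wt$mean)

  # absent regions yield no row; missing voxels are excluded
  l2 <- l; l2[l2 == 4] <- 0L
  st2 <- extract_region_stats(m, l2, "X")
  expect_false("edema" %in% st2$region)
  m[l == 2][1] <- NA
  expect_equal(st$n_voxels[st$region == "ET"], 3)
  st3 <- extract_region_stats(m, l, "X")
  expect_equal(st3$n_voxels[st3$region == "ET"], 2)
})

test_that("NAWM normalization divides by the NAWM mean with the K2 exception", {
  l <- mk_labels()
  m <- array(NA_real_, dim(l)); m[l == 1] <- 2; m[l == 2] <- 8
  k <- array(NA_real_, dim(l)); k[l == 1] <- 0.001; k[l == 2] <- 0.05
  st <- dplyr::bind_rows(extract_region_stats(m, l, "APTw"),
                         extract_region_stats(k, l, "K2"))
  ns <- normalize_to_nawm(st)
  expect_equal(ns$mean[ns$region == "NAWM" & ns$parameter == "APTw"], 1)
  expect_equal(ns$mean[ns$region == "ET" & ns$parameter == "APTw"], 4)
  # K2 passes through untouched
  expect_equal(ns$mean[ns$region == "ET" & ns$parameter == "K2"], 0.05)
  expect_false(any(ns$is_normalized[ns$parameter == "K2"]))
  # re-normalization is refused
  expect_error(normalize_to_nawm(ns), "already")
  # non-positive NAWM mean is an error
  m0 <- m; m0[l == 1] <- 0
  expect_error(normalize_to_nawm(extract_region_stats(m0, l, "APTw")),
               "non-positive")
})

test_that("rank-sum test matches brute-force pair counting", {
  # degenerate cases
  tied <- mann_whitney(rep(1, 5), rep(1, 7))
  expect_equal(tied$u, 5 * 7 / 2)
  expect_equal(tied$p, 1)
  sep <- mann_whitney(11:20, 1:8)
  expect_equal(sep$u, 0)
  expect_lt(sep$p, 0.001)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")

  set.seed(2024)
  for (i in 1:1000) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    a <- rnorm(n1); b <- rnorm(n2, mean = runif(1, -1, 1))
    expect_identical(mann_whitney(a, b)$u, pair_count_u(a, b))
  }
})

test_that("nonparametric AUC matches the rank-sum identity, unflipped", {
  sep <- roc_auc(c(rnorm(10, 5), rnorm(8, 0)), rep(c(TRUE, FALSE), c(10, 8)))
  expect_equal(sep$auc, 1)

  # orientation is fixed: anti-predictive values give AUC < 0.5
  anti <- roc_auc(c(rnorm(10, 0), rnorm(8, 5)), rep(c(TRUE, FALSE), c(10, 8)))
  expect_lt(anti$auc, 0.5)

  set.seed(77)
  for (i in 1:200) {
    n1 <- sample(4:12, 1); n2 <- sample(4:12, 1)
    pos <- rnorm(n1); neg <- rnorm(n2)
    r <- roc_auc(c(pos, neg), rep(c(TRUE, FALSE), c(n1, n2)))
    expect_equal(r$auc, pair_count_auc(pos, neg))
    u <- pair_count_u(pos, neg)
    expect_true(isTRUE(all.equal(r$auc, 1 - u / (n1 * n2))) ||
                  isTRUE(all.equal(r$auc, u / (n1 * n2))))
  }

  # invariance under strictly monotone transforms
  pos <- rnorm(10); neg <- rnorm(8)
  v <- c(pos, neg); lab <- rep(c(TRUE, FALSE), c(10, 8))
  expect_equal(roc_auc(exp(v), lab)$auc, roc_auc(v, lab)$auc)

  # null case: identical distributions at large n
  set.seed(3)
  r0 <- roc_auc(rnorm(4000), rep(c(TRUE, FALSE), 2000))
  expect_equal(r0$auc, 0.5, tolerance = 0.03)

  # Hanley-McNeil SE and unclipped CI
  r <- roc_auc(c(pos + 2, neg), lab)
  expect_equal(r$ci[2], r$auc + 1.96 * r$se)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("logistic combination scores fitted probabilities in-sample", {
  set.seed(8)
  lab <- rep(c(TRUE, FALSE), c(10, 8))
  x <- rnorm(18) + 2 * lab
  single <- logistic_combine(data.frame(x = x), lab)
  # monotone transform invariance: one-predictor AUC equals the raw AUC
  expect_equal(single$roc$auc, roc_auc(x, lab)$auc)

  # complete separation is flagged, not divergent
  xs <- c(rnorm(10, 10), rnorm(8, -10))
  fit <- logistic_combine(data.frame(a = xs, b = rnorm(18)), lab)
  expect_true(fit$separated)
  expect_equal(fit$roc$auc, 1)

  # constant columns dropped with a warning
  expect_warning(
    logistic_combine(data.frame(a = x, b = rep(1, 18)), lab), "constant")

  # joint fit at least matches the best single predictor (in-sample)
  lab2 <- rep(c(TRUE, FALSE), each = 50)
  worse <- 0
  for (i in 1:100) {
    z1 <- rnorm(100) + 1.2 * lab2
    z2 <- 0.6 * z1 + rnorm(100, sd = 0.8) + 0.8 * lab2
    both <- logistic_combine(data.frame(z1 = z1, z2 = z2), lab2)$roc$auc
    best <- max(roc_auc(z1, lab2)$auc, roc_auc(z2, lab2)$auc)
    if (both < best - 0.02) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("cohort report handles null cohorts and keeps the table grid", {
  subjects <- tidyr::expand_grid(
    subject = sprintf("S%02d", 1:8),
    region = c("ET", "NAWM"),
    parameter = c("APTw", "cCBV", "K2")
  )
  subjects$group <- ifelse(subjects$subject <= "S04", "gbm", "met")
  subjects$mean <- 1.5   # identical subjects
  subjects$max <- 3.0
  rep0 <- cohort_report(subjects)
  expect_true(all(rep0$comparison$p == 1))
  expect_true(all(rep0$comparison$u == 16 / 2))
  expect_true(all(rep0$roc$auc == 0.5))

  # schema: one row per parameter x region x statistic
  expect_equal(nrow(rep0$comparison), 3 * 2 * 2)
  expect_setequal(unique(rep0$comparison$statistic), c("mean", "max"))

  # non-degenerate cohort: combinations whose predictors all exist are kept
  set.seed(12)
  subjects$mean <- runif(nrow(subjects), 1, 3)
  subjects$max <- subjects$mean + runif(nrow(subjects))
  rep1 <- cohort_report(subjects)
  expect_setequal(unique(rep1$combined$parameters),
                  c("APTw + cCBV", "APTw + K2", "APTw + cCBV + K2"))
  expect_equal(nrow(rep1$combined), 2 * 3)
})

test_that("AUC and its standard error agree with an independent ROC library", {
  set.seed(41)
  for (i in 1:20) {
    n1 <- sample(6:15, 1); n2 <- sample(6:15, 1)
    v <- c(rnorm(n1, 1), rnorm(n2))
    lab <- rep(c(TRUE, FALSE), c(n1, n2))
    ours <- roc_auc(v, lab)
    ref <- pROC::roc(lab, v, levels = c(FALSE, TRUE), direction = "<",
                     quiet = TRUE)
    expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  }
})
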