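test_that("exact signed-rank p matches hand enumeration and wilcox.test", {
  # n = 5 all-positive differences: two-tailed p = 2 / 2^5
  r <- wilcoxonSignedRank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(r$p_value, 0.0625)
  expect_true(r$exact)
  expect_equal(r$statistic, 15)
  expect_error(wilcoxonSignedRank(1:4, 1:4), "zero")

  # tie-free cases agree with the base-R exact test
  withr::with_seed(17, {
    for (i in 1:20) {
      n <- sample(4:12, 1)
      x <- rnorm(n); y <- rnorm(n)
      ours <- wilcoxonSignedRank(x, y)$p_value
      ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
})

test_that("exact p equals the 2^n sign-flip enumeration oracle under ties", {
  withr::with_seed(23, {
    for (i in 1:15) {
      n <- sample(3:10, 1)
      # discrete values force tied and zero differences
      x <- sample(0:4, n, replace = TRUE)
      y <- sample(0:4, n, replace = TRUE)
      if (all(x == y)) x[1] <- x[1] + 1L
      expect_equal(wilcoxonSignedRank(x, y)$p_value, oracleWilcoxon(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("signed-rank p is permutation-invariant and symmetric in (x, y)", {
  withr::with_seed(29, {
    x <- rnorm(10); y <- rnorm(10)
    p <- wilcoxonSignedRank(x, y)$p_value
    o <- sample(10)
    expect_equal(wilcoxonSignedRank(x[o], y[o])$p_value, p)
    expect_equal(wilcoxonSignedRank(y, x)$p_value, p)
    # large-n branch: consistent direction with exact on a shifted sample
    xs <- rnorm(30) + 0.8; ys <- rnorm(30)
    pa <- wilcoxonSignedRank(xs, ys)$p_value
    expect_false(wilcoxonSignedRank(xs, ys)$exact)
    expect_lt(pa, 0.05)
    expect_equal(wilcoxonSignedRank(ys, xs)$p_value, pa)
  })
})

test_that("median/IQR uses the inclusive interpolation convention", {
  expect_equal(medianIQR(1:5), c(median = 3, q1 = 2, q3 = 4))
  expect_equal(medianIQR(7), c(median = 7, q1 = 7, q3 = 7))
  expect_error(medianIQR(numeric(0)), "at least one")
  withr::with_seed(31, {
    for (i in 1:20) {
      v <- rnorm(sample(1:30, 1))
      got <- medianIQR(v)
      expect_equal(unname(got), unname(
        stats::quantile(v, c(0.5, 0.25, 0.75), type = 7)))
    }
  })
})

test_that("the report flags significance exactly where a shift is planted", {
  # three width datasets as ArtifactQuant-like fixtures: baseline, an
  # identical copy, and one with a planted +2 mm shift
  mkQuant <- function(w) {
    pf <- data.frame(frame = seq_along(w), reference = seq_along(w),
                     blood_gap = 0, threshold = 1, width_mm = w,
                     cnr_blood = 10, cnr_agar = 2, excluded = FALSE,
                     reason = "")
    s <- list(n_analysed = length(w), n_excluded = 0L)
    for (v in c("width_mm", "cnr_blood", "cnr_agar")) {
      q <- medianIQR(pf[[v]])
      nm <- sub("_mm$", "", v)
      s[[paste0(nm, "_median")]] <- q[["median"]]
      s[[paste0(nm, "_q1")]] <- q[["q1"]]
      s[[paste0(nm, "_q3")]] <- q[["q3"]]
    }
    new("ArtifactQuant", perFrame = pf, summary = s, masks = list())
  }
  withr::with_seed(5, {
    base <- 8 + rnorm(20, sd = 0.3)
  })
  rep <- buildReport(quant = list(baseline = mkQuant(base),
                                  same = mkQuant(base),
                                  shifted = mkQuant(base + 2)),
                     detect = list(), outDir = tempfile())
  expect_equal(nrow(rep$detectionTable), 0L)      # header-only table
  cmp <- rep$comparisons
  expect_false(cmp$significant[cmp$comparison == "same vs baseline"])
  expect_true(cmp$significant[cmp$comparison == "shifted vs baseline"])
  expect_equal(nrow(rep$widths), 60L)
})

test_that("identical paired width datasets yield no spurious significance", {
  # all differences zero: the test is undefined and reported as NA,
  # flagged non-significant
  w <- rep(5, 8)
  pf <- data.frame(frame = 1:8, reference = 1:8, blood_gap = 0,
                   threshold = 1, width_mm = w, cnr_blood = 1, cnr_agar = 1,
                   excluded = FALSE, reason = "")
  s <- list(n_analysed = 8L, n_excluded = 0L, width_median = 5, width_q1 = 5,
            width_q3 = 5, cnr_blood_median = 1, cnr_blood_q1 = 1,
            cnr_blood_q3 = 1, cnr_agar_median = 1, cnr_agar_q1 = 1,
            cnr_agar_q3 = 1)
  q <- new("ArtifactQuant", perFrame = pf, summary = s, masks = list())
  rep <- buildReport(quant = list(a = q, b = q))
  expect_true(is.na(rep$comparisons$p_value))
  expect_false(rep$comparisons$significant)
})
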