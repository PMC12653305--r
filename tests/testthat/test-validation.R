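test_that("defoliation categories follow the survey bins with lower boundaries", {
  pct <- c(0, 5, 10, 11, 25, 26, 60, 61, 62, 99, 100)
  expect_equal(as.character(categorize_defoliation(pct)),
               c("None", "None", "None", "Weak", "Weak", "Medium", "Medium",
                 "Severe", "Severe", "Severe", "Dead"))
  expect_error(categorize_defoliation(101), "0, 100")
  expect_error(categorize_defoliation(-1), "0, 100")
})

test_that("the default binarization maps the 5x5 label product correctly", {
  rule <- binarization_rule()
  combos <- expand.grid(class = 0:4, cat = defoliation_category_labels(),
                        stringsAsFactors = FALSE)
  b <- binarize(combos$class, combos$cat, rule)
  expect_equal(b$sat_positive, combos$class %in% c(0, 1))
  expect_equal(b$field_positive, combos$cat %in% c("Medium", "Severe", "Dead"))
  # spec'd spot checks: severe/Severe is TP, regeneration/None is TN,
  # moderate/Medium is FN
  expect_equal(unlist(binarize(0L, "Severe", rule)), c(sat_positive = TRUE,
                                                       field_positive = TRUE))
  expect_equal(unlist(binarize(3L, "None", rule)), c(sat_positive = FALSE,
                                                     field_positive = FALSE))
  expect_equal(unlist(binarize(2L, "Medium", rule)), c(sat_positive = FALSE,
                                                       field_positive = TRUE))
  custom <- binarization_rule(sat_positive_classes = 0L,
                              field_positive_categories = "Dead")
  expect_true(binarize(0L, "Severe", custom)$sat_positive)
  expect_false(binarize(0L, "Severe", custom)$field_positive)
})

test_that("confusion tallies match a brute-force loop", {
  perfect <- confusion(rep(c(TRUE, FALSE), 5), rep(c(TRUE, FALSE), 5))
  expect_equal(c(perfect$fp, perfect$fn), c(0, 0))

  four <- confusion(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unlist(four[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 1, fn = 1, tn = 1))

  set.seed(301)
  pred <- runif(1000) < 0.4; ref <- runif(1000) < 0.3
  mine <- confusion(pred, ref)
  o <- oracle_confusion(pred, ref)
  expect_equal(unlist(mine[c("tp", "fp", "fn", "tn")]), o)

  byref <- confusion(pred, ref, normalize = "reference")
  expect_equal(byref$tp, o["tp"] / (o["tp"] + o["fn"]), ignore_attr = TRUE)
  expect_equal(byref$tn, o["tn"] / (o["tn"] + o["fp"]), ignore_attr = TRUE)
  bytot <- confusion(pred, ref, normalize = "total")
  expect_equal(bytot$tp + bytot$fp + bytot$fn + bytot$tn, 1)
})

test_that("derived metrics reproduce the printed worked example", {
  # normalized confusion components with FP = FN; only the internally
  # consistent cells are asserted (see the acceptance suite for all rows)
  m <- agreement_metrics(c(tp = 0.51, fp = 0.49, fn = 0.49, tn = 0.68))
  expect_equal(m$f1, 0.51, tolerance = 0.005)
  expect_equal(m$specificity, 0.58, tolerance = 0.005)
  expect_equal(m$precision, 0.51, tolerance = 0.005)
  expect_equal(m$sensitivity, 0.51, tolerance = 0.005)

  p <- agreement_metrics(c(tp = 1, fp = 0, fn = 0, tn = 1))
  expect_equal(unlist(p[c("precision", "sensitivity", "specificity",
                          "total_accuracy", "f1")]),
               c(precision = 1, sensitivity = 1, specificity = 1,
                 total_accuracy = 1, f1 = 1))
})

test_that("zero denominators give explicit NA markers, never silent zeros", {
  m <- agreement_metrics(c(tp = 0, fp = 0, fn = 3, tn = 7))
  expect_true(is.na(m$precision))       # no positive predictions
  expect_equal(m$sensitivity, 0)
  m2 <- agreement_metrics(c(tp = 0, fp = 0, fn = 0, tn = 5))
  expect_true(is.na(m2$sensitivity))    # no actual positives
  expect_true(is.na(m2$f1))
})

test_that("F1 is the harmonic mean of precision and sensitivity", {
  set.seed(302)
  for (rep in 1:30) {
    cells <- rmultinom(1, 200, runif(4, 0.05, 1))[, 1]
    m <- agreement_metrics(c(tp = cells[1], fp = cells[2], fn = cells[3],
                             tn = cells[4]))
    if (!is.na(m$precision) && !is.na(m$sensitivity) &&
        m$precision + m$sensitivity > 0) {
      hm <- 2 * m$precision * m$sensitivity / (m$precision + m$sensitivity)
      expect_equal(m$f1, hm, tolerance = 1e-12)
    }
  }
})

test_that("metrics are invariant to duplicating every pair", {
  set.seed(303)
  pred <- runif(200) < 0.5; ref <- runif(200) < 0.5
  m1 <- agreement_metrics(confusion(pred, ref))
  m2 <- agreement_metrics(confusion(rep(pred, 2), rep(ref, 2)))
  for (f in c("precision", "sensitivity", "specificity", "total_accuracy", "f1"))
    expect_equal(m1[[f]], m2[[f]], tolerance = 1e-12)
  expect_equal(cohens_kappa(pred, ref), cohens_kappa(rep(pred, 2), rep(ref, 2)),
               tolerance = 1e-12)
})

test_that("kappa hits its landmarks exactly", {
  x <- sample(c("a", "b", "c"), 60, replace = TRUE)
  expect_equal(cohens_kappa(x, x), 1)

  # one rater constant, the other balanced: p_o = p_e -> kappa = 0
  y <- rep(c(TRUE, FALSE), 30)
  expect_equal(cohens_kappa(rep(TRUE, 60), y), 0)

  # both raters constant: p_e = 1, undefined
  expect_true(is.na(cohens_kappa(rep(1, 10), rep(1, 10))))

  # 2x2 cell counts (45, 15, 25, 15) against the marginal arithmetic
  tab <- matrix(c(45, 25, 15, 15), 2, 2)  # rows rater1, cols rater2
  po <- (45 + 15) / 100
  pe <- (60 / 100) * (70 / 100) + (40 / 100) * (30 / 100)
  expect_equal(cohens_kappa(tab), (po - pe) / (1 - pe))
  expect_equal(cohens_kappa(tab), 0.13043478, tolerance = 1e-7)
})

test_that("kappa matches the oracle on random multi-category labelings", {
  set.seed(304)
  for (rep in 1:25) {
    k <- sample(2:5, 1)
    n <- sample(20:200, 1)
    x <- sample(letters[1:k], n, replace = TRUE)
    y <- ifelse(runif(n) < 0.6, x, sample(letters[1:k], n, replace = TRUE))
    expect_equal(cohens_kappa(x, y), oracle_kappa(x, y), tolerance = 1e-10)
  }
})

test_that("kappa equals one exactly iff observed agreement is perfect", {
  set.seed(305)
  for (rep in 1:20) {
    x <- sample(0:2, 50, replace = TRUE)
    y <- x; y[sample(50, sample(0:3, 1))] <- sample(0:2, 1)
    k <- cohens_kappa(x, y)
    if (!is.na(k)) expect_equal(k == 1, all(x == y))
  }
})

test_that("regression agreement reports in response units with sign freedom", {
  z <- c(-2, -1, 0, 1, 2)
  defol <- 50 - 10 * z
  r <- regression_agreement(z, defol)
  expect_equal(r$r_squared, 1)
  expect_equal(r$rmse, 0, tolerance = 1e-10)
  r_flip <- regression_agreement(z, defol, sign = 1)
  expect_equal(r_flip$r_squared, 1)

  set.seed(306)
  z2 <- rnorm(40); d2 <- pmin(pmax(30 - 8 * z2 + rnorm(40), 0), 100)
  a <- regression_agreement(z2, d2)
  b <- regression_agreement(z2, d2 * 1)  # identical
  expect_equal(a$rmse, b$rmse)
  expect_error(regression_agreement(c(1, 2), c(1, 2)), "at least 3")
})

test_that("pooled reports aggregate strata with missing bookkeeping", {
  d <- data.frame(plot_id = rep(c("p1", "p2", "p3"), each = 2),
                  level = "I",
                  year = rep(c(2021, 2022), 3),
                  z = c(0.5, -2.5, 0.4, -2.2, 0.3, NA),
                  class = c(3L, 0L, 3L, 0L, 3L, NA),
                  defoliation_pct = c(5, 70, 8, 65, 4, 80))
  rep_y <- pooled_report(d, "year")
  expect_equal(rep_y$stratum, c("2021", "2022", "pooled"))
  expect_equal(rep_y$n_missing, c(0, 1, 1))
  expect_equal(rep_y$n_used, c(3, 2, 5))
  expect_equal(rep_y$tp[rep_y$stratum == "2022"], 2)
  expect_equal(rep_y$tn[rep_y$stratum == "2021"], 3)

  # a single stratum equals its own pooled row
  one <- d[d$year == 2021, ]
  rep1 <- pooled_report(one, "year")
  metrics <- c("tp", "fp", "fn", "tn", "kappa", "f1", "total_accuracy")
  expect_equal(rep1[rep1$stratum == "2021", metrics],
               rep1[rep1$stratum == "pooled", metrics], ignore_attr = TRUE)

  # duplicated strata with identical pairs: pooled rates equal stratum rates
  dd <- rbind(d, transform(d, plot_id = paste0(plot_id, "b")))
  rep_p <- pooled_report(dd[!is.na(dd$class), ], "plot", normalize = "total")
  pooled <- rep_p[rep_p$stratum == "pooled", ]
  expect_equal(pooled$total_accuracy, 1)

  # the rule is serialized into the report
  expect_s3_class(attr(rep_y, "rule"), "binarization_rule")
})
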