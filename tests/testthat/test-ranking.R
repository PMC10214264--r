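mkRes <- function(id, value, category = "") {
  r <- new("CriterionResult", criterion = id, value = value, category = "")
  if (nzchar(category)) r@category <- category
  r
}

test_that("categorization respects the per-criterion cutoffs", {
  expect_identical(categorize(0.996, "Ca", "CSI"), "superior")
  expect_identical(categorize(0.604, "Ca", "CSI"), "poor")
  expect_identical(categorize(0.719, "Ca", "CSI"), "good")
  expect_identical(categorize(1.0, "Ca", "CSI"), "superior")
  expect_identical(categorize(1.0, "Cb", "PTI"), "superior")
  # boundary: categorization happens after 3-decimal rounding
  expect_identical(categorize(0.8499, "Ca", "CSI"), "superior") # rounds to .85
  expect_identical(categorize(0.8494, "Ca", "CSI"), "good")
  expect_error(categorize(1.2, "Ca", "CSI"), "range")
  # the published metric/category pairs are reproduced by the defaults
  published <- list(
    CSI = list(Ca = list(superior = c(0.996, 0.936, 0.905),
                         good = c(0.813, 0.794, 0.753, 0.733, 0.719, 0.714,
                                  0.712, 0.739),
                         poor = c(0.604, 0.658, 0.619, 0.654, 0.644, 0.672,
                                  0.697, 0.7)),
               Cb = list(superior = 0.768,
                         good = c(0.722, 0.687, 0.659, 0.646, 0.677, 0.629),
                         poor = c(0.539, 0.618, 0.552, 0.574, 0.541, 0.569,
                                  0.563, 0.55, 0.576, 0.559, 0.571, 0.562)),
               Cc = list(superior = c(0.714, 0.429, 0.391, 0.311, 0.719,
                                      0.4, 0.384, 0.357),
                         good = c(0.214, 0.297, 0.217, 0.296, 0.242, 0.231,
                                  0.243, 0.295),
                         poor = 0.141)),
    PTI = list(Ca = list(good = c(0.627, 0.662, 0.688, 0.617, 0.625, 0.639,
                                  0.604),
                         poor = c(0.564, 0.501, 0.54, 0.534, 0.545, 0.567,
                                  0.529, 0.511, 0.509, 0.532, 0.512)),
               Cb = list(superior = c(0.998, 0.996, 0.999, 0.993, 0.997,
                                      0.986, 0.98, 1),
                         good = c(0.943, 0.929, 0.97, 0.974),
                         poor = c(0.762, 0.649, 0.766, 0.754, 0.04, 0.664)),
               Cc = list(superior = c(0.974, 0.906, 0.87, 0.978, 0.875,
                                      0.93),
                         good = c(0.754, 0.523, 0.849, 0.77, 0.606, 0.785,
                                  0.63, 0.691, 0.605, 0.779),
                         poor = c(0.417, 0.463, 0.44))))
  for (sk in names(published)) for (cr in names(published[[sk]]))
    for (cat in names(published[[sk]][[cr]]))
      for (v in published[[sk]][[cr]][[cat]])
        expect_identical(categorize(v, cr, sk), cat,
                         label = paste(sk, cr, v))
  # one published mis-labelling would break: none does
  expect_identical(categorize(0.7, "Ca", "CSI"), "poor")
})

test_that("quantile cutoffs track the evaluated cohort", {
  vals <- list(Ca = seq(0.1, 1, 0.1))
  co <- quantileCutoffs(vals, "CSI")
  expect_equal(co$CSI$Ca[1], quantile(vals$Ca, 0.9), ignore_attr = TRUE)
  expect_identical(categorize(0.95, "Ca", "CSI", co), "superior")
  expect_identical(categorize(0.5, "Ca", "CSI", co), "poor")
})

test_that("overall scores use the printed weights with 3-dp sums", {
  r <- list(mkRes("Ca", 0.9, "superior"), mkRes("Cb", 0.7, "good"),
            mkRes("Cc", 0.1, "poor"))
  sc <- overallScore(r)
  expect_equal(sc$category_score, 1.9)
  r4 <- list(mkRes("Ca", 1, "superior"), mkRes("Cb", 1, "superior"),
             mkRes("Cc", 1, "superior"), mkRes("Cd", 1, "superior"))
  expect_equal(overallScore(r4)$category_score, 4.0)
  # printed metric triple from the published benchmark table
  tr <- list(mkRes("Ca", 0.627, "good"), mkRes("Cb", 0.998, "superior"),
             mkRes("Cc", 0.974, "superior"))
  expect_equal(overallScore(tr)$metric_sum, 2.599)
  expect_error(overallScore(list()), "no criterion")
})

test_that("ranking orders by category score, metric sum, then string", {
  rep1 <- list(workflow = "AAA+AAA+AAA+AAA",
               results = list(mkRes("Ca", 0.8, "good"),
                              mkRes("Cb", 0.7, "good"),
                              mkRes("Cc", 0.6, "good")))
  rep2 <- list(workflow = "BBB+BBB+BBB+BBB",
               results = list(mkRes("Ca", 0.7, "good"),
                              mkRes("Cb", 0.6, "good"),
                              mkRes("Cc", 0.5, "good")))
  t1 <- rankWorkflows(list(rep1, rep2))
  expect_identical(t1$workflow[1], "AAA+AAA+AAA+AAA")   # higher metric sum

  rep3 <- list(workflow = "CCC+CCC+CCC+CCC",
               results = list(mkRes("Ca", 1, "superior"),
                              mkRes("Cb", 0.1, "poor"),
                              mkRes("Cc", 0.1, "poor")))
  t2 <- rankWorkflows(list(rep3, rep2))
  expect_identical(t2$workflow[1], "BBB+BBB+BBB+BBB")   # 2.4 beats 1.2

  repDup <- rep1; repDup$workflow <- "AAB+AAA+AAA+AAA"
  t3 <- rankWorkflows(list(repDup, rep1))
  expect_identical(t3$workflow, c("AAA+AAA+AAA+AAA", "AAB+AAA+AAA+AAA"))

  # permutation invariance of input order
  t4 <- rankWorkflows(list(rep2, rep1))
  expect_identical(t4, t1)
  expect_identical(t1$rank, 1:2)

  repHet <- list(workflow = "DDD+DDD+DDD+DDD",
                 results = list(mkRes("Ca", 0.5, "poor")))
  expect_error(rankWorkflows(list(rep1, repHet)), "heterogeneous")
})

test_that("export writes ranking and category tables", {
  reps <- lapply(1:3, function(i)
    list(workflow = paste0(c("AAA", "BBB", "CCC")[i], "+NON+NON+NON"),
         results = list(mkRes("Ca", 0.9 - 0.1 * i, "good"),
                        mkRes("Cb", 0.8, "good"),
                        mkRes("Cc", 0.25, "good"))))
  tab <- rankWorkflows(reps)
  d <- withr::local_tempdir()
  paths <- exportResults(tab, d)
  rk <- read.csv(file.path(d, "ranking.csv"))
  expect_identical(nrow(rk), 3L)
  expect_identical(rk$rank, 1:3)
  ct <- read.csv(file.path(d, "categories.csv"))
  expect_identical(dim(ct), c(3L, 4L))
  expect_true(all(unlist(ct[, -1]) %in% c("superior", "good", "poor")))
  expect_error(exportResults(tab[0, ], d), "empty")
})
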