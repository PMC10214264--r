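test_that("linear compensation inverts a known spillover exactly", {
  S <- matrix(c(1, 0.1, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  x <- matrix(c(100, 60), 1, 2, dimnames = list(NULL, c("A", "B")))
  cs <- matrixCytoSet(x, origin = 1L)
  out <- compensateCells(cs, "FLC", spill = S)
  expect_equal(unname(exprs(out)[1, ]), c(100, 50), tolerance = 1e-12)

  # identity spillover leaves any method unchanged
  I2 <- diag(2); dimnames(I2) <- dimnames(S)
  y <- withSeed(1, matrix(rnorm(40, 5), 20, 2,
                          dimnames = list(NULL, c("A", "B"))))
  csy <- matrixCytoSet(y)
  for (m in c("FLC", "CTS", "CMP")) {
    expect_equal(exprs(compensateCells(csy, m, spill = I2)), exprs(csy),
                 tolerance = 1e-10, info = m)
  }
})

test_that("non-negative unmixing is constrained and matches the interior", {
  S <- matrix(c(1, 0.1, 0.05, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  x <- rbind(c(-5, 10), c(100, 60))
  colnames(x) <- c("A", "B")
  cs <- matrixCytoSet(x)
  out <- exprs(compensateCells(cs, "CTS", spill = S))
  expect_true(all(out >= 0))
  # where plain inversion is already non-negative the answers agree
  expect_equal(unname(out[2, ]), unname((x %*% solve(S))[2, ]),
               tolerance = 1e-8)
})

test_that("compensation requires a spillover source and sane matrices", {
  cs <- makeCytoSet(seed = 3, n = 100)
  expect_error(compensateCells(cs, "FLC"), "spillover")
  Sbad <- matrix(c(1, 0.99, 0.99, 1), 2, 2,
                 dimnames = list(c("A", "B"), c("A", "B")))
  Ssing <- matrix(c(1, 1 - 1e-14, 1 - 1e-14, 1), 2, 2,
                  dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(compensateCells(cs, "FLC", spill = Ssing), "singular|ill")
  expect_silent({
    out <- compensateCells(cs, "FLC", spill = Sbad)
  })
})

test_that("AutoSpill-style refinement recovers a perturbed spillover", {
  truthS <- matrix(c(1, 0.15, 0.05, 1), 2, 2, byrow = TRUE,
                   dimnames = list(c("A", "B"), c("A", "B")))
  controls <- withSeed(9, {
    lapply(c(A = 1, B = 2), function(i) {
      true <- matrix(0, 400, 2, dimnames = list(NULL, c("A", "B")))
      true[, i] <- exp(rnorm(400, 4, 0.6))
      obs <- true %*% truthS + matrix(rnorm(800, sd = 0.5), 400)
      colnames(obs) <- c("A", "B")
      CytoFrame(obs, paste0("ctrl", i), "FC")
    })
  })
  start <- diag(2); dimnames(start) <- dimnames(truthS)
  refined <- cytoBench:::.refineSpillover(start, controls)
  expect_lt(max(abs(refined - truthS)), 0.02)
  # without controls ATS degrades to plain inversion with a warning
  cs <- makeCytoSet(seed = 4, n = 100)
  I3 <- diag(3); dimnames(I3) <- list(c("A", "B", "C"), c("A", "B", "C"))
  expect_warning(compensateCells(cs, "ATS", spill = I3), "controls")
})

test_that("transformations reproduce their closed forms", {
  x <- c(0, 5, 99, 0.2, 7, 150)
  cs <- matrixCytoSet(cbind(M1 = x))
  acs <- transformCells(cs, "ACS", params = list(cofactor_fc = 5))
  expect_equal(exprs(acs)[1:2, "M1"], c(0, asinh(1)), tolerance = 1e-12)
  expect_equal(asinh(1), log(1 + sqrt(2)), tolerance = 1e-12)

  lg <- transformCells(matrixCytoSet(cbind(M1 = c(0, 99))), "LOG")
  expect_equal(unname(exprs(lg)[2, "M1"]), 2, tolerance = 1e-12)

  tr <- transformCells(cs, "TRU")
  expect_equal(unname(exprs(tr)[4:5, "M1"]), c(1, 7))

  li <- transformCells(cs, "LIN")
  expect_equal(range(exprs(li)[, "M1"]), c(0, 4.5))

  sc <- transformCells(cs, "SCA")
  expect_equal(mean(exprs(sc)[, "M1"]), 0, tolerance = 1e-12)
  expect_equal(sd(exprs(sc)[, "M1"]), 1, tolerance = 1e-12)

  hp <- transformCells(matrixCytoSet(cbind(M1 = c(-100, 0, 100))), "HPL",
                       params = list(T_fc = 100))
  expect_equal(unname(exprs(hp)[, "M1"]),
               c(-log10(2), 0, log10(2)), tolerance = 1e-12)
})

test_that("biexponential and logicle transforms invert their scales", {
  p <- cytoBench:::.logicleParams(T = 262144, W = 0.5, M = 4.5, A = 0)
  xs <- c(-1000, 0, 10, 1000, 262144)
  ys <- cytoBench:::.logicleInverse(xs, p)
  expect_lt(max(abs(cytoBench:::.logicleScale(ys, p) - xs)), 1e-6)
  expect_true(all(diff(ys) > 0))
  # biexponential bisection satisfies |f(y) - x| below tolerance
  yb <- cytoBench:::.biexpInverse(c(-10, 0, 10), 0.5, 1, 0.5, 1, 0)
  expect_lt(max(abs(0.5 * exp(yb) - 0.5 * exp(-yb) - c(-10, 0, 10))), 1e-8)
})

test_that("every registered transformation is monotone non-decreasing", {
  reg <- defaultRegistry()
  trans <- reg$id[reg$step == "transformation"]
  for (s in 1:3) {
    x <- withSeed(s * 11, {
      base <- exp(rnorm(400, 1, 1))
      if (s == 2) base <- base - 2          # include negatives
      cbind(M1 = base, M2 = rnorm(400, 10, 3))
    })
    cs <- matrixCytoSet(x)
    ord <- order(x[, "M1"])
    for (m in trans) {
      y <- exprs(transformCells(cs, m, seed = s))[, "M1"]
      expect_true(all(diff(y[ord]) >= -1e-9),
                  info = paste(m, "seed", s))
      expect_identical(length(y), nrow(x))
    }
  }
})

test_that("Box-Cox rejects constant channels", {
  cs <- matrixCytoSet(cbind(M1 = rep(2, 100), M2 = rnorm(100)))
  expect_error(transformCells(cs, "BOX"), "constant|parameter-estimation")
})

test_that("peak-alignment normalization aligns shifted copies", {
  base <- withSeed(8, rnorm(2000))
  mk <- function(id, shift) {
    m <- cbind(A = base + shift, Time = sort(runif(2000)))
    CytoFrame(m, id, "FC")
  }
  ann <- makeAnnotation()
  cs <- mergeSamples(list(mk("s1", 0), mk("s2", 2), mk("s3", 0),
                          mk("s4", 2)), ann, perFileN = 2000, seed = 1)
  gn <- normalizeCells(cs, "GSN")
  peaks <- vapply(1:4, function(s) {
    d <- density(exprs(gn)[origin(gn) == s, "A"])
    d$x[which.max(d$y)]
  }, numeric(1))
  expect_lt(diff(range(peaks)), 0.1)
  expect_identical(nrow(exprs(gn)), nrow(exprs(cs)))

  wp <- normalizeCells(cs, "WPS")
  meds <- vapply(1:4, function(s)
    median(exprs(wp)[origin(wp) == s, "A"]), numeric(1))
  expect_lt(diff(range(meds)), 0.1)
})

test_that("normalization demands two samples and warps monotonically", {
  one <- makeCytoSet(seed = 5, n = 100)
  one@exprs <- one@exprs[origin(one) == 1, ]
  one@origin <- one@origin[one@origin == 1]
  one@sampleIDs <- "s1"
  expect_error(normalizeCells(one, "GSN"), "two samples")
  expect_identical(exprs(normalizeCells(makeCytoSet(seed = 5, n = 100),
                                        "NON")),
                   exprs(makeCytoSet(seed = 5, n = 100)))
  cs <- makeCytoSet(seed = 6, n = 300)
  for (m in c("GSN", "WPS", "FDN")) {
    out <- normalizeCells(cs, m)
    for (s in 1:4) {
      rows <- origin(cs) == s
      o <- order(exprs(cs)[rows, "A"])
      expect_true(all(diff(exprs(out)[rows, "A"][o]) >= -1e-9),
                  info = m)
    }
  }
})

test_that("signal cleaning flags an aligned rate-spike segment", {
  set.seed(42)
  t <- c(runif(1000, 0, 50), runif(1000, 55, 100))
  normal <- cbind(A = exp(rnorm(2000, 1, 0.5)), B = exp(rnorm(2000, 2, 0.5)),
                  Time = t)
  anom <- cbind(A = exp(rnorm(500, 1, 0.5)) + 8,
                B = exp(rnorm(500, 2, 0.5)),
                Time = runif(500, 50, 55))
  all <- rbind(normal, anom)
  o <- order(all[, "Time"])
  isAnom <- c(rep(FALSE, 2000), rep(TRUE, 500))[o]
  spiked <- CytoFrame(all[o, ], "sp", "FC")
  ann <- makeAnnotation()
  frames <- withSeed(1, list(spiked, makeFrame("s2", 0, 2500),
                             makeFrame("s3", 0, 2500),
                             makeFrame("s4", 0, 2500)))
  frames[[1]]@sampleID <- "s1"
  cs <- mergeSamples(frames, ann, perFileN = 2500, seed = 1)
  res <- cleanSignal(cs, "FAI")
  mk <- res$mask[origin(cs) == 1]
  expect_gte(mean(mk[isAnom]), 0.9)
  expect_lte(mean(mk[!isAnom]), 0.05)
  # retained events are bit-identical, mask aligns to original order
  expect_identical(exprs(res$data), exprs(cs)[!res$mask, ])
})

test_that("stable data passes through every cleaning method", {
  cs <- makeCytoSet(seed = 10, n = 500)
  for (m in c("FAI", "FCL", "FCU")) {
    res <- cleanSignal(cs, m)
    expect_gte(1 - mean(res$mask), 0.95)
  }
  non <- cleanSignal(cs, "NON")
  expect_false(any(non$mask))
  expect_identical(exprs(non$data), exprs(cs))

  noTime <- matrixCytoSet(cbind(M1 = rnorm(100), M2 = rnorm(100)))
  expect_error(cleanSignal(noTime, "FAI"), "Time")
})

test_that("workflow execution is ordered, logged and deterministic", {
  cs <- makeCytoSet(seed = 12, n = 300)
  pd <- runWorkflow(cs, "NON+NON+NON+NON")
  expect_identical(exprs(pd), exprs(cs))
  expect_false(any(removedEvents(pd)))
  lg <- processingLog(pd)
  expect_identical(length(lg), 4L)
  expect_identical(vapply(lg, `[[`, character(1), "step"),
                   c("compensation", "transformation", "normalization",
                     "signal_clean"))

  logOnly <- runWorkflow(cs, "NON+LOG+NON+NON")
  expect_identical(exprs(logOnly), exprs(transformCells(cs, "LOG")))

  S <- diag(3); dimnames(S) <- list(c("A", "B", "C"), c("A", "B", "C"))
  a <- runWorkflow(cs, "FLC+ACS+GSN+FAI", spill = S, seed = 7)
  b <- runWorkflow(cs, "FLC+ACS+GSN+FAI", spill = S, seed = 7)
  expect_identical(exprs(a), exprs(b))
  expect_identical(removedEvents(a), removedEvents(b))

  expect_error(runWorkflow(cs, "CTS+ACS+NON+NON", spill = S), "invalid")
  err <- tryCatch(runWorkflow(cs, "FLC+ACS+NON+NON"),
                  error = conditionMessage)
  expect_match(err, "compensation")
})
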