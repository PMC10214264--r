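# brute-force silhouette oracle, written independently of the package path
bruteSilhouette <- function(x, labels) {
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(x) - x[i, ])^2))
    a <- mean(di[labels == labels[i] & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(di[labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

test_that("clustering recovers separated populations deterministically", {
  x <- withSeed(2, rbind(matrix(rnorm(300 * 3), 300),
                         matrix(rnorm(300 * 3) + 10, 300)))
  cs <- matrixCytoSet(x)
  cl <- clusterCells(cs, 2, seed = 4)
  expect_equal(mclust::adjustedRandIndex(cl$labels,
                                         rep(1:2, each = 300)), 1)
  cl2 <- clusterCells(cs, 2, seed = 4)
  expect_identical(cl$labels, cl2$labels)
  expect_error(clusterCells(matrixCytoSet(x[1:15, ]), 2, seed = 1),
               "too few events")
  expect_error(clusterCells(cs, 1, seed = 1), "at least 2")
})

test_that("tightness matches the 4-point hand-computed silhouette", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
  colnames(pts) <- c("M1", "M2")
  lab <- c(1L, 1L, 2L, 2L)
  sOracle <- bruteSilhouette(pts, lab)
  expect_gt(sOracle, 0.92)                     # well-separated pairs
  cs <- matrixCytoSet(pts, origin = rep(1L, 4))
  cb <- criterionTightness(cs, list(labels = lab, k = 2))
  expect_equal(cb@value, round((sOracle + 1) / 2, 3))
  # anti-clustering (labels swapped across the blobs) scores below 0.5
  labBad <- c(1L, 2L, 1L, 2L)
  expect_lt(bruteSilhouette(pts, labBad), 0)
  cbBad <- criterionTightness(cs, list(labels = labBad, k = 2))
  expect_lt(cbBad@value, 0.5)
  expect_error(criterionTightness(cs, list(labels = rep(1L, 4), k = 1)),
               "one cluster")
})

test_that("packaged silhouette equals the brute-force oracle", {
  for (s in 1:3) {
    x <- withSeed(s * 5, matrix(rnorm(150 * 4), 150))
    colnames(x) <- paste0("M", 1:4)
    lab <- withSeed(s, sample(1:3, 150, replace = TRUE))
    sil <- cluster::silhouette(lab, dist(x))
    expect_equal(mean(sil[, "sil_width"]), bruteSilhouette(x, lab),
                 tolerance = 1e-9)
  }
})

test_that("accuracy detects a planted abundance shift and nulls out", {
  # one condition doubles the abundance of population 2
  mkAbund <- function(seed) {
    withSeed(seed, {
      labs <- c("a", "a", "a", "b", "b", "b")
      frames <- lapply(1:6, function(i) {
        n <- 300
        p2 <- if (labs[i] == "b") 0.5 else 0.25
        pop <- sample(1:2, n, replace = TRUE, prob = c(1 - p2, p2))
        mu <- rbind(c(1, 1, 1, 1), c(2.5, 2.5, 1, 1))[pop, ]
        m <- exp(mu + matrix(rnorm(n * 4, sd = 0.3), n))
        colnames(m) <- paste0("M", 1:4)
        CytoFrame(cbind(m, Time = sort(runif(n, 0, 100))),
                  paste0("s", i), "FC")
      })
      frames
    })
  }
  ann <- makeAnnotation(paste0("s", 1:6), c("a", "a", "a", "b", "b", "b"))
  cs <- mergeSamples(mkAbund(3), ann, perFileN = 300, seed = 3)
  cl <- clusterCells(cs, 6, seed = 3)
  ca <- criterionAccuracy(cs, cl, ann, seed = 3)
  expect_gte(ca@value, 0.9)

  # permutation null: mean balanced accuracy near chance
  vals <- vapply(1:50, function(r) {
    pl <- withSeed(r * 31, sample(c("a", "a", "a", "b", "b", "b")))
    annP <- makeAnnotation(paste0("s", 1:6), pl)
    criterionAccuracy(cs, cl, annP, seed = r)@value
  }, numeric(1))
  expect_lt(abs(mean(vals) - 0.5), 0.15)

  # a condition with a single sample violates the metadata rule; class
  # validity is bypassed via direct slot mutation to reach the runtime check
  annBad <- makeAnnotation()
  annBad@entries <- data.frame(filename = paste0("s", 1:6),
                               label = c("a", "a", "a", "a", "a", "b"))
  expect_error(criterionAccuracy(cs, cl, annBad, seed = 1), "two samples")
})

test_that("bootstrap stability separates structure from noise", {
  blob <- withSeed(5, rbind(matrix(rnorm(400 * 3), 400),
                            matrix(rnorm(400 * 3) + 10, 400)))
  csb <- matrixCytoSet(blob)
  ccb <- criterionRobustnessCSI(csb, 2, seed = 1, reps = 5)
  expect_gte(ccb@value, 0.95)

  noise <- withSeed(6, matrix(rnorm(800 * 10), 800))
  csn <- matrixCytoSet(noise)
  ccn <- criterionRobustnessCSI(csn, 2, seed = 1, reps = 5)
  expect_lt(ccn@value, ccb@value - 0.2)
  expect_error(criterionRobustnessCSI(csb, 2, seed = 1, reps = 1),
               "at least 2")
})

test_that("correspondence recovers planted directions and flags inversions", {
  fix <- loadCSIDataset(seed = 21)
  pd <- runWorkflow(fix$data, "NON+NON+NON+NON")
  cd <- criterionCorrespondenceCSI(pd, fix$ann, fix$known)
  expect_equal(cd@value, 1)

  # flipping every marker's sign inverts all planted directions
  flipped <- pd
  ch <- analysisChannels(pd)
  flipped@exprs[, ch] <- -flipped@exprs[, ch]
  cdFlip <- criterionCorrespondenceCSI(flipped, fix$ann, fix$known)
  expect_equal(cdFlip@value, 0)

  badKnown <- fix$known
  badKnown$entries$marker[1] <- "CD999"
  expect_error(criterionCorrespondenceCSI(pd, fix$ann, badKnown), "CD999")
  # empty known-marker set skips the criterion
  expect_null(criterionCorrespondenceCSI(
    pd, fix$ann, list(conditions = fix$known$conditions,
                      entries = fix$known$entries[0, ])))
})

test_that("criterion values are three-decimal and inside the unit interval", {
  fix <- loadCSIDataset(seed = 8, eventsPerSample = 300)
  pd <- runWorkflow(fix$data, "NON+ACS+NON+NON")
  cl <- clusterCells(pd, 8, seed = 2)
  res <- list(criterionAccuracy(pd, cl, fix$ann, seed = 2),
              criterionTightness(pd, cl, seed = 2),
              criterionRobustnessCSI(pd, 8, seed = 2, reps = 3),
              criterionCorrespondenceCSI(pd, fix$ann, fix$known))
  for (r in res) {
    expect_gte(r@value, 0)
    expect_lte(r@value, 1)
    expect_equal(r@value, round(r@value, 3))
  }
})
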