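## CSI assessment criteria: Accuracy (Ca), Tightness (Cb), Robustness (Cc)
## and Correspondence (Cd), computed on preprocessed data.

.round3 <- function(x) round(min(max(x, 0), 1), 3)

.criterion <- function(id, value) {
  new("CriterionResult", criterion = id, value = .round3(value),
      category = "")
}

## k-means++ seeding followed by Lloyd iterations; best of nstart restarts
.kmeansPP <- function(x, k, nstart = 10L, iter.max = 100L) {
  n <- nrow(x)
  best <- NULL
  for (r in seq_len(nstart)) {
    cen <- matrix(NA_real_, k, ncol(x))
    cen[1L, ] <- x[sample.int(n, 1L), ]
    d2 <- colSums((t(x) - cen[1L, ])^2)
    for (j in 2L:k) {
      prob <- d2 / sum(d2)
      cen[j, ] <- x[sample.int(n, 1L, prob = prob), ]
      d2 <- pmin(d2, colSums((t(x) - cen[j, ])^2))
    }
    km <- suppressWarnings(stats::kmeans(x, centers = cen,
                                         iter.max = iter.max))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

#' Cluster cells by k-means
#'
#' k-means with k-means++ initialization and multiple restarts; deterministic
#' for a fixed seed. Operates on the selected analysis markers.
#'
#' @param data a \code{CytoSet} or \code{ProcessedCytoSet}.
#' @param k number of clusters (at least 2; needs at least \code{10 * k}
#'   events).
#' @param seed integer seed.
#' @param nstart number of k-means++ restarts.
#' @return a list with \code{k}, \code{labels} (per-event cluster index),
#'   \code{centroids} (k x markers) and \code{seed}.
#' @export
clusterCells <- function(data, k, seed = 1L, nstart = 10L) {
  stopifnot(is(data, "CytoSet"))
  if (!is.numeric(k) || length(k) != 1L || k < 2L)
    stop("argument error: k must be at least 2")
  k <- as.integer(k)
  x <- analysisMatrix(data)
  if (nrow(x) < 10L * k)
    stop("too few events for clustering: need at least ", 10L * k,
         ", got ", nrow(x))
  km <- withSeed(seed, .kmeansPP(x, k, nstart = nstart))
  list(k = k, labels = km$cluster, centroids = km$centers,
       seed = as.integer(seed))
}

## per-sample cluster abundance fractions
.abundanceFeatures <- function(labels, origin, nSamples, k) {
  t(vapply(seq_len(nSamples), function(s) {
    tabulate(labels[origin == s], nbins = k) / max(1L, sum(origin == s))
  }, numeric(k)))
}

#' CSI Accuracy (Ca): condition recovery from cluster abundances
#'
#' Builds one feature vector per sample (cluster abundance fractions) and
#' classifies the sample's condition by leave-one-sample-out cross-validation
#' with a ridge-regularized linear classifier (inverse-class-frequency
#' observation weights remove the leave-one-out class-imbalance bias). Ca is
#' the mean balanced accuracy.
#'
#' @param data a \code{ProcessedCytoSet} (or \code{CytoSet}).
#' @param clusters result of \code{\link{clusterCells}}.
#' @param annotation CSI \code{SampleAnnotation} (at least two samples per
#'   condition).
#' @param seed integer seed.
#' @param lambda ridge penalty.
#' @return a \code{CriterionResult} for Ca.
#' @export
criterionAccuracy <- function(data, clusters, annotation = annotation(data),
                              seed = 1L, lambda = 0.05) {
  stopifnot(is(data, "CytoSet"))
  cond <- annotation@entries$label[match(data@sampleIDs,
                                         annotation@entries$filename)]
  tab <- table(cond)
  if (any(tab < 2L))
    stop("cardinality error: at least two samples for each condition are ",
         "required (metadata rule), violated by: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  nS <- length(data@sampleIDs)
  feat <- .abundanceFeatures(clusters$labels, data@origin, nS, clusters$k)
  y <- factor(cond)
  pred <- character(nS)
  for (i in seq_len(nS)) {
    xtr <- feat[-i, , drop = FALSE]; ytr <- droplevels(y[-i])
    if (nlevels(ytr) < 2L) { pred[i] <- levels(ytr); next }
    w <- 1 / table(ytr)[as.character(ytr)]
    w <- as.numeric(w) * length(ytr) / sum(w)
    fam <- if (nlevels(ytr) == 2L) "binomial" else "multinomial"
    ## glmnet warns about the (intentionally) tiny per-class sample sizes
    fit <- withSeed(seed, suppressWarnings(
      glmnet::glmnet(xtr, ytr, family = fam, alpha = 0, lambda = lambda,
                     weights = w, standardize = TRUE)))
    pred[i] <- as.character(stats::predict(
      fit, feat[i, , drop = FALSE], type = "class", s = lambda))
  }
  recalls <- vapply(levels(y), function(cl)
    mean(pred[y == cl] == cl), numeric(1))
  .criterion("Ca", mean(recalls))
}

## brute-force O(n^2) mean silhouette used nowhere in the pipeline; the
## assessment itself goes through cluster::silhouette
.silhouetteBrute <- function(x, labels) {
  n <- nrow(x)
  D <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1L) mean(D[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(D[i, labels == cl]), numeric(1)))
    s[i] <- if (sum(own) > 1L) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' CSI Tightness (Cb): mean silhouette coefficient
#'
#' Mean silhouette over (a subsample of) the events, Euclidean distance on
#' the selected markers; Cb maps the mean silhouette from [-1, 1] to [0, 1]
#' via \code{(s + 1) / 2}.
#'
#' @param data a \code{ProcessedCytoSet} (or \code{CytoSet}).
#' @param clusters result of \code{\link{clusterCells}}.
#' @param maxEvents subsample cap for the O(n^2) computation.
#' @param seed integer seed for the subsample.
#' @return a \code{CriterionResult} for Cb.
#' @export
criterionTightness <- function(data, clusters, maxEvents = 5000L, seed = 1L) {
  stopifnot(is(data, "CytoSet"))
  x <- analysisMatrix(data)
  lab <- clusters$labels
  if (length(unique(lab)) < 2L)
    stop("undefined-silhouette error: all events fall in one cluster")
  n <- nrow(x)
  if (n > maxEvents) {
    idx <- withSeed(seed, sort(sample.int(n, maxEvents)))
    x <- x[idx, , drop = FALSE]; lab <- lab[idx]
    if (length(unique(lab)) < 2L)
      stop("undefined-silhouette error: subsample lost all but one cluster")
  }
  sil <- cluster::silhouette(lab, stats::dist(x))
  .criterion("Cb", (mean(sil[, "sil_width"]) + 1) / 2)
}

#' CSI Robustness (Cc): bootstrap clustering stability
#'
#' Reclusters bootstrap subsamples (80 percent of events, without
#' replacement) and measures the mean adjusted Rand index against the full
#' clustering restricted to the shared events, clipped to [0, 1].
#'
#' @param data a \code{ProcessedCytoSet} (or \code{CytoSet}).
#' @param k cluster count.
#' @param seed integer seed.
#' @param reps number of subsample replicates (at least 2).
#' @param fraction subsample fraction.
#' @return a \code{CriterionResult} for Cc.
#' @export
criterionRobustnessCSI <- function(data, k, seed = 1L, reps = 5L,
                                   fraction = 0.8) {
  stopifnot(is(data, "CytoSet"))
  if (!is.numeric(reps) || reps < 2L)
    stop("argument error: reps must be at least 2")
  full <- clusterCells(data, k, seed = seed)
  n <- nrow(data@exprs)
  aris <- vapply(seq_len(reps), function(r) {
    idx <- withSeed(seed + 1000L * r,
                    sort(sample.int(n, floor(fraction * n))))
    sub <- data
    sub@exprs <- data@exprs[idx, , drop = FALSE]
    sub@origin <- data@origin[idx]
    cl <- clusterCells(sub, k, seed = seed + r)
    mclust::adjustedRandIndex(cl$labels, full$labels[idx])
  }, numeric(1))
  .criterion("Cc", mean(aris))
}

## ---- correspondence -------------------------------------------------------

#' Read a known-marker ground-truth table
#'
#' CSV whose first line names the two compared conditions (comparison
#' condition first, reference second), followed by a \code{marker,direction}
#' header and one row per marker with direction \code{up} or \code{down}
#' (expression in the comparison condition relative to the reference).
#'
#' @param path CSV path.
#' @return list with \code{conditions} (character(2)) and \code{entries}
#'   (data.frame marker/direction).
#' @export
readKnownMarkers <- function(path) {
  lines <- readLines(path)
  conds <- trimws(strsplit(lines[1L], ",")[[1L]])
  conds <- conds[nzchar(conds)]
  if (length(conds) != 2L)
    stop("known-marker file must name exactly two conditions on line 1")
  df <- utils::read.csv(text = paste(lines[-1L], collapse = "\n"),
                        strip.white = TRUE)
  if (!identical(names(df), c("marker", "direction")))
    stop("known-marker header must be 'marker,direction'")
  if (anyDuplicated(df$marker)) stop("known markers must be unique")
  if (!all(df$direction %in% c("up", "down")))
    stop("directions must be 'up' or 'down'")
  list(conditions = conds, entries = df)
}

#' @rdname readKnownMarkers
#' @param known list as returned by \code{readKnownMarkers}.
#' @export
writeKnownMarkers <- function(known, path) {
  writeLines(c(paste(known$conditions, collapse = ","),
               "marker,direction",
               paste(known$entries$marker, known$entries$direction,
                     sep = ",")), path)
  invisible(path)
}

#' CSI Correspondence (Cd): recovery of known differential markers
#'
#' For every selected marker the standardized median difference between the
#' two conditions is computed (comparison minus reference, scaled by the
#' pooled MAD). A known marker counts as recovered when its sign matches the
#' stated direction and its absolute effect ranks within the top
#' \code{max(n_known, 25 percent)} of all markers. Cd is the recovered
#' fraction.
#'
#' @param data a \code{ProcessedCytoSet} (or \code{CytoSet}).
#' @param annotation CSI \code{SampleAnnotation}.
#' @param known known-marker set (see \code{\link{readKnownMarkers}}).
#' @return a \code{CriterionResult} for Cd, or \code{NULL} when \code{known}
#'   is empty (datasets without a complete biomarker list skip this
#'   criterion).
#' @export
criterionCorrespondenceCSI <- function(data, annotation = annotation(data),
                                       known) {
  stopifnot(is(data, "CytoSet"))
  if (is.null(known) || nrow(known$entries) == 0L) return(NULL)
  mk <- colnames(analysisMatrix(data))
  missing <- setdiff(known$entries$marker, mk)
  if (length(missing))
    stop("known marker(s) absent from the selected panel: ",
         paste(missing, collapse = ", "))
  cond <- annotation@entries$label[match(data@sampleIDs,
                                         annotation@entries$filename)]
  badCond <- setdiff(known$conditions, cond)
  if (length(badCond))
    stop("known-marker conditions not present in metadata: ",
         paste(badCond, collapse = ", "))
  x <- analysisMatrix(data)
  evCond <- cond[data@origin]
  i1 <- evCond == known$conditions[1L]   # comparison
  i2 <- evCond == known$conditions[2L]   # reference
  eff <- vapply(mk, function(m) {
    d <- stats::median(x[i1, m]) - stats::median(x[i2, m])
    sc <- stats::mad(x[c(which(i1), which(i2)), m])
    d / max(sc, 1e-12)
  }, numeric(1))
  topN <- max(nrow(known$entries), ceiling(0.25 * length(mk)))
  ranked <- names(sort(abs(eff), decreasing = TRUE))[seq_len(topN)]
  rec <- vapply(seq_len(nrow(known$entries)), function(i) {
    m <- known$entries$marker[i]
    signOK <- if (known$entries$direction[i] == "up") eff[m] > 0
              else eff[m] < 0
    signOK && m %in% ranked
  }, logical(1))
  .criterion("Cd", mean(rec))
}
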