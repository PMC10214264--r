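## PTI assessment: trajectory inference and the four criteria Conformance
## (Ca), Smoothness (Cb), Robustness (Cc) and Correspondence (Cd).

#' Infer a pseudotime trajectory
#'
#' PCA to \code{nComp} components, k-means over the reduced space
#' (\code{k = kPerTimepoint} times the number of time points), minimum
#' spanning tree over the cluster centroids (Euclidean), root at the centroid
#' with the highest fraction of earliest-time-point events; each event's
#' pseudotime is the geodesic distance of its centroid along the tree plus
#' its projection onto the local edge, min-max normalized to [0, 1].
#' Deterministic for a fixed seed.
#'
#' @param data a \code{ProcessedCytoSet} (or \code{CytoSet}).
#' @param annotation PTI \code{SampleAnnotation} with at least two time
#'   points.
#' @param seed integer seed.
#' @param nComp number of principal components.
#' @param kPerTimepoint clusters per time point.
#' @return a \code{Pseudotime}.
#' @export
inferTrajectory <- function(data, annotation = annotation(data), seed = 1L,
                            nComp = 5L, kPerTimepoint = 2L) {
  stopifnot(is(data, "CytoSet"))
  if (annotation@studyKind != "PTI" || length(annotation@labelOrder) < 2L)
    stop("cardinality error: PTI requires samples collected from at least ",
         "two time points (metadata rule)")
  x <- analysisMatrix(data)
  nComp <- min(nComp, ncol(x), nrow(x) - 1L)
  sds <- apply(x, 2L, stats::sd)
  pc <- stats::prcomp(x[, sds > 1e-12, drop = FALSE],
                      center = TRUE, scale. = TRUE)
  z <- pc$x[, seq_len(min(nComp, ncol(pc$x))), drop = FALSE]

  k <- kPerTimepoint * length(annotation@labelOrder)
  km <- withSeed(seed, .kmeansPP(z, k))
  lab <- km$cluster
  cen <- km$centers

  ## MST over centroids, geodesic distances from the root centroid
  D <- as.matrix(stats::dist(cen))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g)
  tpr <- timepointRank(annotation)
  evRank <- tpr[data@sampleIDs[data@origin]]
  earliest <- min(evRank)
  rootFrac <- vapply(seq_len(k), function(cl)
    mean(evRank[lab == cl] == earliest), numeric(1))
  root <- which.max(rootFrac)
  geo <- as.numeric(igraph::distances(tree, v = root))

  ## local refinement: project each event onto the tree edge that leads
  ## from its centroid towards the adjacent centroid further from the root
  ## (or back towards the parent for leaf clusters)
  adj <- igraph::as_adj_list(tree)
  t0 <- numeric(nrow(z))
  for (cl in seq_len(k)) {
    ev <- which(lab == cl)
    if (!length(ev)) next
    nb <- as.integer(adj[[cl]])
    down <- nb[geo[nb] > geo[cl]]
    up <- nb[geo[nb] < geo[cl]]
    tcl <- rep(geo[cl], length(ev))
    target <- if (length(down)) down else up
    if (length(target)) {
      ## nearest eligible neighbour centroid per event
      dn <- vapply(target, function(nn)
        colSums((t(z[ev, , drop = FALSE]) - cen[nn, ])^2), numeric(length(ev)))
      dn <- matrix(dn, nrow = length(ev))
      pick <- target[max.col(-dn, ties.method = "first")]
      for (u in unique(pick)) {
        sel <- pick == u
        dir <- cen[u, ] - cen[cl, ]
        len <- sqrt(sum(dir^2))
        proj <- as.numeric((z[ev[sel], , drop = FALSE] -
                            matrix(cen[cl, ], sum(sel), ncol(z),
                                   byrow = TRUE)) %*% (dir / len))
        proj <- pmin(pmax(proj, 0), len)
        sgn <- if (geo[u] > geo[cl]) 1 else -1
        tcl[sel] <- geo[cl] + sgn * proj
      }
    }
    t0[ev] <- tcl
  }
  r <- range(t0)
  if (diff(r) < 1e-12)
    stop("degenerate trajectory: constant pseudotime")
  new("Pseudotime", t = (t0 - r[1]) / diff(r), root = as.integer(root),
      seed = as.integer(seed))
}

#' PTI Conformance (Ca): agreement with collection time
#'
#' Kendall's tau-b between per-event pseudotime and the ordinal collection
#' time of the event's sample; Ca = (tau + 1) / 2. Invariant under strictly
#' monotone transforms of pseudotime.
#'
#' @param pt a \code{Pseudotime}.
#' @param annotation PTI \code{SampleAnnotation}.
#' @param origin per-event sample index.
#' @param sampleIDs sample base names indexed by \code{origin}.
#' @return a \code{CriterionResult} for Ca.
#' @export
criterionConformance <- function(pt, annotation, origin, sampleIDs) {
  stopifnot(is(pt, "Pseudotime"))
  tpr <- timepointRank(annotation)
  ord <- as.numeric(tpr[sampleIDs[origin]])
  tau <- stats::cor(pt@t, ord, method = "kendall")
  .criterion("Ca", (tau + 1) / 2)
}

## roughness of a marker profile along an ordering: sum of squared
## successive bin-mean differences over the marker variance
.roughness <- function(x, ordIdx, bins = 50L) {
  v <- x[ordIdx]
  b <- .equalCountBins(length(v), bins)
  mu <- vapply(split(v, b), mean, numeric(1))
  sum(diff(mu)^2) / max(stats::var(x), 1e-300)
}

.equalCountBins <- function(n, bins) {
  bins <- min(bins, n)
  rep.int(seq_len(bins), diff(round(seq(0, n, length.out = bins + 1L))))
}

#' PTI Smoothness (Cb): paired test against a naive ordering
#'
#' Orders events by pseudotime, bins each marker into 50 equal-count bins and
#' computes the roughness \code{sum(diff(binmeans)^2) / var(marker)}; the
#' naive roughness uses a seeded random event ordering. A paired one-sided
#' t-test across markers (alternative: workflow ordering smoother than
#' naive) gives p, and Cb = 1 - p. All-zero differences return 0.5 by
#' convention (no evidence either way).
#'
#' @param pt a \code{Pseudotime}.
#' @param data a \code{ProcessedCytoSet} (at least 3 markers).
#' @param seed integer seed for the naive ordering.
#' @param bins number of equal-count pseudotime bins.
#' @return a \code{CriterionResult} for Cb.
#' @export
criterionSmoothness <- function(pt, data, seed = 1L, bins = 50L) {
  stopifnot(is(pt, "Pseudotime"), is(data, "CytoSet"))
  x <- analysisMatrix(data)
  if (ncol(x) < 3L) stop("smoothness requires at least 3 markers")
  n <- nrow(x)
  ordW <- order(pt@t)
  ordN <- withSeed(seed, sample.int(n))
  Rw <- apply(x, 2L, .roughness, ordIdx = ordW, bins = bins)
  Rn <- apply(x, 2L, .roughness, ordIdx = ordN, bins = bins)
  .criterion("Cb", smoothnessFromRoughness(Rw, Rn))
}

#' Smoothness score from a roughness table
#'
#' The statistic behind the smoothness criterion: given per-marker roughness
#' under the workflow ordering (\code{Rw}) and under the naive ordering
#' (\code{Rn}), runs the paired one-sided t-test (alternative: workflow
#' smoother, i.e. \code{Rn > Rw}) and returns \code{1 - p} unrounded.
#' All-zero differences return 0.5 by convention.
#'
#' @param Rw,Rn numeric vectors of per-marker roughness values.
#' @return numeric(1), the unrounded smoothness score \code{1 - p}.
#' @export
smoothnessFromRoughness <- function(Rw, Rn) {
  stopifnot(length(Rw) == length(Rn), length(Rw) >= 2L)
  d <- Rn - Rw
  if (all(abs(d) < 1e-300)) return(0.5)
  1 - stats::t.test(Rn, Rw, paired = TRUE,
                    alternative = "greater")$p.value
}

#' PTI Robustness (Cc): stability of pseudotime under subsampling
#'
#' For each replicate two independent 80 percent subsamples are drawn,
#' pseudotime is inferred on each, and the absolute Spearman correlation is
#' computed on the shared events (the absolute value absorbs the arbitrary
#' trajectory direction). Cc is the mean over replicates.
#'
#' @param data a \code{ProcessedCytoSet}.
#' @param annotation PTI \code{SampleAnnotation}.
#' @param seed integer seed.
#' @param reps replicates (at least 2).
#' @param fraction subsample fraction.
#' @return a \code{CriterionResult} for Cc.
#' @export
criterionRobustnessPTI <- function(data, annotation = annotation(data),
                                   seed = 1L, reps = 5L, fraction = 0.8) {
  stopifnot(is(data, "CytoSet"))
  if (!is.numeric(reps) || reps < 2L)
    stop("argument error: reps must be at least 2")
  n <- nrow(data@exprs)
  rhos <- vapply(seq_len(reps), function(r) {
    idx <- withSeed(seed + 7919L * r, list(
      a = sort(sample.int(n, floor(fraction * n))),
      b = sort(sample.int(n, floor(fraction * n)))))
    sub <- function(i) {
      s <- data
      s@exprs <- data@exprs[i, , drop = FALSE]
      s@origin <- data@origin[i]
      s
    }
    pa <- inferTrajectory(sub(idx$a), annotation, seed = seed + 2L * r)
    pb <- inferTrajectory(sub(idx$b), annotation, seed = seed + 2L * r + 1L)
    shared <- intersect(idx$a, idx$b)
    abs(stats::cor(pa@t[match(shared, idx$a)],
                   pb@t[match(shared, idx$b)], method = "spearman"))
  }, numeric(1))
  .criterion("Cc", mean(rhos))
}

## ---- pathway hierarchies --------------------------------------------------

#' Read / write a pathway-hierarchy table
#'
#' Semicolon-separated table with one signaling cascade per column; the first
#' row holds each pathway's key protein (the first protein reaching its
#' maximum expression), subsequent rows the downstream proteins in cascade
#' order. Short pathways leave trailing cells empty.
#'
#' @param path file path.
#' @return \code{readPathwayHierarchy}: named list of character vectors (one
#'   per pathway, key protein first).
#' @export
readPathwayHierarchy <- function(path) {
  lines <- readLines(path)
  cells <- strsplit(lines, ";", fixed = TRUE)
  width <- max(lengths(cells))
  grid <- t(vapply(cells, function(r) {
    r <- trimws(r)
    c(r, rep("", width - length(r)))
  }, character(width)))
  grid <- matrix(grid, ncol = width)
  pw <- lapply(seq_len(width), function(j) {
    col <- grid[, j]
    col[nzchar(col)]
  })
  pw <- pw[lengths(pw) > 0L]
  names(pw) <- vapply(pw, `[[`, character(1), 1L)
  for (p in pw) {
    if (anyDuplicated(p))
      stop("pathway '", p[1L], "' lists a protein twice")
  }
  pw
}

#' @rdname readPathwayHierarchy
#' @param hierarchy named list of character vectors (key protein first).
#' @export
writePathwayHierarchy <- function(hierarchy, path) {
  depth <- max(lengths(hierarchy))
  rows <- vapply(seq_len(depth), function(i)
    paste(vapply(hierarchy, function(p)
      if (length(p) >= i) p[i] else "", character(1)), collapse = ";"),
    character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Peak activation pseudotimes of proteins
#'
#' Bins events into equal-count pseudotime bins, smooths each protein's bin
#' means with a short moving average and reports the pseudotime of the
#' maximal bin (ties broken by the earliest bin).
#'
#' @param pt a \code{Pseudotime}.
#' @param data a \code{ProcessedCytoSet}.
#' @param proteins marker names to profile.
#' @param bins number of bins.
#' @param window moving-average window (odd).
#' @return named numeric vector of peak pseudotimes.
#' @export
peakActivationTimes <- function(pt, data, proteins = NULL, bins = 50L,
                                window = 5L) {
  x <- analysisMatrix(data)
  if (is.null(proteins)) proteins <- colnames(x)
  ord <- order(pt@t)
  b <- .equalCountBins(length(ord), bins)
  centers <- vapply(split(pt@t[ord], b), mean, numeric(1))
  half <- (window - 1L) %/% 2L
  vapply(proteins, function(p) {
    mu <- vapply(split(x[ord, p], b), mean, numeric(1))
    sm <- vapply(seq_along(mu), function(i)
      mean(mu[max(1L, i - half):min(length(mu), i + half)]), numeric(1))
    centers[which.max(sm)]
  }, numeric(1))
}

#' PTI Correspondence (Cd): cascade-order consistency
#'
#' A protein is incorrectly sorted when its peak activation pseudotime falls
#' strictly before its pathway's key protein. Cd = 1 - (violating proteins /
#' total proteins in the hierarchy).
#'
#' @param pt a \code{Pseudotime}.
#' @param data a \code{ProcessedCytoSet}.
#' @param hierarchy named list of cascades (key protein first), see
#'   \code{\link{readPathwayHierarchy}}.
#' @param bins number of pseudotime bins for the activation profiles.
#' @return a \code{CriterionResult} for Cd.
#' @export
criterionCorrespondencePTI <- function(pt, data, hierarchy, bins = 50L) {
  stopifnot(is(pt, "Pseudotime"), is(data, "CytoSet"))
  prots <- unique(unlist(hierarchy))
  mk <- colnames(analysisMatrix(data))
  missing <- setdiff(prots, mk)
  if (length(missing))
    stop("hierarchy protein(s) absent from the marker panel: ",
         paste(missing, collapse = ", "))
  peaks <- peakActivationTimes(pt, data, prots, bins = bins)
  total <- 0L; violations <- 0L
  for (pw in hierarchy) {
    keyPeak <- peaks[pw[1L]]
    total <- total + length(pw)
    violations <- violations +
      sum(peaks[pw[-1L]] < keyPeak - 1e-12)
  }
  .criterion("Cd", 1 - violations / total)
}
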