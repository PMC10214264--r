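## Seeded synthetic-data generators with known ground truth: multi-population
## log-normal marker mixtures (CSI), sigmoid activation cascades driven by a
## latent pseudotime (PTI), channel spillover mixing, slow acquisition drift
## and optional abrupt anomaly segments.

#' Generate a random spillover matrix
#'
#' Diagonal 1; off-diagonals Uniform(0, intensity) decaying with channel
#' distance, guaranteeing diagonal dominance (hence invertibility) for
#' intensity below 0.3.
#'
#' @param nChannels number of channels.
#' @param intensity maximal off-diagonal spillover, in [0, 0.3).
#' @param seed integer seed.
#' @param channels channel names (default \code{Ch1..ChN}).
#' @return named square spillover matrix.
#' @export
generateSpillover <- function(nChannels, intensity = 0.05, seed = 1L,
                              channels = paste0("Ch", seq_len(nChannels))) {
  if (intensity < 0 || intensity >= 0.3)
    stop("spillover intensity must lie in [0, 0.3)")
  S <- withSeed(seed, {
    S <- diag(nChannels)
    for (i in seq_len(nChannels)) for (j in seq_len(nChannels)) {
      if (i == j) next
      S[i, j] <- stats::runif(1, 0, intensity) * 0.5^(abs(i - j) - 1)
    }
    S
  })
  dimnames(S) <- list(channels, channels)
  .checkSpillover(S)
}

## multiplicative slow drift over acquisition time plus optional anomaly
## segment (event-rate spike and level shift on a channel subset)
.applyDriftAnomaly <- function(X, tvals, drift, anomaly, seed) {
  n <- nrow(X)
  tf <- (tvals - min(tvals)) / max(diff(range(tvals)), 1e-12)
  X <- X * (1 - drift * tf)            # slow signal decay
  anomIdx <- integer(0)
  if (!is.null(anomaly)) {
    stopifnot(anomaly$start_fraction > 0, anomaly$start_fraction < 1,
              anomaly$length_fraction > 0, anomaly$length_fraction < 1)
    win <- c(anomaly$start_fraction,
             min(anomaly$start_fraction + anomaly$length_fraction, 0.999))
    nExtra <- round(n * anomaly$length_fraction *
                      max(anomaly$magnitude - 1, 1))
    extra <- withSeed(seed + 13L, {
      idx <- sample.int(n, nExtra, replace = TRUE)
      E <- X[idx, , drop = FALSE]
      shiftCh <- seq_len(max(1L, ncol(X) %/% 3L))
      E[, shiftCh] <- E[, shiftCh] +
        anomaly$magnitude * apply(X[, shiftCh, drop = FALSE], 2L,
                                  stats::sd)[col(E[, shiftCh, drop = FALSE])]
      tE <- stats::runif(nExtra, win[1L], win[2L]) * diff(range(tvals)) +
        min(tvals)
      list(E = E, tE = tE)
    })
    X <- rbind(X, extra$E)
    tvals <- c(tvals, extra$tE)
    anomIdx <- seq.int(n + 1L, n + nExtra)
  }
  ord <- order(tvals)
  list(X = X[ord, , drop = FALSE], tvals = tvals[ord],
       anomaly = which(ord %in% anomIdx))
}

.writeSampleFCS <- function(X, tvals, sampleID, technique, outDir) {
  m <- cbind(X, Time = tvals)
  frame <- CytoFrame(m, sampleID = sampleID, technique = technique)
  writeFCS(frame, file.path(outDir, paste0(sampleID, ".fcs")))
  frame
}

#' Generate a synthetic CSI benchmark dataset
#'
#' Two-condition design: each sample draws events from a log-normal mixture
#' of \code{nPopulations} populations sharing mixture weights; the second
#' condition shifts the designated markers (on the log scale) in a known
#' direction, which both displaces cells in marker space (the clustering
#' signal) and creates directional median differences (the correspondence
#' ground truth). Observed values are mixed through a spillover matrix and
#' decay slowly over acquisition time; an optional anomaly segment adds an
#' event-rate spike with a level shift. FC mode adds Gaussian detector noise
#' (negative values possible); MC mode zero-inflates low intensities.
#'
#' @param outDir output directory (created if needed); FCS files,
#'   \code{metadata.csv}, \code{known_markers.csv} and
#'   \code{spillover.csv} are written there.
#' @param nChannels number of measured channels.
#' @param nPopulations mixture components.
#' @param samplesPerCondition samples per condition.
#' @param eventsPerSample events per sample.
#' @param effect named numeric vector of log-scale shifts applied to the
#'   second condition (names = channels, sign = direction); defaults to
#'   +0.9/+0.9/-0.9 on the first three channels.
#' @param spilloverIntensity spillover level in [0, 0.3).
#' @param driftAmplitude fractional slow signal decay over the run.
#' @param anomaly optional list(start_fraction, length_fraction, magnitude).
#' @param technique \code{"FC"} or \code{"MC"}.
#' @param seed integer seed; generation is bit-reproducible.
#' @return (invisibly) a truth record: file names, conditions, spillover,
#'   planted effects, per-sample population labels and anomaly indices.
#' @export
generateCSIDataset <- function(outDir, nChannels = 10L, nPopulations = 3L,
                               samplesPerCondition = 3L,
                               eventsPerSample = 500L, effect = NULL,
                               spilloverIntensity = 0.05,
                               driftAmplitude = 0.05, anomaly = NULL,
                               technique = c("FC", "MC"), seed = 1L) {
  technique <- match.arg(technique)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  channels <- sprintf("M%02d", seq_len(nChannels))
  if (is.null(effect)) {
    effect <- stats::setNames(c(0.9, 0.9, -0.9), channels[1:3])
  }
  stopifnot(all(names(effect) %in% channels))
  spill <- generateSpillover(nChannels, spilloverIntensity, seed = seed + 1L,
                             channels = channels)
  writeSpillover(spill, file.path(outDir, "spillover.csv"))

  ## population log-mean profiles, shared across samples
  centres <- withSeed(seed + 2L, {
    matrix(stats::runif(nPopulations * nChannels, 0.5, 2.5),
           nPopulations, nChannels, dimnames = list(NULL, channels))
  })
  weights <- withSeed(seed + 3L, {
    w <- stats::runif(nPopulations, 0.5, 1.5)
    w / sum(w)
  })
  conditions <- c("ctrl", "case")
  truth <- list(files = character(), conditions = character(),
                spillover = spill, effect = effect,
                populations = list(), anomalies = list(),
                channels = channels)
  meta <- NULL
  for (ci in seq_along(conditions)) {
    for (r in seq_len(samplesPerCondition)) {
      sid <- sprintf("%s_%d", conditions[ci], r)
      sSeed <- seed + 100L * ci + r
      gen <- withSeed(sSeed, {
        pop <- sample.int(nPopulations, eventsPerSample, replace = TRUE,
                          prob = weights)
        mu <- centres[pop, , drop = FALSE]
        if (ci == 2L)
          mu[, names(effect)] <- sweep(mu[, names(effect), drop = FALSE],
                                       2L, effect, `+`)
        X <- exp(mu + matrix(stats::rnorm(eventsPerSample * nChannels,
                                          sd = 0.35),
                             eventsPerSample, nChannels))
        X <- X %*% spill                  # observed = true %*% S
        if (technique == "FC") {
          X <- X + matrix(stats::rnorm(length(X), sd = 0.3), nrow(X))
        } else {
          drop <- matrix(stats::runif(length(X)) < 0.15 / (1 + X), nrow(X))
          X[drop] <- 0
        }
        colnames(X) <- channels
        tvals <- sort(stats::runif(eventsPerSample, 0, 100))
        list(X = X, tvals = tvals, pop = pop)
      })
      da <- .applyDriftAnomaly(gen$X, gen$tvals, driftAmplitude, anomaly,
                               sSeed)
      .writeSampleFCS(da$X, da$tvals, sid, technique, outDir)
      truth$files <- c(truth$files, sid)
      truth$conditions <- c(truth$conditions, conditions[ci])
      truth$populations[[sid]] <- gen$pop
      truth$anomalies[[sid]] <- da$anomaly
      meta <- rbind(meta, data.frame(filename = sid,
                                     condition = conditions[ci]))
    }
  }
  utils::write.csv(meta, file.path(outDir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  known <- list(conditions = c("case", "ctrl"),
                entries = data.frame(
                  marker = names(effect),
                  direction = ifelse(effect > 0, "up", "down")))
  writeKnownMarkers(known, file.path(outDir, "known_markers.csv"))
  invisible(truth)
}

#' Generate a synthetic PTI benchmark dataset
#'
#' Each cell receives a latent progression time u drawn uniformly within its
#' sample's time-point window; protein p's expression follows a Gaussian
#' activation bump centred at its cascade midpoint with additive noise, so
#' proteins peak in the planted hierarchy order (the key protein of each
#' pathway peaks first). Writes FCS files, \code{metadata.csv} and the
#' semicolon-separated \code{Pathway_Hierarchy.csv}.
#'
#' @param outDir output directory.
#' @param nProteins total proteins across pathways.
#' @param nPathways number of signaling cascades.
#' @param nTimepoints collection time points.
#' @param samplesPerTimepoint samples per time point.
#' @param eventsPerSample events per sample.
#' @param noise additive expression noise (SD, bump amplitude is 3).
#' @param driftAmplitude fractional slow signal decay over acquisition time.
#' @param technique \code{"FC"} or \code{"MC"}.
#' @param seed integer seed.
#' @return (invisibly) a truth record: latent times per sample, cascade
#'   midpoints, hierarchy and file names.
#' @export
generatePTIDataset <- function(outDir, nProteins = 39L, nPathways = 7L,
                               nTimepoints = 4L, samplesPerTimepoint = 1L,
                               eventsPerSample = 500L, noise = 0.3,
                               driftAmplitude = 0, technique = c("MC", "FC"),
                               seed = 1L) {
  technique <- match.arg(technique)
  if (nProteins < 2L * nPathways)
    stop("cascades need at least two proteins each")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  proteins <- sprintf("P%02d", seq_len(nProteins))

  ## split proteins into pathways and assign strictly increasing activation
  ## midpoints within each pathway (key protein first and earliest)
  sizes <- rep(nProteins %/% nPathways, nPathways)
  extra <- nProteins %% nPathways
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bounds <- cumsum(c(0L, sizes))
  hierarchy <- lapply(seq_len(nPathways), function(j)
    proteins[(bounds[j] + 1L):bounds[j + 1L]])
  names(hierarchy) <- vapply(hierarchy, `[[`, character(1), 1L)
  ## key proteins activate first (midpoint 0.08); downstream midpoints are
  ## drawn per pathway from a coarse grid (minimum gap 0.08, well above the
  ## 50-bin pseudotime resolution) so cascade layouts differ across pathways
  midpoints <- stats::setNames(numeric(nProteins), proteins)
  grid <- seq(0.16, 0.92, by = 0.08)
  midpoints[vapply(hierarchy, `[[`, character(1), 1L)] <- 0.08
  for (j in seq_len(nPathways)) {
    pw <- hierarchy[[j]]
    midpoints[pw[-1L]] <- withSeed(seed + 17L * j,
      sort(sample(grid, length(pw) - 1L)))
  }
  writePathwayHierarchy(hierarchy,
                        file.path(outDir, "Pathway_Hierarchy.csv"))

  tpLabels <- as.character(seq_len(nTimepoints))
  meta <- NULL
  truth <- list(files = character(), u = list(), midpoints = midpoints,
                hierarchy = hierarchy, proteins = proteins)
  width <- 0.18
  for (tp in seq_len(nTimepoints)) {
    for (r in seq_len(samplesPerTimepoint)) {
      sid <- sprintf("tp%d_%d", tp, r)
      sSeed <- seed + 100L * tp + r
      gen <- withSeed(sSeed, {
        u <- stats::runif(eventsPerSample, (tp - 1) / nTimepoints,
                          tp / nTimepoints)
        X <- vapply(proteins, function(p)
          0.5 + 3 * exp(-(u - midpoints[p])^2 / (2 * width^2)) +
            stats::rnorm(eventsPerSample, sd = noise), numeric(eventsPerSample))
        X <- matrix(X, eventsPerSample, nProteins,
                    dimnames = list(NULL, proteins))
        if (technique == "MC") X <- pmax(X, 0)
        tvals <- sort(stats::runif(eventsPerSample, 0, 100))
        list(u = u, X = X, tvals = tvals)
      })
      da <- .applyDriftAnomaly(gen$X, gen$tvals, driftAmplitude, NULL, sSeed)
      .writeSampleFCS(da$X, da$tvals, sid, technique, outDir)
      truth$files <- c(truth$files, sid)
      truth$u[[sid]] <- gen$u
      meta <- rbind(meta, data.frame(filename = sid, timepoint = tpLabels[tp]))
    }
  }
  utils::write.csv(meta, file.path(outDir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(truth)
}

#' Structure-destroying negative control
#'
#' Corrupts a \code{CytoSet} for benchmarking sanity checks: every analysis
#' channel is z-scored within each sample (erasing between-condition and
#' between-time-point shifts) and the channel-to-marker assignment is then
#' rotated by half the panel, so marker identities no longer match their
#' measured values. Preserved structure should score strictly better than
#' this corruption under the assessment criteria.
#'
#' @param data a \code{CytoSet} or \code{ProcessedCytoSet}.
#' @param permutation \code{"rotate"} shifts the channel values by
#'   \code{rotate} positions; \code{"reverse"} inverts the channel order
#'   (maximally order-inverting, the natural negative control for
#'   cascade-order criteria).
#' @param rotate positions for the rotation (default: half the panel).
#' @param zscore z-score each channel within each sample before permuting
#'   (erases between-sample shifts; disable to corrupt only the
#'   channel-to-marker assignment while keeping the geometry intact).
#' @return the corrupted object (same class, same dimensions).
#' @export
corruptStructure <- function(data, permutation = c("rotate", "reverse"),
                             rotate = NULL, zscore = TRUE) {
  stopifnot(is(data, "CytoSet"))
  permutation <- match.arg(permutation)
  ch <- analysisChannels(data)
  out <- data
  if (zscore) {
    for (s in seq_along(data@sampleIDs)) {
      rows <- which(data@origin == s)
      for (cn in ch) {
        v <- data@exprs[rows, cn]
        s0 <- stats::sd(v)
        out@exprs[rows, cn] <- if (s0 < 1e-300) 0 else (v - mean(v)) / s0
      }
    }
  }
  perm <- if (permutation == "reverse") {
    rev(seq_along(ch))
  } else {
    if (is.null(rotate)) rotate <- max(1L, length(ch) %/% 2L)
    rotate <- rotate %% length(ch)
    if (rotate == 0L) seq_along(ch)
    else c((rotate + 1L):length(ch), seq_len(rotate))
  }
  out@exprs[, ch] <- out@exprs[, ch[perm]]
  out
}
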