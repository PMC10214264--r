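## The 25 preprocessing-method algorithms and four-step workflow execution:
## compensation -> transformation -> normalization -> signal clean.

## ---- spillover ------------------------------------------------------------

#' Read / write a spillover matrix as CSV
#'
#' Square numeric body with a header of channel names; entry (i, j) is the
#' fraction of channel i's true signal observed in channel j.
#'
#' @param path CSV path.
#' @return \code{readSpillover}: named square matrix.
#' @export
readSpillover <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  S <- as.matrix(df)
  rownames(S) <- colnames(S)
  .checkSpillover(S)
  S
}

#' @rdname readSpillover
#' @param S spillover matrix.
#' @export
writeSpillover <- function(S, path) {
  utils::write.csv(as.data.frame(S), path, row.names = FALSE)
  invisible(path)
}

.checkSpillover <- function(S) {
  if (nrow(S) != ncol(S)) stop("spillover matrix must be square")
  if (any(abs(diag(S) - 1) > 1e-9))
    stop("spillover matrix diagonal entries must equal 1")
  off <- S[row(S) != col(S)]
  if (any(off < 0 | off >= 1))
    stop("spillover off-diagonals must lie in [0, 1)")
  if (!is.finite(rcond(S)) || rcond(S) < 1e-12)
    stop("numerical error: spillover matrix is singular or ill-conditioned")
  invisible(S)
}

## per-event non-negative least squares unmixing: min ||x - y S||, y >= 0
.nnlsUnmix <- function(X, S) {
  Sinv <- solve(S)
  Y <- X %*% Sinv
  bad <- which(apply(Y, 1L, function(r) any(r < 0)))
  if (length(bad)) {
    Ct <- t(S)                                  # x^T = S^T y^T
    for (i in bad) Y[i, ] <- pracma::lsqnonneg(Ct, X[i, ])$x
  }
  Y
}

## AutoSpill-style refinement: iterative robust linear fits on single-stain
## controls, then inversion of the refined matrix.
.refineSpillover <- function(S, controls) {
  ch <- colnames(S)
  for (iter in 1:3) {
    Snew <- S
    for (i in seq_along(ch)) {
      ctrl <- controls[[ch[i]]]
      if (is.null(ctrl)) next
      X <- ctrl@exprs[, ch, drop = FALSE] %*% solve(S)   # compensate controls
      xi <- X[, i]
      keep <- xi > stats::quantile(xi, 0.5)              # positive population
      if (sum(keep) < 10L) next
      for (j in seq_along(ch)) {
        if (i == j) next
        fit <- tryCatch(
          MASS::rlm(X[keep, j] ~ xi[keep], maxit = 50),
          error = function(e) NULL)
        if (is.null(fit)) next
        resid_slope <- unname(stats::coef(fit)[2L])
        Snew[i, j] <- min(max(S[i, j] + resid_slope, 0), 0.99)
      }
    }
    S <- Snew
  }
  diag(S) <- 1
  .checkSpillover(S)
}

#' Compensate spillover between detection channels
#'
#' Applies the selected compensation method to the analysis channels (the
#' acquisition-time channel is never touched). \code{FLC} and \code{CMP}
#' invert the supplied spillover matrix linearly; \code{MTC} first subtracts a
#' per-file autofluorescence estimate (per-channel 1st percentile); \code{CTS}
#' unmixes each event by non-negative least squares; \code{ATS} refines the
#' spillover matrix from single-stain controls by iterative robust linear
#' fits before inversion (falling back to plain inversion with a warning when
#' controls are absent). \code{NON} is the identity.
#'
#' @param data a \code{CytoSet}.
#' @param method compensation method ID.
#' @param spill spillover matrix whose channel names are a subset of the
#'   data's channels. Required for every method except \code{NON}.
#' @param controls named list of single-stain control \code{CytoFrame}s
#'   (names = channels), used by \code{ATS}.
#' @return the compensated \code{CytoSet}.
#' @export
compensateCells <- function(data, method, spill = NULL, controls = NULL) {
  stopifnot(is(data, "CytoSet"))
  if (method == "NON") return(data)
  if (!method %in% c("FLC", "ATS", "MTC", "CTS", "CMP"))
    stop("unknown compensation method: ", method)
  if (is.null(spill))
    stop("configuration error: method ", method,
         " requires a spillover matrix (argument or $SPILLOVER keyword)")
  .checkSpillover(spill)
  ch <- colnames(spill)
  missing <- setdiff(ch, colnames(data@exprs))
  if (length(missing))
    stop("spillover channels absent from data: ",
         paste(missing, collapse = ", "))
  X <- data@exprs[, ch, drop = FALSE]

  if (method == "ATS") {
    if (is.null(controls)) {
      warning("ATS: no single-stain controls supplied; ",
              "falling back to plain spillover inversion")
    } else {
      spill <- .refineSpillover(spill, controls)
    }
  }
  Y <- switch(method,
    FLC = , CMP = , ATS = X %*% solve(spill),
    CTS = .nnlsUnmix(X, spill),
    MTC = {
      Xa <- X
      for (s in seq_along(data@sampleIDs)) {
        rows <- data@origin == s
        af <- apply(X[rows, , drop = FALSE], 2L, stats::quantile,
                    probs = 0.01, names = FALSE)
        Xa[rows, ] <- sweep(X[rows, , drop = FALSE], 2L, af)
      }
      Xa %*% solve(spill)
    })
  out <- data
  out@exprs[, ch] <- Y
  out
}

## ---- transformations ------------------------------------------------------

.annCofactor <- function(x) {
  pos <- x[x > 0]
  if (!length(pos)) return(1)
  max(1, stats::quantile(pos, 0.05, names = FALSE))
}

.boxcoxLambda <- function(x, subsample = 1000L) {
  xs <- x - min(x) + 1
  if (length(xs) > subsample) xs <- sample(xs, subsample)
  if (diff(range(xs)) < 1e-12)
    stop("parameter-estimation error: Box-Cox on a constant channel")
  bc <- MASS::boxcox(xs ~ 1, lambda = seq(-2, 2, 0.05), plotit = FALSE)
  bc$x[which.max(bc$y)]
}

.bartlettBins <- function(y, k = 5L) {
  ## deterministic 1-D binning by k-means seeded at spread quantiles
  cen <- unique(stats::quantile(y, probs = seq(0.1, 0.9, length.out = k),
                                names = FALSE))
  if (length(cen) < 2L) return(Inf)
  km <- suppressWarnings(stats::kmeans(y, centers = matrix(cen),
                                       iter.max = 30))
  g <- km$cluster
  sizes <- table(g)
  keep <- g %in% names(sizes)[sizes >= 2L]
  if (length(unique(g[keep])) < 2L) return(Inf)
  v <- tapply(y[keep], g[keep], stats::var)
  if (any(v < 1e-300)) return(Inf)
  unname(stats::bartlett.test(y[keep], factor(g[keep]))$statistic)
}

.fvsCofactor <- function(x, k = 5L, subsample = 2000L) {
  xs <- if (length(x) > subsample) sample(x, subsample) else x
  grid <- 10^seq(-1, 3, length.out = 9)
  stat <- vapply(grid, function(cf) .bartlettBins(asinh(xs / cf), k),
                 numeric(1))
  grid[which.min(stat)]
}

## biexponential f(y) = a e^{by} - c e^{-dy} + f, inverted by bisection
.biexpInverse <- function(x, a, b, c, d, f, lo = -50, hi = 50, iters = 90L) {
  fl <- rep(lo, length(x)); fh <- rep(hi, length(x))
  for (i in seq_len(iters)) {
    mid <- (fl + fh) / 2
    val <- a * exp(b * mid) - c * exp(-d * mid) + f
    up <- val < x
    fl[up] <- mid[up]; fh[!up] <- mid[!up]
  }
  (fl + fh) / 2
}

.logicleParams <- function(T = 262144, W = 0.5, M = 4.5, A = 0) {
  w <- W / (M + A)
  x2 <- A / (M + A); x1 <- x2 + w; x0 <- x2 + 2 * w
  b <- (M + A) * log(10)
  d <- if (w == 0) b else
    stats::uniroot(function(dd) 2 * (log(dd) - log(b)) + w * (b + dd),
                   c(1e-12, b), tol = 1e-14)$root
  ca <- exp(x0 * (b + d))
  fa <- exp(b * x1) - ca / exp(d * x1)
  a <- T / ((exp(b) - fa) - ca / exp(d))
  list(a = a, b = b, c = ca * a, f = -fa * a, d = d, x1 = x1)
}

.logicleScale <- function(y, p) {
  ## value of the logicle scale function at display position y
  pos <- y >= p$x1
  out <- numeric(length(y))
  out[pos] <- p$a * exp(p$b * y[pos]) - p$c * exp(-p$d * y[pos]) + p$f
  yr <- 2 * p$x1 - y[!pos]
  out[!pos] <- -(p$a * exp(p$b * yr) - p$c * exp(-p$d * yr) + p$f)
  out
}

.logicleInverse <- function(x, p, tol = 1e-8) {
  lo <- rep(-0.5, length(x)); hi <- rep(1.5, length(x))
  for (i in seq_len(80L)) {
    mid <- (lo + hi) / 2
    up <- .logicleScale(mid, p) < x
    lo[up] <- mid[up]; hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

## Each transformation maps one channel vector; all are monotone
## non-decreasing on the input domain (strict except TRU below threshold).
.transformChannel <- function(x, method, technique, params) {
  p <- params
  switch(method,
    ACS = asinh(x / if (technique == "MC") p$cofactor_mc else p$cofactor_fc),
    ANN = asinh(x / .annCofactor(x)),
    ARN = {
      y <- asinh(x / if (technique == "MC") p$cofactor_mc else p$cofactor_fc)
      r <- range(y)
      if (diff(r) < 1e-300) rep(0, length(y)) else (y - r[1]) / diff(r)
    },
    BEP = .biexpInverse(x, p$a, p$b, p$c, p$d, p$f),
    BOX = {
      lam <- .boxcoxLambda(x, p$subsample)
      xs <- x - min(x) + 1
      if (abs(lam) < 1e-8) log(xs) else (xs^lam - 1) / lam
    },
    FVS = asinh(x / .fvsCofactor(x, p$k, p$subsample)),
    HPL = {
      T0 <- if (technique == "MC") p$T_mc else p$T_fc
      sign(x) * log10(1 + abs(x) / T0)
    },
    LGT = .logicleInverse(x, .logicleParams(p$T, p$W, p$M, p$A), p$tol),
    LIN = {
      r <- range(x)
      if (diff(r) < 1e-300) rep(0, length(x))
      else (x - r[1]) / diff(r) * p$upper
    },
    LNT = log(x - min(x) + 1),
    LOG = log10(x - min(x) + 1),
    QUA = stats::qnorm(rank(x, ties.method = "average") / (length(x) + 1)),
    SCA = {
      s <- stats::sd(x)
      if (s < 1e-300) rep(0, length(x)) else (x - mean(x)) / s
    },
    TRU = pmax(x, p$threshold),
    stop("unknown transformation method: ", method)
  )
}

#' Transform expression channels
#'
#' Applies a registered transformation independently to each analysis channel
#' (the acquisition-time channel is excluded). All transformations are
#' monotone non-decreasing. Data-driven parameter fits (Box-Cox lambda,
#' variance-stabilizing cofactors) are seeded for determinism.
#'
#' @param data a \code{CytoSet}.
#' @param method transformation method ID or \code{"NON"}.
#' @param params parameter overrides merged over the registry defaults.
#' @param seed integer seed for subsampled parameter estimation.
#' @return the transformed \code{CytoSet}.
#' @export
transformCells <- function(data, method, params = list(), seed = 1L) {
  stopifnot(is(data, "CytoSet"))
  if (method == "NON") return(data)
  reg <- defaultRegistry()
  if (!method %in% reg$id[reg$step == "transformation"])
    stop("unknown transformation method: ", method)
  p <- utils::modifyList(reg$params[[match(method, reg$id)]], params)
  ch <- analysisChannels(data)
  out <- data
  for (j in seq_along(ch)) {
    out@exprs[, ch[j]] <- withSeed(seed + j,
      .transformChannel(data@exprs[, ch[j]], method, data@technique, p))
  }
  out
}

## ---- normalization --------------------------------------------------------

## piecewise-linear monotone warp through (src -> dst) with identity-slope
## extension beyond the outermost anchors
.warpValues <- function(x, src, dst) {
  keep <- !duplicated(src)
  src <- src[keep]; dst <- dst[keep]
  o <- order(src); src <- src[o]; dst <- sort(dst[o])
  L <- length(src)
  if (L == 0L) return(x)
  if (L == 1L) return(x + (dst - src))
  y <- stats::approx(src, dst, xout = x, rule = 1)$y
  low <- x < src[1L]; high <- x > src[L]
  y[low] <- dst[1L] + (x[low] - src[1L])
  y[high] <- dst[L] + (x[high] - src[L])
  y
}

.densityPeaks <- function(x, maxPeaks = 2L) {
  d <- stats::density(x, n = 512)
  yy <- d$y
  loc <- which(diff(sign(diff(yy))) == -2) + 1L
  if (!length(loc)) loc <- which.max(yy)
  loc <- loc[order(yy[loc], decreasing = TRUE)]
  sort(d$x[utils::head(loc, maxPeaks)])
}

#' Normalize channel distributions across samples
#'
#' \code{GSN}: per channel, detects up to two highest kernel-density peaks per
#' sample and piecewise-linearly shifts each sample so the peaks align to the
#' cross-sample mean peak positions. \code{WPS}: monotone piecewise-linear
#' warp mapping each sample's decile anchors to the cross-sample means.
#' \code{FDN}: finer quantile anchoring (5th-95th percentiles in steps of 5).
#' Event counts are never changed and every per-sample map is monotone.
#' Samples with fewer than 50 events are passed through with a warning.
#'
#' @param data a \code{CytoSet} with at least two samples.
#' @param method normalization method ID or \code{"NON"}.
#' @param params parameter overrides.
#' @return the normalized \code{CytoSet}.
#' @export
normalizeCells <- function(data, method, params = list()) {
  stopifnot(is(data, "CytoSet"))
  if (method == "NON") return(data)
  if (!method %in% c("GSN", "WPS", "FDN"))
    stop("unknown normalization method: ", method)
  nS <- length(data@sampleIDs)
  if (nS < 2L)
    stop("normalization requires at least two samples, got ", nS)
  reg <- defaultRegistry()
  p <- utils::modifyList(reg$params[[match(method, reg$id)]], params)
  ch <- analysisChannels(data)
  rowsBy <- lapply(seq_len(nS), function(s) which(data@origin == s))
  small <- vapply(rowsBy, length, integer(1)) < 50L
  if (any(small))
    warning("normalization pass-through for sample(s) with < 50 events: ",
            paste(data@sampleIDs[small], collapse = ", "))
  use <- which(!small)
  if (length(use) < 2L) return(data)

  probs <- switch(method,
    WPS = seq_len(p$anchors) / (p$anchors + 1),
    FDN = seq(0.05, 0.95, by = 0.05),
    NULL)
  out <- data
  for (cn in ch) {
    anchors <- lapply(use, function(s) {
      x <- data@exprs[rowsBy[[s]], cn]
      if (method == "GSN") .densityPeaks(x, p$max_peaks)
      else stats::quantile(x, probs, names = FALSE)
    })
    L <- min(lengths(anchors))
    anchors <- lapply(anchors, function(a)
      if (length(a) > L) a[round(seq(1, length(a), length.out = L))] else a)
    A <- do.call(rbind, anchors)
    target <- colMeans(A)
    for (k in seq_along(use)) {
      s <- use[k]
      out@exprs[rowsBy[[s]], cn] <-
        .warpValues(data@exprs[rowsBy[[s]], cn], A[k, ], target)
    }
  }
  out
}

## ---- signal cleaning ------------------------------------------------------

.timeBins <- function(n, target = 500L, minBins = 10L) {
  B <- max(minBins, floor(n / target))
  sizes <- diff(round(seq(0, n, length.out = B + 1L)))
  rep.int(seq_len(B), sizes)
}

.robustFlag <- function(v, k, floor) {
  med <- stats::median(v)
  thr <- k * max(stats::mad(v), floor)
  abs(v - med) > thr
}

.skewness <- function(x) e1071::skewness(x, type = 2)

.cleanOneFile <- function(X, tvals, method, p) {
  n <- nrow(X)
  ord <- order(tvals)
  bins <- .timeBins(n)
  B <- max(bins)
  binIdx <- split(ord, bins)
  removeBins <- switch(method,
    FAI = {
      span <- vapply(binIdx, function(i) max(diff(range(tvals[i])), 1e-9),
                     numeric(1))
      rate <- lengths(binIdx) / span
      sdC <- apply(X, 2L, stats::sd)
      med <- vapply(binIdx, function(i)
        apply(X[i, , drop = FALSE], 2L, stats::median), numeric(ncol(X)))
      med <- matrix(med, ncol = B)               # channels x bins
      flag <- rep(FALSE, B)
      for (pass in seq_len(p$passes)) {
        ref <- which(!flag)
        if (length(ref) < 3L) break
        ## floors absorb the sampling noise of equal-count bins: rates
        ## fluctuate by ~1/sqrt(bin size), medians by ~sd/sqrt(bin size)
        fr <- .robustFlagRef(rate, ref, p$k,
                             0.5 * abs(stats::median(rate[ref])) + 1e-12)
        ## 0.4 sd floor: bin medians of multimodal mixtures hop between
        ## modes, which is not an acquisition anomaly
        fm <- rep(FALSE, B)
        for (cc in seq_len(nrow(med)))
          fm <- fm | .robustFlagRef(med[cc, ], ref, p$k,
                                    0.4 * sdC[cc] + 1e-12)
        flag <- fr | fm
      }
      which(flag)
    },
    FCL = {
      med <- t(vapply(binIdx, function(i)
        apply(X[i, , drop = FALSE], 2L, stats::median), numeric(ncol(X))))
      med <- matrix(med, nrow = B)
      P <- med - min(med) + 1
      L <- log(P)
      clr <- L - rowMeans(L)
      ## per-channel robust z on the clr profile; the 0.3 log-unit floor
      ## (~35% relative shift of a bin's median composition) absorbs the
      ## sampling noise of equal-count bins
      Z <- vapply(seq_len(ncol(clr)), function(cc) {
        v <- clr[, cc]
        (v - stats::median(v)) / max(stats::mad(v), 0.3)
      }, numeric(B))
      dev <- rowSums(matrix(Z, nrow = B)^2)
      thr <- (p$k / 3) * stats::qchisq(0.999, df = ncol(clr))
      which(dev > thr)
    },
    FCU = {
      statFun <- function(i) {
        xs <- X[i, , drop = FALSE]
        as.numeric(apply(xs, 2L, function(v)
          c(mean(v), stats::median(v),
            stats::quantile(v, c(0.05, 0.2, 0.8, 0.95), names = FALSE),
            stats::var(v), .skewness(v))))
      }
      S <- t(vapply(binIdx, statFun, numeric(8L * ncol(X))))
      S[!is.finite(S)] <- 0
      ## per-column deviation floors tied to each channel's scale so that
      ## plain sampling noise of the bin statistics never drives removals:
      ## central location statistics get 0.25 sd(channel); the 5th/95th
      ## percentiles, variance and skewness are far noisier for small
      ## skewed bins and get proportionally larger floors
      sdC <- apply(X, 2L, stats::sd)
      floors <- as.numeric(vapply(seq_len(ncol(X)), function(cc)
        c(0.25 * sdC[cc], 0.25 * sdC[cc], 0.75 * sdC[cc], 0.25 * sdC[cc],
          0.25 * sdC[cc], 0.75 * sdC[cc],
          stats::median(S[, (cc - 1L) * 8L + 7L]) + 1e-12, 1),
        numeric(8L)))
      alive <- rep(TRUE, B)
      removed <- integer()
      maxRemove <- floor(p$max_removed_fraction * B)
      repeat {
        idx <- which(alive)
        if (length(idx) < 4L) break
        Z <- vapply(seq_len(ncol(S)), function(j) {
          s <- S[idx, j]
          den <- max(stats::mad(s), floors[j], 1e-12)
          abs(s - stats::median(s)) / den
        }, numeric(length(idx)))
        Z <- matrix(Z, nrow = length(idx))
        score <- apply(Z, 1L, max)
        if (max(score) <= p$threshold) break
        if (length(removed) >= maxRemove)
          stop("signal clean would exceed max_removed_fraction (",
               p$max_removed_fraction, "); review FCU parameters")
        worst <- idx[which.max(score)]
        alive[worst] <- FALSE
        removed <- c(removed, worst)
      }
      removed
    },
    stop("unknown signal-clean method: ", method)
  )
  removedEvents <- unlist(binIdx[removeBins], use.names = FALSE)
  mask <- rep(FALSE, n)
  mask[removedEvents] <- TRUE
  mask
}

## robust flag with reference bins defining centre and scale
.robustFlagRef <- function(v, ref, k, floor) {
  med <- stats::median(v[ref])
  thr <- k * max(stats::mad(v[ref]), floor)
  abs(v - med) > thr
}

#' Remove acquisition-time signal anomalies
#'
#' Operates per file: events are binned by acquisition time into equal-count
#' bins (\code{B = max(10, n/500)}). \code{FAI} flags bins whose event rate or
#' per-channel median deviates more than \code{k} MADs (default 3, two-pass)
#' from the file median; \code{FCL} flags bins whose centred-log-ratio
#' population profile deviates beyond a changepoint threshold; \code{FCU}
#' iteratively removes the worst-deviating bin over eight per-bin summary
#' statistics (mean, median, 5th/20th/80th/95th percentiles, variance,
#' skewness) until the maximum deviation falls below threshold. Retained
#' events are bit-identical to the input; the removal mask aligns to the
#' original event order.
#'
#' @param data a \code{CytoSet} whose every sample has a time channel.
#' @param method signal-clean method ID or \code{"NON"}.
#' @param params parameter overrides.
#' @return a list with elements \code{data} (event-subset \code{CytoSet}) and
#'   \code{mask} (logical, \code{TRUE} = removed, original event order).
#' @export
cleanSignal <- function(data, method, params = list()) {
  stopifnot(is(data, "CytoSet"))
  if (method == "NON")
    return(list(data = data, mask = rep(FALSE, nrow(data@exprs))))
  if (!method %in% c("FAI", "FCL", "FCU"))
    stop("unknown signal-clean method: ", method)
  if (is.na(data@timeChannel))
    stop("signal cleaning requires a Time channel, which is missing")
  reg <- defaultRegistry()
  p <- utils::modifyList(reg$params[[match(method, reg$id)]], params)
  if (is.null(p$max_removed_fraction)) p$max_removed_fraction <- 0.5
  ch <- analysisChannels(data)
  mask <- rep(FALSE, nrow(data@exprs))
  for (s in seq_along(data@sampleIDs)) {
    rows <- which(data@origin == s)
    m <- .cleanOneFile(data@exprs[rows, ch, drop = FALSE],
                       data@exprs[rows, data@timeChannel], method, p)
    if (mean(m) > p$max_removed_fraction)
      stop("signal clean would exceed max_removed_fraction (",
           p$max_removed_fraction, ") for sample ", data@sampleIDs[s],
           "; review parameters")
    mask[rows] <- m
  }
  out <- data
  out@exprs <- data@exprs[!mask, , drop = FALSE]
  out@origin <- data@origin[!mask]
  list(data = out, mask = mask)
}

## ---- workflow execution ---------------------------------------------------

#' Run a four-step preprocessing workflow
#'
#' Applies the workflow strictly in the order compensation, transformation,
#' normalization, signal clean, and records a four-entry provenance log.
#' \code{"NON+NON+NON+NON"} is the identity on values. Deterministic for a
#' fixed seed.
#'
#' @param data a \code{CytoSet}.
#' @param spec a \code{WorkflowSpec} or workflow string.
#' @param spill spillover matrix (required by non-NON compensation).
#' @param controls single-stain controls for \code{ATS}.
#' @param params named list of per-method parameter overrides, keyed by
#'   method ID.
#' @param seed integer seed.
#' @param registry method registry.
#' @return a \code{ProcessedCytoSet}.
#' @export
runWorkflow <- function(data, spec, spill = NULL, controls = NULL,
                        params = list(), seed = 1L,
                        registry = defaultRegistry()) {
  stopifnot(is(data, "CytoSet"))
  if (is.character(spec)) spec <- parseWorkflow(spec, registry)
  ok <- validateWorkflow(spec, data@technique, registry)
  if (!ok)
    stop("workflow ", formatWorkflow(spec), " invalid for technique ",
         data@technique, ": ", paste(attr(ok, "reasons"), collapse = "; "))
  ids <- c(spec@compensation, spec@transformation, spec@normalization,
           spec@signalClean)
  log <- vector("list", 4L)
  mask <- rep(FALSE, nrow(data@exprs))
  cur <- data
  for (j in seq_len(4L)) {
    nIn <- nrow(cur@exprs)
    pj <- if (!is.null(params[[ids[j]]])) params[[ids[j]]] else list()
    warns <- character()
    cur <- withCallingHandlers(
      tryCatch(
        switch(.STEPS[j],
          compensation  = compensateCells(cur, ids[j], spill, controls),
          transformation = transformCells(cur, ids[j], pj, seed = seed),
          normalization = normalizeCells(cur, ids[j], pj),
          signal_clean  = {
            res <- cleanSignal(cur, ids[j], pj)
            mask <- res$mask
            res$data
          }),
        error = function(e)
          stop("step ", .STEPS[j], " (", ids[j], "): ",
               conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    log[[j]] <- list(step = .STEPS[j], method = ids[j], params = pj,
                     eventsIn = nIn, eventsOut = nrow(cur@exprs),
                     warnings = warns)
  }
  new("ProcessedCytoSet", cur, removedMask = mask, log = log)
}
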