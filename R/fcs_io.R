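## FCS 3.0/3.1 input/output, metadata parsing, downsampling, merging and
## marker selection. List-mode data only; the (rarely used) analysis segment
## is ignored.

.MC_CYT_PATTERNS <- c("cytof", "helios", "hyperion", "xt")

names2 <- function(x) if (is.null(names(x))) rep("", length(x)) else names(x)

#' Construct a CytoFrame from a matrix
#'
#' Convenience constructor used by the synthetic generators and tests.
#'
#' @param exprs numeric events-by-channels matrix with channel colnames.
#' @param sampleID sample base name.
#' @param technique \code{"FC"} or \code{"MC"}.
#' @param markers marker names (default: channel names).
#' @param timeChannel name of the acquisition-time channel, or \code{NA};
#'   by default the first channel whose name case-insensitively equals
#'   \code{"Time"}.
#' @param keywords named list of extra FCS keywords.
#' @return a \code{CytoFrame}.
#' @export
CytoFrame <- function(exprs, sampleID = "sample", technique = c("FC", "MC"),
                      markers = NULL, timeChannel = NULL, keywords = list()) {
  technique <- match.arg(technique)
  if (is.null(colnames(exprs)))
    colnames(exprs) <- paste0("Ch", seq_len(ncol(exprs)))
  if (is.null(markers)) markers <- colnames(exprs)
  if (is.null(timeChannel)) {
    hit <- which(tolower(colnames(exprs)) == "time")
    timeChannel <- if (length(hit)) colnames(exprs)[hit[1L]] else NA_character_
  }
  new("CytoFrame", sampleID = sampleID, technique = technique,
      exprs = exprs, markers = trimws(markers),
      timeChannel = timeChannel, keywords = keywords)
}

## ---- low-level FCS parsing -----------------------------------------------

.parseFCSText <- function(raw) {
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  delim <- substr(txt, 1L, 1L)
  if (!nzchar(delim)) stop("FCS parse error: empty text segment")
  body <- substring(txt, 2L)
  ## drop a trailing delimiter, then split; doubled delimiters (escapes) are
  ## not expected in the supported dialects
  if (endsWith(body, delim)) body <- substr(body, 1L, nchar(body) - 1L)
  parts <- strsplit(body, delim, fixed = TRUE)[[1L]]
  if (length(parts) %% 2L != 0L)
    stop("FCS parse error: odd number of text-segment tokens")
  keys <- parts[seq(1L, length(parts), 2L)]
  vals <- parts[seq(2L, length(parts), 2L)]
  stats::setNames(as.list(vals), trimws(keys))
}

.fcsKeyword <- function(kw, name, required = TRUE) {
  hit <- which(toupper(names(kw)) == toupper(name))
  if (!length(hit)) {
    if (required) stop("FCS parse error: missing required keyword ", name)
    return(NULL)
  }
  kw[[hit[1L]]]
}

#' Read an FCS file
#'
#' Supports FCS 2.0/3.0/3.1 list-mode files with integer (\code{$DATATYPE I}),
#' float (\code{F}) or double (\code{D}) data. Marker names are taken from
#' \code{$PnS}, falling back to \code{$PnN}; the analytical technique is
#' inferred from the \code{$CYT} keyword when present, otherwise it must be
#' supplied.
#'
#' @param path path to the FCS file.
#' @param technique optional \code{"FC"} or \code{"MC"} override/fallback.
#' @return a \code{CytoFrame}.
#' @export
readFCS <- function(path, technique = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS2.0", "FCS3.0", "FCS3.1"))
    stop("FCS parse error: unsupported version '", version, "'")
  ## six 8-byte ASCII offset fields at bytes 11-58
  offs <- suppressWarnings(as.integer(trimws(
    substring(header, 11L + 8L * (0:5), 18L + 8L * (0:5)))))
  if (any(is.na(offs[1:2])))
    stop("FCS parse error: malformed header segment offsets (TEXT)")
  textBeg <- offs[1L]; textEnd <- offs[2L]
  seek(con, textBeg)
  kw <- .parseFCSText(readBin(con, "raw", textEnd - textBeg + 1L))

  nPar <- as.integer(.fcsKeyword(kw, "$PAR"))
  nTot <- as.integer(.fcsKeyword(kw, "$TOT"))
  if (is.na(nPar) || is.na(nTot))
    stop("FCS parse error: malformed $PAR/$TOT")
  if (nTot == 0L) stop("empty-data error: FCS file contains zero events")
  mode <- .fcsKeyword(kw, "$MODE")
  if (!identical(toupper(mode), "L"))
    stop("FCS parse error: only list mode ($MODE L) is supported, got ", mode)

  dataBeg <- offs[3L]; dataEnd <- offs[4L]
  if (is.na(dataBeg) || dataBeg == 0L) {
    dataBeg <- as.integer(.fcsKeyword(kw, "$BEGINDATA"))
    dataEnd <- as.integer(.fcsKeyword(kw, "$ENDDATA"))
  }
  if (is.na(dataBeg) || is.na(dataEnd) || dataEnd < dataBeg)
    stop("FCS parse error: malformed data segment offsets ($BEGINDATA/$ENDDATA)")

  dtype <- toupper(.fcsKeyword(kw, "$DATATYPE"))
  byteord <- .fcsKeyword(kw, "$BYTEORD")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  bits <- vapply(seq_len(nPar), function(i)
    as.integer(.fcsKeyword(kw, paste0("$P", i, "B"))), integer(1))

  nVal <- nPar * nTot
  seek(con, dataBeg)
  avail <- dataEnd - dataBeg + 1L
  vals <- switch(dtype,
    "F" = {
      if (avail < 4L * nVal)
        stop("FCS parse error: data segment truncated (expected ",
             4L * nVal, " bytes for $TOT x $PAR, found ", avail, ")")
      readBin(con, "numeric", n = nVal, size = 4L, endian = endian)
    },
    "D" = {
      if (avail < 8L * nVal)
        stop("FCS parse error: data segment truncated for $DATATYPE D")
      readBin(con, "numeric", n = nVal, size = 8L, endian = endian)
    },
    "I" = {
      if (length(unique(bits)) != 1L || !unique(bits) %in% c(16L, 32L))
        stop("FCS parse error: integer data requires uniform $PnB of 16 or 32")
      sz <- unique(bits) / 8L
      if (avail < sz * nVal)
        stop("FCS parse error: data segment truncated for $DATATYPE I")
      as.numeric(readBin(con, "integer", n = nVal, size = sz,
                         signed = sz == 4L, endian = endian))
    },
    stop("FCS parse error: unsupported $DATATYPE ", dtype)
  )
  if (length(vals) < nVal)
    stop("FCS parse error: data segment truncated mid event (read ",
         length(vals), " of ", nVal, " values)")
  m <- matrix(vals, nrow = nTot, ncol = nPar, byrow = TRUE)

  chans <- vapply(seq_len(nPar), function(i)
    trimws(.fcsKeyword(kw, paste0("$P", i, "N"))), character(1))
  marks <- vapply(seq_len(nPar), function(i) {
    s <- .fcsKeyword(kw, paste0("$P", i, "S"), required = FALSE)
    if (is.null(s) || !nzchar(trimws(s))) trimws(chans[i]) else trimws(s)
  }, character(1))
  colnames(m) <- chans

  cyt <- .fcsKeyword(kw, "$CYT", required = FALSE)
  tech <- if (!is.null(cyt) &&
              any(vapply(.MC_CYT_PATTERNS, grepl, logical(1),
                         x = tolower(cyt), fixed = TRUE))) "MC"
          else if (!is.null(cyt)) "FC"
          else if (!is.null(technique)) match.arg(technique, c("FC", "MC"))
          else stop("technique could not be inferred from $CYT; ",
                    "pass technique = 'FC' or 'MC'")
  if (!is.null(technique)) tech <- match.arg(technique, c("FC", "MC"))

  hit <- which(tolower(chans) == "time")
  CytoFrame(m, sampleID = sub("\\.[Ff][Cc][Ss]$", "", basename(path)),
            technique = tech, markers = marks,
            timeChannel = if (length(hit)) chans[hit[1L]] else NA_character_,
            keywords = kw)
}

#' Write a CytoFrame as an FCS 3.1 file
#'
#' Writes single-precision float list-mode data (\code{$DATATYPE F},
#' little-endian) preserving channel names, marker names and user keywords.
#'
#' @param frame a non-empty \code{CytoFrame}.
#' @param path output file path.
#' @return the output path, invisibly.
#' @export
writeFCS <- function(frame, path) {
  stopifnot(is(frame, "CytoFrame"))
  m <- frame@exprs
  if (nrow(m) == 0L) stop("cannot write an empty CytoFrame")
  nPar <- ncol(m); nTot <- nrow(m)
  delim <- "/"
  esc <- function(x) gsub(delim, paste0(delim, delim), x, fixed = TRUE)

  kv <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(nPar), "$TOT" = as.character(nTot)
  )
  rng <- pmax(1, ceiling(apply(m, 2L, function(x) max(abs(x), 1))))
  for (i in seq_len(nPar)) {
    kv[paste0("$P", i, "N")] <- colnames(m)[i]
    kv[paste0("$P", i, "B")] <- "32"
    kv[paste0("$P", i, "E")] <- "0,0"
    kv[paste0("$P", i, "R")] <- as.character(rng[i])
    if (frame@markers[i] != colnames(m)[i])
      kv[paste0("$P", i, "S")] <- frame@markers[i]
  }
  if (is.null(frame@keywords[["$CYT"]]))
    kv["$CYT"] <- if (frame@technique == "MC") "CyTOF" else "FACS"
  extra <- frame@keywords[!startsWith(names2(frame@keywords), "$")]
  for (k in names(extra)) kv[k] <- as.character(extra[[k]])

  buildText <- function(begData, endData) {
    all <- c(kv, "$BEGINDATA" = sprintf("%010d", begData),
             "$ENDDATA" = sprintf("%010d", endData))
    paste0(delim,
           paste0(esc(names(all)), delim, esc(unname(all)), delim,
                  collapse = ""))
  }
  textBeg <- 58L
  tmp <- charToRaw(enc2utf8(buildText(0L, 0L)))
  textLen <- length(tmp)                       # byte length is offset-stable
  dataBeg <- textBeg + textLen
  dataEnd <- dataBeg + 4L * nPar * nTot - 1L
  textRaw <- charToRaw(enc2utf8(buildText(dataBeg, dataEnd)))
  stopifnot(length(textRaw) == textLen)

  hdr <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                 textBeg, textBeg + textLen - 1L,
                 if (dataEnd <= 99999999L) dataBeg else 0L,
                 if (dataEnd <= 99999999L) dataEnd else 0L,
                 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  writeBin(textRaw, con)
  writeBin(as.vector(t(m)), con, size = 4L, endian = "little")
  invisible(path)
}

## ---- metadata -------------------------------------------------------------

#' Read study metadata (sample annotation)
#'
#' The metadata is a two-column CSV with a header row named verbatim
#' \code{"filename","condition"} for CSI studies or
#' \code{"filename","timepoint"} for PTI studies. CSI conditions need at least
#' two samples each; PTI needs at least two distinct time points. PTI labels
#' are ordered by their stated collection time when numeric (e.g. days
#' \code{0,2,4,...} or negative baselines), otherwise by order of appearance.
#'
#' @param path metadata CSV path.
#' @param studyKind \code{"CSI"} or \code{"PTI"}.
#' @return a \code{SampleAnnotation}.
#' @export
readMetadata <- function(path, studyKind = c("CSI", "PTI")) {
  studyKind <- match.arg(studyKind)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", strip.white = TRUE)
  expected <- c("filename", if (studyKind == "CSI") "condition" else "timepoint")
  if (ncol(df) != 2L || !identical(names(df), expected))
    stop("metadata schema error: expected header \"",
         paste(expected, collapse = "\",\""), "\" but found \"",
         paste(names(df), collapse = "\",\""), "\"")
  entries <- data.frame(filename = df[[1L]], label = df[[2L]],
                        stringsAsFactors = FALSE)
  if (anyDuplicated(entries$filename))
    stop("metadata error: duplicated filenames")
  if (studyKind == "CSI") {
    tab <- table(entries$label)
    if (any(tab < 2L))
      stop("metadata cardinality error: at least two samples for each ",
           "condition are required (violated by: ",
           paste(names(tab)[tab < 2L], collapse = ", "), ")")
    labelOrder <- unique(entries$label)
  } else {
    labs <- unique(entries$label)
    if (length(labs) < 2L)
      stop("metadata cardinality error: samples collected from at least ",
           "two time points are required")
    num <- suppressWarnings(as.numeric(labs))
    labelOrder <- if (!anyNA(num)) labs[order(num)] else labs
  }
  new("SampleAnnotation", studyKind = studyKind, entries = entries,
      labelOrder = labelOrder)
}

#' Ordinal time index of each sample's label (PTI)
#'
#' @param annotation a PTI \code{SampleAnnotation}.
#' @return named integer vector over sample filenames (1 = earliest).
#' @export
timepointRank <- function(annotation) {
  stopifnot(is(annotation, "SampleAnnotation"))
  stats::setNames(match(annotation@entries$label, annotation@labelOrder),
                  annotation@entries$filename)
}

## ---- downsampling ---------------------------------------------------------

#' Downsample a CytoFrame
#'
#' Samples without replacement; values are never modified. Strategies:
#' \code{uniform_random} (every event equally likely),
#' \code{density_preserving} (inclusion probability inversely proportional to
#' a nearest-neighbour density estimate, balancing dense and sparse regions)
#' and \code{take_first} (earliest events in file order).
#'
#' @param frame a \code{CytoFrame}.
#' @param n target number of events (all retained if fewer are available).
#' @param strategy sampling strategy.
#' @param seed integer seed; identical seed and strategy give identical
#'   selections.
#' @return a \code{CytoFrame} with \code{min(n, available)} events.
#' @export
downsampleEvents <- function(frame, n,
                             strategy = c("uniform_random",
                                          "density_preserving", "take_first"),
                             seed = 1L) {
  stopifnot(is(frame, "CytoFrame"))
  strategy <- match.arg(strategy)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("argument error: n must be a positive count")
  nAvail <- nrow(frame@exprs)
  n <- min(as.integer(n), nAvail)
  idx <- withSeed(seed, {
    switch(strategy,
      take_first = seq_len(n),
      uniform_random = sort(sample.int(nAvail, n)),
      density_preserving = {
        ch <- setdiff(colnames(frame@exprs),
                      if (is.na(frame@timeChannel)) character()
                      else frame@timeChannel)
        x <- scale(frame@exprs[, ch, drop = FALSE])
        x[is.na(x)] <- 0
        ref <- x[sample.int(nAvail, min(500L, nAvail)), , drop = FALSE]
        ## distance to ~10th nearest reference point as inverse-density proxy
        kth <- pmin(10L, nrow(ref) - 1L)
        d <- apply(x, 1L, function(ev)
          sort(sqrt(colSums((t(ref) - ev)^2)))[kth + 1L])
        w <- d / sum(d)
        sort(sample.int(nAvail, n, prob = w))
      })
  })
  new("CytoFrame", sampleID = frame@sampleID, technique = frame@technique,
      exprs = frame@exprs[idx, , drop = FALSE], markers = frame@markers,
      timeChannel = frame@timeChannel, keywords = frame@keywords)
}

## ---- merging and marker selection ----------------------------------------

#' Merge annotated samples into one CytoSet
#'
#' Each frame is downsampled to the same per-file event count (the correction
#' for imbalance in cell composition across files) and pooled; a per-event
#' origin index records the source sample.
#'
#' @param frames list of \code{CytoFrame}s (names ignored; matched to the
#'   annotation by \code{sampleID}).
#' @param annotation a \code{SampleAnnotation} whose filenames match the
#'   frames' sample IDs.
#' @param perFileN events retained per file.
#' @param strategy downsampling strategy (see \code{\link{downsampleEvents}}).
#' @param seed integer seed.
#' @return a \code{CytoSet}; all markers selected initially.
#' @export
mergeSamples <- function(frames, annotation, perFileN = 2000L,
                         strategy = "uniform_random", seed = 1L) {
  stopifnot(is(annotation, "SampleAnnotation"))
  ids <- vapply(frames, function(f) f@sampleID, character(1))
  missing <- setdiff(annotation@entries$filename, ids)
  if (length(missing))
    stop("merge error: no frame supplied for annotated filename(s): ",
         paste(missing, collapse = ", "))
  frames <- frames[match(annotation@entries$filename, ids)]
  techs <- unique(vapply(frames, function(f) f@technique, character(1)))
  if (length(techs) != 1L)
    stop("technique-mismatch error: frames mix ", paste(techs, collapse = "/"))

  common <- Reduce(intersect, lapply(frames, function(f) colnames(f@exprs)))
  if (!length(common)) stop("merge error: frames share no channels")
  common <- colnames(frames[[1L]]@exprs)[colnames(frames[[1L]]@exprs) %in% common]

  down <- lapply(seq_along(frames), function(i)
    downsampleEvents(frames[[i]], perFileN, strategy, seed = seed + i))
  mats <- lapply(down, function(f) f@exprs[, common, drop = FALSE])
  pooled <- do.call(rbind, mats)
  org <- rep.int(seq_along(frames), vapply(mats, nrow, integer(1)))

  mk <- frames[[1L]]@markers[match(common, colnames(frames[[1L]]@exprs))]
  tc <- frames[[1L]]@timeChannel
  if (!is.na(tc) && !tc %in% common) tc <- NA_character_
  sel <- if (is.na(tc)) mk else mk[common != tc]
  new("CytoSet", exprs = pooled, markers = mk, origin = as.integer(org),
      sampleIDs = annotation@entries$filename, annotation = annotation,
      technique = techs, timeChannel = tc, selectedMarkers = sel)
}

#' Select analysis markers
#'
#' Restricts the set to the requested markers. The acquisition-time channel is
#' always retained internally so signal cleaning remains possible.
#'
#' @param data a \code{CytoSet}.
#' @param markers character vector of marker names to keep.
#' @return a column-filtered \code{CytoSet}.
#' @export
selectMarkers <- function(data, markers) {
  stopifnot(is(data, "CytoSet"))
  unknown <- setdiff(markers, data@markers)
  if (length(unknown))
    stop("unknown marker(s): ", paste(unknown, collapse = ", "))
  ch <- colnames(data@exprs)
  keep <- data@markers %in% markers
  if (!is.na(data@timeChannel)) keep <- keep | ch == data@timeChannel
  out <- data
  out@exprs <- data@exprs[, keep, drop = FALSE]
  out@markers <- data@markers[keep]
  out@selectedMarkers <- markers
  validObject(out)
  out
}

## ---- seed plumbing --------------------------------------------------------

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded internals never perturb
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
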