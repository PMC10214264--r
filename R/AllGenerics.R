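#' Accessors for cytometry containers
#'
#' Standard accessors for \code{CytoFrame}, \code{CytoSet} and
#' \code{ProcessedCytoSet} objects: the expression matrix, channel names,
#' marker names, analytical technique, per-event sample origin, study
#' annotation, selected analysis markers, the signal-cleaning removal mask and
#' the processing log.
#'
#' @param object a cytometry container.
#' @return \code{exprs}: numeric matrix; \code{channels}, \code{markers},
#'   \code{selectedMarkers}: character vectors; \code{technique}:
#'   character(1); \code{origin}: integer vector; \code{annotation}:
#'   \code{SampleAnnotation}; \code{removedEvents}: logical vector;
#'   \code{processingLog}: list.
#' @name accessors
#' @aliases exprs channels markers technique origin annotation
#'   selectedMarkers removedEvents processingLog sampleNames
NULL

#' @rdname accessors
#' @export
setGeneric("exprs", function(object) standardGeneric("exprs"))

#' @rdname accessors
#' @export
setGeneric("channels", function(object) standardGeneric("channels"))

#' @rdname accessors
#' @export
setGeneric("markers", function(object) standardGeneric("markers"))

#' @rdname accessors
#' @export
setGeneric("technique", function(object) standardGeneric("technique"))

#' @rdname accessors
#' @export
setGeneric("origin", function(object) standardGeneric("origin"))

#' @rdname accessors
#' @export
setGeneric("annotation", function(object) standardGeneric("annotation"))

#' @rdname accessors
#' @export
setGeneric("selectedMarkers", function(object) standardGeneric("selectedMarkers"))

#' @rdname accessors
#' @export
setGeneric("removedEvents", function(object) standardGeneric("removedEvents"))

#' @rdname accessors
#' @export
setGeneric("processingLog", function(object) standardGeneric("processingLog"))

#' @rdname accessors
#' @export
setGeneric("sampleNames", function(object) standardGeneric("sampleNames"))

#' @rdname accessors
#' @export
setGeneric("pseudotime", function(object) standardGeneric("pseudotime"))

## ---- methods --------------------------------------------------------------

#' @rdname accessors
setMethod("exprs", "CytoFrame", function(object) object@exprs)
#' @rdname accessors
setMethod("exprs", "CytoSet", function(object) object@exprs)

#' @rdname accessors
setMethod("channels", "CytoFrame", function(object) colnames(object@exprs))
#' @rdname accessors
setMethod("channels", "CytoSet", function(object) colnames(object@exprs))

#' @rdname accessors
setMethod("markers", "CytoFrame", function(object) object@markers)
#' @rdname accessors
setMethod("markers", "CytoSet", function(object) object@markers)

#' @rdname accessors
setMethod("technique", "CytoFrame", function(object) object@technique)
#' @rdname accessors
setMethod("technique", "CytoSet", function(object) object@technique)

#' @rdname accessors
setMethod("origin", "CytoSet", function(object) object@origin)

#' @rdname accessors
setMethod("annotation", "CytoSet", function(object) object@annotation)

#' @rdname accessors
setMethod("selectedMarkers", "CytoSet", function(object) object@selectedMarkers)

#' @rdname accessors
setMethod("removedEvents", "ProcessedCytoSet", function(object) object@removedMask)

#' @rdname accessors
setMethod("processingLog", "ProcessedCytoSet", function(object) object@log)

#' @rdname accessors
setMethod("sampleNames", "CytoSet", function(object) object@sampleIDs)

#' @rdname accessors
setMethod("pseudotime", "Pseudotime", function(object) object@t)

#' Columns of the expression matrix used for analysis
#'
#' Returns the channel names whose markers are currently selected, excluding
#' the acquisition-time channel. These are the columns the preprocessing
#' methods and assessment criteria operate on.
#'
#' @param object a \code{CytoSet}.
#' @return character vector of channel names.
#' @export
analysisChannels <- function(object) {
  stopifnot(is(object, "CytoSet"))
  ch <- colnames(object@exprs)
  keep <- object@markers %in% object@selectedMarkers
  if (!is.na(object@timeChannel)) keep <- keep & ch != object@timeChannel
  ch[keep]
}

#' Expression submatrix of the selected analysis markers
#'
#' @param object a \code{CytoSet}.
#' @return numeric matrix with marker names as column names.
#' @export
analysisMatrix <- function(object) {
  ch <- analysisChannels(object)
  m <- object@exprs[, ch, drop = FALSE]
  colnames(m) <- object@markers[match(ch, colnames(object@exprs))]
  m
}
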