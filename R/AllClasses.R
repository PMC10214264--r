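#' @import methods
NULL

#' Per-sample cytometry expression frame
#'
#' A \code{CytoFrame} holds one sample's events-by-channels intensity matrix
#' together with channel and marker annotation, the acquisition-time channel
#' (when present) and the keyword/value pairs of the originating FCS text
#' segment.
#'
#' @slot sampleID character(1), base name of the sample (FCS file name without
#'   extension).
#' @slot technique character(1), \code{"FC"} (flow cytometry) or \code{"MC"}
#'   (mass cytometry / CyTOF).
#' @slot exprs numeric matrix, rows = events, columns = channels; column names
#'   are the channel names.
#' @slot markers character vector, one marker name per channel (falls back to
#'   the channel name where no stain annotation exists).
#' @slot timeChannel character(1) or \code{NA_character_}; name of the channel
#'   recording acquisition time.
#' @slot keywords named list of character keyword values.
#'
#' @exportClass CytoFrame
setClass("CytoFrame",
  representation(
    sampleID    = "character",
    technique   = "character",
    exprs       = "matrix",
    markers     = "character",
    timeChannel = "character",
    keywords    = "list"
  )
)

setValidity("CytoFrame", function(object) {
  msg <- character()
  if (length(object@technique) != 1L || !object@technique %in% c("FC", "MC"))
    msg <- c(msg, "technique must be one of 'FC', 'MC'")
  if (length(object@markers) != ncol(object@exprs))
    msg <- c(msg, "number of marker entries must equal number of channels")
  if (is.null(colnames(object@exprs)))
    msg <- c(msg, "expression matrix must carry channel names as colnames")
  if (nrow(object@exprs) < 1L)
    msg <- c(msg, "expression matrix must contain at least one event")
  if (!is.na(object@timeChannel) &&
      !object@timeChannel %in% colnames(object@exprs))
    msg <- c(msg, "timeChannel not found among channels")
  if (length(msg)) msg else TRUE
})

#' Sample annotation for CSI or PTI studies
#'
#' Maps FCS base names to condition labels (CSI) or collection time points
#' (PTI). CSI studies require at least two samples per condition; PTI studies
#' require at least two distinct time points.
#'
#' @slot studyKind character(1), \code{"CSI"} or \code{"PTI"}.
#' @slot entries data.frame with columns \code{filename} and \code{label}.
#' @slot labelOrder character vector; for PTI the time-point labels in
#'   collection order, for CSI the condition labels in order of appearance.
#'
#' @exportClass SampleAnnotation
setClass("SampleAnnotation",
  representation(
    studyKind  = "character",
    entries    = "data.frame",
    labelOrder = "character"
  )
)

setValidity("SampleAnnotation", function(object) {
  msg <- character()
  if (!object@studyKind %in% c("CSI", "PTI"))
    msg <- c(msg, "studyKind must be 'CSI' or 'PTI'")
  if (!all(c("filename", "label") %in% names(object@entries)))
    msg <- c(msg, "entries must have columns 'filename' and 'label'")
  else {
    if (anyDuplicated(object@entries$filename))
      msg <- c(msg, "filenames must be unique")
    tab <- table(object@entries$label)
    if (object@studyKind == "CSI" && any(tab < 2L))
      msg <- c(msg, "CSI: every condition needs at least two samples")
    if (object@studyKind == "PTI" && length(tab) < 2L)
      msg <- c(msg, "PTI: at least two distinct time points are required")
    if (!setequal(object@labelOrder, unique(object@entries$label)))
      msg <- c(msg, "labelOrder must contain exactly the labels in entries")
  }
  if (length(msg)) msg else TRUE
})

#' Merged multi-sample cytometry data
#'
#' Pooled events from several \code{CytoFrame}s after per-file downsampling,
#' with a per-event origin index, the study annotation and the selected
#' analysis markers. The acquisition-time channel is retained internally
#' (for signal cleaning) independent of marker selection.
#'
#' @slot exprs pooled events-by-channels matrix.
#' @slot markers marker name per column of \code{exprs}.
#' @slot origin integer vector, per-event index into \code{sampleIDs}.
#' @slot sampleIDs character vector of sample base names.
#' @slot annotation \code{SampleAnnotation}.
#' @slot technique \code{"FC"} or \code{"MC"}.
#' @slot timeChannel time channel name or \code{NA_character_}.
#' @slot selectedMarkers markers used for analysis (subset of \code{markers}).
#'
#' @exportClass CytoSet
setClass("CytoSet",
  representation(
    exprs           = "matrix",
    markers         = "character",
    origin          = "integer",
    sampleIDs       = "character",
    annotation      = "SampleAnnotation",
    technique       = "character",
    timeChannel     = "character",
    selectedMarkers = "character"
  )
)

setValidity("CytoSet", function(object) {
  msg <- character()
  if (length(object@origin) != nrow(object@exprs))
    msg <- c(msg, "origin length must equal total event count")
  if (length(object@markers) != ncol(object@exprs))
    msg <- c(msg, "one marker entry per channel required")
  if (length(object@origin) &&
      (min(object@origin) < 1L || max(object@origin) > length(object@sampleIDs)))
    msg <- c(msg, "origin indices out of range")
  if (!all(object@selectedMarkers %in% object@markers))
    msg <- c(msg, "selectedMarkers must be a subset of markers")
  if (length(msg)) msg else TRUE
})

#' Preprocessed cytometry data with provenance
#'
#' A \code{CytoSet} after execution of a four-step preprocessing workflow.
#' Carries the per-original-event removal mask produced by signal cleaning and
#' an ordered log of the four steps.
#'
#' @slot removedMask logical vector over the events of the input
#'   \code{CytoSet}; \code{TRUE} marks events removed by signal cleaning.
#' @slot log list of four entries (one per step) each holding
#'   \code{step}, \code{method}, \code{params}, \code{eventsIn},
#'   \code{eventsOut}.
#'
#' @exportClass ProcessedCytoSet
setClass("ProcessedCytoSet",
  contains = "CytoSet",
  representation(
    removedMask = "logical",
    log         = "list"
  )
)

#' Four-step preprocessing workflow specification
#'
#' Ordered method IDs for compensation, transformation, normalization and
#' signal cleaning; the string form joins the IDs with \code{"+"}, e.g.
#' \code{"ATS+BOX+GSN+NON"}.
#'
#' @slot compensation,transformation,normalization,signalClean character(1)
#'   three-letter method IDs (\code{"NON"} = no method in that step).
#'
#' @exportClass WorkflowSpec
setClass("WorkflowSpec",
  representation(
    compensation   = "character",
    transformation = "character",
    normalization  = "character",
    signalClean    = "character"
  )
)

#' Result of one assessment criterion
#'
#' @slot criterion character(1), one of \code{"Ca"}, \code{"Cb"}, \code{"Cc"},
#'   \code{"Cd"}.
#' @slot value numeric(1) in [0, 1], rounded to three decimal places.
#' @slot category character(1), \code{"superior"}, \code{"good"} or
#'   \code{"poor"} (empty until categorized).
#'
#' @exportClass CriterionResult
setClass("CriterionResult",
  representation(
    criterion = "character",
    value     = "numeric",
    category  = "character"
  )
)

setValidity("CriterionResult", function(object) {
  msg <- character()
  if (!object@criterion %in% c("Ca", "Cb", "Cc", "Cd"))
    msg <- c(msg, "criterion must be one of Ca, Cb, Cc, Cd")
  if (length(object@value) != 1L || is.na(object@value) ||
      object@value < 0 || object@value > 1)
    msg <- c(msg, "value must be a single number in [0, 1]")
  if (abs(object@value - round(object@value, 3)) > .Machine$double.eps * 8)
    msg <- c(msg, "value must be rounded to three decimal places")
  if (length(msg)) msg else TRUE
})

#' Per-event pseudotime along an inferred trajectory
#'
#' @slot t numeric vector in [0, 1] (min 0, max 1 after normalization).
#' @slot root integer(1), index of the cluster centroid chosen as origin.
#' @slot seed integer(1) used for the inference.
#'
#' @exportClass Pseudotime
setClass("Pseudotime",
  representation(
    t    = "numeric",
    root = "integer",
    seed = "integer"
  )
)

setValidity("Pseudotime", function(object) {
  msg <- character()
  if (length(object@t) < 2L)
    msg <- c(msg, "pseudotime needs at least two events")
  else {
    if (abs(min(object@t)) > 1e-12 || abs(max(object@t) - 1) > 1e-12)
      msg <- c(msg, "pseudotime must be min-max normalized to [0, 1]")
    if (diff(range(object@t)) == 0)
      msg <- c(msg, "constant pseudotime is forbidden")
  }
  if (length(msg)) msg else TRUE
})

## ---- show methods ---------------------------------------------------------

setMethod("show", "CytoFrame", function(object) {
  cat("CytoFrame '", object@sampleID, "' (", object@technique, ")\n",
      "  ", nrow(object@exprs), " events x ", ncol(object@exprs),
      " channels\n", sep = "")
  cat("  markers:", paste(utils::head(object@markers, 8), collapse = ", "),
      if (length(object@markers) > 8) "...", "\n")
  if (!is.na(object@timeChannel))
    cat("  time channel:", object@timeChannel, "\n")
})

setMethod("show", "SampleAnnotation", function(object) {
  cat("SampleAnnotation (", object@studyKind, "): ",
      nrow(object@entries), " samples, ",
      length(object@labelOrder), " ",
      if (object@studyKind == "CSI") "conditions" else "time points",
      "\n", sep = "")
})

setMethod("show", "CytoSet", function(object) {
  cat(class(object), ": ", nrow(object@exprs), " events from ",
      length(object@sampleIDs), " samples (", object@technique, ")\n",
      "  channels: ", ncol(object@exprs),
      "; selected markers: ", length(object@selectedMarkers), "\n", sep = "")
})

setMethod("show", "WorkflowSpec", function(object) {
  cat("WorkflowSpec:", formatWorkflow(object), "\n")
})

setMethod("show", "CriterionResult", function(object) {
  cat("Criterion ", object@criterion, ": ",
      formatC(object@value, format = "f", digits = 3),
      if (nzchar(object@category)) paste0(" (", object@category, ")"),
      "\n", sep = "")
})

setMethod("show", "Pseudotime", function(object) {
  cat("Pseudotime over", length(object@t), "events, root centroid",
      object@root, "\n")
})
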