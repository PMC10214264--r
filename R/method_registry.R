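## Registry of the 25 preprocessing methods (three-letter IDs, step,
## FC/MC applicability, default parameters) and workflow string parsing.

.STEPS <- c("compensation", "transformation", "normalization", "signal_clean")

#' The default preprocessing-method registry
#'
#' Returns the 25 methods organized over the four workflow steps:
#' 5 compensations (3 flow-only, 2 mass-only), 14 transformations (all
#' applicable to both techniques), 3 normalizations (1 flow-only, 2 both) and
#' 3 signal cleans (1 mass-only, 2 both). \code{"NON"} is reserved per step as
#' the no-op and is not part of the registry.
#'
#' @return a data.frame with columns \code{id}, \code{step},
#'   \code{applicability} (\code{FC_only}, \code{MC_only} or \code{both}) and
#'   a \code{params} list-column of default parameter lists.
#' @export
defaultRegistry <- function() {
  reg <- rbind(
    data.frame(id = c("ATS", "FLC", "MTC"), step = "compensation",
               applicability = "FC_only"),
    data.frame(id = c("CTS", "CMP"), step = "compensation",
               applicability = "MC_only"),
    data.frame(id = c("ACS", "ANN", "ARN", "BEP", "BOX", "FVS", "HPL",
                      "LGT", "LIN", "LNT", "LOG", "QUA", "SCA", "TRU"),
               step = "transformation", applicability = "both"),
    data.frame(id = "FDN", step = "normalization", applicability = "FC_only"),
    data.frame(id = c("GSN", "WPS"), step = "normalization",
               applicability = "both"),
    data.frame(id = "FCL", step = "signal_clean", applicability = "MC_only"),
    data.frame(id = c("FAI", "FCU"), step = "signal_clean",
               applicability = "both")
  )
  defaults <- list(
    ACS = list(cofactor_fc = 150, cofactor_mc = 5),
    ANN = list(),
    ARN = list(cofactor_fc = 150, cofactor_mc = 5),
    BEP = list(a = 0.5, b = 1, c = 0.5, d = 1, f = 0, tol = 1e-8),
    BOX = list(subsample = 1000L),
    FVS = list(k = 5L, subsample = 2000L),
    HPL = list(T_fc = 100, T_mc = 1),
    LGT = list(T = 262144, W = 0.5, M = 4.5, A = 0, tol = 1e-8),
    LIN = list(upper = 4.5),
    TRU = list(threshold = 1),
    FAI = list(k = 3, passes = 2L),
    FCL = list(k = 3),
    FCU = list(threshold = 4, max_removed_fraction = 0.5),
    GSN = list(max_peaks = 2L),
    WPS = list(anchors = 9L),
    FDN = list(anchors = 9L)
  )
  reg$params <- lapply(reg$id, function(i) {
    p <- defaults[[i]]
    if (is.null(p)) list() else p
  })
  rownames(reg) <- reg$id
  reg
}

.checkRegistry <- function(registry) {
  if (anyDuplicated(registry$id) || "NON" %in% registry$id)
    stop("registry composition error: IDs must be unique and 'NON' reserved")
  counts <- table(factor(registry$step, levels = .STEPS))
  if (!identical(as.integer(counts), c(5L, 14L, 3L, 3L)))
    stop("registry composition error: need 5/14/3/3 methods per step, got ",
         paste(counts, collapse = "/"))
  invisible(registry)
}

#' Look up a registry method
#'
#' @param id three-letter method ID.
#' @param registry registry data.frame (default \code{defaultRegistry()}).
#' @return a one-row data.frame (step, applicability, params).
#' @export
methodInfo <- function(id, registry = defaultRegistry()) {
  if (!id %in% registry$id) stop("unknown method ID: ", id)
  registry[registry$id == id, , drop = FALSE]
}

#' Serialize / deserialize a registry as YAML
#'
#' Allows users to override method parameters in configuration files.
#'
#' @param registry registry data.frame.
#' @param path YAML file path.
#' @return \code{registryToYAML}: the path, invisibly;
#'   \code{registryFromYAML}: a registry data.frame.
#' @export
registryToYAML <- function(registry, path) {
  lst <- lapply(seq_len(nrow(registry)), function(i)
    list(id = registry$id[i], step = registry$step[i],
         applicability = registry$applicability[i],
         params = registry$params[[i]]))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname registryToYAML
#' @export
registryFromYAML <- function(path) {
  lst <- yaml::read_yaml(path)
  reg <- data.frame(
    id = vapply(lst, `[[`, character(1), "id"),
    step = vapply(lst, `[[`, character(1), "step"),
    applicability = vapply(lst, `[[`, character(1), "applicability"))
  reg$params <- lapply(lst, function(e) if (is.null(e$params)) list() else e$params)
  rownames(reg) <- reg$id
  reg
}

## ---- workflow strings -----------------------------------------------------

#' Construct a WorkflowSpec
#'
#' @param compensation,transformation,normalization,signalClean method IDs
#'   (\code{"NON"} for no method).
#' @param registry registry to validate against.
#' @return a \code{WorkflowSpec}.
#' @export
workflowSpec <- function(compensation = "NON", transformation = "NON",
                         normalization = "NON", signalClean = "NON",
                         registry = defaultRegistry()) {
  ids <- c(compensation, transformation, normalization, signalClean)
  for (j in seq_along(ids)) {
    if (ids[j] == "NON") next
    if (!ids[j] %in% registry$id)
      stop("unknown method ID '", ids[j], "' at position ", j)
    step <- registry$step[registry$id == ids[j]]
    if (step != .STEPS[j])
      stop("step-mismatch error: '", ids[j], "' is a ", step,
           " method but appears in the ", .STEPS[j], " slot (position ", j, ")")
  }
  new("WorkflowSpec", compensation = ids[1L], transformation = ids[2L],
      normalization = ids[3L], signalClean = ids[4L])
}

#' Parse a workflow string
#'
#' A workflow string joins four method IDs with \code{"+"} in the fixed step
#' order compensation, transformation, normalization, signal clean (e.g.
#' \code{"ATS+BOX+GSN+NON"}).
#'
#' @param text workflow string.
#' @param registry registry to resolve IDs against.
#' @return a \code{WorkflowSpec}.
#' @export
parseWorkflow <- function(text, registry = defaultRegistry()) {
  toks <- strsplit(trimws(text), "+", fixed = TRUE)[[1L]]
  if (length(toks) != 4L)
    stop("workflow string must have exactly 4 '+'-separated tokens, got '",
         text, "'")
  toks <- trimws(toks)
  workflowSpec(toks[1L], toks[2L], toks[3L], toks[4L], registry = registry)
}

#' Format a WorkflowSpec as its workflow string
#'
#' Inverse of \code{\link{parseWorkflow}}.
#'
#' @param spec a \code{WorkflowSpec}.
#' @return character(1) workflow string.
#' @export
formatWorkflow <- function(spec) {
  stopifnot(is(spec, "WorkflowSpec"))
  paste(spec@compensation, spec@transformation, spec@normalization,
        spec@signalClean, sep = "+")
}
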