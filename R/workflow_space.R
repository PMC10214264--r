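## Enumeration of every workflow valid for a technique (Cartesian product of
## per-step option sets) and applicability validation.

.stepOptions <- function(step, tech, registry) {
  sub <- registry[registry$step == step, , drop = FALSE]
  ok <- switch(tech,
    FC   = sub$applicability %in% c("FC_only", "both"),
    MC   = sub$applicability %in% c("MC_only", "both"),
    both = sub$applicability == "both")
  sort(c("NON", sub$id[ok]))
}

#' Enumerate all workflows applicable to a technique
#'
#' Cartesian product over the per-step option sets (applicable methods plus
#' the no-op \code{"NON"}). Flow cytometry admits 720 workflows, mass
#' cytometry 540, the technique-agnostic intersection 135, and the union
#' 1125. The enumeration is deterministic and lexicographically ordered by
#' workflow string.
#'
#' @param technique \code{"FC"}, \code{"MC"} or \code{"both"} (workflows whose
#'   every non-NON method applies to both techniques).
#' @param registry method registry (must satisfy the 5/14/3/3 composition).
#' @return character vector of workflow strings.
#' @export
enumerateWorkflows <- function(technique = c("FC", "MC", "both"),
                               registry = defaultRegistry()) {
  technique <- match.arg(technique)
  .checkRegistry(registry)
  opts <- lapply(.STEPS, .stepOptions, tech = technique, registry = registry)
  grid <- expand.grid(opts[[4L]], opts[[3L]], opts[[2L]], opts[[1L]],
                      stringsAsFactors = FALSE)
  wf <- paste(grid[[4L]], grid[[3L]], grid[[2L]], grid[[1L]], sep = "+")
  sort(wf)
}

#' Validate a workflow against a technique
#'
#' A workflow is valid iff every non-NON method is applicable to the data's
#' technique (and sits in its correct step slot).
#'
#' @param spec a \code{WorkflowSpec} or workflow string.
#' @param technique \code{"FC"} or \code{"MC"}.
#' @param registry method registry.
#' @return logical(1) with attribute \code{"reasons"} (character vector,
#'   empty when valid).
#' @export
validateWorkflow <- function(spec, technique = c("FC", "MC"),
                             registry = defaultRegistry()) {
  technique <- match.arg(technique)
  if (is.character(spec)) spec <- parseWorkflow(spec, registry)
  ids <- c(spec@compensation, spec@transformation, spec@normalization,
           spec@signalClean)
  reasons <- character()
  for (j in seq_along(ids)) {
    if (ids[j] == "NON") next
    app <- registry$applicability[registry$id == ids[j]]
    bad <- (technique == "FC" && app == "MC_only") ||
           (technique == "MC" && app == "FC_only")
    if (bad)
      reasons <- c(reasons, paste0(ids[j], " is ", app,
                                   " but data technique is ", technique))
  }
  structure(length(reasons) == 0L, reasons = reasons)
}
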