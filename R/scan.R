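## Workflow-space scanning: per-workflow preprocessing + assessment as
## independent, identically-seeded tasks mapped over a process pool, so
## results are invariant to worker count and scheduling order.

## stable per-workflow seed: base seed plus a small hash of the workflow
## string, independent of task order and worker assignment
.workflowSeed <- function(seed, workflow) {
  codes <- utf8ToInt(workflow)
  (as.integer(seed) + sum(codes * seq_along(codes))) %% 1000000L
}

#' Evaluate one workflow end-to-end
#'
#' Runs the preprocessing workflow on the merged data and scores it under the
#' criteria of the study kind: CSI uses Accuracy, Tightness, Robustness and
#' (when a known-marker set is given) Correspondence; PTI uses Conformance,
#' Smoothness, Robustness and (when a pathway hierarchy is given)
#' Correspondence. Criterion values are rounded to three decimals and
#' categorized via the cutoffs.
#'
#' @param data a \code{CytoSet} (merged, markers selected).
#' @param workflow workflow string or \code{WorkflowSpec}.
#' @param studyKind \code{"CSI"} or \code{"PTI"}.
#' @param spill,controls compensation resources (see
#'   \code{\link{runWorkflow}}).
#' @param known CSI known-marker set (optional).
#' @param hierarchy PTI pathway hierarchy (optional).
#' @param k cluster count for CSI (default: 4 x number of conditions).
#' @param reps robustness replicates.
#' @param cutoffs category cutoffs.
#' @param seed integer seed (per-workflow seeds are derived from it).
#' @param params per-method parameter overrides.
#' @return list with \code{workflow}, \code{results} (categorized
#'   \code{CriterionResult}s), \code{events} and \code{seed}.
#' @export
evaluateWorkflow <- function(data, workflow, studyKind = c("CSI", "PTI"),
                             spill = NULL, controls = NULL, known = NULL,
                             hierarchy = NULL, k = NULL, reps = 5L,
                             cutoffs = defaultCutoffs(), seed = 1L,
                             params = list()) {
  studyKind <- match.arg(studyKind)
  wf <- if (is.character(workflow)) workflow else formatWorkflow(workflow)
  wseed <- .workflowSeed(seed, wf)
  ann <- data@annotation
  pd <- runWorkflow(data, wf, spill = spill, controls = controls,
                    params = params, seed = wseed)
  if (studyKind == "CSI") {
    if (is.null(k)) k <- 4L * length(unique(ann@entries$label))
    cl <- clusterCells(pd, k, seed = wseed)
    results <- list(
      criterionAccuracy(pd, cl, ann, seed = wseed),
      criterionTightness(pd, cl, seed = wseed),
      criterionRobustnessCSI(pd, k, seed = wseed, reps = reps),
      criterionCorrespondenceCSI(pd, ann, known))
  } else {
    pt <- inferTrajectory(pd, ann, seed = wseed)
    results <- list(
      criterionConformance(pt, ann, pd@origin, pd@sampleIDs),
      criterionSmoothness(pt, pd, seed = wseed),
      criterionRobustnessPTI(pd, ann, seed = wseed, reps = reps),
      if (!is.null(hierarchy))
        criterionCorrespondencePTI(pt, pd, hierarchy))
  }
  results <- results[!vapply(results, is.null, logical(1))]
  results <- categorizeResults(results, studyKind, cutoffs)
  list(workflow = wf, results = results,
       events = nrow(pd@exprs), seed = wseed)
}

#' Scan a set of workflows in parallel
#'
#' Evaluates every selected workflow as an independent task over a fork-based
#' process pool. Each task derives its seed from the base seed and the
#' workflow string, so the resulting ranking is bit-identical for any number
#' of workers. Per-workflow failures are recorded without aborting the scan.
#'
#' @param data a \code{CytoSet}.
#' @param workflows character vector of workflow strings (default: the full
#'   space for the data's technique).
#' @param studyKind \code{"CSI"} or \code{"PTI"}.
#' @param workers parallel workers (fork-based; 1 = sequential).
#' @param progress print progress to stderr.
#' @param outDir optional directory for per-workflow JSON reports and the
#'   ranking CSVs.
#' @inheritParams evaluateWorkflow
#' @return list with \code{table} (ranking data.frame), \code{reports}
#'   (successful evaluations) and \code{failures} (named character vector of
#'   error messages; invalid-for-technique workflows are recorded as
#'   skipped).
#' @export
scanWorkflows <- function(data, workflows = NULL,
                          studyKind = c("CSI", "PTI"), spill = NULL,
                          controls = NULL, known = NULL, hierarchy = NULL,
                          k = NULL, reps = 5L, cutoffs = defaultCutoffs(),
                          seed = 1L, workers = 1L, progress = FALSE,
                          outDir = NULL, params = list()) {
  studyKind <- match.arg(studyKind)
  if (is.null(workflows)) workflows <- enumerateWorkflows(data@technique)
  if (!length(workflows)) stop("no workflows selected")
  valid <- vapply(workflows, function(w)
    isTRUE(validateWorkflow(w, data@technique)), logical(1))
  failures <- stats::setNames(
    rep("skipped: not applicable to technique", sum(!valid)),
    workflows[!valid])
  workflows <- workflows[valid]
  if (!length(workflows))
    stop("zero valid workflows for technique ", data@technique)

  task <- function(wf) {
    if (progress) message("evaluating ", wf)
    tryCatch({
      t0 <- Sys.time()
      rep <- evaluateWorkflow(data, wf, studyKind, spill = spill,
                              controls = controls, known = known,
                              hierarchy = hierarchy, k = k, reps = reps,
                              cutoffs = cutoffs, seed = seed,
                              params = params)
      rep$duration <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      rep
    }, error = function(e) structure(conditionMessage(e), class = "scanError"))
  }
  res <- if (workers > 1L) {
    parallel::mclapply(workflows, task, mc.cores = workers,
                       mc.preschedule = FALSE)
  } else {
    lapply(workflows, task)
  }
  names(res) <- workflows
  failed <- vapply(res, inherits, logical(1), "scanError")
  failures <- c(failures,
                vapply(res[failed], as.character, character(1)))
  reports <- res[!failed]
  if (!length(reports))
    stop("all workflows failed; diagnostics: ",
         paste(names(failures), unname(failures),
               sep = " -> ", collapse = "; "))
  table <- rankWorkflows(unname(reports))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (rep in reports) writeWorkflowReport(rep, outDir)
    exportResults(table, outDir)
    log <- data.frame(
      workflow = vapply(reports, `[[`, character(1), "workflow"),
      seed = vapply(reports, function(r) r$seed, numeric(1)),
      duration = vapply(reports, function(r) r$duration, numeric(1)))
    utils::write.csv(log, file.path(outDir, "scan_log.csv"),
                     row.names = FALSE)
  }
  list(table = table, reports = reports, failures = failures)
}

#' Write / read a per-workflow JSON report
#'
#' @param report evaluation report from \code{\link{evaluateWorkflow}}.
#' @param outDir report directory.
#' @return \code{writeWorkflowReport}: the path, invisibly.
#' @export
writeWorkflowReport <- function(report, outDir) {
  obj <- list(
    workflow = report$workflow,
    seed = report$seed,
    events = report$events,
    criteria = lapply(report$results, function(r)
      list(criterion = r@criterion, value = r@value, category = r@category)))
  path <- file.path(outDir, paste0(gsub("\\+", "_", report$workflow),
                                   ".json"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeWorkflowReport
#' @param path report JSON path.
#' @export
readWorkflowReport <- function(path) {
  obj <- jsonlite::read_json(path)
  list(workflow = obj$workflow, seed = obj$seed, events = obj$events,
       results = lapply(obj$criteria, function(cc)
         new("CriterionResult", criterion = cc$criterion,
             value = as.numeric(cc$value), category = cc$category)))
}
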