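## Category cutoffs, weighted overall scoring (superior/good/poor =
## 1/0.8/0.1) and the deterministic workflow ranking.

.CATEGORY_WEIGHTS <- c(superior = 1, good = 0.8, poor = 0.1)

#' Default per-criterion category cutoffs
#'
#' Fixed cutoffs per (study kind, criterion): a value is superior at or above
#' the first cutoff, good at or above the second, else poor.
#'
#' @return nested list: \code{cutoffs[[studyKind]][[criterion]]} =
#'   \code{c(superior, good)}.
#' @export
defaultCutoffs <- function() {
  list(
    CSI = list(Ca = c(0.85, 0.71), Cb = c(0.75, 0.62),
               Cc = c(0.30, 0.20), Cd = c(0.90, 0.70)),
    PTI = list(Ca = c(0.75, 0.60), Cb = c(0.98, 0.90),
               Cc = c(0.86, 0.50), Cd = c(0.90, 0.70))
  )
}

#' Cohort-quantile cutoffs
#'
#' Alternative to the fixed defaults: per criterion, the superior/good
#' cutoffs are the 90th/70th percentiles of the evaluated cohort's values.
#'
#' @param values named list mapping criterion ID to the cohort's numeric
#'   values.
#' @param studyKind \code{"CSI"} or \code{"PTI"}.
#' @return cutoffs in the \code{\link{defaultCutoffs}} structure.
#' @export
quantileCutoffs <- function(values, studyKind = c("CSI", "PTI")) {
  studyKind <- match.arg(studyKind)
  out <- list()
  out[[studyKind]] <- lapply(values, function(v)
    unname(stats::quantile(v, c(0.9, 0.7))))
  out
}

#' Read / write cutoffs as YAML
#'
#' @param path YAML path.
#' @return \code{cutoffsFromYAML}: cutoffs list.
#' @export
cutoffsFromYAML <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(sk) lapply(sk, as.numeric))
}

#' @rdname cutoffsFromYAML
#' @param cutoffs cutoffs list.
#' @export
cutoffsToYAML <- function(cutoffs, path) {
  yaml::write_yaml(lapply(cutoffs, function(sk) lapply(sk, as.numeric)), path)
  invisible(path)
}

#' Categorize a criterion value
#'
#' @param value metric value in [0, 1] (rounded to 3 decimals before
#'   comparison).
#' @param criterion criterion ID (\code{"Ca"} ... \code{"Cd"}).
#' @param studyKind \code{"CSI"} or \code{"PTI"}.
#' @param cutoffs cutoffs structure (default \code{\link{defaultCutoffs}}).
#' @return \code{"superior"}, \code{"good"} or \code{"poor"}.
#' @export
categorize <- function(value, criterion, studyKind = c("CSI", "PTI"),
                       cutoffs = defaultCutoffs()) {
  studyKind <- match.arg(studyKind)
  if (!is.numeric(value) || value < 0 || value > 1)
    stop("range error: metric value must lie in [0, 1], got ", value)
  value <- round(value, 3)
  co <- cutoffs[[studyKind]][[criterion]]
  if (is.null(co)) stop("no cutoffs for ", studyKind, "/", criterion)
  if (co[2] >= co[1] || co[2] < 0 || co[1] > 1)
    stop("invalid cutoffs: need 0 <= good < superior <= 1")
  if (value >= co[1]) "superior" else if (value >= co[2]) "good" else "poor"
}

#' Categorize a list of CriterionResults
#'
#' @param results list of \code{CriterionResult}.
#' @inheritParams categorize
#' @return the results with categories filled in.
#' @export
categorizeResults <- function(results, studyKind, cutoffs = defaultCutoffs()) {
  lapply(results, function(r) {
    r@category <- categorize(r@value, r@criterion, studyKind, cutoffs)
    r
  })
}

#' Weighted overall score of one workflow
#'
#' Category score = sum of category weights (superior 1, good 0.8, poor 0.1);
#' metric sum = sum of the 3-decimal metric values (the tie-break).
#'
#' @param results non-empty list of categorized \code{CriterionResult}s
#'   (3 or 4 criteria; Cd is optional).
#' @return list with \code{category_score} and \code{metric_sum}.
#' @export
overallScore <- function(results) {
  results <- results[!vapply(results, is.null, logical(1))]
  if (!length(results)) stop("no criterion results to score")
  cats <- vapply(results, function(r) r@category, character(1))
  if (any(!cats %in% names(.CATEGORY_WEIGHTS)))
    stop("results must be categorized before scoring")
  vals <- vapply(results, function(r) r@value, numeric(1))
  list(category_score = sum(.CATEGORY_WEIGHTS[cats]),
       metric_sum = sum(round(vals, 3)))
}

#' Rank evaluated workflows
#'
#' Stable sort by category score (descending), then metric sum (descending),
#' then workflow string (ascending; the final deterministic tie-break).
#' Permuting the input order never changes the resulting ranks.
#'
#' @param reports list of per-workflow reports, each a list with elements
#'   \code{workflow} (string) and \code{results} (categorized
#'   \code{CriterionResult}s).
#' @return a data.frame with columns rank, workflow, one value and one
#'   category column per criterion, category_score and metric_sum.
#' @export
rankWorkflows <- function(reports) {
  if (!length(reports)) stop("no workflow reports to rank")
  critSets <- lapply(reports, function(r)
    sort(vapply(r$results[!vapply(r$results, is.null, logical(1))],
                function(x) x@criterion, character(1))))
  if (length(unique(vapply(critSets, paste, character(1), collapse = ","))) != 1L)
    stop("heterogeneous criteria sets: all workflows must be evaluated ",
         "under the same criteria")
  crits <- critSets[[1L]]
  rows <- lapply(reports, function(r) {
    res <- r$results[!vapply(r$results, is.null, logical(1))]
    names(res) <- vapply(res, function(x) x@criterion, character(1))
    sc <- overallScore(res)
    row <- data.frame(workflow = r$workflow,
                      category_score = sc$category_score,
                      metric_sum = sc$metric_sum)
    for (cc in crits) {
      row[[paste0(cc, "_value")]] <- res[[cc]]@value
      row[[paste0(cc, "_category")]] <- res[[cc]]@category
    }
    row
  })
  df <- do.call(rbind, rows)
  ord <- order(-df$category_score, -df$metric_sum, df$workflow)
  df <- df[ord, , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' Export ranking tables
#'
#' Writes \code{ranking.csv} (rank, workflow, per-criterion value and
#' category, category score, metric sum) and \code{categories.csv}
#' (workflows by criteria, cells superior/good/poor), plus an optional
#' heatmap (green / light green / red for superior / good / poor) when
#' \pkg{pheatmap} is available.
#'
#' @param table ranking data.frame from \code{\link{rankWorkflows}}.
#' @param outDir output directory (created if needed).
#' @param heatmap logical; also render \code{categories.png}.
#' @return character vector of written paths, invisibly.
#' @export
exportResults <- function(table, outDir, heatmap = FALSE) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("empty ranking table")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rankingPath <- file.path(outDir, "ranking.csv")
  utils::write.csv(table, rankingPath, row.names = FALSE)
  catCols <- grep("_category$", names(table), value = TRUE)
  catM <- table[, catCols, drop = FALSE]
  names(catM) <- sub("_category$", "", names(catM))
  catDf <- cbind(workflow = table$workflow, catM)
  catPath <- file.path(outDir, "categories.csv")
  utils::write.csv(catDf, catPath, row.names = FALSE)
  paths <- c(rankingPath, catPath)
  if (heatmap && requireNamespace("pheatmap", quietly = TRUE)) {
    num <- apply(as.matrix(catM), c(1, 2), function(x)
      switch(x, superior = 2, good = 1, poor = 0))
    rownames(num) <- table$workflow
    png <- file.path(outDir, "categories.png")
    grDevices::png(png, width = 600,
                   height = 200 + 14 * nrow(num))
    pheatmap::pheatmap(num, cluster_rows = FALSE, cluster_cols = FALSE,
                       color = c("#d73027", "#a6d96a", "#1a9850"),
                       breaks = c(-0.5, 0.5, 1.5, 2.5),
                       legend_breaks = c(0, 1, 2),
                       legend_labels = c("poor", "good", "superior"))
    grDevices::dev.off()
    paths <- c(paths, png)
  }
  invisible(paths)
}
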