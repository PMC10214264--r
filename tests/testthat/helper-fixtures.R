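# Programmatic fixtures shared across test files.

# one flow-cytometry sample: lognormal channels A/B/C plus Time
makeFrame <- function(id, shift = 0, n = 600, seed = NULL) {
  build <- function() {
    t <- sort(runif(n, 0, 100))
    m <- cbind(A = exp(rnorm(n, 1 + shift, 0.5)),
               B = exp(rnorm(n, 2, 0.5)),
               C = exp(rnorm(n, 1.5, 0.4)),
               Time = t)
    CytoFrame(m, id, "FC")
  }
  if (is.null(seed)) build() else withSeed(seed, build())
}

makeAnnotation <- function(files = paste0("s", 1:4),
                           labels = c("a", "a", "b", "b"),
                           studyKind = "CSI") {
  new("SampleAnnotation", studyKind = studyKind,
      entries = data.frame(filename = files, label = labels),
      labelOrder = unique(labels))
}

# merged 4-sample CytoSet with a mild condition shift on channel A
makeCytoSet <- function(seed = 1, n = 500, perFileN = n) {
  ann <- makeAnnotation()
  frames <- withSeed(seed, list(
    makeFrame("s1", 0, n), makeFrame("s2", 0.3, n),
    makeFrame("s3", 0, n), makeFrame("s4", 0.2, n)))
  mergeSamples(frames, ann, perFileN = perFileN, seed = seed)
}

# bare CytoSet straight from a matrix (no Time channel); the annotation is a
# 4-sample CSI placeholder, adequate for criteria that ignore it
matrixCytoSet <- function(x, origin = rep(1:2, length.out = nrow(x)),
                          technique = "FC") {
  if (is.null(colnames(x))) colnames(x) <- paste0("M", seq_len(ncol(x)))
  new("CytoSet", exprs = x, markers = colnames(x),
      origin = as.integer(origin),
      sampleIDs = paste0("s", seq_len(max(origin))),
      annotation = makeAnnotation(), technique = technique,
      timeChannel = NA_character_, selectedMarkers = colnames(x))
}

# generate, read back and merge a synthetic CSI dataset
loadCSIDataset <- function(seed, dir = withr::local_tempdir(), ...) {
  truth <- generateCSIDataset(dir, seed = seed, ...)
  ann <- readMetadata(file.path(dir, "metadata.csv"), "CSI")
  frames <- lapply(ann@entries$filename, function(f)
    readFCS(file.path(dir, paste0(f, ".fcs"))))
  list(truth = truth, ann = ann,
       data = mergeSamples(frames, ann, perFileN = 10000L, seed = seed),
       known = readKnownMarkers(file.path(dir, "known_markers.csv")),
       spill = readSpillover(file.path(dir, "spillover.csv")))
}

loadPTIDataset <- function(seed, dir = withr::local_tempdir(), ...) {
  truth <- generatePTIDataset(dir, seed = seed, ...)
  ann <- readMetadata(file.path(dir, "metadata.csv"), "PTI")
  frames <- lapply(ann@entries$filename, function(f)
    readFCS(file.path(dir, paste0(f, ".fcs"))))
  list(truth = truth, ann = ann,
       data = mergeSamples(frames, ann, perFileN = 10000L, seed = seed),
       hierarchy = readPathwayHierarchy(
         file.path(dir, "Pathway_Hierarchy.csv")))
}
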