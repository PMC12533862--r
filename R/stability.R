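#' Apply early-stop censoring to an RMSD series
#'
#' From the first frame whose RMSD strictly exceeds the early-stop
#' threshold (default 5.5 Angstrom), all subsequent values are replaced by
#' the censor value (default 10 Angstrom) and \code{censoredFrom} records
#' the crossing index. Forward censoring preserves the pre-escape part of
#' the trace; set \code{wholeReplicate} in the config to censor the entire
#' replicate instead. Idempotent: censoring a censored series changes
#' nothing.
#'
#' @param series an \linkS4class{RmsdSeries}.
#' @param cfg a \linkS4class{StabilityConfig}.
#' @return The censored \linkS4class{RmsdSeries}.
#' @export
applyEarlyStop <- function(series, cfg = stabilityConfig()) {
  v <- series@values
  cross <- which(v > cfg@earlyStop)
  if (!length(cross)) return(series)
  i <- cross[1]
  from <- if (cfg@wholeReplicate) 1L else i
  v[seq(from, length(v))] <- cfg@censorValue
  RmsdSeries(series@times, v, replicate = series@replicate,
             censoredFrom = as.integer(from))
}

#' Pointwise median across replicate RMSD series
#'
#' Replicates must share a time grid; differing grids are resampled onto
#' the first replicate's grid by nearest time with a warning. The pointwise
#' median uses the standard convention: for even replicate counts, the mean
#' of the two central values.
#'
#' @param replicates list of (censored) \linkS4class{RmsdSeries}.
#' @return An \linkS4class{RmsdSeries} named \code{"median"}.
#' @export
medianAcrossReplicates <- function(replicates) {
  if (!length(replicates)) stop("no replicate series supplied")
  grid <- replicates[[1]]@times
  vals <- vapply(replicates, function(s) {
    if (isTRUE(all.equal(s@times, grid))) return(s@values)
    warning("replicate time grids differ; resampling by nearest time")
    idx <- vapply(grid, function(t) which.min(abs(s@times - t)), integer(1))
    s@values[idx]
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  med <- apply(vals, 1, stats::median)
  RmsdSeries(grid, med, replicate = "median")
}

#' Median RMSD inside the ranking window
#'
#' The median over all frames in the closed window (default 9 to 10 ns,
#' the last nanosecond of a 10 ns simulation), applied to the
#' replicate-median series; this is the ligand-ranking statistic.
#'
#' @param series an \linkS4class{RmsdSeries} (typically the replicate
#'   median).
#' @param cfg a \linkS4class{StabilityConfig}.
#' @return Numeric window median in Angstrom.
#' @export
windowMedian <- function(series, cfg = stabilityConfig()) {
  sel <- series@times >= cfg@windowStart & series@times <= cfg@windowEnd
  if (!any(sel))
    stop(sprintf("no frames inside the %g-%g ns window",
                 cfg@windowStart, cfg@windowEnd))
  stats::median(series@values[sel])
}

#' Classify a window median as bound or unbound
#'
#' Bound iff the window median is strictly below the binding threshold
#' (default 5.5 Angstrom); a value at exactly the threshold classifies as
#' unbound.
#'
#' @param wm numeric window median (Angstrom).
#' @param cfg a \linkS4class{StabilityConfig}.
#' @return Logical: TRUE when bound.
#' @export
classifyBinding <- function(wm, cfg = stabilityConfig()) {
  wm < cfg@bindingThreshold
}

#' Full stability statistic for one compound
#'
#' Censors each replicate, takes the pointwise replicate median, the
#' 9-10 ns window median, and the bound/unbound classification.
#'
#' @param id compound id.
#' @param replicates list of raw \linkS4class{RmsdSeries} (expected
#'   \code{cfg@nReplicates}; a different count warns).
#' @param cfg a \linkS4class{StabilityConfig}.
#' @return List: \code{id}, \code{medianSeries} (RmsdSeries),
#'   \code{windowMedian} (Angstrom), \code{bound} (logical),
#'   \code{nCensored} (replicates that crossed the early stop).
#' @export
compoundStability <- function(id, replicates, cfg = stabilityConfig()) {
  if (length(replicates) != cfg@nReplicates)
    warning(sprintf("compound %s: %d replicates supplied, %d expected",
                    id, length(replicates), cfg@nReplicates))
  cens <- lapply(replicates, applyEarlyStop, cfg = cfg)
  med <- medianAcrossReplicates(cens)
  wm <- windowMedian(med, cfg)
  list(id = id, medianSeries = med, windowMedian = wm,
       bound = classifyBinding(wm, cfg),
       nCensored = sum(!vapply(cens, function(s) is.na(s@censoredFrom),
                               logical(1))))
}

#' Rank ligands by window median
#'
#' Ascending window median (more stable first), ties broken
#' lexicographically by id, 1-based ranks.
#'
#' @param results data.frame with columns \code{id} and
#'   \code{windowMedian}, or a list of \code{\link{compoundStability}}
#'   results.
#' @return data.frame sorted ascending with a \code{rank} column.
#' @export
rankLigands <- function(results) {
  if (!is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, function(r)
      data.frame(id = r$id, windowMedian = r$windowMedian,
                 bound = r$bound, stringsAsFactors = FALSE)))
  }
  if (!nrow(results)) stop("no stability results to rank")
  stopifnot(all(c("id", "windowMedian") %in% names(results)))
  results <- results[order(results$windowMedian, results$id), , drop = FALSE]
  results$rank <- seq_len(nrow(results))
  rownames(results) <- NULL
  results
}

#' Published window-median reference values
#'
#' The seventeen published 9-10 ns window medians for compounds simulated
#' at the SGLT2 glucose/gliflozin site (with their published ranks and
#' licensed-inhibitor flags), shipped as a fixture for worked examples and
#' regression checks.
#'
#' @return data.frame with columns \code{name}, \code{median_rmsd},
#'   \code{rank}, \code{sglt2i}.
#' @export
mdReferenceMedians <- function() {
  path <- system.file("extdata", "md_window_medians.tsv",
                      package = "DockTriage", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Published docking-method benchmark values
#'
#' The ten published symmetry-corrected RMSD values (Angstrom) for
#' empagliflozin re-docking under five scoring functions and two
#' search-volume strategies, as a named numeric vector suitable for
#' \code{\link{benchmarkMethods}}.
#'
#' @return Named numeric vector of RMSD values.
#' @export
dockingBenchmarkValues <- function() {
  path <- system.file("extdata", "docking_benchmark_rmsd.tsv",
                      package = "DockTriage", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$rmsd, df$label)
}
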