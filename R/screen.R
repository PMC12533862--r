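#' Rank a compound screen table
#'
#' Sorts by docking score (ascending when lower-is-better, the empirical
#' docking convention; descending otherwise), breaks ties lexicographically
#' by compound id, and assigns 1-based dense ranks over the sorted order.
#'
#' @param table a \linkS4class{ScreenTable}.
#' @return The same \linkS4class{ScreenTable}, sorted, with a \code{rank}
#'   column.
#' @export
rankCompounds <- function(table) {
  stopifnot(is(table, "ScreenTable"))
  df <- table@compounds
  if (!nrow(df)) stop("cannot rank an empty screen table")
  s <- if (table@lowerIsBetter) df$score else -df$score
  ord <- order(s, df$id)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  screenTable(df, lowerIsBetter = table@lowerIsBetter)
}

# bin size: round-half-up of f * N, never below 1
.topBinSize <- function(n, f) {
  max(1L, as.integer(floor(f * n + 0.5)))
}

#' Top fraction of a ranked screen
#'
#' Returns the first \code{round-half-up(f * N)} rows (minimum 1) of the
#' ranked table; e.g. the top 1 percent of 877 compounds is a bin of 9.
#'
#' @param table a \linkS4class{ScreenTable}; ranked (a missing rank column
#'   triggers \code{\link{rankCompounds}}).
#' @param f fraction in (0, 1).
#' @return A \linkS4class{ScreenTable} holding the top bin.
#' @export
topFraction <- function(table, f) {
  stopifnot(is(table, "ScreenTable"))
  if (f <= 0 || f >= 1) stop("fraction must lie strictly between 0 and 1")
  if (!"rank" %in% names(table@compounds)) table <- rankCompounds(table)
  nTop <- .topBinSize(nrow(table@compounds), f)
  screenTable(table@compounds[seq_len(nTop), , drop = FALSE],
              lowerIsBetter = table@lowerIsBetter)
}

#' Enrichment factor of a labeled, ranked screen
#'
#' EF(f) = (actives in the top bin / bin size) / (actives / library size):
#' the active rate in the top-ranked fraction relative to the overall
#' active rate. The bin size is round-half-up(f * N), minimum 1.
#'
#' @param table a \linkS4class{ScreenTable} with an \code{active} column
#'   (logical or 0/1).
#' @param f fraction in (0, 1]; at f = 1 the bin is the whole library and
#'   EF is identically 1.
#' @return An \linkS4class{EnrichmentResult}.
#' @examples
#' scr <- makeScreen(877, 4, "top_bin", seed = 3)
#' enrichmentFactor(rankCompounds(scr$table), 0.01)
#' @export
enrichmentFactor <- function(table, f) {
  stopifnot(is(table, "ScreenTable"))
  df <- table@compounds
  if (!"active" %in% names(df))
    stop("screen table has no 'active' column")
  if (!"rank" %in% names(df)) {
    table <- rankCompounds(table)
    df <- table@compounds
  }
  act <- as.logical(df$active)
  nActives <- sum(act)
  if (nActives == 0L) stop("no labeled actives in the screen table")
  n <- nrow(df)
  if (f <= 0 || f > 1) stop("fraction must lie in (0, 1]")
  nTop <- if (f == 1) n else .topBinSize(n, f)
  nTopActives <- sum(act[seq_len(nTop)])
  ef <- (nTopActives / nTop) / (nActives / n)
  new("EnrichmentResult", fraction = f, nTop = as.integer(nTop),
      nActivesTop = as.integer(nTopActives), nTotal = as.integer(n),
      nActives = as.integer(nActives), ef = ef)
}

#' Select MD candidates from a scored screen
#'
#' Applies the candidate-selection gates in order: docking score, then
#' key-residue overlap, then the user-supplied clinical-inclusion flag.
#' Every rejected compound's decision trail records the first gate that
#' excluded it. The result is independent of input row order.
#'
#' @param table a \linkS4class{ScreenTable}; columns \code{overlap} /
#'   \code{include} must be present when the corresponding gate is active.
#' @param thresholds a \linkS4class{TriageThresholds}.
#' @return List with \code{candidates} (data.frame of retained compounds,
#'   sorted best-score-first, ties by id) and \code{decisions} (per-compound
#'   trail, sorted by id, with a \code{reason} column: \code{pass},
#'   \code{score}, \code{overlap} or \code{clinical}).
#' @export
selectCandidates <- function(table, thresholds) {
  stopifnot(is(table, "ScreenTable"), is(thresholds, "TriageThresholds"))
  df <- table@compounds
  if (!is.na(thresholds@overlap) && !"overlap" %in% names(df))
    stop("missing required column: overlap")
  if (thresholds@requireClinical && !"include" %in% names(df))
    stop("missing required column: include")

  reason <- rep("pass", nrow(df))
  if (!is.na(thresholds@score)) {
    fail <- if (table@lowerIsBetter) df$score > thresholds@score
            else df$score < thresholds@score
    reason[fail & reason == "pass"] <- "score"
  }
  if (!is.na(thresholds@overlap)) {
    fail <- is.na(df$overlap) | df$overlap < thresholds@overlap
    reason[fail & reason == "pass"] <- "overlap"
  }
  if (thresholds@requireClinical) {
    fail <- !as.logical(df$include)
    reason[(fail | is.na(fail)) & reason == "pass"] <- "clinical"
  }

  decisions <- df
  decisions$reason <- reason
  decisions <- decisions[order(decisions$id), , drop = FALSE]
  rownames(decisions) <- NULL

  cand <- df[reason == "pass", , drop = FALSE]
  s <- if (table@lowerIsBetter) cand$score else -cand$score
  cand <- cand[order(s, cand$id), , drop = FALSE]
  rownames(cand) <- NULL
  list(candidates = cand, decisions = decisions)
}
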