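#' Enumerate chemically valid atom mappings between two poses
#'
#' All element- and bond-preserving bijections (graph isomorphisms) between
#' the heavy atoms of two poses of the same molecule. Bond orders are
#' ignored: docking programs frequently disagree on order assignment, so
#' the isomorphism uses connectivity and element only. The search is a
#' backtracking assignment with element and degree pruning; candidates are
#' tried in increasing index, so the result list is in lexicographic order
#' of the mapped index sequence.
#'
#' @param a,b \linkS4class{MolecularGraph} poses of the same molecule.
#' @param cap maximum number of mappings before aborting (guards
#'   pathological symmetry).
#' @return List of integer vectors; element i of a mapping is the heavy-atom
#'   index in \code{b} matched to heavy atom i of \code{a}. Indices refer to
#'   the heavy-atom subsets (attributes \code{heavyA}/\code{heavyB} give the
#'   original atom indices).
#' @export
enumerateMappings <- function(a, b, cap = 100000L) {
  ha <- .heavyView(a)
  hb <- .heavyView(b)
  if (ha$n != hb$n ||
      !identical(sort(ha$elements), sort(hb$elements)))
    stop("not the same molecule: heavy-atom element multisets differ")
  n <- ha$n
  if (n == 0L) stop("no heavy atoms to map")

  # precomputed candidate sets: element and degree must match
  cands <- lapply(seq_len(n), function(i)
    which(hb$elements == ha$elements[i] & hb$degree == ha$degree[i]))

  mappings <- vector("list", 0L)
  map <- integer(n)
  used <- logical(n)
  count <- 0L

  recurse <- function(i) {
    if (i > n) {
      count <<- count + 1L
      if (count > cap)
        stop(sprintf(
          "mapping explosion: more than %d valid mappings; raise the cap",
          cap))
      mappings[[count]] <<- map
      return(invisible())
    }
    for (j in cands[[i]]) {
      if (used[j]) next
      if (i > 1L) {
        prev <- seq_len(i - 1L)
        # bond to every previously mapped atom must be mirrored in b
        if (!all(ha$adj[i, prev] == hb$adj[j, map[prev]])) next
      }
      map[i] <<- j
      used[j] <<- TRUE
      recurse(i + 1L)
      used[j] <<- FALSE
    }
    invisible()
  }
  recurse(1L)
  structure(mappings, heavyA = ha$idx, heavyB = hb$idx)
}

#' Symmetry-corrected RMSD between two poses
#'
#' The minimal heavy-atom RMSD between two poses of the same molecule over
#' all chemically valid atom correspondences. No superposition is performed:
#' both poses are taken in the same (receptor) frame, as is standard when
#' benchmarking docked poses against a crystallographic reference. The
#' order-based ("naive") RMSD is reported alongside, so the symmetry
#' correction is visible.
#'
#' @param poseA,poseB \linkS4class{MolecularGraph} poses of the same
#'   molecule, in a shared frame.
#' @param cap mapping-enumeration cap, see \code{\link{enumerateMappings}}.
#' @return A \linkS4class{PoseComparison}.
#' @examples
#' hex <- makeSymmetricLigand("ring6", seed = 1)$graph
#' minSymmetryRmsd(hex, hex)
#' @export
minSymmetryRmsd <- function(poseA, poseB, cap = 100000L) {
  maps <- enumerateMappings(poseA, poseB, cap = cap)
  ca <- as.matrix(poseA@atoms[attr(maps, "heavyA"), c("x", "y", "z")])
  cb <- as.matrix(poseB@atoms[attr(maps, "heavyB"), c("x", "y", "z")])
  n <- nrow(ca)
  best <- Inf
  bestMap <- maps[[1]]
  for (m in maps) {
    r <- sqrt(sum((ca - cb[m, , drop = FALSE])^2) / n)
    if (r < best) { best <- r; bestMap <- m }
  }
  naive <- sqrt(sum((ca - cb)^2) / n)
  new("PoseComparison", rmsd = best, mapping = as.integer(bestMap),
      nHeavy = as.integer(n), naiveRmsd = naive,
      nMappings = length(maps))
}

#' Benchmark docking methods against a reference pose
#'
#' Compares candidate poses (one per docking method/approach label) against
#' a reference pose by symmetry-corrected RMSD, or ingests precomputed RMSD
#' values directly (a named numeric vector), and reports the ranking with
#' the best method. Ties are broken lexicographically by label.
#'
#' @param candidates named list of \linkS4class{MolecularGraph} poses, or a
#'   named numeric vector of precomputed RMSD values (Angstrom).
#' @param reference \linkS4class{MolecularGraph} reference pose (required
#'   when candidates are poses).
#' @param cap mapping-enumeration cap.
#' @return List with \code{table} (data.frame label/rmsd sorted ascending),
#'   \code{best} (label) and \code{bestRmsd}.
#' @export
benchmarkMethods <- function(candidates, reference = NULL, cap = 100000L) {
  if (is.numeric(candidates)) {
    if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
      stop("precomputed RMSD values must be named by method label")
    rmsd <- as.numeric(candidates)
    labels <- names(candidates)
  } else {
    if (!length(candidates)) stop("at least one candidate pose required")
    if (is.null(reference))
      stop("a reference pose is required to compare candidate poses")
    labels <- names(candidates)
    rmsd <- vapply(candidates, function(p)
      symRmsd(minSymmetryRmsd(p, reference, cap = cap)), numeric(1))
  }
  ord <- order(rmsd, labels)
  tab <- data.frame(label = labels[ord], rmsd = rmsd[ord],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, best = tab$label[1], bestRmsd = tab$rmsd[1])
}
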