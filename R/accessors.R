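#' Atom table of a molecular object
#' @param x a MolecularGraph or ReceptorStructure.
#' @return data.frame of atoms.
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname atomTable
#' @export
setMethod("atomTable", "MolecularGraph", function(x) x@atoms)

#' @rdname atomTable
#' @export
setMethod("atomTable", "ReceptorStructure", function(x) x@atoms)

#' Bond matrix of a MolecularGraph
#' @param x a MolecularGraph.
#' @return two-column integer matrix of bonded atom index pairs.
#' @export
setGeneric("bondMatrix", function(x) standardGeneric("bondMatrix"))

#' @rdname bondMatrix
#' @export
setMethod("bondMatrix", "MolecularGraph", function(x) x@bonds)

#' HETATM (ligand/cofactor candidate) records of a receptor
#' @param x a ReceptorStructure.
#' @return data.frame of HETATM records.
#' @export
setGeneric("heteroAtoms", function(x) standardGeneric("heteroAtoms"))

#' @rdname heteroAtoms
#' @export
setMethod("heteroAtoms", "ReceptorStructure", function(x) x@hetero)

#' Residue keys of a receptor
#'
#' Unique authored residue identities, in order of first appearance.
#' @param x a ReceptorStructure.
#' @return data.frame with columns chain, resno, insert, resname.
#' @export
setGeneric("residueKeys", function(x) standardGeneric("residueKeys"))

#' @rdname residueKeys
#' @export
setMethod("residueKeys", "ReceptorStructure", function(x) {
  df <- x@atoms[, c("chain", "resno", "insert", "resname")]
  unique(df)
})

#' Times of an RMSD series (ns)
#' @param x an RmsdSeries.
#' @return numeric vector.
#' @export
setGeneric("seriesTimes", function(x) standardGeneric("seriesTimes"))

#' @rdname seriesTimes
#' @export
setMethod("seriesTimes", "RmsdSeries", function(x) x@times)

#' Values of an RMSD series (Angstrom)
#' @param x an RmsdSeries.
#' @return numeric vector.
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @rdname seriesValues
#' @export
setMethod("seriesValues", "RmsdSeries", function(x) x@values)

#' Index of the first censored frame
#' @param x an RmsdSeries.
#' @return integer index, or NA when the series is uncensored.
#' @export
setGeneric("censoredFrom", function(x) standardGeneric("censoredFrom"))

#' @rdname censoredFrom
#' @export
setMethod("censoredFrom", "RmsdSeries", function(x) x@censoredFrom)

#' Compound rows of a ScreenTable
#' @param x a ScreenTable.
#' @return data.frame of compounds.
#' @export
setGeneric("compounds", function(x) standardGeneric("compounds"))

#' @rdname compounds
#' @export
setMethod("compounds", "ScreenTable", function(x) x@compounds)

#' Ranking direction of a ScreenTable
#' @param x a ScreenTable.
#' @return logical; TRUE when lower scores rank first.
#' @export
setGeneric("lowerIsBetter", function(x) standardGeneric("lowerIsBetter"))

#' @rdname lowerIsBetter
#' @export
setMethod("lowerIsBetter", "ScreenTable", function(x) x@lowerIsBetter)

#' Per-residue table of an InteractionReport
#' @param x an InteractionReport.
#' @return data.frame with residue keys, distances and flags.
#' @export
setGeneric("residueReport", function(x) standardGeneric("residueReport"))

#' @rdname residueReport
#' @export
setMethod("residueReport", "InteractionReport", function(x) x@residues)

#' Key-residue score of an InteractionReport
#' @param x an InteractionReport.
#' @return numeric score.
#' @export
setGeneric("interactionScore",
           function(x) standardGeneric("interactionScore"))

#' @rdname interactionScore
#' @export
setMethod("interactionScore", "InteractionReport", function(x) x@score)

#' Key-residue overlap fraction of an InteractionReport
#' @param x an InteractionReport.
#' @return numeric in [0, 1].
#' @export
setGeneric("keyResidueOverlap",
           function(x) standardGeneric("keyResidueOverlap"))

#' @rdname keyResidueOverlap
#' @export
setMethod("keyResidueOverlap", "InteractionReport", function(x) x@overlap)

#' Detected hydrogen bonds of an InteractionReport
#' @param x an InteractionReport.
#' @return data.frame of hydrogen bonds.
#' @export
setGeneric("hbondTable", function(x) standardGeneric("hbondTable"))

#' @rdname hbondTable
#' @export
setMethod("hbondTable", "InteractionReport", function(x) x@hbonds)

#' Symmetry-corrected RMSD of a PoseComparison
#' @param x a PoseComparison.
#' @return numeric RMSD in Angstrom.
#' @export
setGeneric("symRmsd", function(x) standardGeneric("symRmsd"))

#' @rdname symRmsd
#' @export
setMethod("symRmsd", "PoseComparison", function(x) x@rmsd)

#' Order-based (naive) RMSD of a PoseComparison
#' @param x a PoseComparison.
#' @return numeric RMSD in Angstrom.
#' @export
setGeneric("naiveRmsd", function(x) standardGeneric("naiveRmsd"))

#' @rdname naiveRmsd
#' @export
setMethod("naiveRmsd", "PoseComparison", function(x) x@naiveRmsd)

#' Enrichment factor value
#' @param x an EnrichmentResult.
#' @return numeric EF.
#' @export
setGeneric("efValue", function(x) standardGeneric("efValue"))

#' @rdname efValue
#' @export
setMethod("efValue", "EnrichmentResult", function(x) x@ef)

setMethod("show", "MolecularGraph", function(object) {
  nh <- sum(!object@atoms$is_hydrogen)
  cat(sprintf(
    "MolecularGraph: %d atoms (%d heavy), %d bonds [%s]\n",
    nrow(object@atoms), nh, nrow(object@bonds), object@provenance))
})

setMethod("show", "ReceptorStructure", function(object) {
  cat(sprintf(
    "ReceptorStructure: %d protein atoms in %d residues, %d hetero atoms\n",
    nrow(object@atoms), nrow(residueKeys(object)), nrow(object@hetero)))
})

setMethod("show", "RmsdSeries", function(object) {
  n <- length(object@times)
  cens <- if (is.na(object@censoredFrom)) "uncensored"
          else sprintf("censored from frame %d", object@censoredFrom)
  cat(sprintf("RmsdSeries '%s': %d frames, %.3g-%.3g ns, %s\n",
              object@replicate, n,
              if (n) min(object@times) else NA,
              if (n) max(object@times) else NA, cens))
})

setMethod("show", "ScreenTable", function(object) {
  cat(sprintf("ScreenTable: %d compounds (%s is better)%s\n",
              nrow(object@compounds),
              if (object@lowerIsBetter) "lower" else "higher",
              if ("rank" %in% names(object@compounds)) ", ranked" else ""))
})

setMethod("show", "InteractionReport", function(object) {
  cat(sprintf(
    "InteractionReport: score %.3g, key-residue overlap %.3f, %d H-bonds\n",
    object@score, object@overlap, nrow(object@hbonds)))
})

setMethod("show", "PoseComparison", function(object) {
  cat(sprintf(
    "PoseComparison: sym RMSD %.4f A (naive %.4f) over %d heavy atoms, %d mappings\n",
    object@rmsd, object@naiveRmsd, object@nHeavy, object@nMappings))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(
    "EF(%.3g%%) = %.4g  [%d/%d actives in top %d of %d]\n",
    100 * object@fraction, object@ef, object@nActivesTop,
    object@nActives, object@nTop, object@nTotal))
})
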