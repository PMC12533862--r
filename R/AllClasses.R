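#' @import methods
NULL

# Covalent radii (Angstrom, single-bond values) for the elements a docked
# drug-like ligand or protein pocket can reasonably contain.
.COVALENT_RADII <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Na = 1.66, Mg = 1.41, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
  K = 2.03, Ca = 1.76, Mn = 1.39, Fe = 1.32, Co = 1.26, Ni = 1.24,
  Cu = 1.32, Zn = 1.22, Se = 1.20, Br = 1.20, I = 1.39
)

.validElements <- function() names(.COVALENT_RADII)

.checkAtomFrame <- function(atoms, what = "atoms") {
  msgs <- character()
  need <- c("element", "name", "x", "y", "z", "is_hydrogen")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    return(sprintf("%s is missing column(s): %s", what,
                   paste(miss, collapse = ", ")))
  if (nrow(atoms)) {
    bad <- setdiff(unique(atoms$element), .validElements())
    if (length(bad))
      msgs <- c(msgs, sprintf("unknown element symbol(s) in %s: %s", what,
                              paste(bad, collapse = ", ")))
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    if (!all(is.finite(xyz)))
      msgs <- c(msgs, sprintf("non-finite coordinates in %s", what))
    if (!identical(as.logical(atoms$is_hydrogen), atoms$element == "H"))
      msgs <- c(msgs, "is_hydrogen flag inconsistent with element symbol")
  }
  msgs
}

#' Molecular graph of a ligand pose
#'
#' Atoms (element, name, 3-D coordinates in Angstrom, hydrogen flag) plus an
#' explicit covalent bond list. This is the object compared by the
#' symmetry-corrected RMSD machinery; coordinates are interpreted in the
#' receptor frame, i.e. no superposition is ever applied to them.
#'
#' @slot atoms data.frame with columns \code{element}, \code{name},
#'   \code{x}, \code{y}, \code{z}, \code{is_hydrogen}.
#' @slot bonds two-column integer matrix of atom-index pairs (i < j).
#' @slot provenance source format tag (\code{"mol2"}, \code{"sdf"},
#'   \code{"pdb"}, \code{"synthetic"}, ...).
#' @exportClass MolecularGraph
setClass("MolecularGraph",
  representation(atoms = "data.frame", bonds = "matrix",
                 provenance = "character"),
  validity = function(object) {
    msgs <- .checkAtomFrame(object@atoms, "ligand atoms")
    b <- object@bonds
    if (ncol(b) != 2)
      msgs <- c(msgs, "bonds must be a two-column matrix")
    else if (nrow(b)) {
      n <- nrow(object@atoms)
      if (any(b < 1L) || any(b > n))
        msgs <- c(msgs, "bond endpoint outside atom index range")
      if (any(b[, 1] == b[, 2]))
        msgs <- c(msgs, "self-bond present")
    }
    if (length(msgs)) msgs else TRUE
  })

#' Construct a MolecularGraph
#'
#' @param atoms data.frame of atoms; \code{is_hydrogen} is derived from
#'   \code{element} when absent.
#' @param bonds two-column matrix (or data.frame) of 1-based atom index
#'   pairs; duplicates and orientation are normalised.
#' @param provenance source tag.
#' @return A \linkS4class{MolecularGraph}.
#' @export
MolecularGraph <- function(atoms, bonds = NULL, provenance = "r") {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$name)) atoms$name <- atoms$element
  if (is.null(atoms$is_hydrogen)) atoms$is_hydrogen <- atoms$element == "H"
  rownames(atoms) <- NULL
  if (is.null(bonds) || NROW(bonds) == 0) {
    bonds <- matrix(integer(), ncol = 2)
  } else {
    bonds <- as.matrix(bonds)[, 1:2, drop = FALSE]
    storage.mode(bonds) <- "integer"
    bonds <- t(apply(bonds, 1, sort))
    bonds <- unique(bonds)
    bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  }
  dimnames(bonds) <- NULL
  new("MolecularGraph", atoms = atoms, bonds = bonds,
      provenance = provenance)
}

#' Receptor structure
#'
#' Protein (ATOM) records grouped by their authored residue identity
#' (chain, residue number, insertion code, residue name); HETATM records are
#' kept separately as ligand/cofactor candidates. Residue numbering is the
#' authored numbering -- no renumbering is performed, so key-residue lists
#' quoted in the literature (e.g. "ASN 75") match directly.
#'
#' @slot atoms data.frame of ATOM records with columns \code{element},
#'   \code{name}, \code{x}, \code{y}, \code{z}, \code{is_hydrogen},
#'   \code{chain}, \code{resno}, \code{insert}, \code{resname}.
#' @slot hetero data.frame of HETATM records, same columns.
#' @exportClass ReceptorStructure
setClass("ReceptorStructure",
  representation(atoms = "data.frame", hetero = "data.frame"),
  validity = function(object) {
    msgs <- character()
    for (nm in c("atoms", "hetero")) {
      df <- slot(object, nm)
      if (!nrow(df)) next
      msgs <- c(msgs, .checkAtomFrame(df, nm))
      miss <- setdiff(c("chain", "resno", "insert", "resname"), names(df))
      if (length(miss))
        msgs <- c(msgs, sprintf("%s missing residue column(s): %s", nm,
                                paste(miss, collapse = ", ")))
    }
    if (length(msgs)) msgs else TRUE
  })

#' Per-replicate ligand RMSD time series
#'
#' One molecular-dynamics replicate's ligand RMSD trace: strictly increasing
#' times in nanoseconds, RMSD values in Angstrom, and (after early-stop
#' censoring) the index of the first censored frame.
#'
#' @slot replicate replicate identifier.
#' @slot times numeric, ns, strictly increasing.
#' @slot values numeric, Angstrom, non-negative.
#' @slot censoredFrom integer index of the first censored frame, or
#'   \code{NA} when the series never crossed the early-stop threshold.
#' @exportClass RmsdSeries
setClass("RmsdSeries",
  representation(replicate = "character", times = "numeric",
                 values = "numeric", censoredFrom = "integer"),
  prototype(censoredFrom = NA_integer_),
  validity = function(object) {
    msgs <- character()
    n <- length(object@times)
    if (length(object@values) != n)
      msgs <- c(msgs, "times and values differ in length")
    if (n > 1 && any(diff(object@times) <= 0))
      msgs <- c(msgs, "times must be strictly increasing")
    if (any(!is.finite(object@values)) || any(object@values < 0))
      msgs <- c(msgs, "RMSD values must be finite and non-negative")
    cf <- object@censoredFrom
    if (!is.na(cf) && (cf < 1L || cf > n))
      msgs <- c(msgs, "censoredFrom outside the series")
    if (length(msgs)) msgs else TRUE
  })

#' Construct an RmsdSeries
#' @param times numeric times (ns), strictly increasing.
#' @param values numeric RMSD values (Angstrom).
#' @param replicate replicate id.
#' @param censoredFrom optional 1-based index of the first censored frame.
#' @return An \linkS4class{RmsdSeries}.
#' @export
RmsdSeries <- function(times, values, replicate = "rep1",
                       censoredFrom = NA_integer_) {
  new("RmsdSeries", replicate = as.character(replicate),
      times = as.numeric(times), values = as.numeric(values),
      censoredFrom = as.integer(censoredFrom))
}

#' Scored compound table for screen triage
#'
#' Rows of (compound id, docking score) with optional \code{overlap}
#' (key-residue overlap fraction), \code{active} (known-active label) and
#' \code{include} (clinical-inclusion flag) columns, plus the ranking
#' direction. The default is lower-is-better, matching empirical docking
#' score conventions where more negative means a better pose.
#'
#' @slot compounds data.frame with at least \code{id} and \code{score}.
#' @slot lowerIsBetter logical ranking direction.
#' @exportClass ScreenTable
setClass("ScreenTable",
  representation(compounds = "data.frame", lowerIsBetter = "logical"),
  validity = function(object) {
    df <- object@compounds
    msgs <- character()
    if (!all(c("id", "score") %in% names(df)))
      return("compound table needs 'id' and 'score' columns")
    if (anyDuplicated(df$id))
      msgs <- c(msgs, sprintf("duplicate compound id(s): %s",
        paste(unique(df$id[duplicated(df$id)]), collapse = ", ")))
    if (nrow(df) && !all(is.finite(df$score)))
      msgs <- c(msgs, "scores must be finite")
    if ("overlap" %in% names(df) && nrow(df) &&
        any(df$overlap < 0 | df$overlap > 1, na.rm = TRUE))
      msgs <- c(msgs, "overlap values must lie in [0, 1]")
    if (length(msgs)) msgs else TRUE
  })

#' Construct a ScreenTable
#' @param compounds data.frame with \code{id}, \code{score} and optional
#'   \code{overlap}, \code{active}, \code{include} columns.
#' @param lowerIsBetter logical; \code{TRUE} (default) ranks ascending.
#' @return A \linkS4class{ScreenTable}.
#' @export
screenTable <- function(compounds, lowerIsBetter = TRUE) {
  compounds <- as.data.frame(compounds)
  compounds$id <- as.character(compounds$id)
  rownames(compounds) <- NULL
  new("ScreenTable", compounds = compounds,
      lowerIsBetter = isTRUE(lowerIsBetter))
}

#' Key-residue specification
#'
#' The ordered binding-site residue list used for contact and hydrogen-bond
#' scoring, together with the close-contact distance cutoff (default 5
#' Angstrom, the distance at which pocket residues around the reference
#' inhibitor pose were defined).
#'
#' @slot residues data.frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resname}.
#' @slot contactCutoff numeric, Angstrom.
#' @exportClass KeyResidueSpec
setClass("KeyResidueSpec",
  representation(residues = "data.frame", contactCutoff = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (!nrow(object@residues))
      msgs <- c(msgs, "key residue list must be non-empty")
    if (object@contactCutoff <= 0)
      msgs <- c(msgs, "contact cutoff must be positive")
    if (length(msgs)) msgs else TRUE
  })

#' Construct a KeyResidueSpec
#' @param residues data.frame with \code{chain}, \code{resno} and
#'   \code{resname} (an \code{insert} column is added when absent).
#' @param contactCutoff contact distance cutoff in Angstrom.
#' @return A \linkS4class{KeyResidueSpec}.
#' @export
keyResidueSpec <- function(residues, contactCutoff = 5.0) {
  residues <- as.data.frame(residues)
  if (is.null(residues$insert)) residues$insert <- ""
  residues$chain <- as.character(residues$chain)
  residues$resname <- as.character(residues$resname)
  rownames(residues) <- NULL
  new("KeyResidueSpec", residues = residues,
      contactCutoff = as.numeric(contactCutoff))
}

#' Hydrogen-bond geometric criteria
#'
#' Donor-acceptor heavy-atom distance, hydrogen-acceptor distance and
#' donor-hydrogen-acceptor angle gates, plus a heavy-atom fallback used when
#' hydrogens are absent from a partner (as in most crystallographic
#' receptors). All values are configurable; the defaults follow common
#' structural practice.
#'
#' @slot maxDA donor-acceptor max distance, Angstrom (default 3.5).
#' @slot maxHA hydrogen-acceptor max distance, Angstrom (default 2.5).
#' @slot minAngle minimum D-H-A angle, degrees (default 120).
#' @slot heavyAtomFallback logical; degrade to the D-A distance criterion
#'   when the donor partner carries no hydrogens (default TRUE).
#' @exportClass HBondCriteria
setClass("HBondCriteria",
  representation(maxDA = "numeric", maxHA = "numeric", minAngle = "numeric",
                 heavyAtomFallback = "logical"),
  validity = function(object) {
    msgs <- character()
    if (object@maxDA <= 0 || object@maxHA <= 0)
      msgs <- c(msgs, "distance criteria must be positive")
    if (object@minAngle <= 0 || object@minAngle > 180)
      msgs <- c(msgs, "angle criterion must lie in (0, 180]")
    if (length(msgs)) msgs else TRUE
  })

#' Construct HBondCriteria
#' @param maxDA donor-acceptor max distance (Angstrom).
#' @param maxHA hydrogen-acceptor max distance (Angstrom).
#' @param minAngle minimum donor-hydrogen-acceptor angle (degrees).
#' @param heavyAtomFallback use donor-acceptor distance alone when the donor
#'   partner has no hydrogens.
#' @return An \linkS4class{HBondCriteria}.
#' @export
hbondCriteria <- function(maxDA = 3.5, maxHA = 2.5, minAngle = 120,
                          heavyAtomFallback = TRUE) {
  new("HBondCriteria", maxDA = maxDA, maxHA = maxHA, minAngle = minAngle,
      heavyAtomFallback = isTRUE(heavyAtomFallback))
}

#' Pose interaction report
#'
#' Per-residue contact/H-bond flags against a key-residue list, the weighted
#' key-residue score, and the proportion of key residues engaged (the
#' weight-free triage quantity).
#'
#' @slot residues per-residue data.frame (residue key, min heavy-atom
#'   distance, contact flag, hbond flag, is_key flag).
#' @slot hbonds data.frame of detected hydrogen bonds.
#' @slot score weighted key-residue score.
#' @slot overlap engaged key residues / key-list length, in [0, 1].
#' @slot weights named numeric, \code{hbond} and \code{contact} weights.
#' @exportClass InteractionReport
setClass("InteractionReport",
  representation(residues = "data.frame", hbonds = "data.frame",
                 score = "numeric", overlap = "numeric",
                 weights = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (object@overlap < 0 || object@overlap > 1)
      msgs <- c(msgs, "overlap must lie in [0, 1]")
    if (object@score < 0)
      msgs <- c(msgs, "score must be non-negative")
    if (length(msgs)) msgs else TRUE
  })

#' Triage thresholds for candidate selection
#'
#' The gates of the candidate-selection flowchart: a docking-score
#' threshold, a key-residue overlap threshold, and an optional requirement
#' that a user-supplied clinical-inclusion flag be set. \code{NA} disables a
#' gate.
#'
#' @slot score docking score threshold (direction taken from the table).
#' @slot overlap minimum key-residue overlap fraction, in [0, 1].
#' @slot requireClinical logical; require \code{include == TRUE}.
#' @exportClass TriageThresholds
setClass("TriageThresholds",
  representation(score = "numeric", overlap = "numeric",
                 requireClinical = "logical"),
  validity = function(object) {
    if (!is.na(object@overlap) &&
        (object@overlap < 0 || object@overlap > 1))
      "overlap threshold must lie in [0, 1]" else TRUE
  })

#' Construct TriageThresholds
#' @param score docking-score gate (NA disables).
#' @param overlap key-residue overlap gate in [0, 1] (NA disables).
#' @param requireClinical require the clinical-inclusion flag.
#' @return A \linkS4class{TriageThresholds}.
#' @export
triageThresholds <- function(score = NA_real_, overlap = NA_real_,
                             requireClinical = FALSE) {
  new("TriageThresholds", score = as.numeric(score),
      overlap = as.numeric(overlap),
      requireClinical = isTRUE(requireClinical))
}

#' MD stability-statistic configuration
#'
#' Constants of the censored replicate-median stability statistic: the
#' early-stop threshold (5.5 Angstrom, above which a pose is considered
#' non-binding), the censor value substituted from the first crossing
#' onward (10 Angstrom), the expected replicate count (3), the ranking
#' window (9-10 ns, closed) and the binding threshold applied to the window
#' median (5.5 Angstrom, strict).
#'
#' @slot earlyStop early-stop RMSD threshold, Angstrom.
#' @slot censorValue value assigned from the first crossing onward, Angstrom.
#' @slot nReplicates expected replicates per compound.
#' @slot windowStart,windowEnd ranking window, ns (closed interval).
#' @slot bindingThreshold bound iff window median strictly below, Angstrom.
#' @slot wholeReplicate censor the entire replicate (not just from the
#'   crossing) when it ever crosses.
#' @exportClass StabilityConfig
setClass("StabilityConfig",
  representation(earlyStop = "numeric", censorValue = "numeric",
                 nReplicates = "integer", windowStart = "numeric",
                 windowEnd = "numeric", bindingThreshold = "numeric",
                 wholeReplicate = "logical"),
  validity = function(object) {
    msgs <- character()
    if (object@censorValue <= object@earlyStop)
      msgs <- c(msgs, "censor value must exceed the early-stop threshold")
    if (object@windowStart >= object@windowEnd)
      msgs <- c(msgs, "window start must precede window end")
    if (object@nReplicates < 1L)
      msgs <- c(msgs, "at least one replicate expected")
    if (length(msgs)) msgs else TRUE
  })

#' Construct a StabilityConfig
#' @param earlyStop early-stop RMSD threshold (Angstrom).
#' @param censorValue censor value (Angstrom).
#' @param nReplicates expected replicate count.
#' @param windowStart,windowEnd ranking window in ns.
#' @param bindingThreshold binding classification threshold (Angstrom).
#' @param wholeReplicate censor whole replicate on any crossing.
#' @return A \linkS4class{StabilityConfig}.
#' @export
stabilityConfig <- function(earlyStop = 5.5, censorValue = 10,
                            nReplicates = 3, windowStart = 9,
                            windowEnd = 10, bindingThreshold = 5.5,
                            wholeReplicate = FALSE) {
  new("StabilityConfig", earlyStop = earlyStop, censorValue = censorValue,
      nReplicates = as.integer(nReplicates), windowStart = windowStart,
      windowEnd = windowEnd, bindingThreshold = bindingThreshold,
      wholeReplicate = isTRUE(wholeReplicate))
}

#' Symmetry-RMSD pose comparison
#'
#' @slot rmsd minimal RMSD over chemically valid atom mappings, Angstrom.
#' @slot mapping the heavy-atom index mapping achieving the minimum.
#' @slot nHeavy number of heavy atoms compared.
#' @slot naiveRmsd RMSD under the as-given atom order, for reporting.
#' @slot nMappings number of valid mappings enumerated.
#' @exportClass PoseComparison
setClass("PoseComparison",
  representation(rmsd = "numeric", mapping = "integer", nHeavy = "integer",
                 naiveRmsd = "numeric", nMappings = "integer"),
  validity = function(object) {
    if (object@rmsd < 0) "rmsd must be non-negative" else TRUE
  })

#' Enrichment-factor result
#'
#' @slot fraction top fraction f of the ranked library.
#' @slot nTop bin size (round-half-up of f * N, minimum 1).
#' @slot nActivesTop actives found inside the bin.
#' @slot nTotal library size.
#' @slot nActives total labeled actives.
#' @slot ef enrichment factor (active rate in bin / overall active rate).
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  representation(fraction = "numeric", nTop = "integer",
                 nActivesTop = "integer", nTotal = "integer",
                 nActives = "integer", ef = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (object@fraction <= 0 || object@fraction > 1)
      msgs <- c(msgs, "fraction must lie in (0, 1]")
    if (object@ef < 0) msgs <- c(msgs, "EF must be non-negative")
    if (length(msgs)) msgs else TRUE
  })
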