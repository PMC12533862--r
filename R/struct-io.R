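#' Read a receptor structure from PDB text
#'
#' Parses ATOM/HETATM records into a \linkS4class{ReceptorStructure}.
#' ATOM records keep their authored residue identity (chain, residue
#' number, insertion code, residue name); HETATM records are returned
#' separately as ligand/cofactor candidates. When alternate locations are
#' present, the highest-occupancy conformer is kept (ties resolved in favour
#' of altloc \code{A}); the choice is logged via \code{message()}.
#'
#' @param x PDB text: a file path, a single string, or a character vector
#'   of lines.
#' @return A \linkS4class{ReceptorStructure}.
#' @examples
#' pdb <- c("ATOM      1  N   ALA A   1      11.104   6.134  -6.504",
#'          "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147")
#' readReceptor(pdb)
#' @export
readReceptor <- function(x) {
  lines <- .asLines(x)
  rectype <- trimws(substr(lines, 1, 6))
  isRec <- rectype %in% c("ATOM", "HETATM")
  if (!any(isRec))
    stop("PDB format error: no ATOM/HETATM records found")
  for (i in which(isRec)) {
    flds <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
              substr(lines[i], 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(flds)))))
      stop(sprintf("PDB format error: unparseable coordinate field at line %d",
                   i))
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- ""
  at$o[is.na(at$o)] <- 1

  # altloc policy: per (residue, atom name) keep highest occupancy, tie -> 'A'
  if (any(nzchar(at$alt))) {
    grp <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
    keep <- unlist(lapply(split(seq_len(nrow(at)), grp), function(ii) {
      if (length(ii) == 1L) return(ii)
      o <- at$o[ii]
      best <- ii[o == max(o)]
      if (length(best) > 1L) {
        pick <- best[at$alt[best] == "A"]
        best <- if (length(pick)) pick[1] else best[order(at$alt[best])][1]
      }
      best
    }), use.names = FALSE)
    dropped <- nrow(at) - length(keep)
    if (dropped > 0)
      message(sprintf(
        "readReceptor: resolved alternate locations, dropped %d atom(s)",
        dropped))
    at <- at[sort(keep), , drop = FALSE]
  }

  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  elem[bad] <- .elementFromName(at$elety[bad])
  elem <- .elementFromName(elem)

  df <- data.frame(
    element = elem, name = at$elety,
    x = at$x, y = at$y, z = at$z,
    is_hydrogen = elem == "H",
    chain = at$chain, resno = at$resno, insert = at$insert,
    resname = at$resid, stringsAsFactors = FALSE)
  isAtom <- at$type == "ATOM"
  atoms <- df[isAtom, , drop = FALSE]
  hetero <- df[!isAtom, , drop = FALSE]
  rownames(atoms) <- rownames(hetero) <- NULL
  new("ReceptorStructure", atoms = atoms, hetero = hetero)
}

#' Write a receptor structure as PDB text
#'
#' Coordinates are written at PDB precision (3 decimals), so a
#' write-then-read round trip reproduces them exactly to that precision.
#'
#' @param x a \linkS4class{ReceptorStructure}.
#' @param file optional path; when NULL the PDB text is returned as a
#'   character vector of lines.
#' @return Invisibly the PDB lines (also written to \code{file} if given).
#' @export
writeReceptor <- function(x, file = NULL) {
  df <- rbind(
    cbind(x@atoms, type = if (nrow(x@atoms)) "ATOM" else character(0)),
    cbind(x@hetero, type = if (nrow(x@hetero)) "HETATM" else character(0)))
  if (!nrow(df)) stop("empty structure")
  fmt <- "%-6s%5d %-4s %-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  name4 <- ifelse(nchar(df$name) < 4, paste0(" ", df$name), df$name)
  lines <- sprintf(fmt, df$type, seq_len(nrow(df)),
                   substr(sprintf("%-4s", name4), 1, 4),
                   substr(sprintf("%-4s", df$resname), 1, 4),
                   substr(paste0(df$chain, " "), 1, 1),
                   as.integer(df$resno),
                   substr(paste0(df$insert, " "), 1, 1),
                   df$x, df$y, df$z, 1, 0, df$element)
  lines <- c(lines, "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read a ligand from MOL2 or SDF text
#'
#' The format is detected from the content (\code{@<TRIPOS>} blocks for
#' MOL2, a V2000 counts line for SDF). One molecule is read per call; for
#' multi-record input the first molecule is taken with a warning. When the
#' bond block is absent, connectivity is perceived from covalent radii via
#' \code{\link{perceiveBonds}} (with a warning).
#'
#' @param x MOL2 or SDF text: a file path, single string, or lines.
#' @return A \linkS4class{MolecularGraph}.
#' @export
readLigand <- function(x) {
  lines <- .asLines(x)
  if (any(grepl("@<TRIPOS>MOLECULE", lines, fixed = TRUE)))
    return(.readMol2(lines))
  if (any(grepl("V2000", lines, fixed = TRUE)))
    return(.readSdf(lines))
  stop("ligand format error: neither MOL2 nor SDF content recognised")
}

.readMol2 <- function(lines) {
  mol <- grep("@<TRIPOS>MOLECULE", lines, fixed = TRUE)
  if (length(mol) > 1L) {
    warning("multiple MOL2 molecules; taking the first")
    lines <- lines[seq_len(mol[2] - 1L)]
  }
  atomAt <- grep("@<TRIPOS>ATOM", lines, fixed = TRUE)
  if (!length(atomAt)) stop("ligand format error: MOL2 has no ATOM block")
  secStarts <- grep("^@<TRIPOS>", lines)
  .block <- function(start) {
    nxt <- secStarts[secStarts > start]
    end <- if (length(nxt)) nxt[1] - 1L else length(lines)
    blk <- lines[seq(start + 1L, end)]
    blk[nzchar(trimws(blk))]
  }
  atomLines <- .block(atomAt[1])
  if (!length(atomLines)) stop("ligand format error: zero-atom record")
  toks <- strsplit(trimws(atomLines), "[[:space:]]+")
  atoms <- data.frame(
    name = vapply(toks, `[`, "", 2),
    x = as.numeric(vapply(toks, `[`, "", 3)),
    y = as.numeric(vapply(toks, `[`, "", 4)),
    z = as.numeric(vapply(toks, `[`, "", 5)),
    stringsAsFactors = FALSE)
  atoms$element <- .elementFromName(vapply(toks, `[`, "", 6))
  atoms$is_hydrogen <- atoms$element == "H"

  bondAt <- grep("@<TRIPOS>BOND", lines, fixed = TRUE)
  if (!length(bondAt)) {
    warning("MOL2 bond block missing; perceiving bonds from covalent radii")
    bonds <- perceiveBonds(atoms)
  } else {
    bl <- .block(bondAt[1])
    bt <- strsplit(trimws(bl), "[[:space:]]+")
    bonds <- cbind(as.integer(vapply(bt, `[`, "", 2)),
                   as.integer(vapply(bt, `[`, "", 3)))
  }
  g <- MolecularGraph(atoms, bonds, provenance = "mol2")
  if (!.heavyConnected(g))
    warning("ligand heavy-atom graph is not connected")
  g
}

.readSdf <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) > 1L || (length(ends) == 1L && ends[1] < length(lines) &&
      any(nzchar(trimws(lines[seq(ends[1] + 1L, length(lines))]))))) {
    warning("multiple SDF records; taking the first")
    lines <- lines[seq_len(ends[1])]
  }
  counts <- grep("V2000", lines, fixed = TRUE)[1]
  nAtoms <- suppressWarnings(as.integer(substr(lines[counts], 1, 3)))
  nBonds <- suppressWarnings(as.integer(substr(lines[counts], 4, 6)))
  if (is.na(nAtoms) || nAtoms < 1L)
    stop("ligand format error: zero-atom record")
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  sdfset <- ChemmineR::read.SDFset(tmp)
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  atoms <- data.frame(
    element = .elementFromName(sub("_.*$", "", rownames(ab))),
    name = sub("_", "", rownames(ab)),
    x = ab[, 1], y = ab[, 2], z = ab[, 3],
    stringsAsFactors = FALSE)
  atoms$is_hydrogen <- atoms$element == "H"
  if (is.na(nBonds) || nBonds < 1L) {
    warning("SDF bond block missing; perceiving bonds from covalent radii")
    bonds <- perceiveBonds(atoms)
  } else {
    bb <- ChemmineR::bondblock(sdf)
    bonds <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  }
  g <- MolecularGraph(atoms, bonds, provenance = "sdf")
  if (!.heavyConnected(g))
    warning("ligand heavy-atom graph is not connected")
  g
}

#' Write a MolecularGraph as MOL2 text
#'
#' @param g a \linkS4class{MolecularGraph}.
#' @param name molecule name for the MOLECULE block.
#' @param file optional path; when NULL the lines are returned.
#' @return Invisibly the MOL2 lines.
#' @export
writeLigandMol2 <- function(g, name = "LIG", file = NULL) {
  a <- g@atoms
  b <- g@bonds
  lines <- c(
    "@<TRIPOS>MOLECULE", name,
    sprintf("%d %d 1 0 0", nrow(a), nrow(b)),
    "SMALL", "NO_CHARGES", "",
    "@<TRIPOS>ATOM",
    sprintf("%7d %-8s %9.4f %9.4f %9.4f %-5s %5d %-8s %9.4f",
            seq_len(nrow(a)), a$name, a$x, a$y, a$z, a$element, 1L,
            name, 0))
  if (nrow(b))
    lines <- c(lines, "@<TRIPOS>BOND",
               sprintf("%6d %5d %5d %4s", seq_len(nrow(b)),
                       b[, 1], b[, 2], "1"))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Perceive covalent bonds from interatomic distances
#'
#' Atoms i and j are bonded iff their distance lies in
#' \code{[0.4, r_i + r_j + 0.45]} Angstrom, where r are single-bond covalent
#' radii. Symmetric and invariant to atom order by construction.
#'
#' @param atoms data.frame of atoms (element, x, y, z), or a
#'   \linkS4class{MolecularGraph}.
#' @return Two-column integer matrix of bonded index pairs.
#' @examples
#' cc <- data.frame(element = c("C", "C"), x = c(0, 1.54), y = 0, z = 0)
#' perceiveBonds(cc)
#' @export
perceiveBonds <- function(atoms) {
  if (is(atoms, "MolecularGraph")) atoms <- atoms@atoms
  atoms <- as.data.frame(atoms)
  if (!nrow(atoms)) stop("at least one atom required")
  unknown <- setdiff(unique(atoms$element), .validElements())
  if (length(unknown))
    stop(sprintf("unknown element symbol(s): %s",
                 paste(unknown, collapse = ", ")))
  n <- nrow(atoms)
  if (n == 1L) return(matrix(integer(), ncol = 2))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- .crossDist(xyz, xyz)
  r <- .COVALENT_RADII[atoms$element]
  thr <- outer(r, r, "+") + 0.45
  hit <- d >= 0.4 & d <= thr
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  b <- cbind(as.integer(idx[, 1]), as.integer(idx[, 2]))
  b[order(b[, 1], b[, 2]), , drop = FALSE]
}

#' Read an RMSD time series from XVG or CSV text
#'
#' Accepts GROMACS-style XVG (lines beginning with \code{#} or \code{@} are
#' skipped) or two-column CSV/whitespace tables. Times are interpreted in
#' nanoseconds; values are converted to Angstrom when \code{unit = "nm"}
#' (multiplied by 10). All downstream thresholds are in Angstrom, so the
#' conversion happens here at the boundary.
#'
#' @param x text: a file path, single string, or lines.
#' @param unit unit of the value column, \code{"angstrom"} or \code{"nm"}.
#' @param replicate replicate id to attach.
#' @return An \linkS4class{RmsdSeries}.
#' @export
readRmsdSeries <- function(x, unit = c("angstrom", "nm"),
                           replicate = "rep1") {
  unit <- match.arg(unit)
  lines <- .asLines(x)
  lines <- lines[!grepl("^[[:space:]]*[#@]", lines)]
  lines <- lines[nzchar(trimws(lines))]
  # drop a non-numeric header row if present
  if (length(lines)) {
    first <- strsplit(trimws(lines[1]), "[,;[:space:]]+")[[1]]
    if (any(is.na(suppressWarnings(as.numeric(first)))))
      lines <- lines[-1]
  }
  if (length(lines) < 2L)
    stop("RMSD series must contain at least 2 data points")
  toks <- strsplit(trimws(lines), "[,;[:space:]]+")
  times <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 1)))
  values <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 2)))
  if (any(is.na(times)) || any(is.na(values)))
    stop("RMSD series format error: non-numeric data row")
  if (any(diff(times) <= 0))
    stop("RMSD series error: time column is not strictly increasing")
  if (unit == "nm") values <- values * 10
  RmsdSeries(times, values, replicate = replicate)
}
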