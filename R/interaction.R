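#' Packaged SGLT2 key-residue list
#'
#' The nine binding-site residues within 5 Angstrom of the reference
#' empagliflozin pose in the SGLT2-MAP17 complex (ASN 75, HIS 80, THR 87,
#' PHE 98, GLU 99, SER 287, TYR 290, LYS 321, GLN 457), shipped as a
#' packaged fixture and used as the default key-residue list.
#'
#' @param contactCutoff contact cutoff in Angstrom (default 5).
#' @return A \linkS4class{KeyResidueSpec}.
#' @export
sglt2KeyResidues <- function(contactCutoff = 5.0) {
  path <- system.file("extdata", "sglt2_key_residues.tsv",
                      package = "DockTriage", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  keyResidueSpec(df, contactCutoff = contactCutoff)
}

#' Find receptor residues in close contact with a ligand pose
#'
#' A residue is in close contact iff the minimum over all (ligand heavy
#' atom, residue heavy atom) pairs of the Euclidean distance is at most the
#' cutoff (default 5 Angstrom, the close-contact definition used to derive
#' the key-residue list). For context, every residue with any heavy atom
#' within cutoff + 2 Angstrom is reported.
#'
#' @param pose \linkS4class{MolecularGraph} in the receptor frame.
#' @param receptor \linkS4class{ReceptorStructure}.
#' @param cutoff contact cutoff in Angstrom.
#' @return data.frame (chain, resno, insert, resname, min_dist, contact).
#' @export
findCloseContacts <- function(pose, receptor, cutoff = 5.0) {
  lidx <- .heavyIdx(pose)
  if (!length(lidx)) stop("empty pose: no heavy atoms")
  L <- as.matrix(pose@atoms[lidx, c("x", "y", "z")])
  ra <- receptor@atoms
  ra <- ra[!ra$is_hydrogen, , drop = FALSE]
  if (!nrow(ra)) stop("receptor has no heavy atoms")
  d <- .crossDist(as.matrix(ra[, c("x", "y", "z")]), L)
  minAtom <- apply(d, 1, min)
  key <- .resKeysOf(ra)
  minRes <- tapply(minAtom, key, min)
  first <- !duplicated(key)
  out <- data.frame(
    chain = ra$chain[first], resno = ra$resno[first],
    insert = ra$insert[first], resname = ra$resname[first],
    stringsAsFactors = FALSE)
  out$min_dist <- as.numeric(minRes[key[first]])
  out$contact <- out$min_dist <= cutoff
  out <- out[out$min_dist <= cutoff + 2, , drop = FALSE]
  out <- out[order(out$min_dist), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Hydrogens attached to receptor heavy atom rows: receptor PDBs carry no
# connectivity, so attachment is distance-based (< 1.3 A within the residue).
.receptorHydrogens <- function(ra, heavyRow) {
  hk <- .resKeysOf(ra) == .resKeysOf(ra[heavyRow, , drop = FALSE])
  hs <- which(ra$is_hydrogen & hk)
  if (!length(hs)) return(integer(0))
  dd <- .crossDist(as.matrix(ra[hs, c("x", "y", "z"), drop = FALSE]),
                   as.matrix(ra[heavyRow, c("x", "y", "z"), drop = FALSE]))
  hs[dd[, 1] < 1.3]
}

.dhAngle <- function(D, H, A) {
  v1 <- D - H; v2 <- A - H
  cosv <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
}

#' Detect hydrogen bonds between a ligand pose and a receptor
#'
#' Donor/acceptor typing: N and O atoms act as donors when they carry a
#' hydrogen and as acceptors always (S is excluded). A bond is reported
#' when the donor-acceptor distance, the hydrogen-acceptor distance and the
#' D-H-A angle all pass the criteria. When hydrogens are absent from both
#' candidate donors of a pair (common for crystallographic receptors) no
#' strict evaluation is possible; with \code{heavyAtomFallback} set the
#' criterion then degrades to the donor-heavy to acceptor-heavy distance
#' gate alone. A pair whose explicit-hydrogen geometry was evaluated and
#' failed is never rescued by the fallback.
#'
#' @param pose \linkS4class{MolecularGraph}.
#' @param receptor \linkS4class{ReceptorStructure}.
#' @param criteria \linkS4class{HBondCriteria}.
#' @return data.frame of detected bonds: donor/acceptor descriptions,
#'   residue key columns, distances and angle (NA under the fallback).
#'   Zero rows when none found.
#' @export
detectHBonds <- function(pose, receptor, criteria = hbondCriteria()) {
  empty <- data.frame(
    donor = character(0), hydrogen = character(0), acceptor = character(0),
    chain = character(0), resno = numeric(0), insert = character(0),
    resname = character(0), dist_DA = numeric(0), dist_HA = numeric(0),
    angle = numeric(0), stringsAsFactors = FALSE)

  la <- pose@atoms
  lpolar <- which(!la$is_hydrogen & la$element %in% c("N", "O"))
  ra <- receptor@atoms
  rpolar <- which(!ra$is_hydrogen & ra$element %in% c("N", "O"))
  if (!length(lpolar) || !length(rpolar)) return(empty)

  Lxyz <- as.matrix(la[, c("x", "y", "z")])
  Rxyz <- as.matrix(ra[, c("x", "y", "z")])
  dDA <- .crossDist(Lxyz[lpolar, , drop = FALSE],
                    Rxyz[rpolar, , drop = FALSE])

  b <- pose@bonds
  ligH <- function(i) {
    if (!nrow(b)) return(integer(0))
    nb <- c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
    nb[la$is_hydrogen[nb]]
  }

  rows <- list()
  pairs <- which(dDA <= criteria@maxDA, arr.ind = TRUE)
  if (nrow(pairs)) for (p in seq_len(nrow(pairs))) {
    li <- lpolar[pairs[p, 1]]
    ri <- rpolar[pairs[p, 2]]
    da <- dDA[pairs[p, 1], pairs[p, 2]]
    hit <- NULL
    strictPossible <- FALSE
    # direction 1: ligand donor -> receptor acceptor
    hs <- ligH(li)
    if (length(hs)) {
      strictPossible <- TRUE
      for (h in hs) {
        dHA <- sqrt(sum((Lxyz[h, ] - Rxyz[ri, ])^2))
        ang <- .dhAngle(Lxyz[li, ], Lxyz[h, ], Rxyz[ri, ])
        if (dHA <= criteria@maxHA && ang >= criteria@minAngle) {
          hit <- list(h = la$name[h], dHA = dHA, ang = ang,
                      donor = paste0("lig:", la$name[li]),
                      acceptor = paste0("rec:", ra$name[ri]))
          break
        }
      }
    }
    # direction 2: receptor donor -> ligand acceptor
    if (is.null(hit)) {
      hs <- .receptorHydrogens(ra, ri)
      if (length(hs)) {
        strictPossible <- TRUE
        for (h in hs) {
          dHA <- sqrt(sum((Rxyz[h, ] - Lxyz[li, ])^2))
          ang <- .dhAngle(Rxyz[ri, ], Rxyz[h, ], Lxyz[li, ])
          if (dHA <= criteria@maxHA && ang >= criteria@minAngle) {
            hit <- list(h = ra$name[h], dHA = dHA, ang = ang,
                        donor = paste0("rec:", ra$name[ri]),
                        acceptor = paste0("lig:", la$name[li]))
            break
          }
        }
      }
    }
    # fallback: no explicit-hydrogen geometry was evaluable on either side
    if (is.null(hit) && !strictPossible && criteria@heavyAtomFallback) {
      hit <- list(h = NA_character_, dHA = NA_real_, ang = NA_real_,
                  donor = paste0("lig:", la$name[li]),
                  acceptor = paste0("rec:", ra$name[ri]))
    }
    if (!is.null(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        donor = hit$donor, hydrogen = hit$h, acceptor = hit$acceptor,
        chain = ra$chain[ri], resno = ra$resno[ri],
        insert = ra$insert[ri], resname = ra$resname[ri],
        dist_DA = da, dist_HA = hit$dHA, angle = hit$ang,
        stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score a pose against a key-residue list
#'
#' Computes close contacts and hydrogen bonds for a pose, then the weighted
#' key-residue score (default 2 per H-bonded key residue, 1 per key residue
#' in contact only) and the proportion of key residues engaged (contact or
#' H-bond), the weight-free triage quantity. Key residues absent from the
#' receptor raise a warning and count as not engaged.
#'
#' @param pose \linkS4class{MolecularGraph}.
#' @param receptor \linkS4class{ReceptorStructure}.
#' @param spec \linkS4class{KeyResidueSpec}; defaults to the packaged
#'   SGLT2 list.
#' @param criteria \linkS4class{HBondCriteria}.
#' @param weights named numeric: \code{hbond} and \code{contact} weights.
#' @return An \linkS4class{InteractionReport}.
#' @export
keyResidueScore <- function(pose, receptor, spec = sglt2KeyResidues(),
                            criteria = hbondCriteria(),
                            weights = c(hbond = 2, contact = 1)) {
  stopifnot(all(c("hbond", "contact") %in% names(weights)))
  contacts <- findCloseContacts(pose, receptor, cutoff = spec@contactCutoff)
  hbonds <- detectHBonds(pose, receptor, criteria)

  recKeys <- .resKeysOf(residueKeys(receptor))
  keyKeys <- .resKeysOf(spec@residues)
  missing <- setdiff(keyKeys, recKeys)
  if (length(missing))
    warning(sprintf("key residue(s) absent from receptor: %s",
                    paste(missing, collapse = ", ")))

  contactKeys <- .resKeysOf(contacts)[contacts$contact]
  hbondKeys <- if (nrow(hbonds)) unique(.resKeysOf(hbonds)) else character(0)

  res <- contacts
  res$hbond <- .resKeysOf(res) %in% hbondKeys
  res$is_key <- .resKeysOf(res) %in% keyKeys
  # key residues outside the reporting radius still appear, unengaged
  far <- setdiff(setdiff(keyKeys, missing), .resKeysOf(res))
  if (length(far)) {
    kdf <- spec@residues[keyKeys %in% far, , drop = FALSE]
    kdf$min_dist <- NA_real_; kdf$contact <- FALSE
    kdf$hbond <- FALSE; kdf$is_key <- TRUE
    res <- rbind(res, kdf[, names(res)])
  }

  keyHb <- keyKeys %in% hbondKeys
  keyCt <- keyKeys %in% contactKeys
  engaged <- keyHb | keyCt
  score <- sum(ifelse(keyHb, weights[["hbond"]],
                      ifelse(keyCt, weights[["contact"]], 0)))
  overlap <- sum(engaged) / length(keyKeys)
  new("InteractionReport", residues = res, hbonds = hbonds,
      score = score, overlap = overlap,
      weights = c(hbond = weights[["hbond"]],
                  contact = weights[["contact"]]))
}
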