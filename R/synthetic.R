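# Seeded synthetic-data generators. Every generator records the ground
# truth it plants, so each analysis stage can be tested against known
# answers without any external downloads. Same seed + parameters always
# reproduces byte-identical artifacts.

.jitter <- function(n, amp = 0.02) stats::runif(n, -amp, amp)

#' Synthetic binding-pocket fixture with planted contacts and H-bonds
#'
#' Builds a receptor/ligand pair in a shared frame such that exactly
#' \code{nKeyContacts} residues of the packaged SGLT2 key-residue list have
#' a minimum heavy-atom distance within 5 Angstrom of the ligand, of which
#' the first \code{nHbonds} additionally present an ideal hydrogen-bond
#' geometry (H...acceptor 1.9 Angstrom, D-H-A angle 170 degrees, planted
#' well inside the default criteria so detection is insensitive to their
#' exact values). Decoy residues are placed beyond 7 Angstrom. Interaction
#' sites are spaced 3 Angstrom apart along a carbon-chain ligand so no
#' cross-site geometry can satisfy the hydrogen-bond gates.
#'
#' @param nKeyContacts number of key residues planted within the 5 A
#'   cutoff (at most the 9 residues of the key list).
#' @param nHbonds of those, how many get an ideal H-bond geometry
#'   (\code{nHbonds <= nKeyContacts}).
#' @param nDecoys residues planted beyond 7 Angstrom.
#' @param seed RNG seed (coordinates receive a +-0.02 A seeded jitter).
#' @return List: \code{receptor} (\linkS4class{ReceptorStructure}),
#'   \code{ligand} (\linkS4class{MolecularGraph}), \code{receptorText}
#'   (PDB lines), \code{ligandText} (MOL2 lines), \code{groundTruth}
#'   (planted contact/H-bond residue keys and decoy count), \code{seed}.
#' @export
makePocketFixture <- function(nKeyContacts, nHbonds, nDecoys, seed = 1) {
  keys <- sglt2KeyResidues()@residues
  if (nHbonds > nKeyContacts)
    stop("infeasible packing: nHbonds must not exceed nKeyContacts")
  if (nKeyContacts > nrow(keys))
    stop(sprintf("infeasible packing: key-residue list has only %d entries",
                 nrow(keys)))
  .withSeed(seed, {
    nSites <- max(nKeyContacts, 2L)
    nChain <- 2L * nSites - 1L
    siteX <- 3.0 * (seq_len(nSites) - 1L)

    lig <- data.frame(
      element = rep("C", nChain),
      name = sprintf("C%d", seq_len(nChain)),
      x = 1.5 * (seq_len(nChain) - 1L), y = 0, z = 0,
      stringsAsFactors = FALSE)
    bonds <- cbind(seq_len(nChain - 1L), seq_len(nChain - 1L) + 1L)

    recRows <- list()
    addRes <- function(elements, names, xyz, chain, resno, resname) {
      recRows[[length(recRows) + 1L]] <<- data.frame(
        element = elements, name = names,
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        is_hydrogen = elements == "H",
        chain = chain, resno = resno, insert = "", resname = resname,
        stringsAsFactors = FALSE)
    }

    for (i in seq_len(nKeyContacts)) {
      kx <- siteX[i]
      if (i <= nHbonds) {
        # ligand donor O-H pointing at the residue acceptor: H...A 1.9 A,
        # D-H-A 170 degrees
        ligO <- c(kx, 1.40, 0)
        ligH <- c(kx, 2.37, 0)
        acc <- ligH + 1.9 * c(sin(10 * pi / 180), cos(10 * pi / 180), 0)
        ci <- 2L * i - 1L
        lig <- rbind(lig, data.frame(
          element = c("O", "H"), name = sprintf(c("O%d", "H%d"), i),
          x = c(ligO[1], ligH[1]), y = c(ligO[2], ligH[2]),
          z = c(ligO[3], ligH[3]), stringsAsFactors = FALSE))
        nO <- nrow(lig) - 1L
        bonds <- rbind(bonds, c(ci, nO), c(nO, nO + 1L))
        xyz <- rbind(acc, acc + c(0, 1.4, 0), acc + c(0, 2.8, 0))
      } else {
        xyz <- rbind(c(kx, 4.8, 0), c(kx, 6.2, 0), c(kx, 7.6, 0))
      }
      addRes(c("O", "C", "C"), c("OD1", "CB", "CA"), xyz,
             keys$chain[i], keys$resno[i], keys$resname[i])
    }
    # key residues not planted as contacts sit far outside the pocket
    for (i in setdiff(seq_len(nrow(keys)), seq_len(nKeyContacts))) {
      xyz <- rbind(c(3.0 * (i - 1L), -14.0, 0),
                   c(3.0 * (i - 1L), -15.4, 0),
                   c(3.0 * (i - 1L), -16.8, 0))
      addRes(c("O", "C", "C"), c("OD1", "CB", "CA"), xyz,
             keys$chain[i], keys$resno[i], keys$resname[i])
    }
    for (d in seq_len(nDecoys)) {
      xyz <- rbind(c(3.0 * (d - 1L), -8.0 - 0.3 * d, 0),
                   c(3.0 * (d - 1L), -9.4 - 0.3 * d, 0),
                   c(3.0 * (d - 1L), -10.8 - 0.3 * d, 0))
      addRes(c("O", "C", "C"), c("O", "CB", "CA"), xyz,
             "A", 900L + d, "GLY")
    }

    rec <- do.call(rbind, recRows)
    # seeded jitter, small against every planted geometric margin
    lig$x <- lig$x + .jitter(nrow(lig)); lig$y <- lig$y + .jitter(nrow(lig))
    lig$z <- lig$z + .jitter(nrow(lig))
    rec$x <- rec$x + .jitter(nrow(rec)); rec$y <- rec$y + .jitter(nrow(rec))
    rec$z <- rec$z + .jitter(nrow(rec))
    lig$is_hydrogen <- lig$element == "H"

    ligand <- MolecularGraph(lig, bonds, provenance = "synthetic")
    receptor <- new("ReceptorStructure", atoms = rec,
                    hetero = rec[0, , drop = FALSE])
    gt <- list(
      contactResidues = keys[seq_len(nKeyContacts), , drop = FALSE],
      hbondResidues = keys[seq_len(nHbonds), , drop = FALSE],
      nDecoys = nDecoys)
    list(receptor = receptor, ligand = ligand,
         receptorText = writeReceptor(receptor),
         ligandText = writeLigandMol2(ligand, name = "SYNLIG"),
         groundTruth = gt, seed = seed)
  })
}

#' Synthetic ligand graphs with known symmetry groups
#'
#' \code{chain}: a C-N-O chain (asymmetric, 1 automorphism);
#' \code{ring6}: an all-carbon six-ring, ideal hexagon geometry (dihedral
#' symmetry, 12 automorphisms); \code{ring6_hetero}: the same ring with one
#' nitrogen (only the reflection through the nitrogen survives,
#' 2 automorphisms).
#'
#' @param kind one of \code{"chain"}, \code{"ring6"},
#'   \code{"ring6_hetero"}.
#' @param seed RNG seed (coordinates receive a +-0.01 A jitter).
#' @return List: \code{graph} (\linkS4class{MolecularGraph}),
#'   \code{automorphisms} (known count), \code{kind}, \code{seed}.
#' @export
makeSymmetricLigand <- function(kind = c("chain", "ring6", "ring6_hetero"),
                                seed = 1) {
  kind <- match.arg(kind)
  .withSeed(seed, {
    if (kind == "chain") {
      atoms <- data.frame(
        element = c("C", "N", "O"), name = c("C1", "N1", "O1"),
        x = c(0, 1.47, 2.90), y = 0, z = 0, stringsAsFactors = FALSE)
      bonds <- rbind(c(1L, 2L), c(2L, 3L))
      autos <- 1L
    } else {
      ang <- 2 * pi * (0:5) / 6
      atoms <- data.frame(
        element = if (kind == "ring6") rep("C", 6)
                  else c("N", rep("C", 5)),
        name = sprintf("%s%d",
                       if (kind == "ring6") "C" else c("N", rep("C", 5)),
                       1:6),
        x = 1.39 * cos(ang), y = 1.39 * sin(ang), z = 0,
        stringsAsFactors = FALSE)
      bonds <- cbind(1:6, c(2:6, 1L))
      autos <- if (kind == "ring6") 12L else 2L
    }
    atoms$x <- atoms$x + .jitter(nrow(atoms), 0.01)
    atoms$y <- atoms$y + .jitter(nrow(atoms), 0.01)
    atoms$z <- atoms$z + .jitter(nrow(atoms), 0.01)
    list(graph = MolecularGraph(atoms, bonds, provenance = "synthetic"),
         automorphisms = autos, kind = kind, seed = seed)
  })
}

#' Synthetic stable / escaping RMSD trajectory triples
#'
#' Emulates the two families of post-docking ligand-RMSD traces: a
#' \code{stable} pose fluctuates around \code{mu} (a positive-clipped
#' autocorrelated Gaussian, clipped to \code{mu + 4 sigma}, which the
#' precondition keeps below the 5.5 Angstrom threshold), while an
#' \code{escaping} pose leaves the site at \code{crossTime}: from that
#' frame the trace jumps above the threshold and keeps drifting upward, so
#' the first threshold crossing lands exactly on the requested frame.
#' The default grid is 1000 frames at 0.01 ns, i.e. a 10 ns simulation.
#'
#' @param kind \code{"stable"} or \code{"escaping"}.
#' @param mu baseline RMSD (Angstrom).
#' @param sigma noise scale (Angstrom).
#' @param crossTime escape time in ns (escaping only; must precede the
#'   9 ns window start so the window is fully censored).
#' @param nFrames frames per replicate.
#' @param dt frame spacing, ns.
#' @param seed RNG seed.
#' @return List: \code{replicates} (list of 3 \linkS4class{RmsdSeries}),
#'   \code{label} (\code{kind}), \code{params}, \code{seed}.
#' @export
makeTrajectory <- function(kind = c("stable", "escaping"), mu = 1.5,
                           sigma = 0.2, crossTime = 4, nFrames = 1000,
                           dt = 0.01, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "stable" && mu + 4 * sigma >= 5.5)
    stop("stable trajectory requires mu + 4*sigma < 5.5 Angstrom")
  if (kind == "escaping" && crossTime >= 9)
    stop("escaping trajectory requires crossTime < 9 ns")
  .withSeed(seed, {
    times <- dt * seq_len(nFrames)
    reps <- lapply(1:3, function(r) {
      e <- numeric(nFrames)
      innov <- stats::rnorm(nFrames, sd = sigma * sqrt(1 - 0.8^2))
      e[1] <- stats::rnorm(1, sd = sigma)
      for (t in 2:nFrames) e[t] <- 0.8 * e[t - 1] + innov[t]
      v <- pmin(pmax(mu + e, 0.01), min(mu + 4 * sigma, 5.4))
      if (kind == "escaping") {
        esc <- times >= crossTime
        # escape ramp capped at the censor value: the early-stop mechanism
        # terminates a real run at the crossing, so no frame exceeds it
        v[esc] <- pmin(6.0 + 2 * (times[esc] - crossTime) + abs(e[esc]), 10)
      }
      RmsdSeries(times, v, replicate = sprintf("rep%d", r))
    })
    list(replicates = reps, label = kind,
         params = list(mu = mu, sigma = sigma, crossTime = crossTime,
                       nFrames = nFrames, dt = dt), seed = seed)
  })
}

#' Synthetic ranked screen with planted actives
#'
#' Draws docking-like scores (lower is better) for \code{n} compounds and
#' places \code{nActives} active labels either on the best-scoring
#' compounds (\code{top_bin}) or uniformly at random (\code{uniform}).
#' Rows are returned shuffled, so ranking order never leaks from row
#' order. The expected enrichment factor at fraction \code{f} follows in
#' closed form for \code{top_bin}: \code{(N / N_top) * min(1, N_top /
#' nActives)}; for \code{uniform} it is 1 in expectation.
#'
#' @param n library size.
#' @param nActives number of planted actives (\code{<= n}).
#' @param placement \code{"top_bin"} or \code{"uniform"}.
#' @param f fraction used for the recorded expected EF (default 0.01).
#' @param seed RNG seed.
#' @return List: \code{table} (\linkS4class{ScreenTable}),
#'   \code{expectedEF} (closed form for \code{top_bin}, 1 for
#'   \code{uniform}), \code{nTop}, \code{activeIds}, \code{seed}.
#' @export
makeScreen <- function(n, nActives, placement = c("top_bin", "uniform"),
                       f = 0.01, seed = 1) {
  placement <- match.arg(placement)
  if (nActives > n) stop("nActives must not exceed n")
  .withSeed(seed, {
    ids <- sprintf("CMP%05d", seq_len(n))
    scores <- round(stats::rnorm(n, mean = -80, sd = 10), 4)
    ord <- order(scores, ids)
    active <- logical(n)
    pos <- switch(placement,
      top_bin = ord[seq_len(nActives)],
      uniform = sample(n, nActives))
    active[pos] <- TRUE
    df <- data.frame(id = ids, score = scores, active = active,
                     stringsAsFactors = FALSE)
    df <- df[sample(n), , drop = FALSE]
    rownames(df) <- NULL
    nTop <- .topBinSize(n, f)
    expectedEF <- if (placement == "top_bin")
      (n / nTop) * min(1, nTop / nActives) else 1
    list(table = screenTable(df), expectedEF = expectedEF, nTop = nTop,
         activeIds = ids[pos], seed = seed)
  })
}
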