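# Independent oracles and random-molecule generators for the test suite.
# The oracles deliberately share no code with the package's search
# implementation: mappings are found by exhaustive permutation.

# all permutations of a vector (n <= 8 in the suite)
all_perms <- function(v) {
  n <- length(v)
  if (n <= 1) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# exhaustive element- and bond-preserving bijections between the heavy
# atoms of two MolecularGraphs; permutations are composed per element
# class to keep the enumeration tractable
brute_force_mappings <- function(a, b) {
  ha <- which(!atomTable(a)$is_hydrogen)
  hb <- which(!atomTable(b)$is_hydrogen)
  ea <- atomTable(a)$element[ha]
  eb <- atomTable(b)$element[hb]
  stopifnot(length(ha) == length(hb), identical(sort(ea), sort(eb)))
  n <- length(ha)
  adj_of <- function(g, idx) {
    m <- matrix(FALSE, length(idx), length(idx))
    bm <- bondMatrix(g)
    if (nrow(bm)) for (r in seq_len(nrow(bm))) {
      i <- match(bm[r, 1], idx); j <- match(bm[r, 2], idx)
      if (!is.na(i) && !is.na(j)) { m[i, j] <- TRUE; m[j, i] <- TRUE }
    }
    m
  }
  adjA <- adj_of(a, ha); adjB <- adj_of(b, hb)

  classes <- unique(ea)
  per_class <- lapply(classes, function(el)
    all_perms(which(eb == el)))
  slots <- lapply(classes, function(el) which(ea == el))

  maps <- list()
  recurse <- function(ci, map) {
    if (ci > length(classes)) {
      if (all(adjA == adjB[map, map]))
        maps[[length(maps) + 1]] <<- map
      return(invisible())
    }
    for (p in per_class[[ci]]) {
      m2 <- map; m2[slots[[ci]]] <- p
      recurse(ci + 1, m2)
    }
  }
  recurse(1, integer(n))
  maps
}

brute_force_sym_rmsd <- function(a, b) {
  ha <- which(!atomTable(a)$is_hydrogen)
  hb <- which(!atomTable(b)$is_hydrogen)
  ca <- as.matrix(atomTable(a)[ha, c("x", "y", "z")])
  cb <- as.matrix(atomTable(b)[hb, c("x", "y", "z")])
  maps <- brute_force_mappings(a, b)
  min(vapply(maps, function(m)
    sqrt(sum((ca - cb[m, , drop = FALSE])^2) / nrow(ca)), numeric(1)))
}

# random connected molecule with <= 8 heavy atoms (random spanning tree
# plus occasional extra edges), elements drawn from C/N/O
random_molecule <- function(n_heavy, seed) {
  set.seed(seed)
  el <- sample(c("C", "N", "O"), n_heavy, replace = TRUE,
               prob = c(0.6, 0.2, 0.2))
  atoms <- data.frame(element = el, name = paste0(el, seq_len(n_heavy)),
                      x = runif(n_heavy, -4, 4), y = runif(n_heavy, -4, 4),
                      z = runif(n_heavy, -4, 4), stringsAsFactors = FALSE)
  bonds <- NULL
  for (i in seq_len(n_heavy)[-1])
    bonds <- rbind(bonds, c(sample(i - 1, 1), i))
  n_extra <- sample(0:2, 1)
  if (n_heavy > 2 && n_extra > 0) for (k in seq_len(n_extra)) {
    ij <- sort(sample(n_heavy, 2))
    bonds <- rbind(bonds, ij)
  }
  MolecularGraph(atoms, bonds, provenance = "synthetic")
}

# the same graph with coordinates perturbed (a fake second docking pose)
perturbed_pose <- function(g, seed, sd = 0.5) {
  set.seed(seed)
  a <- atomTable(g)
  a$x <- a$x + rnorm(nrow(a), sd = sd)
  a$y <- a$y + rnorm(nrow(a), sd = sd)
  a$z <- a$z + rnorm(nrow(a), sd = sd)
  MolecularGraph(a, bondMatrix(g), provenance = "synthetic")
}

# ideal benzene carbon ring, optionally rotated about its normal
hexagon_ring <- function(rot = 0) {
  ang <- 2 * pi * (0:5) / 6 + rot
  MolecularGraph(
    data.frame(element = "C", name = sprintf("C%d", 1:6),
               x = 1.39 * cos(ang), y = 1.39 * sin(ang), z = 0,
               stringsAsFactors = FALSE),
    cbind(1:6, c(2:6, 1)), provenance = "synthetic")
}

# constant-valued replicate triple on the standard 10 ns grid
constant_replicates <- function(value, n_frames = 100, dt = 0.1) {
  times <- dt * seq_len(n_frames)
  lapply(1:3, function(r)
    RmsdSeries(times, rep(value, n_frames),
               replicate = sprintf("rep%d", r)))
}
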