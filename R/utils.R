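# Internal helpers shared across modules.

# Accept a file path, a single string with embedded newlines, or a character
# vector of lines; return a character vector of lines.
.asLines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    return(readLines(x, warn = FALSE))
  if (length(x) == 1L && grepl("\n", x, fixed = TRUE))
    return(strsplit(x, "\n", fixed = TRUE)[[1]])
  as.character(x)
}

# Element symbol from a PDB/MOL2 atom name or SYBYL type: strip digits,
# primes and SYBYL suffixes, then normalise case against the known table.
.elementFromName <- function(name) {
  vapply(name, function(nm) {
    nm <- sub("\\..*$", "", nm)              # SYBYL "C.3" -> "C"
    nm <- gsub("[0-9'\"]+", "", trimws(nm))
    if (!nzchar(nm)) return(NA_character_)
    cand2 <- paste0(toupper(substr(nm, 1, 1)),
                    tolower(substr(nm, 2, 2)))
    if (nchar(nm) >= 2 && cand2 %in% .validElements()) return(cand2)
    cand1 <- toupper(substr(nm, 1, 1))
    if (cand1 %in% .validElements()) return(cand1)
    nm
  }, character(1), USE.NAMES = FALSE)
}

# Euclidean distance matrix between the rows of two coordinate matrices.
.crossDist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Canonical string form of a residue key, e.g. "A:75:ASN" or "A:75A:ASN".
.resKeyString <- function(chain, resno, insert, resname) {
  ins <- ifelse(is.na(insert) | insert == " ", "", insert)
  sprintf("%s:%s%s:%s", chain, resno, ins, resname)
}

.resKeysOf <- function(df) {
  ins <- if ("insert" %in% names(df)) df$insert else ""
  .resKeyString(df$chain, df$resno, ins, df$resname)
}

# Indices of heavy atoms in a MolecularGraph.
.heavyIdx <- function(g) which(!g@atoms$is_hydrogen)

# Heavy-atom projection of a MolecularGraph: coordinates, elements and an
# adjacency matrix with indices remapped to the heavy subset.
.heavyView <- function(g) {
  idx <- .heavyIdx(g)
  n <- length(idx)
  remap <- integer(nrow(g@atoms)); remap[idx] <- seq_len(n)
  adj <- matrix(FALSE, n, n)
  b <- g@bonds
  if (nrow(b)) {
    keep <- b[, 1] %in% idx & b[, 2] %in% idx
    if (any(keep)) {
      bi <- remap[b[keep, 1]]; bj <- remap[b[keep, 2]]
      adj[cbind(bi, bj)] <- TRUE
      adj[cbind(bj, bi)] <- TRUE
    }
  }
  list(idx = idx, n = n,
       coords = as.matrix(g@atoms[idx, c("x", "y", "z")]),
       elements = g@atoms$element[idx],
       adj = adj, degree = rowSums(adj))
}

# Is the heavy-atom graph connected? (BFS)
.heavyConnected <- function(g) {
  hv <- .heavyView(g)
  if (hv$n <= 1) return(TRUE)
  seen <- logical(hv$n); seen[1] <- TRUE
  queue <- 1L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nb <- which(hv$adj[i, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}
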