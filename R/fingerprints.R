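# Hashed molecular fingerprints: topological (connected-subgraph / linear-path)
# and circular (ECFP-style), with Tanimoto similarity.
#
# Bit positions come from a 32-bit FNV-1a hash implemented in exact double
# arithmetic, so fingerprints are bit-identical across platforms and runs.

.fnv_offset <- 2166136261
.fnv_prime <- 16777619

# (a * .fnv_prime) mod 2^32 without exceeding 2^53
.fnv_mul <- function(a) {
  ah <- a %/% 65536
  al <- a %% 65536
  (((ah * .fnv_prime) %% 65536) * 65536 + al * .fnv_prime) %% 4294967296
}

.fnv_hash <- function(ints) {
  h <- .fnv_offset
  for (x in ints) {
    h <- .fnv_mul(.bitxor32(h, x %% 4294967296))
  }
  h
}

.bitxor32 <- function(a, b) {
  # xor of two doubles holding 32-bit unsigned values
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
    bitwXor(as.integer(al), as.integer(bl))
}

.atom_code <- function(atoms) {
  match(atoms$element, .elements$symbol) * 100 +
    (pmax(pmin(atoms$charge, 4L), -4L) + 4L) * 10 +
    as.integer(atoms$aromatic)
}

.bond_code <- function(bonds) {
  ifelse(bonds$aromatic, 5L, bonds$order)
}

.as_molecule <- function(x) {
  if (inherits(x, "molecule")) x
  else if (is.character(x) && length(x) == 1L) parse_smiles(x)
  else if (inherits(x, "compound_set") && nrow(x) == 1L) parse_smiles(x$smiles)
  else stop("expected a SMILES string, molecule, or single-row compound_set",
            call. = FALSE)
}

.new_fingerprint <- function(bits, nbits, kind, params) {
  structure(list(bits = sort(unique(bits)), nbits = nbits, kind = kind,
                 params = params),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<%s fingerprint: %d/%d bits set>\n", x$kind,
              length(x$bits), x$nbits))
  invisible(x)
}

# 32-bit multiplicative mix (Knuth), exact in double arithmetic.
.mix32 <- function(x) {
  ah <- x %/% 65536
  al <- x %% 65536
  (((ah * 2654435761) %% 65536) * 65536 + al * 2654435761) %% 4294967296
}

# Deterministic isomorphism-invariant hash of a bond-induced subgraph:
# two rounds of Weisfeiler-Lehman refinement with commutative (sum-based)
# neighbour aggregation, so the result is independent of atom and bond
# enumeration order. Identical labelled subgraphs hash identically across
# molecules; WL-2 separates everything that occurs at <= 7 bonds in organic
# chemistry to within negligible collision rates.
.subgraph_hash <- function(sub_bonds, bi, bj, bcode, acode) {
  sa <- c(bi[sub_bonds], bj[sub_bonds])
  atoms <- unique.default(sa)
  lab <- acode[atoms]
  la <- match(bi[sub_bonds], atoms)
  lb <- match(bj[sub_bonds], atoms)
  bc <- bcode[sub_bonds]
  m <- length(sub_bonds)
  for (round in 1:2) {
    ca <- .mix32(lab[la] * 8 + bc)   # contribution across each edge
    cb <- .mix32(lab[lb] * 8 + bc)
    acc <- numeric(length(atoms))
    for (e in seq_len(m)) {          # <= max_path edges: cheap scalar adds
      acc[la[e]] <- acc[la[e]] + cb[e]
      acc[lb[e]] <- acc[lb[e]] + ca[e]
    }
    lab <- .mix32((lab * 3 + acc) %% 4294967296)
  }
  (sum(.mix32(lab)) + 131 * m) %% 4294967296
}

#' Topological (path/subgraph) fingerprint
#'
#' Daylight-style hashed topological fingerprint. By default all connected
#' subgraphs of 1 to `max_path` bonds are enumerated (the behaviour of the
#' reference toolkit's topological fingerprint, which the reported
#' cluster-similarity levels require); `branched = FALSE` restricts the
#' enumeration to strictly linear bond paths. Each subgraph is reduced to an
#' isomorphism-invariant hash (atoms: element/charge/aromaticity; bonds:
#' order or aromatic) and folded onto `nbits` positions with
#' `bits_per_hash` bits per feature.
#'
#' @param x SMILES string or `molecule`.
#' @param nbits fingerprint length (power of two; default 2048).
#' @param max_path maximum number of bonds per subgraph (default 7).
#' @param branched enumerate branched subgraphs (default) or linear paths only.
#' @param bits_per_hash bit positions set per feature (default 2).
#' @return a `fingerprint`.
#' @export
path_fingerprint <- function(x, nbits = 2048L, max_path = 7L,
                             branched = TRUE, bits_per_hash = 2L) {
  mol <- .as_molecule(x)
  b <- mol$bonds
  acode <- .atom_code(mol$atoms)
  params <- list(max_path = max_path, branched = branched,
                 bits_per_hash = bits_per_hash)
  if (nrow(b) == 0L) {
    return(.new_fingerprint(integer(0), nbits, "path", params))
  }
  bcode <- .bond_code(b)
  feats <- if (branched) {
    .enumerate_subgraph_hashes(mol, acode, bcode, max_path)
  } else {
    .enumerate_path_hashes(mol, acode, bcode, max_path)
  }
  bits <- integer(0)
  g <- feats
  for (q in seq_len(bits_per_hash)) {
    g <- .mix32((g + 1) %% 4294967296)
    bits <- c(bits, as.integer(g %% nbits))
  }
  .new_fingerprint(bits, nbits, "path", params)
}

# connected bond subsets of size 1..max_bonds, each enumerated exactly once
.enumerate_subgraph_hashes <- function(mol, acode, bcode, max_bonds) {
  b <- mol$bonds
  nb <- nrow(b)
  bi <- b$i; bj <- b$j
  # bond adjacency
  badj <- vector("list", nb)
  for (a in seq_len(nb)) badj[[a]] <- integer(0)
  for (a in seq_len(nb - 1L)) {
    for (c in (a + 1L):nb) {
      if (bi[a] == bi[c] || bi[a] == bj[c] || bj[a] == bi[c] || bj[a] == bj[c]) {
        badj[[a]] <- c(badj[[a]], c)
        badj[[c]] <- c(badj[[c]], a)
      }
    }
  }
  hashes <- numeric(4096)
  nh <- 0L
  push <- function(h) {
    nh <<- nh + 1L
    if (nh > length(hashes)) hashes <<- c(hashes, numeric(length(hashes)))
    hashes[nh] <<- h
  }
  extend <- function(sub, cand, excl) {
    push(.subgraph_hash(sub, bi, bj, bcode, acode))
    if (length(sub) == max_bonds) return(invisible())
    local_excl <- excl
    for (c in cand) {
      if (c %in% local_excl) next
      new_cand <- setdiff(cand, c(local_excl, c))
      new_cand <- union(new_cand,
                        setdiff(badj[[c]], c(sub, local_excl)))
      extend(c(sub, c), new_cand, local_excl)
      local_excl <- c(local_excl, c)
    }
  }
  for (s in seq_len(nb)) {
    extend(s, setdiff(badj[[s]], seq_len(s)), seq_len(s - 1L))
  }
  unique(hashes[seq_len(nh)])
}

# strictly linear bond paths, canonicalized by direction
.enumerate_path_hashes <- function(mol, acode, bcode, max_path) {
  adj <- .mol_adjlist(mol)
  b <- mol$bonds
  n <- nrow(mol$atoms)
  bond_of <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_len(nrow(b))) {
    assign(paste(b$i[k], b$j[k]), k, envir = bond_of)
    assign(paste(b$j[k], b$i[k]), k, envir = bond_of)
  }
  feats <- new.env(hash = TRUE, parent = emptyenv())
  add_path <- function(atoms_seq) {
    seq1 <- numeric(0)
    for (t in seq_along(atoms_seq)) {
      seq1 <- c(seq1, acode[atoms_seq[t]])
      if (t < length(atoms_seq)) {
        k <- get(paste(atoms_seq[t], atoms_seq[t + 1L]), envir = bond_of)
        seq1 <- c(seq1, bcode[k])
      }
    }
    seq2 <- rev(seq1)
    key <- if (paste(seq1, collapse = ",") <= paste(seq2, collapse = ","))
      seq1 else seq2
    h <- .fnv_hash(key)
    assign(format(h, scientific = FALSE), TRUE, envir = feats)
  }
  dfs <- function(path) {
    if (length(path) > 1L) add_path(path)
    if (length(path) - 1L >= max_path) return(invisible())
    for (nb in adj[[path[length(path)]]]) {
      if (!(nb %in% path)) dfs(c(path, nb))
    }
  }
  for (s in seq_len(n)) dfs(s)
  as.numeric(ls(feats))
}

#' Circular (ECFP-style) fingerprint
#'
#' Iterative atom-environment hashing to the given radius (radius 2 is the
#' ECFP4 equivalent used by the screening funnel). Initial atom invariants
#' are element, heavy degree, hydrogen count, charge and aromaticity.
#'
#' @param x SMILES string or `molecule`.
#' @param radius neighbourhood radius (default 2).
#' @param nbits fingerprint length (default 2048).
#' @return a `fingerprint`.
#' @export
circular_fingerprint <- function(x, radius = 2L, nbits = 2048L) {
  mol <- .as_molecule(x)
  atoms <- mol$atoms
  n <- nrow(atoms)
  adj <- .mol_adjlist(mol)
  b <- mol$bonds
  bcode <- .bond_code(b)
  badj <- vector("list", n)
  for (a in seq_len(n)) badj[[a]] <- numeric(0)
  for (k in seq_len(nrow(b))) {
    badj[[b$i[k]]] <- c(badj[[b$i[k]]], bcode[k])
    badj[[b$j[k]]] <- c(badj[[b$j[k]]], bcode[k])
  }
  ids <- vapply(seq_len(n), function(a) {
    .fnv_hash(c(match(atoms$element[a], .elements$symbol), atoms$degree[a],
                atoms$nh[a], atoms$charge[a] + 4L, as.integer(atoms$aromatic[a])))
  }, 0)
  all_ids <- ids
  if (radius > 0L && n > 1L) {
    for (r in seq_len(radius)) {
      ids <- vapply(seq_len(n), function(a) {
        nbr <- adj[[a]]
        if (length(nbr) == 0L) return(.fnv_hash(c(r, ids[a])))
        enc <- sort(badj[[a]] * 4294967296 + ids[nbr])
        .fnv_hash(c(r, ids[a], enc %/% 4294967296, enc %% 4294967296))
      }, 0)
      all_ids <- c(all_ids, ids)
    }
  }
  bits <- as.integer(unique(all_ids) %% nbits)
  .new_fingerprint(bits, nbits, "circular", list(radius = radius))
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A and B| / |A or B|`. Both fingerprints must share length, kind and
#' parameters. Two all-zero fingerprints are defined as similarity 1 (with a
#' warning): degenerate featureless molecules are treated as identical.
#'
#' @param a,b `fingerprint` objects.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$nbits != b$nbits || a$kind != b$kind || !identical(a$params, b$params)) {
    stop("fingerprints have mismatched length, kind or parameters", call. = FALSE)
  }
  u <- length(union(a$bits, b$bits))
  if (u == 0L) {
    warning("both fingerprints are empty; similarity defined as 1", call. = FALSE)
    return(1)
  }
  length(intersect(a$bits, b$bits)) / u
}

#' Pairwise Tanimoto similarity matrix of a compound set
#'
#' @param set a `compound_set`.
#' @param kind `"path"` or `"circular"`.
#' @param ... fingerprint parameters passed to [path_fingerprint()] or
#'   [circular_fingerprint()].
#' @return a symmetric `similarity_matrix` with unit diagonal and the
#'   compound ids as dimnames.
#' @export
similarity_matrix <- function(set, kind = c("path", "circular"), ...) {
  kind <- match.arg(kind)
  stopifnot(inherits(set, "compound_set"), nrow(set) >= 1L)
  errs <- character(0)
  fps <- vector("list", nrow(set))
  for (k in seq_len(nrow(set))) {
    fps[[k]] <- tryCatch(
      if (kind == "path") path_fingerprint(set$smiles[k], ...)
      else circular_fingerprint(set$smiles[k], ...),
      error = function(e) { errs <<- c(errs, set$id[k]); NULL })
  }
  if (length(errs)) {
    stop("SMILES parse/fingerprint failure for: ", paste(errs, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(set)
  m <- diag(1, n)
  if (n > 1L) {
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        m[a, b] <- m[b, a] <- tanimoto(fps[[a]], fps[[b]])
      }
    }
  }
  dimnames(m) <- list(set$id, set$id)
  structure(m, class = c("similarity_matrix", "matrix"))
}
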