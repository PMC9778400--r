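# Canonical atom ranking (Morgan-style iterative refinement) and a canonical
# SMILES writer. The canonical form is invariant under input atom-order
# permutation and idempotent; atoms left tied after refinement converges are
# treated as automorphic (exact for the tree-like and small-ring chemistry in
# scope).

.canonical_ranks <- function(mol) {
  atoms <- mol$atoms
  n <- nrow(atoms)
  if (n == 1L) return(1L)
  bl <- .bond_label(mol$bonds)
  adj <- .mol_adjlist(mol)
  badj <- vector("list", n)  # bond labels aligned with adj
  for (k in seq_len(n)) badj[[k]] <- numeric(0)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    badj[[b$i[k]]] <- c(badj[[b$i[k]]], bl[k])
    badj[[b$j[k]]] <- c(badj[[b$j[k]]], bl[k])
  }

  key0 <- paste(atoms$element, atoms$degree, atoms$nh, atoms$charge, atoms$aromatic)
  rank <- match(key0, sort(unique(key0)))

  part_id <- function(r) match(r, unique(r))  # partition, first-occurrence labels
  refine <- function(rank) {
    repeat {
      key <- vapply(seq_len(n), function(a) {
        nb <- order(badj[[a]], rank[adj[[a]]])
        paste(rank[a],
              paste(badj[[a]][nb], rank[adj[[a]]][nb], sep = ":", collapse = ","))
      }, "")
      new_rank <- match(key, sort(unique(key)))
      # stop when the partition is stable (labels may legitimately permute)
      if (identical(part_id(new_rank), part_id(rank))) return(new_rank)
      rank <- new_rank
    }
  }
  rank <- refine(rank)
  # tie-breaking: split the lowest tied class and re-refine
  while (max(table(rank)) > 1L) {
    tab <- table(rank)
    cls <- as.integer(names(tab)[tab > 1L][1])
    a <- which(rank == cls)[1]
    rank[a] <- rank[a] - 0.5
    rank <- match(rank, sort(unique(rank)))
    rank <- refine(rank)
  }
  rank
}

.needs_bracket <- function(mol, a) {
  atoms <- mol$atoms
  el <- atoms$element[a]
  if (atoms$charge[a] != 0L) return(TRUE)
  if (!(el %in% .ORGANIC_SUBSET)) return(TRUE)
  # will a bare-atom reader reproduce the implicit H count?
  if (atoms$aromatic[a] && el %in% c("N", "P")) {
    # bare aromatic n/p reads as pyridine-type (no H): pyrrole-type needs [nH]
    return(atoms$nh[a] != 0L)
  }
  b <- mol$bonds
  on_a <- b$i == a | b$j == a
  bondsum <- sum(b$order[on_a])
  vals <- .default_valences[[el]]
  v <- vals[vals >= bondsum]
  implied <- if (length(v) == 0L) 0L else as.integer(v[1] - bondsum)
  implied != atoms$nh[a]
}

.atom_token <- function(mol, a) {
  atoms <- mol$atoms
  el <- atoms$element[a]
  sym <- if (atoms$aromatic[a]) tolower(el) else el
  if (!.needs_bracket(mol, a)) return(sym)
  h <- atoms$nh[a]
  ch <- atoms$charge[a]
  paste0("[", sym,
         if (h == 1L) "H" else if (h > 1L) paste0("H", h) else "",
         if (ch > 0L) paste0("+", if (ch > 1L) ch else "") else "",
         if (ch < 0L) paste0("-", if (ch < -1L) -ch else "") else "",
         "]")
}

.bond_token <- function(mol, k, from, to) {
  b <- mol$bonds
  if (b$aromatic[k]) return("")
  ord <- b$order[k]
  if (ord == 2L) return("=")
  if (ord == 3L) return("#")
  # single bond: explicit only between two aromatic atoms (e.g. biphenyl)
  if (mol$atoms$aromatic[from] && mol$atoms$aromatic[to]) return("-")
  ""
}

.write_smiles <- function(mol, rank = NULL) {
  n <- nrow(mol$atoms)
  if (is.null(rank)) rank <- .canonical_ranks(mol)
  b <- mol$bonds
  adj <- .mol_adjlist(mol)
  bond_idx <- vector("list", n)
  for (k in seq_len(n)) bond_idx[[k]] <- integer(0)
  for (k in seq_len(nrow(b))) {
    bond_idx[[b$i[k]]] <- c(bond_idx[[b$i[k]]], k)
    bond_idx[[b$j[k]]] <- c(bond_idx[[b$j[k]]], k)
  }

  # Pass 1: DFS in rank order, classifying bonds into tree bonds and ring
  # closures and attaching closure digits to both endpoints in discovery order.
  visited <- rep(FALSE, n)
  bond_done <- rep(FALSE, max(nrow(b), 1L))
  ring_digit <- 0L
  children <- vector("list", n)   # list of (atom, bond) in traversal order
  closures <- vector("list", n)   # closure token strings per atom
  pass1 <- function(a, via_bond) {
    visited[a] <<- TRUE
    nbs <- adj[[a]]
    for (t in order(rank[nbs])) {
      nb <- nbs[t]; k <- bond_idx[[a]][t]
      if (!is.na(via_bond) && k == via_bond) next
      if (bond_done[k]) next
      if (visited[nb]) {
        bond_done[k] <<- TRUE
        ring_digit <<- ring_digit + 1L
        d <- if (ring_digit < 10L) as.character(ring_digit)
             else paste0("%", sprintf("%02d", ring_digit))
        tok <- paste0(.bond_token(mol, k, a, nb), d)
        closures[[a]] <<- c(closures[[a]], tok)
        closures[[nb]] <<- c(closures[[nb]], tok)
      } else {
        bond_done[k] <<- TRUE
        children[[a]] <<- c(children[[a]], list(list(atom = nb, bond = k)))
        pass1(nb, k)
      }
    }
  }

  # Pass 2: render; all but the last child branch get parentheses.
  render <- function(a, via_bond) {
    pre <- if (is.na(via_bond)) "" else {
      .bond_token(mol, via_bond, b$i[via_bond] + b$j[via_bond] - a, a)
    }
    kids <- children[[a]]
    body <- ""
    if (length(kids)) {
      parts <- vapply(kids, function(k) render(k$atom, k$bond), "")
      if (length(parts) > 1L) {
        parts[-length(parts)] <- paste0("(", parts[-length(parts)], ")")
      }
      body <- paste0(parts, collapse = "")
    }
    paste0(pre, .atom_token(mol, a), paste0(closures[[a]], collapse = ""), body)
  }

  roots <- character(0)
  repeat {
    todo <- which(!visited)
    if (length(todo) == 0L) break
    start <- todo[which.min(rank[todo])]
    pass1(start, NA_integer_)
    roots <- c(roots, render(start, NA_integer_))
  }
  paste0(roots, collapse = ".")
}

#' Canonicalize a SMILES string
#'
#' Produces a canonical SMILES that is invariant under atom-order permutation
#' of the input and idempotent (`canonicalize(canonicalize(s)) ==
#' canonicalize(s)`). Stereochemistry and isotopes are dropped. Used for
#' structure-based deduplication of screening libraries.
#'
#' @param smiles a single SMILES string.
#' @return the canonical SMILES string.
#' @examples
#' canonicalize("OCC") == canonicalize("CCO")
#' @export
canonicalize <- function(smiles) {
  mol <- if (inherits(smiles, "molecule")) smiles else parse_smiles(smiles)
  .write_smiles(mol)
}
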