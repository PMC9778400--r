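# SMILES reader: tokenizer, kekulization of aromatic input, implicit-hydrogen
# assignment, ring perception and Hueckel aromaticity perception.
#
# The internal `molecule` object is a list with
#   atoms: data.frame(element, aromatic, charge, nh, degree)
#   bonds: data.frame(i, j, order, aromatic, in_ring)   (order is the Kekule order)
#   rings: list of integer vectors (smallest ring through each ring bond)
# Stereochemistry (@, @@, /, \) and isotopes are accepted on input and ignored;
# all 2D machinery here is constitution-only.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_OK <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string into a molecule object
#'
#' Supports the Daylight organic subset, bracket atoms with charge and explicit
#' hydrogen counts, branches, ring-bond closures (including `%nn`), aromatic
#' (lowercase) notation and multi-fragment input separated by `.`. Aromatic
#' input is kekulized; aromaticity is then re-perceived from the Kekule graph
#' so that equivalent aromatic and kekulized inputs yield identical molecules.
#'
#' @param smiles a single SMILES string.
#' @return a `molecule` object.
#' @examples
#' m <- parse_smiles("c1ccccc1O")  # phenol
#' m$atoms$element
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    stop("`smiles` must be a single string", call. = FALSE)
  }
  toks <- .smiles_tokenize(smiles)
  mol <- .smiles_assemble(toks, smiles)
  mol <- .kekulize(mol, smiles)
  mol <- .assign_implicit_h(mol, smiles)
  mol <- .perceive_rings(mol)
  mol <- .perceive_aromaticity(mol)
  class(mol) <- "molecule"
  mol
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule: %d heavy atoms, %d bonds, formula %s>\n",
              nrow(x$atoms), nrow(x$bonds), mol_formula(x)))
  invisible(x)
}

#' Molecular formula (Hill order) of a molecule
#' @param mol a `molecule`.
#' @return a string such as `"C15H10O7"`.
#' @export
mol_formula <- function(mol) {
  counts <- table(mol$atoms$element)
  nh <- sum(mol$atoms$nh)
  syms <- names(counts)
  ord <- c("C", "H", sort(setdiff(c(syms, if (nh > 0) "H"), c("C", "H"))))
  out <- ""
  for (s in ord) {
    n <- if (s == "H") nh else if (s %in% syms) counts[[s]] else 0L
    if (n > 0) out <- paste0(out, s, if (n > 1) n else "")
  }
  charge <- sum(mol$atoms$charge)
  if (charge != 0) {
    out <- paste0(out, if (charge > 0) "+" else "-",
                  if (abs(charge) > 1) abs(charge) else "")
  }
  out
}

# --- tokenizer ---------------------------------------------------------------

.smiles_tokenize <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  push <- function(type, value) toks[[length(toks) + 1L]] <<- list(type = type, value = value)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in SMILES: ", s, call. = FALSE)
      push("bracket", paste0(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r")) {
      two <- paste0(ch, chars[i + 1L])
      if (two %in% c("Cl", "Br")) {
        push("atom", two); i <- i + 2L
      } else {
        push("atom", ch); i <- i + 1L
      }
    } else if (ch %in% .ORGANIC_SUBSET) {
      push("atom", ch); i <- i + 1L
    } else if (ch %in% .AROMATIC_OK) {
      push("aromatic_atom", ch); i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      push("bond", ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring closure in SMILES: ", s, call. = FALSE)
      push("ring", as.integer(paste0(chars[i + 1L], chars[i + 2L], collapse = "")))
      i <- i + 3L
    } else if (grepl("[0-9]", ch)) {
      push("ring", as.integer(ch)); i <- i + 1L
    } else if (ch == "(") {
      push("open", NA); i <- i + 1L
    } else if (ch == ")") {
      push("close", NA); i <- i + 1L
    } else if (ch == ".") {
      push("dot", NA); i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in SMILES: ", s, call. = FALSE)
    }
  }
  toks
}

# Parse the inside of a bracket atom: [isotope]symbol[chirality][Hn][charge][:map]
.parse_bracket <- function(body, s) {
  # strip isotope and atom-map, read element, then scan H count and charge
  body2 <- sub("^[0-9]+", "", body)
  body2 <- sub(":[0-9]+$", "", body2)
  elem <- regmatches(body2, regexpr("^([A-Z][a-z]?|[a-z])", body2))
  if (length(elem) == 0L) stop("cannot parse bracket atom [", body, "] in ", s, call. = FALSE)
  rest <- substring(body2, nchar(elem) + 1L)
  rest <- gsub("@", "", rest, fixed = TRUE)
  nh <- 0L
  hm <- regmatches(rest, regexpr("H[0-9]*", rest))
  if (length(hm) == 1L) {
    nh <- if (hm == "H") 1L else as.integer(substring(hm, 2L))
    rest <- sub("H[0-9]*", "", rest)
  }
  charge <- 0L
  if (nzchar(rest)) {
    cm <- regmatches(rest, regexec("^(\\+{1,2}|-{1,2})([0-9]*)$", rest))[[1]]
    if (length(cm) == 0L) stop("cannot parse bracket atom [", body, "] in ", s, call. = FALSE)
    sign <- if (substring(cm[2], 1L, 1L) == "+") 1L else -1L
    mag <- if (nzchar(cm[3])) as.integer(cm[3]) else nchar(cm[2])
    charge <- sign * mag
  }
  aromatic <- elem %in% .AROMATIC_OK
  if (aromatic) elem <- paste0(toupper(substring(elem, 1L, 1L)), substring(elem, 2L))
  list(element = elem, aromatic = aromatic, charge = charge, nh = nh, bracket = TRUE)
}

# --- assembly ----------------------------------------------------------------

.bond_order_of <- function(sym) {
  switch(sym, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 1L, "/" = 1L, "\\" = 1L,
         stop("unknown bond symbol ", sym, call. = FALSE))
}

.smiles_assemble <- function(toks, s) {
  atoms <- list()
  bonds <- list()
  stack <- integer(0)
  prev <- NA_integer_
  pending <- NULL  # pending bond symbol
  ring_open <- list()

  add_atom <- function(a) {
    atoms[[length(atoms) + 1L]] <<- a
    idx <- length(atoms)
    if (!is.na(prev)) {
      arom <- is.null(pending) && atoms[[prev]]$aromatic && a$aromatic
      order <- if (is.null(pending)) 1L else .bond_order_of(pending)
      if (!is.null(pending) && pending == ":") arom <- TRUE
      bonds[[length(bonds) + 1L]] <<- list(i = prev, j = idx, order = order, aromatic = arom)
    }
    prev <<- idx
    pending <<- NULL
  }

  for (tk in toks) {
    switch(tk$type,
      atom = add_atom(list(element = tk$value, aromatic = FALSE, charge = 0L,
                           nh = NA_integer_, bracket = FALSE)),
      aromatic_atom = add_atom(list(
        element = paste0(toupper(substring(tk$value, 1L, 1L)), substring(tk$value, 2L)),
        aromatic = TRUE, charge = 0L, nh = NA_integer_, bracket = FALSE)),
      bracket = add_atom(.parse_bracket(tk$value, s)),
      bond = { pending <- tk$value },
      ring = {
        key <- as.character(tk$value)
        if (is.na(prev)) stop("ring closure before any atom in SMILES: ", s, call. = FALSE)
        if (is.null(ring_open[[key]])) {
          ring_open[[key]] <- list(atom = prev, sym = pending)
        } else {
          op <- ring_open[[key]]
          sym <- if (!is.null(pending)) pending else op$sym
          if (!is.null(pending) && !is.null(op$sym) && pending != op$sym) {
            stop("conflicting ring-closure bond symbols in SMILES: ", s, call. = FALSE)
          }
          arom <- is.null(sym) && atoms[[op$atom]]$aromatic && atoms[[prev]]$aromatic
          if (!is.null(sym) && sym == ":") arom <- TRUE
          order <- if (is.null(sym)) 1L else .bond_order_of(sym)
          bonds[[length(bonds) + 1L]] <- list(i = op$atom, j = prev,
                                              order = order, aromatic = arom)
          ring_open[[key]] <- NULL
        }
        pending <- NULL
      },
      open = { stack <- c(stack, prev) },
      close = {
        if (length(stack) == 0L) stop("unbalanced parentheses in SMILES: ", s, call. = FALSE)
        prev <- stack[length(stack)]
        stack <- stack[-length(stack)]
      },
      dot = { prev <- NA_integer_; pending <- NULL }
    )
  }
  if (length(ring_open) > 0L && any(!vapply(ring_open, is.null, logical(1)))) {
    stop("unclosed ring bond in SMILES: ", s, call. = FALSE)
  }
  if (length(atoms) == 0L) stop("SMILES contains no atoms: ", s, call. = FALSE)

  atoms_df <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    charge = vapply(atoms, function(a) as.integer(a$charge), 0L),
    nh = vapply(atoms, function(a) as.integer(a$nh), NA_integer_),
    bracket = vapply(atoms, `[[`, FALSE, "bracket"),
    stringsAsFactors = FALSE
  )
  if (!all(atoms_df$element %in% .elements$symbol)) {
    bad <- setdiff(unique(atoms_df$element), .elements$symbol)
    stop("unsupported element(s) in SMILES '", s, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bonds_df <- if (length(bonds)) {
    data.frame(
      i = vapply(bonds, `[[`, 0L, "i"),
      j = vapply(bonds, `[[`, 0L, "j"),
      order = vapply(bonds, `[[`, 0L, "order"),
      aromatic = vapply(bonds, `[[`, FALSE, "aromatic")
    )
  } else {
    data.frame(i = integer(0), j = integer(0), order = integer(0),
               aromatic = logical(0))
  }
  if (nrow(bonds_df) > 0L) {
    key <- paste(pmin(bonds_df$i, bonds_df$j), pmax(bonds_df$i, bonds_df$j))
    if (anyDuplicated(key)) stop("duplicate bond in SMILES: ", s, call. = FALSE)
  }
  list(atoms = atoms_df, bonds = bonds_df)
}

# --- kekulization ------------------------------------------------------------

# Assign alternating double bonds inside the aromatic subgraph written with
# lowercase atoms, so that valence bookkeeping (implicit H) can use ordinary
# rules. An aromatic atom "needs" one ring double bond unless it is a
# pyrrole/furan/thiophene-type donor or already carries an explicit double bond.
.kekulize <- function(mol, s) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  if (!any(atoms$aromatic)) return(mol)

  nb <- nrow(bonds)
  deg <- tabulate(c(bonds$i, bonds$j), nbins = nrow(atoms))
  has_explicit_double <- logical(nrow(atoms))
  if (nb) {
    hi <- bonds$order >= 2L & !bonds$aromatic
    has_explicit_double[bonds$i[hi]] <- TRUE
    has_explicit_double[bonds$j[hi]] <- TRUE
  }
  conn <- deg + ifelse(is.na(atoms$nh), 0L, atoms$nh)

  needs <- rep(FALSE, nrow(atoms))
  for (a in which(atoms$aromatic)) {
    el <- atoms$element[a]; ch <- atoms$charge[a]
    needs[a] <- if (has_explicit_double[a]) FALSE
      else if (el == "C") ch == 0L
      else if (el %in% c("N", "P")) ch == 0L && conn[a] == 2L
      else if (el %in% c("O", "S")) ch == 1L
      else if (el == "B") FALSE
      else FALSE
  }

  arom_bond_idx <- which(bonds$aromatic)
  # adjacency over aromatic bonds restricted to needy atoms
  adj <- lapply(seq_len(nrow(atoms)), function(a) integer(0))
  for (b in arom_bond_idx) {
    i <- bonds$i[b]; j <- bonds$j[b]
    if (needs[i] && needs[j]) {
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  matched <- rep(NA_integer_, nrow(atoms))
  needy <- which(needs)
  solve <- function(k) {
    if (k > length(needy)) return(TRUE)
    a <- needy[k]
    if (!is.na(matched[a])) return(solve(k + 1L))
    for (b in adj[[a]]) {
      if (is.na(matched[b])) {
        matched[a] <<- b; matched[b] <<- a
        if (solve(k + 1L)) return(TRUE)
        matched[a] <<- NA_integer_; matched[b] <<- NA_integer_
      }
    }
    FALSE
  }
  if (!solve(1L)) {
    stop("cannot kekulize aromatic system in SMILES: ", s, call. = FALSE)
  }
  if (nb) {
    for (b in arom_bond_idx) {
      i <- bonds$i[b]; j <- bonds$j[b]
      bonds$order[b] <- if (!is.na(matched[i]) && matched[i] == j) 2L else 1L
    }
  }
  mol$bonds <- bonds
  mol
}

# --- implicit hydrogens ------------------------------------------------------

.assign_implicit_h <- function(mol, s) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  bondsum <- numeric(nrow(atoms))
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      bondsum[bonds$i[b]] <- bondsum[bonds$i[b]] + bonds$order[b]
      bondsum[bonds$j[b]] <- bondsum[bonds$j[b]] + bonds$order[b]
    }
  }
  for (a in seq_len(nrow(atoms))) {
    if (!is.na(atoms$nh[a])) next  # bracket atom: explicit count
    el <- atoms$element[a]
    vals <- .default_valences[[el]]
    if (is.null(vals)) { atoms$nh[a] <- 0L; next }
    v <- vals[vals >= bondsum[a]]
    atoms$nh[a] <- if (length(v) == 0L) 0L else as.integer(v[1] - bondsum[a])
  }
  # simple valence sanity check for common elements (spec: valence errors rejected)
  for (a in seq_len(nrow(atoms))) {
    el <- atoms$element[a]
    total <- bondsum[a] + atoms$nh[a]
    maxv <- switch(el, C = 4, O = 2 + abs(atoms$charge[a]), N = 5, H = 1, 99)
    if (atoms$charge[a] == 0L && el == "C" && total > 4) {
      stop("valence error at atom ", a, " in SMILES: ", s, call. = FALSE)
    }
  }
  atoms$degree <- tabulate(c(bonds$i, bonds$j), nbins = nrow(atoms))
  mol$atoms <- atoms
  mol
}

# --- ring perception ---------------------------------------------------------

.mol_adjlist <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- integer(0)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  adj
}

# Smallest ring through each ring bond (BFS avoiding that bond); rings are
# deduplicated by atom set. This recovers the SSSR for fused 5/6-ring systems.
.perceive_rings <- function(mol) {
  b <- mol$bonds
  n <- nrow(mol$atoms)
  adj <- .mol_adjlist(mol)
  rings <- list()
  seen <- character(0)
  in_ring <- rep(FALSE, max(nrow(b), 1L))
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      src <- b$i[k]; dst <- b$j[k]
      # BFS from src to dst without using bond k
      parent <- rep(NA_integer_, n)
      distv <- rep(NA_integer_, n)
      distv[src] <- 0L
      queue <- src
      while (length(queue) && is.na(distv[dst])) {
        cur <- queue[1]; queue <- queue[-1]
        for (nb in adj[[cur]]) {
          if ((cur == src && nb == dst) || (cur == dst && nb == src)) next
          if (is.na(distv[nb])) {
            distv[nb] <- distv[cur] + 1L
            parent[nb] <- cur
            queue <- c(queue, nb)
          }
        }
      }
      if (!is.na(distv[dst])) {
        in_ring[k] <- TRUE
        path <- dst
        while (path[length(path)] != src) path <- c(path, parent[path[length(path)]])
        key <- paste(sort(path), collapse = ",")
        if (!(key %in% seen)) {
          seen <- c(seen, key)
          rings[[length(rings) + 1L]] <- path
        }
      }
    }
    mol$bonds$in_ring <- in_ring[seq_len(nrow(b))]
  } else {
    mol$bonds$in_ring <- logical(0)
  }
  mol$rings <- rings
  mol
}

# --- aromaticity perception --------------------------------------------------

# Hueckel-style perception on the Kekule graph, following the reference
# toolkit's default model for the chemistry in scope: a ring is aromatic when
# every member is sp2-capable and the pi-electron contributions sum to 6.
#   * atom with a double bond on a ring bond        -> 1
#   * atom with an exocyclic double bond (e.g. C=O) -> 0
#   * neutral O/S with two single bonds             -> 2 (furan-type)
#   * N/P with three single connections incl. H     -> 2 (pyrrole-type)
#   * C- -> 2 ; C+ -> 0 (cyclopentadienyl / tropylium)
# Anything else disqualifies the ring. Rings larger than 7 atoms are skipped.
.perceive_aromaticity <- function(mol) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  atoms$aromatic <- rep(FALSE, nrow(atoms))
  bonds$aromatic <- rep(FALSE, nrow(bonds))

  if (length(mol$rings)) {
    dbl_partner <- vector("list", nrow(atoms))
    dbl_in_ring <- rep(FALSE, nrow(atoms))
    dbl_any <- rep(FALSE, nrow(atoms))
    for (k in seq_len(nrow(bonds))) {
      if (bonds$order[k] >= 2L) {
        dbl_any[bonds$i[k]] <- TRUE
        dbl_any[bonds$j[k]] <- TRUE
        if (bonds$in_ring[k]) {
          dbl_in_ring[bonds$i[k]] <- TRUE
          dbl_in_ring[bonds$j[k]] <- TRUE
        }
      }
    }
    conn3 <- atoms$degree + atoms$nh
    aromatic_rings <- logical(length(mol$rings))
    for (r in seq_along(mol$rings)) {
      ring <- mol$rings[[r]]
      if (length(ring) > 7L) next
      total <- 0L
      ok <- TRUE
      for (a in ring) {
        el <- atoms$element[a]; ch <- atoms$charge[a]
        contrib <- if (dbl_in_ring[a]) 1L
          else if (dbl_any[a]) 0L  # exocyclic double bond, sp2 but no pi in ring
          else if (el %in% c("O", "S") && ch == 0L && atoms$degree[a] == 2L) 2L
          else if (el %in% c("N", "P") && ch == 0L && conn3[a] == 3L) 2L
          else if (el == "N" && ch == -1L && atoms$degree[a] == 2L) 2L
          else if (el == "C" && ch == -1L) 2L
          else if (el == "C" && ch == 1L) 0L
          else NA_integer_
        if (is.na(contrib)) { ok <- FALSE; break }
        total <- total + contrib
      }
      if (ok && total == 6L) {
        aromatic_rings[r] <- TRUE
        atoms$aromatic[ring] <- TRUE
      }
    }
    # bonds whose endpoints are both members of one aromatic ring
    for (r in which(aromatic_rings)) {
      ring <- mol$rings[[r]]
      for (k in seq_len(nrow(bonds))) {
        if (bonds$i[k] %in% ring && bonds$j[k] %in% ring && bonds$in_ring[k]) {
          bonds$aromatic[k] <- TRUE
        }
      }
    }
    mol$aromatic_rings <- mol$rings[aromatic_rings]
  } else {
    mol$aromatic_rings <- list()
  }
  mol$atoms <- atoms
  mol$bonds <- bonds
  mol
}

# Structural bond label used by fingerprints, descriptors and canonical
# ranking: independent of the particular Kekule assignment.
.bond_label <- function(bonds) {
  ifelse(bonds$aromatic, 1.5, as.numeric(bonds$order))
}
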