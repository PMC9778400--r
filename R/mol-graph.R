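# Hydrogen-suppressed molecular graph with atomic properties and topological
# distance matrix: the substrate for all 2D descriptors.

#' Build a molecular graph for descriptor computation
#'
#' Hydrogen-suppressed labelled graph: per heavy atom the element, period
#' (principal quantum number of the valence shell), heavy degree, Kier-Hall
#' valence-electron count `delta_v = Zv - nH`, atomic mass and Bondi van der
#' Waals volume; plus the topological distance matrix (bond-count shortest
#' paths by BFS). Atoms in different fragments get distance `Inf` and are
#' excluded from all lag sums downstream.
#'
#' @param x SMILES string or `molecule`.
#' @return a `molecular_graph`: list with `atoms` (data frame), `bonds`,
#'   `dist` (matrix) and the parsed `molecule`.
#' @examples
#' g <- build_graph("CCC")   # propane
#' g$dist[1, 3]              # 2
#' @export
build_graph <- function(x) {
  mol <- .as_molecule(x)
  atoms <- mol$atoms
  n <- nrow(atoms)
  adj <- .mol_adjlist(mol)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  for (s in seq_len(n)) {
    queue <- s
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (is.infinite(dist[s, nb])) {
          dist[s, nb] <- dist[s, cur] + 1
          queue <- c(queue, nb)
        }
      }
    }
  }
  ga <- data.frame(
    element = atoms$element,
    period = .elem_prop(atoms$element, "period"),
    degree = atoms$degree,
    nh = atoms$nh,
    delta_v = .elem_prop(atoms$element, "zv") - atoms$nh,
    mass = .elem_prop(atoms$element, "mass"),
    vdw_volume = vdw_volume(atoms$element),
    aromatic = atoms$aromatic,
    stringsAsFactors = FALSE
  )
  structure(list(atoms = ga, bonds = mol$bonds, dist = dist, molecule = mol),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  d <- x$dist[is.finite(x$dist)]
  cat(sprintf("<molecular_graph: %d heavy atoms, diameter %d>\n",
              nrow(x$atoms), as.integer(max(d))))
  invisible(x)
}

.as_graph <- function(x) {
  if (inherits(x, "molecular_graph")) x else build_graph(x)
}
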