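# 2D molecular descriptors: Moreau-Broto autocorrelations (ATS/AATS), Basak
# neighbourhood-symmetry information indices (IC/CIC/MIC), and Kier-Hall
# electrotopological-state atom types (the descriptors of the published 2D
# activity model), plus descriptor-table ingestion, cleaning and
# correlation filtering.

#' Moreau-Broto autocorrelation
#'
#' `ATS_k(w) = sum over unordered heavy-atom pairs {i,j} at topological
#' distance k of w_i * w_j`, on the hydrogen-suppressed graph with raw
#' (uncentred) atomic weights. Returns 0 when no pair sits at lag `k`.
#'
#' @param graph a `molecular_graph` (or SMILES).
#' @param k topological lag, `k >= 1`.
#' @param weight `"mass"` or `"vdw_volume"`.
#' @return the autocorrelation sum.
#' @export
ats <- function(graph, k, weight = c("mass", "vdw_volume")) {
  weight <- match.arg(weight)
  g <- .as_graph(graph)
  if (k < 1) stop("lag k must be >= 1", call. = FALSE)
  w <- g$atoms[[weight]]
  at_k <- which(g$dist == k, arr.ind = TRUE)
  at_k <- at_k[at_k[, 1] < at_k[, 2], , drop = FALSE]
  if (nrow(at_k) == 0L) return(0)
  sum(w[at_k[, 1]] * w[at_k[, 2]])
}

#' Averaged Moreau-Broto autocorrelation
#'
#' `ATS_k / (number of pairs at lag k)`; `NA` when no pair exists at that lag
#' (the missing value propagates into descriptor tables).
#'
#' @inheritParams ats
#' @return the averaged autocorrelation, or `NA_real_`.
#' @export
aats <- function(graph, k, weight = c("mass", "vdw_volume")) {
  weight <- match.arg(weight)
  g <- .as_graph(graph)
  if (k < 1) stop("lag k must be >= 1", call. = FALSE)
  npairs <- sum(g$dist == k) / 2
  if (npairs == 0) return(NA_real_)
  ats(g, k, weight) / npairs
}

#' Atom equivalence classes by k-neighbourhood symmetry
#'
#' Atoms are grouped by iterative (Weisfeiler-Lehman style) refinement:
#' initial label = (element, heavy degree); each round appends the sorted
#' multiset of (bond label, neighbour label) pairs, where the bond label is
#' the order with aromatic bonds distinguished. After `k` rounds two atoms
#' share a class iff their rooted neighbourhoods to radius `k` agree as
#' labelled trees. Refinement is monotone: classes only split as `k` grows.
#'
#' @param graph a `molecular_graph` (or SMILES).
#' @param k neighbourhood order, `k >= 0`.
#' @return integer vector of class labels (first-occurrence numbering).
#' @export
neighborhood_classes <- function(graph, k) {
  g <- .as_graph(graph)
  if (k < 0) stop("order k must be >= 0", call. = FALSE)
  n <- nrow(g$atoms)
  lab <- paste(g$atoms$element, g$atoms$degree)
  if (k > 0 && n > 1L) {
    adj <- .mol_adjlist(g$molecule)
    bl <- .bond_label(g$bonds)
    badj <- vector("list", n)
    for (a in seq_len(n)) badj[[a]] <- numeric(0)
    b <- g$bonds
    for (q in seq_len(nrow(b))) {
      badj[[b$i[q]]] <- c(badj[[b$i[q]]], bl[q])
      badj[[b$j[q]]] <- c(badj[[b$j[q]]], bl[q])
    }
    for (round in seq_len(k)) {
      lab <- vapply(seq_len(n), function(a) {
        ns <- adj[[a]]
        if (length(ns) == 0L) return(lab[a])
        pieces <- sort(paste0(badj[[a]], "~", lab[ns]))
        paste(lab[a], paste(pieces, collapse = "|"))
      }, "")
    }
  }
  match(lab, unique(lab))
}

#' Information-content indices of neighbourhood symmetry
#'
#' With equivalence classes of sizes `n_c` over `N` heavy atoms and
#' `p_c = n_c / N`:
#' `IC_k = -sum p_c log2 p_c` (Shannon entropy of the class distribution),
#' `CIC_k = log2(N) - IC_k` (complementary information content), and
#' `MIC_k = log2(N! / prod(n_c!)) / N` (the Brillouin finite-population form
#' of the same entropy, the "modified information content" convention adopted
#' here; see the methods vignette). `IC_k + CIC_k = log2 N` holds exactly.
#'
#' @inheritParams neighborhood_classes
#' @return a single numeric value.
#' @export
ic <- function(graph, k) {
  cls <- neighborhood_classes(graph, k)
  n <- length(cls)
  if (n == 0L) stop("graph has no atoms", call. = FALSE)
  p <- tabulate(cls) / n
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' @rdname ic
#' @export
cic <- function(graph, k) {
  cls <- neighborhood_classes(graph, k)
  log2(length(cls)) - ic(graph, k)
}

#' @rdname ic
#' @export
mic <- function(graph, k) {
  cls <- neighborhood_classes(graph, k)
  n <- length(cls)
  if (n == 0L) stop("graph has no atoms", call. = FALSE)
  sizes <- tabulate(cls)
  (lgamma(n + 1) - sum(lgamma(sizes + 1))) / log(2) / n
}

#' Kier-Hall electrotopological state indices
#'
#' Intrinsic state `I_i = ((2/L_i)^2 * delta_v_i + 1) / delta_i` (`L` the
#' period, `delta_v` the valence-electron count less hydrogens, `delta` the
#' heavy degree) perturbed by all other heavy atoms:
#' `S_i = I_i + sum_j (I_i - I_j) / (d_ij + 1)^2`, with pairs in different
#' fragments excluded. Isolated atoms (`delta = 0`) have no defined intrinsic
#' state.
#'
#' @param graph a `molecular_graph` (or SMILES).
#' @return numeric vector of per-atom E-state values `S_i`.
#' @export
estate_indices <- function(graph) {
  g <- .as_graph(graph)
  a <- g$atoms
  if (any(a$degree == 0)) {
    stop("isolated atom: intrinsic state undefined (delta = 0)", call. = FALSE)
  }
  I <- ((2 / a$period)^2 * a$delta_v + 1) / a$degree
  n <- length(I)
  S <- I
  if (n > 1L) {
    for (i in seq_len(n)) {
      d <- g$dist[i, ]
      ok <- is.finite(d) & seq_len(n) != i
      S[i] <- I[i] + sum((I[i] - I[ok]) / (d[ok] + 1)^2)
    }
  }
  S
}

#' Minimum E-state over a Kier-Hall atom type
#'
#' Currently supports the atom type `"ssCH2"`: sp3 carbon with exactly two
#' single bonds to heavy atoms and two hydrogens. Returns `NA` when no atom
#' matches (many flavonoids have no sp3 CH2).
#'
#' @param graph a `molecular_graph` (or SMILES).
#' @param atom_type Kier-Hall atom-type string.
#' @return minimum `S_i` over matching atoms, or `NA_real_`.
#' @export
min_estate <- function(graph, atom_type = "ssCH2") {
  g <- .as_graph(graph)
  if (atom_type != "ssCH2") {
    stop("unsupported atom type: ", atom_type, call. = FALSE)
  }
  a <- g$atoms
  b <- g$bonds
  single_only <- vapply(seq_len(nrow(a)), function(i) {
    on_i <- b$i == i | b$j == i
    all(b$order[on_i] == 1L & !b$aromatic[on_i])
  }, FALSE)
  match_idx <- which(a$element == "C" & !a$aromatic & a$degree == 2L &
                     a$nh == 2L & single_only)
  if (length(match_idx) == 0L) return(NA_real_)
  S <- estate_indices(g)
  min(S[match_idx])
}

#' The five descriptors of the published 2D activity model
#'
#' Computes `MIC1`, `ATS4v`, `AATS7m`, `CIC3` and `minssCH2` from the
#' molecular graph. A missing `minssCH2` (no sp3 CH2 present) is imputed as 0
#' with a warning, the convention under which the published equation is
#' usable for flavones and flavonols; a missing `AATS7m` (diameter below 7)
#' stays `NA`.
#'
#' @param x SMILES string, `molecule` or `molecular_graph`.
#' @return named numeric vector of the five descriptors.
#' @export
compute_descriptor_vector <- function(x) {
  g <- .as_graph(x)
  mins <- min_estate(g, "ssCH2")
  if (is.na(mins)) {
    warning("no ssCH2 atom; minssCH2 imputed as 0", call. = FALSE)
    mins <- 0
  }
  c(MIC1 = mic(g, 1), ATS4v = ats(g, 4, "vdw_volume"),
    AATS7m = aats(g, 7, "mass"), CIC3 = cic(g, 3), minssCH2 = mins)
}

#' Descriptor table for a compound set
#'
#' Runs [compute_descriptor_vector()] over a compound set, returning the
#' modelling matrix used by the QSAR module.
#'
#' @param set a `compound_set`.
#' @param quiet suppress per-compound imputation warnings (default `TRUE`;
#'   a single summary message is printed instead).
#' @return a `descriptor_table`.
#' @export
native_descriptor_table <- function(set, quiet = TRUE) {
  stopifnot(inherits(set, "compound_set"))
  rows <- lapply(set$smiles, function(s) {
    if (quiet) suppressWarnings(compute_descriptor_vector(s))
    else compute_descriptor_vector(s)
  })
  values <- do.call(rbind, rows)
  rownames(values) <- set$id
  descriptor_table(values)
}

# --- descriptor tables -------------------------------------------------------

#' Construct a descriptor table
#'
#' A named numeric matrix (compounds x descriptors) with unique row ids;
#' missing values are allowed until [clean_descriptors()] is applied.
#'
#' @param values numeric matrix with rownames (ids) and colnames (descriptor
#'   names).
#' @return a `descriptor_table`.
#' @export
descriptor_table <- function(values) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) {
    stop("duplicate compound ids in descriptor table", call. = FALSE)
  }
  structure(list(ids = rownames(values), names = colnames(values),
                 values = values),
            class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("<descriptor_table: %d compounds x %d descriptors, %d missing>\n",
              length(x$ids), length(x$names), sum(is.na(x$values))))
  invisible(x)
}

#' Read a descriptor table from CSV
#'
#' First column is the compound id; remaining columns must be numeric or
#' empty (empty cells become missing values). Duplicate ids and non-numeric
#' cells are errors; the offending row/column is named.
#'
#' @param path CSV file path.
#' @return a `descriptor_table`.
#' @export
ingest_descriptor_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L) stop("descriptor table needs an id column plus data", call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate compound id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  out <- matrix(NA_real_, nrow(vals), ncol(vals),
                dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    cell <- trimws(vals[, j])
    empty <- !nzchar(cell) | toupper(cell) %in% c("NA", "NAN")
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                   ids[bad[1]], colnames(vals)[j], cell[bad[1]]), call. = FALSE)
    }
    out[!empty, j] <- num[!empty]
  }
  descriptor_table(out)
}

#' Write a descriptor table to CSV
#' @param table a `descriptor_table`.
#' @param path output file.
#' @export
write_descriptor_table <- function(table, path) {
  df <- data.frame(id = table$ids, table$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Remove blank, all-zero and constant descriptor columns
#'
#' Drops columns that are entirely missing, entirely zero or constant
#' (zero variance, ignoring missing cells), and rows that are fully missing.
#' The dropped names are recorded in the `"dropped"` attribute.
#'
#' @param table a `descriptor_table`.
#' @return the cleaned `descriptor_table` (no missing values remain only if
#'   the input had none outside dropped rows/columns).
#' @export
clean_descriptors <- function(table) {
  stopifnot(inherits(table, "descriptor_table"))
  v <- table$values
  drop_col <- vapply(seq_len(ncol(v)), function(j) {
    col <- v[, j]
    if (all(is.na(col))) return(TRUE)
    col <- col[!is.na(col)]
    all(col == 0) || length(unique(col)) == 1L
  }, FALSE)
  dropped <- colnames(v)[drop_col]
  v <- v[, !drop_col, drop = FALSE]
  if (ncol(v) == 0L) stop("all descriptor columns dropped", call. = FALSE)
  drop_row <- rowSums(!is.na(v)) == 0L
  v <- v[!drop_row, , drop = FALSE]
  out <- descriptor_table(v)
  attr(out, "dropped") <- dropped
  out
}

#' Greedy correlation filter
#'
#' While any pair of columns has absolute Pearson correlation above the
#' threshold, the member of the worst (highest |r|) pair with the larger mean
#' absolute correlation to all remaining columns is dropped (ties: the later
#' column in input order). The result has no pair with |r| above the
#' threshold.
#'
#' @param table a cleaned `descriptor_table`.
#' @param threshold in (0, 1]; default 0.9 (the published cut).
#' @return the filtered `descriptor_table`, dropped names in the `"dropped"`
#'   attribute.
#' @export
correlation_filter <- function(table, threshold = 0.9) {
  stopifnot(inherits(table, "descriptor_table"))
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  v <- table$values
  keep <- seq_len(ncol(v))
  dropped <- character(0)
  repeat {
    if (length(keep) < 2L) break
    r <- abs(stats::cor(v[, keep, drop = FALSE],
                        use = "pairwise.complete.obs"))
    diag(r) <- 0
    r[is.na(r)] <- 0
    worst <- max(r)
    if (worst <= threshold) break
    idx <- which(r == worst, arr.ind = TRUE)[1, ]
    cand <- sort(c(idx[["row"]], idx[["col"]]))
    meanabs <- colMeans(r)[cand]
    victim <- if (meanabs[1] > meanabs[2]) cand[1]
              else if (meanabs[2] > meanabs[1]) cand[2]
              else cand[2]  # tie: later column in input order
    dropped <- c(dropped, colnames(v)[keep[victim]])
    keep <- keep[-victim]
  }
  out <- descriptor_table(v[, keep, drop = FALSE])
  attr(out, "dropped") <- dropped
  out
}
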