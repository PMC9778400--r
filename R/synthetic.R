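# Synthetic-data generators: correlated descriptor/activity datasets with a
# known linear truth (for GA-recovery and validation-metric tests), and
# flavonoid-like screening libraries with planted near-duplicates of seed
# compounds (for enrichment-recall tests). All generators are pure functions
# of their arguments, seed included.

#' Synthetic linear descriptor/activity dataset
#'
#' Descriptor columns are standard normal draws mixed with a common latent
#' factor so that `cor(x_a, x_b) ~ descriptor_correlation` between columns
#' sharing the factor; the response is
#' `y = intercept + sum(true_coefficients * X) + N(0, noise_sd)`.
#' The generating truth is returned for recovery scoring.
#'
#' @param n observations.
#' @param p_total total descriptor columns (named `D1..Dp`).
#' @param true_coefficients named numeric vector over a subset of the
#'   columns; default 5 strong coefficients on `D1..D5`.
#' @param intercept numeric intercept (default 1).
#' @param noise_sd Gaussian noise standard deviation (default 0.1).
#' @param descriptor_correlation in [0, 1): target pairwise correlation
#'   between consecutive column pairs sharing a latent factor (default 0).
#' @param seed integer seed.
#' @return list with `table` (`descriptor_table`), `y`, and `truth`
#'   (intercept, coefficients, noise_sd, seed).
#' @export
synth_linear_dataset <- function(n = 60L, p_total = 40L,
                                 true_coefficients = NULL, intercept = 1,
                                 noise_sd = 0.1, descriptor_correlation = 0,
                                 seed = 1L) {
  stopifnot(n >= 3L, p_total >= 1L, noise_sd >= 0,
            descriptor_correlation >= 0, descriptor_correlation < 1)
  if (is.null(true_coefficients)) {
    k <- min(5L, p_total)
    true_coefficients <- stats::setNames(seq(2, 3, length.out = k),
                                         paste0("D", seq_len(k)))
  }
  nms <- paste0("D", seq_len(p_total))
  if (!all(names(true_coefficients) %in% nms)) {
    stop("true_coefficients name columns outside D1..D", p_total, call. = FALSE)
  }
  withr_seed(seed, {
    X <- matrix(stats::rnorm(n * p_total), n, p_total,
                dimnames = list(paste0("obs", seq_len(n)), nms))
    if (descriptor_correlation > 0 && p_total >= 2L) {
      # consecutive pairs (2j-1, 2j) share a latent factor
      rho <- descriptor_correlation
      for (j in seq_len(p_total %/% 2L)) {
        z <- stats::rnorm(n)
        X[, 2L * j - 1L] <- sqrt(rho) * z + sqrt(1 - rho) * X[, 2L * j - 1L]
        X[, 2L * j] <- sqrt(rho) * z + sqrt(1 - rho) * X[, 2L * j]
      }
    }
    y <- intercept + drop(X[, names(true_coefficients), drop = FALSE] %*%
                            true_coefficients) +
      stats::rnorm(n, sd = noise_sd)
    list(table = descriptor_table(X), y = y,
         truth = list(intercept = intercept,
                      coefficients = true_coefficients,
                      noise_sd = noise_sd, seed = seed))
  })
}

# substituent vocabulary: CHO-only fragments written for attachment to an
# aromatic ring carbon (appended as a parenthesised branch)
.substituents <- c(
  hydroxy = "O",
  methoxy = "OC",
  glucosyl = "OC1OC(CO)C(O)C(O)C1O",
  rutinosyl = "OC1OC(COC2OC(C)C(O)C(O)C2O)C(O)C(O)C1O",
  galloyl = "OC(=O)c1cc(O)c(O)c(O)c1"
)

#' Synthetic flavonoid-like screening library
#'
#' Random decoration of the 2-phenyl-4H-chromen-4-one (flavone) scaffold:
#' each of seven ring positions (A-ring 5,6,7,8 and B-ring 3',4',5')
#' independently carries nothing or a draw from a small CHO substituent
#' vocabulary (hydroxy, methoxy, glucosyl, rutinosyl, galloyl). When `seeds`
#' is supplied, `planted_per_seed` variants of each seed are appended, with
#' provenance in the `planted` column.
#'
#' Two planted-variant modes exist. The default, `"duplicate"`, re-emits the
#' seed's SMILES from a permuted atom ordering: a textually distinct record of
#' the identical constitution, emulating the duplicate deposits a natural
#' product database holds, with circular-fingerprint similarity exactly 1 --
#' these are the records whose enrichment recall is guaranteed by
#' construction. `"substitution"` performs a single-site chemical edit (one
#' hydroxyl added on an aromatic CH, or a terminal O-methyl removed); measured
#' over the reference flavonoids such edits sit at Tanimoto 0.57-0.82 to the
#' parent, i.e. they straddle the 0.8 enrichment threshold and serve as
#' boundary decoys, not guaranteed recalls (see the methods vignette).
#'
#' @param n_molecules random scaffold decorations to generate.
#' @param seeds optional `compound_set` to plant variants of.
#' @param planted_per_seed variants per seed (default 1).
#' @param planted_mode `"duplicate"` (default) or `"substitution"`; see above.
#' @param seed integer seed.
#' @return a `compound_set` with a logical `planted` column and, for planted
#'   rows, `parent_seed`.
#' @export
synth_library <- function(n_molecules = 100L, seeds = NULL,
                          planted_per_seed = 1L,
                          planted_mode = c("duplicate", "substitution"),
                          seed = 1L) {
  planted_mode <- match.arg(planted_mode)
  stopifnot(n_molecules >= 0L)
  withr_seed(seed, {
    smis <- character(n_molecules)
    probs <- c(none = 0.35, hydroxy = 0.3, methoxy = 0.15, glucosyl = 0.1,
               rutinosyl = 0.05, galloyl = 0.05)
    for (k in seq_len(n_molecules)) {
      pick <- sample(names(probs), 7, replace = TRUE, prob = probs)
      frag <- function(w) if (w == "none") "" else paste0("(", .substituents[[w]], ")")
      # positions: A ring 5,6,7,8 ; B ring 3',4',5'
      smis[k] <- paste0(
        "O=C1C=C(c2cc", frag(pick[5]), "c", frag(pick[6]), "c", frag(pick[7]),
        "c2)Oc2c", frag(pick[4]), "c", frag(pick[3]), "c", frag(pick[2]),
        "c", frag(pick[1]), "c12")
    }
    ids <- sprintf("lib%04d", seq_len(n_molecules))
    out <- compound_set(id = ids, smiles = smis, source = "library",
                        provenance = sprintf("synth_library(seed=%d)", seed),
                        validate = TRUE)
    out$planted <- rep(FALSE, n_molecules)
    out$parent_seed <- rep(NA_character_, n_molecules)
    if (!is.null(seeds) && nrow(seeds) > 0L && planted_per_seed > 0L) {
      pl_id <- character(0); pl_smi <- character(0); pl_parent <- character(0)
      for (s in seq_len(nrow(seeds))) {
        for (v in seq_len(planted_per_seed)) {
          smi <- if (planted_mode == "duplicate") {
            .rewrite_variant(seeds$smiles[s])
          } else {
            .single_edit_variant(seeds$smiles[s], v)
          }
          pl_id <- c(pl_id, sprintf("planted_%s_%d", seeds$id[s], v))
          pl_smi <- c(pl_smi, smi)
          pl_parent <- c(pl_parent, seeds$id[s])
        }
      }
      planted <- compound_set(id = pl_id, smiles = pl_smi, source = "library",
                              validate = TRUE)
      planted$planted <- TRUE
      planted$parent_seed <- pl_parent
      merged <- rbind(as.data.frame(out), as.data.frame(planted))
      attr_prov <- attr(out, "provenance")
      out <- compound_set(id = merged$id, smiles = merged$smiles,
                          name = merged$name, source = "library",
                          provenance = attr_prov, validate = FALSE)
      out$planted <- merged$planted
      out$parent_seed <- merged$parent_seed
    }
    out
  })
}

# Constitution-preserving rewrite: same molecule, different SMILES string
# (atom traversal order drawn from the surrounding RNG state).
.rewrite_variant <- function(smiles) {
  mol <- parse_smiles(smiles)
  .write_smiles(mol, rank = sample(nrow(mol$atoms)))
}

# One structural single-site edit of a parent molecule: add a hydroxyl to the
# v-th aromatic CH (cycling), or -- when the parent has an O-methyl and v is
# even -- remove a terminal methyl from it. Operates on the parsed graph and
# re-emits SMILES, so the edit is constitutional, not textual.
.single_edit_variant <- function(smiles, v = 1L) {
  mol <- parse_smiles(smiles)
  a <- mol$atoms
  # candidate aromatic CH positions
  ch <- which(a$element == "C" & a$aromatic & a$nh > 0L)
  # terminal OMe carbons: CH3 on ether oxygen
  b <- mol$bonds
  ome <- integer(0)
  for (i in which(a$element == "C" & !a$aromatic & a$nh == 3L & a$degree == 1L)) {
    nb <- c(b$j[b$i == i], b$i[b$j == i])
    if (length(nb) == 1L && a$element[nb] == "O" && a$degree[nb] == 2L) {
      ome <- c(ome, i)
    }
  }
  if (length(ome) && v %% 2L == 0L) {
    # demethylate: drop the methyl carbon, oxygen becomes hydroxyl
    keep <- setdiff(seq_len(nrow(a)), ome[1])
    remap <- match(seq_len(nrow(a)), keep)
    nb <- b[!(b$i == ome[1] | b$j == ome[1]), , drop = FALSE]
    nb$i <- remap[nb$i]; nb$j <- remap[nb$j]
    na <- a[keep, , drop = FALSE]
    o_at <- which(na$element == "O" & !(seq_along(keep) %in% c(nb$i, nb$j)))
    mol2 <- list(atoms = data.frame(element = na$element,
                                    aromatic = na$aromatic,
                                    charge = na$charge, nh = NA_integer_,
                                    bracket = FALSE,
                                    stringsAsFactors = FALSE),
                 bonds = nb)
    mol2$atoms$nh[na$bracket] <- na$nh[na$bracket]
    mol2$atoms$bracket <- na$bracket
    mol2 <- .assign_implicit_h(mol2, "variant")
    mol2 <- .perceive_rings(mol2)
    mol2 <- .perceive_aromaticity(mol2)
    class(mol2) <- "molecule"
    return(.write_smiles(mol2))
  }
  if (length(ch) == 0L) stop("no editable aromatic CH in parent", call. = FALSE)
  pos <- ch[((v - 1L) %% length(ch)) + 1L]
  na <- rbind(a, data.frame(element = "O", aromatic = FALSE, charge = 0L,
                            nh = NA_integer_, bracket = FALSE,
                            degree = 1L))
  nb <- rbind(b, data.frame(i = pos, j = nrow(na), order = 1L,
                            aromatic = FALSE, in_ring = FALSE))
  mol2 <- list(atoms = data.frame(element = na$element, aromatic = na$aromatic,
                                  charge = na$charge, nh = NA_integer_,
                                  bracket = FALSE, stringsAsFactors = FALSE),
               bonds = nb[, c("i", "j", "order", "aromatic")])
  mol2 <- .assign_implicit_h(mol2, "variant")
  mol2 <- .perceive_rings(mol2)
  mol2 <- .perceive_aromaticity(mol2)
  class(mol2) <- "molecule"
  .write_smiles(mol2)
}
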