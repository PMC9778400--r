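# Physicochemical property estimators and the QED drug-likeness score.
#
# QED follows the Bickerton weighted-desirability formulation with the
# published asymmetric-double-sigmoid parameters and weights. The underlying
# property estimators are deliberately compact: logP uses a reduced
# Wildman-Crippen-style atom typing and PSA the common Ertl O/N fragment
# contributions (adequate for the C/H/O-dominated chemistry screened here);
# the structural-alerts count is fixed at 0 (no SMARTS engine). See the
# methods vignette for the consequences.

#' Molecular weight
#'
#' Standard average-isotope molecular weight including implicit/explicit
#' hydrogens.
#'
#' @param x SMILES string or `molecule`.
#' @return weight in g/mol.
#' @examples
#' molecular_weight("O")  # 18.02
#' @export
molecular_weight <- function(x) {
  mol <- .as_molecule(x)
  sum(.elem_prop(mol$atoms$element, "mass")) +
    sum(mol$atoms$nh) * .elements["H", "mass"]
}

# reduced Wildman-Crippen atom contributions
.crippen_logp <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  n <- nrow(a)
  dbl_het <- rep(FALSE, n)   # double bond to N/O/S
  att_het <- rep(FALSE, n)   # single-bonded to N/O (aliphatic attachment)
  att_arom <- rep(FALSE, n)
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    if (b$order[k] >= 2L && !b$aromatic[k]) {
      if (a$element[j] %in% c("N", "O", "S")) dbl_het[i] <- TRUE
      if (a$element[i] %in% c("N", "O", "S")) dbl_het[j] <- TRUE
    }
    if (a$element[j] %in% c("N", "O")) att_het[i] <- TRUE
    if (a$element[i] %in% c("N", "O")) att_het[j] <- TRUE
    if (a$aromatic[j]) att_arom[i] <- TRUE
    if (a$aromatic[i]) att_arom[j] <- TRUE
  }
  contrib <- numeric(n)
  hcontrib <- numeric(n)
  for (i in seq_len(n)) {
    el <- a$element[i]
    contrib[i] <- switch(el,
      C = if (a$aromatic[i]) {
            if (a$nh[i] > 0) 0.1581                  # aromatic CH
            else if (att_het[i]) 0.1360              # aromatic C-O/N
            else 0.2955                              # substituted / bridgehead
          } else if (dbl_het[i]) -0.2783             # carbonyl-type carbon
          else if (any(b$order[b$i == i | b$j == i] >= 2L)) 0.1551  # vinylic
          else if (att_het[i]) -0.2035               # sp3 C on heteroatom
          else if (a$degree[i] + a$nh[i] >= 4 && a$degree[i] <= 2) 0.1441
          else 0.0,
      O = if (a$aromatic[i]) 0.1552
          else if (a$nh[i] > 0) -0.2893              # hydroxyl
          else if (dbl_het[i] || any(b$order[(b$i == i | b$j == i)] >= 2L)) -0.1526
          else -0.0684,                              # ether/ester O
      N = -0.60,
      S = 0.6482, P = 0.8612, F = 0.4202, Cl = 0.6895, Br = 0.8456,
      I = 0.8857, B = 0.0, 0.0)
    h_on_het <- el %in% c("O", "N", "S")
    hcontrib[i] <- a$nh[i] * if (h_on_het) -0.2677 else 0.1230
  }
  sum(contrib) + sum(hcontrib)
}

#' Estimated octanol/water log P
#'
#' Reduced Wildman-Crippen-style additive estimate; see the vignette for the
#' atom typing and its accuracy envelope.
#'
#' @param x SMILES string or `molecule`.
#' @return estimated logP.
#' @export
log_p <- function(x) .crippen_logp(.as_molecule(x))

#' Topological polar surface area (Ertl O/N contributions)
#' @param x SMILES string or `molecule`.
#' @return TPSA in Angstrom^2.
#' @export
tpsa <- function(x) {
  mol <- .as_molecule(x)
  a <- mol$atoms
  b <- mol$bonds
  n <- nrow(a)
  has_dbl <- rep(FALSE, n)
  for (k in seq_len(nrow(b))) {
    if (b$order[k] >= 2L && !b$aromatic[k]) {
      has_dbl[b$i[k]] <- TRUE; has_dbl[b$j[k]] <- TRUE
    }
  }
  total <- 0
  for (i in seq_len(n)) {
    el <- a$element[i]
    if (!(el %in% c("N", "O"))) next
    conn <- a$degree[i] + a$nh[i]
    total <- total + if (el == "O") {
      if (a$charge[i] == -1L) 23.06
      else if (a$aromatic[i]) 13.14
      else if (has_dbl[i] && a$degree[i] == 1L) 17.07   # carbonyl O
      else if (a$nh[i] > 0L) 20.23                       # hydroxyl
      else 9.23                                          # ether
    } else {
      if (a$aromatic[i]) {
        if (a$nh[i] > 0L) 15.79 else if (a$degree[i] == 3L) 4.93 else 12.89
      } else if (has_dbl[i]) 12.36
      else if (a$nh[i] >= 2L) 26.02
      else if (a$nh[i] == 1L) 12.03
      else 3.24
    }
  }
  total
}

#' Hydrogen-bond acceptor and donor counts
#'
#' Acceptors: N and O atoms without positive charge. Donors: N/O atoms
#' bearing at least one hydrogen (group count, not hydrogen count).
#'
#' @param x SMILES string or `molecule`.
#' @return integer count.
#' @export
hba <- function(x) {
  a <- .as_molecule(x)$atoms
  sum(a$element %in% c("N", "O") & a$charge <= 0L)
}

#' @rdname hba
#' @export
hbd <- function(x) {
  a <- .as_molecule(x)$atoms
  sum(a$element %in% c("N", "O") & a$nh > 0L)
}

#' Rotatable bond count
#'
#' Single non-ring, non-aromatic bonds between two heavy atoms of degree at
#' least 2, excluding amide C-N bonds.
#'
#' @param x SMILES string or `molecule`.
#' @return integer count.
#' @export
rotatable_bonds <- function(x) {
  mol <- .as_molecule(x)
  a <- mol$atoms; b <- mol$bonds
  if (nrow(b) == 0L) return(0L)
  amide_c <- rep(FALSE, nrow(a))
  for (k in seq_len(nrow(b))) {
    if (b$order[k] == 2L && !b$aromatic[k]) {
      if (a$element[b$j[k]] == "O") amide_c[b$i[k]] <- TRUE
      if (a$element[b$i[k]] == "O") amide_c[b$j[k]] <- TRUE
    }
  }
  cnt <- 0L
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 1L || b$aromatic[k] || b$in_ring[k]) next
    i <- b$i[k]; j <- b$j[k]
    if (a$degree[i] < 2L || a$degree[j] < 2L) next
    is_amide <- (amide_c[i] && a$element[j] == "N") ||
                (amide_c[j] && a$element[i] == "N")
    if (!is_amide) cnt <- cnt + 1L
  }
  cnt
}

#' Aromatic ring count
#' @param x SMILES string or `molecule`.
#' @return integer count of perceived aromatic rings.
#' @export
aromatic_rings <- function(x) {
  length(.as_molecule(x)$aromatic_rings)
}

# Bickerton asymmetric double sigmoid desirability parameters
# (columns a, b, c, d, e, f, dmax) and weights.
.qed_params <- list(
  MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561),
  ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604),
  HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046),
  HBD    = c(1.618662227, 1010.051101, 0.985094388, 0.000000001, 0.713820843, 0.920922555, 258.1632616),
  PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167),
  ROTB   = c(0.010000091, 272.4121427, 2.558379970, 1.565547684, 1.271567166, 2.758063707, 105.4420403),
  AROM   = c(3.217788970, 957.7374108, 2.274627939, 0.000000001, 1.317690384, 0.375760881, 312.3372610),
  ALERTS = c(0.010000000, 1199.094025, -0.09002883, 0.000000001, 0.185904477, 0.875193782, 417.7253140)
)
.qed_weights <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                  PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

.ads <- function(x, p) {
  d <- p[1] +
    p[2] / (1 + exp(-(x - p[3] + p[4] / 2) / p[5])) *
    (1 - 1 / (1 + exp(-(x - p[3] - p[4] / 2) / p[6])))
  max(d / p[7], 1e-9)  # floor avoids log(0) on extreme inputs
}

#' Quantitative estimation of drug-likeness (QED)
#'
#' Weighted geometric mean of desirability transforms of eight properties:
#' MW, logP, H-bond acceptors/donors, polar surface area, rotatable bonds,
#' aromatic rings and structural alerts (the last fixed at 0 here). Returns a
#' value in [0, 1]; 0.5 is the screening default threshold.
#'
#' @param x SMILES string or `molecule`.
#' @return QED score in [0, 1].
#' @export
qed <- function(x) {
  mol <- .as_molecule(x)
  props <- c(MW = molecular_weight(mol), ALOGP = log_p(mol), HBA = hba(mol),
             HBD = hbd(mol), PSA = tpsa(mol), ROTB = rotatable_bonds(mol),
             AROM = aromatic_rings(mol), ALERTS = 0)
  d <- vapply(names(props), function(nm) .ads(props[[nm]], .qed_params[[nm]]), 0)
  exp(sum(.qed_weights * log(d)) / sum(.qed_weights))
}
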