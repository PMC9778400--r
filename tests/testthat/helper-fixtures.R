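# Shared fixtures, computed lazily and cached for the whole test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

reference_set <- function() memo("reference", load_reference_dataset())

# small molecules used across files
SMI <- list(
  methane = "C",
  ethanol = "CCO",
  propane = "CCC",
  benzene_arom = "c1ccccc1",
  benzene_kek = "C1=CC=CC=C1",
  quercetin = "O=C1c2c(O)cc(O)cc2OC(c2ccc(O)c(O)c2)=C1O",
  chlorobenzene = "Clc1ccccc1"
)

# a tiny deterministic compound table on disk
write_tiny_table <- function(rows) {
  tf <- tempfile(fileext = ".csv")
  utils::write.csv(rows, tf, row.names = FALSE, quote = TRUE)
  tf
}

# random connected molecular-graph-like SMILES: trees of C/O/N with single
# and double bonds, for property-style descriptor tests
random_tree_smiles <- function(n_atoms, rng) {
  elements <- c("C", "C", "C", "O", "N")
  build <- function(remaining) {
    el <- sample(elements, 1)
    if (remaining <= 1L) return(el)
    n_children <- sample.int(min(2L, remaining - 1L), 1)
    left <- remaining - 1L
    kids <- character(0)
    for (k in seq_len(n_children)) {
      take <- if (k == n_children) left else sample.int(left, 1)
      if (take > 0L) {
        kids <- c(kids, paste0("(", build(take), ")"))
        left <- left - take
      }
    }
    paste0(el, paste0(kids, collapse = ""))
  }
  build(n_atoms)
}
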