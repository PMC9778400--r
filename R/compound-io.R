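# Compound tables: reading/writing molecule tables, the embedded reference
# fixture, and IC50 <-> pIC50 conversion.

#' Construct a compound set
#'
#' A compound set is a data frame (class `compound_set`) with columns
#' `id`, `name`, `cid`, `smiles`, `pic50`, `source` and unique ids. It is the
#' common currency of the clustering, QSAR and screening modules.
#'
#' @param id character ids (unique).
#' @param smiles SMILES strings.
#' @param name display names (default: the ids).
#' @param cid optional PubChem CIDs (numeric, `NA` allowed).
#' @param pic50 optional experimental pIC50 values on the molar scale;
#'   when present must lie in (0, 15).
#' @param source one of `"reference"`, `"candidate"`, `"library"`.
#' @param provenance free-text provenance attached as an attribute.
#' @param validate parse every SMILES on construction (default `TRUE`).
#' @return a `compound_set`.
#' @export
compound_set <- function(id, smiles, name = id, cid = NA_real_,
                         pic50 = NA_real_, source = "library",
                         provenance = "", validate = TRUE) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("compound ids must be unique; duplicated: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  stopifnot(length(smiles) == length(id))
  source <- match.arg(source, c("reference", "candidate", "library"))
  df <- data.frame(id = id, name = rep_len(as.character(name), length(id)),
                   cid = rep_len(as.numeric(cid), length(id)),
                   smiles = as.character(smiles),
                   pic50 = rep_len(as.numeric(pic50), length(id)),
                   source = rep_len(source, length(id)),
                   stringsAsFactors = FALSE)
  bad_p <- !is.na(df$pic50) & (df$pic50 <= 0 | df$pic50 >= 15)
  if (any(bad_p)) {
    stop("pic50 out of range (0, 15) for: ", paste(df$id[bad_p], collapse = ", "),
         call. = FALSE)
  }
  if (validate && nrow(df)) {
    for (k in seq_len(nrow(df))) parse_smiles(df$smiles[k])
  }
  attr(df, "provenance") <- provenance
  class(df) <- c("compound_set", "data.frame")
  df
}

#' @export
print.compound_set <- function(x, ...) {
  cat(sprintf("<compound_set: %d compounds (%s)>\n", nrow(x),
              paste(unique(x$source), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Read a delimited compound table
#'
#' Reads a CSV/TSV file with a header into a [compound_set()]. Rows whose
#' SMILES fail to parse are collected in the `"parse_failures"` attribute
#' (id, row number and error message) rather than silently dropped.
#'
#' @param path file path or connection.
#' @param columns named list mapping the roles `id`, `name`, `smiles`, `pic50`,
#'   `cid` to column names in the file; only `smiles` is required (rows are
#'   numbered when no id column is given).
#' @param sep field separator; `","` by default, use `"\t"` for TSV.
#' @param source passed to [compound_set()].
#' @return a `compound_set`; inspect `attr(x, "parse_failures")`.
#' @export
read_smiles_table <- function(path, columns = list(smiles = "smiles"),
                              sep = ",", source = "library") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (nrow(df) == 0L) stop("compound table is empty: ", path, call. = FALSE)
  smi_col <- columns$smiles %||% "smiles"
  if (!smi_col %in% names(df)) {
    stop("missing smiles column '", smi_col, "' in ", path, call. = FALSE)
  }
  get <- function(role, default) {
    col <- columns[[role]]
    if (!is.null(col) && col %in% names(df)) df[[col]] else default
  }
  id <- as.character(get("id", seq_len(nrow(df))))
  smiles <- as.character(df[[smi_col]])
  parse_ok <- logical(nrow(df))
  failures <- data.frame(row = integer(0), id = character(0),
                         smiles = character(0), error = character(0))
  for (k in seq_len(nrow(df))) {
    err <- tryCatch({ parse_smiles(smiles[k]); NULL },
                    error = function(e) conditionMessage(e))
    parse_ok[k] <- is.null(err)
    if (!is.null(err)) {
      failures <- rbind(failures, data.frame(
        row = k, id = id[k], smiles = smiles[k], error = err))
    }
  }
  keep <- which(parse_ok)
  out <- compound_set(
    id = id[keep], smiles = smiles[keep],
    name = as.character(get("name", id))[keep],
    cid = suppressWarnings(as.numeric(get("cid", NA_real_)))[keep],
    pic50 = suppressWarnings(as.numeric(get("pic50", NA_real_)))[keep],
    source = source, validate = FALSE)
  attr(out, "parse_failures") <- failures
  if (nrow(failures)) {
    warning(nrow(failures), " row(s) with unparseable SMILES; see attr(x, \"parse_failures\")",
            call. = FALSE)
  }
  out
}

#' Write a compound set to CSV
#' @param set a `compound_set`.
#' @param path output file.
#' @export
write_smiles_table <- function(set, path) {
  utils::write.csv(as.data.frame(set), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a SMILES (.smi) file
#'
#' One record per line: `SMILES<whitespace>id`, id optional.
#' @inheritParams read_smiles_table
#' @param path file path.
#' @return a `compound_set`.
#' @export
read_smi <- function(path, source = "library") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty SMILES file: ", path, call. = FALSE)
  parts <- strsplit(trimws(lines), "[ \t]+")
  smiles <- vapply(parts, `[[`, "", 1L)
  id <- vapply(seq_along(parts), function(k) {
    if (length(parts[[k]]) > 1L) parts[[k]][2L] else as.character(k)
  }, "")
  tmp <- data.frame(id = id, smiles = smiles)
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  utils::write.csv(tmp, tf, row.names = FALSE)
  read_smiles_table(tf, columns = list(id = "id", smiles = "smiles"),
                    source = source)
}

#' Read an SDF (V2000) file into a compound set
#'
#' A minimal MOL/SDF reader sufficient for screening libraries: atoms, bonds
#' and charges from `M  CHG` lines; the title line is used as the id unless an
#' `id` data field is present. Molecules are converted to SMILES via the
#' canonical writer.
#'
#' @param path SDF file path.
#' @param source passed to [compound_set()].
#' @return a `compound_set`.
#' @export
read_sdf <- function(path, source = "library") {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(TRUE, utils::head(lines, -1) == "$$$$")))
  ids <- character(0); smis <- character(0)
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (length(rec) < 4L || !nzchar(paste(rec, collapse = ""))) next
    counts <- rec[4]
    na <- as.integer(substr(counts, 1, 3))
    nb <- as.integer(substr(counts, 4, 6))
    if (is.na(na)) next
    atom_lines <- rec[5:(4 + na)]
    elem <- trimws(substr(atom_lines, 32, 34))
    charge <- rep(0L, na)
    bonds <- if (nb > 0) {
      bl <- rec[(5 + na):(4 + na + nb)]
      data.frame(i = as.integer(substr(bl, 1, 3)),
                 j = as.integer(substr(bl, 4, 6)),
                 order = as.integer(substr(bl, 7, 9)),
                 aromatic = FALSE)
    } else {
      data.frame(i = integer(0), j = integer(0), order = integer(0),
                 aromatic = logical(0))
    }
    for (cl in grep("^M  CHG", rec, value = TRUE)) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), "[ ]+")[[1]])
      nn <- f[1]
      for (q in seq_len(nn)) charge[f[2 * q]] <- f[2 * q + 1]
    }
    # drop explicit hydrogens, crediting them to their heavy neighbour
    hk <- which(elem == "H")
    nh_extra <- rep(0L, na)
    if (length(hk)) {
      for (k in seq_len(nrow(bonds))) {
        if (bonds$i[k] %in% hk) nh_extra[bonds$j[k]] <- nh_extra[bonds$j[k]] + 1L
        if (bonds$j[k] %in% hk) nh_extra[bonds$i[k]] <- nh_extra[bonds$i[k]] + 1L
      }
      keep <- setdiff(seq_len(na), hk)
      remap <- match(seq_len(na), keep)
      bonds <- bonds[!(bonds$i %in% hk) & !(bonds$j %in% hk), , drop = FALSE]
      bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
      elem <- elem[keep]; charge <- charge[keep]; nh_extra <- nh_extra[keep]
      na <- length(keep)
    }
    mol <- list(atoms = data.frame(element = elem, aromatic = FALSE,
                                   charge = charge, nh = NA_integer_,
                                   bracket = charge != 0L,
                                   stringsAsFactors = FALSE),
                bonds = bonds)
    # explicit H from the file augment the implicit count via brackets
    mol <- .assign_implicit_h(mol, basename(path))
    mol$atoms$nh <- mol$atoms$nh + nh_extra
    mol$atoms$bracket <- mol$atoms$bracket | nh_extra > 0L
    mol <- .perceive_rings(mol)
    mol <- .perceive_aromaticity(mol)
    class(mol) <- "molecule"
    # id: data field <id> if present, else title line
    idf <- grep("^> *<id>", rec)
    id <- if (length(idf) && length(rec) > idf[1]) trimws(rec[idf[1] + 1L])
          else trimws(rec[1])
    if (!nzchar(id)) id <- paste0("mol", length(ids) + 1L)
    ids <- c(ids, id); smis <- c(smis, .write_smiles(mol))
  }
  if (length(ids) == 0L) stop("no molecules in SDF: ", path, call. = FALSE)
  ids <- make.unique(ids)
  compound_set(id = ids, smiles = smis, source = source, validate = TRUE)
}

#' The 27-flavonoid reference dataset
#'
#' The embedded fixture of 27 dietary flavonoids with alpha-glucosidase
#' pIC50 values, PubChem CIDs, and the published per-compound 2D/3D model
#' predictions and residues. The CID is the authoritative identity; one entry
#' (CID 5281673) carries the printed name "Myricetin" and the CID-implied
#' `alt_name` "Myricitrin" without resolving the collision. Fixture SMILES are
#' standard PubChem constitutions (stereochemistry dropped); the provenance
#' column records this per compound.
#'
#' @return a `compound_set` of 27 compounds with extra columns
#'   `alt_name`, `pic50pre_2d`, `residue_2d`, `pic50pre_3d`, `residue_3d`.
#' @export
load_reference_dataset <- function() {
  path <- system.file("extdata", "reference_flavonoids.csv",
                      package = "flavoqsar", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  out <- compound_set(id = as.character(df$cid), smiles = df$smiles,
                      name = df$name, cid = df$cid, pic50 = df$pic50,
                      source = "reference",
                      provenance = "embedded reference fixture",
                      validate = FALSE)
  out$alt_name <- df$alt_name
  out$pic50pre_2d <- df$pic50pre_2d
  out$residue_2d <- df$residue_2d
  out$pic50pre_3d <- df$pic50pre_3d
  out$residue_3d <- df$residue_3d
  out
}

#' The five screened candidate molecules
#'
#' The five natural products retained by the published screening funnel,
#' with their predicted IC50 values (micromolar). Structures are drawn from
#' the systematic names; morelosin's structure is a labelled stand-in (see
#' the provenance column).
#'
#' @return a `compound_set` of 5 compounds with extra column `ic50pre_um`.
#' @export
load_candidates <- function() {
  path <- system.file("extdata", "candidates.csv",
                      package = "flavoqsar", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  out <- compound_set(id = df$name, smiles = df$smiles, name = df$name,
                      source = "candidate",
                      provenance = "embedded candidate fixture",
                      validate = FALSE)
  out$ic50pre_um <- df$ic50pre_um
  out
}

#' Convert IC50 to pIC50
#'
#' `pIC50 = -log10(IC50 in mol/L)`. Micromolar inputs are converted to molar
#' first; the package convention is molar internally, micromolar at the
#' boundary.
#'
#' @param ic50 positive concentrations.
#' @param unit `"molar"` or `"micromolar"`.
#' @return pIC50 values.
#' @examples
#' pic50_from_ic50(100, "micromolar")  # 4
#' @export
pic50_from_ic50 <- function(ic50, unit = c("molar", "micromolar")) {
  unit <- match.arg(unit)
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("ic50 must be positive and finite", call. = FALSE)
  }
  m <- if (unit == "micromolar") ic50 * 1e-6 else ic50
  -log10(m)
}

#' Convert pIC50 back to IC50
#' @param pic50 pIC50 values (molar scale).
#' @param unit output unit, `"molar"` or `"micromolar"`.
#' @return IC50 values in the requested unit.
#' @export
ic50_from_pic50 <- function(pic50, unit = c("molar", "micromolar")) {
  unit <- match.arg(unit)
  m <- 10^(-pic50)
  if (unit == "micromolar") m * 1e6 else m
}

#' Element symbols present in a compound
#'
#' Includes hydrogen when any implicit or explicit hydrogen is present.
#' Used to build the screening element whitelist.
#'
#' @param x a SMILES string or `molecule`.
#' @return sorted character vector of element symbols.
#' @examples
#' element_set("CCN")  # C, H, N
#' @export
element_set <- function(x) {
  mol <- if (inherits(x, "molecule")) x else parse_smiles(x)
  out <- unique(mol$atoms$element)
  if (sum(mol$atoms$nh) > 0) out <- c(out, "H")
  sort(unique(out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
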