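#' Molecules as labelled graphs of heavy atoms
#'
#' A `Molecule` is the substrate of signature computation: a graph of heavy
#' (non-hydrogen) atoms, each labelled with its element symbol, formal charge
#' and implicit hydrogen count, connected by bonds of order 1, 2, 3 or
#' `"ar"` (aromatic). Hydrogens are always implicit; stereochemistry and
#' isotopes are discarded. The graph may be disconnected (multi-fragment
#' species such as salts are allowed).
#'
#' @param atoms data.frame with columns `element` (character), `charge`
#'   (integer) and `hydrogens` (integer implicit-H count), one row per heavy
#'   atom.
#' @param bonds data.frame with columns `from`, `to` (1-based atom indices)
#'   and `order` (one of `"1"`, `"2"`, `"3"`, `"ar"`). May have zero rows.
#' @param id opaque identifier carried along for error messages.
#' @return An object of class `Molecule`.
#' @seealso [parse_structure()], [molecular_signature()]
#' @export
molecule <- function(atoms, bonds, id = "") {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  atoms <- data.frame(element = as.character(atoms$element),
                      charge = as.integer(atoms$charge),
                      hydrogens = as.integer(atoms$hydrogens),
                      stringsAsFactors = FALSE)
  bonds <- data.frame(from = as.integer(bonds$from),
                      to = as.integer(bonds$to),
                      order = as.character(bonds$order),
                      stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (nrow(bonds) > 0) {
    if (any(bonds$from < 1 | bonds$from > n | bonds$to < 1 | bonds$to > n))
      stop("bond endpoint out of range in molecule '", id, "'")
    if (any(bonds$from == bonds$to))
      stop("self-bond in molecule '", id, "'")
    if (!all(bonds$order %in% c("1", "2", "3", "ar")))
      stop("bond order must be one of 1, 2, 3, ar")
  }
  structure(list(atoms = atoms, bonds = bonds, id = id), class = "Molecule")
}

#' @export
print.Molecule <- function(x, ...) {
  cat("Molecule", if (nzchar(x$id)) paste0("'", x$id, "'") else "",
      ": ", nrow(x$atoms), " heavy atoms, ", nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Number of heavy atoms in a molecule
#' @param mol a [molecule()].
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

# MDL old-style charge codes (atom-block field 5): 1..3 = +3..+1, 5..7 = -1..-3.
.mdl_charge <- function(code) {
  ifelse(code == 0, 0L,
  ifelse(code >= 1 & code <= 3, 4L - as.integer(code),
  ifelse(code >= 5 & code <= 7, 4L - as.integer(code), 0L)))
}

#' Parse a chemical structure into a Molecule
#'
#' Converts a SMILES string or an MDL Molfile (V2000) into a [molecule()].
#' Conversion is delegated to OpenBabel (via ChemmineOB), which normalizes
#' the input and makes every hydrogen explicit; the explicit hydrogens are
#' then folded back into per-atom implicit counts so the returned graph
#' contains heavy atoms only. Aromatic input is kekulized by OpenBabel, so
#' bond orders in the result are 1/2/3; the same perception is applied to
#' every structure, which keeps reaction-rule differences consistent.
#' Stereochemistry and isotope labels are discarded.
#'
#' @param text the structure, either a SMILES string or the full text of a
#'   Molfile.
#' @param format `"smiles"` or `"molfile"`.
#' @param id identifier stored on the returned molecule.
#' @return A [molecule()].
#' @examples
#' parse_structure("CCO", "smiles")
#' @export
parse_structure <- function(text, format = c("smiles", "molfile"), id = "") {
  format <- match.arg(format)
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text)))
    stop("structure text must be a non-empty string")
  from <- switch(format, smiles = "SMI", molfile = "MOL")
  input <- if (format == "smiles") paste0(text, "\n") else text
  sdf_txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      from, "SDF", input, options = data.frame(names = "h", args = ""))),
    error = function(e) stop("cannot parse ", format, " for '", id, "': ",
                             conditionMessage(e)))
  if (!nzchar(sdf_txt) || !grepl("V2000", sdf_txt, fixed = TRUE))
    stop("OpenBabel failed to parse ", format, " input",
         if (nzchar(id)) paste0(" for '", id, "'") else "",
         ": ", substr(text, 1, 60))
  sdf <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(textConnection(sdf_txt)))
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elements <- sub("_\\d+$", "", rownames(ab))
  charges <- .mdl_charge(ab[, 5])
  nz <- length(elements)
  bonds_all <- if (is.null(dim(bb)) && length(bb) >= 3) {
    data.frame(from = bb[1], to = bb[2], order = bb[3])
  } else if (is.null(dim(bb)) || nrow(bb) == 0) {
    data.frame(from = integer(), to = integer(), order = integer())
  } else {
    data.frame(from = bb[, 1], to = bb[, 2], order = bb[, 3])
  }
  heavy <- which(elements != "H")
  if (length(heavy) == 0)
    stop("molecule has no heavy atoms",
         if (nzchar(id)) paste0(" ('", id, "')") else "")
  hyd <- integer(length(heavy))
  idx_map <- match(seq_len(nz), heavy)  # old index -> new heavy index
  keep <- logical(nrow(bonds_all))
  for (k in seq_len(nrow(bonds_all))) {
    a <- bonds_all$from[k]; b <- bonds_all$to[k]
    ha <- elements[a] == "H"; hb <- elements[b] == "H"
    if (ha && hb) next  # H2 fragment; no heavy carrier
    if (ha || hb) {
      heavy_end <- if (ha) b else a
      hyd[idx_map[heavy_end]] <- hyd[idx_map[heavy_end]] + 1L
    } else keep[k] <- TRUE
  }
  bonds <- bonds_all[keep, , drop = FALSE]
  ord <- as.character(bonds$order)
  ord[ord == "4"] <- "ar"
  molecule(
    atoms = data.frame(element = elements[heavy], charge = charges[heavy],
                       hydrogens = hyd, stringsAsFactors = FALSE),
    bonds = data.frame(from = idx_map[bonds$from], to = idx_map[bonds$to],
                       order = ord, stringsAsFactors = FALSE),
    id = id)
}

#' Elemental formula of a molecule
#'
#' Counts every element including the implicit hydrogens.
#'
#' @param mol a [molecule()].
#' @return Named integer vector of element counts (alphabetical by element).
#' @export
molecule_formula <- function(mol) {
  counts <- table(mol$atoms$element)
  out <- stats::setNames(as.integer(counts), names(counts))
  h <- sum(mol$atoms$hydrogens)
  if (h > 0) out["H"] <- (if ("H" %in% names(out)) out[["H"]] else 0L) + h
  out[order(names(out))]
}

#' Parse a molecular formula string
#'
#' Accepts plain Hill-style formulas such as `"C6H12O6"` (no parentheses,
#' no isotopes). Used for metabolites that carry a formula instead of a
#' structure.
#'
#' @param text formula string.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(text) {
  text <- trimws(text)
  if (!grepl("^([A-Z][a-z]?\\d*)+$", text))
    stop("malformed formula: '", text, "'")
  m <- gregexpr("[A-Z][a-z]?\\d*", text)[[1]]
  parts <- regmatches(text, list(m))[[1]]
  els <- sub("\\d+$", "", parts)
  ns <- as.integer(ifelse(grepl("\\d+$", parts), sub("^[A-Za-z]+", "", parts), "1"))
  out <- tapply(ns, els, sum)
  res <- stats::setNames(as.integer(out), names(out))
  res[order(names(res))]
}

#' Format an element-count vector as a formula string
#' @param counts named integer vector as returned by [parse_formula()].
#' @return A Hill-ordered formula string (C, H, then alphabetical).
#' @export
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  els <- names(counts)
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(hill, function(e)
    paste0(e, if (counts[[e]] > 1) counts[[e]] else ""), ""), collapse = "")
}

# Permute atom indices of a molecule (testing aid for relabeling invariance).
#' Relabel the atoms of a molecule
#'
#' Applies a permutation to the atom indices; the chemical graph is
#' unchanged. Signatures are invariant under this operation.
#'
#' @param mol a [molecule()].
#' @param perm integer permutation of `seq_len(n_atoms(mol))`.
#' @return The relabelled [molecule()].
#' @export
relabel_molecule <- function(mol, perm) {
  n <- n_atoms(mol)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  # perm[k] = old index placed at new position k; map old -> new
  newpos <- integer(n); newpos[perm] <- seq_len(n)
  atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  if (nrow(bonds) > 0) {
    bonds$from <- newpos[bonds$from]
    bonds$to <- newpos[bonds$to]
  }
  molecule(atoms, bonds, id = mol$id)
}
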