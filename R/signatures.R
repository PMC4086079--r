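#' Canonical atomic signature of one atom
#'
#' The signature of an atom at diameter `d` is a canonical string encoding
#' the atom's bonded neighborhood up to `d/2` bonds away. Diameter 0 is the
#' atom label alone, written `[element;Hn;charge]` (e.g. `[C;H4;0]` for
#' methane's carbon). For larger diameters the neighborhood is unfolded into
#' a rooted tree (never stepping straight back along the bond just
#' traversed, so rings re-enter as repeated atoms), children are serialized
#' recursively and sorted lexicographically, and bond orders are written
#' with a fixed symbol per order (`-`, `=`, `#`, `:`). The string is
#' therefore deterministic and invariant under any relabeling of atom
#' indices, and two atoms with isomorphic rooted neighborhoods up to radius
#' `d/2` receive identical strings.
#'
#' @param mol a [molecule()].
#' @param root 1-based atom index.
#' @param diameter even non-negative integer; odd values are rejected.
#' @return Object of class `AtomicSignature` with fields `text`, `root`,
#'   `diameter`.
#' @examples
#' m <- parse_structure("C", "smiles")
#' atomic_signature(m, 1, 0)$text  # "[C;H4;0]"
#' @export
atomic_signature <- function(mol, root, diameter) {
  .check_diameter(diameter)
  if (root < 1 || root > n_atoms(mol))
    stop("root atom index out of range")
  structure(list(text = .sig_text(mol, root, diameter), root = root,
                 diameter = as.integer(diameter)),
            class = "AtomicSignature")
}

#' @export
print.AtomicSignature <- function(x, ...) {
  cat("AtomicSignature d=", x$diameter, " root=", x$root, ": ", x$text, "\n",
      sep = "")
  invisible(x)
}

.check_diameter <- function(diameter) {
  if (length(diameter) != 1 || is.na(diameter) || diameter < 0 ||
      diameter != as.integer(diameter))
    stop("diameter must be a non-negative integer")
  if (diameter %% 2 != 0)
    stop("diameter must be even (the neighborhood radius is d/2)")
  invisible(as.integer(diameter))
}

.atom_label <- function(mol, i) {
  ch <- mol$atoms$charge[i]
  ch_txt <- if (ch > 0) paste0("+", ch) else as.character(ch)
  paste0("[", mol$atoms$element[i], ";H", mol$atoms$hydrogens[i], ";",
         ch_txt, "]")
}

.bond_symbol <- c("1" = "-", "2" = "=", "3" = "#", "ar" = ":")

# Adjacency list: for each atom, matrix-free list of (neighbor, order symbol).
.adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  if (nrow(mol$bonds) > 0) {
    sym <- .bond_symbol[mol$bonds$order]
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$from[k]; b <- mol$bonds$to[k]
      adj[[a]] <- rbind(adj[[a]], c(b, sym[k]))
      adj[[b]] <- rbind(adj[[b]], c(a, sym[k]))
    }
  }
  adj
}

.sig_text <- function(mol, root, diameter) {
  adj <- .adjacency(mol)
  labels <- vapply(seq_len(n_atoms(mol)), function(i) .atom_label(mol, i), "")
  rec <- function(atom, parent, depth) {
    if (depth == 0) return(labels[atom])
    nb <- adj[[atom]]
    if (is.null(nb)) return(labels[atom])
    kids <- character(0)
    for (k in seq_len(nrow(nb))) {
      j <- as.integer(nb[k, 1])
      if (!is.na(parent) && j == parent) next
      kids <- c(kids, paste0(nb[k, 2], rec(j, atom, depth - 1)))
    }
    if (length(kids) == 0) return(labels[atom])
    paste0(labels[atom], "(", paste0(sort(kids), collapse = ""), ")")
  }
  rec(root, NA_integer_, diameter %/% 2)
}

#' Molecular signature: multiset of atomic signatures
#'
#' The molecular signature of a compound at diameter `d` is the multiset of
#' its atoms' signatures: a named integer vector mapping each canonical
#' signature string to the number of atoms that carry it. The counts always
#' sum to the number of heavy atoms.
#'
#' @param mol a [molecule()].
#' @param diameter even non-negative integer.
#' @return A `SignatureVector`: named integer vector (sorted by name) with
#'   attribute `diameter`.
#' @examples
#' molecular_signature(parse_structure("O", "smiles"), 0)  # water
#' @export
molecular_signature <- function(mol, diameter) {
  .check_diameter(diameter)
  adj <- .adjacency(mol)
  labels <- vapply(seq_len(n_atoms(mol)), function(i) .atom_label(mol, i), "")
  texts <- vapply(seq_len(n_atoms(mol)), function(i)
    .sig_text(mol, i, diameter), "")
  tab <- table(texts)
  signature_vector(stats::setNames(as.integer(tab), names(tab)), diameter)
}

#' Construct a signature vector
#' @param counts named integer vector, all counts >= 1.
#' @param diameter the diameter the signatures were computed at.
#' @return A `SignatureVector`.
#' @export
signature_vector <- function(counts, diameter) {
  .check_diameter(diameter)
  counts <- counts[order(names(counts))]
  if (any(counts < 1)) stop("signature counts must be positive")
  structure(as.integer(counts), names = names(counts),
            diameter = as.integer(diameter),
            class = "SignatureVector")
}

#' @export
print.SignatureVector <- function(x, ...) {
  cat("SignatureVector d=", attr(x, "diameter"), " (", length(x),
      " distinct, ", sum(x), " atoms)\n", sep = "")
  for (i in seq_along(x)) cat("  ", x[i], "x ", names(x)[i], "\n", sep = "")
  invisible(x)
}

#' Multiset Tanimoto similarity between signature vectors
#'
#' `sum(min(a_k, b_k)) / sum(max(a_k, b_k))` over the union of signature
#' keys. Equals 1 exactly when the two multisets are identical; by
#' convention two empty vectors also score 1.
#'
#' @param a,b `SignatureVector`s at the same diameter.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  da <- attr(a, "diameter"); db <- attr(b, "diameter")
  if (!is.null(da) && !is.null(db) && da != db)
    stop("signature diameters differ (", da, " vs ", db, ")")
  keys <- union(names(a), names(b))
  if (length(keys) == 0) return(1)
  av <- stats::setNames(rep(0L, length(keys)), keys)
  bv <- av
  av[names(a)] <- as.integer(a)
  bv[names(b)] <- as.integer(b)
  sum(pmin(av, bv)) / sum(pmax(av, bv))
}

#' Write / read a signature vector as two-column TSV
#'
#' Column 1 is the canonical signature string, column 2 the count. The
#' diameter is recorded in a `# diameter=<d>` header comment. Round-trips
#' bit-exactly.
#'
#' @param sig a `SignatureVector`.
#' @param path file path.
#' @return `read_signature_tsv` returns the `SignatureVector`.
#' @export
write_signature_tsv <- function(sig, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# diameter=", attr(sig, "diameter")), con)
  writeLines(paste0(names(sig), "\t", as.integer(sig)), con)
  invisible(path)
}

#' @rdname write_signature_tsv
#' @export
read_signature_tsv <- function(path) {
  lines <- readLines(path)
  d_line <- grep("^# diameter=", lines, value = TRUE)
  if (length(d_line) != 1) stop("missing diameter header in ", path)
  d <- as.integer(sub("^# diameter=", "", d_line))
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) == 0)
    return(signature_vector(stats::setNames(integer(0), character(0)), d))
  parts <- strsplit(body, "\t", fixed = TRUE)
  signature_vector(
    stats::setNames(as.integer(vapply(parts, `[`, "", 2)),
                    vapply(parts, `[`, "", 1)), d)
}
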