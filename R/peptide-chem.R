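# Peptide-to-molecule conversion: one-letter sequences -> SMILES -> molecular
# graphs. Peptides are assembled as linear chains with a free amine N-terminus,
# free acid C-terminus, neutral protonation and free thiols (no disulfides, no
# cyclization linker).

#' The twenty natural amino acids
#'
#' One row per residue: one-letter `code`, `name`, the SMILES of the
#' `internal` residue form (open backbone attachment points, written
#' N-to-C so that fragments concatenate into a peptide), the `free`
#' amino-acid SMILES, and the Hill-notation `formula` of the free form.
#' Internal fragments carry the L-alpha stereocentre.
#'
#' @return A tibble with 20 rows and columns `code`, `name`, `internal`,
#'   `free`, `formula`.
#' @examples
#' amino_acid_table()
#' @export
amino_acid_table <- function() {
  side <- c(
    A = "C",
    R = "CCCNC(=N)N",
    N = "CC(N)=O",
    D = "CC(O)=O",
    C = "CS",
    E = "CCC(O)=O",
    Q = "CCC(N)=O",
    H = "Cc1c[nH]cn1",
    I = "[C@@H](C)CC",
    L = "CC(C)C",
    K = "CCCCN",
    M = "CCSC",
    F = "Cc1ccccc1",
    S = "CO",
    T = "[C@@H](O)C",
    W = "Cc1c[nH]c2ccccc12",
    Y = "Cc1ccc(O)cc1",
    V = "C(C)C"
  )
  codes <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  names_ <- c("alanine", "arginine", "asparagine", "aspartate", "cysteine",
              "glutamate", "glutamine", "glycine", "histidine", "isoleucine",
              "leucine", "lysine", "methionine", "phenylalanine", "proline",
              "serine", "threonine", "tryptophan", "tyrosine", "valine")
  internal <- vapply(codes, function(a) {
    if (a == "G") return("NCC(=O)")
    if (a == "P") return("N1CCC[C@H]1C(=O)")
    paste0("N[C@@H](", side[[a]], ")C(=O)")
  }, character(1))
  formulas <- c(
    A = "C3H7NO2", R = "C6H14N4O2", N = "C4H8N2O3", D = "C4H7NO4",
    C = "C3H7NO2S", E = "C5H9NO4", Q = "C5H10N2O3", G = "C2H5NO2",
    H = "C6H9N3O2", I = "C6H13NO2", L = "C6H13NO2", K = "C6H14N2O2",
    M = "C5H11NO2S", F = "C9H11NO2", P = "C5H9NO2", S = "C3H7NO3",
    T = "C4H9NO3", W = "C11H12N2O2", Y = "C9H11NO3", V = "C5H11NO2"
  )
  tibble(
    code = codes,
    name = names_,
    internal = unname(internal),
    free = paste0(unname(internal), "O"),
    formula = unname(formulas[codes])
  )
}

AA_CODES <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

check_sequence <- function(sequence, arg = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    abort(sprintf("`%s` must be a single non-empty residue string", arg))
  }
  sequence <- toupper(sequence)
  bad <- setdiff(strsplit(sequence, "")[[1]], AA_CODES)
  if (length(bad)) {
    abort(sprintf(
      "unsupported residue code(s) in `%s`: %s (only the 20 natural amino acids are supported)",
      arg, paste(unique(bad), collapse = ", ")
    ))
  }
  sequence
}

#' SMILES fragment for one amino acid
#'
#' @param code One-letter residue code (one of the 20 natural amino acids).
#' @param form `"internal"` for the residue form with open backbone
#'   attachment points (free amino acid minus one water), `"free"` for the
#'   intact neutral amino acid.
#' @return A one-row tibble with columns `code`, `form`, `smiles`, `formula`
#'   (an integer-named element-count vector, stored as a list column).
#' @examples
#' residue_smiles("G", "internal")
#' @export
residue_smiles <- function(code, form = c("internal", "free")) {
  form <- match.arg(form)
  if (length(code) != 1L || is.na(code)) abort("`code` must be a single letter")
  code <- toupper(code)
  aa <- amino_acid_table()
  hit <- aa[aa$code == code, ]
  if (nrow(hit) == 0L) {
    abort(sprintf(
      "unsupported residue code '%s': not one of the 20 natural amino acids", code
    ))
  }
  smiles <- if (form == "free") hit$free else hit$internal
  formula <- parse_formula(hit$formula)
  if (form == "internal") formula <- formula_subtract_water(formula)
  tibble(code = code, form = form, smiles = smiles, formula = list(formula))
}

parse_formula <- function(x) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  parts <- regmatches(x, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  el <- sub("[0-9]*$", "", parts)
  n <- sub("^[A-Z][a-z]?", "", parts)
  n <- ifelse(nzchar(n), as.integer(n), 1L)
  setNames(n, el)
}

formula_subtract_water <- function(f) {
  f[["H"]] <- f[["H"]] - 2L
  f[["O"]] <- f[["O"]] - 1L
  f[f > 0L]
}

#' Assemble a linear peptide molecule from a residue sequence
#'
#' Concatenates internal residue fragments N-to-C with amide bonds, a free
#' amine at the N-terminus and a free carboxylic acid at the C-terminus.
#' Cysteines stay as free thiols; no disulfides or cyclization chemistry are
#' represented, and the molecule is neutral (no zwitterion).
#'
#' @param sequence One-letter residue string (uppercase canonical form).
#' @return A `molecule_graph` (see [parse_smiles()]).
#' @examples
#' mol <- assemble_peptide("CGGSGGC")
#' molecular_formula(mol)
#' @export
assemble_peptide <- function(sequence) {
  sequence <- check_sequence(sequence)
  parse_smiles(peptide_smiles(sequence))
}

#' @rdname assemble_peptide
#' @return For `peptide_smiles()`, the assembled SMILES string (with L-alpha
#'   stereocentres) before canonicalization.
#' @export
peptide_smiles <- function(sequence) {
  sequence <- check_sequence(sequence)
  aa <- amino_acid_table()
  frags <- aa$internal[match(strsplit(sequence, "")[[1]], aa$code)]
  paste0(paste(frags, collapse = ""), "O")
}

# Light syntactic validation so malformed SMILES are reported with an offset
# rather than silently "fixed" downstream.
validate_smiles_syntax <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  depth <- 0L
  bracket <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) abort(sprintf("SMILES parse error at offset %d: unmatched ')'", i))
    }
    if (ch == "[") {
      if (bracket) abort(sprintf("SMILES parse error at offset %d: nested '['", i))
      bracket <- TRUE
    }
    if (ch == "]") {
      if (!bracket) abort(sprintf("SMILES parse error at offset %d: unmatched ']'", i))
      bracket <- FALSE
    }
  }
  if (depth > 0L) {
    abort(sprintf("SMILES parse error at offset %d: unclosed '('", nchar(smiles)))
  }
  if (bracket) {
    abort(sprintf("SMILES parse error at offset %d: unclosed '['", nchar(smiles)))
  }
  invisible(smiles)
}

#' Parse a SMILES string into a molecular graph
#'
#' The SMILES is canonicalized first (OpenBabel canonical dialect), so two
#' writings of the same molecule yield identical graphs. Atoms carry element,
#' formal charge, an aromatic flag and an implicit hydrogen count; bonds are
#' kekulized orders with aromatic ring bonds flagged.
#'
#' @param smiles A syntactically valid SMILES string.
#' @param strip_stereo Drop stereo descriptors before canonicalization (see
#'   [canonical_smiles()]).
#' @return A `molecule_graph`: list with `atoms` (tibble: `element`, `charge`,
#'   `aromatic`, `n_h`), `bonds` (tibble: `from`, `to`, `order`, `aromatic`)
#'   and `smiles` (canonical form).
#' @examples
#' parse_smiles("NCC(=O)O")
#' @export
parse_smiles <- function(smiles, strip_stereo = FALSE) {
  if (length(smiles) != 1L || is.na(smiles) || !nzchar(smiles)) {
    abort("`smiles` must be a single non-empty string")
  }
  validate_smiles_syntax(smiles)
  can <- canonical_smiles(smiles, strip_stereo = strip_stereo)

  # coordinate-free conversion; atoms come out in canonical-SMILES order
  sdf_text <- ChemmineOB::convertFormat("SMI", "SDF", can)
  lines <- strsplit(sdf_text, "\n")[[1]]
  if (length(lines) < 4L) {
    abort(sprintf("SMILES parse error at offset 1: '%s' is not a valid molecule", smiles))
  }
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms) || n_atoms < 1L) {
    abort(sprintf("SMILES parse error at offset 1: '%s' is not a valid molecule", smiles))
  }

  if (n_bonds > 0L) {
    sdf <- suppressWarnings(ChemmineR::read.SDFset(lines))
    if (!ChemmineR::validSDF(sdf)) {
      abort(sprintf("SMILES parse error at offset 1: '%s' is not a valid molecule", smiles))
    }
    mol <- sdf[[1]]
    ab <- ChemmineR::atomblock(mol)
    bb <- ChemmineR::bondblock(mol)
    elements <- sub("_.*$", "", rownames(ab))
    if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1)
    bonds <- tibble(
      from = as.integer(bb[, 1]),
      to = as.integer(bb[, 2]),
      order = as.integer(bb[, 3]),
      aromatic = FALSE
    )
  } else {
    # bondless molecules (single atoms, unbonded fragments) break the SDF
    # reader, but the atom block is just fixed-width element fields
    atom_lines <- lines[5L:(4L + n_atoms)]
    elements <- trimws(substr(atom_lines, 32, 34))
    bonds <- tibble(from = integer(), to = integer(), order = integer(),
                    aromatic = logical())
  }

  charges <- integer(n_atoms)
  chg <- extract_charges(lines)
  if (length(chg)) charges[as.integer(names(chg))] <- chg

  # aromaticity comes from the canonical SMILES itself (lowercase atoms),
  # i.e. OpenBabel's perception; atom order matches the SDF atom block
  tok <- smiles_atom_tokens(can)
  aromatic_atoms <- rep(FALSE, n_atoms)
  if (nrow(tok) == n_atoms && all(toupper(tok$element) == elements)) {
    aromatic_atoms <- tok$aromatic
  }
  if (nrow(bonds) && any(aromatic_atoms)) {
    # an aromatic bond joins two aromatic atoms inside a ring; bridges
    # (e.g. biaryl single bonds) are not ring bonds
    g <- igraph::graph_from_edgelist(cbind(bonds$from, bonds$to),
                                     directed = FALSE)
    br <- igraph::bridges(g)
    in_ring <- !(seq_len(nrow(bonds)) %in% as.integer(br))
    bonds$aromatic <- in_ring & aromatic_atoms[bonds$from] &
      aromatic_atoms[bonds$to]
  }

  atoms <- tibble(
    element = elements,
    charge = charges,
    aromatic = aromatic_atoms
  )
  atoms$n_h <- implicit_hydrogens(atoms, bonds)

  structure(
    list(atoms = atoms, bonds = bonds, smiles = can),
    class = "molecule_graph"
  )
}

# Atom tokens of a SMILES string in writing order: element symbol plus
# whether it was written in aromatic (lowercase) form.
smiles_atom_tokens <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  el <- character(0)
  arom <- logical(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      # optional isotope digits, then the element symbol; trailing chirality,
      # H-count, charge all start with non-lowercase characters, so the
      # regex stops at the right place ([nH] -> "n", [C@@H] -> "C")
      m <- regmatches(inner, regexec("^[0-9]*([A-Za-z][a-z]?)", inner))[[1]][2]
      el <- c(el, m)
      arom <- c(arom, substr(m, 1, 1) %in% letters)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      el <- c(el, paste0(ch, chars[i + 1L]))
      arom <- c(arom, FALSE)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      el <- c(el, ch)
      arom <- c(arom, FALSE)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      el <- c(el, ch)
      arom <- c(arom, TRUE)
      i <- i + 1L
    } else {
      i <- i + 1L  # bonds, digits, branches, dots, %, stereo marks
    }
  }
  tibble(element = el, aromatic = arom)
}

extract_charges <- function(lines) {
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  out <- integer(0)
  for (ln in chg_lines) {
    fields <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    n <- fields[1]
    pairs <- matrix(fields[-1], ncol = 2, byrow = TRUE)[seq_len(n), , drop = FALSE]
    out <- c(out, setNames(pairs[, 2], pairs[, 1]))
  }
  out
}

# Standard valences for implicit-hydrogen filling on neutral organic atoms;
# charge adds to N/P capacity and subtracts from O/S.
STD_VALENCE <- c(H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
                 P = 3L, S = 2L, Cl = 1L, Br = 1L, I = 1L)

implicit_hydrogens <- function(atoms, bonds) {
  n <- nrow(atoms)
  bond_sum <- numeric(n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      o <- bonds$order[k]
      bond_sum[bonds$from[k]] <- bond_sum[bonds$from[k]] + o
      bond_sum[bonds$to[k]] <- bond_sum[bonds$to[k]] + o
    }
  }
  val <- STD_VALENCE[atoms$element]
  val[is.na(val)] <- 0L
  adj <- ifelse(atoms$element %in% c("N", "P"), atoms$charge,
                ifelse(atoms$element %in% c("O", "S"), -abs(atoms$charge), 0L))
  pmax(0L, as.integer(val + adj - bond_sum))
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("<molecule_graph> %d heavy atoms, %d bonds\n",
              nrow(x$atoms), nrow(x$bonds)))
  cat("  ", x$smiles, "\n", sep = "")
  invisible(x)
}

#' Canonical SMILES serialization
#'
#' @param smiles SMILES string.
#' @param strip_stereo Drop stereo descriptors before canonicalization.
#' @return Canonical SMILES (OpenBabel dialect).
#' @export
canonical_smiles <- function(smiles, strip_stereo = FALSE) {
  if (strip_stereo) {
    # [C@@H] -> [CH] etc.; cis/trans bond slashes become plain single bonds
    smiles <- gsub("@", "", smiles, fixed = TRUE)
    smiles <- gsub("[/\\\\]", "", smiles)
  }
  out <- ChemmineOB::convertFormat("SMI", "CAN", smiles)
  out <- trimws(sub("\t.*$", "", out))
  if (!nzchar(out)) {
    abort(sprintf("SMILES parse error at offset 1: cannot canonicalize '%s'", smiles))
  }
  out
}

#' Molecular formula of a graph
#'
#' Counts include implicit hydrogens computed from standard valence rules.
#'
#' @param graph A `molecule_graph`.
#' @return Named integer vector of element counts (Hill order: C, H, then
#'   alphabetical).
#' @examples
#' molecular_formula(parse_smiles("O"))
#' @export
molecular_formula <- function(graph) {
  stopifnot(inherits(graph, "molecule_graph"))
  counts <- table(graph$atoms$element)
  f <- setNames(as.integer(counts), names(counts))
  h <- sum(graph$atoms$n_h) + sum(f[names(f) == "H"])
  f <- f[names(f) != "H"]
  if (h > 0L) f <- c(f, H = as.integer(h))
  hill_order(f)
}

hill_order <- function(f) {
  els <- names(f)
  first <- intersect(c("C", "H"), els)
  rest <- sort(setdiff(els, first))
  f[c(first, rest)]
}

#' @rdname molecular_formula
#' @param formula Named integer vector of element counts.
#' @return For `formula_string()`, the Hill-notation text form (e.g.
#'   `"C2H5NO2"`).
#' @export
formula_string <- function(formula) {
  formula <- hill_order(formula[formula > 0L])
  paste0(names(formula), ifelse(formula > 1L, formula, ""), collapse = "")
}

#' Expected formula of a peptide by residue arithmetic
#'
#' Sum of free-residue formulas minus (L - 1) waters; the independent check
#' for [assemble_peptide()].
#'
#' @param sequence One-letter residue string.
#' @return Named integer element-count vector.
#' @export
expected_peptide_formula <- function(sequence) {
  sequence <- check_sequence(sequence)
  aa <- amino_acid_table()
  codes <- strsplit(sequence, "")[[1]]
  total <- c(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L)
  for (code in codes) {
    f <- parse_formula(aa$formula[aa$code == code])
    total[names(f)] <- total[names(f)] + f
  }
  L <- length(codes)
  total[["H"]] <- total[["H"]] - 2L * (L - 1L)
  total[["O"]] <- total[["O"]] - (L - 1L)
  hill_order(total[total > 0L])
}
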