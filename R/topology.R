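#' Atom tables (topologies)
#'
#' A topology in bilayr is a tibble with one row per atom and columns
#' `atom` (1-based index, unique), `name` (atom name), `resname`,
#' `resid` (residue index), `chain` (optional protomer/segment label,
#' `NA` allowed), `mass` (amu, > 0) and `class` (residue chemistry class,
#' one of cationic, anionic, polar, hydrophobic, solvent, lipid, other).
#' The class labels mirror the usual colouring of peptide residues (cationic,
#' anionic, polar, hydrophobic) extended with solvent/lipid/other.
#'
#' `topology()` validates and normalises a data frame into this shape,
#' filling `mass` from the atom-name element guess and `class` from the
#' residue name when absent.
#'
#' @param atoms A data frame with at least `name`, `resname`, `resid`.
#' @return A tibble of class `bilayr_topology`.
#' @export
topology <- function(atoms) {
  atoms <- as_tibble(atoms)
  required <- c("name", "resname", "resid")
  missing <- setdiff(required, names(atoms))
  if (length(missing)) {
    abort(paste0("topology is missing columns: ", paste(missing, collapse = ", ")))
  }
  n <- nrow(atoms)
  if (n == 0) abort("topology must contain at least one atom")
  if (!"atom" %in% names(atoms)) atoms$atom <- seq_len(n)
  if (anyDuplicated(atoms$atom)) abort("atom indices must be unique within a topology")
  if (!"chain" %in% names(atoms)) atoms$chain <- NA_character_
  if (!"mass" %in% names(atoms)) atoms$mass <- guess_mass(atoms$name)
  if (!"class" %in% names(atoms)) atoms$class <- guess_class(atoms$resname)
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    abort("atom masses must be finite and > 0")
  }
  bad <- setdiff(unique(atoms$class), bilayr_atom_classes())
  if (length(bad)) {
    abort(paste0("unknown atom class(es): ", paste(bad, collapse = ", ")))
  }
  atoms <- atoms[, c("atom", "name", "resname", "resid", "chain", "mass", "class")]
  class(atoms) <- c("bilayr_topology", class(atoms))
  atoms
}

#' @rdname topology
#' @export
bilayr_atom_classes <- function() {
  c("cationic", "anionic", "polar", "hydrophobic", "solvent", "lipid", "other")
}

# element masses (amu) from the leading element letter(s) of an atom name
guess_mass <- function(name) {
  first <- toupper(substr(gsub("^[0-9]+", "", name), 1, 1))
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06)
  out <- unname(m[first])
  out[is.na(out)] <- 12.011
  out
}

guess_class <- function(resname) {
  up <- toupper(resname)
  dplyr::case_when(
    up %in% c("SOL", "WAT", "HOH", "TIP", "SPC") ~ "solvent",
    up %in% c("POPG", "POPC", "DPPC", "DPPG", "PGL", "LIP") ~ "lipid",
    up %in% c("LYS", "ARG", "HIS") ~ "cationic",
    up %in% c("GLU", "ASP") ~ "anionic",
    up %in% c("SER", "THR", "ASN", "GLN", "TYR", "CYS", "GLY", "GLUH", "ASPH") ~ "polar",
    up %in% c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP") ~ "hydrophobic",
    TRUE ~ "other"
  )
}

#' Select atoms from a topology
#'
#' Deterministic, order-preserving atom selection. All supplied criteria are
#' combined with AND; each criterion accepts a vector of admissible values
#' (OR within a criterion). Unions of selections are just `union()` of the
#' returned index vectors, and arbitrary predicates can always be expressed
#' by filtering the topology tibble directly.
#'
#' @param top A [topology()].
#' @param name,resname,chain,class Character vectors of admissible values,
#'   or `NULL` to leave unconstrained.
#' @param resid Integer vector of admissible residue indices (ranges via
#'   `a:b`), or `NULL`.
#' @param strict If `TRUE`, a criterion value matching no atom raises an
#'   error instead of the default warning.
#' @return An integer vector of atom indices (1-based, in topology order).
#' @examples
#' top <- topology(data.frame(
#'   name = c("P", "OW"), resname = c("PGL", "SOL"), resid = 1:2
#' ))
#' select_atoms(top, name = "P")
#' @export
select_atoms <- function(top, name = NULL, resname = NULL, resid = NULL,
                         chain = NULL, class = NULL, strict = FALSE) {
  stopifnot(inherits(top, "bilayr_topology"))
  keep <- rep(TRUE, nrow(top))
  check <- function(keep, values, column, label) {
    if (is.null(values)) return(keep)
    unknown <- setdiff(values, unique(column))
    if (length(unknown)) {
      msg <- paste0("selection ", label, " value(s) not in topology: ",
                    paste(unknown, collapse = ", "))
      if (strict) abort(msg) else warn(msg)
    }
    keep & column %in% values
  }
  keep <- check(keep, name, top$name, "name")
  keep <- check(keep, resname, top$resname, "resname")
  keep <- check(keep, resid, top$resid, "resid")
  keep <- check(keep, chain, top$chain, "chain")
  keep <- check(keep, class, top$class, "class")
  which(keep)
}
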