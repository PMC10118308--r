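# PDB (biounit) parsing into the package's structure model.
#
# Only ATOM/HETATM/TER/MODEL/ENDMDL records are interpreted; the first model
# is used. Waters are dropped, hetero groups are grouped into ligands by
# (chain, residue name, residue number), and common covalently-numbered
# modified residues (e.g. MSE) stay part of the protein chain.

#' Parse a PDB-format structure into a StructureModel
#'
#' @param pdb character: either a path to a PDB file or PDB-format text
#'   (single string with newlines, or a character vector of lines).
#' @param id structure identifier; defaults to the file name or "structure".
#' @return object of class `StructureModel`: a list with
#'   \describe{
#'     \item{id}{structure id}
#'     \item{atoms}{data.frame of atoms with serial, name, element, chain,
#'       resnum, icode, resname, aa, x, y, z, is_hetero, ligand_id (NA for
#'       protein atoms), vdw, uid (chain/resnum/icode residue key)}
#'     \item{chains}{ordered protein chain ids}
#'     \item{ligands}{data.frame with ligand_id, resname, chain, resnum,
#'       n_atoms, is_metal, is_relevant}
#'   }
#' @export
parse_structure <- function(pdb, id = NULL) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
    if (is.null(id)) id <- sub("\\.pdb$", "", basename(pdb))
  } else {
    lines <- if (length(pdb) == 1L) strsplit(pdb, "\n", fixed = TRUE)[[1L]] else pdb
    if (is.null(id)) id <- "structure"
  }
  # first model only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0L) lines <- lines[seq_len(endmdl[1L] - 1L)]
  rec <- substr(lines, 1L, 6L)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(keep) == 0L) stop("no ATOM/HETATM records found")
  ln <- lines[keep]
  lineno <- keep

  f <- function(a, b) trimws(substr(ln, a, b))
  serial <- suppressWarnings(as.integer(f(7, 11)))
  name <- f(13, 16)
  resname <- f(18, 20)
  chain <- trimws(substr(ln, 22, 22))
  resnum <- suppressWarnings(as.integer(f(23, 26)))
  icode <- trimws(substr(ln, 27, 27))
  x <- suppressWarnings(as.numeric(f(31, 38)))
  y <- suppressWarnings(as.numeric(f(39, 46)))
  z <- suppressWarnings(as.numeric(f(47, 54)))
  element <- f(77, 78)
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resnum))
  if (length(bad) > 0L) {
    stop("malformed ATOM/HETATM record at line ", lineno[bad[1L]])
  }
  # element fallback from the atom-name column when columns 77-78 are blank
  noel <- element == ""
  if (any(noel)) {
    guess <- gsub("[^A-Za-z].*$", "", sub("^[0-9]*", "", name[noel]))
    element[noel] <- substr(guess, 1L, 1L)
  }
  is_het <- rec[keep] == "HETATM"
  is_water <- resname %in% .water_names
  is_modres <- is_het & resname %in% .modified_residues & chain != ""
  is_protein <- !is_het | is_modres

  atoms <- data.frame(
    serial = serial, name = name, element = toupper(element),
    chain = chain, resnum = resnum, icode = icode, resname = resname,
    x = x, y = y, z = z,
    is_hetero = is_het & !is_modres,
    stringsAsFactors = FALSE
  )
  atoms <- atoms[!is_water, , drop = FALSE]
  is_protein <- is_protein[!is_water]
  atoms$vdw <- vdw_radius(atoms$element)
  atoms$uid <- paste(atoms$chain, atoms$resnum, atoms$icode, sep = "/")
  atoms$ligand_id <- NA_character_
  het <- which(!is_protein)
  if (length(het) > 0L) {
    atoms$ligand_id[het] <- paste(atoms$resname[het], atoms$chain[het],
                                  atoms$resnum[het], sep = "_")
  }
  atoms$aa <- unname(.aa3to1[atoms$resname])
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z))) {
    stop("non-finite coordinates")
  }

  chains <- unique(atoms$chain[is.na(atoms$ligand_id)])
  if (length(chains) == 0L) stop("no protein chains in structure")

  ligands <- if (length(het) > 0L) {
    la <- atoms[het, , drop = FALSE]
    ids <- unique(la$ligand_id)
    data.frame(
      ligand_id = ids,
      resname = vapply(ids, function(i) la$resname[la$ligand_id == i][1L], ""),
      chain = vapply(ids, function(i) la$chain[la$ligand_id == i][1L], ""),
      resnum = vapply(ids, function(i) la$resnum[la$ligand_id == i][1L], 0L),
      n_atoms = vapply(ids, function(i) sum(la$ligand_id == i), 0L),
      is_metal = vapply(ids, function(i) {
        all(la$element[la$ligand_id == i] %in% .metal_elements)
      }, FALSE),
      is_relevant = TRUE,
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(ligand_id = character(), resname = character(),
               chain = character(), resnum = integer(), n_atoms = integer(),
               is_metal = logical(), is_relevant = logical(),
               stringsAsFactors = FALSE)
  }

  structure(list(id = id, atoms = atoms, chains = chains, ligands = ligands),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel", x$id, "--", nrow(x$atoms), "atoms,",
      length(x$chains), "protein chain(s),", nrow(x$ligands), "ligand(s)\n")
  invisible(x)
}

# protein (non-ligand) atoms of a StructureModel
.protein_atoms <- function(s) s$atoms[is.na(s$atoms$ligand_id), , drop = FALSE]

# data.frame of protein residues (one row per residue)
.protein_residues <- function(s) {
  pa <- .protein_atoms(s)
  idx <- !duplicated(pa$uid)
  data.frame(uid = pa$uid[idx], chain = pa$chain[idx],
             resnum = pa$resnum[idx], icode = pa$icode[idx],
             aa = pa$aa[idx], resname = pa$resname[idx],
             stringsAsFactors = FALSE)
}

#' Serialize a StructureModel back to PDB text
#'
#' Used by the synthetic-data generator; writes ATOM/HETATM records with
#' element symbols, suitable for round-tripping through
#' [parse_structure()].
#'
#' @param s a `StructureModel`.
#' @return character vector of PDB lines.
#' @export
write_pdb <- function(s) {
  a <- s$atoms
  rec <- ifelse(is.na(a$ligand_id), "ATOM  ", "HETATM")
  name4 <- ifelse(nchar(a$name) >= 4L, substr(a$name, 1, 4),
                  sprintf(" %-3s", a$name))
  sprintf("%s%5d %s %-3s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, a$serial, name4, a$resname, a$chain, a$resnum,
          ifelse(a$icode == "", " ", a$icode),
          a$x, a$y, a$z, 1, 0, a$element)
}
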