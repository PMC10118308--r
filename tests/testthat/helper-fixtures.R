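# Shared fixtures: hand-built PDB snippets and memoised synthetic dimers
# (annotation and normal-mode analysis are the slow steps, so each default
# dimer is built once per test run).

pdb_atom_line <- function(rec = "ATOM", serial, name, res3, chain, resnum,
                          x, y, z, element = "C") {
  sprintf("%-6s%5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          rec, serial, name, res3, chain, resnum, x, y, z, element)
}

# two chains x two residues, one atom each, plus optional extras
tiny_dimer_pdb <- function(extra = character()) {
  c(
    pdb_atom_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line("ATOM", 2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_atom_line("ATOM", 3, "CA", "LEU", "B", 1, 0, 3.5, 0),
    pdb_atom_line("ATOM", 4, "CA", "VAL", "B", 2, 3.8, 3.5, 0),
    extra,
    "END"
  )
}

.fixture_cache <- new.env(parent = emptyenv())

cached_dimer <- function(mode = "SBS", seed = 1L, ...) {
  key <- paste(mode, seed, ...)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_dimer(
      dimer_spec(ligand_mode = mode, seed = seed, ...))
  }
  .fixture_cache[[key]]
}

cached_annotation <- function(mode = "SBS", seed = 1L) {
  key <- paste("ann", mode, seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- annotate_structure(cached_dimer(mode, seed)$structure)
  }
  .fixture_cache[[key]]
}

cached_dccm <- function(mode = "SBS", seed = 1L) {
  key <- paste("dccm", mode, seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- compute_dccm(build_enm(cached_dimer(mode, seed)$structure))
  }
  .fixture_cache[[key]]
}

# null-effect signal specification
null_signal <- function(seed) {
  signal_spec(cross_interface = 0, lbr_interface = 0, lbr_lbr = 0,
              alignment = 0, conservation_shift = 0, seed = seed)
}

# a coupling matrix built directly from a score matrix
cm_from_matrix <- function(m, neff = NA_real_) {
  structure(list(scores = m, L = nrow(m), neff = neff, map = NULL),
            class = "CouplingMatrix")
}
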