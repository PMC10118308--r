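# Structure parsing, contacts, SASA, interface / binding-site / surface
# annotation.

test_that("parse_structure handles chains, waters, metals and bad records", {
  s <- parse_structure(tiny_dimer_pdb())
  expect_s3_class(s, "StructureModel")
  expect_equal(s$chains, c("A", "B"))
  expect_equal(nrow(s$atoms), 4L)

  with_water <- tiny_dimer_pdb(c(
    pdb_atom_line("HETATM", 5, "O", "HOH", "A", 100, 50, 50, 50, "O"),
    pdb_atom_line("HETATM", 6, "ZN", "ZN", "A", 101, 60, 60, 60, "ZN")
  ))
  s2 <- parse_structure(with_water)
  expect_false(any(s2$atoms$resname == "HOH"))
  expect_equal(nrow(s2$ligands), 1L)
  expect_true(s2$ligands$is_metal[1L])

  bad <- tiny_dimer_pdb()
  bad[2] <- "ATOM      2  CA  GLY A   2        garbage"
  expect_error(parse_structure(bad), "line 2")
})

test_that("compute_contacts applies the probe-augmented vdW criterion", {
  two_c <- function(d) c(
    pdb_atom_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line("ATOM", 2, "CA", "ALA", "B", 1, d, 0, 0),
    "END")
  # C radius 1.7: threshold 3.9 at probe 0.25
  expect_equal(nrow(compute_contacts(parse_structure(two_c(3.8)), 0.25)), 1L)
  expect_equal(nrow(compute_contacts(parse_structure(two_c(4.0)), 0.25)), 0L)
  # probe 0 -> pure vdW overlap criterion (threshold 3.4)
  expect_equal(nrow(compute_contacts(parse_structure(two_c(3.39)), 0)), 1L)
  expect_equal(nrow(compute_contacts(parse_structure(two_c(3.41)), 0)), 0L)
})

test_that("contact relation is monotone non-decreasing in probe radius", {
  s <- cached_dimer("MBS")$structure
  n_at <- vapply(c(0.1, 0.25, 0.4, 0.5), function(p) {
    nrow(compute_contacts(s, p, include_ligands = FALSE))
  }, 0L)
  expect_true(all(diff(n_at) >= 0))
})

test_that("Shrake-Rupley SASA matches analytic values", {
  iso <- parse_structure(c(
    pdb_atom_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line("ATOM", 2, "CA", "ALA", "A", 2, 100, 0, 0), "END"))
  r <- 1.7; p <- 1.4
  sasa <- compute_sasa(iso, p)
  expect_equal(unname(sasa$atom[1]), 4 * pi * (r + p)^2, tolerance = 1e-3)
  # two far-apart atoms: additive
  expect_equal(sum(sasa$atom), 2 * 4 * pi * (r + p)^2, tolerance = 1e-3)
  # doubling point density moves per-atom SASA by less than the tolerance
  s2 <- compute_sasa(iso, p, n_points = 1920L)
  expect_lt(max(abs(s2$atom - sasa$atom)), 0.5)
  expect_error(compute_sasa(iso, p, n_points = 0L), "positive")
})

test_that("an atom enclosed by a dense shell has SASA near zero", {
  pts <- 30L
  i <- seq_len(pts) - 0.5
  phi <- acos(1 - 2 * i / pts); th <- pi * (1 + sqrt(5)) * i
  shell <- cbind(3 * sin(phi) * cos(th), 3 * sin(phi) * sin(th), 3 * cos(phi))
  lines <- c(pdb_atom_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0),
             vapply(seq_len(pts), function(k) {
               pdb_atom_line("ATOM", k + 1L, "CA", "ALA", "B", k,
                             shell[k, 1], shell[k, 2], shell[k, 3])
             }, ""), "END")
  sasa <- compute_sasa(parse_structure(lines), 1.4)
  expect_lt(unname(sasa$atom[1]), 1e-6)
})

test_that("identify_interface recovers the planted interface exactly", {
  for (mode in c("MBS", "SBS")) {
    d <- cached_dimer(mode)
    for (probe in c(0.1, 0.3, 0.5)) {
      topo <- identify_interface(d$structure,
                                 compute_contacts(d$structure, probe))
      got <- sort(unique(as.integer(sub("^[AB]/(\\d+)/$", "\\1",
                                        unlist(topo$interface_residues)))))
      expect_equal(got, d$truth$interface_pos)
      expect_equal(topo$interface_size, d$truth$interface_size)
    }
  }
})

test_that("ligand-only contacts are not interface; monomers are an error", {
  # residue C/1 touches only the ligand (far from chain A/B contact zone)
  lines <- tiny_dimer_pdb(c(
    pdb_atom_line("ATOM", 5, "CA", "PHE", "A", 3, 50, 0, 0),
    pdb_atom_line("HETATM", 6, "C1", "LIG", "A", 900, 50, 3.0, 0)
  ))
  s <- parse_structure(lines)
  topo <- identify_interface(s, compute_contacts(s))
  expect_false("A/3/" %in% unlist(topo$interface_residues))

  mono <- parse_structure(c(
    pdb_atom_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0), "END"))
  expect_error(identify_interface(mono), "2 protein chains")
})

test_that("ligand-binding residues come from the SASA change criterion", {
  d <- cached_dimer("SBS")
  ann <- cached_annotation("SBS")
  st <- ann$sites[[1L]]
  expect_setequal(st$lbr_set, d$truth$lbr[[1L]]$uids)

  # far ligand occludes nothing
  far <- tiny_dimer_pdb(
    pdb_atom_line("HETATM", 5, "C1", "LIG", "A", 900, 50, 50, 50))
  sf <- parse_structure(far)
  expect_length(identify_ligand_binding_residues(sf, sf$ligands$ligand_id[1]), 0L)

  # infinite tolerance -> empty set
  lig_id <- d$structure$ligands$ligand_id[1]
  expect_length(
    identify_ligand_binding_residues(d$structure, lig_id, tol = Inf), 0L)

  # metal ligands are refused
  zn <- tiny_dimer_pdb(
    pdb_atom_line("HETATM", 5, "ZN", "ZN", "A", 900, 0, 1.8, 0, "ZN"))
  sz <- parse_structure(zn)
  expect_error(identify_ligand_binding_residues(sz, sz$ligands$ligand_id[1]),
               "metal")
})

test_that("classify_binding_site distinguishes MBS from SBS", {
  expect_equal(classify_binding_site(c("A/1/", "B/4/"))$site_type, "MBS")
  expect_equal(classify_binding_site(c("A/1/", "A/2/"))$site_type, "SBS")
  expect_error(classify_binding_site(character()), "empty")
  ann <- cached_annotation("MBS")
  expect_equal(ann$topology$complex_class, "MBS")
  expect_equal(ann$topology$n_mbs_sites, 2L)
  expect_equal(cached_annotation("SBS")$topology$complex_class, "SBS")
})

test_that("binding-site class and ligand distance are rigid-motion invariant", {
  d <- cached_dimer("MBS")
  s <- d$structure
  ann <- cached_annotation("MBS")
  # rotate + translate every atom
  th <- 0.7
  Rm <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% Rm + 5
  s2 <- s
  s2$atoms$x <- xyz[, 1]; s2$atoms$y <- xyz[, 2]; s2$atoms$z <- xyz[, 3]
  ann2 <- annotate_structure(s2)
  expect_equal(ann2$topology$complex_class, "MBS")
  expect_setequal(ann2$sites[[1]]$lbr_set, ann$sites[[1]]$lbr_set)
  expect_equal(ann2$sites[[1]]$distance_to_interface,
               ann$sites[[1]]$distance_to_interface, tolerance = 1e-6)
})

test_that("surface residues need RSA > 0.2 and no other annotation", {
  d <- cached_dimer("SBS")
  ann <- cached_annotation("SBS")
  a <- ann$annotations
  expect_true(all(a$rsa[a$is_surface] > 0.2))
  expect_false(any(a$is_surface & a$is_interface))
  expect_false(any(a$is_surface & a$is_lbr))
  # computed surface avoids interface positions; most designed surface
  # positions clear the RSA threshold on at least one chain (interior slab
  # residues may be buried below RSA 0.2)
  surf_pos <- unique(a$resnum[a$is_surface])
  expect_false(any(surf_pos %in% d$truth$interface_pos))
  expect_gt(length(intersect(surf_pos, d$truth$surface_pos)), 30L)

  # unknown amino acid in the reference table is an error
  bad <- tiny_dimer_pdb()
  bad[1] <- pdb_atom_line("ATOM", 1, "CA", "UNK", "A", 1, 0, 0, 0)
  sb <- parse_structure(bad)
  sasa <- compute_sasa(sb, 1.4)
  expect_error(identify_surface(sb, sasa$residue), "reference table")
})

test_that("ligand_interface_distance averages nearest-LBR distances", {
  # two interface residues with nearest-LBR distances 3 and 5
  lines <- c(
    pdb_atom_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line("ATOM", 2, "CA", "ALA", "A", 2, 10, 0, 0),
    pdb_atom_line("ATOM", 3, "CA", "GLY", "B", 1, 0, 3, 0),
    pdb_atom_line("ATOM", 4, "CA", "GLY", "B", 2, 10, 5, 0),
    "END")
  s <- parse_structure(lines)
  expect_equal(
    ligand_interface_distance(s, c("A/1/", "A/2/"), c("B/1/", "B/2/")), 4)
  # single interface residue: its own nearest distance
  expect_equal(ligand_interface_distance(s, "A/1/", c("B/1/", "B/2/")), 3)
  # all-pairs policy averages the full matrix
  d12 <- sqrt(10^2 + 5^2); d21 <- sqrt(10^2 + 3^2)
  expect_equal(
    ligand_interface_distance(s, c("A/1/", "A/2/"), c("B/1/", "B/2/"),
                              policy = "all_pairs"),
    mean(c(3, d12, d21, 5)))
  expect_error(ligand_interface_distance(s, character(), "B/1/"), "nonempty")
})

test_that("hydrophobic_fraction uses the 7-residue set", {
  expect_equal(hydrophobic_fraction(c("L", "V", "K", "E")), 0.5)
  expect_equal(hydrophobic_fraction(rep("G", 5)), 0)
  expect_equal(hydrophobic_fraction(rep("C", 3)), 1)
  expect_error(hydrophobic_fraction(character()), "empty")
})
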