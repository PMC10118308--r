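# Residue-level annotation of a dimer: probe-augmented van der Waals
# contacts, interface identification, Shrake-Rupley solvent accessibility,
# SASA-change ligand-binding residues, MBS/SBS binding-site classification,
# solvent-accessible surface, and the ligand-interface distance.

#' Residue pairs in contact
#'
#' Two atoms are in contact when their centres lie within
#' `r_i + r_j + 2 * probe_radius`; two residues are in contact when any of
#' their atom pairs are. A probe of 0.25 Angstrom rolled over the van der
#' Waals surface is the default interaction criterion.
#'
#' @param s a `StructureModel`.
#' @param probe_radius probe radius in Angstrom (default 0.25).
#' @param include_ligands also report residue-ligand contacts.
#' @return data.frame with columns uid_i, uid_j, chain_i, chain_j, type
#'   ("protein" for residue-residue, "ligand" for residue-ligand contacts;
#'   for the latter uid_j holds the ligand id). The residue-residue relation
#'   is reported once per unordered pair and is symmetric by construction.
#' @export
compute_contacts <- function(s, probe_radius = 0.25, include_ligands = TRUE) {
  a <- s$atoms
  if (nrow(a) == 0L) stop("empty structure")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(a$vdw, a$vdw, "+") + 2 * probe_radius
  hit <- d <= thr
  diag(hit) <- FALSE
  # atom groups: residue uid for protein atoms, ligand id for ligand atoms
  grp_i <- ifelse(is.na(a$ligand_id), a$uid, a$ligand_id)
  is_lig <- !is.na(a$ligand_id)
  idx <- which(hit & upper.tri(hit), arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(uid_i = character(), uid_j = character(),
                      chain_i = character(), chain_j = character(),
                      type = character(), stringsAsFactors = FALSE))
  }
  gi <- grp_i[idx[, 1L]]; gj <- grp_i[idx[, 2L]]
  li <- is_lig[idx[, 1L]]; lj <- is_lig[idx[, 2L]]
  ci <- a$chain[idx[, 1L]]; cj <- a$chain[idx[, 2L]]
  same <- gi == gj
  gi2 <- ifelse(li & !lj, gj, gi)   # put residue first
  gj2 <- ifelse(li & !lj, gi, gj)
  ci2 <- ifelse(li & !lj, cj, ci)
  cj2 <- ifelse(li & !lj, ci, cj)
  type <- ifelse(li | lj, "ligand", "protein")
  keep <- !same & !(li & lj)
  out <- data.frame(uid_i = gi2[keep], uid_j = gj2[keep],
                    chain_i = ci2[keep], chain_j = cj2[keep],
                    type = type[keep], stringsAsFactors = FALSE)
  # canonical order within protein pairs, then dedupe
  swap <- out$type == "protein" & out$uid_i > out$uid_j
  tmp <- out$uid_i[swap]; out$uid_i[swap] <- out$uid_j[swap]; out$uid_j[swap] <- tmp
  tmp <- out$chain_i[swap]; out$chain_i[swap] <- out$chain_j[swap]; out$chain_j[swap] <- tmp
  out <- out[!duplicated(paste(out$uid_i, out$uid_j)), , drop = FALSE]
  if (!include_ligands) out <- out[out$type == "protein", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Identify interface residues
#'
#' Interface residues are residues from different protein chains that form
#' direct (probe-augmented van der Waals) interactions. Residues contacting
#' only a ligand are not interface residues. Interface size is the sum of
#' interface residues over both chains.
#'
#' @param s a `StructureModel` with at least two protein chains.
#' @param contacts output of [compute_contacts()].
#' @return `ComplexTopology` list: interface_residues (uid vector per
#'   chain), interface_size, n_chains.
#' @export
identify_interface <- function(s, contacts = compute_contacts(s)) {
  if (length(s$chains) < 2L) stop("dimer analysis requires >= 2 protein chains")
  pc <- contacts[contacts$type == "protein" &
                   contacts$chain_i != contacts$chain_j, , drop = FALSE]
  uids <- unique(c(pc$uid_i, pc$uid_j))
  if (length(uids) == 0L) {
    warning("no inter-chain contacts: empty interface")
  }
  res <- .protein_residues(s)
  by_chain <- lapply(s$chains, function(ch) {
    intersect(res$uid[res$chain == ch], uids)
  })
  names(by_chain) <- s$chains
  structure(list(interface_residues = by_chain,
                 interface_size = length(uids),
                 n_chains = length(s$chains)),
            class = "ComplexTopology")
}

# Deterministic near-uniform point lattice on the unit sphere
# (golden-angle / Fibonacci spiral).
.sphere_points <- function(n) {
  if (n <= 0L) stop("sphere point count must be positive")
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a deterministic golden-angle point lattice. Per-residue
#' SASA is the sum over the residue's atoms. Ligand atoms occlude protein
#' atoms when `include_ligands` is TRUE (and vice versa), enabling the
#' with/without-ligand comparison that defines ligand-binding residues.
#'
#' @param s a `StructureModel`.
#' @param probe_radius probe radius in Angstrom.
#' @param include_ligands include ligand atoms as both targets and occluders.
#' @param n_points quadrature points per atom (default 960).
#' @param exclude_ligand_id optional ligand id(s) whose atoms are removed
#'   before the calculation.
#' @return list with `atom` (numeric vector, SASA per retained atom, named by
#'   atom serial) and `residue` (named numeric vector of per-protein-residue
#'   SASA keyed by residue uid).
#' @export
compute_sasa <- function(s, probe_radius = 1.4, include_ligands = TRUE,
                         n_points = 960L, exclude_ligand_id = NULL) {
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  a <- s$atoms
  if (!is.null(exclude_ligand_id)) {
    a <- a[is.na(a$ligand_id) | !(a$ligand_id %in% exclude_ligand_id), ,
           drop = FALSE]
  }
  if (!include_ligands) a <- a[is.na(a$ligand_id), , drop = FALSE]
  n <- nrow(a)
  if (n == 0L) stop("empty structure")
  pts <- .sphere_points(n_points)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- a$vdw + probe_radius
  # neighbour lists from the augmented-radius criterion
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(rad, rad, "+")
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < thr[i, ] & seq_len(n) != i)
    full <- 4 * pi * rad[i]^2
    if (length(nb) == 0L) {
      sasa[i] <- full
      next
    }
    p <- pts * rad[i]
    p <- sweep(p, 2L, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1L] - xyz[j, 1L])^2 + (p[, 2L] - xyz[j, 2L])^2 +
        (p[, 3L] - xyz[j, 3L])^2
      acc <- acc & dj2 > rad[j]^2
      if (!any(acc)) break
    }
    sasa[i] <- full * sum(acc) / n_points
  }
  names(sasa) <- a$serial
  prot <- is.na(a$ligand_id)
  res <- tapply(sasa[prot], a$uid[prot], sum)
  list(atom = sasa, residue = res[unique(a$uid[prot])])
}

#' Ligand-binding residues by solvent-accessibility change
#'
#' A residue binds a ligand when its solvent-accessible area changes by more
#' than `tol` upon removal of the ligand, evaluated with a small probe
#' (default 0.21 Angstrom) that closely tracks direct ligand contacts.
#'
#' @param s a `StructureModel`.
#' @param ligand_id id of a ligand present in `s`.
#' @param probe_radius probe radius in Angstrom (default 0.21).
#' @param tol minimal SASA change in Angstrom^2 counted as binding
#'   (default 1e-3, absorbs quadrature noise).
#' @param n_points quadrature points per atom.
#' @return character vector of residue uids (the LBR set).
#' @export
identify_ligand_binding_residues <- function(s, ligand_id, probe_radius = 0.21,
                                             tol = 1e-3, n_points = 960L) {
  li <- match(ligand_id, s$ligands$ligand_id)
  if (is.na(li)) stop("ligand ", ligand_id, " not present in structure")
  if (s$ligands$is_metal[li]) {
    stop("metal ligands are excluded from binding-site analysis")
  }
  with_l <- compute_sasa(s, probe_radius, include_ligands = TRUE,
                         n_points = n_points)
  without_l <- compute_sasa(s, probe_radius, include_ligands = TRUE,
                            n_points = n_points, exclude_ligand_id = ligand_id)
  uids <- names(with_l$residue)
  delta <- abs(without_l$residue[uids] - with_l$residue[uids])
  uids[!is.na(delta) & delta > tol]
}

#' Classify a ligand-binding site as multichain (MBS) or single-chain (SBS)
#'
#' A binding site is multichain when its ligand-binding residues span at
#' least two protein chains.
#'
#' @param lbr_set character vector of residue uids binding the ligand.
#' @param chain_map named character vector mapping residue uid to chain id
#'   (defaults to the chain encoded in the uid).
#' @param ligand_id optional ligand id carried through to the profile.
#' @return `BindingSiteProfile` list: ligand_id, lbr_set, chains_touched,
#'   site_type ("MBS" or "SBS").
#' @export
classify_binding_site <- function(lbr_set, chain_map = NULL, ligand_id = NA) {
  if (length(lbr_set) == 0L) stop("empty ligand-binding residue set")
  chains <- if (is.null(chain_map)) {
    vapply(strsplit(lbr_set, "/", fixed = TRUE), `[[`, "", 1L)
  } else {
    unname(chain_map[lbr_set])
  }
  chains <- sort(unique(chains))
  structure(list(ligand_id = ligand_id, lbr_set = lbr_set,
                 chains_touched = chains,
                 site_type = if (length(chains) >= 2L) "MBS" else "SBS"),
            class = "BindingSiteProfile")
}

#' Solvent-accessible surface residues
#'
#' Surface residues have relative solvent accessibility (RSA) above 0.2 in
#' the full complex and are neither interface nor ligand-binding residues.
#' RSA is the residue SASA divided by its reference area in an extended
#' Gly-X-Gly tripeptide.
#'
#' @param s a `StructureModel`.
#' @param residue_sasa named per-residue SASA (Angstrom^2) computed in the
#'   full complex, e.g. `compute_sasa(s, 1.4)$residue`.
#' @param interface_uids residue uids annotated as interface.
#' @param lbr_uids residue uids annotated as ligand-binding (any ligand).
#' @param rsa_reference per-amino-acid reference SASA table.
#' @param rsa_cutoff RSA threshold (default 0.2).
#' @return list with `surface` (uid vector) and `rsa` (named numeric vector
#'   over all scored residues).
#' @export
identify_surface <- function(s, residue_sasa, interface_uids = character(),
                             lbr_uids = character(),
                             rsa_reference = gxg_reference_sasa,
                             rsa_cutoff = 0.2) {
  res <- .protein_residues(s)
  miss <- setdiff(unique(res$aa), names(rsa_reference))
  if (length(miss) > 0L || anyNA(res$aa)) {
    stop("amino acid(s) missing from the RSA reference table: ",
         paste(stats::na.omit(c(miss, if (anyNA(res$aa)) "<unknown>")),
               collapse = ", "))
  }
  rsa <- unname(residue_sasa[res$uid]) / unname(rsa_reference[res$aa])
  names(rsa) <- res$uid
  surf <- res$uid[!is.na(rsa) & rsa > rsa_cutoff &
                    !(res$uid %in% interface_uids) &
                    !(res$uid %in% lbr_uids)]
  list(surface = surf, rsa = rsa)
}

#' Mean distance of a ligand-binding site from the interface
#'
#' For each interface residue, the distance to the nearest ligand-binding
#' residue (residue-residue distance being the minimum heavy-atom distance)
#' is taken; the site-interface distance is the mean over interface
#' residues. `policy = "all_pairs"` instead averages over all interface x
#' LBR residue distances.
#'
#' @param s a `StructureModel`.
#' @param interface_uids interface residue uids (nonempty).
#' @param lbr_uids ligand-binding residue uids (nonempty).
#' @param policy "nearest" (default) or "all_pairs".
#' @return distance in Angstrom.
#' @export
ligand_interface_distance <- function(s, interface_uids, lbr_uids,
                                      policy = c("nearest", "all_pairs")) {
  policy <- match.arg(policy)
  if (length(interface_uids) == 0L || length(lbr_uids) == 0L) {
    stop("interface and ligand-binding residue sets must be nonempty")
  }
  pa <- .protein_atoms(s)
  pa <- pa[pa$element != "H", , drop = FALSE]
  ai <- pa[pa$uid %in% interface_uids, , drop = FALSE]
  al <- pa[pa$uid %in% lbr_uids, , drop = FALSE]
  if (nrow(ai) == 0L || nrow(al) == 0L) stop("residue uids not found in structure")
  dx <- outer(ai$x, al$x, "-"); dy <- outer(ai$y, al$y, "-")
  dz <- outer(ai$z, al$z, "-")
  d <- sqrt(dx^2 + dy^2 + dz^2)
  # residue-level min-atom distances
  dres <- matrix(NA_real_, length(unique(ai$uid)), length(unique(al$uid)),
                 dimnames = list(unique(ai$uid), unique(al$uid)))
  for (ui in rownames(dres)) {
    ri <- ai$uid == ui
    for (uj in colnames(dres)) {
      dres[ui, uj] <- min(d[ri, al$uid == uj])
    }
  }
  if (policy == "nearest") mean(apply(dres, 1L, min)) else mean(dres)
}

#' Annotate every residue of a dimer
#'
#' Convenience wrapper running contact detection, interface identification,
#' SASA, ligand-binding residue detection for every relevant non-metal
#' ligand, binding-site typing, and surface identification.
#'
#' @param s a `StructureModel` (two or more protein chains).
#' @param probe_contact contact probe radius (default 0.25 Angstrom).
#' @param probe_lbr SASA-change probe radius for ligand binding
#'   (default 0.21 Angstrom).
#' @param probe_rsa water-probe radius for RSA (default 1.4 Angstrom).
#' @param n_points SASA quadrature points.
#' @param distance_policy see [ligand_interface_distance()].
#' @return list of class `ResidueAnnotation` with elements `annotations`
#'   (per-residue data.frame), `topology` (`ComplexTopology` plus
#'   complex_class and n_mbs_sites), `sites` (list of `BindingSiteProfile`
#'   with distance_to_interface), `contacts`.
#' @export
annotate_structure <- function(s, probe_contact = 0.25, probe_lbr = 0.21,
                               probe_rsa = 1.4, n_points = 960L,
                               distance_policy = "nearest") {
  contacts <- compute_contacts(s, probe_contact)
  topo <- identify_interface(s, contacts)
  iface <- unlist(topo$interface_residues, use.names = FALSE)
  sasa <- compute_sasa(s, probe_rsa, include_ligands = TRUE,
                       n_points = n_points)
  lig <- s$ligands
  lig <- lig[!lig$is_metal & lig$is_relevant, , drop = FALSE]
  sites <- list()
  lbr_all <- character()
  for (lid in lig$ligand_id) {
    lbr <- identify_ligand_binding_residues(s, lid, probe_lbr,
                                            n_points = n_points)
    if (length(lbr) == 0L) next
    site <- classify_binding_site(lbr, ligand_id = lid)
    site$distance_to_interface <- if (length(iface) > 0L) {
      ligand_interface_distance(s, iface, lbr, distance_policy)
    } else NA_real_
    sites[[lid]] <- site
    lbr_all <- union(lbr_all, lbr)
  }
  surf <- identify_surface(s, sasa$residue, iface, lbr_all)
  res <- .protein_residues(s)
  ann <- data.frame(
    structure_id = s$id, uid = res$uid, chain = res$chain,
    resnum = res$resnum, icode = res$icode, aa = res$aa,
    is_interface = res$uid %in% iface,
    is_surface = res$uid %in% surf$surface,
    is_lbr = res$uid %in% lbr_all,
    rsa = unname(surf$rsa[res$uid]),
    sasa = unname(sasa$residue[res$uid]),
    stringsAsFactors = FALSE
  )
  site_types <- vapply(sites, function(x) x$site_type, "")
  topo$n_mbs_sites <- sum(site_types == "MBS")
  topo$complex_class <- if (topo$n_mbs_sites >= 1L) "MBS" else "SBS"
  structure(list(annotations = ann, topology = topo, sites = sites,
                 contacts = contacts),
            class = "ResidueAnnotation")
}

#' Write a per-residue annotation table as TSV
#'
#' @param ann a `ResidueAnnotation` (from [annotate_structure()]).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_annotation_tsv <- function(ann, path) {
  utils::write.table(ann$annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
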