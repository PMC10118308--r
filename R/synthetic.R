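# Synthetic inputs with planted, parameterised ground truth.
#
# The toy dimer is a pair of serpentine-folded pseudo-chains (one C-alpha
# and one sidechain pseudo-atom per residue) arranged as compact stacked
# slabs facing each other, laid out on a lattice so that the designed
# interface, ligand-binding and surface sets are recovered exactly by the
# annotation module (contact probes in [0.1, 0.5] Angstrom for the
# interface). Coupling matrices, conservation profiles, variant tables and
# toy metabolic networks plant effects of controlled size on designated
# residue classes.

# lattice constants (Angstrom)
.syn_dx <- 4.2        # column spacing along the chain axis (x)
.syn_dz <- 3.4        # row stacking distance (z)
.syn_rows <- 7L       # rows per chain; rows 2..6 can carry the interface
.syn_chain_gap <- 7.0 # separation of the facing (unbent) slabs in y
.syn_bend <- 1.75     # inward bend of interface residues (both chains)
.syn_cb_dy <- 1.5     # sidechain pseudo-atom offset, pointing away from
                      # the partner chain
.syn_lig_gap <- 2.8   # ligand y-distance from a single-chain site

#' Specification of a synthetic homodimer
#'
#' The chain folds into `7` stacked rows of `n_per_chain / 7` columns;
#' the interface is a block of central columns on rows 2-6 of both chains,
#' so `interface_width` must be a multiple of 5 and the column count even.
#'
#' @param n_per_chain residues per chain (multiple of 7 with an even
#'   column count; default 98).
#' @param interface_width interface residues per chain (multiple of 5;
#'   default 30, i.e. 6 columns x 5 rows).
#' @param ligand_mode "MBS" (ligand(s) bridging both chains) or "SBS"
#'   (single-chain site).
#' @param n_mbs_sites 1 or 2 multichain sites (MBS mode only).
#' @param ligand_offset distance (Angstrom, along the chain axis) of an SBS
#'   ligand from the interface edge (default 8.4, i.e. 2 lattice columns).
#' @param seed RNG seed controlling the amino-acid sequence.
#' @return `DimerSpec` list.
#' @export
dimer_spec <- function(n_per_chain = 98L, interface_width = 30L,
                       ligand_mode = c("MBS", "SBS"), n_mbs_sites = 2L,
                       ligand_offset = 8.4, seed = 1L) {
  ligand_mode <- match.arg(ligand_mode)
  R <- .syn_rows
  if (n_per_chain %% R != 0L) stop("n_per_chain must be a multiple of 7")
  C <- n_per_chain %/% R
  if (C %% 2L != 0L) stop("column count n_per_chain/7 must be even")
  if (interface_width %% (R - 2L) != 0L) {
    stop("interface_width must be a multiple of 5")
  }
  wc <- interface_width %/% (R - 2L)
  if (wc %% 2L != 0L) stop("interface_width/5 must be even")
  if (wc > C - 4L) stop("interface too wide for the chain")
  if (!n_mbs_sites %in% c(1L, 2L)) stop("n_mbs_sites must be 1 or 2")
  if (ligand_mode == "MBS" && n_mbs_sites == 2L && wc < 4L) {
    stop("interface too narrow for two multichain sites")
  }
  structure(list(n = as.integer(n_per_chain), C = C, R = R,
                 w = as.integer(interface_width), wc = wc,
                 ligand_mode = ligand_mode,
                 n_mbs_sites = as.integer(n_mbs_sites),
                 ligand_offset = ligand_offset, seed = as.integer(seed)),
            class = "DimerSpec")
}

# serpentine position bookkeeping: position p <-> (column, row)
.syn_pos_of <- function(col, r, C) {
  k <- ifelse(r %% 2L == 1L, col, C + 1L - col)
  as.integer((r - 1L) * C + k)
}
.syn_col_of <- function(p, C) {
  r <- (p - 1L) %/% C + 1L
  k <- (p - 1L) %% C + 1L
  list(col = as.integer(ifelse(r %% 2L == 1L, k, C + 1L - k)), row = r)
}

#' Generate a synthetic homodimer with planted ground truth
#'
#' @param spec a `DimerSpec`.
#' @return list with `pdb` (PDB text lines), `structure` (parsed
#'   `StructureModel`), and `truth` — the ground-truth sidecar: sequence,
#'   interface/surface/ligand-binding positions, the cross-interface and
#'   interface/non-interface contacting pair classes, per-ligand binding
#'   sites, C-alpha coordinates, site type and complex class.
#' @export
generate_dimer <- function(spec) {
  n <- spec$n; C <- spec$C; R <- spec$R; wc <- spec$wc
  w0 <- (C - wc) %/% 2L + 1L
  wcols <- w0:(w0 + wc - 1L)           # interface columns (symmetric:
                                       # closed under col -> C+1-col)
  irows <- 2:(R - 1L)                  # interface rows
  set.seed(spec$seed)
  seq_aa <- sample(.aa1, n, replace = TRUE)

  # per-position geometry for both chains
  info <- .syn_col_of(1:n, C)
  col <- info$col; row <- info$row
  iface_mask <- col %in% wcols & row %in% irows
  coords <- list()
  for (chain in c("A", "B")) {
    x <- if (chain == "A") col * .syn_dx else (C + 1L - col) * .syn_dx
    y <- if (chain == "A") ifelse(iface_mask, .syn_bend, 0) else
      ifelse(iface_mask, .syn_chain_gap - .syn_bend, .syn_chain_gap)
    z <- (row - 1L) * .syn_dz
    coords[[chain]] <- cbind(x, y, z)
  }

  # ligand site centre columns (each site occupies columns c, c+1 at the
  # z-midpoint of rows 2 and 3)
  if (spec$ligand_mode == "MBS") {
    centres <- if (spec$n_mbs_sites == 2L) {
      c(wcols[1L], wcols[wc - 1L])
    } else {
      wcols[wc %/% 2L]
    }
  } else {
    off_cols <- max(1L, as.integer(round(spec$ligand_offset / .syn_dx)))
    centres <- wcols[wc] + off_cols
    if (centres + 2L > C) {
      stop("infeasible geometry: ligand offset exceeds chain extent")
    }
  }
  lig_z <- (.syn_dz + 2 * .syn_dz) / 2   # between rows 2 and 3

  lig_atoms <- list()
  lbr <- list()
  for (si in seq_along(centres)) {
    cc <- centres[si]
    # single-chain sites are one column wider (6 binding residues) since
    # they lack the second chain's contribution
    site_cols <- if (spec$ligand_mode == "MBS") c(cc, cc + 1L) else
      cc + 0:2
    if (spec$ligand_mode == "MBS") {
      ly <- .syn_chain_gap / 2
      a_pos <- as.vector(outer(site_cols, 2:3,
                               function(co, r) .syn_pos_of(co, r, C)))
      b_pos <- as.vector(outer(C + 1L - site_cols, 2:3,
                               function(co, r) .syn_pos_of(co, r, C)))
      uids <- c(paste0("A/", a_pos, "/"), paste0("B/", b_pos, "/"))
      pos <- sort(unique(c(a_pos, b_pos)))
      chains_touched <- c("A", "B")
    } else {
      ly <- -.syn_lig_gap
      a_pos <- as.vector(outer(site_cols, 2:3,
                               function(co, r) .syn_pos_of(co, r, C)))
      uids <- paste0("A/", sort(a_pos), "/")
      pos <- sort(a_pos)
      chains_touched <- "A"
    }
    lig_id <- sprintf("LIG_A_%d", 900L + si)
    lig_atoms[[si]] <- data.frame(x = site_cols * .syn_dx, y = ly,
                                  z = lig_z, resnum = 900L + si)
    lbr[[lig_id]] <- list(ligand_id = lig_id, positions = pos,
                          chains = chains_touched, uids = uids,
                          site_type = spec$ligand_mode)
  }

  # PDB text
  lines <- character()
  serial <- 0L
  fmt <- function(rec, serial, name, res3, chain, resnum, x, y, z) {
    sprintf("%s%5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            rec, serial, name, res3, chain, resnum, x, y, z)
  }
  for (chain in c("A", "B")) {
    ca <- coords[[chain]]
    cb_sign <- if (chain == "A") -1 else 1
    for (i in 1:n) {
      res3 <- .aa1to3[[seq_aa[i]]]
      serial <- serial + 1L
      lines <- c(lines, fmt("ATOM  ", serial, "CA", res3, chain, i,
                            ca[i, 1L], ca[i, 2L], ca[i, 3L]))
      serial <- serial + 1L
      lines <- c(lines, fmt("ATOM  ", serial, "CB", res3, chain, i,
                            ca[i, 1L], ca[i, 2L] + cb_sign * .syn_cb_dy,
                            ca[i, 3L]))
    }
    lines <- c(lines, "TER")
  }
  for (si in seq_along(lig_atoms)) {
    la <- lig_atoms[[si]]
    for (k in seq_len(nrow(la))) {
      serial <- serial + 1L
      lines <- c(lines, fmt("HETATM", serial, paste0("C", k), "LIG", "A",
                            la$resnum[k], la$x[k], la$y[k], la$z[k]))
    }
  }
  lines <- c(lines, "END")

  # planted pair classes (sequence-position level, deduplicated)
  cross <- NULL
  for (r in irows) {
    for (co in wcols) {
      p <- .syn_pos_of(co, r, C); q <- .syn_pos_of(C + 1L - co, r, C)
      if (p < q) cross <- rbind(cross, c(p, q))
    }
  }
  refp <- NULL
  for (co in wcols) {
    refp <- rbind(refp,
                  c(.syn_pos_of(co, 2L, C), .syn_pos_of(co, 1L, C)),
                  c(.syn_pos_of(co, R - 1L, C), .syn_pos_of(co, R, C)))
  }
  interface_pos <- sort(unique(as.vector(
    outer(wcols, irows, function(co, r) .syn_pos_of(co, r, C)))))
  lbr_pos_all <- sort(unique(unlist(lapply(lbr, `[[`, "positions"))))
  surface_pos <- setdiff(1:n, union(interface_pos, lbr_pos_all))

  truth <- list(
    L = n, seq = seq_aa, interface_pos = interface_pos,
    interface_size = 2L * length(interface_pos),
    surface_pos = as.integer(surface_pos),
    lbr = lbr, lbr_pos_all = as.integer(lbr_pos_all),
    cross_pairs = unname(cross), ref_pairs = unname(refp),
    ca_coords = coords,
    site_type = spec$ligand_mode,
    complex_class = spec$ligand_mode,
    n_mbs_sites = if (spec$ligand_mode == "MBS") length(centres) else 0L,
    spec = spec
  )
  s <- parse_structure(lines, id = sprintf("syn_%s_seed%d", spec$ligand_mode,
                                           spec$seed))
  list(pdb = lines, structure = s, truth = truth)
}

# analytic SD of the lognormal baseline
.lognorm_sd <- function(meanlog, sdlog) {
  sqrt((exp(sdlog^2) - 1) * exp(2 * meanlog + sdlog^2))
}

#' Plant-effect specification for coupling generation
#'
#' Effect sizes are in units of the baseline (reference) SD; the
#' motion-coupling alignment adds a spatial-proximity-modulated boost to
#' ligand-interface pairs (`exp(-d / 10 Angstrom)`, matching the
#' correlation lengthscale of the elastic network), planting the
#' coupling-dynamics association without editing the dynamics.
#'
#' @param cross_interface,lbr_interface,lbr_lbr,alignment effect sizes (SD
#'   units, >= 0).
#' @param conservation_shift planted interface conservation shift (>= 0).
#' @param baseline lognormal baseline parameters (meanlog, sdlog).
#' @param seed RNG seed.
#' @return `SignalSpec` list.
#' @export
signal_spec <- function(cross_interface = 2, lbr_interface = 3, lbr_lbr = 3,
                        alignment = 4, conservation_shift = 1,
                        baseline = list(meanlog = -2, sdlog = 0.5),
                        seed = 1L) {
  eff <- c(cross_interface, lbr_interface, lbr_lbr, alignment,
           conservation_shift)
  if (any(eff < 0)) stop("all planted effects must be >= 0")
  structure(list(cross_interface = cross_interface,
                 lbr_interface = lbr_interface, lbr_lbr = lbr_lbr,
                 alignment = alignment,
                 conservation_shift = conservation_shift,
                 baseline = baseline, seed = as.integer(seed)),
            class = "SignalSpec")
}

#' Generate a coupling matrix with planted pair-class effects
#'
#' Baseline scores are i.i.d. lognormal for all pairs; designated pair
#' classes are shifted upward by their effect size times the analytic
#' baseline SD. The alignment effect decays with the within-protomer 3D
#' distance between the interface residue and the ligand-binding residue
#' (`exp(-d / 10)`), planting the coupling-dynamics association.
#'
#' @param truth sidecar from [generate_dimer()].
#' @param spec a `SignalSpec`.
#' @param neff_ratio Neff / L of the emitted alignment statistics
#'   (default 2).
#' @return list(cm = `CouplingMatrix`, table = long-format data.frame
#'   (i, j, cn), neff, L).
#' @export
generate_couplings <- function(truth, spec = signal_spec(), neff_ratio = 2) {
  L <- truth$L
  set.seed(spec$seed)
  sdb <- .lognorm_sd(spec$baseline$meanlog, spec$baseline$sdlog)
  sc <- matrix(NA_real_, L, L)
  ut <- upper.tri(sc)
  sc[ut] <- stats::rlnorm(sum(ut), spec$baseline$meanlog, spec$baseline$sdlog)
  add <- function(mat, pairs, amount) {
    if (length(amount) == 1L) amount <- rep(amount, nrow(pairs))
    ii <- pmin(pairs[, 1L], pairs[, 2L]); jj <- pmax(pairs[, 1L], pairs[, 2L])
    keep <- ii != jj
    mat[cbind(ii[keep], jj[keep])] <- mat[cbind(ii[keep], jj[keep])] +
      amount[keep]
    mat
  }
  if (spec$cross_interface > 0) {
    sc <- add(sc, truth$cross_pairs, spec$cross_interface * sdb)
  }
  li_pairs <- .cross_pairs(truth$lbr_pos_all, truth$interface_pos)
  if (nrow(li_pairs) > 0L && spec$lbr_interface > 0) {
    sc <- add(sc, li_pairs, spec$lbr_interface * sdb)
  }
  if (nrow(li_pairs) > 0L && spec$alignment > 0) {
    d <- vapply(seq_len(nrow(li_pairs)), function(k) {
      .min_pair_dist(truth$ca_coords, li_pairs[k, 1L], li_pairs[k, 2L])
    }, 0)
    sc <- add(sc, li_pairs, spec$alignment * sdb * exp(-d / 10))
  }
  if (spec$lbr_lbr > 0 && length(truth$lbr_pos_all) >= 2L) {
    ll <- t(utils::combn(truth$lbr_pos_all, 2L))
    sc <- add(sc, ll, spec$lbr_lbr * sdb)
  }
  sc[lower.tri(sc)] <- t(sc)[lower.tri(sc)]
  idx <- which(upper.tri(sc), arr.ind = TRUE)
  tab <- data.frame(i = idx[, 1L], j = idx[, 2L], cn = sc[idx])
  cm <- structure(list(scores = sc, L = L, neff = neff_ratio * L, map = NULL),
                  class = "CouplingMatrix")
  list(cm = cm, table = tab, neff = neff_ratio * L, L = L)
}

# minimum within-protomer C-alpha distance between two sequence positions
# (couplings are sequence-level; both protomers give the same intra-chain
# geometry by symmetry)
.min_pair_dist <- function(ca_coords, p1, p2) {
  d <- Inf
  for (ch in names(ca_coords)) {
    d <- min(d, sqrt(sum((ca_coords[[ch]][p1, ] - ca_coords[[ch]][p2, ])^2)))
  }
  d
}

#' Generate a conservation profile with a planted interface shift
#'
#' Surface (and all other) residues score ~ Normal(0, 1); interface
#' residues are shifted by `-conservation_shift` (more conserved under the
#' lower-is-more-conserved convention).
#'
#' @param truth sidecar from [generate_dimer()].
#' @param spec a `SignalSpec` (uses `conservation_shift` and `seed`).
#' @return data.frame(pos, score).
#' @export
generate_conservation <- function(truth, spec = signal_spec()) {
  if (spec$conservation_shift < 0) stop("conservation shift must be >= 0")
  set.seed(spec$seed + 7L)
  score <- stats::rnorm(truth$L)
  score[truth$interface_pos] <- score[truth$interface_pos] -
    spec$conservation_shift
  data.frame(pos = seq_len(truth$L), score = score)
}

#' Generate a missense-variant table with a cysteine-excess spectrum
#'
#' Variant positions are uniform over the protein; alternate alleles are
#' drawn from a spectrum in which cysteine has probability
#' `cys_factor / 20` and the remaining mass is spread uniformly over the
#' other 19 amino acids (so the planted variant/region cysteine enrichment
#' is `cys_factor` against a uniform-composition region). Draws equal to
#' the reference amino acid are redrawn.
#'
#' @param truth sidecar from [generate_dimer()].
#' @param n number of variants (>= 1).
#' @param cys_factor planted cysteine excess (default 4).
#' @param seed RNG seed.
#' @return data.frame(pos, ref, alt).
#' @export
generate_variants <- function(truth, n, cys_factor = 4, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  if (cys_factor < 0 || cys_factor > 20) stop("cys_factor must be in [0, 20]")
  set.seed(seed)
  probs <- rep((1 - cys_factor / 20) / 19, 20L)
  names(probs) <- .aa1
  probs["C"] <- cys_factor / 20
  pos <- sample.int(truth$L, n, replace = TRUE)
  ref <- truth$seq[pos]
  alt <- sample(.aa1, n, replace = TRUE, prob = probs)
  while (any(alt == ref)) {
    k <- which(alt == ref)
    alt[k] <- sample(.aa1, length(k), replace = TRUE, prob = probs)
  }
  data.frame(pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Generate a toy metabolic network
#'
#' A linear uptake -> conversion -> sink chain; with `redundant = TRUE` a
#' parallel isoenzyme branch under a different gene duplicates the
#' conversion step.
#'
#' @param redundant include the isoenzyme branch.
#' @param capacity shared flux capacity (mol/day; default 10).
#' @return `MetabolicModel` (already parsed with [read_model()]).
#' @export
generate_network <- function(redundant = FALSE, capacity = 10) {
  rxns <- list(
    list(id = "R_up", lb = 0, ub = capacity, gpr = "g_up",
         metabolites = list(Ext_in = -1, A = 1)),
    list(id = "R_conv", lb = 0, ub = capacity, gpr = "g_conv",
         metabolites = list(A = -1, B = 1)),
    list(id = "R_sink", lb = 0, ub = capacity, gpr = "g_sink",
         metabolites = list(B = -1, Ext_out = 1))
  )
  if (redundant) {
    rxns <- append(rxns, list(
      list(id = "R_conv_iso", lb = 0, ub = capacity, gpr = "g_iso",
           metabolites = list(A = -1, B = 1))), after = 2L)
  }
  read_model(list(
    id = if (redundant) "toy_redundant" else "toy_linear",
    metabolites = list(
      list(id = "Ext_in", boundary = TRUE),
      list(id = "A", boundary = FALSE),
      list(id = "B", boundary = FALSE),
      list(id = "Ext_out", boundary = TRUE)
    ),
    reactions = rxns
  ))
}

#' Generate a full synthetic cohort with truth labels
#'
#' Builds `n_mbs` MBS and `n_sbs` SBS dimers; within each class the first
#' `round(functional_fraction * n)` complexes carry the functional effect
#' profile, the rest the gratuitous profile (interface-related effects
#' zero; ligand-binding-residue coevolution stays planted, since a
#' gratuitous interface does not imply a non-functional binding site).
#'
#' @param n_mbs,n_sbs complexes per class.
#' @param functional_fraction fraction per class with planted functional
#'   effects (default 0.5).
#' @param effects_functional,effects_gratuitous `SignalSpec`-like parameter
#'   lists (without seed) for the two labels.
#' @param seed master seed; per-complex seeds are derived from it.
#' @param out_dir optional directory: per-complex subdirectories with
#'   structure.pdb, couplings.csv, stats.json, conservation.tsv,
#'   variants.tsv are written, plus truth.tsv at the top level.
#' @param n_variants variants per complex (default 100).
#' @return list(complexes = named list of per-complex bundles (dimer,
#'   couplings, conservation, variants, functional), truth = data.frame).
#' @export
generate_cohort <- function(n_mbs, n_sbs, functional_fraction = 0.5,
                            effects_functional = list(cross_interface = 2,
                                                      lbr_interface = 3,
                                                      lbr_lbr = 3,
                                                      alignment = 4,
                                                      conservation_shift = 1),
                            effects_gratuitous = list(cross_interface = 0,
                                                      lbr_interface = 0,
                                                      lbr_lbr = 3,
                                                      alignment = 0,
                                                      conservation_shift = 0),
                            seed = 1L, out_dir = NULL, n_variants = 100L) {
  if (n_mbs < 0L || n_sbs < 0L || n_mbs + n_sbs < 1L) {
    stop("cohort needs at least one complex")
  }
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max %/% 2L, n_mbs + n_sbs)
  classes <- c(rep("MBS", n_mbs), rep("SBS", n_sbs))
  func <- c(seq_len(n_mbs) <= round(functional_fraction * n_mbs),
            seq_len(n_sbs) <= round(functional_fraction * n_sbs))
  complexes <- list()
  rows <- list()
  for (k in seq_along(classes)) {
    id <- sprintf("%s_%03d", tolower(classes[k]), k)
    dspec <- dimer_spec(ligand_mode = classes[k],
                        n_mbs_sites = if (classes[k] == "MBS") 2L else 1L,
                        seed = sub_seeds[k])
    dim <- generate_dimer(dspec)
    eff <- if (func[k]) effects_functional else effects_gratuitous
    sspec <- do.call(signal_spec, c(eff, list(seed = sub_seeds[k])))
    cpl <- generate_couplings(dim$truth, sspec)
    cons <- generate_conservation(dim$truth, sspec)
    vars <- generate_variants(dim$truth, n_variants, seed = sub_seeds[k])
    complexes[[id]] <- list(id = id, dimer = dim, couplings = cpl,
                            conservation = cons, variants = vars,
                            functional = func[k], class = classes[k])
    rows[[id]] <- data.frame(id = id, class = classes[k],
                             functional = func[k],
                             seed = sub_seeds[k], stringsAsFactors = FALSE)
    if (!is.null(out_dir)) {
      d <- file.path(out_dir, id)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      writeLines(dim$pdb, file.path(d, "structure.pdb"))
      utils::write.csv(cpl$table, file.path(d, "couplings.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(neff = cpl$neff, L = cpl$L),
                           file.path(d, "stats.json"), auto_unbox = TRUE)
      utils::write.table(cons, file.path(d, "conservation.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(vars, file.path(d, "variants.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  if (!is.null(out_dir)) {
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(complexes = complexes, truth = truth)
}
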