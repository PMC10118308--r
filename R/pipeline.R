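# Pipeline orchestration: annotation -> statistics -> classification over a
# directory (or in-memory cohort) of complexes, with per-complex failure
# isolation and reproducibility metadata.

#' Default pipeline configuration
#'
#' @param ... overrides of individual fields.
#' @return named list: probe radii, interface minimum (40), stratum
#'   boundary (100), alpha (0.05), replicate counts, seed, and toggles
#'   (Yeo-Johnson transform, exclude_direct, distance and reference
#'   policies, ENM cutoff, FVA flux quantity).
#' @export
default_config <- function(...) {
  cfg <- list(
    probe_contact = 0.25, probe_lbr = 0.21, probe_rsa = 1.4,
    min_interface = 40L, stratum_boundary = 100L, alpha = 0.05,
    n_reps = 1000L, seed = 1L, transform = TRUE, exclude_direct = FALSE,
    distance_policy = "nearest", reference_policy = "contacting",
    enm_cutoff = 15, sasa_points = 960L, fva_quantity = "max_abs",
    dccm_chains = "first"
  )
  over <- list(...)
  if (any(!names(over) %in% names(cfg))) {
    stop("unknown config field(s): ",
         paste(setdiff(names(over), names(cfg)), collapse = ", "))
  }
  cfg[names(over)] <- over
  stopifnot(cfg$min_interface > 0, cfg$stratum_boundary > 0, cfg$alpha > 0)
  cfg
}

# polynomial rolling hash of the serialized config, for provenance stamping
.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Analyze a single complex into a scorecard
#'
#' Runs annotation, the three coevolution Z statistics, conservation,
#' elastic-network dynamics and the coupling-dynamics R^2, selecting the
#' best ligand per statistic (multichain ligands only in MBS complexes).
#' Individual statistics that cannot be computed are recorded as missing.
#'
#' @param id complex id.
#' @param pdb PDB path or text.
#' @param couplings coupling CSV path or data.frame.
#' @param conservation conservation table path or data.frame (optional).
#' @param neff effective number of sequences; `L` defaults to the number of
#'   residues in the first chain.
#' @param config pipeline configuration from [default_config()].
#' @return list(card = one-row scorecard data.frame, annotation, details).
#' @export
analyze_complex <- function(id, pdb, couplings, conservation = NULL,
                            neff = NA_real_, config = default_config()) {
  s <- parse_structure(pdb, id = id)
  ann <- annotate_structure(s, probe_contact = config$probe_contact,
                            probe_lbr = config$probe_lbr,
                            probe_rsa = config$probe_rsa,
                            n_points = config$sasa_points,
                            distance_policy = config$distance_policy)
  a <- ann$annotations
  topo <- ann$topology
  chain1 <- s$chains[1L]
  L <- max(a$resnum)
  cm <- read_coupling_scores(couplings, L = L, neff = neff)
  analyzable <- if (is.na(neff)) TRUE else neff_filter(cm)

  interface_pos <- sort(unique(a$resnum[a$is_interface]))
  surface_pos <- sort(unique(a$resnum[a$is_surface & !a$is_interface &
                                        !a$is_lbr]))
  try_null <- function(expr) tryCatch(expr, error = function(e) NULL)

  classes <- try_null(coupling_pair_classes(
    ann, reference_policy = config$reference_policy))
  zi <- if (!is.null(classes)) {
    try_null(interface_z(cm, classes$cross_pairs, classes$reference_pairs,
                         transform = config$transform))
  } else NULL

  # per-ligand statistics
  sites <- ann$sites
  site_rows <- lapply(sites, function(st) {
    lpos <- sort(unique(a$resnum[a$uid %in% st$lbr_set]))
    zl <- try_null(ligand_interface_z(cm, lpos, interface_pos, surface_pos))
    data.frame(ligand_id = st$ligand_id, site_type = st$site_type,
               value = if (is.null(zl)) NA_real_ else zl$z,
               distance = st$distance_to_interface,
               stringsAsFactors = FALSE)
  })
  site_df <- if (length(site_rows) > 0L) do.call(rbind, site_rows) else NULL
  z_ligand <- NULL; z_lbr <- NULL; best_z <- NULL
  lig_dist <- NA_real_
  if (!is.null(site_df) && any(!is.na(site_df$value))) {
    best_z <- try_null(select_best_ligand(site_df, topo$complex_class))
    if (!is.null(best_z)) {
      st <- sites[[best_z]]
      lpos <- sort(unique(a$resnum[a$uid %in% st$lbr_set]))
      z_ligand <- try_null(ligand_interface_z(cm, lpos, interface_pos,
                                              surface_pos))
      z_lbr <- try_null(lbr_coevolution_z(cm, lpos, surface_pos))
      lig_dist <- st$distance_to_interface
    }
  }

  cons <- NULL
  if (!is.null(conservation)) {
    prof <- try_null(read_conservation(conservation,
                                       positions = sort(unique(a$resnum))))
    if (!is.null(prof)) {
      cons <- try_null(conservation_delta(prof, surface_pos, interface_pos))
    }
  }

  dyn <- NULL
  enm <- try_null(build_enm(s, cutoff = config$enm_cutoff))
  if (!is.null(enm)) {
    dccm <- try_null(compute_dccm(enm))
    if (!is.null(dccm)) {
      iface_uids <- a$uid[a$is_interface]
      # in MBS complexes the (symmetry-equivalent) multichain sites are
      # treated as one binding site for the dynamics statistic
      cand_sets <- if (topo$complex_class == "MBS") {
        mbs <- Filter(function(st) st$site_type == "MBS", sites)
        list(mbs_union = unique(unlist(lapply(mbs, `[[`, "lbr_set"))))
      } else {
        lapply(sites, `[[`, "lbr_set")
      }
      dyn_results <- lapply(cand_sets, function(lbr_set) {
        try_null(coupling_dynamics_r2(
          cm, dccm, iface_uids, lbr_set,
          exclude_direct = config$exclude_direct, contacts = ann$contacts,
          chains = if (identical(config$dccm_chains, "all")) NULL
                   else s$chains[1L]))
      })
      dyn_results <- Filter(Negate(is.null), dyn_results)
      if (length(dyn_results) > 0L) {
        r2s <- vapply(dyn_results, function(x) x$r2, 0)
        best <- names(dyn_results)[order(-r2s, names(dyn_results))][1L]
        dyn <- dyn_results[[best]]
      }
    }
  }

  card <- assemble_scorecard(
    id = id, complex_class = topo$complex_class,
    n_mbs_sites = topo$n_mbs_sites, interface_size = topo$interface_size,
    n_residues = length(unique(a$uid[a$chain == chain1])),
    ligand_distance = lig_dist, neff = neff,
    z_interface = zi, z_ligand = z_ligand, z_lbr = z_lbr,
    conservation = cons, dynamics = dyn, analyzable = analyzable,
    min_interface = config$min_interface,
    stratum_boundary = config$stratum_boundary
  )
  list(card = card, annotation = ann,
       details = list(sites = site_df, best_ligand = best_z))
}

#' Run the full pipeline over a cohort
#'
#' Accepts either a directory laid out as written by [generate_cohort()]
#' (one subdirectory per complex with structure.pdb, couplings.csv,
#' stats.json and optional conservation.tsv) or an in-memory cohort list.
#' Per-complex failures are isolated and logged; classification, overlap
#' and random-expectation summaries are computed across the surviving
#' scorecards.
#'
#' @param input directory path or the `complexes` list of
#'   [generate_cohort()].
#' @param config configuration from [default_config()].
#' @param out_dir optional output directory for TSV/JSON reports.
#' @return pipeline report list: scorecards (flagged), venn (per class and
#'   stratum), overlap_expectation, exclusions, failures, config,
#'   config_hash, seed.
#' @export
run_pipeline <- function(input, config = default_config(), out_dir = NULL) {
  if (is.character(input)) {
    dirs <- list.dirs(input, recursive = FALSE)
    if (length(dirs) == 0L) stop("empty input directory")
    items <- lapply(dirs, function(d) {
      stats_file <- file.path(d, "stats.json")
      neff <- if (file.exists(stats_file)) {
        jsonlite::read_json(stats_file)$neff
      } else NA_real_
      list(id = basename(d), pdb = file.path(d, "structure.pdb"),
           couplings = file.path(d, "couplings.csv"),
           conservation = {
             f <- file.path(d, "conservation.tsv")
             if (file.exists(f)) f else NULL
           },
           neff = as.numeric(neff))
    })
  } else {
    items <- lapply(input, function(cx) {
      list(id = cx$id, pdb = cx$dimer$pdb, couplings = cx$couplings$table,
           conservation = cx$conservation, neff = cx$couplings$neff)
    })
  }
  cards <- list()
  failures <- list()
  for (it in items) {
    res <- tryCatch(
      analyze_complex(it$id, it$pdb, it$couplings, it$conservation,
                      neff = it$neff, config = config),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[it$id]] <- conditionMessage(res)
    } else {
      cards[[it$id]] <- res$card
    }
  }
  if (length(cards) == 0L) stop("no complex could be analyzed")
  sc <- do.call(rbind, cards)
  rownames(sc) <- NULL
  sc <- flag_nonfunctional(sc, alpha = config$alpha)

  venn <- list()
  overlap <- list()
  for (cls in unique(sc$complex_class)) {
    for (strat in unique(sc$stratum)) {
      sub <- sc[sc$complex_class == cls & sc$stratum == strat &
                  sc$gate %in% TRUE, , drop = FALSE]
      key <- paste(cls, strat, sep = "_")
      if (nrow(sub) == 0L) next
      venn[[key]] <- venn_counts(sub)
      sizes <- c(sum(sub$flag_z %in% TRUE), sum(sub$flag_r2 %in% TRUE),
                 sum(sub$flag_cons %in% TRUE))
      if (all(sizes > 0L)) {
        overlap[[key]] <- random_overlap_expectation(
          sizes, nrow(sub), n_reps = config$n_reps, seed = config$seed)
      }
    }
  }
  exclusions <- data.frame(
    id = sc$id,
    reason = ifelse(sc$excluded, "interface_lt_min",
                    ifelse(!sc$analyzable, "neff_ratio_lt_1",
                           ifelse(!(sc$gate %in% TRUE), "gate_failed", ""))),
    stringsAsFactors = FALSE
  )
  report <- list(scorecards = sc, venn = venn,
                 overlap_expectation = overlap,
                 exclusions = exclusions[exclusions$reason != "", ,
                                         drop = FALSE],
                 failures = failures, config = config,
                 config_hash = .config_hash(config), seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(sc, file.path(out_dir, "scorecards.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(venn = venn, overlap = overlap, config = config,
           config_hash = report$config_hash, seed = config$seed,
           exclusions = report$exclusions, failures = failures),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
  }
  report
}
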