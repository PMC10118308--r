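# Elastic-network normal-mode analysis and the coupling-dynamics R^2.
#
# A C-alpha anisotropic network model (uniform springs, 15 Angstrom cutoff)
# replaces all-atom normal modes: the Hessian's pseudoinverse over all
# non-rigid modes yields residue-residue cross-correlations (DCCM), and the
# R^2 statistic relates, per interface residue, mean coupling to the
# ligand-binding residues with mean motional correlation to them.

#' Build a C-alpha anisotropic elastic network model
#'
#' One node per residue at its C-alpha position; node pairs within the
#' cutoff are connected by uniform springs. The 3N x 3N Hessian uses the
#' standard anisotropic super-elements -k/d^2 * dd' with diagonal blocks as
#' negative row sums.
#'
#' @param s a `StructureModel` with at least 3 C-alpha atoms, or a numeric
#'   matrix of node coordinates (n x 3, rownames used as node uids).
#' @param cutoff interaction cutoff in Angstrom (default 15).
#' @param k uniform spring constant (arbitrary units; DCCM is invariant to
#'   it).
#' @return `ElasticNetworkModel` list: hessian, coords, node_uids,
#'   node_chain, cutoff, k.
#' @export
build_enm <- function(s, cutoff = 15, k = 1) {
  if (inherits(s, "StructureModel")) {
    pa <- .protein_atoms(s)
    ca <- pa[pa$name == "CA", , drop = FALSE]
    coords <- as.matrix(ca[, c("x", "y", "z")])
    uids <- ca$uid
    chains <- ca$chain
  } else {
    coords <- as.matrix(s)
    uids <- rownames(coords)
    if (is.null(uids)) uids <- as.character(seq_len(nrow(coords)))
    chains <- rep(NA_character_, nrow(coords))
  }
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 residues with C-alpha atoms")
  d <- as.matrix(stats::dist(coords))
  adj <- d <= cutoff
  diag(adj) <- FALSE
  # connectivity check (BFS)
  comp <- integer(n)
  cid <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  if (cid > 1L) {
    sizes <- table(comp)
    stop("elastic network is disconnected at cutoff ", cutoff, " A: ",
         cid, " components of sizes ", paste(sizes, collapse = ", "))
  }
  H <- matrix(0, 3L * n, 3L * n)
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    dv <- coords[j, ] - coords[i, ]
    blk <- -k * tcrossprod(dv) / sum(dv^2)
    ii <- (3L * (i - 1L) + 1L):(3L * i)
    jj <- (3L * (j - 1L) + 1L):(3L * j)
    H[ii, jj] <- blk
    H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  structure(list(hessian = H, coords = coords, node_uids = uids,
                 node_chain = chains, cutoff = cutoff, k = k),
            class = "ElasticNetworkModel")
}

#' Dynamic cross-correlation matrix from an elastic network model
#'
#' The covariance matrix is the Hessian pseudoinverse over all non-rigid
#' modes (eigenvalues above `zero_tol` relative to the largest); the
#' normalized cross-correlation between residues i and j is the trace of
#' their 3 x 3 covariance block divided by the geometric mean of the
#' diagonal-block traces. Symmetric with unit diagonal, entries in
#' \[-1, 1\].
#'
#' @param enm an `ElasticNetworkModel`.
#' @param zero_tol relative eigenvalue threshold separating rigid-body modes
#'   (default 1e-8). A connected network must yield exactly six such modes.
#' @return `CrossCorrelationMatrix`: N x N numeric matrix with node uids as
#'   dimnames.
#' @export
compute_dccm <- function(enm, zero_tol = 1e-8) {
  eig <- eigen(enm$hessian, symmetric = TRUE)
  lam <- eig$values
  thr <- zero_tol * max(lam)
  rigid <- sum(lam < thr)
  # a collinear node set has one fewer rigid-body mode (the axial rotation
  # is degenerate)
  ctr <- sweep(enm$coords, 2L, colMeans(enm$coords))
  rank <- sum(svd(ctr)$d > 1e-8 * max(svd(ctr)$d, 1))
  expected <- if (rank <= 1L) 5L else 6L
  if (rigid != expected) {
    stop("expected ", expected, " rigid-body modes, found ", rigid,
         " (near-zero eigenvalues)")
  }
  keep <- lam >= thr
  V <- eig$vectors[, keep, drop = FALSE]
  C <- V %*% (t(V) / lam[keep])
  n <- nrow(enm$coords)
  idx <- function(i) (3L * (i - 1L) + 1L):(3L * i)
  tr <- vapply(seq_len(n), function(i) sum(diag(C[idx(i), idx(i)])), 0)
  if (any(tr <= 0)) stop("singular normalization: isolated node in network")
  dccm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    bi <- idx(i)
    for (j in i:n) {
      cij <- C[bi[1L], idx(j)[1L]] + C[bi[2L], idx(j)[2L]] +
        C[bi[3L], idx(j)[3L]]
      dccm[i, j] <- dccm[j, i] <- cij / sqrt(tr[i] * tr[j])
    }
  }
  dimnames(dccm) <- list(enm$node_uids, enm$node_uids)
  structure(dccm, class = c("CrossCorrelationMatrix", "matrix"))
}

#' Coupling-dynamics R^2
#'
#' For each interface residue, its mean coupling score to the ligand-binding
#' residues (x) and its mean cross-correlation with them in the DCCM (y) are
#' computed; R^2 is the squared Pearson correlation of (x, y) over interface
#' residues, with the p-value of the correlation test attached. With
#' `exclude_direct`, interface residues in direct contact with any
#' ligand-binding residue are removed first.
#'
#' @param cm a `CouplingMatrix`.
#' @param dccm a `CrossCorrelationMatrix` with residue uids as dimnames.
#' @param interface_uids,lbr_uids residue uids of the interface and
#'   ligand-binding sets.
#' @param position_of named integer vector mapping residue uid to alignment
#'   position (defaults to the residue number encoded in the uid).
#' @param exclude_direct drop interface residues directly contacting a
#'   ligand-binding residue (contacts at the 0.25 Angstrom probe).
#' @param contacts contact table from [compute_contacts()]; required when
#'   `exclude_direct` is TRUE.
#' @param chains optional chain id(s); restricts the interface residues
#'   entering the statistic to those chains.
#' @return `CouplingDynamicsResult` list: r2, r, p_value, n, and the
#'   per-residue data.frame (uid, coupling, correlation).
#' @export
coupling_dynamics_r2 <- function(cm, dccm, interface_uids, lbr_uids,
                                 position_of = NULL, exclude_direct = FALSE,
                                 contacts = NULL, chains = NULL) {
  if (is.null(position_of)) {
    uids <- rownames(dccm)
    position_of <- stats::setNames(
      as.integer(vapply(strsplit(uids, "/", fixed = TRUE), `[[`, "", 2L)),
      uids)
  }
  iface <- interface_uids
  if (!is.null(chains)) {
    ch <- vapply(strsplit(iface, "/", fixed = TRUE), `[[`, "", 1L)
    iface <- iface[ch %in% chains]
  }
  if (exclude_direct) {
    if (is.null(contacts)) stop("exclude_direct requires the contact table")
    pc <- contacts[contacts$type == "protein", , drop = FALSE]
    direct <- unique(c(pc$uid_i[pc$uid_j %in% lbr_uids],
                       pc$uid_j[pc$uid_i %in% lbr_uids]))
    iface <- setdiff(iface, c(direct, lbr_uids))
  }
  if (length(iface) < 5L) {
    stop("need at least 5 interface residues after exclusions")
  }
  lbr_nodes <- intersect(lbr_uids, rownames(dccm))
  if (length(lbr_nodes) == 0L) stop("no ligand-binding residues in the DCCM")
  lbr_pos <- unique(position_of[lbr_nodes])
  # interface residues that are themselves ligand-binding stay in the point
  # set (their self-pairs are dropped from the coupling average); use
  # exclude_direct to remove them together with all direct contacts
  xy <- do.call(rbind, lapply(iface, function(u) {
    p <- position_of[[u]]
    cp <- setdiff(lbr_pos, p)
    x <- mean(cm$scores[p, cp], na.rm = TRUE)
    y <- mean(dccm[u, lbr_nodes])
    c(x = x, y = y)
  }))
  if (stats::sd(xy[, 1L]) == 0 || stats::sd(xy[, 2L]) == 0) {
    stop("constant coupling or correlation profile: R^2 undefined")
  }
  ct <- stats::cor.test(xy[, 1L], xy[, 2L])
  structure(list(r2 = unname(ct$estimate^2), r = unname(ct$estimate),
                 p_value = ct$p.value, n = length(iface),
                 per_residue = data.frame(uid = iface, coupling = xy[, 1L],
                                          correlation = xy[, 2L],
                                          stringsAsFactors = FALSE)),
            class = "CouplingDynamicsResult")
}

#' Write a DCCM as a square CSV matrix
#'
#' @param dccm a `CrossCorrelationMatrix`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_dccm_csv <- function(dccm, path) {
  utils::write.csv(unclass(dccm), path, row.names = TRUE)
  invisible(path)
}
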