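# Coevolution Z statistics from pairwise evolutionary coupling scores.
#
# All three statistics standardise a focus distribution of coupling scores
# against a reference distribution: z = (mean_focus - mean_reference) /
# sd_reference, with sd the sample standard deviation. Significance is a
# two-sided Wilcoxon rank-sum test (normal approximation, tie- and
# continuity-corrected).

#' Read pairwise coupling scores into a CouplingMatrix
#'
#' Consumes the standard i, j, score CSV dialect of coupling-inference
#' tools (raw "cn" scores). Duplicate pairs must agree; conflicting
#' duplicates are an error.
#'
#' @param x path to a CSV file or a data.frame with columns i, j and a score
#'   column (named `cn` or `score`; otherwise the third column is used).
#' @param L alignment length (number of residues). Defaults to the largest
#'   position index seen.
#' @param neff effective number of sequences of the alignment.
#' @param mapping optional named integer vector mapping structure residue
#'   uids to alignment columns; positions outside `1..L` are dropped with a
#'   message.
#' @return object of class `CouplingMatrix`: list(scores = symmetric L x L
#'   matrix with NA diagonal, L, neff, map).
#' @export
read_coupling_scores <- function(x, L = NULL, neff = NA_real_, mapping = NULL) {
  df <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  cols <- names(df)
  if (!all(c("i", "j") %in% cols)) stop("coupling table needs columns i and j")
  sc <- if ("cn" %in% cols) "cn" else if ("score" %in% cols) "score" else cols[3L]
  i <- as.integer(df$i); j <- as.integer(df$j); v <- as.numeric(df[[sc]])
  if (any(i == j)) stop("self-pairs (i == j) are not allowed")
  if (is.null(L)) L <- max(i, j)
  drop <- i > L | j > L | i < 1L | j < 1L
  if (any(drop)) {
    message(sum(drop), " unmapped coupling rows dropped")
    i <- i[!drop]; j <- j[!drop]; v <- v[!drop]
  }
  key <- paste(pmin(i, j), pmax(i, j))
  if (anyDuplicated(key)) {
    agg <- tapply(v, key, function(z) diff(range(z)))
    if (any(agg > 1e-8)) {
      stop("conflicting duplicate coupling entries for pair(s): ",
           paste(utils::head(names(agg)[agg > 1e-8], 3L), collapse = ", "))
    }
    keep <- !duplicated(key)
    i <- i[keep]; j <- j[keep]; v <- v[keep]
  }
  m <- matrix(NA_real_, L, L)
  m[cbind(i, j)] <- v
  m[cbind(j, i)] <- v
  structure(list(scores = m, L = L, neff = neff, map = mapping),
            class = "CouplingMatrix")
}

#' Alignment-quality filter
#'
#' A protein is analyzable when the ratio of the effective number of
#' sequences to the alignment length is at least one.
#'
#' @param cm a `CouplingMatrix` with known `neff` and `L`.
#' @return logical.
#' @export
neff_filter <- function(cm) {
  if (is.na(cm$neff) || is.null(cm$L)) stop("neff and L must be known")
  cm$neff / cm$L >= 1
}

#' Yeo-Johnson power transform
#'
#' The standard four-branch transform, monotone increasing for every lambda,
#' defined for negative inputs (a generalisation of Box-Cox).
#'
#' @param x numeric vector.
#' @param lambda transform parameter.
#' @return transformed vector.
#' @export
yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  if (abs(lambda) > 1e-12) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-12) {
    out[!pos] <- -((1 - x[!pos])^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[!pos] <- -log1p(-x[!pos])
  }
  out[is.na(x)] <- NA_real_
  out
}

#' Select the Yeo-Johnson lambda maximising normality
#'
#' Maximises the Gaussian profile log-likelihood of the transformed sample
#' (including the Jacobian term) over lambda in \[-5, 5\] by Brent search.
#'
#' @param x reference sample, length >= 8, non-constant.
#' @return the selected lambda.
#' @export
select_lambda <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L) stop("need at least 8 observations to select lambda")
  if (diff(range(x)) < .Machine$double.eps^0.5) {
    stop("constant sample: no transform can normalise it")
  }
  jac <- sum(sign(x) * log1p(abs(x)))
  ll <- function(lambda) {
    y <- yeo_johnson(x, lambda)
    s2 <- mean((y - mean(y))^2)
    -n / 2 * log(s2) + (lambda - 1) * jac
  }
  stats::optimize(ll, c(-5, 5), maximum = TRUE, tol = 1e-6)$maximum
}

# Core Z construction shared by the three statistics.
.z_score <- function(focus, reference, transform = FALSE, lambda = NULL) {
  focus <- focus[!is.na(focus)]; reference <- reference[!is.na(reference)]
  if (length(focus) < 2L || length(reference) < 2L) {
    stop("need at least 2 coupling scores in each class")
  }
  spec <- list(lambda = NA_real_, applied = FALSE)
  if (transform) {
    lam <- if (is.null(lambda)) select_lambda(reference) else lambda
    focus <- yeo_johnson(focus, lam)
    reference <- yeo_johnson(reference, lam)
    spec <- list(lambda = lam, applied = TRUE)
  }
  sdr <- stats::sd(reference)
  if (!is.finite(sdr) || sdr <= 0) stop("reference distribution has zero SD")
  p <- stats::wilcox.test(focus, reference, exact = FALSE,
                          correct = TRUE)$p.value
  structure(list(z = (mean(focus) - mean(reference)) / sdr,
                 mean_focus = mean(focus), mean_reference = mean(reference),
                 sd_reference = sdr, n_focus = length(focus),
                 n_reference = length(reference), p_value = p,
                 transform = spec),
            class = "ZScoreResult")
}

#' @export
print.ZScoreResult <- function(x, ...) {
  cat(sprintf("Z = %.3f (focus n=%d, reference n=%d), p = %.3g%s\n",
              x$z, x$n_focus, x$n_reference, x$p_value,
              if (x$transform$applied) {
                sprintf(" [Yeo-Johnson lambda = %.2f]", x$transform$lambda)
              } else ""))
  invisible(x)
}

# Extract coupling scores for a 2-column matrix of position pairs.
.pair_scores <- function(cm, pairs) {
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2L)
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  key <- paste(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  cm$scores[pairs]
}

# All unordered cross pairs between two position sets.
.cross_pairs <- function(a, b) {
  g <- expand.grid(i = a, j = b)
  g <- g[g$i != g$j, , drop = FALSE]
  key <- paste(pmin(g$i, g$j), pmax(g$i, g$j))
  as.matrix(g[!duplicated(key), , drop = FALSE])
}

#' Interface coevolution Z-score
#'
#' Compares coupling scores of residue pairs interacting across the
#' interface (focus) with pairs of interface residues and the non-interface
#' residues they contact (reference). Positive Z indicates stronger
#' coevolution across the interface. By default both distributions are
#' Yeo-Johnson transformed with lambda selected on the reference
#' distribution.
#'
#' @param cm a `CouplingMatrix`.
#' @param cross_pairs 2-column matrix of alignment positions interacting
#'   across the interface.
#' @param reference_pairs 2-column matrix of interface/non-interface
#'   contacting position pairs.
#' @param transform apply the Yeo-Johnson transform (default TRUE).
#' @return a `ZScoreResult`.
#' @seealso [coupling_pair_classes()] to derive the two pair classes from a
#'   structure annotation.
#' @export
interface_z <- function(cm, cross_pairs, reference_pairs, transform = TRUE) {
  .z_score(.pair_scores(cm, cross_pairs), .pair_scores(cm, reference_pairs),
           transform = transform)
}

#' Ligand-interface coevolution Z-score
#'
#' Compares couplings between ligand-binding residues and interface
#' residues (focus) with couplings between ligand-binding residues and
#' solvent-accessible surface residues (reference). Distributions are not
#' transformed.
#'
#' @param cm a `CouplingMatrix`.
#' @param lbr_pos,interface_pos,surface_pos alignment positions of the
#'   ligand-binding, interface and surface residue sets.
#' @return a `ZScoreResult`.
#' @export
ligand_interface_z <- function(cm, lbr_pos, interface_pos, surface_pos) {
  if (length(lbr_pos) == 0L || length(interface_pos) == 0L ||
      length(surface_pos) == 0L) {
    stop("ligand-binding, interface and surface position sets must be nonempty")
  }
  .z_score(.pair_scores(cm, .cross_pairs(lbr_pos, interface_pos)),
           .pair_scores(cm, .cross_pairs(lbr_pos, surface_pos)),
           transform = FALSE)
}

#' Coevolution between ligand-binding residues
#'
#' Compares couplings among ligand-binding residues (focus) with couplings
#' of ligand-binding residues with surface residues (reference). Used as the
#' gate condition for non-functionality flagging and as an ANCOVA covariate.
#'
#' @param cm a `CouplingMatrix`.
#' @param lbr_pos alignment positions of at least two ligand-binding
#'   residues.
#' @param surface_pos alignment positions of the surface residues.
#' @return a `ZScoreResult`.
#' @export
lbr_coevolution_z <- function(cm, lbr_pos, surface_pos) {
  if (length(lbr_pos) < 2L) stop("need at least 2 ligand-binding residues")
  pairs <- t(utils::combn(lbr_pos, 2L))
  .z_score(.pair_scores(cm, pairs),
           .pair_scores(cm, .cross_pairs(lbr_pos, surface_pos)),
           transform = FALSE)
}

#' Derive coupling pair classes from a structure annotation
#'
#' Maps residue-level contacts onto alignment positions and returns the two
#' pair classes entering [interface_z()]: pairs in contact across the
#' interface, and interface/non-interface contacting pairs. With
#' `reference_policy = "all_pairs"` the reference class contains all
#' interface x non-interface position pairs instead of only contacting ones.
#'
#' @param ann a `ResidueAnnotation` from [annotate_structure()].
#' @param position_of named integer vector mapping residue uid to alignment
#'   position; defaults to the author residue number.
#' @param reference_policy "contacting" (default) or "all_pairs".
#' @return list(cross_pairs, reference_pairs) of 2-column position matrices.
#' @export
coupling_pair_classes <- function(ann, position_of = NULL,
                                  reference_policy = c("contacting",
                                                       "all_pairs")) {
  reference_policy <- match.arg(reference_policy)
  a <- ann$annotations
  pos <- if (is.null(position_of)) {
    stats::setNames(a$resnum, a$uid)
  } else position_of
  iface <- a$uid[a$is_interface]
  pc <- ann$contacts[ann$contacts$type == "protein", , drop = FALSE]
  cross <- pc[pc$chain_i != pc$chain_j &
                pc$uid_i %in% iface & pc$uid_j %in% iface, , drop = FALSE]
  cross_pairs <- cbind(pos[cross$uid_i], pos[cross$uid_j])
  if (reference_policy == "contacting") {
    refc <- pc[xor(pc$uid_i %in% iface, pc$uid_j %in% iface), , drop = FALSE]
    ref_pairs <- cbind(pos[refc$uid_i], pos[refc$uid_j])
  } else {
    ref_pairs <- .cross_pairs(unique(pos[iface]),
                              unique(pos[setdiff(a$uid, iface)]))
  }
  list(cross_pairs = unname(cross_pairs), reference_pairs = unname(ref_pairs))
}

#' Select the best-scoring ligand
#'
#' Picks the candidate ligand with the largest statistic. In MBS complexes
#' only multichain ligands are candidates; metal ligands never are. Ties are
#' broken by lexicographic ligand id.
#'
#' @param results data.frame with columns ligand_id, value (the statistic),
#'   site_type ("MBS"/"SBS").
#' @param complex_class "MBS" or "SBS".
#' @return the chosen ligand_id.
#' @export
select_best_ligand <- function(results, complex_class = "SBS") {
  cand <- results
  if (identical(complex_class, "MBS")) {
    cand <- cand[cand$site_type == "MBS", , drop = FALSE]
  }
  cand <- cand[!is.na(cand$value), , drop = FALSE]
  if (nrow(cand) == 0L) stop("no candidate ligands")
  cand <- cand[order(-cand$value, cand$ligand_id), , drop = FALSE]
  cand$ligand_id[1L]
}
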