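# Cohort-level classification: per-complex scorecards, non-functionality
# flags per method with Benjamini-Hochberg correction, interface-size
# strata, Venn overlaps with simulated random expectations, and the
# covariate-adjusted (ANCOVA) binding-site-type analysis.

#' Assemble a per-complex scorecard
#'
#' Collects the upstream statistics of one complex into a single
#' scorecard row. Missing statistics are recorded as NA; complexes with
#' fewer than 40 interface residues are marked excluded, and complexes
#' failing the alignment-quality filter are marked not analyzable for
#' coupling statistics.
#'
#' @param id complex id.
#' @param complex_class "MBS" or "SBS".
#' @param n_mbs_sites number of distinct multichain ligand sites.
#' @param interface_size total interface residues over both chains.
#' @param n_residues structure size in residues.
#' @param ligand_distance ligand-interface distance (Angstrom).
#' @param neff effective number of sequences; `analyzable` should be the
#'   result of [neff_filter()].
#' @param z_interface,z_ligand,z_lbr `ZScoreResult`s (or NULL).
#' @param conservation result of [conservation_delta()] (or NULL).
#' @param dynamics a `CouplingDynamicsResult` (or NULL).
#' @param analyzable logical from the Neff/L filter.
#' @param min_interface flagging threshold on interface size (default 40).
#' @param stratum_boundary boundary between the small and large interface
#'   strata (default 100).
#' @return one-row data.frame (a `ComplexScoreCard`).
#' @export
assemble_scorecard <- function(id, complex_class, n_mbs_sites = 0L,
                               interface_size = NA_integer_,
                               n_residues = NA_integer_,
                               ligand_distance = NA_real_, neff = NA_real_,
                               z_interface = NULL, z_ligand = NULL,
                               z_lbr = NULL, conservation = NULL,
                               dynamics = NULL, analyzable = TRUE,
                               min_interface = 40L, stratum_boundary = 100L) {
  g <- function(x, field) if (is.null(x)) NA_real_ else x[[field]]
  data.frame(
    id = id, complex_class = complex_class, n_mbs_sites = n_mbs_sites,
    interface_size = interface_size, n_residues = n_residues,
    ligand_distance = ligand_distance, neff = neff,
    analyzable = analyzable,
    excluded = is.na(interface_size) | interface_size < min_interface,
    stratum = ifelse(interface_size < stratum_boundary, "lt100", "ge100"),
    z_interface = g(z_interface, "z"), p_interface = g(z_interface, "p_value"),
    z_ligand = g(z_ligand, "z"), p_ligand = g(z_ligand, "p_value"),
    z_lbr = g(z_lbr, "z"), p_lbr = g(z_lbr, "p_value"),
    cons_delta = g(conservation, "delta"), p_cons = g(conservation, "p_value"),
    r2 = g(dynamics, "r2"), r = g(dynamics, "r"), p_r2 = g(dynamics, "p_value"),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg step-up correction
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return list(q = adjusted q-values, reject = logical rejections at
#'   `q <= alpha`).
#' @export
apply_bh <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  n <- length(p)
  q <- rep(NA_real_, n)
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m > 0L) {
    o <- order(p[ok])
    ranked <- p[ok][o] * m / seq_len(m)
    ranked <- rev(cummin(rev(ranked)))
    qq <- pmin(ranked, 1)
    q[ok[o]] <- qq
  }
  list(q = q, reject = !is.na(q) & q <= alpha)
}

#' Flag putatively non-functional complexes
#'
#' A method flags a complex when its statistic is negative or not
#' statistically significant after Benjamini-Hochberg correction across the
#' cohort: the Z method uses the ligand-interface Z-score, the R2 method the
#' coupling-dynamics correlation (flag when the correlation is not
#' significantly positive), and the CONS method the interface-conservation
#' delta. Flags are only assigned to complexes that pass the gate condition
#' that ligand-binding residues coevolve significantly stronger with each
#' other than with surface residues (BH-corrected), are not excluded by the
#' 40-interface-residue rule, and pass the alignment-quality filter.
#'
#' @param cards scorecard data.frame (rows from [assemble_scorecard()]).
#' @param alpha significance level (default 0.05).
#' @return the scorecard with added columns q_ligand, q_cons, q_r2, q_lbr,
#'   gate (logical), flag_z, flag_r2, flag_cons (logical, NA when the
#'   statistic is missing or the complex is excluded/ungated), and
#'   n_methods_flagging.
#' @export
flag_nonfunctional <- function(cards, alpha = 0.05) {
  eligible <- !cards$excluded & cards$analyzable
  bh_on <- function(p) {
    q <- rep(NA_real_, nrow(cards))
    q[eligible] <- apply_bh(p[eligible], alpha)$q
    q
  }
  cards$q_lbr <- bh_on(cards$p_lbr)
  cards$q_ligand <- bh_on(cards$p_ligand)
  cards$q_cons <- bh_on(cards$p_cons)
  cards$q_r2 <- bh_on(cards$p_r2)
  cards$gate <- eligible & !is.na(cards$q_lbr) &
    cards$q_lbr <= alpha & cards$z_lbr > 0
  fl <- function(stat, q) {
    ifelse(!cards$gate, NA,
           ifelse(is.na(stat) | is.na(q), NA, stat <= 0 | q > alpha))
  }
  cards$flag_z <- fl(cards$z_ligand, cards$q_ligand)
  cards$flag_cons <- fl(cards$cons_delta, cards$q_cons)
  # R^2 >= 0 by construction; flag when the underlying correlation is not
  # significantly positive
  cards$flag_r2 <- ifelse(!cards$gate, NA,
                          ifelse(is.na(cards$r) | is.na(cards$q_r2), NA,
                                 cards$r <= 0 | cards$q_r2 > alpha))
  cards$n_methods_flagging <-
    (cards$flag_z %in% TRUE) + (cards$flag_r2 %in% TRUE) +
    (cards$flag_cons %in% TRUE)
  cards
}

#' Venn region counts for three flag sets
#'
#' @param flags data.frame with logical columns flag_z, flag_r2, flag_cons
#'   (one row per complex in the stratum; NA treated as not flagged).
#' @return list with `counts` (named vector over the 7 Venn regions plus
#'   `none`), `percent` (same regions relative to the stratum size) and `n`.
#' @export
venn_counts <- function(flags) {
  n <- nrow(flags)
  if (is.null(n) || n == 0L) stop("empty stratum")
  A <- flags$flag_z %in% TRUE
  B <- flags$flag_r2 %in% TRUE
  C <- flags$flag_cons %in% TRUE
  counts <- c(
    z_only = sum(A & !B & !C),
    r2_only = sum(!A & B & !C),
    cons_only = sum(!A & !B & C),
    z_r2 = sum(A & B & !C),
    z_cons = sum(A & !B & C),
    r2_cons = sum(!A & B & C),
    all_three = sum(A & B & C),
    none = sum(!A & !B & !C)
  )
  list(counts = counts, percent = 100 * counts / n, n = n,
       any_two = sum((A + B + C) >= 2L), any_two_percent =
         100 * sum((A + B + C) >= 2L) / n)
}

#' Random expectation for subset overlaps
#'
#' Draws, per replicate, uniform random subsets of the given sizes without
#' replacement from an N-element universe and records the percentage of
#' elements in all three subsets, in at least two, and in each pairwise
#' intersection. Reports the mean and SD over replicates together with the
#' analytic expectation of the triple overlap,
#' `100 * prod(sizes / N)`.
#'
#' @param sizes integer vector of three subset sizes.
#' @param N universe size.
#' @param n_reps number of replicates (default 1000).
#' @param seed RNG seed recorded in the output.
#' @return list(triple = c(mean, sd), at_least_two = c(mean, sd),
#'   pairwise = 3 x 2 matrix of means/SDs, analytic_triple, n_reps, seed).
#' @export
random_overlap_expectation <- function(sizes, N, n_reps = 1000L, seed = 1L) {
  if (length(sizes) != 3L) stop("exactly three subset sizes expected")
  if (any(sizes > N)) stop("subset size exceeds universe size")
  set.seed(seed)
  triple <- numeric(n_reps)
  atl2 <- numeric(n_reps)
  pw <- matrix(0, n_reps, 3L)
  for (r in seq_len(n_reps)) {
    s1 <- sample.int(N, sizes[1L]); s2 <- sample.int(N, sizes[2L])
    s3 <- sample.int(N, sizes[3L])
    in1 <- logical(N); in1[s1] <- TRUE
    in2 <- logical(N); in2[s2] <- TRUE
    in3 <- logical(N); in3[s3] <- TRUE
    cnt <- in1 + in2 + in3
    triple[r] <- 100 * sum(cnt == 3L) / N
    atl2[r] <- 100 * sum(cnt >= 2L) / N
    pw[r, ] <- 100 * c(sum(in1 & in2), sum(in1 & in3), sum(in2 & in3)) / N
  }
  list(
    triple = c(mean = mean(triple), sd = stats::sd(triple)),
    at_least_two = c(mean = mean(atl2), sd = stats::sd(atl2)),
    pairwise = rbind(`1x2` = c(mean(pw[, 1L]), stats::sd(pw[, 1L])),
                     `1x3` = c(mean(pw[, 2L]), stats::sd(pw[, 2L])),
                     `2x3` = c(mean(pw[, 3L]), stats::sd(pw[, 3L]))),
    analytic_triple = 100 * prod(sizes / N),
    n_reps = n_reps, seed = seed
  )
}

#' Covariate-adjusted binding-site-type effect (ANCOVA)
#'
#' Ordinary least squares of a response statistic on a binding-site-type
#' factor and log-transformed covariates, with marginal (type-III style)
#' F tests and backwards elimination: the least significant covariate with
#' p > `alpha` is removed iteratively; the factor is never removed.
#'
#' @param data data.frame holding the response, factor and covariates.
#' @param response name of the response column.
#' @param factor_col name of the class factor column (e.g. complex_class).
#' @param covariates character vector of covariate column names; all must be
#'   positive when `log_covariates` is TRUE.
#' @param log_covariates log-transform the covariates (default TRUE).
#' @param alpha retention threshold for covariates (default 0.05).
#' @return list(model, table = final marginal F-test table, factor_p,
#'   factor_coef, eliminated = covariates removed in order).
#' @export
ancova_effect <- function(data, response, factor_col, covariates,
                          log_covariates = TRUE, alpha = 0.05) {
  if (nrow(data) < 10L) stop("need at least 10 complexes for ANCOVA")
  d <- data[, c(response, factor_col, covariates), drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d[[factor_col]] <- factor(d[[factor_col]])
  if (log_covariates) {
    for (cv in covariates) {
      if (any(d[[cv]] <= 0)) stop("covariate ", cv, " must be positive before log")
      d[[cv]] <- log(d[[cv]])
    }
  }
  current <- covariates
  eliminated <- character()
  repeat {
    fml <- stats::reformulate(c(factor_col, current), response)
    fit <- stats::lm(fml, data = d)
    if (any(is.na(stats::coef(fit)))) {
      stop("collinear design; aliased terms: ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "))
    }
    dr <- stats::drop1(fit, test = "F")
    tab <- dr[-1L, , drop = FALSE]
    cov_rows <- rownames(tab)[rownames(tab) %in% current]
    if (length(cov_rows) == 0L) break
    pv <- tab[cov_rows, "Pr(>F)"]
    worst <- cov_rows[which.max(pv)]
    if (max(pv) <= alpha) break
    eliminated <- c(eliminated, worst)
    current <- setdiff(current, worst)
  }
  factor_p <- tab[factor_col, "Pr(>F)"]
  cf <- stats::coef(fit)
  factor_coef <- cf[grep(paste0("^", factor_col), names(cf))]
  list(model = fit, table = tab, factor_p = factor_p,
       factor_coef = factor_coef, eliminated = eliminated,
       retained = current)
}

#' Two-sample test of proportions
#'
#' Chi-square test with continuity correction, two-sided.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return the p-value.
#' @export
proportion_test <- function(k1, n1, k2, n2) {
  if (n1 == 0L || n2 == 0L) stop("group sizes must be positive")
  if (k1 > n1 || k2 > n2) stop("successes exceed trials")
  stats::prop.test(c(k1, k2), c(n1, n2))$p.value
}
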