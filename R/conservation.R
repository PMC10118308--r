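# Interface-conservation delta from per-residue conservation scores
# (ConSurf convention: lower score = more conserved).

#' Read a per-residue conservation summary
#'
#' Accepts a ConSurf-style summary table with a residue-number column and a
#' score column, and maps rows onto structure residues.
#'
#' @param x path to a TSV/CSV file or a data.frame. Recognised columns:
#'   `pos`/`resnum`/`position` for the residue number, `score` for the
#'   normalized conservation score.
#' @param positions optional integer vector of structure residue numbers to
#'   map against; unmapped rows are dropped with a warning.
#' @return named numeric vector of scores keyed by residue number
#'   (class `ConservationProfile`).
#' @export
read_conservation <- function(x, positions = NULL) {
  df <- if (is.character(x)) {
    utils::read.table(x, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else x
  if (nrow(df) == 0L) stop("empty conservation table")
  pcol <- intersect(c("pos", "resnum", "position"), names(df))[1L]
  if (is.na(pcol) || !"score" %in% names(df)) {
    stop("conservation table needs a residue-number column and a score column")
  }
  pos <- as.integer(df[[pcol]])
  score <- as.numeric(df$score)
  if (any(!is.finite(score))) stop("non-finite conservation scores")
  if (!is.null(positions)) {
    keep <- pos %in% positions
    if (!any(keep)) stop("no overlap between conservation table and structure")
    if (any(!keep)) warning(sum(!keep), " unmapped conservation rows dropped")
    pos <- pos[keep]; score <- score[keep]
  }
  structure(stats::setNames(score, pos), class = "ConservationProfile")
}

#' Interface-conservation delta
#'
#' Mean surface score minus mean interface score: positive values mean the
#' interface is more conserved than the solvent-accessible surface (lower
#' ConSurf score = more conserved). Significance is a rank-sum test between
#' the two per-residue score samples.
#'
#' @param profile named numeric conservation scores keyed by residue number
#'   (or a `ConservationProfile`).
#' @param surface_pos,interface_pos residue numbers of the two sets; each
#'   needs at least 3 scored residues.
#' @param alternative passed to [stats::wilcox.test()] ("two.sided" default;
#'   "greater" tests surface > interface scores, i.e. a more conserved
#'   interface).
#' @return list(delta, p_value, n_surface, n_interface).
#' @export
conservation_delta <- function(profile, surface_pos, interface_pos,
                               alternative = "two.sided") {
  s <- unname(profile[as.character(surface_pos)])
  i <- unname(profile[as.character(interface_pos)])
  s <- s[!is.na(s)]; i <- i[!is.na(i)]
  if (length(s) < 3L || length(i) < 3L) {
    stop("need at least 3 scored residues in each of surface and interface")
  }
  p <- stats::wilcox.test(s, i, exact = FALSE, correct = TRUE,
                          alternative = alternative)$p.value
  list(delta = mean(s) - mean(i), p_value = p,
       n_surface = length(s), n_interface = length(i))
}
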