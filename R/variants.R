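# Amino-acid composition of structural regions vs the composition of
# missense-variant alternate alleles mapped onto them. Each variant counts
# once; allele frequencies are not used.

#' Map missense variants onto structural regions
#'
#' @param variants data.frame with columns `pos` (1-based protein
#'   position), `ref`, `alt` (one-letter amino acids).
#' @param interface_pos,surface_pos integer vectors of residue positions.
#' @param L protein length; positions outside `1..L` are an error.
#' @return list of data.frames: interface, surface, neither.
#' @export
map_variants <- function(variants, interface_pos, surface_pos, L) {
  v <- variants
  if (!all(c("pos", "ref", "alt") %in% names(v))) {
    stop("variant table needs columns pos, ref, alt")
  }
  if (any(v$ref == v$alt)) stop("ref and alt amino acids must differ")
  if (!all(v$ref %in% .aa1) || !all(v$alt %in% .aa1)) {
    stop("non-canonical amino acid in variant table")
  }
  bad <- v$pos < 1L | v$pos > L
  if (any(bad)) {
    stop("variant position(s) out of range: ",
         paste(utils::head(v$pos[bad], 5L), collapse = ", "))
  }
  region <- ifelse(v$pos %in% interface_pos, "interface",
                   ifelse(v$pos %in% surface_pos, "surface", "neither"))
  split(v, factor(region, levels = c("interface", "surface", "neither")))
}

#' Amino-acid composition of a region and of its variants
#'
#' @param region_aa one-letter amino acids of the region's residues.
#' @param variant_alt one-letter alternate alleles of the variants mapped to
#'   the region (may be empty).
#' @return `CompositionTable` list with `region` and `variant` frequency
#'   vectors over the 20 amino acids (each summing to 1; variant
#'   frequencies all NA when no variants) and the underlying counts.
#' @export
composition <- function(region_aa, variant_alt = character()) {
  if (length(region_aa) == 0L) stop("empty region")
  rc <- table(factor(region_aa, levels = .aa1))
  vc <- table(factor(variant_alt, levels = .aa1))
  vf <- if (length(variant_alt) > 0L) as.numeric(vc) / length(variant_alt) else
    rep(NA_real_, 20L)
  structure(list(
    region = stats::setNames(as.numeric(rc) / length(region_aa), .aa1),
    variant = stats::setNames(vf, .aa1),
    region_counts = stats::setNames(as.integer(rc), .aa1),
    variant_counts = stats::setNames(as.integer(vc), .aa1)
  ), class = "CompositionTable")
}

#' Test whether a frequency-frequency slope differs from one
#'
#' Ordinary least squares of y on x over the included amino acids, with an
#' F test of the null hypothesis that the slope equals one.
#'
#' @param x,y named 20-amino-acid frequency vectors (e.g. variant and
#'   region frequencies).
#' @param exclusions amino acids (one-letter) dropped before the
#'   regression, e.g. "C" to exclude cysteine.
#' @return list(slope, intercept, F, p_value, df, n).
#' @export
slope_vs_one_test <- function(x, y, exclusions = character()) {
  keep <- setdiff(.aa1, exclusions)
  xv <- x[keep]; yv <- y[keep]
  ok <- !is.na(xv) & !is.na(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 5L) stop("need at least 5 amino acids after exclusions")
  if (stats::sd(xv) == 0) stop("zero-variance x frequencies")
  fit <- stats::lm(yv ~ xv)
  sm <- suppressWarnings(summary(fit))  # tolerate exact-fit degenerate case
  sl <- unname(stats::coef(fit)[2L])
  se <- sm$coefficients[2L, 2L]
  df2 <- fit$df.residual
  Fst <- if (sm$sigma > 1e-10) ((sl - 1) / se)^2 else
    if (abs(sl - 1) < 1e-8) 0 else Inf     # exact fit: H0 holds or fails
  list(slope = sl, intercept = unname(stats::coef(fit)[1L]),
       F = unname(Fst), p_value = stats::pf(Fst, 1, df2, lower.tail = FALSE),
       df = c(1L, df2), n = length(xv))
}

#' Variant-to-region frequency enrichment ratio
#'
#' @param aa one-letter amino acid (e.g. "C").
#' @param variant_freqs,region_freqs named frequency vectors.
#' @return variant frequency divided by region frequency.
#' @export
enrichment_ratio <- function(aa, variant_freqs, region_freqs) {
  rf <- region_freqs[[aa]]
  if (is.na(rf) || rf <= 0) stop("region frequency of ", aa, " is zero")
  variant_freqs[[aa]] / rf
}
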