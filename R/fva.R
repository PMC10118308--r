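# Flux variability analysis on small metabolic models with gene knockouts.
#
# Models are a minimal JSON dialect: metabolites (with boundary flags),
# reactions with stoichiometry, bounds (mol/day) and gene-protein-reaction
# (GPR) boolean rules. Boundary metabolites are excluded from the
# steady-state constraint.

#' Read a metabolic model
#'
#' JSON schema: `{"id": ..., "metabolites": [{"id", "boundary"}],
#' "reactions": [{"id", "lb", "ub", "gpr", "metabolites": {"M": coef}}]}`.
#'
#' @param x path to a JSON file or an equivalent R list.
#' @return `MetabolicModel` list: id, S (metabolites x reactions
#'   stoichiometric matrix over non-boundary metabolites), lb, ub (named by
#'   reaction), gpr (named character), reactions, metabolites, genes.
#' @export
read_model <- function(x) {
  mod <- if (is.character(x)) jsonlite::read_json(x, simplifyVector = FALSE) else x
  mets <- vapply(mod$metabolites, function(m) m$id, "")
  boundary <- vapply(mod$metabolites, function(m) isTRUE(m$boundary), FALSE)
  rxns <- vapply(mod$reactions, function(r) r$id, "")
  lb <- vapply(mod$reactions, function(r) as.numeric(r$lb), 0)
  ub <- vapply(mod$reactions, function(r) as.numeric(r$ub), 0)
  if (any(lb > ub)) {
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(rxns[lb > ub], collapse = ", "))
  }
  gpr <- vapply(mod$reactions, function(r) {
    if (is.null(r$gpr)) "" else as.character(r$gpr)
  }, "")
  internal <- mets[!boundary]
  S <- matrix(0, length(internal), length(rxns),
              dimnames = list(internal, rxns))
  for (k in seq_along(mod$reactions)) {
    st <- mod$reactions[[k]]$metabolites
    for (m in names(st)) {
      if (!m %in% mets) {
        stop("reaction ", rxns[k], " references unknown metabolite ", m)
      }
      if (m %in% internal) S[m, k] <- as.numeric(st[[m]])
    }
  }
  genes <- sort(unique(unlist(lapply(gpr, .gpr_genes))))
  structure(list(id = if (is.null(mod$id)) "model" else mod$id,
                 S = S, lb = stats::setNames(lb, rxns),
                 ub = stats::setNames(ub, rxns),
                 gpr = stats::setNames(gpr, rxns),
                 reactions = rxns, metabolites = mets,
                 boundary = stats::setNames(boundary, mets), genes = genes),
            class = "MetabolicModel")
}

# gene tokens of a GPR string
.gpr_genes <- function(gpr) {
  if (is.na(gpr) || gpr == "") return(character())
  toks <- regmatches(gpr, gregexpr("[A-Za-z_][A-Za-z0-9_.]*", gpr))[[1L]]
  setdiff(toks, c("and", "or", "AND", "OR"))
}

# evaluate a GPR boolean rule given a set of knocked-out genes
.gpr_eval <- function(gpr, knocked) {
  if (is.na(gpr) || gpr == "") return(TRUE)
  genes <- .gpr_genes(gpr)
  expr <- gsub("\\band\\b", "&", gpr, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "|", expr, ignore.case = TRUE)
  env <- new.env(parent = baseenv())
  for (g in genes) assign(g, !(g %in% knocked), envir = env)
  isTRUE(eval(parse(text = expr), envir = env))
}

#' Flux variability analysis
#'
#' For each reaction, solves the LPs maximising and minimising its flux
#' subject to the steady-state constraint `S v = 0` and the bounds.
#'
#' @param model a `MetabolicModel`.
#' @return `FluxRange` data.frame with columns reaction, min, max
#'   (mol/day).
#' @export
run_fva <- function(model) {
  n <- length(model$reactions)
  out <- data.frame(reaction = model$reactions, min = NA_real_,
                    max = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    cvec <- numeric(n); cvec[k] <- 1
    mx <- .solve_bounded_lp(cvec, model$S, model$lb, model$ub, maximize = TRUE)
    mn <- .solve_bounded_lp(cvec, model$S, model$lb, model$ub, maximize = FALSE)
    if (mx$status != "optimal" || mn$status != "optimal") {
      stop("model infeasible when optimising reaction ", model$reactions[k])
    }
    out$max[k] <- mx$objective
    out$min[k] <- mn$objective
  }
  # clamp quadrature-level LP noise
  out$min <- ifelse(abs(out$min) < 1e-9, 0, out$min)
  out$max <- ifelse(abs(out$max) < 1e-9, 0, out$max)
  out
}

#' Simulate a gene knockout
#'
#' Reactions whose GPR rule evaluates to FALSE once the gene is removed get
#' bounds (0, 0); all other reactions are untouched.
#'
#' @param model a `MetabolicModel`.
#' @param gene gene id(s) appearing in at least one GPR rule; a vector
#'   simulates a combined knockout.
#' @return the knocked-out `MetabolicModel`, with attribute
#'   `disabled_reactions` listing the closed reactions.
#' @export
knockout <- function(model, gene) {
  if (!all(gene %in% model$genes)) {
    stop("unknown gene: ", paste(setdiff(gene, model$genes), collapse = ", "))
  }
  closed <- vapply(model$reactions, function(r) {
    !.gpr_eval(model$gpr[[r]], knocked = gene)
  }, FALSE)
  m2 <- model
  m2$lb[closed] <- 0
  m2$ub[closed] <- 0
  attr(m2, "disabled_reactions") <- model$reactions[closed]
  m2
}

#' Quantify the effect of a knockout on flux ranges
#'
#' A reaction is affected when its knockout flux magnitude drops below half
#' (configurable) of its wild-type magnitude; reactions blocked in the wild
#' type, and reactions directly disabled by the knockout's GPR evaluation,
#' are excluded. A reaction is blocked when both extreme fluxes are below
#' 1e-6 mol/day in absolute value.
#'
#' @param wild,ko `FluxRange` data.frames over the same reactions.
#' @param disabled reaction ids directly closed by the knockout (excluded
#'   from the affected set; see [knockout()]).
#' @param affected_threshold fractional flux reduction counted as affected
#'   (default 0.5, i.e. reduced by more than 50 percent).
#' @param blocked_threshold absolute flux below which a reaction is blocked
#'   (default 1e-6 mol/day).
#' @param quantity which FVA quantity the reduction criterion compares:
#'   `"max_abs"` (default; the larger of |min| and |max|), `"min_abs"` (the
#'   smaller), or `"span"` (max - min).
#' @return `KnockoutEffect` list: affected (reaction ids), blocked,
#'   disabled, any_affected.
#' @export
knockout_effect <- function(wild, ko, disabled = character(),
                            affected_threshold = 0.5,
                            blocked_threshold = 1e-6,
                            quantity = c("max_abs", "min_abs", "span")) {
  quantity <- match.arg(quantity)
  if (!identical(wild$reaction, ko$reaction)) {
    stop("wild-type and knockout flux ranges cover different reactions")
  }
  qf <- switch(quantity,
               max_abs = function(r) pmax(abs(r$min), abs(r$max)),
               min_abs = function(r) pmin(abs(r$min), abs(r$max)),
               span = function(r) r$max - r$min)
  qw <- qf(wild); qk <- qf(ko)
  wild_blocked <- pmax(abs(wild$min), abs(wild$max)) < blocked_threshold
  evaluable <- !wild_blocked & !(wild$reaction %in% disabled)
  affected <- wild$reaction[evaluable &
                              qk < (1 - affected_threshold) * qw]
  blocked <- ko$reaction[abs(ko$min) < blocked_threshold &
                           abs(ko$max) < blocked_threshold]
  structure(list(affected = affected, blocked = blocked,
                 disabled = disabled,
                 any_affected = length(affected) > 0L),
            class = "KnockoutEffect")
}

#' Per-gene knockout summary for a model
#'
#' Runs wild-type FVA once, then for each gene the knockout FVA and the
#' affected/blocked criteria.
#'
#' @param model a `MetabolicModel`.
#' @param genes genes to knock out (default: all genes in the model).
#' @param ... passed to [knockout_effect()].
#' @return data.frame with gene, n_affected, n_blocked, any_affected.
#' @export
knockout_screen <- function(model, genes = model$genes, ...) {
  wild <- run_fva(model)
  rows <- lapply(genes, function(g) {
    kom <- knockout(model, g)
    eff <- knockout_effect(wild, run_fva(kom),
                           disabled = attr(kom, "disabled_reactions"), ...)
    data.frame(gene = g, n_affected = length(eff$affected),
               n_blocked = length(eff$blocked),
               any_affected = eff$any_affected, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
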