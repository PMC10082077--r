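#' Construct a stoichiometric metabolic model
#'
#' A lightweight constraint-based model: a stoichiometric matrix with flux
#' bounds, boolean gene-association (GPR) rules per reaction, and a biomass
#' objective. Fluxes are in mmol per gram dry weight per hour; the objective
#' flux is interpreted as the specific growth rate (1/h).
#'
#' @param S numeric matrix, metabolites (rows) by reactions (columns);
#'   dimnames are required and become the metabolite/reaction ids.
#' @param lb,ub numeric vectors of lower/upper flux bounds per reaction.
#' @param gpr character vector of gene-association expressions per reaction
#'   (boolean expressions over gene ids with `and`/`or`; `""` = no gene).
#' @param objective id of the objective (biomass) reaction.
#' @param genes character vector of gene ids; defaults to the genes named in
#'   `gpr`.
#' @param exchanges optional named list tagging special exchange reactions,
#'   e.g. `list(glucose_uptake = "GLC_upt", ethanol_uptake = "ETH_upt",
#'   ethanol_secretion = "ETH_sec")`; used by the dynamic FBA driver.
#' @param uptake_kinetics optional named list of Michaelis-Menten parameters
#'   (`vmax_glc`, `km_glc`, `vmax_eth`, `km_eth`) used by [run_dfba()].
#' @return an object of class `stoich_model`.
#' @export
stoichiometric_model <- function(S, lb, ub, gpr, objective, genes = NULL,
                                 exchanges = list(), uptake_kinetics = list()) {
  S <- as.matrix(S)
  if (is.null(rownames(S)) || is.null(colnames(S))) {
    stop("S must have metabolite rownames and reaction colnames")
  }
  n <- ncol(S)
  if (length(lb) != n || length(ub) != n || length(gpr) != n) {
    stop("lb, ub and gpr must have one entry per reaction")
  }
  if (any(lb > ub)) stop("every lower bound must be <= its upper bound")
  if (!objective %in% colnames(S)) {
    stop("objective reaction not found in the model: ", objective)
  }
  rule_genes <- unique(unlist(lapply(gpr, gpr_genes)))
  if (is.null(genes)) genes <- rule_genes
  if (!all(rule_genes %in% genes)) {
    stop("gene(s) used in GPR rules but missing from the gene list: ",
         paste(setdiff(rule_genes, genes), collapse = ", "))
  }
  structure(list(
    S = S,
    metabolites = rownames(S),
    reactions = colnames(S),
    lb = stats::setNames(as.numeric(lb), colnames(S)),
    ub = stats::setNames(as.numeric(ub), colnames(S)),
    gpr = stats::setNames(as.character(gpr), colnames(S)),
    genes = genes,
    objective = objective,
    exchanges = exchanges,
    uptake_kinetics = uptake_kinetics
  ), class = "stoich_model")
}

#' @export
print.stoich_model <- function(x, ...) {
  cat(sprintf("stoich_model: %d metabolites x %d reactions, %d genes\n",
              nrow(x$S), ncol(x$S), length(x$genes)))
  cat("objective:", x$objective, "\n")
  invisible(x)
}

# gene ids appearing in a GPR expression
gpr_genes <- function(expr) {
  if (is.na(expr) || !nzchar(expr)) return(character())
  toks <- regmatches(expr, gregexpr("[A-Za-z0-9_.-]+", expr))[[1]]
  setdiff(toks, c("and", "or", "AND", "OR"))
}

# Evaluate a GPR boolean expression with the given genes knocked out.
# Returns TRUE when the reaction stays available.
gpr_eval <- function(expr, knockouts = character()) {
  if (is.na(expr) || !nzchar(expr)) return(TRUE)
  genes <- gpr_genes(expr)
  e <- gsub("\\band\\b", "&", expr, ignore.case = TRUE)
  e <- gsub("\\bor\\b", "|", e, ignore.case = TRUE)
  env <- new.env(parent = baseenv())
  for (g in genes) assign(g, !(g %in% knockouts), envir = env)
  # gene ids may contain characters invalid in R symbols; quote them
  for (g in genes) {
    if (make.names(g) != g) {
      e <- gsub(g, sprintf("`%s`", g), e, fixed = TRUE)
    }
  }
  isTRUE(eval(parse(text = e), envir = env))
}

#' Construct a phase-conditioned regulatory rule set
#'
#' Each rule attributes a phase-specific constraint on a reaction to a
#' regulator gene. A rule fires in its phase when its gene is knocked out:
#' the gene is a required activator of the reaction in that phase. Rules with
#' the sentinel gene `"-"` are unconditional and fire in their phase for every
#' strain (wild type included); these encode constitutive phase regulation
#' such as glucose repression of respiratory reactions before the shift.
#'
#' @param rules data.frame with columns `gene`, `phase` (`"pre"`/`"post"`),
#'   `reaction`, `action` (`"disable"` or `"scale-bound"`), and optionally
#'   `factor` (bound multiplier for `scale-bound`, default 0.5).
#' @param model_label label for the model variant (e.g. `"M1"`).
#' @param model optional `stoich_model` to validate reaction/gene references
#'   against.
#' @return object of class `regulatory_rules` (a data.frame).
#' @export
regulatory_rules <- function(rules, model_label = "M1", model = NULL) {
  need <- c("gene", "phase", "reaction", "action")
  if (!all(need %in% names(rules))) {
    stop("rules must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(rules$factor)) rules$factor <- 0.5
  if (!all(rules$phase %in% c("pre", "post"))) {
    stop("rule phases must be 'pre' or 'post'")
  }
  if (!all(rules$action %in% c("disable", "scale-bound"))) {
    stop("rule actions must be 'disable' or 'scale-bound'")
  }
  if (!is.null(model)) {
    bad <- setdiff(rules$reaction, model$reactions)
    if (length(bad)) stop("rules reference unknown reactions: ",
                          paste(bad, collapse = ", "))
  }
  rules <- rules[, c("gene", "phase", "reaction", "action", "factor")]
  structure(rules, class = c("regulatory_rules", "data.frame"),
            model_label = model_label)
}

#' Genes named in a regulatory rule set (excluding the unconditional sentinel)
#' @param rules a `regulatory_rules` object.
#' @return character vector of regulator gene ids.
#' @export
rule_genes <- function(rules) setdiff(unique(rules$gene), "-")

# Apply GPR knockouts and phase-matched regulatory rules to the bounds.
constrained_bounds <- function(model, rules = NULL, knockout = NULL,
                               phase = c("pre", "post")) {
  phase <- match.arg(phase)
  lb <- model$lb
  ub <- model$ub
  if (!is.null(knockout)) {
    if (length(knockout) == 1 && (is.na(knockout) || !nzchar(knockout))) {
      knockout <- NULL
    }
  }
  if (!is.null(knockout)) {
    for (j in seq_along(model$reactions)) {
      if (!gpr_eval(model$gpr[[j]], knockout)) {
        lb[j] <- 0
        ub[j] <- 0
      }
    }
  }
  if (!is.null(rules) && nrow(rules)) {
    fires <- rules$phase == phase &
      (rules$gene == "-" | rules$gene %in% (knockout %||% character()))
    for (i in which(fires)) {
      r <- rules$reaction[i]
      if (rules$action[i] == "disable") {
        lb[r] <- 0
        ub[r] <- 0
      } else {
        lb[r] <- lb[r] * rules$factor[i]
        ub[r] <- ub[r] * rules$factor[i]
      }
    }
  }
  list(lb = lb, ub = ub)
}
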