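# Constraint patches: per-reaction bound overrides with provenance.
#
# Sign convention (used throughout the package): exchange fluxes are negative
# for uptake and positive for secretion.  A kinetic "upper bound" on uptake
# therefore bounds |v| and is applied to the LOWER bound of the exchange flux.

#' Construct a constraint patch
#'
#' @param reaction character vector of reaction ids.
#' @param lb,ub numeric vectors of new bounds (`NA` = leave unchanged).
#' @param provenance one of `"fixed"`, `"dynamic"`, `"genetic"`.
#' @return object of class `constraint_patch` (a data.frame).
#' @export
constraint_patch <- function(reaction = character(0), lb = numeric(0),
                             ub = numeric(0), provenance = "fixed") {
  stopifnot(provenance %in% c("fixed", "dynamic", "genetic"))
  df <- data.frame(reaction = as.character(reaction), lb = as.numeric(lb),
                   ub = as.numeric(ub),
                   provenance = rep_len(provenance, length(reaction)),
                   stringsAsFactors = FALSE)
  bad <- !is.na(df$lb) & !is.na(df$ub) & df$lb > df$ub
  if (any(bad))
    stop_dynafba("dynafba_bound_error", "patch with lb > ub for: ",
                 paste(df$reaction[bad], collapse = ", "))
  structure(df, class = c("constraint_patch", "data.frame"))
}

#' @export
print.constraint_patch <- function(x, ...) {
  cat("constraint_patch (", nrow(x), " overrides, provenance: ",
      paste(unique(x$provenance), collapse = "/"), ")\n", sep = "")
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

#' Effective bounds after applying patches
#'
#' Patches are applied in order, later entries overriding earlier ones,
#' except that genetic zero-bounds are re-asserted last: a knocked-out
#' reaction can never be re-opened by a dynamic patch.
#'
#' @param model a `metabolic_model`.
#' @param patches list of `constraint_patch` objects.
#' @return data.frame(reaction, lb, ub).
#' @export
effective_bounds <- function(model, patches = list()) {
  if (inherits(patches, "constraint_patch")) patches <- list(patches)
  lb <- setNames(model$reactions$lb, model$reactions$id)
  ub <- setNames(model$reactions$ub, model$reactions$id)
  apply_one <- function(p) {
    unknown <- setdiff(p$reaction, names(lb))
    if (length(unknown))
      stop_dynafba("dynafba_unknown_reaction", "patch names unknown reaction(s): ",
                   paste(unknown, collapse = ", "))
    sel <- !is.na(p$lb); lb[p$reaction[sel]] <<- p$lb[sel]
    sel <- !is.na(p$ub); ub[p$reaction[sel]] <<- p$ub[sel]
  }
  for (p in patches) apply_one(p)
  for (p in patches) if (any(p$provenance == "genetic")) {
    g <- p[p$provenance == "genetic", , drop = FALSE]
    apply_one(g)
  }
  data.frame(reaction = names(lb), lb = unname(lb), ub = unname(ub),
             stringsAsFactors = FALSE)
}

#' Anaerobic fixed-constraint set
#'
#' Builds the constraint patch describing anaerobic batch conditions:
#' oxygen uptake closed, the TCA cycle broken into its oxidative and
#' reductive branches (succinate dehydrogenase / succinyl-CoA ligase level),
#' quinone-mediated NADH/FADH2 reoxidation turned off, and sterol, phosphate
#' and sulphate supply treated as non-limiting.  Reactions are located
#' through their tags, so the patch works on any model that declares them.
#' The individual constraints can be toggled for ablation studies.
#'
#' @param model a `metabolic_model`.
#' @param oxygen_off close oxygen uptake (`TRUE` for anaerobiosis).
#' @param split_tca zero the reactions tagged `tca_oxidative_break`.
#' @param quinones_off zero the reactions tagged `quinone`.
#' @param sterols_unlimited relax sterol-uptake exchange bounds; if `FALSE`
#'   the model's own (limiting) bounds stay in force.
#' @param inorganics_unlimited relax phosphate and sulphate exchanges.
#' @return a `constraint_patch` with provenance `"fixed"`.
#' @export
anaerobic_constraints <- function(model, oxygen_off = TRUE, split_tca = TRUE,
                                  quinones_off = TRUE, sterols_unlimited = TRUE,
                                  inorganics_unlimited = TRUE) {
  rxn <- character(0); lb <- numeric(0); ub <- numeric(0)
  zero_out <- function(ids) {
    blb <- model$reactions$lb[match(ids, model$reactions$id)]
    if (any(blb > 0))
      stop_dynafba("dynafba_bound_error",
                   "cannot zero reaction(s) with pre-existing lb > 0: ",
                   paste(ids[blb > 0], collapse = ", "))
    rxn <<- c(rxn, ids); lb <<- c(lb, rep(0, length(ids))); ub <<- c(ub, rep(0, length(ids)))
  }
  if (oxygen_off) {
    o2 <- reactions_with_tag(model, "oxygen_uptake")
    if (!length(o2)) warning("no reaction tagged oxygen_uptake; model may already be anaerobic")
    zero_out(o2)
  }
  if (split_tca) zero_out(reactions_with_tag(model, "tca_oxidative_break"))
  if (quinones_off) zero_out(reactions_with_tag(model, "quinone"))
  if (sterols_unlimited) {
    st <- reactions_with_tag(model, "sterol_uptake")
    rxn <- c(rxn, st); lb <- c(lb, rep(-Inf, length(st))); ub <- c(ub, rep(Inf, length(st)))
  }
  if (inorganics_unlimited) {
    inorg <- model$exchange_map$reaction[
      grepl("^(PI|PO4|PHO|SO4|SLF|SULF)", model$exchange_map$species, ignore.case = TRUE)]
    rxn <- c(rxn, inorg); lb <- c(lb, rep(-Inf, length(inorg))); ub <- c(ub, rep(Inf, length(inorg)))
  }
  constraint_patch(rxn, lb, ub, provenance = "fixed")
}

#' Describe a genetic modification
#'
#' @param target gene id or reaction id.
#' @param kind `"deletion"`, `"insertion"`, `"overexpression"` or
#'   `"downregulation"`.
#' @param factor bound multiplier for over/under-expression (> 1 for
#'   overexpression, in (0,1) for downregulation; published overexpression
#'   levels are rarely stated, so the default is 10).
#' @param added_reaction for insertions: a one-row reaction description,
#'   `list(id, name, stoichiometry, lb, ub, genes, tags)`.
#' @return object of class `genetic_modification`.
#' @export
genetic_modification <- function(target, kind = c("deletion", "insertion",
                                                  "overexpression", "downregulation"),
                                 factor = NULL, added_reaction = NULL) {
  kind <- match.arg(kind)
  if (kind == "overexpression") {
    factor <- factor %||% 10
    if (factor <= 1) stop_dynafba("dynafba_mod_error", "overexpression needs factor > 1")
  }
  if (kind == "downregulation") {
    if (is.null(factor) || factor <= 0 || factor >= 1)
      stop_dynafba("dynafba_mod_error", "downregulation needs 0 < factor < 1")
  }
  if (kind == "insertion" && is.null(added_reaction))
    stop_dynafba("dynafba_mod_error", "insertion requires added_reaction")
  structure(list(target = target, kind = kind, factor = factor,
                 added_reaction = added_reaction),
            class = "genetic_modification")
}

#' Read genetic modifications from a JSON file
#'
#' Expects an array of objects like
#' `[{"target": "GPD1", "kind": "deletion"}]`; insertions carry an
#' `added_reaction` object with `id`, `equation`, `lb`, `ub` fields.
#'
#' @param path JSON file path.
#' @return list of `genetic_modification` objects.
#' @export
read_modifications <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(m) {
    ar <- m$added_reaction
    if (!is.null(ar)) {
      ar <- list(id = ar$id, name = ar$name %||% ar$id,
                 stoichiometry = parse_equation(ar$equation),
                 lb = as.numeric(ar$lb %||% 0), ub = as.numeric(ar$ub %||% Inf),
                 genes = ar$genes %||% "", tags = ar$tags %||% "")
    }
    genetic_modification(m$target, m$kind, factor = m$factor, added_reaction = ar)
  })
}

# Evaluate a boolean gene rule with the given genes deleted.  Reactions with
# no rule are untouched by gene-level deletions.
eval_gene_rule <- function(rule, deleted) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(TRUE)
  toks <- regmatches(rule, gregexpr("[A-Za-z0-9_.-]+|\\(|\\)", rule))[[1]]
  expr <- vapply(toks, function(tk) {
    if (tk %in% c("and", "AND", "&", "&&")) "&&"
    else if (tk %in% c("or", "OR", "|", "||")) "||"
    else if (tk %in% c("(", ")")) tk
    else if (tk %in% deleted) "FALSE" else "TRUE"
  }, character(1))
  eval(parse(text = paste(expr, collapse = " ")), envir = baseenv())
}

#' Apply genetic modifications
#'
#' Deletions zero all reactions whose gene rule evaluates false with the
#' deleted genes removed (multiple deletions are evaluated jointly, so
#' isoenzyme pairs behave correctly), or the named reaction directly.
#' Over/under-expression scales the upper bound (and the magnitude of a
#' negative lower bound) by `factor`.  Insertions extend the model with the
#' new reaction and re-validate it.  The returned patch has provenance
#' `"genetic"` and is enforced for the whole fermentation.
#'
#' @param model a `metabolic_model`.
#' @param mods list of [genetic_modification()] objects.
#' @return list with elements `model` (possibly extended) and `patch`
#'   (a `constraint_patch`).
#' @export
genetic_modifications <- function(model, mods) {
  if (inherits(mods, "genetic_modification")) mods <- list(mods)
  biomass_rxn <- reactions_with_tag(model, "biomass")
  all_genes <- unique(unlist(regmatches(model$reactions$genes,
    gregexpr("[A-Za-z0-9_.-]+", model$reactions$genes))))
  all_genes <- setdiff(all_genes, c("and", "or", "AND", "OR"))

  # insertions first so later bound edits can refer to the new reaction
  for (m in mods) {
    if (m$kind != "insertion") next
    ar <- m$added_reaction
    mets2 <- model$metabolites
    rxns2 <- rbind(model$reactions,
                   data.frame(id = ar$id, name = ar$name %||% ar$id,
                              lb = ar$lb %||% 0, ub = ar$ub %||% Inf,
                              genes = ar$genes %||% "", tags = ar$tags %||% "",
                              stringsAsFactors = FALSE))
    sto2 <- model$stoich
    sto2[[ar$id]] <- ar$stoichiometry
    model <- metabolic_model(mets2, rxns2, sto2)
  }

  deleted_genes <- character(0)
  direct_rxns <- character(0)
  scale <- list()
  for (m in mods) {
    if (m$kind == "insertion") next
    is_rxn <- m$target %in% model$reactions$id
    is_gene <- m$target %in% all_genes
    if (!is_rxn && !is_gene)
      stop_dynafba("dynafba_unknown_target", "unknown modification target '", m$target,
                   "'; known reactions: ", paste(utils::head(model$reactions$id, 8), collapse = ", "),
                   ", ...; known genes: ", paste(utils::head(sort(all_genes), 8), collapse = ", "), ", ...")
    if (m$kind == "deletion") {
      if (is_rxn) direct_rxns <- c(direct_rxns, m$target)
      else deleted_genes <- c(deleted_genes, m$target)
    } else {
      targets <- if (is_rxn) m$target else
        model$reactions$id[vapply(model$reactions$genes, function(g)
          nzchar(trimws(g)) && grepl(paste0("\\b", m$target, "\\b"), g), logical(1))]
      for (r in targets) scale[[r]] <- m$factor
    }
  }
  if (length(deleted_genes)) {
    hit <- model$reactions$id[!vapply(model$reactions$genes, eval_gene_rule,
                                      logical(1), deleted = deleted_genes)]
    direct_rxns <- union(direct_rxns, hit)
  }
  if (length(intersect(direct_rxns, biomass_rxn)))
    stop_dynafba("dynafba_mod_error", "modification would delete the biomass reaction")

  rxn <- character(0); lb <- numeric(0); ub <- numeric(0)
  if (length(direct_rxns)) {
    rxn <- direct_rxns; lb <- rep(0, length(rxn)); ub <- rep(0, length(rxn))
  }
  for (r in names(scale)) {
    i <- match(r, model$reactions$id)
    f <- scale[[r]]
    rxn <- c(rxn, r)
    lb <- c(lb, if (model$reactions$lb[i] < 0) -f * abs(model$reactions$lb[i]) else model$reactions$lb[i])
    ub <- c(ub, f * model$reactions$ub[i])
  }
  list(model = model, patch = constraint_patch(rxn, lb, ub, provenance = "genetic"))
}
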