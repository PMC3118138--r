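# Stoichiometric model container, TSV/SBML readers and writers, validation.
#
# A metabolic_model is a list with
#   metabolites : data.frame(id, name, compartment, formula, mw,
#                            is_extracellular, n_content)
#   reactions   : data.frame(id, name, lb, ub, genes, tags)
#   stoich      : named list; stoich[[rxn]] is a named coefficient vector
#   exchange_map: data.frame(species, reaction) - one exchange per
#                 extracellular species
# mw is in g/mmol; n_content in mg N/mmol (14 per nitrogen atom).

KNOWN_TAGS <- c("oxygen_uptake", "tca_oxidative_break", "quinone",
                "sterol_uptake", "maintenance_atp", "biomass", "exchange",
                "hexose_uptake", "nitrogen_uptake")

#' Construct a metabolic model
#'
#' Low-level constructor; most users will call [load_model()] or
#' [make_toy_network()] instead.  Validates referential integrity, detects
#' exchange reactions (single-metabolite boundary reactions) and builds the
#' exchange map.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula`, `mw` (g/mmol), `is_extracellular`.
#' @param reactions data.frame with columns `id`, `name`, `lb`, `ub`
#'   (mmol/gDW/h), `genes` (boolean rule string or `""`), `tags`
#'   (comma-separated labels).
#' @param stoich named list of named numeric vectors, one per reaction id.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoich) {
  metabolites$id <- as.character(metabolites$id)
  reactions$id <- as.character(reactions$id)
  if (anyDuplicated(metabolites$id))
    stop_dynafba("dynafba_duplicate_id", "duplicate metabolite id: ",
                 paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (anyDuplicated(reactions$id))
    stop_dynafba("dynafba_duplicate_id", "duplicate reaction id: ",
                 paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  if (!setequal(names(stoich), reactions$id))
    stop_dynafba("dynafba_model_error", "stoichiometry list does not match reaction table")
  for (r in reactions$id) {
    sto <- stoich[[r]]
    if (!length(sto))
      stop_dynafba("dynafba_model_error", "reaction with empty stoichiometry: ", r)
    unknown <- setdiff(names(sto), metabolites$id)
    if (length(unknown))
      stop_dynafba("dynafba_unknown_metabolite", "reaction ", r,
                   " references unknown metabolite(s): ", paste(unknown, collapse = ", "))
  }
  bad <- reactions$id[reactions$lb > reactions$ub]
  if (length(bad))
    stop_dynafba("dynafba_bound_error", "lb > ub for reaction(s): ", paste(bad, collapse = ", "))

  if (is.null(metabolites$n_content)) {
    metabolites$n_content <- vapply(metabolites$formula, function(f)
      14 * element_count(f, "N"), numeric(1))
  }
  mwp <- metabolites$mw[!is.na(metabolites$mw)]
  if (any(mwp <= 0))
    stop_dynafba("dynafba_model_error", "molecular weights must be positive")

  for (tg in c("maintenance_atp", "biomass")) {
    hits <- reactions$id[reaction_has_tag(reactions$tags, tg)]
    if (length(hits) > 1L)
      stop_dynafba("dynafba_model_error", "more than one reaction tagged ", tg, ": ",
                   paste(hits, collapse = ", "))
  }

  m <- structure(list(metabolites = metabolites, reactions = reactions,
                      stoich = stoich), class = "metabolic_model")
  m$exchange_map <- detect_exchanges(m)
  ex_ids <- m$exchange_map$reaction
  # make sure detected exchanges carry the exchange tag
  i <- match(ex_ids, m$reactions$id)
  m$reactions$tags[i] <- vapply(m$reactions$tags[i], function(t) {
    tt <- split_tags(t)
    paste(union(tt, "exchange"), collapse = ",")
  }, character(1))
  no_mw <- m$exchange_map$species[is.na(metabolites$mw[match(m$exchange_map$species, metabolites$id)])]
  if (length(no_mw))
    stop_dynafba("dynafba_model_error",
                 "extracellular species without molecular weight: ",
                 paste(no_mw, collapse = ", "))
  m
}

split_tags <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, "[,;]")[[1]])
}

reaction_has_tag <- function(tags, tag) {
  vapply(tags, function(t) tag %in% split_tags(t), logical(1), USE.NAMES = FALSE)
}

#' Reaction ids carrying a tag
#' @param model a `metabolic_model`.
#' @param tag one of the recognised tag labels.
#' @return character vector of reaction ids.
#' @export
reactions_with_tag <- function(model, tag) {
  model$reactions$id[reaction_has_tag(model$reactions$tags, tag)]
}

# single-metabolite reactions on extracellular species cross the boundary
detect_exchanges <- function(model) {
  sp <- character(0); rx <- character(0)
  for (r in model$reactions$id) {
    sto <- model$stoich[[r]]
    if (length(sto) != 1L) next
    met <- names(sto)
    i <- match(met, model$metabolites$id)
    if (isTRUE(model$metabolites$is_extracellular[i])) { sp <- c(sp, met); rx <- c(rx, r) }
  }
  if (anyDuplicated(sp))
    stop_dynafba("dynafba_model_error", "species with more than one exchange reaction: ",
                 paste(unique(sp[duplicated(sp)]), collapse = ", "))
  data.frame(species = sp, reaction = rx, stringsAsFactors = FALSE)
}

#' Stoichiometric matrix
#'
#' @param model a `metabolic_model`.
#' @return dense matrix, metabolites in rows, reactions in columns.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (r in model$reactions$id) {
    sto <- model$stoich[[r]]
    S[names(sto), r] <- sto
  }
  S
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions,", nrow(x$exchange_map), "exchanges\n")
  invisible(x)
}

#' Load a metabolic model from file
#'
#' Reads either the package's tab-separated model dialect (a `# metabolites`
#' block and a `# reactions` block, reaction equations written as
#' `"a A + b B -> c C"`, `<->` marking reversibility) or an SBML Level 3
#' core file.
#'
#' @param path file path.
#' @param format `"tsv"`, `"sbml"`, or `"auto"` (sniffed from the extension
#'   and file head).
#' @return a `metabolic_model`.
#' @export
load_model <- function(path, format = c("auto", "tsv", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_dynafba("dynafba_io_error", "model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else {
      head1 <- readLines(path, n = 1L, warn = FALSE)
      if (grepl("<\\?xml|<sbml", head1)) "sbml" else "tsv"
    }
  }
  if (format == "tsv") read_model_tsv(path) else read_model_sbml(path)
}

read_model_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  met_at <- grep("^#\\s*metabolites", lines, ignore.case = TRUE)
  rxn_at <- grep("^#\\s*reactions", lines, ignore.case = TRUE)
  if (length(met_at) != 1L || length(rxn_at) != 1L || met_at >= rxn_at)
    stop_dynafba("dynafba_parse_error",
                 "model TSV needs one '# metabolites' block followed by one '# reactions' block")
  parse_block <- function(block) {
    block <- block[nzchar(trimws(block)) & !grepl("^#", block)]
    if (length(block) < 2L)
      stop_dynafba("dynafba_parse_error", "empty block in model TSV")
    read.delim(text = paste(block, collapse = "\n"), stringsAsFactors = FALSE,
               na.strings = c("NA", ""))
  }
  mets <- parse_block(lines[(met_at + 1L):(rxn_at - 1L)])
  rxns <- parse_block(lines[(rxn_at + 1L):length(lines)])
  need_m <- c("id", "name", "compartment", "formula", "mw", "extracellular")
  need_r <- c("reaction_id", "name", "equation", "lb", "ub", "genes", "tags")
  if (!all(need_m %in% names(mets)))
    stop_dynafba("dynafba_parse_error", "metabolite block must have columns: ",
                 paste(need_m, collapse = ", "))
  if (!all(need_r %in% names(rxns)))
    stop_dynafba("dynafba_parse_error", "reaction block must have columns: ",
                 paste(need_r, collapse = ", "))
  metabolites <- data.frame(
    id = as.character(mets$id), name = as.character(mets$name),
    compartment = as.character(mets$compartment),
    formula = as.character(mets$formula),
    mw = suppressWarnings(as.numeric(mets$mw)),
    is_extracellular = mets$extracellular %in% c(1, "1", TRUE, "TRUE", "yes"),
    stringsAsFactors = FALSE)
  stoich <- lapply(rxns$equation, parse_equation)
  names(stoich) <- rxns$reaction_id
  reactions <- data.frame(
    id = as.character(rxns$reaction_id), name = as.character(rxns$name),
    lb = parse_bound(rxns$lb), ub = parse_bound(rxns$ub),
    genes = ifelse(is.na(rxns$genes), "", as.character(rxns$genes)),
    tags = ifelse(is.na(rxns$tags), "", as.character(rxns$tags)),
    stringsAsFactors = FALSE)
  metabolic_model(metabolites, reactions, stoich)
}

parse_bound <- function(x) {
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  out[x %in% c("inf", "Inf", "+inf")] <- Inf
  out[x %in% c("-inf", "-Inf")] <- -Inf
  if (anyNA(out)) stop_dynafba("dynafba_parse_error", "unreadable bound value")
  out
}

# "a A + b B -> c C" / "<->"; empty side allowed for boundary reactions
parse_equation <- function(eq) {
  eq <- trimws(eq)
  arrow <- if (grepl("<->", eq, fixed = TRUE)) "<->" else if (grepl("->", eq, fixed = TRUE)) "->"
           else stop_dynafba("dynafba_parse_error", "equation without arrow: ", eq)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      toks <- strsplit(tm, "\\s+")[[1]]
      if (length(toks) == 1L) { coef <- 1; met <- toks }
      else if (length(toks) == 2L) { coef <- as.numeric(toks[1]); met <- toks[2] }
      else stop_dynafba("dynafba_parse_error", "unreadable term '", tm, "' in: ", eq)
      if (is.na(coef)) stop_dynafba("dynafba_parse_error", "bad coefficient in: ", eq)
      out[met] <- (if (met %in% names(out)) out[[met]] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  sto <- lhs
  for (m in names(rhs)) sto[m] <- (if (m %in% names(sto)) sto[[m]] else 0) + rhs[[m]]
  sto <- sto[sto != 0]
  if (!length(sto)) stop_dynafba("dynafba_parse_error", "equation cancels to nothing: ", eq)
  sto
}

format_equation <- function(sto, reversible) {
  fmt <- function(v) paste(vapply(names(v), function(m) {
    co <- abs(v[[m]])
    if (co == 1) m else paste(format(co, digits = 15, scientific = FALSE, trim = TRUE), m)
  }, character(1)), collapse = " + ")
  lhs <- fmt(sto[sto < 0]); rhs <- fmt(sto[sto > 0])
  paste(lhs, if (reversible) "<->" else "->", rhs)
}

#' Write a model in the TSV dialect
#'
#' Reloading the written file with [load_model()] reproduces the model's
#' ids, stoichiometry and bounds exactly.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  mets <- model$metabolites
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# dynafba model", con)
  writeLines("# metabolites", con)
  writeLines(paste(c("id", "name", "compartment", "formula", "mw", "extracellular"),
                   collapse = "\t"), con)
  for (i in seq_len(nrow(mets))) {
    writeLines(paste(c(mets$id[i], mets$name[i], mets$compartment[i],
                       mets$formula[i],
                       format(mets$mw[i], scientific = FALSE, trim = TRUE),
                       as.integer(mets$is_extracellular[i])), collapse = "\t"), con)
  }
  writeLines("# reactions", con)
  writeLines(paste(c("reaction_id", "name", "equation", "lb", "ub", "genes", "tags"),
                   collapse = "\t"), con)
  rx <- model$reactions
  for (i in seq_len(nrow(rx))) {
    rev <- rx$lb[i] < 0 && rx$ub[i] > 0
    writeLines(paste(c(rx$id[i], rx$name[i],
                       format_equation(model$stoich[[rx$id[i]]], rev),
                       format_bound(rx$lb[i]), format_bound(rx$ub[i]),
                       rx$genes[i], rx$tags[i]), collapse = "\t"), con)
  }
  invisible(path)
}

format_bound <- function(x) {
  if (is.infinite(x)) (if (x > 0) "inf" else "-inf")
  else format(x, scientific = FALSE, trim = TRUE)
}

# Minimal SBML Level 3 core reader (species, reactions, fbc bounds and
# formulas where present).  Covers the subset needed to import conventional
# constraint-based models; tags must then be added by the caller.
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp)) stop_dynafba("dynafba_parse_error", "SBML file has no species")
  sid <- xml2::xml_attr(sp, "id")
  comp <- xml2::xml_attr(sp, "compartment")
  formula <- xml2::xml_attr(sp, "chemicalFormula")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% c("true", "1")
  extra <- grepl("(^e$|_e$|extern|extracell)", comp, ignore.case = TRUE)
  mw <- vapply(formula, function(f) if (is.na(f)) NA_real_ else formula_weight(f), numeric(1))
  mets <- data.frame(id = sid, name = ifelse(is.na(xml2::xml_attr(sp, "name")), sid,
                                             xml2::xml_attr(sp, "name")),
                     compartment = comp, formula = formula, mw = unname(mw),
                     is_extracellular = extra & !boundary, stringsAsFactors = FALSE)

  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- setNames(as.numeric(xml2::xml_attr(pars, "value")), xml2::xml_attr(pars, "id"))

  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  ids <- xml2::xml_attr(rx, "id")
  stoich <- list(); lb <- ub <- numeric(length(rx)); genes <- character(length(rx))
  for (i in seq_along(rx)) {
    node <- rx[[i]]
    one_side <- function(xp, sign) {
      refs <- xml2::xml_find_all(node, xp)
      if (!length(refs)) return(setNames(numeric(0), character(0)))
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      setNames(sign * st, xml2::xml_attr(refs, "species"))
    }
    lhs <- one_side("./listOfReactants/speciesReference", -1)
    rhs <- one_side("./listOfProducts/speciesReference", +1)
    sto <- lhs
    for (m in names(rhs)) sto[m] <- (if (m %in% names(sto)) sto[[m]] else 0) + rhs[[m]]
    # drop boundary-condition species so boundary reactions become exchanges
    bnd <- sid[boundary]
    sto <- sto[!(names(sto) %in% bnd)]
    stoich[[ids[i]]] <- sto
    rev <- xml2::xml_attr(node, "reversible") %in% c("true", "1", NA)
    lbp <- xml2::xml_attr(node, "lowerFluxBound")
    ubp <- xml2::xml_attr(node, "upperFluxBound")
    lb[i] <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]] else if (rev) -Inf else 0
    ub[i] <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else Inf
    gpa <- xml2::xml_find_first(node, ".//geneProductAssociation")
    genes[i] <- if (inherits(gpa, "xml_missing")) "" else gene_rule_from_sbml(gpa)
  }
  reactions <- data.frame(id = ids,
                          name = ifelse(is.na(xml2::xml_attr(rx, "name")), ids,
                                        xml2::xml_attr(rx, "name")),
                          lb = lb, ub = ub, genes = genes, tags = "",
                          stringsAsFactors = FALSE)
  keep <- names(stoich)[vapply(stoich, length, integer(1)) > 0]
  reactions <- reactions[reactions$id %in% keep, , drop = FALSE]
  metabolic_model(mets, reactions, stoich[keep])
}

gene_rule_from_sbml <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") return(xml2::xml_attr(node, "geneProduct"))
  kids <- xml2::xml_children(node)
  inner <- vapply(kids, gene_rule_from_sbml, character(1))
  inner <- inner[nzchar(inner)]
  op <- switch(nm, "and" = " and ", "or" = " or ", " or ")
  if (nm == "geneProductAssociation") return(if (length(inner)) inner[[1]] else "")
  paste0("(", paste(inner, collapse = op), ")")
}

#' Elemental balance audit
#'
#' Checks that every non-exchange, non-biomass reaction conserves the given
#' elements exactly, using the metabolite formulas declared in the model.
#'
#' @param model a `metabolic_model`.
#' @param elements elements to audit.
#' @return data.frame of offending (reaction, element, imbalance) rows;
#'   zero rows means the model is balanced.
#' @export
elemental_audit <- function(model, elements = c("C", "H", "N", "O", "P", "S")) {
  skip <- union(model$exchange_map$reaction, reactions_with_tag(model, "biomass"))
  counts <- lapply(model$metabolites$formula, parse_formula)
  names(counts) <- model$metabolites$id
  out <- data.frame(reaction = character(0), element = character(0),
                    imbalance = numeric(0), stringsAsFactors = FALSE)
  for (r in setdiff(model$reactions$id, skip)) {
    sto <- model$stoich[[r]]
    for (el in elements) {
      bal <- sum(vapply(names(sto), function(m) {
        cnt <- counts[[m]]
        sto[[m]] * (if (el %in% names(cnt)) cnt[[el]] else 0)
      }, numeric(1)))
      if (abs(bal) > 1e-9)
        out <- rbind(out, data.frame(reaction = r, element = el, imbalance = bal,
                                     stringsAsFactors = FALSE))
    }
  }
  out
}
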