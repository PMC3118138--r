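# Flux balance core: LP assembly, objective handling, lexicographic solves.

#' Define an LP objective
#'
#' @param sense `"max"` or `"min"`.
#' @param reaction reaction id whose flux is optimised.
#' @return object of class `fba_objective`.
#' @export
fba_objective <- function(sense = c("max", "min"), reaction) {
  sense <- match.arg(sense)
  structure(list(sense = sense, reaction = reaction), class = "fba_objective")
}

# Backend contract: minimise c'x s.t. A x = b, l <= x <= u.  Infinite bounds
# are mapped onto +/-big.  Returns list(x, objective, status) with status in
# {"optimal", "infeasible", "unbounded", "failed"}.
solve_lp <- function(c_vec, A, b, lb, ub, big = BIG_BOUND) {
  if (any(lb > ub)) return(list(x = NULL, objective = NA_real_, status = "infeasible"))
  l <- pmax(lb, -big); u <- pmin(ub, big)
  res <- .simplex_cpp(A, b, c_vec, l, u)
  status <- switch(as.character(res$status), "0" = "optimal", "1" = "infeasible",
                   "2" = "unbounded", "failed")
  if (status != "optimal") return(list(x = NULL, objective = NA_real_, status = status))
  list(x = res$x, objective = res$objective, status = status)
}

# Assemble S (with optional per-patch biomass stoichiometry replacement) and
# effective bounds.
lp_ingredients <- function(model, patches) {
  if (inherits(patches, "constraint_patch")) patches <- list(patches)
  S <- stoich_matrix(model)
  for (p in patches) {
    bs <- attr(p, "biomass_stoich")
    if (!is.null(bs)) {
      br <- reactions_with_tag(model, "biomass")
      if (!length(br))
        stop_dynafba("dynafba_model_error", "patch carries a biomass equation but no reaction is tagged biomass")
      S[, br] <- 0
      S[names(bs), br] <- bs
    }
  }
  eb <- effective_bounds(model, patches)
  list(S = S, lb = setNames(eb$lb, eb$reaction), ub = setNames(eb$ub, eb$reaction))
}

#' Solve a flux balance problem
#'
#' Maximises or minimises one reaction's flux subject to the steady-state
#' constraint `S v = 0` and the composed bound patches.  Bound conflicts
#' (lb > ub) are reported as an infeasible status, not an error.
#'
#' @param model a `metabolic_model`.
#' @param patches list of `constraint_patch` objects (applied in order;
#'   genetic zeros are never relaxed by later patches).
#' @param objective an [fba_objective()].
#' @param big numeric stand-in for unbounded fluxes.
#' @return object of class `flux_distribution`: named flux vector `fluxes`
#'   (mmol/gDW/h), `objective_value`, `status`, and the steady-state
#'   residual `residual`.
#' @export
solve_fba <- function(model, patches = list(), objective, big = BIG_BOUND) {
  ing <- lp_ingredients(model, patches)
  n <- ncol(ing$S)
  j <- match(objective$reaction, colnames(ing$S))
  if (is.na(j))
    stop_dynafba("dynafba_unknown_reaction", "objective reaction not in model: ",
                 objective$reaction)
  c_vec <- numeric(n)
  c_vec[j] <- if (objective$sense == "max") -1 else 1
  res <- solve_lp(c_vec, ing$S, numeric(nrow(ing$S)), ing$lb, ing$ub, big)
  flux_distribution(res, colnames(ing$S), ing$S, objective,
                    obj_value = if (res$status == "optimal") res$x[j] else NA_real_)
}

flux_distribution <- function(res, rxn_ids, S, objective, obj_value) {
  v <- if (res$status == "optimal") setNames(res$x, rxn_ids) else
    setNames(rep(NA_real_, length(rxn_ids)), rxn_ids)
  structure(list(fluxes = v, objective_value = obj_value, status = res$status,
                 objective = objective,
                 residual = if (res$status == "optimal") max(abs(S %*% res$x)) else NA_real_),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("flux_distribution:", x$status)
  if (x$status == "optimal")
    cat(sprintf(", objective %s %s = %.6g", x$objective$sense,
                x$objective$reaction, x$objective_value))
  cat("\n")
  invisible(x)
}

#' Parsimonious flux minimisation at a fixed objective
#'
#' Minimises the total absolute flux `sum(|v|)` subject to the steady state,
#' the composed bounds, and any additional fixing patch.  Used as the
#' default secondary objective so that, among the typically many optimal
#' flux distributions, a unique and solver-reproducible one is returned.
#'
#' @inheritParams solve_fba
#' @param report reaction id whose flux is reported as `objective_value`.
#' @return a `flux_distribution`.
#' @export
solve_parsimonious <- function(model, patches = list(), report = NULL, big = BIG_BOUND) {
  ing <- lp_ingredients(model, patches)
  if (any(ing$lb > ing$ub))
    return(flux_distribution(list(status = "infeasible"), colnames(ing$S), ing$S,
                             fba_objective("min", report %||% colnames(ing$S)[1]), NA_real_))
  S <- ing$S
  lb <- pmax(ing$lb, -big); ub <- pmin(ing$ub, big)
  n <- ncol(S)
  split <- which(lb < 0 & ub > 0)
  A <- cbind(S, if (length(split)) -S[, split, drop = FALSE])
  l2 <- c(pmax(lb, 0), rep(0, length(split)))
  u2 <- c(pmax(ub, 0), -lb[split])
  # columns with ub <= 0: variable itself spans [lb, 0]; |v| = -v
  negonly <- which(ub <= 0)
  l2[negonly] <- lb[negonly]; u2[negonly] <- ub[negonly]
  c2 <- c(rep(1, n), rep(1, length(split)))
  c2[negonly] <- -1
  res <- solve_lp(c2, A, numeric(nrow(S)), l2, u2, big)
  if (res$status != "optimal")
    return(flux_distribution(res, colnames(S), S,
                             fba_objective("min", report %||% colnames(S)[1]), NA_real_))
  v <- res$x[seq_len(n)]
  if (length(split)) v[split] <- v[split] - res$x[n + seq_along(split)]
  names(v) <- colnames(S)
  out <- flux_distribution(list(status = "optimal", x = v), colnames(S), S,
                           fba_objective("min", report %||% colnames(S)[1]),
                           if (!is.null(report)) v[[report]] else sum(abs(v)))
  attr(out, "total_flux") <- sum(abs(v))
  out
}

#' Choose the LP objective for the current state
#'
#' While assimilable nitrogen remains above the exhaustion threshold the
#' cell is assumed to be in exponential phase and growth is maximised; at or
#' below the threshold the objective switches to minimising the maintenance
#' ATP flux with growth clamped to zero (the boundary itself already
#' switches).
#'
#' @param state a [fermentation_state()].
#' @param config a [simulation_config()].
#' @param model a `metabolic_model` (supplies the tagged biomass and
#'   maintenance reactions).
#' @return an [fba_objective()]; carries attribute `clamp_growth`.
#' @export
select_objective <- function(state, config, model) {
  biomass <- reactions_with_tag(model, "biomass")
  atpm <- reactions_with_tag(model, "maintenance_atp")
  if (total_yan(state) > config$n_exhaust_mg_l) {
    obj <- fba_objective("max", biomass)
    attr(obj, "clamp_growth") <- FALSE
  } else {
    if (!length(atpm))
      stop_dynafba("dynafba_model_error", "no reaction tagged maintenance_atp")
    obj <- fba_objective("min", atpm)
    attr(obj, "clamp_growth") <- TRUE
  }
  obj
}

#' Bi-level (lexicographic) optimisation
#'
#' Solves the primary objective, fixes its optimum (to within `tol`) as a
#' constraint, and re-optimises the secondary objective on the optimal
#' face.  The secondary may be another [fba_objective()] or the string
#' `"parsimony"` for total-flux minimisation.
#'
#' @inheritParams solve_fba
#' @param primary,secondary objectives.
#' @param tol relative slack on the fixed primary optimum.
#' @return a `flux_distribution` satisfying both levels; a failed primary
#'   solve is returned as-is.
#' @export
solve_bilevel <- function(model, patches = list(), primary,
                          secondary = "parsimony", tol = 1e-6, big = BIG_BOUND) {
  if (inherits(patches, "constraint_patch")) patches <- list(patches)
  s1 <- solve_fba(model, patches, primary, big)
  if (s1$status != "optimal") return(s1)
  opt <- s1$objective_value
  slack <- tol * max(abs(opt), 1)
  fix <- if (primary$sense == "max")
    constraint_patch(primary$reaction, lb = opt - slack, ub = NA, provenance = "dynamic")
  else
    constraint_patch(primary$reaction, lb = NA, ub = opt + slack, provenance = "dynamic")
  patches2 <- c(patches, list(fix))
  out <- if (identical(secondary, "parsimony"))
    solve_parsimonious(model, patches2, report = primary$reaction, big = big)
  else
    solve_fba(model, patches2, secondary, big)
  if (out$status != "optimal") return(s1)  # numerically marginal fix: keep stage 1
  attr(out, "primary_value") <- opt
  out
}
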