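# Validation scoring: endpoint R scores for genetic-modification predictions
# and per-species profile correlations against experimental time courses.

#' Relative-change R score
#'
#' Compares the model's predicted relative change of a metabolite's final
#' concentration under a genetic modification with the experimentally
#' observed relative change:
#' `R = | (D_M_GM - D_M_WT)/D_M_WT - (D_E_GM - D_E_WT)/D_E_WT |`,
#' where D is the final concentration from the model (M) or experiment (E)
#' for the modified (GM) or wild-type (WT) strain.  Values close to zero
#' mean good predictions.  The score is symmetric in the model/experiment
#' roles and invariant to rescaling all four concentrations by a common
#' factor.  (The score is computed from relative changes as stated; should
#' a different algebra be preferred, this function is the single place to
#' change it.)
#'
#' @param d_m_gm,d_m_wt model final concentrations, modified and wild type
#'   (g/L).
#' @param d_e_gm,d_e_wt experimental final concentrations (g/L).
#' @param metabolite optional name used in error messages.
#' @return the dimensionless score.
#' @export
r_score <- function(d_m_gm, d_m_wt, d_e_gm, d_e_wt, metabolite = "metabolite") {
  if (!(d_m_wt > 0) || !(d_e_wt > 0))
    stop_dynafba("dynafba_undefined_score",
                 "R score undefined for ", metabolite,
                 ": wild-type concentration must be positive")
  abs((d_m_gm - d_m_wt) / d_m_wt - (d_e_gm - d_e_wt) / d_e_wt)
}

#' Score a mutant endpoint table
#'
#' Applies [r_score()] to each row of a table of final concentrations.
#' Rows with a non-positive wild-type concentration are reported as `NA`
#' with a reason instead of failing the whole table.
#'
#' @param quads data.frame with columns `metabolite`, `d_m_gm`, `d_m_wt`,
#'   `d_e_gm`, `d_e_wt`.
#' @return the input with columns `r_score` and `note` appended.
#' @export
r_score_table <- function(quads) {
  quads$r_score <- NA_real_
  quads$note <- ""
  for (i in seq_len(nrow(quads))) {
    res <- tryCatch(r_score(quads$d_m_gm[i], quads$d_m_wt[i],
                            quads$d_e_gm[i], quads$d_e_wt[i],
                            metabolite = quads$metabolite[i]),
                    dynafba_undefined_score = function(e) e)
    if (inherits(res, "condition")) quads$note[i] <- conditionMessage(res)
    else quads$r_score[i] <- res
  }
  quads
}

#' Profile correlation between simulation and experiment
#'
#' Correlation (in percent) between an experimental time series and the
#' simulated trajectory linearly interpolated at the experimental times,
#' computed per species.  Pearson correlation is the default (the reported
#' profile-agreement statistic); Spearman is available by flag.
#'
#' @param traj a `trajectory`.
#' @param experiment tidy data.frame `(time_h, species, value)`; `species`
#'   entries must match trajectory state columns (e.g. `GLC_e`).
#' @param method `"pearson"` or `"spearman"`.
#' @return named vector of correlations in percent.
#' @export
profile_correlation <- function(traj, experiment, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  need <- c("time_h", "species", "value")
  if (!all(need %in% names(experiment)))
    stop_dynafba("dynafba_schema_error",
                 "experiment table needs columns: ", paste(need, collapse = ", "))
  st <- traj$states
  out <- c()
  for (sp in unique(experiment$species)) {
    if (!sp %in% names(st))
      stop_dynafba("dynafba_schema_error", "species not in trajectory: ", sp)
    ex <- experiment[experiment$species == sp, , drop = FALSE]
    if (nrow(ex) < 3)
      stop_dynafba("dynafba_insufficient_data",
                   "need at least 3 time points for ", sp, " (got ", nrow(ex), ")")
    sim <- approx(st$time_h, st[[sp]], xout = ex$time_h, rule = 2)$y
    if (stats::sd(ex$value) < 1e-12 || stats::sd(sim) < 1e-12)
      stop_dynafba("dynafba_degenerate_series",
                   "constant series for ", sp, ": correlation undefined")
    out[sp] <- 100 * cor(sim, ex$value, method = method)
  }
  out
}

#' Sample a synthetic experimental dataset from a trajectory
#'
#' Emulates a measured fermentation: the trajectory is sampled at evenly
#' spaced times and multiplicative Gaussian noise with the given coefficient
#' of variation is added (measurements clamped at zero).  Deterministic for
#' a given seed.
#'
#' @param traj a `trajectory`.
#' @param species state columns to sample.
#' @param cv coefficient of variation of the noise (e.g. 0.05).
#' @param n_points number of sampling times (>= 3).
#' @param seed RNG seed.
#' @return tidy data.frame `(time_h, species, value, unit)`.
#' @export
make_synthetic_experiment <- function(traj, species = c("GLC_e", "FRU_e", "ETH_e", "GLYC_e"),
                                      cv = 0.05, n_points = 20, seed = 1) {
  if (cv < 0) stop_dynafba("dynafba_config_error", "cv must be >= 0")
  if (n_points < 3) stop_dynafba("dynafba_config_error", "need n_points >= 3")
  st <- traj$states
  if (nrow(st) < 2)
    stop_dynafba("dynafba_insufficient_data", "trajectory too short to sample")
  missing_sp <- setdiff(species, names(st))
  if (length(missing_sp))
    stop_dynafba("dynafba_schema_error", "species not in trajectory: ",
                 paste(missing_sp, collapse = ", "))
  times <- seq(min(st$time_h), max(st$time_h), length.out = n_points)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- lapply(species, function(sp) {
    v <- approx(st$time_h, st[[sp]], xout = times, rule = 2)$y
    noisy <- pmax(0, v * (1 + cv * rnorm(length(v))))
    nitro <- sp %in% traj$initial$nitrogen_species
    data.frame(time_h = times, species = sp, value = noisy,
               unit = if (nitro) "mgN_per_L" else "g_per_L",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
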