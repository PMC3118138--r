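# Shared fixtures.  Expensive simulations are computed once per test run and
# cached here.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

toy_model <- function() cached("toy", make_toy_network())
toy_anaerobic <- function() cached("toy_pat", anaerobic_constraints(toy_model()))

# the reference fermentation: 28 degC, 300 mg N/L, 233 g/L sugars
bench_state <- function() fermentation_state()
bench_traj <- function() cached("bench", simulate_fermentation(
  toy_model(), bench_state(), simulation_config(), list(toy_anaerobic())))

# linear chain A_e -> A -> B -> B_e with a 10 mmol/gDW/h bottleneck
chain_model <- function() {
  mets <- data.frame(
    id = c("A_e", "A_c", "B_c", "B_e"), name = c("A", "A", "B", "B"),
    compartment = c("e", "c", "c", "e"), formula = "C2H4O2",
    mw = 0.06, is_extracellular = c(TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_A", "TA", "AB", "TB", "EX_B"),
    name = c("A exchange", "A uptake", "A->B", "B export", "B exchange"),
    lb = c(-10, 0, 0, 0, 0), ub = c(0, 10, 10, 10, 10),
    genes = "", tags = "", stringsAsFactors = FALSE)
  stoich <- list(EX_A = c(A_e = -1), TA = c(A_e = -1, A_c = 1),
                 AB = c(A_c = -1, B_c = 1), TB = c(B_c = -1, B_e = 1),
                 EX_B = c(B_e = -1))
  metabolic_model(mets, rxns, stoich)
}

# brute-force vertex enumeration for min c'v s.t. S v = 0, l <= v <= u.
# A vertex fixes n - rank(S) variables at a bound; all subsets and bound
# sign patterns are enumerated and the best feasible vertex returned.
vertex_enumerate <- function(c_vec, S, lb, ub, tol = 1e-8) {
  n <- ncol(S)
  qrS <- qr(S)
  m <- qrS$rank
  k <- n - m
  best <- NULL
  subsets <- utils::combn(n, k, simplify = FALSE)
  for (fix in subsets) {
    free <- setdiff(seq_len(n), fix)
    Sb <- S[, free, drop = FALSE]
    if (qr(Sb)$rank < m) next
    grid <- expand.grid(rep(list(c(1, 2)), k))
    for (g in seq_len(nrow(grid))) {
      vfix <- ifelse(unlist(grid[g, ]) == 1, lb[fix], ub[fix])
      rhs <- -S[, fix, drop = FALSE] %*% vfix
      vfree <- tryCatch(qr.solve(Sb, rhs, tol = 1e-10), error = function(e) NULL)
      if (is.null(vfree)) next
      v <- numeric(n); v[fix] <- vfix; v[free] <- vfree
      if (any(v < lb - tol) || any(v > ub + tol)) next
      if (max(abs(S %*% v)) > tol) next
      obj <- sum(c_vec * v)
      if (is.null(best) || obj < best$obj - 1e-12) best <- list(obj = obj, v = v)
    }
  }
  best
}

# a small randomly-bounded variant of a 6-reaction branched network used to
# exercise the LP against the enumeration oracle
random_branch_lp <- function(seed) {
  set.seed(seed)
  # A -> B -> D and A -> C -> D, plus input of A, output of D
  S <- matrix(0, 4, 6, dimnames = list(c("A", "B", "C", "D"), paste0("r", 1:6)))
  S["A", 1] <- 1                     # input
  S["A", 2] <- -1; S["B", 2] <- 1
  S["B", 3] <- -1; S["D", 3] <- 1
  S["A", 4] <- -1; S["C", 4] <- 1
  S["C", 5] <- -1; S["D", 5] <- 1
  S["D", 6] <- -1                    # output
  lb <- round(runif(6, -2, 0), 2)
  ub <- lb + round(runif(6, 0.5, 8), 2)
  c_vec <- round(rnorm(6), 2)
  list(S = S, lb = lb, ub = ub, c_vec = c_vec)
}

expect_no_negative_conc <- function(traj) {
  sp <- setdiff(names(traj$states),
                c("time_h", "temperature_C", "biomass_gDW_L", "f_consumed",
                  "phase", "mu", "maintenance_lb", "carb_fraction", "carbon_per_gdw"))
  for (s in sp) expect_true(all(traj$states[[s]] >= 0), label = paste("non-negative", s))
}

# ablation runs reused by several test files
ablation_traj <- function(which) {
  m <- toy_model()
  switch(which,
    quinone = cached("abl_q", simulate_fermentation(
      m, bench_state(), simulation_config(),
      list(anaerobic_constraints(m, quinones_off = FALSE)))),
    fulltca = cached("abl_t", simulate_fermentation(
      m, bench_state(), simulation_config(),
      list(anaerobic_constraints(m, split_tca = FALSE)))),
    oxygen = cached("abl_o2", simulate_fermentation(
      m, bench_state(), simulation_config(max_time_h = 250),
      list(anaerobic_constraints(m, oxygen_off = FALSE)))),
    maint_zero = cached("abl_mz", simulate_fermentation(
      m, bench_state(), simulation_config(maintenance_mode = "zero", max_time_h = 300),
      list(toy_anaerobic()))),
    maint_unbounded = cached("abl_mu", simulate_fermentation(
      m, bench_state(), simulation_config(maintenance_mode = "unbounded", max_time_h = 300),
      list(toy_anaerobic()))),
    stop("unknown ablation"))
}
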