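# Shared helpers for the test suite.

# A small, fast configuration for unit-level ABM tests: tiny grid, few
# agents, short cycles. Calibration identities hold, so no warnings.
tiny_config <- function(...) {
  base <- list(grid_width = 8L, grid_height = 8L,
               init_yeast = 4L, init_wt_bacteria = 8L,
               init_mutant_bacteria = 1L,
               doublings_per_transfer = 2L, n_transfers = 3L,
               max_ticks_per_transfer = 400L)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

# A linear toy chain for LP oracle work: uptake -> conversion -> biomass.
# EX_a imports metabolite a (uptake = reverse direction), R1 converts a to b
# (the only enzymatic step), BIOMASS drains b.
chain_model <- function() {
  metabolic_model(
    stoich = list(EX_a = c(a = -1), R1 = c(a = -1, b = 1), BIOMASS = c(b = -1)),
    lb = c(EX_a = -10, R1 = 0, BIOMASS = 0),
    ub = c(EX_a = 0, R1 = 10, BIOMASS = 10),
    exchange = "EX_a",
    enzymes = list(R1 = "EnzA"),
    biomass_id = "BIOMASS", target_id = "R1")
}

# Independent LP oracle: enumerate the basic feasible solutions of
#   min c'x  s.t.  Aeq x = beq,  0 <= x <= ub
# by choosing every basis (set of m columns) and every lower/upper-bound
# assignment of the nonbasic columns. Returns the optimal value. Only for
# tiny instances.
lp_vertex_oracle <- function(cc, Aeq, beq, ub, tol = 1e-9) {
  n <- length(cc); m <- nrow(Aeq)
  best <- Inf
  for (basis in utils::combn(n, m, simplify = FALSE)) {
    B <- Aeq[, basis, drop = FALSE]
    if (abs(det(B)) < tol) next
    nonbasic <- setdiff(seq_len(n), basis)
    for (mask in 0:(2^length(nonbasic) - 1)) {
      xn <- numeric(length(nonbasic))
      bits <- bitwAnd(bitwShiftR(mask, seq_along(nonbasic) - 1), 1L)
      xn[bits == 1] <- ub[nonbasic][bits == 1]
      rhs <- beq - if (length(nonbasic)) Aeq[, nonbasic, drop = FALSE] %*% xn else 0
      xb <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(xb)) next
      x <- numeric(n); x[basis] <- xb; x[nonbasic] <- xn
      if (all(x >= -tol) && all(x <= ub + tol)) {
        val <- sum(cc * x)
        if (val < best) best <- val
      }
    }
  }
  best
}

# Build the (c, Aeq, beq, ub) standard form of the minimal-uptake LP that
# condition_optimum solves, independently of the package's own assembly:
# variables are the forward and reverse split of each reaction plus one
# slack per lower-bounded row.
uptake_lp_standard_form <- function(model, cond) {
  n <- ncol(model$S)
  rx <- model$reactions
  fub <- pmax(rx$ub, 0); rub <- pmax(-rx$lb, 0)
  if (!is.null(cond$medium)) rub[match(names(cond$medium), rx$id)] <- cond$medium
  cc <- c(numeric(n), as.numeric(rx$exchange & !rx$oxygen))
  Aeq <- cbind(model$S, -model$S)
  beq <- numeric(nrow(model$S))
  ub <- c(fub, rub)
  # growth lower bound as equality with a bounded surplus variable
  gi <- match(model$biomass_id, rx$id)
  row <- numeric(2 * n); row[gi] <- 1
  Aeq <- rbind(Aeq, c(row, -1 * numeric(0)))
  Aeq <- cbind(Aeq, c(numeric(nrow(model$S)), -1))
  beq <- c(beq, cond$growth_lb)
  cc <- c(cc, 0)
  ub <- c(ub, max(fub))
  list(cc = cc, Aeq = Aeq, beq = beq, ub = ub)
}
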