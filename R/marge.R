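#' Construct a stoichiometric metabolic model
#'
#' A light-weight container for flux-balance work: a stoichiometric matrix,
#' per-reaction flux bounds, exchange / oxygen / enzymatic flags, enzyme
#' associations, and the identities of the biomass and target-product
#' reactions. Exchange reactions are written in export convention
#' (`met -> nothing`): positive flux exports, negative flux imports, so a
#' nutrient uptake is the reverse (negative) direction of its exchange.
#'
#' @param stoich Named list: reaction id -> named numeric vector of
#'   metabolite coefficients (negative = consumed).
#' @param lb,ub Named numeric vectors of lower/upper flux bounds
#'   (mmol gCDW^-1 h^-1); names must match reaction ids.
#' @param exchange Character vector of exchange reaction ids.
#' @param oxygen_id Id of the oxygen exchange (excluded from the uptake
#'   objective), or NULL.
#' @param enzymes Named list: reaction id -> character vector of enzyme ids;
#'   reactions listed here are treated as enzymatic.
#' @param biomass_id Id of the (single) biomass reaction.
#' @param target_id Id of the target-product reaction (e.g. riboflavin
#'   synthase) whose flux ratio the fit reports.
#' @return Object of class `metabolic_model` with the stoichiometric matrix
#'   `S` (metabolites x reactions) and a `reactions` data.frame.
#' @export
metabolic_model <- function(stoich, lb, ub, exchange = character(),
                            oxygen_id = NULL, enzymes = list(),
                            biomass_id, target_id) {
  rxn_ids <- names(stoich)
  stopifnot(length(rxn_ids) > 0, !is.null(rxn_ids))
  mets <- sort(unique(unlist(lapply(stoich, names))))
  if (!all(rxn_ids %in% names(lb)) || !all(rxn_ids %in% names(ub)))
    stop("every reaction needs a lower and an upper bound", call. = FALSE)
  lb <- lb[rxn_ids]; ub <- ub[rxn_ids]
  if (any(lb > ub)) stop("lower bound exceeds upper bound for: ",
                         paste(rxn_ids[lb > ub], collapse = ","), call. = FALSE)
  if (!biomass_id %in% rxn_ids) stop("unknown biomass reaction", call. = FALSE)
  if (!target_id %in% rxn_ids) stop("unknown target reaction", call. = FALSE)
  bad <- setdiff(exchange, rxn_ids)
  if (length(bad)) stop("unknown exchange reaction: ", bad[1], call. = FALSE)

  S <- matrix(0, length(mets), length(rxn_ids),
              dimnames = list(mets, rxn_ids))
  for (j in rxn_ids) S[names(stoich[[j]]), j] <- stoich[[j]]

  reactions <- data.frame(
    id = rxn_ids,
    lb = unname(lb), ub = unname(ub),
    exchange = rxn_ids %in% exchange,
    oxygen = !is.null(oxygen_id) & rxn_ids %in% oxygen_id,
    enzymatic = rxn_ids %in% names(enzymes),
    stringsAsFactors = FALSE
  )
  reactions$enzymes <- lapply(rxn_ids, function(j) {
    e <- enzymes[[j]]; if (is.null(e)) character() else e
  })
  structure(list(S = S, reactions = reactions,
                 biomass_id = biomass_id, target_id = target_id),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>", nrow(x$S), "metabolites,", ncol(x$S), "reactions (",
      sum(x$reactions$exchange), "exchanges,", sum(x$reactions$enzymatic),
      "enzymatic )\n")
  cat("  biomass:", x$biomass_id, "  target:", x$target_id, "\n")
  invisible(x)
}

#' Bundled toy network with a riboflavin-like branch
#'
#' A 14-reaction stand-in for a genome-scale lactic acid bacterium model:
#' glucose and amino-acid uptake, a lumped glycolysis/pentose-phosphate
#' reaction, respiration (the oxygen consumer), a GTP branch, the six-step
#' riboflavin pathway (GTP cyclohydrolase II through riboflavin synthase,
#' mirroring EC 3.5.4.25, 3.5.4.26, 1.1.1.193, 3.1.3.104, 2.5.1.78 and
#' 2.5.1.9), riboflavin export and a biomass reaction. All enzymatic
#' reactions are irreversible, which keeps flux magnitudes identifiable in
#' the expression fit.
#'
#' @return A [metabolic_model()].
#' @examples
#' toy_model()
#' @export
toy_model <- function() {
  stoich <- list(
    EX_glc = c(glc = -1),
    EX_aa  = c(aa = -1),
    EX_o2  = c(o2 = -1),
    EX_rib = c(rib = -1),
    GLYC   = c(glc = -1, atp = 2, r5p = 1),
    RESP   = c(glc = -1, o2 = -2, atp = 8),
    PUR    = c(r5p = -1, atp = -2, gtp = 1),
    RIBA   = c(gtp = -1, p1 = 1),     # GTP cyclohydrolase II
    RIBD1  = c(p1 = -1, p2 = 1),      # pyrimidine deaminase
    RIBD2  = c(p2 = -1, p3 = 1),      # uracil reductase
    RIBP   = c(p3 = -1, p4 = 1),      # uracil phosphatase
    RIBH   = c(p4 = -1, dmrl = 1),    # lumazine synthase
    RIBE   = c(dmrl = -1, rib = 1),   # riboflavin synthase
    BIOMASS = c(atp = -10, aa = -2, gtp = -0.2)
  )
  ids <- names(stoich)
  lb <- c(EX_glc = -10, EX_aa = -10, EX_o2 = -20, EX_rib = 0,
          GLYC = 0, RESP = 0, PUR = 0, RIBA = 0, RIBD1 = 0, RIBD2 = 0,
          RIBP = 0, RIBH = 0, RIBE = 0, BIOMASS = 0)
  ub <- setNames(rep(1000, length(ids)), ids)
  ub[c("EX_glc", "EX_aa", "EX_o2")] <- 0   # uptake-only exchanges
  metabolic_model(
    stoich, lb, ub,
    exchange = c("EX_glc", "EX_aa", "EX_o2", "EX_rib"),
    oxygen_id = "EX_o2",
    enzymes = list(GLYC = "GlyK", RESP = "CyoA", PUR = "PurF",
                   RIBA = "RibA", RIBD1 = "RibD", RIBD2 = "RibD",
                   RIBP = "RibP", RIBH = "RibH", RIBE = "RibE"),
    biomass_id = "BIOMASS", target_id = "RIBE"
  )
}

#' Specify one growth condition for the flux fit
#'
#' @param growth_lb Experimentally determined growth rate (h^-1) used as the
#'   lower bound on the biomass flux.
#' @param product_lb Optional lower bound on the target-product flux
#'   (mmol gCDW^-1 h^-1), e.g. the measured specific secretion rate.
#' @param medium Optional named vector: exchange reaction id -> maximal
#'   uptake (relative molar availability). Exchanges not listed keep the
#'   model's own uptake bound.
#' @return Object of class `condition_spec`.
#' @export
condition_spec <- function(growth_lb = 0, product_lb = NULL, medium = NULL) {
  stopifnot(growth_lb >= 0, is.null(product_lb) || product_lb >= 0,
            is.null(medium) || all(medium >= 0))
  structure(list(growth_lb = growth_lb, product_lb = product_lb,
                 medium = medium), class = "condition_spec")
}

#' Expression input for the relative-expression flux fit
#'
#' Holds enzyme (or reaction) log2 fold-changes, evolved versus reference,
#' and applies the significance filter: only entries with
#' `|log2fc| >= threshold` are used (default 0.5, i.e. at least a 50%
#' change in abundance).
#'
#' @param log2fc Named numeric vector: enzyme or reaction id -> log2
#'   fold-change.
#' @param threshold Absolute log2 fold-change below which entries are
#'   dropped.
#' @return Object of class `expression_input` with the filtered entries.
#' @export
expression_input <- function(log2fc, threshold = 0.5) {
  stopifnot(is.numeric(log2fc), threshold >= 0)
  if (length(log2fc) && is.null(names(log2fc)))
    stop("log2fc must be named by enzyme or reaction id", call. = FALSE)
  keep <- abs(log2fc) >= threshold
  structure(list(log2fc = log2fc[keep], threshold = threshold,
                 n_dropped = sum(!keep)), class = "expression_input")
}

# Map enzyme-level fold-changes onto reactions: a reaction's log2fc is the
# mean over its associated enzymes that carry a (filtered) value; reaction
# ids present directly in the table win over enzyme aggregation.
reaction_log2fc <- function(model, expr) {
  fc <- expr$log2fc
  out <- numeric(0)
  for (i in seq_len(nrow(model$reactions))) {
    id <- model$reactions$id[i]
    if (!model$reactions$enzymatic[i]) next
    if (id %in% names(fc)) {
      out[id] <- fc[[id]]
    } else {
      hits <- intersect(model$reactions$enzymes[[i]], names(fc))
      if (length(hits)) out[id] <- mean(fc[hits])
    }
  }
  out
}

# ---- internal LP plumbing -------------------------------------------------

# Split-variable bounds for one condition: forward part in [0, max(ub,0)],
# reverse part in [0, max(-lb,0)]; medium overrides the uptake (reverse)
# bound of exchange reactions; growth/product lower bounds go on the forward
# part.
condition_bounds <- function(model, cond) {
  rx <- model$reactions
  fub <- pmax(rx$ub, 0)
  rub <- pmax(-rx$lb, 0)
  names(fub) <- names(rub) <- rx$id
  if (!is.null(cond$medium)) {
    bad <- setdiff(names(cond$medium), rx$id[rx$exchange])
    if (length(bad)) stop("medium names unknown exchange: ", bad[1], call. = FALSE)
    rub[names(cond$medium)] <- cond$medium
  }
  flb <- setNames(numeric(nrow(rx)), rx$id)
  flb[model$biomass_id] <- cond$growth_lb
  if (!is.null(cond$product_lb))
    flb[model$target_id] <- max(flb[model$target_id], cond$product_lb)
  list(fub = fub, rub = rub, flb = flb)
}

# Solve min c'x s.t. A1 x <= b1, A3 x = b3, x >= 0 with boot::simplex.
solve_lp <- function(cc, A1 = NULL, b1 = NULL, A3 = NULL, b3 = NULL,
                     A2 = NULL, b2 = NULL) {
  n <- length(cc)
  m <- sum(nrow(A1), nrow(A2), nrow(A3))
  res <- boot::simplex(a = cc, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       A3 = A3, b3 = b3, maxi = FALSE,
                       n.iter = 50 * (n + 2 * m), eps = 1e-10)
  if (res$solved != 1)
    stop(if (res$solved == -1) "LP infeasible" else "LP did not converge",
         call. = FALSE)
  list(x = unname(res$soln), value = unname(res$value))
}

# Uptake objective coefficients over (f, r) blocks: sum of reverse
# (uptake-direction) exchange fluxes excluding the oxygen exchange.
uptake_weights <- function(model) {
  rx <- model$reactions
  as.numeric(rx$exchange & !rx$oxygen)
}

#' Minimal total nutrient uptake under a growth condition
#'
#' Solves the linear program that defines a condition's metabolic-state
#' optimum: minimize the summed uptake-direction exchange fluxes, excluding
#' the oxygen exchange, subject to steady state (`S v = 0`), the model and
#' medium flux bounds, the growth lower bound, and any product lower bound.
#'
#' @param model A [metabolic_model()].
#' @param cond A [condition_spec()].
#' @return List with `optimum` (the minimal total uptake U*) and `fluxes`
#'   (a named flux vector attaining it).
#' @examples
#' condition_optimum(toy_model(), condition_spec(growth_lb = 0.1))
#' @export
condition_optimum <- function(model, cond) {
  n <- ncol(model$S)
  bnd <- condition_bounds(model, cond)
  w <- uptake_weights(model)
  cc <- c(numeric(n), w)                       # minimize uptake (reverse) sum
  A3 <- cbind(model$S, -model$S)               # steady state
  b3 <- numeric(nrow(model$S))
  A1 <- rbind(diag(2 * n))                     # upper bounds on f and r
  b1 <- c(bnd$fub, bnd$rub)
  lbrows <- which(bnd$flb > 0)
  A2 <- b2 <- NULL
  if (length(lbrows)) {                        # growth / product lower bounds
    A2 <- matrix(0, length(lbrows), 2 * n)
    A2[cbind(seq_along(lbrows), lbrows)] <- 1
    b2 <- unname(bnd$flb[lbrows])
  }
  sol <- tryCatch(
    solve_lp(cc, A1 = A1, b1 = b1, A2 = A2, b2 = b2, A3 = A3, b3 = b3),
    error = function(e) stop("condition infeasible (growth ",
                             cond$growth_lb, ", product bound ",
                             if (is.null(cond$product_lb)) "none" else cond$product_lb,
                             ", medium bounds as given): ", conditionMessage(e),
                             call. = FALSE))
  v <- sol$x[1:n] - sol$x[(n + 1):(2 * n)]
  names(v) <- model$reactions$id
  list(optimum = sol$value, fluxes = v)
}

#' Fit paired flux states to relative enzyme-abundance changes
#'
#' The joint linear program at the heart of the expression-constrained
#' analysis. Both conditions' flux vectors are solved together, each split
#' into non-negative forward/reverse parts so magnitudes are linear:
#' \itemize{
#'   \item steady state and flux bounds hold per condition;
#'   \item each condition's total non-oxygen uptake stays within
#'     `(1 + epsilon)` of its own optimum U* (equal optimality relaxation,
#'     default 3%);
#'   \item the summed flux magnitude over enzymatic reactions is equal
#'     between conditions (the conserved total metabolic-proteome proxy);
#'   \item the objective minimizes, over reactions with a filtered
#'     fold-change, the absolute deviation
#'     `| |v_evo| - 2^log2fc * |v_ref| |` via slack pairs.
#' }
#' A tie-break term (weight `tie_break`) additionally pulls the magnitudes of
#' all unconstrained enzymatic reactions toward equality across conditions,
#' which makes the fit with an empty expression table return mirrored states.
#'
#' @param model A [metabolic_model()].
#' @param ref,evo [condition_spec()]s for the reference (parental) and
#'   evolved condition.
#' @param expr An [expression_input()] (enzyme or reaction log2
#'   fold-changes, already filtered).
#' @param epsilon Optimality relaxation fraction (default 0.03).
#' @param tie_break Weight of the mirroring regularizer; must be well below
#'   1 so it never competes with the fit itself.
#' @return Object of class `marge_result`: flux vectors `fluxes_ref` and
#'   `fluxes_evo`, per-condition optima `optimum_ref` / `optimum_evo`,
#'   `epsilon`, `residual` (summed weighted slack of the fitted reactions),
#'   `target_ratio` (evolved / reference flux magnitude of the target
#'   reaction), and `proteome_total` (the conserved magnitude sum).
#' @export
fit_relative_expression <- function(model, ref, evo, expr,
                                    epsilon = 0.03, tie_break = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"), epsilon >= 0)
  if (!inherits(expr, "expression_input"))
    expr <- expression_input(expr)
  n <- ncol(model$S); m <- nrow(model$S)
  rx <- model$reactions
  U1 <- condition_optimum(model, ref)
  U2 <- condition_optimum(model, evo)

  fc <- reaction_log2fc(model, expr)
  enz <- which(rx$enzymatic)
  fitted <- intersect(rx$id[enz], names(fc))
  free_enz <- setdiff(rx$id[enz], fitted)
  k_ids <- c(fitted, free_enz)
  wts <- c(rep(1, length(fitted)), rep(tie_break, length(free_enz)))
  gains <- 2^c(fc[fitted], setNames(numeric(length(free_enz)), free_enz))
  nk <- length(k_ids)

  # variable layout: f1, r1, f2, r2 (4n), then slack pairs (s+, s-) per fitted row
  nv <- 4 * n + 2 * nk
  b1c <- condition_bounds(model, ref)
  b2c <- condition_bounds(model, evo)
  w <- uptake_weights(model)
  col <- function(block, j) (block - 1) * n + j   # block 1..4

  cc <- c(numeric(4 * n), rep(wts, each = 2))

  # equalities: steady state x2, proteome budget, fit rows
  A3 <- matrix(0, 2 * m + 1 + nk, nv)
  A3[1:m, 1:n] <- model$S;             A3[1:m, (n + 1):(2 * n)] <- -model$S
  A3[(m + 1):(2 * m), (2 * n + 1):(3 * n)] <- model$S
  A3[(m + 1):(2 * m), (3 * n + 1):(4 * n)] <- -model$S
  # proteome: sum_enz (f2 + r2) - sum_enz (f1 + r1) = 0
  A3[2 * m + 1, c(col(3, enz), col(4, enz))] <- 1
  A3[2 * m + 1, c(col(1, enz), col(2, enz))] <- -1
  for (i in seq_len(nk)) {
    j <- match(k_ids[i], rx$id)
    r <- 2 * m + 1 + i
    A3[r, c(col(3, j), col(4, j))] <- 1
    A3[r, c(col(1, j), col(2, j))] <- -gains[i]
    A3[r, 4 * n + 2 * i - 1] <- -1     # s+
    A3[r, 4 * n + 2 * i]     <- 1      # s-
  }
  b3 <- numeric(nrow(A3))

  # inequalities (<=): variable upper bounds + two relaxed uptake rows
  ubs <- c(b1c$fub, b1c$rub, b2c$fub, b2c$rub)
  A1 <- cbind(diag(4 * n), matrix(0, 4 * n, 2 * nk))
  up1 <- up2 <- numeric(nv)
  up1[col(2, seq_len(n))] <- w
  up2[col(4, seq_len(n))] <- w
  A1 <- rbind(A1, up1, up2)
  b1 <- c(ubs, (1 + epsilon) * U1$optimum, (1 + epsilon) * U2$optimum)

  # (>=): growth / product lower bounds per condition
  A2 <- NULL; b2 <- NULL
  add_lb <- function(bnd, block) {
    rows <- which(bnd$flb > 0)
    if (!length(rows)) return(NULL)
    Ag <- matrix(0, length(rows), nv)
    Ag[cbind(seq_along(rows), col(block, rows))] <- 1
    list(A = Ag, b = unname(bnd$flb[rows]))
  }
  for (z in list(add_lb(b1c, 1), add_lb(b2c, 3))) {
    if (!is.null(z)) { A2 <- rbind(A2, z$A); b2 <- c(b2, z$b) }
  }

  sol <- tryCatch(
    solve_lp(cc, A1 = A1, b1 = b1, A2 = A2, b2 = b2, A3 = A3, b3 = b3),
    error = function(e)
      stop("joint fit infeasible; consider loosening the optimality ",
           "relaxation (epsilon), the proteome budget, or the growth bounds: ",
           conditionMessage(e), call. = FALSE))

  x <- sol$x
  v1 <- x[col(1, 1:n)] - x[col(2, 1:n)]
  v2 <- x[col(3, 1:n)] - x[col(4, 1:n)]
  names(v1) <- names(v2) <- rx$id
  mag1 <- x[col(1, 1:n)] + x[col(2, 1:n)]
  mag2 <- x[col(3, 1:n)] + x[col(4, 1:n)]
  ti <- match(model$target_id, rx$id)
  residual <- if (length(fitted)) {
    sl <- x[4 * n + seq_len(2 * nk)]
    sum(sl[rep(seq_len(nk), each = 2) <= length(fitted)])
  } else 0
  structure(list(
    fluxes_ref = v1, fluxes_evo = v2,
    optimum_ref = U1$optimum, optimum_evo = U2$optimum,
    epsilon = epsilon,
    residual = residual,
    target_ratio = if (mag1[ti] > 1e-12) mag2[ti] / mag1[ti] else NA_real_,
    proteome_total = sum(mag1[enz]),
    proteome_total_evo = sum(mag2[enz]),
    fitted_reactions = fitted
  ), class = "marge_result")
}

#' @export
print.marge_result <- function(x, ...) {
  cat("<marge_result> epsilon", x$epsilon,
      "| residual", signif(x$residual, 4),
      "| target flux ratio (evolved/reference)", signif(x$target_ratio, 4), "\n")
  invisible(x)
}

#' Specific production rate from an end-point titer
#'
#' Converts an extracellular product titer accumulated over a cultivation
#' into a biomass-specific production rate:
#' `rate = (titer * 1e-6 / molar_mass) * 1e3 / duration /
#'  (biomass_fraction * od600 * cdw_per_od)` in mmol gCDW^-1 h^-1.
#' `biomass_fraction` accounts for the producer's share of the total cell
#' concentration (0.5 when the producer is half of a two-member community).
#'
#' @param titer Extracellular product concentration (ng/ml).
#' @param duration Cultivation time (h).
#' @param od600 Final optical density of the culture.
#' @param cdw_per_od Cell dry weight per OD unit (g L^-1 per OD600). Not a
#'   universal constant; it must be supplied from a strain-specific OD-CDW
#'   calibration.
#' @param molar_mass Product molar mass (g/mol); riboflavin is 376.36.
#' @param biomass_fraction Producer's fraction of the total biomass.
#' @return Specific rate in mmol gCDW^-1 h^-1.
#' @examples
#' estimate_specific_rate(42, 72, 2, cdw_per_od = 0.2528)
#' @export
estimate_specific_rate <- function(titer, duration, od600, cdw_per_od,
                                   molar_mass = 376.36,
                                   biomass_fraction = 0.5) {
  if (titer < 0) stop("titer must be non-negative", call. = FALSE)
  if (any(c(duration, od600, cdw_per_od, molar_mass, biomass_fraction) <= 0))
    stop("duration, od600, cdw_per_od, molar_mass and biomass_fraction must be positive",
         call. = FALSE)
  (titer * 1e-6 / molar_mass) * 1e3 / duration /
    (biomass_fraction * od600 * cdw_per_od)
}
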