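#' Simulation configuration for the cross-feeding agent-based model
#'
#' Builds and validates the full parameter set of the spatial mutualism
#' model: a toroidal grid of patches holding amino-acid and vitamin pools,
#' yeast agents that secrete amino acids and require vitamin, and bacterial
#' agents that secrete vitamin (mutants at `mutant_secretion_fold` times the
#' wild-type rate, at proportional energy cost) and require amino acids.
#'
#' Two calibration identities tie the energy economy together and are checked
#' with a warning when violated:
#' \itemize{
#'   \item net energy gain at optimum is one unit per agent per tick for
#'     wild-type agents of both species:
#'     `conversion_efficiency * uptake_max - secretion_cost * secretion_rate = 1`;
#'   \item one yeast supports about eight bacteria:
#'     `yeast_secretion_rate = 8 * bact_uptake_max`.
#' }
#'
#' @param grid_width,grid_height Patch counts of the world (default 32 x 32).
#' @param mixing Per-agent probability in \[0,1\] of relocating to a uniformly
#'   random patch each tick; 0 means agents never move (maximal spatial
#'   structure), 1 emulates a fully shaken liquid culture.
#' @param wander_prob Per-agent probability in \[0,1\] of taking one local
#'   random-walk step (to a uniformly chosen patch in the 3 x 3 Moore
#'   neighbourhood, torus wrap) each tick. This models cell motility at the
#'   patch scale and is independent of `mixing`; without it agents would be
#'   pinned to their natal patch and cross-feeding would collapse to exact
#'   patch co-location.
#' @param diffusion_rate Fraction in \[0,1\] of each patch's metabolite pool
#'   redistributed equally to its 8 toroidal neighbours each tick.
#' @param init_yeast,init_wt_bacteria,init_mutant_bacteria Initial agent
#'   counts (defaults 10 / 79 / 1: a single invading mutant in a community
#'   with about 8x more bacteria than yeast).
#' @param doublings_per_transfer Population doublings that trigger a serial
#'   transfer: growth stops once the census reaches
#'   `init_total * 2^doublings_per_transfer` (default 5).
#' @param n_transfers Number of serial transfers per replicate (default 25).
#' @param energy_init Starting energy of every agent.
#' @param division_threshold Energy at which an agent divides into two
#'   daughters holding half each; must exceed `energy_init`.
#' @param yeast_uptake_max,yeast_secretion_rate,yeast_secretion_cost,yeast_conversion_efficiency
#'   Yeast metabolite economy: maximal vitamin uptake per tick, amino acids
#'   secreted per tick, energy paid per secreted unit, and energy gained per
#'   consumed unit.
#' @param bact_uptake_max,bact_secretion_rate,bact_secretion_cost,bact_conversion_efficiency
#'   The same four parameters for bacteria (vitamin secreted, amino acid
#'   consumed).
#' @param mutant_secretion_fold Multiplier on the bacterial secretion rate
#'   for mutant-strain bacteria; 1 makes the mutant a neutral label.
#' @param max_ticks_per_transfer Safety cap on ticks within one growth cycle;
#'   exceeding it marks the replicate as timed out.
#' @param rng_seed Optional integer seed recorded in the config; functions
#'   that accept a config call `set.seed()` with it when present.
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(mixing = 0.2, mutant_secretion_fold = 2)
#' cfg$mixing
#' @export
sim_config <- function(grid_width = 32L,
                       grid_height = 32L,
                       mixing = 0,
                       wander_prob = 0,
                       diffusion_rate = 0.1,
                       init_yeast = 100L,
                       init_wt_bacteria = 799L,
                       init_mutant_bacteria = 1L,
                       doublings_per_transfer = 5L,
                       n_transfers = 25L,
                       energy_init = 10,
                       division_threshold = 20,
                       yeast_uptake_max = 16,
                       yeast_secretion_rate = 8,
                       yeast_secretion_cost = 0.025,
                       yeast_conversion_efficiency = 0.075,
                       bact_uptake_max = 1,
                       bact_secretion_rate = 1,
                       bact_secretion_cost = 0.1,
                       bact_conversion_efficiency = 1.1,
                       mutant_secretion_fold = 1,
                       max_ticks_per_transfer = 1000L,
                       rng_seed = NULL) {
  cfg <- list(
    grid_width = as.integer(grid_width),
    grid_height = as.integer(grid_height),
    mixing = as.numeric(mixing),
    wander_prob = as.numeric(wander_prob),
    diffusion_rate = as.numeric(diffusion_rate),
    init_yeast = as.integer(init_yeast),
    init_wt_bacteria = as.integer(init_wt_bacteria),
    init_mutant_bacteria = as.integer(init_mutant_bacteria),
    doublings_per_transfer = as.integer(doublings_per_transfer),
    n_transfers = as.integer(n_transfers),
    energy_init = as.numeric(energy_init),
    division_threshold = as.numeric(division_threshold),
    yeast_uptake_max = as.numeric(yeast_uptake_max),
    yeast_secretion_rate = as.numeric(yeast_secretion_rate),
    yeast_secretion_cost = as.numeric(yeast_secretion_cost),
    yeast_conversion_efficiency = as.numeric(yeast_conversion_efficiency),
    bact_uptake_max = as.numeric(bact_uptake_max),
    bact_secretion_rate = as.numeric(bact_secretion_rate),
    bact_secretion_cost = as.numeric(bact_secretion_cost),
    bact_conversion_efficiency = as.numeric(bact_conversion_efficiency),
    mutant_secretion_fold = as.numeric(mutant_secretion_fold),
    max_ticks_per_transfer = as.integer(max_ticks_per_transfer),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  )
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg A list with the fields of `sim_config`.
#' @export
validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)

  in01 <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
  if (!in01(cfg$mixing)) stop_cfg("mixing must lie in [0,1]")
  if (!in01(cfg$wander_prob)) stop_cfg("wander_prob must lie in [0,1]")
  if (!in01(cfg$diffusion_rate)) stop_cfg("diffusion_rate must lie in [0,1]")

  nonneg <- c("init_yeast", "init_wt_bacteria", "init_mutant_bacteria",
              "yeast_uptake_max", "yeast_secretion_rate", "yeast_secretion_cost",
              "yeast_conversion_efficiency", "bact_uptake_max",
              "bact_secretion_rate", "bact_secretion_cost",
              "bact_conversion_efficiency", "mutant_secretion_fold")
  for (f in nonneg) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop_cfg(paste0(f, " must be a non-negative number"))
  }
  pos <- c("grid_width", "grid_height", "doublings_per_transfer",
           "n_transfers", "max_ticks_per_transfer")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1)
      stop_cfg(paste0(f, " must be a positive integer"))
  }
  if (!(cfg$division_threshold > cfg$energy_init && cfg$energy_init > 0))
    stop_cfg("division_threshold > energy_init > 0 is required")

  tol <- 1e-8
  net_y <- cfg$yeast_conversion_efficiency * cfg$yeast_uptake_max -
    cfg$yeast_secretion_cost * cfg$yeast_secretion_rate
  net_b <- cfg$bact_conversion_efficiency * cfg$bact_uptake_max -
    cfg$bact_secretion_cost * cfg$bact_secretion_rate
  if (abs(net_y - 1) > tol || abs(net_b - 1) > tol)
    warning("sim_config calibration: wild-type net energy gain at optimum is ",
            signif(net_y, 4), " (yeast) / ", signif(net_b, 4),
            " (bacteria); the calibrated model uses 1 for both", call. = FALSE)
  if (abs(cfg$yeast_secretion_rate - 8 * cfg$bact_uptake_max) > tol)
    warning("sim_config calibration: yeast_secretion_rate is expected to be ",
            "8 * bact_uptake_max (one yeast supports about 8 bacteria)",
            call. = FALSE)

  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$grid_width, "x", x$grid_height, "patches;",
      "mixing", x$mixing, "; diffusion", x$diffusion_rate, "\n")
  cat("  init", x$init_yeast, "yeast +", x$init_wt_bacteria, "wild +",
      x$init_mutant_bacteria, "mutant bacteria; fold",
      x$mutant_secretion_fold, "\n")
  cat("  ", x$n_transfers, "transfers of", x$doublings_per_transfer,
      "doublings (cap", x$max_ticks_per_transfer, "ticks)\n")
  invisible(x)
}

#' Total number of agents the world is initialized (and re-seeded) with
#' @param cfg A `sim_config`.
#' @return Integer count.
#' @export
init_total <- function(cfg) {
  cfg$init_yeast + cfg$init_wt_bacteria + cfg$init_mutant_bacteria
}

#' Census size that triggers a serial transfer
#'
#' Equal to `init_total(cfg) * 2^doublings_per_transfer`, i.e. the initial
#' census after the configured number of population doublings.
#' @param cfg A `sim_config`.
#' @return Numeric threshold.
#' @export
transfer_threshold <- function(cfg) {
  init_total(cfg) * 2^cfg$doublings_per_transfer
}
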