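#' Initialize an empty world with randomly placed agents
#'
#' Creates the starting state of a growth cycle: both metabolite pools at
#' exactly zero everywhere (a fresh medium carries neither amino acids nor
#' vitamin), and `init_total(cfg)` agents placed uniformly at random, each
#' holding `energy_init` energy.
#'
#' @param cfg A [sim_config()]. If `cfg$rng_seed` is set, the seed is applied
#'   first.
#' @return A list of class `abm_world` with per-patch matrices `amino_acid`
#'   and `vitamin`, parallel agent vectors `species` (0 = yeast,
#'   1 = bacterium), `strain` (0 = wild, 1 = mutant), `energy`, `row`, `col`
#'   (0-based patch coordinates), and the `tick` counter.
#' @export
init_world <- function(cfg) {
  cfg <- validate_sim_config(unclass(cfg))
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  cpp_init_world(cfg)
}

#' Diffuse a metabolite grid over its 8 toroidal neighbours
#'
#' Each patch keeps `1 - rate` of its amount and gives `rate / 8` to each of
#' its eight neighbours (Moore neighbourhood, wrap-around edges). Total mass
#' is conserved exactly up to floating-point rounding.
#'
#' @param grid Non-negative numeric matrix of per-patch amounts.
#' @param rate Fraction in \[0,1\] leaving the focal patch per step.
#' @return Matrix of the same shape.
#' @examples
#' g <- matrix(0, 3, 3); g[2, 2] <- 8
#' diffuse(g, 0.5)
#' @export
diffuse <- function(grid, rate) {
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) ||
      rate < 0 || rate > 1)
    stop("diffusion rate must lie in [0,1]", call. = FALSE)
  if (any(grid < 0)) stop("grid amounts must be non-negative", call. = FALSE)
  cpp_diffuse(grid, rate)
}

#' Advance the world by one tick
#'
#' Applies the fixed sub-step order: (1) mixing movement (each agent teleports
#' to a random patch with probability `cfg$mixing`); (2) secretion (yeast
#' deposit amino acids, bacteria deposit vitamin scaled by the mutant fold,
#' paying the per-unit energy cost unconditionally); (3) diffusion of both
#' pools; (4) consumption in a freshly shuffled agent order, each agent taking
#' up to its uptake maximum from its own patch; (5) death of agents at
#' energy <= 0; (6) division of agents at or above the division threshold into
#' two same-patch daughters holding half the energy each.
#'
#' @param world An `abm_world`.
#' @param cfg The [sim_config()].
#' @return The updated `abm_world` (tick counter incremented).
#' @export
abm_tick <- function(world, cfg) {
  cpp_tick(world, cfg)
}

#' Run one growth cycle up to the transfer threshold
#'
#' Ticks the world until the census reaches `transfer_threshold(cfg)`
#' (`"reached_threshold"`), all agents are dead (`"extinct"`), or
#' `cfg$max_ticks_per_transfer` is exceeded (`"timed_out"`). One population
#' record is appended per tick.
#'
#' @param world An `abm_world`.
#' @param cfg The [sim_config()].
#' @param transfer_index Integer label written into the records.
#' @return A list with `world`, `records` (data.frame with columns
#'   `transfer, tick, n_yeast, n_wt, n_mutant, total_aa, total_vit`), and
#'   `outcome` (one of `"reached_threshold"`, `"extinct"`, `"timed_out"`).
#' @export
run_transfer_cycle <- function(world, cfg, transfer_index = 1L) {
  res <- cpp_run_transfer_cycle(world, cfg, as.integer(transfer_index))
  list(world = res$world,
       records = as.data.frame(res$records),
       outcome = c("reached_threshold", "extinct", "timed_out")[res$outcome + 1L])
}

#' Dilute the population into a fresh world (serial transfer)
#'
#' Samples exactly `init_total(cfg)` agents uniformly without replacement
#' (label-blind; all agents are kept if fewer exist), resets both metabolite
#' pools to zero, re-randomizes agent positions, and preserves agent energies.
#'
#' @param world An `abm_world` holding at least one agent.
#' @param cfg The [sim_config()].
#' @return The diluted `abm_world` with `tick` reset to 0.
#' @export
apply_transfer <- function(world, cfg) {
  if (length(world$energy) == 0)
    stop("cannot transfer an empty world", call. = FALSE)
  cpp_apply_transfer(world, cfg)
}

#' Run one full serial-transfer replicate
#'
#' Initializes a world and alternates growth cycles with serial transfers for
#' `cfg$n_transfers` rounds. A replicate that goes extinct or times out before
#' completing all transfers is flagged `collapsed` (and counts as not
#' invaded). Invasion means at least one mutant bacterium is present
#' immediately after the final transfer's dilution.
#'
#' @param cfg The [sim_config()].
#' @param seed Optional integer seed applied before the run.
#' @param keep_records Keep the per-tick population records (slower).
#' @return A list with `world`, `records` (or NULL), `transfers_completed`,
#'   `collapsed`, `invaded`, `final_mutant_fraction` (mutants over all
#'   bacteria at the end; NA when no bacteria remain), and the final counts
#'   `n_yeast`, `n_wt`, `n_mutant`.
#' @export
run_replicate <- function(cfg, seed = NULL, keep_records = FALSE) {
  cfg <- validate_sim_config(unclass(cfg))
  if (!is.null(seed)) set.seed(seed) else if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  res <- cpp_run_replicate(cfg, isTRUE(keep_records))
  if (!is.null(res$records)) res$records <- as.data.frame(res$records)
  res
}

#' Write per-tick population records as CSV
#'
#' Column layout: `transfer,tick,n_yeast,n_wt,n_mutant,total_aa,total_vit`.
#'
#' @param records Data frame as returned in `records` by
#'   [run_transfer_cycle()] or [run_replicate()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(records, path) {
  want <- c("transfer", "tick", "n_yeast", "n_wt", "n_mutant",
            "total_aa", "total_vit")
  if (!all(want %in% names(records)))
    stop("records must have columns ", paste(want, collapse = ","),
         call. = FALSE)
  write.csv(records[, want], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
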