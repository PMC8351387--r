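# Shared replicate batches for the full-scale invasion analyses. Heavy
# conditions are computed once per test run and reused across test blocks.
.batch_cache <- new.env(parent = emptyenv())

invasion_batch <- function(mixing, fold, n = 200L, base_seed = NULL) {
  if (is.null(base_seed))
    base_seed <- 7000000L + round(1000000 * mixing) + round(1000 * fold)
  key <- paste(mixing, fold, n, base_seed, sep = "|")
  if (!is.null(.batch_cache[[key]])) return(.batch_cache[[key]])
  cfg <- sim_config(mixing = mixing, mutant_secretion_fold = fold)
  out <- run_replicates(cfg, n_replicates = n, base_seed = base_seed)
  .batch_cache[[key]] <- out
  out
}
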