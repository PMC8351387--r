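#' Run many serial-transfer replicates of the invasion experiment
#'
#' Replicate `i` runs [run_replicate()] with seed `base_seed + i - 1`, so the
#' outcome sequence is deterministic for a given `(config, base_seed)` and
#' order-stable: adding replicates never perturbs earlier ones.
#'
#' @param cfg A [sim_config()]; its `mixing` and `mutant_secretion_fold`
#'   define the experimental condition.
#' @param n_replicates Number of independent replicates (the full-scale
#'   experiment uses 200).
#' @param base_seed Integer seed of the first replicate.
#' @param keep_records Keep per-tick population records on each outcome
#'   (memory-heavy at full scale).
#' @return A data.frame with one row per replicate: `mixing`, `fold`, `seed`,
#'   `invaded`, `final_mutant_fraction` (NA unless invaded), `collapsed`,
#'   `transfers_completed`. When `keep_records` is TRUE the records are
#'   attached as a list attribute `"records"`.
#' @export
run_replicates <- function(cfg, n_replicates = 200L, base_seed = 1L,
                           keep_records = FALSE) {
  stopifnot(n_replicates >= 1)
  seeds <- base_seed + seq_len(n_replicates) - 1L
  recs <- if (keep_records) vector("list", n_replicates) else NULL
  rows <- lapply(seq_along(seeds), function(i) {
    r <- run_replicate(cfg, seed = seeds[i], keep_records = keep_records)
    if (keep_records) recs[[i]] <<- r$records
    data.frame(mixing = cfg$mixing, fold = cfg$mutant_secretion_fold,
               seed = seeds[i], invaded = r$invaded,
               final_mutant_fraction = if (r$invaded) r$final_mutant_fraction else NA_real_,
               collapsed = r$collapsed,
               transfers_completed = r$transfers_completed)
  })
  out <- do.call(rbind, rows)
  if (keep_records) attr(out, "records") <- recs
  out
}

#' Summarize invasion outcomes for one (mixing, fold) condition
#'
#' Computes the invasion percentage and the summary statistics of the final
#' mutant fraction over *invaded* replicates only. Following the convention
#' of the full-scale experiment's figures, the fraction mean is reported as 0
#' when there was no successful invasion, and the standard deviation is
#' reported only when more than two invasions occurred.
#'
#' @param outcomes Data.frame from [run_replicates()]; all rows must share
#'   one (mixing, fold) condition.
#' @return One-row data.frame: `mixing`, `fold`, `n`, `invasion_percent`,
#'   `frac_mean`, `frac_sd` (NA when <= 2 invasions), `frac_min`, `frac_max`,
#'   `n_collapsed`.
#' @export
summarize_outcomes <- function(outcomes) {
  if (nrow(outcomes) == 0) stop("no outcomes to summarize", call. = FALSE)
  if (length(unique(outcomes$mixing)) != 1 || length(unique(outcomes$fold)) != 1)
    stop("outcomes must share one (mixing, fold) condition", call. = FALSE)
  inv <- outcomes$invaded
  fr <- outcomes$final_mutant_fraction[inv]
  data.frame(
    mixing = outcomes$mixing[1],
    fold = outcomes$fold[1],
    n = nrow(outcomes),
    invasion_percent = 100 * mean(inv),
    frac_mean = if (any(inv)) mean(fr) else 0,
    frac_sd = if (sum(inv) > 2) sd(fr) else NA_real_,
    frac_min = if (any(inv)) min(fr) else NA_real_,
    frac_max = if (any(inv)) max(fr) else NA_real_,
    n_collapsed = sum(outcomes$collapsed)
  )
}

#' Two-sided Fisher's exact test on two invasion counts
#'
#' Compares `k1` successes of `n1` trials against `k2` of `n2` by the exact
#' hypergeometric two-sided rule: the p-value sums the probabilities of all
#' tables with the same margins whose probability does not exceed that of the
#' observed table.
#'
#' @param k1,n1 Successes and trials in the first condition.
#' @param k2,n2 Successes and trials in the second condition.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' fisher_invasion_test(10, 100, 1, 100)
#' @export
fisher_invasion_test <- function(k1, n1, k2, n2) {
  if (any(c(k1, n1, k2, n2) < 0) || k1 > n1 || k2 > n2)
    stop("counts must satisfy 0 <= k <= n", call. = FALSE)
  m <- k1 + k2                # total successes
  lo <- max(0, m - n2)
  hi <- min(m, n1)
  support <- lo:hi
  probs <- dhyper(support, n1, n2, m)
  p_obs <- dhyper(k1, n1, n2, m)
  # 1e-7 relative slack guards against ties lost to floating point
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, max(p, .Machine$double.xmin))
}

#' Sweep the mixing x secretion-fold grid of the invasion experiment
#'
#' Runs `n_replicates` serial-transfer replicates for every combination of
#' `mixing_values` and `folds` and summarizes each cell with
#' [summarize_outcomes()]. Grid cells use disjoint seed blocks
#' (`base_seed + (cell_index - 1) * seed_stride`), so adding cells never
#' perturbs existing ones.
#'
#' @param cfg Base [sim_config()]; `mixing` and `mutant_secretion_fold` are
#'   overridden per cell.
#' @param mixing_values Mixing strengths (default 0 to 1 in steps of 0.1).
#' @param folds Mutant secretion folds (default 1, 1.5, 2, 3).
#' @param n_replicates Replicates per cell (full scale: 200).
#' @param base_seed First seed of the first cell.
#' @param seed_stride Seed-block size per cell; must be >= `n_replicates`.
#' @param outdir Optional directory; when given, writes `summary.csv` and,
#'   if `per_run_csv` is TRUE, one per-replicate population CSV each.
#' @param per_run_csv Write per-replicate tick records as CSV (slow).
#' @return Data.frame with one summary row per grid cell.
#' @export
sweep_invasion <- function(cfg,
                           mixing_values = seq(0, 1, by = 0.1),
                           folds = c(1, 1.5, 2, 3),
                           n_replicates = 200L,
                           base_seed = 1L,
                           seed_stride = 10000L,
                           outdir = NULL,
                           per_run_csv = FALSE) {
  stopifnot(all(mixing_values >= 0 & mixing_values <= 1), all(folds >= 0),
            seed_stride >= n_replicates)
  grid <- expand.grid(fold = folds, mixing = mixing_values,
                      KEEP.OUT.ATTRS = FALSE)
  cells <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell_cfg <- validate_sim_config(modifyList(
      unclass(cfg), list(mixing = grid$mixing[i],
                         mutant_secretion_fold = grid$fold[i])))
    seed_i <- base_seed + (i - 1L) * as.integer(seed_stride)
    out <- run_replicates(cell_cfg, n_replicates, seed_i,
                          keep_records = per_run_csv)
    if (!is.null(outdir) && per_run_csv) {
      recs <- attr(out, "records")
      for (j in seq_along(recs)) {
        if (is.null(recs[[j]])) next
        f <- file.path(outdir, sprintf("run_m%s_f%s_s%d.csv",
                                       grid$mixing[i], grid$fold[i], out$seed[j]))
        write_population_csv(recs[[j]], f)
      }
    }
    cells[[i]] <- summarize_outcomes(out)
  }
  summary <- do.call(rbind, cells)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.csv(summary, file.path(outdir, "summary.csv"),
              row.names = FALSE, quote = FALSE)
  }
  summary
}
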