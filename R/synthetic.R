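#' Synthetic logistic growth curve with known ground truth
#'
#' Samples `OD(t) = K / (1 + (K / od0 - 1) * 2^(-r t))` on a regular time
#' grid and applies multiplicative noise (Gaussian on log2 OD, standard
#' deviation `sigma`), emulating plate-reader OD600 kinetics of a batch
#' culture. The generator is a pure function of `(arguments, seed)`
#' (Mersenne-Twister via `set.seed()`), and returns its ground truth so
#' estimator tests can close the loop.
#'
#' @param r True low-density growth rate in doublings per hour.
#' @param K Carrying capacity (OD600 units).
#' @param od0 Inoculation OD600; must be below `K`.
#' @param times Sampling times in hours.
#' @param sigma Standard deviation of the noise on log2(OD).
#' @param seed Integer seed.
#' @return List with `curve` (a [growth_curve()]) and `truth`
#'   (`r`, `K`, `od0`, `sigma`).
#' @examples
#' g <- gen_growth_curve(r = 0.5, seed = 1)
#' growth_rate(g$curve)$rate
#' @export
gen_growth_curve <- function(r = 0.5, K = 2, od0 = 0.01,
                             times = seq(0, 48, by = 1),
                             sigma = 0.02, seed = 1L) {
  if (r <= 0) stop("true rate r must be positive", call. = FALSE)
  if (K <= od0) stop("capacity K must exceed the initial OD", call. = FALSE)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  set.seed(seed)
  od <- K / (1 + (K / od0 - 1) * 2^(-r * times))
  if (sigma > 0) od <- 2^(log2(od) + rnorm(length(od), 0, sigma))
  list(curve = growth_curve(times, od),
       truth = list(r = r, K = K, od0 = od0, sigma = sigma))
}

#' Synthetic screening-plate fluorescence with known fold-changes
#'
#' Emulates a supernatant fluorescence screen of evolved isolates against a
#' parental baseline: each isolate's true intensity is
#' `parental_mean * fold`, observed under multiplicative lognormal noise
#' with coefficient of variation `cv`. Isolates are labelled letter +
#' community number (`"A1"`, `"B4"`, ...), the screening-plate naming
#' convention.
#'
#' @param parental_mean True parental fluorescence intensity.
#' @param true_folds Named or unnamed numeric vector of true fold-changes,
#'   one per isolate. Unnamed vectors get plate-style labels.
#' @param n_replicates Replicate wells per strain.
#' @param cv Coefficient of variation of the multiplicative noise
#'   (default 0.39, matching a parental readout spread of about 16.4/42).
#' @param seed Integer seed.
#' @return List with `assay` (fields `parental_values`, `isolate_values`,
#'   `blank_value = NULL`) and `truth` (the fold-change vector).
#' @examples
#' p <- gen_fluorescence_plate(true_folds = c(B4 = 3.2, E6 = 10), seed = 1)
#' sapply(p$assay$isolate_values, mean) / mean(p$assay$parental_values)
#' @export
gen_fluorescence_plate <- function(parental_mean = 42,
                                   true_folds = c(B4 = 3.2, E6 = 10),
                                   n_replicates = 5L,
                                   cv = 0.39, seed = 1L) {
  if (parental_mean <= 0) stop("parental_mean must be positive", call. = FALSE)
  stopifnot(n_replicates >= 1, cv >= 0)
  if (is.null(names(true_folds)))
    names(true_folds) <- paste0(LETTERS[seq_along(true_folds)],
                                seq_along(true_folds))
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  draw <- function(mu) mu * exp(rnorm(n_replicates, -sdlog^2 / 2, sdlog))
  assay <- list(
    parental_values = draw(parental_mean),
    isolate_values = lapply(true_folds, function(f) draw(parental_mean * f)),
    blank_value = NULL
  )
  list(assay = assay, truth = list(parental_mean = parental_mean,
                                   folds = true_folds, cv = cv))
}

#' Synthetic flux-fit case on the bundled toy network
#'
#' Builds a complete input set for [fit_relative_expression()]: the bundled
#' toy [metabolic_model()], an expression table that applies `pathway_log2fc`
#' to the first riboflavin-pathway enzyme (GTP cyclohydrolase II; all other
#' enzymes get 0 and fall below the 0.5 filter), and a reference/evolved
#' condition pair with the stated growth lower bounds.
#'
#' @param pathway_log2fc True log2 fold-change applied to the
#'   riboflavin-branch enzyme.
#' @param mu_ref,mu_evo Growth lower bounds (h^-1) of the two conditions.
#' @param product_lb_ref Riboflavin-production lower bound of the reference
#'   (parental) condition, mmol gCDW^-1 h^-1.
#' @return List with `model`, `expr` (an [expression_input()]), `ref`,
#'   `evo` (two [condition_spec()]s) and `truth`.
#' @examples
#' cs <- gen_toy_model_case(pathway_log2fc = 1)
#' fit_relative_expression(cs$model, cs$ref, cs$evo, cs$expr)$target_ratio
#' @export
gen_toy_model_case <- function(pathway_log2fc = 1,
                               mu_ref = 0.1, mu_evo = 0.1,
                               product_lb_ref = 6.13e-6) {
  model <- toy_model()
  enzymes <- unique(unlist(model$reactions$enzymes))
  fc <- setNames(numeric(length(enzymes)), enzymes)
  fc["RibA"] <- pathway_log2fc
  list(model = model,
       expr = expression_input(fc, threshold = 0.5),
       ref = condition_spec(growth_lb = mu_ref, product_lb = product_lb_ref),
       evo = condition_spec(growth_lb = mu_evo),
       truth = list(pathway_log2fc = pathway_log2fc))
}
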