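#' Load and validate a simulation configuration from YAML or JSON
#'
#' Keys mirror the [sim_config()] field names exactly; missing keys take the
#' documented defaults, unknown keys are rejected by name. An empty file
#' yields the full default configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [sim_config()].
#' @export
load_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  allowed <- names(formals(sim_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, raw)
}

#' Write a configuration back out (normalized form)
#'
#' @param cfg A [sim_config()].
#' @param path Output path ending in `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Read an expression table (id, log2fc) from CSV
#'
#' @param path CSV with columns `id` and `log2fc`.
#' @param threshold Significance filter passed to [expression_input()].
#' @return An [expression_input()].
#' @export
read_expression_csv <- function(path, threshold = 0.5) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "log2fc") %in% names(d)))
    stop("expression CSV needs columns id,log2fc", call. = FALSE)
  expression_input(setNames(as.numeric(d$log2fc), d$id), threshold)
}

#' Read a growth curve (time_h, od600) from CSV
#'
#' @param path CSV with columns `time_h` and `od600` (an optional
#'   `replicate` column splits the file into one curve per replicate).
#' @return A [growth_curve()], or a named list of them when a `replicate`
#'   column is present.
#' @export
read_growth_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "od600") %in% names(d)))
    stop("growth CSV needs columns time_h,od600", call. = FALSE)
  if ("replicate" %in% names(d)) {
    lapply(split(d, d$replicate),
           function(g) growth_curve(g$time_h, g$od600))
  } else {
    growth_curve(d$time_h, d$od600)
  }
}

#' Import a stoichiometric model from SBML
#'
#' Reads an SBML Level 3 file with FBC-style flux bounds (per-reaction
#' `fbc:lowerFluxBound` / `fbc:upperFluxBound` parameter references, with
#' plain `lowerbound`/`upperbound` attributes as fallback) and gene-product
#' associations. Exchange reactions are recognized by an `EX_` id prefix or
#' a single-metabolite stoichiometry touching a boundary species; the oxygen
#' exchange is matched on an `o2` token in its id. Intended for user-supplied
#' genome-scale models; the bundled [toy_model()] covers everything the
#' package itself needs.
#'
#' @param path SBML file path.
#' @param biomass_id,target_id Reaction ids of the biomass and target
#'   product reaction. When NULL, the first id containing "biomass" (case
#'   insensitive) is used for biomass, and the target falls back to the
#'   biomass reaction.
#' @return A [metabolic_model()].
#' @export
read_sbml_model <- function(path, biomass_id = NULL, target_id = NULL) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                    xml2::xml_attr(params, "id"))
  bspecies <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  boundary <- xml2::xml_attr(bspecies, "id")[
    xml2::xml_attr(bspecies, "boundaryCondition") %in% "true"]

  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rxn_nodes)) stop("no reactions found in SBML", call. = FALSE)

  stoich <- list(); lb <- c(); ub <- c(); enzymes <- list()
  for (rn in rxn_nodes) {
    id <- xml2::xml_attr(rn, "id")
    sto <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rn, paste0("./s:", side, "/s:speciesReference"), ns)
      if (!length(refs)) next
      sp <- xml2::xml_attr(refs, "species")
      co <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      co[is.na(co)] <- 1
      if (side == "listOfReactants") co <- -co
      for (i in which(!(sp %in% boundary))) {
        prev <- if (sp[i] %in% names(sto)) sto[[sp[i]]] else 0
        sto[sp[i]] <- prev + co[i]
      }
    }
    stoich[[id]] <- sto
    lref <- xml2::xml_attr(rn, "lowerFluxBound")
    uref <- xml2::xml_attr(rn, "upperFluxBound")
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    lb[id] <- if (!is.na(lref) && lref %in% names(pvals)) pvals[[lref]] else if (rev) -1000 else 0
    ub[id] <- if (!is.na(uref) && uref %in% names(pvals)) pvals[[uref]] else 1000
    gps <- xml2::xml_find_all(rn, ".//fbc:geneProductRef", ns)
    if (length(gps))
      enzymes[[id]] <- unique(xml2::xml_attr(gps, "geneProduct"))
  }
  ids <- names(stoich)
  n_mets <- lengths(stoich)
  exchange <- ids[grepl("^EX_", ids) | n_mets <= 1]
  oxygen <- exchange[grepl("(^|_)o2(_|$)", exchange, ignore.case = TRUE)]
  if (is.null(biomass_id)) {
    hit <- ids[grepl("biomass", ids, ignore.case = TRUE)]
    if (!length(hit)) stop("no biomass reaction found; pass biomass_id",
                           call. = FALSE)
    biomass_id <- hit[1]
  }
  if (is.null(target_id)) target_id <- biomass_id
  metabolic_model(stoich, lb, ub, exchange = exchange,
                  oxygen_id = if (length(oxygen)) oxygen[1] else NULL,
                  enzymes = enzymes,
                  biomass_id = biomass_id, target_id = target_id)
}

#' Write a run manifest beside outputs
#'
#' Records tool version, the fully resolved configuration, the seeds used,
#' digests of input files, the list of outputs and wall-clock timestamps —
#' enough to re-execute a deterministic stage bit-identically.
#'
#' @param path Manifest output path (JSON).
#' @param config Resolved configuration (list).
#' @param seeds Named or plain vector of seeds used.
#' @param inputs Character vector of input file paths (digested with md5).
#' @param outputs Character vector of output file paths.
#' @param started,finished POSIXct timestamps.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seeds = integer(),
                           inputs = character(), outputs = character(),
                           started = Sys.time(), finished = Sys.time()) {
  digest <- vapply(inputs, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_,
    character(1))
  manifest <- list(
    tool = paste0("mutualev ", as.character(utils::packageVersion("mutualev"))),
    config = config, seeds = as.list(seeds),
    inputs = if (length(inputs)) setNames(as.list(digest), inputs) else list(),
    outputs = as.list(outputs),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `sweep`, `marge`, `phenotype` and
#' `synth` over the package's functions; see the thin wrapper script in
#' `inst/cli/mutualev.R`. Returns (rather than calls) an exit status so it
#' is testable in-process.
#'
#' @param args Character vector of command-line arguments (after the
#'   script name).
#' @return Integer exit status: 0 on success, 2 on usage error.
#' @export
mutualev_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mutualev <simulate|sweep|marge|phenotype|synth> [options]",
    "  simulate  --config c.yaml --out dir [--seed N]",
    "  sweep     --config c.yaml --out dir [--seed N] [--mixing 0,0.5,1]",
    "            [--folds 1,1.5,2,3] [--replicates 200]",
    "  marge     --expr expr.csv [--model path.xml] [--mu-ref X] [--mu-evo Y]",
    "            [--epsilon 0.03] [--product-lb Z] --out dir",
    "  phenotype growth --in f.csv --out dir [--min-points 5]",
    "  synth     growth|plate --out dir [--seed N]",
    sep = "\n")
  if (!length(args)) { message(usage); return(2L) }
  cmd <- args[1]; rest <- args[-1]

  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (!length(i)) return(default)
    if (i[1] == length(rest)) stop("missing value for ", flag, call. = FALSE)
    rest[i[1] + 1]
  }
  nums <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
  started <- Sys.time()

  status <- tryCatch({
    outdir <- opt("--out", ".")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(opt("--seed", "1"))
    switch(cmd,
      simulate = {
        cfg <- load_sim_config(opt("--config"))
        r <- run_replicate(cfg, seed = seed, keep_records = TRUE)
        f <- file.path(outdir, "population.csv")
        write_population_csv(r$records, f)
        write_manifest(file.path(outdir, "manifest.json"),
                       config = unclass(cfg), seeds = seed,
                       outputs = f, started = started)
        message("simulate: ", r$transfers_completed, " transfers completed; ",
                "invaded = ", r$invaded)
        0L
      },
      sweep = {
        cfg <- load_sim_config(opt("--config"))
        s <- sweep_invasion(cfg,
               mixing_values = nums(opt("--mixing", "0,0.5,1")),
               folds = nums(opt("--folds", "1,1.5,2,3")),
               n_replicates = as.integer(opt("--replicates", "200")),
               base_seed = seed, outdir = outdir)
        write_manifest(file.path(outdir, "manifest.json"),
                       config = unclass(cfg), seeds = seed,
                       outputs = file.path(outdir, "summary.csv"),
                       started = started)
        message("sweep: ", nrow(s), " cells written to ",
                file.path(outdir, "summary.csv"))
        0L
      },
      marge = {
        mpath <- opt("--model", "toy")
        model <- if (identical(mpath, "toy")) toy_model() else read_sbml_model(mpath)
        expr <- read_expression_csv(opt("--expr"))
        # reference product bound defaults to the parental specific rate that
        # anchors the toy workflow; pass --product-lb for real data
        plb <- as.numeric(opt("--product-lb", "6.13e-6"))
        ref <- condition_spec(growth_lb = as.numeric(opt("--mu-ref", "0.1")),
                              product_lb = plb)
        evo <- condition_spec(growth_lb = as.numeric(opt("--mu-evo", "0.1")))
        fit <- fit_relative_expression(model, ref, evo, expr,
                                       epsilon = as.numeric(opt("--epsilon", "0.03")))
        f <- file.path(outdir, "marge_result.json")
        jsonlite::write_json(list(
          target_ratio = fit$target_ratio, residual = fit$residual,
          epsilon = fit$epsilon,
          fluxes_ref = as.list(fit$fluxes_ref),
          fluxes_evo = as.list(fit$fluxes_evo)), f,
          auto_unbox = TRUE, digits = NA)
        write_manifest(file.path(outdir, "manifest.json"),
                       seeds = integer(), outputs = f, started = started)
        message("marge: target flux ratio ", signif(fit$target_ratio, 4))
        0L
      },
      phenotype = {
        sub <- rest[1]
        if (!identical(sub, "growth"))
          stop("phenotype subcommand must be 'growth'", call. = FALSE)
        curves <- read_growth_csv(opt("--in"))
        if (inherits(curves, "growth_curve")) curves <- list(curve = curves)
        mp <- as.integer(opt("--min-points", "5"))
        res <- data.frame(replicate = names(curves),
                          rate = vapply(curves, function(g)
                            growth_rate(g, mp)$rate, numeric(1)))
        f <- file.path(outdir, "growth_rates.csv")
        write.csv(res, f, row.names = FALSE, quote = FALSE)
        message("phenotype growth: ", nrow(res), " rates written")
        0L
      },
      synth = {
        sub <- rest[1]
        if (identical(sub, "growth")) {
          g <- gen_growth_curve(seed = seed)
          f <- file.path(outdir, "growth_curve.csv")
          write.csv(data.frame(time_h = g$curve$times, od600 = g$curve$ods),
                    f, row.names = FALSE, quote = FALSE)
        } else if (identical(sub, "plate")) {
          p <- gen_fluorescence_plate(seed = seed)
          rows <- rbind(
            data.frame(strain = "parental", intensity = p$assay$parental_values),
            do.call(rbind, lapply(names(p$assay$isolate_values), function(nm)
              data.frame(strain = nm, intensity = p$assay$isolate_values[[nm]]))))
          f <- file.path(outdir, "plate.csv")
          write.csv(rows, f, row.names = FALSE, quote = FALSE)
        } else stop("synth subcommand must be growth or plate", call. = FALSE)
        write_manifest(file.path(outdir, "manifest.json"),
                       seeds = seed, outputs = f, started = started)
        message("synth ", sub, ": written to ", f)
        0L
      },
      { message("unknown subcommand: ", cmd, "\n", usage); 2L })
  }, error = function(e) {
    message("mutualev ", cmd, ": ", conditionMessage(e))
    1L
  })
  status
}
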