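.pipelineDefaults <- function() {
  list(
    natural = NULL,            # path to CSV/TSV/FASTA, or a PromoterSet
    outDir = "promodiff_run",
    seed = 1L,
    splitFraction = 0.2,
    generator = list(steps = 200L, betaStart = 1e-4, betaEnd = 0.1,
                     epochs = 60L, batchSize = 64L, hidden = 64L,
                     blocks = 2L, kernel = 5L, lr = 1e-3,
                     checkpointEvery = 10L, count = 1000L),
    predictor = list(dModel = 64L, heads = 4L, layers = 2L, ff = 128L,
                     dropout = 0.1, wMse = 1, wPcc = 1, lr = 1e-3,
                     epochs = 40L, batchSize = 64L, patience = 20L),
    evaluation = list(ks = 2:6, kmers = NULL, nTopKmers = 6L),
    mutagenesis = list(sampleSize = 200L,
                       regions = list(minus10 = c(-12, -7),
                                      minus35 = c(-36, -31))),
    logLevel = "info")
}

#' Validate (and default-fill) a pipeline configuration
#'
#' Accepts a YAML file path or a list; applies defaults for missing keys,
#' type-checks the rest, and aggregates all problems into a single error
#' instead of failing fast. Unknown keys produce a warning, not an error.
#'
#' @param config A YAML file path or a named list. Recognised keys:
#'   `natural` (input dataset path or PromoterSet), `outDir`, `seed`,
#'   `splitFraction`, and sub-lists `generator`, `predictor`,
#'   `evaluation`, `mutagenesis`.
#' @return The validated config list (class `RunConfig`).
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- tryCatch(yaml::read_yaml(config),
      error = function(e) stop("unparseable config file: ",
                               conditionMessage(e), call. = FALSE))
  }
  if (!is.list(config)) stop("config must be a list or file path",
                             call. = FALSE)
  defaults <- .pipelineDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    warning("unknown config key(s) ignored: ",
            paste(unknown, collapse = ", "))
  merged <- defaults
  for (k in intersect(names(config), names(defaults))) {
    merged[[k]] <- if (is.list(defaults[[k]]) && is.list(config[[k]]) &&
                       !is(config[[k]], "PromoterSet"))
      utils::modifyList(defaults[[k]], config[[k]]) else config[[k]]
  }
  errs <- character()
  if (is.null(merged$natural))
    errs <- c(errs, "natural: an input dataset (path or PromoterSet) is required")
  else if (is.character(merged$natural) && !file.exists(merged$natural))
    errs <- c(errs, paste0("natural: file not found: ", merged$natural))
  sf <- merged$splitFraction
  if (!is.numeric(sf) || sf <= 0 || sf >= 1)
    errs <- c(errs, "splitFraction: must lie strictly between 0 and 1")
  if (!is.numeric(merged$seed) || length(merged$seed) != 1L)
    errs <- c(errs, "seed: must be a single integer")
  g <- merged$generator
  if (g$steps < 1L) errs <- c(errs, "generator.steps: must be >= 1")
  if (g$count < 0L) errs <- c(errs, "generator.count: must be >= 0")
  if (merged$predictor$dModel %% merged$predictor$heads != 0L)
    errs <- c(errs, "predictor.dModel: must be divisible by predictor.heads")
  if (merged$mutagenesis$sampleSize < 1L)
    errs <- c(errs, "mutagenesis.sampleSize: must be >= 1")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  structure(merged, class = c("RunConfig", "list"))
}

.stage <- function(name, quiet, expr) {
  t0 <- Sys.time()
  if (!quiet) message(sprintf("[%s] starting", name))
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
  if (!quiet)
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the end-to-end promoter design pipeline
#'
#' Orchestrates the full workflow: load the natural promoter set, train
#' the diffusion generator on its sequences, sample synthetic promoters,
#' train the transformer strength predictor on the labelled 4:1 train
#' split, predict and rank the synthetic promoters, evaluate generation
#' fidelity (k-mer correlations, positional profiles, sequence logos)
#' against the natural set, run saturation mutagenesis on the test split,
#' and write all tables plus a machine-readable JSON report to the output
#' directory. Fully deterministic given `config$seed`.
#'
#' @param config A config list or YAML path (see [validateConfig()]).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, the report list (also written to
#'   `outDir/report.json`). Written files: `generated.fasta`,
#'   `ddpm_trainlog.csv`, `screened.csv` (ranked predictions, normalized
#'   and raw scale), `kmer_pcc.json`, `spectra_k*.csv`, `profiles.csv`,
#'   `logo_natural.csv`, `logo_generated.csv`, `mutations.csv`,
#'   `mutation_summary.csv`, `region_contrast.csv`, `config.yaml`.
#' @export
runDesignPipeline <- function(config, quiet = FALSE) {
  cfg <- validateConfig(config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  natural <- .stage("load", quiet, {
    if (is(cfg$natural, "PromoterSet")) cfg$natural
    else readPromoterTable(cfg$natural)
  })
  cfgFile <- file.path(cfg$outDir, "config.yaml")
  cfgOut <- cfg
  if (is(cfgOut$natural, "PromoterSet"))
    cfgOut$natural <- sprintf("<in-memory PromoterSet, %d records>",
                              length(natural))
  yaml::write_yaml(unclass(cfgOut), cfgFile)
  meta <- list(package_version = as.character(utils::packageVersion("promodiff")),
               config_md5 = unname(tools::md5sum(cfgFile)),
               seed = cfg$seed)

  g <- cfg$generator
  ddpm <- .stage("generator_training", quiet,
    trainDDPM(natural,
              schedule = buildSchedule(g$steps, g$betaStart, g$betaEnd),
              epochs = g$epochs, batchSize = g$batchSize,
              hidden = g$hidden, blocks = g$blocks, kernel = g$kernel,
              lr = g$lr, checkpointEvery = g$checkpointEvery,
              seed = subSeed(cfg$seed, "ddpm")))
  utils::write.csv(trainingLog(ddpm),
                   file.path(cfg$outDir, "ddpm_trainlog.csv"),
                   row.names = FALSE)
  generated <- .stage("generation", quiet,
    samplePromoters(ddpm, g$count, seed = subSeed(cfg$seed, "sample")))
  writePromoterFasta(generated, file.path(cfg$outDir, "generated.fasta"))

  split <- splitDataset(natural, cfg$splitFraction,
                        seed = subSeed(cfg$seed, "split"))
  pr <- cfg$predictor
  predictor <- .stage("predictor_training", quiet,
    trainPredictor(split$train, predictorConfig(
      dModel = pr$dModel, heads = pr$heads, layers = pr$layers,
      ff = pr$ff, dropout = pr$dropout, wMse = pr$wMse, wPcc = pr$wPcc,
      lr = pr$lr, epochs = pr$epochs, batchSize = pr$batchSize,
      patience = pr$patience, seed = subSeed(cfg$seed, "predictor"))))
  testPcc <- evaluatePredictor(predictor, split$test)

  screened <- .stage("screening", quiet, {
    predNorm <- predictStrength(predictor, generated)
    df <- data.frame(id = names(generated),
                     sequence = as.character(promoterSequences(generated)),
                     predicted_norm = unname(predNorm),
                     predicted_raw = unname(denormalizeStrengths(
                       predNorm, predictor@norm)))
    df[order(-df$predicted_norm), , drop = FALSE]
  })
  utils::write.csv(screened, file.path(cfg$outDir, "screened.csv"),
                   row.names = FALSE)

  ev <- cfg$evaluation
  evalOut <- .stage("evaluation", quiet, {
    pccs <- setNames(vapply(ev$ks, function(k)
      kmerPcc(generated, natural, k), numeric(1)),
      paste0("k", ev$ks))
    for (k in ev$ks) {
      sp <- data.frame(kmer = names(kmerSpectrum(natural, k)),
                       freq_natural = as.numeric(kmerSpectrum(natural, k)),
                       freq_generated = as.numeric(kmerSpectrum(generated, k)))
      utils::write.csv(sp, file.path(cfg$outDir,
                                     sprintf("spectra_k%d.csv", k)),
                       row.names = FALSE)
    }
    kmers <- ev$kmers
    if (is.null(kmers)) {
      sp6 <- kmerSpectrum(natural, 6L)
      kmers <- names(sort(sp6, decreasing = TRUE))[seq_len(ev$nTopKmers)]
    }
    profs <- do.call(rbind, lapply(kmers, function(km) {
      pn <- positionalProfile(natural, km)
      pg <- positionalProfile(generated, km)
      data.frame(kmer = km, position = pn$position,
                 tss_position = pn$tss_position,
                 freq_natural = pn$frequency,
                 freq_generated = pg$frequency)
    }))
    utils::write.csv(profs, file.path(cfg$outDir, "profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(logoMatrix(natural)),
                     file.path(cfg$outDir, "logo_natural.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(logoMatrix(generated)),
                     file.path(cfg$outDir, "logo_generated.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(pccs),
                         file.path(cfg$outDir, "kmer_pcc.json"),
                         auto_unbox = TRUE, digits = NA)
    list(pccs = pccs, kmers = kmers)
  })

  mu <- cfg$mutagenesis
  mutOut <- .stage("mutagenesis", quiet, {
    recs <- saturationMutagenesis(split$test, predictor,
                                  sampleSize = min(mu$sampleSize,
                                                   length(split$test)),
                                  seed = subSeed(cfg$seed, "mutscan"))
    summ <- positionSummaries(recs)
    rc <- regionContrast(summ, mu$regions)
    utils::write.csv(recs, file.path(cfg$outDir, "mutations.csv"),
                     row.names = FALSE)
    utils::write.csv(summ$classSummary,
                     file.path(cfg$outDir, "mutation_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(rc, file.path(cfg$outDir, "region_contrast.csv"),
                     row.names = FALSE)
    list(nRecords = nrow(recs), regionContrast = rc)
  })

  lg <- trainingLog(ddpm)
  report <- list(
    meta = meta,
    generation = list(
      count = length(generated), seqLength = promoterLength(natural),
      heldout_l1_first = lg$heldout_l1[1L],
      heldout_l1_final = lg$heldout_l1[nrow(lg)]),
    screening = list(
      test_pcc = testPcc,
      top_predicted_raw = screened$predicted_raw[1L],
      n_screened = nrow(screened)),
    evaluation = list(kmer_pcc = as.list(evalOut$pccs),
                      profiled_kmers = evalOut$kmers),
    mutagenesis = list(
      n_records = mutOut$nRecords,
      region_contrast = mutOut$regionContrast))
  jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
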