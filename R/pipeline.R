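# End-to-end orchestration: indicators -> index per epoch -> dynamics across
# epochs -> driver detection on the final epoch, with a YAML run
# configuration and a machine-readable run report.

#' Default run configuration
#'
#' Every tunable of the pipeline with its documented default. Supply either
#' \code{scene} (a \code{\link{sceneSpec}} to simulate) or \code{epochs}
#' (a list of per-epoch named band file paths: b1, b2, b4, b6, b7, lst_dn).
#'
#' @param outDir output directory.
#' @param scene optional \code{\link{sceneSpec}}.
#' @param epochs optional list of per-epoch band path lists.
#' @param drivers optional named list of driver raster paths (continuous) or
#'   in-memory \linkS4class{RasterGrid}s; names are factor names.
#' @param waterThreshold MNDWI water threshold.
#' @param saviL SAVI soil-adjustment constant.
#' @param cvEstimator \code{"sd"} or \code{"mad"}.
#' @param opgdSpacing sample stride in cells for driver analysis.
#' @param opgdKRange class counts scanned per continuous factor.
#' @param opgdPerms permutation count for factor significance.
#' @param seed master seed threaded through every stochastic component.
#' @return list of class \code{runConfig}.
#' @export
runConfig <- function(outDir = tempfile("rsei-run-"), scene = NULL,
                      epochs = NULL, drivers = NULL, waterThreshold = 0,
                      saviL = 0.5, cvEstimator = "sd", opgdSpacing = 2L,
                      opgdKRange = 5:10, opgdPerms = 99L, seed = 1L) {
  structure(list(outDir = outDir, scene = scene, epochs = epochs,
                 drivers = drivers, waterThreshold = waterThreshold,
                 saviL = saviL, cvEstimator = cvEstimator,
                 opgdSpacing = as.integer(opgdSpacing),
                 opgdKRange = as.integer(opgdKRange),
                 opgdPerms = as.integer(opgdPerms), seed = as.integer(seed)),
            class = "runConfig")
}

#' Hash a run configuration
#'
#' MD5 of the canonical YAML serialization; changes iff a config field
#' changes.
#'
#' @param config a \code{\link{runConfig}}.
#' @return character MD5 hash.
#' @export
configHash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  cfg <- config
  cfg$outDir <- NULL  # output location does not alter the computation
  writeLines(yaml::as.yaml(cfg), f)
  unname(tools::md5sum(f))
}

#' Write / read a run configuration as YAML
#'
#' @param config a \code{\link{runConfig}}.
#' @param path YAML file path.
#' @return \code{path} / the \code{runConfig}.
#' @export
writeRunConfig <- function(config, path) {
  writeLines(yaml::as.yaml(unclass(config)), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  cfg <- do.call(runConfig, lst[setdiff(names(lst), "scene")])
  if (!is.null(lst$scene)) cfg$scene <- do.call(sceneSpec, lst$scene)
  cfg
}

.loadEpochStack <- function(paths, label) {
  need <- c("b1", "b2", "b4", "b6", "b7", "lst_dn")
  miss <- setdiff(need, names(paths))
  if (length(miss))
    stop("epoch '", label, "': missing band(s) ", paste(miss, collapse = ", "))
  grids <- lapply(need, function(b) {
    if (!file.exists(paths[[b]]))
      stop("epoch '", label, "': band '", b, "' file not found: ", paths[[b]])
    readAsciiGrid(paths[[b]])
  })
  names(grids) <- need
  BandStack(grids[c("b1", "b2", "b4", "b6", "b7")], grids$lst_dn,
            epoch = label)
}

#' Run the full monitoring pipeline
#'
#' Per epoch: water-masked indicators and the composite index; across
#' epochs: consecutive-pair and full-period change summaries, stability
#' (CV) and persistence (Hurst) maps when at least 3 / 8 epochs exist; on
#' the final epoch: optimal-parameter driver detection when drivers are
#' configured. All rasters are written as ASCII grids and tables as TSV
#' under \code{config$outDir}, plus a JSON run report with config hash,
#' seed and per-stage timings.
#'
#' @param config a \code{\link{runConfig}}.
#' @param writeRasters write per-stage rasters (default TRUE).
#' @return the run report, invisibly (list; also written as
#'   \code{report.json}).
#' @export
runPipeline <- function(config, writeRasters = TRUE) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package = "rseikit",
                 version = as.character(utils::packageVersion("rseikit")),
                 seed = config$seed, configHash = configHash(config),
                 timings = list(), stages = list())
  tick <- function() proc.time()[["elapsed"]]
  t0 <- tick()

  # --- assemble epochs ---
  truth <- NULL
  if (!is.null(config$scene)) {
    sim <- simulateTimeseries(config$scene)
    stacks <- sim$stacks
    truth <- sim$truth
  } else if (!is.null(config$epochs)) {
    labels <- names(config$epochs) %||% sprintf("epoch%d",
                                                seq_along(config$epochs))
    stacks <- Map(.loadEpochStack, config$epochs, labels)
  } else stop("config must supply either a scene spec or epoch band paths")
  report$timings$load <- tick() - t0

  # --- per-epoch index ---
  t0 <- tick()
  results <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    st <- stacks[[i]]
    indset <- tryCatch(
      buildIndicatorSet(st, waterThreshold = config$waterThreshold,
                        saviL = config$saviL),
      error = function(e) stop("stage indicators, epoch '", epochLabel(st),
                               "': ", conditionMessage(e)))
    res <- tryCatch(computeRsei(indset),
      error = function(e) stop("stage rsei, epoch '", epochLabel(st), "': ",
                               conditionMessage(e)))
    results[[i]] <- res
    if (writeRasters) {
      writeAsciiGrid(rseiGrid(res),
                     file.path(config$outDir,
                               sprintf("rsei_%s.asc", epochLabel(st))))
      writeAsciiGrid(rseiClasses(res),
                     file.path(config$outDir,
                               sprintf("classes_%s.asc", epochLabel(st))))
    }
    utils::write.table(pcaReport(res),
                       file.path(config$outDir,
                                 sprintf("pca_%s.tsv", epochLabel(st))),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    report$stages$rsei[[epochLabel(st)]] <- list(
      pc1_contribution = contributionRates(rseiPca(res))[1L],
      mean_index = mean(gridValues(rseiGrid(res)), na.rm = TRUE),
      land_cells = sum(!is.na(gridValues(rseiGrid(res)))))
  }
  report$timings$rsei <- tick() - t0

  # --- dynamics ---
  t0 <- tick()
  n <- length(results)
  if (n >= 2L) {
    pairs <- lapply(seq_len(n - 1L), function(i) c(i, i + 1L))
    if (n > 2L) pairs <- c(pairs, list(c(1L, n)))
    chg <- lapply(pairs, function(pr) {
      cs <- changeSummary(rseiClasses(results[[pr[1L]]]),
                          rseiClasses(results[[pr[2L]]]))
      lbl <- sprintf("%s_to_%s", epochLabel(stacks[[pr[1L]]]),
                     epochLabel(stacks[[pr[2L]]]))
      utils::write.table(transitions(cs),
                         file.path(config$outDir,
                                   sprintf("transitions_%s.tsv", lbl)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      d <- gridValues(deltaGrade(cs))
      list(pair = lbl, median_delta = stats::median(d, na.rm = TRUE))
    })
    report$stages$change <- chg
  }
  rseiSeries <- lapply(results, rseiGrid)
  if (n >= 3L) {
    cv <- coefficientOfVariation(rseiSeries, estimator = config$cvEstimator)
    if (writeRasters)
      writeAsciiGrid(cv$cv, file.path(config$outDir, "cv.asc"))
    report$stages$cv <- list(
      mean_cv = mean(gridValues(cv$cv), na.rm = TRUE))
  }
  if (n >= 8L) {
    hu <- hurstExponent(rseiSeries)
    if (writeRasters)
      writeAsciiGrid(hu$hurst, file.path(config$outDir, "hurst.asc"))
    hv <- gridValues(hu$hurst)
    report$stages$hurst <- list(
      mean_h = mean(hv, na.rm = TRUE),
      persistent_pct = 100 * mean(hv[!is.na(hv)] > 0.5))
  }
  report$timings$dynamics <- tick() - t0

  # --- drivers on the final epoch ---
  t0 <- tick()
  if (!is.null(config$drivers) && length(config$drivers)) {
    drv <- lapply(config$drivers, function(d) {
      if (is(d, "RasterGrid")) d else readAsciiGrid(d)
    })
    samp <- sampleGrid(c(list(response = rseiGrid(results[[n]])), drv),
                       spacing = config$opgdSpacing)
    og <- opgdDetect(samp$response,
                     samp[names(drv)],
                     kRange = config$opgdKRange,
                     nPerm = config$opgdPerms, seed = config$seed)
    utils::write.table(factorTable(og),
                       file.path(config$outDir, "opgd_factors.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(interactionTable(og),
                       file.path(config$outDir, "opgd_interactions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    report$stages$opgd <- list(
      factors = factorTable(og)$factor,
      q = factorTable(og)$q)
  }
  report$timings$opgd <- tick() - t0

  report$n_epochs <- n
  if (!is.null(truth)) {
    rl <- vapply(seq_len(n), function(i) {
      rasterCorrelation(rseiGrid(results[[i]]), truth$latent[[i]])
    }, numeric(1L))
    report$latent_correlation <- rl
  }
  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$results <- results
  invisible(report)
}
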