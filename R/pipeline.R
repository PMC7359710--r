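#' Run the settings-driven pipeline on one image
#'
#' Applies the enabled stages in the fixed order atmospheric correction,
#' Mie scattering correction, denoising, wavenumber cutting, baseline
#' correction and normalization, then optionally MCR-ALS decomposition and
#' k-means segmentation of the concentrations. Every stochastic step derives
#' its seed from `settings$seed`, so repeated runs with identical inputs are
#' bit-reproducible.
#'
#' @param img a [HyperImage-class].
#' @param settings a [pipelineSettings()] object.
#' @param atmRef atmospheric [ReferenceSpectrum-class]; default is the
#'   `reference` path in the settings, falling back to the synthetic bundled
#'   line spectrum.
#' @param mieRef initial Mie reference; default is the settings path,
#'   falling back to the image's mean spectrum.
#' @param verbose logical, print one structured line per stage.
#' @return List with `image` (the preprocessed [HyperImage-class]) and,
#'   when enabled, `atmFactors`, `mie` diagnostics, `mcr`
#'   ([MCRResult-class]) and `segmentation` ([SegmentationMap-class]), plus
#'   `timings` (seconds per stage).
#' @export
runPipeline <- function(img, settings = pipelineSettings(), atmRef = NULL,
                        mieRef = NULL, verbose = FALSE) {
  stopifnot(is(img, "HyperImage"), inherits(settings, "PipelineSettings"))
  out <- list()
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stageLog <- function(name, t0, extra = "") {
    timings[[name]] <<- round(tic() - t0, 3)
    if (verbose)
      message(sprintf("[%s] %.2fs %s", name, timings[[name]], extra))
  }
  seed <- as.integer(settings$seed)

  s <- settings$atmospheric
  if (isTRUE(s$enabled)) {
    t0 <- tic()
    if (is.null(atmRef))
      atmRef <- if (!is.null(s$reference)) readReference(s$reference)
                else makeAtmosphereReference()
    res <- atmosphericPipeline(img, atmRef,
                               atmOptions(co2Mode = s$co2Mode,
                                          extraWindowed = isTRUE(s$extraWindowed),
                                          smooth = isTRUE(s$smooth)))
    img <- res$image
    out$atmFactors <- res$factors
    stageLog("atmospheric", t0,
             sprintf("mean factors %s",
                     paste(round(colMeans(res$factors, na.rm = TRUE), 3),
                           collapse = "/")))
  }

  s <- settings$mie
  if (isTRUE(s$enabled)) {
    t0 <- tic()
    # the initial reference must be scattering-free: a spectrum already
    # carrying the image's distortions makes the iteration self-confirming,
    # so the fallback is the bundled clean spectrum, not the image mean
    if (is.null(mieRef))
      mieRef <- if (!is.null(s$reference)) readReference(s$reference)
                else readReference(system.file("extdata",
                                               "reference_synthetic_matrigel.tsv",
                                               package = "vibrospec"),
                                   label = "synthetic matrigel")
    opts <- crmiescOptions(nClusters = s$nClusters,
                           maxIterations = s$maxIterations,
                           stabilize = isTRUE(s$stabilize),
                           clusteringEnabled = isTRUE(s$clusteringEnabled),
                           autoStop = isTRUE(s$autoStop),
                           rescaleByH = isTRUE(s$rescaleByH),
                           extinction = extinctionParams(s$model),
                           N = s$N, seed = seed)
    res <- crmiesc(img, mieRef, opts)
    img <- res$image
    out$mie <- res[c("h", "iterations", "converged")]
    stageLog("mie", t0, sprintf("%d iterations, converged %s",
                                res$iterations, res$converged))
  }

  s <- settings$denoise
  if (isTRUE(s$enabled)) {
    t0 <- tic()
    img <- sgDenoise(img, order = s$order, window = s$window)
    stageLog("denoise", t0)
  }

  s <- settings$cut
  if (isTRUE(s$enabled)) {
    t0 <- tic()
    img <- cutRange(img, s$lo, s$hi)
    stageLog("cut", t0, sprintf("[%g, %g]", s$lo, s$hi))
  }

  s <- settings$baseline
  if (isTRUE(s$enabled) && !identical(s$method, "none")) {
    t0 <- tic()
    img <- subtractBaseline(img, baselineOptions(s$method, lambda = s$lambda,
                                                 p = s$p, ratio = s$ratio,
                                                 iterations = s$iterations))
    stageLog("baseline", t0, s$method)
  }

  s <- settings$normalize
  if (isTRUE(s$enabled)) {
    t0 <- tic()
    img <- normalizeSpectra(img, method = s$method, wn = s$wn)
    stageLog("normalize", t0, s$method)
  }
  out$image <- img

  s <- settings$mcr
  if (isTRUE(s$enabled)) {
    t0 <- tic()
    # MCR operates on non-negative data; clip small negatives from corrections
    D <- pmax(img@spectra, 0)
    cfg <- mcrConfig(s$k, initOn = s$initOn,
                     simplismaAlpha = s$simplismaAlpha, maxIter = s$maxIter,
                     relTol = s$relTol, seed = seed)
    out$mcr <- mcrAls(D, cfg)
    stageLog("mcr", t0,
             sprintf("%d iterations, stop %s, error %.3g%%",
                     length(out$mcr@residuals), out$mcr@stopReason,
                     utils::tail(out$mcr@residuals, 1)))
  }

  s <- settings$cluster
  if (isTRUE(s$enabled) && !is.null(out$mcr)) {
    t0 <- tic()
    out$segmentation <- clusterConcentrations(concentrations(out$mcr), k = s$k,
                                              normalize = isTRUE(s$normalize),
                                              norm = s$norm,
                                              seed = seed + 77L,
                                              dims = img@dims)
    stageLog("cluster", t0, sprintf("k=%g", s$k))
  }
  out$timings <- unlist(timings)
  out
}

#' Batch processing over an image set
#'
#' Processes a manifest of image files independently and sequentially with
#' the same settings. A failing image is logged and skipped; the remaining
#' images are still processed and the summary reports the failure. Outputs
#' per image: the preprocessed spectra (`<name>_corrected.csv`), MCR
#' concentrations and spectra (`<name>_C.csv`, `<name>_S.csv`, with a
#' wavenumber column) and the cluster label map (`<name>_labels.csv` +
#' PNG), plus a `batch_log.txt` with one structured line per stage and a
#' settings copy for provenance.
#'
#' @param manifest character vector of input image paths (non-empty).
#' @param settings a [pipelineSettings()] object.
#' @param outDir output directory (created if needed).
#' @param verbose logical.
#' @return Invisibly, a data.frame summary (file, ok, message, seconds);
#'   attribute `"exitStatus"` is 0 when all images succeeded, 1 otherwise.
#' @export
runBatch <- function(manifest, settings = pipelineSettings(),
                     outDir = ".", verbose = FALSE) {
  if (!length(manifest)) stop("empty manifest")
  stopifnot(inherits(settings, "PipelineSettings"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  saveSettings(settings, file.path(outDir, "settings_used.json"))
  logPath <- file.path(outDir, "batch_log.txt")
  logLine <- function(...) cat(sprintf(...), "\n", file = logPath,
                               append = TRUE, sep = "")
  cat("", file = logPath)
  summary <- data.frame(file = manifest, ok = FALSE, message = "",
                        seconds = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(manifest)) {
    f <- manifest[i]
    nm <- sub("\\.[^.]*$", "", basename(f))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      img <- readImage(f)
      r <- runPipeline(img, settings, verbose = verbose)
      writeImage(r$image, file.path(outDir, paste0(nm, "_corrected.csv")))
      if (!is.null(r$mcr)) {
        data.table::fwrite(data.table::as.data.table(concentrations(r$mcr)),
                           file.path(outDir, paste0(nm, "_C.csv")),
                           col.names = FALSE)
        data.table::fwrite(data.table::as.data.table(
          cbind(r$image@wavenumber, t(pureSpectra(r$mcr)))),
          file.path(outDir, paste0(nm, "_S.csv")), col.names = FALSE)
      }
      if (!is.null(r$segmentation) && !anyNA(r$segmentation@dims))
        writeLabelMap(r$segmentation,
                      file.path(outDir, paste0(nm, "_labels.csv")),
                      png = file.path(outDir, paste0(nm, "_labels.png")))
      for (st in names(r$timings))
        logLine("%s\tstage=%s\tseconds=%.3f", nm, st, r$timings[[st]])
      "ok"
    }, error = function(e) conditionMessage(e))
    dt <- proc.time()[["elapsed"]] - t0
    summary$ok[i] <- identical(res, "ok")
    summary$message[i] <- if (summary$ok[i]) "" else res
    summary$seconds[i] <- round(dt, 3)
    logLine("%s\t%s\tseconds=%.3f%s", nm,
            if (summary$ok[i]) "done" else "FAILED", dt,
            if (summary$ok[i]) "" else paste0("\t", res))
  }
  attr(summary, "exitStatus") <- as.integer(!all(summary$ok))
  invisible(summary)
}

#' Command-line interface
#'
#' Thin argument-parsing front end over the package functions, used by the
#' `inst/scripts/vibrospec` launcher. Subcommands:
#' \describe{
#'   \item{synth}{`--seed N --out dir [--height H --width W --k K]` —
#'     generate a phantom image (CSV + ground-truth sidecars).}
#'   \item{preprocess}{`--in file [...] --out dir [--settings s.json]
#'     [--stages atm,mie,denoise,cut,baseline,normalize]` — preprocessing
#'     only.}
#'   \item{mcr}{`--in file [...] --out dir [--settings s.json]` —
#'     preprocessing plus MCR-ALS.}
#'   \item{cluster}{`--in file [...] --out dir [--settings s.json]` — full
#'     chain through segmentation.}
#'   \item{run}{settings-driven full pipeline, same as cluster but all
#'     stage toggles come from the settings file.}
#' }
#' Common flags: `--settings file.json`, `--seed N`, `--verbose`.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code: 0 on success, 1 on processing failure, 2 on
#'   usage errors.
#' @export
vibroCli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: vibrospec <synth|preprocess|mcr|cluster|run> [options]\n",
        "  common options: --settings file.json --seed N --out dir --verbose\n",
        "  synth: --height H --width W --k K\n",
        "  preprocess/mcr/cluster/run: --in file [--in file ...] [--stages list]\n",
        sep = "")
    2L
  }
  if (!length(argv)) return(usage())
  cmd <- argv[1]
  argv <- argv[-1]
  opts <- list(seed = NULL, out = ".", settings = NULL, verbose = FALSE,
               input = character(0), stages = NULL,
               height = 64, width = 64, k = 4)
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    take <- function() {
      if (i + 1L > length(argv)) stop("missing value for ", a, call. = FALSE)
      i <<- i + 1L
      argv[i]
    }
    handled <- tryCatch({
      switch(a,
        "--seed" = opts$seed <- as.integer(take()),
        "--out" = opts$out <- take(),
        "--settings" = opts$settings <- take(),
        "--verbose" = opts$verbose <- TRUE,
        "--in" = opts$input <- c(opts$input, take()),
        "--stages" = opts$stages <- strsplit(take(), ",")[[1]],
        "--height" = opts$height <- as.integer(take()),
        "--width" = opts$width <- as.integer(take()),
        "--k" = opts$k <- as.integer(take()),
        { cat("unknown flag:", a, "\n"); return(usage()) })
      TRUE
    }, error = function(e) { cat(conditionMessage(e), "\n"); FALSE })
    if (!isTRUE(handled)) return(2L)
    i <- i + 1L
  }
  settings <- if (!is.null(opts$settings)) loadSettings(opts$settings)
              else pipelineSettings()
  if (!is.null(opts$seed)) settings$seed <- as.numeric(opts$seed)

  if (cmd == "synth") {
    dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
    ph <- makePhantom(seed = as.integer(settings$seed),
                      height = opts$height, width = opts$width, k = opts$k)
    writeImage(ph@image, file.path(opts$out, "phantom.csv"))
    data.table::fwrite(data.table::as.data.table(ph@trueC),
                       file.path(opts$out, "phantom_trueC.csv"),
                       col.names = FALSE)
    data.table::fwrite(data.table::as.data.table(ph@trueS),
                       file.path(opts$out, "phantom_trueS.csv"),
                       col.names = FALSE)
    jsonlite::write_json(list(seed = ph@seed, labels = ph@labels),
                         file.path(opts$out, "phantom_truth.json"))
    return(0L)
  }
  if (!cmd %in% c("preprocess", "mcr", "cluster", "run")) return(usage())
  if (!length(opts$input)) { cat("no --in files given\n"); return(usage()) }
  if (cmd %in% c("preprocess", "mcr")) {
    settings$mcr$enabled <- cmd == "mcr"
    settings$cluster$enabled <- FALSE
  }
  if (!is.null(opts$stages)) {
    map <- c(atm = "atmospheric", mie = "mie", denoise = "denoise",
             cut = "cut", baseline = "baseline", normalize = "normalize")
    for (long in map) settings[[long]]$enabled <- FALSE
    for (st in opts$stages) {
      long <- map[[st]]
      if (is.null(long)) { cat("unknown stage:", st, "\n"); return(usage()) }
      settings[[long]]$enabled <- TRUE
    }
  }
  summary <- runBatch(opts$input, settings, outDir = opts$out,
                      verbose = opts$verbose)
  attr(summary, "exitStatus")
}
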