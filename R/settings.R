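#' Pipeline settings
#'
#' One JSON-serializable object describing the whole processing chain:
#' ordered preprocessing stages with per-stage options, the MCR-ALS and
#' clustering configuration, and the master seed every stochastic step
#' derives its randomness from. Settings save/load losslessly, both for
#' convenience and for record-keeping.
#'
#' All numbers are stored as doubles so that a JSON round trip reproduces
#' the object exactly.
#'
#' @param seed master seed (drives phantom generation, k-means and any other
#'   randomized step).
#' @param atmospheric list: `enabled`, `co2Mode` (`"subtract"`/`"spline"`),
#'   `extraWindowed`, `smooth`, `reference` (path to a two-column reference
#'   file, or `NULL` for the bundled synthetic one).
#' @param mie list: `enabled`, `nClusters`, `maxIterations`, `stabilize`,
#'   `clusteringEnabled`, `autoStop`, `rescaleByH`, `model`, `N`,
#'   `reference` (path or `NULL` for a phantom-derived mean spectrum).
#' @param denoise list: `enabled`, `order`, `window`.
#' @param cut list: `enabled`, `lo`, `hi`.
#' @param baseline list: `enabled`, `method`, `lambda`, `p`, `ratio`,
#'   `iterations`.
#' @param normalize list: `enabled`, `method`, `wn`.
#' @param mcr list: `enabled`, `k`, `initOn`, `simplismaAlpha`, `maxIter`,
#'   `relTol`.
#' @param cluster list: `enabled`, `k`, `normalize`, `norm`.
#' @return A named list of class `"PipelineSettings"`.
#' @export
pipelineSettings <- function(
    seed = 1,
    atmospheric = list(enabled = TRUE, co2Mode = "subtract",
                       extraWindowed = TRUE, smooth = TRUE, reference = NULL),
    mie = list(enabled = TRUE, nClusters = 30, maxIterations = 30,
               stabilize = TRUE, clusteringEnabled = TRUE, autoStop = TRUE,
               rescaleByH = TRUE, model = "konevskikh2", N = 7,
               reference = NULL),
    denoise = list(enabled = FALSE, order = 3, window = 9),
    cut = list(enabled = TRUE, lo = 900, hi = 1800),
    baseline = list(enabled = FALSE, method = "rubberband", lambda = 1e6,
                    p = 0.01, ratio = 1e-6, iterations = 10),
    normalize = list(enabled = FALSE, method = "mean", wn = 1650),
    mcr = list(enabled = TRUE, k = 8, initOn = "spectra", simplismaAlpha = 5,
               maxIter = 700, relTol = 0.1),
    cluster = list(enabled = TRUE, k = 5, normalize = TRUE, norm = "sum")) {
  s <- list(seed = seed, atmospheric = atmospheric, mie = mie,
            denoise = denoise, cut = cut, baseline = baseline,
            normalize = normalize, mcr = mcr, cluster = cluster)
  structure(.canonicalizeSettings(s), class = "PipelineSettings")
}

# Coerce every number to double and drop NULLs consistently so that
# fromJSON(toJSON(s)) reproduces the object exactly.
.canonicalizeSettings <- function(x) {
  if (is.list(x)) {
    x <- x[!vapply(x, is.null, TRUE)]
    lapply(x, .canonicalizeSettings)
  } else if (is.numeric(x)) as.numeric(x)
  else x
}

#' Save / load pipeline settings as JSON
#'
#' `loadSettings(saveSettings(s, path))` reproduces `s` exactly.
#'
#' @param settings a [pipelineSettings()] object.
#' @param path JSON file path.
#' @return `saveSettings`: `path`, invisibly. `loadSettings`: a
#'   `"PipelineSettings"` object.
#' @export
saveSettings <- function(settings, path) {
  stopifnot(inherits(settings, "PipelineSettings"))
  jsonlite::write_json(unclass(settings), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname saveSettings
#' @export
loadSettings <- function(path) {
  s <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  structure(.canonicalizeSettings(s), class = "PipelineSettings")
}
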