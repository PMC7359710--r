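#' Segment an image by k-means on MCR concentrations
#'
#' Clusters the per-pixel concentration vectors from an MCR-ALS
#' decomposition. Optional normalization rescales each pixel's vector before
#' clustering (sum-to-one by default, an L2 alternative is available), which
#' lets the segmentation reflect relative chemical composition rather than
#' total intensity — weak components (e.g. a halo around a cell) then
#' separate that raw intensities would mask. Zero concentration vectors are
#' left as zero. k-means runs with a fixed seed and 10 restarts, keeping the
#' best inertia.
#'
#' @param C concentration matrix (pixels-in-ROI x k components) or an
#'   [MCRResult-class] (in which case the ROI mask is taken from it).
#' @param k number of clusters (>= 2; must not exceed the number of distinct
#'   rows).
#' @param normalize logical, normalize concentration vectors per pixel.
#' @param norm `"sum"` (default) or `"l2"`.
#' @param seed integer seed for k-means.
#' @param mask optional logical full-image mask matching the rows of `C`
#'   (`sum(mask) == nrow(C)`); excluded pixels get label `NA`.
#' @param dims image geometry `c(height, width)` if known.
#' @return A [SegmentationMap-class].
#' @export
clusterConcentrations <- function(C, k, normalize = TRUE,
                                  norm = c("sum", "l2"), seed = 1L,
                                  mask = NULL, dims = c(NA_integer_,
                                                        NA_integer_)) {
  norm <- match.arg(norm)
  if (is(C, "MCRResult")) {
    mask <- C@roi
    C <- C@conc
  }
  C <- as.matrix(C)
  stopifnot(k >= 2, all(C >= 0))
  if (k > nrow(unique(C)))
    stop("k exceeds the number of distinct concentration vectors")
  X <- C
  if (normalize) {
    s <- if (norm == "sum") rowSums(X) else sqrt(rowSums(X^2))
    s[s == 0] <- 1              # zero vectors left as zero
    X <- X / s
  }
  km <- .seededKmeans(X, k, seed = seed, nstart = 10L)
  if (is.null(mask)) mask <- rep(TRUE, nrow(C))
  stopifnot(sum(mask) == nrow(C))
  labels <- rep(NA_integer_, length(mask))
  labels[mask] <- km$cluster
  new("SegmentationMap", labels = labels, k = as.integer(k),
      normalization = if (normalize) norm else "none",
      seed = as.integer(seed), dims = as.integer(dims))
}

#' Merge clusters into named regions by annotation
#'
#' Replaces cluster labels with region names according to a manual
#' annotation, allowing several spectrally distinct clusters to be combined
#' into one biologically relevant region. Unmapped clusters become
#' `"unassigned"`; ROI-excluded pixels stay `NA`.
#'
#' @param seg a [SegmentationMap-class].
#' @param ann named character vector mapping cluster ids (as names, e.g.
#'   `c("1" = "background", "2" = "hypha")`) to non-empty region names.
#' @return Factor vector of region names per pixel (`NA` = excluded).
#' @export
mergeByAnnotation <- function(seg, ann) {
  stopifnot(is(seg, "SegmentationMap"), is.character(ann),
            !is.null(names(ann)))
  if (any(!nzchar(ann))) stop("region names must be non-empty")
  regions <- rep(NA_character_, length(seg@labels))
  ok <- !is.na(seg@labels)
  key <- as.character(seg@labels[ok])
  mapped <- ann[key]
  mapped[is.na(mapped)] <- "unassigned"
  regions[ok] <- mapped
  factor(regions)
}

#' Mean spectrum per annotated region
#'
#' Arithmetic mean of the member spectra of every region, with member
#' counts. The count-weighted recombination of the region means equals the
#' global mean over all labelled pixels.
#'
#' @param img a [HyperImage-class].
#' @param regions factor or character vector of per-pixel region names
#'   (`NA` = excluded), length [nPixels()].
#' @return List with `spectra` (regions x wavenumbers matrix, row names =
#'   region names), `counts` (named integer) and `wavenumber`.
#' @export
regionMeanSpectra <- function(img, regions) {
  stopifnot(is(img, "HyperImage"), length(regions) == nrow(img@spectra))
  regions <- factor(regions)
  lev <- levels(droplevels(regions))
  M <- matrix(0, length(lev), ncol(img@spectra),
              dimnames = list(lev, NULL))
  counts <- integer(length(lev)); names(counts) <- lev
  for (i in seq_along(lev)) {
    mem <- which(regions == lev[i])
    counts[i] <- length(mem)
    M[i, ] <- colMeans(img@spectra[mem, , drop = FALSE])
  }
  list(spectra = M, counts = counts, wavenumber = img@wavenumber)
}
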