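# Compact IBSI-style 2D radiomics extractor.
#
# The extractor works on single mid-sagittal slices: a grayscale image
# matrix plus a binary ROI mask on the same grid. Images are intensity-
# normalized, optionally passed through pointwise filter channels, then
# discretized with a fixed bin width before texture-matrix computation.

#' Extraction configuration
#'
#' @param bin_width fixed intensity bin width for discretization
#'   (default 25, applied after normalization).
#' @param scale normalization scale factor: images are standardized to
#'   mean 0 and standard deviation `scale` (default 100, so that a bin
#'   width of 25 yields roughly 8-12 gray levels on a typical ROI).
#' @param channels filter channels to compute in addition to the original
#'   image.
#' @param glcm_distance co-occurrence offset distance in pixels.
#' @param glcm_symmetric add each pixel pair in both orders.
#' @return A list of class `"extraction_config"`.
#' @export
extraction_config <- function(bin_width = 25, scale = 100,
                              channels = c("square", "squareroot",
                                           "logarithm", "exponential",
                                           "gradient"),
                              glcm_distance = 1L, glcm_symmetric = TRUE) {
  stopifnot(bin_width > 0, scale > 0, glcm_distance >= 1)
  known <- c("square", "squareroot", "logarithm", "exponential", "gradient")
  bad <- setdiff(channels, known)
  if (length(bad) > 0)
    stop("unknown filter channel(s): ", paste(bad, collapse = ", "))
  structure(list(bin_width = bin_width, scale = scale, channels = channels,
                 glcm_distance = as.integer(glcm_distance),
                 glcm_symmetric = glcm_symmetric),
            class = "extraction_config")
}

#' Normalize an image to zero mean and fixed spread
#'
#' Standardizes the whole image (not just the ROI) to mean 0 and
#' population standard deviation `scale`.
#'
#' @param image numeric matrix.
#' @param scale target standard deviation.
#' @return The normalized matrix.
#' @export
normalize_image <- function(image, scale = 100) {
  stopifnot(is.numeric(image), all(is.finite(image)), scale > 0)
  s <- pop_sd(as.vector(image))
  if (s == 0)
    stop("degenerate input: constant image cannot be normalized")
  (image - mean(image)) / s * scale
}

#' Pointwise intensity filter channels
#'
#' Applies the extractor-standard pointwise transforms, each rescaled by
#' the image's maximum absolute intensity so the output stays in a
#' comparable range, or the gradient-magnitude image (central differences,
#' replicated edges). All outputs are finite for finite input.
#'
#' @param image numeric matrix.
#' @param kind one of `"square"`, `"squareroot"`, `"logarithm"`,
#'   `"exponential"`, `"gradient"`.
#' @return The filtered matrix.
#' @export
intensity_filter <- function(image,
                             kind = c("square", "squareroot", "logarithm",
                                      "exponential", "gradient")) {
  stopifnot(is.numeric(image), all(is.finite(image)))
  kind <- match.arg(kind)
  m <- max(abs(image))
  out <- switch(kind,
    square = {
      if (m == 0) image * 0 else (image / sqrt(m))^2
    },
    squareroot = {
      sign(image) * sqrt(m * abs(image))
    },
    logarithm = {
      if (m == 0) image * 0
      else sign(image) * (m / log(m + 1)) * log(abs(image) + 1)
    },
    exponential = {
      if (m == 0) image * 0 + 1 else exp(image * (log(m) / m))
    },
    gradient = {
      nr <- nrow(image); nc <- ncol(image)
      up    <- image[c(1L, seq_len(nr - 1L)), , drop = FALSE]
      down  <- image[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
      left  <- image[, c(1L, seq_len(nc - 1L)), drop = FALSE]
      right <- image[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
      sqrt(((down - up) / 2)^2 + ((right - left) / 2)^2)
    })
  out
}

#' Discretize ROI intensities with a fixed bin width
#'
#' Gray level of a voxel with intensity `v` is
#' `floor((v - min_roi) / bin_width) + 1`; the maximum-intensity voxel
#' falls in the top bin, and the number of levels is
#' `floor(range / bin_width) + 1`.
#'
#' @param image numeric matrix.
#' @param mask 0/1 matrix on the same grid.
#' @param bin_width positive bin width.
#' @return A list of class `"discretized_roi"`: `levels` (integer matrix,
#'   `NA` outside the mask), `n_levels`, `bin_edges`, `bin_width`, `mask`.
#' @export
discretize_roi <- function(image, mask, bin_width = 25) {
  stopifnot(all(dim(image) == dim(mask)), bin_width > 0)
  inside <- mask != 0
  if (!any(inside)) stop("empty mask")
  vals <- image[inside]
  lo <- min(vals)
  lv <- matrix(NA_integer_, nrow(image), ncol(image))
  lv[inside] <- as.integer(floor((image[inside] - lo) / bin_width)) + 1L
  n_levels <- max(lv, na.rm = TRUE)
  structure(list(levels = lv, n_levels = n_levels,
                 bin_edges = lo + bin_width * (0:n_levels),
                 bin_width = bin_width, mask = inside),
            class = "discretized_roi")
}

#' First-order intensity statistics of an ROI
#'
#' Returns the standard 18 first-order features. Entropy and Uniformity
#' are computed on the fixed-bin-width discretized histogram; percentiles
#' use linear interpolation; Variance is the population (1/N) variance and
#' Kurtosis is non-excess (a Gaussian scores 3).
#'
#' @param image numeric matrix.
#' @param mask 0/1 matrix on the same grid.
#' @param bin_width bin width for the histogram-based features.
#' @param pixel_area physical area of one pixel (for TotalEnergy).
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(image, mask, bin_width = 25,
                                 pixel_area = 1) {
  stopifnot(all(dim(image) == dim(mask)))
  x <- image[mask != 0]
  if (length(x) == 0) stop("empty mask")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  robust <- x[x >= q[1L] & x <= q[4L]]

  lev <- floor((x - min(x)) / bin_width)
  p <- tabulate(as.integer(lev) + 1L) / n
  p <- p[p > 0]

  c("10Percentile" = q[1L],
    "90Percentile" = q[4L],
    Energy = sum(x^2),
    Entropy = -sum(p * log2(p)),
    InterquartileRange = q[3L] - q[2L],
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Maximum = max(x),
    Mean = mu,
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    Median = stats::median(x),
    Minimum = min(x),
    Range = max(x) - min(x),
    RobustMeanAbsoluteDeviation =
      if (length(robust) > 0) mean(abs(robust - mean(robust))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    TotalEnergy = pixel_area * sum(x^2),
    Uniformity = sum(p^2),
    Variance = m2)
}

#' Extract all features for one image + mask pair
#'
#' Normalizes the image, computes the configured filter channels and, per
#' channel, the 18 first-order and 75 texture-matrix features
#' (24 glcm + 16 glrlm + 16 glszm + 14 gldm + 5 ngtdm). Shape features and
#' the wavelet/LoG/LBP channels are enumerable in the taxonomy but not
#' computed by this compact extractor.
#'
#' @param image numeric matrix.
#' @param mask 0/1 matrix on the same grid.
#' @param config an [extraction_config()].
#' @param pixel_area physical pixel area passed to
#'   [first_order_features()].
#' @return Named numeric vector, names of the form
#'   `"<channel>_<class>_<label>"`.
#' @export
extract_features_single <- function(image, mask,
                                    config = extraction_config(),
                                    pixel_area = 1) {
  stopifnot(inherits(config, "extraction_config"))
  if (!all(dim(image) == dim(mask)))
    stop("image and mask grids differ")
  norm <- normalize_image(image, config$scale)
  channel_images <- c(list(original = norm),
                      stats::setNames(
                        lapply(config$channels, function(k)
                          intensity_filter(norm, k)),
                        config$channels))
  prefixed <- function(prefix, v)
    stats::setNames(v, paste0(prefix, "_", names(v)))
  out <- unlist(lapply(names(channel_images), function(ch) {
    img <- channel_images[[ch]]
    droi <- discretize_roi(img, mask, config$bin_width)
    v <- c(prefixed("firstorder",
                    first_order_features(img, mask, config$bin_width,
                                         pixel_area)),
           prefixed("glcm",
                    glcm_features(droi, distance = config$glcm_distance,
                                  symmetric = config$glcm_symmetric)),
           prefixed("glrlm", texture_matrix_features(droi, "glrlm")),
           prefixed("glszm", texture_matrix_features(droi, "glszm")),
           prefixed("gldm", texture_matrix_features(droi, "gldm")),
           prefixed("ngtdm", texture_matrix_features(droi, "ngtdm")))
    prefixed(ch, v)
  }))
  out
}

#' Extract a feature table from a batch of image + mask pairs
#'
#' @param entries list of entries, each a list with elements `image`,
#'   `mask` and `meta` (a list or one-row data frame of metadata fields;
#'   typically `disc_id`, `species`, `pfirrmann_grade`, `observer_id`,
#'   `replicate_id`).
#' @param config an [extraction_config()].
#' @param sequence sequence prefix for the column names (default `"T2"`).
#' @return A feature table: one row per entry, metadata columns prefixed
#'   `meta_`, feature columns named
#'   `"<sequence>_<channel>_<class>_<label>"`.
#' @export
extract_table <- function(entries, config = extraction_config(),
                          sequence = "T2") {
  stopifnot(length(entries) > 0)
  rows <- lapply(entries, function(e) {
    if (!all(dim(e$image) == dim(e$mask)))
      stop("image and mask grids differ")
    v <- extract_features_single(e$image, e$mask, config)
    names(v) <- paste0(sequence, "_", names(v))
    meta <- as.list(e$meta)
    names(meta) <- paste0("meta_", names(meta))
    if ("meta_pfirrmann_grade" %in% names(meta) &&
        !"meta_binary_label" %in% names(meta))
      meta$meta_binary_label <-
        dichotomize_grade(meta$meta_pfirrmann_grade)
    cbind(as.data.frame(meta, stringsAsFactors = FALSE),
          as.data.frame(as.list(v), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
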