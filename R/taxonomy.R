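# Canonical radiomics feature namespace.
#
# Every feature is identified by a four-token string
# "<sequence>_<channel>_<class>_<label>", e.g. "T2_wavelet-LLL_glcm_Imc2".
# Tokens are separated by underscores; channel tokens may contain hyphens
# (wavelet decompositions, lbp variants) but never underscores, so the
# string form round-trips through parse/format.

.SEQUENCES <- c("T1", "T2")

.WAVELET_CHANNELS <- paste0("wavelet-",
                            c("HHH", "HHL", "HLH", "HLL",
                              "LHH", "LHL", "LLH", "LLL"))

.CHANNELS <- c("original", .WAVELET_CHANNELS, "log", "square", "squareroot",
               "logarithm", "exponential", "gradient",
               "lbp-2D", "lbp-3D-k", "lbp-3D-m1", "lbp-3D-m2")

# Standard extractor feature labels per class (18/14/24/16/16/14/5).
.FEATURE_LABELS <- list(
  firstorder = c("10Percentile", "90Percentile", "Energy", "Entropy",
                 "InterquartileRange", "Kurtosis", "Maximum", "Mean",
                 "MeanAbsoluteDeviation", "Median", "Minimum", "Range",
                 "RobustMeanAbsoluteDeviation", "RootMeanSquared",
                 "Skewness", "TotalEnergy", "Uniformity", "Variance"),
  shape = c("Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
            "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
            "Maximum2DDiameterSlice", "Maximum3DDiameter", "MeshVolume",
            "MinorAxisLength", "Sphericity", "SurfaceArea",
            "SurfaceVolumeRatio", "VoxelVolume"),
  glcm = c("Autocorrelation", "ClusterProminence", "ClusterShade",
           "ClusterTendency", "Contrast", "Correlation",
           "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
           "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
           "JointAverage", "JointEnergy", "JointEntropy", "MCC",
           "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares"),
  glrlm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
            "GrayLevelVariance", "HighGrayLevelRunEmphasis",
            "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
            "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
            "RunEntropy", "RunLengthNonUniformity",
            "RunLengthNonUniformityNormalized", "RunPercentage",
            "RunVariance", "ShortRunEmphasis",
            "ShortRunHighGrayLevelEmphasis", "ShortRunLowGrayLevelEmphasis"),
  glszm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
            "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
            "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
            "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
            "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
            "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
            "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy",
            "ZonePercentage", "ZoneVariance"),
  gldm = c("DependenceEntropy", "DependenceNonUniformity",
           "DependenceNonUniformityNormalized", "DependenceVariance",
           "GrayLevelNonUniformity", "GrayLevelVariance",
           "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
           "LargeDependenceHighGrayLevelEmphasis",
           "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
           "SmallDependenceEmphasis",
           "SmallDependenceHighGrayLevelEmphasis",
           "SmallDependenceLowGrayLevelEmphasis"),
  ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
)

#' Radiomics taxonomy configuration
#'
#' Describes the feature namespace to enumerate: which MRI sequences, which
#' image channels (the original image plus filtered derivatives) and which
#' feature classes. The defaults reproduce the standard extractor's
#' namespace: 2 sequences x (14 shape features on the original channel +
#' 93 intensity/texture features on each of 19 channels) = 3562 features.
#'
#' @param sequences character vector of MRI sequences, subset of
#'   `c("T1", "T2")`.
#' @param channels character vector of image channels. The 19 defaults are
#'   the original image, 8 wavelet decompositions, one
#'   Laplacian-of-Gaussian channel (`"log"`), four pointwise intensity
#'   transforms, the gradient-magnitude image and four local-binary-pattern
#'   variants.
#' @param classes character vector of feature classes, subset of
#'   `c("firstorder", "shape", "glcm", "glrlm", "glszm", "gldm", "ngtdm")`.
#' @return A list of class `"taxonomy_config"`.
#' @export
#' @examples
#' cfg <- taxonomy_config(sequences = "T2")
#' nrow(build_manifest(cfg))  # 1781
taxonomy_config <- function(sequences = .SEQUENCES,
                            channels = .CHANNELS,
                            classes = names(.FEATURE_LABELS)) {
  bad_seq <- setdiff(sequences, .SEQUENCES)
  if (length(bad_seq) > 0)
    stop("unknown sequence token(s): ", paste(bad_seq, collapse = ", "))
  bad_ch <- setdiff(channels, .CHANNELS)
  if (length(bad_ch) > 0)
    stop("unknown channel token(s): ", paste(bad_ch, collapse = ", "))
  bad_cl <- setdiff(classes, names(.FEATURE_LABELS))
  if (length(bad_cl) > 0)
    stop("unknown feature class token(s): ", paste(bad_cl, collapse = ", "))
  structure(list(sequences = sequences, channels = channels,
                 classes = classes,
                 class_sizes = vapply(.FEATURE_LABELS[classes], length, 1L)),
            class = "taxonomy_config")
}

#' Group a channel token into its major image type
#'
#' The 19 concrete channels belong to 10 major image types: the 8 wavelet
#' decompositions collapse to `"wavelet"` and the 3 parameterized lbp-3D
#' variants to `"lbp-3D"`; every other channel is its own type.
#'
#' @param channel character vector of channel tokens.
#' @return character vector of image-type names.
#' @export
image_type_of <- function(channel) {
  out <- channel
  out[startsWith(channel, "wavelet-")] <- "wavelet"
  out[startsWith(channel, "lbp-3D")] <- "lbp-3D"
  out
}

#' Enumerate the radiomics feature manifest
#'
#' Builds the ordered list of every feature name implied by a taxonomy
#' configuration. Shape features exist only on the original channel; all
#' other classes are computed on every channel. With the default
#' configuration this yields 3562 names (1781 per sequence).
#'
#' @param config a [taxonomy_config()].
#' @return A data frame of class `"feature_manifest"` with columns `name`,
#'   `sequence`, `channel`, `image_type`, `feature_class`, `feature_label`;
#'   the configuration is attached as attribute `"config"`.
#' @export
#' @examples
#' m <- build_manifest()
#' nrow(m)                     # 3562
#' count_by(m, "class")["glcm"]  # 912
build_manifest <- function(config = taxonomy_config()) {
  stopifnot(inherits(config, "taxonomy_config"))
  rows <- vector("list", 0L)
  for (sq in config$sequences) {
    for (ch in config$channels) {
      for (cl in config$classes) {
        if (cl == "shape" && ch != "original") next
        labs <- .FEATURE_LABELS[[cl]]
        rows[[length(rows) + 1L]] <- data.frame(
          name = paste(sq, ch, cl, labs, sep = "_"),
          sequence = sq, channel = ch,
          image_type = image_type_of(ch),
          feature_class = cl, feature_label = labs,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(name = character(), sequence = character(),
               channel = character(), image_type = character(),
               feature_class = character(), feature_label = character(),
               stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  if (anyDuplicated(manifest$name))
    stop("internal error: duplicate feature names in manifest")
  structure(manifest, config = config,
            class = c("feature_manifest", "data.frame"))
}

#' Parse a feature name string
#'
#' Splits `"<sequence>_<channel>_<class>_<label>"` into its components and
#' validates the sequence, channel and class tokens against the taxonomy.
#' The label token is free-form (figure axes sometimes abbreviate labels,
#' e.g. `"Zone%"`); pass a manifest to additionally require the full name
#' to be enumerated.
#'
#' @param name a single feature name string.
#' @param manifest optional [build_manifest()] result; if supplied, `name`
#'   must appear in it.
#' @return A list of class `"feature_name"` with fields `sequence`,
#'   `channel`, `image_type`, `feature_class`, `feature_label`.
#' @export
#' @examples
#' parse_feature_name("T2_wavelet-LLL_glcm_Imc2")$channel  # "wavelet-LLL"
parse_feature_name <- function(name, manifest = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  parts <- strsplit(name, "_", fixed = TRUE)[[1L]]
  if (length(parts) != 4L)
    stop("malformed feature name '", name, "': expected 4 underscore-",
         "separated tokens, got ", length(parts))
  if (!parts[1L] %in% .SEQUENCES)
    stop("unknown sequence token '", parts[1L], "' in '", name, "'")
  if (!parts[2L] %in% .CHANNELS)
    stop("unknown channel token '", parts[2L], "' in '", name, "'")
  if (!parts[3L] %in% names(.FEATURE_LABELS))
    stop("unknown feature class token '", parts[3L], "' in '", name, "'")
  if (!nzchar(parts[4L]))
    stop("empty feature label in '", name, "'")
  if (parts[3L] == "shape" && parts[2L] != "original")
    stop("shape features exist only on the original channel: '", name, "'")
  if (!is.null(manifest) && !name %in% manifest$name)
    stop("feature name '", name, "' is not enumerated by the manifest")
  structure(list(sequence = parts[1L], channel = parts[2L],
                 image_type = image_type_of(parts[2L]),
                 feature_class = parts[3L], feature_label = parts[4L]),
            class = "feature_name")
}

#' Format a parsed feature name back to its string form
#'
#' @param x a `"feature_name"` object from [parse_feature_name()].
#' @return The canonical name string.
#' @export
format_feature_name <- function(x) {
  stopifnot(inherits(x, "feature_name"))
  paste(x$sequence, x$channel, x$feature_class, x$feature_label, sep = "_")
}

#' Count manifest features along one axis
#'
#' @param manifest a [build_manifest()] result.
#' @param axis one of `"class"`, `"channel"`, `"sequence"`, `"image_type"`.
#' @return A named integer vector of counts; the counts sum to
#'   `nrow(manifest)`.
#' @export
count_by <- function(manifest,
                     axis = c("class", "channel", "sequence", "image_type")) {
  stopifnot(inherits(manifest, "feature_manifest"))
  axis <- match.arg(axis)
  col <- switch(axis, class = "feature_class", channel = "channel",
                sequence = "sequence", image_type = "image_type")
  if (nrow(manifest) == 0) return(integer(0))
  tab <- table(manifest[[col]])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
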