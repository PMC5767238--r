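# Latent factor scoring: standardise each loaded measure against a
# reference sample, form weighted sums per factor, and apply the
# directionality convention (Semantic and Fluency multiplied by -1 so
# that higher always means better performance).

FACTOR_NAMES <- c("Semantic", "Syntax", "Lexical", "Fluency")

#' Construct a factor-weights configuration
#'
#' @param loadings Named list \code{factor -> named numeric vector}
#'   (measure -> weight). The factor set must be exactly Semantic,
#'   Syntax, Lexical, Fluency, and each measure may load on exactly one
#'   factor.
#' @param sign_flip Named numeric (+1/-1) per factor; the default encodes
#'   the convention that the Semantic and Fluency factors are flipped.
#' @param reference_means,reference_sds Named numerics giving the
#'   standardization constants per loaded measure; usually filled by
#'   \code{\link{calibrate_reference}}. SDs must be positive.
#' @return A \code{factor_weights} object.
#' @export
factor_weights <- function(loadings,
                           sign_flip = c(Semantic = -1, Syntax = 1,
                                         Lexical = 1, Fluency = -1),
                           reference_means = numeric(0),
                           reference_sds = numeric(0)) {
  if (!setequal(names(loadings), FACTOR_NAMES))
    stop("loadings must cover exactly the factors ",
         paste(FACTOR_NAMES, collapse = ", "))
  if (!setequal(names(sign_flip), FACTOR_NAMES) ||
      !all(sign_flip %in% c(-1, 1)))
    stop("sign_flip must map every factor to +1 or -1")
  measures <- unlist(lapply(loadings, names))
  if (anyDuplicated(measures))
    stop("each measure may load on exactly one factor; duplicated: ",
         paste(unique(measures[duplicated(measures)]), collapse = ", "))
  if (length(reference_sds) && any(reference_sds <= 0))
    stop("reference SDs must be positive")
  structure(list(loadings = lapply(loadings, unlist),
                 sign_flip = unlist(sign_flip)[FACTOR_NAMES],
                 reference_means = unlist(reference_means),
                 reference_sds = unlist(reference_sds)),
            class = "factor_weights")
}

#' Built-in default factor configuration
#'
#' Equal unit-magnitude loadings within each factor, signed by the raw
#' direction of each measure inside its construct, with the Semantic and
#' Fluency sign flips. Reference constants are empty until calibrated.
#'
#' @return A \code{factor_weights} object.
#' @export
default_factor_weights <- function() {
  path <- system.file("extdata", "default_factor_weights.yaml",
                      package = "conlang")
  if (!nzchar(path))
    path <- file.path("inst", "extdata", "default_factor_weights.yaml")
  read_factor_weights(path)
}

#' Read a factor-weights configuration from YAML or JSON
#'
#' @param path Configuration file path.
#' @return A \code{factor_weights} object.
#' @export
read_factor_weights <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  factor_weights(cfg$loadings,
                 sign_flip = unlist(cfg$sign_flip),
                 reference_means = unlist(cfg$reference_means),
                 reference_sds = unlist(cfg$reference_sds))
}

#' Write a factor-weights configuration to YAML
#'
#' @param w A \code{factor_weights} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_factor_weights <- function(w, path) {
  yaml::write_yaml(list(loadings = lapply(w$loadings, as.list),
                        sign_flip = as.list(w$sign_flip),
                        reference_means = as.list(w$reference_means),
                        reference_sds = as.list(w$reference_sds)),
                   path)
  invisible(path)
}

#' Calibrate standardization constants on a reference sample
#'
#' Fills the reference means and (sample) SDs of every loaded measure
#' from a collection of feature vectors. Scoring the calibration sample
#' with the result gives each standardized measure mean 0 and SD 1, and
#' each factor mean 0.
#'
#' @param features List of \code{feature_vector}s (or a data.frame with
#'   one column per measure); at least two samples.
#' @param w A \code{factor_weights} object supplying the loadings.
#' @return \code{w} with \code{reference_means}/\code{reference_sds}
#'   filled.
#' @export
calibrate_reference <- function(features, w = default_factor_weights()) {
  df <- features_as_df(features)
  if (nrow(df) < 2L) stop("calibration needs at least 2 samples")
  measures <- unname(unlist(lapply(w$loadings, names)))
  missing_m <- setdiff(measures, names(df))
  if (length(missing_m))
    stop("features lack loaded measures: ", paste(missing_m, collapse = ", "))
  mu <- vapply(measures, function(m) mean(df[[m]], na.rm = TRUE), numeric(1))
  sdev <- vapply(measures, function(m) sd(df[[m]], na.rm = TRUE), numeric(1))
  flat <- measures[is.na(sdev) | sdev == 0]
  if (length(flat))
    stop("constant measure(s) in calibration sample: ",
         paste(flat, collapse = ", "))
  w$reference_means <- mu
  w$reference_sds <- sdev
  w
}

features_as_df <- function(features) {
  if (is.data.frame(features)) return(features)
  do.call(rbind, lapply(features, function(fv)
    as.data.frame(unclass(fv), stringsAsFactors = FALSE)))
}

#' Score the four latent factors for one sample
#'
#' Each factor is \code{sign_flip * sum(weight * (measure - mean) / sd)}
#' over its loaded measures. A missing constituent measure propagates to
#' a missing (NA) factor score -- weights are never silently
#' re-normalised -- and the affected factors are named in the
#' \code{"missing"} attribute of the result.
#'
#' @param f A \code{feature_vector} (or named list/vector of measures).
#' @param w A calibrated \code{factor_weights} object.
#' @return A \code{factor_scores} object: named numeric of length four
#'   (semantic, syntax, lexical, fluency), higher = better performance.
#' @export
score_factors <- function(f, w) {
  stopifnot(inherits(w, "factor_weights"))
  if (length(w$reference_means) == 0L)
    stop("factor weights are not calibrated; run calibrate_reference() first")
  x <- unlist(unclass(f))
  out <- setNames(numeric(4), tolower(FACTOR_NAMES))
  dropped <- character(0)
  for (fac in FACTOR_NAMES) {
    lw <- w$loadings[[fac]]
    vals <- x[names(lw)]
    if (length(vals) != length(lw) || any(is.na(vals))) {
      out[tolower(fac)] <- NA_real_
      dropped <- c(dropped, fac)
      next
    }
    z <- (vals - w$reference_means[names(lw)]) / w$reference_sds[names(lw)]
    out[tolower(fac)] <- w$sign_flip[[fac]] * sum(lw * z)
  }
  structure(out, missing = dropped, class = c("factor_scores", "numeric"))
}

#' Score a collection of samples into a factor-score table
#'
#' @param samples List whose elements carry \code{participant_id},
#'   \code{visit_id} and \code{features} (a \code{feature_vector}).
#' @param w A calibrated \code{factor_weights}.
#' @return data.frame keyed by (participant_id, visit_id) with columns
#'   semantic, syntax, lexical, fluency.
#' @export
score_factor_table <- function(samples, w) {
  rows <- lapply(samples, function(s) {
    sc <- score_factors(s$features, w)
    data.frame(participant_id = s$participant_id, visit_id = s$visit_id,
               semantic = sc[["semantic"]], syntax = sc[["syntax"]],
               lexical = sc[["lexical"]], fluency = sc[["fluency"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
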