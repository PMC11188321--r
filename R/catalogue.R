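#' The 110-feature radiomic catalogue
#'
#' The package computes a fixed catalogue of 110 radiomic features keyed by
#' IBSI feature codes: 12 shape, 43 first-order (20 on continuous SUVs, 23
#' on the discretized intensity histogram), 23 GLCM, 11 GLRLM, 5 NGTDM and
#' 16 GLSZM features. Feature columns are named
#' `family.CODE.human_name` (e.g. `glcm.GYBY.joint_maximum`) so each value
#' stays traceable to its IBSI definition. Note the catalogue deliberately
#' carries both `median` (Y12H) and `p50` (Y12H.1) in the first-order family
#' — numerically identical, kept as two entries to preserve the catalogue
#' count.
#'
#' @return data.frame with columns `family`, `code`, `name` (110 rows).
#' @examples
#' nrow(featureCatalogue())
#' table(featureCatalogue()$family)
#' @export
featureCatalogue <- function() {
  def <- list(
    shape = c(
      RNU0 = "volume", YEKZ = "approx_volume", C0JK = "surface_area",
      "2PR5" = "surface_to_volume_ratio", SKGS = "compactness1",
      BQWJ = "compactness2", KRCK = "spherical_disproportion",
      QCFX = "sphericity", "25C7" = "asphericity", KLMA = "com_shift",
      L0JK = "max_3d_diameter", "99N0" = "integrated_intensity"),
    firstorder = c(
      Q4LE = "mean", ECT3 = "variance", KE2A = "skewness",
      IPH6 = "kurtosis", Y12H = "median", "1GSF" = "minimum",
      QG58 = "p10", Y12H.1 = "p50", "8DWT" = "p90", "84IY" = "maximum",
      SALO = "iqr", "2OJQ" = "range", "4FUA" = "mad", "1128" = "robust_mad",
      N72L = "median_ad", "7TET" = "cov", "9S40" = "qcd", N8CA = "energy",
      "5ZWQ" = "rms", "0F91" = "global_intensity_peak",
      X6K6 = "ih_mean", CH89 = "ih_variance", "88K1" = "ih_skewness",
      C3I7 = "ih_kurtosis", WIFQ = "ih_median", "1PR8" = "ih_minimum",
      GPMT = "ih_p10", OZ0C = "ih_p90", "3NCY" = "ih_maximum",
      AMMC = "ih_mode", WR0O = "ih_iqr", "5Z3W" = "ih_range",
      D2ZX = "ih_mad", WRZB = "ih_robust_mad", "4RNL" = "ih_median_ad",
      CWYJ = "ih_cov", SLWD = "ih_qcd", TLU2 = "ih_entropy",
      BJ5W = "uniformity", "12CE" = "max_hist_gradient",
      "8E6O" = "max_hist_gradient_grey_level", VQB3 = "min_hist_gradient",
      RHQZ = "min_hist_gradient_grey_level"),
    glcm = c(
      GYBY = "joint_maximum", "60VM" = "joint_average",
      UR99 = "joint_variance", TU9B = "joint_entropy",
      TF7R = "difference_average", D3YU = "difference_variance",
      NTRS = "difference_entropy", ZGXS = "sum_average",
      OEEB = "sum_variance", P6QZ = "sum_entropy",
      "8ZQL" = "angular_second_moment", ACUI = "contrast",
      "8S9J" = "dissimilarity", IB1Z = "inverse_difference",
      NDRX = "norm_inverse_difference", WF0Z = "inverse_difference_moment",
      "1QCO" = "norm_inverse_difference_moment", E8JP = "inverse_variance",
      NI2N = "correlation", QWB0 = "autocorrelation",
      DG8W = "cluster_tendency", "7NFM" = "cluster_shade",
      AE86 = "cluster_prominence"),
    glrlm = c(
      "22OV" = "short_runs_emphasis", W4KF = "long_runs_emphasis",
      V3SW = "low_grey_level_run_emphasis",
      G3QZ = "high_grey_level_run_emphasis",
      HTZT = "short_run_low_grey_level_emphasis",
      GD3A = "short_run_high_grey_level_emphasis",
      IVPO = "long_run_low_grey_level_emphasis",
      "3KUM" = "long_run_high_grey_level_emphasis",
      R5YN = "grey_level_non_uniformity",
      W92Y = "run_length_non_uniformity", "9ZK5" = "run_percentage"),
    ngtdm = c(
      QCDE = "coarseness", "65HE" = "contrast", NQ30 = "busyness",
      HDEZ = "complexity", "1X9X" = "strength"),
    glszm = c(
      "5QRC" = "small_zone_emphasis", "48P8" = "large_zone_emphasis",
      XMSY = "low_grey_level_zone_emphasis",
      "5GN9" = "high_grey_level_zone_emphasis",
      "5RAI" = "small_zone_low_grey_level_emphasis",
      HW1V = "small_zone_high_grey_level_emphasis",
      YH51 = "large_zone_low_grey_level_emphasis",
      J17V = "large_zone_high_grey_level_emphasis",
      JNSA = "grey_level_non_uniformity",
      Y1RO = "norm_grey_level_non_uniformity",
      "4JP3" = "zone_size_non_uniformity",
      VB3A = "norm_zone_size_non_uniformity", P30P = "zone_percentage",
      BYLV = "grey_level_variance", "3NSA" = "zone_size_variance",
      GU8N = "zone_size_entropy"))
  out <- do.call(rbind, lapply(names(def), function(fam) {
    data.frame(family = fam, code = names(def[[fam]]),
               human = unname(def[[fam]]))
  }))
  out$name <- paste(out$family, out$code, out$human, sep = ".")
  rownames(out) <- NULL
  out[, c("family", "code", "name")]
}

#' Names of the 11 key RadScore features
#'
#' The eleven catalogue features reported as the key drivers of the radiomic
#' score in the reference analysis: one shape feature (surface area), five
#' first-order features and five GLCM features.
#'
#' @return character vector of 11 catalogue feature names.
#' @export
keyFeatureNames <- function() {
  cat <- featureCatalogue()
  codes <- c("C0JK", "QG58", "0F91", "OZ0C", "8E6O", "VQB3",
             "GYBY", "TF7R", "WF0Z", "DG8W", "AE86")
  cat$name[match(codes, cat$code)]
}
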