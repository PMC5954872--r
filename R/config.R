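#' Pipeline configuration
#'
#' Builds the full parameter set of the detector.  Defaults follow the
#' published operating point: rule thresholds (visual attention 0.5,
#' densification 0.93, shape eccentricity 0.86), patch generation
#' (`k_clusters = 2000` for a 1024x1024 image, spatial balance `S = 25`)
#' and the kernel extreme learning machine (`C = 10`, RBF kernel,
#' kernel parameter 0.01).
#'
#' @param attention_threshold normalized peak-intensity threshold in `[0,1]`
#'   below which a salient component is discarded.
#' @param t_dens densification (co-occurrence correlation) threshold in
#'   `[0,1]`; patches below it are rejected.
#' @param t_e eccentricity threshold in `[0,1]`; patches at or above it are
#'   rejected.
#' @param k_clusters number of initial superpixel cluster centers.
#' @param compactness_mu pixel-compactness weight of the patch similarity
#'   index (unpublished; default 10).
#' @param balance_s constant balancing spatial proximity against gray
#'   distance (default 25).
#' @param opening_radius radius (px) of the flat disk used for the
#'   attention opening.
#' @param enhance_radius radius (px) of the disk used by the
#'   top-hat/bottom-hat enhancement.
#' @param glcm_levels gray levels for patch co-occurrence quantization.
#' @param roi_tau region-growing threshold: maximal standardized feature
#'   distance (RMS over the 12 dimensions) between a patch and the running
#'   ROI mean.
#' @param roi_max_patches cap on the number of patches absorbed per ROI.
#' @param elm_c ELM regularization trade-off `C`.
#' @param elm_kernel kernel type; only `"rbf"` is supported.
#' @param elm_gamma RBF kernel parameter.
#' @param pectoral_removal run the pectoral-muscle removal step.
#' @param enable_enhancement,enable_attention,enable_densification,enable_shape,enable_texture
#'   independent switches for each stage rule, for ablation runs.
#' @param overlap_min minimal overlap ratio for a true-positive mark.
#' @param overlap_denominator `"gt"` (overlap over ground-truth area) or
#'   `"iou"`.
#' @return an object of class `cad_config`.
#' @export
cad_config <- function(attention_threshold = 0.5,
                       t_dens = 0.93,
                       t_e = 0.86,
                       k_clusters = 2000,
                       compactness_mu = 10,
                       balance_s = 25,
                       opening_radius = 6,
                       enhance_radius = 30,
                       glcm_levels = 16,
                       roi_tau = 1.0,
                       roi_max_patches = 40,
                       elm_c = 10,
                       elm_kernel = "rbf",
                       elm_gamma = 0.01,
                       pectoral_removal = FALSE,
                       enable_enhancement = TRUE,
                       enable_attention = TRUE,
                       enable_densification = TRUE,
                       enable_shape = TRUE,
                       enable_texture = TRUE,
                       overlap_min = 0.5,
                       overlap_denominator = "gt") {
  cfg <- structure(as.list(environment()), class = "cad_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk01 <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop("config field '", name, "' must be a fraction in [0, 1], got ", v)
  }
  for (f in c("attention_threshold", "t_dens", "t_e", "overlap_min")) chk01(f)
  chkpos <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0)
      stop("config field '", name, "' must be positive, got ", v)
  }
  for (f in c("compactness_mu", "balance_s", "elm_c", "elm_gamma")) chkpos(f)
  if (cfg$k_clusters < 4) stop("config field 'k_clusters' must be >= 4")
  if (cfg$opening_radius < 1) stop("config field 'opening_radius' must be >= 1")
  if (cfg$enhance_radius < 1) stop("config field 'enhance_radius' must be >= 1")
  if (cfg$glcm_levels < 2) stop("config field 'glcm_levels' must be >= 2")
  if (cfg$roi_max_patches < 1) stop("config field 'roi_max_patches' must be >= 1")
  if (!identical(cfg$elm_kernel, "rbf"))
    stop("config field 'elm_kernel' must be 'rbf'")
  if (!cfg$overlap_denominator %in% c("gt", "iou"))
    stop("config field 'overlap_denominator' must be 'gt' or 'iou'")
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Missing file (or `path = NULL`) returns all defaults; a YAML file may
#' override any subset of fields.  Out-of-range overrides raise a
#' validation error.
#'
#' @param path YAML file or `NULL`.
#' @return a [cad_config()] object.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path) || !file.exists(path)) return(cad_config())
  ov <- yaml::read_yaml(path)
  if (is.null(ov)) return(cad_config())
  unknown <- setdiff(names(ov), names(formals(cad_config)))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(cad_config, ov)
}

#' Serialize a configuration to YAML
#' @param cfg a `cad_config`.
#' @param path destination file.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.cad_config <- function(x, ...) {
  cat("<cad_config>\n")
  for (n in names(x)) cat(sprintf("  %-22s %s\n", n, format(x[[n]])))
  invisible(x)
}

#' Desk-scale benchmark configuration
#'
#' The pipeline configuration used for the package's phantom benchmark.
#' Rule thresholds and ELM hyperparameters are the published defaults of
#' [cad_config()]; only the patch-generation geometry is adapted to the
#' 384 x 384 phantom scale: `k_clusters = 600` keeps the grid spacing near
#' 16 px so that a mass spans several patches and a patch is large enough
#' for a meaningful co-occurrence statistic, `balance_s` equals that grid
#' spacing (the superpixel convention the published `S = 25` follows at
#' 1024 x 1024, where the spacing is ~23 px), and `compactness_mu = 60`
#' keeps patches compact on the steep flanks of a mass so they sample
#' texture isotropically instead of degenerating into iso-intensity bands.
#'
#' @param ... overrides forwarded to [cad_config()].
#' @return a `cad_config`.
#' @export
benchmark_config <- function(...) {
  cad_config(k_clusters = 600, balance_s = sqrt(384 * 384 / 600),
             compactness_mu = 60, roi_tau = 2.5, ...)
}
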