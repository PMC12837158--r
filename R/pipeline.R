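#' Load a case configuration
#'
#' Reads a per-case YAML configuration and fills in the pipeline defaults
#' (0.5 mm slices over a 20 mm region, 200 dots per circumference, 0.1 mm gap
#' threshold, 0.80 decision cutoff). The configuration either points at mesh
#' and centerline files (`input:`) or declares a synthetic case
#' (`synthetic:`).
#'
#' @param path YAML file path, or a list with the same structure.
#' @return a validated config list.
#' @export
load_case_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(id = "case", seed = 1L,
                   region = list(s0 = 0, length = 20, spacing = 0.5,
                                 n_angles = 200),
                   epsilon = 0.1, cutoff = 0.80, centers = "shared",
                   validate = FALSE,
                   gates = list(dice = 0.95, hausdorff = 0.5),
                   material = list(E_L = 3.0, E_C = 1.5, G_LC = 0.6,
                                   v_LC = 0.27))
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$input) && is.null(cfg$synthetic))
    stop("config needs either 'input' mesh paths or a 'synthetic' block")
  cfg
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                           digits = 12)), tmp)
  unname(tools::md5sum(tmp))
}

.synthetic_from_config <- function(sc) {
  defects <- if (!is.null(sc$defects))
    do.call(rbind, lapply(sc$defects, as.data.frame)) else NULL
  sc$defects <- NULL
  do.call(synthetic_case, c(sc, list(defects = defects)))
}

#' Run the full case-level pipeline
#'
#' Orchestrates `analyze -> features -> score` for one case: loads or
#' generates the aorta/graft surface pair and centerline, samples the
#' apposition field over the sealing region, reduces it to the three risk
#' features, computes the Endoleak Risk Index and its binary prediction, and
#' (optionally) runs the geometric-fidelity gates on the reconstructed aortic
#' surface. The report records provenance (configuration hash, seed, package
#' version) and the wall-material stiffness metadata; the run is
#' deterministic for a fixed configuration.
#'
#' @param config YAML path or config list (see [load_case_config()]).
#' @return An object of class `case_report`.
#' @export
run_case <- function(config) {
  cfg <- load_case_config(config)
  region <- do.call(analysis_region, cfg$region)
  if (!is.null(cfg$input)) {
    if (is.null(cfg$input$aorta) || !file.exists(cfg$input$aorta))
      stop("analyze stage [", cfg$id, "]: aorta mesh file not found")
    if (is.null(cfg$input$graft) || !file.exists(cfg$input$graft))
      stop("analyze stage [", cfg$id, "]: graft mesh file not found")
    aorta <- read_mesh(cfg$input$aorta)
    graft <- read_mesh(cfg$input$graft)
    path <- if (!is.null(cfg$input$centerline))
      centerline_path(read_centerline_csv(cfg$input$centerline))
    else centroid_centerline(aorta, spacing = region$spacing)
  } else {
    spec <- .synthetic_from_config(cfg$synthetic)
    ag <- generate_aorta(spec)
    aorta <- ag$mesh
    path <- ag$path
    graft <- generate_deployed_graft(spec)
  }
  field <- tryCatch(
    radial_sampling(aorta, graft, path, region, centers = cfg$centers),
    error = function(e) stop("analyze stage [", cfg$id, "]: ",
                             conditionMessage(e), call. = FALSE))
  feats <- tryCatch(risk_features(field, epsilon = cfg$epsilon),
                    error = function(e) stop("features stage [", cfg$id,
                                             "]: ", conditionMessage(e),
                                             call. = FALSE))
  eri <- compute_eri(feats, cutoff = cfg$cutoff)
  validation <- NULL
  if (isTRUE(cfg$validate)) {
    recon <- reconstruct_surface(aorta, path, spacing = region$spacing,
                                 n_angles = region$n_angles)
    bb <- apply(aorta$vertices, 2, range)
    bb[1, ] <- bb[1, ] - 1
    bb[2, ] <- bb[2, ] + 1
    dice <- dice_coefficient(voxelize(aorta, 0.25, bb),
                             voxelize(recon, 0.25, bb))
    hd <- hausdorff_distance(aorta, recon)
    validation <- list(dice = dice, hausdorff_mm = hd,
                       pass = dice > cfg$gates$dice &&
                         hd < cfg$gates$hausdorff)
  }
  mat <- do.call(orthotropic_material, cfg$material)
  structure(list(
    id = cfg$id,
    region = unclass(region),
    n_measurements = field$n_measurements,
    features = list(ac = feats$ac, sgs2 = feats$sgs2, sgm2 = feats$sgm2,
                    oversizing_mean = feats$oversizing_mean,
                    max_gap_mm = feats$max_gap_mm, epsilon = feats$epsilon),
    eri = list(raw = eri$raw, eri = eri$eri, cutoff = eri$cutoff,
               prediction = eri$prediction),
    validation = validation,
    material = list(E_L = mat$E_L, E_C = mat$E_C, G_LC = mat$G_LC,
                    v_LC = mat$v_LC,
                    E_45deg = elastic_modulus_at_angle(mat, pi / 4)),
    provenance = list(config_hash = .config_hash(cfg), seed = cfg$seed,
                      version = as.character(tryCatch(
                        utils::packageVersion("eritwin"),
                        error = function(e) "dev")))),
    class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat(sprintf("case_report [%s]: %d radius measurements\n",
              x$id, x$n_measurements))
  cat(sprintf("  AC = %.4f, SGS2 = %.4f, SGM2 = %.4f\n",
              x$features$ac, x$features$sgs2, x$features$sgm2))
  cat(sprintf("  ERI = %.4f (cutoff %.2f) -> %s\n",
              x$eri$eri, x$eri$cutoff, x$eri$prediction))
  if (!is.null(x$validation))
    cat(sprintf("  validation: Dice %.4f, Hausdorff %.3f mm -> %s\n",
                x$validation$dice, x$validation$hausdorff_mm,
                if (x$validation$pass) "pass" else "FAIL"))
  invisible(x)
}

#' Write a case report as canonical JSON
#'
#' @param report a `case_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_case_report <- function(report, path) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 12,
                           null = "null", pretty = TRUE)
  writeLines(as.character(json), path)
  invisible(path)
}

#' Cohort-level evaluation of index predictions
#'
#' Applies the decision cutoff to the per-case index values, tabulates the
#' confusion matrix against the observed labels, and reports the full
#' diagnostic-metric table, the ROC analysis of the continuous index, and
#' the between-group index comparison.
#'
#' @param eri numeric index values, one per case.
#' @param labels binary endoleak labels (1 = event), at least 2 per class.
#' @param cutoff decision threshold.
#' @return list with `counts` ([confusion_counts()]), `metrics`
#'   (a `diagnostic_report`), `roc` (a `roc_analysis`), and `groups`
#'   ([compare_eri_groups()] output).
#' @export
run_cohort_eval <- function(eri, labels, cutoff = 0.80) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("cohort must contain both classes")
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("cohort evaluation needs >= 2 cases per class")
  pred <- as.integer(eri >= cutoff)
  counts <- tabulate_confusion(pred, y)
  list(counts = counts,
       metrics = confusion_metrics(counts),
       roc = select_cutoff_roc(eri, y),
       groups = compare_eri_groups(eri[y == 1], eri[y == 0]))
}
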