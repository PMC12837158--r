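#' Aortic conicity (AC)
#'
#' Degree of taper or widening of the sealing zone: the absolute difference
#' between the mean aortic radii at the proximal and distal boundaries of the
#' analysis region, normalized by the larger of the two. Zero for a
#' cylindrical neck, symmetric in taper vs widening, bounded by 1.
#'
#' @param field an `apposition_field` with at least 2 slices.
#' @return AC, dimensionless in \[0, 1\].
#' @export
aortic_conicity <- function(field) {
  if (length(field$s) < 2) stop("conicity needs at least 2 slices")
  r1 <- mean(field$rA[1, ])
  r2 <- mean(field$rA[length(field$s), ])
  if (r1 <= 0 || r2 <= 0) stop("degenerate slice radii")
  abs(r1 - r2) / max(r1, r2)
}

#' Stent-graft shape score (SGS2)
#'
#' Deviation of the deployed graft cross-section from a perfect circle:
#' per-slice `(rG,max - rG,min) / rG,max`, aggregated over slices. The
#' default aggregates by the mean (the per-slice sum normalized by the slice
#' count), which keeps the score in \[0, 1\]; `method = "sum"` gives the raw
#' unnormalized sum.
#'
#' @param field an `apposition_field`.
#' @param method `"mean"` (default) or `"sum"`.
#' @return SGS2, dimensionless (in \[0, 1\] for `"mean"`).
#' @export
graft_shape_score <- function(field, method = c("mean", "sum")) {
  method <- match.arg(method)
  if (any(field$rG_max <= 0)) stop("degenerate slice: rG,max = 0")
  d <- (field$rG_max - field$rG_min) / field$rG_max
  if (method == "mean") mean(d) else sum(d)
}

#' Stent-graft malapposition extent (SGM2)
#'
#' A sample is malapposed when its gap exceeds `epsilon`. For each
#' circumferential angle the longest contiguous longitudinal run of
#' malapposed slices is found; the maximum run over all angles, normalized by
#' the region length, is the malapposition extent — the "maximum length" of
#' seal failure, in \[0, 1\]. `measure = "depth"` instead returns the maximum
#' relative gap depth `max(gap / rA)`, retained as a diagnostic.
#'
#' @param field an `apposition_field`.
#' @param epsilon gap threshold in mm (> 0); the default 0.1 mm is the mesh
#'   noise floor observed on synthetic tolerance tests.
#' @param measure `"extent"` (default) or `"depth"`.
#' @return SGM2, dimensionless in \[0, 1\].
#' @export
malapposition_extent <- function(field, epsilon = 0.1,
                                 measure = c("extent", "depth")) {
  measure <- match.arg(measure)
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (length(field$gap) == 0) stop("empty apposition field")
  gap <- pmax(field$gap, 0)
  if (measure == "depth") return(min(max(gap / field$rA), 1))
  mal <- gap > epsilon
  max_run <- 0L
  for (k in seq_len(ncol(mal))) {
    r <- rle(mal[, k])
    runs <- r$lengths[r$values]
    if (length(runs)) max_run <- max(max_run, max(runs))
  }
  min(max_run * field$region$spacing / field$region$length, 1)
}

#' Physics-informed risk feature set
#'
#' Bundles the three apposition features — aortic conicity (AC), stent-graft
#' shape score (SGS2) and malapposition extent (SGM2) — with the oversizing
#' summary and the gap threshold used. These are the inputs of the Endoleak
#' Risk Index.
#'
#' @param field an `apposition_field`.
#' @param epsilon malapposition gap threshold (mm).
#' @return An object of class `risk_features`: list with `ac`, `sgs2`,
#'   `sgm2`, `oversizing` (per-slice profile), `oversizing_mean`,
#'   `max_gap_mm`, and `epsilon`.
#' @export
risk_features <- function(field, epsilon = 0.1) {
  ov <- withCallingHandlers(oversizing_profile(field),
                            warning = function(w) invokeRestart("muffleWarning"))
  structure(list(ac = aortic_conicity(field),
                 sgs2 = graft_shape_score(field),
                 sgm2 = malapposition_extent(field, epsilon),
                 oversizing = ov,
                 oversizing_mean = mean(ov),
                 max_gap_mm = max(pmax(field$gap, 0)),
                 epsilon = epsilon),
            class = "risk_features")
}

#' @export
print.risk_features <- function(x, ...) {
  cat(sprintf("risk_features: AC = %.4f, SGS2 = %.4f, SGM2 = %.4f\n",
              x$ac, x$sgs2, x$sgm2))
  cat(sprintf("  oversizing (mean) = %.3f, max gap = %.3f mm, epsilon = %.2f mm\n",
              x$oversizing_mean, x$max_gap_mm, x$epsilon))
  invisible(x)
}
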