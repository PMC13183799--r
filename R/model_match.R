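# The model-side task adaptation: pool a model's predicted reflectance over
# each competitor's masked appearances, project the pooled predictions onto
# the R-T constancy axis, interpolate between the two competitors whose
# projections land closest to R, and score the resulting Match with the
# Color Constancy Index.

#' Average predicted Lab over a competitor's masked appearances
#'
#' Unweighted mean over all masked pixels pooled across every map in which
#' the competitor appears (so appearances with more pixels weigh more,
#' exactly as a pooled pixel mean should).
#'
#' @param pred_maps List of H x W x 3 predicted Lab arrays.
#' @param masks List of H x W integer label masks aligned with `pred_maps`.
#' @param competitor_id Integer label of the competitor in the masks.
#' @return Object of class `competitor_prediction`: `lab` (length-3 mean),
#'   `pixel_count`, `competitor_id`.
#' @export
average_masked <- function(pred_maps, masks, competitor_id) {
  stopifnot(length(pred_maps) == length(masks), length(pred_maps) >= 1)
  total <- c(0, 0, 0)
  n <- 0L
  for (i in seq_along(pred_maps)) {
    pm <- pred_maps[[i]]
    mk <- masks[[i]]
    if (!identical(dim(pm)[1:2], dim(mk)[1:2])) {
      stop("mask ", i, " does not align with its prediction map",
           call. = FALSE)
    }
    sel <- mk == competitor_id
    if (!any(sel)) next
    total <- total + vapply(1:3, function(k) sum(pm[, , k][sel]), numeric(1))
    n <- n + sum(sel)
  }
  if (n == 0L) {
    stop("competitor ", competitor_id, " appears in no mask", call. = FALSE)
  }
  lab <- total / n
  if (!all(is.finite(lab))) stop("non-finite masked mean", call. = FALSE)
  structure(list(lab = lab, pixel_count = n, competitor_id = competitor_id),
            class = "competitor_prediction")
}

#' Orthogonal projection onto the R-T constancy axis
#'
#' `Proj(P) = R + (T - R) * <P - R, T - R> / ||T - R||^2`: the foot of the
#' perpendicular from P onto the line through R and T, in CIELAB.
#'
#' @param P Length-3 Lab point to project.
#' @param R,T Length-3 Lab anchors of the constancy axis (must differ).
#' @return Length-3 Lab point on the line.
#' @export
project_onto_rt <- function(P, R, T) {
  P <- as.numeric(P); R <- as.numeric(R); T <- as.numeric(T)
  d <- T - R
  nrm2 <- sum(d^2)
  if (nrm2 < 1e-18) stop("R and T coincide; projection undefined",
                         call. = FALSE)
  R + d * sum((P - R) * d) / nrm2
}

#' Infer the model's Match from its five competitor predictions
#'
#' Implements the projection/interpolation procedure:
#' 1. project each pooled competitor prediction onto the line through R
#'    and T;
#' 2. compute each projection's distance to R;
#' 3. select the two competitors C1, C2 with the smallest distances
#'    d1 <= d2 (ties broken by the canonical order R, S1, S2, T, O, i.e. by
#'    increasing designed distance from R);
#' 4. set Match to the inverse-distance interpolation between the ORIGINAL
#'    Lab values of C1 and C2: weight d2/(d1+d2) on C1 and d1/(d1+d2) on
#'    C2 (both zero distances give C1 exactly).
#'
#' The Match always lies on the segment between the two selected original
#' competitor colors.
#'
#' @param preds Named list of `competitor_prediction` objects (or plain
#'   length-3 Lab vectors), one per competitor; names must match the
#'   competitor set rows.
#' @param competitors A `competitor_set`.
#' @return Length-3 Lab vector with attributes `selected` (the two
#'   competitor ids) and `distances` (all five projected distances to R).
#' @export
infer_model_match <- function(preds, competitors) {
  stopifnot(inherits(competitors, "competitor_set"))
  ids <- rownames(competitors$labs)
  if (!setequal(names(preds), ids)) {
    stop("predictions must cover exactly the five competitors",
         call. = FALSE)
  }
  R <- competitors$labs["R", ]
  T_ <- competitors$labs["T", ]
  tie_order <- c("R", "S1", "S2", "T", "O")
  dists <- vapply(tie_order, function(id) {
    p <- preds[[id]]
    lab <- if (inherits(p, "competitor_prediction")) p$lab else as.numeric(p)
    proj <- project_onto_rt(lab, R, T_)
    sqrt(sum((proj - R)^2))
  }, numeric(1))
  ord <- order(dists)  # stable: ties resolved by tie_order position
  c1 <- tie_order[ord[1]]
  c2 <- tie_order[ord[2]]
  d1 <- dists[ord[1]]
  d2 <- dists[ord[2]]
  if (d1 + d2 == 0) {
    w1 <- 1
  } else {
    w1 <- d2 / (d1 + d2)
  }
  match <- w1 * competitors$labs[c1, ] + (1 - w1) * competitors$labs[c2, ]
  # flag matches that would sit beyond the over-constancy anchor
  beyond <- sqrt(sum((match - T_)^2)) >
    sqrt(sum((competitors$labs["O", ] - T_)^2)) + 1e-9
  structure(drop(match), selected = c(c1, c2), distances = dists,
            beyond_o = beyond)
}

#' Model Color Constancy Index
#'
#' Scores a model Match with the same index used for observers
#' (delegates to [compute_cci()]).
#'
#' @param match Length-3 Lab Match (e.g. from [infer_model_match()]).
#' @param competitors A `competitor_set`.
#' @return CCI in percent.
#' @export
model_cci <- function(match, competitors) {
  compute_cci(as.numeric(match), competitors)
}

#' Score a white-balanced image through the model-match pipeline
#'
#' Bridges the classical algorithms to the behavioral index: the corrected
#' image's Lab values are treated as the predicted reflectance map and run
#' through the identical masked-average / projection / interpolation
#' pipeline as the learned model.
#'
#' @param corrected_images Named-by-competitor list; each element is a list
#'   of corrected H x W x 3 linear RGB images (one per appearance).
#' @param masks Matching named list of lists of label masks.
#' @param competitor_labels Named integer vector mapping competitor id to
#'   mask label.
#' @param competitors A `competitor_set`.
#' @param white,primaries CIELAB conversion parameters.
#' @return Length-3 Lab Match (see [infer_model_match()]).
#' @export
classical_to_match <- function(corrected_images, masks, competitor_labels,
                               competitors, white = white_d65(),
                               primaries = srgb_primaries()) {
  preds <- lapply(names(competitor_labels), function(id) {
    imgs <- corrected_images[[id]]
    mks <- masks[[id]]
    lab_maps <- lapply(imgs, function(im) {
      array(linear_rgb_to_lab(matrix(im, ncol = 3), white, primaries),
            dim = dim(im))
    })
    average_masked(lab_maps, mks, competitor_labels[[id]])
  })
  names(preds) <- names(competitor_labels)
  infer_model_match(preds, competitors)
}
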