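# Synthetic stand-ins for the VR stimuli: a diagonal (von Kries) image
# formation model on flat-patch scenes, with per-pixel ground-truth
# reflectance, integer label masks for competitor objects, and the four
# cue-silencing manipulations.
#
# Conventions: images are height x width x 3 arrays in linear RGB, clipped to
# [0, 1] after rendering; masks are height x width integer matrices with 0 =
# unlabeled; pixel indices are row-major.

SCENE_MECHANISMS <- c("baseline", "local_surround", "maximum_flux",
                      "spatial_mean_add", "spatial_mean_change")

# role codes in the role matrix
ROLE_BACKGROUND <- 0L
ROLE_TEXTURE <- 1L
ROLE_WHITE_PATCH <- 2L
ROLE_FILLER <- 3L
ROLE_SURROUND <- 4L
ROLE_TARGET <- 5L

# Reflectance of the bright achromatic patch: the brightest surface in every
# scene, chosen so it stays inside the display gamut under the strongest
# chromatic gain (no clipping, which would neutralize its chromaticity).
WHITE_PATCH_REFLECTANCE <- 0.62

#' Construct an illuminant specification
#'
#' An illuminant acts on the scene through a per-channel positive gain in
#' linear RGB (diagonal / von Kries image formation). `hue` records the
#' direction of the chromatic shift the illuminant imposes on a gray surface
#' in the a*-b* plane (degrees; NA for neutral).
#'
#' @param name Illuminant name.
#' @param gain Positive length-3 gain applied channel-wise in linear RGB.
#' @param axis One of `"daylight"`, `"orthogonal"`, `"none"`.
#' @param hue Chromatic direction in the a*-b* plane, degrees, or NA.
#' @return An object of class `illuminant_spec`.
#' @export
illuminant_spec <- function(name, gain, axis = "none", hue = NA_real_) {
  gain <- as.numeric(gain)
  if (length(gain) != 3L || !all(is.finite(gain)) || any(gain <= 0)) {
    stop("illuminant gain must be three strictly positive values",
         call. = FALSE)
  }
  if (!axis %in% c("daylight", "orthogonal", "none")) {
    stop("axis must be daylight, orthogonal or none", call. = FALSE)
  }
  structure(list(name = name, gain = gain, axis = axis, hue = hue),
            class = "illuminant_spec")
}

#' @export
print.illuminant_spec <- function(x, ...) {
  cat(sprintf("<illuminant %s: gain = (%.4f, %.4f, %.4f), axis = %s>\n",
              x$name, x$gain[1], x$gain[2], x$gain[3], x$axis))
  invisible(x)
}

# Gain that shifts a reference gray by (da, db) in a*-b* at fixed L.
gain_for_ab_offset <- function(da, db, ref_gray, base_gain, white, primaries) {
  lab0 <- linear_rgb_to_lab(ref_gray * base_gain, white, primaries)
  target <- lab0 + c(0, da, db)
  rgb <- lab_to_linear_rgb(target, white, primaries)
  rgb / ref_gray
}

#' Build the five-illuminant set
#'
#' Five illuminants: a neutral, blue and yellow on the daylight axis, and red
#' and green on the orthogonal axis. The blue gain is constructed so that a
#' reference gray shifts by `-axis_offset` along b* (and red by
#' `+axis_offset` along a*); yellow and green are exact mirrors of blue and
#' red in gain space, so each chromatic pair averages channel-wise to the
#' neutral gain and the neutral gain is the centroid of the four.
#'
#' @param axis_offset Magnitude of the chromatic step in CIELAB a*-b* units
#'   at the reference gray (default 20).
#' @param base_gain Scalar intensity of the neutral illuminant.
#' @param ref_gray Achromatic reference reflectance used to anchor the
#'   chromatic step.
#' @param white,primaries CIELAB white point and RGB primaries matrix.
#' @return Named list of five `illuminant_spec` objects
#'   (neutral, blue, yellow, red, green).
#' @export
make_illuminant_set <- function(axis_offset = 20, base_gain = 1,
                                ref_gray = 0.4, white = white_d65(),
                                primaries = srgb_primaries()) {
  if (!is.finite(axis_offset) || axis_offset < 0) {
    stop("axis_offset must be non-negative", call. = FALSE)
  }
  neutral <- rep(base_gain, 3)
  g_blue <- gain_for_ab_offset(0, -axis_offset, ref_gray, neutral,
                               white, primaries)
  g_red <- gain_for_ab_offset(axis_offset, 0, ref_gray, neutral,
                              white, primaries)
  g_yellow <- 2 * neutral - g_blue
  g_green <- 2 * neutral - g_red
  gains <- list(blue = g_blue, yellow = g_yellow,
                red = g_red, green = g_green)
  bad <- vapply(gains, function(g) any(g <= 0), logical(1))
  if (any(bad)) {
    stop("axis_offset too large: non-positive gain for ",
         paste(names(gains)[bad], collapse = ", "), call. = FALSE)
  }
  list(
    neutral = illuminant_spec("neutral", neutral, "none", NA_real_),
    blue = illuminant_spec("blue", g_blue, "daylight", 270),
    yellow = illuminant_spec("yellow", g_yellow, "daylight", 90),
    red = illuminant_spec("red", g_red, "orthogonal", 0),
    green = illuminant_spec("green", g_green, "orthogonal", 180)
  )
}

# Background palettes: a base reflectance plus texture-patch reflectances.
scene_palette <- function(palette) {
  switch(palette,
    indoor = list(base = c(0.46, 0.43, 0.40),
                  texture = rbind(c(0.55, 0.50, 0.44),
                                  c(0.38, 0.36, 0.34),
                                  c(0.50, 0.47, 0.46))),
    outdoor = list(base = c(0.28, 0.42, 0.24),
                   texture = rbind(c(0.36, 0.50, 0.30),
                                   c(0.22, 0.33, 0.20),
                                   c(0.42, 0.40, 0.30))),
    stop("unknown palette: ", palette, call. = FALSE)
  )
}

# Fixed anchor positions (centers, fractional image coordinates) for target
# placements.
target_anchors <- function(n_locations, size) {
  anchors <- rbind(c(0.28, 0.28), c(0.72, 0.28), c(0.50, 0.72),
                   c(0.28, 0.72), c(0.72, 0.72))
  if (n_locations > nrow(anchors)) {
    stop("at most ", nrow(anchors), " target locations supported",
         call. = FALSE)
  }
  round(anchors[seq_len(n_locations), , drop = FALSE] * size)
}

#' Specify a synthetic scene
#'
#' Lays out a flat-patch scene: a textured background, a small bright
#' achromatic patch (the maximum-flux cue), seeded filler objects, an
#' optional colored surround disk under the target, and a single labeled
#' target patch carrying a competitor reflectance. The seed fully determines
#' the filler layout.
#'
#' @param size Image side in pixels (square image).
#' @param palette `"indoor"` or `"outdoor"` background palette.
#' @param target_reflectance Length-3 reflectance of the labeled target
#'   patch.
#' @param target_label Integer mask label assigned to the target.
#' @param location Which of the fixed target anchor positions to use.
#' @param n_locations Number of anchor positions in the design.
#' @param surround Optional length-3 reflectance of a surround disk placed
#'   under the target (the "leaf").
#' @param surround_name Optional name of the surround color.
#' @param mechanism One of `r paste(SCENE_MECHANISMS, collapse = ", ")`.
#' @param n_fillers Number of seeded filler objects.
#' @param seed Integer seed controlling filler placement.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(size = 64, palette = "indoor",
                       target_reflectance = rep(0.4, 3),
                       target_label = 1L, location = 1L, n_locations = 3L,
                       surround = NULL, surround_name = NA_character_,
                       mechanism = "baseline", n_fillers = 5L, seed = 1L) {
  if (!mechanism %in% SCENE_MECHANISMS) {
    stop("unknown mechanism: ", mechanism, call. = FALSE)
  }
  if (location < 1L || location > n_locations) {
    stop("location out of range", call. = FALSE)
  }
  target_reflectance <- as.numeric(target_reflectance)
  if (length(target_reflectance) != 3L || any(!is.finite(target_reflectance)) ||
      any(target_reflectance < 0)) {
    stop("target_reflectance must be three non-negative values", call. = FALSE)
  }
  structure(list(size = as.integer(size), palette = palette,
                 target_reflectance = target_reflectance,
                 target_label = as.integer(target_label),
                 location = as.integer(location),
                 n_locations = as.integer(n_locations),
                 surround = surround, surround_name = surround_name,
                 mechanism = mechanism, n_fillers = as.integer(n_fillers),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Paint a filled disk into matrix coordinates; returns logical mask.
disk_mask <- function(size, cx, cy, r) {
  x <- matrix(rep(seq_len(size), each = size), nrow = size)   # column index
  y <- matrix(rep(seq_len(size), times = size), nrow = size)  # row index
  (x - cx)^2 + (y - cy)^2 <= r^2
}

rect_mask <- function(size, x0, y0, w, h) {
  m <- matrix(FALSE, size, size)
  xs <- max(1, x0):min(size, x0 + w - 1)
  ys <- max(1, y0):min(size, y0 + h - 1)
  m[ys, xs] <- TRUE
  m
}

# Build the reflectance map, role matrix and label mask for a scene spec.
# Deterministic in spec$seed.
compose_scene <- function(spec) {
  size <- spec$size
  pal <- scene_palette(spec$palette)
  refl <- array(rep(pal$base, each = size * size), dim = c(size, size, 3))
  role <- matrix(ROLE_BACKGROUND, size, size)
  mask <- matrix(0L, size, size)

  set_region <- function(sel, rgb, role_code, label = 0L) {
    for (k in 1:3) {
      ch <- refl[, , k]
      ch[sel] <- rgb[k]
      refl[, , k] <<- ch
    }
    role[sel] <<- role_code
    if (label > 0L) mask[sel] <<- label
  }

  # background texture: three horizontal bands with distinct reflectances
  bands <- round(seq(1, size + 1, length.out = 4))
  for (i in 1:3) {
    sel <- rect_mask(size, 1, bands[i], size, bands[i + 1] - bands[i])
    set_region(sel, pal$texture[i, ], ROLE_TEXTURE)
  }

  # seeded filler objects (small disks, muted reflectances), kept away from
  # the target anchors
  anchors <- target_anchors(spec$n_locations, size)
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    list(pos = matrix(runif(2 * spec$n_fillers, 0.08, 0.92), ncol = 2),
         r = runif(spec$n_fillers, 2.5, 4.5),
         col = matrix(runif(3 * spec$n_fillers, 0.12, 0.60), ncol = 3))
  })
  if (spec$n_fillers > 0) {
    for (i in seq_len(spec$n_fillers)) {
      cx <- rng$pos[i, 1] * size
      cy <- rng$pos[i, 2] * size
      near <- any(sqrt((anchors[, 1] - cx)^2 + (anchors[, 2] - cy)^2) <
                    rng$r[i] + 9)
      if (near) next  # skip fillers that would collide with target anchors
      set_region(disk_mask(size, cx, cy, rng$r[i]), rng$col[i, ], ROLE_FILLER)
    }
  }

  # bright achromatic patch (maximum-flux cue), fixed position
  wp <- rect_mask(size, max(1, round(0.05 * size)), max(1, round(0.05 * size)),
                  max(3, round(0.1 * size)), max(3, round(0.1 * size)))
  set_region(wp, rep(WHITE_PATCH_REFLECTANCE, 3), ROLE_WHITE_PATCH)

  # surround disk then target patch at the chosen anchor
  a <- anchors[spec$location, ]
  if (!is.null(spec$surround)) {
    set_region(disk_mask(size, a[1], a[2], round(0.11 * size)),
               spec$surround, ROLE_SURROUND)
  }
  set_region(disk_mask(size, a[1], a[2], round(0.06 * size)),
             spec$target_reflectance, ROLE_TARGET, spec$target_label)

  list(reflectance = refl, role = role, mask = mask)
}

#' Render a scene under an illuminant
#'
#' Diagonal image formation: each channel of the per-pixel reflectance map is
#' multiplied by the illuminant gain, then clipped to [0, 1]. If the scene
#' spec names a cue-silencing mechanism other than `"baseline"`, the
#' corresponding manipulation is applied via [apply_manipulation()] (which
#' requires the neutral illuminant for its fixed-color overrides).
#'
#' @param spec A [scene_spec()].
#' @param illum The test `illuminant_spec`.
#' @param neutral The neutral `illuminant_spec` (required by manipulations;
#'   defaults to unit gains).
#' @param manip_params Optional parameter list forwarded to
#'   [apply_manipulation()].
#' @return An object of class `rendered_scene` with fields `rgb`,
#'   `reflectance`, `mask`, `role`, `illuminant`, `mechanism`, `clipped`.
#' @export
render_scene <- function(spec, illum,
                         neutral = illuminant_spec("neutral", c(1, 1, 1)),
                         manip_params = list()) {
  stopifnot(inherits(spec, "scene_spec"), inherits(illum, "illuminant_spec"))
  parts <- compose_scene(spec)
  rgb <- parts$reflectance
  for (k in 1:3) rgb[, , k] <- rgb[, , k] * illum$gain[k]
  scene <- structure(list(rgb = rgb, reflectance = parts$reflectance,
                          mask = parts$mask, role = parts$role,
                          illuminant = illum$name, mechanism = "baseline",
                          spec = spec, clipped = FALSE),
                     class = "rendered_scene")
  scene <- apply_manipulation(scene, spec$mechanism, illum, neutral,
                              manip_params)
  clip_scene(scene)
}

clip_scene <- function(scene) {
  over <- scene$rgb > 1 | scene$rgb < 0
  if (any(over)) {
    labeled <- scene$mask > 0
    hit <- apply(over, c(1, 2), any) & labeled
    if (any(hit)) {
      warning("clipping touches a labeled region (",
              sum(hit), " pixels)", call. = FALSE)
    }
    scene$rgb[scene$rgb > 1] <- 1
    scene$rgb[scene$rgb < 0] <- 0
    scene$clipped <- TRUE
  }
  scene
}

#' @export
print.rendered_scene <- function(x, ...) {
  cat(sprintf("<rendered_scene %dx%d, illuminant = %s, mechanism = %s>\n",
              nrow(x$mask), ncol(x$mask), x$illuminant, x$mechanism))
  invisible(x)
}

#' Apply a cue-silencing manipulation to a rendered scene
#'
#' The four mechanisms silence one constancy cue each:
#' * `local_surround` - surround-region pixels are forced to the fixed
#'   rendered color they would have under the neutral illuminant, so the
#'   local edge between target and surround no longer varies with the
#'   illuminant.
#' * `maximum_flux` - the bright achromatic patch is forced to its fixed
#'   neutral-illuminant rendering, removing the "brightest patch tracks the
#'   illuminant" cue.
#' * `spatial_mean_add` - filler disks are inserted whose shared rendered
#'   color opposes the illuminant, solved so the scene mean chromaticity
#'   moves to the opposite side of neutral (up to gamut clamping).
#' * `spatial_mean_change` - background and texture reflectances are rescaled
#'   channel-wise by `(neutral gain / illuminant gain)^2`, so the rendered
#'   background sits opposite the illuminant shift.
#'
#' `baseline` returns the scene unchanged.
#'
#' @param scene A `rendered_scene`.
#' @param mechanism Manipulation name.
#' @param illum,neutral Test and neutral `illuminant_spec`s.
#' @param params Optional list: `n_add` (number of inserted objects) for
#'   `spatial_mean_add`.
#' @return The manipulated `rendered_scene`.
#' @export
apply_manipulation <- function(scene, mechanism, illum,
                               neutral = illuminant_spec("neutral", c(1, 1, 1)),
                               params = list()) {
  stopifnot(inherits(scene, "rendered_scene"))
  if (!mechanism %in% SCENE_MECHANISMS) {
    stop("unknown mechanism: ", mechanism, call. = FALSE)
  }
  if (mechanism == "baseline") return(scene)
  scene$mechanism <- mechanism

  set_rgb <- function(sel, rgb) {
    for (k in 1:3) {
      ch <- scene$rgb[, , k]
      ch[sel] <- rgb[k]
      scene$rgb[, , k] <<- ch
    }
  }

  if (mechanism == "local_surround") {
    sel <- scene$role == ROLE_SURROUND
    if (!any(sel)) {
      stop("scene has no surround region to silence", call. = FALSE)
    }
    srefl <- scene$spec$surround
    set_rgb(sel, srefl * neutral$gain)
  } else if (mechanism == "maximum_flux") {
    sel <- scene$role == ROLE_WHITE_PATCH
    srefl <- rep(WHITE_PATCH_REFLECTANCE, 3)
    set_rgb(sel, srefl * neutral$gain)
  } else if (mechanism == "spatial_mean_add") {
    n_add <- params$n_add %||% 20L
    size <- nrow(scene$mask)
    # The added objects oppose the illuminant in color-opponent terms:
    # their common rendered color is solved (exactly, since the spatial
    # mean is linear in RGB) so that the post-manipulation scene mean
    # lands at the mirror image, about the neutral-illuminant mean, of the
    # current mean - i.e. on the opposite side of neutral from the
    # illuminant shift. Gamut clamping can only shorten that mirror step.
    anchors <- target_anchors(scene$spec$n_locations, size)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(scene$spec$seed + 77L)
    sel_all <- matrix(FALSE, size, size)
    placed <- 0L
    attempts <- 0L
    while (placed < n_add && attempts < 1000L) {
      attempts <- attempts + 1L
      cx <- runif(1, 0.08, 0.92) * size
      cy <- runif(1, 0.08, 0.92) * size
      r <- runif(1, 0.08, 0.12) * size
      if (any(sqrt((anchors[, 1] - cx)^2 + (anchors[, 2] - cy)^2) < r + 9)) next
      sel_all <- sel_all | (disk_mask(size, cx, cy, r) & scene$mask == 0L)
      placed <- placed + 1L
    }
    f <- mean(sel_all)
    if (f > 0) {
      m_cur <- vapply(1:3, function(k) mean(scene$rgb[, , k]), numeric(1))
      m_neu <- vapply(1:3, function(k)
        mean(scene$reflectance[, , k]) * neutral$gain[k], numeric(1))
      m_opp <- pmax(2 * m_neu - m_cur, 1e-3)
      m_rest <- vapply(1:3, function(k) mean(scene$rgb[, , k][!sel_all]),
                       numeric(1))
      color <- pmin(pmax((m_opp - (1 - f) * m_rest) / f, 1e-3), 1)
      rho <- color / illum$gain
      for (k in 1:3) {
        rf <- scene$reflectance[, , k]
        rf[sel_all] <- rho[k]
        scene$reflectance[, , k] <- rf
        ch <- scene$rgb[, , k]
        ch[sel_all] <- color[k]
        scene$rgb[, , k] <- ch
      }
      scene$role[sel_all] <- ROLE_FILLER
    }
  } else if (mechanism == "spatial_mean_change") {
    sel <- scene$role %in% c(ROLE_BACKGROUND, ROLE_TEXTURE)
    factor <- (neutral$gain / illum$gain)^2
    for (k in 1:3) {
      rf <- scene$reflectance[, , k]
      rf[sel] <- pmin(rf[sel] * factor[k], 1)
      scene$reflectance[, , k] <- rf
      ch <- scene$rgb[, , k]
      ch[sel] <- rf[sel] * illum$gain[k]
      scene$rgb[, , k] <- ch
    }
  }
  scene
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct the five-competitor set for one illuminant
#'
#' Builds the R/T/S1/S2/O competitor colors for an achromatic target under a
#' test illuminant, anchored in the *reflectance* CIELAB space (reflectances
#' rendered under the neutral illuminant):
#' * R (reflectance match) shares the target's reflectance - 100% constancy.
#' * T (tristimulus match) is the surface whose reflected light under the
#'   test illuminant equals the target's light under neutral - 0% constancy.
#' * S1 and S2 divide the R-T segment in thirds (S1 nearer R).
#' * O sits one third-step beyond R, away from T (over-constancy).
#'
#' The five Lab points are exactly collinear and uniformly spaced on the
#' grid T = 0, S2 = 1, S1 = 2, R = 3, O = 4 (in S-steps).
#'
#' @param target_reflectance Achromatic length-3 reflectance (equal
#'   channels).
#' @param illum,neutral Test and neutral `illuminant_spec`s.
#' @param white,primaries CIELAB white point and RGB primaries.
#' @return Object of class `competitor_set` with fields `labs` (5 x 3 matrix,
#'   rows R, T, S1, S2, O), `reflectances` (5 x 3), `illuminant`,
#'   `target_reflectance`, `degenerate`.
#' @export
make_competitor_set <- function(target_reflectance = rep(0.4, 3), illum,
                                neutral, white = white_d65(),
                                primaries = srgb_primaries()) {
  stopifnot(inherits(illum, "illuminant_spec"),
            inherits(neutral, "illuminant_spec"))
  rho_t <- as.numeric(target_reflectance)
  if (max(rho_t) - min(rho_t) > 1e-9) {
    stop("target reflectance must be achromatic (equal channels)",
         call. = FALSE)
  }
  rho_T <- rho_t * neutral$gain / illum$gain
  R <- linear_rgb_to_lab(rho_t * neutral$gain, white, primaries)
  T <- linear_rgb_to_lab(rho_T * neutral$gain, white, primaries)
  step <- (T - R) / 3
  labs <- rbind(R = R, T = T, S1 = R + step, S2 = R + 2 * step, O = R - step)
  degenerate <- sqrt(sum((T - R)^2)) < 1e-9
  refl <- lab_to_linear_rgb(labs, white, primaries) /
    matrix(neutral$gain, nrow = 5, ncol = 3, byrow = TRUE)
  rownames(refl) <- rownames(labs)
  structure(list(labs = labs, reflectances = refl, illuminant = illum$name,
                 target_reflectance = rho_t, degenerate = degenerate,
                 white = white, primaries = primaries),
            class = "competitor_set")
}

#' @export
print.competitor_set <- function(x, ...) {
  cat(sprintf("<competitor_set under %s illuminant%s>\n", x$illuminant,
              if (x$degenerate) " (degenerate)" else ""))
  print(round(x$labs, 3))
  invisible(x)
}

#' Competitor order along the constancy axis
#'
#' Canonical order of the competitors from the tristimulus end to the
#' over-constancy end, with their grid positions in S-steps.
#'
#' @return Named numeric vector: T = 0, S2 = 1, S1 = 2, R = 3, O = 4.
#' @export
competitor_grid <- function() {
  c(T = 0, S2 = 1, S1 = 2, R = 3, O = 4)
}

#' The four colored surround reflectances
#'
#' Khaki, rose, purple and teal surrounds placed on the diagonals between the
#' illuminant axes in the a*-b* plane (hue angles 135, 45, 315 and 225
#' degrees), all at the same lightness and chroma, hence symmetric about
#' neutral in opposing pairs (khaki/purple, rose/teal).
#'
#' @param chroma_ab Chroma of each surround in Lab units.
#' @param L Lightness of each surround.
#' @param neutral Neutral `illuminant_spec` used to convert the surround Lab
#'   color into a surface reflectance.
#' @param white,primaries CIELAB white point and RGB primaries.
#' @return Named list; each element has `name`, `hue` (degrees), `lab`, and
#'   `reflectance`.
#' @export
make_surround_color_set <- function(chroma_ab = 20, L = 55,
                                    neutral = illuminant_spec("neutral", c(1, 1, 1)),
                                    white = white_d65(),
                                    primaries = srgb_primaries()) {
  hues <- c(khaki = 135, rose = 45, purple = 315, teal = 225)
  out <- lapply(names(hues), function(nm) {
    h <- hues[[nm]] * pi / 180
    lab <- c(L, chroma_ab * cos(h), chroma_ab * sin(h))
    list(name = nm, hue = hues[[nm]], lab = lab,
         reflectance = lab_to_linear_rgb(lab, white, primaries) / neutral$gain)
  })
  names(out) <- names(hues)
  out
}

#' Classify an illuminant as Neighboring or Opposing a surround color
#'
#' Chromatic illuminants whose hue lies within 90 degrees of the surround hue
#' are Neighboring; the others are Opposing. The neutral illuminant has no
#' chromatic direction and is rejected.
#'
#' @param illum An `illuminant_spec` with a chromatic `hue`.
#' @param surround_hue Surround hue angle in degrees.
#' @return `"Neighboring"` or `"Opposing"`.
#' @export
classify_direction <- function(illum, surround_hue) {
  stopifnot(inherits(illum, "illuminant_spec"))
  if (!is.finite(illum$hue)) {
    stop("neutral illuminant has no chromatic direction", call. = FALSE)
  }
  d <- abs(((illum$hue - surround_hue) + 180) %% 360 - 180)
  if (d < 90) "Neighboring" else "Opposing"
}

#' Generate the model-evaluation dataset for one experiment arm
#'
#' For every combination of mechanism, illuminant, competitor color and
#' target placement, renders a scene in which the target patch carries that
#' competitor's reflectance, labeled in the mask. This mirrors capturing
#' images of each color competitor under each illuminant across all spatial
#' locations.
#'
#' @param illum_set Output of [make_illuminant_set()].
#' @param mechanisms Character vector of mechanisms to include.
#' @param palette Scene palette.
#' @param n_locations Number of target placements.
#' @param target_reflectance Achromatic target reflectance.
#' @param surround Optional surround entry from [make_surround_color_set()]
#'   (placed under the target in every scene, as in the surround-color
#'   experiment). When absent, scenes have no leaf except under the
#'   `local_surround` mechanism, which places the default rose leaf whose
#'   rendered color is then held fixed.
#' @param size Image side in pixels.
#' @param seed Integer seed (fully determines the dataset).
#' @return List with `records` (one element per rendered scene: `scene`,
#'   `competitor`, `location`, `illuminant`, `mechanism`),
#'   `competitor_sets` (one `competitor_set` per illuminant), and `manifest`
#'   (data frame).
#' @export
generate_experiment_dataset <- function(illum_set,
                                        mechanisms = "baseline",
                                        palette = "indoor",
                                        n_locations = 3L,
                                        target_reflectance = rep(0.4, 3),
                                        surround = NULL,
                                        size = 64L, seed = 1L) {
  stopifnot(all(mechanisms %in% SCENE_MECHANISMS))
  neutral <- illum_set$neutral
  comp_sets <- lapply(illum_set, function(il) {
    make_competitor_set(target_reflectance, il, neutral)
  })
  comp_names <- rownames(comp_sets[[1]]$labs)
  records <- list()
  rows <- list()
  i <- 0L
  default_leaf <- make_surround_color_set(neutral = neutral, white = white_d65(),
                                          primaries = srgb_primaries())$rose
  for (mech in mechanisms) {
    sur_use <- if (!is.null(surround)) surround else
      if (mech == "local_surround") default_leaf else NULL
    for (il_name in names(illum_set)) {
      cs <- comp_sets[[il_name]]
      for (ci in seq_along(comp_names)) {
        for (loc in seq_len(n_locations)) {
          i <- i + 1L
          spec <- scene_spec(size = size, palette = palette,
                             target_reflectance = cs$reflectances[ci, ],
                             target_label = ci, location = loc,
                             n_locations = n_locations,
                             surround = if (!is.null(sur_use)) sur_use$reflectance,
                             surround_name = if (!is.null(sur_use)) sur_use$name else NA_character_,
                             mechanism = mech,
                             seed = seed + loc)
          records[[i]] <- list(
            scene = render_scene(spec, illum_set[[il_name]], neutral),
            competitor = comp_names[ci], location = loc,
            illuminant = il_name, mechanism = mech)
          rows[[i]] <- data.frame(index = i, mechanism = mech,
                                  illuminant = il_name,
                                  competitor = comp_names[ci],
                                  location = loc)
        }
      }
    }
  }
  list(records = records, competitor_sets = comp_sets,
       manifest = do.call(rbind, rows))
}
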