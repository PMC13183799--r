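# Scene bundles and tabular result I/O.
#
# A scene bundle is a directory: image.png (8-bit display copy of the
# rendered image), reflectance.tiff (float32, exact ground truth), mask.png
# (8-bit label image, labels 0-255), metadata.json.

#' Write a rendered scene to a bundle directory
#'
#' @param scene A `rendered_scene`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene_bundle <- function(scene, dir) {
  stopifnot(inherits(scene, "rendered_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  png::writePNG(scene$rgb, file.path(dir, "image.png"))
  tiff::writeTIFF(scene$reflectance, file.path(dir, "reflectance.tiff"),
                  bits.per.sample = 32L)
  if (max(scene$mask) > 255L) stop("mask labels exceed 8-bit range",
                                   call. = FALSE)
  png::writePNG(scene$mask / 255, file.path(dir, "mask.png"))
  meta <- list(illuminant = scene$illuminant, mechanism = scene$mechanism,
               size = dim(scene$mask),
               surround = scene$spec$surround_name,
               location = scene$spec$location,
               target_label = scene$spec$target_label,
               seed = scene$spec$seed, clipped = scene$clipped)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a scene bundle directory
#'
#' @param dir Directory written by [write_scene_bundle()].
#' @return List with `rgb` (8-bit quantized), `reflectance` (float32
#'   exact), `mask` (integer matrix) and `metadata`.
#' @export
read_scene_bundle <- function(dir) {
  rgb <- png::readPNG(file.path(dir, "image.png"))
  refl <- tiff::readTIFF(file.path(dir, "reflectance.tiff"))
  mask <- round(png::readPNG(file.path(dir, "mask.png")) * 255)
  storage.mode(mask) <- "integer"
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  list(rgb = rgb, reflectance = refl, mask = mask, metadata = meta)
}

#' Write a CCI record table as CSV
#'
#' Fixed column schema shared by the observer and model pipelines:
#' `agent, agent_type, scene, mechanism, surround, illuminant, cci`.
#'
#' @param tab Data frame of CCI records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cci_table <- function(tab, path) {
  need <- c("agent", "agent_type", "scene", "mechanism", "surround",
            "illuminant", "cci")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("CCI table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(tab[need], path, row.names = FALSE)
  invisible(path)
}

#' Read a CCI record table written by [write_cci_table()]
#'
#' @param path CSV path.
#' @return Data frame of CCI records.
#' @export
read_cci_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
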