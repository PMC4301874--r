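# File interfaces: 8-bit RGB PNG images, single-channel PNG label masks,
# GeoJSON fiber/nucleus annotations, CSV manifests and tables.

#' Read an 8-bit RGB PNG image
#'
#' @param path PNG file path.
#' @return `H x W x 3` integer array in \[0, 255\] (alpha dropped if present).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L)
    stop("grayscale input is not supported (the segmentation is colour-based)")
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  out <- round(a * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write an 8-bit RGB image as PNG
#' @param img `H x W x 3` array in \[0, 255\].
#' @param path Destination path.
#' @export
write_image <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Write / read a ground-truth label mask as single-channel PNG
#'
#' Integer codes (0 = background, 1 = muscle, 2 = collagen, 3 = nucleus)
#' are stored as gray levels code/255.
#' @param mask Integer matrix of codes in \[0, 255\].
#' @param path PNG path.
#' @export
write_label_mask <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  m <- round(a * 255)
  storage.mode(m) <- "integer"
  m
}

#' Write fiber and nucleus annotations as GeoJSON
#'
#' One FeatureCollection: Polygon features carry `fiber_id`; Point features
#' carry `fiber_id` and `is_central`.
#'
#' @param fibers List of [fiber_annotation()]s.
#' @param nuclei data.frame with `x`, `y`, `fiber_id`, optionally
#'   `is_central`.
#' @param path Destination `.geojson` path.
#' @export
write_annotations <- function(fibers, nuclei, path) {
  feats <- list()
  for (f in fibers) {
    ring <- rbind(f$polygon, f$polygon[1, ])
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(unname(apply(ring, 1, as.list,
                                                      simplify = FALSE)))),
      properties = list(fiber_id = as.character(f$fiber_id)))
  }
  if (!is.null(nuclei) && nrow(nuclei)) {
    for (i in seq_len(nrow(nuclei))) {
      props <- list(fiber_id = as.character(nuclei$fiber_id[i]))
      if ("is_central" %in% names(nuclei))
        props$is_central <- isTRUE(nuclei$is_central[i])
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        geometry = list(type = "Point",
                        coordinates = c(nuclei$x[i], nuclei$y[i])),
        properties = props)
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read fiber and nucleus annotations from GeoJSON
#'
#' @param path `.geojson` path in the dialect of [write_annotations()].
#' @return List with `fibers` (list of [fiber_annotation()]s) and `nuclei`
#'   (data.frame `x`, `y`, `fiber_id`, `is_central`).
#' @export
read_annotations <- function(path) {
  gj <- jsonlite::read_json(path)
  fibers <- list(); nuc <- list()
  for (ft in gj$features) {
    if (ft$geometry$type == "Polygon") {
      ring <- ft$geometry$coordinates[[1]]
      poly <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      fibers[[length(fibers) + 1L]] <-
        fiber_annotation(ft$properties$fiber_id, poly)
    } else if (ft$geometry$type == "Point") {
      nuc[[length(nuc) + 1L]] <- data.frame(
        x = ft$geometry$coordinates[[1]],
        y = ft$geometry$coordinates[[2]],
        fiber_id = as.character(ft$properties$fiber_id %||% NA_character_),
        is_central = isTRUE(ft$properties$is_central))
    }
  }
  nuclei <- if (length(nuc)) do.call(rbind, nuc)
            else data.frame(x = numeric(0), y = numeric(0),
                            fiber_id = character(0), is_central = logical(0))
  list(fibers = fibers, nuclei = nuclei)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic section to disk
#'
#' Image as RGB PNG, ground-truth label mask as single-channel PNG, fiber
#' polygons and nuclei as GeoJSON.
#'
#' @param section A `synthetic_section`.
#' @param image_path,gt_path,annotation_path Destination paths.
#' @export
write_section <- function(section, image_path, gt_path = NULL,
                          annotation_path = NULL) {
  write_image(section$image, image_path)
  if (!is.null(gt_path)) write_label_mask(section$gt$label_mask, gt_path)
  if (!is.null(annotation_path))
    write_annotations(gt_fibers(section), section$gt$nuclei, annotation_path)
  invisible(image_path)
}

#' Write / read a cohort manifest CSV
#' @param manifest Manifest data.frame from [generate_cohort()] or built by
#'   hand (columns group, animal, section, image_path, ...).
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
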