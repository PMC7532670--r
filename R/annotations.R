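#' Parse an ImageScope ROI annotation XML
#'
#' Reads carcinoma ROI polygons from an Aperio ImageScope-dialect annotation
#' file (`Annotations/Annotation/Regions/Region/Vertices/Vertex` with `X`,`Y`
#' attributes, level-0 pixel coordinates, y increasing downward). Regions with
#' fewer than 3 vertices are skipped with a warning; duplicated closing
#' vertices are dropped.
#'
#' @param path Annotation XML path.
#' @param slide_id Slide identifier; defaults to the file base name.
#' @return An object of class `roi_annotation`: a list with `slide_id`,
#'   `polygons` (list of n-by-2 vertex matrices, rings implicitly closed) and
#'   `mpp` (microns per pixel, from the `MicronsPerPixel` attribute if present,
#'   else 0.5).
#' @export
parse_annotation_xml <- function(path, slide_id = NULL) {
  if (!file.exists(path)) stop_pathomsi(paste0("annotation not found: ", path))
  doc <- xml2::read_xml(path)
  mpp <- xml2::xml_attr(doc, "MicronsPerPixel")
  mpp <- if (is.na(mpp)) 0.5 else as.numeric(mpp)
  regions <- xml2::xml_find_all(doc, ".//Region")
  polygons <- list()
  for (reg in regions) {
    verts <- xml2::xml_find_all(reg, ".//Vertex")
    if (length(verts) == 0) next
    xy <- cbind(as.numeric(xml2::xml_attr(verts, "X")),
                as.numeric(xml2::xml_attr(verts, "Y")))
    # drop an explicit closing vertex
    if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
    if (nrow(xy) < 3) {
      rlang::warn(paste0("skipping degenerate region with ", nrow(xy), " vertices"))
      next
    }
    polygons <- c(polygons, list(unname(xy)))
  }
  if (length(polygons) == 0) stop_pathomsi("annotation contains no usable region")
  new_roi_annotation(slide_id %||% tools::file_path_sans_ext(basename(path)),
                     polygons, mpp)
}

new_roi_annotation <- function(slide_id, polygons, mpp = 0.5) {
  structure(list(slide_id = slide_id, polygons = polygons, mpp = mpp),
            class = "roi_annotation")
}

#' @export
print.roi_annotation <- function(x, ...) {
  cat("<roi_annotation> slide", x$slide_id, "-", length(x$polygons),
      "polygon(s), mpp", x$mpp, "\n")
  invisible(x)
}

#' Write ROI polygons as ImageScope-dialect XML
#'
#' Inverse of [parse_annotation_xml()]; round-trips vertex coordinates.
#'
#' @param roi An `roi_annotation`.
#' @param path Output XML path.
#' @return `path`, invisibly.
#' @export
write_annotation_xml <- function(roi, path) {
  doc <- xml2::xml_new_root("Annotations", MicronsPerPixel = format(roi$mpp))
  ann <- xml2::xml_add_child(doc, "Annotation", Id = "1")
  regions <- xml2::xml_add_child(ann, "Regions")
  for (i in seq_along(roi$polygons)) {
    reg <- xml2::xml_add_child(regions, "Region", Id = as.character(i))
    verts <- xml2::xml_add_child(reg, "Vertices")
    ring <- roi$polygons[[i]]
    for (j in seq_len(nrow(ring))) {
      xml2::xml_add_child(verts, "Vertex",
                          X = format(ring[j, 1], scientific = FALSE, digits = 15),
                          Y = format(ring[j, 2], scientific = FALSE, digits = 15))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
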