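# Image, annotation and configuration I/O plus the end-to-end detection
# pipeline (edge detection -> weighted graph -> shortest path).
#
# Annotation JSON schema (coordinates are 0-based; x = column, y = row):
#   {"image": "<file>", "side": "left|right",
#    "endpoints": [{"x":..,"y":..}, {"x":..,"y":..}],
#    "keypoints": [{"x":..,"y":..}, ...],
#    "gt_polyline": [[x, y], ...]}          # optional true contour
# Internally the package uses 1-based (row, col) positions.

#' Read an image as a grayscale 0-255 matrix
#'
#' Reads an 8-bit PNG; RGB(A) images are converted with [toGrayscale()]
#' (alpha ignored).
#'
#' @param path PNG file path.
#' @return H x W numeric matrix in \[0, 255\].
#' @export
readImageGray <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  a <- png::readPNG(path) * 255
  if (length(dim(a)) == 3L) {
    a <- if (dim(a)[3] >= 3L) a[, , 1:3] else a[, , 1]  # drop alpha
  }
  toGrayscale(a)
}

#' @noRd
.xy <- function(p) c(as.integer(p$y) + 1L, as.integer(p$x) + 1L)

#' Read a contour annotation
#'
#' @param path annotation JSON file.
#' @return A [ContourAnnotation-class]; when the file carries the true
#'   contour polyline it is attached as the `gtPolyline` attribute (an
#'   n x 2 (row, col) matrix).
#' @export
readAnnotation <- function(path) {
  errs <- validateAnnotation(path)
  if (length(errs) > 0)
    stop("invalid annotation ", path, ":\n  ", paste(errs, collapse = "\n  "))
  j <- jsonlite::read_json(path)
  kp <- if (length(j$keypoints) > 0)
    do.call(rbind, lapply(j$keypoints, .xy)) else NULL
  ann <- contourAnnotation(.xy(j$endpoints[[1]]), .xy(j$endpoints[[2]]),
                           kp, j$side)
  if (!is.null(j$gt_polyline)) {
    gt <- do.call(rbind, lapply(j$gt_polyline, function(p)
      c(as.integer(p[[2]]) + 1L, as.integer(p[[1]]) + 1L)))
    attr(ann, "gtPolyline") <- gt
  }
  ann
}

#' Write a contour annotation
#'
#' @param ann a [ContourAnnotation-class].
#' @param path output JSON file.
#' @param image image file name recorded in the annotation.
#' @param gt optional true contour ([PixelPath-class] or node matrix)
#'   stored as `gt_polyline`.
#' @return invisibly, `path`.
#' @export
writeAnnotation <- function(ann, path, image = "", gt = NULL) {
  toXY <- function(p) list(x = p[2] - 1L, y = p[1] - 1L)
  obj <- list(
    image = image, side = ann@side,
    endpoints = list(toXY(ann@start), toXY(ann@end)),
    keypoints = lapply(seq_len(nrow(ann@keypoints)), function(i)
      toXY(ann@keypoints[i, ])))
  if (!is.null(gt)) {
    n <- .nodes(gt)
    obj$gt_polyline <- lapply(seq_len(nrow(n)), function(i)
      c(n[i, 2] - 1L, n[i, 1] - 1L))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Validate an annotation file against the schema
#'
#' Checks JSON structure, required fields, coordinate types, bounds (when
#' the image shape is known) and keypoint ordering, and reports every
#' violation found.
#'
#' @param x annotation file path or already-parsed list.
#' @param imageShape optional `c(H, W)` for bounds checking.
#' @return character vector of violations; `character(0)` when valid.
#' @export
validateAnnotation <- function(x, imageShape = NULL) {
  if (is.character(x)) {
    if (!file.exists(x)) return(sprintf("file not found: %s", x))
    j <- tryCatch(jsonlite::read_json(x), error = function(e)
      structure(conditionMessage(e), class = "parseError"))
    if (inherits(j, "parseError")) return(sprintf("JSON parse error: %s", j))
  } else j <- x
  errs <- character(0)
  pt <- function(p) is.list(p) && !is.null(p$x) && !is.null(p$y) &&
    is.numeric(p$x %||% NA) && is.numeric(p$y %||% NA) &&
    is.finite(p$x) && is.finite(p$y)
  if (is.null(j$side) || !(j$side %in% c("left", "right")))
    errs <- c(errs, "field 'side' must be 'left' or 'right'")
  if (is.null(j$endpoints)) {
    errs <- c(errs, "field 'endpoints' is missing")
  } else if (length(j$endpoints) != 2L || !all(vapply(j$endpoints, pt, TRUE))) {
    errs <- c(errs, "field 'endpoints' must hold two {x, y} points")
  }
  if (!is.null(j$keypoints)) {
    for (i in seq_along(j$keypoints)) {
      if (!pt(j$keypoints[[i]])) {
        errs <- c(errs, sprintf("keypoint %d is not an {x, y} point", i))
      } else if (j$keypoints[[i]]$x < 0 || j$keypoints[[i]]$y < 0) {
        errs <- c(errs, sprintf("keypoint %d has negative coordinates", i))
      }
    }
  }
  inBounds <- function(p) p$x >= 0 && p$y >= 0 &&
    (is.null(imageShape) || (p$y < imageShape[1] && p$x < imageShape[2]))
  if (length(errs) == 0L) {
    for (i in 1:2)
      if (!inBounds(j$endpoints[[i]]))
        errs <- c(errs, sprintf("endpoint %d is outside the image", i))
    if (!is.null(imageShape) && length(j$keypoints) > 0)
      for (i in seq_along(j$keypoints))
        if (!inBounds(j$keypoints[[i]]))
          errs <- c(errs, sprintf("keypoint %d is outside the image", i))
  }
  errs
}

# Default run configuration; every key can be overridden from YAML.
#' @noRd
.defaultRunConfig <- function() {
  list(edge_op = "sobel", alpha = 1, beta = 0.025, gamma = 0.005,
       diagonal_factor = sqrt(2),
       canny = list(low = 40, high = 90, sigma = 1.4),
       prior = list(strength = 0, band_width = 10, bulge = "down"),
       resize_long_side = 512L, seed = 1L, model = NULL,
       overlay_color = c(255L, 40L, 40L), log_level = "info")
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected so typos fail loudly; missing keys take their
#' defaults.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return named configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- .defaultRunConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      bad <- setdiff(names(user[[nm]]), names(cfg[[nm]]))
      if (length(bad) > 0)
        stop("unknown configuration key(s) under '", nm, "': ",
             paste(bad, collapse = ", "))
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    } else cfg[[nm]] <- user[[nm]]
  }
  if (!cfg$edge_op %in% c("sobel", "prewitt", "canny", "learned"))
    stop("edge_op must be one of sobel, prewitt, canny, learned")
  cfg
}

#' @noRd
.configParams <- function(cfg) {
  edgeWeightParams(cfg$alpha, cfg$beta, cfg$gamma, cfg$diagonal_factor)
}

#' Detect a breast contour in an image
#'
#' The full pipeline: selected edge operator, weighted-graph conversion,
#' optional shape prior, and Dijkstra shortest path between the annotated
#' endpoints.  When `out` is given, the contour is written as a polyline
#' JSON (`{"image", "side", "polyline": [[x, y], ...], "cost"}`, 0-based
#' x/y) plus a provenance record (`<out>.provenance.json`: configuration,
#' seed, package version, input checksums); with `overlay` an RGB PNG with
#' the contour drawn is written next to it.
#'
#' @param imagePath PNG image.
#' @param annotationPath annotation JSON (endpoints required; keypoints
#'   ignored here).
#' @param config configuration list from [readRunConfig()].
#' @param model optional [SobelUNet-class] overriding `config$model` (a
#'   checkpoint path) for `edge_op: learned`.
#' @param out optional output JSON path.
#' @param overlay also write an overlay PNG.
#' @return invisibly, `list(path = PixelPath, polyline = n x 2 matrix,
#'   files = written files)`.
#' @export
detectContour <- function(imagePath, annotationPath,
                          config = readRunConfig(), model = NULL,
                          out = NULL, overlay = FALSE) {
  img <- readImageGray(imagePath)
  ann <- readAnnotation(annotationPath)
  if (config$edge_op == "learned" && is.null(model)) {
    if (is.null(config$model)) stop("edge_op 'learned' needs a model checkpoint")
    model <- loadSobelUNet(config$model)
  }
  op <- .operatorFun(config$edge_op, model, config$canny)
  em <- op(img)
  params <- .configParams(config)
  if (all(ann@start == ann@end))
    warning("start and end coincide: returning a single-point contour")
  prior <- if (config$prior$strength > 0)
    shapePriorMask(ann@start, ann@end, config$prior$strength,
                   config$prior$band_width, dim(img), config$prior$bulge)
  else NULL
  path <- shortestPath(em, ann@start, ann@end, params, prior)
  files <- character(0)
  if (!is.null(out)) {
    n <- path@nodes
    obj <- list(image = basename(imagePath), side = ann@side,
                polyline = lapply(seq_len(nrow(n)), function(i)
                  c(n[i, 2] - 1L, n[i, 1] - 1L)),
                cost = path@cost)
    jsonlite::write_json(obj, out, auto_unbox = TRUE, digits = NA)
    prov <- list(
      package = "contourGraph",
      version = as.character(utils::packageVersion("contourGraph")),
      config = config[setdiff(names(config), "overlay_color")],
      inputs = list(
        image = unname(tools::md5sum(imagePath)),
        annotation = unname(tools::md5sum(annotationPath))))
    provPath <- paste0(out, ".provenance.json")
    jsonlite::write_json(prov, provPath, auto_unbox = TRUE, digits = NA)
    files <- c(out, provPath)
    if (overlay) {
      ovPath <- paste0(sub("\\.json$", "", out), "_overlay.png")
      rgb <- array(img / 255, dim = c(dim(img), 3L))
      for (ci in 1:3) rgb[, , ci][n] <- config$overlay_color[ci] / 255
      png::writePNG(rgb, ovPath)
      files <- c(files, ovPath)
    }
  }
  invisible(list(path = path, polyline = path@nodes, files = files))
}
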