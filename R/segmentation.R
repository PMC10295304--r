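# Mask-producing stage. The trained-network segmenter of the original
# monitoring setup is behind a pluggable contract (frame -> mask + score);
# the package ships a reference intensity-threshold segmenter adequate for
# synthetic and high-contrast recordings, plus score gating, LabelMe
# annotation ingestion and IoU evaluation.

#' Reference intensity-threshold segmenter
#'
#' Thresholds a single-channel (or RGB, reduced to Rec.601 luminance) frame,
#' keeps the largest connected component, fills its holes, and reports a
#' certainty surrogate `1 - spurious_area / total_foreground_area`: 1 when
#' the foreground is a single blob, lower when the threshold also fires on
#' clutter. Any function with this signature (frame -> list(mask, score))
#' can stand in for it, e.g. a trained instance-segmentation backend.
#'
#' @param frame Numeric matrix, or rows x cols x 3 array (RGB).
#' @param threshold Intensity cutoff; default midway between the frame's
#'   min and max.
#' @param polarity `"bright"` (object brighter than background) or
#'   `"dark"`.
#' @param min_region_area Components smaller than this many pixels are
#'   ignored entirely (not counted as spurious).
#' @return `list(mask = logical matrix, score = numeric in [0, 1])`. An
#'   empty foreground yields an all-`FALSE` mask with score 0.
#' @export
segment_threshold <- function(frame, threshold = NULL,
                              polarity = c("bright", "dark"),
                              min_region_area = 1L) {
  polarity <- match.arg(polarity)
  if (length(dim(frame)) == 3L) {
    stopifnot(dim(frame)[3L] >= 3L)
    frame <- 0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] +
      0.114 * frame[, , 3L]
  }
  stopifnot(is.matrix(frame))
  if (is.null(threshold)) threshold <- (min(frame) + max(frame)) / 2
  fg <- if (polarity == "bright") frame > threshold else frame < threshold
  if (!any(fg))
    return(list(mask = matrix(FALSE, nrow(frame), ncol(frame)), score = 0))

  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_region_area)
  if (length(keep) == 0L)
    return(list(mask = matrix(FALSE, nrow(frame), ncol(frame)), score = 0))
  main <- keep[which.max(sizes[keep])]
  total <- sum(sizes[keep])
  score <- max(0, min(1, 1 - (total - sizes[main]) / total))
  list(mask = fill_holes(lab == main), score = score)
}

# Connected-component labelling and hole filling via EBImage.
label_components <- function(fg) {
  matrix(as.integer(EBImage::bwlabel(fg * 1)), nrow(fg), ncol(fg))
}

fill_holes <- function(mask) {
  matrix(as.integer(EBImage::fillHull(mask * 1)) > 0L, nrow(mask), ncol(mask))
}

#' Gate mask validity on the certainty score
#'
#' Marks a frame valid when its certainty score strictly exceeds
#' `score_threshold` and its mask is non-empty. Masks are untouched.
#'
#' @param seq A [mask_sequence()].
#' @param score_threshold Gate on the certainty score (default 0.99).
#' @return The sequence with updated `valid` flags.
#' @export
gate_validity <- function(seq, score_threshold = 0.99) {
  stopifnot(inherits(seq, "mask_sequence"))
  nonempty <- vapply(seq$masks, any, logical(1L))
  seq$valid <- seq$scores > score_threshold & nonempty
  seq
}

#' Read LabelMe polygon annotations
#'
#' Parses one or more LabelMe JSON files (keys `shapes[].points`,
#' `imagePath`, `imageHeight`, `imageWidth`). Vertices are in LabelMe's
#' image coordinates: x = column, y = row, origin at the top-left corner of
#' the top-left pixel.
#'
#' @param paths Character vector of JSON file paths.
#' @return An `annotation_set`: list with `images` (data frame of
#'   `image`, `height`, `width`) and `polygons` (list, one element per file,
#'   each a list of n x 2 vertex matrices).
#' @export
read_labelme <- function(paths) {
  images <- data.frame(image = character(), height = integer(),
                       width = integer())
  polygons <- list()
  for (p in paths) {
    js <- tryCatch(jsonlite::fromJSON(p, simplifyMatrix = TRUE),
                   error = function(e)
                     stop("malformed LabelMe JSON in '", p, "': ",
                          conditionMessage(e)))
    if (is.null(js$imageHeight) || is.null(js$imageWidth))
      stop("LabelMe JSON '", p, "' lacks imageHeight/imageWidth")
    pts <- js$shapes$points
    if (is.null(pts)) stop("LabelMe JSON '", p, "' has no shapes[].points")
    if (!is.list(pts)) pts <- list(pts)
    polys <- lapply(pts, function(m) {
      m <- as.matrix(m)
      if (nrow(m) < 3L) stop("polygon with fewer than 3 vertices in '", p, "'")
      if (any(m[, 1L] < 0 | m[, 1L] > js$imageWidth |
              m[, 2L] < 0 | m[, 2L] > js$imageHeight))
        stop("polygon vertex outside image bounds in '", p, "'")
      m
    })
    images <- rbind(images, data.frame(
      image = if (is.null(js$imagePath)) basename(p) else js$imagePath,
      height = as.integer(js$imageHeight), width = as.integer(js$imageWidth)))
    polygons[[length(polygons) + 1L]] <- polys
  }
  structure(list(images = images, polygons = polygons),
            class = "annotation_set")
}

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
# px, py: point coordinates; verts: n x 2 matrix of (x, y) vertices.
points_in_polygon <- function(px, py, verts) {
  n <- nrow(verts)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- verts[i, 1L]; yi <- verts[i, 2L]
    xj <- verts[j, 1L]; yj <- verts[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize polygon annotations to binary masks
#'
#' A pixel belongs to the mask iff its center (pixel (r, c), 0-based, has
#' center x = c + 0.5, y = r + 0.5 in LabelMe coordinates) lies inside the
#' polygon under the even-odd rule. Multiple polygons on one image are
#' unioned.
#'
#' @param ann An `annotation_set` from [read_labelme()], or a list of n x 2
#'   vertex matrices.
#' @param frame_shape Integer `(rows, cols)`; defaults to the annotation's
#'   recorded image size.
#' @return A [mask_sequence()] (fps 1, scores 1) with one mask per image.
#' @export
polygons_to_masks <- function(ann, frame_shape = NULL) {
  if (!inherits(ann, "annotation_set")) {
    stopifnot(is.list(ann), !is.null(frame_shape))
    ann <- structure(list(
      images = data.frame(image = "polygons", height = frame_shape[1L],
                          width = frame_shape[2L]),
      polygons = list(ann)), class = "annotation_set")
  }
  masks <- vector("list", nrow(ann$images))
  for (k in seq_along(masks)) {
    shp <- if (is.null(frame_shape))
      c(ann$images$height[k], ann$images$width[k]) else frame_shape
    grid_x <- rep(seq_len(shp[2L]) - 0.5, each = shp[1L])
    grid_y <- rep(seq_len(shp[1L]) - 0.5, times = shp[2L])
    m <- matrix(FALSE, shp[1L], shp[2L])
    for (verts in ann$polygons[[k]])
      m <- m | matrix(points_in_polygon(grid_x, grid_y, verts),
                      shp[1L], shp[2L])
    masks[[k]] <- m
  }
  mask_sequence(masks, scores = rep(1, length(masks)), fps = 1)
}

#' Intersection over union of two binary masks
#'
#' `|A intersect B| / |A union B|`; defined as 0 when both masks are empty.
#'
#' @param mask_a,mask_b Logical matrices of identical shape.
#' @return IoU in \[0, 1\].
#' @export
iou <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("mask shapes differ: ", paste(dim(mask_a), collapse = "x"), " vs ",
         paste(dim(mask_b), collapse = "x"))
  uni <- sum(mask_a | mask_b)
  if (uni == 0L) return(0)
  sum(mask_a & mask_b) / uni
}

# Tight bounding box (row_min, col_min, row_max, col_max), half-open,
# 0-based; NULL for an empty mask.
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  c(row_min = min(idx[, 1L]) - 1L, col_min = min(idx[, 2L]) - 1L,
    row_max = max(idx[, 1L]), col_max = max(idx[, 2L]))
}

#' @describeIn iou IoU of the masks' tight axis-aligned bounding boxes.
#' @export
iou_box <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("mask shapes differ")
  ba <- mask_bbox(mask_a); bb <- mask_bbox(mask_b)
  if (is.null(ba) && is.null(bb)) return(0)
  if (is.null(ba) || is.null(bb)) return(0)
  ir <- max(0, min(ba[3L], bb[3L]) - max(ba[1L], bb[1L]))
  ic <- max(0, min(ba[4L], bb[4L]) - max(ba[2L], bb[2L]))
  inter <- ir * ic
  area_a <- (ba[3L] - ba[1L]) * (ba[4L] - ba[2L])
  area_b <- (bb[3L] - bb[1L]) * (bb[4L] - bb[2L])
  unname(inter / (area_a + area_b - inter))
}

#' Count-weighted mean of group means
#'
#' @param means Numeric vector of group means.
#' @param counts Group sizes.
#' @return `sum(counts * means) / sum(counts)`.
#' @export
weighted_mean_by_count <- function(means, counts) {
  stopifnot(length(means) == length(counts), all(counts > 0))
  sum(counts * means) / sum(counts)
}

#' Aggregate per-image IoU values by group
#'
#' Per-group mean and sample (n-1) SD of per-image values, plus the overall
#' mean weighted by group counts — the aggregation used for cross-animal
#' segmentation evaluation tables.
#'
#' @param values Numeric per-image IoU values (ratios or percent).
#' @param group Group label per value (e.g. animal id).
#' @return An `iou_report`: data frame with one row per group
#'   (`group`, `n`, `mean`, `sd`) plus attribute `overall_mean`.
#' @export
aggregate_iou <- function(values, group) {
  stopifnot(length(values) == length(group), length(values) > 0)
  if (anyNA(values)) stop("IoU values must not be NA")
  g <- split(values, group)
  if (any(vapply(g, length, integer(1L)) == 0L)) stop("empty group")
  rep <- data.frame(
    group = names(g),
    n = vapply(g, length, integer(1L)),
    mean = vapply(g, mean, numeric(1L)),
    sd = vapply(g, function(v) if (length(v) > 1L) stats::sd(v) else NA_real_,
                numeric(1L)),
    row.names = NULL
  )
  attr(rep, "overall_mean") <- weighted_mean_by_count(rep$mean, rep$n)
  class(rep) <- c("iou_report", "data.frame")
  rep
}
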