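# Abundance-driven prompt generation and promptable segmentation:
# blur + threshold + local maxima -> point prompts, structure-specific
# morphology, a pluggable segmenter contract with a deterministic
# classical fallback, mask aggregation, compositing, and IoU scoring.

#' Prompt-generation configuration
#'
#' @param blur_sigma_px Gaussian sigma for the abundance blur
#'   (default 4).
#' @param threshold Abundance threshold on the scaled [0, 1] map
#'   (default 0.4; 0.5 is used for nucleic-acid maps).
#' @param min_peak_distance_px Minimum separation between prompts
#'   (default 10).
#' @param close_radius_px Disk radius for a dilate-then-erode
#'   (morphological closing) of the resulting masks; 0 disables.
#'   70 px is used for nucleic acids at full tile scale.
#' @param blur_first Apply the Gaussian blur before thresholding
#'   (default TRUE); FALSE thresholds first, then blurs.
#' @return A `prompt_config` list.
#' @export
promptConfig <- function(blur_sigma_px = 4, threshold = 0.4,
                         min_peak_distance_px = 10, close_radius_px = 0,
                         blur_first = TRUE) {
  stopifnot(blur_sigma_px > 0, threshold > 0, threshold < 1,
            min_peak_distance_px >= 1, close_radius_px >= 0)
  structure(list(blur_sigma_px = blur_sigma_px, threshold = threshold,
                 min_peak_distance_px = as.integer(min_peak_distance_px),
                 close_radius_px = as.integer(close_radius_px),
                 blur_first = isTRUE(blur_first)),
            class = "prompt_config")
}

#' Point prompts from an abundance map
#'
#' Gaussian-blurs the scaled abundance map, zeroes values below the
#' threshold, and takes plateau-aware local maxima (minimum peak
#' distance enforced) as structure-labelled point prompts.
#' Deterministic; an empty prompt set is allowed.
#'
#' @param abundance Numeric matrix in [0, 1] (a scaled abundance map).
#' @param cfg A [promptConfig()].
#' @param label Structure label attached to the prompts.
#' @param tile_id Source tile tag.
#' @return A [PromptSet-class].
#' @export
promptsFromAbundance <- function(abundance, cfg = promptConfig(),
                                 label = "structure", tile_id = "") {
  stopifnot(is.matrix(abundance), all(is.finite(abundance)))
  if (cfg$blur_first) {
    img <- gaussianBlur(abundance, cfg$blur_sigma_px)
    img[img < cfg$threshold] <- 0
    floor_value <- cfg$threshold
  } else {
    img <- abundance
    img[img < cfg$threshold] <- 0
    img <- gaussianBlur(img, cfg$blur_sigma_px)
    floor_value <- .Machine$double.eps  # thresholding already happened
  }
  if (all(img == 0))
    return(PromptSet(data.frame(row = integer(), col = integer(),
                                label = character(),
                                tile_id = character())))
  pk <- findLocalMaxima(img, min_distance = cfg$min_peak_distance_px,
                        min_value = max(floor_value, .Machine$double.eps))
  if (!nrow(pk))
    return(PromptSet(data.frame(row = integer(), col = integer(),
                                label = character(),
                                tile_id = character())))
  PromptSet(data.frame(row = pk$row, col = pk$col, label = label,
                       tile_id = tile_id))
}

#' Morphological closing of a binary mask with a disk element
#'
#' Dilate then erode with a disk structuring element of the given
#' radius, merging nearby fragments (e.g. heterochromatin patches into
#' a nucleus). Radius 0 is the identity; closing is idempotent.
#'
#' @param mask Logical matrix.
#' @param disk_radius Disk radius in pixels.
#' @return Logical matrix.
#' @export
refineMask <- function(mask, disk_radius) {
  stopifnot(is.matrix(mask), is.logical(mask), disk_radius >= 0)
  if (disk_radius == 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(disk_radius) + 1L,
                              shape = "disc")
  m <- EBImage::erode(EBImage::dilate(mask * 1, brush), brush)
  m > 0.5
}

#' Deterministic classical fallback segmenter
#'
#' Returns a segmenter satisfying the pluggable contract
#' `function(image, points) -> list(masks = <list of logical>,
#' scores = <numeric>)`: for each prompt, the image is thresholded at
#' `rel_threshold` times the (3x3-median-stabilised) intensity at the
#' prompt, and the connected component containing the prompt becomes
#' the mask. Never needs a network or GPU; used in tests and wherever
#' no external promptable model is plugged in.
#'
#' @param rel_threshold Fraction of the prompt intensity used as the
#'   region-growing level (default 0.5).
#' @return A segmenter function.
#' @export
fallbackSegmenter <- function(rel_threshold = 0.5) {
  force(rel_threshold)
  function(image, points) {
    masks <- vector("list", nrow(points))
    scores <- numeric(nrow(points))
    n <- nrow(image); m <- ncol(image)
    for (i in seq_len(nrow(points))) {
      r <- points$row[i]; c_ <- points$col[i]
      if (r < 1 || r > n || c_ < 1 || c_ > m)
        stop("prompt ", i, " at (", r, ", ", c_, ") is outside the image")
      # stabilise the seed intensity against single-pixel noise
      rr <- max(1, r - 1):min(n, r + 1)
      cc <- max(1, c_ - 1):min(m, c_ + 1)
      level <- rel_threshold * median(image[rr, cc])
      bin <- image >= level
      if (!bin[r, c_]) {
        masks[[i]] <- matrix(FALSE, n, m)
        scores[i] <- 0
        next
      }
      lab <- EBImage::bwlabel(bin)
      masks[[i]] <- lab == lab[r, c_]
      scores[i] <- 1
    }
    list(masks = masks, scores = scores)
  }
}

#' Segment an image from structure-labelled point prompts
#'
#' Runs the segmenter on every prompt and aggregates per structure:
#' the structure's mask is the union of its prompts' masks, optionally
#' closed with a per-structure disk radius.
#'
#' @param image Numeric matrix the segmenter operates on (e.g. the
#'   structure's abundance map, or a HAADF image for an external
#'   promptable model).
#' @param prompts A [PromptSet-class].
#' @param segmenter A segmenter function (see [fallbackSegmenter()] for
#'   the contract). Default: the classical fallback.
#' @param close_radius Named numeric: per-structure closing radius in
#'   px (unnamed scalar applies to all; default 0).
#' @return A [SegmentationMasks-class], one mask per structure label in
#'   the prompt set (empty prompt set -> one empty "structure" mask).
#' @export
segmentWithPrompts <- function(image, prompts,
                               segmenter = fallbackSegmenter(),
                               close_radius = 0) {
  stopifnot(is.matrix(image), is(prompts, "PromptSet"))
  pts <- prompts@points
  if (!nrow(pts))
    return(SegmentationMasks(list(structure = matrix(FALSE, nrow(image),
                                                     ncol(image)))))
  res <- tryCatch(segmenter(image, pts), error = function(e)
    stop("segmenter failed on ", nrow(pts), " prompt(s) [",
         paste(unique(pts$label), collapse = ", "), "]: ",
         conditionMessage(e)))
  labs <- unique(pts$label)
  masks <- lapply(labs, function(l) {
    sel <- which(pts$label == l)
    m <- Reduce(`|`, res$masks[sel])
    r <- if (length(close_radius) > 1 || !is.null(names(close_radius)))
      close_radius[[l]] %||% 0 else close_radius
    refineMask(m, r)
  })
  names(masks) <- labs
  SegmentationMasks(masks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Intersection over union of two binary masks
#'
#' @param mask_a,mask_b Logical matrices of the same shape.
#' @return Scalar in [0, 1]; two empty masks score 1 by convention.
#' @export
iou <- function(mask_a, mask_b) {
  stopifnot(identical(dim(mask_a), dim(mask_b)))
  inter <- sum(mask_a & mask_b)
  uni <- sum(mask_a | mask_b)
  if (uni == 0) return(1)
  inter / uni
}

#' Composite label image from per-structure masks
#'
#' Each pixel receives the first structure in precedence order whose
#' mask covers it (0 where none does).
#'
#' @param masks A [SegmentationMasks-class].
#' @param precedence Character vector of structure labels, highest
#'   precedence first (default: mask order).
#' @return Integer matrix; value i = i-th label of `precedence`.
#' @export
compositeMasks <- function(masks, precedence = NULL) {
  stopifnot(is(masks, "SegmentationMasks"))
  if (is.null(precedence)) precedence <- masks@labels
  if (!all(precedence %in% masks@labels))
    stop("precedence contains unknown structure labels")
  d <- dim(masks@masks[[1]])
  out <- matrix(0L, d[1], d[2])
  for (i in rev(seq_along(precedence)))
    out[masks@masks[[precedence[i]]]] <- i
  out
}
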