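#' Construct an AP-oriented, masked working sample
#'
#' The unit of quantification: a 2-D multichannel image together with the
#' binary specimen mask traced around the oocyte or embryo, with the
#' anteroposterior (AP) axis horizontal — anterior at the left (small
#' column index), posterior at the right.
#'
#' @param image Numeric matrix (`y` rows, `x` columns) or 3-D array
#'   `(y, x, channel)` of non-negative intensities.
#' @param mask Logical (or 0/1) matrix of the same `y`/`x` extent; `TRUE`
#'   inside the traced specimen. Must contain at least one pixel.
#' @param channel_names Optional character vector naming the channels
#'   (e.g. `c("HA", "Vasa")`). Defaults to `"ch1"`, `"ch2"`, ...
#' @param sample_id Optional identifier carried through result tables.
#' @param orientation_applied Logical flag recording that the AP axis is
#'   already horizontal with the posterior at the right.
#'
#' @return An object of class `oriented_sample`: a list with elements
#'   `image` (3-D array `(y, x, channel)`, zero outside the mask is not
#'   enforced), `mask` (logical matrix), `ap_bounds` (range of mask
#'   columns), `channel_names`, `sample_id`, `orientation_applied`.
#' @seealso [orient_sample()] to build one from a raw image plus
#'   rotation/flip metadata; [zscore_field()] for the next pipeline stage.
#' @export
oriented_sample <- function(image, mask, channel_names = NULL,
                            sample_id = NA_character_,
                            orientation_applied = TRUE) {
  if (is.matrix(image)) {
    image <- array(image, dim = c(dim(image), 1L))
  }
  if (length(dim(image)) != 3L) {
    stop("`image` must be a matrix or a (y, x, channel) array")
  }
  storage.mode(image) <- "double"
  mask <- as_mask(mask)
  if (!all(dim(mask) == dim(image)[1:2])) {
    stop("`mask` and `image` must have the same y/x dimensions")
  }
  if (!any(mask)) stop("`mask` is empty: no specimen pixels")
  if (any(!is.finite(image))) stop("`image` contains non-finite values")
  nch <- dim(image)[3]
  if (is.null(channel_names)) {
    channel_names <- dimnames(image)[[3]]
    if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch))
  }
  if (length(channel_names) != nch) {
    stop("`channel_names` must name every channel")
  }
  dimnames(image) <- list(NULL, NULL, channel_names)
  cols <- which(colSums(mask) > 0)
  structure(
    list(image = image, mask = mask,
         ap_bounds = c(min(cols), max(cols)),
         channel_names = channel_names,
         sample_id = sample_id,
         orientation_applied = isTRUE(orientation_applied)),
    class = "oriented_sample")
}

#' @export
print.oriented_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf(
    "<oriented_sample> %s: %d x %d px, %d channel(s) [%s], %d mask px, AP cols %d..%d\n",
    x$sample_id, d[1], d[2], d[3], paste(x$channel_names, collapse = ", "),
    sum(x$mask), x$ap_bounds[1], x$ap_bounds[2]))
  invisible(x)
}

as_mask <- function(mask) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  if (is.logical(mask)) return(mask)
  mask > 0.5
}

channel_matrix <- function(sample, channel) {
  stopifnot(inherits(sample, "oriented_sample"))
  if (is.character(channel)) {
    idx <- match(channel, sample$channel_names)
    if (is.na(idx)) {
      stop(sprintf("unknown channel '%s' (have: %s)", channel,
                   paste(sample$channel_names, collapse = ", ")))
    }
    channel <- idx
  }
  m <- sample$image[, , channel, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Sum-intensity projection of a confocal z-stack
#'
#' Collapses a z-stack to a single 2-D multichannel image by summing
#' intensities over z, per channel and pixel. Input integers are widened
#' to double before summation so large stacks cannot overflow.
#'
#' @param stack Numeric array, either `(y, x, channel, z)` or `(y, x, z)`
#'   for a single-channel stack. At least one z-plane.
#' @return A `(y, x, channel)` array of per-pixel z-sums (single-channel
#'   input yields a one-channel array).
#' @examples
#' st <- array(1, dim = c(4, 5, 1, 2))
#' sum_project(st)[1, 1, 1]  # 2
#' @export
sum_project <- function(stack) {
  d <- dim(stack)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("`stack` must be a (y, x, z) or (y, x, channel, z) array")
  }
  if (length(d) == 3L) stack <- array(stack, dim = c(d[1], d[2], 1L, d[3]))
  d <- dim(stack)
  if (d[4] < 1L) stop("`stack` has no z-planes")
  storage.mode(stack) <- "double"
  rowSums(stack, dims = 3L)
}

#' Rotate and flip a micrograph onto the anteroposterior convention
#'
#' Applies the per-sample orientation metadata: a rotation that brings the
#' AP axis horizontal, then an optional left-right flip so the anterior
#' ends up at the left. `rotation_deg` rotates the specimen
#' counter-clockwise as the image is displayed with row 1 at the top; the
#' output frame is enlarged as needed to contain the rotated image.
#' The image is rotated with bilinear interpolation; the mask with
#' nearest-neighbour interpolation so it stays strictly binary.
#'
#' @param image Matrix or `(y, x, channel)` array of intensities.
#' @param mask Binary specimen mask matrix, same y/x extent.
#' @param rotation_deg Rotation angle in degrees (counter-clockwise).
#' @param flip_lr Flip left-right after rotation?
#' @param channel_names,sample_id Passed to [oriented_sample()].
#' @return An [oriented_sample()].
#' @export
orient_sample <- function(image, mask, rotation_deg = 0, flip_lr = FALSE,
                          channel_names = NULL, sample_id = NA_character_) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  storage.mode(image) <- "double"
  mask <- as_mask(mask)
  if (rotation_deg %% 360 != 0) {
    rot_ch <- function(m, filter) {
      EBImage::rotate(m, rotation_deg, filter = filter, bg.col = 0)
    }
    chans <- lapply(seq_len(dim(image)[3]), function(k) {
      rot_ch(image[, , k], "bilinear")
    })
    image <- array(unlist(chans, use.names = FALSE),
                   dim = c(dim(chans[[1]]), length(chans)))
    mask <- as_mask(rot_ch(mask + 0, "none"))
    # bilinear interpolation can produce tiny negative overshoot at edges
    image[image < 0] <- 0
  }
  if (isTRUE(flip_lr)) {
    image <- image[, rev(seq_len(ncol(image))), , drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (!any(mask)) stop("mask empty after orientation transform")
  oriented_sample(image, mask, channel_names = channel_names,
                  sample_id = sample_id, orientation_applied = TRUE)
}

#' A deterministic set of mask pixels
#'
#' Plain container for pixel coordinate sets (anterior region, high-HA
#' selection). Coordinates are 1-based `(y, x)` matrix indices.
#'
#' @param y,x Integer coordinate vectors of equal length.
#' @param provenance Label recording how the set was selected.
#' @return A `pixel_set`: a data.frame with columns `y`, `x` and
#'   attributes `provenance`, plus any passed via `...`.
#' @param ... Further attributes stored on the object (e.g. `fraction`).
#' @export
pixel_set <- function(y, x, provenance = "manual", ...) {
  stopifnot(length(y) == length(x))
  ps <- data.frame(y = as.integer(y), x = as.integer(x))
  if (anyDuplicated(ps)) stop("duplicate pixel coordinates in set")
  attr(ps, "provenance") <- provenance
  extra <- list(...)
  for (nm in names(extra)) attr(ps, nm) <- extra[[nm]]
  class(ps) <- c("pixel_set", "data.frame")
  ps
}

#' Select the anterior region of a specimen
#'
#' Two readings of "the anterior-most 15\%" are supported:
#' \describe{
#'   \item{`mode = "pixels"` (default)}{the `round(fraction * N)`
#'     mask pixels with the smallest column index, `N` the mask pixel
#'     count; ties at equal `x` are broken by ascending `y`. Rounding is
#'     round-half-up.}
#'   \item{`mode = "length"`}{all mask pixels with
#'     `x < x_min + fraction * (x_max - x_min)`, i.e. a fraction of the
#'     specimen's AP extent; `fraction = 1` selects the whole mask.}
#' }
#' On a mask whose pixel count per column is constant the two modes agree.
#'
#' @param sample An [oriented_sample()].
#' @param fraction Anterior fraction in `(0, 1]`; default 0.15.
#' @param mode `"pixels"` or `"length"`.
#' @return A [pixel_set()] with provenance `"anterior"` and attributes
#'   `fraction` and `mode`.
#' @export
anterior_region <- function(sample, fraction = 0.15,
                            mode = c("pixels", "length")) {
  stopifnot(inherits(sample, "oriented_sample"))
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]")
  }
  idx <- which(sample$mask, arr.ind = TRUE)  # sorted by column, then row
  if (mode == "pixels") {
    k <- round_half_up(fraction * nrow(idx))
    if (k < 1L) stop("anterior selection is empty at this fraction")
    ord <- order(idx[, "col"], idx[, "row"])
    sel <- idx[ord[seq_len(k)], , drop = FALSE]
  } else {
    xmin <- sample$ap_bounds[1]; xmax <- sample$ap_bounds[2]
    if (fraction >= 1) {
      keep <- rep(TRUE, nrow(idx))
    } else {
      keep <- idx[, "col"] < xmin + fraction * (xmax - xmin)
    }
    if (!any(keep)) stop("anterior selection is empty at this fraction")
    sel <- idx[keep, , drop = FALSE]
  }
  pixel_set(sel[, "row"], sel[, "col"], provenance = "anterior",
            fraction = fraction, mode = mode)
}

round_half_up <- function(x) floor(x + 0.5)

#' Read a multichannel micrograph and its mask from TIFF files
#'
#' The image TIFF holds one directory per channel; the mask TIFF is a
#' single binary (0/1 or 0/255) image. Intensities written by
#' [write_micrograph()] are stored scaled into `[0, 1]`; every statistic
#' in the pipeline (z-scores, enrichment, profiles, Pearson r) is
#' invariant to that positive rescaling.
#'
#' @param image_path,mask_path Paths to the image and mask TIFFs.
#' @param channel_names Optional channel labels, in directory order.
#' @param sample_id Optional identifier.
#' @return An unoriented [oriented_sample()] (`orientation_applied =
#'   FALSE`); pass through [orient_sample()] with the per-sample metadata.
#' @export
read_micrograph <- function(image_path, mask_path, channel_names = NULL,
                            sample_id = NA_character_) {
  planes <- tiff::readTIFF(image_path, all = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  planes <- lapply(planes, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  img <- array(unlist(planes, use.names = FALSE),
               dim = c(dim(planes[[1]]), length(planes)))
  mask <- tiff::readTIFF(mask_path)
  if (length(dim(mask)) == 3L) mask <- mask[, , 1]
  oriented_sample(img, as_mask(mask), channel_names = channel_names,
                  sample_id = sample_id, orientation_applied = FALSE)
}

#' Write a sample's image and mask as TIFF files
#'
#' Channels are written as 32-bit float TIFF directories after division
#' by a single positive factor (the global intensity maximum, if it
#' exceeds 1) so values fit the float-TIFF `[0, 1]` range; the common
#' factor preserves relative channel scale and leaves all downstream
#' statistics unchanged. The mask is written as a binary image.
#'
#' @param sample An [oriented_sample()].
#' @param image_path,mask_path Output TIFF paths.
#' @return Invisibly, the scale factor applied.
#' @export
write_micrograph <- function(sample, image_path, mask_path) {
  stopifnot(inherits(sample, "oriented_sample"))
  scale <- max(sample$image, 1)
  chans <- lapply(seq_len(dim(sample$image)[3]),
                  function(k) sample$image[, , k] / scale)
  tiff::writeTIFF(chans, image_path, bits.per.sample = 32L)
  tiff::writeTIFF(sample$mask + 0, mask_path, bits.per.sample = 8L)
  invisible(scale)
}

#' Read a per-sample orientation manifest
#'
#' CSV with columns `sample_id, genotype, stage, image_path, mask_path,
#' rotation_deg, flip_lr`; relative paths are resolved against the
#' manifest's own directory.
#'
#' @param path Manifest CSV path.
#' @return A data.frame with resolved paths.
#' @export
read_manifest <- function(path) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "image_path", "mask_path",
            "rotation_deg", "flip_lr")
  missing <- setdiff(need, names(man))
  if (length(missing)) {
    stop("manifest lacks columns: ", paste(missing, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  man$image_path <- fix(man$image_path)
  man$mask_path <- fix(man$mask_path)
  man$flip_lr <- as.logical(man$flip_lr)
  man
}
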