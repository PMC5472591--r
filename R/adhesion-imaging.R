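#' Adhesion/cytosol fluorescence intensity ratio
#'
#' Mean intensity over the adhesion mask divided by the mean over the
#' cytosol mask. Ratios of this form are robust to cell-to-cell expression
#' differences (invariant to global multiplicative gain); additive offsets
#' do break the ratio, which is why background subtraction should precede
#' it.
#'
#' @param channel Numeric intensity matrix.
#' @param adhesion_mask,cytosol_mask Logical/0-1 matrices, same shape as
#'   `channel`, disjoint and non-empty.
#' @return Positive scalar ratio.
#' @export
adhesion_cytosol_ratio <- function(channel, adhesion_mask, cytosol_mask) {
  adhesion_mask <- adhesion_mask > 0
  cytosol_mask <- cytosol_mask > 0
  stopifnot(all(dim(channel) == dim(adhesion_mask)),
            all(dim(channel) == dim(cytosol_mask)))
  if (!any(adhesion_mask)) stop("adhesion mask is empty")
  if (!any(cytosol_mask)) stop("cytosol mask is empty")
  if (any(adhesion_mask & cytosol_mask)) {
    stop("adhesion and cytosol masks must be disjoint")
  }
  cyt <- mean(channel[cytosol_mask])
  if (cyt <= 0) stop("cytosolic mean intensity is zero; ratio undefined")
  mean(channel[adhesion_mask]) / cyt
}

#' Vinculin/talin enrichment ratio
#'
#' Quotient of the vinculin adhesion/cytosol ratio over the talin
#' adhesion/cytosol ratio; a falling value with progressive talin
#' destabilization indicates talin accumulating faster than vinculin.
#'
#' @param talin_ratio,vinculin_ratio Positive adhesion/cytosol ratios.
#' @return `vinculin_ratio / talin_ratio`.
#' @export
vinculin_talin_ratio <- function(talin_ratio, vinculin_ratio) {
  if (!is.numeric(talin_ratio) || !is.numeric(vinculin_ratio) ||
      any(talin_ratio <= 0) || any(vinculin_ratio <= 0)) {
    stop("ratios must be positive")
  }
  vinculin_ratio / talin_ratio
}

#' Build a paxillin mask by Gaussian extension and thresholding
#'
#' Blurs the paxillin channel with a Gaussian (extending the adhesion
#' footprint) and thresholds the result, reproducing the mask used to
#' exclude cytosolic fluorescence from colocalization analysis. A
#' threshold outside the blurred intensity range yields an empty or full
#' mask and a warning.
#'
#' @param channel Paxillin intensity matrix.
#' @param blur_sigma_um Gaussian sigma in micrometres (> 0); default 0.3.
#' @param threshold Manual threshold on the blurred image; `NULL` uses Otsu.
#' @param pixel_size_um Pixel size in micrometres.
#' @return Logical mask matrix with attributes `provenance = "paxillin"`
#'   and `threshold`.
#' @export
build_paxillin_mask <- function(channel, blur_sigma_um = 0.3,
                                threshold = NULL, pixel_size_um = 0.1) {
  if (!is.numeric(blur_sigma_um) || blur_sigma_um <= 0) {
    stop("blur_sigma_um must be positive")
  }
  blurred <- gaussian_blur(channel, blur_sigma_um / pixel_size_um)
  if (is.null(threshold)) threshold <- otsu_threshold(blurred)
  mask <- blurred >= threshold
  if (!any(mask)) warning("threshold above the intensity range: empty mask")
  if (all(mask)) warning("threshold at or below the intensity range: full-frame mask")
  structure(mask, provenance = "paxillin", threshold = threshold)
}

# Gaussian blur with sigma in pixels; sigma below resolvable width returns
# the image unchanged.
gaussian_blur <- function(channel, sigma_px) {
  if (sigma_px < 0.3) return(channel)
  # clamp the tiny negative ringing of the separable filter
  pmax(as.matrix(EBImage::gblur(channel, sigma = sigma_px)), 0)
}

otsu_threshold <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  EBImage::otsu(EBImage::Image((x - r[1]) / diff(r)), range = c(0, 1)) *
    diff(r) + r[1]
}

#' Mander's split colocalization coefficient M1
#'
#' Fraction of channel-a intensity, within a mask, that lies on pixels
#' where channel b exceeds a manual threshold:
#' `M = sum(a over mask & b > thr) / sum(a over mask)`. This is the
#' thresholded split coefficient appropriate when the second channel (e.g.
#' labelled fibronectin) is gated manually.
#'
#' @param ch_a,ch_b Intensity matrices, same shape.
#' @param mask Logical/0-1 analysis mask (e.g. the paxillin mask).
#' @param threshold_b Threshold applied to `ch_b`.
#' @return Coefficient in \[0, 1\], or `NA` (with a warning) when channel a
#'   carries no intensity inside the mask.
#' @export
manders_overlap <- function(ch_a, ch_b, mask, threshold_b) {
  mask <- mask > 0
  stopifnot(all(dim(ch_a) == dim(ch_b)), all(dim(ch_a) == dim(mask)))
  if (!any(mask)) stop("mask is empty")
  denom <- sum(ch_a[mask])
  if (denom <= 0) {
    warning("no channel-a intensity inside the mask; coefficient undefined")
    return(NA_real_)
  }
  sum(ch_a[mask & ch_b > threshold_b]) / denom
}

#' Fraction of adhesion area on the fibronectin pattern
#'
#' Area fraction of the adhesion mask intersecting the pattern mask
#' (area-weighted, i.e. pixels, not adhesion counts). By construction the
#' on-pattern and off-pattern fractions sum to one.
#'
#' @param adhesion_mask,pattern_mask Logical/0-1 matrices, same shape.
#' @return Fraction in \[0, 1\], or `NA` (with a warning) for an empty
#'   adhesion mask.
#' @export
fn_fraction <- function(adhesion_mask, pattern_mask) {
  adhesion_mask <- adhesion_mask > 0
  pattern_mask <- pattern_mask > 0
  stopifnot(all(dim(adhesion_mask) == dim(pattern_mask)))
  total <- sum(adhesion_mask)
  if (total == 0) {
    warning("empty adhesion mask; fraction undefined")
    return(NA_real_)
  }
  sum(adhesion_mask & pattern_mask) / total
}

#' Square-lattice micropattern mask
#'
#' Periodic lattice of squares (side `square_um`, pitch `pitch_um`)
#' rasterized with the pixel-centre convention; covered fraction
#' approaches `(square_um / pitch_um)^2` as resolution grows. The 56 %
#' fibronectin layout corresponds to `square/pitch = 0.75`.
#'
#' @param field_um Field of view side length (micrometres).
#' @param square_um Square side (<= pitch).
#' @param pitch_um Lattice pitch.
#' @param pixel_size_um Raster pixel size.
#' @return Logical mask matrix with attribute `pixel_size_um`.
#' @export
make_micropattern <- function(field_um, square_um, pitch_um,
                              pixel_size_um = field_um / 512) {
  if (any(c(field_um, square_um, pitch_um, pixel_size_um) <= 0)) {
    stop("all dimensions must be positive")
  }
  if (square_um > pitch_um) stop("square_um must not exceed pitch_um")
  n <- round(field_um / pixel_size_um)
  centers <- (seq_len(n) - 0.5) * pixel_size_um
  inrow <- (centers %% pitch_um) < square_um
  structure(outer(inrow, inrow, `&`), pixel_size_um = pixel_size_um,
            provenance = "pattern")
}

#' Segment adhesions from a fluorescence channel
#'
#' Default adhesion segmentation for intensity-ratio analysis: Gaussian
#' blur, top-hat style background removal (subtraction of a heavily
#' blurred background), Otsu threshold, and removal of objects below a
#' minimum area. All steps configurable.
#'
#' @param channel Intensity matrix.
#' @param pixel_size_um Pixel size (micrometres).
#' @param blur_sigma_um Pre-smoothing sigma (default 0.2 um).
#' @param background_sigma_um Background estimation sigma (default 2 um).
#' @param min_area_um2 Minimum object area kept (default 0.25 um^2).
#' @param threshold Manual threshold on the background-subtracted image;
#'   `NULL` uses Otsu.
#' @return Logical adhesion mask.
#' @export
segment_adhesions <- function(channel, pixel_size_um,
                              blur_sigma_um = 0.2, background_sigma_um = 2,
                              min_area_um2 = 0.25, threshold = NULL) {
  sm <- gaussian_blur(channel, blur_sigma_um / pixel_size_um)
  bg <- gaussian_blur(channel, background_sigma_um / pixel_size_um)
  det <- pmax(sm - bg, 0)
  if (is.null(threshold)) threshold <- otsu_threshold(det)
  mask <- det >= threshold
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  areas <- table(lab[lab > 0])
  min_px <- min_area_um2 / pixel_size_um^2
  keep <- as.integer(names(areas)[areas >= min_px])
  matrix(as.integer(lab) %in% keep, nrow = nrow(channel))
}

#' Cytosol mask from a cell mask and an adhesion mask
#'
#' Cell area minus the adhesion mask dilated by `dilate_um`, so cytosolic
#' means are not contaminated by adhesion-edge pixels.
#'
#' @param cell_mask,adhesion_mask Logical matrices, same shape.
#' @param pixel_size_um Pixel size.
#' @param dilate_um Dilation radius (default 0.5 um).
#' @return Logical cytosol mask.
#' @export
cytosol_mask <- function(cell_mask, adhesion_mask, pixel_size_um,
                         dilate_um = 0.5) {
  r <- max(1L, round(dilate_um / pixel_size_um))
  kern <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  dil <- as.matrix(EBImage::dilate(EBImage::Image(adhesion_mask * 1),
                                   kern)) > 0
  (cell_mask > 0) & !dil
}

#' Read a single-channel image from TIFF
#'
#' @param path TIFF path.
#' @return Numeric intensity matrix.
#' @export
read_channel_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Write a mask or channel to TIFF
#'
#' Masks are written as 8-bit 0/255; intensity channels are rescaled to
#' \[0, 1\].
#'
#' @param x Matrix (logical mask or numeric channel).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(x, path) {
  if (is.logical(x)) {
    tiff::writeTIFF((x * 1), path, bits.per.sample = 8)
  } else {
    r <- range(x)
    tiff::writeTIFF(if (diff(r) > 0) (x - r[1]) / diff(r) else x * 0, path)
  }
  invisible(path)
}
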