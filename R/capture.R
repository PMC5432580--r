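#' Chroma-key binary mask for a photograph
#'
#' Separates the object from a uniformly colored background. The distance
#' to the key color is computed in a luminance-separated chroma plane
#' (Cb/Cr), so shadows on the green screen stay background. Pixels within
#' the threshold of the key color are set to 0 (background), everything
#' else to 1 (object); the largest connected foreground component is kept
#' and its holes filled.
#'
#' @param photo h x w x 3 RGB array in \[0, 1\].
#' @param key_color length-3 RGB key (default chroma green).
#' @param threshold chroma-distance threshold; chosen automatically (Otsu
#'   valley of the bimodal chroma-distance histogram) when NULL.
#' @return Binary h x w matrix (0 = background, 1 = object).
#' @export
chroma_mask <- function(photo, key_color = c(0, 1, 0), threshold = NULL) {
  if (length(dim(photo)) != 3L || dim(photo)[3] < 3L)
    stop("photo must be an RGB array")
  chroma <- function(r, g, b) {
    y <- 0.299 * r + 0.587 * g + 0.114 * b
    list(cb = b - y, cr = r - y)
  }
  px <- chroma(photo[, , 1], photo[, , 2], photo[, , 3])
  key <- chroma(key_color[1], key_color[2], key_color[3])
  d <- sqrt((px$cb - key$cb)^2 + (px$cr - key$cr)^2)
  if (is.null(threshold)) {
    rng <- range(d)
    if (diff(rng) < 1e-9 || mean(d < 0.5 * diff(rng) + rng[1]) < 0.01) {
      warning("no key-colored region found; returning full-foreground mask")
      return(matrix(1, nrow(d), ncol(d)))
    }
    threshold <- EBImage::otsu(EBImage::Image(t(d)), range = rng)
  }
  mask <- d >= threshold
  if (!any(mask)) return(matrix(0, nrow(d), ncol(d)))
  # keep the largest connected object, fill its holes (EBImage uses x,y)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask) * 1)))
  tab <- tabulate(lab[lab > 0])
  comp <- (lab == which.max(tab)) * 1
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(comp)))
  (t(filled) > 0) * 1
}

#' Normalized image downsampling rate
#'
#' `rate = 1 - (n_images * megapixels) / (n_ref * mp_ref)`, the fraction of
#' pixel information removed relative to the full acquisition (reference:
#' 56 pictures at 24 megapixels). Ranges from 0 (full information) to 1
#' (no information).
#'
#' @param n_images number of photographs.
#' @param megapixels per-image resolution in megapixels.
#' @param n_ref,mp_ref reference acquisition (defaults 56 images, 24 MP).
#' @return Downsampling rate in \[0, 1\].
#' @export
downsampling_rate <- function(n_images, megapixels, n_ref = 56, mp_ref = 24) {
  if (any(c(n_images, megapixels, n_ref, mp_ref) <= 0))
    stop("all arguments must be positive")
  rate <- 1 - (n_images * megapixels) / (n_ref * mp_ref)
  if (any(rate < 0))
    stop("more pixel information than the reference acquisition")
  rate
}

#' Downsample a photograph to a target megapixel count
#'
#' Aspect-ratio-preserving resampling to within 1% of the requested pixel
#' count.
#'
#' @param photo h x w x 3 RGB array (or h x w matrix).
#' @param target_mp target resolution in megapixels, at most the source
#'   resolution.
#' @return The resampled raster.
#' @export
downsample_image <- function(photo, target_mp) {
  d <- dim(photo)
  h <- d[1]; w <- d[2]
  src_mp <- h * w / 1e6
  if (target_mp > src_mp * (1 + 1e-9))
    stop("upsampling requested (target above source resolution)")
  if (abs(target_mp - src_mp) / src_mp < 1e-9) return(photo)
  s <- sqrt(target_mp * 1e6 / (h * w))
  w2 <- round(w * s); h2 <- round(h * s)
  img <- if (length(d) == 3L) EBImage::Image(aperm(photo, c(2, 1, 3)),
                                             colormode = "Color")
         else EBImage::Image(t(photo))
  out <- EBImage::resize(img, w = w2, h = h2)
  arr <- EBImage::imageData(out)
  if (length(dim(arr)) == 3L) aperm(arr, c(2, 1, 3)) else t(arr)
}
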