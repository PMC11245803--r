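## Image loading and colour-space conversion.
##
## All pixel values travel through the package in the bi-hexcone HSL space:
## L = (max+min)/2, S = chroma / (1 - |2L - 1|), H as a fraction of a full
## turn in [0, 1). Lightness cleanly separates the white background (L near
## 1) and black axes/text (L near 0) from coloured curve pixels, which is
## what the downstream thresholds rely on.

.rgb01ToHsl <- function(R, G, B) {
  mx <- pmax(R, G, B)
  mn <- pmin(R, G, B)
  L <- (mx + mn) / 2
  C <- mx - mn
  S <- ifelse(C == 0, 0, C / (1 - abs(2 * L - 1)))
  # sextant hue formula; achromatic pixels get hue 0
  H <- numeric(length(L))
  nz <- which(C > 0)
  if (length(nz)) {
    r <- R[nz]; g <- G[nz]; b <- B[nz]; c <- C[nz]; m <- mx[nz]
    h <- ifelse(m == r, ((g - b) / c) %% 6,
         ifelse(m == g, (b - r) / c + 2, (r - g) / c + 4))
    H[nz] <- h / 6
  }
  H <- H %% 1
  list(h = H, s = pmin(pmax(S, 0), 1), l = pmin(pmax(L, 0), 1))
}

#' Convert 8-bit RGB values to hue-saturation-lightness
#'
#' Bi-hexcone HSL: lightness is `(max + min) / 2` on the unit scale,
#' saturation is chroma over `1 - |2L - 1|` (zero for achromatic pixels),
#' and hue is the standard sextant angle expressed as a fraction of a full
#' turn in `[0, 1)`.
#'
#' @param r,g,b integer channel values in 0..255, recycled to a common
#'   length.
#' @return Numeric matrix with one row per input pixel and columns
#'   `hue`, `saturation`, `lightness`.
#' @examples
#' rgbToHsl(255, 0, 0)    # pure red: (0, 1, 0.5)
#' rgbToHsl(0, 0, 255)    # pure blue: (240/360, 1, 0.5)
#' @seealso [hslToRgb()] for the inverse, [loadImage()] for whole images.
#' @export
rgbToHsl <- function(r, g, b) {
  n <- max(length(r), length(g), length(b))
  r <- rep_len(r, n); g <- rep_len(g, n); b <- rep_len(b, n)
  if (any(!is.finite(c(r, g, b))) ||
      any(c(r, g, b) < 0) || any(c(r, g, b) > 255) ||
      any(c(r, g, b) != floor(c(r, g, b)))) {
    kmStop("kmInputError", "RGB channels must be integers in [0, 255]")
  }
  v <- .rgb01ToHsl(r / 255, g / 255, b / 255)
  cbind(hue = v$h, saturation = v$s, lightness = v$l)
}

#' Convert hue-saturation-lightness back to 8-bit RGB
#'
#' Inverse of [rgbToHsl()]. Used for diagnostics and round-trip testing;
#' the digitizer itself never needs to leave HSL space.
#'
#' @param h hue as a fraction of a turn in `[0, 1)`.
#' @param s,l saturation and lightness in `[0, 1]`.
#' @return Numeric matrix with columns `r`, `g`, `b` in 0..255 (rounded).
#' @export
hslToRgb <- function(h, s, l) {
  n <- max(length(h), length(s), length(l))
  h <- rep_len(h, n); s <- rep_len(s, n); l <- rep_len(l, n)
  C <- (1 - abs(2 * l - 1)) * s
  hp <- (h %% 1) * 6
  X <- C * (1 - abs(hp %% 2 - 1))
  sext <- floor(hp) %% 6
  R1 <- ifelse(sext == 0 | sext == 5, C, ifelse(sext == 1 | sext == 4, X, 0))
  G1 <- ifelse(sext == 0 | sext == 3, X, ifelse(sext == 1 | sext == 2, C, 0))
  B1 <- ifelse(sext == 2 | sext == 5, X, ifelse(sext == 3 | sext == 4, C, 0))
  m <- l - C / 2
  cbind(
    r = round((R1 + m) * 255),
    g = round((G1 + m) * 255),
    b = round((B1 + m) * 255)
  )
}

.sniffFormat <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", n = 8L)
  png_sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(magic) >= 8 && identical(magic, png_sig)) return("png")
  if (length(magic) >= 2 && identical(magic[1:2], as.raw(c(0xff, 0xd8)))) {
    return("jpeg")
  }
  NA_character_
}

#' Load a Kaplan-Meier plot image as an HSL pixel grid
#'
#' Reads a PNG or JPEG file (format detected from the file's magic bytes,
#' not its extension) at its native resolution, composites any alpha
#' channel onto a white background, and converts every pixel to HSL.
#' Grayscale sources yield hue and saturation identically zero.
#'
#' @param path path to a PNG or JPEG file.
#' @return A [PixelGrid-class] object.
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(array(1, c(2, 2, 3)), f)  # 2x2 white image
#' grid <- loadImage(f)
#' range(grid@lightness)  # all 1
#' @export
loadImage <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    kmStop("kmInputError", "image file not found: %s", as.character(path)[1])
  }
  fmt <- .sniffFormat(path)
  if (is.na(fmt)) {
    kmStop("kmInputError",
           "unsupported image format (need PNG or JPEG): %s", path)
  }
  img <- tryCatch(
    if (fmt == "png") png::readPNG(path) else jpeg::readJPEG(path),
    error = function(e) {
      kmStop("kmInputError", "failed to decode %s image %s: %s",
             fmt, path, conditionMessage(e))
    }
  )
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  nch <- dim(img)[3]
  if (dim(img)[1] < 1 || dim(img)[2] < 1) {
    kmStop("kmInputError", "zero-area image: %s", path)
  }
  if (nch == 2L) {         # gray + alpha: composite onto white
    a <- img[, , 2]
    img <- array(img[, , 1] * a + (1 - a), c(dim(img)[1:2], 1L))
    nch <- 1L
  } else if (nch == 4L) {  # RGBA
    a <- img[, , 4]
    img <- array(
      c(img[, , 1] * a + (1 - a), img[, , 2] * a + (1 - a),
        img[, , 3] * a + (1 - a)),
      c(dim(img)[1:2], 3L)
    )
    nch <- 3L
  }
  h <- dim(img)[1]; w <- dim(img)[2]
  if (nch == 1L) {
    L <- pmin(pmax(img[, , 1], 0), 1)
    hue <- sat <- matrix(0, h, w)
    light <- matrix(L, h, w)
  } else {
    v <- .rgb01ToHsl(img[, , 1], img[, , 2], img[, , 3])
    hue <- matrix(v$h, h, w)
    sat <- matrix(v$s, h, w)
    light <- matrix(v$l, h, w)
  }
  new("PixelGrid",
      width = as.integer(w), height = as.integer(h),
      hue = hue, saturation = sat, lightness = light)
}
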