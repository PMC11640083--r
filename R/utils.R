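# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls never perturb user randomness.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a parent seed and a stream label, staying within
# 32-bit integer range.
childSeed <- function(seed, stream) {
  s <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + s) %% .Machine$integer.max)
}

#' Resize a grayscale raster by area averaging or bilinear interpolation
#'
#' Downscaling uses block (area) averaging, which preserves the mean gray
#' level of energy images; upscaling uses bilinear interpolation.
#'
#' @param img numeric matrix.
#' @param size integer length-1 or length-2 target `(height, width)`.
#' @return numeric matrix of the requested shape, same value range.
#' @examples
#' resizeImage(diag(4), 2)
#' @export
resizeImage <- function(img, size) {
  size <- as.integer(rep(size, length.out = 2))
  h <- nrow(img); w <- ncol(img)
  oh <- size[1]; ow <- size[2]
  if (oh == h && ow == w) return(img)
  if (oh <= h && ow <= w) {
    # area average: assign each source pixel to an output cell
    ri <- pmin(oh, floor((seq_len(h) - 1) * oh / h) + 1L)
    ci <- pmin(ow, floor((seq_len(w) - 1) * ow / w) + 1L)
    sums <- rowsum(img, ri)
    sums <- t(rowsum(t(sums), ci))
    cnt <- outer(tabulate(ri, oh), tabulate(ci, ow))
    sums / cnt
  } else {
    # bilinear
    sy <- (seq_len(oh) - 0.5) * h / oh + 0.5
    sx <- (seq_len(ow) - 0.5) * w / ow + 0.5
    y0 <- pmin(pmax(floor(sy), 1L), h); y1 <- pmin(y0 + 1L, h)
    x0 <- pmin(pmax(floor(sx), 1L), w); x1 <- pmin(x0 + 1L, w)
    fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
    a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
    c_ <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
    top <- a * (1 - rep(fx, each = oh)) + b * rep(fx, each = oh)
    bot <- c_ * (1 - rep(fx, each = oh)) + d * rep(fx, each = oh)
    top * (1 - fy) + bot * fy
  }
}
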