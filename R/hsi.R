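# Hue/saturation/intensity colour transform.
#
# This is the classic HSI model (not HSV or HSL): intensity is the channel
# mean, saturation is 1 - min/mean, and hue is the angular coordinate from
# the standard geometric formula. The variant name is recorded in output
# metadata so downstream reports are auditable.

#' Convert an 8-bit RGB image to hue/saturation/intensity
#'
#' Classic HSI transform on 8-bit channels:
#' `I = (R + G + B) / (3 * 255)` in `[0, 1]`;
#' `S = 1 - min(R, G, B) / mean(R, G, B)` in `[0, 1]` (0 when the mean is 0);
#' `H` in degrees `[0, 360)` from
#' `theta = acos(((R-G) + (R-B)) / (2 * sqrt((R-G)^2 + (R-B)(G-B))))`,
#' with `H = theta` when `B <= G` and `H = 360 - theta` otherwise. The hue
#' of achromatic pixels (`S = 0`) is undefined and returned as `NA`.
#'
#' @param image `h x w x 3` numeric array with channel values in 0..255.
#' @return List with matrices `h` (degrees, `NA` where undefined), `s`, `i`
#'   and the string `variant = "HSI (intensity = channel mean)"`.
#' @export
rgb_to_hsi <- function(image) {
  stopifnot(is.array(image), length(dim(image)) == 3, dim(image)[3] == 3)
  h_w <- dim(image)[1:2]
  R <- matrix(image[, , 1], h_w[1], h_w[2])
  G <- matrix(image[, , 2], h_w[1], h_w[2])
  B <- matrix(image[, , 3], h_w[1], h_w[2])
  if (max(image) <= 1 && any(image > 0)) {
    stop("expected 8-bit channel values in 0..255, got values <= 1; ",
         "multiply by 255 first")
  }
  mn <- pmin(R, G, B)
  s3 <- R + G + B
  i <- s3 / (3 * 255)
  s <- ifelse(s3 > 0, 1 - 3 * mn / s3, 0)

  num <- 0.5 * ((R - G) + (R - B))
  den <- sqrt((R - G)^2 + (R - B) * (G - B))
  theta <- acos(clamp(ifelse(den > 0, num / den, 1), -1, 1)) * 180 / pi
  h <- ifelse(B <= G, theta, 360 - theta)
  h[s == 0] <- NA_real_
  h[h >= 360] <- 0
  list(h = h, s = clamp(s, 0, 1), i = clamp(i, 0, 1),
       variant = "HSI (intensity = channel mean)")
}
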