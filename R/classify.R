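# Pixel classification of histological stains by HSI thresholds.

#' Define a stain class by HSI threshold intervals
#'
#' A pixel belongs to the class iff its hue, saturation and intensity all
#' fall inside the given closed intervals. Hue intervals may wrap around 0
#' (e.g. `c(330, 30)` accepts magenta-through-red); the full interval
#' `c(0, 360)` accepts any hue, including the undefined hue of achromatic
#' pixels — use it for dark or grey classes such as elastin and melanin.
#'
#' @param name Class name (e.g. `"collagen"`, `"gag"`, `"elastin"`,
#'   `"melanin"`, `"chromogen"`).
#' @param hue Length-2 numeric, degrees in `[0, 360]`. `lo > hi` wraps.
#' @param sat,int Length-2 numeric in `[0, 1]`, `lo <= hi`.
#' @return A `stain_class_spec`.
#' @export
stain_class_spec <- function(name, hue = c(0, 360), sat = c(0, 1),
                             int = c(0, 1)) {
  stopifnot(is_string(name),
            length(hue) == 2, all(hue >= 0), all(hue <= 360),
            length(sat) == 2, sat[1] <= sat[2], all(sat >= 0), all(sat <= 1),
            length(int) == 2, int[1] <= int[2], all(int >= 0), all(int <= 1))
  structure(list(name = name, hue = hue, sat = sat, int = int),
            class = "stain_class_spec")
}

hue_matches <- function(h, interval) {
  lo <- interval[1]; hi <- interval[2]
  if (lo <= 0 && hi >= 360) {
    return(rep(TRUE, length(h))) # any hue, undefined included
  }
  out <- if (lo > hi) (h >= lo | h <= hi) else (h >= lo & h <= hi)
  out[is.na(h)] <- FALSE
  out
}

#' Built-in stain threshold presets per staining protocol
#'
#' Default HSI intervals for the supported protocols: Movat's pentachrome
#' (yellow collagen, blue GAGs, near-black elastin), Elastica van Gieson
#' (black elastic fibers), and AEC immunohistochemistry (red chromogen,
#' optionally near-black melanin). The original study's numeric thresholds
#' are unpublished; these presets are calibrated on the package's synthetic
#' palettes and are configuration defaults, not reference values. Elastin
#' and melanin are both dark classes distinguished by which protocol (i.e.
#' which adjacent section) is analysed, not by colour.
#'
#' @param protocol `"pentachrome"`, `"van_gieson"` or `"ihc_aec"`.
#' @return List of [stain_class_spec()] in match order.
#' @export
stain_presets <- function(protocol = c("pentachrome", "van_gieson", "ihc_aec")) {
  protocol <- match.arg(protocol)
  switch(protocol,
    pentachrome = list(
      stain_class_spec("collagen", hue = c(30, 75), sat = c(0.25, 1),
                       int = c(0.25, 0.90)),
      stain_class_spec("gag", hue = c(180, 260), sat = c(0.15, 1),
                       int = c(0.20, 0.90)),
      stain_class_spec("elastin", hue = c(0, 360), sat = c(0, 1),
                       int = c(0, 0.22))
    ),
    van_gieson = list(
      stain_class_spec("elastin", hue = c(0, 360), sat = c(0, 1),
                       int = c(0, 0.22))
    ),
    ihc_aec = list(
      stain_class_spec("chromogen", hue = c(330, 25), sat = c(0.30, 1),
                       int = c(0.15, 0.80)),
      stain_class_spec("melanin", hue = c(0, 360), sat = c(0, 1),
                       int = c(0, 0.22))
    ))
}

#' Read stain class specs from a YAML or JSON threshold config
#'
#' Config format: a map of class name to `{hue: [lo, hi], sat: [lo, hi],
#' int: [lo, hi]}`, matched in file order.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return List of [stain_class_spec()].
#' @export
read_stain_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  mapply(function(name, v) {
    stain_class_spec(name,
                     hue = as.numeric(v$hue %||% c(0, 360)),
                     sat = as.numeric(v$sat %||% c(0, 1)),
                     int = as.numeric(v$int %||% c(0, 1)))
  }, names(cfg), cfg, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Classify pixels into stain classes by HSI thresholds
#'
#' A pixel is assigned to a class iff it lies inside the leaflet mask and
#' its hue, saturation and intensity fall within the class intervals. In
#' the default exclusive mode each pixel takes at most one class, resolved
#' first-match in spec order (overlaps are thus resolved deterministically
#' by configuration order); `exclusive = FALSE` allows overlapping masks.
#'
#' @param image `h x w x 3` RGB array (0..255).
#' @param mask A `leaflet_mask` of matching dimensions.
#' @param specs List of [stain_class_spec()] (or a protocol name for
#'   [stain_presets()]).
#' @param exclusive One class per pixel (default `TRUE`)?
#' @return Named list of logical class masks, with attributes `counts`
#'   (pixels per class) and `hsi_variant`.
#' @export
classify_stain <- function(image, mask, specs, exclusive = TRUE) {
  stopifnot(inherits(mask, "leaflet_mask"))
  if (is.character(specs)) specs <- stain_presets(specs)
  stopifnot(length(specs) > 0,
            all(vapply(specs, inherits, logical(1), "stain_class_spec")))
  if (!all(dim(image)[1:2] == dim(mask))) {
    stop("image (", paste(dim(image)[1:2], collapse = "x"),
         ") and mask (", paste(dim(mask), collapse = "x"),
         ") dimensions differ")
  }
  hsi <- rgb_to_hsi(image)
  inmask <- mask_matrix(mask) == 1L
  taken <- matrix(FALSE, nrow(mask), ncol(mask))
  out <- list()
  for (sp in specs) {
    hit <- inmask &
      hue_matches(hsi$h, sp$hue) &
      hsi$s >= sp$sat[1] & hsi$s <= sp$sat[2] &
      hsi$i >= sp$int[1] & hsi$i <= sp$int[2]
    if (exclusive) {
      hit <- hit & !taken
      taken <- taken | hit
    }
    out[[sp$name]] <- hit
  }
  attr(out, "counts") <- vapply(out, sum, numeric(1))
  attr(out, "hsi_variant") <- hsi$variant
  attr(out, "exclusive") <- exclusive
  out
}
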