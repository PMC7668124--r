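# Grey-level co-occurrence (GLCM) texture features of QUS parametric maps.

#' Quantize a parametric map to grey levels
#'
#' Uniform binning between the in-ROI minimum and maximum into `n_levels`
#' levels (0-based). A constant map maps to level 0 everywhere. Quantization
#' is per map per scan, so delta features remain self-contained per time
#' point.
#'
#' @param map Numeric matrix.
#' @param roi_mask Logical matrix; pixels outside (or non-finite) are invalid.
#' @param n_levels Number of grey levels (default 16).
#' @return List with `levels` (integer matrix, NA where invalid) and `valid`
#'   (logical matrix).
#' @export
quantize_map <- function(map, roi_mask, n_levels = 16) {
  stopifnot(n_levels >= 2, all(dim(map) == dim(roi_mask)))
  valid <- roi_mask & is.finite(map)
  if (!any(valid)) stop("empty ROI")
  v <- map[valid]
  lev <- matrix(NA_integer_, nrow(map), ncol(map))
  rng <- range(v)
  if (diff(rng) == 0) {
    lev[valid] <- 0L
  } else {
    q <- floor((map[valid] - rng[1]) / diff(rng) * n_levels)
    lev[valid] <- as.integer(pmin(q, n_levels - 1))
  }
  list(levels = lev, valid = valid, n_levels = n_levels)
}

glcm_offset <- function(distance, angle) {
  # image convention: rows increase downward; 45 degrees looks up-right
  switch(as.character(angle),
         "0" = c(0L, distance),
         "45" = c(-distance, distance),
         "90" = c(-distance, 0L),
         "135" = c(-distance, -distance),
         stop("angle must be one of 0, 45, 90, 135"))
}

#' Grey-level co-occurrence matrix
#'
#' Counts level pairs at the given interpixel distance and direction; both
#' pixels of a pair must be valid. Pairs are counted bidirectionally, so the
#' matrix is symmetric, and it is normalized to sum to 1.
#'
#' @param levels Integer matrix of grey levels (NA = invalid), e.g. from
#'   [quantize_map()].
#' @param valid Logical validity matrix (default: non-NA levels).
#' @param distance Interpixel distance in pixels (1..4 typically).
#' @param angle Direction in degrees: 0, 45, 90 or 135.
#' @param n_levels Number of grey levels G; default `max(levels) + 1`.
#' @return An object of class `glcm`: G x G probability matrix with
#'   attributes `distance` and `angle`.
#' @export
compute_glcm <- function(levels, valid = NULL, distance = 1, angle = 0,
                         n_levels = NULL) {
  if (is.null(valid)) valid <- !is.na(levels)
  if (is.null(n_levels)) n_levels <- max(levels[valid], 0L) + 1L
  off <- glcm_offset(as.integer(distance), angle)
  nr <- nrow(levels); nc <- ncol(levels)
  rlo <- max(1, 1 - off[1]); rhi <- min(nr, nr - off[1])
  clo <- max(1, 1 - off[2]); chi <- min(nc, nc - off[2])
  if (rlo > rhi || clo > chi) stop("no co-occurring pairs")
  r1 <- rlo:rhi
  c1 <- clo:chi
  a <- levels[r1, c1, drop = FALSE]
  b <- levels[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- valid[r1, c1, drop = FALSE] & valid[r1 + off[1], c1 + off[2], drop = FALSE]
  if (!any(ok)) stop("no co-occurring pairs")
  i <- a[ok]; j <- b[ok]
  m <- matrix(tabulate(i * n_levels + j + 1L, nbins = n_levels^2),
              n_levels, n_levels, byrow = TRUE)
  m <- m + t(m)                          # count pairs bidirectionally
  structure(m / sum(m), class = "glcm", distance = distance, angle = angle)
}

#' Haralick features of a single GLCM
#'
#' Contrast `sum p(i,j) (i-j)^2`; correlation
#' `sum p(i,j)(i-mu_i)(j-mu_j) / (sigma_i sigma_j)` (0 when a marginal
#' variance is zero); energy `sum p^2`; homogeneity `sum p / (1 + |i-j|)`.
#'
#' @param glcm A `glcm` (or plain probability matrix).
#' @return Named numeric vector `CON`, `COR`, `ENE`, `HOM`.
#' @export
glcm_features <- function(glcm) {
  p <- unclass(glcm)
  g <- nrow(p)
  i <- matrix(seq_len(g), g, g)          # row index
  j <- t(i)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  var_i <- sum((i - mu_i)^2 * p); var_j <- sum((j - mu_j)^2 * p)
  cor_v <- if (var_i <= 0 || var_j <= 0) 0 else
    sum((i - mu_i) * (j - mu_j) * p) / sqrt(var_i * var_j)
  c(CON = sum(p * (i - j)^2),
    COR = cor_v,
    ENE = sum(p^2),
    HOM = sum(p / (1 + abs(i - j))))
}

#' Texture summary of a parametric map
#'
#' Quantizes the map over the ROI and averages the four Haralick features over
#' the 16 GLCMs formed by four interpixel distances (1-4 pixels) and four
#' directions (0, 45, 90, 135 degrees).
#'
#' @param map Numeric matrix.
#' @param roi_mask Logical matrix of in-ROI pixels.
#' @param n_levels Grey levels for quantization (default 16).
#' @param distances,angles GLCM configurations to enumerate.
#' @return Named numeric vector `CON`, `COR`, `ENE`, `HOM` with attribute
#'   `n_glcms` recording how many GLCMs were averaged.
#' @export
texture_summary <- function(map, roi_mask, n_levels = 16,
                            distances = 1:4, angles = c(0, 45, 90, 135)) {
  q <- quantize_map(map, roi_mask, n_levels)
  acc <- c(CON = 0, COR = 0, ENE = 0, HOM = 0)
  n <- 0L
  for (d in distances) for (a in angles) {
    gl <- compute_glcm(q$levels, q$valid, distance = d, angle = a,
                       n_levels = n_levels)
    acc <- acc + glcm_features(gl)
    n <- n + 1L
  }
  structure(acc / n, n_glcms = n)
}
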