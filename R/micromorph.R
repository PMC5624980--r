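#' Read a binary mask (or graylevel image) from PNG/TIFF
#'
#' @param path Image path (`.png` or `.tif`/`.tiff`).
#' @param threshold Binarization threshold on the normalized intensity in
#'   `[0, 1]`; pixels strictly above it are foreground. Binarization of
#'   micrographs is sensitive to illumination evenness, so the threshold is
#'   always explicit.
#' @return A logical matrix (rows = image rows). Multi-channel images are
#'   reduced to their first channel.
#' @export
read_mask <- function(path, threshold = 0.5) {
  if (!file.exists(path)) abort(paste0("image not found: ", path))
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    abort("unsupported image format (use PNG or TIFF).")
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > threshold
}

# 8-connected Moore boundary tracing; returns the cyclic chain of direction
# codes (0..7, even = axis move, odd = diagonal) around the outer boundary.
trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(FALSE, nr + 2, nc + 2)
  m[2:(nr + 1), 2:(nc + 1)] <- mask
  idx <- which(m, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  start <- idx[1, ]
  # clockwise Moore neighborhood in image coordinates (row grows downward)
  dirs <- matrix(c(-1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1),
                 ncol = 2, byrow = TRUE)
  dir_index <- function(v) {
    which(dirs[, 1] == v[1] & dirs[, 2] == v[2]) - 1L
  }
  p <- start
  b <- start + c(0L, -1L)  # backtrack: the west neighbor (background)
  chain <- integer(0)
  max_steps <- 8L * (sum(mask) + 4L)
  repeat {
    i0 <- dir_index(b - p)
    moved <- FALSE
    for (k in 1:8) {
      j <- (i0 + k) %% 8L
      q <- p + dirs[j + 1L, ]
      if (m[q[1], q[2]]) {
        # Jacob's criterion: leaving the start pixel by the initial move
        # again means the boundary is closed
        if (length(chain) && all(p == start) && j == chain[1]) return(chain)
        chain <- c(chain, j)
        b <- p + dirs[((i0 + k - 1L) %% 8L) + 1L, ]
        p <- q
        moved <- TRUE
        break
      }
    }
    if (!moved) return(integer(0))  # isolated pixel
    if (length(chain) > max_steps)
      abort("boundary tracing failed to terminate; is the mask a single component?")
  }
}

# Vossepoel-Smeulders perimeter estimator on a chain code: corrects the
# systematic over-estimation of staircase boundaries so that digitized disks
# measure close to their true circumference. Used for very small components
# where contour smoothing is not meaningful.
chain_perimeter <- function(chain) {
  if (!length(chain)) return(4)  # isolated pixel: unit-square convention
  n_even <- sum(chain %% 2L == 0L)
  n_odd <- sum(chain %% 2L == 1L)
  n_corner <- sum(chain != c(chain[-1], chain[1]))
  0.980 * n_even + 1.406 * n_odd - 0.091 * n_corner
}

# Geometric boundary length: the closed polygon through the boundary pixel
# centers, smoothed with a circular moving average so that single-pixel
# staircase jags measure as the straight or curved edges they rasterize,
# rather than as extra length. The window grows with the contour length
# (~1/50th, capped) which makes the estimate stable under integer upscaling;
# digitized disks measure ~2*pi*r and filled squares ~4n.
smoothed_boundary_length <- function(chain, window = NULL) {
  window <- window %||%
    min(21L, max(5L, 2L * (length(chain) %/% 100L) + 1L))
  if (length(chain) < 2L * window) return(chain_perimeter(chain))
  dirs <- matrix(c(-1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1),
                 ncol = 2, byrow = TRUE)
  ry <- cumsum(dirs[chain + 1L, 1])
  rx <- cumsum(dirs[chain + 1L, 2])
  k <- (window - 1L) %/% 2L
  circ_smooth <- function(v) {
    n <- length(v)
    ext <- c(v[(n - k + 1L):n], v, v[1:k])
    stats::filter(ext, rep(1 / window, window), sides = 2)[(k + 1L):(k + n)]
  }
  sy <- circ_smooth(ry); sx <- circ_smooth(rx)
  sum(sqrt(diff(c(sy, sy[1]))^2 + diff(c(sx, sx[1]))^2))
}

# Convex hull over the corners of the foreground pixels (each pixel is a
# unit square); guarantees hull area >= pixel area, so fullness <= 1.
convex_hull_area <- function(mask) {
  on_boundary <- mask & !erode4(mask)
  pts <- which(on_boundary, arr.ind = TRUE)
  x <- c(pts[, 2] - 0.5, pts[, 2] + 0.5, pts[, 2] + 0.5, pts[, 2] - 0.5)
  y <- c(pts[, 1] - 0.5, pts[, 1] - 0.5, pts[, 1] + 0.5, pts[, 1] + 0.5)
  h <- grDevices::chull(x, y)
  polygon_area(x[h], y[h])
}

polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

erode4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(FALSE, nr + 2, nc + 2)
  m[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- m[2:(nr + 1), 2:(nc + 1)] &
    m[1:nr, 2:(nc + 1)] & m[3:(nr + 2), 2:(nc + 1)] &
    m[2:(nr + 1), 1:nc] & m[2:(nr + 1), 3:(nc + 2)]
  core
}

# A connected mask's topological skeleton contains a cycle iff the mask has a
# hole, i.e. a background component not connected to the border.
mask_has_hole <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(FALSE, nr + 2, nc + 2)
  m[2:(nr + 1), 2:(nc + 1)] <- mask
  bg_labels <- EBImage::bwlabel(!m)
  length(setdiff(unique(as.vector(bg_labels)), 0)) > 1
}

#' Shape metrics of one binary element
#'
#' Computes the microscopy shape descriptors of a single connected element:
#'
#' * `area` — foreground pixel count, scaled to um^2;
#' * `perimeter` — length of the traced 8-connected boundary polygon
#'   (chain-code estimator with staircase correction), in um;
#' * `convex_area` — area of the convex hull of the foreground pixel squares;
#' * `roughness` — `perimeter^2 / (4 * pi * area)`; 1 for a disk, larger the
#'   hairier the outline;
#' * `fullness` — `area / convex_area`, in `(0, 1]`; 1 for convex shapes;
#' * `skeleton_has_loop` — whether the skeleton of the element contains a
#'   cycle (equivalently: the element encloses a hole), the criterion
#'   separating entangled small clumps from open hyphae;
#' * `has_core` / `core_area` — interior dark region on a graylevel image
#'   (always `FALSE` / 0 for a pure binary mask: core detection needs
#'   intensities).
#'
#' @param mask Logical matrix, a single connected element.
#' @param um_per_px Pixel size in um.
#' @param graylevel Optional numeric matrix in `[0, 1]` (same shape as
#'   `mask`) for core detection.
#' @param core_intensity_max Intensity below which a pixel counts as dark
#'   core candidate.
#' @return A one-row tibble of the metrics above.
#' @export
#' @examples
#' measure_element(simulate_pellet_mask(radius_core = 30, seed = 1)$mask)
measure_element <- function(mask, um_per_px = 1, graylevel = NULL,
                            core_intensity_max = 0.3) {
  mask <- as.matrix(mask) > 0
  n_px <- sum(mask)
  if (!n_px) abort("empty mask.")
  chain <- trace_boundary(mask)
  perimeter <- smoothed_boundary_length(chain) * um_per_px
  area <- n_px * um_per_px^2
  convex_area <- convex_hull_area(mask) * um_per_px^2
  has_core <- FALSE
  core_area <- 0
  if (!is.null(graylevel)) {
    dark <- mask & (graylevel < core_intensity_max)
    interior <- erode4(mask)
    if (any(dark)) {
      lab <- EBImage::bwlabel(dark)
      sizes <- table(lab[lab > 0])
      for (l in names(sizes)) {
        px <- lab == as.integer(l)
        if (all(interior[px])) {
          a <- sum(px) * um_per_px^2
          if (a > core_area) core_area <- a
        }
      }
      has_core <- core_area > 0
    }
  }
  tibble(
    area = area,
    perimeter = perimeter,
    convex_area = convex_area,
    roughness = perimeter^2 / (4 * pi * area),
    fullness = min(1, area / convex_area),
    skeleton_has_loop = mask_has_hole(mask),
    has_core = has_core,
    core_area = core_area
  )
}

#' Measure every element in a labeled mask
#'
#' Labels the connected components of a mask and measures each with
#' [measure_element()].
#'
#' @inheritParams measure_element
#' @param min_px Components smaller than this many pixels are dropped as
#'   noise.
#' @return A tibble with one row per element (`element` id column first).
#' @export
measure_elements <- function(mask, um_per_px = 1, graylevel = NULL,
                             core_intensity_max = 0.3, min_px = 5) {
  mask <- as.matrix(mask) > 0
  lab <- EBImage::bwlabel(mask)
  labels <- setdiff(sort(unique(as.vector(lab))), 0)
  out <- purrr::map_dfr(labels, function(l) {
    sub <- lab == l
    if (sum(sub) < min_px) return(NULL)
    rows <- range(which(rowSums(sub) > 0))
    cols <- range(which(colSums(sub) > 0))
    cropped <- sub[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    g <- if (is.null(graylevel)) NULL else
      graylevel[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    mutate(measure_element(cropped, um_per_px, g, core_intensity_max),
           element = l, .before = 1)
  })
  out
}

#' Microscopy classification of measured elements
#'
#' The image-analysis side of the class definitions: pellets are large
#' (area > 7500 um^2) elements with a dense core of more than 7000 um^2;
#' large clumps exceed 3500 um^2 without qualifying as pellet; among the
#' smaller elements (area in (100, 3500] um^2), a looped skeleton marks an
#' entangled small clump (area additionally > 1000 um^2) and a loop-free
#' skeleton marks hyphae; anything else is unclassified. A total function:
#' every row receives exactly one class.
#'
#' @param metrics Tibble from [measure_element()] / [measure_elements()].
#' @param hyphae_area_min,small_clump_area_min,large_clump_area_min,pellet_area_min,pellet_core_area_min
#'   Area thresholds in um^2 (defaults: 100, 1000, 3500, 7500, 7000).
#' @return `metrics` with a `class` factor column added.
#' @export
classify_microscopy <- function(metrics,
                                hyphae_area_min = 100,
                                small_clump_area_min = 1000,
                                large_clump_area_min = 3500,
                                pellet_area_min = 7500,
                                pellet_core_area_min = 7000) {
  cls <- dplyr::case_when(
    metrics$area > pellet_area_min & metrics$has_core &
      metrics$core_area > pellet_core_area_min ~ "pellet",
    metrics$area > large_clump_area_min ~ "large_clump",
    metrics$area > small_clump_area_min & metrics$skeleton_has_loop ~ "small_clump",
    metrics$area > hyphae_area_min & !metrics$skeleton_has_loop ~ "hyphae",
    .default = "unclassified"
  )
  metrics$class <- factor(cls, levels = pm_classes)
  metrics
}
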