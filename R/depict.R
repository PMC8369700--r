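# 2D depiction rendering and photometric augmentation.
#
# Molecules are laid out by Open Babel's 2D structure diagram generator,
# optionally rotated by a uniformly drawn angle (rotation acts on the
# coordinates before rasterization, so nothing is cropped), and rasterized
# here as 8-bit grayscale images: black skeleton on white background,
# heteroatom labels set in a small built-in bitmap typeface, wedge/hash
# bonds for drawn stereocenters. Rendering is pure integer arithmetic, so a
# given (config, seed) pair is bit-reproducible.

#' Depiction configuration
#'
#' @param size_px Edge length of the square image in pixels.
#' @param rotate Randomly rotate the molecule (uniform 0-360 degrees,
#'   continuous) before rasterization.
#' @param seed Integer seed controlling rotation (and augmentation, when
#'   used through higher-level dataset builders).
#' @param augment Apply one randomly chosen photometric augmentation after
#'   rendering (see [augment_image()]).
#' @return An object of class `ocsr_depict_config`.
#' @export
depiction_config <- function(size_px = 299L, rotate = TRUE, seed = 1L,
                             augment = FALSE) {
  stopifnot(size_px > 0)
  structure(list(size_px = as.integer(size_px), rotate = isTRUE(rotate),
                 seed = as.integer(seed), augment = isTRUE(augment)),
            class = "ocsr_depict_config")
}

# Evaluate `expr` under a private RNG stream, restoring the caller's.
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render a single-structure 2D depiction
#'
#' @param smiles A single, single-fragment SMILES string.
#' @param config A [depiction_config()].
#' @return An integer matrix (`size_px` x `size_px`) of 8-bit gray values
#'   (0 = black ink, 255 = white background).
#' @examples
#' \dontrun{
#' img <- render_structure("C1=CC=CC=C1", depiction_config(seed = 7))
#' dim(img)
#' }
#' @export
render_structure <- function(smiles, config = depiction_config()) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  g <- mol_graphs(smiles, gen2d = TRUE)[[1]]
  if (is.null(g)) stop("unparseable SMILES: ", smiles, call. = FALSE)
  if (n_components(g$n_atoms, g$bonds) > 1L) {
    stop("multi-fragment SMILES cannot be depicted: ", smiles, call. = FALSE)
  }
  rasterize_molecule(g, config)
}

# Batch variant: one Open Babel layout call for the whole corpus.
render_structures <- function(smiles, config = depiction_config()) {
  graphs <- mol_graphs(smiles, gen2d = TRUE)
  lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    if (is.null(g)) stop("unparseable SMILES: ", smiles[i], call. = FALSE)
    cfg <- config
    cfg$seed <- config$seed + i - 1L   # per-molecule rotation stream
    rasterize_molecule(g, cfg)
  })
}

rasterize_molecule <- function(g, config) {
  px <- config$size_px
  img <- matrix(255L, px, px)
  at <- g$atoms
  if (g$n_atoms == 0L) return(img)
  xy <- cbind(at$x, at$y)
  if (config$rotate) {
    theta <- with_rng(config$seed, stats::runif(1, 0, 2 * pi))
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    xy <- xy %*% rot
  }
  # fit into the canvas, preserving aspect; fixed ink scale per bond length
  margin <- max(8, round(px * 0.08))
  rng_x <- range(xy[, 1]); rng_y <- range(xy[, 2])
  span <- max(rng_x[2] - rng_x[1], rng_y[2] - rng_y[1], 1e-6)
  scale <- (px - 2 * margin) / span
  # cap the bond length at ~14% of the canvas so small molecules are not
  # blown up to full frame
  n_bond <- g$n_bonds
  if (n_bond > 0L) {
    bl <- sqrt((xy[g$bonds$from, 1] - xy[g$bonds$to, 1])^2 +
                 (xy[g$bonds$from, 2] - xy[g$bonds$to, 2])^2)
    med <- stats::median(bl)
    if (is.finite(med) && med > 0) scale <- min(scale, px * 0.14 / med)
  }
  cx <- mean(rng_x); cy <- mean(rng_y)
  X <- (xy[, 1] - cx) * scale + px / 2
  Y <- px / 2 - (xy[, 2] - cy) * scale   # raster rows grow downward
  lw <- max(1L, round(px / 200))
  labelled <- at$symbol != "C" | at$charge != 0L
  for (k in seq_len(n_bond)) {
    a <- g$bonds$from[k]; b <- g$bonds$to[k]
    p <- c(X[a], Y[a]); q <- c(X[b], Y[b])
    # shorten towards labelled atoms so bonds do not strike the glyphs
    sh_a <- if (labelled[a]) 0.18 else 0
    sh_b <- if (labelled[b]) 0.18 else 0
    pq <- q - p
    p2 <- p + pq * sh_a
    q2 <- q - pq * sh_b
    ord <- g$bonds$order[k]
    wg <- g$bonds$wedge[k]
    if (wg == 1L) {
      img <- draw_wedge(img, p2, q2, lw)
    } else if (wg == 6L) {
      img <- draw_hash(img, p2, q2, lw)
    } else if (ord == 1L) {
      img <- draw_line(img, p2, q2, lw)
    } else {
      off <- perp_unit(p2, q2) * max(2, px / 100)
      if (ord == 2L) {
        img <- draw_line(img, p2 + off / 2, q2 + off / 2, lw)
        img <- draw_line(img, p2 - off / 2, q2 - off / 2, lw)
      } else {
        img <- draw_line(img, p2, q2, lw)
        img <- draw_line(img, p2 + off, q2 + off, lw)
        img <- draw_line(img, p2 - off, q2 - off, lw)
      }
    }
  }
  fs <- max(1L, round(px / 160))   # glyph scale factor
  for (i in which(labelled)) {
    lab <- at$symbol[i]
    if (at$charge[i] > 0L) lab <- paste0(lab, "+")
    if (at$charge[i] < 0L) lab <- paste0(lab, "-")
    img <- draw_label(img, lab, X[i], Y[i], fs)
  }
  img
}

perp_unit <- function(p, q) {
  v <- q - p
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-9) return(c(0, 0))
  c(-v[2], v[1]) / nrm
}

# Stamp black pixels in a (2r+1)-square around each (x, y) sample point.
stamp <- function(img, xs, ys, r) {
  px <- nrow(img)
  for (dx in -r:r) {
    for (dy in -r:r) {
      ix <- round(xs + dx); iy <- round(ys + dy)
      ok <- ix >= 1 & ix <= px & iy >= 1 & iy <= px
      img[cbind(iy[ok], ix[ok])] <- 0L
    }
  }
  img
}

draw_line <- function(img, p, q, lw) {
  len <- sqrt(sum((q - p)^2))
  n <- max(2L, ceiling(len * 2))
  t <- seq(0, 1, length.out = n)
  stamp(img, p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2]),
        max(1L, lw - 1L))
}

# Solid wedge: triangle widening from p (narrow) to q (wide).
draw_wedge <- function(img, p, q, lw) {
  len <- sqrt(sum((q - p)^2))
  n <- max(2L, ceiling(len * 2))
  t <- seq(0, 1, length.out = n)
  u <- perp_unit(p, q)
  wmax <- max(2, len * 0.12)
  for (s in seq(-1, 1, by = 0.2)) {
    img <- stamp(img,
                 p[1] + t * (q[1] - p[1]) + s * t * wmax * u[1],
                 p[2] + t * (q[2] - p[2]) + s * t * wmax * u[2], 0L)
  }
  img
}

# Hashed wedge: perpendicular rungs widening towards q.
draw_hash <- function(img, p, q, lw) {
  len <- sqrt(sum((q - p)^2))
  n_r <- max(3L, floor(len / 4))
  u <- perp_unit(p, q)
  wmax <- max(2, len * 0.12)
  for (j in seq_len(n_r)) {
    t <- j / n_r
    cx <- p[1] + t * (q[1] - p[1]); cy <- p[2] + t * (q[2] - p[2])
    w <- t * wmax
    img <- draw_line(img, c(cx - u[1] * w, cy - u[2] * w),
                     c(cx + u[1] * w, cy + u[2] * w), 1L)
  }
  img
}

# ---- 5x7 bitmap typeface for atom labels ------------------------------------

OCSR_FONT <- list(
  "C" = c(".###.", "#...#", "#....", "#....", "#....", "#...#", ".###."),
  "B" = c("####.", "#...#", "#...#", "####.", "#...#", "#...#", "####."),
  "N" = c("#...#", "##..#", "##..#", "#.#.#", "#..##", "#..##", "#...#"),
  "O" = c(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  "P" = c("####.", "#...#", "#...#", "####.", "#....", "#....", "#...."),
  "S" = c(".####", "#....", "#....", ".###.", "....#", "....#", "####."),
  "F" = c("#####", "#....", "#....", "####.", "#....", "#....", "#...."),
  "I" = c(".###.", "..#..", "..#..", "..#..", "..#..", "..#..", ".###."),
  "l" = c("..#..", "..#..", "..#..", "..#..", "..#..", "..#..", "..##."),
  "r" = c(".....", ".....", "#.##.", "##..#", "#....", "#....", "#...."),
  "e" = c(".....", ".....", ".###.", "#...#", "#####", "#....", ".###."),
  "+" = c(".....", "..#..", "..#..", "#####", "..#..", "..#..", "....."),
  "-" = c(".....", ".....", ".....", "#####", ".....", ".....", ".....")
)

# Draw `text` centered at (x, y), erasing a white box behind it.
draw_label <- function(img, text, x, y, fs) {
  chars <- strsplit(text, "")[[1]]
  gw <- 5L * fs; gh <- 7L * fs; gap <- fs
  tw <- length(chars) * gw + (length(chars) - 1L) * gap
  px <- nrow(img)
  x0 <- round(x - tw / 2); y0 <- round(y - gh / 2)
  # erase background
  ex <- max(1L, x0 - fs):min(px, x0 + tw + fs)
  ey <- max(1L, y0 - fs):min(px, y0 + gh + fs)
  img[ey, ex] <- 255L
  for (ci in seq_along(chars)) {
    glyph <- OCSR_FONT[[chars[ci]]]
    if (is.null(glyph)) next
    gx <- x0 + (ci - 1L) * (gw + gap)
    for (r in 1:7) {
      row <- strsplit(glyph[r], "")[[1]]
      for (cc in 1:5) {
        if (row[cc] != "#") next
        yy <- (y0 + (r - 1L) * fs):(y0 + r * fs - 1L)
        xx <- (gx + (cc - 1L) * fs):(gx + cc * fs - 1L)
        yy <- yy[yy >= 1 & yy <= px]; xx <- xx[xx >= 1 & xx <= px]
        img[yy, xx] <- 0L
      }
    }
  }
  img
}

# ---- augmentation -----------------------------------------------------------

AUGMENTATION_NAMES <- c("gaussian_blur", "average_blur",
                        "additive_gaussian_noise", "salt_and_pepper",
                        "salt", "pepper", "coarse_dropout", "gamma_contrast",
                        "sharpen", "enhance_brightness")

#' Augmentation inventory
#'
#' The ten photometric augmentations and their parameter ranges. Exactly one
#' is applied per image, chosen uniformly; its parameter is drawn uniformly
#' from the listed range.
#'
#' @return A tibble with columns `name`, `parameter`, `lower`, `upper`.
#' @export
augmentation_specs <- function() {
  tibble::tribble(
    ~name,                     ~parameter,    ~lower, ~upper,
    "gaussian_blur",           "sigma",        0,      1.8,
    "average_blur",            "k",            0,      3,
    "additive_gaussian_noise", "scale",        0,      0.1 * 255,
    "salt_and_pepper",         "p",            0,      0.05,
    "salt",                    "p",            0,      0.05,
    "pepper",                  "p",            0,      0.05,
    "coarse_dropout",          "p",            0,      0.01,
    "gamma_contrast",          "gamma",        0.5,    2.0,
    "sharpen",                 "alpha",        0,      1.0,
    "enhance_brightness",      "factor",       0.95,   1.5
  )
}

#' Apply one random photometric augmentation
#'
#' Chooses one of the ten augmentations uniformly at random and applies it
#' with a parameter drawn uniformly from its range. Shape and 8-bit range
#' are preserved; the operation is deterministic under `seed`.
#'
#' @param image Integer matrix of 8-bit gray values (0-255).
#' @param seed Integer seed.
#' @return The augmented image (same shape, integer 0-255), with attributes
#'   `augmentation` (name) and `parameter` (drawn value).
#' @export
augment_image <- function(image, seed = 1L) {
  check_image8(image)
  spec <- augmentation_specs()
  with_rng(seed, {
    k <- sample.int(nrow(spec), 1L)
    par <- stats::runif(1, spec$lower[k], spec$upper[k])
    out <- apply_augmentation(image, spec$name[k], par)
    structure(out, augmentation = spec$name[k], parameter = par)
  })
}

check_image8 <- function(image) {
  if (!is.matrix(image) || !is.numeric(image) ||
      any(image < 0 | image > 255) || any(image != round(image))) {
    stop("image must be an 8-bit matrix (integer values 0-255)",
         call. = FALSE)
  }
  invisible(TRUE)
}

clip8 <- function(x) {
  matrix(as.integer(pmin(255, pmax(0, round(x)))), nrow(x), ncol(x))
}

apply_augmentation <- function(img, name, par) {
  switch(
    name,
    gaussian_blur = clip8(gaussian_blur(img, par)),
    average_blur = {
      k <- if (par < 2) 1L else 3L   # odd kernel in {1, 3}
      if (k == 1L) clip8(img) else clip8(box_blur(img, k))
    },
    additive_gaussian_noise =
      clip8(img + stats::rnorm(length(img), 0, max(par, 1e-12))),
    salt_and_pepper = {
      m <- stats::runif(length(img)) < par
      v <- ifelse(stats::runif(length(img)) < 0.5, 0L, 255L)
      out <- img; out[m] <- v[m]; clip8(out)
    },
    salt = {
      m <- stats::runif(length(img)) < par
      out <- img; out[m] <- 255L; clip8(out)
    },
    pepper = {
      m <- stats::runif(length(img)) < par
      out <- img; out[m] <- 0L; clip8(out)
    },
    coarse_dropout = {
      gh <- max(1L, round(nrow(img) * 0.9))
      gw <- max(1L, round(ncol(img) * 0.9))
      mask <- matrix(stats::runif(gh * gw) < par, gh, gw)
      up <- mask[pmin(gh, ceiling(seq_len(nrow(img)) * gh / nrow(img))),
                 pmin(gw, ceiling(seq_len(ncol(img)) * gw / ncol(img))),
                 drop = FALSE]
      out <- img; out[up] <- 0L; clip8(out)
    },
    gamma_contrast = clip8(((img / 255)^par) * 255),
    sharpen = {
      # 3x3 kernel [[-1..],[.., 8 + lightness, ..]] blended with identity
      light <- 1.0
      blur <- box_blur(img, 3L)
      sharpened <- (9 + light) * img - 9 * blur
      clip8((1 - par) * img + par * sharpened)
    },
    enhance_brightness = clip8(img * par),
    stop("unknown augmentation: ", name, call. = FALSE)
  )
}

# Separable Gaussian blur, reflected edges.
gaussian_blur <- function(img, sigma) {
  if (sigma < 1e-3) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv_sep(img, k)
}

box_blur <- function(img, k) {
  conv_sep(img, rep(1 / k, k))
}

# Separable convolution via shifted sums with edge replication.
conv_sep <- function(img, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(img); m <- ncol(img)
  pad_idx <- function(i, len) pmin(pmax(i, 1L), len)
  out <- matrix(0, n, m)
  for (j in seq_along(k)) {
    out <- out + k[j] * img[pad_idx(seq_len(n) + j - 1L - r, n), , drop = FALSE]
  }
  out2 <- matrix(0, n, m)
  for (j in seq_along(k)) {
    out2 <- out2 + k[j] * out[, pad_idx(seq_len(m) + j - 1L - r, m),
                              drop = FALSE]
  }
  out2
}

#' Normalize an 8-bit image to [-1, 1]
#'
#' @param image 8-bit matrix or array.
#' @return Numeric array: `pixel / 127.5 - 1` elementwise.
#' @examples
#' normalize_image(matrix(c(0, 255), 1))   # -1, 1
#' @export
normalize_image <- function(image) {
  check_image8(as.matrix(image))
  image / 127.5 - 1
}

#' Write an 8-bit depiction as PNG
#'
#' @param image Integer matrix of gray values (0-255).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depiction <- function(image, path) {
  check_image8(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read a grayscale PNG back as an 8-bit matrix
#'
#' @param path PNG file path.
#' @return Integer matrix of gray values (0-255).
#' @export
read_depiction <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
}
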