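#' Parameters of the synthetic four-chamber phantom
#'
#' The phantom emulates the geometry a hinge-point detector relies on in an
#' apical four-chamber echocardiographic view: four dark blood-filled
#' chambers separated by bright tissue walls, an atrioventricular (annulus)
#' wall interrupted by the open mitral valve, and multiplicative speckle
#' noise. The two endpoints of the valve gap are the ground-truth hinge
#' points (the wall pixels immediately adjacent to the gap).
#'
#' @param image_height,image_width Frame size in pixels (at least 64).
#' @param wall_intensity Gray level of tissue walls, in `[0, 255]`; must
#'   exceed `chamber_intensity`.
#' @param chamber_intensity Gray level of the chamber interiors.
#' @param wall_thickness Wall thickness in pixels.
#' @param annulus_gap Width of the valve opening carved into the annulus
#'   wall, in pixels.
#' @param speckle_shape Shape parameter of the mean-one Gamma multiplier
#'   used as speckle noise. Small values give heavy speckle; `Inf` disables
#'   noise. The phantom's wall/chamber contrast survives (in the mean) for
#'   any `speckle_shape >= 1`, the documented floor.
#' @param jitter_px Half-width of the uniform integer jitter applied to the
#'   valve-gap centre (rows and columns independently) per frame.
#' @param pixel_spacing_mm Physical pixel spacing in millimetres.
#' @param seed Integer seed; a given `(params, seed)` pair is
#'   bit-reproducible.
#'
#' @return An object of class `phantom_params`.
#' @seealso [generate_frame()], [generate_dataset()]
#' @export
phantom_params <- function(image_height = 128L, image_width = 128L,
                           wall_intensity = 200, chamber_intensity = 30,
                           wall_thickness = 5L, annulus_gap = 24L,
                           speckle_shape = 8, jitter_px = 6L,
                           pixel_spacing_mm = 0.7, seed = 1L) {
  p <- list(image_height = as.integer(image_height),
            image_width = as.integer(image_width),
            wall_intensity = wall_intensity,
            chamber_intensity = chamber_intensity,
            wall_thickness = as.integer(wall_thickness),
            annulus_gap = as.integer(annulus_gap),
            speckle_shape = speckle_shape,
            jitter_px = as.integer(jitter_px),
            pixel_spacing_mm = pixel_spacing_mm,
            seed = as.integer(seed))
  assert_that(p$image_height >= 64L && p$image_width >= 64L,
              "phantom dimensions must be at least 64x64")
  assert_that(p$wall_intensity > p$chamber_intensity,
              "wall_intensity must exceed chamber_intensity")
  assert_that(p$wall_intensity <= 255 && p$chamber_intensity >= 0,
              "intensities must lie in [0, 255]")
  assert_that(p$wall_thickness >= 1L && p$annulus_gap >= 2L,
              "wall_thickness must be >= 1 and annulus_gap >= 2")
  assert_that(p$speckle_shape > 0, "speckle_shape must be positive")
  assert_that(p$jitter_px >= 0L, "jitter_px must be nonnegative")
  assert_that(p$pixel_spacing_mm > 0, "pixel_spacing_mm must be positive")
  structure(p, class = "phantom_params")
}

#' Construct a grayscale frame object
#'
#' A `gray_frame` wraps a numeric pixel matrix (gray values in `[0, 255]`,
#' rows increasing downward), the physical pixel spacing, and optionally the
#' ground-truth hinge points.
#'
#' @param pixels Numeric matrix of gray values in `[0, 255]`.
#' @param pixel_spacing_mm Pixel spacing in millimetres.
#' @param truth Optional 2x2 matrix with rows `septal` and `lateral` and
#'   columns `(row, col)`, 1-based, inside the image.
#' @param frame_id Identifier string.
#' @return An object of class `gray_frame`.
#' @export
gray_frame <- function(pixels, pixel_spacing_mm = 1, truth = NULL,
                       frame_id = "frame") {
  assert_that(is.matrix(pixels) && is.numeric(pixels),
              "pixels must be a numeric matrix")
  assert_that(all(is.finite(pixels)) && min(pixels) >= 0 && max(pixels) <= 255,
              "pixel values must be finite and within [0, 255]")
  if (!is.null(truth)) {
    truth <- as.matrix(truth)
    assert_that(all(dim(truth) == c(2L, 2L)), "truth must be a 2x2 matrix")
    dimnames(truth) <- list(c("septal", "lateral"), c("row", "col"))
    inb <- truth[, 1] >= 1 & truth[, 1] <= nrow(pixels) &
      truth[, 2] >= 1 & truth[, 2] <= ncol(pixels)
    assert_that(all(inb), "truth points must lie inside the image")
  }
  structure(list(pixels = pixels, pixel_spacing_mm = pixel_spacing_mm,
                 truth = truth, frame_id = frame_id),
            class = "gray_frame")
}

#' @export
print.gray_frame <- function(x, ...) {
  cat(sprintf("<gray_frame '%s': %d x %d px, %.3g mm/px, truth %s>\n",
              x$frame_id, nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing_mm,
              if (is.null(x$truth)) "absent" else "present"))
  invisible(x)
}

# Deterministic phantom geometry for a given gap centre. Returns the
# noiseless pixel matrix, the truth points and the wall mask.
phantom_geometry <- function(params, gap_row, gap_col) {
  h <- params$image_height; w <- params$image_width
  t2 <- params$wall_thickness %/% 2L
  px <- matrix(params$chamber_intensity, h, w)

  wall <- matrix(FALSE, h, w)
  # outer cardiac border
  wall[1:params$wall_thickness, ] <- TRUE
  wall[(h - params$wall_thickness + 1L):h, ] <- TRUE
  wall[, 1:params$wall_thickness] <- TRUE
  wall[, (w - params$wall_thickness + 1L):w] <- TRUE
  # interatrial/interventricular septum down the middle
  sep_c <- w %/% 2L
  wall[, clamp((sep_c - t2):(sep_c + t2), 1L, w)] <- TRUE
  # atrioventricular (annulus) wall across the frame
  ann_rows <- clamp((gap_row - t2):(gap_row + t2), 1L, h)
  wall[ann_rows, ] <- TRUE
  px[wall] <- params$wall_intensity

  # carve the open mitral valve: a gap in the annulus wall left of the
  # lateral free wall, right of the septum
  half_gap <- params$annulus_gap %/% 2L
  gap_cols <- (gap_col - half_gap):(gap_col + half_gap - 1L +
                                      params$annulus_gap %% 2L)
  assert_that(min(gap_cols) > sep_c + t2 + 1L &&
                max(gap_cols) < w - params$wall_thickness,
              "annulus gap does not fit between septum and free wall")
  px[ann_rows, gap_cols] <- params$chamber_intensity
  wall[ann_rows, gap_cols] <- FALSE

  truth <- rbind(septal = c(gap_row, min(gap_cols) - 1L),
                 lateral = c(gap_row, max(gap_cols) + 1L))
  colnames(truth) <- c("row", "col")
  list(pixels = px, truth = truth, wall = wall)
}

# Multiplicative mean-one Gamma speckle, clipped to [0, 255].
apply_speckle <- function(px, shape) {
  if (is.infinite(shape)) return(px)
  mult <- matrix(stats::rgamma(length(px), shape = shape, rate = shape),
                 nrow(px), ncol(px))
  clamp(px * mult, 0, 255)
}

#' Generate one synthetic four-chamber frame
#'
#' Draws the phantom geometry (chambers, walls, annulus line with a valve
#' gap), jitters the gap position, applies multiplicative speckle and
#' records the two gap endpoints as ground truth. The same
#' `params` (including `params$seed`) always yield a pixelwise-identical
#' frame.
#'
#' @param params A [phantom_params()] object.
#' @param frame_id Identifier stored in the frame.
#' @return A [gray_frame()] with `truth` set.
#' @examples
#' fr <- generate_frame(phantom_params(seed = 1))
#' fr$truth
#' @export
generate_frame <- function(params = phantom_params(), frame_id = "frame001") {
  if (!inherits(params, "phantom_params")) params <- do.call(phantom_params, params)
  h <- params$image_height; w <- params$image_width
  withr::with_seed(params$seed, {
    jr <- if (params$jitter_px > 0)
      sample(-params$jitter_px:params$jitter_px, 2L, replace = TRUE)
    else c(0L, 0L)
    gap_row <- as.integer(round(0.55 * h)) + jr[1]
    gap_col <- as.integer(round(0.72 * w)) + jr[2]
    geo <- phantom_geometry(params, gap_row, gap_col)
    px <- apply_speckle(geo$pixels, params$speckle_shape)
  })
  fr <- gray_frame(px, params$pixel_spacing_mm, geo$truth, frame_id)
  fr$wall_mask <- geo$wall
  fr
}

#' Generate a reproducible phantom dataset
#'
#' Produces `n_frames` frames whose valve-gap positions are independently
#' jittered; each frame's seed is derived deterministically from `seed`.
#'
#' @param n_frames Number of frames (>= 1).
#' @param params A [phantom_params()] object (its `seed` field is ignored
#'   in favour of the derived per-frame seeds).
#' @param seed Master seed for the dataset.
#' @return A list of [gray_frame()] objects.
#' @export
generate_dataset <- function(n_frames, params = phantom_params(), seed = 1L) {
  assert_that(n_frames >= 1, "n_frames must be >= 1")
  seeds <- derive_seeds(seed, n_frames)
  lapply(seq_len(n_frames), function(i) {
    pi <- params
    pi$seed <- seeds[i]
    generate_frame(pi, frame_id = sprintf("frame%03d", i))
  })
}

#' Write a phantom dataset to disk
#'
#' Frames are stored as 8-bit grayscale PNG, ground truth as a CSV with
#' columns `frame_id, point_label, row, col` (1-based pixel coordinates),
#' and a JSON manifest records the pixel spacing, seed and parameters.
#'
#' @param frames List of [gray_frame()] objects.
#' @param dir Output directory (created if missing).
#' @param params,seed Optional provenance stored in the manifest.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(frames, dir, params = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth_rows <- list()
  for (fr in frames) {
    png::writePNG(fr$pixels / 255, file.path(dir, paste0(fr$frame_id, ".png")))
    if (!is.null(fr$truth)) {
      truth_rows[[fr$frame_id]] <- data.frame(
        frame_id = fr$frame_id,
        point_label = rownames(fr$truth),
        row = fr$truth[, "row"], col = fr$truth[, "col"])
    }
  }
  truth <- do.call(rbind, truth_rows)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  manifest <- list(n_frames = length(frames),
                   pixel_spacing_mm = frames[[1]]$pixel_spacing_mm,
                   seed = seed,
                   params = if (!is.null(params)) unclass(params))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a phantom dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A list of [gray_frame()] objects with truth attached where
#'   present in `truth.csv`.
#' @export
read_dataset <- function(dir) {
  assert_that(dir.exists(dir), sprintf("dataset directory '%s' not found", dir))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  spacing <- manifest$pixel_spacing_mm
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path))
    utils::read.csv(truth_path, stringsAsFactors = FALSE)
  pngs <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  lapply(pngs, function(path) {
    id <- sub("\\.png$", "", basename(path))
    px <- round(png::readPNG(path) * 255)
    if (length(dim(px)) == 3L) px <- px[, , 1]
    tr <- NULL
    if (!is.null(truth) && id %in% truth$frame_id) {
      sub <- truth[truth$frame_id == id, ]
      tr <- rbind(septal = unlist(sub[sub$point_label == "septal", c("row", "col")]),
                  lateral = unlist(sub[sub$point_label == "lateral", c("row", "col")]))
    }
    gray_frame(px, spacing, tr, id)
  })
}
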