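#' Per-axis landmark error statistics in millimetres
#'
#' Compares predicted hinge points against the ground-truth annotations,
#' matching septal to septal and lateral to lateral (both sides use the
#' leftmost-is-septal column convention). The x-axis is the image column
#' and the y-axis the image row; per-axis errors are absolute pixel
#' differences scaled by the pixel spacing, summarised by their mean and
#' population variance. Frames without a detection are counted as failures
#' and excluded from the statistics.
#'
#' @param predicted List of `hinge_result` objects, one per frame.
#' @param frames The corresponding annotated [gray_frame()] list.
#' @param pixel_spacing_mm Pixel spacing; defaults to the frames' spacing.
#' @return An object of class `error_table`: per landmark x axis mean
#'   absolute error (mm) and population variance (mm^2), Euclidean error
#'   summaries per landmark, `n_frames`, `n_failures`.
#' @export
landmark_errors <- function(predicted, frames, pixel_spacing_mm = NULL) {
  assert_that(length(predicted) == length(frames),
              "one prediction per annotated frame is required")
  if (is.null(pixel_spacing_mm))
    pixel_spacing_mm <- frames[[1]]$pixel_spacing_mm
  assert_that(pixel_spacing_mm > 0, "pixel spacing must be positive")
  rows <- list()
  for (k in seq_along(frames)) {
    fr <- frames[[k]]; pr <- predicted[[k]]
    assert_that(!is.null(fr$truth),
                sprintf("frame '%s' has no truth annotation", fr$frame_id))
    if (!isTRUE(pr$detected)) next
    for (lm in c("septal", "lateral")) {
      d <- (pr[[lm]] - fr$truth[lm, ]) * pixel_spacing_mm
      rows[[length(rows) + 1L]] <- data.frame(
        landmark = lm, err_x = abs(d[2]), err_y = abs(d[1]),
        err_euclid = sqrt(sum(d^2)))
    }
  }
  errs <- if (length(rows) > 0) do.call(rbind, rows)
          else data.frame(landmark = character(0), err_x = numeric(0),
                          err_y = numeric(0), err_euclid = numeric(0))
  pop_var <- function(x) if (length(x) == 0) NA_real_ else mean((x - mean(x))^2)
  stats <- do.call(rbind, lapply(c("septal", "lateral"), function(lm) {
    e <- errs[errs$landmark == lm, ]
    data.frame(landmark = lm, axis = c("x", "y"),
               mean_mm = c(mean(e$err_x), mean(e$err_y)),
               var_mm2 = c(pop_var(e$err_x), pop_var(e$err_y)))
  }))
  euclid <- do.call(rbind, lapply(c("septal", "lateral"), function(lm) {
    e <- errs[errs$landmark == lm, ]
    data.frame(landmark = lm, mean_mm = mean(e$err_euclid),
               median_mm = stats::median(e$err_euclid))
  }))
  structure(list(stats = stats, euclid = euclid,
                 n_frames = length(frames),
                 n_failures = sum(!vapply(predicted, function(p)
                   isTRUE(p$detected), logical(1))),
                 pixel_spacing_mm = pixel_spacing_mm),
            class = "error_table")
}

#' @export
print.error_table <- function(x, ...) {
  cat(summary_report(x), sep = "\n")
  invisible(x)
}

#' Render an error table as text, CSV or JSON
#'
#' @param table An [landmark_errors()] `error_table`.
#' @param config Optional configuration snapshot echoed into the report.
#' @param format `"text"`, `"csv"` or `"json"`.
#' @param path Optional output file; the report is also returned.
#' @return Character vector of report lines (invisibly when `path` is
#'   given). JSON reports round-trip through [read_error_report()].
#' @export
summary_report <- function(table, config = NULL,
                           format = c("text", "csv", "json"), path = NULL) {
  format <- match.arg(format)
  out <- switch(format,
    text = {
      w <- function(lm, ax, col) {
        table$stats[table$stats$landmark == lm & table$stats$axis == ax, col]
      }
      c("Hinge-point localization errors (mm)",
        sprintf("frames: %d  failures: %d  spacing: %g mm/px",
                table$n_frames, table$n_failures, table$pixel_spacing_mm),
        sprintf("%-8s %-6s %12s %14s", "landmark", "axis", "mean_mm",
                "variance_mm2"),
        unlist(lapply(c("septal", "lateral"), function(lm)
          sapply(c("x", "y"), function(ax)
            sprintf("%-8s %-6s %12.6f %14.6f", lm, ax,
                    w(lm, ax, "mean_mm"), w(lm, ax, "var_mm2"))))),
        sprintf("euclidean mean (mm): septal %.6f, lateral %.6f",
                table$euclid$mean_mm[1], table$euclid$mean_mm[2]))
    },
    csv = {
      con <- textConnection("csvtxt", "w", local = TRUE)
      utils::write.csv(table$stats, con, row.names = FALSE)
      close(con)
      csvtxt
    },
    json = {
      jsonlite::toJSON(list(schema = "error-report-v1",
                            stats = table$stats, euclid = table$euclid,
                            n_frames = table$n_frames,
                            n_failures = table$n_failures,
                            pixel_spacing_mm = table$pixel_spacing_mm,
                            config = config),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
    })
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Read a JSON error report back into an `error_table`
#' @param path Path to a JSON report written by [summary_report()].
#' @return An `error_table` equal (up to serialization) to the original.
#' @export
read_error_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  assert_that(identical(obj$schema, "error-report-v1"),
              "unrecognised report schema")
  structure(list(stats = obj$stats, euclid = obj$euclid,
                 n_frames = obj$n_frames, n_failures = obj$n_failures,
                 pixel_spacing_mm = obj$pixel_spacing_mm),
            class = "error_table")
}
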