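#' Read and write counting-frame tables
#'
#' CSV with columns `x`, `y` (site coordinates, mm), `frame_side` (um),
#' `count`; optional `species`, `retina_id`, `eye_side` columns are carried
#' through.
#'
#' @param path CSV path.
#' @param frames A [counting_frames()] table.
#' @return `read_counting_frames` returns a `counting_frames` data frame.
#' @export
read_counting_frames <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "frame_side", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  nf <- if ("n_frames" %in% names(df)) df$n_frames else 1L
  out <- counting_frames(df$x, df$y, df$frame_side, df$count, nf)
  for (extra in intersect(c("species", "retina_id", "eye_side"), names(df)))
    out[[extra]] <- df[[extra]]
  out
}

#' @rdname read_counting_frames
#' @export
write_counting_frames <- function(frames, path) {
  utils::write.csv(as.data.frame(frames), path, row.names = FALSE)
  invisible(path)
}

#' Read a retinal outline polygon
#'
#' CSV with columns `x`, `y` in mm (vertices in order, closed implicitly);
#' an optional `retina_id` column allows several outlines in one file.
#'
#' @param path CSV path.
#' @param retina_id Optional id to select when the file holds several
#'   outlines.
#' @return Data frame with columns `x`, `y`.
#' @export
read_outline <- function(path, retina_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df))) stop("outline needs columns x, y")
  if (!is.null(retina_id) && "retina_id" %in% names(df))
    df <- df[df$retina_id == retina_id, , drop = FALSE]
  if (!nrow(df)) stop("no outline vertices", if (!is.null(retina_id))
    paste0(" for retina_id ", retina_id))
  df[, c("x", "y")]
}

#' Export a density field as a dense grid CSV plus a JSON header
#'
#' The CSV holds the density matrix (rows = x index, columns = y index,
#' `NA` for masked cells); the JSON header records the grid origin, step,
#' dimensions and the outline polygon.
#'
#' @param field A `density_field`.
#' @param csv_path,json_path Output paths.
#' @export
write_density_field <- function(field, csv_path, json_path) {
  utils::write.table(field$z, csv_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  hdr <- list(origin = c(field$x[1], field$y[1]), step = field$step,
              nx = length(field$x), ny = length(field$y),
              outline = field$outline)
  jsonlite::write_json(hdr, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Read a density field written by [write_density_field()]
#'
#' @param csv_path,json_path Paths written by [write_density_field()].
#' @return A `density_field`.
#' @export
read_density_field <- function(csv_path, json_path) {
  hdr <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  z <- as.matrix(utils::read.table(csv_path, sep = ",", header = FALSE))
  dimnames(z) <- NULL
  x <- hdr$origin[1] + hdr$step * (seq_len(hdr$nx) - 1L)
  y <- hdr$origin[2] + hdr$step * (seq_len(hdr$ny) - 1L)
  density_field(x = x, y = y, z = z,
                outline = as.data.frame(hdr$outline), step = hdr$step)
}

#' Export isodensity contours as CSV polylines
#'
#' One row per vertex with columns `level`, `piece`, `x`, `y`.
#'
#' @param contours Output of [isodensity_contours()].
#' @param path CSV path.
#' @export
write_contours <- function(contours, path) {
  rows <- list()
  for (lv in names(contours)) {
    pieces <- contours[[lv]]
    for (i in seq_along(pieces))
      rows[[length(rows) + 1L]] <-
        data.frame(level = as.numeric(lv), piece = i,
                   x = pieces[[i]]$x, y = pieces[[i]]$y)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(level = numeric(0), piece = integer(0),
               x = numeric(0), y = numeric(0))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a species trait table
#'
#' CSV with columns `species`, `head_rate` (movements/min), `eye_movement`
#' (degrees), `axial_length` (mm).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "head_rate", "eye_movement", "axial_length")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$species)) stop("duplicate species in trait table")
  df
}
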