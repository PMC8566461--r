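# File I/O for the package's external formats: ROI JSON/CSV, 8/16-bit TIFF
# images (single- or multi-page), masks, and the tidy CSV tables.
#
# Images are represented internally as numeric matrices of photon counts
# ([row, col] = [y+1, x+1]); TIFFs are written as 16-bit with counts stored
# in 0..65535.

#' Read cell ROIs from JSON
#'
#' One record per cell with fields `cell` and `nucleus` (each an object with
#' numeric arrays `x` and `y`) and optional `pixel_size` and `cell_id`.
#'
#' @param path JSON file path.
#' @return named list of [cell_roi()] objects.
#' @export
read_roi_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- lapply(recs, function(r) {
    cell_roi(cbind(x = unlist(r$cell$x), y = unlist(r$cell$y)),
             cbind(x = unlist(r$nucleus$x), y = unlist(r$nucleus$y)),
             pixel_size = if (is.null(r$pixel_size)) 1 else r$pixel_size)
  })
  names(out) <- vapply(seq_along(recs), function(i) {
    id <- recs[[i]]$cell_id
    if (is.null(id)) sprintf("cell_%03d", i) else as.character(id)
  }, "")
  out
}

#' Write cell ROIs to JSON
#' @param rois named list of [cell_roi()] objects.
#' @param path output path.
#' @export
write_roi_json <- function(rois, path) {
  recs <- lapply(names(rois), function(id) {
    r <- rois[[id]]
    list(cell_id = id,
         pixel_size = r$pixel_size,
         cell = list(x = unname(r$cell_outline[, 1]), y = unname(r$cell_outline[, 2])),
         nucleus = list(x = unname(r$nucleus_outline[, 1]), y = unname(r$nucleus_outline[, 2])))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read cell ROIs from long-format CSV
#'
#' Columns: `cell_id`, `structure` (`cell` or `nucleus`), `vertex_index`,
#' `x`, `y`.
#' @param path CSV file path.
#' @param pixel_size micrometres per pixel applied to every ROI.
#' @return named list of [cell_roi()] objects.
#' @export
read_roi_csv <- function(path, pixel_size = 1) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "structure", "vertex_index", "x", "y")
  if (!all(need %in% names(df)))
    trk_stop("bad-config", paste("ROI CSV must have columns", paste(need, collapse = ", ")))
  out <- lapply(split(df, df$cell_id), function(d) {
    poly <- function(s) {
      dd <- d[d$structure == s, ]
      dd <- dd[order(dd$vertex_index), ]
      cbind(x = dd$x, y = dd$y)
    }
    cell_roi(poly("cell"), poly("nucleus"), pixel_size = pixel_size)
  })
  out
}

#' Read an intensity image (or stack) from TIFF
#'
#' @param path TIFF path; multi-page files return a list of matrices.
#' @return numeric matrix of counts, or list of matrices for a stack.
#' @export
read_image_tiff <- function(path) {
  if (!file.exists(path)) trk_stop("missing-input", path)
  img <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  img <- lapply(img, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  if (length(img) == 1L) img[[1]] else img
}

#' Write an intensity image (or stack) as 16-bit TIFF
#'
#' Counts are rounded and clamped to 0..65535.
#' @param img numeric matrix or list of matrices (pages).
#' @param path output path.
#' @export
write_image_tiff <- function(img, path) {
  pages <- if (is.matrix(img)) list(img) else img
  pages <- lapply(pages, function(m) {
    m <- round(m)
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Export a boolean mask as an 8-bit TIFF (0/255)
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask)), path,
                  bits.per.sample = 8, compression = "none")
  invisible(path)
}

#' Read a track table CSV
#'
#' Columns `track_id`, `frame`, `t`, `x`, `y` (extra columns are kept).
#' @param path CSV path.
#' @return data.frame ordered by track and time.
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("track_id", "t", "x", "y")
  if (!all(need %in% names(df)))
    trk_stop("bad-config", paste("track CSV must have columns", paste(need, collapse = ", ")))
  df[order(df$track_id, df$t), ]
}

#' Read an in-cell ELISA plate table CSV
#'
#' Columns `well`, `condition`, `time_min`, `signal`, `bca_signal`, `role`
#' with `role` one of `sample`, `surface_total`, `strip_control`.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("well", "condition", "time_min", "signal", "bca_signal", "role")
  if (!all(need %in% names(df)))
    trk_stop("bad-config", paste("plate CSV must have columns", paste(need, collapse = ", ")))
  bad <- setdiff(unique(df$role), c("sample", "surface_total", "strip_control"))
  if (length(bad)) trk_stop("bad-config", paste("unknown plate roles:", paste(bad, collapse = ", ")))
  df
}

# deterministic CSV writer (fixed eol/quoting so byte-identity is meaningful)
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(path)
}
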