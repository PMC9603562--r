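#' Write a grayscale image as plain-text PGM (P2)
#'
#' Intensities in `[0, 1]` are scaled to `maxval`. Plain PGM keeps synthetic
#' fixtures human-readable and dependency-free; PNG is supported through the
#' optional \pkg{png} package.
#'
#' @param pixels Numeric matrix in `[0, 1]` (row 1 = top of image).
#' @param path Output path.
#' @param maxval Maximum gray value (default 255).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(pixels, path, maxval = 255L) {
  cf_assert(is.matrix(pixels) && all(is.finite(pixels)), "cf_invalid_input",
            "pixels must be a finite numeric matrix")
  v <- round(pmin(pmax(pixels, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(v), nrow(v)),
               sprintf("%d", maxval)), con)
  # row-major, as PGM expects
  writeLines(apply(v, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read a grayscale image (PGM or PNG)
#'
#' Reads plain (P2) and binary (P5, 8-bit) PGM natively; PNG when the
#' \pkg{png} package is installed. Returns intensities scaled to `[0, 1]`.
#'
#' @param path Image file (.pgm or .png).
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  cf_assert(file.exists(path), "cf_invalid_input",
            paste("no such image file:", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    cf_assert(requireNamespace("png", quietly = TRUE), "cf_invalid_input",
              "reading PNG requires the 'png' package")
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1]
    return(a)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  cf_assert(magic %in% c("P2", "P5"), "cf_invalid_input",
            paste("unsupported image format in", path))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) break
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) break else next
      }
      tok <- paste0(tok, ch)
    }
    tok
  }
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  cf_assert(is.finite(w) && is.finite(h) && w > 0 && h > 0 && maxval > 0,
            "cf_invalid_input", "malformed PGM header")
  n <- w * h
  if (magic == "P5") {
    cf_assert(maxval < 256L, "cf_invalid_input", "only 8-bit P5 supported")
    raw <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
    vals <- raw
  } else {
    vals <- integer(0)
    while (length(vals) < n) {
      chunk <- scan(con, what = integer(), n = n - length(vals), quiet = TRUE)
      if (length(chunk) == 0L) break
      vals <- c(vals, chunk)
    }
  }
  cf_assert(length(vals) == n, "cf_invalid_input", "truncated PGM data")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Read an image-sequence directory as a time-lapse stack
#'
#' Reads every `.pgm`/`.png` file in `dir` in lexicographic order and
#' returns a list of intensity matrices. Frame times follow the filename
#' index times the frame interval unless a `times.csv` (column `t_h`) sits
#' alongside the frames.
#'
#' @param dir Directory of frames.
#' @return `list(frames, times_h)`; `times_h` is `NULL` unless a
#'   `times.csv` is present.
#' @export
read_image_stack <- function(dir) {
  cf_assert(dir.exists(dir), "cf_invalid_input",
            paste("no such stack directory:", dir))
  files <- sort(list.files(dir, pattern = "\\.(pgm|png)$", ignore.case = TRUE,
                           full.names = TRUE))
  cf_assert(length(files) >= 1L, "cf_invalid_input",
            paste("no frames found in", dir))
  frames <- lapply(files, read_gray_image)
  times <- NULL
  tpath <- file.path(dir, "times.csv")
  if (file.exists(tpath)) {
    d <- utils::read.csv(tpath)
    cf_assert("t_h" %in% names(d) && nrow(d) == length(frames),
              "cf_invalid_input",
              "times.csv must have column t_h with one row per frame")
    times <- d$t_h
  }
  list(frames = frames, times_h = times)
}

#' Write a time-lapse stack as numbered PGM frames
#'
#' @param frames List of intensity matrices.
#' @param dir Output directory (created if missing).
#' @param times_h Optional frame times written to `times.csv`.
#' @return `dir`, invisibly.
#' @export
write_image_stack <- function(frames, dir, times_h = NULL) {
  cf_assert(is.list(frames) && length(frames) >= 1L, "cf_invalid_input",
            "frames must be a non-empty list")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  width <- max(5L, nchar(length(frames)))
  for (i in seq_along(frames)) {
    write_pgm(frames[[i]],
              file.path(dir, sprintf(paste0("frame_%0", width, "d.pgm"), i)))
  }
  if (!is.null(times_h)) {
    utils::write.csv(data.frame(t_h = times_h), file.path(dir, "times.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
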