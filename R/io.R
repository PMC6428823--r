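#' Read a grayscale image file
#'
#' Supported formats (chosen by extension):
#' * `.png` — 8-bit grayscale (RGB is averaged), tagged uint8 domain;
#' * `.pgm` — ASCII (P2) portable graymap; maxval <= 255 is read as uint8,
#'   larger maxval is interpreted as HU stored with the +1024 offset
#'   (pixel value - 1024 = HU), the package's plain-text HU persistence
#'   format;
#' * `.csv` — headerless numeric matrix, HU domain.
#'
#' Pixel spacing is not carried by these formats and comes from the
#' `spacing_mm` argument (or the pipeline configuration).
#'
#' @param path file path.
#' @param spacing_mm in-plane spacing assigned to the image, default 1.
#' @return a [gray_image()].
#' @export
read_image <- function(path, spacing_mm = 1) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                         c(1, 2), mean)
    gray_image(round(a * 255), "uint8", spacing_mm)
  } else if (ext == "pgm") {
    read_pgm(path, spacing_mm)
  } else if (ext == "csv") {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(m) <- NULL
    gray_image(m, "HU", spacing_mm)
  } else {
    stop("unsupported image format for ", path,
         " (expected .png, .pgm or .csv)", call. = FALSE)
  }
}

#' Write a grayscale image file
#'
#' uint8 images go to PNG or ASCII PGM; HU images go to ASCII PGM with the
#' +1024 offset (maxval 4096) or CSV. Logical masks are written as 0/255
#' PNG/PGM.
#'
#' @param image a [gray_image()] or logical mask matrix.
#' @param path destination; extension selects the format.
#' @export
write_image <- function(image, path) {
  if (is.logical(image)) {
    image <- gray_image(ifelse(image, 255, 0), "uint8")
  }
  stopifnot(inherits(image, "gray_image"))
  ext <- tolower(tools::file_ext(path))
  px <- as_plain_matrix(image)
  if (ext == "png") {
    if (image_domain(image) != "uint8") {
      stop("PNG output requires a uint8 image", call. = FALSE)
    }
    png::writePNG(px / 255, path)
  } else if (ext == "pgm") {
    if (image_domain(image) == "uint8") {
      write_pgm(round(px), 255L, path)
    } else {
      write_pgm(round(pmin(pmax(px + 1024, 0), 4096)), 4096L, path)
    }
  } else if (ext == "csv") {
    utils::write.table(px, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    stop("unsupported output format for ", path, call. = FALSE)
  }
  invisible(path)
}

read_pgm <- function(path, spacing_mm = 1) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (tok[1] != "P2") stop("only ASCII (P2) PGM is supported", call. = FALSE)
  dims <- as.integer(tok[2:3])          # width height
  maxval <- as.integer(tok[4])
  v <- as.numeric(tok[-(1:4)])
  if (length(v) != prod(dims)) stop("corrupt PGM: wrong pixel count",
                                    call. = FALSE)
  m <- matrix(v, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  if (maxval <= 255L) gray_image(m, "uint8", spacing_mm)
  else gray_image(m - 1024, "HU", spacing_mm)
}

write_pgm <- function(m, maxval, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
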