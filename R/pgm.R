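#' Read and write portable graymap (PGM) images
#'
#' 8-bit grayscale image I/O. `write_pgm()` emits binary (`P5`, compact) or
#' ASCII (`P2`, plain-text, diffable) portable graymaps; `read_pgm()` reads
#' both. PGM is used because it round-trips integer grayscale images exactly
#' and the ASCII variant is a plain-text format suitable for small fixtures.
#'
#' @param image integer matrix, values in 0..255; rows are image rows.
#' @param path file path.
#' @param format `"P5"` (binary) or `"P2"` (ASCII).
#' @return `read_pgm()` returns an integer matrix; `write_pgm()` returns
#'   `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".pgm")
#' m <- matrix(0:24, 5, 5)
#' write_pgm(m, p, format = "P2")
#' identical(read_pgm(p), matrix(as.integer(0:24), 5, 5))
#' @export
write_pgm <- function(image, path, format = c("P5", "P2")) {
  format <- match.arg(format)
  image <- round(image)
  if (any(image < 0 | image > 255))
    stop("image values must lie in 0..255")
  nr <- nrow(image); nc <- ncol(image)
  if (format == "P2") {
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(c("P2", paste(nc, nr), "255"), con)
    writeLines(apply(image, 1, paste, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(sprintf("P5\n%d %d\n255\n", nc, nr)), con)
    writeBin(as.raw(t(image)), con)
  }
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch) || !nzchar(ch)) break
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(tok)) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("not a P2/P5 PGM file: ", path)
  nc <- as.integer(read_token())
  nr <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (is.na(nc) || is.na(nr) || is.na(maxval) || maxval > 255)
    stop("unsupported PGM header in ", path)
  n <- nr * nc
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n))
  } else {
    vals <- integer(0)
    while (length(vals) < n) {
      chunk <- readLines(con, n = 64L)
      if (!length(chunk)) break
      chunk <- sub("#.*", "", chunk)
      vals <- c(vals, as.integer(unlist(strsplit(trimws(chunk), "[[:space:]]+"))))
    }
    vals <- vals[!is.na(vals)]
    if (length(vals) < n) stop("truncated P2 payload in ", path)
    vals <- vals[seq_len(n)]
  }
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}
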