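# Dataset interchange. Images are 8-bit Netpbm rasters: PPM (RGB) for
# images, PGM (gray, {0,255}) for masks; both the binary (P5/P6) and ASCII
# (P2/P3) variants are supported. Directory layout written and read:
#   {domain}/{split}/{images,masks}/NNNN.ppm|pgm    + manifest.json at root

#' Write / read 8-bit Netpbm images
#'
#' \code{write_pnm} writes an \code{H x W} matrix as PGM or an
#' \code{H x W x 3} array as PPM, scaling \code{[0,1]} values to 0..255.
#' \code{read_pnm} reads P2/P3/P5/P6 files back to \code{[0,1]} arrays.
#'
#' @param img matrix (gray) or \code{H x W x 3} array, values in [0,1].
#' @param path file path (conventionally .pgm for gray, .ppm for RGB).
#' @param ascii write the ASCII (P2/P3) variant instead of binary (P5/P6).
#' @return \code{read_pnm} returns the image array; \code{write_pnm} the
#'   path, invisibly.
#' @export
write_pnm <- function(img, path, ascii = FALSE) {
  gray <- is.null(dim(img)) || length(dim(img)) == 2L
  if (gray) img <- as.matrix(img)
  v <- as.integer(round(clamp(img, 0, 1) * 255))
  h <- nrow(img); w <- ncol(img)
  # Netpbm is row-major, channels interleaved
  ord <- if (gray) as.vector(t(matrix(v, h, w)))
  else as.vector(aperm(array(v, dim(img)), c(3, 2, 1)))
  magic <- if (gray) { if (ascii) "P2" else "P5" } else
    if (ascii) "P3" else "P6"
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n255\n", magic, w, h), con, eos = NULL)
  if (ascii) writeChar(paste(ord, collapse = "\n"), con, eos = NULL)
  else writeBin(as.raw(ord), con)
  invisible(path)
}

#' @rdname write_pnm
#' @export
read_pnm <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  tok <- function() { # whitespace/comment-aware token reader
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch)) stop("unexpected end of PNM header")
      if (ch == "#") repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!length(ch) || ch == "\n") break
      } else if (!grepl("^\\s$", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch) || grepl("^\\s$", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported Netpbm format: ", magic)
  w <- as.integer(tok()); h <- as.integer(tok())
  maxv <- as.integer(tok())
  gray <- magic %in% c("P2", "P5")
  npx <- h * w * if (gray) 1L else 3L
  v <- if (magic %in% c("P5", "P6"))
    as.integer(readBin(con, "raw", npx))
  else as.integer(scan(con, what = integer(), n = npx, quiet = TRUE))
  if (length(v) != npx) stop("truncated PNM payload in ", path)
  v <- v / maxv
  if (gray) t(matrix(v, w, h))
  else aperm(array(v, c(3, w, h)), c(3, 2, 1))
}

#' Write a dataset (or two-domain benchmark) to disk
#'
#' Emits the \code{{domain}/{split}/{images,masks}/NNNN.ppm|pgm} layout plus
#' a \code{manifest.json} recording seed, geometry and style parameters.
#'
#' @param x a \code{nucadapt_dataset} or the two-element benchmark list from
#'   [make_benchmark()].
#' @param root output directory (created if needed).
#' @param ascii write ASCII Netpbm variants.
#' @return invisibly, \code{root}.
#' @export
write_dataset <- function(x, root, ascii = FALSE) {
  if (!inherits(x, "nucadapt_dataset") && !is.null(x$source)) {
    write_dataset(x$source, root, ascii)
    write_dataset(x$target, root, ascii)
    manifest <- list(seed = x$seed,
                     domains = c(x$source$domain, x$target$domain),
                     geometry = unclass(x$source$params),
                     style_source = unclass(x$source$style),
                     style_target = unclass(x$target$style))
    jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(root))
  }
  stopifnot(inherits(x, "nucadapt_dataset"))
  for (sp in c("train", "val", "test")) {
    di <- file.path(root, x$domain, sp, "images")
    dm <- file.path(root, x$domain, sp, "masks")
    dir.create(di, recursive = TRUE, showWarnings = FALSE)
    dir.create(dm, recursive = TRUE, showWarnings = FALSE)
    imgs <- x[[sp]]$images; masks <- x[[sp]]$masks
    for (i in seq_len(batch_size(as_batch(imgs)))) {
      write_pnm(imgs[, , , i], file.path(di, sprintf("%04d.ppm", i)), ascii)
      write_pnm(masks[, , 1, i], file.path(dm, sprintf("%04d.pgm", i)),
                ascii)
    }
  }
  invisible(root)
}

#' Load a dataset from the on-disk layout
#'
#' Reads one domain directory (as written by [write_dataset()], or user data
#' arranged the same way) back into a \code{nucadapt_dataset}. Images are
#' scaled to \code{[0,1]}; masks are binarized at 128/255. Files are paired
#' in lexicographic order, which is also the deterministic dataset order.
#'
#' @param root path to a domain directory (containing \code{train/val/test}).
#' @param labeled if \code{TRUE}, every image must have a mask; if
#'   \code{FALSE}, masks are ignored even when present.
#' @param domain domain id stored on the result (default: directory name).
#' @return a \code{nucadapt_dataset}.
#' @export
load_dataset <- function(root, labeled = TRUE, domain = basename(root)) {
  out <- list()
  for (sp in c("train", "val", "test")) {
    di <- file.path(root, sp, "images")
    if (!dir.exists(di)) stop("missing split directory: ", di)
    files <- sort(list.files(di, full.names = TRUE))
    if (!length(files)) stop("no images under ", di)
    imgs <- NULL
    masks <- NULL
    for (i in seq_along(files)) {
      im <- read_pnm(files[i])
      if (is.null(imgs))
        imgs <- array(0, c(dim(im)[1], dim(im)[2], 3, length(files)))
      if (!identical(dim(im)[1:2], dim(imgs)[1:2]))
        stop("inconsistent image sizes under ", di)
      imgs[, , , i] <- im
      if (labeled) {
        mf <- file.path(root, sp, "masks",
                        sub("\\.[^.]+$", ".pgm", basename(files[i])))
        if (!file.exists(mf))
          stop("labeled split but mask missing for ", basename(files[i]))
        mk <- read_pnm(mf)
        if (!identical(dim(mk), dim(imgs)[1:2]))
          stop("image/mask size mismatch for ", basename(files[i]))
        if (is.null(masks))
          masks <- array(0L, c(dim(mk), 1, length(files)))
        masks[, , 1, i] <- (mk >= 128 / 255) * 1L
      }
    }
    out[[sp]] <- list(images = imgs, masks = masks)
  }
  n <- sum(vapply(out, function(s) batch_size(s$images), numeric(1)))
  structure(c(out, list(domain = domain, n = n,
                        params = list(size = dim(out$train$images)[1]))),
            class = "nucadapt_dataset")
}
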