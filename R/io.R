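## Volume I/O: NIfTI (via RNifti), NRRD (minimal built-in reader/writer:
## no installed R package reads NRRD) and a plain-text fixture format so
## tests and synthetic cohorts need no imaging dependency.

.detectFormat <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.nrrd$", path)) "nrrd"
  else if (grepl("\\.(dgrid|txt)$", path)) "fixture"
  else stop("cannot infer volume format from extension: ", path)
}

#' Read a volumetric dose grid or ROI mask
#'
#' Supported formats: NIfTI (`.nii`/`.nii.gz`), NRRD (`.nrrd`, raw or text
#' encoding with diagonal orientation), and the package's plain-text fixture
#' format (`.dgrid`, see [writeVolume()]). Masks are binarized with a > 0.5
#' threshold on read.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"nifti"`, `"nrrd"`, `"fixture"`.
#' @param mask logical; read as a [RoiMask-class] instead of a
#'   [DoseGrid-class].
#' @return A [DoseGrid-class] or [RoiMask-class].
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, format = c("auto", "nifti", "nrrd", "fixture"),
                       mask = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .detectFormat(path)
  raw <- switch(format,
    nifti = .readNifti(path),
    nrrd = .readNrrd(path),
    fixture = .readFixture(path))
  if (length(dim(raw$values)) != 3L) stop("expected 3 axes, got a ",
                                          length(dim(raw$values)), "D volume")
  if (is.null(raw$spacing)) stop("volume is missing the 'spacing' field")
  if (mask)
    RoiMask(raw$values, raw$spacing, raw$origin, raw$orientation)
  else
    DoseGrid(raw$values, raw$spacing, raw$origin, raw$orientation)
}

#' Write a volumetric grid
#'
#' The fixture format (`.dgrid`) is a small self-describing text container:
#' a header (`dosiomics-grid 1`, `type`, `dims`, `spacing`, `origin`)
#' followed by all voxel values, x index fastest.
#'
#' @param x a [DoseGrid-class] or [RoiMask-class].
#' @param path output path; extension selects the format unless given.
#' @param format one of `"auto"`, `"nifti"`, `"nrrd"`, `"fixture"`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path, format = c("auto", "nifti", "nrrd", "fixture")) {
  format <- match.arg(format)
  if (format == "auto") format <- .detectFormat(path)
  switch(format,
    nifti = .writeNifti(x, path),
    nrrd = .writeNrrd(x, path),
    fixture = .writeFixture(x, path))
  invisible(path)
}

## ---- fixture format --------------------------------------------------------

.writeFixture <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- dim(x@values)
  writeLines(c("dosiomics-grid 1",
               paste("type", if (is(x, "RoiMask")) "mask" else "dose"),
               paste("dims", paste(d, collapse = " ")),
               paste("spacing", paste(format(x@spacing, digits = 17),
                                      collapse = " ")),
               paste("origin", paste(format(x@origin, digits = 17),
                                     collapse = " "))), con)
  writeLines(paste(format(as.vector(x@values), digits = 17, trim = TRUE),
                   collapse = " "), con)
}

.readFixture <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "dosiomics-grid"))
    stop("not a dosiomics fixture grid: ", path)
  hdr <- list()
  for (i in 2:5) {
    parts <- strsplit(lines[i], " +")[[1L]]
    hdr[[parts[1L]]] <- parts[-1L]
  }
  if (is.null(hdr$spacing)) stop("volume is missing the 'spacing' field")
  d <- as.integer(hdr$dims)
  vals <- as.numeric(strsplit(paste(lines[-(1:5)], collapse = " "),
                              " +")[[1L]])
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(d)) stop("fixture value count does not match dims")
  list(values = array(vals, d), spacing = as.numeric(hdr$spacing),
       origin = as.numeric(hdr$origin), orientation = "internal-xyz")
}

## ---- NIfTI -----------------------------------------------------------------

.readNifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(as.array(img)), dim(img))
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  xf <- RNifti::xform(img)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))   # column scales of the affine
  if (any(spacing <= 0)) spacing <- as.numeric(RNifti::pixdim(img)[1:3])
  orig <- as.numeric(xf[1:3, 4])
  list(values = arr, spacing = as.numeric(spacing), origin = orig,
       orientation = paste0("nifti:", RNifti::orientation(img)))
}

.writeNifti <- function(x, path) {
  img <- RNifti::asNifti(x@values)
  RNifti::pixdim(img) <- x@spacing
  xf <- diag(c(x@spacing, 1))
  xf[1:3, 4] <- x@origin
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
}

## ---- NRRD (minimal) --------------------------------------------------------

.readNrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr("^[^:]+", line))
    val <- sub("^[^:]+:=?\\s*", "", line)
    hdr[[tolower(trimws(kv))]] <- trimws(val)
  }
  dims <- as.integer(strsplit(hdr$sizes, " +")[[1L]])
  if (length(dims) != 3L) stop("expected 3 axes, got ", length(dims))
  spacing <- NULL
  if (!is.null(hdr$spacings)) {
    spacing <- as.numeric(strsplit(hdr$spacings, " +")[[1L]])
  } else if (!is.null(hdr[["space directions"]])) {
    vecs <- regmatches(hdr[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", hdr[["space directions"]]))[[1L]]
    m <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1L]]), numeric(3)))
    offdiag <- m; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-9))
      stop("only diagonal (axis-aligned) NRRD orientations are supported")
    spacing <- diag(m)
  }
  if (is.null(spacing)) stop("volume is missing the 'spacing' field")
  origin <- c(0, 0, 0)
  if (!is.null(hdr[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", hdr[["space origin"]]),
                                  ",")[[1L]])
  enc <- tolower(hdr$encoding)
  n <- prod(dims)
  if (enc %in% c("raw")) {
    type <- tolower(hdr$type)
    endian <- if (!is.null(hdr$endian) && hdr$endian == "big") "big" else "little"
    vals <- switch(type,
      "double" = readBin(con, "double", n, size = 8, endian = endian),
      "float" = readBin(con, "double", n, size = 4, endian = endian),
      "short" = readBin(con, "integer", n, size = 2, endian = endian),
      "int" = , "signed int" = readBin(con, "integer", n, size = 4,
                                       endian = endian),
      "uchar" = , "unsigned char" = as.numeric(readBin(con, "integer", n,
                                      size = 1, signed = FALSE)),
      stop("unsupported NRRD type: ", hdr$type))
  } else if (enc %in% c("text", "txt", "ascii")) {
    vals <- as.numeric(strsplit(paste(readLines(con), collapse = " "),
                                "[ \t]+")[[1L]])
    vals <- vals[!is.na(vals)]
  } else stop("unsupported NRRD encoding: ", hdr$encoding)
  if (length(vals) != n) stop("NRRD payload does not match 'sizes'")
  list(values = array(as.numeric(vals), dims), spacing = spacing,
       origin = origin, orientation = "nrrd:native")
}

.writeNrrd <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(x@values)
  hdr <- c("NRRD0004",
           "type: double",
           "dimension: 3",
           "space: left-posterior-superior",
           paste("sizes:", paste(d, collapse = " ")),
           paste("space directions:",
                 sprintf("(%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
                         x@spacing[1], x@spacing[2], x@spacing[3])),
           "kinds: domain domain domain",
           "endian: little",
           "encoding: raw",
           paste("space origin:", sprintf("(%.9g,%.9g,%.9g)",
                 x@origin[1], x@origin[2], x@origin[3])),
           "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(x@values), con, size = 8, endian = "little")
}
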