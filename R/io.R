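#' Read a 3D volume from NIfTI or NRRD
#'
#' Supported formats: NIfTI-1 (`.nii`, `.nii.gz`, via RNifti) and NRRD
#' (`.nrrd`, `.nhdr` with attached data; raw or gzip encoding, axis-aligned
#' `space directions`). The image must be a 3D scalar volume.
#'
#' @param path file path.
#' @param mask if `TRUE`, threshold the values at 0.5 and return a binary
#'   mask (use for segmentations stored as integer label maps).
#' @return an [image_grid] carrying voxels, spacing (mm) and origin (mm).
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path))
    stop("cannot read volume: no such file: ", path, call. = FALSE)
  ext <- tolower(path)
  g <- if (grepl("\\.(nrrd|nhdr)$", ext)) read_nrrd(path) else read_nifti(path)
  if (mask) g <- as_mask(g, 0.5)
  g
}

#' Write a 3D volume to NIfTI or NRRD
#'
#' Format is chosen from the file extension. Geometry (spacing, origin) is
#' stored so that `read_volume(write_volume(g, path))` round-trips spacing
#' and origin exactly and voxel values within float precision (NRRD stores
#' doubles; NIfTI stores float64 here as well).
#'
#' @param grid an [image_grid].
#' @param path destination path (`.nii`, `.nii.gz`, `.nrrd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(is_image_grid(grid))
  if (grepl("\\.nrrd$", tolower(path))) write_nrrd(grid, path)
  else write_nifti(grid, path)
  invisible(path)
}

read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), " dimensions: ", path,
         call. = FALSE)
  xf <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  origin <- as.numeric(xf[1:3, 4])
  # RNifti reports RAS-oriented xforms; volumes written by write_volume use a
  # diagonal sform so no permutation/flip handling is needed here.
  image_grid(array(as.numeric(img), dim = d), spacing = abs(spacing),
             origin = origin)
}

write_nifti <- function(grid, path) {
  img <- RNifti::asNifti(grid$voxels)
  img <- RNifti::`pixdim<-`(img, grid$spacing)
  m <- diag(4)
  m[1, 1] <- grid$spacing[1]
  m[2, 2] <- grid$spacing[2]
  m[3, 3] <- grid$spacing[3]
  m[1:3, 4] <- grid$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
}

# --- minimal NRRD0004 reader/writer (attached data, axis-aligned) ---------

nrrd_types <- list(
  "double" = list(what = "double", size = 8),
  "float"  = list(what = "double", size = 4),
  "int"    = list(what = "integer", size = 4),
  "short"  = list(what = "integer", size = 2),
  "uchar"  = list(what = "integer", size = 1),
  "unsigned char" = list(what = "integer", size = 1)
)

parse_nrrd_vectors <- function(s) {
  m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(m, function(v)
    as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
}

read_nrrd <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  # header ends at the first blank line
  nl <- which(raw == as.raw(10))
  hdr_end <- NA
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L || (p == prev + 2L && raw[p - 1L] == as.raw(13))) {
      hdr_end <- p; break
    }
    prev <- p
  }
  if (is.na(hdr_end)) stop("malformed NRRD header: ", path, call. = FALSE)
  hdr <- strsplit(rawToChar(raw[seq_len(hdr_end)]), "\r?\n")[[1]]
  if (!grepl("^NRRD", hdr[1])) stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  for (line in hdr[-1]) {
    if (grepl("^\\s*#", line) || !nzchar(trimws(line))) next
    parts <- strsplit(line, ":=?", perl = TRUE)[[1]]
    fields[[trimws(tolower(parts[1]))]] <- trimws(paste(parts[-1], collapse = ":"))
  }
  ndim <- as.integer(fields[["dimension"]])
  if (is.na(ndim) || ndim != 3L)
    stop("expected a 3D NRRD image, got dimension ", fields[["dimension"]],
         call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  type <- nrrd_types[[fields[["type"]]]]
  if (is.null(type)) stop("unsupported NRRD type: ", fields[["type"]], call. = FALSE)
  enc <- tolower(fields[["encoding"]] %||% "raw")
  spacing <- c(1, 1, 1)
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_nrrd_vectors(fields[["space directions"]])
    for (a in 1:3) {
      v <- dirs[[a]]
      if (sum(v != 0) != 1L || v[a] == 0)
        stop("only axis-aligned NRRD space directions are supported", call. = FALSE)
      spacing[a] <- abs(v[a])
    }
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- abs(as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]]))
  }
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vectors(fields[["space origin"]])[[1]]
  payload <- raw[(hdr_end + 1L):length(raw)]
  if (enc %in% c("gzip", "gz")) payload <- memDecompress(payload, type = "gzip")
  else if (enc != "raw") stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  endian <- if (identical(fields[["endian"]], "big")) "big" else "little"
  vals <- readBin(payload, what = type$what, n = prod(sizes), size = type$size,
                  endian = endian)
  if (length(vals) < prod(sizes))
    stop("truncated NRRD data block: ", path, call. = FALSE)
  image_grid(array(as.numeric(vals), dim = sizes), spacing, origin)
}

write_nrrd <- function(grid, path) {
  d <- dim(grid$voxels)
  s <- grid$spacing
  o <- grid$origin
  hdr <- c(
    "NRRD0004",
    "# generated by idlss",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    "space dimension: 3",
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            s[1], s[2], s[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)", o[1], o[2], o[3]),
    "endian: little",
    "encoding: raw",
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  writeBin(as.numeric(grid$voxels), con, size = 8, endian = "little")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
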