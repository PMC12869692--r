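# File I/O: MetaImage phantoms (viewable in standard medical-imaging tools),
# float TIFF + JSON sidecars for projection images and GF maps.

.MHA_LEGEND <- "0=air 1=adipose 2=fibroglandular 3=skin"

#' Write a phantom as MetaImage
#'
#' Single-file MetaImage (.mha) with uint8 labels; the label legend rides in
#' the header so the volume is interpretable in standard viewers.
#'
#' @param phantom A \code{voxel_phantom}.
#' @param path Output path (conventionally ending in .mha).
#' @return \code{path}, invisibly.
#' @export
write_phantom_mha <- function(phantom, path) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  d <- dim(phantom$labels)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %g %g %g", phantom$pitch_mm, phantom$pitch_mm,
            phantom$pitch_mm),
    sprintf("Offset = %g %g %g", phantom$origin_mm[1], phantom$origin_mm[2],
            phantom$origin_mm[3]),
    "ElementType = MET_UCHAR",
    sprintf("AnatomicalOrientation = ???"),
    sprintf("Comment = labels: %s", .MHA_LEGEND),
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(as.raw(as.vector(phantom$labels)), con)
  invisible(path)
}

#' Read a MetaImage phantom
#'
#' Reads .mha files written by [write_phantom_mha()] (uint8, LOCAL data).
#'
#' @param path Input .mha path.
#' @return A \code{voxel_phantom}.
#' @export
read_phantom_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    hdr <- c(hdr, line)
    if (grepl("^ElementDataFile", line)) break
    if (length(hdr) > 50) stop("malformed MetaImage header", call. = FALSE)
  }
  get_field <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  if (!identical(get_field("ElementType"), "MET_UCHAR")) {
    stop("only MET_UCHAR phantoms are supported", call. = FALSE)
  }
  d <- as.integer(strsplit(get_field("DimSize"), " +")[[1]])
  sp <- as.numeric(strsplit(get_field("ElementSpacing"), " +")[[1]])
  off <- as.numeric(strsplit(get_field("Offset"), " +")[[1]])
  raw <- readBin(con, "raw", n = prod(d))
  labels <- array(as.integer(raw), dim = d)
  .new_phantom(labels, sp[1], off)
}

#' Write an image (projection or GF map) as float TIFF with JSON sidecar
#'
#' The 2-D pixel grid is stored as 32-bit float TIFF (values must lie in
#' [0, 1], which both transmission images and GF maps satisfy); geometry
#' metadata (source position, pitch, thickness) goes to \code{<path>.json}.
#'
#' @param img A \code{projection_image} or \code{gf_map}.
#' @param path Output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  m <- if (inherits(img, "gf_map")) img$gf else img$image
  m <- pmin(pmax(m, 0), 1)
  tiff::writeTIFF(t(m), path, bits.per.sample = 32)
  meta <- list(kind = class(img)[1],
               pixel_pitch_mm = img$geom$pixel_pitch_mm,
               source_mm = img$geom$source_mm,
               det_z_mm = img$geom$det_z_mm,
               det_origin_mm = img$geom$det_origin_mm)
  if (inherits(img, "gf_map")) meta$thickness_mm <- img$thickness_mm
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image written by [write_image_tiff()]
#'
#' @param path TIFF path (expects \code{<path>.json} sidecar alongside).
#' @return A matrix with attribute \code{meta} (the sidecar contents).
#' @export
read_image_tiff <- function(path) {
  m <- t(tiff::readTIFF(path))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
  attr(m, "meta") <- meta
  m
}
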