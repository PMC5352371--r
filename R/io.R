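#' Read a segmentation mask from NIfTI or NRRD
#'
#' Any non-zero voxel is foreground; spacing is read from the header. NIfTI
#' (`.nii`, `.nii.gz`) goes through RNifti; NRRD (`.nrrd`) through a minimal
#' built-in reader supporting attached headers with `raw`, `gzip` or ASCII
#' encodings and axis-aligned `space directions` / `spacings`.
#'
#' @param path Path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @return A [seg_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1:3]
    arr <- array(as.numeric(img), dim = dim(img)[1:3])
    seg_mask(arr, spacing = sp)
  } else if (grepl("\\.nrrd$", lower)) {
    read_nrrd_mask(path)
  } else {
    stop("unsupported mask format (expect .nii, .nii.gz or .nrrd): ", path,
      call. = FALSE
    )
  }
}

#' Write a segmentation mask
#'
#' NIfTI output stores the mask as uint8 with the spacing in the header;
#' NRRD output writes an attached raw-encoded header.
#'
#' @param mask A [seg_mask()].
#' @param path Output path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!is_seg_mask(mask)) stop("`mask` must be a seg_mask", call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    arr <- array(as.integer(mask), dim = dim(mask))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- mask_spacing(mask)
    RNifti::writeNifti(img, path, datatype = "uint8")
  } else if (grepl("\\.nrrd$", lower)) {
    write_nrrd_mask(mask, path)
  } else {
    stop("unsupported mask format (expect .nii, .nii.gz or .nrrd): ", path,
      call. = FALSE
    )
  }
  invisible(path)
}

# --- minimal NRRD support (attached header; raw / gzip / ascii encodings) ---

nrrd_type_info <- function(type) {
  switch(type,
    "signed char" = ,
    "int8" = ,
    "int8_t" = list(what = "integer", size = 1, signed = TRUE),
    "uchar" = ,
    "unsigned char" = ,
    "uint8" = ,
    "uint8_t" = list(what = "integer", size = 1, signed = FALSE),
    "short" = ,
    "int16" = ,
    "int16_t" = list(what = "integer", size = 2, signed = TRUE),
    "ushort" = ,
    "uint16" = ,
    "uint16_t" = list(what = "integer", size = 2, signed = FALSE),
    "int" = ,
    "int32" = ,
    "int32_t" = list(what = "integer", size = 4, signed = TRUE),
    "uint" = ,
    "uint32" = ,
    "uint32_t" = list(what = "integer", size = 4, signed = FALSE),
    "float" = list(what = "numeric", size = 4, signed = TRUE),
    "double" = list(what = "numeric", size = 8, signed = TRUE),
    stop("unsupported NRRD type: ", type, call. = FALSE)
  )
}

read_nrrd_mask <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header", call. = FALSE)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ":=?", fixed = FALSE)[[1]]
    key <- tolower(trimws(kv[1]))
    fields[[key]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  if (is.null(fields$sizes) || is.null(fields$type) || is.null(fields$encoding)) {
    stop("NRRD header missing sizes/type/encoding", call. = FALSE)
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD masks are supported", call. = FALSE)
  if (!is.null(fields[["data file"]]) || !is.null(fields$datafile)) {
    stop("detached NRRD headers are not supported", call. = FALSE)
  }

  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(
      fields[["space directions"]],
      gregexpr("\\(([^)]*)\\)", fields[["space directions"]])
    )[[1]]
    if (length(vecs) == 3L) {
      spacing <- vapply(vecs, function(v) {
        nums <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
        sqrt(sum(nums^2))
      }, numeric(1), USE.NAMES = FALSE)
    }
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  }

  ti <- nrrd_type_info(fields$type)
  n <- prod(sizes)
  enc <- tolower(fields$encoding)
  endian <- if (!is.null(fields$endian) && tolower(fields$endian) == "big") "big" else "little"
  vals <- if (enc %in% c("raw")) {
    readBin(con, ti$what, n = n, size = ti$size, signed = ti$signed, endian = endian)
  } else if (enc %in% c("gzip", "gz")) {
    comp <- readBin(con, "raw", n = file.info(path)$size)
    readBin(memDecompress(comp, type = "gzip"), ti$what,
      n = n, size = ti$size, signed = ti$signed, endian = endian
    )
  } else if (enc %in% c("ascii", "text", "txt")) {
    as.numeric(scan(con, what = double(), n = n, quiet = TRUE))
  } else {
    stop("unsupported NRRD encoding: ", fields$encoding, call. = FALSE)
  }
  if (length(vals) != n) stop("truncated NRRD data block", call. = FALSE)
  seg_mask(array(vals, dim = sizes), spacing = spacing)
}

write_nrrd_mask <- function(mask, path) {
  sp <- mask_spacing(mask)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# produced by compactvol",
    "type: uint8",
    "dimension: 3",
    "space: left-posterior-superior",
    paste("sizes:", paste(dim(mask), collapse = " ")),
    sprintf(
      "space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
      sp[1], sp[2], sp[3]
    ),
    "kinds: domain domain domain",
    "encoding: raw",
    "endian: little",
    ""
  )
  writeLines(hdr, con, sep = "\n")
  writeBin(as.raw(as.integer(mask)), con)
  invisible(path)
}
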