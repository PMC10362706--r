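# Minimal DICOM series I/O: explicit VR little endian, uncompressed,
# single-frame slices, 16-bit unsigned pixels. Covers what a CBCT export
# needs (geometry tags + pixel data); anything else in a file is skipped on
# read and never written.

# values must have even byte length; space padding is used throughout and
# stripped again on read (keeps all values rawToChar-safe)
.dcm_pad <- function(s) {
  if (nchar(s) %% 2 == 1) paste0(s, " ") else s
}

.dcm_elem <- function(group, elem, vr, value_raw) {
  len <- length(value_raw)
  hdr <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
           writeBin(as.integer(elem), raw(), size = 2, endian = "little"),
           charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    hdr <- c(hdr, as.raw(c(0, 0)),
             writeBin(as.integer(len), raw(), size = 4, endian = "little"))
  } else {
    hdr <- c(hdr, writeBin(as.integer(len), raw(), size = 2,
                           endian = "little"))
  }
  c(hdr, value_raw)
}

.dcm_str <- function(group, elem, vr, s) {
  .dcm_elem(group, elem, vr, charToRaw(.dcm_pad(s)))
}

.dcm_us <- function(group, elem, x) {
  .dcm_elem(group, elem, "US",
            writeBin(as.integer(x), raw(), size = 2, endian = "little"))
}

#' Write a voxel volume as a DICOM series
#'
#' One uncompressed explicit-VR-little-endian CT slice file per z index,
#' 16-bit unsigned pixels. Intensities are rounded and clamped to
#' \[0, 65535\].
#'
#' @param vol a [voxel_volume].
#' @param dir output directory (created if needed).
#' @param series_uid series instance UID; the default derives a fresh one
#'   from the current time so separate calls produce distinct series.
#' @param instance_order permutation of slice order used for file naming;
#'   reading must be invariant to it (slices are sorted by position).
#' @return `dir`, invisibly.
#' @export
write_dicom_series <- function(vol, dir,
                               series_uid = NULL,
                               instance_order = seq_len(dim(vol$data)[3])) {
  dims <- dim(vol$data)
  if (is.null(series_uid))
    series_uid <- paste0("1.2.826.0.1.3680043.9999.",
                         format(as.numeric(Sys.time()) * 1000, digits = 15,
                                scientific = FALSE))
  study_uid <- paste0(series_uid, ".0")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rowdir <- vol$orientation[, 1]
  coldir <- vol$orientation[, 2]
  normal <- vol$orientation[, 3]
  ds <- function(x) paste(sprintf("%.10g", x), collapse = "\\")
  for (pos in seq_along(instance_order)) {
    k <- instance_order[pos]
    ipp <- vol$origin + (k - 1) * vol$spacing[3] * normal
    px <- as.integer(pmin(pmax(round(as.vector(vol$data[, , k])), 0), 65535))
    body <- c(
      .dcm_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      .dcm_str(0x0008, 0x0018, "UI", paste0(series_uid, ".", k)),
      .dcm_str(0x0008, 0x0060, "CS", "CT"),
      .dcm_str(0x0018, 0x0050, "DS", ds(vol$spacing[3])),
      .dcm_str(0x0020, 0x000D, "UI", study_uid),
      .dcm_str(0x0020, 0x000E, "UI", series_uid),
      .dcm_str(0x0020, 0x0013, "IS", as.character(k)),
      .dcm_str(0x0020, 0x0032, "DS", ds(ipp)),
      .dcm_str(0x0020, 0x0037, "DS", ds(c(rowdir, coldir))),
      .dcm_us(0x0028, 0x0002, 1L),
      .dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcm_us(0x0028, 0x0010, dims[2]),   # Rows (y)
      .dcm_us(0x0028, 0x0011, dims[1]),   # Columns (x)
      .dcm_str(0x0028, 0x0030, "DS", ds(vol$spacing[c(2, 1)])),
      .dcm_us(0x0028, 0x0100, 16L),
      .dcm_us(0x0028, 0x0101, 16L),
      .dcm_us(0x0028, 0x0102, 15L),
      .dcm_us(0x0028, 0x0103, 0L),
      .dcm_elem(0x7FE0, 0x0010, "OW",
                writeBin(px, raw(), size = 2, endian = "little")))
    meta <- c(
      .dcm_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      .dcm_str(0x0002, 0x0003, "UI", paste0(series_uid, ".", k)),
      .dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
    meta <- c(.dcm_elem(0x0002, 0x0000, "UL",
                        writeBin(length(meta), raw(), size = 4,
                                 endian = "little")),
              meta)
    con <- file(file.path(dir, sprintf("slice_%04d.dcm", pos)), "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(c(meta, body), con)
    close(con)
  }
  invisible(dir)
}

.dcm_parse_file <- function(path) {
  r <- readBin(path, "raw", file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  u16 <- function(i) as.integer(r[i]) + 256L * as.integer(r[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  pos <- 133L
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(r)) {
    group <- u16(pos)
    elem <- u16(pos + 2L)
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop(sprintf("unsupported (implicit VR?) element at byte %d of %s",
                   pos, path))
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      vstart <- pos + 8L
    }
    if (vstart + len - 1L > length(r))
      stop("truncated DICOM element in ", path)
    val <- r[vstart:(vstart + len - 1L)]
    tag <- sprintf("%04X,%04X", group, elem)
    if (tag == "7FE0,0010") {
      out$pixel_raw <- val
      break
    }
    txt <- function() trimws(rawToChar(val))
    nums <- function() as.numeric(strsplit(txt(), "\\\\")[[1]])
    us <- function() as.integer(val[1]) + 256L * as.integer(val[2])
    switch(tag,
           "0020,000E" = { out$series_uid <- txt() },
           "0020,0013" = { out$instance <- as.integer(txt()) },
           "0020,0032" = { out$position <- nums() },
           "0020,0037" = { out$orientation <- nums() },
           "0018,0050" = { out$slice_thickness <- nums() },
           "0028,0010" = { out$rows <- us() },
           "0028,0011" = { out$cols <- us() },
           "0028,0030" = { out$pixel_spacing <- nums() },
           "0028,0100" = { out$bits <- us() },
           "0028,0103" = { out$pixrep <- us() },
           NULL)
    pos <- vstart + len
  }
  for (need in c("position", "orientation", "rows", "cols", "pixel_spacing"))
    if (is.null(out[[need]])) stop("missing geometry tag ", need, " in ", path)
  if (is.null(out$pixel_raw)) stop("missing pixel data in ", path)
  if (!is.null(out$bits) && out$bits != 16L)
    stop("only 16-bit pixel data is supported: ", path)
  n <- out$rows * out$cols
  px <- readBin(out$pixel_raw, "integer", n = n, size = 2,
                endian = "little", signed = FALSE)
  if (!is.null(out$pixrep) && out$pixrep == 1L)
    px <- ifelse(px > 32767, px - 65536, px)
  out$pixels <- px
  out$pixel_raw <- NULL
  out
}

#' Read a DICOM series directory as a voxel volume
#'
#' Reads every `.dcm` file in `dir`, verifies the slices form one coherent
#' series (same series UID, dimensions, pixel spacing and orientation), and
#' stacks them sorted by the projection of the image position onto the slice
#' normal, so the result is independent of the on-disk file order. Missing
#' or irregularly spaced slices are an error.
#'
#' @param dir directory holding one series.
#' @return A [voxel_volume].
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L) stop("no .dcm files in ", dir)
  slices <- lapply(files, .dcm_parse_file)
  uid <- unique(vapply(slices, function(s)
    if (is.null(s$series_uid)) "" else s$series_uid, ""))
  if (length(uid) != 1L)
    stop("mixed series in ", dir, ": ", paste(uid, collapse = ", "))
  dims_ok <- length(unique(vapply(slices, function(s)
    paste(s$rows, s$cols, paste(s$pixel_spacing, collapse = ","),
          paste(round(s$orientation, 9), collapse = ",")), ""))) == 1L
  if (!dims_ok) stop("inconsistent slice geometry in ", dir)
  s1 <- slices[[1]]
  rowdir <- s1$orientation[1:3]
  coldir <- s1$orientation[4:6]
  normal <- .cross3(rowdir, coldir)
  z <- vapply(slices, function(s) sum(s$position * normal), numeric(1))
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  nz <- length(slices)
  if (nz > 1L) {
    dz <- diff(z)
    if (any(dz <= 0) || (max(dz) - min(dz)) > 1e-4 * max(dz) + 1e-9)
      stop("missing or duplicated slices: irregular slice spacing in ", dir)
    dz <- median(dz)
  } else {
    dz <- if (!is.null(s1$slice_thickness)) s1$slice_thickness else 1
  }
  nx <- s1$cols
  ny <- s1$rows
  arr <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) arr[, , k] <- slices[[k]]$pixels
  voxel_volume(arr,
               spacing = c(s1$pixel_spacing[2], s1$pixel_spacing[1], dz),
               origin = slices[[1]]$position,
               orientation = cbind(rowdir, coldir, normal))
}
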