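#' Read a calibrated TIFF / OME-TIFF stack
#'
#' Reads a multi-page TIFF into an [image_stack]. Axis bookkeeping is resolved
#' in this order of precedence:
#'
#' 1. a JSON sidecar `<path>.json` written by [write_stack()];
#' 2. an OME-XML `ImageDescription` (OME-TIFF): `SizeT/C/Z/Y/X`,
#'    `DimensionOrder`, `PhysicalSizeX`, `TimeIncrement` are honoured;
#' 3. an explicit `dims`/`page_order` specification from the caller.
#'
#' A multi-page plain TIFF with none of these is ambiguous and is refused
#' with an error naming the missing information rather than guessed at.
#' Explicit calibration overrides always win over file metadata (a warning is
#' emitted when they disagree).
#'
#' @param path TIFF file.
#' @param pixel_size_um,frame_interval_s Optional calibration overrides (> 0).
#' @param dims Optional named integer vector with entries `T`, `C`, `Z`
#'   describing how the pages factor (product must equal the page count).
#' @param page_order Order in which the non-planar axes vary across pages,
#'   fastest first; one of `"ZCT"` (OME default), `"CZT"`, `"ZTC"`, `"CTZ"`,
#'   `"TZC"`, `"TCZ"`.
#' @param channel_names Optional channel labels.
#' @return An [image_stack]; the Z axis, when present with more than one
#'   plane, is preserved for [project_z()].
#' @export
read_stack <- function(path, pixel_size_um = NULL, frame_interval_s = NULL,
                       dims = NULL, page_order = "ZCT", channel_names = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read '", path, "'"))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_pages <- length(pages)

  meta <- list(pixel_size_um = NULL, frame_interval_s = NULL,
               channel_names = NULL, scale = 1)
  sidecar <- paste0(path, ".json")
  desc <- attr(pages[[1L]], "description")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    dims <- c(T = sc$size_t, C = sc$size_c, Z = sc$size_z)
    page_order <- sc$page_order
    meta$pixel_size_um <- sc$pixel_size_um
    meta$frame_interval_s <- sc$frame_interval_s
    meta$channel_names <- sc$channel_names
    if (!is.null(sc$scale)) meta$scale <- sc$scale
  } else if (!is.null(desc) && grepl("<OME", desc, fixed = TRUE)) {
    ome <- parse_ome_description(desc)
    dims <- c(T = ome$size_t, C = ome$size_c, Z = ome$size_z)
    page_order <- ome$page_order
    meta$pixel_size_um <- ome$pixel_size_um
    meta$frame_interval_s <- ome$frame_interval_s
  } else if (is.null(dims)) {
    if (n_pages == 1L) {
      dims <- c(T = 1L, C = 1L, Z = 1L)
    } else {
      abort(paste0(
        "'", path, "' has ", n_pages, " pages but no OME metadata, no ",
        "sidecar, and no `dims` specification: the T/C/Z factorisation of ",
        "the pages is ambiguous. Pass dims = c(T = ..., C = ..., Z = ...) ",
        "and `page_order`."))
    }
  }
  dims <- dims[c("T", "C", "Z")]
  if (anyNA(dims)) abort("`dims` must name all of T, C and Z")
  if (prod(dims) != n_pages) {
    abort(paste0("dims imply ", prod(dims), " pages, file has ", n_pages))
  }

  # multi-sample single pages (e.g. RGB) expose samples as channels
  if (n_pages == 1L && length(dim(pages[[1L]])) == 3L && dims[["C"]] == 1L) {
    s <- dim(pages[[1L]])[3L]
    pages <- lapply(seq_len(s), function(k) pages[[1L]][, , k])
    dims[["C"]] <- s
    n_pages <- s
    page_order <- "CZT"
  }

  yx <- dim(pages[[1L]])[1:2]
  ok <- vapply(pages, function(p) identical(dim(p)[1:2], yx), logical(1))
  if (!all(ok)) abort("all pages must share the same Y x X dimensions")

  idx <- page_index_table(dims, page_order)
  data <- array(0, c(dims[["T"]], dims[["C"]], dims[["Z"]], yx))
  for (p in seq_len(n_pages)) {
    data[idx$t[p], idx$c[p], idx$z[p], , ] <- pages[[p]]
  }
  data <- data * meta$scale
  if (dims[["Z"]] == 1L) data <- array(data, c(dims[["T"]], dims[["C"]], yx))

  px <- resolve_calibration(pixel_size_um, meta$pixel_size_um, 1,
                            "pixel_size_um")
  dt <- resolve_calibration(frame_interval_s, meta$frame_interval_s,
                            NA_real_, "frame_interval_s")
  if (is.null(channel_names)) channel_names <- meta$channel_names
  image_stack(data, px, dt, channel_names)
}

resolve_calibration <- function(override, from_meta, fallback, what) {
  if (!is.null(override)) {
    if (!is.null(from_meta) && is.finite(from_meta) &&
        abs(override - from_meta) > 1e-9 * max(abs(from_meta), 1)) {
      warn(paste0(what, ": explicit override ", override,
                  " differs from file metadata ", from_meta,
                  "; using the override"))
    }
    return(override)
  }
  if (!is.null(from_meta) && is.finite(from_meta)) return(from_meta)
  if (what == "pixel_size_um") {
    warn("no pixel size in metadata or arguments; assuming 1 um/px")
  }
  fallback
}

# fastest-first page order -> per-page (t, c, z) indices
page_index_table <- function(dims, page_order) {
  letters3 <- strsplit(toupper(page_order), "")[[1L]]
  if (!setequal(letters3, c("T", "C", "Z"))) {
    abort("`page_order` must be a permutation of T, C, Z (fastest first)")
  }
  sizes <- dims[letters3]
  grid <- expand.grid(i1 = seq_len(sizes[1L]), i2 = seq_len(sizes[2L]),
                      i3 = seq_len(sizes[3L]))
  out <- list()
  for (k in 1:3) out[[tolower(letters3[k])]] <- grid[[k]]
  out
}

parse_ome_description <- function(desc) {
  doc <- xml2::read_xml(desc)
  px <- xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) abort("OME description lacks a Pixels node")
  at <- function(name) xml2::xml_attr(px, name)
  num <- function(name) suppressWarnings(as.numeric(at(name)))
  dim_order <- at("DimensionOrder")           # e.g. "XYZCT"
  page_order <- substr(dim_order, 3L, 5L)     # after the in-plane XY
  list(size_t = as.integer(num("SizeT")), size_c = as.integer(num("SizeC")),
       size_z = as.integer(num("SizeZ")),
       pixel_size_um = num("PhysicalSizeX"),
       frame_interval_s = num("TimeIncrement"),
       page_order = page_order)
}

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are written in `"ZCT"` fastest-first order. Integer-valued data in
#' `[0, 65535]` is stored as 16-bit, which round-trips bit-exactly through
#' [read_stack()]; other data is rescaled into `[0, 1]`, stored as 32-bit
#' float (single precision) and un-scaled on read using the `scale` recorded
#' in the sidecar. The sidecar (`<path>.json`) carries the axis sizes, page
#' order, calibration and channel names.
#'
#' @param stack An [image_stack].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  if (length(d) == 4L) d <- c(d[1:2], 1L, d[3:4])
  data <- array(stack$data, d)
  integerish <- all(data >= 0) && all(data <= 65535) &&
    all(data == round(data))
  if (integerish) {
    # stored as uint16; readTIFF(as.is = TRUE) restores the raw integers
    scale <- 1
    bits <- 16L
  } else {
    scale <- max(abs(data), 1e-12)
    bits <- 32L
  }
  pages <- vector("list", prod(d[1:3]))
  p <- 0L
  for (t in seq_len(d[1L])) for (ch in seq_len(d[2L])) for (z in seq_len(d[3L])) {
    p <- p + 1L
    pages[[p]] <- matrix(data[t, ch, z, , ], d[4L], d[5L]) /
      (if (bits == 16L) 65535 else scale)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  jsonlite::write_json(
    list(size_t = d[1L], size_c = d[2L], size_z = d[3L],
         page_order = "ZCT",
         pixel_size_um = stack$pixel_size_um,
         frame_interval_s = stack$frame_interval_s,
         channel_names = stack$channel_names,
         scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write tidy records to CSV
#'
#' Thin wrapper over [readr::write_csv()] that refuses to write an empty
#' table (a degenerate analysis should fail loudly, not produce an empty
#' file). Values round-trip to at least 12 significant digits.
#'
#' @param records A data frame with at least one row.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) abort("refusing to write an empty table")
  readr::write_csv(records, path)
  invisible(path)
}

#' Render a matrix as a diverging-scale PNG heat map
#'
#' Used for radial-velocity heat maps: the colour scale is symmetric about
#' zero (blue = inward/negative, white = zero, red = outward/positive), so a
#' zero matrix renders uniformly mid-scale. Missing values render as grey.
#'
#' @param matrix Numeric matrix (may contain `NA`).
#' @param path Output PNG path.
#' @param limit Positive scalar fixing the scale to `[-limit, limit]`;
#'   default is the maximum absolute finite value (or 1 if all zero).
#' @param scale_px Integer nearest-neighbour upscaling factor for visibility.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(matrix, path, limit = NULL, scale_px = 8L) {
  m <- as.matrix(matrix)
  finite <- is.finite(m)
  if (!any(finite)) abort("heat map input has no finite values")
  if (is.null(limit)) limit <- max(abs(m[finite]), 0)
  if (limit <= 0) limit <- 1
  z <- pmax(pmin(m / limit, 1), -1)          # [-1, 1]
  ramp <- grDevices::colorRamp(c("#2166AC", "#FFFFFF", "#B2182B"))
  rgb <- array(0.5, c(nrow(m), ncol(m), 3L))
  if (any(finite)) {
    cols <- ramp((z[finite] + 1) / 2) / 255
    for (k in 1:3) {
      plane <- rgb[, , k]
      plane[finite] <- cols[, k]
      rgb[, , k] <- plane
    }
  }
  if (scale_px > 1L) {
    up <- function(p) p[rep(seq_len(nrow(p)), each = scale_px),
                        rep(seq_len(ncol(p)), each = scale_px)]
    rgb <- array(c(up(rgb[, , 1]), up(rgb[, , 2]), up(rgb[, , 3])),
                 c(nrow(m) * scale_px, ncol(m) * scale_px, 3L))
  }
  png::writePNG(rgb, path)
  invisible(path)
}
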