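#' Decode a plate-scan filename into scan metadata
#'
#' Plate scans are named with an underscore-delimited dialect carrying the
#' leaf side, the ecotype, the biological replicate, a batch tag and the
#' number of leaves mounted on the plate, e.g. `"D_A_1_I_2_K1_12"`:
#' side `D` (abaxial), ecotype `A` number 1, replicate 2 (tagged `I`),
#' batch `K1`, 12 leaves. The dialect is configurable through
#' `config$filename` (token order, side codes, tags) so that other labs'
#' conventions can be expressed without code changes.
#'
#' @param name filename (with or without the `.tif`/`.tiff` extension).
#' @param config an [ms_config()] list; only `config$filename` is used.
#' @return a `scan_meta` list: `side` ("abaxial"/"adaxial"),
#'   `ecotype_label`, `ecotype_index`, `replicate`, `batch`,
#'   `declared_leaf_count`, `raw_name`.
#' @export
#' @examples
#' parse_scan_filename("D_A_1_I_2_K1_12")
parse_scan_filename <- function(name, config = ms_config()) {
  fn <- config$filename
  raw <- sub("\\.(tif|tiff)$", "", name, ignore.case = TRUE)
  tokens <- strsplit(raw, "_", fixed = TRUE)[[1]]
  if (length(tokens) != length(fn$tokens)) {
    stop(sprintf("cannot parse scan name '%s': expected %d '_'-separated tokens, got %d",
                 name, length(fn$tokens), length(tokens)), call. = FALSE)
  }
  tok <- stats::setNames(tokens, fn$tokens)

  side_code <- tok[["side"]]
  if (!side_code %in% names(fn$side_codes)) {
    stop(sprintf("unknown side code '%s' in scan name '%s' (expected one of: %s)",
                 side_code, name, paste(names(fn$side_codes), collapse = ", ")),
         call. = FALSE)
  }
  if (tok[["rep_tag"]] != fn$rep_tag) {
    stop(sprintf("malformed scan name '%s': replicate tag token is '%s', expected '%s'",
                 name, tok[["rep_tag"]], fn$rep_tag), call. = FALSE)
  }
  num <- function(field) {
    v <- suppressWarnings(as.integer(tok[[field]]))
    if (is.na(v)) stop(sprintf("malformed scan name '%s': token '%s' (%s) is not an integer",
                               name, tok[[field]], field), call. = FALSE)
    v
  }
  batch <- tok[["batch"]]
  if (!startsWith(batch, fn$batch_prefix)) {
    stop(sprintf("malformed scan name '%s': batch token '%s' lacks prefix '%s'",
                 name, batch, fn$batch_prefix), call. = FALSE)
  }
  meta <- new_scan_meta(
    side = unname(fn$side_codes[[side_code]]),
    ecotype_label = tok[["ecotype_label"]],
    ecotype_index = num("ecotype_index"),
    replicate = num("replicate"),
    batch = batch,
    declared_leaf_count = num("leaf_count"),
    raw_name = raw
  )
  meta
}

#' @rdname parse_scan_filename
#' @param meta a `scan_meta` object.
#' @return `encode_scan_filename()` returns the filename (no extension);
#'   `encode(parse(x)) == x` for any valid `x`.
#' @export
encode_scan_filename <- function(meta, config = ms_config()) {
  fn <- config$filename
  codes <- stats::setNames(names(fn$side_codes), fn$side_codes)
  vals <- c(
    side = unname(codes[[meta$side]]),
    ecotype_label = meta$ecotype_label,
    ecotype_index = as.character(meta$ecotype_index),
    rep_tag = fn$rep_tag,
    replicate = as.character(meta$replicate),
    batch = meta$batch,
    leaf_count = as.character(meta$declared_leaf_count)
  )
  paste(vals[fn$tokens], collapse = "_")
}

#' @keywords internal
new_scan_meta <- function(side, ecotype_label, ecotype_index, replicate,
                          batch, declared_leaf_count, raw_name = NA_character_) {
  if (!side %in% c("abaxial", "adaxial"))
    stop("side must be 'abaxial' or 'adaxial'", call. = FALSE)
  if (declared_leaf_count < 1)
    stop("declared_leaf_count must be >= 1", call. = FALSE)
  if (ecotype_index < 1 || replicate < 1)
    stop("ecotype_index and replicate must be positive", call. = FALSE)
  structure(list(side = side, ecotype_label = ecotype_label,
                 ecotype_index = as.integer(ecotype_index),
                 replicate = as.integer(replicate), batch = batch,
                 declared_leaf_count = as.integer(declared_leaf_count),
                 raw_name = raw_name),
            class = "scan_meta")
}

#' Convert a scan resolution to a physical pixel size
#'
#' `25400 / dpi` micrometres per pixel: the plate scanner used for this
#' assay runs at 8500 dpi, i.e. approximately 3 um per pixel, which is
#' what makes 100-150 um mite eggs resolvable.
#'
#' @param dpi dots per inch, > 0.
#' @return micrometres per pixel edge.
#' @export
#' @examples
#' dpi_to_um_per_px(8500) # ~2.99 um
dpi_to_um_per_px <- function(dpi) {
  if (!is.numeric(dpi) || any(dpi <= 0)) stop("dpi must be > 0", call. = FALSE)
  25400 / dpi
}

#' @keywords internal
new_scan_image <- function(pixels, um_per_px, side, meta = NULL) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (!is.numeric(um_per_px) || um_per_px <= 0)
    stop("um_per_px must be > 0", call. = FALSE)
  structure(list(pixels = pixels, um_per_px = um_per_px,
                 side = side, meta = meta),
            class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<scan_image> %d x %d px, %.3f um/px (%.1f x %.1f mm), side: %s\n",
              d[1], d[2], x$um_per_px,
              d[1] * x$um_per_px / 1000, d[2] * x$um_per_px / 1000,
              x$side %||% "?"))
  invisible(x)
}

#' Read and write plate scans
#'
#' Scans are 8-bit RGB TIFF files; the physical scale is resolved with the
#' precedence: explicit `um_per_px` argument, then the TIFF X-resolution
#' tag, then a JSON sidecar (`<file>.scale.json`, written by
#' `write_scan()`), then `config$dpi`. Filename metadata is decoded with
#' [parse_scan_filename()] unless `meta` overrides it.
#'
#' @param path TIFF file path.
#' @param um_per_px explicit physical pixel size, micrometres; overrides
#'   everything else.
#' @param meta optional `scan_meta` override; `NA` skips filename parsing.
#' @param config an [ms_config()] list.
#' @return a `scan_image`.
#' @export
read_scan <- function(path, um_per_px = NULL, meta = NULL, config = ms_config()) {
  if (!grepl("\\.(tif|tiff)$", path, ignore.case = TRUE))
    stop(sprintf("'%s' is not a TIFF file", path), call. = FALSE)
  px <- tiff::readTIFF(path, info = TRUE)
  d <- dim(px)
  if (length(d) == 2L) px <- array(rep(px, 3L), dim = c(d, 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]

  scale <- um_per_px
  if (is.null(scale)) {
    xres <- attr(px, "x.resolution")
    unit <- attr(px, "resolution.unit") %||% "inch"
    if (!is.null(xres) && is.numeric(xres) && xres > 1) {
      dpi <- if (identical(unit, "cm")) xres * 2.54 else xres
      scale <- dpi_to_um_per_px(dpi)
    }
  }
  if (is.null(scale)) {
    sidecar <- paste0(path, ".scale.json")
    if (file.exists(sidecar)) {
      sc <- jsonlite::read_json(sidecar)
      scale <- dpi_to_um_per_px(sc$dpi)
    }
  }
  if (is.null(scale)) {
    if (is.null(config$dpi)) stop("no scale available: give um_per_px, a TIFF resolution tag, a sidecar, or config$dpi", call. = FALSE)
    scale <- dpi_to_um_per_px(config$dpi)
  }

  if (is.null(meta)) {
    meta <- tryCatch(parse_scan_filename(basename(path), config),
                     error = function(e) NULL)
  } else if (length(meta) == 1L && is.na(meta)) {
    meta <- NULL
  }
  pix <- array(as.numeric(px), dim = dim(px)[1:3])
  new_scan_image(pix, scale, side = meta$side %||% NA_character_, meta = meta)
}

#' @rdname read_scan
#' @param scan a `scan_image` to write.
#' @param sidecar write a `<file>.scale.json` sidecar carrying the dpi so
#'   that the scale survives the round trip (the installed TIFF writer does
#'   not emit resolution tags).
#' @return `write_scan()` returns `path` invisibly.
#' @export
write_scan <- function(scan, path, sidecar = TRUE) {
  stopifnot(inherits(scan, "scan_image"))
  tiff::writeTIFF(scan$pixels, path, bits.per.sample = 8L, compression = "deflate")
  if (sidecar) {
    jsonlite::write_json(list(dpi = 25400 / scan$um_per_px), paste0(path, ".scale.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# Quantize to exact 8-bit levels so that a write/read TIFF round trip is
# bit-exact.
quantize8 <- function(px) round(clamp(px, 0, 1) * 255) / 255
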