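## File-format plumbing: TIFF images, YAML/JSON sidecars, CSV tables for
## theta samples and lookup tables, directory-convention pooling.

## TIFF storage is normalized to [0, 1]; intensities are mapped through a
## fixed 16-bit count scale so photon counts survive a round trip exactly
## (float32 carries integers up to 2^24).
.TIFF_SCALE <- 65536

#' Read a grayscale TIFF as an intensity matrix (or stack)
#'
#' Values are returned on the 16-bit count scale used by
#' [writeImageTiff()] (stored value times 65536), which also maps standard
#' 8/16-bit integer TIFFs onto a proportional count scale.
#'
#' @param path TIFF file; multi-page files return a 3-D array.
#' @param scale multiplier applied to the stored \[0, 1\] samples.
#' @return numeric matrix or array (rows x cols x pages).
#' @export
readImageTiff <- function(path, scale = .TIFF_SCALE) {
  img <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  flat <- lapply(img, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]
    m * scale
  })
  if (length(flat) == 1) flat[[1]] else
    array(unlist(flat), dim = c(dim(flat[[1]]), length(flat)))
}

#' Write an intensity matrix, stack or RGB array as 32-bit float TIFF
#'
#' Intensities are divided by the fixed count scale (65536) before
#' storage; [readImageTiff()] reverses this, so counts below 2^16 round-
#' trip exactly. Values above the scale are clipped with a warning.
#'
#' @param x matrix, 3-D array (pages) or `nrow x ncol x 3` RGB array in
#'   \[0, 1\] (written as a single RGB page when `rgb = TRUE`, unscaled).
#' @param path output path.
#' @param rgb logical; treat the third dimension as color.
#' @export
writeImageTiff <- function(x, path, rgb = FALSE) {
  if (!rgb) {
    if (max(x) > .TIFF_SCALE)
      warning("intensities above ", .TIFF_SCALE, " are clipped")
    x <- pmin(x / .TIFF_SCALE, 1)
  }
  if (rgb || is.matrix(x)) {
    tiff::writeTIFF(x, path, bits.per.sample = 32L, reduce = FALSE)
  } else {
    pages <- lapply(seq_len(dim(x)[3]), function(i) x[, , i])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(path)
}

#' Write an RGB render as PNG
#'
#' @param rgb `nrow x ncol x 3` array in \[0, 1\].
#' @param path output path.
#' @export
writeRGBImage <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}

#' Read / write acquisition sidecar metadata (YAML or JSON by extension)
#'
#' Sidecars record modality, modulation scheme and phase, stack angles and
#' calibration so that images remain self-describing.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return named list.
#' @export
readSidecar <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname readSidecar
#' @param meta named list to serialize.
#' @export
writeSidecar <- function(meta, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(meta, path)
  else jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                            digits = NA)
  invisible(path)
}

#' Write / read theta samples as CSV
#'
#' Column layout: `object_id, modality, geometry, theta_deg, log2r,
#' weight`.
#'
#' @param samples a [ThetaSamples-class].
#' @param path CSV path.
#' @export
writeThetaSamples <- function(samples, path) {
  methods::validObject(samples)
  s <- samples@samples
  utils::write.csv(data.frame(object_id = samples@objectId,
                              modality = samples@modality,
                              geometry = samples@geometry,
                              theta_deg = s$theta, log2r = s$log2r,
                              weight = s$weight),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeThetaSamples
#' @return `readThetaSamples`: a [ThetaSamples-class].
#' @export
readThetaSamples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  methods::new("ThetaSamples",
               samples = data.frame(theta = df$theta_deg %% 180,
                                    log2r = df$log2r, weight = df$weight),
               modality = as.character(df$modality[1]),
               geometry = as.character(df$geometry[1]),
               objectId = as.character(df$object_id[1]))
}

#' Pool theta-sample CSVs from a directory tree
#'
#' Directory convention: one subdirectory per object, containing CSVs
#' written by [writeThetaSamples()] (any name); modality and geometry are
#' read from the files. Files directly in `dir` are accepted too.
#'
#' @param dir root directory.
#' @return list of [ThetaSamples-class].
#' @export
readPooledDirectory <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", recursive = TRUE,
                      full.names = TRUE)
  if (!length(files)) stop("no theta-sample CSV files under ", dir)
  lapply(sort(files), readThetaSamples)
}

#' Write / read a lookup table as a CSV sidecar
#'
#' Columns `alpha0_deg, sigma_deg, B1P, B2P, C2P`, preceded by comment
#' lines recording the grid specification, the package version and a
#' content hash of the data lines.
#'
#' @param table an [LDLookupTable-class].
#' @param path CSV path.
#' @export
writeLookupTable <- function(table, path) {
  methods::validObject(table)
  g <- expand.grid(alpha0_deg = table@alpha0, sigma_deg = table@sigma)
  df <- data.frame(g, B1P = as.vector(table@b1p), B2P = as.vector(table@b2p),
                   C2P = as.vector(table@c2p))
  lines <- c(sprintf("%.6g,%.6g,%.10g,%.10g,%.10g", df$alpha0_deg,
                     df$sigma_deg, df$B1P, df$B2P, df$C2P))
  hdr <- c("# polarLD lookup table",
           sprintf("# alpha0: n=%d min=%g max=%g", length(table@alpha0),
                   min(table@alpha0), max(table@alpha0)),
           sprintf("# sigma: n=%d min=%g max=%g", length(table@sigma),
                   min(table@sigma), max(table@sigma)),
           sprintf("# version: %s",
                   as.character(utils::packageVersion("polarLD"))),
           sprintf("# hash: %s", contentHash(paste(lines, collapse = "\n"))),
           "alpha0_deg,sigma_deg,B1P,B2P,C2P")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname writeLookupTable
#' @return `readLookupTable`: an [LDLookupTable-class]; a content-hash
#'   mismatch is an error.
#' @export
readLookupTable <- function(path) {
  all <- readLines(path)
  hdr <- all[startsWith(all, "#")]
  body <- all[!startsWith(all, "#")]
  stored <- sub("^# hash: ", "", hdr[startsWith(hdr, "# hash:")])
  dataLines <- body[-1]
  if (length(stored) == 1 &&
      !identical(stored, contentHash(paste(dataLines, collapse = "\n"))))
    stop("lookup table content hash mismatch: file corrupted or edited")
  df <- utils::read.csv(textConnection(body))
  a0 <- sort(unique(df$alpha0_deg)); sg <- sort(unique(df$sigma_deg))
  o <- order(match(df$sigma_deg, sg), match(df$alpha0_deg, a0))
  shape <- function(v) matrix(v[o], length(a0), length(sg))
  methods::new("LDLookupTable", alpha0 = a0, sigma = sg,
               b1p = shape(df$B1P), b2p = shape(df$B2P), c2p = shape(df$C2P))
}

#' FNV-1a content hash of a string
#'
#' 32-bit FNV-1a, returned as 8 hex digits; used to fingerprint lookup
#' table sidecars.
#'
#' @param txt character scalar.
#' @return character hash.
#' @export
contentHash <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h - 2^31 * (h >= 2^31)), b)
    if (h < 0) h <- h + 2^32
    ## h * 16777619 = h * 2^24 + h * 403, both exact in doubles mod 2^32
    h <- ((h %% 256) * 16777216 + (h * 403) %% 2^32) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Serialize a goodness map
#'
#' Writes `<prefix>.json` (grids, best cell, modality) and
#' `<prefix>.tif` (slices r2, RMSD, chi2, confidence as float pages).
#'
#' @param map a [GoodnessMap-class].
#' @param prefix output path prefix.
#' @export
writeGoodnessMap <- function(map, prefix) {
  methods::validObject(map)
  jsonlite::write_json(list(alpha0 = map@alpha0, sigma = map@sigma,
                            best_alpha0 = map@best[1],
                            best_sigma = map@best[2],
                            modality = map@modality),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  r2 <- map@r2; r2[!is.finite(r2)] <- 0
  sl <- array(0, dim = c(dim(r2), 4L))
  sl[, , 1] <- pmax(r2, 0); sl[, , 2] <- map@rmsd / max(map@rmsd, 1e-12)
  sl[, , 3] <- map@chi2 / max(map@chi2, 1e-12)
  sl[, , 4] <- map@confidence * 1
  writeImageTiff(sl, paste0(prefix, ".tif"))
  invisible(prefix)
}
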