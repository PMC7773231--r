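# File formats: multi-page TIFF stacks with a JSON metadata sidecar,
# two-column CSV transients, and float-TIFF parameter maps with a JSON
# manifest.  All writes are atomic (write to a temporary file in the
# target directory, then rename).

atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", "tmp"))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file to ", path)
  invisible(path)
}

#' Write a FLIM stack as multi-page TIFF plus JSON sidecar
#'
#' Time is the page axis.  Integer counts up to 65535 are stored as
#' 16-bit unsigned samples (lossless); anything else is stored as 32-bit
#' float scaled into `[0, 1]` with the scale recorded in the sidecar.
#' The sidecar records `n_bins`, `bin_width_ns`, `origin_ns`, the image
#' shape and the storage encoding.
#'
#' @param image a [flim_image()].
#' @param path_tiff output TIFF path.
#' @param path_sidecar output JSON path; default `path_tiff` with a
#'   `.json` suffix appended.
#' @return `path_tiff`, invisibly.
#' @export
write_flim_stack <- function(image, path_tiff,
                             path_sidecar = paste0(path_tiff, ".json")) {
  stopifnot(inherits(image, "flim_image"))
  d <- dim(image$counts)
  counts <- image$counts
  int16 <- all(counts == round(counts)) && max(counts) <= 65535
  scale <- if (int16) 65535 else max(counts, 1)
  pages <- lapply(seq_len(d[1]), function(j) counts[j, , ] / scale)
  atomic_write(path_tiff, function(tmp)
    tiff::writeTIFF(pages, tmp,
                    bits.per.sample = if (int16) 16L else 32L,
                    reduce = FALSE))
  meta <- list(n_bins = d[1], bin_width_ns = image$grid$bin_width_ns,
               origin_ns = image$grid$origin_ns,
               height = d[2], width = d[3],
               dtype = if (int16) "uint16" else "float32",
               scale = scale)
  atomic_write(path_sidecar, function(tmp)
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA))
  invisible(path_tiff)
}

#' Read a FLIM stack from multi-page TIFF plus JSON sidecar
#'
#' @param path_tiff TIFF file with time as the page axis.
#' @param path_sidecar JSON sidecar with at least `n_bins`,
#'   `bin_width_ns` and optionally `origin_ns`, `dtype`, `scale`.
#' @return a [flim_image()].
#' @export
read_flim_stack <- function(path_tiff,
                            path_sidecar = paste0(path_tiff, ".json")) {
  meta <- jsonlite::read_json(path_sidecar, simplifyVector = TRUE)
  for (f in c("n_bins", "bin_width_ns"))
    if (is.null(meta[[f]])) stop("sidecar is missing field '", f, "'")
  int16 <- identical(meta$dtype %||% "uint16", "uint16")
  pages <- tiff::readTIFF(path_tiff, all = TRUE, as.is = int16)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_bins)
    stop(sprintf("sidecar declares n_bins = %d but the TIFF has %d pages",
                 meta$n_bins, length(pages)))
  d2 <- dim(pages[[1]])
  counts <- array(0, dim = c(length(pages), d2[1], d2[2]))
  for (j in seq_along(pages))
    counts[j, , ] <- if (int16) pages[[j]] else pages[[j]] * meta$scale
  grid <- time_grid(meta$n_bins, meta$bin_width_ns, meta$origin_ns %||% 0)
  flim_image(counts, grid)
}

#' Read a single transient from a two-column CSV
#'
#' The file must have a header and two numeric columns `(time_ns,
#' counts)`; the time column holds bin centres on a uniform grid (spacing
#' drift beyond 1e-6 relative is an error).
#'
#' @param path CSV file path.
#' @return a [decay_curve()].
#' @export
read_transient_csv <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2 || !is.numeric(df[[1]]) || !is.numeric(df[[2]]))
    stop("transient CSV needs two numeric columns (time_ns, counts)")
  tv <- df[[1]]
  dts <- diff(tv)
  dt <- stats::median(dts)
  if (dt <= 0 || any(abs(dts - dt) > 1e-6 * abs(dt)))
    stop("time column is not uniformly spaced (tolerance 1e-6 relative)")
  grid <- time_grid(nrow(df), dt, origin_ns = tv[1] - dt / 2)
  decay_curve(df[[2]], grid)
}

#' Write a transient (or IRF) as a two-column CSV
#'
#' @param decay a [decay_curve()] or [flim_irf()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transient_csv <- function(decay, path) {
  grid <- decay$grid
  df <- data.frame(time_ns = bin_centers(grid), counts = decay$counts)
  atomic_write(path, function(tmp)
    utils::write.csv(df, tmp, row.names = FALSE))
}

#' Read an IRF from a two-column CSV
#'
#' Convenience wrapper: reads the prompt on the same CSV dialect as
#' [read_transient_csv()] and returns it as a [flim_irf()].
#'
#' @param path CSV file path.
#' @return a [flim_irf()].
#' @export
read_irf_csv <- function(path) flim_irf(read_transient_csv(path))

#' Write parameter maps as float TIFFs plus a JSON manifest
#'
#' Each map is written as one single-page 32-bit float TIFF, linearly
#' rescaled into `[0.25, 1]` with the affine transform recorded per map
#' in the manifest.  Non-finite pixels (below-threshold or failed fits)
#' are encoded as zero in the TIFF — outside the valid band — and
#' restored as NaN on read.
#'
#' @param maps a `flim_maps` object from [fit_image()].
#' @param dir output directory (created if missing).
#' @return path of the manifest file, invisibly.
#' @export
write_param_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "flim_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- list()
  for (nm in names(maps$maps)) {
    m <- maps$maps[[nm]]
    ok <- is.finite(m)
    lo <- if (any(ok)) min(m[ok]) else 0
    hi <- if (any(ok)) max(m[ok]) else 1
    span <- if (hi > lo) hi - lo else 1
    enc <- 0.25 + 0.75 * (m - lo) / span
    enc[!ok] <- 0
    file <- paste0(nm, ".tif")
    atomic_write(file.path(dir, file), function(tmp)
      tiff::writeTIFF(enc, tmp, bits.per.sample = 32L, reduce = FALSE))
    entries[[nm]] <- list(file = file, offset = lo, scale = span)
  }
  atomic_write(file.path(dir, "mask.tif"), function(tmp)
    tiff::writeTIFF(ifelse(maps$mask, 1, 0), tmp, bits.per.sample = 8L))
  manifest <- list(parameters = names(maps$maps), maps = entries,
                   mask = "mask.tif", method = maps$method,
                   n_components = maps$n_components,
                   noise = maps$noise$kind,
                   fit_range = c(maps$fit_range$start_bin,
                                 maps$fit_range$end_bin),
                   shape = dim(maps$mask))
  path <- file.path(dir, "manifest.json")
  atomic_write(path, function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' Read parameter maps written by [write_param_maps()]
#'
#' @param dir directory containing `manifest.json` and the map TIFFs.
#' @return a `flim_maps` object (without the intensity map).
#' @export
read_param_maps <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  mask <- tiff::readTIFF(file.path(dir, manifest$mask)) > 0.5
  maps <- list()
  for (nm in manifest$parameters) {
    e <- manifest$maps[[nm]]
    enc <- tiff::readTIFF(file.path(dir, e$file))
    m <- (enc - 0.25) / 0.75 * e$scale + e$offset
    m[enc < 0.125 | !mask] <- NaN
    maps[[nm]] <- m
  }
  fr <- fit_range(manifest$fit_range[1], manifest$fit_range[2])
  structure(list(maps = maps, intensity = NULL, mask = mask,
                 method = manifest$method,
                 n_components = manifest$n_components,
                 fit_range = fr, noise = noise_model(manifest$noise)),
            class = "flim_maps")
}
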