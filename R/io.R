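#' Write a diffraction stack to the portable datacube layout
#'
#' The native container is a directory of plain-text files:
#' `meta.json` (beam, detector, scan and provenance groups, each dataset with
#' a units attribute), `mask.csv`, `positions.csv`, and `frames.csv` (one row
#' per scan position, frames flattened column-major). Counts are stored as
#' integers; the provenance block is append-only.
#'
#' @param stack a [diffraction_stack()].
#' @param path directory to create/overwrite.
#' @param provenance optional named list appended to the provenance history.
#' @return `path`, invisibly.
#' @export
write_datacube <- function(stack, path, provenance = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack$frames)
  g <- stack$grid
  prev <- attr(stack, "provenance")
  prov <- c(if (is.null(prev)) list() else prev,
            if (is.null(provenance)) list() else list(provenance))
  meta <- list(
    schema = list(name = "eptycho-datacube", version = 1L),
    data = list(shape = d, units = "counts", dtype = "integer"),
    mask = list(units = "boolean"),
    scan = list(step_nm = g$nominal_step_nm, grid_shape = g$grid_shape,
                jitter_fraction = g$jitter_fraction, jitter_seed = g$seed,
                units = "nm"),
    beam = list(energy_keV = stack$energy_kev, units = "keV"),
    detector = list(reciprocal_pixel_invA = stack$reciprocal_pixel_invA,
                    center = stack$center, units = "1/Angstrom"),
    provenance = prov
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  data.table::fwrite(data.table::as.data.table(stack$mask * 1L),
                     file.path(path, "mask.csv"), col.names = FALSE)
  data.table::fwrite(g$positions, file.path(path, "positions.csv"))
  flat <- matrix(as.integer(round(stack$frames)), nrow = d[3], byrow = TRUE)
  data.table::fwrite(data.table::as.data.table(flat),
                     file.path(path, "frames.csv"), col.names = FALSE)
  invisible(path)
}

#' Read a diffraction stack from the portable datacube layout
#'
#' Lossless counterpart of [write_datacube()]. Missing groups or units raise
#' a schema error naming the field; unknown extra groups in `meta.json` are
#' preserved in a `legacy_extras` attribute.
#'
#' @param path datacube directory.
#' @return a [diffraction_stack()].
#' @export
read_datacube <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("datacube schema error: missing meta.json", call. = FALSE)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  for (grp in c("data", "mask", "scan", "beam", "detector")) {
    if (is.null(meta[[grp]])) {
      stop(sprintf("datacube schema error: missing group '%s'", grp), call. = FALSE)
    }
    if (is.null(meta[[grp]]$units)) {
      stop(sprintf("datacube schema error: group '%s' lacks a units attribute", grp),
           call. = FALSE)
    }
  }
  for (f in c("mask.csv", "positions.csv", "frames.csv")) {
    if (!file.exists(file.path(path, f))) {
      stop(sprintf("datacube schema error: missing %s", f), call. = FALSE)
    }
  }
  d <- as.integer(meta$data$shape)
  mask <- as.matrix(data.table::fread(file.path(path, "mask.csv"),
                                      header = FALSE)) > 0.5
  dimnames(mask) <- NULL
  posdf <- data.table::fread(file.path(path, "positions.csv"))
  flat <- as.matrix(data.table::fread(file.path(path, "frames.csv"),
                                      header = FALSE))
  frames <- array(0, dim = d)
  for (j in seq_len(d[3])) frames[, , j] <- matrix(flat[j, ], d[1], d[2])
  g <- structure(list(
    nominal_step_nm = meta$scan$step_nm,
    grid_shape = as.integer(meta$scan$grid_shape),
    jitter_fraction = meta$scan$jitter_fraction,
    seed = meta$scan$jitter_seed,
    positions = tibble::as_tibble(posdf)
  ), class = "scan_grid")
  out <- diffraction_stack(frames, mask, g, meta$beam$energy_keV,
                           meta$detector$reciprocal_pixel_invA,
                           center = as.numeric(meta$detector$center))
  attr(out, "provenance") <- meta$provenance
  known <- c("schema", "data", "mask", "scan", "beam", "detector", "provenance")
  extras <- meta[setdiff(names(meta), known)]
  if (length(extras)) attr(out, "legacy_extras") <- extras
  out
}

#' Render a complex wave as a colour-wheel image
#'
#' Hue encodes phase (one full hue cycle per 2 pi), brightness encodes
#' amplitude clipped to `amplitude_range`. Writes a display PNG and a
#' lossless float TIFF (amplitude and phase planes); for power-spectrum
#' display a gamma adjustment and percentile saturation are available.
#'
#' @param wave complex matrix.
#' @param path output path without extension; writes `<path>.png` and
#'   `<path>.tif`.
#' @param amplitude_range length-2 clip range; default the amplitude range.
#' @param gamma gamma applied to the brightness channel.
#' @param saturate_pct percent of extreme amplitude pixels saturated at each
#'   end before scaling (e.g. 1 for power-spectrum display).
#' @return tibble of the metadata recorded alongside (also written to
#'   `<path>.json`).
#' @export
export_complex_image <- function(wave, path, amplitude_range = NULL,
                                 gamma = 1, saturate_pct = 0) {
  amp <- Mod(wave); ph <- Arg(wave)
  if (saturate_pct > 0) {
    q <- stats::quantile(amp, c(saturate_pct / 100, 1 - saturate_pct / 100))
    amp <- pmin(pmax(amp, q[1]), q[2])
  }
  if (is.null(amplitude_range)) amplitude_range <- range(amp)
  v <- (amp - amplitude_range[1]) / max(diff(amplitude_range), 1e-300)
  v <- pmin(pmax(v, 0), 1)^gamma
  h <- (ph %% (2 * pi)) / (2 * pi)
  rgb <- grDevices::hsv(h, s = 1, v = v)
  n <- nrow(wave); m <- ncol(wave)
  arr <- array(0, dim = c(n, m, 3))
  cc <- grDevices::col2rgb(rgb) / 255
  arr[, , 1] <- matrix(cc[1, ], n, m)
  arr[, , 2] <- matrix(cc[2, ], n, m)
  arr[, , 3] <- matrix(cc[3, ], n, m)
  png::writePNG(arr, paste0(path, ".png"))
  # lossless planes scaled to [0, 1]: amplitude / amp_scale and
  # (phase + pi) / 2 pi; scales recorded in the JSON metadata
  amp_scale <- max(Mod(wave), 1e-300)
  tiff::writeTIFF(list(matrix(as.numeric(Mod(wave) / amp_scale), n, m),
                       matrix(as.numeric((ph + pi) / (2 * pi)), n, m)),
                  paste0(path, ".tif"), bits.per.sample = 32,
                  reduce = FALSE)
  meta <- tibble::tibble(amplitude_min = amplitude_range[1],
                         amplitude_max = amplitude_range[2],
                         amplitude_scale = amp_scale,
                         gamma = gamma, saturate_pct = saturate_pct)
  jsonlite::write_json(as.list(meta), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  meta
}

#' Read a run configuration
#'
#' Validates a YAML configuration document with `phantom`, `beam`,
#' `geometry`, `engine`, `distortion` and `metrics` sections; unknown
#' top-level keys are rejected and every stochastic element must carry a
#' seed.
#'
#' @param path YAML file.
#' @return named list of sections.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("phantom", "beam", "geometry", "engine", "distortion", "metrics",
             "seed", "schema_version")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop(sprintf("unknown config section(s): %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(cfg$seed)) stop("config must declare a top-level seed", call. = FALSE)
  cfg
}
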