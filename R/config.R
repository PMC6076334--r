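#' Simulation and imaging configuration
#'
#' Central container for the physical and camera parameters shared by the
#' simulator, the renderer and the statistics layer.
#'
#' @param pixel_size pixel size, um/pixel. The camera pixel size is a property
#'   of the instrument; 0.1 um/px is a typical EMCCD + 60x TIRF value and is
#'   the package default. Everything physical is derived from this value.
#' @param frame_interval time between frames, seconds (default 0.033).
#' @param field_size image size in pixels, `c(height, width)`.
#' @param n_frames default number of movie frames.
#' @param psf_sigma point-spread-function Gaussian width, pixels (default 2).
#' @param monomer_mean mean fitted peak intensity of a single fluorophore
#'   (a.u.); an n-mer draws its intensity from mean `n * monomer_mean`,
#'   variance `n * monomer_sd^2`.
#' @param monomer_sd intensity standard deviation of a single fluorophore.
#' @param background_offset camera background offset (a.u.).
#' @param background_slope planar background inclination `c(a, b)` in a.u./px
#'   along x and y.
#' @param noise_model `"poisson-gaussian"` (shot noise plus additive read
#'   noise, EMCCD-like without explicit EM gain) or `"gaussian"` or `"none"`.
#' @param read_noise_sd additive read noise SD (a.u.).
#' @param rng_seed integer seed used by simulator functions unless overridden.
#' @return object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(pixel_size = 0.1)
#' cfg$frame_interval
#' @export
sim_config <- function(pixel_size = 0.1,
                       frame_interval = 0.033,
                       field_size = c(512L, 512L),
                       n_frames = 30L,
                       psf_sigma = 2,
                       monomer_mean = 1000,
                       monomer_sd = 200,
                       background_offset = 100,
                       background_slope = c(0, 0),
                       noise_model = c("poisson-gaussian", "gaussian", "none"),
                       read_noise_sd = 10,
                       rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (pixel_size <= 0) stopf("pixel_size must be > 0")
  if (frame_interval <= 0) stopf("frame_interval must be > 0")
  if (psf_sigma <= 0) stopf("psf_sigma must be > 0")
  if (monomer_mean <= 0) stopf("monomer_mean must be > 0")
  if (monomer_sd < 0) stopf("monomer_sd must be >= 0")
  if (length(field_size) == 1L) field_size <- rep(field_size, 2L)
  structure(list(
    pixel_size = pixel_size, frame_interval = frame_interval,
    field_size = as.integer(field_size), n_frames = as.integer(n_frames),
    psf_sigma = psf_sigma, monomer_mean = monomer_mean,
    monomer_sd = monomer_sd, background_offset = background_offset,
    background_slope = background_slope, noise_model = noise_model,
    read_noise_sd = read_noise_sd, rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

#' Read / write a plain-text key=value configuration file
#'
#' @param path file path.
#' @return for `read_config`, a `sim_config`; unknown keys are ignored with a
#'   warning.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1L], collapse = "="), ""))
  known <- names(formals(sim_config))
  bad <- setdiff(keys, known)
  if (length(bad)) warning("ignoring unknown config keys: ", paste(bad, collapse = ", "))
  args <- list()
  for (i in seq_along(keys)) {
    if (!(keys[i] %in% known)) next
    v <- vals[i]
    parsed <- if (keys[i] == "noise_model") v else {
      nums <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
      if (anyNA(nums)) v else nums
    }
    args[[keys[i]]] <- parsed
  }
  do.call(sim_config, args)
}

#' @rdname read_config
#' @param config a `sim_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  fmt <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, paste(format(v, scientific = FALSE), collapse = ","))
  }, "")
  writeLines(fmt, path)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (k in names(x))
    cat(sprintf("  %-18s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  invisible(x)
}
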