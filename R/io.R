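#' Read and write trajectory files
#'
#' Trajectory files are comma-separated with header
#' `t,theta,theta_dot,tau,tau_floor,phi`, SI units (seconds, radians, N m),
#' one row per sample. Values are written with 17 significant digits so that
#' write-then-read is the identity at full double precision. Columns are
#' matched by name, so header order is free; non-uniform time stamps are
#' rejected with the offending row.
#'
#' @param path file path.
#' @return `read_trajectory` returns a `stance_trajectory` data frame.
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path, check.names = TRUE)
  need <- c("t", "theta", "theta_dot", "tau", "tau_floor", "phi")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_bad_arg("trajectory file lacks columns: ", paste(miss, collapse = ", "))
  df <- df[need]
  dts <- diff(df$t)
  if (length(dts)) {
    bad <- which(abs(dts - dts[1]) > 1e-9)
    if (length(bad))
      stop_bad_arg("non-uniform sampling in ", path, " at row ", bad[1] + 1)
  }
  attr(df, "dt") <- if (length(dts)) dts[1] else NA_real_
  class(df) <- c("stance_trajectory", "data.frame")
  df
}

write_full_precision <- function(df, path) {
  out <- as.data.frame(lapply(df, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)))
  names(out) <- names(df)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_trajectory
#' @param traj a `stance_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  need <- c("t", "theta", "theta_dot", "tau", "tau_floor", "phi")
  stopifnot(all(need %in% names(traj)))
  write_full_precision(as.data.frame(traj)[need], path)
}

#' Read and write marker files
#'
#' Comma-separated marker coordinates with header `t,<landmark>_x,
#' <landmark>_y,...` in meters at a uniform rate (nominally 200 Hz).
#'
#' @param path file path.
#' @return `read_markers` returns a [marker_frames()] object.
#' @export
read_markers <- function(path) {
  marker_frames(read.csv(path, check.names = TRUE))
}

#' @rdname read_markers
#' @param frames a [marker_frames()] object.
#' @export
write_markers <- function(frames, path) {
  write_full_precision(as.data.frame(frames), path)
}

default_config <- function() {
  list(
    body = list(m = 0.404, h = 0.107, g = 9.81, J = NULL,
                kP_mgh = 0.34, kD_mgh = 0.03, sigma_mNm = 0.50),
    floor = list(onset = 0, duration = 0.25, amplitude_deg = 8.8),
    controller = list(type = "mpc", Hp = 0.96, Hu = 0.0244, delay = 0.040,
                      preview = TRUE,
                      pd_variant = "linear"),
    sim = list(dt = 0.001, t_start = -0.35, t_end = 0.45,
               noise_scaling = "per-sample", integrator = "rk4"),
    ga = list(pop_size = 40, generations = 60, n_rep = 5)
  )
}

#' Load and validate a configuration file
#'
#' YAML with sections `body`, `floor`, `controller`, `sim`, `ga`; every
#' unspecified field takes the default experimental value (m = 0.404 kg,
#' h = 0.107 m, 8.8 deg over 0.25 s, 40 ms delay, 1 ms sampling, identified
#' controller operating point). Gains are given as multiples of `mgh` and
#' the noise magnitude in mNm; they are converted to SI internally. All
#' out-of-range values are reported together.
#'
#' @param path YAML file path, or `NULL` for the pure defaults.
#' @return A validated configuration list with class `ratstance_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (sec in intersect(names(user), names(cfg)))
      cfg[[sec]] <- modifyList(cfg[[sec]], user[[sec]])
    extra <- setdiff(names(user), names(cfg))
    if (length(extra))
      stop_bad_arg("unknown config sections: ", paste(extra, collapse = ", "))
  }
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  b <- cfg$body
  chk(b$m > 0, "body.m must be positive")
  chk(b$h > 0, "body.h must be positive")
  chk(b$g > 0, "body.g must be positive")
  chk(is.null(b$J) || b$J > 0, "body.J must be positive when given")
  chk(b$kP_mgh >= 0, "body.kP_mgh must be non-negative")
  chk(b$kD_mgh >= 0, "body.kD_mgh must be non-negative")
  chk(b$sigma_mNm >= 0, "body.sigma_mNm must be non-negative")
  chk(cfg$floor$duration > 0, "floor.duration must be positive")
  ct <- cfg$controller
  chk(ct$type %in% c("mpc", "pd", "none"), "controller.type must be mpc, pd or none")
  chk(ct$Hp > 0, "controller.Hp must be positive")
  chk(ct$Hu > 0, "controller.Hu must be positive")
  chk(ct$delay >= 0, "controller.delay must be non-negative")
  chk(cfg$sim$dt > 0, "sim.dt must be positive")
  chk(cfg$sim$t_end > cfg$sim$t_start, "sim.t_end must exceed sim.t_start")
  chk(cfg$ga$pop_size >= 4, "ga.pop_size must be at least 4")
  if (length(problems))
    stop_bad_arg("invalid configuration:\n  ",
                 paste(problems, collapse = "\n  "))
  structure(cfg, class = c("ratstance_config", "list"))
}

#' Build model objects from a configuration
#'
#' @param cfg a [load_config()] result.
#' @return A list with `params`, `profile`, `sim`, `controller` and
#'   `mpc`/`pd` configs ready for [simulate_stance()].
#' @export
config_objects <- function(cfg) {
  b <- cfg$body
  s <- b$m * b$g * b$h
  params <- pendulum_params(m = b$m, h = b$h, g = b$g,
                            J = b$J %||% (b$m * b$h^2),
                            kP = b$kP_mgh * s, kD = b$kD_mgh * s,
                            sigma = b$sigma_mNm * 1e-3)
  profile <- floor_profile(cfg$floor$onset, cfg$floor$duration,
                           cfg$floor$amplitude_deg)
  sim <- sim_config(dt = cfg$sim$dt, t_start = cfg$sim$t_start,
                    t_end = cfg$sim$t_end,
                    noise_scaling = cfg$sim$noise_scaling,
                    integrator = cfg$sim$integrator)
  ct <- cfg$controller
  mcfg <- mpc_config(Hp = ct$Hp, Hu = ct$Hu, dt = cfg$sim$dt,
                     delay = ct$delay, preview_enabled = isTRUE(ct$preview))
  controller <- switch(ct$type,
    mpc = mpc_controller(params, mcfg),
    pd = pd_controller(pd_config(ct$pd_variant), params, delay = ct$delay),
    none = no_controller())
  list(params = params, profile = profile, sim = sim, mpc = mcfg,
       controller = controller)
}

#' Run manifest for reproducible command-line runs
#'
#' Records the full configuration, an MD5 hash of its canonical YAML form,
#' the seeds used, the artifact paths and the package version, so that a
#' deterministic stage can be re-run bit-for-bit from the manifest alone.
#'
#' @param config a configuration list.
#' @param seeds named or unnamed integer seeds used by the run.
#' @param artifacts character vector of output paths.
#' @param path optional JSON path to write the manifest to.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(config, seeds, artifacts, path = NULL) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  man <- list(config = config,
              config_md5 = unname(tools::md5sum(tmp)),
              seeds = seeds,
              artifacts = artifacts,
              package_version = as.character(utils::packageVersion("ratstance")),
              timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    return(invisible(man))
  }
  man
}
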