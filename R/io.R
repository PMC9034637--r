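#' Read and write configuration files
#'
#' The YAML configuration schema mirrors [cortex_params()]: sections
#' `grid` (width, height, periodic), `actin` / `crosslinker` / `myosin`
#' (mu0, N0, gamma, E_link), `global` (E0, W3, kappa, log_base, and the
#' rule flags) and optionally `run` (n_iterations, record_every,
#' snapshot_every, seed).  A `preset` key expands into the same schema
#' with any other keys acting as overrides.
#'
#' @param params A [cortex_params()] object.
#' @param path File path.
#' @param run Optional named list written under the `run` section.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a list with `params` (a `cortex_params`) and `run`.
#' @export
write_config <- function(params, path, run = NULL) {
  stopifnot(inherits(params, "cortex_params"))
  spec <- function(i) list(mu0 = params$mu0[i], N0 = params$N0[i],
                           gamma = params$gamma[i], E_link = params$E_link[i])
  cfg <- list(
    grid = list(width = params$width, height = params$height,
                periodic = params$periodic),
    actin = spec(1), crosslinker = spec(2), myosin = spec(3),
    global = list(E0 = params$E0, W3 = params$W3, kappa = params$kappa,
                  log_base = params$log_base,
                  forbid_interior_removal = params$forbid_interior_removal,
                  ac_link_oligomers = params$ac_link_oligomers,
                  independent_positions = params$independent_positions))
  if (!is.null(run)) cfg$run <- run
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$preset)) {
    params <- cortex_preset(cfg$preset)
  } else {
    params <- cortex_params()
  }
  sp <- function(section, fallback) {
    if (is.null(section)) return(fallback)
    species_params(section$mu0 %||% fallback$mu0,
                   section$N0 %||% fallback$N0,
                   section$gamma %||% fallback$gamma,
                   section$E_link %||% fallback$E_link)
  }
  fb <- function(i) species_params(params$mu0[i], params$N0[i],
                                   params$gamma[i], params$E_link[i])
  g <- cfg$global %||% list()
  gr <- cfg$grid %||% list()
  params <- cortex_params(
    actin = sp(cfg$actin, fb(1)),
    crosslinker = sp(cfg$crosslinker, fb(2)),
    myosin = sp(cfg$myosin, fb(3)),
    E0 = g$E0 %||% params$E0, W3 = g$W3 %||% params$W3,
    width = gr$width %||% params$width, height = gr$height %||% params$height,
    periodic = gr$periodic %||% params$periodic,
    kappa = g$kappa %||% params$kappa,
    log_base = g$log_base %||% params$log_base,
    forbid_interior_removal = g$forbid_interior_removal %||%
      params$forbid_interior_removal,
    ac_link_oligomers = g$ac_link_oligomers %||% params$ac_link_oligomers,
    independent_positions = g$independent_positions %||%
      params$independent_positions)
  list(params = params, run = cfg$run)
}

#' Write a trajectory as a TSV time series
#'
#' Tab-separated, `.` decimal separator, LF line endings -- pinned so
#' identical runs produce byte-identical files.
#'
#' @param trajectory A trajectory tibble or a `cortex_sim`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(trajectory, path) {
  tr <- if (inherits(trajectory, "cortex_sim")) trajectory$trajectory
        else trajectory
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(tr), collapse = "\t"), con, sep = "\n")
  body <- do.call(paste, c(lapply(tr, format_tsv_col), list(sep = "\t")))
  if (length(body) > 0) writeLines(body, con, sep = "\n")
  invisible(path)
}

format_tsv_col <- function(x) {
  if (is.double(x)) formatC(x, digits = 15, format = "g") else as.character(x)
}

#' @rdname write_timeseries
#' @return `read_timeseries()` returns the trajectory tibble.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  tibble::as_tibble(df)
}

#' Export the filament census as TSV
#'
#' One row per filament with its orientation, length, end coordinates
#' and elastic load.
#'
#' @param state A [cortex_state()].
#' @param params A [cortex_params()] (for the load computation).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filament_census <- function(state, params, path) {
  fl <- filament_loads(state, params)
  out <- fl[, c("id", "orientation", "length", "x_pointed", "y_pointed",
                "x_barbed", "y_barbed", "e_load")]
  names(out)[1] <- "filament_id"
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  body <- do.call(paste, c(lapply(out, format_tsv_col), list(sep = "\t")))
  if (length(body) > 0) writeLines(body, con, sep = "\n")
  invisible(path)
}
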