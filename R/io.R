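#' Load and validate a run configuration
#'
#' Reads a YAML or JSON run configuration, fills defaults, rejects unknown
#' keys, and validates every force level against the named model (so an
#' island configuration with `m <= 1/2` is refused at load time).
#'
#' Recognized keys: `model` ("ou" or "island", required), `sigma0` (OU
#' noise magnitude), `protocol` (list with `kind` plus the arguments of the
#' matching `protocol_*` constructor, `levels` being a list of named force
#' vectors), `solver` (`rtol`, `atol`), `grid` (`n_cells`), `seed`,
#' `horizon`, `n_times`, `n_traj`, `dt`, `snapshot_times`, `outdir`.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return object of class `run_config`: the validated list with defaults
#'   filled and a `protocol` element instantiated as a [drive_protocol].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- c("model", "sigma0", "protocol", "solver", "grid", "seed",
               "horizon", "n_times", "n_traj", "dt", "snapshot_times",
               "outdir")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(raw$model) || !raw$model %in% c("ou", "island")) {
    stop("config must name a model: 'ou' or 'island'", call. = FALSE)
  }
  defaults <- list(sigma0 = 0.1, solver = list(rtol = 1e-8, atol = 1e-10),
                   grid = list(n_cells = 400L), seed = 1L, horizon = 40,
                   n_times = 201L, n_traj = 0L, dt = 0.01,
                   snapshot_times = NULL, outdir = ".")
  cfg <- utils::modifyList(defaults, raw)
  model <- if (cfg$model == "ou") ou_model(cfg$sigma0) else island_model()
  if (is.null(cfg$protocol) || is.null(cfg$protocol$kind)) {
    stop("config must contain a protocol with a 'kind'", call. = FALSE)
  }
  p <- cfg$protocol
  levels <- lapply(p$levels, unlist)
  for (lv in levels) assert_valid_forces(model, lv)
  cfg$protocol_spec <- p
  cfg$protocol <- switch(p$kind,
    constant = protocol_constant(levels[[1]]),
    step = protocol_step(levels[[1]], levels[[2]],
                         at = p$at %||% 0),
    square_wave = protocol_square_wave(levels, p$period,
                                       t0 = p$t0 %||% 0),
    smooth_periodic = protocol_smooth_periodic(
      levels, p$period, t0 = p$t0 %||% 0,
      ramp_fraction = p$ramp_fraction %||% 1),
    custom_table = protocol_table(p$times, levels),
    stop("unknown protocol kind: ", p$kind, call. = FALSE))
  cfg$model_object <- model
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a comparison report (or simple results) to disk
#'
#' Writes deterministic, plainly named CSV files plus a JSON manifest
#' (`manifest.json`) echoing the parameters, seeds, tolerances and package
#' version, so that any run can be reproduced from its output directory
#' alone. Density snapshot files always integrate to 1 within 1e-6.
#'
#' @param report a `dme_comparison` (or a list with any of `times`,
#'   `forces`, `observables`, `kl`, `snapshots`, `manifest`).
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put <- function(df, name) {
    f <- file.path(outdir, name)
    utils::write.csv(df, f, row.names = FALSE)
    written <<- c(written, f)
  }
  if (!is.null(report$forces)) {
    put(data.frame(t = report$times, report$forces), "effective_forces.csv")
  }
  for (nm in names(report$observables)) {
    ob <- report$observables[[nm]]
    if (!is.null(ob)) put(ob, paste0("observables_", nm, ".csv"))
  }
  if (!is.null(report$kl)) {
    put(data.frame(t = report$times, kl = report$kl), "kl.csv")
  }
  for (s in report$snapshots) {
    df <- data.frame(x = s$fpe$grid, fpe = s$fpe$values, dme = s$dme$values)
    put(df, sprintf("density_t%g.csv", s$t))
  }
  manifest <- c(report$manifest,
                list(package = "dmaxent",
                     version = as.character(utils::packageVersion("dmaxent")),
                     files = basename(written)))
  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(written, mf))
}
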