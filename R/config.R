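log_info <- function(...) message("[clickassembly] ", sprintf(...))
log_debug <- function(...) {
  if (isTRUE(getOption("clickassembly.debug")))
    message("[clickassembly:debug] ", sprintf(...))
}

#' Load and validate a run configuration
#'
#' A run config is a JSON file selecting an assembly (inline object or a
#' path relative to the config file), a backend (`"ode"` or `"ca"`), backend
#' parameters, optional analysis requests and an RNG seed. Defaults are
#' filled (seed 0, [ode_params()] defaults) and the effective configuration
#' is echoed to the log. Keys belonging to the other backend are a schema
#' error naming the offending keys.
#'
#' Recognized top-level keys: `assembly`, `overrides`, `backend`, `ode`,
#' `ca`, `analysis`, `seed`, `out_dir`.
#'
#' @param path Path to a JSON run config.
#' @return A list of class `run_config` with the resolved `assembly`
#'   (a `click_assembly`), `backend`, `params` ([ode_params()]), `init`,
#'   `help_level`, `ca` (list), `analysis` (list), `seed`, `out_dir` and
#'   `config_hash`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("run config not found: ", path)
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                          simplifyVector = TRUE)
  known <- c("assembly", "overrides", "backend", "ode", "ca", "analysis",
             "seed", "out_dir")
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("run config has unknown keys: ", paste(extra, collapse = ", "))
  if (is.null(x$backend)) x$backend <- "ode"
  if (!x$backend %in% c("ode", "ca"))
    stop("backend must be 'ode' or 'ca', got: ", x$backend)
  if (x$backend == "ode" && !is.null(x$ca))
    stop("backend 'ode' but CA-only keys present: ",
         paste(paste0("ca.", names(x$ca)), collapse = ", "))
  if (x$backend == "ca" && !is.null(x$ode))
    stop("backend 'ca' but ODE-only keys present: ",
         paste(paste0("ode.", names(x$ode)), collapse = ", "))
  if (is.null(x$assembly)) stop("run config must name an assembly")
  if (is.character(x$assembly)) {
    apath <- x$assembly
    if (!file.exists(apath))
      apath <- file.path(dirname(path), x$assembly)
    a <- read_assembly(apath)
  } else {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(x$assembly, tmp, auto_unbox = TRUE, digits = NA)
    a <- read_assembly(tmp)
  }
  if (!is.null(x$overrides)) a <- apply_overrides(a, as.list(x$overrides))
  if (is.null(x$seed)) {
    x$seed <- 0L
    log_info("seed omitted; default seed 0 filled")
  }
  ode_in <- as.list(x$ode)
  params <- ode_params(
    absolute_tolerance = ode_in$absolute_tolerance %||% 1e-9,
    relative_tolerance = ode_in$relative_tolerance %||% 1e-7,
    t_end = ode_in$t_end %||% 400,
    n_samples = ode_in$n_samples %||% 2001,
    extinction_threshold = ode_in$extinction_threshold %||% 1e-8)
  init <- ode_in$init
  if (!is.null(init)) init <- unlist(init)[a$populations$id]
  cfg <- structure(list(
    assembly = a, backend = x$backend, params = params,
    init = init, help_level = ode_in$help_level,
    ca = as.list(x$ca), analysis = as.list(x$analysis),
    seed = as.integer(x$seed), out_dir = x$out_dir,
    config_hash = fingerprint(x), path = path), class = "run_config")
  log_info("loaded run config %s (backend %s, seed %d, hash %s)",
           basename(path), cfg$backend, cfg$seed, cfg$config_hash)
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run config (%s backend, seed %d, hash %s)\n",
              x$backend, x$seed, x$config_hash))
  print(x$assembly)
  invisible(x)
}

# Machine-readable provenance record written alongside CLI outputs.
write_provenance <- function(out_dir, cfg_hash, seed, command) {
  rec <- list(package = "clickassembly",
              version = as.character(utils::packageVersion("clickassembly")),
              command = command, config_hash = cfg_hash, seed = seed)
  jsonlite::write_json(rec, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(rec)
}
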