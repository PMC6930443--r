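canonical_fixture <- function(name) {
  path <- system.file("extdata", name, package = "clickassembly")
  if (!nzchar(path))
    path <- file.path("inst", "extdata", name)  # pre-install fallback
  if (!file.exists(path)) stop("shipped fixture not found: ", name)
  path
}

# Apply a flat named override map to an assembly. Recognized keys:
#   carrying_capacity, help_level,
#   kill_rate (all edges) or kill_rate.<killer>.<victim>,
#   maturation_rate (all edges) or maturation_rate.<source>,
#   <pop>.growth_rate / .death_rate / .help_coefficient / .initial_abundance
apply_overrides <- function(a, overrides) {
  for (key in names(overrides)) {
    val <- overrides[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    if (key == "carrying_capacity") {
      a$carrying_capacity <- val
    } else if (key == "help_level") {
      a$bystander_inputs$help_level <- val
    } else if (parts[1L] == "kill_rate") {
      if (length(parts) == 1L) {
        a$kill_edges$kill_rate <- val
      } else if (length(parts) == 3L) {
        hit <- a$kill_edges$killer == parts[2L] & a$kill_edges$victim == parts[3L]
        if (!any(hit)) stop("unknown override key: ", key)
        a$kill_edges$kill_rate[hit] <- val
      } else stop("unknown override key: ", key)
    } else if (parts[1L] == "maturation_rate") {
      if (length(parts) == 1L) {
        a$maturation_edges$rate <- val
      } else if (length(parts) == 2L) {
        hit <- a$maturation_edges$source == parts[2L]
        if (!any(hit)) stop("unknown override key: ", key)
        a$maturation_edges$rate[hit] <- val
      } else stop("unknown override key: ", key)
    } else if (length(parts) == 2L && parts[1L] %in% a$populations$id &&
               parts[2L] %in% c("growth_rate", "death_rate",
                                "help_coefficient", "initial_abundance")) {
      a$populations[a$populations$id == parts[1L], parts[2L]] <- val
    } else {
      stop("unknown override key: ", key)
    }
  }
  a
}

#' The canonical 4-click assembly (Tc, Tnk, Th, Tr1)
#'
#' Builds the four-population intransitive assembly spanning the cytotoxic
#' lineage (naive cytotoxic T cells `Tc` maturing into NK-receptor-bearing
#' `Tnk`) and the type-1 helper lineage (`Th` maturing into regulatory
#' `Tr1`). The kill cycle is `Tc -| Tnk -| Th -| Tr1 -| Tc`: young cells
#' regulate the mature generation of their own lineage and mature cells
#' regulate the young generation of the other lineage. Bystander help enters
#' through `Th`. The calibrated default rates are data, shipped in
#' `inst/extdata/fig1_4click.json`; identical calls yield identical
#' assemblies.
#'
#' @param overrides Optional flat named list of parameter overrides; see the
#'   recognized keys in the details of [canonical_preset()]. Unknown keys
#'   are an error.
#' @return A strict-valid `click_assembly`.
#' @examples
#' a <- build_canonical_4click()
#' validate_assembly(a, strict = TRUE)$valid
#' smallest_directed_cycle(a)
#' @export
build_canonical_4click <- function(overrides = NULL) {
  a <- read_assembly(canonical_fixture("fig1_4click.json"))
  if (!is.null(overrides)) a <- apply_overrides(a, overrides)
  a
}

#' Shipped canonical presets
#'
#' Loads one of the calibrated run presets that ship with the package:
#' \describe{
#'   \item{`"fig2a"`}{the resting default: ODE run of the canonical 4-click
#'     at the default bystander help; converges to the Tr1-dominant
#'     coexistence equilibrium.}
#'   \item{`"fig2b"`}{the Tnk-knockdown preset: Tnk initial abundance zero
#'     and a reduced Tc maturation rate; the attractor flips to
#'     Tc-dominant.}
#'   \item{`"fig2c"`}{the bystander-help scan: help grid spanning both
#'     regimes, plus the calibrated transition-window and bistable help
#'     levels and the transition time window used for return maps.}
#' }
#' Override keys accepted by `overrides` arguments across the package:
#' `carrying_capacity`, `help_level`, `kill_rate` (all edges) or
#' `kill_rate.<killer>.<victim>`, `maturation_rate` (all edges) or
#' `maturation_rate.<source>`, and `<pop>.growth_rate`, `<pop>.death_rate`,
#' `<pop>.help_coefficient`, `<pop>.initial_abundance`.
#'
#' @param name One of `"fig2a"`, `"fig2b"`, `"fig2c"`.
#' @return A `run_config` (see [load_run_config()]).
#' @export
canonical_preset <- function(name = c("fig2a", "fig2b", "fig2c")) {
  name <- match.arg(name)
  load_run_config(canonical_fixture(paste0(name, ".config.json")))
}
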