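#' Read a click assembly from a JSON config file
#'
#' The config dialect has top-level keys `populations`, `kill_edges`,
#' `maturation_edges`, `bystander_inputs` and `carrying_capacity`; a formal
#' JSON schema ships at `system.file("extdata", "assembly.schema.json",
#' package = "clickassembly")`. Missing optional fields receive defaults
#' (death rate 0, help coefficient 0, kill rate 1, empty mechanism).
#'
#' @param path Path to a JSON assembly config.
#' @return A `click_assembly`.
#' @export
read_assembly <- function(path) {
  if (!file.exists(path)) stop("assembly config not found: ", path)
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  req <- "populations"
  missing_keys <- setdiff(req, names(x))
  if (length(missing_keys))
    stop("assembly config is missing required keys: ",
         paste(missing_keys, collapse = ", "))
  pops <- as.data.frame(x$populations, stringsAsFactors = FALSE)
  for (f in c("id", "lineage", "stage"))
    if (is.null(pops[[f]]))
      stop("assembly config populations lack field: ", f)
  if (is.null(pops$growth_rate)) pops$growth_rate <- 1
  if (is.null(pops$death_rate)) pops$death_rate <- 0
  if (is.null(pops$help_coefficient)) pops$help_coefficient <- 0
  if (is.null(pops$initial_abundance)) pops$initial_abundance <- 0.1
  fix_df <- function(df, defaults) {
    if (is.null(df) || !length(df)) return(NULL)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
    df
  }
  ke <- fix_df(x$kill_edges, list(kill_rate = 1, mechanism = ""))
  me <- fix_df(x$maturation_edges, list(rate = 0.1))
  bi <- fix_df(x$bystander_inputs, list(help_level = 0))
  K <- if (is.null(x$carrying_capacity)) 1 else x$carrying_capacity
  assembly(pops, ke, me, bi, carrying_capacity = K)
}

#' Write a click assembly to a JSON config file
#'
#' @param a A `click_assembly`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(a, path) {
  x <- list(populations = a$populations,
            kill_edges = a$kill_edges,
            maturation_edges = a$maturation_edges,
            bystander_inputs = a$bystander_inputs,
            carrying_capacity = a$carrying_capacity)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Serialize a validation report to JSON
#'
#' @param report A `validation_report` from [validate_assembly()].
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
write_validation_report <- function(report, path = NULL) {
  x <- list(valid = report$valid, violations = report$violations)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, dataframe = "rows",
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# Stable fingerprint of any R value: polynomial rolling hash of its JSON
# serialization, reported as hex. Not cryptographic; provenance only.
fingerprint <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h1 <- 0; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 131 + b) %% 2147483629
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

#' Write a trajectory as tab-separated values
#'
#' Format: `#`-prefixed metadata comment lines, then a mandatory header row
#' `time` plus one column per population id, then one row per output time.
#'
#' @param traj A `click_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- traj$metadata
  for (nm in names(meta)) {
    val <- meta[[nm]]
    if (!is.character(val) || length(val) != 1L)
      val <- as.character(jsonlite::toJSON(val, auto_unbox = TRUE, digits = NA))
    writeLines(sprintf("# %s: %s", nm, val), con)
  }
  tab <- cbind(time = traj$times, traj$abundances)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path Path to a trajectory TSV.
#' @return A `click_trajectory`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_meta]) {
    body <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", body)
    val <- sub("^[^:]*:\\s*", "", body)
    parsed <- tryCatch(jsonlite::fromJSON(val), error = function(e) val)
    meta[[key]] <- parsed
  }
  tab <- utils::read.table(text = lines[!is_meta], sep = "\t", header = TRUE,
                           check.names = FALSE)
  new_trajectory(times = tab$time,
                 abundances = as.matrix(tab[, -1L, drop = FALSE]),
                 metadata = meta)
}

new_trajectory <- function(times, abundances, metadata) {
  structure(list(times = times, abundances = abundances, metadata = metadata),
            class = "click_trajectory")
}

#' @export
print.click_trajectory <- function(x, ...) {
  cat(sprintf("click trajectory (%s backend): %d time points, populations %s\n",
              x$metadata$backend %||% "?", length(x$times),
              paste(colnames(x$abundances), collapse = ", ")))
  fin <- x$abundances[nrow(x$abundances), ]
  cat("  final state:", paste(sprintf("%s=%.4f", colnames(x$abundances), fin),
                              collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a dice set from a JSON config file
#'
#' The file holds a list of `{label, faces}` records, 6 integer faces each.
#'
#' @param path Path to a JSON dice config.
#' @return A named list of [die()] objects, in file order.
#' @export
read_dice <- function(path) {
  if (!file.exists(path)) stop("dice config not found: ", path)
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  dice <- lapply(x, function(d) die(d$label, unlist(d$faces)))
  stats::setNames(dice, vapply(dice, function(d) d$label, character(1)))
}

#' Write a dice set to a JSON config file
#'
#' @param dice A list of [die()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dice <- function(dice, path) {
  x <- lapply(dice, function(d) list(label = d$label, faces = d$faces))
  names(x) <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
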