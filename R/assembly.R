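#' Define a cell population
#'
#' A population is one node of a click assembly: a cell type at a given
#' maturational stage within a lineage, with its demographic parameters.
#' Abundances are on a normalized response scale in \[0, 1\].
#'
#' @param id Short unique string label (e.g. `"Tc"`).
#' @param lineage Lineage name (e.g. `"cytotoxic"`, `"helper"`).
#' @param stage Maturational stage, `"young"` or `"mature"`.
#' @param growth_rate Per-unit-time self-renewal rate r >= 0.
#' @param death_rate Per-unit-time spontaneous death rate d >= 0.
#' @param help_coefficient Dimensionless sensitivity beta >= 0 of growth to
#'   bystander help: growth is scaled by `(1 + beta * h)` where `h` is the
#'   help level delivered to this population.
#' @param initial_abundance Starting abundance in \[0, 1\].
#' @return A one-row `data.frame` suitable for [assembly()].
#' @export
population <- function(id, lineage, stage = c("young", "mature"),
                       growth_rate = 1, death_rate = 0,
                       help_coefficient = 0, initial_abundance = 0.1) {
  stage <- match.arg(stage)
  data.frame(id = as.character(id), lineage = as.character(lineage),
             stage = stage, growth_rate = growth_rate,
             death_rate = death_rate, help_coefficient = help_coefficient,
             initial_abundance = initial_abundance,
             stringsAsFactors = FALSE)
}

#' Define a click (directed kill edge)
#'
#' A click is a receptor-ligand pairing between two cell types that triggers
#' the death of exactly one of them: the `victim`. Killing is directional and
#' at most one click may connect any unordered pair of populations.
#'
#' @param killer,victim Population ids.
#' @param kill_rate Mass-action kill rate kappa >= 0 (per unit time per unit
#'   killer abundance).
#' @param mechanism Free-text annotation (e.g. `"NK receptor"`,
#'   `"CTLA4 transendocytosis"`); not interpreted by the model.
#' @return A one-row `data.frame` suitable for [assembly()].
#' @export
kill_edge <- function(killer, victim, kill_rate = 1, mechanism = "") {
  data.frame(killer = as.character(killer), victim = as.character(victim),
             kill_rate = kill_rate, mechanism = as.character(mechanism),
             stringsAsFactors = FALSE)
}

#' Define a within-lineage maturation edge
#'
#' @param source Young population id.
#' @param target Mature population id in the same lineage.
#' @param rate Per-unit-time maturation flow rate m >= 0.
#' @return A one-row `data.frame` suitable for [assembly()].
#' @export
maturation_edge <- function(source, target, rate = 0.1) {
  data.frame(source = as.character(source), target = as.character(target),
             rate = rate, stringsAsFactors = FALSE)
}

#' Define a bystander help input
#'
#' Bystander help (cytokines, tissue factors) scales the growth of its target
#' population without altering the intransitive kill wiring. The help level
#' `h` is the model's main control parameter.
#'
#' @param target Population id receiving help.
#' @param help_level Dimensionless help level h >= 0.
#' @return A one-row `data.frame` suitable for [assembly()].
#' @export
bystander_input <- function(target, help_level = 0) {
  data.frame(target = as.character(target), help_level = help_level,
             stringsAsFactors = FALSE)
}

empty_df <- function(...) {
  cols <- list(...)
  as.data.frame(lapply(cols, function(type) vector(type, 0L)),
                stringsAsFactors = FALSE)
}

#' Assemble populations and edges into a click assembly
#'
#' @param populations `data.frame` of rows from [population()].
#' @param kill_edges `data.frame` of rows from [kill_edge()] (may be empty).
#' @param maturation_edges `data.frame` of rows from [maturation_edge()].
#' @param bystander_inputs `data.frame` of rows from [bystander_input()].
#' @param carrying_capacity Normalization K > 0 of total abundance
#'   (default 1, the normalized response scale).
#' @return An object of class `click_assembly`.
#' @seealso [validate_assembly()], [build_canonical_4click()]
#' @export
assembly <- function(populations,
                     kill_edges = NULL, maturation_edges = NULL,
                     bystander_inputs = NULL, carrying_capacity = 1) {
  if (is.null(kill_edges) || nrow(kill_edges) == 0L)
    kill_edges <- empty_df(killer = "character", victim = "character",
                           kill_rate = "numeric", mechanism = "character")
  if (is.null(maturation_edges) || nrow(maturation_edges) == 0L)
    maturation_edges <- empty_df(source = "character", target = "character",
                                 rate = "numeric")
  if (is.null(bystander_inputs) || nrow(bystander_inputs) == 0L)
    bystander_inputs <- empty_df(target = "character", help_level = "numeric")
  structure(list(populations = populations,
                 kill_edges = kill_edges,
                 maturation_edges = maturation_edges,
                 bystander_inputs = bystander_inputs,
                 carrying_capacity = carrying_capacity),
            class = "click_assembly")
}

#' @export
print.click_assembly <- function(x, ...) {
  cat(sprintf("click assembly: %d populations, %d kill edges, %d maturation edges, %d bystander inputs (K = %g)\n",
              nrow(x$populations), nrow(x$kill_edges),
              nrow(x$maturation_edges), nrow(x$bystander_inputs),
              x$carrying_capacity))
  if (nrow(x$populations))
    cat("  populations:", paste(x$populations$id, collapse = ", "), "\n")
  if (nrow(x$kill_edges))
    cat("  clicks:", paste(sprintf("%s -| %s", x$kill_edges$killer,
                                   x$kill_edges$victim), collapse = ", "), "\n")
  invisible(x)
}

violation <- function(rule, message, elements) {
  data.frame(rule = rule, message = message,
             elements = paste(elements, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Validate a click assembly against the click rules
#'
#' Checks the structural invariants of a click assembly. The two core rules
#' are: clicks are exclusive to a pair of cells (at most one kill edge per
#' unordered pair of populations, so mutual kills are forbidden), and killing
#' is directional (no self-kills; exactly one partner dies). Strict mode
#' additionally enforces the canonical wiring of the 4-click: maturation
#' edges run young to mature within one lineage, within-lineage kill edges
#' run young to mature, and cross-lineage kill edges run mature to young
#' (newly generated cells regulate an older generation, not its progeny).
#'
#' All problems surface in the report; malformed references are violations,
#' not errors, so the validator never throws on bad wiring.
#'
#' @param a A `click_assembly`.
#' @param strict Logical; enforce the canonical young/old wiring rules.
#' @return An object of class `validation_report`: list with `valid`
#'   (logical) and `violations` (`data.frame` with columns `rule`,
#'   `message`, `elements`). `valid` is `TRUE` iff `violations` is empty.
#' @export
validate_assembly <- function(a, strict = FALSE) {
  v <- list()
  pops <- a$populations
  ids <- pops$id

  if (anyDuplicated(ids))
    v[[length(v) + 1L]] <- violation("pop-id-unique",
      "population ids must be unique", unique(ids[duplicated(ids)]))
  bad_stage <- !pops$stage %in% c("young", "mature")
  if (any(bad_stage))
    v[[length(v) + 1L]] <- violation("pop-stage",
      "stage must be 'young' or 'mature'", ids[bad_stage])
  rates <- cbind(pops$growth_rate, pops$death_rate, pops$help_coefficient)
  bad_rate <- apply(rates, 1L, function(r) any(!is.finite(r) | r < 0))
  if (any(bad_rate))
    v[[length(v) + 1L]] <- violation("pop-rates",
      "growth, death and help coefficients must be finite and >= 0",
      ids[bad_rate])
  bad_init <- !is.finite(pops$initial_abundance) |
    pops$initial_abundance < 0 | pops$initial_abundance > 1
  if (any(bad_init))
    v[[length(v) + 1L]] <- violation("pop-init",
      "initial abundance must lie in [0, 1]", ids[bad_init])
  if (!is.finite(a$carrying_capacity) || a$carrying_capacity <= 0)
    v[[length(v) + 1L]] <- violation("carrying-capacity",
      "carrying capacity must be finite and > 0", "K")

  ke <- a$kill_edges
  if (nrow(ke)) {
    bad_ref <- !(ke$killer %in% ids) | !(ke$victim %in% ids)
    if (any(bad_ref))
      v[[length(v) + 1L]] <- violation("kill-ref",
        "kill edge endpoints must reference existing populations",
        paste0(ke$killer[bad_ref], "-|", ke$victim[bad_ref]))
    self <- ke$killer == ke$victim
    if (any(self))
      v[[length(v) + 1L]] <- violation("kill-directional",
        "a population cannot click with itself", ke$killer[self])
    pair <- apply(cbind(ke$killer, ke$victim), 1L,
                  function(p) paste(sort(p), collapse = "|"))
    dup <- duplicated(pair) | duplicated(pair, fromLast = TRUE)
    if (any(dup & !self))
      v[[length(v) + 1L]] <- violation("kill-exclusive",
        "at most one click per unordered pair of populations; mutual kill edges are forbidden",
        unique(pair[dup & !self]))
    bad_kr <- !is.finite(ke$kill_rate) | ke$kill_rate < 0
    if (any(bad_kr))
      v[[length(v) + 1L]] <- violation("kill-rate",
        "kill rates must be finite and >= 0",
        paste0(ke$killer[bad_kr], "-|", ke$victim[bad_kr]))
  }

  me <- a$maturation_edges
  if (nrow(me)) {
    bad_ref <- !(me$source %in% ids) | !(me$target %in% ids)
    if (any(bad_ref))
      v[[length(v) + 1L]] <- violation("maturation-ref",
        "maturation edge endpoints must reference existing populations",
        paste0(me$source[bad_ref], "->", me$target[bad_ref]))
    if (anyDuplicated(me$source))
      v[[length(v) + 1L]] <- violation("maturation-out",
        "each population has at most one outgoing maturation edge",
        unique(me$source[duplicated(me$source)]))
    if (anyDuplicated(me$target))
      v[[length(v) + 1L]] <- violation("maturation-in",
        "each population has at most one incoming maturation edge",
        unique(me$target[duplicated(me$target)]))
    bad_mr <- !is.finite(me$rate) | me$rate < 0
    if (any(bad_mr))
      v[[length(v) + 1L]] <- violation("maturation-rate",
        "maturation rates must be finite and >= 0",
        paste0(me$source[bad_mr], "->", me$target[bad_mr]))
  }

  bi <- a$bystander_inputs
  if (nrow(bi)) {
    bad_ref <- !(bi$target %in% ids)
    if (any(bad_ref))
      v[[length(v) + 1L]] <- violation("bystander-ref",
        "bystander input targets must reference existing populations",
        bi$target[bad_ref])
    bad_h <- !is.finite(bi$help_level) | bi$help_level < 0
    if (any(bad_h))
      v[[length(v) + 1L]] <- violation("bystander-level",
        "help levels must be finite and >= 0", bi$target[bad_h])
  }

  if (strict) {
    stage_of <- stats::setNames(pops$stage, ids)
    lin_of <- stats::setNames(pops$lineage, ids)
    if (nrow(me)) {
      ok_ref <- me$source %in% ids & me$target %in% ids
      bad_lin <- ok_ref & (lin_of[me$source] != lin_of[me$target] |
                             stage_of[me$source] != "young" |
                             stage_of[me$target] != "mature")
      if (any(bad_lin))
        v[[length(v) + 1L]] <- violation("maturation-lineage",
          "maturation must run young -> mature within one lineage",
          paste0(me$source[bad_lin], "->", me$target[bad_lin]))
    }
    if (nrow(ke)) {
      ok_ref <- ke$killer %in% ids & ke$victim %in% ids & ke$killer != ke$victim
      same_lin <- ok_ref & lin_of[ke$killer] == lin_of[ke$victim]
      bad_within <- same_lin & !(stage_of[ke$killer] == "young" &
                                   stage_of[ke$victim] == "mature")
      bad_cross <- ok_ref & !same_lin & !(stage_of[ke$killer] == "mature" &
                                            stage_of[ke$victim] == "young")
      bad <- bad_within | bad_cross
      if (any(bad))
        v[[length(v) + 1L]] <- violation("kill-wiring",
          "canonical wiring: within-lineage clicks young -> mature, cross-lineage clicks mature -> young",
          paste0(ke$killer[bad], "-|", ke$victim[bad]))
    }
  }

  violations <- if (length(v)) do.call(rbind, v) else
    empty_df(rule = "character", message = "character", elements = "character")
  structure(list(valid = nrow(violations) == 0L, violations = violations),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$valid) {
    cat("assembly is valid\n")
  } else {
    cat(sprintf("assembly is INVALID (%d violations):\n", nrow(x$violations)))
    for (i in seq_len(nrow(x$violations)))
      cat(sprintf("  [%s] %s (%s)\n", x$violations$rule[i],
                  x$violations$message[i], x$violations$elements[i]))
  }
  invisible(x)
}

#' Generate a random strict-valid click assembly
#'
#' Builds `n_lineages` lineages, each with a young and a mature stage, wired
#' as one directed kill cycle obeying the canonical rules (young kills mature
#' within a lineage; mature kills the young of the next lineage), with
#' young -> mature maturation edges and a bystander input on the first young
#' population. Rates are drawn uniformly: growth in \[0.5, 1.5\], death in
#' \[0, 0.2\], kill in \[0.5, 3\], maturation in \[0.02, 0.3\], initial
#' abundances in \[0.05, 0.25\]. Mainly a property-test fixture generator.
#'
#' @param n_lineages Number of lineages (>= 2); the assembly has
#'   `2 * n_lineages` populations.
#' @param rng_seed Integer seed; the same seed yields an identical assembly.
#' @return A strict-valid `click_assembly`.
#' @export
random_assembly <- function(n_lineages, rng_seed = 0L) {
  if (n_lineages < 2L)
    stop("random_assembly() needs at least 2 lineages")
  with_preserved_rng({
    set.seed(rng_seed)
    pops <- list(); kes <- list(); mes <- list()
    for (i in seq_len(n_lineages)) {
      lin <- sprintf("L%02d", i)
      yid <- paste0(lin, "y"); mid <- paste0(lin, "m")
      pops[[2L * i - 1L]] <- population(yid, lin, "young",
        growth_rate = stats::runif(1, 0.5, 1.5),
        death_rate = stats::runif(1, 0, 0.2),
        initial_abundance = stats::runif(1, 0.05, 0.25))
      pops[[2L * i]] <- population(mid, lin, "mature",
        growth_rate = stats::runif(1, 0.5, 1.5),
        death_rate = stats::runif(1, 0, 0.2),
        initial_abundance = stats::runif(1, 0.05, 0.25))
      kes[[2L * i - 1L]] <- kill_edge(yid, mid,
        kill_rate = stats::runif(1, 0.5, 3))
      nxt <- sprintf("L%02dy", i %% n_lineages + 1L)
      kes[[2L * i]] <- kill_edge(mid, nxt, kill_rate = stats::runif(1, 0.5, 3))
      mes[[i]] <- maturation_edge(yid, mid, rate = stats::runif(1, 0.02, 0.3))
    }
    assembly(do.call(rbind, pops), do.call(rbind, kes), do.call(rbind, mes),
             bystander_input("L01y", help_level = 0))
  })
}

# Evaluate expr without disturbing the caller's RNG stream.
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}
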