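#' Define a six-faced die
#'
#' @param label String label (e.g. `"A"`).
#' @param faces Exactly 6 finite integer face values (repeats allowed).
#' @return A list of class `click_die`.
#' @export
die <- function(label, faces) {
  faces <- as.integer(faces)
  if (length(faces) != 6L || any(is.na(faces)))
    stop("a die has exactly 6 finite integer faces")
  structure(list(label = as.character(label), faces = faces),
            class = "click_die")
}

#' @export
print.click_die <- function(x, ...) {
  cat(sprintf("die %s: {%s}\n", x$label, paste(x$faces, collapse = ", ")))
  invisible(x)
}

#' The canonical Efron dice set
#'
#' Four dice forming a directed cycle A beats B beats C beats D beats A,
#' each edge with win probability exactly 24/36 = 2/3 and no draws. The set
#' ships as `inst/extdata/efron.json`; face values are the classical Efron
#' numbering.
#'
#' @return Named list of four [die()] objects A, B, C, D.
#' @export
efron_dice <- function() {
  read_dice(canonical_fixture("efron.json"))
}

#' Exact win probability of one die against another
#'
#' Enumerates all 36 ordered face pairs with integer arithmetic; no floating
#' point enters the probabilities, which are returned as counts over 36.
#'
#' @param a,b [die()] objects (`a` is the candidate winner).
#' @return A `win_record`: list with integer counts `wins`, `losses`,
#'   `draws` (summing to 36), the implied numerics `p_win`, `p_loss`,
#'   `p_draw`, and the labels.
#' @export
win_probability <- function(a, b) {
  stopifnot(inherits(a, "click_die"), inherits(b, "click_die"))
  diffs <- outer(a$faces, b$faces, "-")
  wins <- sum(diffs > 0L)
  losses <- sum(diffs < 0L)
  draws <- 36L - wins - losses
  structure(list(a = a$label, b = b$label,
                 wins = wins, losses = losses, draws = draws,
                 p_win = wins / 36, p_loss = losses / 36, p_draw = draws / 36),
            class = "win_record")
}

#' @export
print.win_record <- function(x, ...) {
  cat(sprintf("%s vs %s: win %d/36, loss %d/36, draw %d/36\n",
              x$a, x$b, x$wins, x$losses, x$draws))
  invisible(x)
}

#' Verify that an ordered dice set forms an intransitive cycle
#'
#' True iff every die beats its cyclic successor with win probability
#' strictly above 1/2 and zero draws — the Efron tournament condition under
#' which no single die wins against all others, yet a winning reply always
#' exists.
#'
#' @param dice Ordered list of at least 3 [die()] objects.
#' @return List with `intransitive` (logical), `cycle` (labels in order if
#'   intransitive, else `character(0)`) and `edges` (list of `win_record`
#'   for each successive pair).
#' @export
verify_intransitive_cycle <- function(dice) {
  if (length(dice) < 3L)
    stop("an intransitive cycle needs at least 3 dice")
  n <- length(dice)
  edges <- lapply(seq_len(n), function(i)
    win_probability(dice[[i]], dice[[i %% n + 1L]]))
  ok <- all(vapply(edges, function(e) e$wins > 18L && e$draws == 0L,
                   logical(1)))
  labels <- unname(vapply(dice, function(d) d$label, character(1)))
  list(intransitive = ok,
       cycle = if (ok) labels else character(0),
       edges = edges)
}

#' Pick the best reply die against a known opponent
#'
#' The winning strategy of the Efron tournament: choose only after the
#' opponent has. Returns the pool die with the highest exact win
#' probability; ties break by lexicographic label order.
#'
#' @param opponent The opponent's [die()].
#' @param pool Non-empty list of candidate [die()] objects.
#' @return List with `die` (the best reply) and `record` (its
#'   `win_record` against the opponent).
#' @export
best_response <- function(opponent, pool) {
  if (length(pool) == 0L) stop("best_response() needs a non-empty pool")
  recs <- lapply(pool, win_probability, b = opponent)
  wins <- vapply(recs, function(r) r$wins, integer(1))
  labels <- vapply(pool, function(d) d$label, character(1))
  best <- order(-wins, labels)[1L]
  list(die = pool[[best]], record = recs[[best]])
}

#' Simulate repeated rolls of one die against another
#'
#' Stochastic cross-check of [win_probability()]: seeded simulation of
#' `n_rolls` matches, returning the empirical win fraction, which converges
#' to the enumerated probability at the binomial rate.
#'
#' @param a,b [die()] objects.
#' @param n_rolls Number of rolls (>= 1).
#' @param seed Integer RNG seed.
#' @return Empirical fraction of rolls won by `a`.
#' @export
monte_carlo_match <- function(a, b, n_rolls, seed = 0L) {
  if (n_rolls < 1L) stop("n_rolls must be >= 1")
  with_preserved_rng({
    set.seed(seed)
    fa <- sample(a$faces, n_rolls, replace = TRUE)
    fb <- sample(b$faces, n_rolls, replace = TRUE)
    mean(fa > fb)
  })
}

#' Full round-robin tournament over a dice set
#'
#' @param dice Named or ordered list of [die()] objects.
#' @return A `tournament_result`: list with `dice` (labels), `records`
#'   (matrix-indexed list of `win_record` for every ordered pair),
#'   `win_matrix` (numeric p_win), `intransitive_cycle_found` and `cycle`.
#' @export
dice_tournament <- function(dice) {
  labels <- vapply(dice, function(d) d$label, character(1))
  n <- length(dice)
  wm <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  records <- vector("list", n * n)
  dim(records) <- c(n, n)
  dimnames(records) <- list(labels, labels)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    rec <- win_probability(dice[[i]], dice[[j]])
    records[[i, j]] <- rec
    wm[i, j] <- rec$p_win
  }
  ver <- if (n >= 3L) verify_intransitive_cycle(dice) else
    list(intransitive = FALSE, cycle = character(0))
  structure(list(dice = labels, records = records, win_matrix = wm,
                 intransitive_cycle_found = ver$intransitive,
                 cycle = ver$cycle),
            class = "tournament_result")
}

#' @export
print.tournament_result <- function(x, ...) {
  cat("dice tournament, p(row beats column):\n")
  print(round(x$win_matrix, 4))
  if (x$intransitive_cycle_found)
    cat("intransitive cycle:", paste(x$cycle, collapse = " > "), ">",
        x$cycle[1L], "\n")
  invisible(x)
}

#' Write a tournament result as a TSV matrix
#'
#' One row per ordered pair with rational (`wins/36`) and decimal columns.
#'
#' @param tr A `tournament_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tournament <- function(tr, path) {
  rows <- list()
  for (i in tr$dice) for (j in tr$dice) {
    if (i == j) next
    rec <- tr$records[[i, j]]
    rows[[length(rows) + 1L]] <- data.frame(
      a = i, b = j, rational = sprintf("%d/36", rec$wins),
      p_win = rec$p_win, p_draw = rec$p_draw, stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
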