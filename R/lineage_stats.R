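#' @title Lineage-level analytics
#' @description Pure functions over a [lineage_db]: population expansion
#' curves, event tallies, post-MD/CF fate patterns, doubling-time statistics,
#' per-lineage SNA1 summaries and the reproductive MD-progeny estimate.
#' @name lineage_stats
NULL

# Alive-at-t rule shared by population_curve() and the TME engine:
# a cell is counted at t when birth <= t < fate_time, except that cells
# alive at observation end (ALIVE_END) are counted through fate_time itself.
count_alive_at <- function(birth, fate_time, fate, times) {
  vapply(times, function(t)
    sum(birth <= t & (t < fate_time | (fate == "ALIVE_END" & t <= fate_time))),
    0L)
}

#' Population expansion curve
#'
#' Number of cells alive at each observation frame. With `normalize_to` the
#' whole series is rescaled so that the first time point equals it (e.g. 100,
#' mirroring curves adjusted to 100 progenitors at time point 1).
#'
#' @param db a [lineage_db].
#' @param normalize_to optional count for the first time point.
#' @param times time grid in minutes; defaults to every frame from 0 to the
#'   observation end.
#' @return data.frame with columns `time` and `n` (and `n_raw` when
#'   normalized).
#' @export
population_curve <- function(db, normalize_to = NULL, times = NULL) {
  if (is.null(times))
    times <- seq(0, observation_end(db), by = frame_interval(db))
  n <- count_alive_at(db$birth_time, db$fate_time, db$fate, times)
  out <- data.frame(time = times, n = as.numeric(n))
  if (!is.null(normalize_to) && nrow(out)) {
    out$n_raw <- out$n
    if (out$n_raw[1] > 0) out$n <- out$n * normalize_to / out$n_raw[1]
  }
  out
}

#' Per-lineage and population totals of MD, CD and CF events
#'
#' @param db a [lineage_db].
#' @return list with `total` (named vector MD/CD/CF) and `per_lineage`
#'   (data.frame `lineage_id`, `md`, `cd`, `cf`).
#' @export
event_totals <- function(db) {
  lin <- sort(unique(db$lineage_id))
  per <- data.frame(
    lineage_id = lin,
    md = vapply(lin, function(l) sum(db$fate == "MD" & db$lineage_id == l), 0L),
    cd = vapply(lin, function(l) sum(db$fate == "CD" & db$lineage_id == l), 0L),
    cf = vapply(lin, function(l) sum(db$fate == "CF" & db$lineage_id == l), 0L))
  list(total = c(MD = sum(per$md), CD = sum(per$cd), CF = sum(per$cf)),
       per_lineage = per)
}

PATTERN_PRIORS <- c("CF", "MD")
PATTERN_NEXTS <- c("BD", "MD", "CD", "CF")

#' Fates of cells produced by multipolar division and cell fusion
#'
#' For every product of an MD or CF event whose own fate is a recorded
#' terminal event (BD/MD/CD/CF), the pattern `"<parent event> > <own fate>"`
#' is incremented; products still alive at observation end count nothing.
#' Combined `"MD + CF > X"` totals are the sums of the two components.
#'
#' @param db a [lineage_db].
#' @return named integer vector over patterns `"CF > BD"`, ..., `"MD > CF"`,
#'   plus the combined `"MD + CF > BD"`, ... totals.
#' @export
fate_patterns <- function(db) {
  counts <- stats::setNames(
    integer(length(PATTERN_PRIORS) * length(PATTERN_NEXTS)),
    as.vector(outer(PATTERN_PRIORS, PATTERN_NEXTS,
                    function(a, b) paste(a, ">", b))))
  key <- paste(db$lineage_id, db$cell_id)
  p1 <- match(paste(db$lineage_id, db$parent1), key)
  for (i in seq_len(nrow(db))) {
    prior <- if (!is.na(db$parent2[i])) "CF"
             else if (!is.na(p1[i]) && db$fate[p1[i]] == "MD") "MD"
             else next
    if (db$fate[i] %in% PATTERN_NEXTS) {
      pat <- paste(prior, ">", db$fate[i])
      counts[pat] <- counts[pat] + 1L
    }
  }
  comb <- stats::setNames(
    vapply(PATTERN_NEXTS, function(nx)
      sum(counts[paste(PATTERN_PRIORS, ">", nx)]), 0L),
    paste("MD + CF >", PATTERN_NEXTS))
  c(counts, comb)
}

#' Doubling-time statistics (BD-to-BD intervals)
#'
#' A cell qualifies when it was born from a bipolar division and itself
#' divides bipolarly; its doubling time is `fate_time - birth_time`.
#'
#' @param db a [lineage_db].
#' @return list with `n`, `mean`, `min`, `max` (minutes) and `mean_h`
#'   (hours); all `NA` with `n = 0` when no cell qualifies.
#' @export
doubling_time_stats <- function(db) {
  iv <- bd_bd_intervals(db)
  if (!length(iv))
    return(list(n = 0L, mean = NA_real_, min = NA_real_, max = NA_real_,
                mean_h = NA_real_))
  list(n = length(iv), mean = mean(iv), min = min(iv), max = max(iv),
       mean_h = mean(iv) / 60)
}

bd_bd_intervals <- function(db, subset = NULL) {
  key <- paste(db$lineage_id, db$cell_id)
  p1 <- match(paste(db$lineage_id, db$parent1), key)
  ok <- db$fate == "BD" & is.na(db$parent2) & !is.na(p1) & db$fate[pmax(p1, 1)] == "BD"
  ok[is.na(ok)] <- FALSE
  if (!is.null(subset)) ok <- ok & subset
  (db$fate_time - db$birth_time)[ok]
}

#' Per-lineage summaries and the size-vs-SNA1 regression
#'
#' One row per lineage: total cell count, summed SNA1 (back-propagated values
#' included when present), MD/CD/CF counts, and the SNA1 category used to bin
#' lineages: `low` (< 2000), `mid` (2000-3999) and `high` (>= 4000) total
#' SNA1 units.
#'
#' @param db a [lineage_db].
#' @return data.frame with columns `lineage_id`, `n_cells`, `total_sna1`,
#'   `md_count`, `cd_count`, `cf_count`, `sna1_category`.
#' @seealso [lineage_regression()]
#' @export
lineage_summaries <- function(db) {
  lin <- sort(unique(db$lineage_id))
  out <- data.frame(
    lineage_id = lin,
    n_cells = vapply(lin, function(l) sum(db$lineage_id == l), 0L),
    total_sna1 = vapply(lin, function(l)
      sum(db$sna1[db$lineage_id == l], na.rm = TRUE), 0),
    md_count = vapply(lin, function(l)
      sum(db$fate == "MD" & db$lineage_id == l), 0L),
    cd_count = vapply(lin, function(l)
      sum(db$fate == "CD" & db$lineage_id == l), 0L),
    cf_count = vapply(lin, function(l)
      sum(db$fate == "CF" & db$lineage_id == l), 0L))
  out$sna1_category <- sna1_category(out$total_sna1)
  out
}

#' SNA1 total to category (`low` < 2000, `mid` 2000-3999, `high` >= 4000)
#' @param total numeric vector of summed SNA1 values.
#' @export
sna1_category <- function(total) {
  ifelse(total < 2000, "low", ifelse(total < 4000, "mid", "high"))
}

#' Ordinary least-squares fit of total SNA1 against lineage size
#'
#' @param summaries output of [lineage_summaries()].
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
lineage_regression <- function(summaries) {
  fit <- stats::lm(total_sna1 ~ n_cells, data = summaries)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared, n = nrow(summaries))
}

#' Reproductive progeny of multipolar divisions
#'
#' A cell counts as reproductive MD-progeny when it is an MD product or
#' descends from one, and it undergoes at least one bipolar division during
#' the observation. The fraction divides that count by the number of cells
#' alive at observation end.
#'
#' @param db a [lineage_db].
#' @return list with `count` and `fraction` (0 when the end population is
#'   empty).
#' @export
md_reproductive_progeny <- function(db) {
  key <- paste(db$lineage_id, db$cell_id)
  p1 <- match(paste(db$lineage_id, db$parent1), key)
  p2 <- match(paste(db$lineage_id, db$parent2), key)
  # seed set: products of an MD
  in_set <- (!is.na(p1) & db$fate[pmax(p1, 1)] == "MD")
  in_set[is.na(in_set)] <- FALSE
  repeat {
    grown <- in_set |
      (!is.na(p1) & in_set[pmax(p1, 1)]) |
      (!is.na(p2) & in_set[pmax(p2, 1)])
    grown[is.na(grown)] <- FALSE
    if (identical(grown, in_set)) break
    in_set <- grown
  }
  count <- sum(in_set & db$fate == "BD")
  n_end <- sum(db$fate == "ALIVE_END")
  list(count = count,
       fraction = if (n_end > 0) count / n_end else 0)
}
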