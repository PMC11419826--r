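#' @title Synthetic input generators
#'
#' @description Every pipeline input can be generated synthetically with a
#' known ground truth: lineage databases with chosen event-transition
#' probabilities, log-normal waiting times, MD arities and terminal SNA1
#' expression linked (with tunable strength) to doubling time; and per-case
#' landscape composition tables with the full set of mapped cell types. The
#' generators are independent implementations of the branching process — they
#' do not call [simulate_population()] — so parameter-recovery tests have an
#' external data source.
#' @name fixtures
NULL

#' Specification of a synthetic lineage database
#'
#' Default rates emulate an adherent cancer cell line under long-term
#' single-cell tracking: bipolar division dominates, multipolar division,
#' death and fusion are rare, waiting times are right-skewed around a ~25 h
#' doubling time, and roughly half of the terminal cells express SNA1.
#'
#' @param n_lineages number of progenitors.
#' @param horizon observation window, minutes.
#' @param probs list of named probability vectors over
#'   `c(BD, MD, CD, CF)` per prior event (`START`, `BD`, `MD`, `CF`).
#' @param meanlog,sdlog log-normal waiting-time parameters (minutes).
#' @param md_arity_probs probabilities of arities 3, 4, ... for MD.
#' @param frac_expressing fraction of terminal cells given a positive SNA1
#'   value (the rest are measured as 0).
#' @param expr_meanlog,expr_sdlog log-normal SNA1 value parameters.
#' @param association strength in `[0, 1]` linking expression to doubling
#'   time: at 1, expressing terminals are drawn only from cells whose
#'   parental division interval lies within +/-10% of the mean interval; at
#'   0, uniformly.
#' @param seed RNG seed.
#' @export
fixture_spec <- function(n_lineages = 50, horizon = 6000,
                         probs = list(
                           START = c(BD = 0.94, MD = 0.02, CD = 0.03, CF = 0.01),
                           BD = c(BD = 0.94, MD = 0.02, CD = 0.03, CF = 0.01),
                           MD = c(BD = 0.30, MD = 0.05, CD = 0.55, CF = 0.10),
                           CF = c(BD = 0.35, MD = 0.05, CD = 0.50, CF = 0.10)),
                         meanlog = log(1500), sdlog = 0.12,
                         md_arity_probs = c(0.9, 0.1),
                         frac_expressing = 0.5,
                         expr_meanlog = log(2000), expr_sdlog = 0.6,
                         association = 1, seed = 1L) {
  for (pr in names(probs)) {
    if (abs(sum(probs[[pr]]) - 1) > 1e-8)
      stop("probabilities for prior ", pr, " do not sum to 1")
    if (any(probs[[pr]] < 0)) stop("negative probability for prior ", pr)
  }
  stopifnot(n_lineages >= 1, horizon > 0, frac_expressing >= 0,
            frac_expressing <= 1, association >= 0, association <= 1)
  list(n_lineages = as.integer(n_lineages), horizon = horizon, probs = probs,
       meanlog = meanlog, sdlog = sdlog, md_arity_probs = md_arity_probs,
       frac_expressing = frac_expressing, expr_meanlog = expr_meanlog,
       expr_sdlog = expr_sdlog, association = association,
       seed = as.integer(seed))
}

#' Generate a synthetic lineage database with terminal SNA1 values
#'
#' @param spec a [fixture_spec()].
#' @return a validated [lineage_db]; every `ALIVE_END` cell carries a
#'   measured `sna1` (zeros for non-expressing cells). Bit-identical across
#'   runs with an equal spec.
#' @export
make_synthetic_lineage_db <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  rows <- vector("list", spec$n_lineages)
  for (lin in seq_len(spec$n_lineages))
    rows[[lin]] <- fixture_lineage(spec, lin)
  db <- do.call(rbind, rows)
  db <- assign_terminal_expression(db, spec)
  lineage_db(db, frame_interval = 10, observation_end = spec$horizon)
}

draw_event <- function(spec, prior) {
  p <- spec$probs[[prior]]
  # fusions are recorded on both partners, so an initiating CF is drawn at
  # half the cell-level rate (the recruited partner supplies the other half)
  for (try in 1:100) {
    ev <- sample(names(p), 1L, prob = p)
    if (ev != "CF" || stats::runif(1) < 0.5) break
  }
  list(event = ev, duration = stats::rlnorm(1, spec$meanlog, spec$sdlog))
}

# Chronological event generation of one lineage, independent of the
# deduced-population engine.
fixture_lineage <- function(spec, lineage_id) {
  cells <- list()  # each: id, p1, p2, birth, fate_t, fate, mdp, done
  nid <- 0L
  new_cell <- function(p1, p2, birth, prior) {
    dr <- draw_event(spec, prior)
    ft <- birth + dr$duration
    if (ft >= spec$horizon)
      list(id = (nid <<- nid + 1L) - 1L, p1 = p1, p2 = p2, birth = birth,
           fate_t = spec$horizon, fate = "ALIVE_END", mdp = NA_integer_,
           done = TRUE)
    else
      list(id = (nid <<- nid + 1L) - 1L, p1 = p1, p2 = p2, birth = birth,
           fate_t = ft, fate = dr$event, mdp = NA_integer_, done = FALSE)
  }
  cells[[1]] <- new_cell(NA_integer_, NA_integer_, 0, "START")
  repeat {
    open <- which(!vapply(cells, `[[`, TRUE, "done"))
    if (!length(open)) break
    i <- open[which.min(vapply(cells[open], `[[`, 1, "fate_t"))]
    c0 <- cells[[i]]
    cells[[i]]$done <- TRUE
    t <- c0$fate_t
    if (c0$fate == "BD") {
      for (k in 1:2) cells[[length(cells) + 1L]] <-
        new_cell(c0$id, NA_integer_, t, "BD")
    } else if (c0$fate == "MD") {
      arity <- 2L + sample.int(length(spec$md_arity_probs), 1L,
                               prob = spec$md_arity_probs)
      cells[[i]]$mdp <- arity
      for (k in seq_len(arity)) cells[[length(cells) + 1L]] <-
        new_cell(c0$id, NA_integer_, t, "MD")
    } else if (c0$fate == "CF") {
      partners <- which(vapply(cells, function(c2)
        c2$birth <= t && c2$fate_t > t && c2$id != c0$id, TRUE))
      if (!length(partners)) {
        # no partner available: redraw a non-fusion fate for this cell
        repeat {
          dr <- draw_event(spec, "BD")
          if (dr$event != "CF") break
        }
        ft <- c0$birth + dr$duration
        if (ft >= spec$horizon) {
          cells[[i]]$fate_t <- spec$horizon; cells[[i]]$fate <- "ALIVE_END"
        } else {
          cells[[i]]$fate_t <- ft; cells[[i]]$fate <- dr$event
          cells[[i]]$done <- FALSE
        }
      } else {
        j <- partners[sample.int(length(partners), 1L)]
        cells[[j]]$fate_t <- t; cells[[j]]$fate <- "CF"
        cells[[j]]$done <- TRUE; cells[[j]]$mdp <- NA_integer_
        cells[[length(cells) + 1L]] <-
          new_cell(c0$id, cells[[j]]$id, t, "CF")
      }
    }
  }
  data.frame(
    lineage_id = lineage_id,
    cell_id = vapply(cells, `[[`, 1L, "id"),
    parent1 = vapply(cells, `[[`, 1L, "p1"),
    parent2 = vapply(cells, `[[`, 1L, "p2"),
    birth_time = vapply(cells, `[[`, 1, "birth"),
    fate_time = vapply(cells, `[[`, 1, "fate_t"),
    fate = vapply(cells, `[[`, "", "fate"),
    md_poles = vapply(cells, `[[`, 1L, "mdp"),
    sna1 = NA_real_, stringsAsFactors = FALSE)
}

# Terminal SNA1 assignment: expressing terminals are sampled with weights
# favouring cells whose parental division interval sits within +/-10% of the
# mean interval, with mixing weight `association`.
assign_terminal_expression <- function(db, spec) {
  term <- which(db$fate == "ALIVE_END")
  if (!length(term)) return(db)
  key <- paste(db$lineage_id, db$cell_id)
  p1 <- match(paste(db$lineage_id, db$parent1), key)
  parent_iv <- ifelse(is.na(p1[term]), NA_real_,
                      db$fate_time[pmax(p1[term], 1)] -
                        db$birth_time[pmax(p1[term], 1)])
  m <- mean(parent_iv, na.rm = TRUE)
  in_window <- !is.na(parent_iv) & abs(parent_iv - m) <= 0.10 * m
  w <- (1 - spec$association) + spec$association * as.numeric(in_window)
  n_expr <- round(spec$frac_expressing * length(term))
  db$sna1[term] <- 0
  if (n_expr > 0 && any(w > 0)) {
    n_expr <- min(n_expr, sum(w > 0))
    chosen <- sample(term, n_expr, prob = w)
    db$sna1[chosen] <- stats::rlnorm(n_expr, spec$expr_meanlog,
                                     spec$expr_sdlog)
  }
  db
}

#' Generate a synthetic per-case landscape composition table
#'
#' One row per case; columns cover every mapped cell type plus the excluded
#' M1 macrophage and neutrophil types. Percentages are drawn from
#' case-specific Dirichlet-like gamma compositions scaled to a total immune
#' content of 30-70%.
#'
#' @param n_cases number of cancer cases (> 0).
#' @param seed RNG seed.
#' @param path optional CSV destination; when given, the table is written
#'   and the path returned invisibly.
#' @return data.frame with `case_id` and one percentage column per type.
#' @export
make_synthetic_landscape <- function(n_cases, seed = 1L, path = NULL) {
  if (n_cases <= 0) stop("n_cases must be positive")
  set.seed(seed)
  types <- default_cell_type_map()$type
  shape <- stats::setNames(stats::runif(length(types), 0.4, 2), types)
  rows <- t(vapply(seq_len(n_cases), function(i) {
    g <- stats::rgamma(length(types), shape = shape)
    total <- stats::runif(1, 30, 70)
    round(g / sum(g) * total, 3)
  }, numeric(length(types))))
  out <- data.frame(case_id = sprintf("case_%03d", seq_len(n_cases)),
                    rows, check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("case_id", types)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(path))
  }
  out
}
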