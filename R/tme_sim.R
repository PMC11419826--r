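#' @title 3D tumor-microenvironment simulation
#'
#' @description Deduced cancer cells and suppressive/permissive/lethal
#' microenvironment agents are positioned uniformly inside a solid sphere
#' (radius 50 px by default). Agent anchors are static — displayed motility
#' is capped at 2 px around the anchor and never enters the effect geometry —
#' so a cancer cell's two nearest microenvironment agents within the 6 px
#' search radius are fixed for its whole lifetime, and its effect casework is
#' resolved once, at the first timestep at which it is alive:
#'
#' * nearest lethal: a resistance draw (see [effect_probability()]) then a
#'   `s_lethal`/100 draw; on success the cell dies and its whole subtree is
#'   removed from the lineage database.
#' * nearest suppressive, second not permissive: resistance draw, then the
#'   cell's remaining waiting time and all descendant waiting times are
#'   prolonged by `s_sup` percent.
#' * nearest permissive, second not suppressive: waiting times shortened by
#'   `s_perm` percent, floored at the shortest doubling time observed in the
#'   deduced population; no resistance draw (resistance applies to
#'   suppressive and lethal effects only).
#' * mixed nearest pair: the nearer effect is applied at the
#'   distance-weighted adjusted strength of
#'   [adjusted_suppressive_strength()].
#'
#' A cell receives at most one suppressive-or-permissive modification in its
#' lifetime; its daughters (placed within 6 px of the parent anchor) are
#' again eligible.
#' @name tme_sim
NULL

#' Parameters of the 3D TME simulation
#'
#' @param sphere_radius radius of the simulation sphere, pixels.
#' @param search_radius neighbor search radius around a cancer cell, pixels.
#' @param daughter_radius placement radius for newborn daughters, pixels.
#' @param motility_cap maximum display displacement around an anchor, pixels
#'   (rendering only; anchors are static).
#' @param s_sup,s_perm percent prolongation / shortening of waiting times.
#' @param s_lethal percent probability that a triggering lethal encounter
#'   induces cell death.
#' @param resistance_max maximum fold-resistance of a cell expressing at the
#'   observed SNA1 maximum (>= 1; 1 disables resistance).
#' @param v_max SNA1 value mapped to `resistance_max`; defaults at run time
#'   to the maximum expression in the deduced population.
#' @param timestep minutes between effect-resolution time points.
#' @param horizon simulated minutes.
#' @param seed RNG seed.
#' @export
tme_params <- function(sphere_radius = 50, search_radius = 6,
                       daughter_radius = 6, motility_cap = 2,
                       s_sup = 10, s_perm = 10, s_lethal = 100,
                       resistance_max = 1, v_max = NULL,
                       timestep = 10, horizon = 6000, seed = 1L) {
  stopifnot(sphere_radius > 0, search_radius > 0, daughter_radius > 0,
            motility_cap >= 0, s_sup >= 0, s_perm >= 0, s_perm < 100,
            s_lethal >= 0, s_lethal <= 100, resistance_max >= 1,
            timestep > 0, horizon > 0)
  list(sphere_radius = sphere_radius, search_radius = search_radius,
       daughter_radius = daughter_radius, motility_cap = motility_cap,
       s_sup = s_sup, s_perm = s_perm, s_lethal = s_lethal,
       resistance_max = resistance_max, v_max = v_max,
       timestep = timestep, horizon = horizon, seed = as.integer(seed))
}

runif_ball <- function(n, radius, center = c(0, 0, 0)) {
  # uniform in a solid ball: isotropic direction, radius ~ R * U^(1/3)
  z <- matrix(stats::rnorm(3 * n), ncol = 3)
  z <- z / sqrt(rowSums(z^2))
  r <- radius * stats::runif(n)^(1 / 3)
  sweep(z * r, 2, center, `+`)
}

#' Place microenvironment agents and cancer progenitors in the sphere
#'
#' All positions are i.i.d. uniform over the solid sphere; radial distances
#' therefore follow the CDF `(r/R)^3`.
#'
#' @param n_by_category named counts `c(suppressive = , permissive = ,
#'   lethal = )` (missing names default to 0).
#' @param n_cancer number of cancer progenitors to position.
#' @param params a [tme_params()] list; `params$seed` makes placement
#'   reproducible.
#' @return object of class `tme_world`: list with `micro` (data.frame `id`,
#'   `category`, `x`, `y`, `z`) and `cancer` (data.frame `id`, `x`, `y`,
#'   `z`), plus the sphere radius.
#' @export
place_agents <- function(n_by_category, n_cancer, params = tme_params()) {
  set.seed(params$seed)
  cats <- c("suppressive", "permissive", "lethal")
  n_by_category <- stats::setNames(
    vapply(cats, function(k) {
      v <- n_by_category[k]
      if (is.na(v)) 0L else as.integer(v)
    }, 1L), cats)
  if (any(n_by_category < 0) || n_cancer < 0) stop("counts must be >= 0")
  nm <- sum(n_by_category)
  micro <- data.frame(id = seq_len(nm),
                      category = rep(cats, n_by_category),
                      stringsAsFactors = FALSE)
  pos <- runif_ball(nm, params$sphere_radius)
  micro$x <- pos[, 1]; micro$y <- pos[, 2]; micro$z <- pos[, 3]
  cpos <- runif_ball(n_cancer, params$sphere_radius)
  cancer <- data.frame(id = seq_len(n_cancer), x = cpos[, 1],
                       y = cpos[, 2], z = cpos[, 3])
  structure(list(micro = micro, cancer = cancer,
                 sphere_radius = params$sphere_radius),
            class = "tme_world")
}

#' @export
print.tme_world <- function(x, ...) {
  cat(sprintf("<tme_world> R = %g px; %d cancer progenitors; micro: %s\n",
              x$sphere_radius, nrow(x$cancer),
              paste(names(table(x$micro$category)),
                    table(x$micro$category), sep = "=", collapse = " ")))
  invisible(x)
}

#' Two nearest microenvironment agents within the search radius
#'
#' @param position numeric `c(x, y, z)` of the cancer cell's anchor.
#' @param micro data.frame of microenvironment agents (`id`, `category`,
#'   `x`, `y`, `z`).
#' @param radius search radius (> 0).
#' @param k number of neighbors to return (default 2).
#' @return the `<= k` nearest agent rows, ordered by Euclidean distance with
#'   ties broken by ascending id, with a `distance` column appended.
#' @export
neighbors_within <- function(position, micro, radius, k = 2L) {
  stopifnot(radius > 0)
  if (!nrow(micro)) return(cbind(micro, distance = numeric(0)))
  d <- sqrt((micro$x - position[1])^2 + (micro$y - position[2])^2 +
            (micro$z - position[3])^2)
  keep <- which(d <= radius)
  keep <- keep[order(d[keep], micro$id[keep])]
  keep <- utils::head(keep, k)
  out <- micro[keep, , drop = FALSE]
  out$distance <- d[keep]
  rownames(out) <- NULL
  out
}

#' Distance-weighted adjusted strength for a mixed nearest pair
#'
#' When the nearest agent is suppressive at distance `d_sup` and the second
#' nearest is permissive at `d_perm`, the permissive influence discounts the
#' suppressive strength in proportion to the distance ratio:
#' `max(0, s_sup - s_perm * d_sup / d_perm)`. With both strengths 50 and
#' distances 3 and 6 px this yields 25. The symmetric call (arguments
#' swapped) adjusts a permissive-nearest pair.
#'
#' @param s_near strength of the nearest agent's effect (percent).
#' @param s_second strength of the second-nearest, opposing agent.
#' @param d_near,d_second distances from the cancer cell, `0 < d_near <=
#'   d_second`.
#' @return adjusted strength, >= 0.
#' @export
adjusted_suppressive_strength <- function(s_near, s_second, d_near, d_second) {
  if (d_near <= 0 || d_second <= 0) stop("distances must be positive")
  max(0, s_near - s_second * (d_near / d_second))
}

#' Probability that a suppressive or lethal encounter takes effect
#'
#' Expression maps linearly onto a fold-resistance
#' `1 + (resistance_max - 1) * expression / v_max` (absent expression gives
#' fold 1), and the effect succeeds with probability one over that fold. A cell at the observed maximum under
#' 5-fold maximum resistance is hit with probability 0.2 — one in five.
#'
#' @param expression SNA1 value of the cell (`NA` = non-expressing).
#' @param v_max maximum observed SNA1 value (> 0 unless expression absent).
#' @param resistance_max maximum fold resistance (>= 1).
#' @return probability in (0, 1].
#' @export
effect_probability <- function(expression, v_max, resistance_max) {
  if (resistance_max < 1) stop("resistance_max must be >= 1")
  if (is.null(expression) || is.na(expression)) return(1)
  if (is.null(v_max) || is.na(v_max) || v_max <= 0) return(1)
  r <- 1 + (resistance_max - 1) * (expression / v_max)
  1 / r
}

# ---- timeline surgery on a lineage table ------------------------------

db_index <- function(db) {
  key <- paste(db$lineage_id, db$cell_id)
  p1 <- match(paste(db$lineage_id, db$parent1), key)
  p2 <- match(paste(db$lineage_id, db$parent2), key)
  children <- vector("list", nrow(db))
  for (i in seq_len(nrow(db))) {
    if (!is.na(p1[i])) children[[p1[i]]] <- c(children[[p1[i]]], i)
    if (!is.na(p2[i])) children[[p2[i]]] <- c(children[[p2[i]]], i)
  }
  list(key = key, p1 = p1, p2 = p2, children = children)
}

# Rescale the remaining waiting time of cell i (from time t) and every
# descendant waiting time by k. Rescaled durations are clamped from below at
# floor_d unless the original duration was already shorter (durations below
# the observed minimum doubling time are never extended by the clamp).
# Fusion products are visited once even though they hang under two parents;
# their parents' fate_times are re-synchronised so partners keep fusing
# simultaneously, including a partner outside the rescaled subtree.
rescale_subtree_times <- function(db, idx, i, t, k, floor_d = 0) {
  clamp <- function(dur) if (dur > floor_d) max(dur * k, floor_d) else dur * k
  dur0 <- db$fate_time[i] - db$birth_time[i]
  rem <- (db$fate_time[i] - t) * k
  if (dur0 > floor_d) rem <- max(rem, floor_d - (t - db$birth_time[i]))
  db$fate_time[i] <- max(t, db$birth_time[i] + 1e-9, t + rem)
  desc <- integer(0)
  frontier <- i
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(p) idx$children[[p]])))
    nxt <- setdiff(nxt, c(desc, i))
    desc <- c(desc, nxt)
    frontier <- nxt
  }
  # original birth order puts every parent before its children
  for (ch in desc[order(db$birth_time[desc])]) {
    newdur <- clamp(db$fate_time[ch] - db$birth_time[ch])
    par <- c(idx$p1[ch], idx$p2[ch])
    par <- par[!is.na(par)]
    b <- max(db$fate_time[par])
    if (length(par) == 2L) db$fate_time[par] <- b  # fusion stays synchronous
    db$birth_time[ch] <- b
    db$fate_time[ch] <- b + newdur
  }
  db
}

#' Apply a suppressive effect: prolong a cell's waiting times
#'
#' The cell's remaining inter-event duration (from `time`) and all descendant
#' durations are multiplied by `1 + strength/100`; a worked case: a 25 h
#' doubling time under strength 10 becomes 27.5 h.
#'
#' @param db a [lineage_db].
#' @param lineage_id,cell_id the affected cell.
#' @param strength percent prolongation (>= 0).
#' @param time simulation time of the encounter (default: the cell's birth).
#' @return `db` with the subtree timeline recomputed.
#' @export
apply_suppressive <- function(db, lineage_id, cell_id, strength, time = NULL) {
  idx <- db_index(db)
  i <- match(paste(lineage_id, cell_id), idx$key)
  if (is.na(i)) stop("unknown cell")
  if (is.null(time)) time <- db$birth_time[i]
  rescale_subtree_times(db, idx, i, time, 1 + strength / 100)
}

#' Apply a permissive effect: shorten waiting times, floored
#'
#' Durations are multiplied by `1 - strength/100` and clamped from below at
#' `min_doubling`, the shortest doubling time observed within the deduced
#' population.
#'
#' @inheritParams apply_suppressive
#' @param strength percent shortening (0 <= strength < 100).
#' @param min_doubling duration floor in minutes.
#' @export
apply_permissive <- function(db, lineage_id, cell_id, strength, min_doubling,
                             time = NULL) {
  if (strength >= 100) stop("permissive strength must be < 100")
  idx <- db_index(db)
  i <- match(paste(lineage_id, cell_id), idx$key)
  if (is.na(i)) stop("unknown cell")
  if (is.null(time)) time <- db$birth_time[i]
  rescale_subtree_times(db, idx, i, time, 1 - strength / 100, min_doubling)
}

#' Apply a lethal effect: mark the cell dead and remove its progeny
#'
#' The cell's fate is overwritten to `CD` at the encounter time and every
#' descendant record is deleted from the database.
#'
#' @inheritParams apply_suppressive
#' @param time simulation time of death (default: the cell's birth time plus
#'   one-tenth of its remaining duration, for standalone use).
#' @return `db` without the subtree below the killed cell.
#' @export
apply_lethal <- function(db, lineage_id, cell_id, time = NULL) {
  ids <- subtree(db, lineage_id, cell_id)
  i <- which(db$lineage_id == lineage_id & db$cell_id == cell_id)
  if (is.null(time))
    time <- db$birth_time[i] + 0.1 * (db$fate_time[i] - db$birth_time[i])
  db$fate[i] <- "CD"
  db$fate_time[i] <- max(time, db$birth_time[i] + 1e-9)
  db$md_poles[i] <- NA_integer_
  drop <- db$lineage_id == lineage_id & db$cell_id %in% setdiff(ids, cell_id)
  db[!drop, , drop = FALSE]
}

# ---- the engine -------------------------------------------------------

#' Run the 3D TME simulation
#'
#' Processes the deduced population in birth order under the effect rules
#' described in [tme_sim]. Fully deterministic for a given `(deduced, world,
#' params)` triple.
#'
#' @param deduced a deduced [lineage_db] (progenitor cells = lineages); the
#'   number of lineages must equal `nrow(world$cancer)`.
#' @param world a `tme_world` from [place_agents()].
#' @param params a [tme_params()] list.
#' @return object of class `tme_result`: list with `trace` (data.frame
#'   `time`, `n`), `final_population`, `effect_log` (one row per resolved
#'   encounter: `time`, `lineage_id`, `cell_id`, `agent_id`, `effect`,
#'   `strength`, `success`), `final_expression` (SNA1 of cells alive at the
#'   horizon), `md_progeny`, `db_final`, `positions` (anchor of every
#'   realized cell) and `params`.
#' @export
run_simulation <- function(deduced, world, params = tme_params()) {
  stopifnot(inherits(deduced, "lineage_db"), inherits(world, "tme_world"))
  lineages <- sort(unique(deduced$lineage_id))
  if (length(lineages) != nrow(world$cancer))
    stop("world has ", nrow(world$cancer), " cancer positions for ",
         length(lineages), " lineages")
  set.seed(params$seed + 1L)
  v_max <- params$v_max
  if (is.null(v_max))
    v_max <- if (all(is.na(deduced$sna1))) NA_real_
             else max(deduced$sna1, na.rm = TRUE)
  min_doubling <- {
    bd <- deduced$fate == "BD"
    if (any(bd)) min(deduced$fate_time[bd] - deduced$birth_time[bd]) else 0
  }

  db <- as.data.frame(deduced)
  n <- nrow(db)
  idx <- db_index(db)
  removed <- logical(n); unborn <- logical(n); processed <- logical(n)
  px <- rep(NA_real_, n); py <- px; pz <- px
  prog_pos <- world$cancer[order(world$cancer$id), , drop = FALSE]
  lin_of <- match(db$lineage_id, lineages)
  micro <- world$micro
  horizon <- params$horizon
  grid0 <- function(b) ceiling(b / params$timestep - 1e-9) * params$timestep

  log_time <- numeric(0); log_lin <- integer(0); log_cell <- integer(0)
  log_agent <- integer(0); log_eff <- character(0)
  log_str <- numeric(0); log_ok <- logical(0)
  add_log <- function(t, i, agent, eff, str, ok) {
    log_time <<- c(log_time, t); log_lin <<- c(log_lin, db$lineage_id[i])
    log_cell <<- c(log_cell, db$cell_id[i]); log_agent <<- c(log_agent, agent)
    log_eff <<- c(log_eff, eff); log_str <<- c(log_str, str)
    log_ok <<- c(log_ok, ok)
  }
  mark_removed <- function(i) {
    frontier <- i
    while (length(frontier)) {
      nxt <- integer(0)
      for (p in frontier) nxt <- c(nxt, idx$children[[p]])
      nxt <- nxt[!removed[nxt]]
      removed[nxt] <<- TRUE
      frontier <- nxt
    }
  }

  repeat {
    cand <- which(!processed & !removed & !unborn)
    if (!length(cand)) break
    i <- cand[which.min(db$birth_time[cand])]
    processed[i] <- TRUE
    if (db$birth_time[i] >= horizon) { unborn[i] <- TRUE; next }
    # anchor placement
    if (is.na(idx$p1[i])) {
      p <- as.numeric(prog_pos[lin_of[i], c("x", "y", "z")])
    } else {
      par <- idx$p1[i]
      parent_pos <- c(px[par], py[par], pz[par])
      p <- NULL
      for (try in 1:100) {
        cand_p <- as.numeric(runif_ball(1, params$daughter_radius, parent_pos))
        if (sqrt(sum(cand_p^2)) <= params$sphere_radius) { p <- cand_p; break }
      }
      if (is.null(p)) { # project radially back inside the sphere
        cand_p <- as.numeric(runif_ball(1, params$daughter_radius, parent_pos))
        p <- cand_p * (params$sphere_radius / sqrt(sum(cand_p^2))) * 0.999
      }
    }
    px[i] <- p[1]; py[i] <- p[2]; pz[i] <- p[3]

    # effect resolution at the first timestep at which the cell is alive
    t_res <- grid0(db$birth_time[i])
    alive_at <- function(t) t < db$fate_time[i] ||
      (db$fate[i] == "ALIVE_END" && t <= db$fate_time[i])
    if (t_res > horizon || !alive_at(t_res) || !nrow(micro)) next
    nb <- neighbors_within(p, micro, params$search_radius)
    if (!nrow(nb)) next
    cat1 <- nb$category[1]
    cat2 <- if (nrow(nb) >= 2) nb$category[2] else NA_character_
    p_eff <- effect_probability(db$sna1[i], v_max, params$resistance_max)

    if (cat1 == "lethal") {
      ok <- stats::runif(1) < p_eff && stats::runif(1) < params$s_lethal / 100
      add_log(t_res, i, nb$id[1], "lethal", params$s_lethal, ok)
      if (ok) {
        db$fate[i] <- "CD"
        db$fate_time[i] <- max(t_res, db$birth_time[i] + 1e-9)
        db$md_poles[i] <- NA_integer_
        mark_removed(i)
      }
    } else if (cat1 == "suppressive") {
      s <- if (identical(cat2, "permissive"))
        adjusted_suppressive_strength(params$s_sup, params$s_perm,
                                      nb$distance[1], nb$distance[2])
      else params$s_sup
      ok <- stats::runif(1) < p_eff
      add_log(t_res, i, nb$id[1], "suppressive", s, ok)
      if (ok && s > 0)
        db <- rescale_subtree_times(db, idx, i, t_res, 1 + s / 100)
    } else { # permissive nearest
      s <- if (identical(cat2, "suppressive"))
        adjusted_suppressive_strength(params$s_perm, params$s_sup,
                                      nb$distance[1], nb$distance[2])
      else params$s_perm
      add_log(t_res, i, nb$id[1], "permissive", s, TRUE)
      if (s > 0)
        db <- rescale_subtree_times(db, idx, i, t_res, 1 - s / 100,
                                    min_doubling)
    }
  }

  # finalize: drop removed records, censor survivors at the horizon
  keep <- !removed & !unborn
  out <- db[keep, , drop = FALSE]
  over <- out$fate_time > horizon |
    (out$fate != "ALIVE_END" & out$fate_time >= horizon)
  # orphaned fusion partners (partner or product removed) survive unfused
  okey <- paste(out$lineage_id, out$cell_id)
  cf <- which(out$fate == "CF")
  if (length(cf)) {
    has_prod <- vapply(cf, function(i) {
      any(!is.na(out$parent2) &
          ((paste(out$lineage_id, out$parent1) == okey[i]) |
           (paste(out$lineage_id, out$parent2) == okey[i])), na.rm = TRUE)
    }, TRUE)
    over[cf[!has_prod]] <- TRUE
  }
  out$fate[over] <- "ALIVE_END"
  out$md_poles[over] <- NA_integer_
  out$fate_time[over] <- horizon
  out <- out[out$birth_time < horizon, , drop = FALSE]

  times <- seq(0, horizon, by = params$timestep)
  trace <- data.frame(
    time = times,
    n = as.numeric(count_alive_at(out$birth_time, out$fate_time, out$fate,
                                  times)))
  effect_log <- data.frame(time = log_time, lineage_id = log_lin,
                           cell_id = log_cell, agent_id = log_agent,
                           effect = log_eff, strength = log_str,
                           success = log_ok, stringsAsFactors = FALSE)
  db_final <- lineage_db(out, frame_interval = params$timestep,
                         observation_end = horizon, validate = FALSE)
  positions <- data.frame(lineage_id = db$lineage_id[keep],
                          cell_id = db$cell_id[keep],
                          x = px[keep], y = py[keep], z = pz[keep])
  structure(list(trace = trace,
                 final_population = trace$n[length(times)],
                 effect_log = effect_log,
                 final_expression = out$sna1[out$fate == "ALIVE_END"],
                 md_progeny = md_reproductive_progeny(db_final),
                 db_final = db_final, positions = positions,
                 world = world, params = params),
            class = "tme_result")
}

#' @export
print.tme_result <- function(x, ...) {
  cat(sprintf(
    "<tme_result> final population %g at %g min; %d effect(s) resolved\n",
    x$final_population, max(x$trace$time), nrow(x$effect_log)))
  invisible(x)
}

#' Enumerate a ratio sweep grid over the three categories
#'
#' The Cartesian product of the per-category ratio grids; ranges 1:0 to 1:1
#' in steps of 0.1 for all three categories enumerate 11^3 = 1331
#' configurations. Each configuration carries a seed derived from the base
#' seed and its grid index, so runs are independent of execution order.
#'
#' @param suppressive,permissive,lethal numeric `c(lo, hi)` ratio ranges.
#' @param increment grid step (> 0).
#' @param base_seed seed from which per-run seeds are derived.
#' @return data.frame with columns `run`, `suppressive`, `permissive`,
#'   `lethal`, `seed`.
#' @export
sweep_grid <- function(suppressive = c(0, 1), permissive = c(0, 1),
                       lethal = c(0, 1), increment = 0.1, base_seed = 1L) {
  if (increment <= 0) stop("increment must be positive")
  axis <- function(rg) {
    if (rg[2] < rg[1]) stop("range hi < lo")
    rg[1] + increment * seq.int(0L, floor((rg[2] - rg[1]) / increment + 1e-9))
  }
  g <- expand.grid(suppressive = axis(suppressive),
                   permissive = axis(permissive), lethal = axis(lethal),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$suppressive, g$permissive, g$lethal), , drop = FALSE]
  rownames(g) <- NULL
  g$run <- seq_len(nrow(g))
  g$seed <- (as.integer(base_seed) + g$run) %% .Machine$integer.max
  g[c("run", "suppressive", "permissive", "lethal", "seed")]
}

#' Run every configuration of a sweep grid
#'
#' For each row the three category ratios are converted to agent counts
#' relative to the number of deduced lineages, a world is placed with the
#' row's derived seed, and [run_simulation()] is executed.
#'
#' @param deduced a deduced [lineage_db].
#' @param grid output of [sweep_grid()].
#' @param params a [tme_params()] list (its `seed` is replaced per run).
#' @return list with `summary` (grid plus `final_population`) and `results`
#'   (list of `tme_result`).
#' @export
run_sweep <- function(deduced, grid, params = tme_params()) {
  n_cancer <- length(unique(deduced$lineage_id))
  results <- vector("list", nrow(grid))
  final <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    counts <- agent_counts(n_cancer, c(suppressive = grid$suppressive[r],
                                       permissive = grid$permissive[r],
                                       lethal = grid$lethal[r]))
    pr <- params
    pr$seed <- grid$seed[r]
    world <- place_agents(counts, n_cancer, pr)
    results[[r]] <- run_simulation(deduced, world, pr)
    final[r] <- results[[r]]$final_population
  }
  summary <- cbind(grid, final_population = final)
  list(summary = summary, results = results)
}
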