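#' @title Cell-fate simulation
#'
#' @description The fate simulator is driven by an empirical event-transition
#' model: for each prior event (progenitor start, BD, MD, CF) it stores the
#' multiset of observed `(next event, inter-event duration)` pairs. Deduced
#' populations are generated by resampling those joint pairs, so the observed
#' association between event type and waiting time is preserved without any
#' parametric assumption. Cells whose sampled event falls beyond the horizon
#' are censored as `ALIVE_END`, exactly as observation truncates real
#' lineages; censored observations are kept in the model but do not enter the
#' transition probabilities.
#' @name fate_sim
NULL

PRIORS <- c("START", "BD", "MD", "CF")

#' Fit the event-transition model of a lineage database
#'
#' Every cell contributes one observation: its prior event (START for
#' progenitors, otherwise the parent event that created it), its own fate and
#' the duration `fate_time - birth_time`. Completed events (BD/MD/CD/CF) form
#' the resampling multiset and the empirical conditional probabilities;
#' `ALIVE_END` observations are stored as censored. MD arities observed in
#' the data are retained for arity resampling.
#'
#' @param db a [lineage_db] with at least one completed event.
#' @return object of class `transition_model` with elements `pairs`
#'   (data.frame `prior`, `next_event`, `duration`), `censored` (data.frame
#'   `prior`, `duration`), `md_arities` (integer vector) and `probs` (list of
#'   named probability vectors per prior).
#' @export
fit_transition_model <- function(db) {
  if (nrow(db) == 0L) stop("cannot fit a transition model: no records")
  key <- paste(db$lineage_id, db$cell_id)
  p1 <- match(paste(db$lineage_id, db$parent1), key)
  prior <- ifelse(is.na(p1), "START",
           ifelse(!is.na(db$parent2), "CF", db$fate[pmax(p1, 1)]))
  dur <- db$fate_time - db$birth_time
  done <- db$fate %in% c("BD", "MD", "CD", "CF")
  if (!any(done)) stop("cannot fit a transition model: no completed events")
  pairs <- data.frame(prior = prior[done], next_event = db$fate[done],
                      duration = dur[done], stringsAsFactors = FALSE)
  censored <- data.frame(prior = prior[!done], duration = dur[!done],
                         stringsAsFactors = FALSE)
  probs <- lapply(stats::setNames(PRIORS, PRIORS), function(pr) {
    sub <- pairs$next_event[pairs$prior == pr]
    if (!length(sub)) return(NULL)
    tab <- table(factor(sub, levels = c("BD", "MD", "CD", "CF")))
    as.vector(tab) / length(sub) -> p
    stats::setNames(p, names(tab))
  })
  structure(list(pairs = pairs, censored = censored,
                 md_arities = db$md_poles[!is.na(db$md_poles)],
                 probs = probs),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model> %d completed pairs, %d censored\n",
              nrow(x$pairs), nrow(x$censored)))
  for (pr in PRIORS) {
    p <- x$probs[[pr]]
    if (is.null(p)) next
    cat(sprintf("  P(.|%s): %s\n", pr,
                paste(sprintf("%s=%.3f", names(p), p), collapse = " ")))
  }
  invisible(x)
}

#' Serialize / deserialize a transition model as JSON
#' @param model a `transition_model`.
#' @param path file path.
#' @export
write_transition_model <- function(model, path) {
  jsonlite::write_json(
    list(schema = "tmesim-model-v1", pairs = model$pairs,
         censored = model$censored, md_arities = model$md_arities),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_transition_model
#' @export
read_transition_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "tmesim-model-v1"))
    stop("not a tmesim-model-v1 file: ", path)
  pairs <- as.data.frame(obj$pairs)
  censored <- as.data.frame(obj$censored)
  if (!nrow(censored))
    censored <- data.frame(prior = character(), duration = numeric())
  probs <- lapply(stats::setNames(PRIORS, PRIORS), function(pr) {
    sub <- pairs$next_event[pairs$prior == pr]
    if (!length(sub)) return(NULL)
    tab <- table(factor(sub, levels = c("BD", "MD", "CD", "CF")))
    stats::setNames(as.vector(tab) / length(sub), names(tab))
  })
  structure(list(pairs = pairs, censored = censored,
                 md_arities = as.integer(obj$md_arities), probs = probs),
            class = "transition_model")
}

#' Parameters of the deduced-population generator
#'
#' Defaults follow the simulator's standard conditions: 500 progenitors, a
#' 170 h (10,200 min) horizon, a +/-10% doubling-time gate for expression
#' assignment and a +/-15% sibling variation window.
#'
#' @param n_progenitors number of independent lineages to generate.
#' @param horizon simulated minutes.
#' @param doubling_window half-width (fraction) of the expression gate.
#' @param sibling_window half-width (fraction) of the sibling value draw.
#' @param scale_factor expression scaling factor (1.5, 1.0, 0.5, 0.25, ...).
#' @param seed RNG seed; every run is reproducible from it.
#' @export
fate_sim_params <- function(n_progenitors = 500, horizon = 10200,
                            doubling_window = 0.10, sibling_window = 0.15,
                            scale_factor = 1.0, seed = 1L) {
  stopifnot(n_progenitors >= 1, horizon > 0,
            doubling_window > 0, doubling_window < 1,
            sibling_window > 0, sibling_window < 1, scale_factor > 0)
  list(n_progenitors = as.integer(n_progenitors), horizon = horizon,
       doubling_window = doubling_window, sibling_window = sibling_window,
       scale_factor = scale_factor, seed = as.integer(seed))
}

sample_pair <- function(model, prior, exclude = NULL) {
  sub <- model$pairs[model$pairs$prior == prior, , drop = FALSE]
  if (length(exclude))
    sub <- sub[!(sub$next_event %in% exclude), , drop = FALSE]
  if (!nrow(sub))
    stop("transition model has no observations conditioned on prior event '",
         prior, "'")
  # a fusion writes CF on both partners, so the empirical per-cell CF
  # frequency counts each event twice; initiating fusions are therefore
  # drawn at half that rate and the recruited partner supplies the rest
  for (try in 1:100) {
    row <- sub[sample.int(nrow(sub), 1L), ]
    if (row$next_event != "CF" || stats::runif(1) < 0.5) break
  }
  if (row$next_event == "CF") {
    # recorded fusion waits are truncated at the recruited partner's clock,
    # so the initiator's intrinsic wait is drawn from the prior's pooled
    # duration multiset instead of the contracted CF-only durations
    row$duration <- sub$duration[sample.int(nrow(sub), 1L)]
  }
  row
}

sample_md_arity <- function(model) {
  if (length(model$md_arities))
    model$md_arities[sample.int(length(model$md_arities), 1L)]
  else 3L
}

#' Generate a deduced cell population
#'
#' Each of `n_progenitors` lineages starts from one progenitor whose first
#' `(event, duration)` pair is drawn conditioned on START; the first event
#' time is then shortened by a uniform cell-cycle phase in `[0, duration)`,
#' so progenitors begin at different stages of the cell cycle. Thereafter
#' every newborn cell samples its `(next event, duration)` jointly from the
#' model conditioned on the event that created it. BD spawns two daughters,
#' MD an arity resampled from the observed arities, CF fuses the cell with a
#' concurrently alive cell of the same lineage (the pair is resampled when no
#' partner exists). Events falling at or beyond the horizon leave the cell
#' `ALIVE_END`.
#'
#' @param model a `transition_model`.
#' @param params a [fate_sim_params()] list.
#' @return a validated [lineage_db] with `observation_end = horizon` and the
#'   source frame interval; bit-identical across runs with equal inputs.
#' @export
simulate_population <- function(model, params = fate_sim_params()) {
  stopifnot(inherits(model, "transition_model"))
  if (params$horizon <= 0) stop("horizon must be positive")
  set.seed(params$seed)
  all <- vector("list", params$n_progenitors)
  for (lin in seq_len(params$n_progenitors))
    all[[lin]] <- simulate_lineage(model, lin, params$horizon)
  db <- do.call(rbind, all)
  lineage_db(db, frame_interval = 10, observation_end = params$horizon)
}

# Event-driven generation of one lineage. Cells carry a scheduled fate;
# the earliest unexecuted fate is processed until every cell is terminal.
simulate_lineage <- function(model, lineage_id, horizon) {
  cap <- 64L
  cell_id <- integer(cap); parent1 <- integer(cap); parent2 <- integer(cap)
  birth <- numeric(cap); fate_t <- numeric(cap); fate <- character(cap)
  mdp <- integer(cap); pending <- logical(cap)
  n <- 0L; next_id <- 0L

  grow <- function() {
    cap2 <- cap * 2L
    length(cell_id) <<- cap2; length(parent1) <<- cap2
    length(parent2) <<- cap2; length(birth) <<- cap2
    length(fate_t) <<- cap2; length(fate) <<- cap2
    length(mdp) <<- cap2; length(pending) <<- cap2
    pending[(cap + 1L):cap2] <<- FALSE
    cap <<- cap2
  }
  add_cell <- function(p1, p2, b, ft, f) {
    if (n == cap) grow()
    n <<- n + 1L
    cell_id[n] <<- next_id; next_id <<- next_id + 1L
    parent1[n] <<- p1; parent2[n] <<- p2
    birth[n] <<- b; fate_t[n] <<- ft; fate[n] <<- f
    mdp[n] <<- NA_integer_
    pending[n] <<- f %in% c("BD", "MD", "CF")
    n
  }
  schedule <- function(p1, p2, b, prior) {
    pr <- sample_pair(model, prior)
    ft <- b + pr$duration
    if (ft >= horizon) add_cell(p1, p2, b, horizon, "ALIVE_END")
    else add_cell(p1, p2, b, ft, pr$next_event)
  }

  # progenitor: cycle-phase offset of the first event
  pr <- sample_pair(model, "START")
  phase <- stats::runif(1, 0, pr$duration)
  ft <- pr$duration - phase
  if (ft <= 0) ft <- pr$duration * 1e-9  # degenerate draw guard
  if (ft >= horizon) add_cell(NA_integer_, NA_integer_, 0, horizon, "ALIVE_END")
  else add_cell(NA_integer_, NA_integer_, 0, ft, pr$next_event)

  repeat {
    idx <- which(pending[seq_len(n)])
    if (!length(idx)) break
    i <- idx[which.min(fate_t[idx])]
    pending[i] <- FALSE
    t <- fate_t[i]
    if (fate[i] == "BD") {
      for (k in 1:2) schedule(cell_id[i], NA_integer_, t, "BD")
    } else if (fate[i] == "MD") {
      arity <- sample_md_arity(model)
      mdp[i] <- arity
      for (k in seq_len(arity)) schedule(cell_id[i], NA_integer_, t, "MD")
    } else if (fate[i] == "CF") {
      # partner: any co-resident cell of this lineage whose own fate has not
      # yet occurred (its scheduled event, if any, is cancelled by the fusion)
      cand <- setdiff(which(birth[seq_len(n)] <= t & fate_t[seq_len(n)] > t), i)
      if (!length(cand)) {
        # no one to fuse with: resample this cell's own (event, duration)
        my_prior <- if (is.na(parent1[i])) "START"
                    else prior_of(i, parent1, parent2, fate, cell_id, n)
        pr <- NULL
        for (try in 1:50) {
          cand_pr <- sample_pair(model, my_prior)
          if (cand_pr$next_event != "CF") { pr <- cand_pr; break }
        }
        if (is.null(pr)) pr <- sample_pair(model, my_prior, exclude = "CF")
        ft2 <- birth[i] + pr$duration
        if (ft2 >= horizon) { fate_t[i] <- horizon; fate[i] <- "ALIVE_END" }
        else { fate_t[i] <- ft2; fate[i] <- pr$next_event
               pending[i] <- pr$next_event %in% c("BD", "MD", "CF") }
      } else {
        j <- cand[sample.int(length(cand), 1L)]
        fate_t[j] <- t; fate[j] <- "CF"; pending[j] <- FALSE
        schedule(cell_id[i], cell_id[j], t, "CF")
      }
    }
  }
  data.frame(lineage_id = lineage_id, cell_id = cell_id[seq_len(n)],
             parent1 = parent1[seq_len(n)], parent2 = parent2[seq_len(n)],
             birth_time = birth[seq_len(n)], fate_time = fate_t[seq_len(n)],
             fate = fate[seq_len(n)], md_poles = mdp[seq_len(n)],
             sna1 = NA_real_, stringsAsFactors = FALSE)
}

prior_of <- function(i, parent1, parent2, fate, cell_id, n) {
  if (!is.na(parent2[i])) return("CF")
  p <- match(parent1[i], cell_id[seq_len(n)])
  fate[p]
}

#' Assign SNA1 expression to the daughters of bipolar divisions
#'
#' For each BD in the deduced population the two daughters are gated on
#' their own sampled inter-event duration: a daughter is eligible when at
#' least one SNA1-expressing source cell (sna1 > 0 after back-propagation)
#' has a BD-to-BD doubling time within `+/- doubling_window` of that
#' duration (`gate_mode = "any"`, the default), or when the duration lies
#' within the window of the expressing cells' *average* doubling time
#' (`gate_mode = "average"`). The first eligible daughter draws a value
#' uniformly from the expression list; a second eligible daughter draws
#' uniformly from `[v1 * (1 - sibling_window), v1 * (1 + sibling_window)]`.
#' Ineligible daughters keep `sna1` absent.
#'
#' @param deduced deduced [lineage_db] from [simulate_population()].
#' @param expr_list an `expression_list` (must be non-empty).
#' @param source_db back-propagated source [lineage_db] providing the
#'   doubling times of expressing cells.
#' @param params a [fate_sim_params()] list (`doubling_window`,
#'   `sibling_window`, `seed + 1` used for the draws).
#' @param gate_mode `"any"` (compare against each expressing cell) or
#'   `"average"` (compare against their mean doubling time).
#' @return `deduced` with `sna1` filled where assigned.
#' @export
assign_expression <- function(deduced, expr_list, source_db,
                              params = fate_sim_params(),
                              gate_mode = c("any", "average")) {
  gate_mode <- match.arg(gate_mode)
  if (!length(expr_list$values)) stop("expression list is empty")
  pool <- expressing_doubling_times(source_db)
  if (!length(pool)) {
    warning("no expressing source cells with BD-to-BD intervals; ",
            "no expression assigned")
    return(deduced)
  }
  set.seed(params$seed + 1L)
  w <- params$doubling_window
  gate <- if (gate_mode == "any") {
    function(T) any(pool >= T * (1 - w) & pool <= T * (1 + w))
  } else {
    m <- mean(pool)
    function(T) abs(T - m) <= w * m
  }
  key <- paste(deduced$lineage_id, deduced$cell_id)
  p1 <- match(paste(deduced$lineage_id, deduced$parent1), key)
  bd_parents <- which(deduced$fate == "BD")
  # deterministic iteration order: by lineage, then event time, then id
  bd_parents <- bd_parents[order(deduced$lineage_id[bd_parents],
                                 deduced$fate_time[bd_parents],
                                 deduced$cell_id[bd_parents])]
  for (i in bd_parents) {
    kids <- which(p1 == i & is.na(deduced$parent2))
    kids <- kids[order(deduced$cell_id[kids])]
    if (!length(kids)) next
    v1 <- NA_real_
    for (k in kids) {
      T <- deduced$fate_time[k] - deduced$birth_time[k]
      if (!gate(T)) next
      if (is.na(v1)) {
        v1 <- expr_list$values[sample.int(length(expr_list$values), 1L)]
        deduced$sna1[k] <- v1
      } else {
        deduced$sna1[k] <- stats::runif(1, v1 * (1 - params$sibling_window),
                                        v1 * (1 + params$sibling_window))
      }
    }
  }
  deduced
}

# BD-to-BD doubling times of SNA1-expressing (sna1 > 0) source cells.
expressing_doubling_times <- function(source_db) {
  bd_bd_intervals(source_db,
                  subset = !is.na(source_db$sna1) & source_db$sna1 > 0)
}

#' Scale SNA1 expression by a factor, capped at the observed maximum
#'
#' @param db a [lineage_db] with assigned `sna1`.
#' @param factor positive multiplier (e.g. 1.5, 0.5, 0.25).
#' @param v_max cap: the highest SNA1 value observed in the source
#'   population; scaled values exceeding it are set to `v_max`.
#' @return `db` with `sna1` replaced by `min(factor * sna1, v_max)`;
#'   absent values stay absent.
#' @export
scale_expression <- function(db, factor, v_max) {
  if (!is.numeric(factor) || factor <= 0) stop("factor must be positive")
  db$sna1 <- ifelse(is.na(db$sna1), NA_real_, pmin(factor * db$sna1, v_max))
  db
}
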