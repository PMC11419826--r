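# Small hand-built lineage databases used across the suite.

rec <- function(lin, id, p1 = NA, p2 = NA, birth, fate_t, fate,
                mdp = NA, sna1 = NA) {
  data.frame(lineage_id = lin, cell_id = id, parent1 = p1, parent2 = p2,
             birth_time = birth, fate_time = fate_t, fate = fate,
             md_poles = mdp, sna1 = sna1, stringsAsFactors = FALSE)
}

mk_db <- function(..., frame_interval = 10, observation_end = NULL,
                  validate = TRUE) {
  lineage_db(do.call(rbind, list(...)), frame_interval = frame_interval,
             observation_end = observation_end, validate = validate)
}

# progenitor divides at 600; both daughters alive at 1200
toy_bd3 <- function(sna1 = c(NA, NA, NA)) {
  mk_db(rec(1, 0, birth = 0, fate_t = 600, fate = "BD", sna1 = sna1[1]),
        rec(1, 1, p1 = 0, birth = 600, fate_t = 1200, fate = "ALIVE_END",
            sna1 = sna1[2]),
        rec(1, 2, p1 = 0, birth = 600, fate_t = 1200, fate = "ALIVE_END",
            sna1 = sna1[3]),
        observation_end = 1200)
}

# complete two-generation bipolar tree: 1 + 2 + 4 = 7 cells
toy_bd7 <- function(leaf_sna1 = rep(NA_real_, 4)) {
  mk_db(rec(1, 0, birth = 0, fate_t = 600, fate = "BD"),
        rec(1, 1, p1 = 0, birth = 600, fate_t = 1200, fate = "BD"),
        rec(1, 2, p1 = 0, birth = 600, fate_t = 1200, fate = "BD"),
        rec(1, 3, p1 = 1, birth = 1200, fate_t = 1800, fate = "ALIVE_END",
            sna1 = leaf_sna1[1]),
        rec(1, 4, p1 = 1, birth = 1200, fate_t = 1800, fate = "ALIVE_END",
            sna1 = leaf_sna1[2]),
        rec(1, 5, p1 = 2, birth = 1200, fate_t = 1800, fate = "ALIVE_END",
            sna1 = leaf_sna1[3]),
        rec(1, 6, p1 = 2, birth = 1200, fate_t = 1800, fate = "ALIVE_END",
            sna1 = leaf_sna1[4]),
        observation_end = 1800)
}

# progenitor divides; the daughters fuse; the product survives
toy_fusion <- function(prod_sna1 = NA) {
  mk_db(rec(1, 0, birth = 0, fate_t = 600, fate = "BD"),
        rec(1, 1, p1 = 0, birth = 600, fate_t = 1200, fate = "CF"),
        rec(1, 2, p1 = 0, birth = 600, fate_t = 1200, fate = "CF"),
        rec(1, 3, p1 = 1, p2 = 2, birth = 1200, fate_t = 1800,
            fate = "ALIVE_END", sna1 = prod_sna1),
        observation_end = 1800)
}

# tripolar division; daughter fates BD / CD / ALIVE_END
toy_md <- function() {
  mk_db(rec(1, 0, birth = 0, fate_t = 600, fate = "MD", mdp = 3),
        rec(1, 1, p1 = 0, birth = 600, fate_t = 1800, fate = "BD"),
        rec(1, 2, p1 = 0, birth = 600, fate_t = 1200, fate = "CD"),
        rec(1, 3, p1 = 0, birth = 600, fate_t = 2000, fate = "ALIVE_END"),
        rec(1, 4, p1 = 1, birth = 1800, fate_t = 2000, fate = "ALIVE_END"),
        rec(1, 5, p1 = 1, birth = 1800, fate_t = 2000, fate = "ALIVE_END"),
        observation_end = 2000)
}

# fixed-duration pure-BD transition model (every event after `dur` minutes)
deterministic_bd_model <- function(dur = 1500) {
  structure(list(
    pairs = data.frame(prior = c("START", "BD"), next_event = c("BD", "BD"),
                       duration = c(dur, dur), stringsAsFactors = FALSE),
    censored = data.frame(prior = character(), duration = numeric()),
    md_arities = integer(),
    probs = list(START = c(BD = 1, MD = 0, CD = 0, CF = 0),
                 BD = c(BD = 1, MD = 0, CD = 0, CF = 0),
                 MD = NULL, CF = NULL)),
    class = "transition_model")
}

# hand-placed world: explicit agent and progenitor coordinates
mk_world <- function(micro, cancer, sphere_radius = 50) {
  structure(list(micro = micro, cancer = cancer,
                 sphere_radius = sphere_radius), class = "tme_world")
}

# transition model with a known multiset, covering every prior event
mk_model <- function(seed, p = c(BD = .95, MD = .01, CD = .04, CF = 0),
                     meanlog = log(1300), sdlog = 0.12, n = 400) {
  set.seed(seed)
  mk <- function(prior, probs) data.frame(
    prior = prior, next_event = sample(names(probs), n, TRUE, probs),
    duration = stats::rlnorm(n, meanlog, sdlog), stringsAsFactors = FALSE)
  pairs <- rbind(mk("START", p), mk("BD", p),
                 mk("MD", c(BD = .4, MD = 0, CD = .6, CF = 0)),
                 mk("CF", c(BD = .6, MD = 0, CD = .4, CF = 0)))
  structure(list(pairs = pairs,
                 censored = data.frame(prior = character(),
                                       duration = numeric()),
                 md_arities = c(3L, 3L, 3L, 4L), probs = list()),
            class = "transition_model")
}

# brute-force oracles -------------------------------------------------

oracle_subtree_bfs <- function(db, lin, id) {
  sub <- db[db$lineage_id == lin, ]
  out <- id
  queue <- id
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    kids <- sub$cell_id[(!is.na(sub$parent1) & sub$parent1 == cur) |
                        (!is.na(sub$parent2) & sub$parent2 == cur)]
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    queue <- c(queue, kids)
  }
  sort(out)
}

oracle_pop_count <- function(db, t) {
  n <- 0L
  for (i in seq_len(nrow(db))) {
    alive <- db$birth_time[i] <= t &&
      (t < db$fate_time[i] ||
         (db$fate[i] == "ALIVE_END" && t <= db$fate_time[i]))
    if (alive) n <- n + 1L
  }
  n
}

oracle_fate_patterns <- function(db) {
  pats <- as.vector(outer(c("CF", "MD"), c("BD", "MD", "CD", "CF"),
                          function(a, b) paste(a, ">", b)))
  counts <- setNames(integer(length(pats)), pats)
  for (i in seq_len(nrow(db))) {
    if (!is.na(db$parent2[i])) prior <- "CF"
    else if (!is.na(db$parent1[i])) {
      p <- which(db$lineage_id == db$lineage_id[i] &
                 db$cell_id == db$parent1[i])
      if (db$fate[p] != "MD") next
      prior <- "MD"
    } else next
    if (db$fate[i] %in% c("BD", "MD", "CD", "CF"))
      counts[paste(prior, ">", db$fate[i])] <-
        counts[paste(prior, ">", db$fate[i])] + 1L
  }
  counts
}

# recursive memoised back-propagation on one lineage
oracle_backprop <- function(db) {
  val <- db$sna1
  get_val <- function(i) {
    if (db$fate[i] %in% c("ALIVE_END", "CD")) return(val[i])
    kids <- which(db$lineage_id == db$lineage_id[i] &
                  ((!is.na(db$parent1) & db$parent1 == db$cell_id[i]) |
                   (!is.na(db$parent2) & db$parent2 == db$cell_id[i])))
    kv <- vapply(kids, get_val, 1)
    kv <- kv[!is.na(kv)]
    if (length(kv)) mean(kv) else NA_real_
  }
  for (i in seq_len(nrow(db)))
    if (is.na(val[i])) val[i] <- get_val(i)
  val
}

oracle_nearest <- function(position, micro, radius, k = 2) {
  if (!nrow(micro)) return(integer())
  d <- apply(micro[c("x", "y", "z")], 1, function(a)
    sqrt(sum((a - position)^2)))
  ord <- order(d, micro$id)
  ord <- ord[d[ord] <= radius]
  head(micro$id[ord], k)
}
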