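#' @title Cell lineage databases
#'
#' @description A `lineage_db` is the package's central container: one row per
#' tracked (or simulated) cell, with its genealogy and timed fate event. The
#' four fate events are bipolar division (`BD`, 2 daughters), multipolar
#' division (`MD`, >= 3 daughters), cell death (`CD`) and cell fusion (`CF`,
#' two cells merge into one fusion product with two parents). Cells still
#' alive when observation stops carry the explicit fate `ALIVE_END`, so
#' censoring is distinguishable from truncated data.
#'
#' Columns: `lineage_id`, `cell_id` (unique within a lineage; progenitors are
#' cell 0 by convention), `parent1`/`parent2` (cell ids, `NA` when absent;
#' fusion products have both), `birth_time` and `fate_time` in minutes,
#' `fate`, `md_poles` (daughter count of an MD, `NA` otherwise) and `sna1`
#' (SNA1 lectin fluorescence, arbitrary units, `NA` when unmeasured).
#' Attributes `frame_interval` (minutes per observation frame, default 10)
#' and `observation_end` (minutes) describe the observation window.
#' @name lineage_db
NULL

FATES <- c("BD", "MD", "CD", "CF", "ALIVE_END")
LINEAGE_SCHEMA_VERSION <- "tmesim-lineage-v1"
LINEAGE_COLS <- c("lineage_id", "cell_id", "parent1", "parent2",
                  "birth_time", "fate_time", "fate", "md_poles", "sna1")

#' Construct a lineage database
#'
#' @param records data.frame with columns `lineage_id`, `cell_id`, `parent1`,
#'   `parent2`, `birth_time`, `fate_time`, `fate`, `md_poles`, `sna1`.
#'   Missing optional columns (`parent2`, `md_poles`, `sna1`) are added as
#'   `NA`.
#' @param frame_interval minutes per observation frame (default 10).
#' @param observation_end end of the observation window in minutes; defaults
#'   to the largest `fate_time` present (0 for an empty database).
#' @param validate check all structural invariants (default `TRUE`).
#' @return An object of class `lineage_db`.
#' @export
lineage_db <- function(records = empty_lineage_records(), frame_interval = 10,
                       observation_end = NULL, validate = TRUE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("parent1", "parent2", "md_poles", "sna1")) {
    if (is.null(records[[col]])) records[[col]] <- rep(NA_real_, nrow(records))
  }
  need <- setdiff(LINEAGE_COLS, names(records))
  if (length(need))
    stop("lineage records lack column(s): ", paste(need, collapse = ", "))
  records <- records[LINEAGE_COLS]
  records$lineage_id <- as.integer(records$lineage_id)
  records$cell_id <- as.integer(records$cell_id)
  records$parent1 <- as.integer(records$parent1)
  records$parent2 <- as.integer(records$parent2)
  records$birth_time <- as.numeric(records$birth_time)
  records$fate_time <- as.numeric(records$fate_time)
  records$fate <- as.character(records$fate)
  records$md_poles <- as.integer(records$md_poles)
  records$sna1 <- as.numeric(records$sna1)
  rownames(records) <- NULL
  if (is.null(observation_end))
    observation_end <- if (nrow(records)) max(records$fate_time) else 0
  db <- structure(records, class = c("lineage_db", "data.frame"),
                  frame_interval = as.numeric(frame_interval),
                  observation_end = as.numeric(observation_end))
  if (validate) validate_lineage_db(db)
  db
}

#' @export
empty_lineage_records <- function() {
  data.frame(lineage_id = integer(), cell_id = integer(),
             parent1 = integer(), parent2 = integer(),
             birth_time = numeric(), fate_time = numeric(),
             fate = character(), md_poles = integer(), sna1 = numeric(),
             stringsAsFactors = FALSE)
}

#' Frame interval of a lineage database (minutes)
#' @param db a `lineage_db`.
#' @export
frame_interval <- function(db) attr(db, "frame_interval")

#' Observation end of a lineage database (minutes)
#' @param db a `lineage_db`.
#' @export
observation_end <- function(db) attr(db, "observation_end")

rec_label <- function(db, i) {
  sprintf("lineage %d cell %d", db$lineage_id[i], db$cell_id[i])
}

#' Validate the structural invariants of a lineage database
#'
#' Checks id uniqueness, parent resolution, fate arity (BD has exactly 2
#' daughters, MD exactly `md_poles` >= 3, CD/ALIVE_END none, CF exactly one
#' fusion product sharing the partner's `fate_time`), time consistency
#' (each child born at its parent's `fate_time`; `fate_time > birth_time`;
#' progenitors born at 0) and acyclicity.
#'
#' @param db a `lineage_db`.
#' @return `db`, invisibly; signals an error naming the offending record.
#' @export
validate_lineage_db <- function(db) {
  n <- nrow(db)
  if (n == 0L) return(invisible(db))
  key <- paste(db$lineage_id, db$cell_id)
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate cell id: ", rec_label(db, which(dup)[1]))
  if (any(bad <- !(db$fate %in% FATES)))
    stop("unknown fate '", db$fate[which(bad)[1]], "' at ",
         rec_label(db, which(bad)[1]))
  if (any(bad <- db$birth_time < 0))
    stop("negative birth_time at ", rec_label(db, which(bad)[1]))
  if (any(bad <- db$fate_time <= db$birth_time))
    stop("fate_time not after birth_time at ", rec_label(db, which(bad)[1]))
  if (any(bad <- !is.na(db$sna1) & db$sna1 < 0))
    stop("negative sna1 at ", rec_label(db, which(bad)[1]))
  if (any(bad <- db$fate == "MD" & (is.na(db$md_poles) | db$md_poles < 3L)))
    stop("MD without md_poles >= 3 at ", rec_label(db, which(bad)[1]))
  if (any(bad <- db$fate != "MD" & !is.na(db$md_poles)))
    stop("md_poles present on non-MD record at ", rec_label(db, which(bad)[1]))
  if (any(bad <- is.na(db$parent1) & !is.na(db$parent2)))
    stop("parent2 without parent1 at ", rec_label(db, which(bad)[1]))

  p1 <- match(paste(db$lineage_id, db$parent1), key)
  p2 <- match(paste(db$lineage_id, db$parent2), key)
  if (any(bad <- !is.na(db$parent1) & is.na(p1)))
    stop("dangling parent reference at ", rec_label(db, which(bad)[1]))
  if (any(bad <- !is.na(db$parent2) & is.na(p2)))
    stop("dangling parent reference at ", rec_label(db, which(bad)[1]))
  if (any(bad <- !is.na(p1) & p1 == seq_len(n)))
    stop("cell is its own parent at ", rec_label(db, which(bad)[1]))

  # progenitors start the observation
  root <- is.na(db$parent1)
  if (any(bad <- root & db$birth_time != 0))
    stop("progenitor with birth_time != 0 at ", rec_label(db, which(bad)[1]))
  # child born when the parent met its fate
  if (any(bad <- !is.na(p1) & db$birth_time != db$fate_time[p1]))
    stop("child birth_time differs from parent fate_time at ",
         rec_label(db, which(bad)[1]))
  if (any(bad <- !is.na(p2) & db$birth_time != db$fate_time[p2]))
    stop("child birth_time differs from parent fate_time at ",
         rec_label(db, which(bad)[1]))
  # acyclic: birth strictly increases along parent edges (guaranteed by the
  # two checks above plus fate_time > birth_time), so no further walk needed.

  # fate arity
  nchild <- tabulate(p1[!is.na(p1)], nbins = n) +
    tabulate(p2[!is.na(p2)], nbins = n)
  expected <- ifelse(db$fate == "BD", 2L,
              ifelse(db$fate == "MD", db$md_poles,
              ifelse(db$fate == "CF", 1L, 0L)))
  if (any(bad <- nchild != expected))
    stop(sprintf("fate %s expects %d daughter record(s), found %d, at %s",
                 db$fate[which(bad)[1]], expected[which(bad)[1]],
                 nchild[which(bad)[1]], rec_label(db, which(bad)[1])))
  # CF partners fuse simultaneously and the product names this cell
  cf <- which(db$fate == "CF")
  for (i in cf) {
    prod <- which(!is.na(p2) & (p1 == i | p2 == i))
    if (length(prod) != 1L)
      stop("CF cell without a two-parent fusion product at ", rec_label(db, i))
    partner <- setdiff(c(p1[prod], p2[prod]), i)
    if (db$fate[partner] != "CF" || db$fate_time[partner] != db$fate_time[i])
      stop("fusion partners disagree on fate/fate_time at ", rec_label(db, i))
  }
  invisible(db)
}

#' Read a lineage database from CSV or JSON
#'
#' The CSV layout is one row per cell with a `parent_ids` column holding a
#' semicolon-joined id list (empty for progenitors, two ids for fusion
#' products) and a first comment line `#tmesim-lineage-v1,frame_interval,
#' observation_end` carrying the schema version and window metadata. The JSON
#' layout stores the same fields natively (`parent_ids` as an array).
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`; inferred from the extension by default.
#' @return a validated [lineage_db].
#' @export
read_lineage_db <- function(path, format = c("auto", "csv", "json")) {
  format <- resolve_format(match.arg(format), path)
  if (format == "csv") {
    header <- strsplit(readLines(path, n = 1L), ",")[[1]]
    if (length(header) < 3L || header[1] != paste0("#", LINEAGE_SCHEMA_VERSION))
      stop("not a ", LINEAGE_SCHEMA_VERSION, " file: ", path)
    raw <- utils::read.csv(path, comment.char = "#",
                           colClasses = c(parent_ids = "character"),
                           na.strings = c("NA", ""), stringsAsFactors = FALSE)
    parents <- parse_parent_ids(raw$parent_ids)
    rec <- data.frame(lineage_id = raw$lineage_id, cell_id = raw$cell_id,
                      parent1 = parents[, 1], parent2 = parents[, 2],
                      birth_time = raw$birth_time, fate_time = raw$fate_time,
                      fate = raw$fate, md_poles = raw$md_poles,
                      sna1 = raw$sna1, stringsAsFactors = FALSE)
    lineage_db(rec, frame_interval = as.numeric(header[2]),
               observation_end = as.numeric(header[3]))
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = TRUE)
    if (!identical(obj$schema, LINEAGE_SCHEMA_VERSION))
      stop("not a ", LINEAGE_SCHEMA_VERSION, " file: ", path)
    raw <- obj$records
    if (is.null(raw) || length(raw) == 0L || nrow(as.data.frame(raw)) == 0L) {
      rec <- empty_lineage_records()
    } else {
      raw <- as.data.frame(raw)
      pl <- raw$parent_ids
      if (is.null(pl)) pl <- rep(list(integer()), nrow(raw))
      p1 <- vapply(pl, function(p) if (length(p) >= 1) as.integer(p[1]) else NA_integer_, 1L)
      p2 <- vapply(pl, function(p) if (length(p) >= 2) as.integer(p[2]) else NA_integer_, 1L)
      rec <- data.frame(lineage_id = raw$lineage_id, cell_id = raw$cell_id,
                        parent1 = p1, parent2 = p2,
                        birth_time = raw$birth_time, fate_time = raw$fate_time,
                        fate = raw$fate,
                        md_poles = if (is.null(raw$md_poles)) NA else raw$md_poles,
                        sna1 = if (is.null(raw$sna1)) NA else raw$sna1,
                        stringsAsFactors = FALSE)
    }
    lineage_db(rec, frame_interval = obj$frame_interval,
               observation_end = obj$observation_end)
  }
}

#' Write a lineage database to CSV or JSON
#'
#' @param db a validated [lineage_db].
#' @param path destination file path.
#' @param format `"csv"` or `"json"`; inferred from the extension by default.
#' @return `path`, invisibly. `read_lineage_db(write_lineage_db(db))`
#'   reproduces `db` exactly, including absent (`NA`) `sna1` values.
#' @export
write_lineage_db <- function(db, path, format = c("auto", "csv", "json")) {
  format <- resolve_format(match.arg(format), path)
  stopifnot(inherits(db, "lineage_db"))
  pid <- format_parent_ids(db$parent1, db$parent2)
  if (format == "csv") {
    # 17 significant digits keep the times/values bit-identical on re-read
    num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
    out <- data.frame(lineage_id = db$lineage_id, cell_id = db$cell_id,
                      parent_ids = pid, birth_time = num(db$birth_time),
                      fate_time = num(db$fate_time), fate = db$fate,
                      md_poles = db$md_poles, sna1 = num(db$sna1),
                      stringsAsFactors = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#%s,%.17g,%.17g", LINEAGE_SCHEMA_VERSION,
                       frame_interval(db), observation_end(db)), con)
    utils::write.csv(out, con, row.names = FALSE, na = "")
  } else {
    pl <- mapply(function(a, b) as.integer(c(a, b)[!is.na(c(a, b))]),
                 db$parent1, db$parent2, SIMPLIFY = FALSE)
    recs <- lapply(seq_len(nrow(db)), function(i) {
      r <- list(lineage_id = db$lineage_id[i], cell_id = db$cell_id[i],
                parent_ids = pl[[i]], birth_time = db$birth_time[i],
                fate_time = db$fate_time[i], fate = db$fate[i])
      if (!is.na(db$md_poles[i])) r$md_poles <- db$md_poles[i]
      if (!is.na(db$sna1[i])) r$sna1 <- db$sna1[i]
      r
    })
    jsonlite::write_json(
      list(schema = LINEAGE_SCHEMA_VERSION,
           frame_interval = frame_interval(db),
           observation_end = observation_end(db), records = recs),
      path, auto_unbox = TRUE, digits = I(17), null = "null")
  }
  invisible(path)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
}

parse_parent_ids <- function(x) {
  x[is.na(x)] <- ""
  parts <- strsplit(x, ";", fixed = TRUE)
  t(vapply(parts, function(p) {
    p <- p[nzchar(p)]
    c(if (length(p) >= 1) as.integer(p[1]) else NA_integer_,
      if (length(p) >= 2) as.integer(p[2]) else NA_integer_)
  }, integer(2)))
}

format_parent_ids <- function(p1, p2) {
  out <- ifelse(is.na(p1), "",
         ifelse(is.na(p2), as.character(p1), paste(p1, p2, sep = ";")))
  as.character(out)
}

#' Cells of a subtree: a cell and all of its descendants
#'
#' Descent follows the child relation, so fusion products are included
#' whenever *either* of their parents is already in the set.
#'
#' @param db a `lineage_db`.
#' @param lineage_id lineage containing the cell.
#' @param cell_id id of the subtree root within that lineage.
#' @return integer vector of cell ids (sorted), always containing `cell_id`.
#' @export
subtree <- function(db, lineage_id, cell_id) {
  cell_id <- as.integer(cell_id)
  sub <- db[db$lineage_id == lineage_id, , drop = FALSE]
  if (!any(sub$cell_id == cell_id))
    stop("unknown cell id ", cell_id, " in lineage ", lineage_id)
  found <- cell_id
  frontier <- cell_id
  while (length(frontier)) {
    kids <- sub$cell_id[(sub$parent1 %in% frontier & !is.na(sub$parent1)) |
                        (sub$parent2 %in% frontier & !is.na(sub$parent2))]
    frontier <- setdiff(kids, found)
    found <- c(found, frontier)
  }
  sort(unique(found))
}

#' @export
print.lineage_db <- function(x, ...) {
  cat(sprintf(
    "<lineage_db> %d cells in %d lineage(s); frame %g min, window %g min\n",
    nrow(x), length(unique(x$lineage_id)), frame_interval(x),
    observation_end(x)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}
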