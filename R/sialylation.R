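#' @title SNA1 expression back-propagation and expression lists
#'
#' @description Terminal SNA1 lectin staining measures alpha2-6 sialylation
#' only for cells alive at the end of live-cell imaging. These terminal
#' values are traced back up the lineage map: every dividing ancestor is
#' assigned the arithmetic mean of its daughters' (post-propagation) values.
#' Dead branches carry no stain and are excluded from the averages; a fusion
#' product's value propagates to both of its parents. The resulting values of
#' all cells, zeros included, form the expression list sampled during deduced
#' population generation.
#' @name sialylation
NULL

#' Back-propagate terminal SNA1 values up each lineage tree
#'
#' @param db a [lineage_db] in which every `ALIVE_END` cell of a lineage to
#'   be processed carries a measured `sna1` (other cells absent/`NA`).
#' @return `db` with `sna1` filled for internal division/fusion cells.
#'   Lineages without a single measured terminal cell are left untouched,
#'   with a warning. The operation is idempotent.
#' @export
backpropagate_expression <- function(db) {
  key <- paste(db$lineage_id, db$cell_id)
  p1 <- match(paste(db$lineage_id, db$parent1), key)
  p2 <- match(paste(db$lineage_id, db$parent2), key)
  children <- vector("list", nrow(db))
  for (i in seq_len(nrow(db))) {
    if (!is.na(p1[i])) children[[p1[i]]] <- c(children[[p1[i]]], i)
    if (!is.na(p2[i])) children[[p2[i]]] <- c(children[[p2[i]]], i)
  }
  val <- db$sna1
  # process cells deepest-first so daughters resolve before parents
  ord <- order(db$birth_time, decreasing = TRUE)
  for (i in ord) {
    if (db$fate[i] %in% c("ALIVE_END", "CD")) next
    kv <- val[children[[i]]]
    kv <- kv[!is.na(kv)]
    if (length(kv)) val[i] <- mean(kv)
  }
  untouched <- vapply(split(is.na(val), db$lineage_id), all, TRUE)
  if (any(untouched) && nrow(db))
    warning("lineage(s) without measured terminal cells left untouched: ",
            paste(names(untouched)[untouched], collapse = ", "))
  db$sna1[is.na(db$sna1)] <- val[is.na(db$sna1)]
  db
}

#' Build the expression list of a back-propagated lineage database
#'
#' One entry per cell (all generations) carrying an SNA1 value; zeros are
#' kept, since non-expressing cells are part of the sampling pool.
#'
#' @param db a [lineage_db] after [backpropagate_expression()].
#' @param source identifier of the originating database (default `"db"`).
#' @return object of class `expression_list`: list with `values`, `v_max`
#'   (maximum observed value; `NA` with a warning when empty) and `source`.
#' @export
build_expression_list <- function(db, source = "db") {
  values <- db$sna1[!is.na(db$sna1)]
  if (!length(values)) {
    warning("empty expression list: no measured cells; v_max undefined")
    v_max <- NA_real_
  } else v_max <- max(values)
  structure(list(values = as.numeric(values), v_max = v_max, source = source),
            class = "expression_list")
}

#' @export
print.expression_list <- function(x, ...) {
  cat(sprintf("<expression_list> %d values from '%s', v_max = %g, %d zero(s)\n",
              length(x$values), x$source, x$v_max, sum(x$values == 0)))
  invisible(x)
}

#' Write an expression list as a one-column CSV with metadata header
#' @param x an `expression_list`.
#' @param path destination path.
#' @export
write_expression_list <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#tmesim-exprlist-v1,%s,%.15g", x$source, x$v_max), con)
  utils::write.csv(data.frame(sna1 = x$values), con, row.names = FALSE)
  invisible(path)
}

#' Read an expression list written by [write_expression_list()]
#' @param path file path.
#' @export
read_expression_list <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (header[1] != "#tmesim-exprlist-v1")
    stop("not a tmesim-exprlist-v1 file: ", path)
  vals <- utils::read.csv(path, comment.char = "#")$sna1
  structure(list(values = as.numeric(vals), v_max = as.numeric(header[3]),
                 source = header[2]),
            class = "expression_list")
}
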