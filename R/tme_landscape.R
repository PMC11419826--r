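#' @title Immune-landscape categorization
#'
#' @description Per-case tumor cell-composition tables (ConsensusTME-style:
#' one row per cancer case, one column per immune/stromal cell type, values
#' in percent) are reduced to three microenvironment categories. Suppressive
#' covers CD4+ and CD8+ T cells, gamma-delta T cells, B cells, plasma cells
#' and monocytes; permissive covers M2 macrophages, regulatory T cells, mast
#' cells, endothelial cells and cancer-associated fibroblasts; lethal covers
#' cytotoxic cells and natural killer cells. M1 macrophages and neutrophils
#' play context-dependent dual roles and are deliberately excluded.
#' @name tme_landscape
NULL

#' Default cell-type-to-category map
#'
#' Editable: deconvolution exports label cell types inconsistently, so the
#' map is a plain data.frame users can extend. Matching is performed on
#' names normalized to lower case with punctuation collapsed to spaces.
#' Category `"ignore"` marks types that are recognized but contribute to no
#' fraction (M1 macrophages, neutrophils).
#'
#' @return data.frame with columns `type` and `category`.
#' @export
default_cell_type_map <- function() {
  data.frame(
    type = c("T cell CD4+", "T cell CD8+", "T cell gamma delta", "B cells",
             "Plasma cells", "Monocyte",
             "Macrophage M2", "T cells regulatory", "Mast cells",
             "Endothelial cells", "Cancer associated fibroblast",
             "Cytotoxic cells", "NK cells",
             "Macrophage M1", "Neutrophils"),
    category = c(rep("suppressive", 6), rep("permissive", 5),
                 rep("lethal", 2), rep("ignore", 2)),
    stringsAsFactors = FALSE)
}

normalize_type <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

#' Reduce a cell-type composition to category fractions
#'
#' Each fraction is the sum of its member types' percentages divided by 100;
#' unmapped and `"ignore"`-mapped types contribute nothing. Fractions are
#' independent ratios to cancer cells and may sum above 1; no normalization
#' is applied.
#'
#' @param composition named numeric vector of percentages (>= 0).
#' @param map cell-type map, see [default_cell_type_map()].
#' @return named numeric vector `c(suppressive, permissive, lethal)`.
#' @export
categorize_composition <- function(composition, map = default_cell_type_map()) {
  if (any(composition < 0, na.rm = TRUE)) stop("negative percentage")
  cat_of <- stats::setNames(map$category, normalize_type(map$type))
  cats <- cat_of[normalize_type(names(composition))]
  out <- c(suppressive = 0, permissive = 0, lethal = 0)
  for (k in names(out))
    out[k] <- sum(composition[!is.na(cats) & cats == k], na.rm = TRUE) / 100
  out
}

#' Microenvironment agent counts for a simulation
#'
#' Counts are ratios to the cancer-cell population: a 45% suppressive
#' fraction with 500 cancer cells places 225 suppressive agents; an explicit
#' 1:0.5 ratio places 250. Rounding is to the nearest integer, ties to even.
#'
#' @param n_cancer number of deduced cancer progenitors (> 0).
#' @param fractions named vector as returned by [categorize_composition()],
#'   or any named non-negative ratios.
#' @return named integer vector `c(n_suppressive, n_permissive, n_lethal)`
#'   (names follow the input).
#' @export
agent_counts <- function(n_cancer, fractions) {
  stopifnot(n_cancer > 0)
  if (any(fractions < 0)) stop("negative fraction")
  stats::setNames(as.integer(round(n_cancer * fractions)), names(fractions))
}

#' Read a per-case landscape table and compute category fractions
#'
#' Expects a CSV with a `case_id` column (the first column is used when
#' absent) and one column per cell type. Columns that resolve to no map
#' entry are reported with a warning — never silently dropped — and excluded
#' from the fractions, as are `"ignore"`-mapped types.
#'
#' @param path CSV path.
#' @param map cell-type map, see [default_cell_type_map()].
#' @return data.frame of class `landscape_cases`: `case_id`, the three
#'   fractions, plus the raw composition columns (attribute `composition`).
#' @export
read_landscape_table <- function(path, map = default_cell_type_map()) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  idcol <- if ("case_id" %in% names(raw)) "case_id" else names(raw)[1]
  types <- setdiff(names(raw), idcol)
  known <- normalize_type(types) %in% normalize_type(map$type)
  if (any(!known))
    warning("unmapped cell-type column(s) excluded from fractions: ",
            paste(types[!known], collapse = ", "))
  comp <- as.matrix(raw[types])
  frac <- t(apply(comp, 1, function(row)
    categorize_composition(stats::setNames(as.numeric(row), types), map)))
  out <- data.frame(case_id = as.character(raw[[idcol]]),
                    suppressive = frac[, "suppressive"],
                    permissive = frac[, "permissive"],
                    lethal = frac[, "lethal"],
                    stringsAsFactors = FALSE)
  attr(out, "composition") <- raw
  class(out) <- c("landscape_cases", "data.frame")
  out
}

#' Write categorized landscape results (fractions and agent counts)
#'
#' @param cases a `landscape_cases` data.frame.
#' @param n_cancer cancer-cell count used to derive agent counts.
#' @param path destination CSV.
#' @export
write_landscape_results <- function(cases, n_cancer, path) {
  counts <- t(apply(cases[c("suppressive", "permissive", "lethal")], 1,
                    function(f) agent_counts(n_cancer, unlist(f))))
  out <- cbind(cases[c("case_id", "suppressive", "permissive", "lethal")],
               n_suppressive = counts[, 1], n_permissive = counts[, 2],
               n_lethal = counts[, 3])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
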