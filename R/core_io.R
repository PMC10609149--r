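# Data model and readers/writers for metabolite tables and descriptor
# matrices, plus the built-in SMILES -> descriptor adapter.

# Fixed label vocabulary.  Leaf labels AD/SQ are subtypes of NS; SC (and NS
# without a known subtype) carry no sub-label.  Synonyms cover the two
# conventions found in source datasets.
.top_levels <- c("NS", "SC")
.sub_levels <- c("AD", "SQ", "NONE")
.label_map <- list(
  NS     = c(top = "NS", sub = "NONE"),
  NSCLC  = c(top = "NS", sub = "NONE"),
  SC     = c(top = "SC", sub = "NONE"),
  SCLC   = c(top = "SC", sub = "NONE"),
  AD     = c(top = "NS", sub = "AD"),
  SQ     = c(top = "NS", sub = "SQ")
)

map_class_label <- function(label) {
  key <- toupper(trimws(as.character(label)))
  unknown <- setdiff(unique(key), names(.label_map))
  if (length(unknown) > 0L)
    mt_validation_error("unknown class label(s): ", paste(unknown, collapse = ", "),
                        " (accepted: ", paste(names(.label_map), collapse = ", "), ")")
  data.frame(
    top_label = factor(vapply(.label_map[key], `[[`, "", "top"), levels = .top_levels),
    sub_label = factor(vapply(.label_map[key], `[[`, "", "sub"), levels = .sub_levels),
    stringsAsFactors = FALSE
  )
}

# Leaf label used by folds and the naive multiclass baseline: AD, SQ, SC,
# plus NS for NS rows without a known subtype.
leaf_labels <- function(top, sub) {
  out <- as.character(sub)
  out[out == "NONE"] <- as.character(top)[out == "NONE"]
  factor(out, levels = intersect(c("AD", "SQ", "SC", "NS"), unique(out)))
}

#' Construct a metabolite table
#'
#' A metabolite table holds the raw per-metabolite records (name, optional
#' SMILES, p-value and fold change from the differential-abundance analysis,
#' and the cancer-type label) before descriptor computation.
#'
#' @param name Character vector of unique metabolite names.
#' @param p_value Per-metabolite p-values in `[0, 1]`.
#' @param fold_change Positive fold changes (cancer vs control abundance ratio).
#' @param label Class labels: `AD`, `SQ`, `SC`, `NS` (synonyms `NSCLC`,
#'   `SCLC` accepted, case-insensitively). `AD`/`SQ` imply top label `NS`.
#' @param smiles Optional SMILES strings (may be `NA`).
#' @return A `data.frame` of class `metabolite_table` with columns `name`,
#'   `smiles`, `p_value`, `fold_change`, `top_label`, `sub_label`.
#' @export
#' @examples
#' metabolite_table(c("trp", "met"), c(0.01, 0.2), c(1.5, 1.1), c("AD", "SC"))
metabolite_table <- function(name, p_value, fold_change, label, smiles = NA_character_) {
  n <- length(name)
  if (n == 0L) mt_validation_error("metabolite table must have at least one record")
  name <- as.character(name)
  if (anyDuplicated(name))
    mt_validation_error("duplicate metabolite names: ",
                        paste(unique(name[duplicated(name)]), collapse = ", "))
  p_value <- as.numeric(p_value)
  fold_change <- as.numeric(fold_change)
  if (any(!is.finite(p_value)) || any(p_value < 0 | p_value > 1))
    mt_validation_error("p_value must lie in [0, 1]")
  if (any(!is.finite(fold_change)) || any(fold_change <= 0))
    mt_validation_error("fold_change must be positive")
  lab <- map_class_label(label)
  out <- data.frame(
    name = name,
    smiles = rep_len(as.character(smiles), n),
    p_value = p_value,
    fold_change = fold_change,
    top_label = lab$top_label,
    sub_label = lab$sub_label,
    stringsAsFactors = FALSE
  )
  class(out) <- c("metabolite_table", "data.frame")
  out
}

# Display label for writing: the leaf class (AD/SQ/SC/NS).
table_file_label <- function(tab) as.character(leaf_labels(tab$top_label, tab$sub_label))

#' Read a metabolite table from CSV/TSV
#'
#' The file must carry a header with at least `name`, `p_value`,
#' `fold_change` and `label` columns; a `smiles` column is optional.  Label
#' strings are mapped case-insensitively (`NSCLC`/`SCLC` synonyms accepted).
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"tsv"`.
#' @return A [metabolite_table()].
#' @export
read_metabolite_table <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) mt_format_error("file not found: ", path)
  dt <- data.table::fread(path, sep = if (dialect == "csv") "," else "\t",
                          header = TRUE, colClasses = "character",
                          data.table = FALSE)
  required <- c("name", "p_value", "fold_change", "label")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols) > 0L)
    mt_format_error("missing required column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("p_value", "fold_change")) {
    vals <- suppressWarnings(as.numeric(dt[[col]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0L)
      mt_format_error("unparseable numeric value(s) in column '", col,
                      "' at row(s): ", paste(bad, collapse = ", "))
    dt[[col]] <- vals
  }
  metabolite_table(
    name = dt$name,
    p_value = dt$p_value,
    fold_change = dt$fold_change,
    label = dt$label,
    smiles = if ("smiles" %in% names(dt)) dt$smiles else NA_character_
  )
}

#' Write a metabolite table to CSV/TSV
#'
#' Inverse of [read_metabolite_table()]; the `label` column is the leaf class
#' (`AD`, `SQ`, `SC`, or `NS` when no subtype is known).
#'
#' @param table A [metabolite_table()].
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_metabolite_table <- function(table, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "metabolite_table"))
  out <- data.frame(
    name = table$name,
    smiles = table$smiles,
    p_value = table$p_value,
    fold_change = table$fold_change,
    label = table_file_label(table),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = if (dialect == "csv") "," else "\t")
  invisible(path)
}

#' Validate a descriptor matrix
#'
#' The pipeline's working representation is a plain numeric matrix whose row
#' names are metabolite names and whose column names are descriptor names
#' (both unique, no missing values).
#'
#' @param values Numeric matrix with unique row and column names.
#' @return The validated matrix, invisibly classed as given.
#' @export
as_descriptor_matrix <- function(values) {
  check_matrix(values, "descriptor matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    mt_validation_error("descriptor matrix must have row names (metabolites) and column names (descriptors)")
  if (anyDuplicated(rownames(values)))
    mt_validation_error("duplicate metabolite names in descriptor matrix")
  if (anyDuplicated(colnames(values)))
    mt_validation_error("duplicate descriptor names in descriptor matrix")
  if (any(!is.finite(values)))
    mt_validation_error("descriptor matrix contains non-finite values after load")
  values
}

#' Read a descriptor matrix from CSV
#'
#' Expects a header row and a first column `name` holding metabolite names;
#' every remaining column is a numeric descriptor.  Empty cells (or `NA`) are
#' imputed with the column median; columns that are entirely missing are
#' dropped.  The count of imputed cells is logged and attached as attribute
#' `imputed`.
#'
#' @param path Path to the CSV file.
#' @return Numeric matrix (metabolites x descriptors).
#' @export
read_descriptor_matrix <- function(path) {
  if (!file.exists(path)) mt_format_error("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                          data.table = FALSE)
  if (nrow(dt) == 0L || ncol(dt) < 2L)
    mt_validation_error("empty descriptor matrix: ", path)
  if (names(dt)[1L] != "name")
    mt_format_error("first column of a descriptor matrix must be 'name' (got '",
                    names(dt)[1L], "')")
  ids <- dt$name
  raw <- dt[, -1L, drop = FALSE]
  mat <- matrix(NA_real_, nrow(raw), ncol(raw),
                dimnames = list(ids, names(raw)))
  for (j in seq_len(ncol(raw))) {
    cell <- trimws(raw[[j]])
    empty <- is.na(cell) | cell == "" | toupper(cell) == "NA"
    vals <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(vals))
    if (length(bad) > 0L)
      mt_format_error("non-numeric cell at row ", bad[1L], ", column '",
                      names(raw)[j], "': '", cell[bad[1L]], "'")
    mat[, j] <- vals
  }
  all_missing <- colSums(is.na(mat)) == nrow(mat)
  if (any(all_missing)) {
    mt_log("dropping ", sum(all_missing), " all-missing descriptor column(s): ",
           paste(colnames(mat)[all_missing], collapse = ", "))
    mat <- mat[, !all_missing, drop = FALSE]
  }
  n_imputed <- sum(is.na(mat))
  if (n_imputed > 0L) {
    for (j in which(colSums(is.na(mat)) > 0L)) {
      med <- stats::median(mat[, j], na.rm = TRUE)
      mat[is.na(mat[, j]), j] <- med
    }
  }
  mt_log("read descriptor matrix ", nrow(mat), " x ", ncol(mat),
         " (", n_imputed, " cell(s) imputed with column median)")
  out <- as_descriptor_matrix(mat)
  attr(out, "imputed") <- n_imputed
  out
}

#' Write a descriptor matrix to CSV
#'
#' @param matrix Numeric matrix with metabolite row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_matrix <- function(matrix, path) {
  as_descriptor_matrix(matrix)
  df <- data.frame(name = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = ",")
  invisible(path)
}

# The builtin descriptor set: deterministic pure-string features of a SMILES,
# so the whole pipeline runs with no external chemistry engine.  SMILES are
# opaque strings here; no chemistry validation beyond non-emptiness.
.builtin_descriptor_fns <- list(
  smiles_length   = function(s) nchar(s),
  n_C             = function(s) count_char(s, "C"),
  n_N             = function(s) count_char(s, "N"),
  n_O             = function(s) count_char(s, "O"),
  n_S             = function(s) count_char(s, "S"),
  n_P             = function(s) count_char(s, "P"),
  n_ring_digits   = function(s) lengths(gregexpr("[0-9]", s)) * (grepl("[0-9]", s)),
  n_branch_open   = function(s) count_char(s, "("),
  branch_depth    = function(s) vapply(s, paren_depth, 0L, USE.NAMES = FALSE),
  n_charge        = function(s) count_char(s, "+") + count_char(s, "-"),
  n_aromatic      = function(s) lengths(gregexpr("[a-z]", s)) * (grepl("[a-z]", s)),
  n_double_bond   = function(s) count_char(s, "="),
  n_triple_bond   = function(s) count_char(s, "#")
)

count_char <- function(s, ch) {
  vapply(strsplit(s, "", fixed = TRUE),
         function(x) sum(x == ch), 0L, USE.NAMES = FALSE)
}

paren_depth <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- cumsum((ch == "(") - (ch == ")"))
  if (length(depth) == 0L) 0L else max(0L, depth)
}

#' Compute molecular descriptors from SMILES
#'
#' The `builtin_count` backend returns a small deterministic descriptor set
#' computed from the SMILES string alone (length, C/N/O/S/P symbol counts,
#' ring-opening digits, branching, charges, aromatic lowercase, bond
#' symbols), so the pipeline never requires an external descriptor engine.
#' The `external_engine` backend delegates to a full descriptor calculator
#' (e.g. PaDEL-style engines producing ~1083 columns) registered by the user
#' as a function via `options(metabotree.descriptor_engine = <function>)`;
#' when none is registered, a capability error instructs use of
#' `builtin_count` or a precomputed matrix.
#'
#' @param smiles Character vector of non-empty SMILES strings; names (if
#'   present) become row names, otherwise `mN` indices are used.
#' @param backend `"builtin_count"` or `"external_engine"`.
#' @return Numeric descriptor matrix (one row per SMILES).
#' @export
#' @examples
#' compute_descriptors(c(methane = "C", ethane = "CC"))[, "n_C"]
compute_descriptors <- function(smiles, backend = c("builtin_count", "external_engine")) {
  backend <- match.arg(backend)
  ids <- names(smiles) %||% paste0("m", seq_along(smiles))
  smiles <- unname(as.character(smiles))
  bad <- which(is.na(smiles) | !nzchar(smiles))
  if (length(bad) > 0L)
    mt_validation_error("empty/missing SMILES for record(s): ",
                        paste(ids[bad], collapse = ", "))
  if (backend == "external_engine") {
    engine <- getOption("metabotree.descriptor_engine", NULL)
    if (!is.function(engine))
      mt_capability_error("no external descriptor engine registered; ",
                          "use backend = 'builtin_count' or supply a ",
                          "precomputed descriptor matrix")
    out <- engine(smiles)
    dimnames(out) <- list(ids, colnames(out))
    return(as_descriptor_matrix(out))
  }
  cols <- lapply(.builtin_descriptor_fns, function(f) as.numeric(f(smiles)))
  mat <- do.call(cbind, cols)
  dimnames(mat) <- list(ids, names(.builtin_descriptor_fns))
  as_descriptor_matrix(mat)
}

#' Construct a labeled dataset
#'
#' Bundles a descriptor matrix with the two-level labels the tree classifier
#' consumes: a top label (`NS`/`SC`) for every row and a sub label
#' (`AD`/`SQ`, or `NONE`) that may be non-`NONE` only for `NS` rows.
#'
#' @param descriptors Numeric descriptor matrix (see [as_descriptor_matrix()]).
#' @param top_labels Vector coercible to factor with levels `NS`, `SC`.
#' @param sub_labels Vector coercible to factor with levels `AD`, `SQ`, `NONE`.
#' @return A list of class `labeled_dataset`.
#' @export
labeled_dataset <- function(descriptors, top_labels, sub_labels) {
  descriptors <- as_descriptor_matrix(descriptors)
  top <- factor(as.character(top_labels), levels = .top_levels)
  sub <- factor(as.character(sub_labels), levels = .sub_levels)
  if (length(top) != nrow(descriptors) || length(sub) != nrow(descriptors))
    mt_validation_error("label vectors must align with descriptor matrix rows")
  if (anyNA(top) || anyNA(sub))
    mt_validation_error("labels must be NS/SC (top) and AD/SQ/NONE (sub)")
  if (any(sub != "NONE" & top != "NS"))
    mt_validation_error("sub_label other than NONE requires top_label NS")
  structure(list(descriptors = descriptors, top_labels = top, sub_labels = sub),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", nrow(x$descriptors), " metabolites x ",
      ncol(x$descriptors), " descriptors\n", sep = "")
  print(table(leaf = leaf_labels(x$top_labels, x$sub_labels)))
  invisible(x)
}

# Build a labeled dataset from a metabolite table plus its descriptor matrix
# (rows matched by name).
dataset_from_table <- function(table, descriptors) {
  stopifnot(inherits(table, "metabolite_table"))
  descriptors <- as_descriptor_matrix(descriptors)
  missing_rows <- setdiff(table$name, rownames(descriptors))
  if (length(missing_rows) > 0L)
    mt_validation_error("descriptor matrix lacks rows for: ",
                        paste(missing_rows, collapse = ", "))
  labeled_dataset(descriptors[table$name, , drop = FALSE],
                  table$top_label, table$sub_label)
}
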