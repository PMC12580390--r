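#' Phenotype gating rules
#'
#' A phenotype rule names a cell phenotype and lists the markers that must be
#' positive and the markers that must be negative for a cell to receive that
#' label. The default rule set encodes the operational definitions used for
#' stromal phenotyping of multiplex-IF lung cohorts: CAFs are aSMA+/CK- and
#' TAECs are CD31+/CK- (CK marks epithelial/tumor cells; every row of a cell
#' table is a DAPI-nucleated cell, so no DAPI column is carried).
#'
#' @param name Phenotype label (nonempty string).
#' @param positive Character vector of markers that must be 1.
#' @param negative Character vector of markers that must be 0.
#' @return An object of class `phenotype_rule`.
#' @examples
#' phenotype_rule("CAF", positive = "aSMA", negative = "CK")
#' @export
phenotype_rule <- function(name, positive = character(), negative = character()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("phenotype rule name must be a nonempty string", call. = FALSE)
  }
  positive <- as.character(positive)
  negative <- as.character(negative)
  structure(
    list(name = name, positive = positive, negative = negative),
    class = "phenotype_rule"
  )
}

#' @export
print.phenotype_rule <- function(x, ...) {
  pos <- if (length(x$positive)) paste0(x$positive, "+", collapse = "/") else ""
  neg <- if (length(x$negative)) paste0(x$negative, "-", collapse = "/") else ""
  cat("<phenotype_rule> ", x$name, ": ",
      paste(c(pos, neg)[nzchar(c(pos, neg))], collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Default CAF/TAEC phenotype rules
#'
#' CAF = aSMA+/CK-, TAEC = CD31+/CK-. Order matters: when a cell satisfies
#' more than one rule (e.g. an aSMA+/CD31+/CK- double positive), the first
#' matching rule in the list wins, so the default resolves such cells as CAF.
#'
#' @return A list of [phenotype_rule()] objects, CAF first.
#' @export
default_phenotype_rules <- function() {
  list(
    phenotype_rule("CAF",  positive = "aSMA", negative = "CK"),
    phenotype_rule("TAEC", positive = "CD31", negative = "CK")
  )
}

#' Validate a phenotype rule set
#'
#' Checks a rule list for configuration mistakes: a marker required both
#' positive and negative in one rule, duplicate phenotype names, and rules
#' with no marker requirements at all. Returns a report rather than erroring,
#' so a configuration UI can surface every problem at once.
#'
#' @param rules List of [phenotype_rule()] objects.
#' @return A tibble with columns `rule` and `issue`; zero rows when the rule
#'   set is clean.
#' @export
validate_rules <- function(rules) {
  stopifnot(is.list(rules))
  issues <- list()
  add <- function(rule, issue) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(rule = rule, issue = issue)
  }
  nms <- vapply(rules, function(r) r$name, character(1))
  for (dup in unique(nms[duplicated(nms)])) {
    add(dup, "duplicate rule name")
  }
  for (r in rules) {
    both <- intersect(r$positive, r$negative)
    if (length(both)) {
      add(r$name, paste0("marker in both positive and negative sets: ",
                         paste(both, collapse = ", ")))
    }
    if (length(r$positive) + length(r$negative) == 0L) {
      add(r$name, "rule has no marker requirements")
    }
  }
  if (length(issues)) dplyr::bind_rows(issues) else {
    tibble::tibble(rule = character(), issue = character())
  }
}

.default_markers <- c("CK", "aSMA", "CD31", "PDL1", "PD1")

#' Column-name schema for per-cell CSV exports
#'
#' Maps the canonical field names used by the package onto the column names of
#' an inForm-style per-cell export. Override individual entries to match local
#' export conventions. Marker entries (names other than patient_id, core_id,
#' cell_id, x, y) define which binary positivity columns are read; coordinates
#' are taken as micrometres.
#'
#' @param ... Named overrides, e.g. `x = "Cell.X.Position"`.
#' @return Named character vector mapping canonical names to column names.
#' @export
default_schema <- function(...) {
  schema <- c(
    patient_id = "patient_id", core_id = "core_id", cell_id = "cell_id",
    x = "x_um", y = "y_um",
    CK = "ck_pos", aSMA = "asma_pos", CD31 = "cd31_pos",
    PDL1 = "pdl1_pos", PD1 = "pd1_pos"
  )
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(schema))
    if (length(bad)) stop("unknown schema field(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    schema[names(over)] <- over
  }
  schema
}

schema_markers <- function(schema) {
  setdiff(names(schema), c("patient_id", "core_id", "cell_id", "x", "y"))
}

#' Construct a per-core cell table
#'
#' A cell table is the unit of spatial analysis: all segmented cells of one
#' TMA core of one patient, with centroid coordinates in micrometres and
#' binary marker positivity. Coordinates use the imaging convention (origin
#' top-left, y increasing downward); all distances are origin-invariant.
#'
#' @param patient_id,core_id Identifiers (strings).
#' @param cells Data frame with columns `cell_id`, `x`, `y` and one 0/1 column
#'   per marker.
#' @param width,height Core bounds in micrometres. Defaults to the smallest
#'   integer box containing all cells.
#' @param markers Character vector naming the marker columns of `cells`.
#' @return An object of class `cell_table`.
#' @export
cell_table <- function(patient_id, core_id, cells,
                       width = NULL, height = NULL,
                       markers = intersect(.default_markers, names(cells))) {
  cells <- tibble::as_tibble(cells)
  req <- c("cell_id", "x", "y", markers)
  miss <- setdiff(req, names(cells))
  if (length(miss)) stop("cell table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  cells$cell_id <- as.character(cells$cell_id)
  if (anyDuplicated(cells$cell_id)) {
    stop("duplicate cell_id within core ", core_id, call. = FALSE)
  }
  for (cc in c("x", "y")) {
    v <- cells[[cc]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      stop("coordinate column '", cc, "' must be finite, non-negative numeric",
           call. = FALSE)
    }
  }
  if (is.null(width))  width  <- if (nrow(cells)) ceiling(max(cells$x)) else 0
  if (is.null(height)) height <- if (nrow(cells)) ceiling(max(cells$y)) else 0
  if (nrow(cells) && (any(cells$x > width) || any(cells$y > height))) {
    stop("cell coordinates fall outside the declared core bounds", call. = FALSE)
  }
  for (m in markers) {
    v <- cells[[m]]
    if (!all(v %in% c(0, 1))) {
      stop("marker column '", m, "' contains non-binary values", call. = FALSE)
    }
    cells[[m]] <- as.integer(v)
  }
  structure(
    list(patient_id = as.character(patient_id), core_id = as.character(core_id),
         width = as.numeric(width), height = as.numeric(height),
         markers = markers, cells = cells),
    class = "cell_table"
  )
}

#' @export
print.cell_table <- function(x, ...) {
  cat("<cell_table> patient ", x$patient_id, ", core ", x$core_id, ": ",
      nrow(x$cells), " cells in ", x$width, " x ", x$height, " um\n", sep = "")
  if ("phenotype" %in% names(x$cells)) {
    print(table(x$cells$phenotype))
  }
  invisible(x)
}

#' Parse a per-cell CSV export into cell tables
#'
#' Reads a UTF-8 comma-separated per-cell export (one row per segmented cell)
#' and splits it into one [cell_table()] per (patient, core) pair, preserving
#' row order. Coordinates are taken as micrometres. Marker columns must be
#' coercible to 0/1; any other value aborts with the offending data line
#' number(s).
#'
#' @param source Path to a CSV file, or a data frame already read.
#' @param schema Column-name map from [default_schema()].
#' @param width,height Optional shared core bounds in micrometres; by default
#'   each core's bounds are the smallest integer box containing its cells.
#' @return Named list of `cell_table` objects; names are `patientid/coreid`.
#' @export
parse_cell_table <- function(source, schema = default_schema(),
                             width = NULL, height = NULL) {
  df <- if (is.data.frame(source)) {
    tibble::as_tibble(source)
  } else {
    readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  }
  miss <- setdiff(unname(schema), names(df))
  if (length(miss)) {
    stop("input is missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  markers <- schema_markers(schema)
  out <- tibble::tibble(
    patient_id = as.character(df[[schema[["patient_id"]]]]),
    core_id = as.character(df[[schema[["core_id"]]]]),
    cell_id = as.character(df[[schema[["cell_id"]]]]),
    x = df[[schema[["x"]]]],
    y = df[[schema[["y"]]]]
  )
  for (cc in c("x", "y")) {
    if (!is.numeric(out[[cc]])) {
      stop("coordinate column '", schema[[cc]], "' is not numeric", call. = FALSE)
    }
  }
  for (m in markers) {
    v <- df[[schema[[m]]]]
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(vn) | !(vn %in% c(0, 1)))
    if (length(bad)) {
      stop("marker column '", schema[[m]], "' has non-binary value(s) on line(s) ",
           paste(utils::head(bad + 1L, 5L), collapse = ", "),
           " (line 1 is the header)", call. = FALSE)
    }
    out[[m]] <- as.integer(vn)
  }
  key <- paste(out$patient_id, out$core_id, sep = "/")
  tables <- lapply(split(seq_len(nrow(out)), factor(key, levels = unique(key))),
                   function(idx) {
    sub <- out[idx, , drop = FALSE]
    cell_table(sub$patient_id[1], sub$core_id[1],
               sub[, c("cell_id", "x", "y", markers)],
               width = width, height = height, markers = markers)
  })
  tables
}

#' Write cell tables back to the CSV schema
#'
#' Inverse of [parse_cell_table()]: flattens a list of cell tables to one data
#' frame in the export schema (plus a `phenotype` column when phenotypes have
#' been assigned) and optionally writes it to CSV.
#'
#' @param tables A `cell_table` or list of them.
#' @param path Optional output CSV path.
#' @param schema Column-name map from [default_schema()].
#' @return The flattened tibble, invisibly when `path` is given.
#' @export
write_cell_table <- function(tables, path = NULL, schema = default_schema()) {
  if (inherits(tables, "cell_table")) tables <- list(tables)
  rows <- lapply(tables, function(tab) {
    d <- tab$cells
    out <- tibble::tibble(!!schema[["patient_id"]] := tab$patient_id,
                          !!schema[["core_id"]] := tab$core_id,
                          !!schema[["cell_id"]] := d$cell_id,
                          !!schema[["x"]] := d$x,
                          !!schema[["y"]] := d$y)
    for (m in tab$markers) out[[schema[[m]]]] <- d[[m]]
    if ("phenotype" %in% names(d)) out$phenotype <- d$phenotype
    out
  })
  df <- dplyr::bind_rows(rows)
  if (!is.null(path)) {
    readr::write_csv(df, path)
    return(invisible(df))
  }
  df
}

#' Assign phenotypes to a cell table
#'
#' Applies gating rules in priority order: a cell receives a rule's label iff
#' every `positive` marker is 1 and every `negative` marker is 0; when several
#' rules match, the first in the list wins; cells matching no rule are labeled
#' `other_label`. The number of multi-rule conflicts (e.g. aSMA+/CD31+/CK-
#' double positives under the default rules) is recorded in the
#' `n_conflicted` attribute of the returned table for auditing.
#'
#' Phenotyping is idempotent, and with any rule set plus the catch-all label
#' the labels partition the cells.
#'
#' @param table A [cell_table()].
#' @param rules List of [phenotype_rule()] in priority order.
#' @param other_label Label for unmatched cells.
#' @return The cell table with a `phenotype` column on `$cells`.
#' @export
assign_phenotypes <- function(table, rules = default_phenotype_rules(),
                              other_label = "other") {
  stopifnot(inherits(table, "cell_table"))
  rep_df <- validate_rules(rules)
  if (nrow(rep_df)) {
    stop("invalid rule set: ",
         paste(paste0(rep_df$rule, ": ", rep_df$issue), collapse = "; "),
         call. = FALSE)
  }
  used <- unique(unlist(lapply(rules, function(r) c(r$positive, r$negative))))
  unknown <- setdiff(used, table$markers)
  if (length(unknown)) {
    stop("rule(s) reference marker(s) not present in the table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  d <- table$cells
  n <- nrow(d)
  match_mat <- vapply(rules, function(r) {
    ok <- rep(TRUE, n)
    for (m in r$positive) ok <- ok & d[[m]] == 1L
    for (m in r$negative) ok <- ok & d[[m]] == 0L
    ok
  }, logical(n))
  match_mat <- matrix(match_mat, nrow = n)
  n_match <- rowSums(match_mat)
  first <- apply(match_mat, 1L, function(z) if (any(z)) which(z)[1] else NA_integer_)
  labels <- vapply(rules, function(r) r$name, character(1))
  d$phenotype <- ifelse(is.na(first), other_label, labels[first])
  table$cells <- d
  attr(table, "n_conflicted") <- sum(n_match > 1L)
  table
}

#' Count cells of a phenotype or marker
#'
#' @param table A phenotyped [cell_table()].
#' @param phenotype Phenotype label to count, or `NULL`.
#' @param marker Marker whose positive cells to count, or `NULL`.
#' @return Integer count.
#' @keywords internal
count_cells <- function(table, phenotype = NULL, marker = NULL) {
  stopifnot(inherits(table, "cell_table"), xor(is.null(phenotype), is.null(marker)))
  d <- table$cells
  if (!is.null(phenotype)) {
    if (!"phenotype" %in% names(d)) {
      stop("table has no phenotype column; run assign_phenotypes() first",
           call. = FALSE)
    }
    sum(d$phenotype == phenotype)
  } else {
    if (!marker %in% table$markers) stop("unknown marker: ", marker, call. = FALSE)
    sum(d[[marker]] == 1L)
  }
}
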