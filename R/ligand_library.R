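#' Ligand libraries
#'
#' A `ligand_library` holds an ordered table of molecules (one row per
#' ligand) plus provenance: the source files it was read from and the full
#' history of filters applied to it. Records carry a unique `ligand_id`, a
#' canonical SMILES `structure`, and, once [compute_properties()] has run,
#' the physicochemical descriptors used by [lipinski_veber_filter()].
#'
#' @param records data.frame with at least `ligand_id` and `structure`.
#' @param provenance list with elements `sources` (character) and
#'   `filter_history` (list).
#' @return An object of class `ligand_library`.
#' @export
ligand_library <- function(records, provenance = list()) {
  stopifnot(is.data.frame(records),
            all(c("ligand_id", "structure") %in% names(records)))
  records$ligand_id <- as.character(records$ligand_id)
  records$structure <- as.character(records$structure)
  dup <- records$ligand_id[duplicated(records$ligand_id)]
  if (length(dup)) {
    stop("duplicate ligand_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  provenance$sources <- provenance$sources %||% character()
  provenance$filter_history <- provenance$filter_history %||% list()
  structure(list(records = records, provenance = provenance),
            class = "ligand_library")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ligand_library <- function(x, ...) {
  cat("<ligand_library> ", nrow(x$records), " record(s)\n", sep = "")
  if (length(x$provenance$sources)) {
    cat("  sources: ", paste(x$provenance$sources, collapse = ", "), "\n",
        sep = "")
  }
  for (h in x$provenance$filter_history) {
    cat("  filter '", h$filter, "': ", h$n_before, " -> ", h$n_after,
        " record(s)\n", sep = "")
  }
  invisible(x)
}

#' @export
length.ligand_library <- function(x) nrow(x$records)

#' Read a ligand library
#'
#' Reads molecules from a SMILES table (whitespace-delimited `SMILES id`
#' lines), an SDF file, or a CSV with declared column names. Structures are
#' parsed and canonicalised with Open Babel; entries it cannot parse are
#' counted in `provenance$skipped` (and named in `provenance$skipped_ids`
#' where an id was readable), never silently dropped. Input order is
#' preserved.
#'
#' @param path input file.
#' @param format one of `"smiles-table"`, `"sdf"`, `"csv"`.
#' @param smiles_col,id_col column names used when `format = "csv"`.
#' @param canonicalize canonicalise structures on load (default `TRUE`).
#' @return A [ligand_library()].
#' @export
load_ligands <- function(path, format = c("smiles-table", "sdf", "csv"),
                         smiles_col = "smiles", id_col = "ligand_id",
                         canonicalize = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- switch(format,
    "smiles-table" = read_smiles_table(path),
    "sdf" = read_sdf_entries(path),
    "csv" = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      if (!all(c(smiles_col, id_col) %in% names(df))) {
        stop("csv must contain columns '", smiles_col, "' and '", id_col, "'",
             call. = FALSE)
      }
      data.frame(ligand_id = as.character(df[[id_col]]),
                 structure = as.character(df[[smiles_col]]),
                 stringsAsFactors = FALSE)
    }
  )
  dup <- raw$ligand_id[duplicated(raw$ligand_id)]
  if (length(dup)) {
    stop("duplicate ligand_id in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  n_in <- nrow(raw)
  if (n_in > 0L && canonicalize) {
    can <- ob_canonical(raw$structure, raw$ligand_id)
    keep <- raw$ligand_id %in% can$ligand_id
    skipped_ids <- raw$ligand_id[!keep]
    raw <- raw[keep, , drop = FALSE]
    raw$structure <- can$cansmi[match(raw$ligand_id, can$ligand_id)]
  } else {
    skipped_ids <- character()
  }
  if (nrow(raw) == 0L) {
    stop("zero parseable records in ", path, call. = FALSE)
  }
  rownames(raw) <- NULL
  ligand_library(raw, provenance = list(
    sources = path,
    skipped = n_in - nrow(raw),
    skipped_ids = skipped_ids,
    filter_history = list()
  ))
}

read_smiles_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  ok <- vapply(parts, length, 1L) >= 2L
  parts <- parts[ok]
  data.frame(
    ligand_id = vapply(parts, `[`, "", 2L),
    structure = vapply(parts, `[`, "", 1L),
    stringsAsFactors = FALSE
  )
}

# Minimal SDF ingestion: record titles from the header block, structures via
# Open Babel conversion of the whole file to SMILES.
read_sdf_entries <- function(path) {
  out <- ob_run(c("-e", "-isdf", path, "-osmi"))
  out <- out[nzchar(out)]
  if (length(out) == 0L) {
    stop("zero parseable records in ", path, call. = FALSE)
  }
  parts <- strsplit(out, "[[:space:]]+")
  parts <- parts[vapply(parts, length, 1L) >= 2L]
  data.frame(
    ligand_id = vapply(parts, `[`, "", 2L),
    structure = vapply(parts, `[`, "", 1L),
    stringsAsFactors = FALSE
  )
}

#' Write a ligand library as a SMILES table
#'
#' Writes `SMILES id` lines; a JSON sidecar with the provenance (sources,
#' skip counts and filter history) is written next to it when
#' `report = TRUE`.
#'
#' @param lib a [ligand_library()].
#' @param path output `.smi` path.
#' @param report also write `<path>.json` provenance sidecar.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path, report = FALSE) {
  stopifnot(inherits(lib, "ligand_library"))
  writeLines(paste(lib$records$structure, lib$records$ligand_id), path)
  if (report) {
    jsonlite::write_json(lib$provenance, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Attach an annotation table to a library
#'
#' Left-joins an annotation data.frame (for example externally predicted
#' QSAR properties) onto the records by `ligand_id`. Existing columns are
#' not overwritten.
#'
#' @param lib a [ligand_library()].
#' @param annotations data.frame with a `ligand_id` column.
#' @return The annotated library.
#' @export
annotate_ligands <- function(lib, annotations) {
  stopifnot(inherits(lib, "ligand_library"),
            is.data.frame(annotations), "ligand_id" %in% names(annotations))
  new_cols <- setdiff(names(annotations), c("ligand_id", names(lib$records)))
  idx <- match(lib$records$ligand_id, annotations$ligand_id)
  for (cl in new_cols) lib$records[[cl]] <- annotations[[cl]][idx]
  lib
}
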