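#' Receptor target manifests
#'
#' A manifest describes the docking receptors: one row per search box, with
#' a unique `target_id`, the source `conformation` label, the
#' `domain_class` (`"NBD"` for a nucleotide binding domain box, `"DBD"` for
#' a drug binding domain box), the box centre and size in Angstroms, and an
#' optional `pair_group` linking the DBD and NBD boxes of one conformation
#' for ratio scoring. Boxes with `pair_group` `NA` are docked but contribute
#' no ratio.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON manifest file. Each entry needs
#'   `target_id`, `conformation`, `domain_class`, `box_center` (x, y, z) and
#'   `box_size` (sx, sy, sz); `pair_group` is optional.
#' @return data.frame of class `receptor_manifest` with columns
#'   `target_id`, `conformation`, `domain_class`, `pair_group`, `cx`, `cy`,
#'   `cz`, `sx`, `sy`, `sz`.
#' @export
load_target_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  if (!is.null(raw$targets)) raw <- raw$targets
  rows <- lapply(seq_along(raw), function(i) {
    t <- raw[[i]]
    need <- c("target_id", "conformation", "domain_class", "box_center",
              "box_size")
    if (!all(need %in% names(t))) {
      stop("manifest entry ", i, " is missing field(s): ",
           paste(setdiff(need, names(t)), collapse = ", "), call. = FALSE)
    }
    ctr <- as.numeric(unlist(t$box_center))
    sz <- as.numeric(unlist(t$box_size))
    if (length(ctr) != 3L || length(sz) != 3L || any(is.na(c(ctr, sz)))) {
      stop("manifest entry ", i, " (", t$target_id,
           "): box_center and box_size must be numeric length 3",
           call. = FALSE)
    }
    data.frame(target_id = as.character(t$target_id),
               conformation = as.character(t$conformation),
               domain_class = as.character(t$domain_class),
               pair_group = if (is.null(t$pair_group)) NA_character_
                            else as.character(t$pair_group),
               cx = ctr[1], cy = ctr[2], cz = ctr[3],
               sx = sz[1], sy = sz[2], sz = sz[3],
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  validate_manifest(man, where = path)
}

#' Validate a receptor manifest
#'
#' Checks target-id uniqueness, domain-class values, strictly positive box
#' sizes, and that every non-missing pair group contains at least one DBD
#' and one NBD box.
#'
#' @param man manifest data.frame (see [load_target_manifest()]).
#' @param where label used in error messages.
#' @return The manifest, classed `receptor_manifest`.
#' @export
validate_manifest <- function(man, where = "manifest") {
  dup <- man$target_id[duplicated(man$target_id)]
  if (length(dup)) {
    stop(where, ": duplicate target_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- !man$domain_class %in% c("NBD", "DBD")
  if (any(bad)) {
    stop(where, ": domain_class must be NBD or DBD (offending: ",
         paste(man$target_id[bad], collapse = ", "), ")", call. = FALSE)
  }
  nonpos <- man$sx <= 0 | man$sy <= 0 | man$sz <= 0
  if (any(nonpos)) {
    stop(where, ": non-positive box size for ",
         paste(man$target_id[nonpos], collapse = ", "), call. = FALSE)
  }
  for (pg in unique(stats::na.omit(man$pair_group))) {
    cls <- man$domain_class[!is.na(man$pair_group) & man$pair_group == pg]
    if (!all(c("NBD", "DBD") %in% cls)) {
      stop(where, ": pair_group '", pg,
           "' lacks a ", setdiff(c("NBD", "DBD"), cls),
           " target", call. = FALSE)
    }
  }
  class(man) <- c("receptor_manifest", "data.frame")
  man
}

#' Parse docking-engine output
#'
#' Reads one docking result file into a table of per-mode binding energies.
#' Three dialects are supported:
#' \describe{
#'   \item{`pdbqt-remark`}{AutoDock-Vina output PDBQT; one
#'     `REMARK VINA RESULT: <energy> <rmsd_lb> <rmsd_ub>` line per pose.}
#'   \item{`log-table`}{Vina console log; the `mode | affinity | ...`
#'     table.}
#'   \item{`score-tsv`}{tab-separated `ligand_id`, `target_id`, `dg`
#'     columns, one row per mode (may cover many ligand-target pairs).}
#' }
#' The best energy per ligand-target pair is the minimum over modes.
#'
#' @param path input file.
#' @param dialect one of `"pdbqt-remark"`, `"log-table"`, `"score-tsv"`.
#' @param ligand_id,target_id identifiers for the single-pair dialects
#'   (`pdbqt-remark`, `log-table`); by default parsed from a
#'   `<ligand>__<target>` file-name stem.
#' @return data.frame of class `docking_results`: `ligand_id`, `target_id`,
#'   `best_dg`, `n_modes`, and list column `all_dg`.
#' @export
parse_vina_output <- function(path,
                              dialect = c("pdbqt-remark", "log-table",
                                          "score-tsv"),
                              ligand_id = NULL, target_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "score-tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("ligand_id", "target_id", "dg")
    if (!all(need %in% names(df))) {
      stop(path, ": score-tsv needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (nrow(df) == 0L) stop(path, ": no result lines", call. = FALSE)
    if (any(is.na(df$dg))) {
      stop(path, ": malformed numeric in dg at row ",
           which(is.na(df$dg))[1L], call. = FALSE)
    }
    return(collapse_modes(df))
  }
  lines <- readLines(path, warn = FALSE)
  if (dialect == "pdbqt-remark") {
    hits <- grep("^REMARK VINA RESULT:", lines)
    if (length(hits) == 0L) stop(path, ": no result lines", call. = FALSE)
    vals <- sub("^REMARK VINA RESULT:[[:space:]]*", "", lines[hits])
    dg <- suppressWarnings(
      as.numeric(vapply(strsplit(vals, "[[:space:]]+"), `[`, "", 1L)))
  } else {
    tab <- grep("^[[:space:]]*[0-9]+[[:space:]]+-?[0-9.]+[[:space:]]+", lines,
                value = TRUE)
    if (length(tab) == 0L) stop(path, ": no result lines", call. = FALSE)
    dg <- suppressWarnings(
      as.numeric(vapply(strsplit(trimws(tab), "[[:space:]]+"), `[`, "", 2L)))
    hits <- match(tab, lines)
  }
  if (any(is.na(dg))) {
    stop(path, ": malformed numeric at line ", hits[which(is.na(dg))[1L]],
         call. = FALSE)
  }
  stem <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(ligand_id) || is.null(target_id)) {
    parts <- strsplit(stem, "__", fixed = TRUE)[[1]]
    if (length(parts) == 2L) {
      ligand_id <- ligand_id %||% parts[1L]
      target_id <- target_id %||% parts[2L]
    } else {
      ligand_id <- ligand_id %||% stem
      target_id <- target_id %||% NA_character_
    }
  }
  collapse_modes(data.frame(ligand_id = ligand_id, target_id = target_id,
                            dg = dg, stringsAsFactors = FALSE))
}

collapse_modes <- function(df) {
  key <- paste(df$ligand_id, df$target_id, sep = "\r")
  sp <- split(df$dg, key)
  first <- !duplicated(key)
  out <- data.frame(
    ligand_id = df$ligand_id[first],
    target_id = df$target_id[first],
    stringsAsFactors = FALSE
  )
  k <- key[first]
  out$best_dg <- vapply(sp[k], min, 0)
  out$n_modes <- vapply(sp[k], length, 0L)
  out$all_dg <- unname(sp[k])
  rownames(out) <- NULL
  class(out) <- c("docking_results", "data.frame")
  out
}

#' Ingest a directory of docking output files
#'
#' Parses every file matching `pattern` under `dir` with
#' [parse_vina_output()] and binds the results.
#'
#' @param dir directory of docking outputs.
#' @param dialect passed to [parse_vina_output()].
#' @param pattern file-name regular expression.
#' @return Combined `docking_results` data.frame.
#' @export
ingest_docking_dir <- function(dir, dialect = "pdbqt-remark",
                               pattern = "\\.(pdbqt|log|tsv)$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (length(files) == 0L) stop("no docking files under ", dir, call. = FALSE)
  res <- lapply(files, parse_vina_output, dialect = dialect)
  out <- do.call(rbind, res)
  class(out) <- c("docking_results", "data.frame")
  out
}

#' Deterministic mock docking engine
#'
#' Stands in for an external docking engine during tests and simulations.
#' Energies follow a planted landscape: for ligand `i` on target `t`,
#' `dG = base(domain_class(t)) + offset(i, domain_class(t)) + noise`, with
#' Gaussian noise of standard deviation `noise_sd` drawn once per
#' ligand-target pair from the landscape seed. Results are bit-identical
#' across calls with the same landscape, and a ligand keeps the same energy
#' for a given target no matter in which screening round it is docked.
#'
#' @param ligand_ids character vector of ligands to dock.
#' @param targets a `receptor_manifest`.
#' @param landscape a [planted_landscape()].
#' @param n_modes number of poses per result; extra poses are spaced 0.3
#'   kcal/mol above the best.
#' @return `docking_results` data.frame, one row per ligand-target pair.
#' @export
mock_dock <- function(ligand_ids, targets, landscape, n_modes = 1L) {
  stopifnot(inherits(landscape, "planted_landscape"))
  unknown <- setdiff(ligand_ids, landscape$ligand_ids)
  if (length(unknown)) {
    stop("landscape does not cover ligand(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  grid <- expand.grid(ligand_id = ligand_ids, target_id = targets$target_id,
                      stringsAsFactors = FALSE)
  dc <- targets$domain_class[match(grid$target_id, targets$target_id)]
  base <- ifelse(dc == "NBD", landscape$base_dg_nbd, landscape$base_dg_dbd)
  off <- ifelse(dc == "NBD",
                landscape$offset_nbd[grid$ligand_id],
                landscape$offset_dbd[grid$ligand_id])
  li <- match(grid$ligand_id, landscape$ligand_ids)
  ti <- match(grid$target_id, colnames(landscape$noise))
  if (anyNA(ti)) {
    stop("landscape noise table does not cover target(s): ",
         paste(unique(grid$target_id[is.na(ti)]), collapse = ", "),
         call. = FALSE)
  }
  noise <- landscape$noise[cbind(li, ti)]
  dg <- base + unname(off) + noise
  out <- grid
  out$best_dg <- dg
  out$n_modes <- as.integer(n_modes)
  out$all_dg <- lapply(dg, function(g) g + 0.3 * (seq_len(n_modes) - 1L))
  class(out) <- c("docking_results", "data.frame")
  out
}
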