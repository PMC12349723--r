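# Thin wrappers around the Open Babel command-line toolkit. All chemistry
# (SMILES parsing, canonicalisation, descriptors, SMARTS matching, path
# fingerprints) is delegated to `obabel`; nothing chemical is re-implemented.

ob_binary <- function() {
  bin <- Sys.which("obabel")
  if (!nzchar(bin)) {
    stop("Open Babel ('obabel') was not found on the PATH; ",
         "it is required for all structure handling.", call. = FALSE)
  }
  unname(bin)
}

#' Is Open Babel available?
#'
#' @return `TRUE` if the `obabel` executable is on the PATH.
#' @export
have_openbabel <- function() nzchar(Sys.which("obabel"))

ob_run <- function(args, stdin_lines = NULL) {
  infile <- NULL
  if (!is.null(stdin_lines)) {
    infile <- tempfile(fileext = ".smi")
    writeLines(stdin_lines, infile)
    on.exit(unlink(infile), add = TRUE)
    args <- c(infile, args)
  }
  out <- suppressWarnings(
    system2(ob_binary(), args, stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("obabel exited with status ", status, call. = FALSE)
  }
  as.character(out)
}

# Write a two-column SMILES file ("SMILES id"). ids must be whitespace-free.
ob_smi_lines <- function(smiles, ids) {
  stopifnot(length(smiles) == length(ids))
  if (any(grepl("[[:space:]]", ids))) {
    stop("ligand ids must not contain whitespace", call. = FALSE)
  }
  paste(smiles, ids)
}

# Parse and canonicalise SMILES. Returns a data.frame (id, cansmi) containing
# only the molecules Open Babel could read; callers diff against the input to
# find unparseable entries.
ob_canonical <- function(smiles, ids) {
  out <- ob_run(c("-e", "-ocan"), stdin_lines = ob_smi_lines(smiles, ids))
  out <- out[nzchar(out)]
  if (length(out) == 0L) {
    return(data.frame(ligand_id = character(), cansmi = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(out, "[[:space:]]+")
  keep <- vapply(parts, length, 1L) >= 2L
  parts <- parts[keep]
  data.frame(
    ligand_id = vapply(parts, `[`, "", 2L),
    cansmi = vapply(parts, `[`, "", 1L),
    stringsAsFactors = FALSE
  )
}

# Physicochemical descriptors for a set of molecules, one obabel pass.
# Returns data.frame keyed by id; molecules obabel cannot read are absent.
ob_descriptors <- function(smiles, ids) {
  out <- ob_run(c("-e", "-otxt", "--append", "MW logP TPSA HBD HBA1 rotors"),
                stdin_lines = ob_smi_lines(smiles, ids))
  out <- out[nzchar(out)]
  if (length(out) == 0L) {
    return(data.frame(ligand_id = character(), mw = numeric(),
                      logp = numeric(), tpsa = numeric(), hbd = integer(),
                      hba = integer(), rot_bonds = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(out, "[[:space:]]+")
  keep <- vapply(parts, length, 1L) == 7L
  parts <- parts[keep]
  df <- data.frame(
    ligand_id = vapply(parts, `[`, "", 1L),
    mw = as.numeric(vapply(parts, `[`, "", 2L)),
    logp = as.numeric(vapply(parts, `[`, "", 3L)),
    tpsa = as.numeric(vapply(parts, `[`, "", 4L)),
    hbd = as.integer(vapply(parts, `[`, "", 5L)),
    hba = as.integer(vapply(parts, `[`, "", 6L)),
    rot_bonds = as.integer(vapply(parts, `[`, "", 7L)),
    stringsAsFactors = FALSE
  )
  df[stats::complete.cases(df), , drop = FALSE]
}

# ids of molecules matching a SMARTS pattern.
ob_smarts_match <- function(smiles, ids, smarts) {
  if (length(smiles) == 0L) return(character())
  out <- ob_run(c("-e", "-osmi", "--filter", paste0("s='", smarts, "'")),
                stdin_lines = ob_smi_lines(smiles, ids))
  out <- out[nzchar(out)]
  if (length(out) == 0L) return(character())
  parts <- strsplit(out, "[[:space:]]+")
  parts <- parts[vapply(parts, length, 1L) >= 2L]
  vapply(parts, `[`, "", 2L)
}

# Hashed path fingerprints (FPS hex dialect). Returns a logical matrix with
# one row per parseable molecule, rownames = ids.
ob_fingerprints <- function(smiles, ids, scheme = "FP2") {
  out_file <- tempfile(fileext = ".fps")
  on.exit(unlink(out_file), add = TRUE)
  infile <- tempfile(fileext = ".smi")
  writeLines(ob_smi_lines(smiles, ids), infile)
  on.exit(unlink(infile), add = TRUE)
  suppressWarnings(system2(
    ob_binary(), c(infile, "-e", "-ofps", "-xf", scheme, "-O", out_file),
    stdout = FALSE, stderr = FALSE
  ))
  lines <- if (file.exists(out_file)) readLines(out_file) else character()
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    empty <- matrix(FALSE, nrow = 0L, ncol = 1024L)
    return(empty)
  }
  tabs <- strsplit(lines, "\t", fixed = TRUE)
  hex <- vapply(tabs, `[`, "", 1L)
  out_ids <- trimws(vapply(tabs, `[`, "", 2L))
  bits <- hex_to_bits(hex)
  rownames(bits) <- out_ids
  bits
}

# 256-char hex strings -> logical matrix, 4 bits per hex digit, MSB first.
hex_to_bits <- function(hex) {
  n <- length(hex)
  width <- nchar(hex[1])
  mat <- matrix(FALSE, nrow = n, ncol = width * 4L)
  lut <- matrix(FALSE, 16L, 4L)
  for (v in 0:15) lut[v + 1L, ] <- bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0L
  for (i in seq_len(n)) {
    digits <- strtoi(strsplit(hex[i], "")[[1]], base = 16L)
    mat[i, ] <- as.vector(t(lut[digits + 1L, , drop = FALSE]))
  }
  mat
}
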