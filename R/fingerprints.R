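#' Fingerprint a ligand library
#'
#' Computes hashed path fingerprints for every record with Open Babel
#' (default scheme `FP2`, a 1024-bit hashed linear-fragment fingerprint;
#' `FP3`, `FP4` and `MACCS` are also accepted). Fingerprints are
#' deterministic: the same structure under the same scheme always yields the
#' same bits, and two different SMILES spellings of one molecule yield
#' identical fingerprints.
#'
#' @param lib a [ligand_library()], or a character vector of SMILES named by
#'   ligand id.
#' @param scheme fingerprint scheme label passed to Open Babel.
#' @return A `fingerprint_set`: logical matrix (ligands x bits) with
#'   rownames = ligand ids and attribute `scheme`.
#' @export
fingerprint_library <- function(lib, scheme = "FP2") {
  if (inherits(lib, "ligand_library")) {
    smiles <- lib$records$structure
    ids <- lib$records$ligand_id
  } else {
    smiles <- unname(lib)
    ids <- names(lib)
    if (is.null(ids)) stop("SMILES vector must be named by ligand id")
  }
  if (length(smiles) == 0L) stop("no structures to fingerprint")
  if (any(!nzchar(smiles))) {
    stop("empty structure for ligand: ",
         paste(ids[!nzchar(smiles)], collapse = ", "), call. = FALSE)
  }
  bits <- ob_fingerprints(smiles, ids, scheme = scheme)
  missing <- setdiff(ids, rownames(bits))
  if (length(missing)) {
    stop("unparseable structure for ligand: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bits <- bits[match(ids, rownames(bits)), , drop = FALSE]
  structure(bits, scheme = paste0("OpenBabel-", scheme, "/", ncol(bits)),
            class = c("fingerprint_set", class(bits)))
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat("<fingerprint_set> ", nrow(x), " ligand(s), ", ncol(x), " bits, ",
      attr(x, "scheme"), "\n", sep = "")
  invisible(x)
}

check_same_scheme <- function(a, b) {
  sa <- attr(a, "scheme")
  sb <- attr(b, "scheme")
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb)) {
    stop("fingerprint scheme mismatch: ", sa, " vs ", sb, call. = FALSE)
  }
  la <- if (is.matrix(a)) ncol(a) else length(a)
  lb <- if (is.matrix(b)) ncol(b) else length(b)
  if (la != lb) {
    stop("fingerprint length mismatch: ", la, " vs ", lb, call. = FALSE)
  }
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|`. When both fingerprints are all-zero the
#' similarity is defined as 1 (featureless molecules are treated as
#' mutually redundant).
#'
#' @param a,b logical bit vectors of equal length (rows of a
#'   `fingerprint_set`).
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  check_same_scheme(a, b)
  a <- as.logical(a)
  b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

#' All-pairs Tanimoto similarity matrix
#'
#' Computes the full similarity matrix between the rows of `x` and the rows
#' of `y` (by default `x` itself) using a single cross-product, suitable for
#' libraries of a few thousand ligands.
#'
#' @param x,y `fingerprint_set` matrices with a common scheme.
#' @return Numeric matrix `nrow(x)` x `nrow(y)` with dimnames from the
#'   ligand ids.
#' @export
tanimoto_matrix <- function(x, y = x) {
  check_same_scheme(x, y)
  xm <- matrix(as.numeric(x), nrow = nrow(x))
  ym <- matrix(as.numeric(y), nrow = nrow(y))
  inter <- xm %*% t(ym)
  px <- rowSums(xm)
  py <- rowSums(ym)
  un <- outer(px, py, "+") - inter
  sim <- ifelse(un == 0, 1, inter / pmax(un, 1e-300))
  dimnames(sim) <- list(rownames(x), rownames(y))
  sim
}
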