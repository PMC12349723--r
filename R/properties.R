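#' Open Babel property calculator
#'
#' The default property-calculator contract for [compute_properties()]. A
#' calculator is a function that takes vectors of SMILES and ids and returns
#' a data.frame with columns `ligand_id`, `mw`, `logp`, `tpsa`, `hbd`,
#' `hba`, `rot_bonds`, `has_aldehyde`, `has_thiol`; molecules it fails on
#' are simply absent from the result. Descriptor definitions (rotatable-bond
#' convention, TPSA parameterisation, acceptor counting) are those of the
#' calculator, which is pluggable precisely so another toolkit can be
#' substituted without touching the filter.
#'
#' Substructure flags use SMARTS: aldehyde `[CX3H1]=O`, thiol `[SX2H]`.
#'
#' @return A calculator function.
#' @export
obabel_calculator <- function() {
  function(smiles, ids) {
    desc <- ob_descriptors(smiles, ids)
    ald <- ob_smarts_match(smiles, ids, "[CX3H1]=O")
    thi <- ob_smarts_match(smiles, ids, "[SX2H]")
    desc$has_aldehyde <- desc$ligand_id %in% ald
    desc$has_thiol <- desc$ligand_id %in% thi
    desc
  }
}

DESCRIPTOR_COLS <- c("mw", "logp", "tpsa", "hbd", "hba", "rot_bonds",
                     "has_aldehyde", "has_thiol")

#' Populate physicochemical descriptors
#'
#' Runs the property calculator over every record and stores molecular
#' weight (g/mol), logP, topological polar surface area (A^2), H-bond donor
#' and acceptor counts, rotatable-bond count and the aldehyde/thiol
#' substructure flags. Records the calculator fails on are flagged
#' `descriptor_failed` and are excluded from later filtering (their count is
#' logged in the provenance); they are not dropped from the library.
#'
#' @param lib a [ligand_library()].
#' @param calculator a property calculator; see [obabel_calculator()].
#' @return The library with descriptor columns populated.
#' @export
compute_properties <- function(lib, calculator = obabel_calculator()) {
  stopifnot(inherits(lib, "ligand_library"))
  rec <- lib$records
  desc <- calculator(rec$structure, rec$ligand_id)
  need <- c("ligand_id", DESCRIPTOR_COLS)
  if (!all(need %in% names(desc))) {
    stop("calculator must return columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(rec$ligand_id, desc$ligand_id)
  for (cl in DESCRIPTOR_COLS) rec[[cl]] <- desc[[cl]][idx]
  rec$descriptor_failed <- is.na(idx)
  lib$records <- rec
  lib$provenance$descriptor_failed <- sum(rec$descriptor_failed)
  lib
}

# The seven drug-likeness criteria, each a predicate on the record table.
# Bounds follow the usual oral-drug-likeness conventions: strict "<" (and
# ">" for the molecular-weight floor) everywhere except rotatable bonds,
# which is inclusive at 7; reactive aldehydes and thiols are excluded.
lv_criteria <- list(
  mw         = function(r) r$mw > 150 & r$mw < 500,
  logp       = function(r) r$logp < 5,
  tpsa       = function(r) r$tpsa < 150,
  hbd        = function(r) r$hbd < 5,
  hba        = function(r) r$hba < 10,
  rot_bonds  = function(r) r$rot_bonds <= 7,
  reactive   = function(r) !r$has_aldehyde & !r$has_thiol
)

#' Lipinski-Veber drug-likeness filter
#'
#' Retains exactly the records with 150 < MW < 500 g/mol, logP < 5,
#' TPSA < 150 A^2, H-bond donors < 5, acceptors < 10, rotatable bonds <= 7,
#' and neither an aldehyde nor a thiol group. All "less than" bounds are
#' strict; only the rotatable-bond bound is inclusive. The filter history in
#' the provenance gains one entry with per-criterion rejection counts (a
#' record violating several criteria is counted once per criterion but
#' removed once). Records flagged `descriptor_failed` are removed and
#' counted separately. The operation is idempotent.
#'
#' @param lib a [ligand_library()] with descriptors populated.
#' @return The filtered library.
#' @export
lipinski_veber_filter <- function(lib) {
  stopifnot(inherits(lib, "ligand_library"))
  rec <- lib$records
  if (!all(DESCRIPTOR_COLS %in% names(rec)) ||
      (nrow(rec) > 0L && all(is.na(rec$mw)))) {
    stop("descriptors are not populated; run compute_properties() first",
         call. = FALSE)
  }
  failed <- rec$descriptor_failed %||% rep(FALSE, nrow(rec))
  eval_rec <- rec[!failed, , drop = FALSE]
  pass_mat <- vapply(lv_criteria, function(f) f(eval_rec),
                     logical(nrow(eval_rec)))
  if (nrow(eval_rec) == 1L) pass_mat <- matrix(pass_mat, nrow = 1L,
                                               dimnames = list(NULL, names(lv_criteria)))
  keep <- rowSums(!pass_mat) == 0L
  rejected <- colSums(!pass_mat)
  out <- eval_rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  hist_entry <- list(
    filter = "lipinski_veber",
    n_before = nrow(rec),
    n_after = nrow(out),
    descriptor_failed = sum(failed),
    rejected_by = as.list(rejected)
  )
  lib$records <- out
  lib$provenance$filter_history <-
    c(lib$provenance$filter_history, list(hist_entry))
  lib
}
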