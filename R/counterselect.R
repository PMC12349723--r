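#' Estimated dissociation constant from a docking energy
#'
#' Inverts `dG = R T ln(Kd)`: `Kd = exp(dG / (R T))`, with the dissociation
#' constant expressed in molar units relative to a 1 M standard state. The
#' defaults are body temperature (310 K) and the gas constant in
#' kcal mol^-1 K^-1. Docking energies are estimates; the resulting Kd
#' values are used only to form ratios, never as binding-affinity claims.
#'
#' @param dg binding free energy, kcal/mol (vectorised).
#' @param temperature Kelvin, > 0.
#' @param gas_constant kcal mol^-1 K^-1.
#' @return Estimated Kd (molar), strictly increasing in `dg`.
#' @export
kd_from_dg <- function(dg, temperature = 310, gas_constant = 1.987e-3) {
  if (any(!is.finite(dg))) stop("dg must be finite", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  exp(dg / (gas_constant * temperature))
}

#' Counter-selection ratio for one receptor pair
#'
#' `Kd(DBD) / Kd(NBD) = exp((dG_DBD - dG_NBD) / (R T))`. Values above 1
#' mean tighter predicted binding at the nucleotide binding domain than at
#' the drug binding domain; a weak DBD binder with a strong NBD energy gets
#' a large ratio. The ratio depends only on the energy difference, so it is
#' invariant to any common shift of the two energies.
#'
#' @param dg_dbd,dg_nbd best binding energies (kcal/mol) of one ligand on
#'   the DBD and NBD boxes of one receptor pair (vectorised).
#' @inheritParams kd_from_dg
#' @return Positive ratio (unitless).
#' @export
ratio_score <- function(dg_dbd, dg_nbd, temperature = 310,
                        gas_constant = 1.987e-3) {
  if (any(!is.finite(dg_dbd)) || any(!is.finite(dg_nbd))) {
    stop("binding energies must be finite", call. = FALSE)
  }
  exp((dg_dbd - dg_nbd) / (gas_constant * temperature))
}

#' Aggregate per-pair ratios into one score
#'
#' `min` (the default) scores a ligand by its worst receptor pair: the
#' ligand must prefer the NBDs in every conformation to rank highly.
#' `geometric-mean` returns `exp(mean(log(ratios)))`.
#'
#' @param ratios named numeric vector of per-pair ratios (> 0).
#' @param policy `"min"` or `"geometric-mean"`.
#' @return Single aggregate score.
#' @export
aggregate_ratios <- function(ratios, policy = c("min", "geometric-mean")) {
  policy <- match.arg(policy)
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0L) stop("no per-pair ratios to aggregate",
                                 call. = FALSE)
  switch(policy,
         "min" = min(ratios),
         "geometric-mean" = exp(mean(log(ratios))))
}

#' Score ligands by DBD/NBD affinity ratios
#'
#' For every ligand and every receptor pair group in the manifest, takes
#' the best (minimum) energy across the group's DBD boxes and across its
#' NBD boxes, forms the per-pair ratio with [ratio_score()], and aggregates
#' across pairs with [aggregate_ratios()]. A ligand with no result on one
#' side of a pair receives, under the `min` policy, a ratio of 0 for that
#' pair (dropping it from top-n contention) unless `missing_pair = "skip"`;
#' the count of such ligands is reported in the attribute
#' `incomplete_ligands`.
#'
#' @param results a `docking_results` data.frame.
#' @param manifest a `receptor_manifest`.
#' @param policy aggregation policy, see [aggregate_ratios()].
#' @param missing_pair `"zero"` (default) or `"skip"`.
#' @inheritParams kd_from_dg
#' @return data.frame of class `ratio_scores`: `ligand_id`, one
#'   `ratio_<pair>` column per pair group, `aggregate`, plus attributes
#'   `policy` and `incomplete_ligands`.
#' @export
score_ligands <- function(results, manifest,
                          policy = c("min", "geometric-mean"),
                          missing_pair = c("zero", "skip"),
                          temperature = 310, gas_constant = 1.987e-3) {
  policy <- match.arg(policy)
  missing_pair <- match.arg(missing_pair)
  pairs <- unique(stats::na.omit(manifest$pair_group))
  if (length(pairs) == 0L) stop("manifest defines no pair groups",
                                call. = FALSE)
  ligands <- unique(results$ligand_id)
  ratio_mat <- matrix(NA_real_, nrow = length(ligands), ncol = length(pairs),
                      dimnames = list(ligands, pairs))
  for (pg in pairs) {
    dbd_t <- manifest$target_id[manifest$pair_group %in% pg &
                                  manifest$domain_class == "DBD"]
    nbd_t <- manifest$target_id[manifest$pair_group %in% pg &
                                  manifest$domain_class == "NBD"]
    rd <- results[results$target_id %in% dbd_t, c("ligand_id", "best_dg")]
    rn <- results[results$target_id %in% nbd_t, c("ligand_id", "best_dg")]
    best_d <- tapply(rd$best_dg, rd$ligand_id, min)
    best_n <- tapply(rn$best_dg, rn$ligand_id, min)
    common <- intersect(names(best_d), names(best_n))
    if (length(common)) {
      ratio_mat[common, pg] <- ratio_score(
        unname(best_d[common]), unname(best_n[common]),
        temperature = temperature, gas_constant = gas_constant)
    }
  }
  incomplete <- rowSums(is.na(ratio_mat)) > 0L
  agg <- apply(ratio_mat, 1L, function(r) {
    if (all(is.na(r))) return(if (missing_pair == "zero") 0 else NA_real_)
    if (missing_pair == "zero" && anyNA(r) && policy == "min") return(0)
    aggregate_ratios(r[!is.na(r)], policy = policy)
  })
  out <- data.frame(ligand_id = ligands, stringsAsFactors = FALSE)
  for (pg in pairs) out[[paste0("ratio_", pg)]] <- ratio_mat[, pg]
  out$aggregate <- unname(agg)
  attr(out, "policy") <- policy
  attr(out, "incomplete_ligands") <- sum(incomplete)
  class(out) <- c("ratio_scores", "data.frame")
  out
}

#' Rank ligands and select the top n
#'
#' Orders by aggregate score descending, ties broken by ligand id
#' ascending, and keeps the first `n`. Deterministic: permuting the input
#' never changes the ranking.
#'
#' @param scores a `ratio_scores` data.frame.
#' @param n selection size (default 100, the usual top-hits size of one
#'   screening round).
#' @param round_label label stored on the result.
#' @return data.frame of class `screen_ranking` with a leading `rank`
#'   column.
#' @export
rank_and_select <- function(scores, n = 100, round_label = "round1") {
  stopifnot(n >= 1)
  scores <- scores[!is.na(scores$aggregate), , drop = FALSE]
  ord <- order(-scores$aggregate, scores$ligand_id)
  if (n > nrow(scores)) {
    warning("requested top ", n, " but only ", nrow(scores),
            " scored ligands; returning all")
    n <- nrow(scores)
  }
  out <- scores[ord[seq_len(n)], , drop = FALSE]
  out <- cbind(rank = seq_len(n), out)
  out$round <- round_label
  rownames(out) <- NULL
  class(out) <- c("screen_ranking", "data.frame")
  out
}

#' Two-round iterative counter-selective screen
#'
#' Round 1 docks a sphere-exclusion diversity subset of the library,
#' scores every docked ligand by its DBD/NBD ratio and keeps the top
#' `n_top`. Round 2 expands those top hits into their similarity
#' neighbourhood (band `band`, default 0.70-0.99) within the full library,
#' docks the not-yet-docked neighbours, and scores them the same way. The
#' final ranking merges both rounds, deduplicated by ligand id with the
#' best aggregate winning.
#'
#' @param lib a [ligand_library()].
#' @param manifest a `receptor_manifest`.
#' @param dock_fun docking provider: `function(ligand_ids, manifest)`
#'   returning a `docking_results` data.frame (for example a closure over
#'   [mock_dock()] and a landscape, or a reader of real engine output).
#' @param cutoff Tanimoto cutoff for the round-1 diversity subset.
#' @param band inclusive similarity band for round-2 expansion.
#' @param n_top selection size per round.
#' @param policy aggregation policy, see [aggregate_ratios()].
#' @param order_seed passed to [diversity_subset()].
#' @param scheme fingerprint scheme.
#' @return List with `round1`, `round2` (each a `screen_ranking` or `NULL`),
#'   `final` (merged ranking), and `provenance` (sizes, seeds, policy).
#' @export
iterate_screen <- function(lib, manifest, dock_fun, cutoff = 0.90,
                           band = c(0.70, 0.99), n_top = 100,
                           policy = "min", order_seed = NULL,
                           scheme = "FP2") {
  fps <- fingerprint_library(lib, scheme = scheme)
  sub <- diversity_subset(fps, cutoff = cutoff, order_seed = order_seed)
  r1_ids <- sub$retained_ids
  res1 <- dock_fun(r1_ids, manifest)
  sc1 <- score_ligands(res1, manifest, policy = policy)
  rank1 <- rank_and_select(sc1, n = min(n_top, nrow(sc1)),
                           round_label = "round1")

  top_ids <- rank1$ligand_id
  nb <- similarity_expand(fps[top_ids, , drop = FALSE], fps, band = band)
  expand_ids <- setdiff(unique(unlist(lapply(nb, `[[`, "ligand_id"))), r1_ids)
  rank2 <- NULL
  sc2 <- NULL
  if (length(expand_ids)) {
    res2 <- dock_fun(expand_ids, manifest)
    sc2 <- score_ligands(res2, manifest, policy = policy)
    rank2 <- rank_and_select(sc2, n = min(n_top, nrow(sc2)),
                             round_label = "round2")
  }
  all_sc <- rbind(as.data.frame(sc1),
                  if (!is.null(sc2)) as.data.frame(sc2))
  # dedup by ligand_id, best aggregate wins
  all_sc <- all_sc[order(-all_sc$aggregate, all_sc$ligand_id), , drop = FALSE]
  all_sc <- all_sc[!duplicated(all_sc$ligand_id), , drop = FALSE]
  class(all_sc) <- c("ratio_scores", "data.frame")
  final <- rank_and_select(all_sc, n = min(n_top, nrow(all_sc)),
                           round_label = "final")
  list(
    round1 = rank1,
    round2 = rank2,
    final = final,
    provenance = list(
      n_library = length(lib),
      cutoff = cutoff,
      order_seed = order_seed,
      subset_size = length(r1_ids),
      band = band,
      n_expanded = length(expand_ids),
      expansion_per_query = vapply(nb, nrow, 0L),
      n_top = n_top,
      policy = policy,
      scheme = attr(fps, "scheme")
    )
  )
}
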