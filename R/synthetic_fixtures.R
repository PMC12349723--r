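# Synthetic data generators. Everything here is seed-deterministic and
# produces inputs in exactly the formats the readers in this package parse,
# so the whole pipeline can be exercised without external software or
# downloads.

# Ring units with a valid in-chain SMILES and a halogen-substituted variant.
# Heteroaromatic/heterocyclic only, so generated molecules stay drug-like
# (logP < 5) while the aromatic systems still give rich path fingerprints.
RING_UNITS <- list(
  benzene     = c("c1ccccc1",      "c1cc(%s)ccc1"),
  pyridine    = c("c1ccncc1",      "c1cc(%s)ncc1"),
  furan       = c("c1ccoc1",       "c1cc(%s)oc1"),
  pyrrole     = c("c1cc[nH]c1",    "c1cc(%s)[nH]c1"),
  oxolane     = c("C1CCOC1",       "C1CC(%s)OC1"),
  pyrrolidine = c("C1CCNC1",       "C1CC(%s)NC1"),
  morpholine  = c("C1COCCN1",      "C1COC(%s)CN1")
)
POLAR_RINGS <- c("oxolane", "pyrrolidine", "morpholine")
AROMATIC_RINGS <- c("benzene", "pyridine", "furan", "pyrrole")
SUBSTITUENTS <- c("F", "Cl", "Br", "C", "O", "N")  # single substitutions
SUBSTITUENTS2 <- c("F", "Cl", "O", "N")  # double substitutions (logP-safe)
# scaffold acceptance bounds: leave room for the heaviest/greasiest
# substitution (Br: about +79 g/mol, +0.9 logP; 2x Cl: about +1.3 logP)
SCAF_MAX_LOGP <- 3.6
SCAF_MAX_MW <- 420

#' Generate a clustered synthetic ligand library
#'
#' Builds `n` molecules in `n_clusters` chemical clusters from a small
#' fragment grammar. Each cluster has a representative scaffold (a chain of
#' five directly bonded heterocyclic ring systems, screened to leave
#' headroom inside the drug-likeness window) and satellite members derived
#' from it by a small substituent (halogen, methyl, hydroxyl or amino) at
#' one or two ring positions. Because a satellite's fingerprint strictly contains the
#' representative's, the representative-satellite Tanimoto similarity is
#' high and controllable: satellites are chosen, among all candidate
#' substitutions, closest to `within_cluster_similarity`. Different
#' clusters use different ring-system tuples and are mutually dissimilar.
#' Members are emitted cluster by cluster, representative first, so a
#' sphere-exclusion pass in input order retains the representative and
#' assigns its satellites to it.
#'
#' A fraction of members can be turned into deliberate drug-likeness
#' violators (a long alkyl tail pushes them over the molecular-weight and
#' rotatable-bond bounds).
#'
#' @param n library size.
#' @param n_clusters number of clusters, `1 <= n_clusters <= n`.
#' @param within_cluster_similarity target representative-satellite
#'   Tanimoto similarity, feasible range about `[0.55, 0.96]` for the FP2
#'   scheme.
#' @param violator_fraction fraction of members rewritten as Lipinski-Veber
#'   violators (never the representatives).
#' @param seed integer; the generator is bit-deterministic given the seed.
#' @return A [ligand_library()]; records carry `cluster` and
#'   `is_representative` columns, provenance records the parameters.
#' @export
gen_ligand_library <- function(n, n_clusters,
                               within_cluster_similarity = 0.90,
                               violator_fraction = 0, seed = 1) {
  stopifnot(n >= n_clusters, n_clusters >= 1)
  if (within_cluster_similarity < 0.55 || within_cluster_similarity > 0.96) {
    stop("within_cluster_similarity must lie in [0.55, 0.96] for the FP2 ",
         "fingerprint scheme; tighter targets are not reachable by single ",
         "substitutions on drug-sized scaffolds", call. = FALSE)
  }
  sizes <- rep(n %/% n_clusters, n_clusters)
  extra <- n %% n_clusters
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  max_cand <- 5L * 6L + 10L * 16L   # single + double substitutions
  if (any(sizes - 1L > max_cand)) {
    stop("cluster size ", max(sizes), " exceeds the ", max_cand + 1L,
         " distinct members a scaffold supports; increase n_clusters",
         call. = FALSE)
  }
  with_seed(as.integer(seed), {
    # Sample candidate ring tuples (at least two polar saturated rings, at
    # most one benzene), then screen the resulting scaffolds against
    # descriptor bounds that leave room for the halogen substituents, so
    # cluster members land inside the drug-likeness window. Rejected
    # scaffolds are resampled, deterministically under the seed.
    sample_tuple <- function(seen) {
      for (try in 1:1000) {
        tp <- sample(names(RING_UNITS), 5L, replace = TRUE)
        if (sum(tp %in% POLAR_RINGS) < 2L) next
        if (sum(tp %in% AROMATIC_RINGS) < 2L) next
        if (sum(tp == "benzene") > 1L) next
        key <- paste(tp, collapse = "|")
        if (key %in% seen) next
        return(tp)
      }
      stop("could not find a distinct ring tuple", call. = FALSE)
    }
    tuples <- vector("list", n_clusters)
    seen <- character()
    pending <- seq_len(n_clusters)
    for (round in 1:25) {
      for (k in pending) {
        tuples[[k]] <- sample_tuple(seen)
        seen <- c(seen, paste(tuples[[k]], collapse = "|"))
      }
      reps <- vapply(tuples[pending], function(tp)
        paste(vapply(tp, function(u) RING_UNITS[[u]][1], ""), collapse = ""),
        "")
      d <- ob_descriptors(reps, sprintf("t%04d", pending))
      ok_ids <- d$ligand_id[d$logp < SCAF_MAX_LOGP & d$mw < SCAF_MAX_MW]
      pending <- pending[!sprintf("t%04d", pending) %in% ok_ids]
      if (length(pending) == 0L) break
    }
    # candidate substitutions per cluster, deterministic order; the double
    # substitutions are only materialised when a cluster is too large for
    # single substitutions alone
    singles <- expand.grid(p1 = 1:5, h1 = SUBSTITUENTS, p2 = NA, h2 = NA,
                           stringsAsFactors = FALSE)
    cands <- singles
    if (max(sizes) - 1L > 20L) {
      dpos <- utils::combn(5L, 2L)
      doubles <- do.call(rbind, lapply(seq_len(ncol(dpos)), function(j) {
        expand.grid(p1 = dpos[1, j], h1 = SUBSTITUENTS2, p2 = dpos[2, j],
                    h2 = SUBSTITUENTS2, stringsAsFactors = FALSE)
      }))
      cands <- rbind(singles, doubles)
    }

    cand_smiles <- function(tp, row) {
      parts <- vapply(tp, function(u) RING_UNITS[[u]][1], "")
      parts[row$p1] <- sprintf(RING_UNITS[[tp[row$p1]]][2], row$h1)
      if (!is.na(row$p2)) {
        parts[row$p2] <- sprintf(RING_UNITS[[tp[row$p2]]][2], row$h2)
      }
      paste(parts, collapse = "")
    }

    all_smi <- character()
    all_ids <- character()
    for (k in seq_len(n_clusters)) {
      tp <- tuples[[k]]
      rep_smi <- paste(vapply(tp, function(u) RING_UNITS[[u]][1], ""),
                       collapse = "")
      cs <- vapply(seq_len(nrow(cands)), function(j)
        cand_smiles(tp, cands[j, ]), "")
      all_smi <- c(all_smi, rep_smi, cs)
      all_ids <- c(all_ids, sprintf("c%03d_rep", k),
                   sprintf("c%03d_s%03d", k, seq_len(nrow(cands))))
    }
    fps <- ob_fingerprints(all_smi, all_ids, scheme = "FP2")

    records <- list()
    idc <- 0L
    for (k in seq_len(n_clusters)) {
      rep_id <- sprintf("c%03d_rep", k)
      rep_fp <- fps[rep_id, ]
      cand_ids <- sprintf("c%03d_s%03d", k, seq_len(nrow(cands)))
      cand_ids <- cand_ids[cand_ids %in% rownames(fps)]
      sims <- vapply(cand_ids, function(cid) tanimoto(rep_fp, fps[cid, ]), 0)
      ok <- sims < 1
      cand_ids <- cand_ids[ok]; sims <- sims[ok]
      m_sat <- sizes[k] - 1L
      if (m_sat > length(cand_ids)) {
        stop("cluster ", k, ": only ", length(cand_ids),
             " usable satellite candidates for ", m_sat, " members",
             call. = FALSE)
      }
      pick <- order(abs(sims - within_cluster_similarity),
                    cand_ids)[seq_len(m_sat)]
      ids_k <- c(rep_id, cand_ids[pick])
      smi_k <- all_smi[match(ids_k, all_ids)]
      idc_new <- idc + seq_along(ids_k)
      records[[k]] <- data.frame(
        ligand_id = sprintf("SYN%05d", idc_new),
        structure = smi_k,
        cluster = k,
        is_representative = c(TRUE, rep(FALSE, m_sat)),
        stringsAsFactors = FALSE
      )
      idc <- idc + length(ids_k)
    }
    rec <- do.call(rbind, records)
    rec$lv_violator <- FALSE
    if (violator_fraction > 0) {
      pool <- which(!rec$is_representative)
      n_v <- min(length(pool), ceiling(violator_fraction * nrow(rec)))
      v <- sort(sample(pool, n_v))
      rec$structure[v] <- paste0(rec$structure[v],
                                 "CCCCCCCCCCCCCCCCCCCCCCCC")
      rec$lv_violator[v] <- TRUE
    }
    rownames(rec) <- NULL
    ligand_library(rec, provenance = list(
      sources = sprintf("gen_ligand_library(n=%d, n_clusters=%d, wcs=%s, seed=%d)",
                        n, n_clusters,
                        format(within_cluster_similarity), as.integer(seed)),
      generator = list(n = n, n_clusters = n_clusters,
                       within_cluster_similarity = within_cluster_similarity,
                       violator_fraction = violator_fraction,
                       seed = as.integer(seed))
    ))
  })
}

#' Planted docking-affinity landscape
#'
#' Defines the ground truth for [mock_dock()]: a base binding energy per
#' domain class, a per-ligand NBD offset for the planted NBD-preferring
#' ligands (negative values mean tighter NBD binding), and a frozen
#' Gaussian noise table drawn once per ligand-target pair so that repeated
#' docking of the same pair is consistent.
#'
#' @param ligand_ids all ligands the landscape covers.
#' @param targets a `receptor_manifest`.
#' @param base_dg_dbd,base_dg_nbd base energies, kcal/mol.
#' @param planted_ids subset of `ligand_ids` given the NBD offset.
#' @param planted_offset_nbd kcal/mol, added to planted ligands' NBD
#'   energies (negative = NBD-preferring).
#' @param noise_sd Gaussian noise SD, kcal/mol, `>= 0`.
#' @param seed integer seed for the noise table.
#' @return Object of class `planted_landscape`.
#' @export
planted_landscape <- function(ligand_ids, targets, base_dg_dbd = -7,
                              base_dg_nbd = -7, planted_ids = character(),
                              planted_offset_nbd = -3, noise_sd = 0,
                              seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!all(planted_ids %in% ligand_ids)) {
    stop("planted_ids must be a subset of ligand_ids", call. = FALSE)
  }
  nt <- nrow(targets)
  noise <- with_seed(as.integer(seed), {
    matrix(stats::rnorm(length(ligand_ids) * nt, sd = noise_sd),
           nrow = length(ligand_ids),
           dimnames = list(ligand_ids, targets$target_id))
  })
  off_n <- stats::setNames(rep(0, length(ligand_ids)), ligand_ids)
  off_n[planted_ids] <- planted_offset_nbd
  off_d <- stats::setNames(rep(0, length(ligand_ids)), ligand_ids)
  structure(list(
    ligand_ids = ligand_ids,
    base_dg_dbd = base_dg_dbd,
    base_dg_nbd = base_dg_nbd,
    planted_ids = planted_ids,
    planted_offset_nbd = planted_offset_nbd,
    offset_nbd = off_n,
    offset_dbd = off_d,
    noise_sd = noise_sd,
    seed = as.integer(seed),
    noise = noise
  ), class = "planted_landscape")
}

format_dg <- function(x) sprintf("%.4f", x)

#' Write docking results as a score TSV
#'
#' One row per pose: `ligand_id`, `target_id`, `dg`. Energies are written
#' at fixed precision so that write-parse-write cycles are byte-identical.
#'
#' @param results a `docking_results` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_tsv <- function(results, path) {
  rows <- do.call(rbind, lapply(seq_len(nrow(results)), function(i) {
    data.frame(ligand_id = results$ligand_id[i],
               target_id = results$target_id[i],
               dg = format_dg(results$all_dg[[i]]),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write one docking result as a Vina-style output PDBQT
#'
#' Emits `MODEL`/`REMARK VINA RESULT`/`ENDMDL` blocks, one per pose.
#'
#' @param result one row of a `docking_results` data.frame.
#' @param path output path (conventionally `<ligand>__<target>.pdbqt`).
#' @return `path`, invisibly.
#' @export
write_vina_pdbqt <- function(result, path) {
  lines <- unlist(lapply(seq_along(result$all_dg[[1]]), function(m) {
    c(sprintf("MODEL %d", m),
      sprintf("REMARK VINA RESULT:    %s      0.000      0.000",
              format_dg(result$all_dg[[1]][m])),
      "ENDMDL")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write one docking result as a Vina-style console log
#'
#' @inheritParams write_vina_pdbqt
#' @return `path`, invisibly.
#' @export
write_vina_log <- function(result, path) {
  dg <- result$all_dg[[1]]
  lines <- c(
    "mode |   affinity | dist from best mode",
    "     | (kcal/mol) | rmsd l.b.| rmsd u.b.",
    "-----+------------+----------+----------",
    sprintf("%4d   %10s      0.000      0.000", seq_along(dg),
            format_dg(dg))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Generate docking fixture files from a planted landscape
#'
#' Runs [mock_dock()] over every ligand-target pair and writes the results
#' in the requested dialect: one `scores.tsv` for `score-tsv`, or one file
#' per ligand-target pair for `pdbqt-remark` / `log-table`. A
#' `truth.tsv` with the noiseless planted energies is written alongside.
#'
#' @param landscape a [planted_landscape()].
#' @param targets a `receptor_manifest`.
#' @param dialect output dialect, as in [parse_vina_output()].
#' @param dir output directory (created if missing).
#' @param n_modes poses per result.
#' @return List `files` (written docking files), `truth` (noiseless energy
#'   table), `results` (the mocked `docking_results`).
#' @export
gen_docking_fixtures <- function(landscape, targets,
                                 dialect = c("score-tsv", "pdbqt-remark",
                                             "log-table"),
                                 dir, n_modes = 3L) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- mock_dock(landscape$ligand_ids, targets, landscape,
                   n_modes = n_modes)
  dc <- targets$domain_class[match(res$target_id, targets$target_id)]
  truth <- data.frame(
    ligand_id = res$ligand_id, target_id = res$target_id,
    dg_true = ifelse(dc == "NBD",
                     landscape$base_dg_nbd +
                       unname(landscape$offset_nbd[res$ligand_id]),
                     landscape$base_dg_dbd +
                       unname(landscape$offset_dbd[res$ligand_id])),
    stringsAsFactors = FALSE
  )
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (dialect == "score-tsv") {
    f <- file.path(dir, "scores.tsv")
    write_score_tsv(res, f)
    files <- f
  } else {
    ext <- if (dialect == "pdbqt-remark") ".pdbqt" else ".log"
    writer <- if (dialect == "pdbqt-remark") write_vina_pdbqt
              else write_vina_log
    files <- vapply(seq_len(nrow(res)), function(i) {
      f <- file.path(dir, paste0(res$ligand_id[i], "__", res$target_id[i],
                                 ext))
      writer(res[i, , drop = FALSE], f)
      f
    }, "")
  }
  list(files = files, truth = truth, results = res)
}

#' Assay ground truth for the synthetic generators
#'
#' @param compound_ids all compounds the assays cover.
#' @param inhibitor_ids compounds that re-sensitize (true pump inhibitors).
#' @param substrate_ids compounds that are transport substrates.
#' @param survival_decrease percentage-point drop in chemo survival caused
#'   by an inhibitor (default 50, well past the 30-point call threshold).
#' @param chemo_only_survival percent survival of resistant cells under the
#'   chemotherapeutic alone (default 90, resistant cells are barely hurt).
#' @param accumulation_fold fold increase of a substrate's +inhibitor
#'   accumulation (default 3).
#' @param dau_fold fold increase in daunorubicin fluorescence caused by an
#'   inhibitor (default 2).
#' @param noise_cv coefficient of variation of replicate noise (default
#'   0.05).
#' @return Object of class `assay_ground_truth`.
#' @export
assay_ground_truth <- function(compound_ids, inhibitor_ids = character(),
                               substrate_ids = character(),
                               survival_decrease = 50,
                               chemo_only_survival = 90,
                               accumulation_fold = 3, dau_fold = 2,
                               noise_cv = 0.05) {
  stopifnot(all(inhibitor_ids %in% compound_ids),
            all(substrate_ids %in% compound_ids))
  structure(list(compound_ids = compound_ids,
                 inhibitor_ids = inhibitor_ids,
                 substrate_ids = substrate_ids,
                 survival_decrease = survival_decrease,
                 chemo_only_survival = chemo_only_survival,
                 accumulation_fold = accumulation_fold,
                 dau_fold = dau_fold,
                 noise_cv = noise_cv),
            class = "assay_ground_truth")
}

#' Generate synthetic assay datasets
#'
#' Emits the three assay tables this package analyses, with Gaussian
#' replicate noise around the group means implied by the ground truth:
#' an MTT plate table (vehicle centred at absorbance 1.0, inhibitors
#' lowering compound+chemo survival by the stated effect), an LC-MS/MS
#' sample table (substrates showing the stated +inhibitor accumulation
#' fold), and a daunorubicin fluorescence table. With `noise_cv = 0` the
#' analysis functions recover the ground truth exactly.
#'
#' @param truth an [assay_ground_truth()].
#' @param n_replicates replicates per group (>= 3).
#' @param n_trials independent LC-MS/MS trials per compound.
#' @param seed integer seed.
#' @return List of data.frames `plate`, `lcms`, `fluorescence`.
#' @export
gen_assay_data <- function(truth, n_replicates = 3, n_trials = 2, seed = 1) {
  stopifnot(inherits(truth, "assay_ground_truth"), n_replicates >= 3)
  cv <- truth$noise_cv
  with_seed(as.integer(seed), {
    jitter <- function(mu, n) mu * (1 + cv * stats::rnorm(n))
    n_mtt <- max(n_replicates, 8L)
    plate <- rbind(
      data.frame(treatment = "vehicle", compound_id = NA_character_,
                 absorbance = jitter(1.0, n_mtt)),
      data.frame(treatment = "chemo-only", compound_id = NA_character_,
                 absorbance = jitter(truth$chemo_only_survival / 100, n_mtt)),
      do.call(rbind, lapply(truth$compound_ids, function(cid) {
        drop <- if (cid %in% truth$inhibitor_ids) truth$survival_decrease
                else 0
        mu <- (truth$chemo_only_survival - drop) / 100
        rbind(
          data.frame(treatment = "compound+chemo", compound_id = cid,
                     absorbance = jitter(mu, n_mtt)),
          data.frame(treatment = "compound-only", compound_id = cid,
                     absorbance = jitter(1.0, n_mtt))
        )
      }))
    )
    plate <- cbind(well_id = sprintf("W%04d", seq_len(nrow(plate))),
                   cell_line = "RESISTANT", plate)

    lcms <- do.call(rbind, lapply(truth$compound_ids, function(cid) {
      base_level <- 1.0
      fold <- if (cid %in% truth$substrate_ids) truth$accumulation_fold
              else 1.0
      do.call(rbind, lapply(seq_len(n_trials), function(tr) {
        is_peak <- 2000
        lysate <- 0.5
        rbind(
          data.frame(compound_id = cid, condition = "minus_TQR", trial = tr,
                     analyte_peak = jitter(base_level * is_peak * lysate,
                                           n_replicates),
                     is_peak = is_peak, lysate = lysate),
          data.frame(compound_id = cid, condition = "plus_TQR", trial = tr,
                     analyte_peak = jitter(fold * base_level * is_peak *
                                             lysate, n_replicates),
                     is_peak = is_peak, lysate = lysate)
        )
      }))
    }))

    fluor <- rbind(
      data.frame(compound_id = "DAU_ALONE",
                 fluorescence = jitter(1000, 3L * n_replicates)),
      do.call(rbind, lapply(truth$compound_ids, function(cid) {
        fold <- if (cid %in% truth$inhibitor_ids) truth$dau_fold else 1.0
        data.frame(compound_id = cid,
                   fluorescence = jitter(1000 * fold, 3L * n_replicates))
      }))
    )
    rownames(plate) <- rownames(lcms) <- rownames(fluor) <- NULL
    list(plate = plate, lcms = lcms, fluorescence = fluor)
  })
}

format_num <- function(x) {
  if (is.numeric(x)) sprintf("%.10g", x) else as.character(x)
}

#' Write / read assay CSV tables
#'
#' Canonical CSV serialisation for the assay tables: numbers at fixed
#' significant precision, no quoting, no row names, so that
#' write-read-write cycles are byte-identical.
#'
#' @param df assay data.frame.
#' @param path file path.
#' @return `path` (writer) or the data.frame (reader).
#' @export
write_assay_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, format_num), stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assay_csv
#' @export
read_assay_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Published LC-MS/MS accumulation summary statistics
#'
#' Returns the embedded reference table of LC-MS/MS relative-accumulation
#' summary statistics (mean and SD of the internal-standard-normalized
#' ratio, with and without the pump inhibitor tariquidar, n = 3 samples per
#' group, up to three independent trials) for the daunorubicin positive
#' control and nine experimental compounds. Rows whose analyte was below
#' quantification carry `quantifiable = FALSE`. The `p_printed` column
#' holds the originally reported p-values for cross-checking
#' ([classify_substrate()] recomputes them from the summaries).
#'
#' @param include_controls keep the daunorubicin positive-control rows
#'   (default `TRUE`).
#' @return data.frame in the summary-statistics dialect accepted by
#'   [classify_substrate()].
#' @export
table1_fixture <- function(include_controls = TRUE) {
  path <- system.file("extdata", "lcms_accumulation_reference.csv",
                      package = "counterscreen", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = c(compound_id = "character"))
  df$quantifiable <- as.logical(df$quantifiable)
  if (!include_controls) df <- df[df$compound_id != "DAU", , drop = FALSE]
  rownames(df) <- NULL
  df
}
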