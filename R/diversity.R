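#' Diversity subset by sphere exclusion
#'
#' Greedy leader (sphere-exclusion) pass over the library: ligands are
#' offered in library order (or in a seeded random order when `order_seed`
#' is given) and retained if and only if their Tanimoto similarity to every
#' previously retained ligand is at most `cutoff`. Each excluded ligand is
#' assigned to the first retained ligand whose similarity to it exceeds the
#' cutoff. The result therefore satisfies two invariants: no two retained
#' ligands are more than `cutoff` similar, and every excluded ligand exceeds
#' the cutoff against its representative.
#'
#' @param fps a `fingerprint_set` from [fingerprint_library()].
#' @param cutoff Tanimoto similarity threshold in `[0, 1]`.
#' @param order_seed optional integer; when given, the offer order is a
#'   seeded permutation instead of input order. Recorded in the result.
#' @return A `diversity_subset`: list with `retained_ids` (ordered),
#'   `assignment` (data.frame `excluded_id`, `representative_id`,
#'   `similarity`), `cutoff`, `order_seed`.
#' @export
diversity_subset <- function(fps, cutoff, order_seed = NULL) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff < 0 || cutoff > 1) {
    stop("cutoff must be a number in [0, 1]", call. = FALSE)
  }
  ids <- rownames(fps)
  n <- nrow(fps)
  ord <- seq_len(n)
  if (!is.null(order_seed)) {
    ord <- with_seed(as.integer(order_seed), sample.int(n))
  }
  bits <- matrix(as.numeric(fps), nrow = n)
  pop <- rowSums(bits)
  retained <- integer(0)
  rep_of <- integer(n)   # 0 = retained
  sim_to_rep <- rep(NA_real_, n)
  ret_mat <- matrix(0, nrow = 0, ncol = ncol(bits))
  for (i in ord) {
    if (length(retained) == 0L) {
      retained <- i
      ret_mat <- bits[i, , drop = FALSE]
      next
    }
    inter <- as.vector(ret_mat %*% bits[i, ])
    un <- pop[retained] + pop[i] - inter
    sims <- ifelse(un == 0, 1, inter / pmax(un, 1e-300))
    over <- which(sims > cutoff)
    if (length(over) == 0L) {
      retained <- c(retained, i)
      ret_mat <- rbind(ret_mat, bits[i, ])
    } else {
      first <- over[1L]
      rep_of[i] <- retained[first]
      sim_to_rep[i] <- sims[first]
    }
  }
  excl <- which(rep_of > 0L)
  structure(list(
    retained_ids = ids[retained],
    assignment = data.frame(
      excluded_id = ids[excl],
      representative_id = ids[rep_of[excl]],
      similarity = sim_to_rep[excl],
      stringsAsFactors = FALSE
    ),
    cutoff = cutoff,
    order_seed = order_seed
  ), class = "diversity_subset")
}

#' @export
print.diversity_subset <- function(x, ...) {
  cat("<diversity_subset> cutoff ", x$cutoff, ": ",
      length(x$retained_ids), " retained, ", nrow(x$assignment),
      " assigned\n", sep = "")
  invisible(x)
}

#' Similarity-band neighbour search
#'
#' For each query ligand, finds every pool ligand whose Tanimoto similarity
#' to the query lies inside the inclusive band `[low, high]`, excluding the
#' query itself. This is the expansion step of iterative screening: top hits
#' from one docking round pull in their chemical neighbours (for example the
#' 0.70-0.99 band) for the next round.
#'
#' @param query_fps `fingerprint_set` of the query ligands.
#' @param pool_fps `fingerprint_set` of the pool (same scheme).
#' @param band numeric length-2, inclusive similarity bounds
#'   `c(low, high)`, `0 <= low <= high <= 1`.
#' @return Named list: for each query id a data.frame (`ligand_id`,
#'   `similarity`) ordered by descending similarity, ties broken by
#'   ascending ligand id.
#' @export
similarity_expand <- function(query_fps, pool_fps, band = c(0.70, 0.99)) {
  stopifnot(length(band) == 2L)
  low <- band[1L]; high <- band[2L]
  if (!(low >= 0 && low <= high && high <= 1)) {
    stop("band must satisfy 0 <= low <= high <= 1", call. = FALSE)
  }
  if (nrow(pool_fps) == 0L) {
    warning("empty pool; returning no neighbours")
    out <- rep(list(data.frame(ligand_id = character(),
                               similarity = numeric())), nrow(query_fps))
    names(out) <- rownames(query_fps)
    return(out)
  }
  sims <- tanimoto_matrix(query_fps, pool_fps)
  pool_ids <- rownames(pool_fps)
  out <- lapply(rownames(query_fps), function(q) {
    s <- sims[q, ]
    sel <- which(s >= low & s <= high & pool_ids != q)
    df <- data.frame(ligand_id = pool_ids[sel], similarity = unname(s[sel]),
                     stringsAsFactors = FALSE)
    df[order(-df$similarity, df$ligand_id), , drop = FALSE]
  })
  names(out) <- rownames(query_fps)
  out
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
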