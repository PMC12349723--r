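test_that("tanimoto matches its set formula and edge conventions", {
  a <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  b <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  expect_equal(tanimoto(a, b), 2 / 4)       # |a|=3, |b|=3, |and|=2
  expect_equal(tanimoto(a, a), 1.0)
  expect_equal(tanimoto(a, !a), 0.0)
  expect_equal(tanimoto(logical(5), logical(5)), 1.0)  # all-zero rule
})

test_that("tanimoto is symmetric and bounded on random fingerprints", {
  fps <- random_fps(40, seed = 3)
  s <- tanimoto_matrix(fps)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(s, t(s))
  expect_equal(unname(diag(s)), rep(1, 40))
  # agrees with the scalar definition
  for (k in 1:20) {
    i <- sample(40, 1); j <- sample(40, 1)
    expect_equal(s[i, j], tanimoto_ref(fps[i, ], fps[j, ]))
  }
})

test_that("fingerprints are canonicalisation-invariant and schemes guarded", {
  fps <- fingerprint_library(c(a = "OCC", b = "CCO", c = "c1ccccc1"))
  expect_identical(unname(fps["a", ]), unname(fps["b", ]))
  expect_false(identical(unname(fps["a", ]), unname(fps["c", ])))
  expect_error(fingerprint_library(c(x = "")), "empty structure")
  expect_error(fingerprint_library(c(x = "not)(smiles")), "unparseable")
  fp3 <- fingerprint_library(c(a = "CCO"), scheme = "FP3")
  expect_error(tanimoto(fps[1, ], fp3[1, ]), "mismatch")
})

test_that("tanimoto agrees with Open Babel's own similarity engine", {
  smis <- c(a = "CCO", b = "CCN", c = "c1ccccc1CCO",
            d = "CC(=O)Oc1ccccc1C(=O)O", e = "c1ccncc1C(F)(F)F")
  fps <- fingerprint_library(smis)
  for (ref in names(smis)) {
    # obabel -ofpt prints the Tanimoto of every molecule against the first
    f <- write_tmp_smi(paste(smis[c(ref, setdiff(names(smis), ref))],
                             c(ref, setdiff(names(smis), ref))))
    out <- suppressWarnings(system2("obabel", c(f, "-ofpt"),
                                    stdout = TRUE, stderr = FALSE))
    hits <- regmatches(out, regexec("^>(\\S+)\\s+Tanimoto from \\S+ = ([0-9.eE+-]+)", out))
    hits <- hits[vapply(hits, length, 1L) == 3L]
    expect_gt(length(hits), 0)
    for (h in hits) {
      expect_equal(tanimoto(fps[ref, ], fps[h[2], ]), as.numeric(h[3]),
                   tolerance = 1e-5)
    }
  }
})

test_that("sphere exclusion satisfies its invariants (brute-force check)", {
  for (case in list(list(n = 50, cutoff = 0.6, seed = 1),
                    list(n = 120, cutoff = 0.4, seed = 2),
                    list(n = 80, cutoff = 0.8, seed = 3))) {
    fps <- random_fps(case$n, nbits = 64, density = 0.3, seed = case$seed)
    sub <- diversity_subset(fps, case$cutoff)
    s <- tanimoto_matrix(fps)
    ret <- sub$retained_ids
    # no two retained ligands more similar than the cutoff
    sr <- s[ret, ret, drop = FALSE]
    diag(sr) <- 0
    expect_true(all(sr <= case$cutoff))
    # every excluded ligand exceeds the cutoff against its representative
    a <- sub$assignment
    expect_equal(sort(c(ret, a$excluded_id)), sort(rownames(fps)))
    for (k in seq_len(nrow(a))) {
      expect_gt(s[a$excluded_id[k], a$representative_id[k]], case$cutoff)
      expect_equal(a$similarity[k], s[a$excluded_id[k], a$representative_id[k]])
    }
  }
})

test_that("sphere exclusion handles duplicates and all-dissimilar inputs", {
  fps <- random_fps(1, nbits = 32, density = 0.5, seed = 9)
  trip <- fps[c(1, 1, 1), , drop = FALSE]
  rownames(trip) <- c("x", "y", "z")
  sub <- diversity_subset(trip, 0.90)
  expect_equal(sub$retained_ids, "x")
  expect_equal(sort(sub$assignment$excluded_id), c("y", "z"))
  expect_equal(unique(sub$assignment$representative_id), "x")

  # pairwise-disjoint fingerprints: everything retained below cutoff 1
  dis <- diag(4) == 1
  rownames(dis) <- letters[1:4]
  expect_equal(diversity_subset(dis, 0.99)$retained_ids, letters[1:4])

  expect_error(diversity_subset(dis, 1.5), "cutoff")
})

test_that("subset size shrinks as the cutoff tightens", {
  fps <- random_fps(150, nbits = 64, density = 0.3, seed = 5)
  sizes <- vapply(c(0.2, 0.4, 0.6, 0.8),
                  function(cu) length(diversity_subset(fps, cu)$retained_ids),
                  0)
  expect_true(all(diff(sizes) >= 0))
})

test_that("seeded ordering is deterministic and recorded", {
  fps <- random_fps(60, seed = 8)
  s1 <- diversity_subset(fps, 0.5, order_seed = 17)
  s2 <- diversity_subset(fps, 0.5, order_seed = 17)
  expect_identical(s1$retained_ids, s2$retained_ids)
  expect_equal(s1$order_seed, 17)
})

test_that("similarity_expand equals a brute-force scan and obeys the band", {
  fps <- random_fps(200, nbits = 64, density = 0.3, seed = 11)
  q <- fps[1:5, , drop = FALSE]
  band <- c(0.30, 0.60)
  nb <- similarity_expand(q, fps, band = band)
  s <- tanimoto_matrix(q, fps)
  for (qq in rownames(q)) {
    want <- colnames(s)[s[qq, ] >= band[1] & s[qq, ] <= band[2] &
                          colnames(s) != qq]
    expect_setequal(nb[[qq]]$ligand_id, want)
    # ordering: descending similarity, ties by id
    df <- nb[[qq]]
    expect_identical(df, df[order(-df$similarity, df$ligand_id), ])
  }
  # full band returns everything but the query itself
  all_nb <- similarity_expand(q[1, , drop = FALSE], fps, band = c(0, 1))
  expect_setequal(all_nb[[1]]$ligand_id, setdiff(rownames(fps), rownames(q)[1]))
  # empty pool warns
  expect_warning(similarity_expand(q, fps[0, , drop = FALSE]), "empty pool")
  expect_error(similarity_expand(q, fps, band = c(0.9, 0.2)), "band")
})
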