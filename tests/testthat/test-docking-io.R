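test_that("manifest loading validates structure and pair groups", {
  man <- shared_manifest()
  expect_s3_class(man, "receptor_manifest")
  expect_equal(nrow(man), 14L)
  expect_setequal(unique(man$domain_class), c("NBD", "DBD"))
  for (pg in unique(stats::na.omit(man$pair_group))) {
    cls <- man$domain_class[!is.na(man$pair_group) & man$pair_group == pg]
    expect_true(all(c("NBD", "DBD") %in% cls))
  }

  bad <- data.frame(target_id = c("a", "a"), conformation = "x",
                    domain_class = "NBD", pair_group = NA,
                    cx = 0, cy = 0, cz = 0, sx = 10, sy = 10, sz = 10)
  expect_error(validate_manifest(bad), "duplicate target_id")
  bad2 <- bad; bad2$target_id <- c("a", "b"); bad2$sx[1] <- -1
  expect_error(validate_manifest(bad2), "non-positive box")
  bad3 <- bad; bad3$target_id <- c("a", "b"); bad3$pair_group <- "g"
  expect_error(validate_manifest(bad3), "lacks a DBD")
})

test_that("yaml manifests with one valid pair load; json dialect too", {
  y <- tempfile(fileext = ".yaml")
  writeLines(c(
    "targets:",
    "  - target_id: X_DBD", "    conformation: X", "    domain_class: DBD",
    "    pair_group: X", "    box_center: [0, 0, 0]",
    "    box_size: [20, 20, 20]",
    "  - target_id: X_NBD", "    conformation: X", "    domain_class: NBD",
    "    pair_group: X", "    box_center: [0, 0, -30]",
    "    box_size: [24, 24, 24]"), y)
  man <- load_target_manifest(y)
  expect_equal(man$target_id, c("X_DBD", "X_NBD"))
  j <- tempfile(fileext = ".json")
  jsonlite::write_json(list(targets = list(
    list(target_id = "A_DBD", conformation = "A", domain_class = "DBD",
         pair_group = "A", box_center = c(0, 0, 0), box_size = c(20, 20, 20)),
    list(target_id = "A_NBD", conformation = "A", domain_class = "NBD",
         pair_group = "A", box_center = c(0, 0, -30),
         box_size = c(24, 24, 24)))), j, auto_unbox = TRUE)
  expect_equal(nrow(load_target_manifest(j)), 2L)
})

test_that("pdbqt-remark and log-table dialects take the best mode", {
  p <- tempfile(fileext = ".pdbqt")
  writeLines(c("MODEL 1", "REMARK VINA RESULT:    -7.4      0.000      0.000",
               "ENDMDL", "MODEL 2",
               "REMARK VINA RESULT:    -8.0      1.2      2.1", "ENDMDL",
               "MODEL 3", "REMARK VINA RESULT:    -6.9      2.0      3.3",
               "ENDMDL"), p)
  r <- parse_vina_output(p, "pdbqt-remark", ligand_id = "lig", target_id = "t")
  expect_equal(r$best_dg, -8.0)
  expect_equal(r$n_modes, 3L)

  l <- tempfile(fileext = ".log")
  writeLines(c("mode |   affinity | dist from best mode",
               "-----+------------+----------",
               "   1      -5.2      0.000      0.000"), l)
  r2 <- parse_vina_output(l, "log-table", ligand_id = "lig", target_id = "t")
  expect_equal(r2$best_dg, -5.2)
  expect_equal(r2$n_modes, 1L)

  # ligand/target parsed from the file-name stem convention
  p2 <- file.path(tempdir(), "mylig__mytarget.pdbqt")
  file.copy(p, p2, overwrite = TRUE)
  r3 <- parse_vina_output(p2, "pdbqt-remark")
  expect_equal(r3$ligand_id, "mylig")
  expect_equal(r3$target_id, "mytarget")
})

test_that("parser errors name the file and the offending line", {
  f <- tempfile(fileext = ".pdbqt")
  writeLines(c("ATOM 1"), f)
  expect_error(parse_vina_output(f, "pdbqt-remark"), "no result lines")
  writeLines(c("REMARK VINA RESULT:  abc  0 0"), f)
  expect_error(parse_vina_output(f, "pdbqt-remark"), "line 1")
  t <- tempfile(fileext = ".tsv")
  writeLines("ligand_id\ttarget_id\twrong", t)
  expect_error(parse_vina_output(t, "score-tsv"), "needs columns")
})

test_that("best_dg is invariant to mode order", {
  f1 <- tempfile(fileext = ".pdbqt")
  f2 <- tempfile(fileext = ".pdbqt")
  dg <- c(-6.1, -8.3, -7.2)
  mk <- function(v) unlist(lapply(seq_along(v), function(m) {
    c(sprintf("MODEL %d", m),
      sprintf("REMARK VINA RESULT:  %.1f  0.0  0.0", v[m]), "ENDMDL")
  }))
  writeLines(mk(dg), f1)
  writeLines(mk(rev(dg)), f2)
  expect_equal(parse_vina_output(f1, "pdbqt-remark", "a", "t")$best_dg,
               parse_vina_output(f2, "pdbqt-remark", "a", "t")$best_dg)
})

test_that("mock_dock is seed-deterministic and realises the landscape", {
  man <- shared_manifest()
  ids <- sprintf("L%02d", 1:10)
  ls0 <- planted_landscape(ids, man, base_dg_dbd = -6.5, base_dg_nbd = -7.5,
                           planted_ids = "L03", planted_offset_nbd = -3,
                           noise_sd = 0, seed = 4)
  r <- mock_dock(ids, man, ls0)
  expect_equal(nrow(r), 10L * 14L)
  dc <- man$domain_class[match(r$target_id, man$target_id)]
  expect_true(all(r$best_dg[dc == "DBD"] == -6.5))
  planted_nbd <- r$best_dg[r$ligand_id == "L03" & dc == "NBD"]
  expect_true(all(planted_nbd == -10.5))
  expect_true(all(r$best_dg[r$ligand_id != "L03" & dc == "NBD"] == -7.5))

  ls1 <- planted_landscape(ids, man, noise_sd = 0.5, seed = 4)
  expect_identical(mock_dock(ids, man, ls1), mock_dock(ids, man, ls1))
  ls2 <- planted_landscape(ids, man, noise_sd = 0.5, seed = 5)
  expect_false(identical(mock_dock(ids, man, ls1), mock_dock(ids, man, ls2)))
  expect_error(planted_landscape(ids, man, noise_sd = -1), "noise_sd")
})

test_that("fixture writers round-trip through the parsers in all dialects", {
  man <- shared_manifest()[1:2, ]
  class(man) <- c("receptor_manifest", "data.frame")
  ids <- sprintf("L%02d", 1:10)
  ls0 <- planted_landscape(ids, man, noise_sd = 0.8, seed = 6)

  d1 <- file.path(tempdir(), "fix_tsv")
  fx <- gen_docking_fixtures(ls0, man, "score-tsv", d1, n_modes = 3)
  parsed <- parse_vina_output(fx$files, "score-tsv")
  expect_equal(nrow(parsed), nrow(fx$results))
  # byte-identical rewrite
  f2 <- tempfile(fileext = ".tsv")
  write_score_tsv(parsed, f2)
  expect_identical(readLines(fx$files), readLines(f2))

  for (dia in c("pdbqt-remark", "log-table")) {
    d <- file.path(tempdir(), paste0("fix_", substr(dia, 1, 3)))
    fx2 <- gen_docking_fixtures(ls0, man, dia, d, n_modes = 2)
    one <- fx2$files[1]
    pr <- parse_vina_output(one, dia)
    i <- which(paste0(fx2$results$ligand_id, "__", fx2$results$target_id) ==
                 sub("\\.[^.]*$", "", basename(one)))
    expect_equal(pr$n_modes, 2L)
    expect_equal(pr$all_dg[[1]],
                 as.numeric(sprintf("%.4f", fx2$results$all_dg[[i]])))
    rewrite <- tempfile()
    if (dia == "pdbqt-remark") write_vina_pdbqt(pr, rewrite)
    else write_vina_log(pr, rewrite)
    expect_identical(readLines(one), readLines(rewrite))
  }
})
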