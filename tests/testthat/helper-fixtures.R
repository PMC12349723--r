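# Shared test fixtures, built in code.

# A small record table with hand-set descriptors, for exercising the
# drug-likeness filter without touching the property calculator.
manual_records <- function(...) {
  rows <- list(...)
  base <- data.frame(
    ligand_id = sprintf("L%03d", seq_along(rows)),
    structure = "CCO",
    mw = 300, logp = 2, tpsa = 80, hbd = 2, hba = 5, rot_bonds = 4,
    has_aldehyde = FALSE, has_thiol = FALSE, descriptor_failed = FALSE,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(rows)) {
    for (nm in names(rows[[i]])) base[i, nm] <- rows[[i]][[nm]]
  }
  base
}

manual_library <- function(...) ligand_library(manual_records(...))

# Random synthetic fingerprint matrix (not chemistry-derived); density is
# the expected fraction of set bits.
random_fps <- function(n, nbits = 128, density = 0.2, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(n * nbits) < density, nrow = n)
  rownames(m) <- sprintf("FP%04d", seq_len(n))
  m
}

# Reference Tanimoto via explicit set arithmetic.
tanimoto_ref <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) 1 else sum(a & b) / u
}

# One shared small clustered library per test run (obabel-backed, so built
# once and reused).
shared_lib <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- gen_ligand_library(30, 3, within_cluster_similarity = 0.95,
                                   seed = 7)
    }
    cache
  }
})

shared_manifest <- function() {
  load_target_manifest(system.file("extdata", "targets_synthetic.yaml",
                                   package = "counterscreen"))
}

write_tmp_smi <- function(lines) {
  f <- tempfile(fileext = ".smi")
  writeLines(lines, f)
  f
}
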