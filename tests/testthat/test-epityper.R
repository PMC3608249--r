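test_that("bisulfite conversion retains only methylated CpG cytosines", {
  # CpG at position 3 methylated: non-CpG C converts, CpG C retained
  expect_equal(bisulfite_convert("ACCGT", 3), "ATCGT")
  expect_equal(bisulfite_convert("ACCGT"), "ATTGT")
  expect_equal(bisulfite_convert("AGGTA"), "AGGTA")
  expect_error(bisulfite_convert("ACCGT", 2), "not a CpG")
  expect_equal(nchar(bisulfite_convert("ACCGT", 3)), 5L)
})

test_that("cleavage cuts 3' of every U and tiles the transcript", {
  fr <- cleave_fragments("CCGUAAGU")
  expect_equal(fr$sequence, c("CCGU", "AAGU"))
  expect_equal(cleave_fragments("CCGA")$sequence, "CCGA")
  set.seed(30)
  for (i in 1:1000) {
    tx <- rc_transcript(bisulfite_convert(random_dna(sample(5:80, 1))))
    fr <- cleave_fragments(tx)
    expect_identical(paste(fr$sequence, collapse = ""), tx)
    expect_identical(fr$start, c(1L, head(fr$end, -1L) + 1L))
  }
})

test_that("fragment masses follow the documented residue table", {
  expect_equal(fragment_mass("AAGU"), 329.21 + 329.21 + 345.21 + 306.17 + 18.02)
  expect_equal(fragment_mass(""), 18.02)
  expect_error(fragment_mass("AAGU", 2, 1), "n_methylated")
})

test_that("each methylated CpG shifts the fragment mass by exactly 16 Da", {
  expect_equal(fragment_mass("AAGU", 1, 1) - fragment_mass("AAGU", 0, 1), 16)
  # fully methylated minus unmethylated = 16 * cpg_count, exactly
  set.seed(31)
  for (i in 1:50) {
    sq <- paste(sample(c("A", "C", "G", "U"), sample(3:20, 1),
                       replace = TRUE), collapse = "")
    k <- sample(0:4, 1)
    expect_equal(fragment_mass(sq, k, k) - fragment_mass(sq, 0, k), 16 * k)
  }
})

test_that("mass is additive over concatenation up to the terminal water", {
  set.seed(32)
  for (i in 1:50) {
    a <- paste(sample(c("A", "C", "G", "U"), 8, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), 5, replace = TRUE), collapse = "")
    expect_equal(fragment_mass(paste0(a, b)),
                 fragment_mass(a) + fragment_mass(b) - 18.02)
  }
})

test_that("CpGs sharing a cleavage fragment form one multi-site unit", {
  # CpGs at 2 and 5 both land on the terminal A-free stretch of the
  # transcript: one unit with two member sites
  amp <- amplicon("two_on_one", "TCGTCGG")
  units <- map_cpg_units(amp)
  expect_equal(nrow(units), 1L)
  expect_equal(units$unit_label, "1/2")
  expect_equal(units$cpg_count, 2L)
  expect_equal(units$ambiguity_flag, "clean")
})

test_that("isolated CpGs on mass-distinct fragments are all clean", {
  amp <- amplicon("clean", "ACGGGTAACGT")
  units <- map_cpg_units(amp)
  expect_equal(nrow(units), 2L)
  expect_true(all(units$ambiguity_flag == "clean"))
  expect_true(all(units$cpg_count == 1L))
})

test_that("equal-mass CpG fragments are flagged as a mass collision", {
  # transcript fragments ACAU and CAAU: distinct sequences, identical
  # composition, one CpG each -> identical mass ladders
  amp <- amplicon("collide", "ATCGACGT", cpg_positions = c(3, 6))
  units <- map_cpg_units(amp)
  expect_equal(nrow(units), 2L)
  expect_true(all(units$ambiguity_flag == "mass_collision"))
  expect_equal(units$collision_group[1], units$collision_group[2])
  # exhaustive verification: the flagged pair's full ladders coincide
  lad <- lapply(seq_len(2), function(i)
    units$base_mass[i] + 16 * (0:units$cpg_count[i]))
  expect_equal(lad[[1]], lad[[2]])
})

test_that("a CpG fragment masked by a CpG-free fragment is unresolvable", {
  # at coarse mass resolution the methylated state of the CGT-site
  # fragment is indistinguishable from a CpG-free fragment
  amp <- amplicon("masked", "ACGTATTT")
  fine <- map_cpg_units(amp, mass_resolution = 1)
  coarse <- map_cpg_units(amp, mass_resolution = 30)
  expect_equal(fine$ambiguity_flag, "clean")
  expect_equal(coarse$ambiguity_flag, "unresolvable")
})

test_that("intensity ladders quantify to the state-weighted fraction", {
  expect_equal(quantify_unit(c(3, 1)), 0.25)
  expect_equal(quantify_unit(c(0, 1, 1)), 0.75)
  expect_true(is.na(quantify_unit(c(0, 0))))
  expect_error(quantify_unit(c(-1, 2)), "non-negative")
})

test_that("noiseless simulation and quantification invert each other", {
  for (truth in c(0, 0.17, 0.4, 0.5, 0.93, 1)) {
    reps <- simulate_measurement(truth, noise_sd = 0, replicates = 3)
    expect_equal(reps, rep(truth, 3))
    # K = 1 intensity ladder at the simulated fraction
    expect_equal(quantify_unit(c(1 - truth, truth)), truth,
                 tolerance = 1e-12)
  }
})

test_that("measurement simulation is seeded and control panel calibrated", {
  expect_identical(simulate_measurement(0.3, 0.05, 3, seed = 9),
                   simulate_measurement(0.3, 0.05, 3, seed = 9))
  controls <- c(0, 0.25, 0.5, 0.75, 1)
  means <- vapply(seq_along(controls), function(i)
    mean(simulate_measurement(controls[i], noise_sd = 0.02,
                              replicates = 100, seed = 100 + i)),
    numeric(1))
  expect_true(all(abs(means - controls) < 0.02))
})

test_that("amplicons round-trip through FASTA plus YAML sidecar", {
  skip_if_not_installed("Biostrings")
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "amp.fa")
  writeLines(c(">amp1", "ACGTACGTT"), fa)
  yml <- file.path(dir, "amp.yaml")
  yaml::write_yaml(list(name = "amp1", strand = "+", start = 101,
                        cpg_positions = c(2L, 6L)), yml)
  amp <- read_amplicon(fa, yml)
  expect_equal(amp$sequence, "ACGTACGTT")
  expect_equal(amp$cpg_positions, c(2L, 6L))
  expect_equal(amp$start, 101)
})
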