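test_that("packaged tables carry the expected thermodynamic constants", {
  expect_equal(TP$au_penalty, 0.5)
  expect_equal(TP$RT, 1.98717e-3 * 310.15, tolerance = 1e-12)
  expect_equal(TP$ml_a, 9.3)
  expect_equal(TP$ml_b, -0.9)
  expect_equal(unname(TP$hairpin_init[3L]), 5.4)
  # every canonical pair present in every pair-indexed table
  expect_true(all(is.finite(TP$stack)))
  expect_true(all(is.finite(TP$dangle5)) && all(is.finite(TP$dangle3)))
  expect_true(all(is.finite(TP$mm_hairpin)) && all(is.finite(TP$mm_internal)))
})

test_that("reloading the parameter source is idempotent", {
  files <- c(system.file("extdata", "turner2004.txt", package = "dualpf"),
             system.file("extdata", "turner2004_int22.txt", package = "dualpf"))
  a <- load_parameters(files)
  b <- load_parameters(files)
  expect_identical(a, b)
})

test_that("loop energies extrapolate logarithmically beyond size 30", {
  expect_equal(hairpin_energy(TP, 30L), TP$hairpin_init[30L])
  expect_equal(bulge_energy(TP, 30L), TP$bulge_init[30L])
  expect_equal(hairpin_energy(ZP, 60L), 1.75 * ZP$RT * log(2))
  expect_equal(internal_energy(ZP, 62L), 1.75 * ZP$RT * log(62 / 30))
  # monotone non-decreasing beyond the table
  sizes <- 30:80
  expect_true(all(diff(hairpin_energy(TP, sizes)) >= 0))
  expect_true(all(diff(bulge_energy(TP, sizes)) >= 0))
  expect_true(all(diff(internal_energy(TP, sizes)) >= 0))
  expect_error(hairpin_energy(TP, 2L), "steric")
})

test_that("terminal AU penalty applies to AU/UA/GU/UG only", {
  expect_equal(au_penalty_of(TP, "GC"), 0)
  expect_equal(au_penalty_of(TP, "CG"), 0)
  expect_equal(au_penalty_of(TP, "GU"), 0.5)
  expect_equal(au_penalty_of(TP, c("AU", "UA", "UG")), c(0.5, 0.5, 0.5))
  expect_error(au_penalty_of(TP, "AG"), "canonical")
})

test_that("the all-zero model makes every accessor zero", {
  expect_equal(hairpin_energy(ZP, 12L), 0)
  expect_equal(bulge_energy(ZP, 7L), 0)
  expect_equal(au_penalty_of(ZP, "AU"), 0)
  expect_equal(energy_of_structure("GGGGAAACCCC", "((((...))))", ZP, "d2"), 0)
})

test_that("malformed parameter sources are rejected with the block name", {
  tf <- tempfile(fileext = ".txt")
  src <- readLines(system.file("extdata", "turner2004.txt", package = "dualpf"))
  src[grep("^STACK$", src) + 1L] <- "-1.10 junk -2.20 -0.90 -1.40 -0.60"
  writeLines(src, tf)
  expect_error(load_parameters(tf), "STACK")
  writeLines(c("MISC", "au_penalty 0.5"), tf)
  expect_error(load_parameters(tf), "temperature|MISC|mandatory")
})
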