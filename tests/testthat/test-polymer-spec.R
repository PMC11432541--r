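# Polymer/binder/parameter domain types, spec-file round trips and system
# validation.

test_that("polymer spec files load, validate and round-trip", {
  # 4-bead homopolymer
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#types: A",
               "bead_index\tchrom\tstart_bp\ttypes",
               "0\tchr1\t0\tA", "1\tchr1\t2500\tA",
               "2\tchr1\t5000\tA", "3\tchr1\t7500\tA"), f)
  spec <- load_polymer_spec(f)
  expect_equal(spec$n_beads, 4)
  expect_equal(length(spec$type_catalog), 1)
  expect_equal(spec$bp_per_bead, 2500)

  # paper-scale heteropolymer with multi-label beads
  big <- make_binding_profile(800, 10, n_domains = 25,
                              domain_length = 32, overlap_prob = 0.4,
                              inert_frac = 0.05, seed = 3)
  expect_equal(big$n_beads, 800)
  expect_equal(length(big$type_catalog), 10)
  expect_true(any(lengths(big$bead_types) >= 2))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  save_polymer_spec(big, f2)
  back <- load_polymer_spec(f2)
  expect_identical(back$bead_types, big$bead_types)
  expect_identical(back$type_catalog, big$type_catalog)
  expect_equal(back$bp_per_bead, big$bp_per_bead)

  # label missing from the declared catalog is rejected
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#types: A",
               "bead_index\tchrom\tstart_bp\ttypes",
               "0\tchr1\t0\tA", "1\tchr1\t2500\tZ"), f3)
  expect_error(load_polymer_spec(f3), "not in catalog")

  # degenerate chain refused before write
  expect_error(polymer_spec(list()), "at least 2 beads")
})

test_that("volume fraction <-> count conversion and system validation", {
  p <- simulation_params(box_edge = 50)
  b <- binder_ensemble("A", affinity = 5, volume_fraction = 0.1)
  resolved <- resolve_binder_counts(b, p)
  expect_equal(resolved$count, 23873)  # round(0.1 * 50^3 / (pi/6))

  # conversion is self-inverse within one binder of rounding
  b2 <- binder_ensemble("A", affinity = 5, count = resolved$count)
  r2 <- resolve_binder_counts(b2, p)
  b3 <- binder_ensemble("A", affinity = 5,
                        volume_fraction = r2$volume_fraction)
  expect_equal(resolve_binder_counts(b3, p)$count, resolved$count,
               tolerance = 1)

  spec <- homopolymer_spec(10)
  # cut-off exceeding half the box is flagged
  p_small <- simulation_params(box_edge = 2)
  rep1 <- validate_system(spec, b, p_small)
  expect_true(any(rep1$level == "error" & rep1$what == "cutoffs"))

  # affinity outside the sampled 0-8 kT range draws a warning row
  b_hot <- binder_ensemble("A", affinity = 9, volume_fraction = 0.01)
  rep2 <- validate_system(spec, b_hot, p)
  expect_true(any(rep2$level == "warning" & rep2$what == "binders"))

  # validation is pure and a clean system reports no errors
  b_ok <- binder_ensemble("A", affinity = 5, volume_fraction = 0.01)
  before <- unserialize(serialize(list(spec, b_ok, p), NULL))
  rep3 <- validate_system(spec, b_ok, p)
  expect_false(any(rep3$level == "error"))
  expect_identical(list(spec, b_ok, p), before)
  expect_equal(attr(rep3, "binders")$count,
               round(0.01 * 50^3 / (pi / 6)))
})
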