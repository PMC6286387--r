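# Secondary-shift computation, helix calling, and state comparison.

bound_segments <- data.frame(start = c(39, 50, 81, 99),
                             end = c(44, 69, 88, 109),
                             offset = 3.5)
free_segments <- data.frame(start = c(39, 55), end = c(44, 62),
                            offset = 2.0)

coil <- simulate_shift_table(NULL)

test_that("secondary shifts are observed-minus-coil with missing propagation", {
  expect_equal(secondary_shifts(coil, coil)$delta, rep(0, 85))
  obs <- simulate_shift_table(data.frame(start = 50, end = 60, offset = 3.1))
  prof <- secondary_shifts(obs, coil)
  in_seg <- prof$residue_number >= 50 & prof$residue_number <= 60
  expect_equal(prof$delta[in_seg], rep(3.1, 11))
  expect_equal(prof$delta[!in_seg], rep(0, sum(!in_seg)))
  # exchange-broadened residues flagged missing and excluded
  obs2 <- simulate_shift_table(bound_segments, missing = 92:95)
  prof2 <- secondary_shifts(obs2, coil)
  expect_equal(attr(prof2, "missing_residues"), 92:95)
  expect_true(all(is.na(prof2$delta[prof2$residue_number %in% 92:95])))
  # residue-type mismatch names the position
  bad <- shift_table(28:112, rev(coil$residue_type), coil$ca_shift)
  expect_error(secondary_shifts(bad, coil), "position")
})

test_that("bound-state fixture yields exactly the four stable helices", {
  obs <- simulate_shift_table(bound_segments, missing = 92:95)
  prof <- call_helices(secondary_shifts(obs, coil))
  segs <- helix_segments(prof)
  expect_identical(segs$class, rep("stable_helix", 4))
  expect_equal(segs$start, c(39, 50, 81, 99))
  expect_equal(segs$end, c(44, 69, 88, 109))
})

test_that("free-state fixture yields exactly the two marginal helices", {
  obs <- simulate_shift_table(free_segments)
  prof <- call_helices(secondary_shifts(obs, coil))
  segs <- helix_segments(prof)
  expect_identical(segs$class, rep("marginal_helix", 2))
  expect_equal(segs$start, c(39, 55))
  expect_equal(segs$end, c(44, 62))
  # all-zero deviations call nothing
  none <- call_helices(secondary_shifts(coil, coil))
  expect_equal(nrow(helix_segments(none)), 0)
})

test_that("calling is monotone in the stable threshold", {
  obs <- simulate_shift_table(bound_segments, missing = 92:95)
  prof <- secondary_shifts(obs, coil)
  n_stable <- function(th) {
    segs <- helix_segments(call_helices(prof, stable_threshold = th))
    sum(segs$class == "stable_helix")
  }
  counts <- vapply(c(2.0, 3.0, 3.4, 3.6, 5.0), n_stable, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 4)   # everything above 2.0 is stable
  expect_equal(counts[5], 0)   # nothing reaches 5.0
})

test_that("segment recovery survives noise well below the threshold margin", {
  # offset at threshold + 3 sigma (3.0 + 3*0.3 = 3.9): boundaries must
  # be recovered within max_gap across seeded replicates
  segs <- data.frame(start = c(39, 50, 81, 99), end = c(44, 69, 88, 109),
                     offset = 3.9)
  set.seed(21)
  for (rep in 1:20) {
    obs <- simulate_shift_table(segs, noise_sd = 0.3, missing = 92:95)
    called <- helix_segments(call_helices(secondary_shifts(obs, coil)))
    stable <- called[called$class == "stable_helix", ]
    expect_equal(nrow(stable), 4)
    expect_true(all(abs(stable$start - segs$start) <= 1))
    expect_true(all(abs(stable$end - segs$end) <= 1))
  }
})

test_that("state comparison classifies free vs bound and is antisymmetric", {
  free <- call_helices(secondary_shifts(simulate_shift_table(free_segments),
                                        coil))
  bound <- call_helices(secondary_shifts(
    simulate_shift_table(bound_segments, missing = 92:95), coil))
  cmp <- compare_states(free, bound)
  expect_identical(cmp$free_class, "molten-globule-like")
  expect_identical(cmp$bound_class, "folded")
  expect_equal(nrow(cmp$gained[cmp$gained$class == "stable_helix", ]), 4)
  # swap antisymmetry
  rev_cmp <- compare_states(bound, free)
  expect_equal(cmp$gained, rev_cmp$lost)
  expect_equal(cmp$lost, rev_cmp$gained)
  # self-comparison gains and loses nothing
  self_cmp <- compare_states(bound, bound)
  expect_equal(nrow(self_cmp$gained), 0)
  expect_equal(nrow(self_cmp$lost), 0)
  # deleting one segment is reported as exactly one loss
  smaller <- call_helices(secondary_shifts(
    simulate_shift_table(bound_segments[-2, ], missing = 92:95), coil))
  cmp2 <- compare_states(bound, smaller)
  expect_equal(nrow(cmp2$lost), 1)
  expect_equal(cmp2$lost$start, 50)
})

test_that("amide dispersion heuristic reports spread and hint", {
  narrow <- amide_dispersion(stats::runif(50, 7.9, 8.5))
  expect_true(narrow$disorder_hint)
  wide <- amide_dispersion(c(6.5, stats::runif(50, 7, 9.5), 10.2))
  expect_false(wide$disorder_hint)
  expect_error(amide_dispersion(NA_real_), "finite")
})
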