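mk_ions <- function(mz, charge, intensity = 1e6, rt = 30) {
  data.frame(run_id = "r1", mz = mz, charge = charge, intensity = intensity,
             rt = rt, stringsAsFactors = FALSE)
}

test_that("intensity filter uses a strict-below exclusion boundary", {
  ions <- mk_ions(c(500, 600, 700), c(2, 2, 2),
                  intensity = c(4.9e5, 5.0e5, 6e5))
  kept <- filter_ions(ions)
  expect_equal(kept$intensity, c(5.0e5, 6e5))
  expect_equal(nrow(filter_ions(ions[0, ])), 0)
  expect_warning(kept2 <- filter_ions(mk_ions(500, 2, intensity = -1)),
                 "negative")
  expect_equal(nrow(kept2), 0)
})

test_that("charge states of one species merge into one cluster", {
  M <- 3690.489
  ions <- mk_ions(mz_from_mass(M, c(4, 5)), c(4, 5))
  cl <- cluster_ions(ions)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$neutral_mass, M, tolerance = 1e-6)
  expect_equal(cl$clusters$total_intensity, 2e6)
  # 100 ppm apart stays apart at 10 ppm tolerance
  cl2 <- cluster_ions(mk_ions(mz_from_mass(c(1000.0, 1000.1), 1), c(1, 1)))
  expect_equal(nrow(cl2$clusters), 2)
  cl3 <- cluster_ions(mk_ions(500, 2))
  expect_equal(nrow(cl3$clusters), 1)
  expect_equal(cl3$clusters$n_members, 1)
})

test_that("clustering partitions the input and ignores row order", {
  set.seed(23)
  M <- runif(40, 600, 8000)
  z <- sample(2:6, 40, replace = TRUE)
  ions <- mk_ions(mz_from_mass(M, z) * (1 + runif(40, -3e-6, 3e-6)), z,
                  intensity = runif(40, 1e5, 1e7))
  cl <- cluster_ions(ions)
  expect_equal(nrow(cl$members), nrow(ions))
  expect_equal(sum(cl$clusters$n_members), nrow(ions))
  expect_equal(sum(cl$clusters$total_intensity), sum(ions$intensity))
  perm <- sample(nrow(ions))
  cl2 <- cluster_ions(ions[perm, ])
  expect_equal(sort(cl2$clusters$neutral_mass), sort(cl$clusters$neutral_mass))
})

test_that("unknown-charge ions pass through as unclustered singletons", {
  ions <- mk_ions(c(900, 900, 901), c(3, 0, 0))
  cl <- cluster_ions(ions)
  expect_equal(nrow(cl$clusters), 3)
  expect_equal(sum(cl$clusters$unclustered), 2)
})

test_that("exclude mode keeps the most intense redundant ion only", {
  M <- 2000
  ions <- mk_ions(mz_from_mass(M, c(2, 3)), c(2, 3), intensity = c(1e6, 5e6))
  cl <- cluster_ions(ions, mode = "exclude")
  expect_equal(nrow(cl$members), 1)
  expect_equal(cl$members$charge, 3)
})

test_that("the theoretical ladder spans the charge range in order", {
  lad <- theoretical_ladder(3690.489)
  expect_equal(nrow(lad), 8)
  expect_equal(lad$z, 2:9)
  expect_equal(lad$mz[1], (3690.489 + 2 * 1.00727646) / 2, tolerance = 1e-9)
  expect_true(all(diff(lad$mz) < 0))
  one <- theoretical_ladder(1000, 1, 1)
  expect_equal(one$mz, 1000 + 1.00727646)
  expect_error(theoretical_ladder(1000, 5, 2), "charge range")
})

test_that("toxin matching applies ppm tolerance and MS/MS gating", {
  toxins <- data.frame(id = "U1-TRTX-Agm3a",
                       sequence = "ACGSFMWKCSERLPCCQEYVCSPQWKWCQNP",
                       ss_bonds = 3, stringsAsFactors = FALSE)
  theo <- monoisotopic_mass(toxins$sequence, 3)
  near <- cluster_ions(mk_ions(mz_from_mass(theo * (1 - 2.4e-6), 4), 4))
  far <- cluster_ions(mk_ions(mz_from_mass(theo + 1, 4), 4))
  hit <- match_toxins(toxins, near)
  expect_true(hit$validated)
  expect_lt(abs(hit$best_ppm_error), 10)
  expect_false(match_toxins(toxins, far)$validated)
  # matched mass without MS/MS support is not validation
  toxins$msms_supported <- FALSE
  expect_false(match_toxins(toxins, near)$validated)
  expect_true(match_toxins(toxins, near, require_msms = FALSE)$validated)
})

test_that("only charges in the ladder range can trigger a match", {
  toxins <- data.frame(id = "t", sequence = "VPPILKY", ss_bonds = 0,
                       stringsAsFactors = FALSE)
  theo <- monoisotopic_mass("VPPILKY")
  singly <- cluster_ions(mk_ions(mz_from_mass(theo, 1), 1))
  expect_false(match_toxins(toxins, singly)$validated)
  expect_true(match_toxins(toxins, singly, z_min = 1)$validated)
})
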