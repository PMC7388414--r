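test_that("the generator is deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 5)
  t1 <- generate_toxins(cfg)
  t2 <- generate_toxins(cfg)
  expect_identical(t1, t2)
  expect_identical(simulate_evidence(t1, cfg), simulate_evidence(t2, cfg))
  expect_identical(simulate_ion_map(t1, cfg), simulate_ion_map(t2, cfg))
})

test_that("generated toxins respect the precursor architecture", {
  cfg <- synthetic_config(seed = 9)
  tr <- generate_toxins(cfg)
  expect_equal(nrow(tr), cfg$n_crp + cfg$n_short)
  # mature slice of the precursor equals the mature sequence
  expect_equal(substring(tr$precursor, tr$mature_start,
                         nchar(tr$precursor)), tr$mature)
  # propeptide ends with the Arg processing motif
  expect_true(all(substring(tr$precursor, tr$propeptide_end,
                            tr$propeptide_end) == "R"))
  expect_true(all(tr$true_mass[tr$is_crp] >= 3000 &
                    tr$true_mass[tr$is_crp] <= 9000))
  expect_true(all(tr$true_mass[!tr$is_crp] < 1500))
  expect_true(all(2 * tr$ss_bonds[tr$is_crp] ==
                    nchar(gsub("[^C]", "", tr$mature[tr$is_crp]))))
  only_short <- generate_toxins(synthetic_config(seed = 9, n_crp = 0))
  expect_true(all(!only_short$is_crp))
})

test_that("evidence coordinates are exact and dropout behaves at extremes", {
  cfg0 <- synthetic_config(seed = 2, dropout_prob = 0)
  tr <- generate_toxins(cfg0)
  ev <- simulate_evidence(tr, cfg0)
  expect_equal(ev$sequence,
               substring(tr$precursor[match(ev$parent_id, tr$id)],
                         ev$start, ev$end))
  # zero dropout: for every toxin and enzyme the fully specific 0-missed
  # peptides tile the whole mature sequence
  catalog <- enzyme_catalog()
  for (i in sample(nrow(tr), 3)) {
    for (enz in names(catalog)) {
      sub <- ev[ev$parent_id == tr$id[i] & ev$enzyme == enz, ]
      cov <- build_coverage(sub, tr$precursor[i])
      span <- cov$depth[tr$mature_start[i]:nchar(tr$precursor[i])]
      expect_true(all(span >= 1))
    }
  }
  ev1 <- simulate_evidence(tr, synthetic_config(seed = 2, dropout_prob = 1))
  expect_equal(nrow(ev1), 0)
})

test_that("ion maps honour jitter bounds and decoy offsets", {
  cfg <- synthetic_config(seed = 4, mz_jitter_ppm = 0, ions_per_toxin = 1)
  tr <- generate_toxins(cfg)
  im <- simulate_ion_map(tr, cfg)
  real <- im[!im$is_decoy, ]
  expect_equal(mass_from_mz(real$mz, real$charge),
               tr$true_mass[match(real$toxin_id, tr$id)], tolerance = 1e-9)
  cfg2 <- synthetic_config(seed = 4)
  im2 <- simulate_ion_map(tr, cfg2)
  real2 <- im2[!im2$is_decoy, ]
  ppm <- abs(mass_from_mz(real2$mz, real2$charge) -
               tr$true_mass[match(real2$toxin_id, tr$id)]) /
    tr$true_mass[match(real2$toxin_id, tr$id)] * 1e6
  expect_true(all(ppm <= cfg2$mz_jitter_ppm + 1e-6))
  decoys <- im2[im2$is_decoy & im2$charge > 0, ]
  dmass <- mass_from_mz(decoys$mz, decoys$charge)
  for (m in dmass) {
    expect_true(all(abs(m - tr$true_mass) / tr$true_mass * 1e6 >=
                      cfg2$decoy_min_offset_ppm))
  }
})

test_that("decoy-only ion maps validate nothing at 10 ppm", {
  cfg <- synthetic_config(seed = 6)
  tr <- generate_toxins(cfg)
  im <- simulate_ion_map(tr, cfg)
  decoy_cl <- cluster_ions(filter_ions(im[im$is_decoy, ]))
  toxins <- data.frame(id = tr$id, sequence = tr$mature,
                       ss_bonds = tr$ss_bonds, stringsAsFactors = FALSE)
  val <- match_toxins(toxins, decoy_cl)
  expect_equal(sum(val$validated), 0)
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(cys_count_range = c(6, 40),
                                crp_length_range = c(30, 62)), "infeasible")
  expect_error(synthetic_config(dropout_prob = 1.5))
})
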