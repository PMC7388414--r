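catalog <- enzyme_catalog()

test_that("the enzyme catalog holds the five aliquot enzymes", {
  expect_length(catalog, 5)
  expect_setequal(names(catalog), c("trypsin", "chymotrypsin", "glu-c",
                                    "asp-n", "thermolysin"))
  expect_equal(catalog$trypsin$side, "C")
  expect_setequal(catalog$trypsin$targets, c("K", "R"))
  expect_equal(catalog$`asp-n`$side, "N")
  expect_equal(catalog$`asp-n`$targets, "D")
  # phosphate-buffer Glu-C cleaves after both E and D; E-only selectable
  expect_setequal(catalog$`glu-c`$targets, c("E", "D"))
  expect_equal(enzyme_catalog(glu_c = "E")$`glu-c`$targets, "E")
})

test_that("cleavage sites follow specificity and proline blocking", {
  expect_equal(cleavage_sites("GRAAKAPK", catalog$trypsin), c(2L, 5L))
  expect_equal(cleavage_sites("AKPA", catalog$trypsin), integer(0))
  expect_equal(cleavage_sites("GGLGGFG", catalog$thermolysin), c(2L, 5L))
  expect_equal(cleavage_sites("AEADA", catalog$`glu-c`), c(2L, 4L))
  expect_equal(cleavage_sites("A", catalog$trypsin), integer(0))
})

test_that("fully specific digestion tiles the parent", {
  pep <- digest("GRAAKAPK", catalog$trypsin, 0, 0)
  expect_setequal(pep$sequence, c("GR", "AAK", "APK"))
  expect_equal(paste(pep$sequence[order(pep$start)], collapse = ""),
               "GRAAKAPK")
  pep1 <- digest("GRAAKAPK", catalog$trypsin, 1, 0)
  expect_true(all(c("GRAAK", "AAKAPK") %in% pep1$sequence))
  expect_setequal(digest("AEADA", catalog$`glu-c`, 0, 0)$sequence,
                  c("AE", "AD", "A"))
})

test_that("tiling and count laws hold on random sequences", {
  set.seed(31)
  for (i in 1:15) {
    s <- random_sequence(sample(5:30, 1))
    rule <- catalog[[sample(length(catalog), 1)]]
    pep <- digest(s, rule, 0, 0)
    expect_equal(paste(pep$sequence[order(pep$start)], collapse = ""), s)
    expect_equal(nrow(pep), length(cleavage_sites(s, rule)) + 1L)
    expect_equal(sum(nchar(pep$sequence)), nchar(s))
  }
})

test_that("peptide sets grow monotonically in missed and semi settings", {
  set.seed(47)
  key <- function(p) paste(p$start, p$end)
  for (i in 1:8) {
    s <- random_sequence(sample(8:25, 1))
    rule <- catalog[[sample(length(catalog), 1)]]
    prev <- character(0)
    for (mm in 0:2) {
      cur <- key(digest(s, rule, mm, 0))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
    expect_true(all(key(digest(s, rule, 2, 0)) %in%
                      key(digest(s, rule, 2, 1))))
  }
})

test_that("digest agrees with the brute-force substring oracle", {
  set.seed(101)
  for (i in 1:12) {
    s <- random_sequence(sample(5:30, 1))
    rule <- catalog[[sample(length(catalog), 1)]]
    mm <- sample(0:2, 1)
    ms <- sample(0:1, 1)
    got <- digest(s, rule, mm, ms)
    want <- oracle_digest(s, rule, mm, ms)
    got <- got[order(got$start, got$end), ]
    expect_equal(unname(cbind(got$start, got$end, got$missed_cleavages,
                              got$nonspecific_termini)),
                 unname(want), ignore_attr = TRUE)
    expect_equal(got$sequence, substring(s, want[, "start"], want[, "end"]))
  }
})

test_that("digest validates its inputs and applies report filters", {
  expect_error(digest("", catalog$trypsin), "non-empty")
  pep <- digest("GRAAKAPK", catalog$trypsin, 2, 1, length_range = c(4, 65))
  expect_true(all(nchar(pep$sequence) >= 4))
  pep <- digest("GRAAKAPK", catalog$trypsin, 0, 0, mass_range = c(250, 1e4))
  expect_true(all(vapply(pep$sequence, monoisotopic_mass, numeric(1)) >= 250))
})
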