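ev <- function(...) {
  rows <- list(...)
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      enzyme = character(), stringsAsFactors = FALSE))
  }
  data.frame(start = sapply(rows, `[[`, 1), end = sapply(rows, `[[`, 2),
             enzyme = sapply(rows, `[[`, 3), stringsAsFactors = FALSE)
}
parent9 <- "ACDEFGHIK"

test_that("coverage depth is an exact per-residue tally", {
  cov <- build_coverage(ev(list(1, 5, "trypsin"), list(4, 9, "glu-c")),
                        parent9)
  expect_equal(cov$depth, c(1, 1, 1, 2, 2, 1, 1, 1, 1))
  expect_equal(build_coverage(ev(), parent9)$depth, rep(0L, 9))
  # duplicates count twice in depth, once in enzyme support
  cov2 <- build_coverage(ev(list(1, 5, "trypsin"), list(1, 5, "trypsin")),
                         parent9)
  expect_equal(cov2$depth[1:5], rep(2L, 5))
  expect_equal(cov2$boundary_support[["1"]], "trypsin")
})

test_that("coverage depth conservation holds on random evidence", {
  set.seed(19)
  for (i in 1:10) {
    L <- sample(10:40, 1)
    parent <- random_sequence(L)
    n <- sample(1:30, 1)
    s <- sample(L, n, replace = TRUE)
    e <- pmin(L, s + sample(0:8, n, replace = TRUE))
    evd <- data.frame(start = s, end = e,
                      enzyme = sample(c("trypsin", "glu-c", "asp-n"), n,
                                      replace = TRUE))
    cov <- build_coverage(evd, parent)
    expect_equal(sum(cov$depth), sum(e - s + 1L))
  }
})

test_that("out-of-bounds evidence is rejected with its row", {
  expect_error(build_coverage(ev(list(1, 10, "trypsin")), parent9),
               "row\\(s\\) 1")
  expect_error(build_coverage(ev(list(5, 3, "trypsin")), parent9), "bounds")
})

test_that("consensus N-terminus needs distinct-enzyme agreement", {
  cov <- build_coverage(ev(list(3, 6, "trypsin"), list(3, 8, "glu-c"),
                           list(5, 9, "trypsin")), parent9)
  expect_equal(consensus_n_terminus(cov), 3L)
  cov1 <- build_coverage(ev(list(3, 6, "trypsin")), parent9)
  expect_true(is.na(consensus_n_terminus(cov1, min_enzymes = 2)))
  # the native (undigested) channel counts as an enzyme
  cov2 <- build_coverage(ev(list(1, 4, "asp-n"), list(1, 6, "thermolysin"),
                            list(1, 9, "native")), parent9)
  expect_equal(consensus_n_terminus(cov2), 1L)
})

test_that("consensus is invariant to row order and duplication", {
  rows <- list(list(3, 6, "trypsin"), list(3, 8, "glu-c"),
               list(5, 9, "asp-n"))
  set.seed(5)
  base <- consensus_n_terminus(build_coverage(do.call(ev, rows), parent9))
  for (i in 1:5) {
    shuffled <- rows[sample(length(rows))]
    doubled <- c(shuffled, shuffled)
    expect_equal(consensus_n_terminus(
      build_coverage(do.call(ev, doubled), parent9)), base)
  }
})

test_that("full sequencing requires overlap, not just abutment", {
  cov <- build_coverage(ev(list(1, 5, "trypsin"), list(4, 9, "glu-c")),
                        parent9)
  expect_true(is_fully_sequenced(cov, c(1, 9))$fully_sequenced)

  abut <- build_coverage(ev(list(1, 4, "trypsin"), list(5, 9, "glu-c")),
                         parent9)
  res <- is_fully_sequenced(abut, c(1, 9))
  expect_false(res$fully_sequenced)
  expect_equal(res$first_gap, 5L)

  gap <- build_coverage(ev(list(1, 5, "trypsin"), list(7, 9, "glu-c")),
                        parent9)
  res <- is_fully_sequenced(gap, c(1, 9))
  expect_false(res$fully_sequenced)
  expect_equal(res$first_gap, 6L)
  expect_error(is_fully_sequenced(cov, c(0, 9)), "outside")
})

test_that("maturation comparison reports delta and extension", {
  cmp <- compare_maturation(3, 1, "NREHCYIP")
  expect_equal(cmp$delta_residues, 2L)
  expect_equal(cmp$extension_sequence, "NR")
  cmp0 <- compare_maturation(4, 4, parent9)
  expect_equal(cmp0$delta_residues, 0L)
  expect_equal(cmp0$extension_sequence, "")
  expect_equal(compare_maturation(1, 4, parent9)$delta_residues, -3L)
})
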