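test_that("consecutive available pairs follow the gene's own availability", {
  p <- consecutive_available_pairs(c("blastula", "mid gastrula", "planula"))
  expect_equal(p$initial, c("blastula", "mid gastrula"))
  expect_equal(p$final, c("mid gastrula", "planula"))
  expect_equal(nrow(consecutive_available_pairs(stage_names())), 6)
  expect_error(consecutive_available_pairs("blastula"), "at least 2")
})

test_that("transition classification is exhaustive and mutually exclusive", {
  regions <- c("R1", "R2", "R3")
  subsets <- lapply(0:7, function(m) regions[as.logical(intToBits(m)[1:3])])
  for (ri in subsets) for (rf in subsets) {
    got <- classify_transition(ri, rf)
    expected <- if (length(ri) == 0 && length(rf) == 0) "none"
      else if (length(ri) == 0) "appeared"
      else if (length(rf) == 0) "vanished"
      else if (setequal(ri, rf)) "minor" else "major"
    expect_equal(got, expected)
  }
  expect_equal(classify_transition("R1", "R1"), "minor")
  expect_equal(classify_transition("R1", c("R1", "R2")), "major")
  expect_error(classify_transition("R9", "R1"), "regions")
})

test_that("pairwise matrices match a hand tally on a small table", {
  tab <- domain_table(data.frame(
    gene = c("g1", "g1", "g1",          # R1 -> R1 -> R1,R2
             "g2", "g2",                # R2 -> R3
             "g3", "g3",                # R1 -> (empty)
             "g4", "g4",                # (empty) -> R2
             "g5", "g5"),               # R1,R2 -> R1,R2 (multi-region start)
    stage = c("blastula", "early gastrula", "mid gastrula",
              "blastula", "late gastrula",
              "early gastrula", "planula",
              "blastula", "planula",
              "blastula", "early gastrula"),
    domains = c("Cd", "pEn", "En;OrEc",
                "Cr", "AbEc",
                "pEn", "",
                "", "OrEc",
                "Cd;Er", "pEn;bEc")))
  all5 <- build_pairwise_matrix(tab, filter = "all")
  expect_equal(sum(all5), 6L)
  expect_equal(all5["blastula", "early gastrula", "minor"], 2L)  # g1, g5
  expect_equal(all5["early gastrula", "mid gastrula", "major"], 1L)
  expect_equal(all5["blastula", "late gastrula", "major"], 1L)
  expect_equal(all5["early gastrula", "planula", "vanished"], 1L)
  expect_equal(all5["blastula", "planula", "appeared"], 1L)

  r1 <- build_pairwise_matrix(tab, filter = "R1")
  expect_equal(sum(r1), 3L)  # g1's two pairs and g3's vanish start exactly {R1}
  expect_equal(r1["blastula", "early gastrula", "minor"], 1L)
  expect_equal(r1["early gastrula", "mid gastrula", "major"], 1L)
  expect_equal(r1["early gastrula", "planula", "vanished"], 1L)
  # multi-region starts are excluded from every region filter
  r2 <- build_pairwise_matrix(tab, filter = "R2")
  expect_equal(sum(r2), 1L)  # g2 only
})

test_that("unmapped-only stages are skipped with a warning", {
  tab <- domain_table(data.frame(
    gene = c("g1", "g1", "g2", "g2"),
    stage = c("blastula", "early gastrula", "blastula", "early gastrula"),
    domains = c("AnHe", "pEn", "Cd", "pEn")))
  expect_warning(m <- build_pairwise_matrix(tab, filter = "all"), "unmapped")
  expect_equal(sum(m), 1L)  # only g2 counted
})

test_that("empty tables aggregate to all-zero summaries", {
  empty <- domain_table(data.frame(gene = character(0), stage = character(0),
                                   domains = character(0)))
  m <- build_pairwise_matrix(empty, filter = "all")
  expect_equal(sum(m), 0L)
  s <- aggregate_periods(m)
  expect_true(all(s$counts == 0))
  expect_true(all(s$percentages == 0))
})

test_that("period aggregation conserves count x span", {
  ref <- nv_reference_counts()
  for (m in ref) {
    s <- aggregate_periods(m)
    span_total <- 0
    for (i in 1:6) for (f in (i + 1):7) {
      span_total <- span_total + sum(m[i, f, ]) * (f - i)
    }
    expect_equal(sum(s$counts), span_total)
  }
})

test_that("integer percentages round ties away from zero", {
  expect_equal(percent_tuple(c(9, 4, 0)), c(69L, 31L, 0L))
  expect_equal(percent_tuple(c(0, 0, 0)), c(0L, 0L, 0L))
  expect_equal(percent_tuple(c(1, 1, 1)), c(33L, 33L, 33L))
  expect_equal(percent_tuple(c(1, 7)), c(13L, 88L))  # 12.5 rounds up
  expect_error(percent_tuple(c(-1, 2)), "nonnegative")
})

test_that("change rates sum selected category percentages per period", {
  s <- aggregate_periods(nv_reference_counts()$all)
  rate <- period_change_rate(s, c("major", "appeared"))
  expect_equal(unname(rate[2:4]), c(45L, 48L, 55L))
  expect_equal(unname(rate[5:6]), c(37L, 25L))
  expect_equal(unname(period_change_rate(s, character(0))), rep(0L, 6))
  expect_error(period_change_rate(s, "sideways"), "unknown")
})

test_that("Fisher two-tail handles trivial and hand-enumerated tables", {
  expect_equal(fisher_exact_two_tail(1, 1, 1, 1), 1)
  expect_equal(fisher_exact_two_tail(3, 1, 1, 3), 34 / 70)
  expect_equal(fisher_exact_two_tail(0, 0, 5, 7), 1)  # zero margin
  expect_equal(fisher_exact_two_tail(4, 0, 6, 0), 1)
  expect_error(fisher_exact_two_tail(-1, 1, 1, 1), "nonnegative")
})

test_that("Fisher two-tail matches stats::fisher.test on random tables", {
  set.seed(7)
  for (i in 1:200) {
    cells <- as.integer(rpois(4, 6))
    got <- fisher_exact_two_tail(cells[1], cells[2], cells[3], cells[4])
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("kernel parameters are recovered from synthetic tables", {
  sim <- generate_domain_table(400,
                               kernel = transition_kernel(minor = 0.7,
                                                          major = 0.3),
                               seed = 13)
  m <- build_pairwise_matrix(sim$table, filter = "all")
  tot <- colSums(aggregate_periods(m)$counts)
  pct <- 100 * tot / sum(tot)
  expect_lt(abs(pct[["minor"]] - 70), 5)
  expect_lt(abs(pct[["major"]] - 30), 5)
})
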