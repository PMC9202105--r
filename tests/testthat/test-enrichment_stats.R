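test_that("two-sided Fisher p matches exhaustive enumeration", {
  expect_equal(fisher_exact_two_sided(rbind(c(3, 1), c(1, 3))), 34 / 70,
               tolerance = 1e-12)
  # degenerate margin: only one table possible
  expect_equal(fisher_exact_two_sided(rbind(c(0, 5), c(0, 7))), 1)
  expect_error(fisher_exact_two_sided(rbind(c(-1, 2), c(3, 4))), "negative")

  set.seed(202)
  for (rep in 1:40) {
    tot <- sample(20:1000, 1)
    cells <- as.vector(stats::rmultinom(1, tot, runif(4, 0.05, 1)))
    tab <- matrix(cells, 2, 2)
    p <- fisher_exact_two_sided(tab)
    expect_equal(p, fisher_enum(tab), tolerance = 1e-12)
    # cross-check against the reference implementation
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher p is invariant under transposition and row/column swaps", {
  set.seed(57)
  for (rep in 1:10) {
    tab <- matrix(sample(0:40, 4, replace = TRUE), 2, 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_two_sided(tab)
    expect_equal(fisher_exact_two_sided(t(tab)), p, tolerance = 1e-12)
    expect_equal(fisher_exact_two_sided(tab[2:1, 2:1]), p, tolerance = 1e-12)
    expect_lte(p, 1)
  }
})

test_that("label enrichment builds the disjoint table and calls direction", {
  all_p <- sprintf("y%04d", 1:6681)
  novel <- all_p[1:139]
  labeled <- c(all_p[1:28], all_p[140:993])   # 28 of the novel + 854 others
  res <- label_enrichment(novel, all_p, labeled)
  expect_equal(unname(res$table), rbind(c(28, 111), c(854, 5688)))
  expect_lt(res$p_two_sided, 0.05)
  expect_equal(res$direction, "enriched")
  expect_equal(res$odds_ratio, (28 * 5688) / (111 * 854))

  td <- tidy(res)
  expect_equal(td$p.value, res$p_two_sided)
  expect_equal(glance(res)$n_total, 6681)

  # novel = labeled = all: degenerate, p = 1, no direction
  u <- letters[1:5]
  res0 <- label_enrichment(u, u, u)
  expect_equal(res0$p_two_sided, 1)
  expect_equal(res0$direction, "none")

  expect_error(label_enrichment(c("a", "zz"), u, u), "subset")
})

test_that("null rejection rate agrees with exact enumeration", {
  # exact type-I error at alpha = 0.05 for the study margins, by enumeration
  N <- 6681; K <- 882; n <- 139
  a <- 0:60  # beyond 60 the null mass is negligible (< 1e-12)
  pvals <- vapply(a, function(x) {
    fisher_exact_two_sided(rbind(c(x, n - x), c(K - x, N - K - n + x)))
  }, numeric(1))
  dens <- stats::dhyper(a, K, N - K, n)
  exact_rate <- sum(dens[pvals <= 0.05])
  expect_lte(exact_rate, 0.05)  # exact test is never anti-conservative
  expect_gt(exact_rate, 0.01)   # and not vacuously conservative here

  # Monte-Carlo draws from the permutation null land inside the binomial CI
  # around the enumerated rate
  set.seed(909)
  n_sim <- 400
  draws <- stats::rhyper(n_sim, K, N - K, n)
  mc_rate <- mean(pvals[match(draws, a)] <= 0.05)
  se <- sqrt(exact_rate * (1 - exact_rate) / n_sim)
  expect_lt(abs(mc_rate - exact_rate), 3.5 * se + 1e-9)
})

test_that("percentages round half up at the requested precision", {
  expect_equal(percent_summary(28, 139), 20)
  expect_equal(percent_summary(16, 28), 57)
  expect_equal(percent_summary(20, 41), 49)
  expect_equal(percent_summary(0, 10), 0)
  expect_equal(percent_summary(1, 8), 13)            # 12.5 rounds up
  expect_equal(percent_summary(1, 8, "one_decimal"), 12.5)
  expect_error(percent_summary(1, 0), "positive")
})

test_that("term enrichment: EASE is conservative, overlap one is null", {
  bg <- sprintf("p%03d", 1:100)
  fg <- bg[1:5]
  tm <- tibble::tibble(protein_id = bg[1:5], label = "hit")

  f <- term_enrichment(fg, bg, tm, mode = "fisher", adjust = FALSE)
  e <- term_enrichment(fg, bg, tm, mode = "ease", adjust = FALSE)
  expect_gt(e$p, f$p)
  # enumeration oracle: P(X >= k) for X ~ Hypergeom(5 of 100, 5 drawn)
  enum_tail <- function(k) {
    ks <- k:5
    sum(exp(lchoose(5, ks) + lchoose(95, 5 - ks) - lchoose(100, 5)))
  }
  expect_equal(f$p, enum_tail(5), tolerance = 1e-12)
  expect_equal(e$p, enum_tail(4), tolerance = 1e-12)

  # a term covering the whole background is uninformative
  tm_all <- tibble::tibble(protein_id = bg, label = "everything")
  expect_equal(term_enrichment(fg, bg, tm_all, adjust = FALSE)$p, 1)

  # EASE decrements the overlap: a single-protein overlap scores p = 1
  tm1 <- tibble::tibble(protein_id = bg[1], label = "solo")
  expect_equal(term_enrichment(fg, bg, tm1, mode = "ease", adjust = FALSE)$p, 1)

  # terms with no background representation are skipped with a warning
  tm_out <- tibble::tibble(protein_id = "foreign", label = "ghost")
  expect_warning(out <- term_enrichment(fg, bg, tm_out), "skipped")
  expect_equal(nrow(out), 0)

  expect_error(term_enrichment(c(fg, "foreign"), bg, tm), "subset")
})

test_that("significance flag follows the cutoff", {
  bg <- sprintf("p%03d", 1:100)
  fg <- bg[1:10]
  tm <- tibble::tibble(protein_id = c(bg[1:6], bg[50:80]),
                       label = rep(c("good", "noise"), c(6, 31)))
  out <- term_enrichment(fg, bg, tm, mode = "fisher", cutoff = 0.1)
  expect_true(out$significant[out$term == "good"])
  expect_equal(out$term[1], "good")  # sorted by p
})
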