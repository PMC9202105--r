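test_that("group presence fractions count species straight from the matrix", {
  tax <- toy_taxonomy(n_per = c(A = 4, B = 6), n_out = 0)
  mat <- matrix(FALSE, 2, 10, dimnames = list(NULL, tax$species_id))
  mat[1, c("A1", "A2", "A3", "A4")] <- TRUE
  mat[1, c("B1", "B2", "B3")] <- TRUE
  mat[2, c("A1", "A2")] <- TRUE
  pa <- make_pa(mat)
  expect_equal(group_presence_fraction(pa, tax, "OG001", "A"), 1)
  expect_equal(group_presence_fraction(pa, tax, "OG001", "B"), 0.5)
  expect_equal(group_presence_fraction(pa, tax, "OG002", "A"), 0.5)
  expect_error(group_presence_fraction(pa, tax, "OG001", "Z"), "no sampled species")
})

test_that("the node rule is inclusive at 50% and tolerates one outside presence", {
  tax <- toy_taxonomy(n_per = c(A = 4, B = 4), n_out = 3)
  lad <- clade_ladder(tibble::tibble(node = c("root", "tipA"),
                                     phyla = list(c("A", "B"), "A"),
                                     terminal = c(FALSE, FALSE)))
  base <- matrix(FALSE, 1, 11, dimnames = list(NULL, tax$species_id))
  base[1, c("A1", "A2", "B1", "B2", "B3")] <- TRUE   # A 2/4, B 3/4

  r0 <- is_novel_at_node(make_pa(base), tax, lad, "OG001", "root")
  expect_true(r0$qualifies)
  expect_equal(unname(r0$per_group_fraction), c(0.5, 0.75))
  expect_equal(r0$outgroup_present_count, 0L)

  one_out <- base; one_out[1, "OUT1"] <- TRUE
  expect_true(is_novel_at_node(make_pa(one_out), tax, lad, "OG001", "root")$qualifies)

  two_out <- one_out; two_out[1, "OUT2"] <- TRUE
  expect_false(is_novel_at_node(make_pa(two_out), tax, lad, "OG001", "root")$qualifies)

  # at the inner node, non-member fungi count as outgroup too
  r_tip <- is_novel_at_node(make_pa(base), tax, lad, "OG001", "tipA")
  expect_equal(r_tip$outgroup_present_count, 3L)
  expect_false(r_tip$qualifies)
})

test_that("origin assignment matches the brute-force rule evaluator", {
  tax <- toy_taxonomy(n_per = c(A = 4, B = 4, C = 4), n_out = 3)
  lad <- toy_ladder()
  set.seed(101)
  for (rep in 1:5) {
    pa <- random_pa(40, tax$species_id, p = runif(1, 0.2, 0.6))
    calls <- assign_origin(pa, tax, lad)
    expect_equal(calls$origin_node, brute_assign(pa, tax, lad))
  }
})

test_that("clade-restricted orthogroups map to their node, ubiquitous ones do not", {
  tax <- toy_taxonomy(n_per = c(A = 4, B = 4, C = 4), n_out = 3)
  lad <- toy_ladder()
  mat <- matrix(FALSE, 3, 15, dimnames = list(NULL, tax$species_id))
  # OG1: >=50% of B and C, absent in A and outgroup -> N2
  mat[1, c("B1", "B2", "C1", "C2", "C3")] <- TRUE
  # OG2: present everywhere including all outgroups -> unassigned
  mat[2, ] <- TRUE
  # OG3: single species of C -> unassigned at cutoff 0.5
  mat[3, "C1"] <- TRUE
  pa <- make_pa(mat)
  calls <- assign_origin(pa, tax, lad)
  expect_equal(calls$origin_node, c("N2", "unassigned", "unassigned"))

  # monotonicity in cutoff: the singleton is recovered at cutoff 0.1
  calls_low <- assign_origin(pa, tax, lad, cutoff = 0.1)
  expect_equal(calls_low$origin_node[3], "N3")
})

test_that("terminal nodes are evaluated per subphylum", {
  tax <- toy_taxonomy(n_per = c(A = 4, B = 4), n_out = 2, subphyla = "B")
  lad <- clade_ladder(tibble::tibble(node = c("root", "B"),
                                     phyla = list(c("A", "B"), "B"),
                                     terminal = c(FALSE, TRUE)))
  # B species alternate subphyla X,Y: B1,B3 in X; B2,B4 in Y
  mat <- matrix(FALSE, 2, 10, dimnames = list(NULL, tax$species_id))
  mat[1, c("B1", "B3")] <- TRUE            # all of X, none of Y
  mat[2, c("B1", "B2")] <- TRUE            # half of X, half of Y
  calls <- assign_origin(make_pa(mat), tax, lad)
  expect_equal(calls$origin_node, c("unassigned", "B"))
})

test_that("validation demotes candidates at the hit threshold, keeps audit trail", {
  calls <- tibble::tibble(
    orthogroup_id = c("OG1", "OG2", "OG3", "OG4", "OG5"),
    origin_node = c("N1", "N1", "N2", "unassigned", "N2"),
    validated = NA,
    outgroup_present_count = 0L
  )
  hits <- tibble::tibble(
    orthogroup_id = c("OG1", "OG2", "OG3"),
    n_nonfungal_eukaryote_organisms = c(9L, 10L, 0L)
  )
  expect_warning(out <- validate_calls(calls, hits), "pending")
  expect_equal(out$validated[1:3], c(TRUE, FALSE, TRUE))
  expect_equal(out$origin_node[2], "unassigned")
  expect_equal(out$candidate_node[2], "N1")
  expect_true(is.na(out$validated[5]))           # no hit count -> pending
  expect_equal(out$origin_node[5], "N2")
  strict <- suppressWarnings(validate_calls(calls, hits, strict = TRUE))
  expect_false(strict$validated[5])
  expect_equal(strict$origin_node[5], "unassigned")
})

test_that("core flags require half of all descendants of the origin node", {
  tax <- toy_taxonomy(n_per = c(A = 4, B = 6), n_out = 2)
  lad <- clade_ladder(tibble::tibble(node = "root", phyla = list(c("A", "B")),
                                     terminal = FALSE))
  mat <- matrix(FALSE, 3, 12, dimnames = list(NULL, tax$species_id))
  mat[1, c("A1", "A2", "B1", "B2", "B3")] <- TRUE      # 5/10 -> core
  mat[2, tax$species_id[tax$role == "ingroup"]] <- TRUE  # 10/10 -> core
  mat[3, c("A1", "A2", "B1", "B2")] <- TRUE            # 4/10 -> not core
  pa <- make_pa(mat)
  # a permissive assignment cutoff lets OG3 in; the core flag still uses 0.5
  calls <- assign_origin(pa, tax, lad, cutoff = 0.3)
  expect_equal(calls$origin_node, rep("root", 3))
  flags <- core_orthogroup_flags(pa, tax, lad, calls)
  expect_equal(flags$core, c(TRUE, TRUE, FALSE))
})

test_that("calls are invariant to species relabeling and row shuffles", {
  tax <- toy_taxonomy()
  lad <- toy_ladder()
  set.seed(77)
  pa <- random_pa(30, tax$species_id, p = 0.4)
  ref <- assign_origin(pa, tax, lad)

  shuffle <- sample(nrow(pa))
  out <- assign_origin(pa[shuffle, ], tax, lad)
  expect_equal(out$origin_node[order(out$orthogroup_id)],
               ref$origin_node[order(ref$orthogroup_id)])

  new_names <- stats::setNames(sprintf("sp_%02d", seq_len(nrow(tax))), tax$species_id)
  tax2 <- tax
  tax2$species_id <- unname(new_names[tax$species_id])
  pa2 <- pa
  names(pa2)[-1] <- unname(new_names[names(pa)[-1]])
  expect_equal(assign_origin(pa2, tax2, lad)$origin_node, ref$origin_node)
})

test_that("assignment counts are monotone in cutoff and outgroup tolerance", {
  tax <- toy_taxonomy()
  lad <- toy_ladder()
  set.seed(31)
  for (rep in 1:3) {
    pa <- random_pa(60, tax$species_id, p = runif(1, 0.25, 0.55))
    n_assigned <- function(cutoff, tol) {
      sum(assign_origin(pa, tax, lad, cutoff = cutoff,
                        outgroup_tolerance = tol)$origin_node != "unassigned")
    }
    by_cutoff <- vapply(c(0.25, 0.5, 0.75, 1), n_assigned, 1, tol = 1)
    expect_true(all(diff(by_cutoff) <= 0))
    by_tol <- vapply(0:3, function(t) n_assigned(0.5, t), 1)
    expect_true(all(diff(by_tol) >= 0))
  }
})
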