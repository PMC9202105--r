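# Shared fixtures and independent oracles. The oracles re-derive results
# straight from the definitions (explicit loops, lchoose arithmetic) and share
# no code with the package internals they check.

toy_taxonomy <- function(n_per = c(A = 4, B = 4, C = 4), n_out = 3,
                         subphyla = character()) {
  rows <- lapply(names(n_per), function(ph) {
    n <- n_per[[ph]]
    sub <- if (ph %in% subphyla) {
      paste0(ph, "_sub", rep_len(c("X", "Y"), n))
    } else rep("", n)
    tibble::tibble(species_id = sprintf("%s%d", ph, seq_len(n)),
                   phylum = ph, subphylum = sub, role = "ingroup")
  })
  out <- dplyr::bind_rows(rows)
  if (n_out > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      species_id = sprintf("OUT%d", seq_len(n_out)),
      phylum = "outgrp", subphylum = "", role = "outgroup_eukaryote"))
  }
  out
}

toy_ladder <- function() {
  clade_ladder(tibble::tibble(
    node = c("N1", "N2", "N3"),
    phyla = list(c("A", "B", "C"), c("B", "C"), "C"),
    terminal = c(FALSE, FALSE, FALSE)
  ))
}

# presence-absence tibble from a logical/integer matrix with species colnames
make_pa <- function(mat, og_ids = sprintf("OG%03d", seq_len(nrow(mat)))) {
  dplyr::bind_cols(tibble::tibble(orthogroup_id = og_ids),
                   tibble::as_tibble(as.data.frame(mat)))
}

random_pa <- function(n_og, species, p = 0.3) {
  mat <- matrix(stats::runif(n_og * length(species)) < p, n_og, length(species),
                dimnames = list(NULL, species))
  make_pa(mat)
}

# Brute-force origin assignment straight from the rule definition: for every
# orthogroup walk the ladder root-to-tip, recompute every group fraction and
# the outside-clade census with explicit loops, assign the first hit.
brute_assign <- function(pa, tax, ladder, cutoff = 0.5, tol = 1) {
  m <- as.matrix(pa[setdiff(names(pa), "orthogroup_id")]) >= 1
  res <- character(nrow(m))
  for (r in seq_len(nrow(m))) {
    assigned <- "unassigned"
    for (i in seq_len(nrow(ladder))) {
      phyla <- ladder$phyla[[i]]
      groups <- if (ladder$terminal[i]) {
        unique(tax$subphylum[tax$role == "ingroup" & tax$phylum %in% phyla &
                               tax$subphylum != ""])
      } else phyla
      ok <- TRUE
      for (g in groups) {
        gsp <- tax$species_id[tax$role == "ingroup" &
                                (tax$phylum == g | tax$subphylum == g)]
        if (sum(m[r, gsp]) / length(gsp) < cutoff) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        member <- tax$species_id[tax$role == "ingroup" & tax$phylum %in% phyla]
        outside <- setdiff(colnames(m), member)
        if (length(outside) > 0 && sum(m[r, outside]) > tol) ok <- FALSE
      }
      if (ok) {
        assigned <- ladder$node[i]
        break
      }
    }
    res[r] <- assigned
  }
  res
}

# Exhaustive hypergeometric enumeration of the two-sided Fisher p, via
# lchoose arithmetic (no dhyper).
fisher_enum <- function(tab) {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ])
  n1 <- sum(tab[, 1])
  N <- sum(tab)
  ks <- max(0, m1 + n1 - N):min(m1, n1)
  lp <- lchoose(n1, ks) + lchoose(N - n1, m1 - ks) - lchoose(N, m1)
  lobs <- lchoose(n1, a) + lchoose(N - n1, m1 - a) - lchoose(N, m1)
  sum(exp(lp[lp <= lobs + log1p(1e-7)]))
}
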