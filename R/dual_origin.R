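#' Classify species by joint presence of a prokaryote- and a
#' eukaryote-derived orthogroup
#'
#' For an enzyme encoded by two distinct orthogroups of different phylogenetic
#' origin (e.g. the two dihydroorotate dehydrogenase families, one acquired
#' horizontally from prokaryotes and one vertically inherited), each species
#' falls into one of four categories from its two presence flags: `both`,
#' `prokaryotic_only`, `eukaryotic_only` or `neither`. Which orthogroup is the
#' prokaryote-derived one is caller-supplied knowledge (established upstream
#' by homology searches and gene trees), not inferred here. Paralogs within an
#' orthogroup do not change the category: presence means at least one copy.
#'
#' @param pa Presence-absence (or count) tibble.
#' @param og_prok Orthogroup id of the prokaryote-derived family.
#' @param og_euk Orthogroup id of the eukaryote-derived family.
#' @return A tibble with columns `species_id`, `prokaryotic` (logical),
#'   `eukaryotic` (logical), `category` (factor with the four levels).
#' @export
classify_dual_origin <- function(pa, og_prok, og_euk) {
  stopifnot(is.data.frame(pa), "orthogroup_id" %in% names(pa))
  for (og in c(og_prok, og_euk)) {
    if (!og %in% pa$orthogroup_id) stop("unknown orthogroup id: ", og, call. = FALSE)
  }
  sp <- setdiff(names(pa), "orthogroup_id")
  p <- as.logical(unlist(pa[pa$orthogroup_id == og_prok, sp]) >= 1)
  e <- as.logical(unlist(pa[pa$orthogroup_id == og_euk, sp]) >= 1)
  tibble::tibble(
    species_id = sp,
    prokaryotic = p,
    eukaryotic = e,
    category = factor(
      dplyr::case_when(
        p & e ~ "both",
        p & !e ~ "prokaryotic_only",
        !p & e ~ "eukaryotic_only",
        TRUE ~ "neither"
      ),
      levels = c("both", "prokaryotic_only", "eukaryotic_only", "neither")
    )
  )
}

#' Summarize dual-origin categories by phylum
#'
#' Tabulates the four categories per phylum plus overall totals. The
#' `prokaryotic_only` census is the replacement count (species where the
#' horizontally acquired copy has displaced the eukaryotic one), `both` is
#' coexistence, and `neither` is full loss of the function's gene family pair.
#'
#' @param profiles Output of [classify_dual_origin()].
#' @param taxonomy Taxonomy tibble covering every profiled species.
#' @return An object of class `dual_origin_summary`: list with `by_phylum`
#'   (tibble phylum x category counts plus `n_species`), `totals` (named
#'   counts), `replacement_count`, `coexistence_count`, `full_loss_count`.
#' @export
summarize_dual_origin <- function(profiles, taxonomy) {
  missing_sp <- setdiff(profiles$species_id, taxonomy$species_id)
  if (length(missing_sp) > 0) {
    stop("species missing from taxonomy: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  joined <- dplyr::left_join(profiles,
                             taxonomy[c("species_id", "phylum")],
                             by = "species_id")
  by_phylum <- joined |>
    dplyr::count(.data$phylum, .data$category, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L) |>
    dplyr::mutate(n_species = .data$both + .data$prokaryotic_only +
                    .data$eukaryotic_only + .data$neither)
  totals <- vapply(c("both", "prokaryotic_only", "eukaryotic_only", "neither"),
                   function(cat) sum(profiles$category == cat), integer(1))
  structure(
    list(
      by_phylum = by_phylum,
      totals = totals,
      replacement_count = unname(totals["prokaryotic_only"]),
      coexistence_count = unname(totals["both"]),
      full_loss_count = unname(totals["neither"])
    ),
    class = "dual_origin_summary"
  )
}

#' @export
print.dual_origin_summary <- function(x, ...) {
  cat("<dual_origin_summary>\n")
  print(x$by_phylum)
  cat(sprintf("replacement (prokaryotic only): %d | coexistence (both): %d | full loss: %d\n",
              x$replacement_count, x$coexistence_count, x$full_loss_count))
  invisible(x)
}

#' @export
tidy.dual_origin_summary <- function(x, ...) {
  tidyr::pivot_longer(x$by_phylum,
                      cols = c("both", "prokaryotic_only",
                               "eukaryotic_only", "neither"),
                      names_to = "category", values_to = "n")
}

#' @export
glance.dual_origin_summary <- function(x, ...) {
  tibble::tibble(
    n_species = sum(x$by_phylum$n_species),
    replacement_count = x$replacement_count,
    coexistence_count = x$coexistence_count,
    full_loss_count = x$full_loss_count
  )
}
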