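#' Read an orthogroup gene-count table
#'
#' Reads a TSV in the layout produced by orthology-clustering pipelines
#' (`Orthogroups.GeneCount.tsv`): the first column is the orthogroup id, the
#' remaining columns are per-species gene counts. In the `"orthofinder"`
#' dialect a trailing `Total` column may be present; it is dropped.
#'
#' @param path Path to a TSV file.
#' @param dialect `"orthofinder"` (default; drops a `Total` column if present)
#'   or `"plain"` (all columns after the first are species).
#' @return A tibble with column `orthogroup_id` followed by one integer column
#'   per species.
#' @export
read_gene_counts <- function(path, dialect = c("orthofinder", "plain")) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) stop("gene-count table needs an orthogroup column and at least one species", call. = FALSE)
  names(raw)[1] <- "orthogroup_id"
  if (dialect == "orthofinder" && names(raw)[ncol(raw)] == "Total") {
    raw <- raw[, -ncol(raw), drop = FALSE]
  }
  if (anyDuplicated(raw$orthogroup_id)) {
    dup <- unique(raw$orthogroup_id[duplicated(raw$orthogroup_id)])
    stop("duplicate orthogroup id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  for (col in names(raw)[-1]) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(is.na(v) | v < 0 | raw[[col]] != as.character(v))
    if (length(bad) > 0) {
      stop("column '", col, "': cannot parse count '", raw[[col]][bad[1]],
           "' at data line ", bad[1], " (counts must be non-negative integers)",
           call. = FALSE)
    }
    raw[[col]] <- v
  }
  raw
}

#' Binarize a gene-count table into presence-absence
#'
#' Copy-number variation is deliberately ignored downstream: presence means at
#' least one gene copy in the species, whatever the copy number.
#'
#' @param counts A gene-count tibble from [read_gene_counts()] or
#'   [simulate_presence()].
#' @return A tibble of the same shape with logical presence flags.
#' @export
binarize <- function(counts) {
  stopifnot(is.data.frame(counts), "orthogroup_id" %in% names(counts))
  out <- tibble::as_tibble(counts)
  for (col in names(out)[-1]) {
    if (!is.numeric(out[[col]]) && !is.logical(out[[col]])) {
      stop("non-numeric count column: ", col, call. = FALSE)
    }
    out[[col]] <- out[[col]] >= 1
  }
  out
}

#' Filter genomes on assembly quality and publication status
#'
#' Keeps species whose BUSCO completeness is strictly greater than
#' `busco_min` and whose genome is published. Both criteria mirror standard
#' genome-selection practice for comparative datasets.
#'
#' @param meta A data frame with columns `species_id`, `busco_completeness`
#'   (percentage in \[0, 100\]) and `published` (logical).
#' @param busco_min Completeness threshold in percent; strictly-greater-than
#'   comparison. Default 90.
#' @return Character vector of retained species ids (sorted).
#' @export
filter_genomes <- function(meta, busco_min = 90) {
  stopifnot(is.data.frame(meta),
            all(c("species_id", "busco_completeness", "published") %in% names(meta)))
  if (busco_min < 0 || busco_min > 100) stop("busco_min must be in [0, 100]", call. = FALSE)
  if (any(meta$busco_completeness < 0 | meta$busco_completeness > 100)) {
    stop("busco_completeness values must lie in [0, 100]", call. = FALSE)
  }
  keep <- meta$species_id[meta$busco_completeness > busco_min & meta$published]
  if (length(keep) == 0) warning("no genomes pass the filter", call. = FALSE)
  sort(keep)
}

#' Read a species taxonomy table
#'
#' TSV with columns `species_id`, `phylum`, `subphylum`, `role`. `role` must be
#' `ingroup` or `outgroup_eukaryote`. Subphylum may be empty except for species
#' of terminal phyla (checked later by [validate_ladder()]).
#'
#' @param path Path to a TSV file.
#' @return A tibble with the four columns; empty subphylum is `""`.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  req <- c("species_id", "phylum", "subphylum", "role")
  if (!all(req %in% names(tax))) {
    stop("taxonomy must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  tax <- tax[req]
  tax$subphylum[is.na(tax$subphylum)] <- ""
  validate_taxonomy(tax)
}

validate_taxonomy <- function(tax) {
  if (anyDuplicated(tax$species_id)) {
    dup <- unique(tax$species_id[duplicated(tax$species_id)])
    stop("duplicate species id(s) in taxonomy: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(tax$role), c("ingroup", "outgroup_eukaryote"))
  if (length(bad_role) > 0) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "),
         " (expected 'ingroup' or 'outgroup_eukaryote')", call. = FALSE)
  }
  no_phylum <- tax$species_id[tax$role == "ingroup" &
                                (is.na(tax$phylum) | tax$phylum == "")]
  if (length(no_phylum) > 0) {
    stop("ingroup species without a phylum: ", paste(no_phylum, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(tax)
}

#' Check that matrix species and taxonomy agree
#'
#' Species matching is exact and case-sensitive; any species present in the
#' presence-absence matrix but missing from the taxonomy is a hard error
#' (silent dropping would hide taxon-sampling bugs).
#'
#' @param pa Presence-absence (or count) tibble, species in columns 2..n.
#' @param taxonomy Taxonomy tibble.
#' @return Invisibly, the character vector of matrix species.
#' @export
check_species_match <- function(pa, taxonomy) {
  sp <- setdiff(names(pa), "orthogroup_id")
  missing_sp <- setdiff(sp, taxonomy$species_id)
  if (length(missing_sp) > 0) {
    stop("species in matrix missing from taxonomy: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  invisible(sp)
}

#' Read a protein-protein interaction edge list
#'
#' TSV with columns `protein_a`, `protein_b`, `score` (in \[0, 1\]).
#' Self-loops are dropped with a warning; a pair listed in both orders
#' collapses to a single undirected edge (the larger score is kept).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `protein_a`, `protein_b`, `score`, with
#'   `protein_a < protein_b` lexicographically.
#' @export
read_edge_list <- function(path) {
  ed <- readr::read_tsv(path, col_types = readr::cols(
    protein_a = readr::col_character(),
    protein_b = readr::col_character(),
    score = readr::col_double()
  ), progress = FALSE)
  normalize_edges(ed)
}

normalize_edges <- function(ed) {
  stopifnot(all(c("protein_a", "protein_b", "score") %in% names(ed)))
  if (any(ed$score < 0 | ed$score > 1, na.rm = TRUE)) {
    stop("edge scores must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(ed) == 0) {
    return(tibble::tibble(protein_a = character(), protein_b = character(),
                          score = numeric()))
  }
  loops <- ed$protein_a == ed$protein_b
  if (any(loops)) {
    warning(sum(loops), " self-loop edge(s) dropped", call. = FALSE)
    ed <- ed[!loops, , drop = FALSE]
  }
  a <- pmin(ed$protein_a, ed$protein_b)
  b <- pmax(ed$protein_a, ed$protein_b)
  ed$protein_a <- a
  ed$protein_b <- b
  ed |>
    dplyr::group_by(.data$protein_a, .data$protein_b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop") |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
}

#' Read a protein annotation table
#'
#' TSV with columns `protein_id`, `label`; one row per (protein, label) pair.
#' The long format is kept: a protein may carry any number of labels.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `protein_id`, `label`, duplicates removed.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    label = readr::col_character()
  ), progress = FALSE)
  dplyr::distinct(ann)
}

#' Read per-orthogroup non-fungal homolog hit counts
#'
#' TSV with columns `orthogroup_id` and `n_nonfungal_eukaryote_organisms`: the
#' number of distinct non-fungal eukaryote organisms with a homolog of the
#' orthogroup in a broad database search. Used by [validate_calls()].
#'
#' @param path Path to a TSV file.
#' @return A tibble with the two columns.
#' @export
read_hit_counts <- function(path) {
  hits <- readr::read_tsv(path, col_types = readr::cols(
    orthogroup_id = readr::col_character(),
    n_nonfungal_eukaryote_organisms = readr::col_integer()
  ), progress = FALSE)
  if (any(hits$n_nonfungal_eukaryote_organisms < 0, na.rm = TRUE)) {
    stop("hit counts must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(hits$orthogroup_id)) {
    stop("duplicate orthogroup id(s) in hit-count table", call. = FALSE)
  }
  hits
}

#' Read a clade-ladder configuration
#'
#' YAML file with a top-level `nodes:` list; each entry has `name`, `phyla`
#' (list of member phylum names) and optional `terminal` (default false).
#'
#' @param path Path to a YAML file.
#' @return A [clade_ladder()].
#' @export
read_clade_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$nodes)) stop("clade config needs a top-level 'nodes:' list", call. = FALSE)
  clade_ladder(tibble::tibble(
    node = purrr::map_chr(cfg$nodes, function(n) {
      if (is.null(n$name)) stop("every clade node needs a 'name'", call. = FALSE)
      n$name
    }),
    phyla = purrr::map(cfg$nodes, function(n) as.character(unlist(n$phyla))),
    terminal = purrr::map_lgl(cfg$nodes, function(n) isTRUE(n$terminal))
  ))
}

#' Write a result table to TSV
#'
#' Thin wrapper used for all tabular outputs so that written files round-trip
#' through the matching reader without loss.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}
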