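#' Presence fraction of an orthogroup in a taxonomic group
#'
#' The fraction of the group's sampled species in which the orthogroup is
#' present. The group may be a phylum or a subphylum; the rule is undefined
#' (and errors) for a group with no sampled species.
#'
#' @param pa Presence-absence tibble (see [binarize()]).
#' @param taxonomy Taxonomy tibble.
#' @param og Orthogroup id.
#' @param group Phylum or subphylum name.
#' @return A fraction in \[0, 1\].
#' @export
group_presence_fraction <- function(pa, taxonomy, og, group) {
  sp <- group_species(taxonomy, group)
  if (length(sp) == 0) {
    stop("group '", group, "' has no sampled species", call. = FALSE)
  }
  row <- pa[pa$orthogroup_id == og, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown orthogroup id: ", og, call. = FALSE)
  mean(as.logical(row[1, sp, drop = TRUE] >= 1))
}

# species of a phylum or subphylum (ingroup only)
group_species <- function(taxonomy, group) {
  ing <- taxonomy[taxonomy$role == "ingroup", , drop = FALSE]
  ing$species_id[ing$phylum == group | ing$subphylum == group]
}

# groups evaluated at a node: member phyla, or their subphyla when terminal
node_groups <- function(ladder, taxonomy, i) {
  phyla <- ladder$phyla[[i]]
  if (!ladder$terminal[i]) return(phyla)
  ing <- taxonomy[taxonomy$role == "ingroup" & taxonomy$phylum %in% phyla, , drop = FALSE]
  sub <- unique(ing$subphylum[ing$subphylum != ""])
  if (length(sub) == 0) {
    stop("terminal node '", ladder$node[i], "' has no sampled subphyla", call. = FALSE)
  }
  sub
}

#' Test the novelty rule for one orthogroup at one ladder node
#'
#' An orthogroup qualifies as novel at a clade when (a) its presence fraction
#' is at least `cutoff` in every member phylum of the node -- in every member
#' subphylum for terminal nodes -- and (b) at most `outgroup_tolerance` species
#' outside the clade (non-member fungi plus all non-fungal eukaryote outgroups)
#' carry it. The single-species tolerance absorbs occasional horizontal
#' transfer or database error.
#'
#' @inheritParams group_presence_fraction
#' @param ladder A [clade_ladder()].
#' @param node Ladder node name.
#' @param cutoff Minimum in-clade per-group presence fraction (inclusive).
#' @param outgroup_tolerance Maximum outside-clade presences (inclusive).
#' @return A list with `qualifies` (logical), `per_group_fraction` (named
#'   numeric) and `outgroup_present_count` (integer).
#' @export
is_novel_at_node <- function(pa, taxonomy, ladder, og, node,
                             cutoff = 0.5, outgroup_tolerance = 1) {
  stopifnot(inherits(ladder, "clade_ladder"))
  i <- match(node, ladder$node)
  if (is.na(i)) stop("unknown ladder node: ", node, call. = FALSE)
  groups <- node_groups(ladder, taxonomy, i)
  fr <- vapply(groups, function(g) group_presence_fraction(pa, taxonomy, og, g),
               numeric(1))
  member_sp <- taxonomy$species_id[taxonomy$role == "ingroup" &
                                     taxonomy$phylum %in% ladder$phyla[[i]]]
  all_sp <- intersect(names(pa)[-1], taxonomy$species_id)
  outside_sp <- setdiff(all_sp, member_sp)
  row <- pa[pa$orthogroup_id == og, , drop = FALSE]
  out_count <- if (length(outside_sp) > 0) {
    sum(as.logical(unlist(row[1, outside_sp]) >= 1))
  } else 0L
  list(
    qualifies = all(fr >= cutoff) && out_count <= outgroup_tolerance,
    per_group_fraction = fr,
    outgroup_present_count = as.integer(out_count)
  )
}

#' Assign every orthogroup to its phylogenetic origin node
#'
#' Scans the clade ladder from the most inclusive node towards the tips and
#' assigns each orthogroup to the first (deepest) node at which the novelty
#' rule holds; orthogroups qualifying nowhere are `"unassigned"`. The
#' deepest-node tie-break follows parsimony: a single older gain is preferred
#' over a younger gain plus horizontal transfer.
#'
#' @param pa Presence-absence tibble (species columns are logical or 0/1).
#' @param taxonomy Taxonomy tibble covering every matrix species.
#' @param ladder A [clade_ladder()]; defaults to [default_clade_ladder()].
#' @param cutoff Minimum per-group presence fraction, inclusive (default 0.5).
#' @param outgroup_tolerance Maximum presences outside the focal clade
#'   (default 1).
#' @return A tibble of class `novelty_calls` with columns `orthogroup_id`,
#'   `origin_node`, `validated` (`NA` until [validate_calls()] runs),
#'   `outgroup_present_count` (relative to the assigned node; for unassigned
#'   orthogroups, relative to the root clade), then one `frac_<group>` column
#'   per evaluated phylum/subphylum.
#' @export
assign_origin <- function(pa, taxonomy, ladder = default_clade_ladder(),
                          cutoff = 0.5, outgroup_tolerance = 1) {
  stopifnot(inherits(ladder, "clade_ladder"))
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]", call. = FALSE)
  if (outgroup_tolerance < 0) stop("outgroup_tolerance must be >= 0", call. = FALSE)
  check_species_match(pa, taxonomy)
  validate_ladder(ladder, taxonomy)

  sp <- setdiff(names(pa), "orthogroup_id")
  M <- as.matrix(pa[sp]) >= 1
  rownames(M) <- pa$orthogroup_id

  # every group evaluated anywhere on the ladder
  all_groups <- unique(unlist(purrr::map(seq_len(nrow(ladder)),
                                         function(i) node_groups(ladder, taxonomy, i))))
  frac <- vapply(all_groups, function(g) {
    gs <- intersect(group_species(taxonomy, g), sp)
    rowMeans(M[, gs, drop = FALSE])
  }, numeric(nrow(M)))
  frac <- matrix(frac, nrow = nrow(M),
                 dimnames = list(rownames(M), all_groups))

  origin <- rep("unassigned", nrow(M))
  out_count <- integer(nrow(M))
  root_members <- taxonomy$species_id[taxonomy$role == "ingroup" &
                                        taxonomy$phylum %in% ladder$phyla[[1]]]
  out_count[] <- rowSums(M[, setdiff(sp, root_members), drop = FALSE])

  unset <- rep(TRUE, nrow(M))
  for (i in seq_len(nrow(ladder))) {
    groups <- node_groups(ladder, taxonomy, i)
    members <- taxonomy$species_id[taxonomy$role == "ingroup" &
                                     taxonomy$phylum %in% ladder$phyla[[i]]]
    oc <- rowSums(M[, setdiff(sp, members), drop = FALSE])
    ok <- unset &
      apply(frac[, groups, drop = FALSE] >= cutoff, 1, all) &
      oc <= outgroup_tolerance
    origin[ok] <- ladder$node[i]
    out_count[ok] <- oc[ok]
    unset <- unset & !ok
  }

  frac_tbl <- tibble::as_tibble(frac)
  names(frac_tbl) <- paste0("frac_", all_groups)
  out <- dplyr::bind_cols(
    tibble::tibble(
      orthogroup_id = pa$orthogroup_id,
      origin_node = origin,
      validated = NA,
      outgroup_present_count = as.integer(out_count)
    ),
    frac_tbl
  )
  structure(out,
            ladder = ladder,
            params = list(cutoff = cutoff, outgroup_tolerance = outgroup_tolerance),
            class = c("novelty_calls", class(out)))
}

#' Validate novelty calls against non-fungal homolog hit counts
#'
#' A candidate novel orthogroup is confirmed when fewer than
#' `max_hit_organisms` distinct non-fungal eukaryote organisms have a homolog
#' in a broad database search (strict inequality); candidates at or above the
#' threshold are taken to be older families missed by the taxon sampling and
#' are demoted to `"unassigned"`. The pre-validation assignment is retained in
#' a `candidate_node` column for auditing. Candidates without a hit count are
#' reported as pending (`validated = NA`) and keep their assignment, unless
#' `strict = TRUE`, in which case they are demoted too.
#'
#' @param calls A `novelty_calls` tibble from [assign_origin()].
#' @param hits Hit-count tibble (see [read_hit_counts()]).
#' @param max_hit_organisms Rejection threshold (default 10; a count of 9
#'   validates, 10 rejects).
#' @param strict Treat missing hit counts as failures (default `FALSE`).
#' @return The calls tibble with `validated` filled in, demotions applied and
#'   a `candidate_node` audit column.
#' @export
validate_calls <- function(calls, hits, max_hit_organisms = 10, strict = FALSE) {
  stopifnot(is.data.frame(calls), all(c("orthogroup_id", "origin_node") %in% names(calls)))
  out <- calls
  out$candidate_node <- out$origin_node
  idx <- match(out$orthogroup_id, hits$orthogroup_id)
  n_hits <- hits$n_nonfungal_eukaryote_organisms[idx]
  assigned <- out$origin_node != "unassigned"

  out$validated <- NA
  out$validated[assigned & !is.na(n_hits)] <-
    n_hits[assigned & !is.na(n_hits)] < max_hit_organisms
  pending <- assigned & is.na(n_hits)
  if (strict) out$validated[pending] <- FALSE
  if (any(pending) && !strict) {
    warning(sum(pending), " assigned orthogroup(s) without a hit count left pending",
            call. = FALSE)
  }
  out$origin_node[assigned & !is.na(out$validated) & !out$validated] <- "unassigned"
  out
}

#' Flag core orthogroups
#'
#' A core orthogroup is one retained in at least `cutoff` of *all* species
#' descending from its origin node (union of the node's member phyla), i.e.
#' broadly kept after its emergence. Only assigned orthogroups are flagged;
#' unassigned ones are excluded from the output.
#'
#' @inheritParams assign_origin
#' @param calls A `novelty_calls` tibble.
#' @param cutoff Minimum overall presence fraction (default 0.5).
#' @return A tibble with columns `orthogroup_id`, `origin_node`, `core`.
#' @export
core_orthogroup_flags <- function(pa, taxonomy, ladder, calls, cutoff = 0.5) {
  stopifnot(inherits(ladder, "clade_ladder"))
  assigned <- calls[calls$origin_node != "unassigned", , drop = FALSE]
  sp <- setdiff(names(pa), "orthogroup_id")
  M <- as.matrix(pa[sp]) >= 1
  rownames(M) <- pa$orthogroup_id
  purrr::map_dfr(seq_len(nrow(assigned)), function(j) {
    i <- match(assigned$origin_node[j], ladder$node)
    members <- intersect(
      taxonomy$species_id[taxonomy$role == "ingroup" &
                            taxonomy$phylum %in% ladder$phyla[[i]]], sp)
    tibble::tibble(
      orthogroup_id = assigned$orthogroup_id[j],
      origin_node = assigned$origin_node[j],
      core = mean(M[assigned$orthogroup_id[j], members]) >= cutoff
    )
  })
}

#' Count assigned orthogroups per ladder node
#'
#' @param calls A `novelty_calls` tibble.
#' @return A tibble with columns `origin_node`, `n`, ordered root-to-tip with
#'   `"unassigned"` last.
#' @export
tally_origins <- function(calls) {
  ladder <- attr(calls, "ladder")
  lv <- if (!is.null(ladder)) c(ladder$node, "unassigned") else
    unique(c(setdiff(unique(calls$origin_node), "unassigned"), "unassigned"))
  calls |>
    dplyr::count(origin_node = factor(.data$origin_node, levels = lv),
                 .drop = FALSE) |>
    dplyr::mutate(origin_node = as.character(.data$origin_node))
}
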