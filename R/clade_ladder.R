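#' Build a clade ladder
#'
#' A clade ladder is the ordered, nested sequence of evaluation clades on the
#' backbone phylogeny against which every orthogroup's presence-absence pattern
#' is tested. Nodes are ordered from the most inclusive clade (the root, e.g.
#' the most recent common ancestor of all sampled fungi) towards the tips; each
#' node's member-phylum set must be a strict subset of some earlier node's set,
#' so sibling terminal phyla (e.g. Ascomycota and Basidiomycota under Dikarya)
#' are both allowed.
#'
#' Terminal nodes (`terminal = TRUE`) are evaluated at subphylum resolution:
#' the presence cutoff must hold in every sampled subphylum of the member
#' phylum, not just in the phylum as a whole.
#'
#' @param nodes A data frame with columns `node` (unique character names),
#'   `phyla` (list-column of character vectors of member phylum names) and
#'   `terminal` (logical; subphylum-resolution rule applies).
#' @return A tibble of class `clade_ladder` with columns `node`, `phyla`,
#'   `terminal`.
#' @examples
#' clade_ladder(data.frame(
#'   node = c("root", "inner"),
#'   phyla = I(list(c("A", "B", "C"), c("B", "C"))),
#'   terminal = c(FALSE, FALSE)
#' ))
#' @export
clade_ladder <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  req <- c("node", "phyla", "terminal")
  missing_cols <- setdiff(req, names(nodes))
  if (length(missing_cols) > 0) {
    stop("clade ladder is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(nodes[req])
  out$node <- as.character(out$node)
  out$phyla <- purrr::map(out$phyla, as.character)
  out$terminal <- as.logical(out$terminal)
  if (anyDuplicated(out$node)) {
    stop("clade ladder node names must be unique", call. = FALSE)
  }
  if (nrow(out) == 0) stop("clade ladder has no nodes", call. = FALSE)
  if (any(lengths(out$phyla) == 0)) {
    stop("every ladder node needs at least one member phylum", call. = FALSE)
  }
  # nesting: each non-root node is a strict subset of some earlier node
  for (i in seq_len(nrow(out))[-1]) {
    mem <- out$phyla[[i]]
    ok <- purrr::map_lgl(out$phyla[seq_len(i - 1)], function(prev) {
      all(mem %in% prev) && length(mem) < length(prev)
    })
    if (!any(ok)) {
      stop("node '", out$node[i], "' is not a strict subset of any earlier node; ",
           "ladder nodes must be nested (or sibling clades under a shared parent)",
           call. = FALSE)
    }
  }
  class(out) <- c("clade_ladder", class(out))
  out
}

#' Default fungal clade ladder
#'
#' Seven evaluation nodes mirroring the backbone fungal phylogeny: the fungal
#' root; the MRCA of Blastocladiomycota and sister groups (Blastocladiomycota
#' and Chytridiomycota kept as an unresolved pair inside the node, since their
#' branching order is not settled); the MRCA of Zoopagomycota and sisters; the
#' MRCA of Mucoromycota and sisters; Dikarya; and the two terminal phyla
#' Ascomycota and Basidiomycota, which are evaluated at subphylum resolution.
#'
#' @return A `clade_ladder` with seven nodes over seven fungal phyla.
#' @export
default_clade_ladder <- function() {
  all_phyla <- c("Cryptomycota", "Chytridiomycota", "Blastocladiomycota",
                 "Zoopagomycota", "Mucoromycota", "Ascomycota", "Basidiomycota")
  clade_ladder(tibble::tibble(
    node = c("MRCA_Fungi",
             "MRCA_Blastocladiomycota_sisters",
             "MRCA_Zoopagomycota_sisters",
             "MRCA_Mucoromycota_sisters",
             "Dikarya",
             "Ascomycota",
             "Basidiomycota"),
    phyla = list(
      all_phyla,
      setdiff(all_phyla, "Cryptomycota"),
      c("Zoopagomycota", "Mucoromycota", "Ascomycota", "Basidiomycota"),
      c("Mucoromycota", "Ascomycota", "Basidiomycota"),
      c("Ascomycota", "Basidiomycota"),
      "Ascomycota",
      "Basidiomycota"
    ),
    terminal = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  ))
}

#' Check a ladder against a species taxonomy
#'
#' Verifies that the ladder can be evaluated on the sampled species: the root
#' node must contain every ingroup phylum, every member phylum of every node
#' must have at least one sampled species (the presence rule is undefined on an
#' unsampled phylum, so this is a hard error rather than a silent skip), and
#' species of terminal phyla must carry a subphylum.
#'
#' @param ladder A [clade_ladder()].
#' @param taxonomy Taxonomy tibble (see [read_taxonomy()]).
#' @return `ladder`, invisibly, if all checks pass.
#' @export
validate_ladder <- function(ladder, taxonomy) {
  stopifnot(inherits(ladder, "clade_ladder"))
  ingroup <- taxonomy[taxonomy$role == "ingroup", , drop = FALSE]
  root <- ladder$phyla[[1]]
  missing_ph <- setdiff(unique(ingroup$phylum), root)
  if (length(missing_ph) > 0) {
    stop("ingroup phyla absent from the root ladder node: ",
         paste(missing_ph, collapse = ", "), call. = FALSE)
  }
  sampled <- table(ingroup$phylum)
  for (i in seq_len(nrow(ladder))) {
    unsampled <- ladder$phyla[[i]][!(ladder$phyla[[i]] %in% names(sampled))]
    if (length(unsampled) > 0) {
      stop("node '", ladder$node[i], "' includes phyla with zero sampled species: ",
           paste(unsampled, collapse = ", "), call. = FALSE)
    }
  }
  term_phyla <- unique(unlist(ladder$phyla[ladder$terminal]))
  if (length(term_phyla) > 0) {
    bad <- ingroup$species_id[ingroup$phylum %in% term_phyla &
                                (is.na(ingroup$subphylum) | ingroup$subphylum == "")]
    if (length(bad) > 0) {
      stop("species of terminal phyla lack a subphylum: ",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) ", ..." else "", call. = FALSE)
    }
  }
  invisible(ladder)
}

#' Check ladder consistency against a Newick species tree
#'
#' Optional sanity check: each ladder node's member species (species of its
#' member phyla) should form a monophyletic group on the supplied species tree.
#' Nodes whose species are not monophyletic on the tree are reported.
#'
#' @param ladder A [clade_ladder()].
#' @param tree An `ape::phylo` tree whose tip labels are species ids, or a path
#'   to a Newick file.
#' @param taxonomy Taxonomy tibble.
#' @return A tibble with columns `node`, `n_species`, `monophyletic`.
#' @export
check_ladder_tree <- function(ladder, tree, taxonomy) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for tree checks", call. = FALSE)
  }
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(ladder, "clade_ladder"))
  ingroup <- taxonomy[taxonomy$role == "ingroup", , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(ladder)), function(i) {
    sp <- ingroup$species_id[ingroup$phylum %in% ladder$phyla[[i]]]
    sp <- intersect(sp, tree$tip.label)
    tibble::tibble(
      node = ladder$node[i],
      n_species = length(sp),
      monophyletic = if (length(sp) < 1) NA else
        ape::is.monophyletic(tree, sp)
    )
  })
}

#' @export
print.clade_ladder <- function(x, ...) {
  cat("<clade_ladder> ", nrow(x), " nodes\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %d. %s%s: %s\n", i, x$node[i],
                if (x$terminal[i]) " [terminal]" else "",
                paste(x$phyla[[i]], collapse = ", ")))
  }
  invisible(x)
}
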