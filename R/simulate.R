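#' Simulation configuration for synthetic presence-absence data
#'
#' Describes a gene gain-and-retention scenario on a clade ladder: orthogroups
#' are born at a chosen evaluation node, retained in each descendant species
#' independently with probability `retention`, and appear spuriously outside
#' the clade (horizontal transfer or annotation error) with rate
#' `outgroup_noise`. Background (ancient, ubiquitous) families are present in
#' every species with probability `retention`. Per-species independence is a
#' deliberate simplification of branch-correlated loss: the detection rule
#' only sees marginal per-group presence fractions, so independent retention
#' suffices to exercise it.
#'
#' @param ladder A [clade_ladder()]; defaults to [default_clade_ladder()].
#' @param species_per_phylum Named integer vector: sampled species per ingroup
#'   phylum. Defaults cover the seven default-ladder phyla with 3-8 species
#'   each, echoing the uneven taxon sampling of real fungal datasets.
#' @param n_subphyla Number of subphyla per terminal phylum (species are
#'   spread round-robin). Default 2.
#' @param n_outgroup Number of non-fungal eukaryote outgroup species.
#'   Default 6.
#' @param ogs_per_node Orthogroups born at each ladder node: a scalar or a
#'   vector named by node. Default 20.
#' @param n_background Ubiquitous background orthogroups. Default 30.
#' @param retention Per-species retention probability after emergence
#'   (default 0.9).
#' @param outgroup_noise Per-species spurious-presence rate outside the clade
#'   of origin (default 0.005).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(ladder = default_clade_ladder(),
                       species_per_phylum = c(
                         Cryptomycota = 3, Chytridiomycota = 4,
                         Blastocladiomycota = 3, Zoopagomycota = 4,
                         Mucoromycota = 5, Ascomycota = 8, Basidiomycota = 8),
                       n_subphyla = 2,
                       n_outgroup = 6,
                       ogs_per_node = 20,
                       n_background = 30,
                       retention = 0.9,
                       outgroup_noise = 0.005) {
  stopifnot(inherits(ladder, "clade_ladder"))
  if (retention < 0 || retention > 1) stop("retention must be in [0, 1]", call. = FALSE)
  if (outgroup_noise < 0 || outgroup_noise > 1) {
    stop("outgroup_noise must be in [0, 1]", call. = FALSE)
  }
  root_phyla <- ladder$phyla[[1]]
  missing_ph <- setdiff(root_phyla, names(species_per_phylum))
  if (length(missing_ph) > 0) {
    stop("species_per_phylum lacks counts for: ",
         paste(missing_ph, collapse = ", "), call. = FALSE)
  }
  if (length(ogs_per_node) == 1 && is.null(names(ogs_per_node))) {
    ogs_per_node <- stats::setNames(rep(ogs_per_node, nrow(ladder)), ladder$node)
  }
  bad_nodes <- setdiff(names(ogs_per_node), ladder$node)
  if (length(bad_nodes) > 0) {
    stop("ogs_per_node names absent from ladder: ",
         paste(bad_nodes, collapse = ", "), call. = FALSE)
  }
  structure(list(
    ladder = ladder,
    species_per_phylum = species_per_phylum[root_phyla],
    n_subphyla = n_subphyla,
    n_outgroup = n_outgroup,
    ogs_per_node = ogs_per_node,
    n_background = n_background,
    retention = retention,
    outgroup_noise = outgroup_noise
  ), class = "sim_config")
}

# derived substream so each generator draws from its own seed; adding a new
# generator call never perturbs earlier outputs
sub_seed <- function(seed, op_id) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + op_id * 97 + 1)
}

sim_taxonomy <- function(config) {
  terminal_phyla <- unique(unlist(config$ladder$phyla[config$ladder$terminal]))
  rows <- purrr::imap(config$species_per_phylum, function(n, ph) {
    if (n < 1) return(NULL)
    sub <- if (ph %in% terminal_phyla) {
      paste0(ph, "_sub", rep_len(LETTERS[seq_len(config$n_subphyla)], n))
    } else rep("", n)
    tibble::tibble(
      species_id = sprintf("%s_sp%02d", ph, seq_len(n)),
      phylum = ph, subphylum = sub, role = "ingroup"
    )
  })
  out <- dplyr::bind_rows(rows)
  if (config$n_outgroup > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      species_id = sprintf("Outgroup_sp%02d", seq_len(config$n_outgroup)),
      phylum = "non_fungal_eukaryote", subphylum = "",
      role = "outgroup_eukaryote"
    ))
  }
  out
}

#' Simulate an orthogroup gene-count table with known origins
#'
#' Draws a gene-count table, matching taxonomy and ground-truth origin table
#' under a [sim_config()]. Present orthogroups carry 1 or 2 gene copies
#' (equally likely) so downstream binarization is exercised; absent means 0.
#' Byte-identical output for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list with `counts` (gene-count tibble), `taxonomy` (tibble) and
#'   `truth` (tibble `orthogroup_id`, `true_node`; `"background"` for
#'   ubiquitous families).
#' @export
simulate_presence <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  taxonomy <- sim_taxonomy(config)
  ladder <- config$ladder

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(seed, 1))

  sp <- taxonomy$species_id
  node_of_og <- c(
    rep(names(config$ogs_per_node), config$ogs_per_node),
    rep("background", config$n_background)
  )
  n_og <- length(node_of_og)
  if (n_og == 0) stop("configuration generates no orthogroups", call. = FALSE)
  og_ids <- sprintf("OG%06d", seq_len(n_og))

  member_sp <- lapply(seq_len(nrow(ladder)), function(i) {
    taxonomy$species_id[taxonomy$role == "ingroup" &
                          taxonomy$phylum %in% ladder$phyla[[i]]]
  })
  names(member_sp) <- ladder$node

  pres <- matrix(FALSE, n_og, length(sp), dimnames = list(og_ids, sp))
  for (j in seq_len(n_og)) {
    node <- node_of_og[j]
    if (node == "background") {
      pres[j, ] <- stats::runif(length(sp)) < config$retention
    } else {
      inside <- sp %in% member_sp[[node]]
      pres[j, inside] <- stats::runif(sum(inside)) < config$retention
      pres[j, !inside] <- stats::runif(sum(!inside)) < config$outgroup_noise
    }
  }
  copies <- matrix(sample(1:2, n_og * length(sp), replace = TRUE),
                   n_og, length(sp))
  counts_mat <- ifelse(pres, copies, 0L)

  counts <- dplyr::bind_cols(
    tibble::tibble(orthogroup_id = og_ids),
    tibble::as_tibble(counts_mat)
  )
  list(
    counts = counts,
    taxonomy = taxonomy,
    truth = tibble::tibble(orthogroup_id = og_ids, true_node = node_of_og)
  )
}

#' Origin-recovery rate of the novelty rule on simulated data
#'
#' Simulates under `config` and measures the fraction of node-born orthogroups
#' (background families excluded) whose origin [assign_origin()] recovers
#' exactly; repeated over `seeds` for a Monte-Carlo estimate.
#'
#' @param config A [sim_config()].
#' @param seeds Integer vector of simulation seeds.
#' @param cutoff,outgroup_tolerance Passed to [assign_origin()].
#' @return A tibble with columns `seed`, `n_true`, `n_recovered`, `recovery`.
#' @export
origin_recovery <- function(config, seeds, cutoff = 0.5, outgroup_tolerance = 1) {
  purrr::map_dfr(seeds, function(s) {
    sim <- simulate_presence(config, seed = s)
    calls <- assign_origin(binarize(sim$counts), sim$taxonomy, config$ladder,
                           cutoff = cutoff,
                           outgroup_tolerance = outgroup_tolerance)
    truth <- sim$truth[sim$truth$true_node != "background", , drop = FALSE]
    got <- calls$origin_node[match(truth$orthogroup_id, calls$orthogroup_id)]
    tibble::tibble(
      seed = s,
      n_true = nrow(truth),
      n_recovered = sum(got == truth$true_node),
      recovery = sum(got == truth$true_node) / nrow(truth)
    )
  })
}

#' Simulate an annotation table with a fixed overlap
#'
#' Labels exactly `target_overlap` of the novel proteins and
#' `background_labeled` proteins in total (the remainder drawn uniformly from
#' the non-novel proteins), so enrichment arithmetic on the fixture reproduces
#' a chosen 2x2 table exactly.
#'
#' @param proteins Character vector: the protein universe.
#' @param novel Character vector: the novel subset.
#' @param target_overlap Number of novel proteins to label.
#' @param background_labeled Total number of labeled proteins.
#' @param label Label string (default `"mitochondrion"`).
#' @param seed Integer seed.
#' @return A tibble with columns `protein_id`, `label`.
#' @export
simulate_annotations <- function(proteins, novel, target_overlap,
                                 background_labeled,
                                 label = "mitochondrion", seed = 1) {
  proteins <- unique(proteins)
  novel <- unique(novel)
  if (!all(novel %in% proteins)) stop("novel must be a subset of proteins", call. = FALSE)
  if (target_overlap > length(novel)) {
    stop("target_overlap exceeds the number of novel proteins", call. = FALSE)
  }
  if (target_overlap > background_labeled) {
    stop("target_overlap exceeds background_labeled", call. = FALSE)
  }
  n_rest <- background_labeled - target_overlap
  non_novel <- setdiff(proteins, novel)
  if (n_rest > length(non_novel)) {
    stop("background_labeled infeasible for this universe", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(seed, 2))
  labeled <- c(sample(novel, target_overlap), sample(non_novel, n_rest))
  tibble::tibble(protein_id = sort(labeled), label = label)
}

#' Simulate a protein-protein interaction edge list
#'
#' Builds an edge list over `nodes` in which exactly `connected_target` nodes
#' have at least one interaction: the requested components are planted
#' (internally connected via a random spanning tree plus a few extra edges)
#' and the remaining connected nodes are paired into dyads. If an odd node is
#' left over it joins a planted component (or forms a triangle with two
#' dyad-destined nodes when nothing is planted). All scores are drawn in
#' \[0.4, 1\], above the usual display threshold.
#'
#' @param nodes Character vector of proteins.
#' @param planted_components Integer vector of component sizes (each >= 2).
#' @param connected_target Total number of nodes that must end up with
#'   degree >= 1.
#' @param seed Integer seed.
#' @return A tibble with columns `protein_a`, `protein_b`, `score`.
#' @export
simulate_ppi <- function(nodes, planted_components = integer(),
                         connected_target = 0, seed = 1) {
  nodes <- unique(as.character(nodes))
  planted_components <- as.integer(planted_components)
  if (any(planted_components < 2)) {
    stop("planted component sizes must be at least 2", call. = FALSE)
  }
  if (sum(planted_components) > connected_target) {
    stop("planted components exceed connected_target", call. = FALSE)
  }
  if (connected_target > length(nodes)) {
    stop("connected_target exceeds the number of nodes", call. = FALSE)
  }
  empty <- tibble::tibble(protein_a = character(), protein_b = character(),
                          score = numeric())
  if (connected_target == 0) return(empty)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(seed, 3))

  chosen <- sample(nodes, connected_target)
  sizes <- planted_components
  leftover <- connected_target - sum(sizes)
  if (leftover %% 2 == 1) {
    if (length(sizes) > 0) {
      sizes[1] <- sizes[1] + 1L
      leftover <- leftover - 1L
    } else if (leftover >= 3) {
      sizes <- 3L
      leftover <- leftover - 3L
    } else {
      stop("a single leftover connected node is infeasible without a planted component",
           call. = FALSE)
    }
  }
  groups <- c(as.list(sizes), rep(list(2L), leftover / 2))
  idx <- 0
  edges <- purrr::map_dfr(groups, function(sz) {
    members <- chosen[idx + seq_len(sz)]
    idx <<- idx + sz
    if (sz == 2) {
      tibble::tibble(protein_a = members[1], protein_b = members[2])
    } else {
      # random spanning tree: attach each node to an earlier one
      tree <- tibble::tibble(
        protein_a = members[vapply(2:sz, function(i) sample.int(i - 1, 1), 1L)],
        protein_b = members[2:sz]
      )
      extra_n <- max(0, stats::rbinom(1, sz, 0.3))
      extra <- if (extra_n > 0 && sz >= 3) {
        pairs <- t(replicate(extra_n, sample(members, 2)))
        tibble::tibble(protein_a = pairs[, 1], protein_b = pairs[, 2])
      } else NULL
      dplyr::bind_rows(tree, extra)
    }
  })
  edges$score <- stats::runif(nrow(edges), 0.4, 1)
  normalize_edges(edges)
}
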