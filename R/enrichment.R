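#' Exact two-sided Fisher test for a 2x2 table
#'
#' Conditional on the table margins, sums the hypergeometric probability of
#' every table at most as probable as the observed one (the probability-mass
#' two-sided convention used by the common statistical implementations). The
#' enumeration is carried out in log space for numerical stability.
#'
#' @param tab A 2x2 matrix of non-negative counts `rbind(c(a, b), c(c, d))`,
#'   rows = novel / non-novel, columns = labeled / unlabeled.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_two_sided(rbind(c(3, 1), c(1, 3)))  # 34/70
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("expected a 2x2 table", call. = FALSE)
  if (any(tab < 0)) stop("negative cell in contingency table", call. = FALSE)
  if (sum(tab) == 0) stop("empty contingency table", call. = FALSE)
  a <- tab[1, 1]
  m1 <- sum(tab[1, ])          # row-1 margin (draws)
  n1 <- sum(tab[, 1])          # column-1 margin (successes)
  N <- sum(tab)
  klo <- max(0, m1 + n1 - N)
  khi <- min(m1, n1)
  if (klo == khi) return(1)    # degenerate margin: only one table possible
  k <- klo:khi
  logp <- stats::dhyper(k, n1, N - n1, m1, log = TRUE)
  logp_obs <- stats::dhyper(a, n1, N - n1, m1, log = TRUE)
  keep <- logp <= logp_obs + log1p(1e-7)   # relative tolerance for ties
  mx <- max(logp[keep])
  p <- exp(mx) * sum(exp(logp[keep] - mx))
  min(p, 1)
}

#' Test enrichment of an annotation label among novel proteins
#'
#' Builds the disjoint 2x2 contingency table -- novel vs non-novel crossed
#' with labeled vs unlabeled, so no protein is counted twice -- and applies
#' the exact two-sided Fisher test. The sample odds ratio `a*d / (b*c)` is
#' reported (possibly 0 or `Inf` on degenerate margins).
#'
#' @param novel_proteins Character vector: proteins from novel orthogroups.
#' @param all_proteins Character vector: the full protein universe.
#' @param labeled Character vector: proteins carrying the label of interest.
#' @return An object of class `og_enrichment`: list with `table` (2x2 matrix),
#'   `odds_ratio`, `p_two_sided` and `direction` (`"enriched"`, `"depleted"`
#'   or `"none"`).
#' @export
label_enrichment <- function(novel_proteins, all_proteins, labeled) {
  novel_proteins <- unique(novel_proteins)
  all_proteins <- unique(all_proteins)
  labeled <- unique(labeled)
  if (!all(novel_proteins %in% all_proteins)) {
    stop("novel_proteins must be a subset of all_proteins", call. = FALSE)
  }
  if (!all(labeled %in% all_proteins)) {
    stop("labeled must be a subset of all_proteins", call. = FALSE)
  }
  a <- length(intersect(novel_proteins, labeled))
  b <- length(setdiff(novel_proteins, labeled))
  cc <- length(setdiff(labeled, novel_proteins))
  d <- length(all_proteins) - a - b - cc
  tab <- rbind(c(a, b), c(cc, d))
  dimnames(tab) <- list(c("novel", "non_novel"), c("labeled", "unlabeled"))
  p <- fisher_exact_two_sided(tab)
  or <- if (b * cc == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * cc)
  direction <- if (is.na(or) || or == 1) "none" else if (or > 1) "enriched" else "depleted"
  structure(
    list(table = tab, odds_ratio = or, p_two_sided = p, direction = direction),
    class = "og_enrichment"
  )
}

#' @export
print.og_enrichment <- function(x, ...) {
  cat("<og_enrichment>\n")
  print(x$table)
  cat(sprintf("odds ratio = %s, two-sided p = %.4g, %s\n",
              format(x$odds_ratio, digits = 4), x$p_two_sided, x$direction))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.og_enrichment <- function(x, ...) {
  tibble::tibble(
    a = x$table[1, 1], b = x$table[1, 2],
    c = x$table[2, 1], d = x$table[2, 2],
    estimate = x$odds_ratio,
    p.value = x$p_two_sided,
    direction = x$direction
  )
}

#' @importFrom generics glance
#' @export
glance.og_enrichment <- function(x, ...) {
  tibble::tibble(
    n_total = sum(x$table),
    n_novel = sum(x$table[1, ]),
    n_labeled = sum(x$table[, 1]),
    odds_ratio = x$odds_ratio,
    p.value = x$p_two_sided,
    direction = x$direction
  )
}

#' Percentage with explicit rounding
#'
#' `100 * numerator / denominator` rounded to the nearest integer (default) or
#' to one decimal. Half-way cases round up, so printed summaries are stable
#' across platforms.
#'
#' @param numerator,denominator Non-negative counts; `denominator > 0`.
#' @param rounding `"nearest_integer"` or `"one_decimal"`.
#' @return The rounded percentage.
#' @examples
#' percent_summary(28, 139)  # 20
#' percent_summary(16, 28)   # 57
#' @export
percent_summary <- function(numerator, denominator,
                            rounding = c("nearest_integer", "one_decimal")) {
  rounding <- match.arg(rounding)
  if (denominator <= 0) stop("denominator must be positive", call. = FALSE)
  x <- 100 * numerator / denominator
  if (rounding == "nearest_integer") floor(x + 0.5) else floor(10 * x + 0.5) / 10
}

#' Term enrichment of a foreground protein set
#'
#' One-sided hypergeometric (Fisher) enrichment of each annotation term in a
#' foreground set against a background universe, with an optional EASE-style
#' variant in which the foreground overlap is decremented by one before the
#' tail probability is computed -- a conservative convention that damps terms
#' supported by a single protein (an overlap of 1 yields p = 1).
#'
#' @param foreground Character vector, subset of `background`.
#' @param background Character vector: the protein universe.
#' @param term_map Long tibble with columns `protein_id`, `label` (one row per
#'   protein-term pair), e.g. from [read_annotations()].
#' @param mode `"fisher"` (plain one-sided) or `"ease"`.
#' @param cutoff Significance flag threshold on the raw p (default 0.1).
#' @param adjust Add a Benjamini-Hochberg adjusted column (default `TRUE`).
#' @return A tibble with one row per term overlapping the foreground:
#'   `term`, `overlap`, `term_size`, `p`, optionally `p_adjusted`,
#'   `significant`, sorted by `p`.
#' @export
term_enrichment <- function(foreground, background, term_map,
                            mode = c("fisher", "ease"), cutoff = 0.1,
                            adjust = TRUE) {
  mode <- match.arg(mode)
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background)) {
    stop("foreground must be a subset of background", call. = FALSE)
  }
  stopifnot(all(c("protein_id", "label") %in% names(term_map)))
  tm <- dplyr::distinct(term_map[c("protein_id", "label")])
  n_fg <- length(foreground)
  n_bg <- length(background)

  terms <- split(tm$protein_id, tm$label)
  rows <- purrr::imap(terms, function(prot, term) {
    in_bg <- intersect(prot, background)
    if (length(in_bg) == 0) {
      warning("term '", term, "' has no background proteins; skipped", call. = FALSE)
      return(NULL)
    }
    k <- length(intersect(in_bg, foreground))
    if (k == 0) return(NULL)
    k_eff <- if (mode == "ease") k - 1 else k
    # P(X >= k_eff) for X ~ Hypergeom(term_size successes, n_fg draws)
    p <- stats::phyper(k_eff - 1, length(in_bg), n_bg - length(in_bg), n_fg,
                       lower.tail = FALSE)
    tibble::tibble(term = term, overlap = k, term_size = length(in_bg), p = p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(term = character(), overlap = integer(),
                          term_size = integer(), p = numeric(),
                          significant = logical()))
  }
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p <= cutoff
  dplyr::arrange(out, .data$p, .data$term)
}
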