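#' Continuity-corrected confidence interval for a difference of proportions
#'
#' Computes `diff = x1/n1 - x2/n2` with the Wald interval plus Yates
#' continuity correction, numerically identical to the confidence interval
#' of the standard equal-proportions test (`stats::prop.test` with
#' `correct = TRUE`): half-width
#' `z * sqrt(p1(1-p1)/n1 + p2(1-p2)/n2) + min(0.5 * (1/n1 + 1/n2), |diff|)`,
#' clamped to `[-1, 1]`. All arguments are vectorized.
#'
#' @param x1,n1 Successes and trials in the first sample (`n1 > 0`).
#' @param x2,n2 Successes and trials in the second sample (`n2 > 0`).
#' @param conf_level Confidence level in (0, 1).
#' @return A tibble with columns `diff`, `ci_lower`, `ci_upper`.
#' @examples
#' two_proportion_ci(30, 100, 10, 200, 0.95)
#' @export
two_proportion_ci <- function(x1, n1, x2, n2, conf_level = 0.95) {
  if (any(n1 <= 0) || any(n2 <= 0)) {
    stop_gmrsd("`n1` and `n2` must be positive (a proportion with zero trials is undefined)")
  }
  if (any(x1 < 0) || any(x2 < 0) || any(x1 > n1) || any(x2 > n2)) {
    stop_gmrsd("counts must satisfy 0 <= x1 <= n1 and 0 <= x2 <= n2")
  }
  if (any(conf_level <= 0) || any(conf_level >= 1)) {
    stop_gmrsd("`conf_level` must be strictly between 0 and 1")
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  d <- p1 - p2
  z <- qnorm((1 + conf_level) / 2)
  cc <- pmin(0.5 * (1 / n1 + 1 / n2), abs(d))
  width <- z * sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2) + cc
  tibble::tibble(
    diff = d,
    ci_lower = pmax(d - width, -1),
    ci_upper = pmin(d + width, 1)
  )
}

#' Bonferroni-adjusted enrichment analysis of a domain count table
#'
#' For each of the M domains in the table, computes the difference between
#' its proportion among neighborhood domain instances and among background
#' instances, with a [two_proportion_ci()] at the Bonferroni-adjusted
#' individual confidence level `1 - alpha / M` (so the familywise error
#' rate over all M intervals is controlled at `alpha`). A domain is called
#' enriched iff its interval lies entirely above zero. Domains are ranked
#' by the lower confidence bound; by default the most enriched (largest
#' lower bound) comes first.
#'
#' @param counts A count table from [build_count_table()] (columns
#'   `domain_id`, `x1`, `x2`, and optionally `n1`, `n2`; denominators
#'   default to the column sums).
#' @param alpha Familywise error rate (default 0.05).
#' @param rank_direction `"descending"` (default; most enriched first) or
#'   `"ascending"` (smallest lower bound first).
#' @return A tibble of class `gmrsd_enrichment` with columns `domain_id`,
#'   `x1`, `n1`, `x2`, `n2`, `p1`, `p2`, `diff`, `ci_lower`, `ci_upper`,
#'   `level`, `enriched`, `rank`, sorted in rank order.
#' @examples
#' tab <- tibble::tibble(domain_id = c("A", "B"), x1 = c(30, 10),
#'                       x2 = c(10, 40))
#' enrichment_analysis(tab)
#' @export
enrichment_analysis <- function(counts, alpha = 0.05,
                                rank_direction = c("descending", "ascending")) {
  assert_columns(counts, c("domain_id", "x1", "x2"), "counts")
  assert_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE,
                strict_max = TRUE)
  rank_direction <- match.arg(rank_direction)
  if (!nrow(counts)) {
    out <- tibble::tibble(
      domain_id = character(0), x1 = integer(0), n1 = integer(0),
      x2 = integer(0), n2 = integer(0), p1 = numeric(0), p2 = numeric(0),
      diff = numeric(0), ci_lower = numeric(0), ci_upper = numeric(0),
      level = numeric(0), enriched = logical(0), rank = integer(0)
    )
    return(new_gmrsd_enrichment(out, alpha, 0L, NA_real_, rank_direction))
  }
  if (anyDuplicated(counts$domain_id)) {
    stop_gmrsd("`counts` must have one row per domain")
  }
  n1 <- if ("n1" %in% names(counts)) counts$n1[1] else sum(counts$x1)
  n2 <- if ("n2" %in% names(counts)) counts$n2[1] else sum(counts$x2)
  m <- nrow(counts)
  level <- 1 - alpha / m
  ci <- two_proportion_ci(counts$x1, n1, counts$x2, n2, conf_level = level)
  out <- tibble::tibble(
    domain_id = counts$domain_id,
    x1 = counts$x1, n1 = n1, x2 = counts$x2, n2 = n2,
    p1 = counts$x1 / n1, p2 = counts$x2 / n2,
    diff = ci$diff, ci_lower = ci$ci_lower, ci_upper = ci$ci_upper,
    level = level,
    enriched = ci$ci_lower > 0
  )
  out <- if (rank_direction == "descending") {
    dplyr::arrange(out, dplyr::desc(.data$ci_lower), .data$domain_id)
  } else {
    dplyr::arrange(out, .data$ci_lower, .data$domain_id)
  }
  out$rank <- seq_len(nrow(out))
  new_gmrsd_enrichment(out, alpha, m, level, rank_direction)
}

new_gmrsd_enrichment <- function(out, alpha, m, level, rank_direction) {
  class(out) <- c("gmrsd_enrichment", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "n_domains") <- m
  attr(out, "conf_level") <- level
  attr(out, "rank_direction") <- rank_direction
  out
}

#' @export
print.gmrsd_enrichment <- function(x, ...) {
  cat(sprintf(
    "# Neighborhood enrichment: M = %d domains, individual CI level %.6g, %d enriched\n",
    attr(x, "n_domains"), attr(x, "conf_level"), sum(x$enriched)
  ))
  NextMethod()
}

#' @rdname enrichment_analysis
#' @param x A `gmrsd_enrichment` object.
#' @param ... Unused.
#' @method tidy gmrsd_enrichment
#' @export
tidy.gmrsd_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "gmrsd_enrichment")
  tibble::as_tibble(out)
}

#' @rdname enrichment_analysis
#' @method glance gmrsd_enrichment
#' @export
glance.gmrsd_enrichment <- function(x, ...) {
  tibble::tibble(
    n_domains = attr(x, "n_domains"),
    alpha = attr(x, "alpha"),
    conf_level = attr(x, "conf_level"),
    n_enriched = sum(x$enriched),
    n1 = if (nrow(x)) x$n1[1] else NA_integer_,
    n2 = if (nrow(x)) x$n2[1] else NA_integer_
  )
}

#' Defense-island enrichment analysis of a focal gene family
#'
#' The full genomic-neighborhood pipeline: extract the +/- k ORF windows
#' around every focal gene, de-duplicate shared neighbor proteins, count
#' top-scoring non-overlapping domain hits in the neighborhood set and in
#' the background (all domain annotations of the genomes carrying at least
#' one focal gene, neighborhoods included, optionally excluded), and run
#' the Bonferroni-adjusted two-proportion analysis. Focal proteins
#' themselves are excluded from the neighborhood set.
#'
#' @param annotation Ordered-ORF table (see [extract_neighborhoods()]).
#' @param hits Domain-hit tibble.
#' @param focal_ids Protein ids of the focal (GmrSD-like) genes.
#' @param k Window half-width in ORFs (default 10).
#' @param evalue_max E-value threshold for neighborhood/background domain
#'   selection (default `1e-3`).
#' @param alpha Familywise error rate (default 0.05).
#' @param background `"all"` (default) or `"exclude_neighborhood"`.
#' @param rank_direction Passed to [enrichment_analysis()].
#' @return A `gmrsd_enrichment` tibble (see [enrichment_analysis()]).
#' @export
neighborhood_enrichment <- function(annotation, hits, focal_ids, k = 10,
                                    evalue_max = 1e-3, alpha = 0.05,
                                    background = c("all", "exclude_neighborhood"),
                                    rank_direction = c("descending", "ascending")) {
  background <- match.arg(background)
  windows <- extract_neighborhoods(annotation, focal_ids, k = k)
  nb_proteins <- setdiff(unique(windows$protein_id), focal_ids)
  focal_genomes <- unique(
    annotation$genome_id[annotation$protein_id %in% focal_ids]
  )
  bg_proteins <- annotation$protein_id[annotation$genome_id %in% focal_genomes]
  if (background == "exclude_neighborhood") {
    bg_proteins <- setdiff(bg_proteins, c(nb_proteins, focal_ids))
  }
  tab <- build_count_table(nb_proteins, bg_proteins, hits,
                           evalue_max = evalue_max)
  enrichment_analysis(tab, alpha = alpha, rank_direction = rank_direction)
}
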