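#' Pearson correlation profile of a query gene
#'
#' Computes the Pearson correlation coefficient (PCC) between the query
#' gene's expression vector and every other gene's, across all samples.
#' Zero-variance genes must be removed first (see
#' [filter_constant_genes()]), since PCC is undefined for them.
#'
#' @param expr Expression tibble (`gene_id` plus numeric sample columns).
#' @param query Query gene identifier.
#' @return A tibble with columns `query`, `partner`, `pcc`, one row per
#'   other gene, in matrix order.
#' @export
pearson_profile <- function(expr, query) {
  expr <- validate_expression(expr, require_nonneg = FALSE)
  x <- expr_values(expr)
  check_query(x, query)
  check_no_constant(x)
  r <- as.vector(stats::cor(x[query, ], t(x)))
  names(r) <- rownames(x)
  r <- r[names(r) != query]
  tibble(query = query, partner = names(r), pcc = unname(r))
}

#' Directed co-expression ranks from a correlation profile
#'
#' Ranks a query's partners by PCC descending; rank 1 is the most
#' correlated partner. Ties are broken deterministically by ascending
#' partner identifier (ordinal policy), so the ranks of `G - 1` partners
#' are always a permutation of `1..G-1`.
#'
#' @param profile Tibble from [pearson_profile()].
#' @return The profile with an integer `rank` column, sorted by rank.
#' @export
directed_ranks <- function(profile) {
  stopifnot(all(c("query", "partner", "pcc") %in% names(profile)))
  if (nrow(profile) == 0) stop_validation("empty correlation profile")
  if (any(!is.finite(profile$pcc))) {
    stop_validation("correlation profile contains non-finite PCC")
  }
  out <- dplyr::arrange(profile, desc(.data$pcc), .data$partner)
  out$rank <- seq_len(nrow(out))
  out
}

#' Highest Reciprocal Rank of a gene pair
#'
#' `HRR(A, B) = max(rank(A, B), rank(B, A))`: the worse of the two directed
#' co-expression ranks. A small HRR means each gene ranks the other among
#' its top co-expression partners — a stringent reciprocal criterion.
#'
#' @param rank_ab,rank_ba Directed ranks (integers >= 1); vectorised.
#' @return Integer vector of HRR values.
#' @export
#' @examples
#' hrr_value(3, 7) # 7
hrr_value <- function(rank_ab, rank_ba) {
  if (length(rank_ab) != length(rank_ba)) {
    stop_validation("rank vectors must have equal length")
  }
  ok <- is.finite(rank_ab) & is.finite(rank_ba) &
    rank_ab >= 1 & rank_ba >= 1 &
    rank_ab == as.integer(rank_ab) & rank_ba == as.integer(rank_ba)
  if (!all(ok)) stop_validation("ranks must be integers >= 1")
  as.integer(pmax(rank_ab, rank_ba))
}

#' HRR co-expression neighborhood of a query gene
#'
#' Extracts the query's co-expressed gene list: all partners whose HRR with
#' the query passes the cutoff (`hrr <= cutoff` when `inclusive`, the
#' default, else `hrr < cutoff`). Computation is per-query: only the
#' query's correlation row and candidate partners' rows are evaluated, in
#' blocks, never the full genes-by-genes correlation matrix. The result is
#' identical to [hrr_all_pairs()] restricted to the query.
#'
#' @param expr Expression tibble with no zero-variance genes.
#' @param query Query gene identifier.
#' @param cutoff Positive integer HRR cutoff (500 in typical use).
#' @param inclusive Keep edges with `hrr <= cutoff` (default) rather than
#'   `hrr < cutoff`.
#' @param block_size Number of candidate rows correlated per block.
#' @return A `hrr_neighborhood` tibble with columns `query`, `partner`,
#'   `pcc`, `rank_query_to_partner`, `rank_partner_to_query`, `hrr`,
#'   sorted by (`hrr`, `partner`).
#' @export
hrr_neighborhood <- function(expr, query, cutoff = 500L, inclusive = TRUE,
                             block_size = 512L) {
  expr <- validate_expression(expr, require_nonneg = FALSE)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 1 ||
      cutoff != as.integer(cutoff)) {
    stop_validation("cutoff must be a positive integer")
  }
  cutoff <- as.integer(cutoff)
  x <- expr_values(expr)
  check_query(x, query)
  check_no_constant(x)
  ids <- rownames(x)
  tx <- t(x)

  r_q <- as.vector(stats::cor(x[query, ], tx))
  names(r_q) <- ids
  partners <- ids[ids != query]
  ord <- order(-r_q[partners], partners, method = "radix")
  rank_ab <- integer(length(partners))
  rank_ab[ord] <- seq_along(partners)
  names(rank_ab) <- partners

  # hrr >= rank_ab, so only partners the query itself ranks within the
  # cutoff can pass; their reciprocal rank is computed blockwise.
  cand <- partners[rank_ab <= cutoff]
  if (length(cand) == 0) {
    return(new_hrr_neighborhood(empty_edges(query), query, cutoff, inclusive))
  }
  rank_ba <- integer(length(cand))
  names(rank_ba) <- cand
  for (start in seq(1, length(cand), by = block_size)) {
    blk <- cand[start:min(start + block_size - 1, length(cand))]
    cb <- stats::cor(t(x[blk, , drop = FALSE]), tx) # |blk| x G
    for (i in seq_along(blk)) {
      b <- blk[i]
      v <- cb[i, ]
      r_bq <- v[[query]]
      n_gt <- sum(v > r_bq) - (v[[b]] > r_bq)
      n_tie <- sum(v == r_bq & ids < query & ids != b)
      rank_ba[b] <- 1L + n_gt + n_tie
    }
  }
  hrr <- pmax(rank_ab[cand], rank_ba)
  keep <- if (inclusive) hrr <= cutoff else hrr < cutoff
  edges <- tibble(
    query = query,
    partner = cand[keep],
    pcc = unname(r_q[cand[keep]]),
    rank_query_to_partner = unname(rank_ab[cand[keep]]),
    rank_partner_to_query = unname(rank_ba[keep]),
    hrr = as.integer(unname(hrr[keep]))
  )
  edges <- dplyr::arrange(edges, .data$hrr, .data$partner)
  new_hrr_neighborhood(edges, query, cutoff, inclusive)
}

#' Brute-force HRR edge list over all gene pairs
#'
#' Reference implementation: materialises the full correlation matrix and
#' every directed rank table, then applies the HRR definition to every
#' unordered pair. Quadratic in genes; guarded to at most 2000 genes.
#'
#' @param expr Expression tibble with no zero-variance genes.
#' @return Tibble with columns `gene_a`, `gene_b` (`gene_a < gene_b`),
#'   `pcc`, `rank_ab`, `rank_ba`, `hrr`.
#' @export
hrr_all_pairs <- function(expr) {
  expr <- validate_expression(expr, require_nonneg = FALSE)
  x <- expr_values(expr)
  if (nrow(x) > 2000) {
    stop_size("hrr_all_pairs() is a quadratic reference implementation; refusing > 2000 genes")
  }
  if (nrow(x) < 2) stop_validation("need at least two genes")
  check_no_constant(x)
  ids <- rownames(x)
  g <- length(ids)
  tx <- t(x)
  cc <- stats::cor(tx, tx)

  # rank_mat[i, j] = rank of gene j in gene i's profile (diagonal NA)
  rank_mat <- matrix(NA_integer_, g, g, dimnames = list(ids, ids))
  for (i in seq_len(g)) {
    p <- cc[i, -i]
    ord <- order(-p, ids[-i], method = "radix")
    rk <- integer(g - 1)
    rk[ord] <- seq_len(g - 1)
    rank_mat[i, -i] <- rk
  }
  pairs <- which(upper.tri(cc), arr.ind = TRUE)
  tibble(
    gene_a = ids[pairs[, 1]],
    gene_b = ids[pairs[, 2]],
    pcc = cc[pairs],
    rank_ab = rank_mat[pairs],
    rank_ba = rank_mat[pairs[, c(2, 1), drop = FALSE]],
    hrr = as.integer(pmax(rank_mat[pairs], rank_mat[pairs[, c(2, 1), drop = FALSE]]))
  )
}

#' Write a neighborhood to TSV
#'
#' @param nb A `hrr_neighborhood` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_neighborhood_tsv <- function(nb, path) {
  readr::write_tsv(as_tibble(nb), path, progress = FALSE)
  invisible(path)
}

#' @export
glance.hrr_neighborhood <- function(x, ...) {
  tibble(
    query = attr(x, "query"),
    cutoff = attr(x, "cutoff"),
    inclusive = attr(x, "inclusive"),
    n_partners = nrow(x),
    min_hrr = if (nrow(x)) min(x$hrr) else NA_integer_,
    max_hrr = if (nrow(x)) max(x$hrr) else NA_integer_,
    mean_pcc = if (nrow(x)) mean(x$pcc) else NA_real_
  )
}

#' Plot a co-expression neighborhood
#'
#' Scatter of PCC against HRR for every partner in the neighborhood.
#'
#' @param object A `hrr_neighborhood` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.hrr_neighborhood <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$hrr, y = .data$pcc)) +
    geom_point(alpha = 0.6) +
    labs(
      title = paste0("Co-expression neighborhood of ", attr(object, "query")),
      x = "Highest Reciprocal Rank",
      y = "Pearson correlation with query"
    )
}

#' @export
print.hrr_neighborhood <- function(x, ...) {
  cat("# HRR neighborhood of ", attr(x, "query"),
      " (cutoff ", if (attr(x, "inclusive")) "<= " else "< ",
      attr(x, "cutoff"), "): ", nrow(x), " partner(s)\n", sep = "")
  print(as_tibble(x), ...)
  invisible(x)
}

# ---- internal ---------------------------------------------------------------

new_hrr_neighborhood <- function(edges, query, cutoff, inclusive) {
  structure(edges,
            class = c("hrr_neighborhood", class(edges)),
            query = query, cutoff = cutoff, inclusive = inclusive)
}

empty_edges <- function(query) {
  tibble(query = character(), partner = character(), pcc = double(),
         rank_query_to_partner = integer(), rank_partner_to_query = integer(),
         hrr = integer())
}

check_query <- function(x, query) {
  if (!is.character(query) || length(query) != 1) {
    stop_validation("query must be a single gene identifier")
  }
  if (!query %in% rownames(x)) {
    stop_lookup(paste0("query gene not in expression matrix: ", query))
  }
}

check_no_constant <- function(x) {
  v <- rowSums((x - rowMeans(x))^2)
  if (any(v == 0)) {
    stop_validation(paste0(
      "zero-variance gene(s) present (first: ", rownames(x)[v == 0][1],
      "); run filter_constant_genes() first"))
  }
}
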