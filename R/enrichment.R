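GO_ASPECTS <- c(P = "biological_process", F = "molecular_function",
                C = "cellular_component")

#' Read a gene-to-GO annotation table
#'
#' Three-column TSV: gene id, term id, aspect code (`P`, `F`, `C`, or the
#' long names). A header row is detected and skipped if its third field is
#' not a recognised aspect.
#'
#' @param path Path to the TSV file.
#' @return An annotation tibble with columns `gene`, `term`, `aspect`
#'   (long-form aspect names), distinct rows.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_io(paste0("file not found: ", path))
  tbl <- readr::read_tsv(path, col_names = c("gene", "term", "aspect"),
                         col_types = "ccc", progress = FALSE)
  if (nrow(tbl) == 0) stop_format(paste0("empty annotation table: ", path))
  if (!tbl$aspect[1] %in% c(names(GO_ASPECTS), GO_ASPECTS)) {
    tbl <- tbl[-1, , drop = FALSE] # header row
    if (nrow(tbl) == 0) stop_format(paste0("no annotation rows in ", path))
  }
  validate_annotations(tbl)
}

#' Read gene-to-GO annotations from a GAF 2.x file
#'
#' Uses columns 2 (gene id), 5 (GO id) and 9 (aspect); comment lines
#' starting with `!` are skipped.
#'
#' @param path Path to the GAF file.
#' @return An annotation tibble (`gene`, `term`, `aspect`).
#' @export
read_gaf <- function(path) {
  if (!file.exists(path)) stop_io(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!")]
  if (length(lines) == 0) stop_format(paste0("no annotation rows in ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 9)
  if (length(short) > 0) {
    stop_format(paste0("GAF line with fewer than 9 columns in ", path))
  }
  tbl <- tibble(
    gene = vapply(fields, `[[`, character(1), 2),
    term = vapply(fields, `[[`, character(1), 5),
    aspect = vapply(fields, `[[`, character(1), 9)
  )
  validate_annotations(tbl)
}

#' Upper-tail hypergeometric p-value
#'
#' Probability of observing at least `k` annotated genes when drawing `n`
#' genes without replacement from a universe of `N` genes of which `K`
#' carry the annotation: `P(X >= k)` for `X ~ hypergeometric(N, K, n)`.
#' Evaluated through [stats::phyper()], whose log-space mode gives stable
#' extreme tails.
#'
#' @param k Observed annotated genes in the draw.
#' @param K Annotated genes in the universe.
#' @param n Draw (query list) size.
#' @param N Universe size.
#' @param log.p Return the natural log of the p-value.
#' @return The upper-tail probability; 1 when `k = 0`. Vectorised over all
#'   four count arguments.
#' @export
#' @examples
#' hypergeom_upper_tail(5, 5, 5, 10) # 1/252
hypergeom_upper_tail <- function(k, K, n, N, log.p = FALSE) {
  args <- cbind(k = k, K = K, n = n, N = N)
  if (any(!is.finite(args)) || any(args != floor(args)) || any(args < 0)) {
    stop_validation("k, K, n, N must be non-negative integers")
  }
  bad <- args[, "K"] > args[, "N"] | args[, "n"] > args[, "N"] |
    args[, "k"] > pmin(args[, "K"], args[, "n"])
  if (any(bad)) {
    stop_validation("require 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(K, n)")
  }
  unname(stats::phyper(args[, "k"] - 1, args[, "K"], args[, "N"] - args[, "K"],
                       args[, "n"], lower.tail = FALSE, log.p = log.p))
}

#' GO-term over-representation in a gene list
#'
#' Tests each GO term of the requested aspect for over-representation in a
#' query gene list relative to a universe, with an upper-tail
#' hypergeometric test. Defaults follow common practice for co-expression
#' lists: terms are reported when at least `min_genes` query genes carry
#' them (k >= 5) and the raw p-value is at or below `alpha` (0.001); no
#' multiple-testing correction unless requested.
#'
#' @param query Character vector of query gene ids (the co-expressed list).
#' @param annotations Annotation tibble (`gene`, `term`, `aspect`), as from
#'   [read_annotations()].
#' @param universe Character vector of universe gene ids (typically all
#'   genes surviving [filter_constant_genes()]).
#' @param aspect Aspect to test: `"biological_process"` (default),
#'   `"molecular_function"`, `"cellular_component"`, or `"all"`.
#' @param min_genes Minimum number of genes required to report a term
#'   (default 5).
#' @param alpha Raw p-value cutoff (default 0.001).
#' @param count_filter Whether `min_genes` applies to the query count `k`
#'   (default) or the universe count `K`.
#' @param annotated_only Restrict the universe to annotated genes
#'   (default), keeping N, K and n self-consistent.
#' @param p_adjust `"none"` (default) or `"BH"`; with `"BH"` the
#'   Benjamini-Hochberg adjusted p-value is added and the `alpha` filter
#'   applies to it.
#' @return A `go_enrichment` tibble with columns `term`, `aspect`, `k`,
#'   `K`, `n`, `N`, `p_value` (and `p_adj` under BH), sorted by p-value
#'   then term.
#' @export
go_enrich <- function(query, annotations, universe,
                      aspect = c("biological_process", "molecular_function",
                                 "cellular_component", "all"),
                      min_genes = 5L, alpha = 0.001,
                      count_filter = c("query", "universe"),
                      annotated_only = TRUE,
                      p_adjust = c("none", "BH")) {
  aspect <- match.arg(aspect)
  count_filter <- match.arg(count_filter)
  p_adjust <- match.arg(p_adjust)
  if (min_genes < 1) stop_validation("min_genes must be >= 1")
  if (alpha <= 0 || alpha > 1) stop_validation("alpha must be in (0, 1]")
  annotations <- validate_annotations(annotations)

  universe <- unique(as.character(universe))
  if (annotated_only) {
    universe <- intersect(universe, unique(annotations$gene))
  }
  if (length(universe) == 0) {
    stop_validation("universe is empty after filtering to annotated genes")
  }
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(paste0("go_enrich(): dropped ", length(outside),
                " query gene(s) outside the universe"))
    query <- intersect(query, universe)
  }
  n <- length(query)
  N <- length(universe)

  ann <- dplyr::filter(annotations, .data$gene %in% universe)
  if (aspect != "all") ann <- dplyr::filter(ann, .data$aspect == !!aspect)
  if (nrow(ann) == 0) {
    return(new_go_enrichment(empty_enrichment(), n, N, aspect, min_genes, alpha))
  }
  per_term <- dplyr::summarise(
    dplyr::group_by(ann, .data$term, .data$aspect),
    K = dplyr::n_distinct(.data$gene),
    k = dplyr::n_distinct(.data$gene[.data$gene %in% query]),
    .groups = "drop")

  res <- dplyr::mutate(per_term,
                       n = n, N = N,
                       p_value = hypergeom_upper_tail(.data$k, .data$K, n, N))
  res <- dplyr::filter(res, if (count_filter == "query") .data$k >= min_genes
                       else .data$K >= min_genes)
  if (p_adjust == "BH") {
    res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
    res <- dplyr::filter(res, .data$p_adj <= alpha)
  } else {
    res <- dplyr::filter(res, .data$p_value <= alpha)
  }
  res <- dplyr::arrange(res, .data$p_value, .data$term)
  res <- dplyr::select(res, "term", "aspect", "k", "K", "n", "N",
                       dplyr::any_of(c("p_value", "p_adj")))
  new_go_enrichment(res, n, N, aspect, min_genes, alpha)
}

#' Write enrichment results to TSV
#'
#' @param x A `go_enrichment` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @export
glance.go_enrichment <- function(x, ...) {
  tibble(
    n_terms = nrow(x),
    query_size = attr(x, "query_size"),
    universe_size = attr(x, "universe_size"),
    aspect = attr(x, "aspect"),
    min_genes = attr(x, "min_genes"),
    alpha = attr(x, "alpha"),
    min_p = if (nrow(x)) min(x$p_value) else NA_real_
  )
}

#' Plot GO enrichment results
#'
#' Horizontal bars of -log10 p-value, one per enriched term, annotated
#' with the query gene count.
#'
#' @param object A `go_enrichment` tibble.
#' @param top Show at most this many terms (smallest p first).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.go_enrichment <- function(object, top = 20, ...) {
  d <- utils::head(as_tibble(object), top)
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot(d, aes(x = -log10(.data$p_value), y = .data$term)) +
    geom_col() +
    ggplot2::geom_text(aes(label = .data$k), hjust = -0.3, size = 3) +
    labs(x = expression(-log[10](italic(p))), y = NULL,
         title = "GO term over-representation")
}

#' @export
print.go_enrichment <- function(x, ...) {
  cat("# GO enrichment (", attr(x, "aspect"), "): ", nrow(x),
      " term(s) with k >= ", attr(x, "min_genes"), " and p <= ",
      format(attr(x, "alpha")), "\n", sep = "")
  print(as_tibble(x), ...)
  invisible(x)
}

# ---- internal ---------------------------------------------------------------

validate_annotations <- function(tbl) {
  if (!is.data.frame(tbl) || !all(c("gene", "term", "aspect") %in% names(tbl))) {
    stop_validation("annotations need columns gene, term, aspect")
  }
  tbl <- as_tibble(tbl[, c("gene", "term", "aspect")])
  short <- tbl$aspect %in% names(GO_ASPECTS)
  tbl$aspect[short] <- GO_ASPECTS[tbl$aspect[short]]
  bad <- !tbl$aspect %in% GO_ASPECTS
  if (any(bad)) {
    stop_validation(paste0("unknown GO aspect: ", tbl$aspect[bad][1]))
  }
  conflicted <- dplyr::summarise(dplyr::group_by(tbl, .data$term),
                                 n_aspects = dplyr::n_distinct(.data$aspect),
                                 .groups = "drop")
  if (any(conflicted$n_aspects > 1)) {
    stop_validation(paste0(
      "term with conflicting aspects: ",
      conflicted$term[conflicted$n_aspects > 1][1]))
  }
  distinct(tbl)
}

empty_enrichment <- function() {
  tibble(term = character(), aspect = character(), k = integer(),
         K = integer(), n = integer(), N = integer(), p_value = double())
}

new_go_enrichment <- function(tbl, n, N, aspect, min_genes, alpha) {
  structure(tbl, class = c("go_enrichment", class(tbl)),
            query_size = n, universe_size = N, aspect = aspect,
            min_genes = min_genes, alpha = alpha)
}
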