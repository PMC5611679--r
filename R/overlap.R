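#' Exclusive Venn region counts for named gene lists
#'
#' Buckets every gene in the union of 2 to 6 named lists by its exact
#' membership signature and counts genes per exclusive region, the numbers
#' a Venn diagram displays. Counts over all regions always sum to the size
#' of the union.
#'
#' @param lists Named list of character vectors (set semantics; duplicates
#'   within a list are ignored).
#' @return A `venn_regions` tibble with columns `region` (labels joined by
#'   `+`), `degree` (number of lists in the region) and `count`, covering
#'   all `2^m - 1` regions, zeros included. Attributes `labels` and
#'   `union_size`.
#' @export
#' @examples
#' venn_regions(list(P = c("1", "2", "3"), Q = c("2", "3", "4")))
venn_regions <- function(lists) {
  if (!is.list(lists) || length(lists) < 2 || length(lists) > 6) {
    stop_validation("venn_regions() takes between 2 and 6 named lists")
  }
  labels <- names(lists)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels)) {
    stop_validation("list labels must be present and distinct")
  }
  sets <- lapply(lists, function(x) unique(as.character(x)))
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- matrix(
    unlist(lapply(sets, function(s) universe %in% s)),
    nrow = length(universe), ncol = length(labels),
    dimnames = list(NULL, labels))
  sig <- apply(membership, 1, function(row) paste(labels[row], collapse = "+"))
  sig <- as.character(sig)

  m <- length(labels)
  all_regions <- unlist(lapply(seq_len(m), function(k) {
    utils::combn(labels, k, FUN = paste, collapse = "+")
  }))
  counts <- table(factor(sig, levels = all_regions))
  out <- tibble(
    region = all_regions,
    degree = lengths(strsplit(all_regions, "+", fixed = TRUE)),
    count = as.integer(counts[all_regions])
  )
  structure(out, class = c("venn_regions", class(out)),
            labels = labels, union_size = length(universe))
}

#' Number of genes shared by two lists
#'
#' @param list_a,list_b Character vectors of gene identifiers from the same
#'   namespace.
#' @return Integer size of the intersection (set semantics).
#' @export
pairwise_shared <- function(list_a, list_b) {
  length(intersect(unique(as.character(list_a)), unique(as.character(list_b))))
}

#' Pairwise shared-gene matrix for several lists
#'
#' @param lists Named list of character vectors.
#' @return A tibble: `label` column plus one integer column per list;
#'   cell (i, j) is the intersection size of lists i and j.
#' @export
pairwise_shared_matrix <- function(lists) {
  labels <- names(lists)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop_validation("lists must be uniquely named")
  }
  m <- vapply(lists, function(a) {
    vapply(lists, function(b) pairwise_shared(a, b), integer(1))
  }, integer(length(lists)))
  out <- as_tibble(t(m))
  out <- dplyr::bind_cols(tibble(label = labels), out)
  out
}

#' Read a two-column ortholog map
#'
#' Headerless TSV with one ortholog pair per line: species-X gene, then
#' species-Y gene. Many-to-many relations are allowed; exact duplicate
#' pairs are dropped with a warning.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene_x`, `gene_y`.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) stop_io(paste0("file not found: ", path))
  tbl <- readr::read_tsv(path, col_names = c("gene_x", "gene_y"),
                         col_types = "cc", progress = FALSE)
  if (nrow(tbl) == 0) stop_format(paste0("empty ortholog map: ", path))
  ndup <- nrow(tbl) - nrow(distinct(tbl))
  if (ndup > 0) {
    warn(paste0("dropped ", ndup, " duplicate ortholog pair(s) from ", path))
    tbl <- distinct(tbl)
  }
  tbl
}

#' Cross-species overlap of two co-expressed gene lists
#'
#' Compares a species-X gene list with a species-Y list through an ortholog
#' map that may be many-to-many. "Shared" is defined at the ortholog-pair
#' level: a pair is shared when its X member is in `list_x` and its Y
#' member in `list_y`. Distinct shared genes are counted per species, and
#' each percentage is taken against that species' list size, which keeps
#' percentages at most 100 even under many-to-many maps.
#'
#' @param list_x,list_y Character vectors of gene ids in each species'
#'   namespace.
#' @param orthologs Tibble/data frame with columns `gene_x`, `gene_y`.
#' @return A `cross_species_overlap` object; see [tidy()] for the shared
#'   pairs and [glance()] for the one-row summary.
#' @export
cross_species_shared <- function(list_x, list_y, orthologs) {
  if (!is.data.frame(orthologs) || nrow(orthologs) == 0) {
    stop_validation("ortholog map is empty; cross-species comparison would be vacuous")
  }
  if (!all(c("gene_x", "gene_y") %in% names(orthologs))) {
    names(orthologs)[1:2] <- c("gene_x", "gene_y")
  }
  orthologs <- distinct(as_tibble(orthologs[, c("gene_x", "gene_y")]))
  lx <- unique(as.character(list_x))
  ly <- unique(as.character(list_y))
  shared <- dplyr::filter(orthologs, .data$gene_x %in% lx, .data$gene_y %in% ly)
  res <- list(
    shared_pairs = shared,
    n_pairs = nrow(shared),
    n_shared_x = length(unique(shared$gene_x)),
    n_shared_y = length(unique(shared$gene_y)),
    n_x = length(lx),
    n_y = length(ly),
    pct_x = if (length(lx)) 100 * length(unique(shared$gene_x)) / length(lx) else 0,
    pct_y = if (length(ly)) 100 * length(unique(shared$gene_y)) / length(ly) else 0
  )
  structure(res, class = "cross_species_overlap")
}

#' @export
tidy.cross_species_overlap <- function(x, ...) x$shared_pairs

#' @export
glance.cross_species_overlap <- function(x, ...) {
  tibble(
    n_pairs = x$n_pairs, n_shared_x = x$n_shared_x, n_shared_y = x$n_shared_y,
    n_x = x$n_x, n_y = x$n_y, pct_x = x$pct_x, pct_y = x$pct_y
  )
}

#' @export
print.cross_species_overlap <- function(x, ...) {
  cat("# Cross-species co-expression overlap\n",
      "  shared ortholog pairs: ", x$n_pairs, "\n",
      "  distinct species-X genes: ", x$n_shared_x, " / ", x$n_x,
      " (", sprintf("%.1f", x$pct_x), "%)\n",
      "  distinct species-Y genes: ", x$n_shared_y, " / ", x$n_y,
      " (", sprintf("%.1f", x$pct_y), "%)\n", sep = "")
  invisible(x)
}

#' Plot Venn region counts
#'
#' Bar chart of exclusive region counts, ordered by region degree; the
#' machine-readable companion of a Venn diagram (ellipse layout is out of
#' scope).
#'
#' @param object A `venn_regions` tibble.
#' @param drop_empty Hide regions with zero count.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.venn_regions <- function(object, drop_empty = TRUE, ...) {
  d <- as_tibble(object)
  if (drop_empty) d <- dplyr::filter(d, .data$count > 0)
  d$region <- factor(d$region, levels = object$region)
  ggplot(d, aes(x = .data$region, y = .data$count)) +
    geom_col() +
    labs(x = "Exclusive Venn region", y = "Genes") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Venn regions as JSON
#'
#' @param x A `venn_regions` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_venn_json <- function(x, path) {
  counts <- as.list(stats::setNames(x$count, x$region))
  jsonlite::write_json(
    list(labels = attr(x, "labels"),
         union_size = attr(x, "union_size"),
         region_counts = counts),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
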