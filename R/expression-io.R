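#' Read a per-sample transcript quantification table
#'
#' Reads one quantification table in the `quant.sf` dialect: a TSV with
#' header columns `Name`, `Length`, `EffectiveLength`, `TPM`, `NumReads`.
#' Only the `Name` and `TPM` columns enter downstream analysis; the rest are
#' carried along for provenance.
#'
#' @param path Path to a tab-separated quantification file.
#' @param sample_id Sample identifier. Defaults to the file's basename
#'   without extension.
#'
#' @return A tibble with columns `sample_id`, `name`, `length`,
#'   `effective_length`, `tpm`, `num_reads`, rows in file order.
#' @export
#' @examples
#' path <- tempfile(fileext = ".sf")
#' writeLines(c("Name\tLength\tEffectiveLength\tTPM\tNumReads",
#'              "g1\t1000\t900.5\t12.5\t100"), path)
#' read_quant_table(path)
read_quant_table <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop_io(paste0("file not found: ", path))
  required <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    stop_format(paste0("quantification table ", path,
                       " lacks required column(s): ",
                       paste(missing, collapse = ", ")))
  }
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    Name = readr::col_character(),
    Length = readr::col_double(),
    EffectiveLength = readr::col_double(),
    TPM = readr::col_double(),
    NumReads = readr::col_double()
  ), progress = FALSE)
  if (nrow(tbl) == 0) stop_format(paste0("no data rows in ", path))
  if (anyDuplicated(tbl$Name)) {
    dup <- tbl$Name[duplicated(tbl$Name)][1]
    stop_validation(paste0("duplicate transcript name in ", path, ": ", dup))
  }
  if (any(!is.finite(tbl$TPM)) || any(tbl$TPM < 0)) {
    stop_validation(paste0("non-finite or negative TPM value in ", path))
  }
  if (is.null(sample_id)) sample_id <- tools::file_path_sans_ext(basename(path))
  tibble(
    sample_id = sample_id,
    name = tbl$Name,
    length = tbl$Length,
    effective_length = tbl$EffectiveLength,
    tpm = tbl$TPM,
    num_reads = tbl$NumReads
  )
}

#' Combine per-sample quantification tables into an expression matrix
#'
#' Assembles a genes-by-samples TPM table from a list of quantification
#' tables (one per sample, as returned by [read_quant_table()]). Under
#' `join = "strict"` every table must cover an identical gene set; under
#' `join = "intersect"` the common gene set is used and the number of
#' dropped genes is reported.
#'
#' @param tables List of quantification tibbles, each with a single
#'   `sample_id`.
#' @param join `"strict"` (default) or `"intersect"`.
#'
#' @return An expression tibble: character column `gene_id` followed by one
#'   numeric TPM column per sample, in input order. Under `"intersect"` the
#'   attribute `dropped_genes` holds the genes excluded from the union.
#' @export
combine_samples <- function(tables, join = c("strict", "intersect")) {
  join <- match.arg(join)
  if (!is.list(tables) || length(tables) < 2) {
    stop_validation("combine_samples() needs at least two quantification tables")
  }
  ids <- vapply(tables, function(t) t$sample_id[1], character(1))
  if (anyDuplicated(ids)) {
    stop_validation(paste0("duplicate sample identifier: ",
                           ids[duplicated(ids)][1]))
  }
  gene_sets <- lapply(tables, function(t) t$name)
  ref <- gene_sets[[1]]
  if (join == "strict") {
    for (j in seq_along(gene_sets)[-1]) {
      off <- c(setdiff(ref, gene_sets[[j]]), setdiff(gene_sets[[j]], ref))
      if (length(off) > 0) {
        stop_validation(paste0(
          "gene sets differ between samples '", ids[1], "' and '", ids[j],
          "' (first offending gene: ", off[1],
          "); use join = \"intersect\" to keep the common set"))
      }
    }
    keep <- ref
  } else {
    keep <- Reduce(intersect, gene_sets)
    if (length(keep) == 0) stop_validation("no genes common to all samples")
  }
  dropped <- setdiff(Reduce(union, gene_sets), keep)
  out <- tibble(gene_id = keep)
  for (j in seq_along(tables)) {
    tpm <- tables[[j]]$tpm[match(keep, tables[[j]]$name)]
    out[[ids[j]]] <- tpm
  }
  if (join == "intersect" && length(dropped) > 0) {
    inform(paste0("combine_samples(): dropped ", length(dropped),
                  " gene(s) absent from at least one sample"))
  }
  attr(out, "dropped_genes") <- dropped
  validate_expression(out)
}

#' Read a combined genes-by-samples TPM matrix from TSV
#'
#' Expects a header whose first field is `gene_id` (or any gene-id label)
#' followed by sample identifiers; one row per gene, `.` decimal separator.
#' Round-trips losslessly with [write_expression_tsv()].
#'
#' @param path Path to the TSV file.
#' @return An expression tibble (`gene_id` plus one numeric column per
#'   sample).
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop_io(paste0("file not found: ", path))
  if (file.size(path) == 0) stop_format(paste0("empty expression file: ", path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) {
    stop_format(paste0("expression file needs a gene-id column and at least one sample column: ", path))
  }
  # all columns come in as character; numeric conversion goes through R's
  # strtod, which is correctly rounded and round-trips %.17g output exactly
  tbl <- suppressWarnings(readr::read_tsv(
    path, col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  ))
  names(tbl)[1] <- "gene_id"
  if (nrow(tbl) == 0) stop_format(paste0("expression file has no data rows: ", path))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    # problems() counts the header line; report the data row
    stop_validation(paste0("malformed row in ", path, " at data row ",
                           probs$row[1] - 1, " (", probs$expected[1],
                           " expected, ", probs$actual[1], " found)"))
  }
  for (j in seq_along(tbl)[-1]) {
    num <- suppressWarnings(as.numeric(tbl[[j]]))
    bad <- which(is.na(num))
    if (length(bad) > 0) {
      stop_validation(paste0("non-numeric cell in ", path, " at data row ",
                             bad[1], ", column ", names(tbl)[j],
                             " (value '", tbl[[j]][bad[1]], "')"))
    }
    tbl[[j]] <- num
  }
  validate_expression(tbl)
}

#' Write an expression matrix to TSV
#'
#' @param expr Expression tibble (`gene_id` plus numeric sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  expr <- validate_expression(expr)
  # %.17g preserves every double bit-exactly across a write/read cycle
  out <- dplyr::mutate(expr, across(-"gene_id", ~ sprintf("%.17g", .x)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Remove genes with zero expression variance
#'
#' Pearson correlation is undefined for a gene whose expression is constant
#' across samples, so such genes are removed before any correlation is
#' computed. The removed identifiers are attached as the `removed_genes`
#' attribute and reported.
#'
#' @param expr Expression tibble.
#' @param quiet Suppress the removal message.
#' @return The filtered expression tibble with attribute `removed_genes`.
#' @export
filter_constant_genes <- function(expr, quiet = FALSE) {
  expr <- validate_expression(expr)
  x <- expr_values(expr)
  v <- rowSums((x - rowMeans(x))^2)
  keep <- v > 0
  if (!any(keep)) {
    stop_validation("all genes have constant expression; nothing to correlate")
  }
  removed <- expr$gene_id[!keep]
  if (length(removed) > 0 && !quiet) {
    inform(paste0("filter_constant_genes(): removed ", length(removed),
                  " zero-variance gene(s)"))
  }
  out <- expr[keep, , drop = FALSE]
  attr(out, "removed_genes") <- removed
  out
}

#' Log-transform TPM values
#'
#' @param expr Expression tibble.
#' @param method `"none"` (identity) or `"log2p1"` for log2(TPM + 1).
#' @return The transformed expression tibble.
#' @export
transform_expression <- function(expr, method = c("none", "log2p1")) {
  method <- match.arg(method)
  expr <- validate_expression(expr)
  if (method == "none") return(expr)
  dplyr::mutate(expr, across(-"gene_id", ~ log2(.x + 1)))
}

# ---- internal ---------------------------------------------------------------

# Checks the expression-tibble contract: unique character gene ids, unique
# sample columns, all values finite and non-negative.
validate_expression <- function(expr, require_nonneg = TRUE) {
  if (!is.data.frame(expr) || ncol(expr) < 2) {
    stop_validation("an expression table needs a gene_id column and at least one sample column")
  }
  expr <- as_tibble(expr)
  if (names(expr)[1] != "gene_id") names(expr)[1] <- "gene_id"
  if (!is.character(expr$gene_id)) expr$gene_id <- as.character(expr$gene_id)
  if (anyDuplicated(expr$gene_id)) {
    stop_validation(paste0("duplicate gene identifier: ",
                           expr$gene_id[duplicated(expr$gene_id)][1]))
  }
  if (anyDuplicated(names(expr))) {
    stop_validation(paste0("duplicate sample identifier: ",
                           names(expr)[duplicated(names(expr))][1]))
  }
  vals <- as.matrix(expr[-1])
  if (!is.numeric(vals)) stop_validation("sample columns must be numeric")
  if (any(!is.finite(vals))) stop_validation("expression values must be finite")
  if (require_nonneg && any(vals < 0)) {
    stop_validation("expression values must be non-negative (TPM scale)")
  }
  expr
}

# genes x samples numeric matrix with gene_id rownames
expr_values <- function(expr) {
  x <- as.matrix(expr[-1])
  rownames(x) <- expr$gene_id
  x
}
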