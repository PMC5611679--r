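#' Build a validated pipeline configuration
#'
#' Collects every knob of the co-expression analysis in one object.
#' Defaults follow the conventions of HRR-based co-expression studies:
#' cutoff `HRR <= 500`, raw hypergeometric p-value cutoff 0.001,
#' biological-process terms backed by at least 5 query genes.
#'
#' @param queries Character vector of query gene identifiers.
#' @param matrix Path to a combined expression TSV (mutually exclusive with
#'   `quant_dir`).
#' @param quant_dir Directory of per-sample quantification tables
#'   (`*.sf`/`*.tsv`), combined with [combine_samples()].
#' @param join Gene-set policy when combining quantification tables.
#' @param hrr_cutoff HRR cutoff (default 500).
#' @param inclusive Use `hrr <= cutoff` (default) rather than `<`.
#' @param transform `"none"` (default) or `"log2p1"`.
#' @param annotations Optional path to a gene/term/aspect TSV.
#' @param universe `"annotated"` (default) restricts the enrichment
#'   universe to annotated matrix genes; `"all"` uses every matrix gene.
#' @param aspect GO aspect for enrichment.
#' @param min_genes Minimum query genes per reported term.
#' @param alpha Raw p-value cutoff.
#' @param ortholog_map Optional path to a two-column ortholog TSV.
#' @param cross_species Optional named character vector mapping a query
#'   gene to a file holding its other-species ortholog's co-expressed list
#'   (one gene id per line).
#' @param output_dir Directory for run artifacts.
#' @param seed Seed recorded in the manifest (used by the `simulate`
#'   subcommand of the CLI; the analysis itself is deterministic).
#' @return A `hrr_config` list.
#' @export
pipeline_config <- function(queries,
                            matrix = NULL, quant_dir = NULL,
                            join = c("strict", "intersect"),
                            hrr_cutoff = 500L, inclusive = TRUE,
                            transform = c("none", "log2p1"),
                            annotations = NULL,
                            universe = c("annotated", "all"),
                            aspect = "biological_process",
                            min_genes = 5L, alpha = 0.001,
                            ortholog_map = NULL, cross_species = NULL,
                            output_dir = "hrrnet_out", seed = 1L) {
  join <- match.arg(join)
  transform <- match.arg(transform)
  universe <- match.arg(universe)
  if (is.null(matrix) == is.null(quant_dir)) {
    stop_validation("provide exactly one of `matrix` or `quant_dir`")
  }
  if (length(queries) < 1) stop_validation("at least one query gene is required")
  if (hrr_cutoff < 1) stop_validation("hrr_cutoff must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha must be in (0, 1)")
  if (min_genes < 1) stop_validation("min_genes must be >= 1")
  if (!is.null(cross_species)) {
    if (is.null(names(cross_species)) || any(!nzchar(names(cross_species)))) {
      stop_validation("cross_species must be a named vector: query gene -> list file")
    }
    if (is.null(ortholog_map)) {
      stop_validation("cross_species comparison needs an ortholog_map")
    }
  }
  structure(list(
    queries = as.character(queries), matrix = matrix, quant_dir = quant_dir,
    join = join, hrr_cutoff = as.integer(hrr_cutoff), inclusive = inclusive,
    transform = transform, annotations = annotations, universe = universe,
    aspect = aspect, min_genes = as.integer(min_genes), alpha = alpha,
    ortholog_map = ortholog_map, cross_species = cross_species,
    output_dir = output_dir, seed = as.integer(seed)
  ), class = "hrr_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `hrr_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_io(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop_validation(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$cross_species)) raw$cross_species <- unlist(raw$cross_species)
  do.call(pipeline_config, raw)
}

#' Run the full co-expression analysis pipeline
#'
#' Matrix in; per-query HRR neighborhoods, within-species overlap (Venn
#' region counts and a pairwise shared-gene matrix), optional
#' cross-species ortholog overlap, optional per-query GO enrichment, and a
#' run manifest out. Re-running on identical inputs reproduces identical
#' analysis outputs (the manifest records timings and is excluded from
#' that guarantee). On any stage failure, partial outputs are removed.
#'
#' @param config A `hrr_config` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results and the paths of
#'   all written artifacts.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "hrr_config"))
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  note <- function(...) if (!quiet) inform(paste0("[hrrnet] ", ...))
  timings <- list()
  timed <- function(stage, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      unlink(written)
      cls <- intersect(class(e), c(
        "hrrnet_validation_error", "hrrnet_format_error", "hrrnet_lookup_error",
        "hrrnet_size_error", "hrrnet_io_error", "hrrnet_error"))
      abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)),
            class = cls, parent = e)
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(path) { written <<- c(written, path); path }

  expr <- timed("load_matrix", function() {
    if (!is.null(config$matrix)) {
      read_expression_tsv(config$matrix)
    } else {
      files <- sort(list.files(config$quant_dir, pattern = "\\.(sf|tsv)$",
                               full.names = TRUE))
      if (length(files) < 2) {
        stop_validation("quant_dir must contain at least two quantification tables")
      }
      combine_samples(lapply(files, read_quant_table), join = config$join)
    }
  })
  note("loaded matrix: ", nrow(expr), " genes x ", ncol(expr) - 1, " samples")

  expr <- timed("filter", function() {
    e <- filter_constant_genes(expr, quiet = TRUE)
    transform_expression(e, config$transform)
  })
  n_removed <- length(attr(expr, "removed_genes"))
  if (n_removed > 0) note("removed ", n_removed, " zero-variance gene(s)")

  missing_q <- setdiff(config$queries, expr$gene_id)
  if (length(missing_q) > 0) {
    unlink(written)
    stop_lookup(paste0("query gene(s) absent from the filtered matrix: ",
                       paste(missing_q, collapse = ", ")))
  }

  neighborhoods <- timed("neighborhoods", function() {
    nbs <- lapply(config$queries, function(q) {
      nb <- hrr_neighborhood(expr, q, cutoff = config$hrr_cutoff,
                             inclusive = config$inclusive)
      write_neighborhood_tsv(nb, emit(file.path(out_dir, paste0("neighborhood_", q, ".tsv"))))
      nb
    })
    stats::setNames(nbs, config$queries)
  })
  note("extracted ", length(neighborhoods), " neighborhood(s)")

  gene_lists <- lapply(neighborhoods, function(nb) nb$partner)
  venn <- NULL
  if (length(gene_lists) >= 2) {
    venn <- timed("overlap", function() {
      v <- venn_regions(gene_lists[seq_len(min(length(gene_lists), 6))])
      write_venn_json(v, emit(file.path(out_dir, "venn_regions.json")))
      readr::write_tsv(pairwise_shared_matrix(gene_lists),
                       emit(file.path(out_dir, "pairwise_shared.tsv")),
                       progress = FALSE)
      v
    })
  }

  enrichments <- NULL
  if (!is.null(config$annotations)) {
    enrichments <- timed("enrichment", function() {
      ann <- read_annotations(config$annotations)
      res <- lapply(config$queries, function(q) {
        e <- go_enrich(neighborhoods[[q]]$partner, ann,
                       universe = expr$gene_id, aspect = config$aspect,
                       min_genes = config$min_genes, alpha = config$alpha,
                       annotated_only = config$universe == "annotated")
        write_enrichment_tsv(e, emit(file.path(out_dir, paste0("enrichment_", q, ".tsv"))))
        e
      })
      stats::setNames(res, config$queries)
    })
    note("enrichment written for ", length(enrichments), " query list(s)")
  }

  cross <- NULL
  if (!is.null(config$cross_species)) {
    cross <- timed("cross_species", function() {
      map <- read_ortholog_map(config$ortholog_map)
      res <- lapply(names(config$cross_species), function(q) {
        if (!q %in% names(neighborhoods)) {
          stop_lookup(paste0("cross_species pairing names unknown query: ", q))
        }
        yfile <- config$cross_species[[q]]
        if (!file.exists(yfile)) stop_io(paste0("gene-list file not found: ", yfile))
        ylist <- readLines(yfile)
        ylist <- ylist[nzchar(ylist)]
        cross_species_shared(neighborhoods[[q]]$partner, ylist, map)
      })
      names(res) <- names(config$cross_species)
      jsonlite::write_json(
        lapply(res, function(o) as.list(glance(o))),
        emit(file.path(out_dir, "cross_species_overlap.json")),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
      res
    })
  }

  manifest <- list(
    package = "hrrnet",
    version = as.character(utils::packageVersion("hrrnet")),
    r_version = R.version.string,
    config = unclass(config),
    inputs = input_checksums(config),
    n_genes_analyzed = nrow(expr),
    n_zero_variance_removed = n_removed,
    timings_sec = timings
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  note("run complete; artifacts in ", out_dir)
  invisible(list(
    expression = expr, neighborhoods = neighborhoods, venn = venn,
    enrichments = enrichments, cross_species = cross,
    files = c(written, file.path(out_dir, "manifest.json"))
  ))
}

# md5 checksums of every configured input file
input_checksums <- function(config) {
  paths <- c(config$matrix, config$annotations, config$ortholog_map,
             unname(config$cross_species))
  if (!is.null(config$quant_dir)) {
    paths <- c(paths, list.files(config$quant_dir, pattern = "\\.(sf|tsv)$",
                                 full.names = TRUE))
  }
  paths <- paths[!is.null(paths)]
  if (length(paths) == 0) return(list())
  sums <- tools::md5sum(paths)
  as.list(sums)
}
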