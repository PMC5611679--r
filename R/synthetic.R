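#' Simulate a TPM matrix with planted co-expression modules
#'
#' Single-latent-factor Gaussian model: each module `m` with loading
#' `beta_m` draws one latent condition vector `z_m` (standard normal over
#' samples); a gene in the module takes
#' `baseline + beta_m * z_m + noise`, a background gene `baseline + noise`,
#' with independent `noise ~ N(0, noise_sd)` per gene. The whole matrix is
#' then shifted by a constant so its minimum is exactly 0 (TPM-like
#' non-negativity) — Pearson correlation is shift-invariant, so the planted
#' structure is preserved exactly. The expected PCC between two genes of
#' the same module is `beta^2 / (beta^2 + noise_sd^2)`.
#'
#' Seeding is hierarchical: the latent factor of module `m` and the noise
#' of gene `g` each use their own stream derived from `seed`, so adding a
#' module or genes does not perturb earlier genes' draws.
#'
#' @param n_genes Total number of genes.
#' @param n_samples Number of samples (experimental conditions).
#' @param modules List of planted modules, each a list/vector with `size`
#'   (>= 2 genes) and `loading` (beta >= 0). Module genes occupy the first
#'   positions of the matrix, in module order.
#' @param noise_sd Standard deviation of per-gene noise (> 0).
#' @param baseline Baseline expression level (>= 0); does not affect
#'   correlations.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return A list with `expression` (expression tibble, genes `g00001`...,
#'   samples `s0001`...) and `truth` (list with `module_of` tibble mapping
#'   gene to module index, `NA` for background, and `params`).
#' @export
#' @examples
#' sim <- simulate_expression(n_genes = 60, n_samples = 30,
#'                            modules = list(c(size = 10, loading = 2)),
#'                            seed = 1)
#' dim(sim$expression)
simulate_expression <- function(n_genes = 1000L, n_samples = 100L,
                                modules = list(c(size = 50, loading = 2)),
                                noise_sd = 1, baseline = 10, seed = 1L) {
  if (n_genes < 2 || n_samples < 3) {
    stop_validation("need at least 2 genes and 3 samples")
  }
  if (noise_sd <= 0) stop_validation("noise_sd must be > 0")
  if (baseline < 0) stop_validation("baseline must be >= 0")
  sizes <- vapply(modules, function(m) as.numeric(m[["size"]]), numeric(1))
  loadings <- vapply(modules, function(m) as.numeric(m[["loading"]]), numeric(1))
  if (length(sizes) > 0 && (any(sizes < 2) || any(loadings < 0))) {
    stop_validation("every module needs size >= 2 and loading >= 0")
  }
  if (sum(sizes) > n_genes) {
    stop_validation("module sizes exceed the number of genes")
  }
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  sample_ids <- sprintf("s%04d", seq_len(n_samples))

  module_of <- rep(NA_integer_, n_genes)
  pos <- 1L
  for (m in seq_along(sizes)) {
    module_of[pos:(pos + sizes[m] - 1L)] <- m
    pos <- pos + as.integer(sizes[m])
  }

  # per-module latent streams (seed - m), per-gene noise streams (seed + g)
  latents <- lapply(seq_along(sizes), function(m) {
    withr::with_seed(mix_seed(seed, -m), stats::rnorm(n_samples))
  })
  x <- matrix(0, n_genes, n_samples)
  for (g in seq_len(n_genes)) {
    eps <- withr::with_seed(mix_seed(seed, g), stats::rnorm(n_samples, sd = noise_sd))
    m <- module_of[g]
    x[g, ] <- baseline + eps + if (is.na(m)) 0 else loadings[m] * latents[[m]]
  }
  x <- x - min(x) # non-negative, TPM-like; PCC unchanged

  expr <- as_tibble(as.data.frame(x))
  names(expr) <- sample_ids
  expr <- dplyr::bind_cols(tibble(gene_id = gene_ids), expr)
  truth <- list(
    module_of = tibble(gene_id = gene_ids, module = module_of),
    params = list(n_genes = n_genes, n_samples = n_samples,
                  sizes = sizes, loadings = loadings,
                  noise_sd = noise_sd, baseline = baseline, seed = seed)
  )
  list(expression = expr, truth = truth)
}

#' Simulate GO annotations with planted enriched terms
#'
#' Each planted module receives one dedicated `biological_process` term
#' annotating a random `module_coverage` fraction of its genes; background
#' terms are sprinkled over all genes independently at `background_rate`
#' per gene-term pair, with aspects assigned round-robin over the three GO
#' aspects so aspect filtering is exercised.
#'
#' @param truth Truth list from [simulate_expression()].
#' @param n_terms Number of background terms.
#' @param background_rate Probability that a given gene carries a given
#'   background term.
#' @param module_coverage Fraction of each module's genes annotated with
#'   its planted term, in `[0, 1]`.
#' @param seed Integer seed.
#' @return An annotation tibble (`gene`, `term`, `aspect`) with attribute
#'   `planted_terms`: a tibble mapping `module` to its planted `term`.
#' @export
simulate_annotations <- function(truth, n_terms = 50L, background_rate = 0.05,
                                 module_coverage = 0.8, seed = 1L) {
  if (module_coverage < 0 || module_coverage > 1) {
    stop_validation("module_coverage must be in [0, 1]")
  }
  if (background_rate < 0 || background_rate > 1) {
    stop_validation("background_rate must be in [0, 1]")
  }
  genes <- truth$module_of$gene_id
  mods <- sort(unique(stats::na.omit(truth$module_of$module)))
  planted <- tibble(module = mods,
                    term = sprintf("GO:PLANTED%03d", mods))
  rows <- list()
  for (m in mods) {
    members <- genes[!is.na(truth$module_of$module) & truth$module_of$module == m]
    hit <- withr::with_seed(mix_seed(seed, 7919 + m),
                            stats::runif(length(members)) < module_coverage)
    if (any(hit)) {
      rows[[length(rows) + 1]] <- tibble(
        gene = members[hit],
        term = planted$term[planted$module == m],
        aspect = "biological_process")
    }
  }
  if (n_terms > 0 && background_rate > 0) {
    bg_terms <- sprintf("GO:BG%04d", seq_len(n_terms))
    bg_aspects <- rep(unname(GO_ASPECTS), length.out = n_terms)
    hits <- withr::with_seed(
      mix_seed(seed, 104729),
      matrix(stats::runif(length(genes) * n_terms) < background_rate,
             nrow = length(genes)))
    idx <- which(hits, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      rows[[length(rows) + 1]] <- tibble(
        gene = genes[idx[, 1]],
        term = bg_terms[idx[, 2]],
        aspect = bg_aspects[idx[, 2]])
    }
  }
  if (length(rows) == 0) {
    stop_validation("simulation produced no annotations; raise coverage or background_rate")
  }
  ann <- dplyr::arrange(distinct(bind_rows(rows)), .data$gene, .data$term)
  attr(ann, "planted_terms") <- planted
  ann
}

#' Simulate a partly many-to-many two-species ortholog map
#'
#' A `one_to_one` fraction of species-X genes is paired bijectively with
#' distinct species-Y genes; a further `duplicated` fraction receives two
#' Y partners each (modelling post-duplication paralogy); remaining X
#' genes get no ortholog.
#'
#' @param genes_x,genes_y Character vectors of gene ids for each species.
#' @param one_to_one Fraction of X genes with exactly one Y partner.
#' @param duplicated Fraction of X genes with exactly two Y partners.
#' @param seed Integer seed.
#' @return A tibble with columns `gene_x`, `gene_y`; no duplicate pairs.
#' @export
simulate_orthologs <- function(genes_x, genes_y, one_to_one = 0.8,
                               duplicated = 0.1, seed = 1L) {
  if (one_to_one < 0 || one_to_one > 1 || duplicated < 0 || duplicated > 1 ||
      one_to_one + duplicated > 1) {
    stop_validation("one_to_one and duplicated must be fractions summing to <= 1")
  }
  genes_x <- unique(as.character(genes_x))
  genes_y <- unique(as.character(genes_y))
  n1 <- round(one_to_one * length(genes_x))
  n2 <- round(duplicated * length(genes_x))
  if (length(genes_y) < n1 + 2 * (n2 > 0)) {
    stop_validation("not enough species-Y genes for the requested map structure")
  }
  withr::with_seed(mix_seed(seed, 15485863), {
    xs <- sample(genes_x, n1 + n2)
    y_one <- sample(genes_y, n1)
    pairs <- tibble(gene_x = xs[seq_len(n1)], gene_y = y_one)
    if (n2 > 0) {
      x_dup <- xs[n1 + seq_len(n2)]
      y_pool <- setdiff(genes_y, y_one)
      if (length(y_pool) < 2) y_pool <- genes_y
      dup <- bind_rows(lapply(x_dup, function(x) {
        tibble(gene_x = x, gene_y = sample(y_pool, 2))
      }))
      pairs <- bind_rows(pairs, dup)
    }
    dplyr::arrange(distinct(pairs), .data$gene_x, .data$gene_y)
  })
}

#' Write a truth object to JSON
#'
#' @param truth Truth list from [simulate_expression()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(module_of = truth$module_of, params = truth$params),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
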