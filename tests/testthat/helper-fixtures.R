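# Shared fixtures and independent oracles, built in code at test time.

# 4-gene toy matrix with hand-computable correlations:
# PCC(A,B) = 1, PCC(A,C) = -1, PCC(A,D) = 0.8
toy_matrix <- function() {
  tibble::tibble(
    gene_id = c("A", "B", "C", "D"),
    s1 = c(1, 2, 4, 1),
    s2 = c(2, 4, 3, 3),
    s3 = c(3, 6, 2, 2),
    s4 = c(4, 8, 1, 4)
  )
}

# random strictly-positive expression tibble, deterministic given seed
random_matrix <- function(n_genes, n_samples, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(stats::rgamma(n_genes * n_samples, shape = 2, scale = 5),
                n_genes, n_samples)
    expr <- tibble::as_tibble(as.data.frame(x))
    names(expr) <- sprintf("s%03d", seq_len(n_samples))
    dplyr::bind_cols(
      tibble::tibble(gene_id = sprintf("g%04d", seq_len(n_genes))), expr)
  })
}

write_quant_fixture <- function(path, names, tpm,
                                lengths = rep(1000L, length(names))) {
  lines <- c("Name\tLength\tEffectiveLength\tTPM\tNumReads",
             sprintf("%s\t%d\t%.1f\t%s\t%.1f", names, lengths,
                     lengths - 99.5, format(tpm, trim = TRUE), tpm * 10))
  writeLines(lines, path)
  path
}

# Exhaustive-sum oracle for the upper-tail hypergeometric probability,
# independent of phyper: direct evaluation of the combinatorial sum.
hyper_upper_oracle <- function(k, K, n, N) {
  i <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Brute-force per-query neighborhood from an hrr_all_pairs edge table.
oracle_neighborhood <- function(edges, query, cutoff, inclusive = TRUE) {
  e <- edges[edges$gene_a == query | edges$gene_b == query, ]
  keep <- if (inclusive) e$hrr <= cutoff else e$hrr < cutoff
  e <- e[keep, ]
  partner <- ifelse(e$gene_a == query, e$gene_b, e$gene_a)
  rank_qp <- ifelse(e$gene_a == query, e$rank_ab, e$rank_ba)
  rank_pq <- ifelse(e$gene_a == query, e$rank_ba, e$rank_ab)
  out <- tibble::tibble(partner = as.character(partner),
                        pcc = as.double(e$pcc),
                        rank_query_to_partner = as.integer(rank_qp),
                        rank_partner_to_query = as.integer(rank_pq),
                        hrr = as.integer(e$hrr))
  out[order(out$hrr, out$partner, method = "radix"), ]
}
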