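#' Derive a prognosis gene signature at a p-value cutoff
#'
#' Univariate Cox screen of every gene against the endpoint; genes at or
#' below the cutoff form the signature. The conventional tiers are 2e-6
#' (genome-wide significant after Bonferroni correction at ~25k genes),
#' 5e-4 and 0.05 (liberal tiers for cross-study comparison), and 0.01.
#' By default no clinicopathologic adjustment is applied, keeping the
#' signature comparable with published lists derived without adjustment.
#'
#' @param expr numeric matrix, genes in rows, patients in columns.
#' @param outcome a [survival_outcome()] aligned with the columns.
#' @param p_cutoff inclusion threshold on the two-sided Wald p.
#' @param adjust optional adjustment covariate matrix (patients x q); used
#'   only when `adjusted = TRUE`.
#' @param adjusted include the adjustment covariates in the screen.
#' @return List of class `gene_signature`: `genes`, per-gene `p`,
#'   `p_cutoff`, and `universe` (all non-degenerate gene ids screened).
#' @export
derive_signature <- function(expr, outcome, p_cutoff = 5e-4,
                             adjust = NULL, adjusted = FALSE) {
  expr <- as.matrix(expr)
  det <- suppressWarnings(univariate_screen(
    t(expr), outcome, adjust = if (adjusted) adjust else NULL,
    details = TRUE))
  elig <- det[!det$degenerate, , drop = FALSE]
  hit <- elig[elig$p <= p_cutoff, , drop = FALSE]
  hit <- hit[order(hit$p, hit$feature), , drop = FALSE]
  structure(list(genes = hit$feature, p = setNames(hit$p, hit$feature),
                 p_cutoff = p_cutoff, adjusted = adjusted,
                 universe = elig$feature),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("Gene signature: %d genes at p <= %g (universe %d%s)\n",
              length(x$genes), x$p_cutoff, length(x$universe),
              if (x$adjusted) ", adjusted" else ""))
  invisible(x)
}

#' Hypergeometric overlap enrichment of two gene sets
#'
#' Tests whether sets A and B share more genes than expected for random
#' draws from the universe. The one-sided upper-tail p is
#' `P(X >= k)` with `X ~ Hypergeometric(N, |B|, |A|)`; fold enrichment is
#' `k * N / (|A| * |B|)` (0 when the overlap is empty). Genes outside the
#' universe are dropped with a warning and counted.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @param universe character vector of all eligible gene ids.
#' @return List of class `overlap_result`: `n_a`, `n_b`, `n_universe`,
#'   `overlap` (k), `expected`, `fold`, `p`, and `n_dropped`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L)
    ps_stop("empty universe", "schema_error")
  a0 <- unique(as.character(set_a)); b0 <- unique(as.character(set_b))
  a <- intersect(a0, universe); b <- intersect(b0, universe)
  n_dropped <- (length(a0) - length(a)) + (length(b0) - length(b))
  if (n_dropped > 0L)
    ps_warn(sprintf("%d gene(s) outside the universe dropped", n_dropped),
            "universe_drop_warning")
  N <- length(universe)
  k <- length(intersect(a, b))
  expected <- length(a) * length(b) / N
  fold <- if (k == 0L) 0 else k / expected
  p <- phyper(k - 1L, length(b), N - length(b), length(a),
              lower.tail = FALSE)
  structure(list(n_a = length(a), n_b = length(b), n_universe = N,
                 overlap = k, expected = expected, fold = fold,
                 p = min(max(p, .Machine$double.xmin), 1),
                 n_dropped = n_dropped),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Overlap %d of |A|=%d x |B|=%d in N=%d (expected %.2f): fold %.2f, p = %.3g\n",
    x$overlap, x$n_a, x$n_b, x$n_universe, x$expected, x$fold, x$p))
  invisible(x)
}

#' Two-part membership table across published gene lists
#'
#' Part 1 lists genes reaching genome-wide significance in this study
#' (Wald p at or below `strict_cutoff`). Part 2 lists genes present in at
#' least two of the published lists, with a presence indicator ("1"/"-")
#' per list and this study's p shown only when at or below
#' `liberal_cutoff` ("-" otherwise).
#'
#' @param signature a [derive_signature()] result built at a liberal cutoff
#'   (its per-gene p values feed both parts).
#' @param published named list of character vectors (published gene lists).
#' @param strict_cutoff part-1 threshold (default 2e-6).
#' @param liberal_cutoff display threshold for part 2 (default 0.01).
#' @return List with data frames `genome_wide` and `recurrent`.
#' @export
multi_list_membership <- function(signature, published,
                                  strict_cutoff = 2e-6,
                                  liberal_cutoff = 0.01) {
  if (length(published) == 0L)
    ps_stop("no published lists supplied", "schema_error")
  p_all <- signature$p
  part1_genes <- names(p_all)[p_all <= strict_cutoff]
  part1 <- data.frame(gene = part1_genes,
                      p = unname(p_all[part1_genes]),
                      stringsAsFactors = FALSE)
  part1 <- part1[order(part1$p, part1$gene), , drop = FALSE]
  rownames(part1) <- NULL

  published <- lapply(published, function(x) unique(toupper(x)))
  all_genes <- sort(unique(unlist(published)))
  pres <- vapply(published, function(lst) all_genes %in% lst,
                 logical(length(all_genes)))
  pres <- matrix(pres, nrow = length(all_genes),
                 dimnames = list(all_genes, names(published)))
  recurrent_genes <- all_genes[rowSums(pres) >= 2L]
  p_here <- p_all[match(recurrent_genes, toupper(names(p_all)))]
  p_disp <- ifelse(!is.na(p_here) & p_here <= liberal_cutoff,
                   formatC(p_here, format = "e", digits = 2), "-")
  ind <- ifelse(pres[recurrent_genes, , drop = FALSE], "1", "-")
  part2 <- data.frame(gene = recurrent_genes, p = p_disp, ind,
                      stringsAsFactors = FALSE, check.names = FALSE)
  rownames(part2) <- NULL
  list(genome_wide = part1, recurrent = part2)
}
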