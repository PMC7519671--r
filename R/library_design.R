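#' Promoter catalog for combinatorial library design
#'
#' The catalog lists, per target gene, the bin of candidate promoters with a
#' relative strength (normalized within bin) and an empirical pick
#' probability (the frequency at which each promoter is expected among
#' correctly assembled colonies; uniform when unknown).
#'
#' @param catalog data.frame with columns `gene`, `promoter`,
#'   `relative_strength`, `pick_probability`. Gene order of first appearance
#'   is the canonical gene order.
#' @return validated data.frame of class `promoter_catalog`.
#' @export
promoter_catalog <- function(catalog) {
  need <- c("gene", "promoter", "relative_strength", "pick_probability")
  if (!all(need %in% names(catalog)))
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  catalog$gene <- as.character(catalog$gene)
  catalog$promoter <- as.character(catalog$promoter)
  genes <- unique(catalog$gene)
  for (g in genes) {
    bin <- catalog[catalog$gene == g, ]
    if (nrow(bin) < 1) stop("gene ", g, ": empty promoter bin")
    if (anyDuplicated(bin$promoter)) stop("gene ", g, ": duplicate promoters")
    if (abs(sum(bin$relative_strength) - 1) > 1e-9)
      stop("gene ", g, ": relative strengths must sum to 1")
    if (abs(sum(bin$pick_probability) - 1) > 1e-9)
      stop("gene ", g, ": pick probabilities must sum to 1")
  }
  attr(catalog, "genes") <- genes
  class(catalog) <- c("promoter_catalog", "data.frame")
  catalog
}

#' @export
print.promoter_catalog <- function(x, ...) {
  genes <- catalog_genes(x)
  counts <- vapply(genes, function(g) sum(x$gene == g), integer(1))
  cat("Promoter catalog:", length(genes), "genes,",
      nrow(x), "promoters (design space ",
      format(prod(counts), big.mark = ","), ")\n", sep = " ")
  print.data.frame(x, ...)
  invisible(x)
}

#' @rdname promoter_catalog
#' @param x a `promoter_catalog`.
#' @export
catalog_genes <- function(x) attr(x, "genes")

catalog_bins <- function(x) {
  lapply(stats::setNames(nm = catalog_genes(x)),
         function(g) x[x$gene == g, , drop = FALSE])
}

#' Default five-gene, six-promoter catalog
#'
#' The study design: five precursor-supply genes (PCK1, TAL1, TKL1, CDC19,
#' PFK1), each controlled by a bin of six promoters (the native promoter
#' plus five spanning a wide expression range), for a 6^5 = 7776 design
#' space. Relative strengths are a fixed graded series per bin. Pick
#' probabilities are uniform by default; `picks = "skewed"` gives each bin a
#' graded skew anchored at the observed extremes of library representation
#' (rarest promoter ~1\%, commonest ~35\%).
#'
#' @param picks `"uniform"` or `"skewed"`.
#' @return a [promoter_catalog].
#' @export
default_catalog <- function(picks = c("uniform", "skewed")) {
  picks <- match.arg(picks)
  bins <- list(
    PCK1  = c("pPCK1", "pREV1", "pRNR2", "pCYC1", "pTEF2", "pTDH3"),
    TAL1  = c("pTAL1", "pTEF1", "pADH1", "pPGI1", "pTPI1", "pENO2"),
    TKL1  = c("pTKL1", "pPGK1", "pMLS1", "pGPD1", "pHXT7", "pCUP1"),
    CDC19 = c("pCDC19", "pACT1", "pTPK2", "pPDC1", "pFBA1", "pGPM1"),
    PFK1  = c("pPFK1", "pTPK1", "pSED1", "pPYK2", "pADH2", "pICL1"))
  # graded strengths covering weak..strong, identical shape per bin
  strength <- c(0.30, 0.02, 0.05, 0.10, 0.18, 0.35)
  pick <- switch(picks,
                 uniform = rep(1 / 6, 6),
                 skewed = c(0.20, 0.01, 0.35, 0.14, 0.12, 0.18))
  promoter_catalog(data.frame(
    gene = rep(names(bins), each = 6),
    promoter = unlist(bins, use.names = FALSE),
    relative_strength = rep(strength, times = 5),
    pick_probability = rep(pick, times = 5),
    stringsAsFactors = FALSE))
}

#' Canonical genotype key
#'
#' Joins gene:promoter pairs in catalog gene order, giving an injective
#' string key over the design space.
#'
#' @param genotype data.frame with one column per catalog gene holding
#'   promoter names (one row per genotype).
#' @param catalog a [promoter_catalog].
#' @return character vector of keys.
#' @export
genotype_key <- function(genotype, catalog) {
  genes <- catalog_genes(catalog)
  parts <- lapply(genes, function(g) paste0(g, ":", genotype[[g]]))
  do.call(paste, c(parts, sep = "|"))
}

#' Enumerate the full combinatorial design space
#'
#' All combinations of one promoter per gene, in lexicographic gene-major
#' order (the first catalog gene varies slowest).
#'
#' @param catalog a [promoter_catalog].
#' @return data.frame with a `key` column and one promoter column per gene;
#'   `prod(bin sizes)` rows, no duplicates.
#' @export
enumerate_design_space <- function(catalog) {
  bins <- catalog_bins(catalog)
  genes <- catalog_genes(catalog)
  grid <- expand.grid(rev(lapply(bins, `[[`, "promoter")),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(genes)), drop = FALSE]
  names(grid) <- genes
  out <- cbind(data.frame(key = genotype_key(grid, catalog),
                          stringsAsFactors = FALSE), grid)
  rownames(out) <- NULL
  out
}

#' DNA parts accounting for one-pot assembly
#'
#' Each assembly joins one promoter and one ORF unit per gene plus fixed
#' parts (selection-marker cassette and flanking homology arms). The parts
#' pool for the one-pot transformation holds every promoter once, one ORF
#' per gene, and the fixed parts.
#'
#' @param catalog a [promoter_catalog].
#' @param n_markers number of marker cassettes per assembly (default 1).
#' @param n_homology_arms number of homology arms per assembly (default 2).
#' @return list with `parts_per_assembly` and `unique_parts_pool`.
#' @export
parts_accounting <- function(catalog, n_markers = 1, n_homology_arms = 2) {
  n_genes <- length(catalog_genes(catalog))
  n_prom <- nrow(catalog)
  list(parts_per_assembly = 2L * n_genes + n_markers + n_homology_arms,
       unique_parts_pool = n_prom + n_genes + n_markers + n_homology_arms)
}

#' Monte Carlo estimate of library coverage
#'
#' Repeatedly samples `n_colonies` colonies; each is correctly assembled
#' with probability `p_correct`, and each correct colony draws one promoter
#' per gene independently from the catalog's pick probabilities. Reports the
#' mean and sd of the number of unique genotypes over replicates, and the
#' expected coverage of the full design space.
#'
#' @param catalog a [promoter_catalog].
#' @param n_colonies colonies sampled per replicate.
#' @param p_correct probability a colony is a correct assembly.
#' @param n_reps Monte Carlo replicates.
#' @param seed integer seed (local RNG; does not disturb the global stream).
#' @return list with `mean_unique`, `sd_unique`, `coverage`
#'   (mean_unique / design-space size), `space_size`, and the call settings.
#' @export
simulate_coverage <- function(catalog, n_colonies = 10000, p_correct = 0.82,
                              n_reps = 10000, seed = 1) {
  stopifnot(n_colonies >= 1, n_reps >= 1, p_correct >= 0, p_correct <= 1)
  bins <- catalog_bins(catalog)
  sizes <- vapply(bins, nrow, integer(1))
  G <- prod(sizes)
  base <- cumprod(c(1, sizes[-length(sizes)]))
  uniq <- local_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      n_ok <- stats::rbinom(1, n_colonies, p_correct)
      if (n_ok == 0) return(0L)
      code <- numeric(n_ok)
      for (j in seq_along(bins)) {
        idx <- sample.int(sizes[j], n_ok, replace = TRUE,
                          prob = bins[[j]]$pick_probability)
        code <- code + (idx - 1) * base[j]
      }
      length(unique(code))
    }, integer(1))
  })
  list(mean_unique = mean(uniq), sd_unique = stats::sd(uniq),
       coverage = mean(uniq) / G, space_size = G,
       n_colonies = n_colonies, p_correct = p_correct, n_reps = n_reps,
       seed = seed)
}

#' Summarize genotyping outcomes of a sampled library
#'
#' Percentages use the stated denominators: cured and correctly assembled
#' out of sufficiently growing colonies; duplicate genotypes out of fully
#' filtered library genotype calls (growing, cured, correctly assembled,
#' call present, controls excluded). Values are unrounded; round only at
#' the reporting layer. Zero denominators yield `NA`, never 0.
#'
#' @param sample data.frame with logical columns `growing`, `cured`,
#'   `correctly_assembled`, `is_control` (optional, default all FALSE) and a
#'   character `genotype_call` (`NA` when genotyping failed).
#' @return list of percentages and the underlying counts.
#' @export
summarize_genotyping <- function(sample) {
  stopifnot(nrow(sample) >= 1)
  if (is.null(sample$is_control)) sample$is_control <- FALSE
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  n_growing <- sum(sample$growing)
  n_cured <- sum(sample$growing & sample$cured)
  n_correct <- sum(sample$growing & sample$correctly_assembled)
  filtered <- sample$growing & sample$cured & sample$correctly_assembled &
    !is.na(sample$genotype_call)
  lib <- filtered & !sample$is_control
  calls <- sample$genotype_call[lib]
  n_dup <- sum(duplicated(calls))
  list(pct_cured = pct(n_cured, n_growing),
       pct_correct = pct(n_correct, n_growing),
       pct_duplicates = pct(n_dup, length(calls)),
       n_colonies = nrow(sample), n_growing = n_growing,
       n_cured = n_cured, n_correct = n_correct,
       n_filtered_library = length(calls), n_duplicates = n_dup)
}
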