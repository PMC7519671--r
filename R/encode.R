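#' One-hot encode promoter genotypes
#'
#' Deterministic block layout: genes in catalog order, promoters in catalog
#' order within each gene block; each row has exactly one 1 per gene block
#' (dimension = total number of promoters, 30 for the default catalog).
#' The encoding is invertible via [one_hot_decode].
#'
#' @param genotypes data.frame with one promoter column per catalog gene,
#'   or a character vector of canonical keys (see [genotype_key]).
#' @param catalog a [promoter_catalog].
#' @return numeric matrix, rows = genotypes, columns named `gene:promoter`.
#' @export
one_hot_encode <- function(genotypes, catalog) {
  if (is.character(genotypes)) genotypes <- decode_genotype_key(genotypes, catalog)
  genes <- catalog_genes(catalog)
  cols <- paste(catalog$gene, catalog$promoter, sep = ":")
  X <- matrix(0, nrow(genotypes), length(cols),
              dimnames = list(NULL, cols))
  for (g in genes) {
    lab <- paste(g, genotypes[[g]], sep = ":")
    j <- match(lab, cols)
    if (anyNA(j)) {
      bad <- which(is.na(j))[1]
      stop("unknown promoter for gene ", g, ": ", genotypes[[g]][bad])
    }
    X[cbind(seq_len(nrow(genotypes)), j)] <- 1
  }
  X
}

#' @rdname one_hot_encode
#' @param X one-hot matrix as produced by [one_hot_encode].
#' @export
one_hot_decode <- function(X, catalog) {
  genes <- catalog_genes(catalog)
  out <- lapply(stats::setNames(nm = genes), function(g) {
    block <- which(catalog$gene == g)
    proms <- catalog$promoter[block]
    idx <- apply(X[, block, drop = FALSE], 1, function(r) {
      k <- which(r == 1)
      if (length(k) != 1) stop("row violates one-hot block constraint for gene ", g)
      k
    })
    proms[idx]
  })
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  cbind(data.frame(key = genotype_key(out, catalog),
                   stringsAsFactors = FALSE), out)
}

#' Parse canonical genotype keys back into promoter columns
#' @param keys character vector of keys like `"PCK1:pPCK1|TAL1:pTAL1|..."`.
#' @inheritParams one_hot_encode
#' @return data.frame with one promoter column per gene.
#' @export
decode_genotype_key <- function(keys, catalog) {
  genes <- catalog_genes(catalog)
  parts <- strsplit(keys, "|", fixed = TRUE)
  bad <- lengths(parts) != length(genes)
  if (any(bad)) stop("malformed genotype key: ", keys[which(bad)[1]])
  out <- lapply(seq_along(genes), function(i) {
    p <- vapply(parts, `[[`, character(1), i)
    pre <- paste0(genes[i], ":")
    if (!all(startsWith(p, pre)))
      stop("key field ", i, " does not match gene ", genes[i])
    substring(p, nchar(pre) + 1)
  })
  names(out) <- genes
  as.data.frame(out, stringsAsFactors = FALSE)
}
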