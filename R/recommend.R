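#' Expected improvement of a Gaussian prediction over an incumbent
#'
#' For predictive mean `mu`, sd `sigma` and incumbent best `f_best`,
#' EI = (mu - f*) Phi(z) + sigma phi(z) with z = (mu - f*)/sigma; at
#' sigma = 0 it degenerates to max(mu - f*, 0). Vectorized.
#'
#' @param mu predictive mean (MFI/h).
#' @param sigma predictive sd (MFI/h), >= 0.
#' @param f_best incumbent best observed value (MFI/h).
#' @return expected improvement (MFI/h), >= 0.
#' @export
expected_improvement <- function(mu, sigma, f_best) {
  stopifnot(all(sigma >= 0))
  d <- mu - f_best
  out <- pmax(d, 0)
  pos <- sigma > 0
  if (any(pos)) {
    z <- d[pos] / sigma[pos]
    out[pos] <- d[pos] * stats::pnorm(z) + sigma[pos] * stats::dnorm(z)
  }
  out
}

#' Rank unseen designs for the next build round
#'
#' Enumerates the full combinatorial design space, drops already-seen
#' designs, scores every remaining candidate with the ensemble's predictive
#' distribution and returns the top `n`. Exploit mode ranks by predictive
#' mean; explore mode by expected improvement over the best observed
#' training mean (so high predictive uncertainty is rewarded). Ties break
#' lexicographically on the genotype key for reproducibility.
#'
#' @param object a fitted [trp_ensemble].
#' @param catalog a [promoter_catalog]; defaults to the model's.
#' @param mode `"exploit"` (rank by mu) or `"explore"` (rank by EI).
#' @param n number of recommendations.
#' @param exclude character vector of genotype keys to exclude; defaults to
#'   the model's training genotypes (recommend unseen designs only).
#' @param f_best incumbent for EI; defaults to the maximum observed
#'   training response.
#' @return data.frame of class `trp_recommendations`: rank, key, per-gene
#'   promoters, `mu`, `sigma`, `score`, `mode`.
#' @export
recommend_designs <- function(object, catalog = object$catalog,
                              mode = c("exploit", "explore"), n = 30,
                              exclude = object$keys,
                              f_best = max(object$y)) {
  mode <- match.arg(mode)
  space <- enumerate_design_space(catalog)
  if (is.null(exclude)) exclude <- character(0)
  cand <- space[!space$key %in% exclude, , drop = FALSE]
  if (n > nrow(cand))
    stop("requested ", n, " recommendations but only ", nrow(cand),
         " unseen designs remain (space ", nrow(space), ", excluded ",
         length(unique(exclude)), ")")
  pr <- predict(object, cand$key)
  score <- if (mode == "exploit") pr$mu
           else expected_improvement(pr$mu, pr$sigma, f_best)
  ord <- order(-score, cand$key)
  top <- utils::head(ord, n)
  out <- cbind(data.frame(rank = seq_len(n)), cand[top, , drop = FALSE],
               mu = pr$mu[top], sigma = pr$sigma[top], score = score[top],
               mode = mode, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("trp_recommendations", "data.frame")
  out
}

#' @export
print.trp_recommendations <- function(x, ...) {
  cat(x$mode[1], "recommendations (top", nrow(x), "unseen designs)\n")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4,
                   row.names = FALSE)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more\n")
  invisible(x)
}

#' Overlap between two recommendation sets
#'
#' @param a,b recommendation data.frames (or anything with a `key` column /
#'   character vectors of keys).
#' @return list with `count` (shared genotypes) and `fraction`
#'   (count / |a|).
#' @export
recommendation_overlap <- function(a, b) {
  ka <- if (is.character(a)) a else a$key
  kb <- if (is.character(b)) b else b$key
  count <- length(intersect(ka, kb))
  list(count = count,
       fraction = if (length(ka)) count / length(ka) else NA_real_)
}
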