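#' Reaction scores: average flux fold change under suboptimal growth
#'
#' For each reaction, the score is the mean over scan conditions of the
#' absolute flux fold change relative to the maximum-growth reference,
#' with a pseudo-flux guard against zero reference fluxes:
#' \deqn{s_r = mean_f (|v_f| + \delta) / (|v_{ref}| + \delta).}
#' Reactions carrying less than `pseudo_flux` in the reference and in every
#' scan condition are marked unscored (score `NA`): a fold change of 1 there
#' would be an artifact of the guard, not a signal.
#'
#' @param scan list of [solve_pfba] distributions at suboptimal fractions.
#' @param reference the maximum-growth [solve_pfba] distribution.
#' @param pseudo_flux the guard flux delta (mmol/gDW/h).
#' @return data.frame with columns `reaction`, `score`, `scored`,
#'   `direction_change` (TRUE when any scan flux has opposite sign to a
#'   nonzero reference flux).
#' @export
reaction_scores <- function(scan, reference, pseudo_flux = 1e-4) {
  rxns <- names(reference$fluxes)
  for (d in scan) {
    if (!setequal(names(d$fluxes), rxns)) {
      diff <- c(setdiff(names(d$fluxes), rxns), setdiff(rxns, names(d$fluxes)))
      stop("scan and reference reaction sets differ: ",
           paste(unique(diff), collapse = ", "))
    }
  }
  vref <- abs(reference$fluxes[rxns])
  vmat <- vapply(scan, function(d) abs(d$fluxes[rxns]), numeric(length(rxns)))
  vmat <- matrix(vmat, nrow = length(rxns))
  smat <- vapply(scan, function(d) d$fluxes[rxns], numeric(length(rxns)))
  smat <- matrix(smat, nrow = length(rxns))
  score <- rowMeans((vmat + pseudo_flux) / (vref + pseudo_flux))
  scored <- !(vref < pseudo_flux & apply(vmat < pseudo_flux, 1, all))
  score[!scored] <- NA_real_
  dirch <- vapply(seq_along(rxns), function(i) {
    rv <- reference$fluxes[rxns[i]]
    any(rv != 0 & smat[i, ] != 0 & sign(smat[i, ]) != sign(rv))
  }, logical(1))
  data.frame(reaction = rxns, score = score, scored = scored,
             direction_change = dirch, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Gene scores: average of associated reaction scores
#'
#' A gene's score is the unweighted mean of the scores of its associated
#' scored reactions. A score above one classifies the gene as an
#' overexpression target (its reactions gain flux as production shifts
#' toward tryptophan); below one, a downregulation target; equal to one,
#' neutral. AND/OR structure of gene-reaction rules is deliberately ignored
#' (plain averaging over associated reactions).
#'
#' @param reaction_part output of [reaction_scores].
#' @param model the [stoich_model] providing gene-reaction associations.
#' @param genes genes to score; defaults to all genes in the model.
#' @param tol scores within `tol` of 1 classify as neutral.
#' @return data.frame with columns `gene`, `score`, `classification`
#'   (`overexpress`/`downregulate`/`neutral`, `NA` when unscored) and
#'   `n_reactions` (scored reactions contributing). Genes with no associated
#'   reactions are reported in the `"unmapped"` attribute, not dropped
#'   silently.
#' @export
gene_scores <- function(reaction_part, model, genes = model_genes(model),
                        tol = 1e-9) {
  rs <- stats::setNames(reaction_part$score, reaction_part$reaction)
  assoc <- lapply(model$reactions, `[[`, "genes")
  res <- lapply(genes, function(g) {
    rxns <- names(assoc)[vapply(assoc, function(a) g %in% a, logical(1))]
    if (!length(rxns)) return(NULL)
    sc <- rs[rxns]
    sc <- sc[!is.na(sc)]
    if (!length(sc))
      return(data.frame(gene = g, score = NA_real_,
                        classification = NA_character_, n_reactions = 0L,
                        stringsAsFactors = FALSE))
    s <- mean(sc)
    cls <- if (abs(s - 1) <= tol) "neutral" else if (s > 1) "overexpress" else "downregulate"
    data.frame(gene = g, score = s, classification = cls,
               n_reactions = length(sc), stringsAsFactors = FALSE)
  })
  unmapped <- genes[vapply(res, is.null, logical(1))]
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(gene = character(0), score = numeric(0),
                      classification = character(0), n_reactions = integer(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  out
}

#' Score all genes of a model for over-/under-expression
#'
#' Convenience wrapper: reference pFBA solve at maximum growth, suboptimal
#' scan over `fractions`, reaction scores, gene scores.
#'
#' @inheritParams suboptimal_scan
#' @inheritParams reaction_scores
#' @return list of class `target_scores` with elements `reference`, `scan`,
#'   `fractions`, `reaction_scores`, `gene_scores`, `pseudo_flux`.
#' @export
score_targets <- function(model, fractions = default_fraction_grid(),
                          pseudo_flux = 1e-4) {
  reference <- solve_pfba(model, 1)
  scan <- suboptimal_scan(model, fractions)
  rsc <- reaction_scores(scan, reference, pseudo_flux)
  gsc <- gene_scores(rsc, model)
  structure(list(reference = reference, scan = scan, fractions = fractions,
                 reaction_scores = rsc, gene_scores = gsc,
                 pseudo_flux = pseudo_flux),
            class = "target_scores")
}

#' @export
print.target_scores <- function(x, ...) {
  g <- x$gene_scores
  cat("Gene target scores over", length(x$fractions), "suboptimal fractions\n")
  cat(sprintf("  %d genes: %d overexpress, %d downregulate, %d neutral, %d unscored\n",
              nrow(g), sum(g$classification == "overexpress", na.rm = TRUE),
              sum(g$classification == "downregulate", na.rm = TRUE),
              sum(g$classification == "neutral", na.rm = TRUE),
              sum(is.na(g$classification))))
  invisible(x)
}

#' Classified targets shared between two scoring runs
#'
#' Used to find candidates robust across carbon-source regimes (e.g., the
#' glucose and ethanol scans): the overlap is the per-class intersection of
#' classified gene sets.
#'
#' @param a,b `target_scores` objects (or their `gene_scores` data.frames).
#' @return list with `overexpress` and `downregulate` character vectors.
#' @export
target_overlap <- function(a, b) {
  ga <- if (inherits(a, "target_scores")) a$gene_scores else a
  gb <- if (inherits(b, "target_scores")) b$gene_scores else b
  pick <- function(g, cls) g$gene[!is.na(g$classification) & g$classification == cls]
  list(overexpress = intersect(pick(ga, "overexpress"), pick(gb, "overexpress")),
       downregulate = intersect(pick(ga, "downregulate"), pick(gb, "downregulate")))
}

#' Pathway overrepresentation of predicted targets
#'
#' Two-sided Fisher's exact test per pathway on the 2x2 table of pathway
#' membership against target membership, over an explicit gene universe.
#'
#' @param targets character vector of target gene ids (subset of `universe`).
#' @param pathway_membership named list, pathway -> gene ids.
#' @param universe character vector of all genes considered.
#' @return data.frame with per-pathway table cells `a` (target, in pathway),
#'   `b` (non-target, in pathway), `c` (target, outside), `d` (non-target,
#'   outside), fold representation and the two-sided exact p-value.
#' @export
pathway_enrichment <- function(targets, pathway_membership, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  if (!all(targets %in% universe))
    stop("targets not in universe: ",
         paste(setdiff(targets, universe), collapse = ", "))
  res <- lapply(names(pathway_membership), function(p) {
    pw <- unique(pathway_membership[[p]])
    if (!all(pw %in% universe))
      stop("pathway ", p, " has genes outside the universe: ",
           paste(setdiff(pw, universe), collapse = ", "))
    a <- length(intersect(pw, targets))
    b <- length(pw) - a
    c_ <- length(targets) - a
    d <- length(universe) - a - b - c_
    p2 <- stats::fisher.test(matrix(c(a, b, c_, d), 2),
                             alternative = "two.sided")$p.value
    fold <- if (length(targets) > 0 && length(pw) > 0)
      (a / length(pw)) / (length(targets) / length(universe)) else NA_real_
    data.frame(pathway = p, n_pathway = length(pw), a = a, b = b, c = c_,
               d = d, fold = fold, p_two_sided = min(p2, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
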