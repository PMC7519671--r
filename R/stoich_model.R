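#' Construct a stoichiometric model
#'
#' A minimal constraint-based metabolic model: metabolites, reactions with
#' stoichiometry and flux bounds (mmol/gDW/h), gene associations and pathway
#' labels, plus a growth objective reaction and a production target reaction
#' (here, a tryptophan sink).
#'
#' @param metabolites character vector of metabolite ids.
#' @param reactions list of reaction records; each a list with elements
#'   `id`, `stoich` (named numeric, metabolite -> coefficient; negative =
#'   consumed), `lb`, `ub` (flux bounds), and optionally `genes` (character)
#'   and `pathway` (single string).
#' @param objective id of the growth objective reaction.
#' @param target id of the production target reaction.
#' @return An object of class `stoich_model`.
#' @export
stoich_model <- function(metabolites, reactions, objective, target) {
  stopifnot(is.character(metabolites), length(metabolites) >= 1)
  ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate reaction ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  if (anyDuplicated(metabolites)) stop("duplicate metabolite ids")
  reactions <- lapply(reactions, function(r) {
    r$genes <- as.character(if (is.null(r$genes)) character(0) else r$genes)
    r$pathway <- if (is.null(r$pathway)) NA_character_ else as.character(r$pathway)
    if (is.null(r$lb) || is.null(r$ub)) stop("reaction ", r$id, ": missing bounds")
    if (r$lb > r$ub) stop("reaction ", r$id, ": lb > ub")
    bad <- setdiff(names(r$stoich), metabolites)
    if (length(bad)) stop("reaction ", r$id, ": undeclared metabolites: ",
                          paste(bad, collapse = ", "))
    r
  })
  names(reactions) <- ids
  if (!objective %in% ids) stop("objective reaction not found: ", objective)
  if (!target %in% ids) stop("target reaction not found: ", target)
  structure(list(metabolites = metabolites, reactions = reactions,
                 objective = objective, target = target),
            class = "stoich_model")
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("Stoichiometric model:", length(x$metabolites), "metabolites,",
      length(x$reactions), "reactions\n")
  cat("  objective:", x$objective, "  target:", x$target, "\n")
  genes <- model_genes(x)
  cat("  genes:", length(genes), " pathways:",
      length(unique(stats::na.omit(model_pathways(x)))), "\n")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `stoich_model`.
#' @return numeric matrix, metabolites x reactions.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, length(model$metabolites), length(model$reactions),
              dimnames = list(model$metabolites, names(model$reactions)))
  for (r in model$reactions) S[names(r$stoich), r$id] <- unname(r$stoich)
  S
}

reaction_bounds <- function(model) {
  lb <- vapply(model$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(model$reactions, `[[`, numeric(1), "ub")
  cbind(lb = lb, ub = ub)
}

#' Gene ids referenced by a model
#' @param model a `stoich_model`.
#' @return character vector of unique gene ids.
#' @export
model_genes <- function(model)
  unique(unlist(lapply(model$reactions, `[[`, "genes"), use.names = FALSE))

model_pathways <- function(model)
  vapply(model$reactions, `[[`, character(1), "pathway")

#' Gene -> pathway membership sets from reaction annotations
#'
#' Collects, per pathway label, the genes associated with that pathway's
#' reactions. Reactions without a pathway label are skipped.
#'
#' @param model a `stoich_model`.
#' @return named list of character vectors (pathway -> gene ids).
#' @export
pathway_gene_sets <- function(model) {
  out <- list()
  for (r in model$reactions) {
    if (is.na(r$pathway) || !length(r$genes)) next
    out[[r$pathway]] <- union(out[[r$pathway]], r$genes)
  }
  out
}

#' Read / write the native JSON model format
#'
#' The on-disk schema is a single JSON object:
#' `{metabolites: [id, ...], reactions: [{id, stoich: {met: coef}, lb, ub,
#' genes: [...], pathway}, ...], objective: id, target: id}`.
#'
#' @param path file path.
#' @return `read_model_json` returns a `stoich_model`.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  reactions <- lapply(doc$reactions, function(r) {
    list(id = r$id,
         stoich = unlist(r$stoich),
         lb = r$lb, ub = r$ub,
         genes = as.character(unlist(r$genes)),
         pathway = if (is.null(r$pathway)) NA_character_ else r$pathway)
  })
  stoich_model(as.character(unlist(doc$metabolites)), reactions,
               doc$objective, doc$target)
}

#' @rdname read_model_json
#' @param model a `stoich_model`.
#' @export
write_model_json <- function(model, path) {
  doc <- list(
    metabolites = model$metabolites,
    reactions = lapply(unname(model$reactions), function(r) {
      list(id = r$id, stoich = as.list(r$stoich), lb = r$lb, ub = r$ub,
           genes = r$genes,
           pathway = if (is.na(r$pathway)) NULL else r$pathway)
    }),
    objective = model$objective, target = model$target)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Four-reaction toy chain model
#'
#' Glucose uptake (capped at `uptake`) feeds an intermediate that is converted
#' to a branch point metabolite drained by either growth or a tryptophan sink.
#' Useful for hand-checkable flux simulations.
#'
#' @param uptake upper bound on the uptake flux.
#' @return a `stoich_model`.
#' @export
toy_chain_model <- function(uptake = 10) {
  stoich_model(
    metabolites = c("glc", "node"),
    reactions = list(
      list(id = "uptake", stoich = c(glc = 1), lb = 0, ub = uptake,
           genes = "gUPT", pathway = "transport"),
      list(id = "conv", stoich = c(glc = -1, node = 1), lb = 0, ub = 1000,
           genes = "gCONV", pathway = "glycolysis"),
      list(id = "growth", stoich = c(node = -1), lb = 0, ub = 1000,
           genes = character(0), pathway = NA),
      list(id = "trp", stoich = c(node = -1), lb = 0, ub = 1000,
           genes = "gTRP", pathway = "shikimate")),
    objective = "growth", target = "trp")
}
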