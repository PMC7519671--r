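# Seed plumbing and small shared helpers.

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's
# RNG stream.
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a named substream seed from a root seed
#'
#' Every stochastic stage draws its seed deterministically from one root
#' seed plus the stage name, so a single `--seed` reproduces the whole run
#' while stages stay independent.
#'
#' @param root integer root seed.
#' @param name stage name.
#' @return integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(root, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((as.numeric(root) * 7919 + h) %% (2^31 - 1))
}

md5_file <- function(path) unname(tools::md5sum(path))
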