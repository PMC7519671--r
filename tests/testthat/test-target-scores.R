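make_dist <- function(fluxes, frac = 0.5) {
  structure(list(fluxes = fluxes, growth_fraction = frac),
            class = "flux_distribution")
}

test_that("reaction scores implement the guarded fold-change formula", {
  ref <- make_dist(c(r1 = 2, r2 = 3, r3 = 0), 1)
  scan <- list(make_dist(c(r1 = 4, r2 = 3, r3 = 1)),
               make_dist(c(r1 = 4, r2 = 3, r3 = 2)))
  rs <- reaction_scores(scan, ref, pseudo_flux = 1e-4)
  # v_ref = 2, flux 4 everywhere -> fold 2 (delta negligible)
  expect_equal(rs$score[rs$reaction == "r1"], (4 + 1e-4) / (2 + 1e-4))
  # identical flux everywhere -> exactly 1
  expect_identical(rs$score[rs$reaction == "r2"], 1)
  # zero reference: delta formula, computed by independent arithmetic
  delta <- 1e-4
  expect_equal(rs$score[rs$reaction == "r3"],
               mean(c((1 + delta) / delta, (2 + delta) / delta)))
  expect_true(all(rs$scored))
})

test_that("reactions silent in reference and scan are unscored, not 1", {
  ref <- make_dist(c(r1 = 1, r2 = 0), 1)
  scan <- list(make_dist(c(r1 = 1, r2 = 0)))
  rs <- reaction_scores(scan, ref)
  expect_false(rs$scored[rs$reaction == "r2"])
  expect_true(is.na(rs$score[rs$reaction == "r2"]))
})

test_that("mismatched reaction sets error with the symmetric difference", {
  ref <- make_dist(c(r1 = 1), 1)
  scan <- list(make_dist(c(r2 = 1)))
  expect_error(reaction_scores(scan, ref), "r2")
})

test_that("scoring the reference against itself gives 1 for scored reactions", {
  m <- random_feasible_model(seed = 5)
  ref <- solve_pfba(m, 1)
  rs <- reaction_scores(list(ref), ref)
  expect_true(all(rs$score[rs$scored] == 1))
})

test_that("gene scores average associated reaction scores", {
  m <- stoich_model(
    c("A", "B"),
    list(list(id = "r1", stoich = c(A = 1), lb = 0, ub = 10, genes = c("g1")),
         list(id = "r2", stoich = c(A = -1, B = 1), lb = 0, ub = 10,
              genes = c("g1", "g2")),
         list(id = "growth", stoich = c(B = -1), lb = 0, ub = 10),
         list(id = "trp", stoich = c(B = -1), lb = 0, ub = 10,
              genes = "g3")),
    "growth", "trp")
  rs <- data.frame(reaction = c("r1", "r2", "growth", "trp"),
                   score = c(2, 1, 1, 5), scored = TRUE,
                   direction_change = FALSE)
  gs <- gene_scores(rs, m)
  expect_equal(gs$score[gs$gene == "g1"], 1.5)     # mean of {2, 1}
  expect_equal(gs$classification[gs$gene == "g1"], "overexpress")
  expect_equal(gs$score[gs$gene == "g2"], 1)
  expect_equal(gs$classification[gs$gene == "g2"], "neutral")
  expect_equal(gs$classification[gs$gene == "g3"], "overexpress")
  # independent groupby-average oracle on a random model
  m2 <- random_feasible_model(seed = 8)
  st <- score_targets(m2, fractions = c(0.4, 0.7))
  for (g in model_genes(m2)) {
    rxns <- names(m2$reactions)[vapply(m2$reactions,
                                       function(r) g %in% r$genes, logical(1))]
    sc <- st$reaction_scores$score[st$reaction_scores$reaction %in% rxns]
    sc <- sc[!is.na(sc)]
    if (length(sc))
      expect_equal(st$gene_scores$score[st$gene_scores$gene == g], mean(sc))
  }
})

test_that("genes without reactions are reported unmapped, not dropped", {
  m <- toy_chain_model()
  rs <- reaction_scores(list(solve_pfba(m, 0.5)), solve_pfba(m, 1))
  gs <- gene_scores(rs, m, genes = c(model_genes(m), "ghost"))
  expect_equal(attr(gs, "unmapped"), "ghost")
  expect_false("ghost" %in% gs$gene)
})

test_that("classification is invariant under reaction reordering and gene relabeling", {
  m <- random_feasible_model(seed = 13)
  st1 <- score_targets(m, fractions = c(0.4, 0.6))
  perm <- rev(seq_along(m$reactions))
  m2 <- stoich_model(m$metabolites,
                     unname(m$reactions[perm]), m$objective, m$target)
  st2 <- score_targets(m2, fractions = c(0.4, 0.6))
  g1 <- st1$gene_scores[order(st1$gene_scores$gene), ]
  g2 <- st2$gene_scores[order(st2$gene_scores$gene), ]
  expect_equal(g1$classification, g2$classification)
  expect_equal(g1$score, g2$score, tolerance = 1e-8)
  # relabel genes bijectively: classifications map across the relabeling
  m3 <- stoich_model(m$metabolites,
                     lapply(unname(m$reactions), function(r) {
                       if (length(r$genes)) r$genes <- paste0("Z_", r$genes)
                       r
                     }), m$objective, m$target)
  st3 <- score_targets(m3, fractions = c(0.4, 0.6))
  g3 <- st3$gene_scores
  g3$gene <- sub("^Z_", "", g3$gene)
  g3 <- g3[order(g3$gene), ]
  expect_equal(g1$classification, g3$classification)
})

test_that("carbon-regime overlap intersects classified target sets", {
  a <- data.frame(gene = c("g1", "g2", "g3"),
                  score = c(2, 0.5, 1.2),
                  classification = c("overexpress", "downregulate", "overexpress"))
  b <- data.frame(gene = c("g1", "g2", "g3"),
                  score = c(1.5, 0.7, 0.4),
                  classification = c("overexpress", "downregulate", "downregulate"))
  ov <- target_overlap(a, b)
  expect_equal(ov$overexpress, "g1")
  expect_equal(ov$downregulate, "g2")
})
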