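make_plate <- function(n_t = 5, wells = list(), media_od = 0, media_gfp = 0,
                       plate = "P1") {
  tt <- seq(0, by = 0.25, length.out = n_t)
  rows <- list()
  for (w in names(wells))
    rows[[w]] <- data.frame(plate = plate, well = w, time_h = tt,
                            od600 = wells[[w]]$od, gfp = wells[[w]]$gfp)
  rows[["MED"]] <- data.frame(plate = plate, well = "MED", time_h = tt,
                              od600 = media_od, gfp = media_gfp)
  reads <- do.call(rbind, rows)
  map <- data.frame(plate = plate, well = c(names(wells), "MED"),
                    strain = c(names(wells), "media"))
  list(reads = reads, map = map)
}

test_that("zero media background leaves readings untouched", {
  p <- make_plate(wells = list(W1 = list(od = 1:5 / 10, gfp = 1:5 * 100)))
  out <- subtract_background(p$reads, p$map)
  expect_equal(out$od600[out$well == "W1"], 1:5 / 10)
  expect_equal(out$gfp[out$well == "W1"], 1:5 * 100)
})

test_that("constant media offset shifts every sample well exactly", {
  p <- make_plate(wells = list(W1 = list(od = 1:5 / 10, gfp = 1:5 * 100)),
                  media_od = 0.04, media_gfp = 30)
  out <- subtract_background(p$reads, p$map)
  expect_equal(out$od600[out$well == "W1"], 1:5 / 10 - 0.04)
  expect_equal(out$gfp[out$well == "W1"], 1:5 * 100 - 30)
  expect_true(all(out$is_media[out$well == "MED"]))
  # media wells retained unchanged
  expect_equal(out$od600[out$well == "MED"], rep(0.04, 5))
})

test_that("two media wells subtract their per-timepoint mean", {
  tt <- seq(0, 1, 0.25)
  reads <- rbind(
    data.frame(plate = "P1", well = "W1", time_h = tt, od600 = 0.1,
               gfp = 100),
    data.frame(plate = "P1", well = "M1", time_h = tt, od600 = 0.02,
               gfp = tt * 10),
    data.frame(plate = "P1", well = "M2", time_h = tt, od600 = 0.06,
               gfp = tt * 30))
  map <- data.frame(plate = "P1", well = c("W1", "M1", "M2"),
                    strain = c("s1", "media", "media"))
  out <- subtract_background(reads, map)
  expect_equal(out$od600[out$well == "W1"], rep(0.1 - 0.04, 5))
  expect_equal(out$gfp[out$well == "W1"], 100 - tt * 20)
})

test_that("missing media wells are an error", {
  reads <- data.frame(plate = "P1", well = "W1", time_h = 0:1, od600 = 1,
                      gfp = 1)
  map <- data.frame(plate = "P1", well = "W1", strain = "s1")
  expect_error(subtract_background(reads, map), "no media wells")
})

test_that("the five QC criteria and missing-metadata handling", {
  meta <- data.frame(strain = c("A", "B", "C"),
                     sequencing_complete = c(TRUE, TRUE, NA),
                     assembly_exact = TRUE, cured = TRUE,
                     single_genotype = TRUE)
  max_od <- c(A = 0.2, B = 0.12, C = 0.3)
  qc <- apply_qc(max_od, meta)
  expect_true(qc$pass[qc$strain == "A"])
  expect_false(qc$pass[qc$strain == "B"])          # insufficient growth
  expect_match(qc$reasons[qc$strain == "B"], "od_range")
  expect_false(qc$pass[qc$strain == "C"])          # missing metadata fails
  expect_match(qc$reasons[qc$strain == "C"], "missing")
})

test_that("windowed rate: endpoint and slope estimators on exact data", {
  # OD rising 0.075 -> 0.150 while GFP rises 100 -> 250 over 1 h
  tt <- seq(0, 1, 0.25)
  od <- seq(0.075, 0.150, length.out = 5)
  gfp <- seq(100, 250, length.out = 5)
  r <- gfp_synthesis_rate(tt, od, gfp)
  expect_equal(r$rate, 150)
  expect_equal(r$n_points, 5L)
  expect_equal(gfp_synthesis_rate(tt, od, rep(7, 5))$rate, 0)
  # exactly linear GFP: both estimators return the slope to machine precision
  gfp2 <- 12.5 + 42 * tt
  expect_equal(gfp_synthesis_rate(tt, od, gfp2, estimator = "endpoint")$rate, 42)
  expect_equal(gfp_synthesis_rate(tt, od, gfp2, estimator = "slope")$rate, 42)
})

test_that("windowed rate: first contiguous run only, undefined when too short", {
  tt <- seq(0, 2, 0.25)
  od <- c(0.05, 0.08, 0.1, 0.14, 0.2, 0.25, 0.1, 0.12, 0.13)  # re-entry later
  gfp <- c(0, 10, 20, 30, 40, 50, 999, 999, 999)
  r <- gfp_synthesis_rate(tt, od, gfp)
  expect_equal(r$n_points, 3L)            # indices 2:4 only
  expect_equal(r$rate, (30 - 10) / 0.5)
  bad <- gfp_synthesis_rate(c(0, 1), c(0.1, 0.3), c(0, 1))
  expect_equal(bad$n_points, 1L)
  expect_true(is.na(bad$rate))
  expect_match(bad$reason, "fewer than 2")
})

test_that("rate is invariant to GFP offset and time translation, linear in gain", {
  tt <- seq(0, 3, 0.25)
  od <- seq(0.05, 0.2, length.out = length(tt))
  gfp <- 5 + 60 * tt + sin(tt)
  base <- gfp_synthesis_rate(tt, od, gfp)$rate
  expect_equal(gfp_synthesis_rate(tt, od, gfp + 300)$rate, base)
  expect_equal(gfp_synthesis_rate(tt + 13, od, gfp)$rate, base)
  expect_equal(gfp_synthesis_rate(tt, od, 3.5 * gfp)$rate, 3.5 * base)
})

test_that("replicate aggregation: mean, SEM and CV formulas", {
  a <- aggregate_replicates(c(140, 150, 160))
  expect_equal(a$mean, 150)
  expect_equal(a$sem, 10 / sqrt(3))
  expect_equal(a$cv_pct, 100 * (10 / sqrt(3)) / 150)
  one <- aggregate_replicates(42)
  expect_equal(one$mean, 42)
  expect_true(is.na(one$sem))
  same <- aggregate_replicates(c(5, 5, 5))
  expect_equal(same$sem, 0)
  expect_equal(same$cv_pct, 0)
  expect_equal(aggregate_replicates(c(NA, NA))$n, 0L)
})

test_that("percentile filter removes whole strains owning extreme replicates", {
  set.seed(1)
  reps <- data.frame(strain = rep(sprintf("s%03d", 1:40), each = 3),
                     rate = rep(seq(60, 240, length.out = 40), each = 3) *
                       (1 + rnorm(120, 0, 0.01)))
  # tight strains: nothing removed when all replicates equal within strain
  tight <- data.frame(strain = rep(paste0("t", 1:10), each = 3),
                      rate = rep(1:10 * 10, each = 3))
  expect_length(outlier_filter_percentile(tight)$removed_strains, 0)
  # a 10x replicate among >= 100 replicates is exactly what goes
  reps$rate[5] <- reps$rate[5] * 10
  fl <- outlier_filter_percentile(reps, fraction = 0.01)
  expect_equal(fl$removed_strains, "s002")
  expect_false("s002" %in% fl$kept$strain)
  expect_equal(nrow(fl$kept), 117)
  # fraction 0 removes nothing
  expect_length(outlier_filter_percentile(reps, 0)$removed_strains, 0)
})

test_that("robust MAD filter flags gross replicates and drops lone survivors", {
  reps <- data.frame(strain = rep(paste0("s", 1:20), each = 3),
                     rate = rep(seq(80, 200, length.out = 20), each = 3) +
                       rep(c(-1, 0, 1), 20))
  expect_length(outlier_filter_robust(reps)$removed_strains, 0)
  # triplicate {150, 151, 600}: only the 600 goes, strain keeps 2 replicates
  reps2 <- rbind(reps, data.frame(strain = "bad", rate = c(150, 151, 600)))
  fl <- outlier_filter_robust(reps2)
  expect_true(fl$flagged[61:63][3])
  expect_equal(sum(fl$kept$strain == "bad"), 2)
  # duplicate {150, 600} among tight strains cannot keep a lone survivor
  reps3 <- rbind(reps, data.frame(strain = "dup", rate = c(150, 600)))
  fl3 <- outlier_filter_robust(reps3)
  expect_true("dup" %in% fl3$removed_strains)
  expect_false("dup" %in% fl3$kept$strain)
})

test_that("robust filter is idempotent", {
  set.seed(7)
  reps <- data.frame(strain = rep(sprintf("s%02d", 1:30), each = 3),
                     rate = rep(runif(30, 50, 250), each = 3) *
                       (1 + rnorm(90, 0, 0.04)))
  reps$rate[c(4, 50)] <- reps$rate[c(4, 50)] * c(5, 0.1)
  fl1 <- outlier_filter_robust(reps)
  fl2 <- outlier_filter_robust(fl1$kept)
  expect_length(fl2$removed_strains, 0)
  expect_equal(fl2$kept, fl1$kept)
})
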