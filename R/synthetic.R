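# Synthetic-data generator: ground-truth genotype->rate surfaces, sampled
# strain libraries with realistic defect rates, and rendered plate-reader
# time series with the statistical structure the analysis pipeline assumes.

#' Ground-truth genotype-to-rate surface
#'
#' Draws per-gene per-promoter additive effects on a latent log-rate scale,
#' plus (by default) small pairwise gene-by-gene interaction terms so that
#' the response is not exactly additive. The latent surface is calibrated
#' so that the minimum and maximum over the full design space hit
#' `rate_range` and the anchor design (all native promoters) hits
#' `anchor_rate` (within numerical precision), via a monotone
#' exponential-affine link that preserves the additive-on-log-rate
#' structure of the effects.
#'
#' @param catalog a [promoter_catalog].
#' @param seed integer seed.
#' @param rate_range attainable rate range over the space, MFI/h
#'   (default c(40, 260)).
#' @param anchor_rate rate of the anchor design, MFI/h (default 145).
#' @param effect_sd sd of additive promoter effects (latent scale).
#' @param interaction_sd sd of pairwise interaction terms; 0 disables them.
#' @param anchor promoter name per gene for the anchor design; defaults to
#'   `"p<GENE>"` (the native promoter) where present, else the bin's first
#'   promoter.
#' @return object of class `ground_truth`.
#' @export
make_ground_truth <- function(catalog, seed = 1, rate_range = c(40, 260),
                              anchor_rate = 145, effect_sd = 0.35,
                              interaction_sd = 0.08, anchor = NULL) {
  stopifnot(rate_range[1] < rate_range[2])
  if (anchor_rate <= rate_range[1] || anchor_rate >= rate_range[2])
    stop("anchor_rate must lie strictly inside rate_range")
  genes <- catalog_genes(catalog)
  bins <- catalog_bins(catalog)
  if (is.null(anchor))
    anchor <- vapply(genes, function(g) {
      nat <- paste0("p", g)
      if (nat %in% bins[[g]]$promoter) nat else bins[[g]]$promoter[1]
    }, character(1))
  truth <- local_seed(seed, {
    effects <- lapply(bins, function(b)
      stats::setNames(stats::rnorm(nrow(b), 0, effect_sd), b$promoter))
    inter <- NULL
    if (interaction_sd > 0 && length(genes) >= 2) {
      pairs <- utils::combn(genes, 2, simplify = FALSE)
      inter <- lapply(pairs, function(p) {
        m <- matrix(stats::rnorm(nrow(bins[[p[1]]]) * nrow(bins[[p[2]]]),
                                 0, interaction_sd),
                    nrow(bins[[p[1]]]), nrow(bins[[p[2]]]),
                    dimnames = list(bins[[p[1]]]$promoter,
                                    bins[[p[2]]]$promoter))
        list(genes = p, effects = m)
      })
    }
    list(effects = effects, interactions = inter)
  })
  obj <- structure(list(catalog = catalog, effects = truth$effects,
                        interactions = truth$interactions,
                        rate_range = rate_range, anchor_rate = anchor_rate,
                        anchor = anchor, seed = seed),
                   class = "ground_truth")
  space <- enumerate_design_space(catalog)
  lat <- latent_score(obj, space)
  lmin <- min(lat); lmax <- max(lat)
  if (lmax - lmin < 1e-12) {           # degenerate surface: every design = anchor
    obj$calibration <- list(degenerate = TRUE, lmin = lmin, lmax = lmax)
    return(obj)
  }
  a_key <- genotype_key(as.data.frame(as.list(anchor),
                                      col.names = genes,
                                      stringsAsFactors = FALSE), catalog)
  u_a <- (lat[match(a_key, space$key)] - lmin) / (lmax - lmin)
  if (is.na(u_a) || u_a <= 0 || u_a >= 1)
    stop("infeasible calibration: anchor design sits at the edge of the latent range")
  # exponential-affine calibration: rate = rmin + range * (e^{cu} - 1)/(e^c - 1)
  # keeps the declared additive-on-log-rate structure (monotone exp link);
  # c is the unique effect-size scale putting the anchor at anchor_rate
  q <- (anchor_rate - rate_range[1]) / diff(rate_range)
  cc <- if (abs(u_a - q) < 1e-12) 0 else {
    f <- function(cx) (exp(cx * u_a) - 1) / (exp(cx) - 1) - q
    if (q < u_a) stats::uniroot(f, c(1e-9, 50), tol = 1e-12)$root
    else stats::uniroot(f, c(-50, -1e-9), tol = 1e-12)$root
  }
  obj$calibration <- list(degenerate = FALSE, lmin = lmin, lmax = lmax,
                          c = cc, anchor_key = a_key)
  obj
}

latent_score <- function(truth, genotypes) {
  genes <- catalog_genes(truth$catalog)
  if (is.character(genotypes))
    genotypes <- decode_genotype_key(genotypes, truth$catalog)
  s <- rep(0, nrow(genotypes))
  for (g in genes) s <- s + truth$effects[[g]][genotypes[[g]]]
  for (it in truth$interactions)
    s <- s + it$effects[cbind(genotypes[[it$genes[1]]],
                              genotypes[[it$genes[2]]])]
  unname(s)
}

#' True rate of genotypes under a ground-truth surface
#'
#' @param truth a [make_ground_truth] object.
#' @param genotypes genotype data.frame or character keys.
#' @return numeric vector of true rates (MFI/h).
#' @export
true_rate <- function(truth, genotypes) {
  cal <- truth$calibration
  if (cal$degenerate) {
    n <- if (is.character(genotypes)) length(genotypes) else nrow(genotypes)
    return(rep(truth$anchor_rate, n))
  }
  lat <- latent_score(truth, genotypes)
  u <- pmin(pmax((lat - cal$lmin) / (cal$lmax - cal$lmin), 0), 1)
  g <- if (cal$c == 0) u else (exp(cal$c * u) - 1) / (exp(cal$c) - 1)
  truth$rate_range[1] + diff(truth$rate_range) * g
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground-truth response surface, seed", x$seed, "\n")
  cat(sprintf("  calibrated range [%g, %g] MFI/h, anchor %g MFI/h%s\n",
              x$rate_range[1], x$rate_range[2], x$anchor_rate,
              if (x$calibration$degenerate) " (degenerate: flat surface)" else ""))
  invisible(x)
}

#' Sample a synthetic training library
#'
#' Draws `n_strains` distinct genotypes from the catalog's pick
#' distribution, generates `n_reps` replicate rates per strain with
#' multiplicative noise calibrated so the coefficient of variation of the
#' replicate mean is about `cv`, and injects QC defects into the genotyping
#' metadata at the given rates (incorrect assembly, failed curing,
#' duplicate-genotype sequencing calls).
#'
#' @param truth a [make_ground_truth] object.
#' @param n_strains number of distinct genotypes (default 250).
#' @param n_reps technical replicates per strain (default 3).
#' @param cv target coefficient of variation of the replicate mean
#'   (default 0.043).
#' @param defect_rates list with `correct`, `cured`, `duplicate`
#'   probabilities (defaults 0.82, 0.92, 0.037).
#' @param seed integer seed.
#' @return list: `strains` (strain, key, promoter columns, true_rate),
#'   `replicates` (strain, replicate, rate), `metadata` (QC columns for
#'   [apply_qc]).
#' @export
sample_training_set <- function(truth, n_strains = 250, n_reps = 3,
                                cv = 0.043,
                                defect_rates = list(correct = 0.82,
                                                    cured = 0.92,
                                                    duplicate = 0.037),
                                seed = 1) {
  catalog <- truth$catalog
  bins <- catalog_bins(catalog)
  sizes <- vapply(bins, nrow, integer(1))
  if (n_strains > prod(sizes)) stop("n_strains exceeds the design space")
  local_seed(seed, {
    keys <- character(0)
    geno <- NULL
    while (length(keys) < n_strains) {          # weighted draws, deduplicated
      m <- 2 * (n_strains - length(keys)) + 8
      draw <- lapply(bins, function(b)
        b$promoter[sample.int(nrow(b), m, replace = TRUE,
                              prob = b$pick_probability)])
      draw <- as.data.frame(draw, stringsAsFactors = FALSE)
      names(draw) <- catalog_genes(catalog)
      k <- genotype_key(draw, catalog)
      new <- !duplicated(k) & !k %in% keys
      keys <- c(keys, k[new])
      geno <- rbind(geno, draw[new, , drop = FALSE])
    }
    keys <- keys[seq_len(n_strains)]
    geno <- geno[seq_len(n_strains), , drop = FALSE]
    rownames(geno) <- NULL
    rate <- true_rate(truth, geno)
    strains <- cbind(data.frame(strain = sprintf("S%04d", seq_len(n_strains)),
                                key = keys, stringsAsFactors = FALSE),
                     geno, true_rate = rate)
    # replicate sd = cv * sqrt(n_reps) * rate  =>  sem/mean ~ cv
    rep_sd <- cv * sqrt(n_reps)
    replicates <- data.frame(
      strain = rep(strains$strain, each = n_reps),
      replicate = rep(seq_len(n_reps), n_strains),
      rate = rep(rate, each = n_reps) *
        (1 + stats::rnorm(n_strains * n_reps, 0, rep_sd)))
    metadata <- data.frame(
      strain = strains$strain,
      sequencing_complete = TRUE,
      assembly_exact = stats::runif(n_strains) < defect_rates$correct,
      cured = stats::runif(n_strains) < defect_rates$cured,
      single_genotype = stats::runif(n_strains) >= defect_rates$duplicate,
      stringsAsFactors = FALSE)
    list(strains = strains, replicates = replicates, metadata = metadata,
         catalog = catalog, cv = cv, n_reps = n_reps, seed = seed)
  })
}

#' Growth and measurement parameters for rendered time series
#'
#' Logistic growth from an initial OD600 of 0.025 with maximum specific
#' growth rate `mu` (1/h) toward carrying capacity `K`; GFP accumulates at
#' the strain's synthesis rate while the culture is inside the OD window
#' (ramping up below it, per-cell fluorescence declining above it);
#' measurements add media background offsets and noise.
#'
#' @param od0 initial OD600.
#' @param mu maximum specific growth rate (1/h).
#' @param K carrying capacity (OD600).
#' @param window OD window in which GFP synthesis is at full rate.
#' @param od_noise_sd additive OD measurement noise sd.
#' @param gfp_cv multiplicative GFP measurement noise (CV).
#' @param bg_od,bg_gfp media background offsets added to all raw readings.
#' @return list of parameters.
#' @export
growth_params <- function(od0 = 0.025, mu = 0.28, K = 0.6,
                          window = c(0.075, 0.150),
                          od_noise_sd = 0.0015, gfp_cv = 0.01,
                          bg_od = 0.04, bg_gfp = 30) {
  list(od0 = od0, mu = mu, K = K, window = window,
       od_noise_sd = od_noise_sd, gfp_cv = gfp_cv,
       bg_od = bg_od, bg_gfp = bg_gfp)
}

logistic_od <- function(t, p) p$K / (1 + (p$K - p$od0) / p$od0 * exp(-p$mu * t))

# GFP synthesis speed multiplier as a function of OD: ramps linearly up to
# the window, is 1 inside it, and decays above (per-cell signal declining).
gfp_shape <- function(od, window) {
  ifelse(od < window[1], od / window[1],
         ifelse(od <= window[2], 1, (window[2] / od)^2))
}

#' Render a plate-reader time series for one well
#'
#' Deterministic trajectory plus seeded measurement noise, on the default
#' grid of 82 points spaced 15 min apart. With noise disabled, running the
#' windowed endpoint estimator on the background-subtracted series returns
#' the true rate exactly (the synthesis speed is constant across the whole
#' OD window).
#'
#' @param rate true GFP synthesis rate (MFI/h); 0 renders a media well
#'   (background only).
#' @param growth a [growth_params] list.
#' @param n_points number of time points (default 82).
#' @param dt grid spacing in hours (default 0.25).
#' @param seed integer seed for the measurement noise; `NULL` for noiseless.
#' @return data.frame: time_h, od600, gfp (raw readings incl. background).
#' @export
render_timeseries <- function(rate, growth = growth_params(), n_points = 82,
                              dt = 0.25, seed = NULL) {
  tgrid <- (seq_len(n_points) - 1) * dt
  if (rate == 0) {                      # media well: background only
    od <- rep(growth$bg_od, n_points)
    gfp <- rep(growth$bg_gfp, n_points)
  } else {
    sub <- 10                           # fine substeps for the GFP integral
    tf <- seq(0, tgrid[n_points], by = dt / sub)
    odf <- logistic_od(tf, growth)
    speed <- rate * gfp_shape(odf, growth$window)
    # trapezoidal cumulative integral of dGFP/dt
    cum <- c(0, cumsum((speed[-1] + speed[-length(speed)]) / 2 * diff(tf)))
    idx <- round(tgrid / (dt / sub)) + 1
    od <- odf[idx] + growth$bg_od
    gfp <- cum[idx] + growth$bg_gfp
  }
  out <- data.frame(time_h = tgrid, od600 = od, gfp = gfp)
  if (!is.null(seed) && rate != 0) {
    out <- local_seed(seed, {
      out$od600 <- out$od600 + stats::rnorm(n_points, 0, growth$od_noise_sd)
      out$gfp <- out$gfp * (1 + stats::rnorm(n_points, 0, growth$gfp_cv))
      out
    })
  }
  out
}

#' Generate a complete synthetic study
#'
#' One call emulating a full screen: ground truth surface, sampled strain
#' library with defects, and raw plate-reader time series for every
#' replicate well (96-well plates, four media wells each). Optionally
#' writes the CSV files consumed by [phenotype_plates] and [trp_ensemble].
#'
#' @param n_strains distinct genotypes (default 250).
#' @param n_reps replicates per strain (default 3).
#' @param seed integer root seed.
#' @param cv replicate-mean coefficient of variation (default 0.043).
#' @param catalog a [promoter_catalog].
#' @param defect_rates see [sample_training_set].
#' @param growth a [growth_params] list.
#' @param render logical; render raw time series (set FALSE to keep only
#'   replicate-level rates).
#' @param dir if non-NULL, directory to write reads.csv, map.csv,
#'   metadata.csv, genotypes.csv, catalog.csv.
#' @return list: `truth`, `strains`, `replicates`, `metadata`, and (when
#'   rendered) `reads`, `map`.
#' @export
generate_mock_study <- function(n_strains = 250, n_reps = 3, seed = 7,
                                cv = 0.043, catalog = default_catalog(),
                                defect_rates = list(correct = 0.82,
                                                    cured = 0.92,
                                                    duplicate = 0.037),
                                growth = growth_params(), render = TRUE,
                                dir = NULL) {
  truth <- make_ground_truth(catalog, seed = substream_seed(seed, "truth"))
  lib <- sample_training_set(truth, n_strains, n_reps, cv, defect_rates,
                             seed = substream_seed(seed, "library"))
  out <- list(truth = truth, strains = lib$strains,
              replicates = lib$replicates, metadata = lib$metadata,
              catalog = catalog, seed = seed)
  if (render) {
    n_media <- 4
    per_plate <- 96 - n_media
    wells <- lib$replicates
    wells$plate <- sprintf("P%02d", (seq_len(nrow(wells)) - 1) %/% per_plate + 1)
    wells$well <- sprintf("W%02d", (seq_len(nrow(wells)) - 1) %% per_plate + 1)
    reads <- vector("list", nrow(wells))
    for (i in seq_len(nrow(wells))) {
      ts <- render_timeseries(wells$rate[i], growth,
                              seed = substream_seed(seed, paste0("well_", i)))
      reads[[i]] <- cbind(plate = wells$plate[i], well = wells$well[i], ts)
    }
    plates <- unique(wells$plate)
    media <- vector("list", length(plates) * n_media)
    k <- 0
    for (p in plates) for (j in seq_len(n_media)) {
      k <- k + 1
      ts <- render_timeseries(0, growth)
      media[[k]] <- cbind(plate = p, well = sprintf("M%02d", j), ts)
    }
    out$reads <- do.call(rbind, c(reads, media))
    map_media <- do.call(rbind, lapply(plates, function(p)
      data.frame(plate = p, well = sprintf("M%02d", seq_len(n_media)),
                 strain = "media", replicate_index = NA_integer_)))
    out$map <- rbind(
      data.frame(plate = wells$plate, well = wells$well,
                 strain = wells$strain, replicate_index = wells$replicate),
      map_media)
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(d, f) utils::write.csv(d, file.path(dir, f), row.names = FALSE)
    if (render) { w(out$reads, "reads.csv"); w(out$map, "map.csv") }
    w(out$metadata, "metadata.csv")
    w(out$strains, "genotypes.csv")
    w(as.data.frame(catalog), "catalog.csv")
  }
  out
}
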