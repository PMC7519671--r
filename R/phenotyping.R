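# Plate-reader phenotyping: background subtraction, QC, windowed GFP
# synthesis rates, replicate aggregation and the two outlier filters.
#
# Long-format conventions: `reads` has columns plate, well, time_h, od600,
# gfp; `map` has plate, well, strain (the literal "media" marks blank
# wells), replicate_index.

#' Subtract per-plate media background
#'
#' For every plate and time point, the mean OD600 and GFP of that plate's
#' media wells is subtracted from every sample well. Media wells are kept
#' unchanged and flagged via the `is_media` column.
#'
#' @param reads long data.frame (plate, well, time_h, od600, gfp).
#' @param map well map data.frame (plate, well, strain); wells whose strain
#'   is `"media"` are blanks.
#' @return `reads` with background-subtracted sample wells and an
#'   `is_media` column.
#' @export
subtract_background <- function(reads, map) {
  key <- paste(reads$plate, reads$well, sep = "\r")
  mkey <- paste(map$plate, map$well, sep = "\r")
  strain <- map$strain[match(key, mkey)]
  if (anyNA(strain)) stop("wells missing from the map: ",
                          paste(unique(key[is.na(strain)]), collapse = ", "))
  reads$is_media <- strain == "media"
  out <- reads
  for (p in unique(reads$plate)) {
    sel <- reads$plate == p
    med <- reads[sel & reads$is_media, ]
    if (!nrow(med)) stop("plate ", p, ": no media wells")
    bg_od <- tapply(med$od600, med$time_h, mean)
    bg_gfp <- tapply(med$gfp, med$time_h, mean)
    smp <- sel & !reads$is_media
    tt <- as.character(reads$time_h[smp])
    out$od600[smp] <- reads$od600[smp] - unname(bg_od[tt])
    out$gfp[smp] <- reads$gfp[smp] - unname(bg_gfp[tt])
  }
  out
}

#' Apply the five strain quality-control criteria
#'
#' Pass requires all of: (1) the background-subtracted OD600 covers the
#' range up to `od_max_required` (excluding uninoculated or poorly growing
#' wells); (2) sequencing results exist for all promoter-gene junctions;
#' (3) the assembled sequence is exactly as designed; (4) the
#' complementation plasmid is cured; (5) sequencing shows a single genotype.
#' A missing metadata field fails its criterion with reason "missing".
#'
#' @param max_od named numeric: per strain, the maximum background-subtracted
#'   OD600 across its wells (see [strain_max_od]).
#' @param metadata data.frame (strain, sequencing_complete, assembly_exact,
#'   cured, single_genotype), logical columns.
#' @param od_max_required OD the growth curve must reach (default 0.15).
#' @return data.frame: strain, the five criterion flags, `pass`, `reasons`.
#' @export
apply_qc <- function(max_od, metadata, od_max_required = 0.15) {
  flag <- function(col) {
    v <- metadata[[col]]
    if (is.null(v)) v <- rep(NA, nrow(metadata))
    ifelse(is.na(v), FALSE, as.logical(v))
  }
  missing_reason <- function(col, label) {
    v <- metadata[[col]]
    if (is.null(v)) v <- rep(NA, nrow(metadata))
    ifelse(is.na(v), paste0(label, ":missing"),
           ifelse(v, NA_character_, label))
  }
  od <- max_od[metadata$strain]
  rec <- data.frame(
    strain = metadata$strain,
    od_range_ok = !is.na(od) & od >= od_max_required,
    sequencing_complete = flag("sequencing_complete"),
    assembly_exact = flag("assembly_exact"),
    plasmid_cured = flag("cured"),
    single_genotype = flag("single_genotype"),
    stringsAsFactors = FALSE)
  rec$pass <- rec$od_range_ok & rec$sequencing_complete & rec$assembly_exact &
    rec$plasmid_cured & rec$single_genotype
  reasons <- cbind(
    ifelse(rec$od_range_ok, NA, ifelse(is.na(od), "od_range:missing", "od_range")),
    missing_reason("sequencing_complete", "sequencing"),
    missing_reason("assembly_exact", "assembly"),
    missing_reason("cured", "curing"),
    missing_reason("single_genotype", "multiple_genotypes"))
  rec$reasons <- apply(reasons, 1, function(r)
    paste(r[!is.na(r)], collapse = ";"))
  rec
}

#' Maximum background-subtracted OD per strain
#' @inheritParams subtract_background
#' @return named numeric vector (strain -> max OD600).
#' @export
strain_max_od <- function(reads, map) {
  key <- paste(reads$plate, reads$well, sep = "\r")
  mkey <- paste(map$plate, map$well, sep = "\r")
  strain <- map$strain[match(key, mkey)]
  keep <- !is.na(strain) & strain != "media"
  tapply(reads$od600[keep], strain[keep], max)
}

#' GFP synthesis rate of one well within an OD window
#'
#' The rate (MFI/h) is computed over the first contiguous run of time
#' points whose OD600 lies in `window`. The default estimator is the
#' endpoint difference quotient, (GFP_last - GFP_first)/(t_last - t_first);
#' the alternative is the least-squares slope of GFP against time over the
#' in-window points.
#'
#' @param time_h,od600,gfp numeric vectors of equal length (hours,
#'   background-subtracted OD, background-subtracted GFP).
#' @param window OD600 interval, default `c(0.075, 0.150)`.
#' @param estimator `"endpoint"` or `"slope"`.
#' @return list: `rate` (MFI/h, `NA` when undefined), `n_points`,
#'   `estimator`, `reason` (`NA` or why the rate is undefined).
#' @export
gfp_synthesis_rate <- function(time_h, od600, gfp,
                               window = c(0.075, 0.150),
                               estimator = c("endpoint", "slope")) {
  estimator <- match.arg(estimator)
  stopifnot(length(time_h) == length(od600), length(od600) == length(gfp),
            !is.unsorted(time_h, strictly = TRUE))
  inw <- which(od600 >= window[1] & od600 <= window[2])
  if (!length(inw))
    return(list(rate = NA_real_, n_points = 0L, estimator = estimator,
                reason = "no points in OD window"))
  run_end <- c(which(diff(inw) > 1), length(inw))
  idx <- inw[seq_len(run_end[1])]       # first contiguous in-window run
  if (length(idx) < 2)
    return(list(rate = NA_real_, n_points = length(idx),
                estimator = estimator,
                reason = "fewer than 2 points in OD window"))
  rate <- if (estimator == "endpoint") {
    (gfp[idx[length(idx)]] - gfp[idx[1]]) /
      (time_h[idx[length(idx)]] - time_h[idx[1]])
  } else {
    unname(stats::coef(stats::lm(gfp[idx] ~ time_h[idx]))[2])
  }
  list(rate = rate, n_points = length(idx), estimator = estimator,
       reason = NA_character_)
}

#' Aggregate replicate rates into a strain phenotype
#'
#' @param rates numeric vector of replicate rates (MFI/h); `NA`s are
#'   undefined replicates and are dropped.
#' @return list: `mean`, `sem` (sd/sqrt(n), `NA` at n = 1), `cv_pct`
#'   (SEM/mean * 100, the coefficient of variation of the mean), `n`,
#'   `rates` (the finite replicate rates).
#' @export
aggregate_replicates <- function(rates) {
  r <- rates[is.finite(rates)]
  if (!length(r))
    return(list(mean = NA_real_, sem = NA_real_, cv_pct = NA_real_, n = 0L,
                rates = numeric(0)))
  m <- mean(r)
  sem <- if (length(r) >= 2) stats::sd(r) / sqrt(length(r)) else NA_real_
  cv <- if (!is.na(sem) && m > 0) 100 * sem / m else NA_real_
  list(mean = m, sem = sem, cv_pct = cv, n = length(r), rates = r)
}

#' Percentile outlier filter (whole-strain removal)
#'
#' Per replicate, the deviation is |rate - strain mean| / strain mean. The
#' replicates above the (1 - fraction) quantile of all deviations are
#' flagged, and every strain owning a flagged replicate is removed whole.
#'
#' @param replicates data.frame (strain, rate), one row per replicate.
#' @param fraction fraction of most extreme deviations to flag (default 0.01).
#' @return list: `kept` (filtered data.frame), `removed_strains`,
#'   `threshold` (deviation cutoff).
#' @export
outlier_filter_percentile <- function(replicates, fraction = 0.01) {
  stopifnot(length(unique(replicates$strain)) >= 2)
  mu <- tapply(replicates$rate, replicates$strain, mean)
  dev <- abs(replicates$rate - mu[replicates$strain]) /
    abs(mu[replicates$strain])
  thr <- stats::quantile(dev, 1 - fraction, names = FALSE)
  flagged <- dev > thr
  removed <- unique(replicates$strain[flagged])
  list(kept = replicates[!replicates$strain %in% removed, , drop = FALSE],
       removed_strains = removed, threshold = thr)
}

#' Robust (median/MAD) outlier filter (per-replicate removal)
#'
#' Replicates are flagged when their absolute deviation from the strain
#' median exceeds `c_mad` times a robust scale: the strain's own scaled MAD
#' for strains with three or more replicates, or, for two-replicate strains
#' (whose own MAD cannot isolate one replicate), the scaled MAD of the
#' deviations pooled across all strains. Strains left with one or zero
#' replicates after flagging are dropped whole, as a lone surviving
#' replicate carries no reproducibility information.
#'
#' @param replicates data.frame (strain, rate), one row per replicate.
#' @param c_mad cutoff multiplier (default 3).
#' @return list: `kept` (filtered data.frame), `removed_strains`,
#'   `flagged` (logical vector aligned with the input rows).
#' @export
outlier_filter_robust <- function(replicates, c_mad = 3) {
  stopifnot(nrow(replicates) >= 1)
  med <- tapply(replicates$rate, replicates$strain, stats::median)
  dev <- abs(replicates$rate - med[replicates$strain])
  pooled_scale <- 1.4826 * stats::median(dev)
  n_rep <- table(replicates$strain)
  strain_mad <- tapply(replicates$rate, replicates$strain, stats::mad)
  scale <- ifelse(n_rep[replicates$strain] >= 3,
                  strain_mad[replicates$strain], pooled_scale)
  flagged <- dev > c_mad * scale
  left <- table(replicates$strain[!flagged])
  removed <- unique(c(names(left)[left <= 1],
                      setdiff(replicates$strain, names(left))))
  keep <- !flagged & !replicates$strain %in% removed
  list(kept = replicates[keep, , drop = FALSE],
       removed_strains = removed, flagged = flagged)
}

#' Phenotype a full plate-reader run
#'
#' Background-subtracts, computes per-well rates, aggregates replicates per
#' strain, and attaches QC. Returns one row per strain.
#'
#' @inheritParams subtract_background
#' @param metadata genotyping metadata for [apply_qc].
#' @inheritParams gfp_synthesis_rate
#' @return data.frame: strain, rate_mean, sem, cv_pct, n, qc_pass,
#'   qc_reasons; replicate-level rates in the `"replicates"` attribute.
#' @export
phenotype_plates <- function(reads, map, metadata,
                             window = c(0.075, 0.150),
                             estimator = c("endpoint", "slope")) {
  estimator <- match.arg(estimator)
  bs <- subtract_background(reads, map)
  key <- paste(bs$plate, bs$well, sep = "\r")
  mkey <- paste(map$plate, map$well, sep = "\r")
  bs$strain <- map$strain[match(key, mkey)]
  smp <- bs[!bs$is_media, ]
  wells <- unique(smp[, c("plate", "well", "strain")])
  wells$rate <- NA_real_
  for (i in seq_len(nrow(wells))) {
    w <- smp[smp$plate == wells$plate[i] & smp$well == wells$well[i], ]
    w <- w[order(w$time_h), ]
    wells$rate[i] <- gfp_synthesis_rate(w$time_h, w$od600, w$gfp,
                                        window, estimator)$rate
  }
  strains <- unique(wells$strain)
  agg <- lapply(strains, function(s) aggregate_replicates(wells$rate[wells$strain == s]))
  qc <- apply_qc(strain_max_od(bs, map), metadata)
  qi <- match(strains, qc$strain)
  out <- data.frame(
    strain = strains,
    rate_mean = vapply(agg, `[[`, numeric(1), "mean"),
    sem = vapply(agg, `[[`, numeric(1), "sem"),
    cv_pct = vapply(agg, `[[`, numeric(1), "cv_pct"),
    n = vapply(agg, `[[`, integer(1), "n"),
    qc_pass = !is.na(qi) & qc$pass[qi],
    qc_reasons = ifelse(is.na(qi), "no metadata", qc$reasons[qi]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "replicates") <- wells[, c("strain", "plate", "well", "rate")]
  out
}
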