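#' Region-level discharge parameters per origin, class and epoch
#'
#' For each analysed region, event amplitude and duration are obtained by
#' averaging the values recorded by the region's two designated adjacent
#' electrodes along the pyramidal (CA3, CA1, Sub) or granule (DG) cell layer;
#' a discharge missing one pair electrode uses the available one and is
#' counted in `n_pair_incomplete`. Frequency is the number of contributing
#' discharges per minute of epoch duration.
#'
#' @param ds An annotated `discharge_set`.
#' @param regions A [region_map()] with `cell_layer_pairs`.
#' @param epochs `NULL` (one epoch spanning the recording) or
#'   data.frame(label, start_s, end_s).
#' @param duration_s Recording duration, required when `epochs` is `NULL`.
#' @return data.frame: `epoch`, `region`, `origin`, `class`, `n`,
#'   `frequency_per_min`, `mean_amplitude_uV`, `mean_duration_s`,
#'   `n_pair_incomplete`.
#' @export
region_parameters <- function(ds, regions, epochs = NULL, duration_s = NULL) {
  if (!length(regions$cell_layer_pairs))
    stop("region map designates no cell-layer electrode pairs")
  if (is.null(epochs)) {
    if (is.null(duration_s)) stop("duration_s required when epochs is NULL")
    epochs <- data.frame(label = "all", start_s = 0, end_s = duration_s,
                         stringsAsFactors = FALSE)
  }
  d <- ds$discharges
  mem <- ds$members
  out <- list()
  for (k in seq_len(nrow(epochs))) {
    ep <- epochs[k, ]
    minutes <- (ep$end_s - ep$start_s) / 60
    in_ep <- d$network_onset_s >= ep$start_s & d$network_onset_s < ep$end_s
    for (reg in names(regions$cell_layer_pairs)) {
      pair <- regions$cell_layer_pairs[[reg]]
      for (org in c("CA3", "Sub")) {
        for (cls in c("IID", "ID")) {
          ids <- d$discharge_id[in_ep & d$origin == org &
                                  d$discharge_class == cls]
          pm <- mem[mem$discharge_id %in% ids &
                      mem$electrode_id %in% pair, , drop = FALSE]
          if (nrow(pm)) {
            per <- split(pm, pm$discharge_id)
            amp <- vapply(per, function(m) mean(m$peak_amplitude_uV), 0)
            dur <- vapply(per, function(m) mean(m$duration_s), 0)
            incomplete <- sum(vapply(per, nrow, 0L) < 2L)
            n <- length(per)
          } else {
            amp <- dur <- numeric(0); incomplete <- 0L; n <- 0L
          }
          out[[length(out) + 1L]] <- data.frame(
            epoch = ep$label, region = reg, origin = org, class = cls,
            n = n, frequency_per_min = n / minutes,
            mean_amplitude_uV = if (n) mean(amp) else NA_real_,
            mean_duration_s = if (n) mean(dur) else NA_real_,
            n_pair_incomplete = incomplete, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare matched values across recording epochs
#'
#' Two matched epochs are compared with a two-sided paired t-test; three or
#' more (e.g. control / drug / washout) with a fixed-effects one-way ANOVA on
#' per-slice epoch means. P-values are raw (no multiple-testing correction is
#' applied, and reports should flag them as such).
#'
#' @param values For `design = "paired"`: a 2-column matrix/data.frame or a
#'   list of two equal-length vectors (slices x epochs). For
#'   `design = "anova"`: a list of >= 2 numeric vectors, one per epoch/group.
#' @param design `"paired"` or `"anova"`.
#' @param alpha Significance level (default 0.05).
#' @return data.frame of class `stat_result`: `test`, `statistic`, `df`
#'   (for ANOVA, `df` and `df2`), `p_value`, `significant`.
#' @export
compare_epochs <- function(values, design = c("paired", "anova"),
                           alpha = 0.05) {
  design <- match.arg(design)
  if (design == "paired") {
    if (is.list(values) && !is.data.frame(values)) {
      stopifnot(length(values) == 2L)
      a <- values[[1]]; b <- values[[2]]
    } else {
      values <- as.matrix(values)
      if (ncol(values) != 2L) stop("paired design needs exactly two columns")
      a <- values[, 1]; b <- values[, 2]
    }
    if (length(a) != length(b)) stop("paired design needs matched samples")
    if (length(a) < 2L) stop("need at least 2 pairs")
    if (stats::sd(a - b) == 0) {
      # zero-variance differences: t.test refuses these. All-equal pairs
      # mean no effect (t = 0, p = 1); a constant non-zero shift is an
      # infinitely precise effect (|t| = Inf, p = 0).
      m <- mean(a - b)
      res <- data.frame(test = "paired-t",
                        statistic = if (m == 0) 0 else sign(m) * Inf,
                        df = length(a) - 1, df2 = NA_real_,
                        p_value = if (m == 0) 1 else 0,
                        significant = m != 0, stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      res <- data.frame(test = "paired-t", statistic = unname(tt$statistic),
                        df = unname(tt$parameter), df2 = NA_real_,
                        p_value = tt$p.value,
                        significant = tt$p.value < alpha,
                        stringsAsFactors = FALSE)
    }
  } else {
    if (!is.list(values) || length(values) < 2L)
      stop("ANOVA design needs a list of >= 2 groups")
    if (any(lengths(values) < 2L)) stop("each group needs at least 2 values")
    grp <- factor(rep(seq_along(values), lengths(values)))
    y <- unlist(values, use.names = FALSE)
    fit <- stats::aov(y ~ grp)
    s <- summary(fit)[[1]]
    res <- data.frame(test = "one-way-ANOVA", statistic = s$`F value`[1],
                      df = s$Df[1], df2 = s$Df[2],
                      p_value = s$`Pr(>F)`[1],
                      significant = s$`Pr(>F)`[1] < alpha,
                      stringsAsFactors = FALSE)
  }
  class(res) <- c("stat_result", "data.frame")
  res
}

#' Normalise Western-blot densitometry and compare regions
#'
#' Relative protein level = target-band intensity over the same sample's
#' beta-actin loading control; each subicular relative level is then
#' normalised to the corresponding hippocampus-proper (HP) level, so HP is
#' 1.0 by construction. HP and subiculum are compared per protein with a
#' paired t-test across animals on the relative (actin-normalised) levels.
#'
#' @param tab data.frame with columns `animal`, `region` (`"HP"` or
#'   `"Sub"`), `protein` (targets plus `"beta-actin"`), `intensity` (> 0).
#'   Every animal needs all proteins in both regions.
#' @param loading_control Protein name of the loading control
#'   (default `"beta-actin"`).
#' @param alpha Significance level for the paired test (default 0.05).
#' @return List: `relative` (animal x region x protein relative levels),
#'   `normalized` (per animal and protein, Sub level with HP fixed at 1.0),
#'   `tests` (per-protein [compare_epochs()]-style paired-t results,
#'   HP vs Sub).
#' @export
normalize_densitometry <- function(tab, loading_control = "beta-actin",
                                   alpha = 0.05) {
  req <- c("animal", "region", "protein", "intensity")
  if (!all(req %in% names(tab)))
    stop("densitometry table needs columns ", paste(req, collapse = ", "))
  if (any(!is.finite(tab$intensity) | tab$intensity <= 0))
    stop("band intensities must be positive")
  if (!all(tab$region %in% c("HP", "Sub")))
    stop("region must be 'HP' or 'Sub'")
  targets <- setdiff(unique(tab$protein), loading_control)
  if (!length(targets)) stop("no target proteins besides the loading control")
  key <- function(animal, region, protein)
    tab$intensity[tab$animal == animal & tab$region == region &
                    tab$protein == protein]
  rel <- list()
  for (an in unique(tab$animal)) {
    for (rg in c("HP", "Sub")) {
      actin <- key(an, rg, loading_control)
      if (length(actin) != 1L)
        stop("animal ", an, " region ", rg, " lacks a single ",
             loading_control, " intensity")
      for (pr in targets) {
        v <- key(an, rg, pr)
        if (length(v) != 1L)
          stop("animal ", an, " region ", rg, " lacks a single ", pr,
               " intensity")
        rel[[length(rel) + 1L]] <- data.frame(
          animal = an, region = rg, protein = pr,
          relative_level = v / actin, stringsAsFactors = FALSE)
      }
    }
  }
  rel <- do.call(rbind, rel)
  norm <- list(); tests <- list()
  for (pr in targets) {
    hp <- rel[rel$protein == pr & rel$region == "HP", ]
    sub <- rel[rel$protein == pr & rel$region == "Sub", ]
    sub <- sub[match(hp$animal, sub$animal), ]
    norm[[length(norm) + 1L]] <- data.frame(
      animal = hp$animal, protein = pr,
      HP = 1.0, Sub = sub$relative_level / hp$relative_level,
      stringsAsFactors = FALSE)
    tt <- compare_epochs(list(hp$relative_level, sub$relative_level),
                         design = "paired", alpha = alpha)
    tt$protein <- pr
    tests[[length(tests) + 1L]] <- tt
  }
  list(relative = rel,
       normalized = do.call(rbind, norm),
       tests = do.call(rbind, tests))
}

#' Simulate a synthetic densitometry table
#'
#' Generates a synthetic animal x region x protein band-intensity table (this
#' is a stand-in constructed for testing the normalisation workflow, not
#' measured data): per-animal log-normal actin and target intensities with a
#' region effect on each target given as the true Sub/HP ratio of
#' actin-normalised levels.
#'
#' @param n_animals Number of animals (default 8).
#' @param effects Named numeric: true Sub/HP ratio per target protein
#'   (default NKCC1 lower in Sub, NR2A/NR2B higher in Sub).
#' @param cv Lognormal coefficient of variation of intensities (default 0.15).
#' @param seed Integer seed.
#' @return data.frame suitable for [normalize_densitometry()].
#' @export
simulate_densitometry <- function(n_animals = 8,
                                  effects = c(NKCC1 = 0.55, NR2A = 1.9,
                                              NR2B = 1.75),
                                  cv = 0.15, seed = 1) {
  with_sim_seed(seed, {
    sdlog <- sqrt(log(1 + cv^2))
    rows <- list()
    for (an in seq_len(n_animals)) {
      for (rg in c("HP", "Sub")) {
        actin <- stats::rlnorm(1, log(1000), sdlog)
        rows[[length(rows) + 1L]] <- data.frame(
          animal = an, region = rg, protein = "beta-actin",
          intensity = actin, stringsAsFactors = FALSE)
        for (pr in names(effects)) {
          mu <- 500 * if (rg == "Sub") effects[[pr]] else 1
          rows[[length(rows) + 1L]] <- data.frame(
            animal = an, region = rg, protein = pr,
            intensity = actin / 1000 * stats::rlnorm(1, log(mu), sdlog),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
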