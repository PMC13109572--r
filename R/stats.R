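# Summaries of the 3-D fPAR field: vertical profiles, gradients, grouped
# aggregates, one-way ANOVA and Duncan's multiple range test.

#' Vertical profile of a voxel attribute
#'
#' Bins voxels by centroid height into contiguous half-open intervals of
#' `bin_width` metres starting at 0 and reports the per-bin mean and count;
#' bins without voxels keep `NA` means.
#'
#' @param table Voxel table with `z` and the value column.
#' @param bin_width Bin width in metres (default 5, the stratification used
#'   for vertical summaries; 2 matches the voxel resolution).
#' @param value Column to average (default `"fpar_pred"`).
#' @return Data frame `bin_low`, `bin_high`, `mean`, `count`.
#' @export
vertical_profile <- function(table, bin_width = 5, value = "fpar_pred") {
  stopifnot(bin_width > 0, value %in% names(table))
  if (nrow(table) == 0)
    return(data.frame(bin_low = numeric(), bin_high = numeric(),
                      mean = numeric(), count = integer()))
  k <- bin_index(table$z, 0, bin_width)
  kmax <- max(k)
  means <- tapply(table[[value]], k, mean, na.rm = TRUE)
  counts <- tapply(table[[value]], k, length)
  bins <- 0:kmax
  cnt <- unname(counts[as.character(bins)])
  data.frame(bin_low = bins * bin_width, bin_high = (bins + 1) * bin_width,
             mean = as.numeric(means[as.character(bins)]),
             count = as.integer(ifelse(is.na(cnt), 0L, cnt)))
}

#' Relative lower-to-upper increase, in percent
#'
#' `100 * (upper - lower) / lower`; undefined (NA with a warning) when the
#' lower mean is not positive.
#'
#' @param upper,lower Mean fPAR of the upper and lower stratum.
#' @return Percent increase from lower to upper.
#' @export
gradient_percent <- function(upper, lower) {
  if (any(lower <= 0)) {
    warning("lower-stratum mean is not positive; gradient undefined")
    return(NA_real_)
  }
  100 * (upper - lower) / lower
}

#' Zone assignment for validation-style height zonings
#'
#' Assigns each height to the first matching `[low, high)` interval of a
#' named zone list, `NA` outside every zone.
#'
#' @param z Heights (m).
#' @param zones Named list of `c(low, high)` pairs, e.g.
#'   `list(upper = c(15, 20), middle = c(10, 15), lower = c(0, 5))`.
#' @return Character vector of zone names (NA outside all zones).
#' @export
assign_zone <- function(z, zones) {
  out <- rep(NA_character_, length(z))
  for (nm in names(zones)) {
    zz <- zones[[nm]]
    hit <- is.na(out) & z >= zz[1] & z < zz[2]
    out[hit] <- nm
  }
  out
}

#' Aggregate voxel fPAR by tree, stratum, month and family
#'
#' Group means with voxel counts carried; any subset of the grouping columns
#' present in the table can be used. When a `zones` list is supplied, voxel
#' stratum labels are recomputed from it and voxels outside every zone are
#' excluded (count recorded in the `excluded` attribute).
#'
#' @param table Voxel table with a value column and grouping columns.
#' @param by Character vector of grouping columns.
#' @param value Column to average.
#' @param zones Optional named zone list (see [assign_zone()]).
#' @return Data frame of group means and voxel counts.
#' @export
aggregate_fpar <- function(table, by = c("tree_id", "stratum"),
                           value = "fpar_pred", zones = NULL) {
  excluded <- 0L
  if (!is.null(zones)) {
    table$stratum <- assign_zone(table$z, zones)
    excluded <- sum(is.na(table$stratum))
    table <- table[!is.na(table$stratum), , drop = FALSE]
  }
  by <- intersect(by, names(table))
  stopifnot(length(by) > 0, value %in% names(table))
  dt <- data.table::as.data.table(table[, c(by, value)])
  data.table::setnames(dt, value, ".value")
  out <- dt[, list(mean = mean(.value, na.rm = TRUE),
                   n_voxels = sum(!is.na(.value))), by = by]
  data.table::setorderv(out, by)
  out <- as.data.frame(out)
  attr(out, "excluded") <- excluded
  out
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition via [stats::lm()]; with zero
#' within-group variance and unequal means, F is infinite and p = 0.
#'
#' @param values Numeric response.
#' @param groups Grouping factor (>= 2 levels; >= 2 residual df).
#' @return List with `F`, `df1`, `df2`, `p`, `ms_within` and `group_means`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  g <- nlevels(groups)
  n <- length(values)
  if (g < 2)
    stop_voxfpar("one-way ANOVA needs at least 2 groups", "voxfpar_data_error")
  if (n - g < 2)
    stop_voxfpar("one-way ANOVA needs at least 2 residual degrees of freedom",
                 "voxfpar_data_error")
  fit <- stats::lm(values ~ groups)
  # the degenerate zero-residual case is handled explicitly below, so the
  # "essentially perfect fit" warning carries no information here
  a <- suppressWarnings(stats::anova(fit))
  msb <- a$`Mean Sq`[1]; msw <- a$`Mean Sq`[2]
  # exact within-group fits leave only rounding residue
  if (msw <= 1e-12 * max(msb, 1)) msw <- 0
  if (msw == 0) {
    Fv <- if (msb > 0) Inf else 0
    p <- if (msb > 0) 0 else 1
  } else {
    Fv <- a$`F value`[1]
    p <- a$`Pr(>F)`[1]
  }
  list(F = Fv, df1 = a$Df[1], df2 = a$Df[2], p = p, ms_within = msw,
       group_means = tapply(values, groups, mean))
}

# Duncan critical range for a span of p means:
# protection level alpha_p = 1 - (1 - alpha)^(p - 1), critical value from the
# studentized range distribution, standard error from the harmonic mean n.
duncan_range <- function(p_span, alpha, df2, ms_within, n_h) {
  alpha_p <- 1 - (1 - alpha)^(p_span - 1)
  stats::qtukey(1 - alpha_p, p_span, df2) * sqrt(ms_within / n_h)
}

#' Duncan's multiple range test
#'
#' Means are sorted descending and compared by the stepwise range procedure:
#' a span of `p` means is non-significant when its extreme difference falls
#' inside the Duncan critical range for that span, and no span inside a
#' non-significant span may be declared significant (protection). Unequal
#' group sizes use the harmonic mean n. Groups sharing a letter do not differ
#' at level `alpha`.
#'
#' @param values Numeric response.
#' @param groups Grouping factor.
#' @param alpha Significance level (default 0.05).
#' @return Data frame `group`, `mean`, `n`, `letters`, sorted by descending
#'   mean; attributes carry the ANOVA pieces used.
#' @export
duncan_mrt <- function(values, groups, alpha = 0.05) {
  an <- one_way_anova(values, groups)
  groups <- factor(groups)
  means <- sort(tapply(values, groups, mean), decreasing = TRUE)
  ns <- tapply(values, groups, length)[names(means)]
  g <- length(means)
  n_h <- g / sum(1 / ns)
  # nonsig[a, b]: the span from rank a to rank b is non-significant
  nonsig <- matrix(FALSE, g, g)
  if (an$ms_within == 0) {
    for (a in seq_len(g)) for (b in a:g)
      nonsig[a, b] <- means[a] == means[b]
  } else {
    # examine spans from widest to narrowest; protection: any span inside an
    # already non-significant span is non-significant too
    for (span in g:2) {
      for (a in seq_len(g - span + 1)) {
        b <- a + span - 1
        wider <- which(nonsig, arr.ind = TRUE)
        inside <- nrow(wider) > 0 && any(wider[, 1] <= a & wider[, 2] >= b)
        crit <- duncan_range(span, alpha, an$df2, an$ms_within, n_h)
        if (inside || (means[a] - means[b] <= crit))
          nonsig[a, b] <- TRUE
      }
    }
    diag(nonsig) <- TRUE
  }
  # letters: each maximal non-significant run [a, b] gets one letter
  runs <- list()
  for (a in seq_len(g)) {
    b <- a
    while (b < g && nonsig[a, b + 1]) b <- b + 1
    runs[[a]] <- c(a, b)
  }
  runs <- unique(runs)
  maximal <- Filter(function(r) {
    !any(vapply(runs, function(s)
      (s[1] < r[1] && s[2] >= r[2]) || (s[1] <= r[1] && s[2] > r[2]),
      logical(1)))
  }, runs)
  lett <- rep("", g)
  for (ri in seq_along(maximal)) {
    r <- maximal[[ri]]
    idx <- r[1]:r[2]
    lett[idx] <- paste0(lett[idx], letters[(ri - 1) %% 26 + 1])
  }
  out <- data.frame(group = names(means), mean = as.numeric(means),
                    n = as.integer(ns), letters = lett)
  attr(out, "anova") <- an
  attr(out, "alpha") <- alpha
  out
}
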