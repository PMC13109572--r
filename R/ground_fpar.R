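# Turning six-component quantum-sensor PAR readings into tree/stratum fPAR
# labels and attaching them to fused voxels.
#
# Component naming (umol m-2 s-1): PAR_ci/PAR_cr incident and reflected at
# the canopy top, PAR_mi/PAR_mr mid-canopy, PAR_gi/PAR_gr at the base.

PAR_COMPONENTS <- c("PAR_ci", "PAR_cr", "PAR_mi", "PAR_mr", "PAR_gi", "PAR_gr")

#' Average PAR readings over cardinal directions
#'
#' Component-wise arithmetic mean of the available directions for each
#' tree x date; the number of directions averaged is recorded in
#' `n_directions`.
#'
#' @param par Wide PAR table (see [simulate_par()]).
#' @return One row per tree x date with averaged components.
#' @export
average_directions <- function(par) {
  if (nrow(par) == 0)
    stop_voxfpar("no PAR records to average", "voxfpar_data_error")
  if (!all(PAR_COMPONENTS %in% names(par)))
    stop_voxfpar("PAR table missing component columns", "voxfpar_format_error")
  key <- paste(par$tree_id, par$date, sep = "\r")
  groups <- split(seq_len(nrow(par)), key)
  out <- do.call(rbind, lapply(groups, function(idx) {
    row <- data.frame(tree_id = par$tree_id[idx[1]], date = par$date[idx[1]])
    for (cc in PAR_COMPONENTS) row[[cc]] <- mean(par[[cc]][idx])
    row$n_directions <- length(idx)
    row
  }))
  rownames(out) <- NULL
  out[order(out$tree_id, out$date), , drop = FALSE]
}

#' Compute APAR and fPAR from six-component readings
#'
#' `three_layer` mode implements the published three-layer balance verbatim:
#' `APAR = PAR_ci - PAR_cr - (PAR_gi - PAR_gr) - (PAR_mi - PAR_mr)`, i.e. it
#' subtracts both the middle and ground net fluxes from the top net flux,
#' which can go negative when the middle flux is large. `two_layer` mode uses
#' the physically consistent whole-canopy balance
#' `APAR = (PAR_ci - PAR_cr) - (PAR_gi - PAR_gr)`. In both modes
#' `fPAR = APAR / PAR_ci`; values outside [0, 1] are retained but flagged
#' `valid = FALSE`, never clipped.
#'
#' @param par Table with the six component columns (`PAR_ci` > 0).
#' @param mode `"three_layer"` (default, verbatim balance) or `"two_layer"`.
#' @return `par` with `apar`, `fpar` and `valid` columns.
#' @export
compute_apar_fpar <- function(par, mode = c("three_layer", "two_layer")) {
  mode <- match.arg(mode)
  if (any(par$PAR_ci <= 0))
    stop_voxfpar("PAR_ci must be positive for a usable record",
                 "voxfpar_data_error")
  apar <- if (mode == "three_layer") {
    par$PAR_ci - par$PAR_cr - (par$PAR_gi - par$PAR_gr) -
      (par$PAR_mi - par$PAR_mr)
  } else {
    (par$PAR_ci - par$PAR_cr) - (par$PAR_gi - par$PAR_gr)
  }
  par$apar <- apar
  par$fpar <- apar / par$PAR_ci
  par$valid <- par$fpar >= 0 & par$fpar <= 1
  attr(par, "fpar_mode") <- mode
  par
}

#' Per-stratum fPAR from one six-component balance
#'
#' Net downward flux at each level: `phi_c = PAR_ci - PAR_cr`,
#' `phi_m = PAR_mi - PAR_mr`, `phi_g = PAR_gi - PAR_gr`. The layer absorbed
#' fractions are `upper = (phi_c - phi_m)/PAR_ci`,
#' `middle = (phi_m - phi_g)/PAR_ci` and
#' `lower = phi_g * (1 - tau_floor)/PAR_ci`, where `tau_floor` is the assumed
#' transmission through the lowest layer to the forest floor (default 0: all
#' remaining flux is attributed to the lower layer).
#'
#' @param par Averaged component table (one row per tree x date).
#' @param tau_floor Floor transmission constant in [0, 1).
#' @return Long table: `tree_id`, `date`, `stratum`, `apar`, `fpar`;
#'   attribute `strategy` records the layering rule.
#' @export
compute_layer_fpar <- function(par, tau_floor = 0) {
  if (any(par$PAR_ci <= 0))
    stop_voxfpar("PAR_ci must be positive", "voxfpar_data_error")
  stopifnot(tau_floor >= 0, tau_floor < 1)
  phi_c <- par$PAR_ci - par$PAR_cr
  phi_m <- par$PAR_mi - par$PAR_mr
  phi_g <- par$PAR_gi - par$PAR_gr
  ap <- cbind(upper = phi_c - phi_m, middle = phi_m - phi_g,
              lower = phi_g * (1 - tau_floor))
  out <- data.frame(
    tree_id = rep(par$tree_id, 3),
    date = rep(par$date, 3),
    stratum = rep(c("upper", "middle", "lower"), each = nrow(par)),
    apar = c(ap[, "upper"], ap[, "middle"], ap[, "lower"]))
  out$fpar <- out$apar / rep(par$PAR_ci, 3)
  out$valid <- out$fpar >= 0 & out$fpar <= 1
  attr(out, "strategy") <- sprintf("net-flux differencing (tau_floor = %g)",
                                   tau_floor)
  out[order(out$tree_id, out$date,
            match(out$stratum, c("upper", "middle", "lower"))), , drop = FALSE]
}

#' Derive stratum height thresholds from tree heights
#'
#' Linear-interpolation percentiles (the default quantile definition) of the
#' LiDAR-derived height distribution; the published zoning (15 m / 7 m)
#' corresponds approximately to the 75th and 40th percentiles of its stand.
#'
#' @param heights Numeric tree heights (>= 2 values, not all equal).
#' @param p_upper,p_lower Percentiles in (0, 100), `p_upper > p_lower`.
#' @return List with `t_upper`, `t_lower` (metres).
#' @export
derive_thresholds <- function(heights, p_upper = 75, p_lower = 40) {
  heights <- heights[!is.na(heights)]
  if (length(heights) < 2)
    stop_voxfpar("need at least two tree heights", "voxfpar_data_error")
  stopifnot(p_upper > p_lower, p_lower > 0, p_upper < 100)
  t_upper <- unname(stats::quantile(heights, p_upper / 100, type = 7))
  t_lower <- unname(stats::quantile(heights, p_lower / 100, type = 7))
  if (t_upper <= t_lower || t_lower <= 0)
    stop_voxfpar("degenerate stand: percentile thresholds do not separate strata",
                 "voxfpar_degenerate_error")
  list(t_upper = t_upper, t_lower = t_lower)
}

#' Assign a canopy stratum to each voxel
#'
#' Upper if `z >= t_upper`, middle if `t_lower <= z < t_upper`, lower if
#' `z < t_lower`, with `z` the voxel centroid height. A partition: every
#' voxel gets exactly one label.
#'
#' @param table Fused voxel table with centroid heights `z`.
#' @param thresholds List with `t_upper` and `t_lower`
#'   (`t_upper > t_lower > 0`), e.g. from [derive_thresholds()] or the fixed
#'   published zoning `list(t_upper = 15, t_lower = 7)`.
#' @return `table` with a `stratum` column.
#' @export
assign_strata <- function(table, thresholds = list(t_upper = 15, t_lower = 7)) {
  stopifnot(thresholds$t_upper > thresholds$t_lower, thresholds$t_lower > 0)
  table$stratum <- ifelse(table$z >= thresholds$t_upper, "upper",
                          ifelse(table$z >= thresholds$t_lower, "middle",
                                 "lower"))
  attr(table, "thresholds") <- thresholds
  table
}

#' Label voxels with measured stratum fPAR and build the training table
#'
#' Each voxel is assigned to a segmented tree by looking its column's (x, y)
#' up in the segmentation label raster; segment labels are linked to measured
#' tree ids through `tree_map`. Voxels of a measured tree receive that tree's
#' fPAR for their stratum; background voxels and unmeasured trees stay
#' unlabeled. Tree-level training rows average the spectral predictors over
#' each tree x stratum.
#'
#' @param table Fused voxel table with `stratum` and index columns.
#' @param stratum_fpar Long table from [compute_layer_fpar()].
#' @param segmentation A [segment_trees()] result.
#' @param tree_map Data frame `seg_id` -> `tree_id` (e.g. [match_trees()]);
#'   `NULL` means segment labels are already measured-tree ids.
#' @return List with `voxels` (labelled voxel table with `tree_id` and
#'   `fpar_label`) and `training` (one row per tree x stratum x date: mean
#'   predictors plus `fpar`).
#' @export
label_voxels <- function(table, stratum_fpar, segmentation, tree_map = NULL) {
  lab <- raster_sample(segmentation$labels, table$x, table$y)[, 1]
  lab[is.na(lab) | lab == 0] <- NA
  if (!is.null(tree_map)) {
    table$tree_id <- tree_map$tree_id[match(lab, tree_map$seg_id)]
  } else table$tree_id <- lab
  if (!"stratum" %in% names(table))
    stop_voxfpar("voxel table has no stratum labels: run assign_strata() first",
                 "voxfpar_data_error")
  key_v <- paste(table$tree_id, table$stratum)
  key_m <- paste(stratum_fpar$tree_id, stratum_fpar$stratum)
  hit <- match(key_v, key_m)
  table$fpar_label <- stratum_fpar$fpar[hit]
  if ("date" %in% names(stratum_fpar)) table$date <- stratum_fpar$date[hit]
  measured <- unique(stratum_fpar$tree_id)
  miss <- setdiff(unique(stats::na.omit(table$tree_id)), measured)
  if (length(miss))
    warning(sprintf("%d segmented tree(s) have no PAR measurements and stay unlabeled",
                    length(miss)))
  pred_cols <- intersect(c("R450", "R560", "R650", "R730", "R840", vi_names()),
                         names(table))
  lab_rows <- !is.na(table$fpar_label)
  training <- if (any(lab_rows)) {
    dt <- data.table::as.data.table(table[lab_rows, c("tree_id", "stratum",
                                                      pred_cols, "fpar_label")])
    tr <- dt[, c(lapply(.SD, mean, na.rm = TRUE),
                 list(n_voxels = .N)),
             by = c("tree_id", "stratum", "fpar_label"),
             .SDcols = pred_cols]
    tr <- as.data.frame(tr)
    names(tr)[names(tr) == "fpar_label"] <- "fpar"
    tr[order(tr$tree_id, match(tr$stratum, c("upper", "middle", "lower"))), ,
       drop = FALSE]
  } else {
    data.frame()
  }
  list(voxels = table, training = training)
}
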