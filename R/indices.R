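# Registry of the fourteen vegetation indices computed on the five bands
# (450 = blue, 560 = green, 650 = red, 730 = red edge, 840 = NIR).
#
# Two variants ship for every entry. The published table this registry
# transcribes contains typographic corruption: its NDRE is printed as a bare
# difference "(NIR - red - red edge)", its ARI duplicates GNDVI, and the
# denominator of RECI/MARI is ambiguous between "red minus red edge" and the
# red-edge band itself. The `canonical` variant resolves those four entries
# to their literature forms (NDRE = (NIR-RE)/(NIR+RE); ARI = 1/G - 1/RE;
# RECI = NIR/RE - 1; MARI = NIR/RE); `as_printed` evaluates the printed
# text verbatim where it parses. GCI, LCI, GRVI, MGRVI and MACI keep their
# printed formulas in both variants even though some differ from the indices
# usually published under those names; the formula strings below are the
# authoritative definitions used here.

vi_formula_table <- function() {
  # b, g, r, e, n = reflectance at 450, 560, 650, 730, 840 nm
  def <- list(
    NDVI  = list(can = function(b, g, r, e, n) (n - r) / (n + r),
                 can_s = "(N-R)/(N+R)"),
    OSAVI = list(can = function(b, g, r, e, n) 1.16 * (n - r) / (n + r + 0.16),
                 can_s = "1.16*(N-R)/(N+R+0.16)"),
    GNDVI = list(can = function(b, g, r, e, n) (n - g) / (n + g),
                 can_s = "(N-G)/(N+G)"),
    SAVI  = list(can = function(b, g, r, e, n) 1.5 * (n - r) / (n + r + 0.5),
                 can_s = "1.5*(N-R)/(N+R+0.5)"),
    MSAVI = list(can = function(b, g, r, e, n) 1.1 * (n - r) / (n + r + 0.1),
                 can_s = "1.1*(N-R)/(N+R+0.1)"),   # L = 0.1
    GCI   = list(can = function(b, g, r, e, n) (g - r) / r,
                 can_s = "(G-R)/R"),
    RECI  = list(can = function(b, g, r, e, n) n / e - 1,
                 can_s = "N/RE-1",
                 printed = function(b, g, r, e, n) n / (r - e) - 1,
                 printed_s = "N/(R-RE)-1"),
    LCI   = list(can = function(b, g, r, e, n) (n - g) / g,
                 can_s = "(N-G)/G"),
    GRVI  = list(can = function(b, g, r, e, n) g / n,
                 can_s = "G/N"),
    MGRVI = list(can = function(b, g, r, e, n) g / (n + r),
                 can_s = "G/(N+R)"),
    NDRE  = list(can = function(b, g, r, e, n) (n - e) / (n + e),
                 can_s = "(N-RE)/(N+RE)",
                 printed = function(b, g, r, e, n) n - r - e,
                 printed_s = "N-R-RE"),
    MACI  = list(can = function(b, g, r, e, n) n / r,
                 can_s = "N/R"),
    ARI   = list(can = function(b, g, r, e, n) 1 / g - 1 / e,
                 can_s = "1/G-1/RE",
                 printed = function(b, g, r, e, n) (n - g) / (n + g),
                 printed_s = "(N-G)/(N+G)"),
    MARI  = list(can = function(b, g, r, e, n) n / e,
                 can_s = "N/RE",
                 printed = function(b, g, r, e, n) n / (r - e),
                 printed_s = "N/(R-RE)"))
  def
}

#' Names of the fourteen registered vegetation indices
#' @return Character vector of index names.
#' @export
vi_names <- function() names(vi_formula_table())

#' Dump the vegetation-index registry
#'
#' @return Data frame with `name`, `variant` and `formula` (one row per
#'   name x variant), suitable for export as CSV documentation.
#' @export
vi_registry <- function() {
  tab <- vi_formula_table()
  do.call(rbind, lapply(names(tab), function(nm) {
    e <- tab[[nm]]
    data.frame(name = nm,
               variant = c("canonical", "as_printed"),
               formula = c(e$can_s, e$printed_s %||% e$can_s))
  }))
}

eval_index <- function(fn, b, g, r, e, n) {
  out <- fn(b, g, r, e, n)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Compute one vegetation index on band reflectance
#'
#' Zero denominators yield `NA`, never an error. Vectorized over bands.
#'
#' @param name Registered index name (see [vi_names()]).
#' @param blue,green,red,rededge,nir Reflectance at 450/560/650/730/840 nm.
#' @param variant `"canonical"` or `"as_printed"` (see the registry notes).
#' @return Numeric vector of index values (`NA` where undefined).
#' @export
compute_index <- function(name, blue, green, red, rededge, nir,
                          variant = c("canonical", "as_printed")) {
  variant <- match.arg(variant)
  tab <- vi_formula_table()
  if (!name %in% names(tab))
    stop_voxfpar(sprintf("unknown vegetation index '%s'; valid names: %s",
                         name, paste(names(tab), collapse = ", ")),
                 "voxfpar_lookup_error")
  e <- tab[[name]]
  fn <- if (variant == "as_printed") (e$printed %||% e$can) else e$can
  eval_index(fn, blue, green, red, rededge, nir)
}

#' Add all fourteen vegetation-index columns to a fused voxel table
#'
#' Missing reflectance propagates to missing index values; because
#' reflectance is constant within a column, every index is too.
#'
#' @param table A [propagate_reflectance()] table (columns `R450`..`R840`).
#' @param variant Registry variant, as in [compute_index()].
#' @return `table` with one additional column per index.
#' @export
compute_indices <- function(table, variant = c("canonical", "as_printed")) {
  variant <- match.arg(variant)
  need <- c("R450", "R560", "R650", "R730", "R840")
  if (!all(need %in% names(table)))
    stop_voxfpar("reflectance columns R450..R840 are required",
                 "voxfpar_format_error")
  for (nm in vi_names())
    table[[nm]] <- compute_index(nm, table$R450, table$R560, table$R650,
                                 table$R730, table$R840, variant = variant)
  attr(table, "index_variant") <- variant
  table
}
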