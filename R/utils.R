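#' @keywords internal
#' @import data.table
"_PACKAGE"

# Derive a stage-scoped seed from a master seed. Keeps all randomness funneled
# through one user-visible integer while giving each stage an independent
# stream. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_voxfpar <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "voxfpar_error")))
}

# half-open floor binning used everywhere a coordinate meets a grid
bin_index <- function(x, origin, cell) as.integer(floor((x - origin) / cell))

grid_origin <- function(xmin, cell) floor(xmin / cell) * cell
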