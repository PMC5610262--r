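## Internal helpers.

# Column schema of the per-cell color measurement table. Every reader,
# writer and analysis entry point checks against this.
.cellCols <- c("cell_id", "islet_id", "stage_dpf",
               "r_mean", "g_mean", "b_mean",
               "r_sd", "g_sd", "b_sd",
               "n_pixels", "x", "y", "z")

.checkCellTable <- function(cells, need = .cellCols) {
  stopifnot(is.data.frame(cells))
  missing <- setdiff(need, names(cells))
  if (length(missing))
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(cells)
}

# All simulator randomness is scoped: the caller's RNG state is untouched
# and a given seed always reproduces the same draw sequence.
.withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

.checkProb <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop(name, " must be a single probability in [0,1]", call. = FALSE)
  p
}

# signif() already rounds to significant figures; kept as a named wrapper
# so the round-then-square convention in backgroundRecombination reads
# clearly at the call site.
.sigfig <- function(x, digits) signif(x, digits)
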