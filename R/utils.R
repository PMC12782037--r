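#' @keywords internal
"_PACKAGE"

# Closed sets of taxon names used by the generator and by taxonomic
# filtering. Orders are macroinvertebrate orders; anything outside the
# pool (e.g. contaminant pseudo-taxa) is treated as non-target.
MACRO_ORDER_POOL <- c(
  "Ephemeroptera", "Plecoptera", "Trichoptera", "Diptera",
  "Coleoptera", "Odonata", "Megaloptera", "Hemiptera"
)

NONTARGET_ORDER_POOL <- c(
  "Nematoda_indet", "Rotifera_indet", "Fungi_indet",
  "Platyhelminthes_indet", "Chlorophyta_indet"
)

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one root seed; each stage
#' (taxonomy, specimens, frames, weights, otus, folds, training) draws
#' from its own named sub-stream so stages can be re-run independently
#' without perturbing each other.
#'
#' @param seed integer root seed.
#' @param name character scalar naming the sub-stream.
#' @return an integer seed in `[0, 2^31 - 1)`, deterministic in
#'   `(seed, name)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- as.double(seed %% 2147483647)
  for (k in codes) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h)
}

# run expr under a local RNG state seeded from (seed, name)
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(substream_seed(seed, name))
  expr
}

abort_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

zero_pad <- function(i, width = 2) formatC(i, width = width, flag = "0")
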