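# Internal helpers shared across modules.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All package randomness flows through this
# so that no function perturbs (or depends on) global random state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# The 20 standard residues, the ambiguity/rare codes the pipeline tolerates.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_AMBIGUOUS <- c("X", "B", "Z", "J", "U", "O")

HABITAT_LEVELS <- c("freshwater", "brackish", "marine", "halophile")
LOCALIZATION_LEVELS <- c("secreted", "transmembrane", "cytoplasmic")
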