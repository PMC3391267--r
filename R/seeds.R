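#' Derive a child seed from a master seed and a label
#'
#' All randomness in the package flows from a single master seed.  Child
#' seeds for independent purposes (one subject's run design, its behavioral
#' draws, its noise realization, ...) are derived by hashing the master seed
#' together with a character label, so that changing one stage's label never
#' perturbs another stage's stream.
#'
#' The hash is a plain polynomial rolling hash over the label bytes, folded
#' into the positive 31-bit integer range R accepts in [set.seed].
#'
#' @param master_seed integer master seed.
#' @param ... components of the label (subject id, run id, purpose tag);
#'   collapsed with \code{"/"}.
#' @return an integer seed in \code{[0, 2^31 - 2]}.
#' @examples
#' child_seed(42, "sub01", 3, "behavior")
#' @export
child_seed <- function(master_seed, ...) {
  label <- paste(c(as.character(master_seed), vapply(list(...), as.character, "")),
                 collapse = "/")
  m <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% m
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
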