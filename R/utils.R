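#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

#' Derive a reproducible sub-seed from a master seed and string labels
#'
#' Analyses over many (cancer, pathway, endpoint) cells need independent,
#' individually reproducible random streams: regenerating one cell must not
#' shift any other cell's stream. Each cell therefore hashes its labels
#' together with the master seed into its own seed.
#'
#' @param seed Master integer seed.
#' @param ... Character or numeric labels identifying the substream
#'   (e.g. cancer type, pathway name, endpoint).
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "BRCA", "folate", "OS")
#' @export
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "\r")
  bytes <- utf8ToInt(labels)
  # 32-bit FNV-1a, folded into the positive integer range
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (gene/sample labels are 8-bit); keep h
    # as a double since it exceeds the signed-integer range
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # multiply by FNV prime 16777619 = 2^24 + 403, mod 2^32, kept exact in doubles
    h <- ((h * 403) %% 4294967296 + (h %% 256) * 16777216) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(seed)
  force(expr)
}

# assert helper: stop with a typed condition
check_that <- function(ok, msg, class = "pathmeta_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}
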