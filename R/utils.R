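#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# log(sum(exp(x))) without overflow; returns -Inf for empty input
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

fragment_name_pattern <- "^(.*)_([0-9]+)_([0-9]+)$"

#' Parse fragment names into scaffold, ordinal and length
#'
#' Fragment names follow the scheme `"{scaffold}_{ordinal}_{length}"`, e.g.
#' `"Sca971_3_662"` is the third retained fragment of scaffold Sca971 and is
#' 662 bp long.
#'
#' @param x Character vector of fragment names.
#' @return A tibble with columns `name`, `scaffold_id`, `ordinal`, `length`.
#' @examples
#' parse_fragment_names(c("Sca971_3_662", "Sca28791_1_303"))
#' @export
parse_fragment_names <- function(x) {
  stopifnot(is.character(x))
  ok <- grepl(fragment_name_pattern, x)
  if (any(!ok)) {
    abort(paste0(
      "fragment names not matching '{scaffold}_{ordinal}_{length}': ",
      paste(utils::head(x[!ok], 5L), collapse = ", ")
    ))
  }
  tibble(
    name = x,
    scaffold_id = sub(fragment_name_pattern, "\\1", x),
    ordinal = as.integer(sub(fragment_name_pattern, "\\2", x)),
    length = as.integer(sub(fragment_name_pattern, "\\3", x))
  )
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}
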