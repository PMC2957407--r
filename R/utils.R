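#' @importFrom rlang .data abort warn :=
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats median sd cor setNames
NULL

# Wide binding tables carry features in the first column and one column per
# sample. These helpers move between that layout and a plain numeric matrix.

#' Convert a wide binding table to a numeric matrix
#'
#' @param tbl A data frame whose first column holds feature identifiers and
#'   whose remaining columns are numeric sample intensities.
#' @return A numeric matrix with feature rownames.
#' @export
binding_as_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), ncol(tbl) >= 2)
  ids <- as.character(tbl[[1]])
  if (anyDuplicated(ids)) {
    abort("duplicate feature ids in binding table")
  }
  m <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("sample columns must be numeric")
  rownames(m) <- ids
  m
}

#' Convert a numeric matrix back to a wide binding table
#'
#' @param m Numeric matrix with feature rownames.
#' @param feature_col Name for the feature column.
#' @return A tibble, features in `feature_col`, samples as columns.
#' @export
binding_as_tibble <- function(m, feature_col = "feature") {
  stopifnot(is.matrix(m))
  out <- as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(!!feature_col := rownames(m)), out)
  out
}

# Positive integer seed derived from a base seed and a stream index, kept
# below 2^31 so it is a valid R integer everywhere.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 1299721) %% 2147483647
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
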