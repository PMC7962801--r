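#' Style-pair matrices
#'
#' A pair matrix is a square numeric matrix indexed by the style roster,
#' rows denoting the target style and columns the distractor style; the
#' diagonal (a style against itself) is undefined and carried as `NA`,
#' except for distance matrices whose diagonal is 0. The `statistic`
#' attribute records what the cells mean (`"accuracy"`, `"mean_rt"`,
#' `"effective_rt"`, `"distance"`, `"asymmetry"`, ...).
#'
#' @param values square numeric matrix.
#' @param styles style roster matching the matrix order.
#' @param statistic character tag for the cell statistic.
#' @return the matrix with class `pair_matrix`, `dimnames` set to the
#'   styles, and a `statistic` attribute.
#' @export
pair_matrix <- function(values, styles, statistic) {
  styles <- as_style_set(styles)
  n <- length(styles)
  if (!is.matrix(values) || nrow(values) != n || ncol(values) != n) {
    stop(sprintf("`values` must be a %d x %d matrix matching the roster",
                 n, n), call. = FALSE)
  }
  dimnames(values) <- list(target = as.character(styles),
                           distractor = as.character(styles))
  structure(values, statistic = statistic,
            class = c("pair_matrix", class(values)))
}

#' @export
print.pair_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Pair matrix [%s], rows = target, columns = distractor\n",
              attr(x, "statistic")))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

# strip class/attr for arithmetic
pm_values <- function(x) {
  a <- unclass(x)
  attr(a, "statistic") <- NULL
  a
}

check_same_roster <- function(a, b) {
  if (!identical(rownames(a), rownames(b))) {
    stop("style rosters of the two matrices differ", call. = FALSE)
  }
  invisible(TRUE)
}
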