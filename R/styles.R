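#' Style rosters
#'
#' A style set is an ordered vector of unique style labels. The order is
#' fixed and used consistently for all matrix indexing (rows = target style,
#' columns = distractor style). The default roster is the eight styles of the
#' painterly-style experiments: early/late Impressionism (EI, LI), early/late
#' Expressionism (EE, LE), Gauguin (G), Photography (P), Cezanne (C) and
#' van Gogh (VG).
#'
#' @param labels character vector of unique style labels, length >= 2.
#' @return a character vector of class `style_set`.
#' @examples
#' style_set()
#' style_set(c("A", "B", "C"))
#' @export
style_set <- function(labels = c("EI", "LI", "EE", "LE", "G", "P", "C", "VG")) {
  labels <- as.character(labels)
  if (length(labels) < 2) {
    stop("a style set needs at least 2 styles", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("style labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(labels)) || any(labels == "")) {
    stop("style labels must be non-empty and non-missing", call. = FALSE)
  }
  structure(labels, class = c("style_set", "character"))
}

# coerce + validate a roster argument
as_style_set <- function(styles) {
  if (inherits(styles, "style_set")) return(styles)
  style_set(styles)
}

# check that all labels occur in the roster; error names the offenders
check_styles_known <- function(labels, styles, what = "style label") {
  unknown <- setdiff(unique(as.character(labels)), as.character(styles))
  if (length(unknown) > 0) {
    stop(sprintf("unknown %s(s): %s", what, paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}
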