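#' Build a filtered simplicial complex
#'
#' A filtration is a nested family of simplicial complexes indexed by a
#' scale value: every simplex enters at some value and stays.  It is the
#' object persistent homology is computed from.  `filtration()` stores it
#' as a tibble with one row per simplex, sorted into filtration order:
#' by entry value, then dimension, then lexicographic vertex tuple, which
#' fixes the pairing of simultaneous entries deterministically.
#'
#' @param simplices list of integer vectors, the vertex ids of each
#'   simplex (ids are non-negative integers; order within a vector does
#'   not matter, they are sorted).
#' @param values numeric vector of entry values, one per simplex.
#' @param validate check the face-closure property (every face of every
#'   simplex present with entry value no later than the simplex's)?
#' @return A `filtration`: tibble with columns `value` (dbl), `dim`
#'   (int) and `simplex` (list of sorted integer vectors), in filtration
#'   order.
#' @examples
#' # a triangle born edge by edge
#' filtration(
#'   simplices = list(1, 2, 3, c(1, 2), c(2, 3), c(1, 3)),
#'   values    = c(0, 0, 0, 1, 1, 2)
#' )
#' @export
filtration <- function(simplices, values, validate = TRUE) {
  if (length(simplices) != length(values)) {
    abort("`simplices` and `values` must have the same length.")
  }
  simplices <- lapply(simplices, function(v) {
    v <- as.integer(v)
    if (length(v) == 0 || anyNA(v) || any(v < 0)) {
      abort("each simplex must be a non-empty vector of non-negative vertex ids")
    }
    v <- sort(v)
    if (anyDuplicated(v)) abort("simplex vertices must be distinct")
    v
  })
  flt <- tibble(
    value = as.numeric(values),
    dim = vapply(simplices, length, integer(1)) - 1L,
    simplex = simplices
  )
  flt <- flt[order(flt$value, flt$dim, simplex_lex_key(flt$simplex)), ]
  flt <- structure(flt, class = c("filtration", class(tibble())))
  if (validate) validate_filtration(flt)
  flt
}

# lexicographic sort key for a list of vertex tuples
simplex_lex_key <- function(simplices) {
  vapply(simplices, function(v) paste(sprintf("%09d", v), collapse = ","),
         character(1))
}

simplex_id <- function(simplices) {
  vapply(simplices, paste, character(1), collapse = ",")
}

#' Validate a filtration
#'
#' Checks that every proper face of every simplex is present, and enters
#' the filtration no later than the simplex itself (the nesting property
#' of a filtration).  Called for you by [filtration()]; exposed so that
#' filtrations read from files can be checked.
#'
#' @param flt a [filtration()].
#' @return `flt`, invisibly; signals an `hrvtda_invalid_filtration`
#'   error otherwise.
#' @export
validate_filtration <- function(flt) {
  stopifnot(is.data.frame(flt), all(c("value", "dim", "simplex") %in% names(flt)))
  ids <- simplex_id(flt$simplex)
  if (anyDuplicated(ids)) {
    abort("duplicate simplex in filtration", class = "hrvtda_invalid_filtration")
  }
  first_value <- stats::setNames(flt$value, ids)
  for (i in seq_len(nrow(flt))) {
    v <- flt$simplex[[i]]
    if (length(v) == 1L) next
    for (drop in seq_along(v)) {
      face <- paste(v[-drop], collapse = ",")
      fv <- first_value[face]
      if (is.na(fv)) {
        abort(
          sprintf("face {%s} of simplex {%s} missing from filtration",
                  face, paste(v, collapse = ",")),
          class = "hrvtda_invalid_filtration"
        )
      }
      if (fv > flt$value[i]) {
        abort(
          sprintf("face {%s} enters at %g, after its coface {%s} at %g",
                  face, fv, paste(v, collapse = ","), flt$value[i]),
          class = "hrvtda_invalid_filtration"
        )
      }
    }
  }
  invisible(flt)
}

#' Read / write a filtration as CSV
#'
#' The format has a `value` column followed by vertex columns
#' `v0, v1, ...`; rows with fewer vertices leave the trailing columns
#' empty.
#'
#' @param path file path.
#' @param flt a [filtration()].
#' @return `read_filtration()` returns a validated [filtration()];
#'   `write_filtration()` returns `path` invisibly.
#' @export
read_filtration <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  df$value <- as.numeric(df$value)
  vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
  if (!"value" %in% names(df) || length(vcols) == 0) {
    abort("filtration CSV needs a `value` column and v0, v1, ... vertex columns")
  }
  vcols <- vcols[order(as.integer(sub("^v", "", vcols)))]
  simplices <- apply(as.matrix(df[vcols]), 1L, function(r) r[!is.na(r)],
                     simplify = FALSE)
  filtration(simplices, df$value)
}

#' @rdname read_filtration
#' @export
write_filtration <- function(flt, path) {
  maxv <- max(flt$dim) + 1L
  mat <- t(vapply(flt$simplex, function(v) c(v, rep(NA_integer_, maxv - length(v))),
                  integer(maxv)))
  out <- as_tibble(mat, .name_repair = ~ paste0("v", seq_along(.x) - 1L))
  out <- dplyr::bind_cols(tibble(value = flt$value), out)
  readr::write_csv(out, path)
  invisible(path)
}

#' @export
print.filtration <- function(x, ...) {
  cat(sprintf("# Filtration: %d simplexes, max dim %d, values [%g, %g]\n",
              nrow(x), max(x$dim), min(x$value), max(x$value)))
  NextMethod()
}
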