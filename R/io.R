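#' Coerce to a glomerulus-by-odor response matrix
#'
#' Accepts a numeric matrix (rows = glomeruli) or a data frame whose first
#' column holds glomerulus labels and remaining columns odor responses
#' (empty cells = missing).
#'
#' @param x matrix or data frame.
#' @return Numeric matrix with glomerulus rownames and odor colnames.
#' @export
as_response_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  x <- as.data.frame(x)
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(x[[1]])
  m
}

#' Read / write a response matrix CSV
#'
#' CSV schema: first column `glomerulus`, remaining columns odors; empty
#' cells are missing values.
#'
#' @param path file path.
#' @return `read_response_matrix()`: numeric matrix with dimnames.
#' @export
read_response_matrix <- function(path) {
  as_response_matrix(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_response_matrix
#' @param m numeric matrix, glomeruli x odors.
#' @export
write_response_matrix <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "glomerulus")
  readr::write_csv(df, path, na = "")
  invisible(m)
}

#' Tidy a response matrix into long form
#'
#' @param m glomeruli x odors matrix (e.g. `al_response$pn`).
#' @return Tibble `glomerulus`, `odor`, `rate`.
#' @export
response_to_tibble <- function(m) {
  tibble::as_tibble(m, rownames = "glomerulus") |>
    tidyr::pivot_longer(-"glomerulus", names_to = "odor",
                        values_to = "rate")
}
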