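`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_drh <- function(..., class = "drh_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Run an expression under a temporary RNG seed
#'
#' When `seed` is `NULL` the expression uses the current RNG stream.
#' @noRd
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x)

#' @noRd
check_grades <- function(grades, arg = "grades") {
  if (length(grades) == 0) stop_drh(arg, " is empty")
  if (any(is.na(grades)) || any(grades != as.integer(grades)) ||
      any(grades < 0) || any(grades > 4)) {
    stop_drh(arg, " must contain integer severity grades in 0..4",
             class = "drh_label_error")
  }
  as.integer(grades)
}

# Add a row vector b to every row of matrix M (column-major trick, no sweep).
#' @noRd
add_bias <- function(M, b) M + rep(b, each = nrow(M))
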