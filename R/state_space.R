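#' Discrete state spaces with integer encoding
#'
#' A state space is an ordered list of integer-valued variables, each with an
#' inclusive `[min, max]` range. States are tuples of variable values; every
#' state has a unique 1-based integer index under a mixed-radix encoding in
#' which the first variable varies fastest.
#'
#' @param variables a data.frame with columns `name`, `min`, `max` (integers,
#'   `min <= max`), one row per variable, in encoding order.
#' @return an object of class `state_space` with fields `vars`, `ranges`,
#'   `n_states` and the radix multipliers used by [encode_state()].
#' @seealso [encode_state()], [decode_state()], [water_state_space()]
#' @export
#' @examples
#' sp <- state_space(data.frame(name = c("a", "b"), min = c(0, -1), max = c(1, 1)))
#' sp$n_states # 6
state_space <- function(variables) {
  stopifnot(is.data.frame(variables),
            all(c("name", "min", "max") %in% names(variables)),
            nrow(variables) >= 1L)
  variables$min <- as.integer(variables$min)
  variables$max <- as.integer(variables$max)
  if (any(variables$min > variables$max)) {
    stop("every variable must satisfy min <= max")
  }
  if (anyDuplicated(variables$name)) stop("variable names must be unique")
  ranges <- variables$max - variables$min + 1L
  structure(
    list(
      vars = variables,
      ranges = as.integer(ranges),
      n_states = prod(as.double(ranges)),
      mult = cumprod(c(1, as.double(ranges[-length(ranges)])))
    ),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat("<state_space>", nrow(x$vars), "variables,", x$n_states, "states\n")
  print(x$vars, row.names = FALSE)
  invisible(x)
}

#' Encode states to integer indices
#'
#' @param space a [state_space()].
#' @param values a named numeric vector (one state) or a matrix/data.frame
#'   with one column per variable (any column order, matched by name).
#' @return integer vector of 1-based state indices.
#' @export
encode_state <- function(space, values) {
  if (is.null(dim(values))) {
    values <- matrix(values, nrow = 1L, dimnames = list(NULL, names(values)))
  }
  v <- as.matrix(as.data.frame(values)[, space$vars$name, drop = FALSE])
  digits <- sweep(v, 2L, space$vars$min, "-")
  if (any(digits < 0) || any(sweep(digits, 2L, space$ranges, ">="))) {
    stop("state value out of range for this state space")
  }
  as.integer(digits %*% space$mult) + 1L
}

#' Decode integer indices to states
#'
#' @param space a [state_space()].
#' @param index integer vector of 1-based state indices.
#' @return integer matrix with one row per index and one named column per
#'   variable; `decode_state(space, encode_state(space, s))` recovers `s`.
#' @export
decode_state <- function(space, index) {
  index <- as.integer(index)
  if (any(index < 1L | index > space$n_states)) {
    stop("state index out of range")
  }
  idx <- index - 1L
  k <- nrow(space$vars)
  out <- matrix(0L, length(idx), k, dimnames = list(NULL, space$vars$name))
  for (j in seq_len(k)) {
    out[, j] <- idx %% space$ranges[j] + space$vars$min[j]
    idx <- idx %/% space$ranges[j]
  }
  out
}
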