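# Internal helpers shared across modules: canonical ordering, tuple label
# encoding, structured error conditions, and a portable congruential RNG.

# Canonical ordering of labels. Radix sort is locale-independent (byte order),
# which makes every downstream enumeration deterministic across platforms.
canon_sort <- function(x) {
  if (length(x) == 0L) return(character(0))
  sort(x, method = "radix")
}

canon_order <- function(x) order(x, method = "radix")

#' Encode labels as a tuple label
#'
#' Pair and triple elements are plain labels of the form `"(x,y)"` /
#' `"(x,y,z)"` with no whitespace, so nested constructions stay ordinary
#' string labels.
#'
#' @param ... character vectors of component labels, recycled to a common
#'   length and joined position-wise.
#' @return A character vector of tuple labels.
#' @examples
#' tuple_label("mare", "colt")
#' @export
tuple_label <- function(...) {
  parts <- list(...)
  if (max(lengths(parts)) == 0L) return(character(0))
  paste0("(", do.call(paste, c(parts, sep = ",")), ")")
}

#' Split tuple labels into components
#'
#' Inverse of [tuple_label()]. Splitting is nesting-aware: commas inside inner
#' parentheses do not separate components, so labels such as
#' `"((a,b),(b,c))"` split into two components.
#'
#' @param x a character vector of tuple labels.
#' @return A list of character vectors, one per label.
#' @export
tuple_split <- function(x) {
  lapply(x, function(lab) {
    if (!nzchar(lab) || substr(lab, 1L, 1L) != "(") return(lab)
    inner <- substr(lab, 2L, nchar(lab) - 1L)
    chars <- strsplit(inner, "", fixed = TRUE)[[1]]
    depth <- 0L
    cut <- logical(length(chars))
    for (i in seq_along(chars)) {
      ch <- chars[i]
      if (ch == "(") depth <- depth + 1L
      else if (ch == ")") depth <- depth - 1L
      else if (ch == "," && depth == 0L) cut[i] <- TRUE
    }
    if (!any(cut)) return(inner)
    starts <- c(1L, which(cut) + 1L)
    ends <- c(which(cut) - 1L, length(chars))
    vapply(seq_along(starts), function(k) {
      paste(chars[seq.int(starts[k], ends[k])], collapse = "")
    }, character(1))
  })
}

# Structured condition helper: every catsys error carries a specific class
# (e.g. "catsys_composition_mismatch") under the umbrella "catsys_error".
cs_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "catsys_error")))
}

cs_assert <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) cs_stop(class, msg, ...)
  invisible(TRUE)
}

# Portable 31-bit linear congruential generator (Park-Miller minimal standard,
# a = 16807, m = 2^31 - 1). Used by the random-domain generator so that the
# stream is reproducible from the seed alone, independent of R's RNG kind, and
# reproducible in any other language from this four-line definition.
lcg_new <- function(seed) {
  seed <- as.integer(seed)
  state <- seed %% 2147483647L
  if (state <= 0L) state <- state + 2147483646L
  list(state = as.double(state))
}

lcg_next <- function(rng) {
  rng$state <- (16807 * rng$state) %% 2147483647
  rng
}

# Integer in 1..n, advancing the generator once.
lcg_int <- function(rng, n) {
  rng <- lcg_next(rng)
  list(rng = rng, value = as.integer(rng$state %% n) + 1L)
}
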